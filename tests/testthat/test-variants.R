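vt <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r) {
    data.frame(chrom = "c1", pos = r[[1]], ref = r[[2]], alt = r[[3]],
               H9553 = r[[4]], H9492 = r[[5]], H9775 = r[[6]],
               stringsAsFactors = FALSE)
  }))
}

test_that("the resistance-specific rule keeps shared-resistant, different-susceptible sites", {
  v <- vt(
    list(10, "A", "G", "G", "G", "A"),   # kept: pair share alt, sus = ref
    list(20, "C", "T", "T", "T", "T"),   # dropped: all three share alt
    list(30, "G", "A", "A", "G", "G"),   # dropped: resistant pair discordant
    list(40, "T", "C", "C/T", "C/T", "T"), # kept: het pair vs hom sus
    list(50, "A", "G", "T/C", "C/T", "A")  # kept: unordered het comparison
  )
  rs <- resistance_specific_snps(v)
  expect_equal(rs$pos, c(10, 40, 50))
  ## idempotent
  expect_equal(resistance_specific_snps(rs)$pos, rs$pos)
  ## subset of input
  expect_true(all(rs$pos %in% v$pos))
})

test_that("missing calls and non-SNP records are skipped and counted", {
  v <- vt(
    list(10, "A", "G", "G", "G", "A"),
    list(20, "A", "G", ".", "G", "A"),      # missing call
    list(30, "AT", "A", "A", "A", "AT"),    # indel
    list(40, "C", "CGG", "CGG", "CGG", "C") # insertion
  )
  rs <- resistance_specific_snps(v)
  expect_equal(rs$pos, 10)
  expect_equal(attr(rs, "n_skipped_missing"), 1)
  expect_equal(attr(rs, "n_skipped_nonsnp"), 2)
  expect_error(resistance_specific_snps(v[, -5]), "missing from variant table")
})

test_that("filter output equals an exhaustive truth-table scan on 1,000 sites", {
  sim <- simulate_variants(variant_sim_spec(
    n_sites = 1000, resistance_specific_fraction = 0.1, seed = 17
  ))
  rs <- resistance_specific_snps(sim$variants)
  brute <- naive_resistance_filter(sim$variants, c("H9553", "H9492"), "H9775")
  expect_equal(nrow(rs), 100)
  expect_equal(sum(brute), 100)
  expect_equal(rs$pos, sim$variants$pos[brute])
  expect_equal(sort(rs$pos),
               sort(sim$variants$pos[sim$truth$resistance_specific]))
})

test_that("promoter windows follow the strand-aware flip-and-clip rule", {
  g <- data.frame(gene = c("plus", "edge", "minus"),
                  chrom = "c1",
                  start = c(10000, 3, 9001),
                  end = c(12000, 500, 10000),
                  strand = c("+", "+", "-"))
  pr <- promoter_windows(g, window = 5000, chrom_lengths = c(c1 = 12000))
  expect_equal(pr$start[pr$gene == "plus"], 5000)
  expect_equal(pr$end[pr$gene == "plus"], 9999)
  expect_equal(pr$end[pr$gene == "plus"] - pr$start[pr$gene == "plus"] + 1, 5000)
  expect_equal(pr$start[pr$gene == "edge"], 1)
  expect_equal(pr$end[pr$gene == "edge"], 2)
  ## minus-strand gene ending at 10,000 on a 12,000-bp chromosome:
  ## the 15,000 end is clipped to the chromosome end
  expect_equal(pr$start[pr$gene == "minus"], 10001)
  expect_equal(pr$end[pr$gene == "minus"], 12000)
  expect_error(promoter_windows(transform(g, strand = "?")), "strand")
  ## promoters never overlap their gene body
  for (i in seq_len(nrow(pr))) {
    gi <- g[g$gene == pr$gene[i], ]
    expect_true(pr$end[i] < gi$start || pr$start[i] > gi$end)
  }
})

test_that("a gene starting at position 1 has no promoter window", {
  g <- data.frame(gene = "g", chrom = "c1", start = 1, end = 100, strand = "+")
  expect_equal(nrow(promoter_windows(g)), 0)
})

test_that("the W-box scanner respects IUPAC degeneracy and strand", {
  hits <- scan_motif("AATTGACCAATTGACTAATTGACA", both_strands = FALSE)
  expect_equal(hits$start, c(3, 11))
  expect_equal(hits$match, c("TTGACC", "TTGACT"))  # TTGACA does not match
  rev <- scan_motif("AAGGTCAAAA")
  expect_equal(nrow(rev), 1)
  expect_equal(rev$strand, "-")
  expect_equal(rev$match, "TTGACC")
  expect_equal(rev$start, 3)
  ## N never matches
  expect_equal(nrow(scan_motif("TTGACN", both_strands = FALSE)), 0)
  expect_error(scan_motif("ACGT", pattern = "TTGAXY"), "IUPAC")
})

test_that("motif scan equals a sliding-window brute force on random sequences", {
  set.seed(19)
  for (i in 1:10) {
    seq <- paste(sample(c("A", "C", "G", "T"), 2000, replace = TRUE),
                 collapse = "")
    hits <- scan_motif(seq)
    brute <- naive_scan_motif(seq)
    expect_equal(hits$start[hits$strand == "+"], brute$forward)
    expect_equal(hits$start[hits$strand == "-"], brute$reverse)
  }
})

test_that("scanning the reverse complement mirrors coordinates and strands", {
  set.seed(20)
  seq <- paste(sample(c("A", "C", "G", "T"), 500, replace = TRUE),
               collapse = "")
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
  h1 <- scan_motif(seq)
  h2 <- scan_motif(rc)
  mirror_start <- 500 - h1$end + 1
  flip <- ifelse(h1$strand == "+", "-", "+")
  o1 <- order(mirror_start, flip)
  o2 <- order(h2$start, h2$strand)
  expect_equal(h2$start[o2], mirror_start[o1])
  expect_equal(h2$strand[o2], flip[o1])
})

test_that("SNP/motif overlap honours interval containment and motif breakage", {
  hits <- data.frame(chrom = "c1", start = 3, end = 8, strand = "+",
                     match = "TTGACC")
  prom <- data.frame(gene = "LIF1", chrom = "c1", start = 1, end = 100,
                     strand = "+")
  inside <- vt(list(5, "A", "G", "G", "G", "A"))
  ov <- snp_motif_overlap(inside, hits, prom)
  expect_equal(nrow(ov), 1)
  expect_equal(ov$gene, "LIF1")

  past_end <- vt(list(9, "A", "G", "G", "G", "A"))
  expect_equal(nrow(snp_motif_overlap(past_end, hits, prom)), 0)

  ## alt G at the motif Y position (offset 6) breaks TTGACY; alt T does not
  at_y <- vt(list(8, "C", "G", "G", "G", "C"))
  expect_true(snp_motif_overlap(at_y, hits, prom)$breaks_motif)
  at_y_ok <- vt(list(8, "C", "T", "T", "T", "C"))
  expect_false(snp_motif_overlap(at_y_ok, hits, prom)$breaks_motif)

  ## minus-strand hit: forward alt is complemented before the check
  hits_m <- data.frame(chrom = "c1", start = 3, end = 8, strand = "-",
                       match = "TTGACC")
  at_y_m <- vt(list(3, "G", "A", "A", "A", "G"))  # pattern Y position
  expect_false(snp_motif_overlap(at_y_m, hits_m, prom)$breaks_motif)
  at_y_m_bad <- vt(list(3, "G", "C", "C", "C", "G"))
  expect_true(snp_motif_overlap(at_y_m_bad, hits_m, prom)$breaks_motif)
})

test_that("a planted fixture yields exactly the constructed overlap count", {
  sim <- simulate_variants(variant_sim_spec(
    n_sites = 300, resistance_specific_fraction = 0.1,
    planted_wbox_positions = 9000L, seed = 23
  ))
  rs <- resistance_specific_snps(sim$variants)
  clens <- setNames(nchar(sim$reference), names(sim$reference))
  prom <- promoter_windows(sim$genes, 5000, clens)
  hits <- scan_motif(sim$reference, chrom = names(sim$reference))
  ov <- snp_motif_overlap(rs, hits, prom)
  planted <- ov[ov$motif_start == 9000, ]
  expect_equal(nrow(planted), 1)
  expect_equal(planted$pos, 9005)
  expect_true(planted$breaks_motif)
})

test_that("BED export converts to 0-based half-open coordinates", {
  pr <- data.frame(gene = "g", chrom = "c1", start = 5000, end = 9999,
                   strand = "+")
  path <- withr::local_tempfile(fileext = ".bed")
  write_promoter_bed(pr, path)
  fields <- strsplit(readLines(path), "\t")[[1]]
  expect_equal(fields[2], "4999")
  expect_equal(fields[3], "9999")
})
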