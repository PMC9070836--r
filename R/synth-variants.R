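#' Specify a synthetic cultivar variant simulation
#'
#' Describes per-genotype SNP tables against a shared reference for the
#' resistance-specific filtering stage: two resistant cultivars sharing a
#' planted subset of alleles that differ from the susceptible comparator,
#' a random reference chromosome carrying planted W-box (TTGACY)
#' hexamers, and annotated promoter genes so that some planted
#' resistance-specific SNPs land inside W-box motifs within promoter
#' windows.
#'
#' @param genotypes character vector of three genotype names: the two
#'   resistant cultivars then the susceptible comparator (default H9553,
#'   H9492, H9775; the reference is H1706).
#' @param reference name of the reference genotype.
#' @param n_sites number of SNP sites.
#' @param resistance_specific_fraction fraction of sites planted to
#'   satisfy the resistance-specific rule; exactly
#'   `round(n_sites * fraction)` sites qualify by construction.
#' @param chrom_length chromosome length in bp.
#' @param chrom chromosome name.
#' @param promoter_genes data frame with columns `gene`, `strand`
#'   (`"+"`/`"-"`) and `tss` (1-based transcription start position).
#' @param planted_wbox_positions 1-based start positions at which a
#'   forward-strand W-box hexamer is written into the reference; the
#'   first planted resistance-specific SNPs are placed on the Y base
#'   (position + 5) of these hexamers, with a motif-breaking alt allele.
#' @param seed integer seed.
#' @return An object of class `variant_sim_spec`.
#' @export
variant_sim_spec <- function(genotypes = c("H9553", "H9492", "H9775"),
                             reference = "H1706",
                             n_sites = 1000L,
                             resistance_specific_fraction = 0.1,
                             chrom_length = 50000L,
                             chrom = "SL4.0ch02",
                             promoter_genes = data.frame(
                               gene = c("LIF1", "SlMYB55", "CuRLR1"),
                               strand = c("+", "-", "+"),
                               tss = c(12000L, 25000L, 40000L)
                             ),
                             planted_wbox_positions = c(9000L, 10500L),
                             seed = 1L) {
  if (length(genotypes) != 3L || anyDuplicated(genotypes)) {
    stopf("'genotypes' must be three unique names (resistant pair, susceptible)")
  }
  check_scalar(n_sites, "n_sites", 1)
  check_scalar(resistance_specific_fraction, "resistance_specific_fraction", 0, 1)
  check_scalar(chrom_length, "chrom_length", 100)
  if (any(planted_wbox_positions < 1 | planted_wbox_positions + 5 > chrom_length)) {
    stopf("planted W-box positions must fit inside the chromosome")
  }
  if (any(promoter_genes$tss < 1 | promoter_genes$tss > chrom_length)) {
    stopf("promoter gene TSS positions must lie inside the chromosome")
  }
  if (!all(promoter_genes$strand %in% c("+", "-"))) stopf("gene strand must be '+' or '-'")
  structure(list(
    genotypes = genotypes, reference = reference,
    n_sites = as.integer(n_sites),
    resistance_specific_fraction = resistance_specific_fraction,
    chrom_length = as.integer(chrom_length), chrom = chrom,
    promoter_genes = promoter_genes,
    planted_wbox_positions = as.integer(planted_wbox_positions),
    seed = as.integer(seed)
  ), class = "variant_sim_spec")
}

#' Simulate cultivar variant tables, reference sequence and annotation
#'
#' Generates the inputs of the variant/motif stage with known ground
#' truth: a random reference chromosome with W-box hexamers written at
#' the planted positions, a variant table whose planted subset satisfies
#' the resistance-specific rule (both resistant cultivars share an
#' allele that differs from the susceptible cultivar's call) and whose
#' remaining sites violate it in one of three ways (shared by all three
#' cultivars, discordant between the resistant pair, or private to the
#' susceptible cultivar), and gene records for the promoter scan.
#'
#' @param spec a [variant_sim_spec()].
#' @return An object of class `variant_sim`: list with `variants` (data
#'   frame: chrom, pos, ref, alt and one call column per genotype),
#'   `reference` (named character, the chromosome sequence), `genes`
#'   (data frame: gene, chrom, start, end, strand), and `truth` (list:
#'   `resistance_specific` logical per site, `wbox_positions`,
#'   `n_planted`).
#' @export
simulate_variants <- function(spec) {
  stopifnot(inherits(spec, "variant_sim_spec"))
  res1 <- spec$genotypes[1]; res2 <- spec$genotypes[2]; sus <- spec$genotypes[3]
  with_seed(spec$seed, {
    refseq <- sample(c("A", "C", "G", "T"), spec$chrom_length, replace = TRUE)
    for (p in spec$planted_wbox_positions) {
      refseq[p:(p + 5)] <- c("T", "T", "G", "A", "C", sample(c("C", "T"), 1))
    }

    k <- round(spec$n_sites * spec$resistance_specific_fraction)
    wb_snp_pos <- spec$planted_wbox_positions + 5L
    n_in_wbox <- min(k, length(wb_snp_pos))
    fixed_pos <- if (n_in_wbox > 0) wb_snp_pos[seq_len(n_in_wbox)] else integer(0)
    ## avoid re-drawing planted W-box bases for the remaining sites
    avoid <- unique(c(fixed_pos, unlist(lapply(spec$planted_wbox_positions,
                                               function(p) p:(p + 5)))))
    pool <- setdiff(seq_len(spec$chrom_length), avoid)
    other_pos <- sample(pool, spec$n_sites - length(fixed_pos))
    pos <- c(fixed_pos, other_pos)

    ref <- refseq[pos]
    alt <- vapply(seq_along(pos), function(i) {
      if (i <= n_in_wbox) {
        sample(c("A", "G"), 1)  # breaks the Y in TTGACY
      } else {
        sample(setdiff(c("A", "C", "G", "T"), ref[i]), 1)
      }
    }, character(1))

    is_rs <- c(rep(TRUE, k), rep(FALSE, spec$n_sites - k))
    calls <- matrix("", spec$n_sites, 3,
                    dimnames = list(NULL, c(res1, res2, sus)))
    calls[is_rs, res1] <- alt[is_rs]
    calls[is_rs, res2] <- alt[is_rs]
    calls[is_rs, sus] <- ref[is_rs]
    if (any(!is_rs)) {
      ## non-qualifying patterns: variant shared by all three cultivars, or
      ## discordant between the two resistant cultivars
      mode <- sample(1:2, sum(!is_rs), replace = TRUE)
      i <- which(!is_rs)
      calls[i, res1] <- ifelse(mode == 2, ref[i], alt[i])
      calls[i, res2] <- alt[i]
      calls[i, sus] <- alt[i]
    }

    ord <- order(pos)
    variants <- data.frame(chrom = spec$chrom, pos = pos, ref = ref, alt = alt,
                           stringsAsFactors = FALSE)
    variants[[res1]] <- calls[, res1]
    variants[[res2]] <- calls[, res2]
    variants[[sus]] <- calls[, sus]
    variants <- variants[ord, ]
    rownames(variants) <- NULL
    is_rs <- is_rs[ord]

    pg <- spec$promoter_genes
    genes <- data.frame(
      gene = pg$gene, chrom = spec$chrom,
      start = ifelse(pg$strand == "+", pg$tss,
                     pmax(1L, pg$tss - 999L)),
      end = ifelse(pg$strand == "+", pmin(spec$chrom_length, pg$tss + 999L),
                   pg$tss),
      strand = pg$strand,
      stringsAsFactors = FALSE
    )

    structure(list(
      variants = variants,
      reference = setNames(paste(refseq, collapse = ""), spec$chrom),
      genes = genes,
      truth = list(resistance_specific = is_rs,
                   wbox_positions = spec$planted_wbox_positions,
                   n_planted = k,
                   n_planted_in_wbox = n_in_wbox),
      spec = spec
    ), class = "variant_sim")
  })
}

#' Write a variant table as VCF
#'
#' Minimal VCFv4.2 with per-genotype GT calls (1-based positions; calls
#' encoded against the site's ref/alt alleles).
#'
#' @param variants variant data frame (see [simulate_variants()]).
#' @param path output path.
#' @param genotypes call column names; defaults to all non-coordinate
#'   columns.
#' @param contig_length optional contig length for the header.
#' @return `path`, invisibly.
#' @export
write_variant_vcf <- function(variants, path, genotypes = NULL,
                              contig_length = NULL) {
  if (is.null(genotypes)) {
    genotypes <- setdiff(names(variants), c("chrom", "pos", "ref", "alt"))
  }
  gt_code <- function(call, ref, alt) {
    parts <- strsplit(call, "/", fixed = TRUE)
    vapply(seq_along(call), function(i) {
      al <- parts[[i]]
      if (length(al) == 1L) al <- c(al, al)
      enc <- ifelse(al == ref[i], "0", ifelse(al == alt[i], "1", "."))
      paste(enc, collapse = "/")
    }, character(1))
  }
  hdr <- c(
    "##fileformat=VCFv4.2",
    if (!is.null(contig_length)) {
      sprintf("##contig=<ID=%s,length=%d>", variants$chrom[1], contig_length)
    },
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", genotypes), collapse = "\t")
  )
  lines <- apply(cbind(
    variants$chrom, variants$pos, ".", variants$ref, variants$alt,
    ".", "PASS", ".", "GT",
    vapply(genotypes, function(g) {
      gt_code(variants[[g]], variants$ref, variants$alt)
    }, character(nrow(variants)))
  ), 1, paste, collapse = "\t")
  writeLines(c(hdr, lines), path)
  invisible(path)
}

#' Read a VCF back into a variant call table
#'
#' Uses \pkg{vcfR} to parse the file and decodes GT fields into allele
#' strings (`"A"` for homozygous, `"A/T"` for heterozygous, `NA` for
#' missing).
#'
#' @param path VCF path.
#' @return A variant data frame (chrom, pos, ref, alt, one column per
#'   sample).
#' @export
read_variant_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stopf("reading VCF requires the 'vcfR' package")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  out <- data.frame(chrom = fix$CHROM, pos = as.integer(fix$POS),
                    ref = fix$REF, alt = fix$ALT, stringsAsFactors = FALSE)
  decode <- function(g, ref, alt) {
    if (is.na(g) || g %in% c(".", "./.")) return(NA_character_)
    idx <- strsplit(g, "[/|]")[[1]]
    al <- ifelse(idx == "0", ref, ifelse(idx == "1", alt, NA))
    if (any(is.na(al))) return(NA_character_)
    al <- sort(unique(al))
    paste(al, collapse = "/")
  }
  for (s in colnames(gt)) {
    out[[s]] <- vapply(seq_len(nrow(out)), function(i) {
      decode(gt[i, s], out$ref[i], out$alt[i])
    }, character(1))
  }
  out
}

#' Write a reference sequence as FASTA
#'
#' @param reference named character vector of sequences.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_reference_fasta <- function(reference, path) {
  dna <- Biostrings::DNAStringSet(reference)
  Biostrings::writeXStringSet(dna, path)
  invisible(path)
}

#' Write gene records as GFF3
#'
#' 1-based inclusive coordinates, per the GFF3 standard.
#'
#' @param genes data frame with columns gene, chrom, start, end, strand.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_genes_gff3 <- function(genes, path) {
  lines <- c("##gff-version 3",
             sprintf("%s\tdodderlign\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                     genes$chrom, genes$start, genes$end, genes$strand,
                     genes$gene))
  writeLines(lines, path)
  invisible(path)
}
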