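small_spec <- function(...) {
  section_spec(image_size = c(96, 96),
               radii = list(pith = 10, xylem = c(18, 26),
                            cortex = c(30, 42), epidermis = 45),
               ...)
}

test_that("section rendering honours zero and saturation stain fractions", {
  none <- render_section(small_spec(cortex_stain_fraction = 0,
                                    xylem_stained = FALSE))
  expect_equal(sum(none$masks$stained_cortex), 0)
  expect_equal(sum(none$masks$lignin), 0)

  full <- render_section(small_spec(cortex_stain_fraction = 1,
                                    xylem_stained = TRUE))
  expect_true(all(full$masks$lignin == (full$masks$cortex | full$masks$xylem)))
})

test_that("rendered tissue masks are disjoint and nested in the section", {
  img <- render_section(small_spec(cortex_stain_fraction = 0.5))
  m <- img$masks
  overlap <- m$pith + m$xylem + m$cortex + m$epidermis
  expect_true(all(overlap <= 1))
  for (nm in c("pith", "xylem", "cortex", "epidermis")) {
    expect_true(all(m$section[m[[nm]]]))
  }
  expect_true(all(m$cortex[m$stained_cortex]))
})

test_that("section rendering is byte-identical under a fixed seed", {
  a <- render_section(small_spec(noise_sd = 5, seed = 42))
  b <- render_section(small_spec(noise_sd = 5, seed = 42))
  expect_identical(a$pixels, b$pixels)
  c <- render_section(small_spec(noise_sd = 5, seed = 43))
  expect_false(identical(a$pixels, c$pixels))
})

test_that("invalid section specs are rejected", {
  expect_error(section_spec(radii = list(pith = 30, xylem = c(18, 26),
                                         cortex = c(30, 42), epidermis = 45)),
               "nested")
  expect_error(section_spec(cortex_stain_fraction = 1.2), "range")
})

test_that("count simulation is reproducible and respects invariants", {
  sp <- expr_sim_spec(n_genes = 100, strata = default_strata(2L), seed = 9)
  a <- simulate_counts(sp)
  b <- simulate_counts(sp)
  expect_identical(a$counts, b$counts)
  expect_true(all(a$counts >= 0))
  expect_true(all(a$counts == round(a$counts)))
  expect_equal(ncol(a$counts), nrow(a$samples))
  expect_false(any(is.na(a$samples$genotype)))
})

test_that("unreplicated strata and oversized plans are rejected", {
  bad <- default_strata(2L); bad$n_rep[1] <- 1L
  expect_error(expr_sim_spec(strata = bad), "2 replicates")
  expect_error(expr_sim_spec(n_genes = 50, cluster_plan = list(
    list(size = 60, shift = rep(0, 8)))), "exceed")
  expect_error(expr_sim_spec(module_plan = list(list(size = 10, cor = 1))),
               "correlations")
})

test_that("zero module correlation leaves genes uncorrelated", {
  st <- data.frame(genotype = "g", condition = "infested", n_rep = 20L)
  sim <- simulate_counts(expr_sim_spec(
    n_genes = 40, strata = st,
    module_plan = list(list(size = 20, cor = 0)), seed = 4
  ))
  cc <- cor(t(log2(cpm_normalize(sim) + 0.5)))
  offdiag <- cc[upper.tri(cc)]
  ## no systematic co-expression ...
  expect_lt(abs(mean(offdiag)), 0.1)
  ## ... and |r| at the pure sampling bound for n = 20 samples,
  ## E|r| = sqrt(2 / (pi * (n - 1))) ~ 0.183
  bound <- sqrt(2 / (pi * 19))
  expect_lt(mean(abs(offdiag)), bound * 1.25)
})

test_that("planted module members carry latent-factor correlation", {
  st <- data.frame(genotype = "g", condition = "infested", n_rep = 20L)
  sim <- simulate_counts(expr_sim_spec(
    n_genes = 120, strata = st, dispersion = 0.01, biovar_sd = 0.15,
    module_plan = list(list(size = 20, cor = 0.9, hub = TRUE)), seed = 4
  ))
  cc <- cor(t(log2(cpm_normalize(sim) + 0.5)))
  members <- which(sim$truth$module == 1)
  background <- which(sim$truth$module == 0)
  within <- cc[members, members][upper.tri(diag(length(members)))]
  between <- cc[members, background]
  expect_gt(mean(within), 0.6)
  expect_lt(mean(abs(between)), 0.2)
  hub <- which(sim$truth$hub)
  expect_gt(mean(cc[hub, setdiff(members, hub)]), mean(within))
})

test_that("variant simulation plants the exact resistance-specific count", {
  sp <- variant_sim_spec(n_sites = 500, resistance_specific_fraction = 0.2,
                         seed = 11)
  sim <- simulate_variants(sp)
  expect_equal(sum(sim$truth$resistance_specific), 100)
  expect_equal(nrow(sim$variants), 500)
  ## reference carries the planted W-box hexamers
  for (p in sp$planted_wbox_positions) {
    hex <- substr(sim$reference, p, p + 5)
    expect_match(hex, "^TTGAC[CT]$")
  }
  ## determinism
  sim2 <- simulate_variants(sp)
  expect_identical(sim$variants, sim2$variants)
  expect_identical(sim$reference, sim2$reference)
})

test_that("zero resistance-specific fraction yields an empty filter result", {
  sim <- simulate_variants(variant_sim_spec(
    n_sites = 200, resistance_specific_fraction = 0, seed = 3
  ))
  rs <- resistance_specific_snps(sim$variants)
  expect_equal(nrow(rs), 0)
})

test_that("variant spec rejects out-of-range planted positions", {
  expect_error(variant_sim_spec(chrom_length = 1000,
                                planted_wbox_positions = 998),
               "inside the chromosome")
  expect_error(variant_sim_spec(
    promoter_genes = data.frame(gene = "x", strand = "+", tss = 99999999)
  ), "inside the chromosome")
})

test_that("written VCF/FASTA/GFF3 round-trip through standard parsers", {
  skip_if_not_installed("vcfR")
  skip_if_not_installed("rtracklayer")
  sim <- simulate_variants(variant_sim_spec(n_sites = 50, seed = 8))
  td <- withr::local_tempdir()
  vf <- file.path(td, "v.vcf"); ff <- file.path(td, "r.fasta")
  gf <- file.path(td, "g.gff3")
  write_variant_vcf(sim$variants, vf, contig_length = nchar(sim$reference))
  write_reference_fasta(sim$reference, ff)
  write_genes_gff3(sim$genes, gf)

  back <- read_variant_vcf(vf)
  expect_equal(back$pos, sim$variants$pos)
  expect_equal(back$H9553, sim$variants$H9553)
  expect_equal(back$H9775, sim$variants$H9775)

  seqs <- Biostrings::readDNAStringSet(ff)
  expect_equal(as.character(seqs[[1]]), unname(sim$reference))

  gr <- rtracklayer::import(gf)
  expect_equal(length(gr), nrow(sim$genes))
  expect_equal(BiocGenerics::start(gr), sim$genes$start)
  expect_equal(BiocGenerics::end(gr), sim$genes$end)
})
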