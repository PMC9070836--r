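#' Specify a synthetic RNA-seq count simulation
#'
#' Describes a negative-binomial count simulation with the cultivar-by-
#' infestation structure of the dodder resistance experiment: strata are
#' (genotype, condition) cells with replicated libraries; `cluster_plan`
#' plants groups of genes with shared stratum mean-shift patterns (what the
#' expression-clustering stage should recover); `module_plan` plants
#' co-expression modules driven by shared latent factors (what the network
#' stage should recover), optionally restricted to a subset of strata and
#' optionally with a designated hub gene that loads more strongly on the
#' factor than the other members.
#'
#' @param n_genes total number of genes.
#' @param strata data frame with columns `genotype`, `condition`
#'   (`"infested"` or `"uninfested"`) and `n_rep` (replicates, >= 2).
#'   Defaults to the four Heinz cultivars (H1706, H9775, H9492, H9553)
#'   with and without dodder, 3 replicates each.
#' @param cluster_plan list of plans, each a list with `size` (genes) and
#'   `shift` (named or unnamed numeric vector of log2 mean-shifts, one per
#'   stratum row).
#' @param module_plan list of plans, each a list with `size`, `cor` (target
#'   within-module correlation of log-expression, in `(-1, 1)`), optional
#'   `hub` (logical), optional `strata` (indices of strata rows in
#'   which the module factor is active; default all) and optional `shift`
#'   (per-stratum log2 mean-shift vector, so module genes can also be
#'   differentially expressed).
#' @param library_size expected total counts per sample.
#' @param dispersion negative-binomial dispersion (so that
#'   variance = mu + dispersion * mu^2).
#' @param base_log2_range range of baseline log2 mean counts genes are
#'   drawn from.
#' @param biovar_sd biological log2-scale gene-level noise standard
#'   deviation (the non-shared part of expression variation).
#' @param seed integer seed.
#' @return An object of class `expr_sim_spec`.
#' @export
expr_sim_spec <- function(n_genes = 2000L,
                          strata = default_strata(),
                          cluster_plan = list(),
                          module_plan = list(),
                          library_size = 1e6,
                          dispersion = 0.05,
                          base_log2_range = c(3, 9),
                          biovar_sd = 0.25,
                          seed = 1L) {
  strata <- as.data.frame(strata)
  need <- c("genotype", "condition", "n_rep")
  if (!all(need %in% names(strata))) stopf("'strata' needs columns genotype, condition, n_rep")
  if (any(strata$n_rep < 2)) stopf("every stratum needs at least 2 replicates")
  if (!all(strata$condition %in% c("infested", "uninfested"))) {
    stopf("condition must be 'infested' or 'uninfested'")
  }
  check_scalar(n_genes, "n_genes", 1)
  check_scalar(library_size, "library_size", 1)
  check_scalar(dispersion, "dispersion", 0)
  check_scalar(biovar_sd, "biovar_sd", 0)
  csize <- sum(vapply(cluster_plan, function(p) p$size, numeric(1)), 0)
  msize <- sum(vapply(module_plan, function(p) p$size, numeric(1)), 0)
  if (csize + msize > n_genes) stopf("cluster and module plans exceed n_genes")
  for (p in cluster_plan) {
    if (length(p$shift) != nrow(strata)) stopf("each cluster 'shift' needs one value per stratum")
  }
  for (p in module_plan) {
    if (abs(p$cor) >= 1) stopf("module correlations must lie in (-1, 1)")
    if (!is.null(p$strata) && any(!p$strata %in% seq_len(nrow(strata)))) {
      stopf("module 'strata' indices out of range")
    }
    if (!is.null(p$shift) && length(p$shift) != nrow(strata)) {
      stopf("each module 'shift' needs one value per stratum")
    }
  }
  structure(list(
    n_genes = as.integer(n_genes), strata = strata,
    cluster_plan = cluster_plan, module_plan = module_plan,
    library_size = library_size, dispersion = dispersion,
    base_log2_range = base_log2_range, biovar_sd = biovar_sd,
    seed = as.integer(seed)
  ), class = "expr_sim_spec")
}

#' Default four-cultivar, two-condition design
#'
#' The two resistant Heinz hybrids (H9492, H9553) and the two susceptible
#' cultivars (H1706, H9775), each with and without dodder infestation.
#'
#' @param n_rep replicates per stratum.
#' @return A data frame with columns `genotype`, `condition`, `n_rep`.
#' @export
default_strata <- function(n_rep = 3L) {
  data.frame(
    genotype = rep(c("H1706", "H9775", "H9492", "H9553"), each = 2),
    condition = rep(c("uninfested", "infested"), times = 4),
    n_rep = as.integer(n_rep)
  )
}

#' Simulate a structured RNA-seq count matrix with known ground truth
#'
#' Counts are drawn from a negative binomial whose gene-level means are
#' modulated by stratum effects (planted expression clusters) and shared
#' latent factors (planted co-expression modules). For a module with
#' target correlation `rho`, member genes receive factor loadings chosen
#' so that the latent log-scale correlation between members equals `rho`
#' (`b = biovar_sd * sqrt(rho / (1 - rho))`); a hub gene loads three times
#' more strongly, which makes it the most connected member once counts are
#' thresholded into a network. (With the formula above the planted
#' correlation is the latent log-scale one; counting noise attenuates
#' the measured correlation somewhat, most at low expression or high
#' dispersion.)
#'
#' @param spec an [expr_sim_spec()].
#' @return An object of class `count_matrix`: list with `counts` (gene x
#'   sample integer matrix), `samples` (data frame: sample, genotype,
#'   condition, replicate), `gene_ids`, `truth` (list: `cluster` integer
#'   labels, 0 = unplanted; `module` integer labels, 0 = none; `hub`
#'   logical per gene).
#' @export
simulate_counts <- function(spec) {
  stopifnot(inherits(spec, "expr_sim_spec"))
  st <- spec$strata
  n_samp <- sum(st$n_rep)
  samples <- data.frame(
    sample = character(0), genotype = character(0),
    condition = character(0), replicate = integer(0),
    stratum = integer(0)
  )
  for (i in seq_len(nrow(st))) {
    samples <- rbind(samples, data.frame(
      sample = sprintf("%s_%s_r%d", st$genotype[i],
                       substr(st$condition[i], 1, 3), seq_len(st$n_rep[i])),
      genotype = st$genotype[i], condition = st$condition[i],
      replicate = seq_len(st$n_rep[i]), stratum = i
    ))
  }

  G <- spec$n_genes
  cluster <- integer(G); module <- integer(G); hub <- logical(G)
  g <- 1L
  for (k in seq_along(spec$cluster_plan)) {
    idx <- g:(g + spec$cluster_plan[[k]]$size - 1L)
    cluster[idx] <- k
    g <- g + spec$cluster_plan[[k]]$size
  }
  for (k in seq_along(spec$module_plan)) {
    idx <- g:(g + spec$module_plan[[k]]$size - 1L)
    module[idx] <- k
    if (isTRUE(spec$module_plan[[k]]$hub)) hub[idx[1]] <- TRUE
    g <- g + spec$module_plan[[k]]$size
  }

  out <- with_seed(spec$seed, {
    base <- runif(G, spec$base_log2_range[1], spec$base_log2_range[2])
    ## module genes are drawn at low-mid abundance: high enough that
    ## counting noise does not mask the planted covariance, low enough
    ## that the shared factor moves a negligible share of the library
    ## (otherwise per-million scaling leaks the factor into every gene)
    if (any(module > 0)) {
      lo <- spec$base_log2_range[1]
      base[module > 0] <- runif(sum(module > 0), lo + 1, lo + 2)
    }
    ## likewise for shifted cluster genes, so a strong planted fold change
    ## does not move enough library mass to bias every other gene
    if (any(cluster > 0)) {
      lo <- spec$base_log2_range[1]
      base[cluster > 0] <- runif(sum(cluster > 0), lo + 1, lo + 3)
    }
    logmu <- matrix(base, G, n_samp)  # log2 scale
    ## planted cluster mean shifts per stratum
    for (k in seq_along(spec$cluster_plan)) {
      sh <- spec$cluster_plan[[k]]$shift
      logmu[cluster == k, ] <- logmu[cluster == k, , drop = FALSE] +
        matrix(sh[samples$stratum], sum(cluster == k), n_samp, byrow = TRUE)
    }
    for (k in seq_along(spec$module_plan)) {
      sh <- spec$module_plan[[k]]$shift
      if (is.null(sh)) next
      logmu[module == k, ] <- logmu[module == k, , drop = FALSE] +
        matrix(sh[samples$stratum], sum(module == k), n_samp, byrow = TRUE)
    }
    ## biological gene-level noise and module latent factors
    noise <- matrix(rnorm(G * n_samp, sd = spec$biovar_sd), G, n_samp)
    for (k in seq_along(spec$module_plan)) {
      p <- spec$module_plan[[k]]
      rho <- p$cor
      if (rho == 0) next
      b <- spec$biovar_sd * sqrt(abs(rho) / (1 - abs(rho)))
      active <- if (is.null(p$strata)) seq_len(nrow(st)) else p$strata
      z <- rnorm(n_samp)
      z[!samples$stratum %in% active] <- 0
      idx <- which(module == k)
      load <- rep(b, length(idx))
      if (rho < 0) load[seq_along(idx) %% 2 == 0] <- -b
      load[hub[idx]] <- 3 * b
      noise[idx, ] <- noise[idx, , drop = FALSE] + outer(load, z)
    }
    logmu <- logmu + noise
    mu <- 2^logmu
    ## scale each sample so expected totals match the library size
    mu <- sweep(mu, 2, colSums(mu), "/") * spec$library_size
    counts <- matrix(
      rnbinom(G * n_samp, mu = mu,
              size = if (spec$dispersion > 0) 1 / spec$dispersion else Inf),
      G, n_samp
    )
    counts
  })

  gene_ids <- sprintf("gene%05d", seq_len(G))
  dimnames(out) <- list(gene_ids, samples$sample)
  structure(list(
    counts = out, samples = samples[, c("sample", "genotype", "condition", "replicate")],
    gene_ids = gene_ids,
    truth = list(cluster = cluster, module = module, hub = hub)
  ), class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("<count_matrix> %d genes x %d samples (%d strata)\n",
              nrow(x$counts), ncol(x$counts),
              nrow(unique(x$samples[c("genotype", "condition")]))))
  invisible(x)
}

#' Write / read a count matrix as TSV pair
#'
#' `write_count_matrix()` writes `<prefix>_counts.tsv` (genes x samples)
#' and `<prefix>_samples.tsv` (metadata); `read_count_matrix()` reads the
#' pair back.
#'
#' @param x a `count_matrix`.
#' @param prefix file path prefix.
#' @return The file paths, invisibly (write); a `count_matrix` (read).
#' @export
write_count_matrix <- function(x, prefix) {
  cf <- paste0(prefix, "_counts.tsv")
  sf <- paste0(prefix, "_samples.tsv")
  write.table(x$counts, cf, sep = "\t", quote = FALSE, col.names = NA)
  write.table(x$samples, sf, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(counts = cf, samples = sf))
}

#' @rdname write_count_matrix
#' @export
read_count_matrix <- function(prefix) {
  counts <- as.matrix(read.table(paste0(prefix, "_counts.tsv"), sep = "\t",
                                 header = TRUE, row.names = 1, check.names = FALSE))
  samples <- read.table(paste0(prefix, "_samples.tsv"), sep = "\t", header = TRUE)
  storage.mode(counts) <- "integer"
  structure(list(counts = counts, samples = samples,
                 gene_ids = rownames(counts), truth = NULL),
            class = "count_matrix")
}
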