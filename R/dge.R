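#' Differential-expression thresholds
#'
#' The selection thresholds used throughout the study: adjusted p-value
#' (BH false discovery rate) below 0.1 combined with an absolute log2 fold
#' change above 1 for the interaction contrast, and a plain fold change
#' above 1.5 for the time-course variant.
#'
#' @param fdr_max maximum BH-adjusted p-value.
#' @param log2fc_min minimum absolute log2 fold change (interaction DGE).
#' @param fc_min minimum fold change (time-course DGE variant).
#' @return An object of class `dge_thresholds`.
#' @export
dge_thresholds <- function(fdr_max = 0.1, log2fc_min = 1, fc_min = 1.5) {
  check_scalar(fdr_max, "fdr_max", 0, 1, open_lower = TRUE)
  check_scalar(log2fc_min, "log2fc_min", 0)
  check_scalar(fc_min, "fc_min", 0, open_lower = TRUE)
  structure(list(fdr_max = fdr_max, log2fc_min = log2fc_min, fc_min = fc_min),
            class = "dge_thresholds")
}

#' Counts-per-million normalisation
#'
#' Scales every library so its column sums to one million.
#'
#' @param x a `count_matrix` (see [simulate_counts()]) or a plain
#'   gene x sample matrix of non-negative counts.
#' @return A numeric matrix of CPM values with the input's dimnames.
#' @export
cpm_normalize <- function(x) {
  counts <- if (inherits(x, "count_matrix")) x$counts else as.matrix(x)
  if (any(counts < 0)) stopf("counts must be non-negative")
  tot <- colSums(counts)
  if (any(tot == 0)) {
    bad <- colnames(counts)[tot == 0]
    if (is.null(bad)) bad <- which(tot == 0)
    stopf("sample(s) with zero total counts: %s", paste(bad, collapse = ", "))
  }
  sweep(counts, 2, tot, "/") * 1e6
}

#' @noRd
log2cpm <- function(x) log2(cpm_normalize(x) + 0.5)

#' Row-wise linear-model fit against a shared design matrix
#'
#' @return list with coef (G x p), se (G x p), df, sigma2
#' @noRd
fit_rows <- function(Y, X) {
  n <- ncol(Y); p <- ncol(X)
  if (n <= p) stopf("not enough samples (%d) for %d coefficients", n, p)
  xtx_inv <- solve(crossprod(X))
  coef <- Y %*% X %*% xtx_inv
  fitted <- coef %*% t(X)
  rss <- rowSums((Y - fitted)^2)
  df <- n - p
  sigma2 <- rss / df
  se <- sqrt(outer(sigma2, diag(xtx_inv)))
  list(coef = coef, se = se, df = df, sigma2 = sigma2, rss = rss)
}

#' Row-wise omnibus F statistic for a design versus the intercept
#' @noRd
row_omnibus_f <- function(Y, X) {
  ft <- fit_rows(Y, X)
  n <- ncol(Y); p <- ncol(X)
  rss0 <- rowSums((Y - rowMeans(Y))^2)
  f <- ((rss0 - ft$rss) / (p - 1)) / (ft$rss / (n - p))
  pval <- stats::pf(f, p - 1, n - p, lower.tail = FALSE)
  list(f = f, p = pval, df1 = p - 1, df2 = n - p)
}

#' @noRd
check_strata_replicated <- function(samples) {
  tab <- table(samples$genotype, samples$condition)
  if (any(tab > 0 & tab < 2)) {
    stopf("unreplicated genotype x condition stratum; every stratum needs >= 2 replicates")
  }
  invisible(tab)
}

#' Interaction-model differential expression
#'
#' Per-gene linear model on log2(CPM + 0.5) with condition, genotype and
#' condition:genotype terms (the interaction design
#' `~ condition + genotype + condition:genotype`). The tested contrast is
#' the interaction coefficient of `genotype_test` against
#' `genotype_ref` -- the difference-of-differences
#' (test infested - test uninfested) - (ref infested - ref uninfested)
#' on the log2 scale -- so it isolates genes whose infestation response
#' differs between the two cultivars. P-values come from the per-gene
#' t-test of that coefficient; BH adjustment across genes; a gene passes
#' at adjusted p < `fdr_max` and |log2FC| > `log2fc_min` (defaults 0.1
#' and 1).
#'
#' @param x a `count_matrix`.
#' @param genotype_test,genotype_ref the two genotypes whose infestation
#'   responses are contrasted (defaults: resistant H9553 vs susceptible
#'   H9775).
#' @param thresholds a [dge_thresholds()].
#' @return A `dge_result` data frame: gene, log2fc, p, fdr, passes.
#' @export
interaction_dge <- function(x, genotype_test = "H9553", genotype_ref = "H9775",
                            thresholds = dge_thresholds()) {
  stopifnot(inherits(x, "count_matrix"))
  s <- x$samples
  check_strata_replicated(s)
  for (g in c(genotype_test, genotype_ref)) {
    if (!g %in% s$genotype) stopf("genotype '%s' not present in samples", g)
  }
  geno <- stats::relevel(factor(s$genotype), ref = genotype_ref)
  cond <- stats::relevel(factor(s$condition), ref = "uninfested")
  X <- stats::model.matrix(~ cond * geno)
  Y <- log2cpm(x)
  ft <- fit_rows(Y, X)
  term <- paste0("condinfested:geno", genotype_test)
  if (!term %in% colnames(X)) stopf("interaction term for '%s' not estimable", genotype_test)
  j <- match(term, colnames(X))
  log2fc <- ft$coef[, j]
  tstat <- log2fc / ft$se[, j]
  p <- 2 * stats::pt(-abs(tstat), df = ft$df)
  fdr <- p.adjust(p, method = "BH")
  res <- data.frame(
    gene = rownames(Y), log2fc = log2fc, p = p, fdr = fdr,
    passes = fdr < thresholds$fdr_max & abs(log2fc) > thresholds$log2fc_min,
    row.names = NULL
  )
  class(res) <- c("dge_result", "data.frame")
  attr(res, "contrast") <- sprintf("(%s infested - uninfested) - (%s infested - uninfested)",
                                   genotype_test, genotype_ref)
  res
}

#' Two-factor ANOVA differential expression
#'
#' Per-gene two-way ANOVA on log2(CPM + 0.5) with cultivar and infestation
#' condition as factors: the omnibus F test of the full
#' `~ condition * genotype` model against the intercept flags genes with
#' any factor or interaction effect. BH adjustment across genes;
#' selection at adjusted p < `fdr_max` (default 0.1). The reported
#' `log2fc` is the largest absolute log2 difference between any stratum
#' mean and the grand mean, a descriptive effect size that is not part of
#' the selection rule.
#'
#' @inheritParams interaction_dge
#' @return A `dge_result` data frame: gene, log2fc, p, fdr, passes.
#' @export
twofactor_anova_dge <- function(x, thresholds = dge_thresholds()) {
  stopifnot(inherits(x, "count_matrix"))
  s <- x$samples
  check_strata_replicated(s)
  X <- stats::model.matrix(~ factor(s$condition) * factor(s$genotype))
  Y <- log2cpm(x)
  om <- row_omnibus_f(Y, X)
  stratum <- interaction(s$genotype, s$condition, drop = TRUE)
  cell_means <- vapply(levels(stratum),
                       function(l) rowMeans(Y[, stratum == l, drop = FALSE]),
                       numeric(nrow(Y)))
  eff <- apply(abs(cell_means - rowMeans(Y)), 1, max)
  fdr <- p.adjust(om$p, method = "BH")
  res <- data.frame(
    gene = rownames(Y), log2fc = eff, p = om$p, fdr = fdr,
    passes = fdr < thresholds$fdr_max, row.names = NULL
  )
  class(res) <- c("dge_result", "data.frame")
  attr(res, "contrast") <- "omnibus condition * genotype"
  res
}

#' @export
print.dge_result <- function(x, ...) {
  cat(sprintf("<dge_result> %d genes, %d passing (%s)\n",
              nrow(x), sum(x$passes), attr(x, "contrast")))
  NextMethod()
}

#' Write a DGE result table as TSV
#'
#' @param res a `dge_result`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_dge_result <- function(res, path) {
  write.table(res, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Overlap counts of labelled DEG sets
#'
#' Computes the size of every intersection region among the given gene
#' sets (the counts a Venn diagram displays). Regions are exclusive --
#' each gene of the union is counted in exactly one region.
#'
#' @param deg_sets named list of character vectors (e.g. DEG sets per
#'   days-post-attachment time point).
#' @return A data frame with one logical membership column per set and a
#'   `count` column; attribute `"union_size"` carries the union size.
#' @export
deg_overlap <- function(deg_sets) {
  if (is.null(names(deg_sets)) || any(names(deg_sets) == "")) {
    names(deg_sets) <- paste0("set", seq_along(deg_sets))
  }
  universe <- unique(unlist(deg_sets))
  memb <- vapply(deg_sets, function(s) universe %in% s, logical(length(universe)))
  if (length(universe) == 1L) memb <- matrix(memb, nrow = 1, dimnames = list(NULL, names(deg_sets)))
  k <- length(deg_sets)
  grid <- expand.grid(rep(list(c(FALSE, TRUE)), k))
  names(grid) <- names(deg_sets)
  counts <- integer(nrow(grid))
  if (length(universe)) {
    key <- apply(memb, 1, function(r) paste(r, collapse = "."))
    gkey <- apply(grid, 1, function(r) paste(r, collapse = "."))
    tab <- table(key)
    counts <- as.integer(ifelse(gkey %in% names(tab), tab[gkey], 0L))
  }
  out <- cbind(grid, count = counts)
  attr(out, "union_size") <- length(universe)
  out
}

#' Hierarchical-clustering leaf order for expression heat maps
#'
#' Agglomerative clustering with Euclidean distance and complete linkage
#' on rows and columns; returns the dendrogram leaf orders used to arrange
#' a heat map.
#'
#' @param expr numeric matrix.
#' @return List with `row_order` and `col_order` (integer permutations).
#' @export
heatmap_order <- function(expr) {
  expr <- as.matrix(expr)
  if (any(!is.finite(expr))) stopf("'expr' must be finite")
  ord <- function(m) {
    if (nrow(m) < 2L) return(seq_len(nrow(m)))
    stats::hclust(stats::dist(m, method = "euclidean"), method = "complete")$order
  }
  list(row_order = ord(expr), col_order = ord(t(expr)))
}
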