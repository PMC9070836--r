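#' t-SNE embedding parameters
#'
#' Defaults follow the expression-clustering stage of the study:
#' perplexity 20, early exaggeration for the first 250 iterations (the
#' "lying" phase), seed 2 and a minimum cluster size ("cutoff") of 20 in
#' the companion [density_cluster()] step.
#'
#' @param perplexity target perplexity of the conditional neighbour
#'   distributions; must satisfy `3 * perplexity < n_points - 1`.
#' @param lying number of early-exaggeration iterations.
#' @param seed integer seed fixing the random initialisation.
#' @param n_iter total gradient-descent iterations.
#' @param theta Barnes-Hut accuracy parameter carried for interface
#'   compatibility; gradients here are computed exactly (equivalent to
#'   `theta = 0`), which is fast at the gene-list sizes this package
#'   targets.
#' @param exaggeration early-exaggeration multiplier.
#' @param eta gradient-descent learning rate.
#' @return An object of class `tsne_params`.
#' @export
tsne_params <- function(perplexity = 20, lying = 250, seed = 2L,
                        n_iter = 1000L, theta = 0.5,
                        exaggeration = 12, eta = 200) {
  check_scalar(perplexity, "perplexity", 1)
  check_scalar(lying, "lying", 0)
  check_scalar(n_iter, "n_iter", 1)
  check_scalar(exaggeration, "exaggeration", 1)
  check_scalar(eta, "eta", 0, open_lower = TRUE)
  structure(list(perplexity = perplexity, lying = as.integer(lying),
                 seed = as.integer(seed), n_iter = as.integer(n_iter),
                 theta = theta, exaggeration = exaggeration, eta = eta),
            class = "tsne_params")
}

#' Row-standardise an expression matrix (z-scores)
#'
#' Each non-constant row is centred and scaled to unit standard deviation
#' (sample sd, denominator n - 1); constant rows become all zeros and are
#' flagged in the `"constant"` attribute.
#'
#' @param expr gene x sample numeric matrix with at least 2 columns.
#' @return The standardised matrix, with attribute `constant` (logical
#'   per row).
#' @export
zscore_rows <- function(expr) {
  expr <- as.matrix(expr)
  if (ncol(expr) < 2L) stopf("need at least 2 samples to standardise")
  mu <- rowMeans(expr)
  s <- apply(expr, 1, sd)
  const <- s == 0 | !is.finite(s)
  z <- (expr - mu) / ifelse(const, 1, s)
  z[const, ] <- 0
  attr(z, "constant") <- const
  z
}

#' Conditional similarities at a fixed perplexity (binary search on beta)
#' @noRd
perplexity_probs <- function(D2, perplexity, tol = 1e-5) {
  n <- nrow(D2)
  P <- matrix(0, n, n)
  logU <- log(perplexity)
  for (i in seq_len(n)) {
    beta <- 1; betamin <- -Inf; betamax <- Inf
    Di <- D2[i, -i]
    for (iter in 1:50) {
      Pi <- exp(-Di * beta)
      sumP <- sum(Pi)
      if (sumP == 0) sumP <- .Machine$double.xmin
      H <- log(sumP) + beta * sum(Di * Pi) / sumP
      diff <- H - logU
      if (abs(diff) < tol) break
      if (diff > 0) {
        betamin <- beta
        beta <- if (is.finite(betamax)) (beta + betamax) / 2 else beta * 2
      } else {
        betamax <- beta
        beta <- if (is.finite(betamin)) (beta + betamin) / 2 else beta / 2
      }
    }
    P[i, -i] <- Pi / sum(Pi)
  }
  P
}

#' t-SNE embedding of standardised expression profiles
#'
#' t-distributed stochastic neighbour embedding into 2-D with the
#' standard gradient-descent schedule: Gaussian input similarities
#' calibrated per point to the target perplexity, early exaggeration for
#' the first `lying` iterations, momentum 0.5 switching to 0.8, and
#' adaptive per-coordinate gains. Deterministic for a fixed
#' `params$seed` within one environment; coordinates are not comparable
#' across t-SNE implementations, only the recovered structure is.
#'
#' @param x gene x sample matrix (typically [zscore_rows()] output).
#' @param params a [tsne_params()].
#' @return An n x 2 matrix of coordinates (rownames preserved) of class
#'   `tsne_embedding`, with `params` attached as an attribute.
#' @export
tsne_embed <- function(x, params = tsne_params()) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n - 1 < 3 * params$perplexity) {
    stopf("perplexity %g too large for %d points (need 3 * perplexity < n - 1)",
          params$perplexity, n)
  }
  D2 <- as.matrix(dist(x))^2
  P <- perplexity_probs(D2, params$perplexity)
  P <- (P + t(P)) / (2 * n)
  P[P < 1e-12] <- 1e-12
  P <- P / sum(P)

  Y <- with_seed(params$seed, matrix(rnorm(n * 2, sd = 1e-4), n, 2))
  dY <- matrix(0, n, 2)
  gains <- matrix(1, n, 2)
  Pex <- P * params$exaggeration
  for (iter in seq_len(params$n_iter)) {
    Pit <- if (iter <= params$lying) Pex else P
    num <- 1 / (1 + as.matrix(dist(Y))^2)
    diag(num) <- 0
    Q <- num / sum(num)
    L <- (Pit - Q) * num
    grad <- 4 * (diag(rowSums(L)) - L) %*% Y
    momentum <- if (iter <= 250) 0.5 else 0.8
    gains <- ifelse(sign(grad) != sign(dY), gains + 0.2, gains * 0.8)
    gains[gains < 0.01] <- 0.01
    dY <- momentum * dY - params$eta * gains * grad
    Y <- Y + dY
    Y <- sweep(Y, 2, colMeans(Y))
  }
  rownames(Y) <- rownames(x)
  colnames(Y) <- c("x", "y")
  attr(Y, "params") <- params
  class(Y) <- c("tsne_embedding", class(Y))
  Y
}

#' @export
plot.tsne_embedding <- function(x, labels = NULL, ...) {
  col <- if (is.null(labels)) "grey30" else labels + 1L
  graphics::plot(x[, 1], x[, 2], col = col, pch = 16, cex = 0.6,
                 xlab = "t-SNE 1", ylab = "t-SNE 2", ...)
  invisible(x)
}

#' Density-based clustering of an embedding with a noise group
#'
#' DBSCAN-style grouping on the 2-D embedding. The neighbourhood radius
#' is picked from the knee of the k-nearest-neighbour distance curve
#' (k = `cutoff`, the point of maximum deviation from the chord joining
#' the curve's endpoints); core points have at least `cutoff` neighbours
#' (self included) within that radius. Any candidate group smaller than
#' `cutoff` is dissolved into the noise group (label 0); remaining
#' clusters are renumbered by decreasing size.
#'
#' @param coords n x 2 coordinate matrix (a [tsne_embed()] result).
#' @param cutoff minimum cluster size (default 20).
#' @param eps optional fixed neighbourhood radius overriding the knee
#'   heuristic.
#' @return An object of class `cluster_assignment`: list with `labels`
#'   (integer per point; 0 = noise), `n_clusters`, `cutoff`, `eps`.
#' @export
density_cluster <- function(coords, cutoff = 20L, eps = NULL) {
  if (cutoff < 1) stopf("'cutoff' must be at least 1")
  coords <- as.matrix(coords)
  n <- nrow(coords)
  if (any(!is.finite(coords))) stopf("coordinates must be finite")
  d <- as.matrix(dist(coords))
  if (is.null(eps)) {
    k <- min(cutoff, n - 1L)
    kdist <- apply(d, 1, function(r) sort(r)[k + 1L])
    s <- sort(kdist, decreasing = TRUE)
    ## knee: farthest point from the chord between the curve's endpoints
    m <- length(s)
    xs <- seq_len(m)
    dx <- m - 1; dy <- s[m] - s[1]
    perp <- abs(dy * (xs - 1) - dx * (s - s[1])) / sqrt(dx^2 + dy^2)
    eps <- s[which.max(perp)]
  }
  nb <- d <= eps
  core <- rowSums(nb) >= cutoff
  labels <- integer(n)
  cl <- 0L
  for (i in seq_len(n)) {
    if (labels[i] != 0L || !core[i]) next
    cl <- cl + 1L
    queue <- i
    labels[i] <- cl
    while (length(queue)) {
      j <- queue[1]; queue <- queue[-1]
      if (!core[j]) next
      for (nb_j in which(nb[j, ] & labels == 0L)) {
        labels[nb_j] <- cl
        if (core[nb_j]) queue <- c(queue, nb_j)
      }
    }
  }
  ## dissolve sub-cutoff groups into noise, renumber by decreasing size
  sizes <- table(labels[labels > 0])
  keep <- as.integer(names(sizes)[sizes >= cutoff])
  labels[!labels %in% keep] <- 0L
  if (length(keep)) {
    ord <- keep[order(-sizes[as.character(keep)], keep)]
    labels <- ifelse(labels == 0L, 0L, match(labels, ord))
  }
  structure(list(labels = labels, n_clusters = length(keep),
                 cutoff = as.integer(cutoff), eps = eps),
            class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat(sprintf("<cluster_assignment> %d clusters (size >= %d), %d noise of %d points, eps = %.3g\n",
              x$n_clusters, x$cutoff, sum(x$labels == 0), length(x$labels), x$eps))
  invisible(x)
}

#' Per-cluster mean expression profiles
#'
#' One mean profile row per non-noise cluster (and a separate `noise` row
#' when the noise group is non-empty), computed over the matrix whose rows
#' were clustered.
#'
#' @param assignment a [density_cluster()] result.
#' @param expr the matrix whose rows were clustered (e.g. z-scores).
#' @return Matrix of mean profiles; rownames `cluster<k>` and optionally
#'   `noise`.
#' @export
cluster_summary <- function(assignment, expr) {
  stopifnot(inherits(assignment, "cluster_assignment"))
  expr <- as.matrix(expr)
  if (nrow(expr) != length(assignment$labels)) {
    stopf("labels and matrix rows do not align")
  }
  labs <- assignment$labels
  ids <- sort(unique(labs[labs > 0]))
  rows <- lapply(ids, function(k) colMeans(expr[labs == k, , drop = FALSE]))
  nms <- sprintf("cluster%d", ids)
  if (any(labs == 0)) {
    rows <- c(rows, list(colMeans(expr[labs == 0, , drop = FALSE])))
    nms <- c(nms, "noise")
  }
  out <- do.call(rbind, rows)
  rownames(out) <- nms
  out
}

#' Write an embedding + cluster table as TSV
#'
#' The written table (gene, x, y, cluster) is the gene-list interface the
#' network stage consumes.
#'
#' @param coords a [tsne_embed()] result.
#' @param assignment a [density_cluster()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_embedding <- function(coords, assignment, path) {
  df <- data.frame(
    gene = rownames(coords) %||% seq_len(nrow(coords)),
    x = coords[, 1], y = coords[, 2],
    cluster = assignment$labels
  )
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a
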