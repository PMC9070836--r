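#' Pearson correlation matrix over a gene subset
#'
#' Product-moment correlations between gene expression profiles within
#' one stratum. Genes with zero variance have undefined correlations;
#' their rows/columns are set to `NA` and flagged so the thresholding
#' step excludes them from edges.
#'
#' @param expr gene x sample numeric matrix (>= 3 samples).
#' @return Symmetric correlation matrix with unit diagonal; attribute
#'   `constant` flags zero-variance genes.
#' @export
pearson_corr_matrix <- function(expr) {
  expr <- as.matrix(expr)
  if (ncol(expr) < 3L) stopf("need at least 3 samples to correlate")
  s <- apply(expr, 1, sd)
  const <- s == 0 | !is.finite(s)
  cc <- suppressWarnings(cor(t(expr), method = "pearson"))
  cc[const, ] <- NA_real_
  cc[, const] <- NA_real_
  diag(cc) <- 1
  attr(cc, "constant") <- const
  cc
}

#' Threshold a correlation matrix into a co-expression graph
#'
#' In the default `"normal"` mode, off-diagonal correlations are Fisher
#' z-transformed, standardised by their own mean and standard deviation,
#' and a pair becomes an edge when its standardised value exceeds the
#' standard-normal quantile at `q` (about 2.748 for the default
#' q = 0.997); only the upper tail forms edges, matching the reading of
#' an edge as a co-expression connection. In `"empirical"` mode the
#' threshold is instead the empirical `q`-quantile of the absolute
#' off-diagonal correlations, so strong negative correlations can also
#' form edges. Edges carry the original correlation as weight.
#'
#' @param corr correlation matrix (from [pearson_corr_matrix()]).
#' @param q quantile cutoff in (0.5, 1); default 0.997.
#' @param mode `"normal"` (Gaussian reference on standardised Fisher z)
#'   or `"empirical"` (empirical quantile of |r|).
#' @param stratum optional label describing the (genotype, condition)
#'   stratum the graph belongs to.
#' @return An object of class `gcn_graph`: list with `nodes` (gene ids),
#'   `edges` (data frame: from, to, weight), `stratum`, `q`, `mode`.
#' @export
edge_threshold <- function(corr, q = 0.997, mode = c("normal", "empirical"),
                           stratum = NA_character_) {
  mode <- match.arg(mode)
  if (q <= 0.5 || q >= 1) stopf("'q' must lie in (0.5, 1)")
  corr <- as.matrix(corr)
  n <- nrow(corr)
  nodes <- rownames(corr) %||% sprintf("g%d", seq_len(n))
  ut <- upper.tri(corr)
  r <- corr[ut]
  idx <- which(ut, arr.ind = TRUE)
  ok <- is.finite(r)
  keep <- logical(length(r))
  if (any(ok)) {
    if (mode == "normal") {
      z <- atanh(pmin(pmax(r[ok], -1 + 1e-12), 1 - 1e-12))
      sdz <- sd(z)
      if (sdz == 0) {
        keep[ok] <- FALSE
      } else {
        keep[ok] <- (z - mean(z)) / sdz > qnorm(q)
      }
    } else {
      thr <- quantile(abs(r[ok]), probs = q, names = FALSE)
      keep[ok] <- abs(r[ok]) > thr
    }
  }
  edges <- data.frame(
    from = nodes[idx[keep, 1]],
    to = nodes[idx[keep, 2]],
    weight = r[keep],
    stringsAsFactors = FALSE
  )
  structure(list(nodes = nodes, edges = edges, stratum = stratum,
                 q = q, mode = mode),
            class = "gcn_graph")
}

#' @export
print.gcn_graph <- function(x, ...) {
  cat(sprintf("<gcn_graph> %d nodes, %d edges (q = %g, %s mode%s)\n",
              length(x$nodes), nrow(x$edges), x$q, x$mode,
              if (is.na(x$stratum)) "" else paste0(", stratum ", x$stratum)))
  invisible(x)
}

#' @noRd
as_igraph <- function(graph) {
  igraph::graph_from_data_frame(
    graph$edges[, c("from", "to")],
    directed = FALSE,
    vertices = data.frame(name = graph$nodes)
  )
}

#' Community detection on a co-expression graph
#'
#' Modularity-maximising partition by greedy agglomeration (fast-greedy
#' community detection); isolated nodes each form their own singleton
#' module. Deterministic for a fixed node ordering.
#'
#' @param graph a [edge_threshold()] result.
#' @return An object of class `module_partition`: list with `membership`
#'   (named integer vector over all nodes) and `modularity`.
#' @export
detect_communities <- function(graph) {
  stopifnot(inherits(graph, "gcn_graph"))
  if (length(graph$nodes) == 0L) {
    return(structure(list(membership = integer(0), modularity = NA_real_),
                     class = "module_partition"))
  }
  g <- as_igraph(graph)
  if (nrow(graph$edges) == 0L) {
    memb <- seq_along(graph$nodes)
    names(memb) <- graph$nodes
    return(structure(list(membership = memb, modularity = NA_real_),
                     class = "module_partition"))
  }
  cm <- igraph::cluster_fast_greedy(g)
  memb <- igraph::membership(cm)
  structure(list(membership = setNames(as.integer(memb), names(memb)),
                 modularity = igraph::modularity(g, memb)),
            class = "module_partition")
}

#' @export
print.module_partition <- function(x, ...) {
  cat(sprintf("<module_partition> %d modules over %d nodes, modularity %.3f\n",
              length(unique(x$membership)), length(x$membership), x$modularity))
  invisible(x)
}

#' Degree-based hub ranking and isolated-gene report
#'
#' Degrees counted from the edge list; nodes are ranked by decreasing
#' degree (ties broken by node order) and genes with no co-expression
#' connection at all are listed separately, mirroring the unconnected
#' gene lists shown beside each cultivar's network.
#'
#' @param graph a [edge_threshold()] result.
#' @return An object of class `hub_report`: list with `degrees` (named,
#'   in input node order), `ranking` (node names by decreasing degree)
#'   and `isolated` (character vector).
#' @export
hub_rank <- function(graph) {
  stopifnot(inherits(graph, "gcn_graph"))
  deg <- setNames(integer(length(graph$nodes)), graph$nodes)
  if (nrow(graph$edges)) {
    tab <- table(c(graph$edges$from, graph$edges$to))
    deg[names(tab)] <- as.integer(tab)
  }
  structure(list(
    degrees = deg,
    ranking = names(deg)[order(-deg)],  # stable: ties keep node order
    isolated = names(deg)[deg == 0]
  ), class = "hub_report")
}

#' @export
print.hub_report <- function(x, ...) {
  top <- head(x$ranking, 5)
  cat(sprintf("<hub_report> %d nodes, %d isolated; top hubs: %s\n",
              length(x$degrees), length(x$isolated),
              paste(sprintf("%s(%d)", top, x$degrees[top]), collapse = ", ")))
  invisible(x)
}

#' Per-stratum co-expression networks over a selected gene list
#'
#' Splits the samples into (genotype, condition) strata and, for each,
#' correlates the selected genes, thresholds the correlations into a
#' graph ([edge_threshold()]), detects modules and ranks hubs, emitting
#' one comparable report per stratum.
#'
#' @param x a `count_matrix`.
#' @param gene_list character vector of gene ids to include.
#' @param q quantile cutoff (default 0.997).
#' @param mode threshold mode, see [edge_threshold()].
#' @return Named list (one element per stratum `genotype.condition`) of
#'   lists with `graph`, `modules`, `hubs`.
#' @export
build_stratified_gcns <- function(x, gene_list, q = 0.997,
                                  mode = c("normal", "empirical")) {
  stopifnot(inherits(x, "count_matrix"))
  mode <- match.arg(mode)
  missing_genes <- setdiff(gene_list, rownames(x$counts))
  if (length(missing_genes)) {
    stopf("gene(s) not in count matrix: %s",
          paste(head(missing_genes, 5), collapse = ", "))
  }
  Y <- log2cpm(x)[gene_list, , drop = FALSE]
  s <- x$samples
  strata <- unique(s[, c("genotype", "condition")])
  out <- list()
  for (i in seq_len(nrow(strata))) {
    sel <- s$genotype == strata$genotype[i] & s$condition == strata$condition[i]
    label <- paste(strata$genotype[i], strata$condition[i], sep = ".")
    if (sum(sel) < 3L) stopf("stratum %s has fewer than 3 samples", label)
    corr <- pearson_corr_matrix(Y[, sel, drop = FALSE])
    graph <- edge_threshold(corr, q = q, mode = mode, stratum = label)
    out[[label]] <- list(graph = graph,
                         modules = detect_communities(graph),
                         hubs = hub_rank(graph))
  }
  out
}

#' Write a co-expression graph as TSV edge list and GraphML
#'
#' @param graph a `gcn_graph`.
#' @param prefix output path prefix; writes `<prefix>_edges.tsv` and
#'   `<prefix>.graphml`.
#' @return The file paths, invisibly.
#' @export
write_gcn <- function(graph, prefix) {
  ef <- paste0(prefix, "_edges.tsv")
  gf <- paste0(prefix, ".graphml")
  write.table(graph$edges, ef, sep = "\t", quote = FALSE, row.names = FALSE)
  igraph::write_graph(as_igraph(graph), gf, format = "graphml")
  invisible(c(edges = ef, graphml = gf))
}
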