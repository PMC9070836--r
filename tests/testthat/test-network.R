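mk_graph <- function(edges, nodes) {
  structure(list(nodes = nodes, edges = edges, stratum = NA_character_,
                 q = 0.997, mode = "normal"), class = "gcn_graph")
}

test_that("correlation matrix matches the product-moment formula", {
  set.seed(2)
  expr <- matrix(rnorm(15), 3, 5, dimnames = list(paste0("g", 1:3), NULL))
  cc <- pearson_corr_matrix(expr)
  expect_equal(diag(cc), setNames(rep(1, 3), rownames(expr)))
  for (i in 1:2) for (j in (i + 1):3) {
    x <- expr[i, ]; y <- expr[j, ]
    hand <- sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
    expect_equal(cc[i, j], hand)
    expect_equal(cc[i, j], cc[j, i])
  }
  ## anti-proportional pair
  anti <- rbind(a = 1:5, b = -(1:5) * 2)
  expect_equal(pearson_corr_matrix(anti)["a", "b"], -1)
  ## constant genes flagged, too few samples rejected
  const <- rbind(a = 1:5, b = rep(2, 5))
  ccc <- pearson_corr_matrix(const)
  expect_true(is.na(ccc["b", "a"]))
  expect_error(pearson_corr_matrix(matrix(1:4, 2, 2)), "3 samples")
})

test_that("thresholding an identity correlation matrix yields no edges", {
  cc <- diag(10)
  rownames(cc) <- colnames(cc) <- paste0("g", 1:10)
  g <- edge_threshold(cc, q = 0.997)
  expect_equal(nrow(g$edges), 0)
  expect_error(edge_threshold(cc, q = 0.4), "q")
  expect_error(edge_threshold(cc, q = 1), "q")
})

test_that("edge sets are nested: a higher quantile never adds edges", {
  set.seed(11)
  for (rep in 1:3) {
    x <- matrix(rnorm(30 * 12), 30, 12,
                dimnames = list(sprintf("g%02d", 1:30), NULL))
    cc <- pearson_corr_matrix(x)
    for (mode in c("normal", "empirical")) {
      lo <- edge_threshold(cc, q = 0.997, mode = mode)
      hi <- edge_threshold(cc, q = 0.999, mode = mode)
      key <- function(g) paste(g$edges$from, g$edges$to)
      expect_true(all(key(hi) %in% key(lo)))
    }
  }
})

test_that("emitted graphs are undirected with no self-loops and bounded weights", {
  set.seed(12)
  x <- matrix(rnorm(40 * 10), 40, 10,
              dimnames = list(sprintf("g%02d", 1:40), NULL))
  g <- edge_threshold(pearson_corr_matrix(x), q = 0.99)
  expect_true(all(g$edges$from != g$edges$to))
  expect_true(all(g$edges$weight >= -1 & g$edges$weight <= 1))
  expect_false(any(duplicated(rbind(
    paste(g$edges$from, g$edges$to), paste(g$edges$to, g$edges$from)
  ))))
})

test_that("negative correlations form edges only in empirical mode", {
  set.seed(13)
  z <- rnorm(12)
  x <- rbind(a = z + rnorm(12, sd = 0.01), b = -z + rnorm(12, sd = 0.01),
             matrix(rnorm(20 * 12), 20, 12))
  rownames(x)[3:22] <- sprintf("g%02d", 3:22)
  cc <- pearson_corr_matrix(x)
  gn <- edge_threshold(cc, q = 0.997, mode = "normal")
  expect_false(any(gn$edges$weight < 0))
  ge <- edge_threshold(cc, q = 0.997, mode = "empirical")
  expect_true(any(ge$edges$weight < 0))
})

test_that("communities of two disconnected triangles are the components", {
  edges <- data.frame(from = c("a", "b", "c", "x", "y", "z"),
                      to = c("b", "c", "a", "y", "z", "x"),
                      weight = 1)
  g <- mk_graph(edges, c("a", "b", "c", "x", "y", "z"))
  part <- detect_communities(g)
  expect_equal(length(unique(part$membership)), 2)
  expect_equal(length(unique(part$membership[c("a", "b", "c")])), 1)
  expect_equal(length(unique(part$membership[c("x", "y", "z")])), 1)
  expect_gte(part$modularity, 0)  # at least the all-in-one partition
})

test_that("a barbell graph is split between its two cliques", {
  clique <- function(nodes) {
    p <- t(combn(nodes, 2))
    data.frame(from = p[, 1], to = p[, 2], weight = 1)
  }
  n1 <- paste0("a", 1:5); n2 <- paste0("b", 1:5)
  edges <- rbind(clique(n1), clique(n2),
                 data.frame(from = "a5", to = "b1", weight = 1))
  part <- detect_communities(mk_graph(edges, c(n1, n2)))
  expect_equal(length(unique(part$membership[n1])), 1)
  expect_equal(length(unique(part$membership[n2])), 1)
  expect_false(part$membership["a1"] == part$membership["b5"])
})

test_that("hub ranking counts degrees exactly and lists isolated genes", {
  star <- mk_graph(data.frame(from = "hub", to = paste0("leaf", 1:5),
                              weight = 0.9),
                   c("hub", paste0("leaf", 1:5), "orphan"))
  hb <- hub_rank(star)
  expect_equal(unname(hb$degrees["hub"]), 5)
  expect_equal(hb$ranking[1], "hub")
  expect_equal(hb$isolated, "orphan")

  set.seed(14)
  x <- matrix(rnorm(25 * 10), 25, 10,
              dimnames = list(sprintf("g%02d", 1:25), NULL))
  g <- edge_threshold(pearson_corr_matrix(x), q = 0.98)
  hb2 <- hub_rank(g)
  brute <- setNames(integer(25), g$nodes)
  for (i in seq_len(nrow(g$edges))) {
    brute[g$edges$from[i]] <- brute[g$edges$from[i]] + 1L
    brute[g$edges$to[i]] <- brute[g$edges$to[i]] + 1L
  }
  expect_equal(hb2$degrees, brute)
})

test_that("identical strata produce identical edge sets", {
  set.seed(15)
  base <- matrix(rpois(50 * 4, 300), 50, 4)
  counts <- cbind(base, base)
  dimnames(counts) <- list(sprintf("g%02d", 1:50), paste0("s", 1:8))
  cm <- structure(list(
    counts = counts,
    samples = data.frame(sample = colnames(counts),
                         genotype = rep(c("A", "B"), each = 4),
                         condition = "infested",
                         replicate = rep(1:4, 2)),
    gene_ids = rownames(counts), truth = NULL
  ), class = "count_matrix")
  gc <- build_stratified_gcns(cm, rownames(counts), q = 0.99)
  expect_equal(gc$A.infested$graph$edges, gc$B.infested$graph$edges)
  expect_error(build_stratified_gcns(cm, c("g01", "nope")), "not in count")
})

test_that("planted two-module simulation is recovered with high edge precision", {
  st <- data.frame(genotype = "H9553", condition = "infested", n_rep = 20)
  sim <- simulate_counts(expr_sim_spec(
    n_genes = 100, strata = st,
    module_plan = list(list(size = 20, cor = 0.9), list(size = 20, cor = 0.9)),
    seed = 5
  ))
  cc <- pearson_corr_matrix(log2(cpm_normalize(sim) + 0.5))
  g <- edge_threshold(cc, q = 0.997)
  mod <- sim$truth$module
  i <- match(g$edges$from, sim$gene_ids)
  j <- match(g$edges$to, sim$gene_ids)
  precision <- mean(mod[i] > 0 & mod[i] == mod[j])
  expect_gt(nrow(g$edges), 20)
  expect_gte(precision, 0.9)
})

test_that("a stratum-specific hub ranks first at home and is isolated away", {
  sim <- sim_hub_strata(seed = 1)
  hub <- sim$gene_ids[sim$truth$hub]
  gc <- build_stratified_gcns(sim, sim$gene_ids, q = 0.997)
  active <- gc[["H9553.infested"]]$hubs
  control <- gc[["H9553.uninfested"]]$hubs
  expect_equal(active$ranking[1], hub)
  expect_true(hub %in% control$isolated)
})
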