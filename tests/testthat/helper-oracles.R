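## Independent brute-force oracles used across the test files. These are
## deliberately naive re-implementations (double loops, closed forms) kept
## separate from the package's vectorised code paths.

## Direct 2-D Gaussian convolution by double loop, mirrored borders,
## kernel truncated at 3 sigma (the documented convention).
naive_gaussian_blur <- function(m, sigma) {
  r <- as.integer(ceiling(3 * sigma))
  k1 <- dnorm(seq(-r, r), sd = sigma)
  k1 <- k1 / sum(k1)
  k2 <- outer(k1, k1)
  H <- nrow(m); W <- ncol(m)
  reflect <- function(i, n) {
    while (i < 1 || i > n) {
      if (i < 1) i <- 2 - i
      if (i > n) i <- 2 * n - i
    }
    i
  }
  out <- matrix(0, H, W)
  for (y in seq_len(H)) for (x in seq_len(W)) {
    acc <- 0
    for (dy in -r:r) for (dx in -r:r) {
      acc <- acc + k2[dy + r + 1, dx + r + 1] *
        m[reflect(y + dy, H), reflect(x + dx, W)]
    }
    out[y, x] <- acc
  }
  out
}

## Closed-form sRGB (D65) -> CIELAB for a single 8-bit RGB triple.
naive_lab <- function(rgb) {
  v <- rgb / 255
  lin <- ifelse(v <= 0.04045, v / 12.92, ((v + 0.055) / 1.055)^2.4)
  M <- matrix(c(0.4124564, 0.3575761, 0.1804375,
                0.2126729, 0.7151522, 0.0721750,
                0.0193339, 0.1191920, 0.9503041), 3, 3, byrow = TRUE)
  xyz <- as.vector(M %*% lin) / c(0.95047, 1, 1.08883)
  f <- ifelse(xyz > (6 / 29)^3, xyz^(1 / 3), xyz / (3 * (6 / 29)^2) + 4 / 29)
  c(L = 116 * f[2] - 16, a = 500 * (f[1] - f[2]), b = 200 * (f[2] - f[3]))
}

## Histogram peak by an explicit counting loop over 256 bins.
naive_histogram_peak <- function(v) {
  counts <- integer(256)
  for (x in as.vector(v)) counts[x + 1] <- counts[x + 1] + 1
  best <- 1
  for (b in 2:256) if (counts[b] > counts[best]) best <- b
  best - 1
}

## Per-pixel evaluation of the adaptive threshold rule on Lab channels.
naive_lignin_mask <- function(L8, a8) {
  pl <- naive_histogram_peak(L8)
  pa <- naive_histogram_peak(a8)
  out <- matrix(FALSE, nrow(L8), ncol(L8))
  for (y in seq_len(nrow(L8))) for (x in seq_len(ncol(L8))) {
    out[y, x] <- (L8[y, x] <= pl) && (a8[y, x] >= pa)
  }
  out
}

## Character-level sliding-window IUPAC motif scan, both strands.
IUPAC_TEST <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

naive_scan_motif <- function(seq, pattern = "TTGACY", both_strands = TRUE) {
  chars <- strsplit(toupper(seq), "")[[1]]
  pat <- strsplit(toupper(pattern), "")[[1]]
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  rc_pat <- rev(unname(vapply(pat, function(p) {
    s <- IUPAC_TEST[[p]]
    cs <- sort(comp[s])
    for (nm in names(IUPAC_TEST)) {
      if (identical(sort(IUPAC_TEST[[nm]]), unname(cs))) return(nm)
    }
    stop("no complement code")
  }, character(1))))
  m <- length(pat)
  match_at <- function(p, patv) {
    for (k in seq_len(m)) {
      if (!chars[p + k - 1] %in% IUPAC_TEST[[patv[k]]]) return(FALSE)
    }
    TRUE
  }
  starts_f <- integer(0); starts_r <- integer(0)
  for (p in seq_len(length(chars) - m + 1)) {
    if (match_at(p, pat)) starts_f <- c(starts_f, p)
    if (both_strands && match_at(p, rc_pat)) starts_r <- c(starts_r, p)
  }
  list(forward = starts_f, reverse = starts_r)
}

## Truth-table scan of the resistance-specific rule, row by row.
naive_resistance_filter <- function(variants, resistant, susceptible) {
  norm1 <- function(x) paste(sort(unique(strsplit(x, "/")[[1]])), collapse = "/")
  keep <- logical(nrow(variants))
  for (i in seq_len(nrow(variants))) {
    r1 <- variants[[resistant[1]]][i]
    r2 <- variants[[resistant[2]]][i]
    su <- variants[[susceptible]][i]
    if (any(is.na(c(r1, r2, su))) || any(c(r1, r2, su) %in% c(".", ""))) next
    if (!variants$ref[i] %in% c("A", "C", "G", "T")) next
    if (!variants$alt[i] %in% c("A", "C", "G", "T")) next
    keep[i] <- norm1(r1) == norm1(r2) && norm1(r1) != norm1(su)
  }
  keep
}

## Mean silhouette width from a distance matrix and labels.
naive_silhouette <- function(d, labels) {
  d <- as.matrix(d)
  n <- nrow(d)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- labels == labels[i]
    a <- mean(d[i, own & seq_len(n) != i])
    b <- min(vapply(setdiff(unique(labels), labels[i]),
                    function(l) mean(d[i, labels == l]), numeric(1)))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

## Small structured count simulation used by several test files: three
## planted expression clusters with distinct infestation patterns plus
## unstructured background genes.
sim_three_clusters <- function(seed, n_background = 30) {
  simulate_counts(expr_sim_spec(
    n_genes = 150 + n_background,
    strata = default_strata(3L),
    cluster_plan = list(
      list(size = 50, shift = c(0, 4, 0, 4, 0, 0, 0, 0)),
      list(size = 50, shift = c(0, 0, 0, 0, 0, 4, 0, 4)),
      list(size = 50, shift = c(4, 0, 4, 0, 0, 0, 0, 0))
    ),
    seed = seed
  ))
}

## The hub-specificity simulation: a defence module with a hub, active in
## the infested stratum only, plus quantile-absorbing modules in each
## stratum so the relative edge threshold is anchored by planted structure.
sim_hub_strata <- function(seed) {
  simulate_counts(expr_sim_spec(
    n_genes = 150,
    strata = data.frame(genotype = "H9553",
                        condition = c("infested", "uninfested"),
                        n_rep = 20L),
    dispersion = 0.01, biovar_sd = 0.1,
    module_plan = list(
      list(size = 20, cor = 0.97, hub = TRUE, strata = 1),
      list(size = 24, cor = 0.97, strata = 2),
      list(size = 20, cor = 0.97, strata = 1)
    ),
    seed = seed
  ))
}
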