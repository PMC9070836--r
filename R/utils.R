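## Internal helpers shared across modules.

#' Evaluate an expression with a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so that generators are deterministic
#' for a fixed seed without disturbing the caller's RNG stream.
#' @noRd
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("'seed' must be a single integer", call. = FALSE)
  }
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  expr
}

#' @noRd
stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' Check a scalar is a number within (optionally open) bounds
#' @noRd
check_scalar <- function(x, name, lower = -Inf, upper = Inf,
                         open_lower = FALSE, open_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    stopf("'%s' must be a single finite number", name)
  }
  lo_ok <- if (open_lower) x > lower else x >= lower
  hi_ok <- if (open_upper) x < upper else x <= upper
  if (!lo_ok || !hi_ok) {
    stopf("'%s' = %g is outside the allowed range", name, x)
  }
  invisible(x)
}

#' Reflective (mirror) index vector used for border handling
#'
#' Maps positions (1-r):(n+r) into 1..n by mirroring about the edge pixels
#' (position 0 maps to 2, position n+1 maps to n-1).
#' @noRd
reflect_idx <- function(n, r) {
  i <- (1L - r):(n + r)
  j <- abs(i - 1L) %% (2L * (n - 1L))
  j <- ifelse(j >= n, 2L * (n - 1L) - j, j)
  j + 1L
}

#' Separable Gaussian blur of a numeric matrix with reflective borders
#'
#' Kernel is the sampled Gaussian truncated at 3 sigma and renormalised.
#' @noRd
blur_matrix <- function(m, sigma) {
  r <- as.integer(ceiling(3 * sigma))
  k <- stats::dnorm(seq(-r, r), sd = sigma)
  k <- k / sum(k)
  conv_cols <- function(x) {
    n <- nrow(x)
    xp <- x[reflect_idx(n, r), , drop = FALSE]
    out <- matrix(0, n, ncol(x))
    for (j in seq_along(k)) {
      out <- out + k[j] * xp[j:(j + n - 1L), , drop = FALSE]
    }
    out
  }
  t(conv_cols(t(conv_cols(m))))
}

#' Clip to [0, 255] and round to integers
#' @noRd
quantize8 <- function(x) {
  x <- round(x)
  x[x < 0] <- 0
  x[x > 255] <- 255
  storage.mode(x) <- "integer"
  x
}
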