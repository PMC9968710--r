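# Spearman rank-correlation engine with exact small-sample inference.
#
# Within-subject per-CpG concordance between two tissues rests entirely on
# this engine: average-rank Spearman rho, an exhaustive permutation null for
# small tie-free samples, and the t approximation (df = n - 2) otherwise.

# cache of exact permutation rho distributions, keyed by n
.perm_cache <- new.env(parent = emptyenv())

# all permutations of 1:n as an n! x n matrix (n <= 8 in practice)
perm_matrix <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- perm_matrix(n - 1L)
  out <- matrix(0L, nrow = n * nrow(sub), ncol = n)
  for (i in seq_len(n)) {
    rows <- seq_len(nrow(sub)) + (i - 1L) * nrow(sub)
    out[rows, 1L] <- i
    rest <- seq_len(n)[-i]
    out[rows, -1L] <- matrix(rest[sub], nrow(sub), n - 1L)
  }
  out
}

# null distribution of rho for tie-free samples of size n (depends on n only)
exact_rho_null <- function(n) {
  key <- as.character(n)
  if (!is.null(.perm_cache[[key]])) return(.perm_cache[[key]])
  perms <- perm_matrix(n)
  d2 <- rowSums((perms - rep(seq_len(n), each = nrow(perms)))^2)
  rho <- 1 - 6 * d2 / (n * (n^2 - 1))
  .perm_cache[[key]] <- rho
  rho
}

#' Spearman rho between two vectors (average ranks, pairwise complete)
#'
#' @param x,y Numeric vectors of equal length; pairs with any NA are dropped.
#' @return Spearman correlation, or NA if fewer than 2 complete pairs or
#'   either vector is constant.
#' @export
spearman_rho <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 2L) return(NA_real_)
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) return(NA_real_)
  stats::cor(rx, ry)
}

# two-sided p for observed rho via the t approximation with df = n - 2
spearman_p_t <- function(rho, n) {
  if (is.na(rho) || n < 3L) return(NA_real_)
  if (abs(rho) >= 1) return(0)
  tval <- rho * sqrt((n - 2) / (1 - rho^2))
  2 * stats::pt(-abs(tval), df = n - 2)
}

# two-sided p from the exhaustive permutation null (tie-free, n <= 8)
spearman_p_exact <- function(rho, n) {
  null <- exact_rho_null(n)
  mean(abs(null) >= abs(rho) - 1e-12)
}

#' Two-sided p-value for a Spearman correlation
#'
#' Routes to the exhaustive n! permutation null when `n <= 8` and neither
#' vector carries ties; otherwise to the t approximation
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` with `n - 2` degrees of freedom.
#' Ties always take the t route (the exact null assumes distinct ranks).
#'
#' @param rho Observed Spearman correlation.
#' @param n Number of complete pairs.
#' @param has_ties Whether either input had tied values.
#' @return Two-sided p-value at full precision (never truncated).
#' @export
spearman_p <- function(rho, n, has_ties = FALSE) {
  if (is.na(rho)) return(NA_real_)
  if (n <= 8L && !has_ties) spearman_p_exact(rho, n) else spearman_p_t(rho, n)
}

#' Minimal absolute Spearman rho significant at a given level
#'
#' Inverts the t approximation: the critical t is `qt(1 - alpha/2, n - 2)`
#' and the corresponding correlation is `t / sqrt(n - 2 + t^2)`. At n = 19
#' and alpha = 0.05 this gives 0.456, i.e. 0.46 at two decimals — the
#' smallest per-CpG correlation that reaches nominal significance in a
#' 19-subject cohort.
#'
#' @param n Sample size (>= 4).
#' @param alpha Two-sided significance level in (0, 1).
#' @return List with `rho` (full precision) and `rho_2dp` (rounded).
#' @export
critical_rho <- function(n, alpha = 0.05) {
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
    stop("alpha must lie in (0, 1)")
  if (n < 4L) stop("n must be >= 4")
  tcrit <- stats::qt(1 - alpha / 2, df = n - 2)
  rho <- tcrit / sqrt(n - 2 + tcrit^2)
  list(rho = rho, rho_2dp = round(rho, 2))
}

#' Benjamini-Hochberg step-up q-values
#'
#' Standard step-up: with p-values sorted ascending, `q_(i) = min_{j >= i}
#' m * p_(j) / j`, capped at 1, returned in input order. NAs pass through
#' and do not count toward m.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return q-values aligned with the input.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  q <- rep(NA_real_, length(p))
  ok <- which(!is.na(p))
  m <- length(ok)
  if (m == 0L) return(q)
  o <- order(p[ok])
  ps <- p[ok][o]
  adj <- rev(cummin(rev(m * ps / seq_len(m))))
  q[ok[o]] <- pmin(1, adj)
  q
}
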