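# Shared fixture builders and independent oracles. Everything is generated
# in code at test time; no stored data.

# small probe-by-subject matrix with dimnames
toy_beta <- function(n_probes, n_subjects, seed = 1, rmin = 0.05, rmax = 0.95) {
  set.seed(seed)
  m <- matrix(stats::runif(n_probes * n_subjects, rmin, rmax),
              n_probes, n_subjects,
              dimnames = list(sprintf("cg%06d", seq_len(n_probes)),
                              sprintf("S%02d", seq_len(n_subjects))))
  m
}

# genotype-cluster probe values: centers for k clusters, each realized
# cluster occupied by at least min_size subjects
genotype_probe <- function(n = 19, k = 3, sd = 0.02, min_size = 2,
                           centers = c(0.05, 0.5, 0.95)) {
  cen <- if (k == 2L) centers[c(1L, 3L)] else centers[seq_len(k)]
  repeat {
    g <- sample.int(k, n, replace = TRUE)
    if (length(unique(g)) == k && min(tabulate(g, k)) >= min_size) break
  }
  v <- cen[g] + stats::rnorm(n, 0, sd)
  pmin(1, pmax(0, v))
}

# unimodal null probe on the beta scale
null_probe <- function(n = 19, spread = 0.3) {
  stats::plogis(stats::rnorm(1, 0, 1.5) + stats::rnorm(n, 0, spread))
}

# independent permutation enumerator (Heap's algorithm, iterative) --
# deliberately a different construction from the package's recursive one
heap_permutations <- function(n) {
  a <- seq_len(n)
  out <- matrix(0L, factorial(n), n)
  c_vec <- integer(n)
  out[1L, ] <- a
  row <- 1L
  i <- 1L
  while (i <= n) {
    if (c_vec[i] < i - 1L) {
      if (i %% 2L == 1L) {
        tmp <- a[1L]; a[1L] <- a[i]; a[i] <- tmp
      } else {
        tmp <- a[c_vec[i] + 1L]; a[c_vec[i] + 1L] <- a[i]; a[i] <- tmp
      }
      row <- row + 1L
      out[row, ] <- a
      c_vec[i] <- c_vec[i] + 1L
      i <- 1L
    } else {
      c_vec[i] <- 0L
      i <- i + 1L
    }
  }
  out
}

# exhaustive two-sided Spearman p oracle for tie-free vectors
oracle_exact_spearman_p <- function(x, y) {
  n <- length(x)
  rx <- rank(x); ry <- rank(y)
  obs <- stats::cor(rx, ry)
  perms <- heap_permutations(n)
  rhos <- apply(perms, 1L, function(pp) stats::cor(rx, ry[pp]))
  mean(abs(rhos) >= abs(obs) - 1e-12)
}

# hand-rolled trimmed-range oracle: explicit linear-interpolation
# percentiles (type-7 formula written out), drop strictly outside, span
oracle_trimmed_range <- function(v, trim = 10) {
  v <- sort(v[!is.na(v)])
  n <- length(v)
  if (n < 3L) return(NA_real_)
  interp_q <- function(p) {
    h <- (n - 1) * p + 1
    lo <- floor(h)
    v[lo] + (h - lo) * (v[min(lo + 1, n)] - v[lo])
  }
  p10 <- interp_q(trim / 100)
  p90 <- interp_q(1 - trim / 100)
  kept <- v[v >= p10 & v <= p90]
  if (!length(kept)) 0 else max(kept) - min(kept)
}

# tiny shared cohort, generated once per test run
.fixture_env <- new.env()
small_cohort <- function() {
  if (is.null(.fixture_env$cohort)) {
    .fixture_env$cohort <- generate_cohort(sim_config(
      n_probes = 1200, n_subjects = 19, frac_correlated = 0.15,
      rho_true = 0.7, frac_snp2 = 0.02, frac_snp3 = 0.02,
      n_bad_probes = 10, n_bad_samples = 0, seed = 101L))
  }
  .fixture_env$cohort
}

# full pipeline over the shared cohort, computed once (snpdetect dominates)
small_pipeline <- function() {
  if (is.null(.fixture_env$pipeline)) {
    .fixture_env$pipeline <- suppressMessages(
      run_pipeline(small_cohort(), adjust = TRUE, snp_seed = 9L))
  }
  .fixture_env$pipeline
}
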