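# Correlation machinery above the Spearman engine: across-subject Pearson,
# per-CpG records, summaries, per-subject correlations, MDS, ancestry PCs.

test_that("across-subject correlation hits the exact geometries", {
  beta <- toy_beta(100, 10, seed = 41)
  expect_equal(across_subject_correlation(beta, beta)$r, 1)
  flipped <- 1 - beta
  expect_equal(across_subject_correlation(beta, flipped)$r, -1)
  # direct covariance/variance oracle
  other <- toy_beta(100, 10, seed = 42)
  r <- across_subject_correlation(beta, other)$r
  mA <- rowMeans(beta); mB <- rowMeans(other)
  oracle <- sum((mA - mean(mA)) * (mB - mean(mB))) /
    sqrt(sum((mA - mean(mA))^2) * sum((mB - mean(mB))^2))
  expect_equal(r, oracle, tolerance = 1e-12)
  expect_error(across_subject_correlation(beta[1:1, , drop = FALSE], beta),
               "at least 2 probes")
  const <- beta; const[] <- 0.5
  expect_error(across_subject_correlation(const, beta), "zero-variance")
})

test_that("per-CpG records carry rho, routed p, q and reason codes", {
  A <- toy_beta(60, 19, seed = 43)
  B <- toy_beta(60, 19, seed = 44)
  rec <- within_subject_cpg_correlation(A, B, tissue_pair = "brain-blood")
  expect_equal(nrow(rec), 60)
  expect_true(all(abs(rec$rho) <= 1))
  expect_equal(rec$q, bh_adjust(rec$p))
  # fast path agrees with the per-probe scalar path (forced via NA)
  A2 <- A; A2[1, 1] <- NA
  rec2 <- within_subject_cpg_correlation(A2, B, tissue_pair = "brain-blood")
  i <- 5
  expect_equal(rec2$rho[i], rec$rho[i], tolerance = 1e-12)
  expect_equal(rec2$p[i], rec$p[i], tolerance = 1e-12)
  expect_equal(rec2$n_used[1], 18L)
  # constant probe gets a reason code, not a crash
  A3 <- A; A3[2, ] <- 0.4
  rec3 <- within_subject_cpg_correlation(A3, B)
  expect_true(is.na(rec3$rho[2]))
  expect_equal(rec3$reason_code[2], "zero_variance")
  # min_n guard
  A4 <- A; A4[3, 1:16] <- NA
  rec4 <- within_subject_cpg_correlation(A4, B)
  expect_equal(rec4$reason_code[3], "insufficient_n")
})

test_that("monotone perfect association gives |rho| = 1 records", {
  n <- 19
  A <- matrix(rep(seq(0.1, 0.9, length.out = n), each = 3), 3, n,
              dimnames = list(c("a", "b", "c"), sprintf("S%02d", 1:n)))
  B <- A^2                        # strictly monotone transform
  rec <- within_subject_cpg_correlation(A, B)
  expect_true(all(rec$rho == 1))
  recd <- within_subject_cpg_correlation(A, 1 - B)
  expect_true(all(recd$rho == -1))
})

test_that("summaries reconcile with direct filtering of the record table", {
  set.seed(45)
  rec <- data.frame(probe_id = sprintf("cg%03d", 1:400),
                    tissue_pair = "brain-blood",
                    rho = c(runif(150, 0.55, 0.95), runif(250, -0.4, 0.5)),
                    n_used = 19L, reason_code = "")
  rec$p <- vapply(rec$rho, spearman_p, numeric(1), n = 19, has_ties = TRUE)
  rec$q <- bh_adjust(rec$p)
  s <- summarize_correlations(rec)
  expect_equal(s$frac_nominal, mean(rec$p < 0.05))
  expect_equal(s$frac_moderate, mean(rec$rho > 0.5))
  expect_equal(s$rho_mean, mean(rec$rho))
  expect_equal(s$n_bh_significant, sum(rec$q < 0.05))
  expect_equal(s$min_rho_bh, min(abs(rec$rho[rec$q < 0.05])))
  # degenerate: everything perfectly correlated
  rec$rho <- 1; rec$p <- 0; rec$q <- 0
  s2 <- summarize_correlations(rec)
  expect_equal(s2$frac_nominal, 1)
  expect_equal(s2$frac_moderate, 1)
})

test_that("per-subject correlations match the direct formula", {
  probes <- sprintf("cg%02d", 1:5)
  subj <- c("S01", "S02")
  A <- matrix(c(0.1, 0.2, 0.3, 0.4, 0.5,
                0.5, 0.1, 0.4, 0.2, 0.3), 5, 2,
              dimnames = list(probes, subj))
  B <- matrix(c(0.2, 0.1, 0.5, 0.3, 0.6,
                0.6, 0.2, 0.3, 0.1, 0.5), 5, 2,
              dimnames = list(probes, subj))
  ps <- per_subject_correlation(list(brain = A, blood = B))
  expect_equal(ps$r[ps$subject_id == "S01"], cor(A[, 1], B[, 1]))
  expect_equal(ps$r[ps$subject_id == "S02"], cor(A[, 2], B[, 2]))
  # identical tissues: every subject r = 1, coupling undefined
  ps2 <- per_subject_correlation(list(brain = A, blood = A))
  expect_true(all(ps2$r == 1))
})

test_that("cross-pair coupling recovers a planted sign", {
  set.seed(46)
  n_sub <- 19
  # subjects with a shared "quality" factor driving both pair correlations
  quality <- runif(n_sub, 0, 1)
  probes <- 200
  brain <- matrix(runif(probes * n_sub), probes, n_sub)
  buccal <- blood <- brain
  for (s in seq_len(n_sub)) {
    w <- quality[s]
    buccal[, s] <- w * brain[, s] + (1 - w) * runif(probes)
    blood[, s] <- w * brain[, s] + (1 - w) * runif(probes)
  }
  dimnames(brain) <- dimnames(buccal) <- dimnames(blood) <-
    list(sprintf("cg%03d", 1:probes), sprintf("S%02d", 1:n_sub))
  ps <- per_subject_correlation(list(brain = brain, blood = blood,
                                     buccal = buccal))
  cp <- coupling_statistic(ps, "brain-buccal", "blood-buccal")
  expect_gt(cp$r, 0.5)
  expect_lt(cp$p, 0.01)
  # coupling on constant columns is undefined
  ps_const <- per_subject_correlation(list(brain = brain, blood = brain,
                                           buccal = brain))
  cp2 <- coupling_statistic(ps_const, "brain-blood", "brain-buccal")
  expect_true(is.na(cp2$r))
})

test_that("classical MDS reproduces exact low-rank geometry", {
  # samples on a line in beta space: 1-D embedding is exact
  set.seed(48)
  n <- 6
  t_line <- seq(0, 1, length.out = n)
  base <- runif(40, 0.2, 0.4)
  dirn <- runif(40, -0.15, 0.15)
  X <- outer(base, rep(1, n)) + outer(dirn, t_line)
  dimnames(X) <- list(sprintf("cg%02d", 1:40), sprintf("S%02d", 1:n))
  emb <- mds_embedding(list(brain = X), k = 1)
  d_emb <- as.matrix(dist(emb$dim1))
  d_true <- as.matrix(dist(t(X)))
  expect_equal(unname(d_emb), unname(d_true), tolerance = 1e-9)
  # duplicate samples coincide
  X2 <- X; X2[, 2] <- X2[, 1]
  emb2 <- mds_embedding(list(brain = X2), k = 1)
  expect_equal(emb2$dim1[1], emb2$dim1[2], tolerance = 1e-9)
})

test_that("MDS separates tissues in a planted two-cluster cohort", {
  co <- small_cohort()
  emb <- mds_embedding(co$tissues, k = 2)
  # brain must separate from the peripheral cloud on the leading axes
  brain <- emb[emb$tissue == "brain", ]
  periph <- emb[emb$tissue != "brain", ]
  gap <- sqrt((mean(brain$dim1) - mean(periph$dim1))^2 +
                (mean(brain$dim2) - mean(periph$dim2))^2)
  spread <- max(sd(brain$dim1), sd(brain$dim2))
  expect_gt(gap, spread)
})

test_that("ancestry PCs separate planted populations and degenerate cleanly", {
  set.seed(47)
  n_probes <- 150; n_sub <- 24
  probes <- sprintf("cg%04d", 1:n_probes)
  ann <- data.frame(probe_id = probes, snp_distance_bp = 0)
  pop <- rep(c(0, 1), each = n_sub / 2)
  freq_a <- runif(n_probes, 0.1, 0.4)
  freq_b <- pmin(0.9, freq_a + 0.4)     # shifted allele frequencies
  beta <- matrix(0, n_probes, n_sub,
                 dimnames = list(probes, sprintf("S%02d", 1:n_sub)))
  for (s in seq_len(n_sub)) {
    f <- if (pop[s] == 0) freq_a else freq_b
    g <- rbinom(n_probes, 2, f)
    beta[, s] <- c(0.05, 0.5, 0.95)[g + 1] + rnorm(n_probes, 0, 0.02)
  }
  beta[beta < 0] <- 0; beta[beta > 1] <- 1
  pcs <- ancestry_pcs(beta, ann, max_dist = 0, k = 3)
  gap <- abs(mean(pcs[pop == 0, 1]) - mean(pcs[pop == 1, 1]))
  spread <- max(sd(pcs[pop == 0, 1]), sd(pcs[pop == 1, 1]))
  expect_gt(gap, spread)
  # identical subjects give all-zero scores
  same <- beta; same[] <- rep(beta[, 1], n_sub)
  expect_equal(max(abs(ancestry_pcs(same, ann, k = 3))), 0)
  # full-rank SVD reconstructs the centered data
  k_full <- n_sub - 1
  sub <- beta[1:40, ]
  pcs_f <- ancestry_pcs(sub, ann, k = k_full)
  Xc <- sub - rowMeans(sub)
  sv <- svd(Xc)
  recon <- sv$u %*% diag(sv$d) %*% t(sv$v)
  expect_equal(recon, unname(Xc), tolerance = 1e-9)
  expect_error(ancestry_pcs(beta, ann, max_dist = -1), "no SNP-proximal")
})
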