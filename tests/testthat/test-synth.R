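# Synthetic cohort generator: configuration guards, determinism, planted
# structure recovery.

test_that("configuration invariants are enforced", {
  expect_s3_class(sim_config(), "sim_config")
  expect_error(sim_config(n_subjects = 2), "n_subjects")
  expect_error(sim_config(frac_correlated = 0.8, frac_snp2 = 0.2,
                          frac_snp3 = 0.1), "fractions")
  expect_error(sim_config(rho_true = 1.2), "rho_true")
  expect_error(sim_config(rho_true = 1, noise_sd = 0.05), "unattainable")
  expect_error(sim_config(allele_freq = 0), "allele_freq")
  expect_error(sim_config(tissues = c("brain", "liver")), "unknown tissues")
})

test_that("regeneration with the same seed is bit-identical", {
  cfg <- sim_config(n_probes = 300, seed = 55L)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$tissues, b$tissues)
  expect_identical(a$detp, b$detp)
  expect_identical(a$truth, b$truth)
})

test_that("emitted betas are in range with aligned subjects", {
  co <- small_cohort()
  ids <- colnames(co$tissues[[1]])
  for (tn in names(co$tissues)) {
    expect_identical(colnames(co$tissues[[tn]]), ids)
    expect_true(all(co$tissues[[tn]] >= 0 & co$tissues[[tn]] <= 1))
  }
})

test_that("no planted signal gives null cross-tissue correlation", {
  cfg <- sim_config(n_probes = 4000, frac_correlated = 0, frac_snp2 = 0,
                    frac_snp3 = 0, frac_cell = 0, seed = 77L)
  co <- generate_cohort(cfg)
  rec <- within_subject_cpg_correlation(co$tissues$brain, co$tissues$blood)
  expect_lt(abs(mean(rec$rho, na.rm = TRUE)), 0.02)
})

test_that("noiseless planted signal yields rho = 1 on every planted probe", {
  cfg <- sim_config(n_probes = 300, frac_correlated = 1, frac_snp2 = 0,
                    frac_snp3 = 0, frac_cell = 0, rho_true = 1,
                    noise_sd = 0, frac_detection_fail = 0, seed = 78L)
  co <- generate_cohort(cfg)
  rec <- within_subject_cpg_correlation(co$tissues$brain, co$tissues$saliva)
  expect_true(all(rec$rho == 1))
})

test_that("planted correlation is recovered near its target", {
  cfg <- sim_config(n_probes = 8000, frac_correlated = 0.15, rho_true = 0.7,
                    seed = 79L)
  co <- generate_cohort(cfg)
  rec <- within_subject_cpg_correlation(co$tissues$brain, co$tissues$blood)
  planted <- rec$rho[rec$probe_id %in% co$truth$correlated_probes]
  expect_gt(length(planted), 1000)
  expect_lt(abs(mean(planted) - 0.7), 0.1)
})

test_that("genotype probes cluster consistently across a subject's tissues", {
  co <- small_cohort()
  snp <- co$truth$snp_probes
  g <- co$truth$genotypes
  # Hardy-Weinberg occupancy: genotype counts follow Binomial(2, q)
  q <- co$config$allele_freq
  counts <- table(factor(g, 0:2)) / length(g)
  expect_equal(unname(as.vector(counts)),
               c((1 - q)^2, 2 * q * (1 - q), q^2), tolerance = 0.05)
  # same subject, same probe, different tissues -> same cluster side
  centers3 <- c(0.05, 0.5, 0.95)
  for (p3 in snp$probe_id[snp$k == 3][1:5]) {
    for (tn in names(co$tissues)) {
      v <- co$tissues[[tn]][p3, ]
      # every subject's value sits near its genotype's center, same
      # assignment in every tissue
      expect_true(all(abs(v - centers3[g[p3, ] + 1L]) < 0.2))
    }
  }
})

test_that("dominant 2-cluster occupancy matches the binomial expectation", {
  # allele_freq 0.5, 19 subjects: E[carrier cluster] = 19 * 0.75 = 14.25
  cfg <- sim_config(n_probes = 2000, frac_correlated = 0, frac_snp2 = 0.5,
                    frac_snp3 = 0, allele_freq = 0.5, seed = 80L)
  co <- generate_cohort(cfg)
  g <- co$truth$genotypes
  carrier <- rowSums(g < 2)    # AA and AB collapse under dominant coding
  expect_equal(mean(carrier), 14.25, tolerance = 0.02)
  expect_equal(mean(19 - carrier), 4.75, tolerance = 0.05)
})

test_that("detection failures land where designed", {
  # frac = 0 -> nothing fails
  cfg0 <- sim_config(n_probes = 200, frac_detection_fail = 0, seed = 81L)
  co0 <- generate_cohort(cfg0)
  expect_true(all(vapply(co0$detp, function(m) all(m <= 0.01), logical(1))))
  # one designated bad sample: the unique all-failing column
  cfg1 <- sim_config(n_probes = 200, frac_detection_fail = 0,
                     n_bad_samples = 1, seed = 82L)
  co1 <- generate_cohort(cfg1)
  col_fail <- colMeans(co1$detp$brain > 0.01)
  expect_equal(sum(col_fail == 1), 1)
  expect_true(all(col_fail[col_fail < 1] == 0))
  # 50 designated bad probes in 5000: exactly those rows fail heavily
  cfg2 <- sim_config(n_probes = 5000, frac_detection_fail = 0,
                     n_bad_probes = 50, seed = 83L)
  co2 <- generate_cohort(cfg2)
  row_fail <- rowMeans(co2$detp$brain > 0.01)
  expect_equal(sum(row_fail > 0.5), 50)
})

test_that("cohorts round-trip through the TSV directory format", {
  co <- generate_cohort(sim_config(n_probes = 80, seed = 84L))
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  back <- read_cohort(dir)
  expect_equal(back$tissues[order(names(back$tissues))],
               co$tissues[order(names(co$tissues))], tolerance = 1e-12)
  expect_equal(back$config$seed, 84L)
  expect_setequal(names(back$proportions), names(co$proportions))
})
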