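# Synthetic multi-tissue methylation cohorts with known ground truth.
#
# The generator emulates an EPIC-style cross-tissue study: ~19 subjects,
# four tissues (brain, blood, saliva, buccal), beta values in [0,1] with
# the bimodal marginal typical of array data, tissue-specific baselines so
# tissues separate in an MDS plot, a planted fraction of probes whose
# inter-individual deviations are shared between tissues at a controlled
# correlation, cell-type mixing driven by subject-varying proportions,
# genotype-driven 2-/3-cluster probes consistent across a subject's
# tissues, and sporadic detection failures.
#
# Betas are built on the logit scale (baseline + cell effect + shared
# subject deviation + tissue-specific noise, then inverse-logit) so values
# stay in range while rank correlation is controlled: for planted probes
# the shared deviation has variance rho/(1-rho) times the noise variance,
# giving latent Pearson correlation rho between any two tissues, and the
# inverse logit is monotone so Spearman is preserved.

TISSUES <- c("brain", "blood", "saliva", "buccal")

#' Build and validate a simulation configuration
#'
#' Defaults state the emulated world: 19 subjects, four tissues, 15% of
#' probes carrying cross-tissue correlated deviations at rho 0.7, 2% /
#' 1% of probes with 2- / 3-cluster genotype signal at allele frequency
#' 0.3, beta-scale noise sd 0.03, and 0.2% sporadic detection failures.
#'
#' @param n_subjects Number of subjects (>= 3).
#' @param n_probes Number of probes.
#' @param tissues Tissue labels (subset of brain/blood/saliva/buccal).
#' @param frac_correlated Fraction of probes with planted cross-tissue
#'   signal.
#' @param rho_true Target cross-tissue correlation for planted probes.
#' @param frac_snp2,frac_snp3 Fractions of 2-/3-cluster genotype probes.
#' @param frac_cell Fraction of probes whose methylation tracks cell
#'   composition (the confound the adjustment stage removes).
#' @param cell_sd Logit-scale sd of the per-probe cell-composition effect.
#' @param allele_freq Minor-allele frequency in (0, 1) for genotype draws.
#' @param noise_sd Beta-scale noise standard deviation (applied as 4x on
#'   the logit scale, the slope of the inverse logit at 0.5).
#' @param frac_detection_fail Background fraction of detection failures.
#' @param n_bad_probes,n_bad_samples Designated wholesale-failure probes /
#'   samples per tissue for the greedy-cut target (default 0).
#' @param seed Integer seed governing all randomness.
#' @return Validated config list of class "sim_config".
#' @export
sim_config <- function(n_subjects = 19, n_probes = 10000,
                       tissues = TISSUES, frac_correlated = 0.15,
                       rho_true = 0.7, frac_snp2 = 0.02, frac_snp3 = 0.01,
                       frac_cell = 0.10, cell_sd = 0.5,
                       allele_freq = 0.3, noise_sd = 0.03,
                       frac_detection_fail = 0.002,
                       n_bad_probes = 0, n_bad_samples = 0, seed = 1L) {
  cfg <- list(n_subjects = as.integer(n_subjects),
              n_probes = as.integer(n_probes),
              tissues = tissues, frac_correlated = frac_correlated,
              rho_true = rho_true, frac_snp2 = frac_snp2,
              frac_snp3 = frac_snp3, frac_cell = frac_cell,
              cell_sd = cell_sd, allele_freq = allele_freq,
              noise_sd = noise_sd,
              frac_detection_fail = frac_detection_fail,
              n_bad_probes = as.integer(n_bad_probes),
              n_bad_samples = as.integer(n_bad_samples),
              seed = as.integer(seed))
  if (cfg$n_subjects < 3L)
    stop("configuration error: n_subjects must be >= 3")
  if (!all(tissues %in% TISSUES))
    stop("configuration error: unknown tissues: ",
         paste(setdiff(tissues, TISSUES), collapse = ", "))
  fr <- c(frac_correlated, frac_snp2, frac_snp3, frac_cell)
  if (any(fr < 0) || sum(fr) > 1)
    stop("configuration error: probe-class fractions must be >= 0 and sum to <= 1")
  if (abs(rho_true) > 1)
    stop("configuration error: rho_true must lie in [-1, 1]")
  if (abs(rho_true) == 1 && noise_sd > 0)
    stop("configuration error: |rho_true| = 1 is unattainable with noise_sd > 0")
  if (allele_freq <= 0 || allele_freq >= 1)
    stop("configuration error: allele_freq must lie in (0, 1)")
  if (frac_detection_fail < 0 || frac_detection_fail > 1)
    stop("configuration error: frac_detection_fail must lie in [0, 1]")
  class(cfg) <- "sim_config"
  cfg
}

# deterministic per-stage sub-seed derived from the master seed
sub_seed <- function(seed, stage) {
  (as.integer(seed) * 101L + stage * 7919L) %% .Machine$integer.max
}

#' Generate a multi-tissue synthetic cohort with ground truth
#'
#' Produces one beta matrix per tissue (identical subject ids, identical
#' probe universe), per-tissue cell-proportion tables, detection p-value
#' matrices, probe annotation, and a truth object recording which probes
#' carry planted cross-tissue signal, which are genotype-driven (with the
#' subject genotype assignment), and which are expected to be variable.
#'
#' @param config A [sim_config()].
#' @return List with elements `tissues` (named list of beta matrices),
#'   `proportions` (named list of data.frames), `detp` (named list of
#'   matrices), `annotation` (data.frame), `truth` (list), `config`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_subjects
  p <- config$n_probes
  tissues <- config$tissues
  subjects <- sprintf("S%02d", seq_len(n))
  probes <- sprintf("cg%08d", seq_len(p))

  # probe class assignment (disjoint by construction)
  n_corr <- round(config$frac_correlated * p)
  n_snp2 <- round(config$frac_snp2 * p)
  n_snp3 <- round(config$frac_snp3 * p)
  n_cell <- round(config$frac_cell * p)
  set.seed(sub_seed(config$seed, 1L))
  cls <- sample(rep(c("corr", "snp2", "snp3", "cell", "null"),
                    c(n_corr, n_snp2, n_snp3, n_cell,
                      p - n_corr - n_snp2 - n_snp3 - n_cell)))
  idx_corr <- which(cls == "corr")
  idx_snp2 <- which(cls == "snp2")
  idx_snp3 <- which(cls == "snp3")
  idx_cell <- which(cls == "cell")

  # bimodal baseline: each probe is hypo- or hyper-methylated; per-tissue
  # logit offsets make tissue baselines differ (brain most distinct)
  set.seed(sub_seed(config$seed, 2L))
  hyper <- stats::runif(p) < 0.45
  base_beta <- ifelse(hyper, stats::rbeta(p, 8, 2), stats::rbeta(p, 2, 8))
  base_logit <- logit(pmin(0.995, pmax(0.005, base_beta)))
  tissue_shift <- list(brain = 1.2, blood = -0.4, saliva = -0.1, buccal = 0.2)
  # probe-specific tissue offsets so separation is genome-wide, not a
  # constant shift (constant shifts vanish under per-probe ranking anyway)
  probe_tissue_off <- lapply(tissues, function(tn)
    stats::rnorm(p, 0, 0.4) + tissue_shift[[tn]] * stats::rnorm(p, 1, 0.3))
  names(probe_tissue_off) <- tissues

  # cell proportions, subject-varying
  set.seed(sub_seed(config$seed, 3L))
  proportions <- list()
  for (tn in tissues) {
    proportions[[tn]] <- switch(tn,
      brain = {
        neuron <- stats::rbeta(n, 8, 12)          # ~0.4 +- 0.1
        data.frame(subject_id = subjects, neuron = neuron,
                   non_neuron = 1 - neuron, stringsAsFactors = FALSE)
      },
      blood = {
        alpha <- c(B = 6, NK = 6, CD4T = 14, CD8T = 10, Mono = 8, Neutro = 56)
        g <- matrix(stats::rgamma(n * 6, shape = rep(alpha, each = n)), n, 6)
        pr <- g / rowSums(g)
        colnames(pr) <- names(alpha)
        data.frame(subject_id = subjects, pr, stringsAsFactors = FALSE)
      },
      {
        epi <- if (tn == "saliva") stats::rbeta(n, 10, 6) else
          stats::rbeta(n, 18, 2)                   # buccal mostly epithelial
        data.frame(subject_id = subjects, epithelial = epi,
                   immune = 1 - epi, stringsAsFactors = FALSE)
      })
  }

  # cell-composition effect: a subset of probes methylate differently per
  # cell type, so bulk beta tracks the mixing proportion
  set.seed(sub_seed(config$seed, 4L))
  cell_sens <- numeric(p)
  cell_sens[idx_cell] <- stats::rnorm(length(idx_cell), 0, config$cell_sd)
  lead_prop <- lapply(tissues, function(tn) {
    pr <- proportions[[tn]]
    v <- switch(tn, brain = pr$neuron, blood = pr$CD4T + pr$CD8T,
                pr$epithelial)
    as.numeric(scale(v))
  })
  names(lead_prop) <- tissues

  # planted cross-tissue signal: shared per-subject-per-probe deviation
  sigma <- 4 * config$noise_sd            # logit-scale noise sd
  rho <- config$rho_true
  tau <- if (abs(rho) == 1 || sigma == 0) {
    if (rho == 0) 0 else 0.8              # pure shared signal, no noise
  } else {
    sigma * sqrt(abs(rho) / (1 - abs(rho)))
  }
  set.seed(sub_seed(config$seed, 5L))
  shared <- matrix(0, p, n)
  if (length(idx_corr) && tau > 0)
    shared[idx_corr, ] <- matrix(stats::rnorm(length(idx_corr) * n, 0, tau),
                                 length(idx_corr), n)

  # genotypes: subject-level, Hardy-Weinberg at allele_freq; additive map
  # AA/AB/BB -> 0.05/0.5/0.95 for k=3; dominant collapse (AA,AB -> 0.05,
  # BB -> 0.95) for k=2
  set.seed(sub_seed(config$seed, 6L))
  q <- config$allele_freq
  geno <- matrix(0L, length(idx_snp2) + length(idx_snp3), n)
  if (nrow(geno))
    geno[] <- stats::rbinom(length(geno), 2L, q)
  rownames(geno) <- probes[c(idx_snp2, idx_snp3)]
  colnames(geno) <- subjects
  snp_centers3 <- c(0.05, 0.5, 0.95)

  tissue_mats <- list()
  for (ti in seq_along(tissues)) {
    tn <- tissues[ti]
    set.seed(sub_seed(config$seed, 10L + ti))
    noise <- matrix(stats::rnorm(p * n, 0, sigma), p, n)
    # negative rho target: peripheral tissues take the mirrored deviation
    shared_sign <- if (rho < 0 && tn != "brain") -1 else 1
    L <- base_logit + probe_tissue_off[[tn]] +
      outer(cell_sens, lead_prop[[tn]]) + shared_sign * shared + noise
    beta <- inv_logit(L)
    # genotype probes overwrite the baseline: cluster center + beta noise
    if (length(idx_snp3)) {
      g3 <- geno[probes[idx_snp3], , drop = FALSE]
      beta[idx_snp3, ] <- snp_centers3[g3 + 1L] +
        matrix(stats::rnorm(length(g3), 0, max(config$noise_sd, 0.01)),
               nrow(g3), n)
    }
    if (length(idx_snp2)) {
      g2 <- geno[probes[idx_snp2], , drop = FALSE]
      dominant <- ifelse(g2 == 2L, 0.95, 0.05)
      beta[idx_snp2, ] <- dominant +
        matrix(stats::rnorm(length(dominant), 0, max(config$noise_sd, 0.01)),
               nrow(dominant), n)
    }
    beta <- clip01(beta)
    dimnames(beta) <- list(probes, subjects)
    tissue_mats[[tn]] <- beta
  }

  # probe annotation. The planted genotype probes emulate SNPs missing from
  # the annotation (the reason a data-driven detector exists), so they get
  # NA distance; filter fodder comes from null probes: ~2% carry a SNP
  # distance of 0-10 bp and ~1% are non-CpG context probes.
  set.seed(sub_seed(config$seed, 20L))
  snp_distance <- rep(NA_real_, p)
  idx_null <- which(cls == "null")
  n_prox <- round(0.02 * p)
  if (n_prox > 0 && length(idx_null) >= n_prox)
    snp_distance[sample(idx_null, n_prox)] <- sample(0:10, n_prox, TRUE)
  context <- rep("cpg", p)
  n_ctx <- round(0.01 * p)
  if (n_ctx > 0 && length(idx_null) >= n_ctx)
    context[sample(idx_null, n_ctx)] <- "non_cpg"
  annotation <- data.frame(probe_id = probes,
                           chrom = sample(paste0("chr", 1:22), p, TRUE),
                           pos = sample.int(2^28, p, TRUE),
                           snp_distance_bp = snp_distance,
                           context = context, stringsAsFactors = FALSE)

  detp <- inject_detection_failures(tissue_mats, config)

  truth <- list(
    correlated_probes = probes[idx_corr],
    rho_true = rho,
    snp_probes = data.frame(
      probe_id = probes[c(idx_snp2, idx_snp3)],
      k = rep(c(2L, 3L), c(length(idx_snp2), length(idx_snp3))),
      stringsAsFactors = FALSE),
    genotypes = geno,
    cell_probes = probes[idx_cell],
    variable_probes_expected = probes[sort(c(idx_corr, idx_snp2, idx_snp3,
                                             idx_cell))],
    cell_proportions_true = proportions)

  list(tissues = tissue_mats, proportions = proportions, detp = detp,
       annotation = annotation, truth = truth, config = config)
}

#' Detection p-value matrices with planted failures
#'
#' Background entries fail (p drawn uniform above 0.01) at rate
#' `frac_detection_fail`; `n_bad_probes` designated probes fail in 80% of
#' samples and `n_bad_samples` designated samples fail everywhere, giving
#' the greedy-cut a recoverable target. Passing entries draw uniform on
#' \[0, 0.01\].
#'
#' @param tissue_mats Named list of beta matrices.
#' @param config A [sim_config()].
#' @return Named list of detection p matrices aligned to the beta matrices.
#' @export
inject_detection_failures <- function(tissue_mats, config) {
  set.seed(sub_seed(config$seed, 30L))
  out <- list()
  for (tn in names(tissue_mats)) {
    m <- tissue_mats[[tn]]
    pm <- matrix(stats::runif(length(m), 0, 0.01), nrow(m), ncol(m),
                 dimnames = dimnames(m))
    if (config$frac_detection_fail > 0) {
      fail <- stats::runif(length(m)) < config$frac_detection_fail
      pm[fail] <- stats::runif(sum(fail), 0.011, 1)
    }
    if (config$n_bad_probes > 0) {
      bad_p <- seq_len(min(config$n_bad_probes, nrow(m)))
      sel <- matrix(stats::runif(length(bad_p) * ncol(m)) < 0.8,
                    length(bad_p), ncol(m))
      pm[bad_p, ][sel] <- stats::runif(sum(sel), 0.011, 1)
    }
    if (config$n_bad_samples > 0) {
      bad_s <- ncol(m) - seq_len(min(config$n_bad_samples, ncol(m))) + 1L
      pm[, bad_s] <- stats::runif(nrow(m) * length(bad_s), 0.011, 1)
    }
    out[[tn]] <- pm
  }
  out
}

#' Write a generated cohort to a directory as TSV
#'
#' One beta matrix and one detection p matrix per tissue, cell proportions
#' per tissue, probe annotation, truth sidecars, and the configuration as
#' YAML.
#'
#' @param cohort Output of [generate_cohort()].
#' @param dir Target directory (created if absent).
#' @return Invisibly, the directory.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (tn in names(cohort$tissues)) {
    write_beta_tsv(cohort$tissues[[tn]], file.path(dir, paste0("beta_", tn, ".tsv")))
    write_beta_tsv(cohort$detp[[tn]], file.path(dir, paste0("detp_", tn, ".tsv")))
    write_table_tsv(cohort$proportions[[tn]],
                    file.path(dir, paste0("proportions_", tn, ".tsv")))
  }
  write_table_tsv(cohort$annotation, file.path(dir, "annotation.tsv"))
  write_table_tsv(data.frame(probe_id = cohort$truth$correlated_probes),
                  file.path(dir, "truth_correlated.tsv"))
  write_table_tsv(cohort$truth$snp_probes, file.path(dir, "truth_snp.tsv"))
  yaml::write_yaml(unclass(cohort$config), file.path(dir, "config.yaml"))
  invisible(dir)
}
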