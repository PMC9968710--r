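# Cross-tissue correlation machinery: across-subject Pearson summaries,
# within-subject per-CpG Spearman records, per-subject correlations, MDS,
# and methylation-derived ancestry PCs.

#' Across-subject correlation between two tissues
#'
#' Computes per-probe mean beta across subjects in each tissue (pairwise
#' complete over subjects), then the Pearson correlation of the two mean
#' vectors over the common probe set. This is the "global" view of
#' concordance: one number per tissue pair, driven by probes' average
#' methylation levels rather than inter-individual variation.
#'
#' @param betaA,betaB Beta matrices (probes x subjects) for the two tissues.
#' @param probe_set Optional probe ids to restrict to; default all shared.
#' @return List with `tissue_pair` left NA for the caller, `r` and `n_probes`.
#' @export
across_subject_correlation <- function(betaA, betaB, probe_set = NULL) {
  al <- align_matrices(betaA, betaB)
  if (!is.null(probe_set)) {
    keep <- intersect(rownames(al$A), probe_set)
    al$A <- al$A[keep, , drop = FALSE]
    al$B <- al$B[keep, , drop = FALSE]
  }
  if (nrow(al$A) < 2L) stop("need at least 2 probes in common")
  mA <- rowMeans(al$A, na.rm = TRUE)
  mB <- rowMeans(al$B, na.rm = TRUE)
  if (stats::sd(mA) == 0 || stats::sd(mB) == 0)
    stop("zero-variance mean methylation vector; correlation undefined")
  list(r = stats::cor(mA, mB), n_probes = nrow(al$A))
}

#' Within-subject per-CpG Spearman correlation between two tissues
#'
#' For every probe, the Spearman correlation across subjects between the two
#' tissues' beta values, with a two-sided p (exact permutation null for
#' n <= 8 without ties, t approximation otherwise) and BH q-values computed
#' over the defined records. Probes with fewer than `min_n` complete pairs
#' or zero variance in either tissue are emitted with NA rho and a reason
#' code rather than dropped.
#'
#' @param betaA,betaB Beta matrices with aligned subject ids.
#' @param min_n Minimum complete pairs per probe (default 5).
#' @param tissue_pair Label stored in the output (e.g. "brain-blood").
#' @return data.frame: probe_id, tissue_pair, rho, p, q, n_used, reason_code.
#' @export
within_subject_cpg_correlation <- function(betaA, betaB, min_n = 5,
                                           tissue_pair = "A-B") {
  al <- align_matrices(betaA, betaB)
  A <- al$A; B <- al$B
  n_probes <- nrow(A)
  n_sub <- ncol(A)
  rho <- rep(NA_real_, n_probes)
  p <- rep(NA_real_, n_probes)
  n_used <- integer(n_probes)
  reason <- rep("", n_probes)

  complete <- !(anyNA(A) || anyNA(B))
  if (complete && n_sub > 8L) {
    # fast vectorized path: rank rows once, Pearson on standardized ranks
    rA <- t(apply(A, 1L, rank, ties.method = "average"))
    rB <- t(apply(B, 1L, rank, ties.method = "average"))
    sdA <- apply(rA, 1L, stats::sd)
    sdB <- apply(rB, 1L, stats::sd)
    ok <- sdA > 0 & sdB > 0
    zA <- (rA - rowMeans(rA)) / sdA
    zB <- (rB - rowMeans(rB)) / sdB
    rho[ok] <- rowSums(zA[ok, , drop = FALSE] * zB[ok, , drop = FALSE]) /
      (n_sub - 1)
    rho <- pmin(1, pmax(-1, rho))
    n_used[] <- n_sub
    p[ok] <- vapply(rho[ok], spearman_p_t, numeric(1), n = n_sub)
    reason[!ok] <- "zero_variance"
  } else {
    for (i in seq_len(n_probes)) {
      x <- A[i, ]; y <- B[i, ]
      keep <- stats::complete.cases(x, y)
      n_used[i] <- sum(keep)
      if (n_used[i] < min_n) {
        reason[i] <- "insufficient_n"
        next
      }
      x <- x[keep]; y <- y[keep]
      r <- spearman_rho(x, y)
      if (is.na(r)) {
        reason[i] <- "zero_variance"
        next
      }
      ties <- anyDuplicated(x) > 0L || anyDuplicated(y) > 0L
      rho[i] <- r
      p[i] <- spearman_p(r, n_used[i], has_ties = ties)
    }
  }

  data.frame(probe_id = rownames(A), tissue_pair = tissue_pair,
             rho = rho, p = p, q = bh_adjust(p), n_used = n_used,
             reason_code = reason, stringsAsFactors = FALSE)
}

#' Summarize a per-CpG correlation table
#'
#' Fractions are computed over probes with defined rho. `frac_moderate`
#' uses signed rho > 0.5; the negative tail (rho < -0.5) is reported
#' separately as `frac_moderate_neg`.
#'
#' @param records Output of [within_subject_cpg_correlation()].
#' @param q_threshold BH significance threshold (default 0.05).
#' @param alpha Nominal p threshold (default 0.05).
#' @return List of summary statistics for the tissue pair.
#' @export
summarize_correlations <- function(records, q_threshold = 0.05, alpha = 0.05) {
  stopifnot(nrow(records) > 0L)
  def <- records[!is.na(records$rho), , drop = FALSE]
  n_def <- nrow(def)
  bh_sig <- !is.na(def$q) & def$q < q_threshold
  list(
    tissue_pair = records$tissue_pair[1],
    n_probes = nrow(records),
    n_defined = n_def,
    frac_nominal = mean(def$p < alpha, na.rm = TRUE),
    frac_moderate = mean(def$rho > 0.5),
    frac_moderate_neg = mean(def$rho < -0.5),
    rho_mean = mean(def$rho),
    rho_median = stats::median(def$rho),
    n_bh_significant = sum(bh_sig),
    min_rho_bh = if (any(bh_sig)) min(abs(def$rho[bh_sig])) else NA_real_
  )
}

#' Per-subject cross-tissue correlations and cross-pair coupling
#'
#' For each subject, the Pearson correlation between that subject's beta
#' vectors in two tissues over a probe set — one row per subject per tissue
#' pair. Also returns the coupling statistic between two per-subject
#' correlation columns (e.g. whether subjects whose buccal tracks their
#' brain also have buccal tracking their blood): Pearson over subjects
#' between the two columns.
#'
#' @param tissues Named list of beta matrices sharing subject ids.
#' @param probe_set Optional probe ids (default: probes shared by all).
#' @param pairs Character vector of "tissueA-tissueB" pairs; default all.
#' @return List: `per_subject` data.frame (subject_id, tissue_pair, r) and
#'   `coupling(pair1, pair2)` available via [coupling_statistic()].
#' @export
per_subject_correlation <- function(tissues, probe_set = NULL, pairs = NULL) {
  stopifnot(is.list(tissues), length(tissues) >= 2L, !is.null(names(tissues)))
  probes <- Reduce(intersect, lapply(tissues, rownames))
  if (!is.null(probe_set)) probes <- intersect(probes, probe_set)
  if (length(probes) < 2L) stop("need at least 2 probes shared by all tissues")
  if (is.null(pairs)) {
    cmb <- utils::combn(names(tissues), 2L)
    pairs <- paste(cmb[1L, ], cmb[2L, ], sep = "-")
  }
  out <- list()
  for (pr in pairs) {
    tt <- strsplit(pr, "-", fixed = TRUE)[[1L]]
    A <- tissues[[tt[1L]]]; B <- tissues[[tt[2L]]]
    subjects <- intersect(colnames(A), colnames(B))
    skipped <- setdiff(union(colnames(A), colnames(B)), subjects)
    if (length(skipped))
      message("pair ", pr, ": skipping subjects without both tissues: ",
              paste(skipped, collapse = ", "))
    r <- vapply(subjects, function(s) {
      x <- A[probes, s]; y <- B[probes, s]
      ok <- stats::complete.cases(x, y)
      if (sum(ok) < 2L || stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0)
        return(NA_real_)
      stats::cor(x[ok], y[ok])
    }, numeric(1))
    out[[pr]] <- data.frame(subject_id = subjects, tissue_pair = pr, r = r,
                            stringsAsFactors = FALSE)
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Coupling between two per-subject correlation columns
#'
#' Pearson correlation, over subjects, between the per-subject r of one
#' tissue pair and that of another, with a two-sided p from the Pearson
#' t-test.
#'
#' @param per_subject Output of [per_subject_correlation()].
#' @param pair1,pair2 Tissue-pair labels present in the table.
#' @return List with `r`, `p`, `n`; `r` is NA if either column is constant.
#' @export
coupling_statistic <- function(per_subject, pair1, pair2) {
  a <- per_subject[per_subject$tissue_pair == pair1, ]
  b <- per_subject[per_subject$tissue_pair == pair2, ]
  m <- merge(a, b, by = "subject_id")
  ok <- stats::complete.cases(m$r.x, m$r.y)
  n <- sum(ok)
  # sd tolerance: cor() of identical vectors can return 1 - 1ulp, leaving
  # a "constant" column with sd ~ 1e-16
  if (n < 3L || stats::sd(m$r.x[ok]) < 1e-12 || stats::sd(m$r.y[ok]) < 1e-12)
    return(list(r = NA_real_, p = NA_real_, n = n))
  r <- stats::cor(m$r.x[ok], m$r.y[ok])
  tval <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * stats::pt(-abs(tval), df = n - 2), n = n)
}

#' Classical (Torgerson) MDS of samples across tissues
#'
#' Stacks all samples (columns) from all tissues, restricts to
#' complete-case probes, and embeds the samples by classical metric MDS of
#' the Euclidean distance matrix: double-centered squared distances, top-k
#' eigenvectors scaled by the square roots of their eigenvalues.
#' Deterministic up to sign. Used as the sample-mixup QC view: tissues
#' should form separate clusters.
#'
#' @param tissues Named list of beta matrices over a common probe universe.
#' @param k Number of dimensions (default 2).
#' @return data.frame: sample_id, tissue, subject_id, dim1..dimk.
#' @export
mds_embedding <- function(tissues, k = 2) {
  stopifnot(is.list(tissues), length(tissues) >= 1L)
  probes <- Reduce(intersect, lapply(tissues, rownames))
  cols <- lapply(names(tissues), function(tn) {
    m <- tissues[[tn]][probes, , drop = FALSE]
    colnames(m) <- paste(tn, colnames(m), sep = ":")
    m
  })
  X <- do.call(cbind, cols)
  X <- X[stats::complete.cases(X), , drop = FALSE]
  if (ncol(X) < 3L) stop("need at least 3 samples")
  d <- stats::dist(t(X))
  fit <- stats::cmdscale(d, k = k, eig = TRUE)
  got <- ncol(fit$points)
  if (got < k)
    warning("only ", got, " positive-eigenvalue dimensions available")
  pts <- fit$points
  ids <- do.call(rbind, strsplit(rownames(pts), ":", fixed = TRUE))
  out <- data.frame(sample_id = rownames(pts), tissue = ids[, 1L],
                    subject_id = ids[, 2L], stringsAsFactors = FALSE)
  for (j in seq_len(ncol(pts))) out[[paste0("dim", j)]] <- pts[, j]
  out
}

#' Methylation-derived ancestry principal components
#'
#' Restricts a beta matrix to probes overlapping a SNP within `max_dist`
#' base pairs (default 0: probes sitting directly on a polymorphism, whose
#' beta values behave like genotypes), centers each probe across subjects,
#' and returns the top-k subject scores from the SVD. Population structure
#' dominates these probes, so the leading PCs separate ancestral groups.
#'
#' @param beta Beta matrix (probes x subjects), typically blood.
#' @param annotation data.frame with probe_id and snp_distance_bp.
#' @param max_dist Maximum SNP distance in bp (default 0).
#' @param k Number of PCs (default 3).
#' @return Matrix subjects x k of PC scores; deterministic up to sign.
#' @export
ancestry_pcs <- function(beta, annotation, max_dist = 0, k = 3) {
  if (ncol(beta) < k + 1L) stop("need at least k + 1 subjects")
  snp_probes <- annotation$probe_id[!is.na(annotation$snp_distance_bp) &
                                      annotation$snp_distance_bp <= max_dist]
  keep <- intersect(rownames(beta), snp_probes)
  if (length(keep) == 0L) stop("no SNP-proximal probes within ", max_dist, " bp")
  X <- beta[keep, , drop = FALSE]
  X <- X[stats::complete.cases(X), , drop = FALSE]
  Xc <- X - rowMeans(X)
  sv <- svd(Xc, nu = 0, nv = k)
  scores <- sv$v * rep(sv$d[seq_len(k)], each = ncol(X))
  rownames(scores) <- colnames(beta)
  colnames(scores) <- paste0("PC", seq_len(k))
  scores
}
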