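# Cell-composition adjustment. Bulk tissue methylation is a mixture over
# cell types whose proportions vary between subjects; regressing each
# probe's betas on the composition covariates and keeping the residual
# removes that source of spurious cross-tissue concordance. Covariates per
# tissue follow the fixed rules: brain uses the neuron proportion only;
# blood uses five of the six immune fractions (B, NK, CD4T, CD8T, Mono —
# Neutro dropped because the six sum to one and would be collinear);
# saliva and buccal use the epithelial fraction only.

#' Covariate columns used for a tissue's composition adjustment
#' @param tissue One of "brain", "blood", "saliva", "buccal".
#' @return Character vector of cell-type column names.
#' @export
tissue_covariates <- function(tissue) {
  switch(tissue,
         brain = "neuron",
         blood = c("B", "NK", "CD4T", "CD8T", "Mono"),
         saliva = "epithelial",
         buccal = "epithelial",
         stop("unknown tissue: ", tissue))
}

#' Residualize beta values on cell-composition covariates
#'
#' Per probe, fits ordinary least squares of beta on the covariates across
#' subjects and returns residual + probe mean, clipped to \[0, 1\]. Adding
#' the mean back keeps values interpretable on the beta scale; downstream
#' correlation is rank-based so the shift is inert. Probes with missing
#' values are fitted on their complete subjects, with a minimum-n guard:
#' below `min_n` complete subjects the probe passes through unadjusted and
#' is flagged.
#'
#' @param beta Beta matrix (probes x subjects).
#' @param props data.frame of per-subject proportions; rownames or a
#'   `subject_id` column must match `colnames(beta)`.
#' @param tissue Tissue label selecting the covariate rule, or NULL to use
#'   `covariates` as given.
#' @param covariates Character vector of proportion columns to adjust for;
#'   default from [tissue_covariates()].
#' @param min_n Minimum complete subjects to fit a probe (default 5).
#' @return List: `beta` (adjusted matrix), `covariates`, `unadjusted_probes`
#'   (ids passed through by the min-n guard), `adjusted = TRUE`.
#' @export
residualize <- function(beta, props, tissue = NULL, covariates = NULL,
                        min_n = 5) {
  if (is.null(covariates)) {
    if (is.null(tissue)) stop("supply either tissue or covariates")
    covariates <- tissue_covariates(tissue)
  }
  if ("subject_id" %in% names(props)) {
    rownames(props) <- props$subject_id
  }
  missing_cov <- setdiff(covariates, names(props))
  if (length(missing_cov))
    stop("proportion table lacks columns: ", paste(missing_cov, collapse = ", "))
  subjects <- colnames(beta)
  if (!all(subjects %in% rownames(props)))
    stop("proportion table lacks subjects: ",
         paste(setdiff(subjects, rownames(props)), collapse = ", "))
  Xc <- as.matrix(props[subjects, covariates, drop = FALSE])
  storage.mode(Xc) <- "double"
  X <- cbind(`(Intercept)` = 1, Xc)

  # drop covariates constant across subjects (the intercept absorbs them)
  const <- apply(Xc, 2L, function(v) stats::sd(v) == 0)
  if (any(const)) X <- X[, c(TRUE, !const), drop = FALSE]
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[seq.int(qrX$rank + 1L, ncol(X))]]
    stop("covariate matrix is rank deficient (multicollinearity); ",
         "collinear columns: ", paste(dropped, collapse = ", "))
  }

  out <- beta
  unadj <- character(0)
  if (!anyNA(beta)) {
    H <- X %*% solve(crossprod(X), t(X))   # hat matrix, n x n
    fitted <- beta %*% H
    out <- clip01(beta - fitted + rowMeans(beta))
  } else {
    for (i in seq_len(nrow(beta))) {
      y <- beta[i, ]
      ok <- !is.na(y)
      if (sum(ok) < min_n) {
        unadj <- c(unadj, rownames(beta)[i])
        next
      }
      fit <- stats::lm.fit(X[ok, , drop = FALSE], y[ok])
      out[i, ok] <- fit$residuals + mean(y[ok])
    }
    out <- clip01(out)
  }
  list(beta = out, covariates = covariates, unadjusted_probes = unadj,
       adjusted = TRUE)
}

#' Validate a cell-proportion table for a tissue
#'
#' Checks that each subject's proportions sum to 1 within tolerance and
#' that the tissue's expected cell types are present (blood: B, NK, CD4T,
#' CD8T, Mono, Neutro; brain: neuron, non_neuron; saliva/buccal:
#' epithelial, immune).
#'
#' @param props data.frame with subject_id and one column per cell type.
#' @param tissue Tissue label.
#' @param tol Sum-to-one tolerance (default 1e-6).
#' @return Invisibly TRUE; errors otherwise.
#' @export
validate_proportions <- function(props, tissue, tol = 1e-6) {
  expected <- switch(tissue,
                     blood = c("B", "NK", "CD4T", "CD8T", "Mono", "Neutro"),
                     brain = c("neuron", "non_neuron"),
                     saliva = c("epithelial", "immune"),
                     buccal = c("epithelial", "immune"),
                     stop("unknown tissue: ", tissue))
  missing <- setdiff(expected, names(props))
  if (length(missing))
    stop(tissue, " proportions lack cell types: ",
         paste(missing, collapse = ", "))
  sums <- rowSums(props[, expected, drop = FALSE])
  if (any(abs(sums - 1) > tol))
    stop(tissue, " proportions do not sum to 1 for ",
         sum(abs(sums - 1) > tol), " subject(s)")
  invisible(TRUE)
}
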