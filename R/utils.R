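# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

# preserves dim/dimnames (pmin/pmax would take attributes from the scalar)
clip01 <- function(x) {
  x[which(x < 0)] <- 0
  x[which(x > 1)] <- 1
  x
}

logit <- function(p) log(p / (1 - p))

inv_logit <- function(x) 1 / (1 + exp(-x))

# TSV dialect used by every stage: tab-separated, '.' decimal, "NA" missing,
# header mandatory. Matrices carry probe ids in the first column.

#' Write a probe-by-subject matrix as TSV
#'
#' First column `probe_id`, one column per subject. This dialect is shared by
#' beta matrices and detection p-value matrices so stages round-trip exactly.
#'
#' @param mat Numeric matrix with probe-id rownames and subject-id colnames.
#' @param path Output file path.
#' @export
write_beta_tsv <- function(mat, path) {
  stopifnot(is.matrix(mat), !is.null(rownames(mat)), !is.null(colnames(mat)))
  df <- data.frame(probe_id = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA", fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a probe-by-subject matrix from TSV
#'
#' @param path File written by [write_beta_tsv()].
#' @return Numeric matrix, probe ids as rownames, subject ids as colnames.
#' @export
read_beta_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  mat <- as.matrix(df[, -1, drop = FALSE])
  rownames(mat) <- df[[1]]
  storage.mode(mat) <- "double"
  mat
}

write_table_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA", fileEncoding = "UTF-8")
  invisible(path)
}

read_table_tsv <- function(path) {
  utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
}

# Aligns two beta matrices on shared probes and subjects, preserving order of A.
align_matrices <- function(betaA, betaB) {
  probes <- intersect(rownames(betaA), rownames(betaB))
  subjects <- intersect(colnames(betaA), colnames(betaB))
  if (length(probes) == 0L) stop("no probes in common between matrices")
  if (length(subjects) == 0L) stop("no subjects in common between matrices")
  list(A = betaA[probes, subjects, drop = FALSE],
       B = betaB[probes, subjects, drop = FALSE])
}
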