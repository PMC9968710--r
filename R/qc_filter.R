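# Probe quality filters applied before any correlation analysis:
#   1. probes overlapping a SNP within 5 bp of the interrogated site,
#   2. unreliable measurements by detection p-value, removed iteratively
#      by a greedy-cut over probes and samples,
#   3. context-specific (non-CpG) probes.

#' Probes within a given distance of a SNP
#'
#' "Within" is inclusive: a probe at exactly `max_dist` bp is removed. An
#' NA distance means no SNP within the annotation window, so the probe is
#' kept. Probes absent from the annotation table entirely are a metadata
#' gap: [apply_probe_filters()] retains them with a warning — filters fail
#' open on missing metadata, closed only on measured unreliability.
#'
#' @param annotation data.frame with columns probe_id, snp_distance_bp
#'   (NA = no SNP nearby).
#' @param max_dist Maximum distance in bp (default 5).
#' @return Character vector of probe ids to remove.
#' @export
filter_snp_proximity <- function(annotation, max_dist = 5) {
  if (!is.numeric(max_dist) || max_dist < 0) stop("max_dist must be >= 0")
  if (nrow(annotation) == 0L) return(character(0))
  annotation$probe_id[!is.na(annotation$snp_distance_bp) &
                        annotation$snp_distance_bp <= max_dist]
}

#' Context-specific (non-CpG) probes
#'
#' @param annotation data.frame with columns probe_id, context
#'   ("cpg" or "non_cpg").
#' @return Character vector of probe ids with context other than "cpg".
#' @export
filter_context <- function(annotation) {
  if (nrow(annotation) == 0L) return(character(0))
  if (anyNA(annotation$context)) stop("context must be populated for all probes")
  annotation$probe_id[annotation$context != "cpg"]
}

#' Greedy-cut removal of unreliable probes and samples
#'
#' Iteratively removes the probe (row) or sample (column) with the highest
#' fraction of detection p-values above `threshold` until no entry exceeds
#' it. Ties break toward removing a probe rather than a sample (samples are
#' precious at n = 19), and among probes toward the lexicographically
#' smallest id, so the procedure is fully deterministic.
#'
#' @param detp Detection p-value matrix (probes x samples) with dimnames.
#' @param threshold Detection p threshold in (0, 1); default 0.01.
#' @return List: `removed_probes`, `removed_samples`, `removal_order`
#'   (data.frame kind/id/fail_frac in removal order), `report`.
#' @export
greedycut <- function(detp, threshold = 0.01) {
  stopifnot(is.matrix(detp), !is.null(rownames(detp)), !is.null(colnames(detp)))
  if (threshold <= 0 || threshold >= 1) stop("threshold must lie in (0, 1)")
  fail <- detp > threshold
  order_log <- list()
  while (nrow(fail) > 0L && ncol(fail) > 0L && any(fail)) {
    row_frac <- rowMeans(fail)
    col_frac <- colMeans(fail)
    best_row <- max(row_frac)
    best_col <- max(col_frac)
    if (best_row >= best_col) {
      cand <- rownames(fail)[row_frac == best_row]
      id <- sort(cand)[1L]
      order_log[[length(order_log) + 1L]] <-
        data.frame(kind = "probe", id = id, fail_frac = best_row,
                   stringsAsFactors = FALSE)
      fail <- fail[setdiff(rownames(fail), id), , drop = FALSE]
    } else {
      cand <- colnames(fail)[col_frac == best_col]
      id <- sort(cand)[1L]
      order_log[[length(order_log) + 1L]] <-
        data.frame(kind = "sample", id = id, fail_frac = best_col,
                   stringsAsFactors = FALSE)
      fail <- fail[, setdiff(colnames(fail), id), drop = FALSE]
    }
  }
  removal_order <- if (length(order_log)) {
    do.call(rbind, c(order_log, list(make.row.names = FALSE)))
  } else {
    data.frame(kind = character(0), id = character(0), fail_frac = numeric(0))
  }
  removed_probes <- removal_order$id[removal_order$kind == "probe"]
  removed_samples <- removal_order$id[removal_order$kind == "sample"]
  if (nrow(fail) == 0L || ncol(fail) == 0L)
    warning("greedy-cut removed an entire dimension of the matrix")
  list(removed_probes = removed_probes,
       removed_samples = removed_samples,
       removal_order = removal_order,
       report = list(n_probes_removed = length(removed_probes),
                     n_samples_removed = length(removed_samples),
                     n_probes_surviving = nrow(fail),
                     n_samples_surviving = ncol(fail)))
}

#' Apply all probe filters to a set of tissue beta matrices
#'
#' Runs SNP-proximity, greedy-cut (per tissue, when a detection p matrix is
#' supplied), and context filters, removes the union of flagged probes from
#' every tissue (and flagged samples from the affected tissue), and returns
#' a reconciled report: per-rule raw counts may overlap, the unique union
#' plus survivors equals the input probe count.
#'
#' @param tissues Named list of beta matrices over a common probe universe.
#' @param annotation Probe annotation data.frame.
#' @param detp Optional named list of detection p matrices per tissue.
#' @param max_dist SNP distance cutoff (default 5 bp).
#' @param threshold Detection p threshold (default 0.01).
#' @return List: `tissues` (filtered), `report` (FilterReport fields),
#'   `removed` (per-rule id sets).
#' @export
apply_probe_filters <- function(tissues, annotation, detp = NULL,
                                max_dist = 5, threshold = 0.01) {
  probes <- rownames(tissues[[1L]])
  unannotated <- setdiff(probes, annotation$probe_id)
  if (length(unannotated))
    warning(length(unannotated),
            " probes missing from the annotation; retained")
  rm_snp <- intersect(filter_snp_proximity(annotation, max_dist), probes)
  rm_ctx <- intersect(filter_context(annotation), probes)
  rm_det <- character(0)
  removed_samples <- list()
  if (!is.null(detp)) {
    for (tn in names(detp)) {
      gc <- greedycut(detp[[tn]], threshold)
      rm_det <- union(rm_det, gc$removed_probes)
      if (length(gc$removed_samples))
        removed_samples[[tn]] <- gc$removed_samples
    }
    rm_det <- intersect(rm_det, probes)
  }
  rm_all <- union(union(rm_snp, rm_det), rm_ctx)
  keep <- setdiff(probes, rm_all)
  out <- lapply(names(tissues), function(tn) {
    m <- tissues[[tn]][keep, , drop = FALSE]
    bad <- removed_samples[[tn]]
    if (!is.null(bad)) m <- m[, setdiff(colnames(m), bad), drop = FALSE]
    m
  })
  names(out) <- names(tissues)
  list(tissues = out,
       removed = list(snp_proximity = rm_snp, detection = rm_det,
                      context = rm_ctx, union = rm_all,
                      samples = removed_samples),
       report = list(n_input = length(probes),
                     n_removed_snp = length(rm_snp),
                     n_removed_detection = length(rm_det),
                     n_removed_context = length(rm_ctx),
                     n_removed_unique = length(rm_all),
                     n_surviving = length(keep),
                     removed_sample_ids = unlist(removed_samples,
                                                 use.names = FALSE)))
}
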