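# Cross-database stability of per-CpG correlations. Two cohorts measuring
# the same tissue pair rarely agree probe-by-probe; probes whose rho
# differs by less than 0.2 in absolute value between databases are classed
# as stable (less dependent on cohort differences — ancestry, age, brain
# region, cell composition), the rest as unstable.

#' Align two per-CpG correlation tables and classify stability
#'
#' Inner-joins on probe_id and tissue_pair, excluding probes with
#' undefined rho in either table, computes delta = |rho_A - rho_B| and the
#' stability class (strictly delta < threshold; a boundary delta of
#' exactly 0.2 is unstable), plus the per-pair correlation-of-correlations
#' (Pearson between the two rho columns).
#'
#' @param tableA,tableB data.frames with columns probe_id, tissue_pair,
#'   rho (extra columns ignored).
#' @param threshold Stability cutoff on delta (default 0.2).
#' @return List: `records` (probe_id, tissue_pair, rho_A, rho_B, delta,
#'   stable), `rho_of_rho` (per tissue pair: r, n), `n_excluded_undefined`.
#' @export
align_and_compare <- function(tableA, tableB, threshold = 0.2) {
  a <- tableA[!is.na(tableA$rho), c("probe_id", "tissue_pair", "rho")]
  b <- tableB[!is.na(tableB$rho), c("probe_id", "tissue_pair", "rho")]
  n_excl <- (nrow(tableA) - nrow(a)) + (nrow(tableB) - nrow(b))
  m <- merge(a, b, by = c("probe_id", "tissue_pair"),
             suffixes = c("_A", "_B"))
  pairs <- unique(c(a$tissue_pair, b$tissue_pair))
  for (pr in pairs) {
    if (!any(m$tissue_pair == pr))
      stop("no shared probes with defined rho for tissue pair: ", pr)
  }
  m$delta <- abs(m$rho_A - m$rho_B)
  m$stable <- m$delta < threshold
  ror <- do.call(rbind, lapply(split(m, m$tissue_pair), function(d) {
    r <- if (nrow(d) >= 2L && stats::sd(d$rho_A) > 0 && stats::sd(d$rho_B) > 0)
      stats::cor(d$rho_A, d$rho_B) else NA_real_
    data.frame(tissue_pair = d$tissue_pair[1L], r = r, n = nrow(d),
               stringsAsFactors = FALSE)
  }))
  rownames(ror) <- NULL
  list(records = m[order(m$tissue_pair, m$probe_id), ],
       rho_of_rho = ror, n_excluded_undefined = n_excl)
}

#' Three-set Venn region counts of stable probes
#'
#' Given stability records for the three brain-peripheral tissue pairs,
#' counts probes stable in each subset of pairs (the 7 regions of a
#' three-set Venn diagram). Region counts sum to the number of probes
#' stable in at least one pair.
#'
#' @param records Stability records ([align_and_compare()]`$records`)
#'   covering exactly three tissue pairs.
#' @return List: `regions` (named counts, names like "blood-brain",
#'   "blood-brain&saliva-brain", ...), `triple` (count stable in all
#'   three), `per_pair` (stable totals per pair).
#' @export
venn_counts <- function(records) {
  pairs <- sort(unique(records$tissue_pair))
  if (length(pairs) != 3L)
    stop("venn_counts expects exactly 3 tissue pairs, got ", length(pairs))
  sets <- lapply(pairs, function(pr)
    records$probe_id[records$tissue_pair == pr & records$stable])
  names(sets) <- pairs
  universe <- unique(unlist(sets))
  member <- vapply(sets, function(s) universe %in% s, logical(length(universe)))
  if (length(universe) == 1L) member <- matrix(member, nrow = 1L,
                                               dimnames = list(NULL, pairs))
  key <- apply(member, 1L, function(row) paste(pairs[row], collapse = "&"))
  regions <- table(factor(key, levels = vapply(
    seq_len(7L), function(i) {
      bits <- as.logical(bitwAnd(i, c(1L, 2L, 4L)))
      paste(pairs[bits], collapse = "&")
    }, character(1))))
  regions <- as.integer(regions)
  names(regions) <- vapply(seq_len(7L), function(i) {
    bits <- as.logical(bitwAnd(i, c(1L, 2L, 4L)))
    paste(pairs[bits], collapse = "&")
  }, character(1))
  list(regions = regions,
       triple = unname(regions[paste(pairs, collapse = "&")]),
       per_pair = vapply(sets, length, integer(1)))
}

#' Annotate records with methylation-QTL membership
#'
#' Flags probes under known genetic control. When the mQTL list carries a
#' p-value column, the canonical cutoff p < 1e-14 is applied first; a bare
#' probe-id list is used as-is.
#'
#' @param records Any data.frame with a probe_id column.
#' @param mqtl_list data.frame with probe_id and optionally p, or a
#'   character vector of probe ids.
#' @param p_cutoff Cutoff applied when a p column is present
#'   (default 1e-14).
#' @return `records` with a logical `mqtl` column appended.
#' @export
annotate_mqtl <- function(records, mqtl_list, p_cutoff = 1e-14) {
  ids <- if (is.character(mqtl_list)) {
    mqtl_list
  } else if ("p" %in% names(mqtl_list)) {
    mqtl_list$probe_id[!is.na(mqtl_list$p) & mqtl_list$p < p_cutoff]
  } else {
    mqtl_list$probe_id
  }
  records$mqtl <- records$probe_id %in% ids
  records
}
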