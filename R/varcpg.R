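# Variable-CpG classification: most CpGs barely vary between people, and
# correlating near-constant probes across tissues mostly measures noise.
# The trimmed-range rule drops each probe's upper and lower 10th
# percentiles and calls the probe variable when the surviving values still
# span at least 0.05 on the beta scale.

#' Trimmed range and variability flag per probe
#'
#' Per probe, computes the 10th and 90th percentiles (linear-interpolation
#' quantiles, `type = 7`), drops values strictly outside \[P10, P90\]
#' (values equal to a percentile are retained), and flags the probe as
#' variable when max - min of the retained values is at least
#' `range_threshold` (inclusive: a span of exactly 0.05 is variable).
#' Probes with fewer than 3 non-missing values get NA range and flag.
#'
#' @param beta Beta matrix (probes x subjects).
#' @param trim Percentile trimmed from each tail (default 10; must be < 50).
#' @param range_threshold Beta-scale span for "variable" (default 0.05).
#' @param quantile_type Quantile estimator passed to [stats::quantile()]
#'   (default 7, linear interpolation).
#' @return data.frame: probe_id, n_used, trimmed_range, variable.
#' @export
classify_variable <- function(beta, trim = 10, range_threshold = 0.05,
                              quantile_type = 7) {
  if (trim >= 50) stop("trim must be < 50 (percent per tail)")
  probs <- c(trim, 100 - trim) / 100
  res <- apply(beta, 1L, function(v) {
    v <- v[!is.na(v)]
    if (length(v) < 3L) return(c(NA_real_, NA_real_))
    qs <- stats::quantile(v, probs, type = quantile_type, names = FALSE)
    kept <- v[v >= qs[1L] & v <= qs[2L]]
    c(length(v), if (length(kept)) max(kept) - min(kept) else 0)
  })
  trimmed_range <- res[2L, ]
  data.frame(probe_id = rownames(beta),
             n_used = as.integer(res[1L, ]),
             trimmed_range = trimmed_range,
             # inclusive threshold, robust to double rounding (0.15 - 0.10
             # is below 0.05 by one ulp in binary)
             variable = trimmed_range >= range_threshold - 1e-12,
             stringsAsFactors = FALSE)
}

#' Probes variable in every tissue
#'
#' Exact intersection of the variable sets of all supplied tissues; probes
#' with an undefined flag in any tissue are excluded.
#'
#' @param flags Named list of [classify_variable()] outputs, one per tissue.
#' @return List: `probes` (character vector), `count`, `per_tissue` counts.
#' @export
intersect_variable <- function(flags) {
  stopifnot(is.list(flags), length(flags) >= 1L)
  sets <- lapply(flags, function(f) f$probe_id[!is.na(f$variable) & f$variable])
  probes <- Reduce(intersect, sets)
  list(probes = probes, count = length(probes),
       per_tissue = vapply(sets, length, integer(1)))
}
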