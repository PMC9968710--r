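# End-to-end orchestration: filter -> (optional) adjust -> correlate ->
# variability -> SNP detection -> (optional) cross-database -> lookup
# export. When adjustment is configured both the Raw and Adj branches run
# in parallel, and the lookup table is assembled from each stage's own
# output (no recomputation).

#' Run the full cross-tissue concordance pipeline
#'
#' @param cohort A cohort as returned by [generate_cohort()] or
#'   [read_cohort()]: named beta matrices in `$tissues`, plus optional
#'   `$annotation`, `$detp`, `$proportions`.
#' @param out_dir Optional directory; when given, every stage's table is
#'   written as TSV and a run log is emitted.
#' @param adjust Run the cell-composition-adjusted branch alongside Raw
#'   (requires `$proportions`).
#' @param brain_pairs_only Correlate brain against each peripheral tissue
#'   only (default TRUE), mirroring the surrogate-tissue question.
#' @param reference_table Optional external correlation table
#'   (probe_id, tissue_pair, rho) for cross-database comparison.
#' @param mqtl_list Optional mQTL probe list for annotation.
#' @param snp_seed Seed for the gap-statistic reference draws (default 1).
#' @param min_n,q_threshold,range_threshold,delta_threshold Stage
#'   parameters with their standard defaults.
#' @return List of stage outputs: `filter_report`, `branches` (Raw and
#'   optionally Adj, each with `correlations`, `summaries`, `variability`,
#'   `variable_in_all`, `lookup`), `snp_report`, `crossdb` (if supplied).
#' @export
run_pipeline <- function(cohort, out_dir = NULL, adjust = FALSE,
                         brain_pairs_only = TRUE, reference_table = NULL,
                         mqtl_list = NULL, snp_seed = 1L, min_n = 5,
                         q_threshold = 0.05, range_threshold = 0.05,
                         delta_threshold = 0.2) {
  log_lines <- character(0)
  note <- function(...) {
    msg <- paste0(format(Sys.time(), "%H:%M:%S "), ...)
    log_lines <<- c(log_lines, msg)
    message(msg)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }

  tissues <- cohort$tissues
  note("pipeline start: ", length(tissues), " tissues, ",
       nrow(tissues[[1L]]), " probes, ", ncol(tissues[[1L]]), " subjects")

  # -- filter ---------------------------------------------------------
  filter_report <- NULL
  if (!is.null(cohort$annotation)) {
    fl <- stage("filter", apply_probe_filters(tissues, cohort$annotation,
                                              detp = cohort$detp))
    tissues <- fl$tissues
    filter_report <- fl$report
    note("filter: removed ", fl$report$n_removed_unique, " probes (snp=",
         fl$report$n_removed_snp, ", detection=", fl$report$n_removed_detection,
         ", context=", fl$report$n_removed_context, "); ",
         fl$report$n_surviving, " surviving")
  }

  # -- branches -------------------------------------------------------
  branch_inputs <- list(Raw = tissues)
  if (adjust) {
    if (is.null(cohort$proportions))
      stop("stage 'adjust' failed: no cell proportions supplied")
    adj <- stage("adjust", {
      lapply(stats::setNames(names(tissues), names(tissues)), function(tn)
        residualize(tissues[[tn]], cohort$proportions[[tn]], tissue = tn)$beta)
    })
    branch_inputs$Adj <- adj
    note("adjust: Adj branch produced for ", length(adj), " tissues")
  }

  pair_list <- if (brain_pairs_only && "brain" %in% names(tissues)) {
    lapply(setdiff(names(tissues), "brain"), function(tn) c("brain", tn))
  } else {
    cmb <- utils::combn(names(tissues), 2L, simplify = FALSE)
    cmb
  }

  branches <- list()
  for (br in names(branch_inputs)) {
    tm <- branch_inputs[[br]]
    cors <- list(); summ <- list()
    for (pp in pair_list) {
      lab <- paste(pp, collapse = "-")
      rec <- stage("correlate", within_subject_cpg_correlation(
        tm[[pp[1L]]], tm[[pp[2L]]], min_n = min_n, tissue_pair = lab))
      cors[[lab]] <- rec
      s <- summarize_correlations(rec, q_threshold = q_threshold)
      summ[[lab]] <- as.data.frame(s, stringsAsFactors = FALSE)
    }
    correlations <- do.call(rbind, c(cors, list(make.row.names = FALSE)))
    summaries <- do.call(rbind, c(summ, list(make.row.names = FALSE)))
    note(br, ": correlated ", length(cors), " tissue pairs")

    flags <- stage("variability", lapply(
      stats::setNames(names(tm), names(tm)), function(tn)
        classify_variable(tm[[tn]], range_threshold = range_threshold)))
    var_all <- intersect_variable(flags)
    note(br, ": ", var_all$count, " probes variable in all tissues")
    branches[[br]] <- list(tissues = tm, correlations = correlations,
                           summaries = summaries, variability = flags,
                           variable_in_all = var_all)
  }

  # -- SNP detection (on the Raw branch, per tissue) ------------------
  snp_report <- stage("snpdetect", {
    reps <- lapply(stats::setNames(names(tissues), names(tissues)),
                   function(tn) detect_snp_probes(branch_inputs$Raw[[tn]],
                                                  seed = snp_seed))
    reps
  })
  snp_any <- Reduce(`|`, lapply(snp_report, function(r) r$flagged))
  note("snpdetect: ", sum(snp_any), " probes flagged in >= 1 tissue")

  # -- cross-database -------------------------------------------------
  crossdb <- NULL
  if (!is.null(reference_table)) {
    crossdb <- stage("crossdb", align_and_compare(
      branches$Raw$correlations, reference_table,
      threshold = delta_threshold))
    note("crossdb: ", sum(crossdb$records$stable), " / ",
         nrow(crossdb$records), " records stable (delta < ",
         delta_threshold, ")")
  }

  # -- lookup export --------------------------------------------------
  for (br in names(branches)) {
    branches[[br]]$lookup <- stage("export", build_lookup(
      branches[[br]], snp_report, crossdb, mqtl_list))
  }

  result <- list(filter_report = filter_report, branches = branches,
                 snp_report = snp_report, crossdb = crossdb,
                 log = log_lines)
  if (!is.null(out_dir)) write_pipeline_outputs(result, out_dir)
  result
}

# Assemble the per-probe lookup table from stage outputs. One row per
# probe; per-pair rho/p/q columns, per-tissue variability columns, SNP
# flag and cluster number, cross-database delta/stability, mQTL flag.
build_lookup <- function(branch, snp_report, crossdb = NULL,
                         mqtl_list = NULL) {
  cors <- branch$correlations
  probes <- unique(cors$probe_id)
  lookup <- data.frame(probe_id = probes, stringsAsFactors = FALSE)
  for (pr in unique(cors$tissue_pair)) {
    d <- cors[cors$tissue_pair == pr, ]
    i <- match(probes, d$probe_id)
    lookup[[paste0("rho_", pr)]] <- d$rho[i]
    lookup[[paste0("p_", pr)]] <- d$p[i]
    lookup[[paste0("q_", pr)]] <- d$q[i]
  }
  for (tn in names(branch$variability)) {
    f <- branch$variability[[tn]]
    i <- match(probes, f$probe_id)
    lookup[[paste0("variable_", tn)]] <- f$variable[i]
    lookup[[paste0("trimmed_range_", tn)]] <- f$trimmed_range[i]
  }
  lookup$variable_all <- probes %in% branch$variable_in_all$probes
  snp_k <- rep(1L, length(probes))
  snp_flag <- rep(FALSE, length(probes))
  for (tn in names(snp_report)) {
    r <- snp_report[[tn]]
    i <- match(probes, r$probe_id)
    hit <- ifelse(is.na(i), FALSE, r$flagged[i])
    snp_flag <- snp_flag | hit
    snp_k <- pmax(snp_k, ifelse(is.na(i), 1L, r$chosen_k[i]))
  }
  lookup$snp_flagged <- snp_flag
  lookup$snp_cluster_k <- snp_k
  if (!is.null(crossdb)) {
    for (pr in unique(crossdb$records$tissue_pair)) {
      d <- crossdb$records[crossdb$records$tissue_pair == pr, ]
      i <- match(probes, d$probe_id)
      lookup[[paste0("delta_", pr)]] <- d$delta[i]
      lookup[[paste0("stable_", pr)]] <- d$stable[i]
    }
  }
  if (!is.null(mqtl_list)) lookup <- annotate_mqtl(lookup, mqtl_list)
  lookup
}

write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (br in names(result$branches)) {
    b <- result$branches[[br]]
    write_table_tsv(b$correlations,
                    file.path(out_dir, paste0("correlations_", br, ".tsv")))
    write_table_tsv(b$summaries,
                    file.path(out_dir, paste0("summaries_", br, ".tsv")))
    for (tn in names(b$variability))
      write_table_tsv(b$variability[[tn]],
                      file.path(out_dir, paste0("variability_", tn, "_", br, ".tsv")))
    write_table_tsv(data.frame(probe_id = b$variable_in_all$probes),
                    file.path(out_dir, paste0("variable_in_all_", br, ".tsv")))
    write_table_tsv(b$lookup, file.path(out_dir, paste0("lookup_", br, ".tsv")))
  }
  for (tn in names(result$snp_report))
    write_table_tsv(result$snp_report[[tn]],
                    file.path(out_dir, paste0("snp_report_", tn, ".tsv")))
  if (!is.null(result$crossdb)) {
    write_table_tsv(result$crossdb$records,
                    file.path(out_dir, "crossdb_records.tsv"))
    write_table_tsv(result$crossdb$rho_of_rho,
                    file.path(out_dir, "crossdb_rho_of_rho.tsv"))
  }
  writeLines(result$log, file.path(out_dir, "run.log"))
  invisible(out_dir)
}

#' Query lookup records by probe id
#'
#' Exact-match retrieval from a lookup table; unknown ids are reported via
#' a warning, never silently dropped.
#'
#' @param lookup Lookup table (a branch's `$lookup` or a TSV read back).
#' @param probe_ids Character vector of ids, or path to a one-column file.
#' @return The matching rows, in the requested order.
#' @export
query_probes <- function(lookup, probe_ids) {
  if (length(probe_ids) == 1L && file.exists(probe_ids))
    probe_ids <- read_table_tsv(probe_ids)[[1L]]
  unknown <- setdiff(probe_ids, lookup$probe_id)
  if (length(unknown))
    warning("unknown probe ids: ", paste(unknown, collapse = ", "))
  lookup[match(intersect(probe_ids, lookup$probe_id), lookup$probe_id), ,
         drop = FALSE]
}

#' Read a cohort directory written by [write_cohort()]
#'
#' @param dir Directory containing beta_/detp_/proportions_ TSVs,
#'   annotation.tsv, and config.yaml.
#' @return Cohort list usable by [run_pipeline()].
#' @export
read_cohort <- function(dir) {
  beta_files <- list.files(dir, pattern = "^beta_.*\\.tsv$", full.names = TRUE)
  if (!length(beta_files)) stop("no beta_<tissue>.tsv files in ", dir)
  tn <- sub("^beta_(.*)\\.tsv$", "\\1", basename(beta_files))
  tissues <- lapply(beta_files, read_beta_tsv)
  names(tissues) <- tn
  grab <- function(prefix, reader) {
    fs <- file.path(dir, paste0(prefix, "_", tn, ".tsv"))
    if (!all(file.exists(fs))) return(NULL)
    out <- lapply(fs, reader)
    names(out) <- tn
    out
  }
  ann_path <- file.path(dir, "annotation.tsv")
  cfg_path <- file.path(dir, "config.yaml")
  list(tissues = tissues,
       detp = grab("detp", read_beta_tsv),
       proportions = grab("proportions", read_table_tsv),
       annotation = if (file.exists(ann_path)) read_table_tsv(ann_path),
       config = if (file.exists(cfg_path)) yaml::read_yaml(cfg_path))
}
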