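# Probe filters: SNP proximity, context, greedy-cut.

make_annotation <- function(dist, context = NULL) {
  n <- length(dist)
  data.frame(probe_id = sprintf("cg%06d", seq_len(n)),
             snp_distance_bp = dist,
             context = context %||% rep("cpg", n),
             stringsAsFactors = FALSE)
}

test_that("SNP proximity filter is inclusive at the boundary", {
  ann <- make_annotation(c(0, 3, 5, 6))
  expect_setequal(filter_snp_proximity(ann, 5), ann$probe_id[1:3])
  expect_length(filter_snp_proximity(make_annotation(numeric(0))), 0)
  expect_error(filter_snp_proximity(ann, -1), "max_dist")
  # NA distance means no SNP nearby: kept, silently
  ann$snp_distance_bp[2] <- NA
  expect_setequal(filter_snp_proximity(ann, 5), ann$probe_id[c(1, 3)])
  # probes absent from the annotation are retained with a warning
  beta <- toy_beta(6, 4, seed = 12)
  rownames(beta) <- sprintf("cg%06d", 1:6)
  expect_warning(apply_probe_filters(list(brain = beta), ann),
                 "missing from the annotation")
})

test_that("SNP proximity filter matches brute-force enumeration", {
  set.seed(3)
  dist <- sample(0:10, 1000, replace = TRUE)
  ann <- make_annotation(dist)
  expect_setequal(filter_snp_proximity(ann, 5), ann$probe_id[dist <= 5])
})

test_that("context filter removes exactly the non-CpG probes", {
  ann <- make_annotation(rep(10, 10),
                         context = rep(c("cpg", "non_cpg"), c(7, 3)))
  expect_setequal(filter_context(ann), ann$probe_id[8:10])
  expect_length(filter_context(make_annotation(rep(10, 5))), 0)
  set.seed(4)
  ctx <- ifelse(runif(5000) < 0.029, "non_cpg", "cpg")
  ann <- make_annotation(rep(10, 5000), context = ctx)
  expect_length(filter_context(ann), sum(ctx == "non_cpg"))
})

test_that("greedycut trivial cases behave", {
  detp <- matrix(0.001, 20, 6,
                 dimnames = list(sprintf("cg%02d", 1:20), sprintf("S%d", 1:6)))
  gc <- greedycut(detp)
  expect_length(gc$removed_probes, 0)
  expect_length(gc$removed_samples, 0)
  # one all-failing sample, all else clean -> only that sample goes
  detp[, 3] <- 0.5
  gc <- greedycut(detp)
  expect_identical(gc$removed_samples, "S3")
  expect_length(gc$removed_probes, 0)
})

test_that("greedycut reaches a clean end state on random matrices", {
  set.seed(9)
  for (i in 1:5) {
    detp <- matrix(runif(200 * 10, 0, 0.01), 200, 10,
                   dimnames = list(sprintf("cg%03d", 1:200),
                                   sprintf("S%02d", 1:10)))
    bad_rows <- sample(200, 8)
    detp[bad_rows, ] <- ifelse(runif(8 * 10) < 0.6, 0.5, 0.001)
    bad_col <- sample(10, 1)
    detp[, bad_col] <- ifelse(runif(200) < 0.5, 0.5, 0.001)
    gc <- greedycut(detp)
    kept <- detp[setdiff(rownames(detp), gc$removed_probes),
                 setdiff(colnames(detp), gc$removed_samples), drop = FALSE]
    # post-condition: no failing entry survives (the same invariant an
    # exhaustive removal oracle must reach)
    expect_true(all(kept <= 0.01))
    # termination bound: at most rows + columns removals
    expect_lte(nrow(gc$removal_order), 210)
  }
})

test_that("greedycut tie-break prefers probes, then lexicographic id", {
  detp <- matrix(0.001, 3, 3,
                 dimnames = list(c("cgB", "cgA", "cgC"), c("S1", "S2", "S3")))
  detp["cgB", ] <- 0.5   # row fraction 1
  detp["cgA", ] <- 0.5   # row fraction 1 (tie with cgB)
  gc <- greedycut(detp)
  expect_identical(gc$removal_order$id[1:2], c("cgA", "cgB"))
  expect_identical(gc$removal_order$kind[1:2], c("probe", "probe"))
})

test_that("all-failing matrix removes everything with a warning", {
  detp <- matrix(0.9, 4, 3,
                 dimnames = list(sprintf("cg%d", 1:4), sprintf("S%d", 1:3)))
  expect_warning(gc <- greedycut(detp), "entire dimension")
  expect_equal(gc$report$n_probes_surviving * gc$report$n_samples_surviving, 0)
})

test_that("apply_probe_filters reconciles counts and is idempotent", {
  co <- small_cohort()
  res <- apply_probe_filters(co$tissues, co$annotation, co$detp)
  rep <- res$report
  expect_equal(rep$n_removed_unique + rep$n_surviving, rep$n_input)
  expect_setequal(res$removed$union,
                  union(union(res$removed$snp_proximity,
                              res$removed$detection), res$removed$context))
  # idempotence: re-filtering the filtered set removes nothing
  ann2 <- co$annotation[co$annotation$probe_id %in%
                          rownames(res$tissues[[1]]), ]
  detp2 <- lapply(names(co$detp), function(tn) {
    m <- co$detp[[tn]]
    m[intersect(rownames(m), rownames(res$tissues[[tn]])),
      intersect(colnames(m), colnames(res$tissues[[tn]])), drop = FALSE]
  })
  names(detp2) <- names(co$detp)
  res2 <- apply_probe_filters(res$tissues, ann2, detp2)
  expect_equal(res2$report$n_removed_unique, 0)
})
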