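rec1 <- function(confidence = 99, coverage = 85, d_score = 12,
                 by = TRUE, sample = "OC01", group = "OC",
                 peptide = "PEPTIDEK", site = 8) {
  data.frame(sample_id = sample, group = group, protein = "PROT",
             peptide = peptide, ptm_kind = "ACETYL_K", site = site,
             confidence = confidence, coverage_pct = coverage,
             d_score = d_score, by_pairs_ok = by,
             stringsAsFactors = FALSE)
}

test_that("quality filters keep and drop records at the published thresholds", {
  recs <- rbind(rec1(),                       # passes all
                rec1(coverage = 79),          # fails coverage (boundary)
                rec1(confidence = 97.9),      # fails confidence
                rec1(d_score = 9.9),          # fails D-score
                rec1(by = FALSE))             # fails b/y
  out <- filter_identifications(recs)
  expect_equal(nrow(out$passed), 1)
  expect_equal(unname(out$filter_log),
               c(1L, 1L, 1L, 1L))
  # conservation: input = passed + sum(removed)
  expect_equal(nrow(recs), nrow(out$passed) + sum(out$filter_log))
  # boundary values pass at exactly the threshold
  exact <- rec1(confidence = 98, coverage = 80, d_score = 10)
  expect_equal(nrow(filter_identifications(exact)$passed), 1)
  # empty input: empty output, zero log
  e <- filter_identifications(recs[0, ])
  expect_equal(nrow(e$passed), 0)
  expect_true(all(e$filter_log == 0))
  expect_error(filter_identifications(recs[, -7]), "lacks column")
})

test_that("filters are idempotent and monotone in their thresholds", {
  gen <- make_identification_table(cohort_design(seed = 3))
  f1 <- filter_identifications(gen$records)
  f2 <- filter_identifications(f1$passed)
  expect_equal(nrow(f2$passed), nrow(f1$passed))
  expect_true(all(f2$filter_log == 0))
  # relaxing any threshold never shrinks the passed set
  relaxed <- filter_identifications(gen$records, confidence_min = 90,
                                    coverage_min = 50, d_score_min = 0,
                                    require_by = FALSE)
  expect_gte(nrow(relaxed$passed), nrow(f1$passed))
})

test_that("phenotype specificity enforces prevalence, control absence, carriers", {
  cohort <- data.frame(
    sample_id = c(sprintf("OC%02d", 1:10), sprintf("CNT%02d", 1:5)),
    group = c(rep("OC", 10), rep("CNT", 5)), stringsAsFactors = FALSE)
  # peptide in 6/10 OC, 0 CNT
  good <- do.call(rbind, lapply(sprintf("OC%02d", 1:6), function(s) {
    rec1(sample = s)
  }))
  sets <- phenotype_specific_ptms(good, cohort)
  expect_equal(nrow(sets$OC), 1)
  # one control observation disqualifies it
  with_ctrl <- rbind(good, rec1(sample = "CNT01", group = "CNT"))
  sets2 <- phenotype_specific_ptms(with_ctrl, cohort)
  expect_equal(nrow(sets2$OC), 0)
  # below 50% prevalence
  few <- good[1:4, ]
  expect_equal(nrow(phenotype_specific_ptms(few, cohort)$OC), 0)
  expect_error(phenotype_specific_ptms(rec1(sample = "NOPE"), cohort),
               "unknown sample")
})

test_that("synthetic cohort: planted peptides recovered exactly, decoys rejected", {
  gen <- make_identification_table(cohort_design(seed = 11))
  res <- run_curation_pipeline(gen$records, gen$cohort)
  keyize <- function(d) sort(paste(d$peptide, d$ptm_kind, d$site))
  expect_identical(keyize(res$sets$OC), keyize(gen$truth$oc))
  expect_identical(keyize(res$sets$BC), keyize(gen$truth$bc))
  # no decoy leaks into either set
  expect_false(any(gen$truth$decoys$peptide %in%
                     c(res$sets$OC$peptide, res$sets$BC$peptide)))
  # every decoy was generated
  expect_equal(nrow(gen$truth$decoys), 7)
})

test_that("count summary reproduces the published per-group counts", {
  tr <- table1_as_records()
  res <- run_curation_pipeline(tr$records, tr$cohort)
  expect_equal(res$counts$per_group$OC$peptides, 12)
  expect_equal(res$counts$per_group$OC$proteins, 8)
  expect_equal(res$counts$per_group$BC$peptides, 6)
  expect_equal(res$counts$per_group$BC$proteins, 3)
  # empty sets give zero counts
  z <- count_summary(list(OC = res$sets$OC[0, ], BC = NULL))
  expect_equal(z$per_group$OC$peptides, 0)
  expect_equal(z$per_group$OC$proteins, 0)
})

test_that("differential abundance applies floor, fold-change and rank-sum rules", {
  set.seed(5)
  n <- 10
  samples <- c(sprintf("OC%02d", 1:n), sprintf("CNT%02d", 1:n))
  groups <- stats::setNames(c(rep("OC", n), rep("CNT", n)), samples)
  base <- matrix(stats::rlnorm(2 * n * 3, log(1e7), 0.5), ncol = 3,
                 dimnames = list(samples, c("SAME", "UP", "ABSENT")))
  base[1:n, "UP"] <- base[1:n, "UP"] * 4
  base[1:n, "ABSENT"] <- 0
  res <- differential_abundance(base, groups, case = "OC")
  same <- res[res$protein == "SAME", ]
  expect_lt(abs(same$log2_fc), 1)
  up <- res[res$protein == "UP", ]
  expect_true(up$significant)
  expect_equal(up$log2_fc, 2, tolerance = 0.5)
  # all-floored case group: log2 fc = log2(floor / median control) < -1
  ab <- res[res$protein == "ABSENT", ]
  expect_equal(ab$log2_fc, log2(1e5 / ab$median_control))
  expect_lt(ab$log2_fc, -1)
  expect_equal(ab$frequency, 0)
  # identical intensities: nothing significant, p well above threshold
  ident <- matrix(rep(stats::rlnorm(n, log(1e7), 0.3), 2 * 3), ncol = 3,
                  dimnames = list(samples, c("A", "B", "C")))
  res0 <- differential_abundance(ident, groups, case = "OC")
  expect_true(all(res0$log2_fc == 0))
  expect_false(any(res0$significant))
  expect_error(differential_abundance(base[1:12, , drop = FALSE],
                                      groups, case = "BC"), "absent")
})

test_that("a planted four-fold shift is flagged in nearly all replicates", {
  # scaled-down version of the recovery simulation (full grid in the
  # acceptance suite)
  hits <- 0
  for (r in 1:40) {
    set.seed(1000 + r)
    n <- 10
    samples <- c(sprintf("OC%02d", 1:n), sprintf("CNT%02d", 1:n))
    groups <- stats::setNames(c(rep("OC", n), rep("CNT", n)), samples)
    x <- matrix(stats::rlnorm(2 * n, meanlog = log(1e7),
                              sdlog = 0.5 * log(2)), ncol = 1,
                dimnames = list(samples, "PLANT"))
    x[1:n, 1] <- x[1:n, 1] * 4
    res <- differential_abundance(x, groups, case = "OC")
    hits <- hits + res$significant
  }
  expect_gte(hits / 40, 0.95)
})
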