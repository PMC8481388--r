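#!/usr/bin/env Rscript
# Cohort-level curation: reproduce the per-group phenotype-specific
# peptide/protein counts from the packaged modified-peptide table, then
# verify on a fully synthetic cohort (53 ovarian / 24 breast / 30
# control, planted peptides plus seven rule-violating decoys) that the
# quality filters and specificity rules recover exactly the planted
# truth, and measure the differential-abundance detection rate for a
# planted four-fold shift. Writes results/curation_counts.json.

suppressMessages(library(helixptm))
dir.create("results", showWarnings = FALSE)

tab1 <- table1_as_records()
cur <- run_curation_pipeline(tab1$records, tab1$cohort)
cat("Packaged-table curation counts:\n")
print(cur$counts)

gen <- make_identification_table(cohort_design(seed = 7))
res <- run_curation_pipeline(gen$records, gen$cohort)
keyize <- function(d) sort(paste(d$peptide, d$ptm_kind, d$site))
sens <- mean(keyize(gen$truth$oc) %in% keyize(res$sets$OC)) *
  mean(keyize(gen$truth$bc) %in% keyize(res$sets$BC))
fp <- sum(!(keyize(res$sets$OC) %in% keyize(gen$truth$oc))) +
  sum(!(keyize(res$sets$BC) %in% keyize(gen$truth$bc)))
cat(sprintf("\nSynthetic cohort: sensitivity %.2f, false positives %d; filter log:\n",
            sens, fp))
print(res$filter_log)

n_reps <- 200
hits <- 0
for (r in seq_len(n_reps)) {
  set.seed(3000 + r)
  n <- 10
  samples <- c(sprintf("OC%02d", 1:n), sprintf("CNT%02d", 1:n))
  groups <- setNames(c(rep("OC", n), rep("CNT", n)), samples)
  x <- matrix(rlnorm(2 * n, meanlog = log(1e7), sdlog = 0.5 * log(2)),
              ncol = 1, dimnames = list(samples, "PLANT"))
  x[1:n, 1] <- x[1:n, 1] * 4
  hits <- hits + differential_abundance(x, groups, case = "OC")$significant
}
cat(sprintf("Planted 4-fold shift detected in %.1f%% of %d replicates.\n",
            100 * hits / n_reps, n_reps))

jsonlite::write_json(list(
  table_counts = list(
    OC = list(peptides = cur$counts$per_group$OC$peptides,
              proteins = cur$counts$per_group$OC$proteins),
    BC = list(peptides = cur$counts$per_group$BC$peptides,
              proteins = cur$counts$per_group$BC$proteins)),
  synthetic_recovery = list(sensitivity = sens, false_positives = fp,
                            n_carriers = gen$truth$n_carriers),
  abundance_detection_rate = hits / n_reps
), "results/curation_counts.json", auto_unbox = TRUE, digits = NA,
pretty = TRUE)
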