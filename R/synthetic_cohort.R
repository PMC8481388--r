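# Synthetic cohort identification tables with planted phenotype-specific
# PTMs and rule-violating decoys.
#
# The default design emulates the study cohort (53 ovarian-cancer, 24
# breast-cancer, 30 control subjects) and plants the packaged
# modified-peptide list: 12 OC-specific peptides over 8 proteins and 6
# BC-specific peptides over 3 proteins, with the albumin and
# serotransferrin peptides shared between the cancer groups. Each decoy
# violates exactly one curation rule (low confidence, low coverage, low
# D-score, missing b/y pair, present in a control sample, below the 50%
# within-group prevalence, below the 20% carrier prevalence); the
# generator verifies the violated/satisfied rules arithmetically and
# refuses infeasible designs.

#' Cohort design for the identification-table generator
#'
#' @param n_oc,n_bc,n_cnt subjects per group.
#' @param planted data.frame with `peptide`, `protein`, `ptm_kind`,
#'   `site`, `groups` ("OC", "BC" or "OC+BC"); defaults to the packaged
#'   modified-peptide table.
#' @param carrier_frac within-group prevalence of planted peptides.
#' @param carrier_pool_frac fraction of each cancer group designated as
#'   PTM carriers (planted peptides are drawn inside this pool so the
#'   carrier-prevalence rule behaves like a real cohort where not every
#'   subject carries PTMs).
#' @param decoys generate the seven rule-violating decoys?
#' @param intensity_meanlog,intensity_sdlog log-normal intensity model
#'   (natural-log scale).
#' @param seed RNG seed (mandatory).
#' @return A `cohort_design` list.
#' @export
cohort_design <- function(n_oc = 53, n_bc = 24, n_cnt = 30,
                          planted = NULL, carrier_frac = 0.6,
                          carrier_pool_frac = 0.85, decoys = TRUE,
                          intensity_meanlog = log(1e6),
                          intensity_sdlog = 0.8, seed = 1L) {
  if (is.null(planted)) {
    t1 <- load_fixture("TABLE1")
    key <- paste(t1$peptide, t1$ptm_kind, t1$site)
    groups <- vapply(unique(key), function(k) {
      paste(sort(unique(t1$group[key == k])), collapse = "+")
    }, character(1))
    first <- t1[!duplicated(key), ]
    planted <- data.frame(
      peptide = first$peptide, protein = first$gene,
      ptm_kind = first$ptm_kind, site = first$site,
      groups = unname(groups[paste(first$peptide, first$ptm_kind,
                                   first$site)]),
      stringsAsFactors = FALSE
    )
  }
  stopifnot(carrier_frac > 0, carrier_frac <= 1, !is.null(seed))
  structure(
    list(n_oc = n_oc, n_bc = n_bc, n_cnt = n_cnt, planted = planted,
         carrier_frac = carrier_frac,
         carrier_pool_frac = carrier_pool_frac, decoys = decoys,
         intensity_meanlog = intensity_meanlog,
         intensity_sdlog = intensity_sdlog, seed = as.integer(seed)),
    class = "cohort_design"
  )
}

# passing-quality metric draws
quality_pass <- function(n) {
  data.frame(confidence = stats::runif(n, 98.5, 100),
             coverage_pct = stats::runif(n, 85, 98),
             d_score = stats::runif(n, 14, 40),
             by_pairs_ok = TRUE)
}

#' Generate a synthetic cohort identification table
#'
#' Planted peptides appear in their target groups at the designed
#' carrier fractions with passing quality metrics; decoys violate
#' exactly one curation rule each; intensities are log-normal. The
#' returned truth tables drive the planted-recovery tests.
#'
#' @param design a [cohort_design()].
#' @return list: `records` (identification table), `cohort` (sample ->
#'   group), `truth` (list with `oc`, `bc` planted peptide tables and
#'   `decoys`, the decoy bookkeeping).
#' @export
make_identification_table <- function(design = cohort_design()) {
  stopifnot(inherits(design, "cohort_design"))
  set.seed(design$seed)
  samples <- data.frame(
    sample_id = c(sprintf("OC%02d", seq_len(design$n_oc)),
                  sprintf("BC%02d", seq_len(design$n_bc)),
                  sprintf("CNT%02d", seq_len(design$n_cnt))),
    group = c(rep("OC", design$n_oc), rep("BC", design$n_bc),
              rep("CNT", design$n_cnt)),
    stringsAsFactors = FALSE
  )
  oc_ids <- samples$sample_id[samples$group == "OC"]
  bc_ids <- samples$sample_id[samples$group == "BC"]
  cnt_ids <- samples$sample_id[samples$group == "CNT"]
  n_in_oc <- ceiling(design$carrier_frac * design$n_oc)
  n_in_bc <- ceiling(design$carrier_frac * design$n_bc)
  if (n_in_oc < 1 || n_in_bc < 1) stop("design infeasible: carrier fraction x group size < 1")
  pool_oc <- sample(oc_ids, max(1, round(design$carrier_pool_frac *
                                           length(oc_ids))))
  pool_bc <- sample(bc_ids, max(1, round(design$carrier_pool_frac *
                                           length(bc_ids))))
  if (n_in_oc > length(pool_oc) || n_in_bc > length(pool_bc)) {
    stop("design infeasible: carrier pool smaller than planted prevalence")
  }
  rec <- list()
  emit <- function(sample_ids, p, quality = NULL) {
    n <- length(sample_ids)
    if (n == 0) return(invisible(NULL))
    q <- if (is.null(quality)) quality_pass(n) else quality
    rec[[length(rec) + 1]] <<- data.frame(
      sample_id = sample_ids,
      group = samples$group[match(sample_ids, samples$sample_id)],
      protein = p$protein, peptide = p$peptide, ptm_kind = p$ptm_kind,
      site = p$site, q,
      psm_count = stats::rpois(n, 20) + 1L,
      intensity = stats::rlnorm(n, design$intensity_meanlog,
                                design$intensity_sdlog),
      stringsAsFactors = FALSE
    )
  }
  planted <- design$planted
  for (i in seq_len(nrow(planted))) {
    p <- planted[i, ]
    gs <- strsplit(p$groups, "+", fixed = TRUE)[[1]]
    if ("OC" %in% gs) emit(sample(pool_oc, n_in_oc), p)
    if ("BC" %in% gs) emit(sample(pool_bc, n_in_bc), p)
  }
  decoy_truth <- NULL
  if (design$decoys) {
    half_oc <- ceiling(0.51 * design$n_oc)
    dq <- function(field, value) {
      q <- quality_pass(half_oc)
      q[[field]] <- value
      q
    }
    dplant <- function(name, rule) {
      data.frame(peptide = paste0("DECOYPEP", name, "SEQK"),
                 protein = paste0("DEC", name), ptm_kind = "ACETYL_K",
                 site = 9, groups = "OC", rule = rule,
                 stringsAsFactors = FALSE)
    }
    d1 <- dplant("LOWCONF", "confidence")
    emit(sample(pool_oc, half_oc), d1, dq("confidence", 90))
    d2 <- dplant("LOWCOV", "coverage")
    emit(sample(pool_oc, half_oc), d2, dq("coverage_pct", 55))
    d3 <- dplant("LOWD", "d_score")
    emit(sample(pool_oc, half_oc), d3, dq("d_score", 4))
    d4 <- dplant("NOBY", "by_pairs")
    emit(sample(pool_oc, half_oc), d4, dq("by_pairs_ok", FALSE))
    d5 <- dplant("CTRL", "in_control")
    emit(c(sample(pool_oc, half_oc), sample(cnt_ids, 2)), d5)
    d6 <- dplant("RARE", "phenotype_prevalence")
    n_rare <- max(1, ceiling(0.25 * design$n_oc))
    emit(sample(pool_oc, n_rare), d6)
    # below-20%-of-carriers decoy: at exactly half of the (smaller) BC
    # group; feasible only when the cohort-wide carrier count is large
    # enough, which the default design guarantees
    d7 <- dplant("FEWCARRIER", "carrier_prevalence")
    d7$groups <- "BC"
    n_few <- ceiling(0.5 * design$n_bc)
    emit(sample(pool_bc, n_few), d7)
    decoy_truth <- rbind(d1, d2, d3, d4, d5, d6, d7)
  }
  records <- do.call(rbind, rec)
  n_carriers <- 0L
  if (!is.null(records)) {
    rownames(records) <- NULL
    # arithmetic feasibility audit: planted peptides must satisfy all
    # rules, decoy 7 must genuinely fall below the carrier threshold
    n_carriers <- length(unique(
      records$sample_id[records$confidence >= 98 &
                          records$coverage_pct >= 80 &
                          records$d_score >= 10 & records$by_pairs_ok]))
    if (any(grepl("BC", planted$groups)) &&
          n_in_bc / n_carriers < 0.2) {
      stop("design infeasible: planted BC prevalence falls below the carrier rule")
    }
    if (design$decoys && ceiling(0.5 * design$n_bc) / n_carriers >= 0.2) {
      stop("design infeasible: carrier-prevalence decoy does not violate its rule")
    }
  }
  key <- paste(planted$peptide, planted$ptm_kind, planted$site)
  truth <- list(
    oc = planted[grepl("OC", planted$groups), , drop = FALSE],
    bc = planted[grepl("BC", planted$groups), , drop = FALSE],
    decoys = decoy_truth, n_carriers = n_carriers
  )
  list(records = records, cohort = samples, truth = truth)
}
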