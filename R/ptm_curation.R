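# Curation of PTM identification tables: PSM-level quality filters,
# cohort-level phenotype-specificity rules, and differential-abundance
# thresholds.
#
# A record is one peptide-PTM observation in one sample. The quality
# filters keep records with >= 98% identification confidence, >= 80%
# fragment-spectra sequence coverage, >= 10 units of site-localization
# D-score, and a proper flanking b/y ion pair. A modified peptide is then
# phenotype-specific for a cancer group when it is seen in at least half
# of that group's samples, in no control sample, and in at least 20% of
# all PTM-carrying subjects.

#' Required columns of an identification table
#' @return character vector of column names.
#' @export
identification_columns <- function() {
  c("sample_id", "group", "protein", "peptide", "ptm_kind", "site",
    "confidence", "coverage_pct", "d_score", "by_pairs_ok")
}

check_id_columns <- function(records, extra = character(0)) {
  miss <- setdiff(c(identification_columns(), extra), names(records))
  if (length(miss) > 0) {
    stop("identification table lacks column(s): ",
         paste(miss, collapse = ", "))
  }
  invisible(TRUE)
}

# distinct modified-peptide identity
peptide_key <- function(records) {
  paste(records$peptide, records$ptm_kind, records$site, sep = "#")
}

#' PSM-level quality filters
#'
#' Keeps records with confidence >= `confidence_min`, coverage >=
#' `coverage_min`, D-score >= `d_score_min`, and (optionally) a proper
#' flanking b/y ion pair. Removals are logged per rule in application
#' order (confidence, coverage, D-score, b/y); the passed set itself is a
#' pure conjunction and therefore order-independent.
#'
#' @param records identification table (see [identification_columns()]).
#' @param confidence_min,coverage_min,d_score_min thresholds (%).
#' @param require_by require `by_pairs_ok`.
#' @return list(`passed` = the surviving records, `filter_log` = named
#'   removal counts whose sum plus `nrow(passed)` equals `nrow(records)`).
#' @export
filter_identifications <- function(records, confidence_min = 98,
                                   coverage_min = 80, d_score_min = 10,
                                   require_by = TRUE) {
  check_id_columns(records)
  log <- c(confidence = 0L, coverage = 0L, d_score = 0L, by_pairs = 0L)
  cur <- records
  drop_rule <- function(cur, keep, rule) {
    log[[rule]] <<- sum(!keep)
    cur[keep, , drop = FALSE]
  }
  cur <- drop_rule(cur, cur$confidence >= confidence_min, "confidence")
  cur <- drop_rule(cur, cur$coverage_pct >= coverage_min, "coverage")
  cur <- drop_rule(cur, cur$d_score >= d_score_min, "d_score")
  if (require_by) cur <- drop_rule(cur, cur$by_pairs_ok, "by_pairs")
  rownames(cur) <- NULL
  list(passed = cur, filter_log = log)
}

#' Phenotype-specific modified peptides per cancer group
#'
#' A modified peptide — identified by (sequence, PTM kind, site) — is
#' specific for cancer group G when it appears in at least
#' `min_phenotype_frac` of G's samples, in zero control samples, and in
#' at least `min_carrier_frac` of PTM-carrying subjects. Peptides may be
#' shared between the two cancer groups but never with the control.
#'
#' @param records quality-passed identification records.
#' @param cohort data.frame with `sample_id`, `group` for every cohort
#'   subject (groups `"OC"`, `"BC"`, `"CNT"`).
#' @param min_phenotype_frac within-group prevalence threshold.
#' @param min_carrier_frac carrier-prevalence threshold.
#' @param carrier_denominator `"cohort"`: carriers are subjects with any
#'   passed modified peptide anywhere in the cohort (default);
#'   `"group"`: carriers within the candidate group only.
#' @return list of data.frames (`OC`, `BC`), each with `peptide`,
#'   `ptm_kind`, `site`, `protein`, `n_group`, `frac_group`,
#'   `frac_carriers`; attribute `"n_carriers"`.
#' @export
phenotype_specific_ptms <- function(records, cohort,
                                    min_phenotype_frac = 0.5,
                                    min_carrier_frac = 0.2,
                                    carrier_denominator = c("cohort", "group")) {
  check_id_columns(records)
  carrier_denominator <- match.arg(carrier_denominator)
  stopifnot(all(c("sample_id", "group") %in% names(cohort)))
  unknown <- setdiff(records$sample_id, cohort$sample_id)
  if (length(unknown) > 0) {
    stop("unknown sample(s) in records: ", paste(unknown, collapse = ", "))
  }
  grp <- stats::setNames(cohort$group, cohort$sample_id)
  records$group <- unname(grp[records$sample_id])
  key <- peptide_key(records)
  carriers_all <- unique(records$sample_id)
  out <- list()
  for (g in c("OC", "BC")) {
    n_g <- sum(cohort$group == g)
    if (n_g < 1) { out[[g]] <- NULL; next }
    carriers <- if (carrier_denominator == "cohort") {
      carriers_all
    } else {
      unique(records$sample_id[records$group == g])
    }
    n_car <- length(carriers)
    rows <- list()
    for (k in unique(key)) {
      rk <- records[key == k, , drop = FALSE]
      samp_g <- unique(rk$sample_id[rk$group == g])
      samp_cnt <- unique(rk$sample_id[rk$group == "CNT"])
      samp_car <- intersect(unique(rk$sample_id), carriers)
      frac_g <- length(samp_g) / n_g
      frac_car <- if (n_car > 0) length(samp_car) / n_car else 0
      if (length(samp_cnt) == 0 && frac_g >= min_phenotype_frac &&
            frac_car >= min_carrier_frac) {
        rows[[length(rows) + 1]] <- data.frame(
          peptide = rk$peptide[1], ptm_kind = rk$ptm_kind[1],
          site = rk$site[1], protein = rk$protein[1],
          n_group = length(samp_g), frac_group = frac_g,
          frac_carriers = frac_car, stringsAsFactors = FALSE
        )
      }
    }
    res <- if (length(rows)) do.call(rbind, rows) else data.frame(
      peptide = character(0), ptm_kind = character(0), site = integer(0),
      protein = character(0), n_group = integer(0),
      frac_group = numeric(0), frac_carriers = numeric(0),
      stringsAsFactors = FALSE)
    attr(res, "n_carriers") <- n_car
    out[[g]] <- res
  }
  out
}

#' Distinct peptide and protein counts per group
#'
#' @param sets per-group PTM sets from [phenotype_specific_ptms()].
#' @param protein_map optional named vector peptide -> protein; defaults
#'   to the `protein` column carried in the sets.
#' @return A `curation_result`: per-group distinct modified-peptide and
#'   distinct protein counts with the peptide lists.
#' @export
count_summary <- function(sets, protein_map = NULL) {
  per_group <- lapply(sets, function(s) {
    if (is.null(s) || nrow(s) == 0) {
      return(list(peptides = 0L, proteins = 0L, ptm_list = s))
    }
    key <- paste(s$peptide, s$ptm_kind, s$site)
    s <- s[!duplicated(key), , drop = FALSE]
    prot <- if (is.null(protein_map)) {
      s$protein
    } else {
      mp <- protein_map[s$peptide]
      if (anyNA(mp)) {
        stop("peptide(s) without protein mapping: ",
             paste(s$peptide[is.na(mp)], collapse = ", "))
      }
      unname(mp)
    }
    list(peptides = nrow(s), proteins = length(unique(prot)),
         ptm_list = s)
  })
  structure(list(per_group = per_group), class = "curation_result")
}

#' @export
print.curation_result <- function(x, ...) {
  for (g in names(x$per_group)) {
    cat(sprintf("%s: %d modified peptides from %d proteins\n", g,
                x$per_group[[g]]$peptides, x$per_group[[g]]$proteins))
  }
  invisible(x)
}

#' Differential protein abundance versus the control group
#'
#' Null or missing intensities are replaced by the instrument floor
#' (1e5 counts by default). Per protein and case group: the median-ratio
#' log2 fold change toward the control, the two-sided Wilcoxon rank-sum
#' p-value (exact for small samples without ties, normal approximation
#' with tie correction otherwise), and the detection frequency (fraction
#' of case samples above the floor). A protein is significant when
#' |log2FC| > 1, p < 0.05 and frequency > 0.8; no multiplicity
#' correction is applied.
#'
#' @param intensities numeric matrix, samples x proteins (rownames =
#'   sample ids).
#' @param groups named character vector sample -> group.
#' @param case case group label.
#' @param control control group label.
#' @param floor replacement intensity for null values, counts.
#' @return data.frame, one row per protein: medians, `log2_fc`,
#'   `p_value`, `frequency`, `significant`.
#' @export
differential_abundance <- function(intensities, groups, case = "OC",
                                   control = "CNT", floor = 1e5) {
  stopifnot(is.matrix(intensities))
  sg <- groups[rownames(intensities)]
  if (!case %in% sg || !control %in% sg) stop("group absent: ", case, "/", control)
  ci <- intensities[sg == case, , drop = FALSE]
  ki <- intensities[sg == control, , drop = FALSE]
  if (nrow(ci) < 3 || nrow(ki) < 3) {
    stop("need at least 3 samples per group for the rank-sum test")
  }
  fl <- function(x) { x[is.na(x) | x <= 0] <- floor; pmax(x, floor) }
  out <- lapply(colnames(intensities), function(p) {
    xc <- fl(ci[, p]); xk <- fl(ki[, p])
    med_c <- stats::median(xc); med_k <- stats::median(xk)
    lfc <- log2(med_c / med_k)
    pv <- if (stats::sd(c(xc, xk)) == 0) {
      1  # all-constant protein: test undefined
    } else {
      suppressWarnings(stats::wilcox.test(xc, xk, exact = (length(xc) <= 12 &&
                                                             length(xk) <= 12))$p.value)
    }
    freq <- mean(xc > floor)
    data.frame(protein = p, median_case = med_c, median_control = med_k,
               log2_fc = lfc, p_value = pv, frequency = freq,
               significant = abs(lfc) > 1 & pv < 0.05 & freq > 0.8,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
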