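# End-to-end orchestration: structure -> helices -> motif selection ->
# PTM mounting -> solvent-accessibility deltas -> trajectory verdicts,
# and identification table -> curation -> counts -> differential
# abundance. Every threshold is carried in one config object and echoed
# into the report so each run is auditable.

#' Pipeline configuration
#'
#' All thresholds with their defaults: tight-contact selection (r = d
#' within 0.5 Angstrom, r at most 16 Angstrom, axis fit RMSD at most 1
#' Angstrom), solvent accessibility (probe 1.4 Angstrom, 960 lattice
#' points, environment cutoff 6 Angstrom), curation (98% confidence, 80%
#' coverage, 10 D-score units), phenotype specificity (50% within-group
#' prevalence, 20% carrier prevalence), abundance (1e5-count floor,
#' |log2FC| > 1, p < 0.05, frequency > 0.8), and stability (0.9 stable /
#' 0.5 rupture contact fractions, 2 Angstrom rupture gap).
#'
#' @param ... overrides of the defaults listed above.
#' @return A named list of thresholds.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    r_max = 16, eps_contact = 0.5, rmsd_max = 1.0, proximity_window = 2,
    hairpin_theta = 120, v_max_conn = 5,
    probe_radius = 1.4, n_points = 960, env_cutoff = 6.0,
    confidence_min = 98, coverage_min = 80, d_score_min = 10,
    require_by = TRUE,
    min_phenotype_frac = 0.5, min_carrier_frac = 0.2,
    carrier_denominator = "cohort",
    abundance_floor = 1e5,
    stable_fraction = 0.9, rupture_fraction = 0.5, rupture_gap = 2,
    shift_k = 2, seed = 1L
  )
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad) > 0) stop("unknown config field(s): ", paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  cfg
}

#' Run the structural analysis pipeline on one structure and PTM site
#'
#' Assigns helices, fits axes, selects tight-contact helical pairs
#' covering the PTM site, mounts the moiety, computes the
#' solvent-accessibility delta report, and — when trajectories are given
#' — tracks the pair geometry over both runs and renders the stability
#' verdict.
#'
#' @param pdb path to a PDB file or a `ptm_structure`.
#' @param site list(chain, resno, insert = "") of the modified residue.
#' @param ptm PTM kind (see [ptm_spec()]).
#' @param trajectory_intact,trajectory_modified optional trajectories
#'   (paths or `ptm_trajectory` objects) over the intact and modified
#'   structures.
#' @param spans_modified optional list(span_a, span_b) re-indexed helix
#'   spans in the modified topology (defaults to the intact spans).
#' @param config a [pipeline_config()].
#' @return list with `helices`, `motifs` (selection table; zero rows is
#'   the explicit "no motif under criteria" outcome), `mount`,
#'   `sasa_report`, and optionally `series`, `stats`, `verdict`; plus
#'   the applied `config`.
#' @export
run_structural_pipeline <- function(pdb, site, ptm,
                                    trajectory_intact = NULL,
                                    trajectory_modified = NULL,
                                    spans_modified = NULL,
                                    config = pipeline_config()) {
  st <- if (inherits(pdb, "ptm_structure")) pdb else read_structure(pdb)
  insert <- if (is.null(site$insert)) "" else site$insert
  ridx <- find_residue(st, site$chain, site$resno, insert)
  helices <- assign_helices(st)
  motifs <- select_motifs(
    st, helices, ridx, r_max = config$r_max,
    eps_contact = config$eps_contact, rmsd_max = config$rmsd_max,
    proximity_window = config$proximity_window,
    hairpin_theta = config$hairpin_theta, v_max_conn = config$v_max_conn)
  spec <- ptm_spec(ptm, site$chain, site$resno, insert)
  mount <- mount_ptm(st, spec)
  env <- active_environment(st, ridx, config$env_cutoff)
  sasa_rep <- sasa_delta_report(st, mount$structure, ridx, env,
                                probe_radius = config$probe_radius,
                                n_points = config$n_points)
  out <- list(structure = st, helices = helices, motifs = motifs,
              mount = mount, sasa_report = sasa_rep, config = config)
  if (!is.null(trajectory_intact) && !is.null(trajectory_modified) &&
        nrow(motifs) > 0) {
    tri <- if (inherits(trajectory_intact, "ptm_trajectory")) {
      trajectory_intact
    } else read_trajectory(trajectory_intact)
    trm <- if (inherits(trajectory_modified, "ptm_trajectory")) {
      trajectory_modified
    } else read_trajectory(trajectory_modified)
    span_a <- c(motifs$helix_a_start[1], motifs$helix_a_end[1])
    span_b <- c(motifs$helix_b_start[1], motifs$helix_b_end[1])
    sp_mod <- if (is.null(spans_modified)) {
      list(span_a = span_a, span_b = span_b)
    } else spans_modified
    ser_i <- track_geometry(tri, span_a, span_b, chain = motifs$chain[1])
    ser_m <- track_geometry(trm, sp_mod$span_a, sp_mod$span_b,
                            chain = motifs$chain[1])
    st_i <- summarize_geometry(ser_i)
    st_m <- summarize_geometry(ser_m)
    out$series <- list(intact = ser_i, modified = ser_m)
    out$stats <- list(intact = st_i, modified = st_m)
    out$verdict <- stability_verdict(
      st_m, st_i, ser_m, eps_contact = config$eps_contact,
      stable_fraction = config$stable_fraction,
      rupture_fraction = config$rupture_fraction,
      rupture_gap = config$rupture_gap, k = config$shift_k)
    out$span_mapping <- list(intact = list(span_a = span_a, span_b = span_b),
                             modified = sp_mod)
  }
  out
}

#' Run the curation pipeline on an identification table
#'
#' Applies the PSM-level quality filters, the phenotype-specificity
#' rules, and the distinct peptide/protein count summary; when an
#' intensity matrix is given, adds differential-abundance statistics for
#' each cancer group against the control.
#'
#' @param ids identification table (data.frame or TSV path).
#' @param cohort sample -> group table (data.frame or TSV path); derived
#'   from the records' own `sample_id`/`group` columns when omitted.
#' @param intensities optional samples x proteins matrix.
#' @param config a [pipeline_config()].
#' @return list with `filter_log`, `passed`, `sets`, `counts` (a
#'   `curation_result`), optionally `abundance`, and the applied config.
#' @export
run_curation_pipeline <- function(ids, cohort = NULL, intensities = NULL,
                                  config = pipeline_config()) {
  records <- if (is.character(ids)) {
    utils::read.delim(ids, stringsAsFactors = FALSE)
  } else ids
  check_id_columns(records)
  if (is.null(cohort)) {
    cohort <- unique(records[, c("sample_id", "group")])
  } else if (is.character(cohort)) {
    cohort <- utils::read.delim(cohort, stringsAsFactors = FALSE)
  }
  flt <- filter_identifications(
    records, confidence_min = config$confidence_min,
    coverage_min = config$coverage_min, d_score_min = config$d_score_min,
    require_by = config$require_by)
  sets <- phenotype_specific_ptms(
    flt$passed, cohort, min_phenotype_frac = config$min_phenotype_frac,
    min_carrier_frac = config$min_carrier_frac,
    carrier_denominator = config$carrier_denominator)
  counts <- count_summary(sets)
  out <- list(filter_log = flt$filter_log, passed = flt$passed,
              sets = sets, counts = counts, config = config)
  if (!is.null(intensities)) {
    grp <- stats::setNames(cohort$group, cohort$sample_id)
    out$abundance <- list(
      OC = differential_abundance(intensities, grp, case = "OC",
                                  floor = config$abundance_floor),
      BC = differential_abundance(intensities, grp, case = "BC",
                                  floor = config$abundance_floor))
  }
  out
}

#' Curate the packaged modified-peptide table into per-sample records
#'
#' The packaged peptide list is a curated summary (one row per
#' group-specific modified peptide), not a per-sample table; this helper
#' expands it into one passing record per (row, synthetic carrier
#' sample) so the curation pipeline reproduces the published per-group
#' counts from the fixture alone.
#'
#' @param table1 the `TABLE1` fixture (loaded when omitted).
#' @param n_oc,n_bc,n_cnt cohort sizes.
#' @return list(`records`, `cohort`) ready for
#'   [run_curation_pipeline()].
#' @export
table1_as_records <- function(table1 = load_fixture("TABLE1"),
                              n_oc = 53, n_bc = 24, n_cnt = 30) {
  design <- cohort_design(n_oc = n_oc, n_bc = n_bc, n_cnt = n_cnt,
                          planted = NULL, decoys = FALSE, seed = 101L)
  # planted defaults derive from TABLE1; regenerate with the given table
  key <- paste(table1$peptide, table1$ptm_kind, table1$site)
  groups <- vapply(unique(key), function(k) {
    paste(sort(unique(table1$group[key == k])), collapse = "+")
  }, character(1))
  first <- table1[!duplicated(key), ]
  design$planted <- data.frame(
    peptide = first$peptide, protein = first$gene,
    ptm_kind = first$ptm_kind, site = first$site,
    groups = unname(groups[paste(first$peptide, first$ptm_kind,
                                 first$site)]),
    stringsAsFactors = FALSE
  )
  gen <- make_identification_table(design)
  list(records = gen$records, cohort = gen$cohort)
}
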