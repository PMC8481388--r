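# Tracking the six helical-pair descriptors (d, r, alpha, theta, S, P)
# across trajectory frames and summarizing their means and standard
# deviations into a stability verdict for intact-vs-modified runs.

#' Track helical-pair geometry along a trajectory
#'
#' Both axes are re-fitted on every frame's coordinates (features are
#' recomputed per recorded snapshot, never propagated); frames where an
#' axis fit fails are flagged, not dropped.
#'
#' @param trajectory a `ptm_trajectory`.
#' @param span_a,span_b residue spans of the two helices, as
#'   `c(start, end)` author residue numbers (span_a N-terminal).
#' @param chain chain identifier of the motif.
#' @return A `geometry_series`: data.frame (frame, time, d, r, alpha,
#'   theta, S, P, crossing, flagged) with the frame interval and spans as
#'   attributes.
#' @export
track_geometry <- function(trajectory, span_a, span_b, chain = "A") {
  stopifnot(inherits(trajectory, "ptm_trajectory"))
  frames <- trajectory$frames
  span_res <- function(st, span) {
    ri <- residue_index(st)
    idx <- ri$index[ri$chain == chain & ri$resno >= span[1] &
                      ri$resno <= span[2]]
    if (length(idx) == 0) {
      stop(sprintf("motif residues %d-%d absent from a frame",
                   span[1], span[2]))
    }
    idx
  }
  rows <- vector("list", length(frames))
  for (k in seq_along(frames)) {
    st <- frames[[k]]
    ia <- span_res(st, span_a)
    ib <- span_res(st, span_b)
    g <- tryCatch({
      ax_a <- fit_helix_axis(atom_coords(st, ia, elety = "CA"),
                             atom_coords(st, ia, heavy_only = TRUE))
      ax_b <- fit_helix_axis(atom_coords(st, ib, elety = "CA"),
                             atom_coords(st, ib, heavy_only = TRUE))
      pair_geometry(ax_a, ax_b)
    }, error = function(e) NULL)
    rows[[k]] <- if (is.null(g)) {
      data.frame(frame = k, time = (k - 1) * trajectory$frame_interval,
                 d = NA_real_, r = NA_real_, alpha = NA_real_,
                 theta = NA_real_, S = NA_real_, P = NA_real_,
                 crossing = NA, flagged = TRUE)
    } else {
      data.frame(frame = k, time = (k - 1) * trajectory$frame_interval,
                 d = g$d, r = g$r, alpha = g$alpha, theta = g$theta,
                 S = g$S, P = g$P, crossing = g$crossing, flagged = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "frame_interval") <- trajectory$frame_interval
  attr(out, "span_a") <- span_a
  attr(out, "span_b") <- span_b
  class(out) <- c("geometry_series", "data.frame")
  out
}

#' Means and standard deviations of a geometry series
#'
#' Arithmetic means and population standard deviations over the
#' unflagged frames (flagged frames are excluded and counted).
#'
#' @param series a `geometry_series`.
#' @return A `trajectory_stats`: named lists `mean` and `sd` over the six
#'   descriptors, plus `n_frames`, `n_flagged`.
#' @export
summarize_geometry <- function(series) {
  ok <- !series$flagged
  if (sum(ok) < 2) stop("fewer than 2 usable frames")
  feats <- c("d", "r", "alpha", "theta", "S", "P")
  mu <- vapply(feats, function(f) mean(series[[f]][ok]), numeric(1))
  pop_sd <- vapply(feats, function(f) {
    x <- series[[f]][ok]
    sqrt(mean((x - mean(x))^2))
  }, numeric(1))
  structure(
    list(mean = as.list(mu), sd = as.list(pop_sd),
         n_frames = nrow(series), n_flagged = sum(!ok)),
    class = "trajectory_stats"
  )
}

#' @export
print.trajectory_stats <- function(x, ...) {
  cat(sprintf(
    "<trajectory_stats> %d frames (%d flagged)\n", x$n_frames, x$n_flagged))
  for (f in names(x$mean)) {
    cat(sprintf("  %-6s mean %8.3f  sd %7.3f\n", f, x$mean[[f]], x$sd[[f]]))
  }
  invisible(x)
}

#' Stability verdict for a modified motif versus its intact twin
#'
#' STABLE when the helices stay in contact (|r - d| within the contact
#' tolerance) and keep a non-null projection in at least the required
#' fraction of frames; RUPTURED when contact drops below the rupture
#' fraction or the mean gap r - d opens beyond the rupture gap;
#' FLUCTUATING otherwise. The comparison lists per-feature deltas of
#' modified vs intact means and flags features shifted by more than `k`
#' intact standard deviations.
#'
#' @param modified_stats,intact_stats `trajectory_stats` over the same
#'   motif (spans may be offset between topologies; the caller maps them).
#' @param series_mod the modified run's `geometry_series`.
#' @param eps_contact contact tolerance |r - d|, Angstrom.
#' @param stable_fraction minimal contact / non-null-projection fraction
#'   for STABLE.
#' @param rupture_fraction contact fraction below which the motif is
#'   RUPTURED.
#' @param rupture_gap mean r - d gap (Angstrom) that also means rupture.
#' @param k flag features whose modified mean deviates by more than
#'   `k * sd_intact`.
#' @return A `stability_report`: `verdict`, `contact_fraction`,
#'   `nonnull_projection_fraction`, and the per-feature `comparison`.
#' @export
stability_verdict <- function(modified_stats, intact_stats, series_mod,
                              eps_contact = 0.5, stable_fraction = 0.9,
                              rupture_fraction = 0.5, rupture_gap = 2,
                              k = 2) {
  ok <- !series_mod$flagged
  contact <- mean(abs(series_mod$r[ok] - series_mod$d[ok]) <= eps_contact)
  nonnull <- mean(series_mod$S[ok] > 0)
  gap <- modified_stats$mean$r - modified_stats$mean$d
  verdict <- if (contact < rupture_fraction || gap > rupture_gap) {
    "RUPTURED"
  } else if (contact >= stable_fraction && nonnull >= stable_fraction) {
    "STABLE"
  } else {
    "FLUCTUATING"
  }
  feats <- names(modified_stats$mean)
  comparison <- data.frame(
    feature = feats,
    mean_intact = unlist(intact_stats$mean),
    mean_modified = unlist(modified_stats$mean),
    delta = unlist(modified_stats$mean) - unlist(intact_stats$mean),
    sd_intact = unlist(intact_stats$sd),
    stringsAsFactors = FALSE
  )
  comparison$flagged <- abs(comparison$delta) >
    k * pmax(comparison$sd_intact, 1e-12)
  rownames(comparison) <- NULL
  structure(
    list(verdict = verdict, contact_fraction = contact,
         nonnull_projection_fraction = nonnull, comparison = comparison,
         thresholds = list(eps_contact = eps_contact,
                           stable_fraction = stable_fraction,
                           rupture_fraction = rupture_fraction,
                           rupture_gap = rupture_gap, k = k)),
    class = "stability_report"
  )
}

#' @export
print.stability_report <- function(x, ...) {
  cat(sprintf(
    "<stability_report> %s (contact %.2f, non-null projection %.2f)\n",
    x$verdict, x$contact_fraction, x$nonnull_projection_fraction))
  flg <- x$comparison$feature[x$comparison$flagged]
  if (length(flg)) cat("  shifted features:", paste(flg, collapse = ", "), "\n")
  invisible(x)
}
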