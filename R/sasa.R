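# Solvent-accessible surface area by the Shrake-Rupley rolling-probe
# method, plus the active-environment delta report comparing an intact
# structure with its PTM-mounted twin.
#
# Each heavy atom is expanded to radius r_vdw + probe and covered with a
# deterministic golden-spiral lattice; the accessible fraction of lattice
# points (those outside every neighboring expanded sphere) times the
# expanded-sphere area gives the atom's SASA. Hydrogens are ignored
# throughout, consistent with the PTM builder (heavy atoms only).

#' Default van der Waals radii (Angstrom)
#'
#' @return named numeric vector keyed by element symbol.
#' @export
default_vdw_radii <- function() {
  c(C = 1.76, N = 1.65, O = 1.40, S = 1.85, P = 1.90)
}

# deterministic golden-spiral lattice on the unit sphere
sphere_lattice <- function(n_points) {
  k <- seq_len(n_points) - 0.5
  phi <- acos(1 - 2 * k / n_points)
  theta <- pi * (1 + sqrt(5)) * k
  cbind(cos(theta) * sin(phi), sin(theta) * sin(phi), cos(phi))
}

#' Shrake-Rupley solvent-accessible surface area
#'
#' @param structure a `ptm_structure` with at least one heavy atom.
#' @param probe_radius probe sphere radius, Angstrom.
#' @param n_points lattice points per atom.
#' @param radii named van der Waals radii table (Angstrom) by element.
#' @param default_radius radius used (with a warning) for elements
#'   missing from the table.
#' @return A `sasa_result`: list with `per_atom` (Angstrom^2, aligned to
#'   the heavy-atom rows of the structure), `atoms` (their metadata),
#'   `probe_radius`, `n_points`, `radii_table_id`.
#' @export
compute_sasa <- function(structure, probe_radius = 1.4, n_points = 960,
                         radii = default_vdw_radii(),
                         default_radius = 1.70) {
  a <- structure$atoms[structure$atoms$is_heavy, , drop = FALSE]
  if (nrow(a) == 0) stop("structure has no heavy atoms")
  X <- as.matrix(a[, c("x", "y", "z")])
  el <- a$element
  r <- unname(radii[el])
  unknown <- is.na(r)
  if (any(unknown)) {
    warning("unknown element(s) ", paste(unique(el[unknown]), collapse = ", "),
            ": using default radius ", default_radius, " A")
    r[unknown] <- default_radius
  }
  re <- r + probe_radius
  lattice <- sphere_lattice(n_points)
  n <- nrow(X)
  area <- numeric(n)
  # neighbor prescreen on the maximal contact distance
  max_re <- max(re)
  for (i in seq_len(n)) {
    di <- sqrt(colSums((t(X) - X[i, ])^2))
    nb <- which(di < re[i] + max_re & seq_len(n) != i)
    nb <- nb[di[nb] < re[i] + re[nb]]
    pts <- sweep(lattice * re[i], 2, X[i, ], "+")
    acc <- rep(TRUE, n_points)
    for (j in nb) {
      dj2 <- (pts[, 1] - X[j, 1])^2 + (pts[, 2] - X[j, 2])^2 +
        (pts[, 3] - X[j, 3])^2
      acc <- acc & dj2 > re[j]^2
      if (!any(acc)) break
    }
    area[i] <- 4 * pi * re[i]^2 * sum(acc) / n_points
  }
  structure(
    list(per_atom = area,
         atoms = a[, c("elety", "resid", "chain", "resno", "insert",
                       "res_index", "element")],
         probe_radius = probe_radius, n_points = n_points,
         radii_table_id = "vdw-default"),
    class = "sasa_result"
  )
}

#' Per-residue solvent-accessible area
#'
#' @param sasa a `sasa_result`.
#' @return data.frame: `res_index`, `chain`, `resno`, `insert`, `resid`,
#'   `area` (sum of the residue's atom areas, Angstrom^2).
#' @export
residue_sasa <- function(sasa) {
  agg <- stats::aggregate(sasa$per_atom,
                          by = list(res_index = sasa$atoms$res_index),
                          FUN = sum)
  idx <- match(agg$res_index, sasa$atoms$res_index)
  data.frame(
    res_index = agg$res_index,
    chain = sasa$atoms$chain[idx], resno = sasa$atoms$resno[idx],
    insert = sasa$atoms$insert[idx], resid = sasa$atoms$resid[idx],
    area = agg$x, stringsAsFactors = FALSE
  )
}

#' Active environment of a residue
#'
#' The set of residues with any heavy atom within `cutoff` of any heavy
#' atom of the center residue, always computed on the intact structure so
#' that intact and modified sums run over the same member set.
#'
#' @param structure a `ptm_structure` (the intact structure).
#' @param res_index internal index of the center residue.
#' @param cutoff Angstrom.
#' @return list(`center` = res_index, `members` = integer residue
#'   indices (excluding the center), `cutoff`).
#' @export
active_environment <- function(structure, res_index, cutoff = 6.0) {
  a <- structure$atoms[structure$atoms$is_heavy, , drop = FALSE]
  if (!res_index %in% a$res_index) stop("residue not found: ", res_index)
  ctr <- as.matrix(a[a$res_index == res_index, c("x", "y", "z"),
                     drop = FALSE])
  members <- integer(0)
  if (cutoff > 0) {
    other <- a[a$res_index != res_index, , drop = FALSE]
    if (nrow(other) > 0) {
      Xo <- as.matrix(other[, c("x", "y", "z")])
      mind <- apply(ctr, 1, function(p) sqrt(colSums((t(Xo) - p)^2)))
      near <- apply(mind <= cutoff, 1, any)
      members <- sort(unique(other$res_index[near]))
    }
  }
  list(center = res_index, members = members, cutoff = cutoff)
}

#' Solvent-accessibility delta report for a mounted PTM
#'
#' Compares the modified residue's area and its active-environment area
#' (environment members plus the center residue, so the two sums cover
#' identical residue sets) between the intact structure and its
#' PTM-mounted twin. Moiety atoms are attributed to the modified residue.
#' The modified structure must differ from the intact one only by the
#' mounted moiety atoms.
#'
#' @param intact,modified `ptm_structure` twins.
#' @param res_index internal index of the modified residue.
#' @param env environment from [active_environment()] on the intact
#'   structure; computed at the default cutoff when omitted.
#' @param probe_radius,n_points passed to [compute_sasa()].
#' @return A `sasa_report`: residue and environment areas (intact /
#'   modified, Angstrom^2), their deltas, the member list and parameters.
#' @export
sasa_delta_report <- function(intact, modified, res_index, env = NULL,
                              probe_radius = 1.4, n_points = 960) {
  ai <- intact$atoms
  am <- modified$atoms
  id_i <- paste(ai$chain, ai$resno, ai$insert, ai$elety)
  id_m <- paste(am$chain, am$resno, am$insert, am$elety)
  extra <- setdiff(id_m, id_i)
  if (length(setdiff(id_i, id_m)) > 0) {
    stop("modified structure lacks atoms of the intact one: not a mounted twin")
  }
  same <- id_m %in% id_i
  ci <- as.matrix(ai[match(id_m[same], id_i), c("x", "y", "z")])
  cm <- as.matrix(am[same, c("x", "y", "z")])
  if (max(abs(ci - cm)) > 1e-6) {
    stop("intact atom coordinates moved: structures differ beyond the moiety")
  }
  extra_res <- unique(am$res_index[!same])
  target_key <- with(residue_index(intact),
                     paste(chain, resno, insert)[index == res_index])
  if (length(extra) > 0) {
    extra_keys <- unique(with(am[!same, ], paste(chain, resno, insert)))
    if (!all(extra_keys == target_key)) {
      stop("moiety atoms attached to a residue other than the declared target")
    }
  }
  if (is.null(env)) env <- active_environment(intact, res_index)
  si <- compute_sasa(intact, probe_radius, n_points)
  sm <- compute_sasa(modified, probe_radius, n_points)
  area_of <- function(s, idx_set) sum(s$per_atom[s$atoms$res_index %in% idx_set])
  # residue indices are structure-internal: map via (chain, resno, insert)
  key_i <- with(residue_index(intact), paste(chain, resno, insert))
  key_m <- with(residue_index(modified), paste(chain, resno, insert))
  map_idx <- function(idx_set) {
    match(key_i[match(idx_set, residue_index(intact)$index)], key_m)
  }
  res_m <- residue_index(modified)$index[map_idx(res_index)]
  env_set_i <- c(env$members, res_index)
  env_set_m <- residue_index(modified)$index[map_idx(env_set_i)]
  out <- list(
    res_index = res_index,
    residue_intact = area_of(si, res_index),
    residue_modified = area_of(sm, res_m),
    environment_intact = area_of(si, env_set_i),
    environment_modified = area_of(sm, env_set_m),
    members = env$members, cutoff = env$cutoff,
    probe_radius = probe_radius, n_points = n_points
  )
  out$delta_residue <- out$residue_modified - out$residue_intact
  out$delta_environment <- out$environment_modified - out$environment_intact
  class(out) <- "sasa_report"
  out
}

#' @export
print.sasa_report <- function(x, ...) {
  cat(sprintf(
    paste0("<sasa_report> residue %d: %.2f -> %.2f A^2 (delta %+0.2f); ",
           "environment (%d members + center): %.2f -> %.2f A^2 (delta %+0.2f)\n"),
    x$res_index, x$residue_intact, x$residue_modified, x$delta_residue,
    length(x$members), x$environment_intact, x$environment_modified,
    x$delta_environment))
  invisible(x)
}
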