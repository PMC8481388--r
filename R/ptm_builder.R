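# In-silico mounting of PTM moieties: Nepsilon-acetyl-lysine,
# phospho-Ser/Thr/Tyr, and the Gly-Gly ubiquitination remnant.
#
# Moieties are built heavy-atoms-only from idealized internal coordinates
# on the side-chain anchor atom (NZ for lysine, OG/OG1/OH for Ser/Thr/
# Tyr). The single rotatable anchor dihedral is chosen by a deterministic
# 30-degree grid scan that maximizes the minimum distance between moiety
# atoms and all non-target heavy atoms (a steric, not energetic,
# objective). Existing atoms are never moved.

MONO_MASS <- c(C = 12, H = 1.00782503207, N = 14.0030740048,
               O = 15.9949146196, P = 30.97376163)

PTM_KINDS <- c("ACETYL_K", "PHOSPHO_S", "PHOSPHO_T", "PHOSPHO_Y", "GG_K")

ptm_formula <- function(kind) {
  switch(kind,
         ACETYL_K = c(C = 2, H = 2, O = 1),
         PHOSPHO_S = , PHOSPHO_T = , PHOSPHO_Y = c(H = 1, P = 1, O = 3),
         GG_K = c(C = 4, H = 6, N = 2, O = 2),
         stop("unknown PTM kind: ", kind))
}

ptm_mass_shift <- function(kind) {
  f <- ptm_formula(kind)
  sum(MONO_MASS[names(f)] * f)
}

ptm_target_aa <- function(kind) {
  switch(kind,
         ACETYL_K = "LYS", GG_K = "LYS", PHOSPHO_S = "SER",
         PHOSPHO_T = "THR", PHOSPHO_Y = "TYR")
}

#' Specify a PTM to mount
#'
#' @param kind one of `"ACETYL_K"`, `"PHOSPHO_S"`, `"PHOSPHO_T"`,
#'   `"PHOSPHO_Y"`, `"GG_K"`.
#' @param chain,resno,insert target residue (author numbering).
#' @return A `ptm_spec` with the monoisotopic mass shift (42.0106 Da for
#'   acetyl, 79.9663 for phospho, 114.0429 for the Gly-Gly remnant).
#' @export
ptm_spec <- function(kind, chain, resno, insert = "") {
  kind <- match.arg(kind, PTM_KINDS)
  structure(
    list(kind = kind, chain = chain, resno = resno, insert = insert,
         mass_shift = ptm_mass_shift(kind)),
    class = "ptm_spec"
  )
}

# anchor atom name and its two frame-defining parents per kind/residue
ptm_anchor_frame <- function(kind) {
  switch(kind,
         ACETYL_K = , GG_K = c(anchor = "NZ", parent = "CE",
                               grandparent = "CD"),
         PHOSPHO_S = c(anchor = "OG", parent = "CB", grandparent = "CA"),
         PHOSPHO_T = c(anchor = "OG1", parent = "CB", grandparent = "CA"),
         PHOSPHO_Y = c(anchor = "OH", parent = "CZ", grandparent = "CE1"))
}

# build moiety heavy atoms for a given anchor dihedral (degrees);
# returns named list of 3-vectors in file order
build_moiety <- function(kind, G, Pp, A, dihedral) {
  # G = grandparent, Pp = parent, A = anchor coordinates
  if (kind == "ACETYL_K") {
    C1 <- place_atom(G, Pp, A, 1.33, 120.0, dihedral)
    O1 <- place_atom(Pp, A, C1, 1.23, 121.0, 0)
    CM <- place_atom(Pp, A, C1, 1.50, 116.0, 180)  # sp2 planar amide
    list(CAC = list(el = "C", p = C1), OAC = list(el = "O", p = O1),
         CME = list(el = "C", p = CM))
  } else if (kind %in% c("PHOSPHO_S", "PHOSPHO_T", "PHOSPHO_Y")) {
    P1 <- place_atom(G, Pp, A, 1.61, 119.0, dihedral)
    O1 <- place_atom(Pp, A, P1, 1.52, 109.5, 60)
    O2 <- place_atom(Pp, A, P1, 1.52, 109.5, 180)
    O3 <- place_atom(Pp, A, P1, 1.52, 109.5, -60)
    list(P = list(el = "P", p = P1), O1P = list(el = "O", p = O1),
         O2P = list(el = "O", p = O2), O3P = list(el = "O", p = O3))
  } else if (kind == "GG_K") {
    # proximal glycine (complete: C, O, CA, N) condensed on NZ plus the
    # distal carbonyl (C, O): the 6-heavy-atom reduced remnant
    C1 <- place_atom(G, Pp, A, 1.33, 120.0, dihedral)
    O1 <- place_atom(Pp, A, C1, 1.23, 121.0, 0)
    CA1 <- place_atom(Pp, A, C1, 1.52, 116.0, 180)
    N1 <- place_atom(A, C1, CA1, 1.46, 111.0, 180)
    C2 <- place_atom(C1, CA1, N1, 1.33, 121.5, 180)
    O2 <- place_atom(CA1, N1, C2, 1.23, 121.0, 0)
    list(C1G = list(el = "C", p = C1), O1G = list(el = "O", p = O1),
         CA1 = list(el = "C", p = CA1), N1G = list(el = "N", p = N1),
         C2G = list(el = "C", p = C2), O2G = list(el = "O", p = O2))
  }
}

#' Mount a PTM moiety onto a structure
#'
#' Builds the moiety with idealized internal coordinates (acetyl: N-C
#' 1.33, C=O 1.23, C-CH3 1.50 Angstrom, planar sp2 amide; phospho: O-P
#' 1.61, P-O 1.52 Angstrom, tetrahedral; Gly-Gly: standard peptide-bond
#' geometry on NZ) and selects the anchor dihedral on a 30-degree grid by
#' maximizing the minimum distance to non-target heavy atoms. The intact
#' atoms are untouched; moiety atoms are appended to the target residue
#' as HETATM records.
#'
#' @param structure a `ptm_structure`.
#' @param spec a [ptm_spec()].
#' @param grid_step scan step, degrees.
#' @param clash_floor hard minimum distance (Angstrom); if every rotamer
#'   falls below it, mounting fails with a worst-case report.
#' @return A `mount_result`: `structure` (intact + moiety),
#'   `added_atoms` (their table), `chosen_dihedral` (degrees),
#'   `min_clash_distance` (Angstrom; `Inf` when there are no non-target
#'   atoms), `spec`.
#' @export
mount_ptm <- function(structure, spec, grid_step = 30, clash_floor = 1.5) {
  stopifnot(inherits(spec, "ptm_spec"))
  a <- structure$atoms
  ridx <- find_residue(structure, spec$chain, spec$resno, spec$insert)
  ri <- residue_index(structure)
  aa <- ri$resid[ri$index == ridx]
  want <- ptm_target_aa(spec$kind)
  if (aa != want) {
    stop(sprintf("PTM %s requires %s but residue %s:%s is %s",
                 spec$kind, want, spec$chain, spec$resno, aa))
  }
  fr <- ptm_anchor_frame(spec$kind)
  getp <- function(name) {
    r <- which(a$res_index == ridx & a$elety == name)
    if (length(r) == 0) {
      stop(sprintf("missing anchor atom %s on residue %s:%s",
                   name, spec$chain, spec$resno))
    }
    as.numeric(a[r[1], c("x", "y", "z")])
  }
  A <- getp(fr[["anchor"]])
  Pp <- getp(fr[["parent"]])
  G <- getp(fr[["grandparent"]])
  other <- a[a$is_heavy & a$res_index != ridx, , drop = FALSE]
  Xo <- as.matrix(other[, c("x", "y", "z")])
  min_dist <- function(moiety) {
    if (nrow(Xo) == 0) return(Inf)
    mm <- do.call(rbind, lapply(moiety, `[[`, "p"))
    min(apply(mm, 1, function(p) min(sqrt(colSums((t(Xo) - p)^2)))))
  }
  grid <- seq(0, 360 - grid_step, by = grid_step)
  scores <- vapply(grid, function(dh) {
    min_dist(build_moiety(spec$kind, G, Pp, A, dh))
  }, numeric(1))
  best <- which.max(scores)  # ties: first grid angle (deterministic)
  if (is.finite(scores[best]) && scores[best] < clash_floor) {
    stop(sprintf(
      "all rotamers clash: best minimum moiety distance %.2f A (< %.1f A floor) at dihedral %d deg",
      scores[best], clash_floor, grid[best]))
  }
  moiety <- build_moiety(spec$kind, G, Pp, A, grid[best])
  added <- data.frame(
    type = "HETATM", elety = names(moiety),
    resid = aa, chain = spec$chain, resno = spec$resno,
    insert = spec$insert,
    x = vapply(moiety, function(m) m$p[1], numeric(1)),
    y = vapply(moiety, function(m) m$p[2], numeric(1)),
    z = vapply(moiety, function(m) m$p[3], numeric(1)),
    o = 1,
    element = vapply(moiety, `[[`, character(1), "el"),
    stringsAsFactors = FALSE
  )
  cols <- c("type", "elety", "resid", "chain", "resno", "insert",
            "x", "y", "z", "o", "element")
  out <- new_structure(rbind(a[, cols], added),
                       model_id = structure$model_id,
                       source = structure$source)
  structure(
    list(structure = out, added_atoms = added,
         chosen_dihedral = grid[best],
         min_clash_distance = scores[best], spec = spec),
    class = "mount_result"
  )
}

#' @export
print.mount_result <- function(x, ...) {
  cat(sprintf(
    "<mount_result> %s on %s:%s — %d heavy atoms added, dihedral %g deg, min clash distance %s A\n",
    x$spec$kind, x$spec$chain, x$spec$resno, nrow(x$added_atoms),
    x$chosen_dihedral,
    if (is.finite(x$min_clash_distance)) sprintf("%.2f", x$min_clash_distance)
    else "Inf"))
  invisible(x)
}

#' Steric clash report for a mounted moiety
#'
#' @param result a `mount_result`.
#' @param structure the intact structure the mount was made on.
#' @return list(`min_distance` (Angstrom; `Inf` marker when there are no
#'   non-target atoms), `moiety_atom`, `structure_atom`, `flagged`
#'   (below 2.4 Angstrom)).
#' @export
clash_report <- function(result, structure) {
  a <- structure$atoms
  ridx <- find_residue(structure, result$spec$chain, result$spec$resno,
                       result$spec$insert)
  other <- a[a$is_heavy & a$res_index != ridx, , drop = FALSE]
  mm <- as.matrix(result$added_atoms[, c("x", "y", "z")])
  if (nrow(other) == 0) {
    return(list(min_distance = Inf, moiety_atom = NA_character_,
                structure_atom = NA_character_, flagged = FALSE))
  }
  Xo <- as.matrix(other[, c("x", "y", "z")])
  best <- c(Inf, NA, NA)
  for (i in seq_len(nrow(mm))) {
    dd <- sqrt(colSums((t(Xo) - mm[i, ])^2))
    j <- which.min(dd)
    if (dd[j] < best[1]) best <- c(dd[j], i, j)
  }
  list(min_distance = best[1],
       moiety_atom = result$added_atoms$elety[best[2]],
       structure_atom = sprintf("%s:%s %s", other$chain[best[3]],
                                other$resno[best[3]], other$elety[best[3]]),
       flagged = best[1] < 2.4)
}
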