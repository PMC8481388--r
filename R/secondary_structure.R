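# Helix assignment with the Kabsch-Sander hydrogen-bond method.
#
# A backbone hydrogen bond is recorded between the N-H of a donor residue
# and the C=O of an acceptor residue when the electrostatic energy
#
#   E = 0.084 * 332 * (1/r_ON + 1/r_CH - 1/r_OH - 1/r_CN)  kcal/mol
#     = 27.888 * (...)
#
# falls below -0.5 kcal/mol. An n-turn at residue i is a bond from the
# N-H of residue i+n to the C=O of residue i (n = 3, 4, 5); two
# consecutive n-turns (at i-1 and i) make residues i..i+n-1 helical of
# the matching type: 3/10 (n=3), alpha (n=4), pi (n=5). Overlaps resolve
# with priority alpha > 3/10 > pi.

DSSP_Q <- 27.888        # kcal*Angstrom/mol (q1*q2*332)
DSSP_CUTOFF <- -0.5     # kcal/mol
DSSP_MAXDIST <- 9.0     # CA-CA prescreen, Angstrom

#' Kabsch-Sander hydrogen-bond energy from the four inter-atomic distances
#'
#' @param r_on,r_ch,r_oh,r_cn distances O..N, C..H, O..H, C..N (Angstrom).
#' @return energy in kcal/mol.
#' @export
hbond_energy <- function(r_on, r_ch, r_oh, r_cn) {
  DSSP_Q * (1 / r_on + 1 / r_ch - 1 / r_oh - 1 / r_cn)
}

#' Place missing amide hydrogens
#'
#' For each non-N-terminal residue whose backbone N lacks a hydrogen, an
#' H is added 1.00 Angstrom from N along the unit vector from the
#' previous residue's carbonyl O to its C (the standard convention for
#' PDB entries without experimental hydrogens). Existing amide hydrogens
#' are kept; residues with incomplete backbones are skipped.
#'
#' @param structure a `ptm_structure`.
#' @return The structure with `H` atoms added where needed.
#' @export
place_amide_hydrogens <- function(structure) {
  a <- structure$atoms
  ri <- residue_index(structure)
  add <- list()
  for (k in seq_len(nrow(ri))) {
    i <- ri$index[k]
    rows <- which(a$res_index == i)
    if (any(a$elety[rows] %in% c("H", "HN"))) next
    if (!"N" %in% a$elety[rows]) next
    # previous residue in the same chain, sequence-adjacent
    if (k == 1 || ri$chain[k - 1] != ri$chain[k]) next
    prev <- which(a$res_index == ri$index[k - 1])
    if (!all(c("C", "O") %in% a$elety[prev])) next
    N <- as.numeric(a[rows[a$elety[rows] == "N"][1], c("x", "y", "z")])
    Cp <- as.numeric(a[prev[a$elety[prev] == "C"][1], c("x", "y", "z")])
    Op <- as.numeric(a[prev[a$elety[prev] == "O"][1], c("x", "y", "z")])
    # chain-break guard: peptide bond N..C distance must be plausible
    if (vnorm(N - Cp) > 2.5) next
    H <- N + unitv(Cp - Op)
    add[[length(add) + 1]] <- data.frame(
      type = "ATOM", elety = "H", resid = ri$resid[k],
      chain = ri$chain[k], resno = ri$resno[k], insert = ri$insert[k],
      x = H[1], y = H[2], z = H[3], o = 1, element = "H",
      stringsAsFactors = FALSE
    )
  }
  if (length(add) == 0) return(structure)
  cols <- c("type", "elety", "resid", "chain", "resno", "insert",
            "x", "y", "z", "o", "element")
  new_structure(rbind(a[, cols], do.call(rbind, add)),
                model_id = structure$model_id, source = structure$source)
}

# backbone coordinate table: one row per residue with N, H, C, O, CA
backbone_table <- function(structure) {
  a <- structure$atoms
  ri <- residue_index(structure)
  get1 <- function(i, name) {
    r <- which(a$res_index == i & a$elety == name)
    if (length(r) == 0) return(c(NA_real_, NA_real_, NA_real_))
    as.numeric(a[r[1], c("x", "y", "z")])
  }
  nr <- nrow(ri)
  out <- list(N = matrix(NA_real_, nr, 3), H = matrix(NA_real_, nr, 3),
              C = matrix(NA_real_, nr, 3), O = matrix(NA_real_, nr, 3),
              CA = matrix(NA_real_, nr, 3))
  for (k in seq_len(nr)) {
    i <- ri$index[k]
    out$N[k, ] <- get1(i, "N")
    h <- get1(i, "H")
    if (anyNA(h)) h <- get1(i, "HN")
    out$H[k, ] <- h
    out$C[k, ] <- get1(i, "C")
    out$O[k, ] <- get1(i, "O")
    out$CA[k, ] <- get1(i, "CA")
  }
  out$ri <- ri
  out
}

# energy of the candidate bond donor k_d (N-H) -> acceptor k_a (C=O);
# NA when an atom is missing (excluded from bonding, not an error)
residue_hbond_energy <- function(bb, k_d, k_a) {
  N <- bb$N[k_d, ]; H <- bb$H[k_d, ]
  C <- bb$C[k_a, ]; O <- bb$O[k_a, ]
  if (anyNA(N) || anyNA(H) || anyNA(C) || anyNA(O)) return(NA_real_)
  hbond_energy(vnorm(O - N), vnorm(C - H), vnorm(O - H), vnorm(C - N))
}

#' Assign helical secondary structure
#'
#' Kabsch-Sander helix typing from backbone hydrogen bonds; distinguishes
#' alpha (i+4), 3/10 (i+3) and pi (i+5) helices with overlap priority
#' alpha > 3/10 > pi and minimal lengths 4 / 3 / 5 residues. Amide
#' hydrogens are placed automatically if absent. Chain breaks terminate
#' segments. Segments shorter than 5 residues are flagged as not fittable
#' for axis estimation.
#'
#' @param structure a `ptm_structure`.
#' @param hbond_cutoff bond threshold, kcal/mol.
#' @param types helix types to report.
#' @return data.frame of segments: `chain`, `start_index`, `end_index`
#'   (internal residue indices), `start_resno`, `end_resno` (author
#'   numbers), `helix_type`, `n_res`, `fittable`.
#' @export
assign_helices <- function(structure, hbond_cutoff = DSSP_CUTOFF,
                           types = c("ALPHA", "THREE_TEN", "PI")) {
  structure <- place_amide_hydrogens(structure)
  bb <- backbone_table(structure)
  ri <- bb$ri
  nr <- nrow(ri)
  if (nr < 4) return(empty_helix_table())
  # sequence adjacency within a chain (no break): consecutive internal
  # index, same chain, plausible peptide bond
  adjacent <- function(k1, k2) {
    if (k2 != k1 + 1 || ri$chain[k1] != ri$chain[k2]) return(FALSE)
    if (anyNA(bb$C[k1, ]) || anyNA(bb$N[k2, ])) return(FALSE)
    vnorm(bb$N[k2, ] - bb$C[k1, ]) < 2.5
  }
  chain_ok <- vapply(seq_len(nr - 1), function(k) adjacent(k, k + 1),
                     logical(1))
  # contiguous run id so turns never span a chain break
  run <- cumsum(c(TRUE, !chain_ok))
  turn <- matrix(FALSE, nr, 3)  # columns n = 3, 4, 5
  colnames(turn) <- c("3", "4", "5")
  for (n in 3:5) {
    for (k in seq_len(nr - n)) {
      if (run[k] != run[k + n]) next
      if (!anyNA(bb$CA[k, ]) && !anyNA(bb$CA[k + n, ]) &&
          vnorm(bb$CA[k + n, ] - bb$CA[k, ]) > DSSP_MAXDIST) next
      e <- residue_hbond_energy(bb, k + n, k)
      if (!is.na(e) && e < hbond_cutoff) turn[k, as.character(n)] <- TRUE
    }
  }
  # helix membership per type: two consecutive turns at i-1 and i make
  # residues i .. i+n-1 helical
  member <- matrix(FALSE, nr, 3)
  colnames(member) <- c("3", "4", "5")
  for (n in 3:5) {
    cn <- as.character(n)
    for (k in 2:nr) {
      if (k - 1 >= 1 && turn[k - 1, cn] && k <= nr - n + 1 &&
          k <= nrow(turn) && turn[k, cn]) {
        member[k:(k + n - 1), cn] <- TRUE
      }
    }
  }
  # priority alpha (4) > 3/10 (3) > pi (5)
  state <- rep(NA_character_, nr)
  state[member[, "5"]] <- "PI"
  state[member[, "3"]] <- "THREE_TEN"
  state[member[, "4"]] <- "ALPHA"
  min_len <- c(ALPHA = 4, THREE_TEN = 3, PI = 5)
  segs <- list()
  k <- 1
  while (k <= nr) {
    if (is.na(state[k])) { k <- k + 1; next }
    j <- k
    while (j < nr && !is.na(state[j + 1]) && state[j + 1] == state[k] &&
             run[j + 1] == run[k]) {
      j <- j + 1
    }
    len <- j - k + 1
    if (state[k] %in% types && len >= min_len[[state[k]]]) {
      segs[[length(segs) + 1]] <- data.frame(
        chain = ri$chain[k], start_index = ri$index[k],
        end_index = ri$index[j], start_resno = ri$resno[k],
        end_resno = ri$resno[j], helix_type = state[k], n_res = len,
        fittable = len >= 5, stringsAsFactors = FALSE
      )
    }
    k <- j + 1
  }
  if (length(segs) == 0) return(empty_helix_table())
  out <- do.call(rbind, segs)
  rownames(out) <- NULL
  out
}

empty_helix_table <- function() {
  data.frame(chain = character(0), start_index = integer(0),
             end_index = integer(0), start_resno = integer(0),
             end_resno = integer(0), helix_type = character(0),
             n_res = integer(0), fittable = logical(0),
             stringsAsFactors = FALSE)
}
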