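# Structure and trajectory input/output on the PDB dialect.
#
# The atom table is the common substrate of every downstream stage: one row
# per atom with chain, author residue number, insertion code, 3-letter
# residue code, atom name, element, coordinates (Angstrom), and occupancy.
# Parsing and serialization are delegated to bio3d; this module layers the
# policies the analysis needs (alt-loc resolution by occupancy, water
# removal, MODEL selection, per-frame consistency checks).

#' Construct a structure object from an atom table
#'
#' Internal constructor. Atoms are sorted by chain, then author residue
#' number and insertion code; the residue order defines the internal
#' 1-based residue index used by all geometry code.
#'
#' @param atoms data.frame with columns `type`, `elety`, `resid`, `chain`,
#'   `resno`, `insert`, `x`, `y`, `z`, `o`, `element`.
#' @param model_id integer MODEL number the coordinates came from.
#' @param source provenance string (file path or generator name).
#' @return An object of class `ptm_structure`.
#' @keywords internal
new_structure <- function(atoms, model_id = 1L, source = "memory") {
  stopifnot(is.data.frame(atoms))
  need <- c("type", "elety", "resid", "chain", "resno", "insert",
            "x", "y", "z", "o", "element")
  miss <- setdiff(need, names(atoms))
  if (length(miss) > 0) {
    stop("atom table lacks column(s): ", paste(miss, collapse = ", "))
  }
  atoms$insert[is.na(atoms$insert)] <- ""
  atoms$element <- toupper(trimws(atoms$element))
  if (any(!is.finite(as.matrix(atoms[, c("x", "y", "z")])))) {
    stop("non-finite atom coordinates")
  }
  if (any(atoms$element == "")) stop("empty element symbol in atom table")
  atoms$is_heavy <- atoms$element != "H" & atoms$element != "D"
  # stable sort: keep file order within a residue
  ord <- order(atoms$chain, atoms$resno, atoms$insert)
  atoms <- atoms[ord, , drop = FALSE]
  rownames(atoms) <- NULL
  key <- paste(atoms$chain, atoms$resno, atoms$insert, sep = "|")
  ukey <- unique(key)
  atoms$res_index <- match(key, ukey)
  structure(
    list(atoms = atoms, model_id = as.integer(model_id), source = source),
    class = "ptm_structure"
  )
}

#' @export
print.ptm_structure <- function(x, ...) {
  ri <- residue_index(x)
  cat(sprintf(
    "<ptm_structure> %d atoms (%d heavy), %d residues, %d chain(s); model %d; source: %s\n",
    nrow(x$atoms), sum(x$atoms$is_heavy), nrow(ri),
    length(unique(ri$chain)), x$model_id, x$source))
  invisible(x)
}

#' Residue index of a structure
#'
#' One row per residue in internal order: chain, author residue number,
#' insertion code, 3-letter code, internal index, and a backbone
#' completeness flag (N, CA, C, O all present).
#'
#' @param structure a `ptm_structure`.
#' @return data.frame with columns `index`, `chain`, `resno`, `insert`,
#'   `resid`, `complete_backbone`.
#' @export
residue_index <- function(structure) {
  a <- structure$atoms
  idx <- !duplicated(a$res_index)
  ri <- data.frame(
    index = a$res_index[idx],
    chain = a$chain[idx],
    resno = a$resno[idx],
    insert = a$insert[idx],
    resid = a$resid[idx],
    stringsAsFactors = FALSE
  )
  bb <- vapply(ri$index, function(i) {
    nm <- a$elety[a$res_index == i]
    all(c("N", "CA", "C", "O") %in% nm)
  }, logical(1))
  ri$complete_backbone <- bb
  ri
}

#' Locate a residue by chain and author number
#'
#' @param structure a `ptm_structure`.
#' @param chain one-character chain identifier.
#' @param resno author residue number.
#' @param insert insertion code ("" for none).
#' @return The internal residue index (scalar integer).
#' @export
find_residue <- function(structure, chain, resno, insert = "") {
  a <- structure$atoms
  hit <- which(a$chain == chain & a$resno == resno & a$insert == insert)
  if (length(hit) == 0) {
    stop(sprintf("residue %s:%s%s not found", chain, resno, insert))
  }
  a$res_index[hit[1]]
}

#' Coordinates of selected atoms
#'
#' @param structure a `ptm_structure`.
#' @param res_index optional residue indices to restrict to.
#' @param elety optional atom-name filter (e.g. "CA").
#' @param heavy_only drop hydrogens.
#' @return numeric matrix n x 3.
#' @export
atom_coords <- function(structure, res_index = NULL, elety = NULL,
                        heavy_only = FALSE) {
  a <- structure$atoms
  keep <- rep(TRUE, nrow(a))
  if (!is.null(res_index)) keep <- keep & a$res_index %in% res_index
  if (!is.null(elety)) keep <- keep & a$elety %in% elety
  if (heavy_only) keep <- keep & a$is_heavy
  as.matrix(a[keep, c("x", "y", "z"), drop = FALSE])
}

# resolve alternate locations: keep the highest-occupancy copy of each
# (residue, atom name); ties go to the first listed
resolve_altloc <- function(atoms, policy = c("occupancy", "first")) {
  policy <- match.arg(policy)
  has_alt <- !is.na(atoms$alt) & atoms$alt != ""
  if (!any(has_alt)) {
    atoms$alt <- NULL
    return(atoms)
  }
  key <- paste(atoms$chain, atoms$resno,
               ifelse(is.na(atoms$insert), "", atoms$insert),
               atoms$elety, sep = "|")
  keep <- logical(nrow(atoms))
  for (k in unique(key)) {
    rows <- which(key == k)
    if (length(rows) == 1) {
      keep[rows] <- TRUE
    } else if (policy == "first") {
      keep[rows[1]] <- TRUE
    } else {
      occ <- atoms$o[rows]
      occ[is.na(occ)] <- 0
      keep[rows[which.max(occ)]] <- TRUE  # which.max: ties -> first listed
    }
  }
  atoms <- atoms[keep, , drop = FALSE]
  atoms$alt <- NULL
  atoms
}

WATER_RESID <- c("HOH", "WAT", "DOD", "H2O")

# quick structural scan of a PDB file: MODEL boundaries and per-model
# coordinate-record counts, with light per-line validation
scan_pdb_models <- function(path) {
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  is_coord <- rec %in% c("ATOM  ", "HETATM")
  if (!any(is_coord)) stop("no ATOM record found in ", path)
  bad <- which(is_coord & nchar(lines) < 54)
  if (length(bad) > 0) {
    stop(sprintf("malformed ATOM/HETATM record at line %d of %s",
                 bad[1], path))
  }
  xyz_txt <- substr(lines[is_coord], 31, 54)
  xs <- suppressWarnings(as.numeric(substr(xyz_txt, 1, 8)))
  ys <- suppressWarnings(as.numeric(substr(xyz_txt, 9, 16)))
  zs <- suppressWarnings(as.numeric(substr(xyz_txt, 17, 24)))
  if (anyNA(xs) || anyNA(ys) || anyNA(zs)) {
    bad <- which(is_coord)[which(is.na(xs) | is.na(ys) | is.na(zs))[1]]
    stop(sprintf("malformed ATOM/HETATM record at line %d of %s (bad coordinates)",
                 bad, path))
  }
  model_starts <- which(rec == "MODEL ")
  n_models <- max(1L, length(model_starts))
  # count coordinate records per MODEL block
  if (length(model_starts) == 0) {
    counts <- sum(is_coord)
  } else {
    block <- findInterval(which(is_coord), model_starts)
    counts <- tabulate(block, nbins = length(model_starts))
  }
  list(n_models = n_models, counts = counts)
}

# split a PDB file into per-MODEL line blocks (single-model files yield
# one block covering the whole file)
split_model_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  starts <- which(rec == "MODEL ")
  if (length(starts) == 0) return(list(lines))
  ends <- c(starts[-1] - 1L, length(lines))
  emdl <- which(rec == "ENDMDL")
  lapply(seq_along(starts), function(m) {
    stopi <- emdl[emdl >= starts[m]]
    stopi <- if (length(stopi)) min(stopi, ends[m]) else ends[m]
    lines[starts[m]:stopi]
  })
}

# parse one MODEL block (character lines) through bio3d
parse_model_block <- function(block, altloc = "occupancy") {
  tmp <- tempfile(fileext = ".pdb")
  on.exit(unlink(tmp))
  keep <- substr(block, 1, 6) %in% c("ATOM  ", "HETATM", "TER   ")
  writeLines(c(block[keep], "END"), tmp)
  pdb <- bio3d::read.pdb(tmp, multi = FALSE, rm.alt = FALSE, verbose = FALSE)
  atoms <- pdb$atom
  atoms$insert[is.na(atoms$insert)] <- ""
  atoms$element <- atoms$elesy
  noel <- is.na(atoms$element) | trimws(atoms$element) == ""
  if (any(noel)) {
    # infer element from the atom name (strip leading digits/primes, take
    # the first alphabetic character)
    nm <- gsub("[^A-Za-z].*$", "", gsub("^[0-9']+", "", atoms$elety[noel]))
    atoms$element[noel] <- substr(nm, 1, 1)
  }
  keep_cols <- c("type", "elety", "alt", "resid", "chain", "resno",
                 "insert", "x", "y", "z", "o", "element")
  atoms <- atoms[, keep_cols]
  atoms$o[is.na(atoms$o)] <- 1
  atoms <- atoms[!(atoms$resid %in% WATER_RESID), , drop = FALSE]
  resolve_altloc(atoms, altloc)
}

# read a PDB file into a list of raw atom tables, one per MODEL; `models`
# restricts parsing to the requested MODEL numbers
read_pdb_models <- function(path, altloc = "occupancy", models = NULL,
                            check_counts = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  scan <- scan_pdb_models(path)
  if (check_counts && scan$n_models > 1 &&
      length(unique(scan$counts)) > 1) {
    bad <- which(scan$counts != scan$counts[1])[1]
    stop(sprintf(
      "inconsistent atom count across MODELs in %s: frame %d has %d coordinate records, frame 1 has %d",
      path, bad, scan$counts[bad], scan$counts[1]))
  }
  blocks <- split_model_lines(path)
  if (is.null(models)) models <- seq_along(blocks)
  if (any(models < 1 | models > length(blocks))) {
    stop(sprintf("model out of range: %s has %d MODEL(s)",
                 path, length(blocks)))
  }
  out <- vector("list", length(blocks))
  for (m in models) out[[m]] <- parse_model_block(blocks[[m]], altloc)
  attr(out, "n_models") <- length(blocks)
  out
}

#' Read a protein structure from a PDB file
#'
#' Reads the requested MODEL (default: the first). Alternate locations are
#' resolved per policy (default: highest occupancy, ties to the first
#' listed); water molecules are discarded; hydrogens are retained when
#' present.
#'
#' @param path PDB file.
#' @param model 1-based MODEL to read.
#' @param altloc `"occupancy"` (default) or `"first"`.
#' @return A `ptm_structure`.
#' @export
read_structure <- function(path, model = 1L, altloc = c("occupancy", "first")) {
  altloc <- match.arg(altloc)
  models <- read_pdb_models(path, altloc, models = model)
  new_structure(models[[model]], model_id = model, source = path)
}

#' Read a multi-MODEL PDB file as a trajectory
#'
#' One frame per MODEL record. All frames must share the same atom count
#' and atom identity ordering; a mismatch signals a corrupt trajectory and
#' is an error naming the offending frame.
#'
#' @param path multi-MODEL PDB file.
#' @param frame_interval time between frames (ns).
#' @param altloc alt-loc policy, as in [read_structure()].
#' @return A `ptm_trajectory`: list of frames (each a `ptm_structure`),
#'   `frame_interval`, and `duration = (n_frames - 1) * frame_interval`.
#' @export
read_trajectory <- function(path, frame_interval = 0.005,
                            altloc = c("occupancy", "first")) {
  altloc <- match.arg(altloc)
  models <- read_pdb_models(path, altloc, check_counts = TRUE)
  frames <- lapply(seq_along(models), function(m) {
    new_structure(models[[m]], model_id = m, source = path)
  })
  check_frame_identity(frames, path)
  new_trajectory(frames, frame_interval)
}

new_trajectory <- function(frames, frame_interval = 0.005) {
  structure(
    list(frames = frames,
         frame_interval = frame_interval,
         duration = (length(frames) - 1) * frame_interval),
    class = "ptm_trajectory"
  )
}

check_frame_identity <- function(frames, label = "trajectory") {
  if (length(frames) < 2) return(invisible(TRUE))
  id0 <- with(frames[[1]]$atoms, paste(chain, resno, insert, elety))
  for (m in seq_along(frames)[-1]) {
    idm <- with(frames[[m]]$atoms, paste(chain, resno, insert, elety))
    if (length(idm) != length(id0) || any(idm != id0)) {
      stop(sprintf("frame %d of %s does not match frame 1's atom identity ordering",
                   m, label))
    }
  }
  invisible(TRUE)
}

#' @export
print.ptm_trajectory <- function(x, ...) {
  cat(sprintf("<ptm_trajectory> %d frames, interval %g ns, duration %g ns\n",
              length(x$frames), x$frame_interval, x$duration))
  invisible(x)
}

#' Write a structure (or trajectory) as a PDB file
#'
#' Standard fixed-width ATOM/HETATM records. Reading back preserves atom
#' count, names, residue identities, and coordinates to 0.001 Angstrom.
#'
#' @param structure a `ptm_structure` or `ptm_trajectory` (written as a
#'   multi-MODEL file).
#' @param path output file.
#' @return Invisibly, `path`.
#' @export
write_structure <- function(structure, path) {
  if (inherits(structure, "ptm_trajectory")) {
    frames <- structure$frames
    if (length(frames) == 0) stop("empty trajectory")
    con <- file(path, "w")
    close(con)
    for (m in seq_along(frames)) {
      cat(sprintf("MODEL     %4d\n", m), file = path, append = TRUE)
      write_structure_atoms(frames[[m]], path, append = TRUE)
      cat("ENDMDL\n", file = path, append = TRUE)
    }
    cat("END\n", file = path, append = TRUE)
    return(invisible(path))
  }
  if (!inherits(structure, "ptm_structure")) stop("not a ptm_structure")
  if (nrow(structure$atoms) == 0) stop("refusing to write an empty structure")
  write_structure_atoms(structure, path, append = FALSE)
  cat("END\n", file = path, append = TRUE)
  invisible(path)
}

write_structure_atoms <- function(structure, path, append = FALSE) {
  a <- structure$atoms
  xyz <- as.vector(t(as.matrix(a[, c("x", "y", "z")])))
  bio3d::write.pdb(
    file = path, xyz = xyz, type = a$type, resno = a$resno,
    resid = a$resid, eleno = seq_len(nrow(a)), elety = a$elety,
    chain = a$chain, insert = ifelse(a$insert == "", NA, a$insert),
    o = a$o, b = rep(0, nrow(a)), elesy = a$element,
    append = append, end = FALSE, verbose = FALSE
  )
  invisible(path)
}
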