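# Synthetic structure generators: ideal/perturbed helices, helical pairs
# with prescribed inter-planar geometry, and jittered/drifting
# multi-frame trajectories. These are the ground-truth substrates for the
# axis-fitting, pair-geometry and trajectory modules: every generator
# returns the exact construction parameters alongside the coordinates.

IDEAL_PHI <- -57
IDEAL_PSI <- -47

# idealized backbone internal coordinates (Angstrom / degrees)
BB_N_CA <- 1.46
BB_CA_C <- 1.52
BB_C_N <- 1.33
BB_C_O <- 1.23
ANG_N_CA_C <- 111.0
ANG_CA_C_N <- 116.5
ANG_C_N_CA <- 121.5
ANG_CA_C_O <- 121.0

#' Generate an ideal alpha-helix with a known axis
#'
#' `CA_ONLY` places the Calpha trace exactly on a cylinder of the given
#' radius, rise and twist about the requested axis, so every radial
#' distance equals `radius` by construction. `FULL_BACKBONE` builds N, CA,
#' C, O (and side chains for ALA/LYS/SER/THR/TYR/GLY) from idealized
#' internal coordinates at constant phi/psi = -57/-47 degrees; because the
#' torsions are constant the chain has exact screw symmetry and the
#' returned axis is the analytic screw axis (the cylinder parameters then
#' follow from the torsions rather than from `radius`/`rise`/`twist`).
#'
#' @param n_res number of residues (>= 4).
#' @param radius Calpha cylinder radius, Angstrom (CA_ONLY).
#' @param rise axial rise per residue, Angstrom (CA_ONLY).
#' @param twist rotation per residue, degrees (CA_ONLY).
#' @param phase phase of the first residue, degrees.
#' @param anchor 3-vector: axial projection of the first Calpha.
#' @param direction axis direction (will be normalized), oriented N to C.
#' @param backbone `"CA_ONLY"` or `"FULL_BACKBONE"`.
#' @param chain chain identifier.
#' @param start_resno author residue number of the first residue.
#' @param sequence optional vector of 3-letter residue codes (recycled).
#' @return list with `structure` (a `ptm_structure`) and `axis` (a
#'   `helix_axis` holding the exact construction axis).
#' @export
make_ideal_helix <- function(n_res = 20, radius = 2.3, rise = 1.5,
                             twist = 100, phase = 0,
                             anchor = c(0, 0, 0), direction = c(0, 0, 1),
                             backbone = c("CA_ONLY", "FULL_BACKBONE"),
                             chain = "A", start_resno = 1L,
                             sequence = "ALA") {
  backbone <- match.arg(backbone)
  stopifnot(n_res >= 4, rise > 0)
  direction <- unitv(direction)
  sequence <- rep_len(toupper(sequence), n_res)
  if (backbone == "CA_ONLY") {
    k <- seq_len(n_res) - 1
    ang <- deg2rad(phase + k * twist)
    X <- cbind(radius * cos(ang), radius * sin(ang), k * rise)
    R <- rotation_between(c(0, 0, 1), direction)
    X <- sweep(X %*% t(R), 2, anchor, "+")
    atoms <- data.frame(
      type = "ATOM", elety = "CA", resid = sequence, chain = chain,
      resno = start_resno + k, insert = "",
      x = X[, 1], y = X[, 2], z = X[, 3], o = 1, element = "C",
      stringsAsFactors = FALSE
    )
    axis <- new_helix_axis(anchor, direction, 0, (n_res - 1) * rise,
                           radius, 0)
    return(list(structure = new_structure(atoms, source = "make_ideal_helix"),
                axis = axis))
  }
  built <- build_torsion_helix(n_res, sequence, chain, start_resno)
  scr <- screw_axis_of(built)
  # re-rig: move the screw axis onto (anchor, direction), phase about axis
  ca1 <- built$coords[built$atoms$elety == "CA", , drop = FALSE][1, ]
  a0 <- scr$point + sum((ca1 - scr$point) * scr$dir) * scr$dir
  R <- rotation_between(scr$dir, direction)
  Rp <- rotation_about(direction, phase)
  X <- sweep(built$coords, 2, a0)
  X <- X %*% t(R) %*% t(Rp)
  X <- sweep(X, 2, anchor, "+")
  atoms <- built$atoms
  atoms$x <- X[, 1]; atoms$y <- X[, 2]; atoms$z <- X[, 3]
  ca <- X[atoms$elety == "CA", , drop = FALSE]
  proj <- as.numeric(sweep(ca, 2, anchor) %*% direction)
  axis <- new_helix_axis(anchor, direction, min(proj), max(proj),
                         mean(point_line_distance(ca, anchor, direction)),
                         0)
  list(structure = new_structure(atoms, source = "make_ideal_helix"),
       axis = axis)
}

# build an n-residue chain at constant ideal alpha torsions via natural
# extension (NeRF); returns atoms data.frame (without coords) + coords
build_torsion_helix <- function(n_res, sequence, chain, start_resno,
                                phi = IDEAL_PHI, psi = IDEAL_PSI) {
  coords <- list()
  meta <- list()
  add <- function(res_i, name, el, p) {
    coords[[length(coords) + 1]] <<- p
    meta[[length(meta) + 1]] <<- c(res_i, name, el)
  }
  # seed frame for residue 1
  N <- c(0, 0, 0)
  CA <- c(BB_N_CA, 0, 0)
  C <- CA + BB_CA_C * c(cos(deg2rad(180 - ANG_N_CA_C)),
                        sin(deg2rad(180 - ANG_N_CA_C)), 0)
  for (i in seq_len(n_res)) {
    add(i, "N", "N", N)
    add(i, "CA", "C", CA)
    add(i, "C", "C", C)
    Nn <- place_atom(N, CA, C, BB_C_N, ANG_CA_C_N, psi)
    O <- place_atom(N, CA, C, BB_C_O, ANG_CA_C_O, psi + 180)
    add(i, "O", "O", O)
    for (sc in side_chain_atoms(sequence[i], N, CA, C)) {
      add(i, sc$name, sc$element, sc$coord)
    }
    if (i < n_res) {
      CAn <- place_atom(CA, C, Nn, BB_N_CA, ANG_C_N_CA, 180)
      Cn <- place_atom(C, Nn, CAn, BB_CA_C, ANG_N_CA_C, phi)
      N <- Nn; CA <- CAn; C <- Cn
    }
  }
  meta <- do.call(rbind, meta)
  atoms <- data.frame(
    type = "ATOM", elety = meta[, 2],
    resid = sequence[as.integer(meta[, 1])], chain = chain,
    resno = start_resno + as.integer(meta[, 1]) - 1L, insert = "",
    x = 0, y = 0, z = 0, o = 1, element = meta[, 3],
    stringsAsFactors = FALSE
  )
  list(atoms = atoms, coords = do.call(rbind, coords))
}

# idealized side-chain heavy atoms for the residue types the PTM builder
# targets; extended (all-trans) rotamers so side chains point away from
# the helix body
side_chain_atoms <- function(resid, N, CA, C) {
  if (resid == "GLY") return(list())
  CB <- place_atom(C, N, CA, 1.53, 110.5, -122.5)  # L-configuration
  out <- list(list(name = "CB", element = "C", coord = CB))
  chain_from <- function(A, B, C0, names, bonds, angles, dihedrals,
                         elements) {
    res <- list()
    for (j in seq_along(names)) {
      D <- place_atom(A, B, C0, bonds[j], angles[j], dihedrals[j])
      res[[j]] <- list(name = names[j], element = elements[j], coord = D)
      A <- B; B <- C0; C0 <- D
    }
    res
  }
  if (resid == "LYS") {
    out <- c(out, chain_from(N, CA, CB,
                             c("CG", "CD", "CE", "NZ"),
                             c(1.52, 1.52, 1.52, 1.49),
                             c(114, 111, 111, 112),
                             c(180, 180, 180, 180),
                             c("C", "C", "C", "N")))
  } else if (resid == "SER") {
    out <- c(out, chain_from(N, CA, CB, "OG", 1.41, 110.8, 180, "O"))
  } else if (resid == "THR") {
    out <- c(out,
             chain_from(N, CA, CB, "OG1", 1.43, 109.6, 180, "O"),
             chain_from(N, CA, CB, "CG2", 1.52, 110.5, -60, "C"))
  } else if (resid == "TYR") {
    CG <- place_atom(N, CA, CB, 1.51, 113.9, 180)
    out <- c(out, list(list(name = "CG", element = "C", coord = CG)))
    CD1 <- place_atom(CA, CB, CG, 1.39, 120.8, 90)
    CD2 <- place_atom(CA, CB, CG, 1.39, 120.8, -90)
    CE1 <- place_atom(CB, CG, CD1, 1.39, 121.2, 180)
    CE2 <- place_atom(CB, CG, CD2, 1.39, 121.2, 180)
    CZ <- place_atom(CG, CD1, CE1, 1.39, 119.6, 0)
    OH <- place_atom(CD1, CE1, CZ, 1.38, 119.9, 180)
    ring <- list(CD1 = CD1, CD2 = CD2, CE1 = CE1, CE2 = CE2,
                 CZ = CZ, OH = OH)
    el <- c(rep("C", 5), "O")
    for (j in seq_along(ring)) {
      out <- c(out, list(list(name = names(ring)[j], element = el[j],
                              coord = ring[[j]])))
    }
  } else if (resid != "ALA") {
    # other residue types carry only CB in synthetic structures
  }
  out
}

# analytic screw axis of a constant-torsion chain: the rigid transform
# taking residue i onto residue i+1 is a screw motion whose axis is the
# helix axis
screw_axis_of <- function(built) {
  bb <- built$atoms$elety %in% c("N", "CA", "C", "O")
  res <- built$atoms$resno
  mid <- sort(unique(res))[ceiling(length(unique(res)) / 2)]
  P <- built$coords[bb & res == mid, , drop = FALSE]
  Q <- built$coords[bb & res == mid + 1, , drop = FALSE]
  tr <- kabsch_transform(P, Q)
  R <- tr$R; tvec <- tr$t
  ev <- eigen(R)
  i1 <- which.min(abs(ev$values - 1))
  u <- Re(ev$vectors[, i1])
  u <- unitv(u)
  ca_dir <- colMeans(Q) - colMeans(P)
  if (sum(u * ca_dir) < 0) u <- -u
  # point on axis: (I - R) p = t - (u . t) u, min-norm solution
  A <- diag(3) - R
  b <- tvec - sum(u * tvec) * u
  sv <- svd(A)
  dinv <- ifelse(sv$d > 1e-8, 1 / sv$d, 0)
  p <- sv$v %*% (dinv * (t(sv$u) %*% b))
  list(point = as.numeric(p), dir = u)
}

#' Generate a helical pair with prescribed inter-planar geometry
#'
#' Helix 1 is laid along a base axis in the plane z = 0; helix 2 lies in
#' the parallel plane z = `d`, its direction rotated by `theta` (signed,
#' right-hand rule about the plane normal pointing from plane 1 to plane
#' 2). With `crossing = TRUE` the two axis-segment projections intersect
#' at the prescribed fractional positions, which forces the minimal
#' segment distance r to equal the inter-planar distance d exactly. The
#' implied inter-axial angle is |theta| folded to [0, 90] degrees: for two
#' axes lying in parallel planes the 3-D angle and the in-plane angle
#' coincide.
#'
#' @param d inter-planar distance, Angstrom.
#' @param theta signed torsion angle between the axes, degrees.
#' @param crossing should the projected segments intersect?
#' @param crossing_offset fractional position (0-1) of the projected
#'   crossing along each segment (scalar or length-2).
#' @param lengths residues per helix (length-2).
#' @param connection_length residues in the connecting segment (built as a
#'   Calpha-only linker, excluded from helix assignment).
#' @param separation in-plane offset (Angstrom) used to pull the second
#'   helix away when `crossing = FALSE`.
#' @param backbone passed to [make_ideal_helix()].
#' @param rise,radius,twist Calpha cylinder parameters (CA_ONLY).
#' @param sequence1,sequence2 3-letter residue codes per helix.
#' @param chain chain identifier.
#' @return list with `structure`, `axes` (two `helix_axis`), `geometry`
#'   (the analytic `pair_geometry` of the constructed axes), and the
#'   residue spans `span1`, `span2` (author residue numbers).
#' @export
make_helix_pair <- function(d = 11.7, theta = -57, crossing = TRUE,
                            crossing_offset = 0.5, lengths = c(16, 16),
                            connection_length = 5, separation = 25,
                            backbone = c("CA_ONLY", "FULL_BACKBONE"),
                            rise = 1.5, radius = 2.3, twist = 100,
                            sequence1 = "ALA", sequence2 = "ALA",
                            chain = "A") {
  backbone <- match.arg(backbone)
  stopifnot(d >= 0, abs(theta) <= 180, length(lengths) == 2)
  f <- rep_len(crossing_offset, 2)
  if (any(f <= 0 | f >= 1) && crossing) stop("infeasible crossing_offset")
  u_a <- c(1, 0, 0)
  u_b <- as.numeric(rotation_about(c(0, 0, 1), theta) %*% u_a)
  L <- (lengths - 1) * rise
  anchor_a <- c(-f[1] * L[1], 0, 0)
  anchor_b <- c(0, 0, d) - f[2] * L[2] * u_b
  if (!crossing) {
    # slide helix 2 along its own direction so the projections no longer
    # overlap (a V/L-like open pair)
    anchor_b <- anchor_b + separation * u_b
  }
  h1 <- make_ideal_helix(lengths[1], radius = radius, rise = rise,
                         twist = twist, anchor = anchor_a,
                         direction = u_a, backbone = backbone,
                         chain = chain, start_resno = 1L,
                         sequence = sequence1)
  h2 <- make_ideal_helix(lengths[2], radius = radius, rise = rise,
                         twist = twist, anchor = anchor_b,
                         direction = u_b, backbone = backbone,
                         chain = chain,
                         start_resno = lengths[1] + connection_length + 1L,
                         sequence = sequence2)
  atoms <- rbind(h1$structure$atoms[, setdiff(names(h1$structure$atoms),
                                              c("is_heavy", "res_index"))],
                 h2$structure$atoms[, setdiff(names(h2$structure$atoms),
                                              c("is_heavy", "res_index"))])
  if (connection_length > 0) {
    a1 <- h1$structure$atoms
    a2 <- h2$structure$atoms
    ca_end <- as.numeric(a1[a1$elety == "CA" & a1$resno == lengths[1],
                            c("x", "y", "z")])
    ca_beg <- as.numeric(a2[a2$elety == "CA" &
                              a2$resno == lengths[1] + connection_length + 1L,
                            c("x", "y", "z")][1, ])
    tfrac <- seq_len(connection_length) / (connection_length + 1)
    link <- t(vapply(tfrac, function(s) ca_end + s * (ca_beg - ca_end),
                     numeric(3)))
    atoms <- rbind(atoms, data.frame(
      type = "ATOM", elety = "CA", resid = "GLY", chain = chain,
      resno = lengths[1] + seq_len(connection_length), insert = "",
      x = link[, 1], y = link[, 2], z = link[, 3], o = 1, element = "C",
      stringsAsFactors = FALSE
    ))
  }
  st <- new_structure(atoms, source = "make_helix_pair")
  geom <- pair_geometry(h1$axis, h2$axis)
  list(structure = st, axes = list(h1$axis, h2$axis), geometry = geom,
       span1 = c(1L, lengths[1]),
       span2 = c(lengths[1] + connection_length + 1L,
                 lengths[1] + connection_length + lengths[2]),
       connection_length = connection_length)
}

#' Generate a jittered / drifting synthetic trajectory
#'
#' Frame k carries i.i.d. Gaussian coordinate jitter of the given standard
#' deviation plus, optionally, a cumulative per-frame translation of a
#' residue span (emulating one helix drifting away). Reproducible under
#' the seed; frame 1 of a drift-free, jitter-free trajectory is the input
#' structure itself.
#'
#' @param structure a `ptm_structure`.
#' @param n_frames number of frames (>= 1).
#' @param jitter_sd Gaussian jitter per coordinate, Angstrom.
#' @param drift optional list(res_index = residue indices, step = 3-vector
#'   Angstrom/frame): span translated by `(k - 1) * step` in frame k.
#' @param seed RNG seed (mandatory for reproducibility).
#' @param frame_interval time between frames, ns.
#' @return A `ptm_trajectory`.
#' @export
make_trajectory <- function(structure, n_frames = 100, jitter_sd = 0,
                            drift = NULL, seed = 1L,
                            frame_interval = 0.005) {
  stopifnot(inherits(structure, "ptm_structure"), n_frames >= 1)
  set.seed(seed)
  X0 <- as.matrix(structure$atoms[, c("x", "y", "z")])
  drift_rows <- if (!is.null(drift)) {
    which(structure$atoms$res_index %in% drift$res_index)
  } else integer(0)
  frames <- vector("list", n_frames)
  for (k in seq_len(n_frames)) {
    X <- X0
    if (jitter_sd > 0) {
      X <- X + matrix(stats::rnorm(length(X), sd = jitter_sd), ncol = 3)
    }
    if (length(drift_rows) > 0) {
      X[drift_rows, ] <- sweep(X[drift_rows, , drop = FALSE], 2,
                               (k - 1) * drift$step, "+")
    }
    fr <- structure
    fr$atoms$x <- X[, 1]; fr$atoms$y <- X[, 2]; fr$atoms$z <- X[, 3]
    fr$model_id <- k
    frames[[k]] <- fr
  }
  new_trajectory(frames, frame_interval)
}
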