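# Helical-pair geometry: least-squares helix axes and the six-descriptor
# characterization of a pair of helices.
#
# Two helix axes lying in space admit a unique pair of parallel planes,
# one through each axis. The pair is then described by: d, the
# inter-planar distance; r, the minimal distance between the two finite
# axis segments (r = d exactly when the projected segments cross); alpha,
# the unsigned inter-axial angle folded to [0, 90] degrees; theta, the
# signed torsion (dihedral) of axis 1 onto axis 2 about the inter-plane
# normal; and S, P, the area and perimeter of the intersection of the two
# cylinder-silhouette rectangles projected onto the mid-plane.

new_helix_axis <- function(anchor, direction, seg_start, seg_end,
                           radius, fit_rmsd) {
  direction <- unitv(direction)
  if (seg_end <= seg_start) stop("degenerate axis segment")
  structure(
    list(anchor = as.numeric(anchor), direction = direction,
         seg_start = seg_start, seg_end = seg_end,
         radius = radius, fit_rmsd = fit_rmsd),
    class = "helix_axis"
  )
}

#' @export
print.helix_axis <- function(x, ...) {
  cat(sprintf(
    "<helix_axis> dir (%.3f, %.3f, %.3f), span %.2f A, radius %.2f A, fit rmsd %.3f A\n",
    x$direction[1], x$direction[2], x$direction[3],
    x$seg_end - x$seg_start, x$radius, x$fit_rmsd))
  invisible(x)
}

# segment endpoints in 3-D
axis_endpoints <- function(axis) {
  list(p = axis$anchor + axis$seg_start * axis$direction,
       q = axis$anchor + axis$seg_end * axis$direction)
}

#' Fit a helix axis by least squares
#'
#' Finds the line minimizing the variance of point-to-line radial
#' distances of the Calpha trace — the cylinder axis the helix is wound
#' on. The search is initialized from the principal direction of the
#' point cloud and refined by Nelder-Mead over the axis orientation and
#' its in-plane offset. The cylinder radius is the mean radial distance
#' over `heavy_coords` when given (the all-heavy-atom silhouette radius
#' used for projection rectangles), else over the Calpha set; `fit_rmsd`
#' is the standard deviation of the Calpha radial distances — the axis
#' quality measure used by motif selection.
#'
#' @param ca_coords n x 3 matrix of Calpha coordinates, N- to C-terminal
#'   order (n >= 5).
#' @param heavy_coords optional m x 3 matrix of all heavy atoms of the
#'   helix, used for the radius.
#' @return A `helix_axis`; direction is oriented N to C, `seg_start` /
#'   `seg_end` are the axial projections of the first/last Calpha
#'   relative to `anchor`.
#' @export
fit_helix_axis <- function(ca_coords, heavy_coords = NULL) {
  X <- as.matrix(ca_coords)
  n <- nrow(X)
  if (n < 5) stop("need at least 5 Calpha points to fit a helix axis")
  ctr <- colMeans(X)
  Xc <- sweep(X, 2, ctr)
  sv <- svd(Xc)
  v0 <- sv$v[, 1]
  # collinearity guard: points on a line have no cylinder
  if (sv$d[2] < 1e-8 * max(sv$d[1], 1)) stop("collinear points: degenerate cylinder")
  # parametrize the axis as (center + a*e1 + b*e2, direction(angles))
  obj <- function(par) {
    u <- sph_dir(par[1], par[2])
    basis <- plane_basis(u)
    a <- ctr + par[3] * basis$e1 + par[4] * basis$e2
    rr <- point_line_distance(X, a, u)
    stats::var(rr)
  }
  p0 <- c(dir_sph(v0), 0, 0)
  opt <- stats::optim(p0, obj, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-12))
  u <- sph_dir(opt$par[1], opt$par[2])
  basis <- plane_basis(u)
  a <- ctr + opt$par[3] * basis$e1 + opt$par[4] * basis$e2
  # orient N -> C
  if (sum(u * (X[n, ] - X[1, ])) < 0) u <- -u
  proj <- as.numeric(sweep(X, 2, a) %*% u)
  rr <- point_line_distance(X, a, u)
  rad_set <- if (!is.null(heavy_coords)) {
    point_line_distance(as.matrix(heavy_coords), a, u)
  } else rr
  # re-anchor at the axial foot of the first Calpha
  anchor <- a + proj[1] * u
  new_helix_axis(anchor, u, 0, proj[n] - proj[1],
                 radius = mean(rad_set),
                 fit_rmsd = stats::sd(rr))
}

sph_dir <- function(theta, phi) {
  c(sin(theta) * cos(phi), sin(theta) * sin(phi), cos(theta))
}

dir_sph <- function(u) {
  u <- unitv(u)
  c(acos(max(-1, min(1, u[3]))), atan2(u[2], u[1]))
}

plane_basis <- function(u) {
  p <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- unitv(cross3(u, p))
  e2 <- cross3(u, e1)
  list(e1 = e1, e2 = e2)
}

#' Parallel planes through two helix axes
#'
#' Through two non-intersecting straight lines one can draw two parallel
#' planes, each containing one line; their common normal is the cross
#' product of the directions. Returns the unit normal signed to point
#' from the plane of `axis_a` to the plane of `axis_b`, and the distance
#' `d` between the planes. For (near-)parallel axes the normal falls back
#' to the inter-anchor component perpendicular to the common direction
#' and `d` to the line-to-line distance.
#'
#' @param axis_a,axis_b `helix_axis` objects.
#' @return list(normal = unit 3-vector, d = Angstrom).
#' @export
pair_planes <- function(axis_a, axis_b) {
  ua <- axis_a$direction; ub <- axis_b$direction
  w <- axis_b$anchor - axis_a$anchor
  cr <- cross3(ua, ub)
  if (vnorm(cr) < 1e-8) {
    perp <- w - sum(w * ua) * ua
    d <- vnorm(perp)
    normal <- if (d < 1e-12) plane_basis(ua)$e1 else unitv(perp)
    return(list(normal = normal, d = d))
  }
  normal <- unitv(cr)
  d_signed <- sum(w * normal)
  if (d_signed < 0) {
    normal <- -normal
    d_signed <- -d_signed
  }
  list(normal = normal, d = d_signed)
}

# minimal distance between two finite 3-D segments (closed form; standard
# clamped quadratic minimization)
segment_min_distance <- function(p1, q1, p2, q2) {
  d1 <- q1 - p1; d2 <- q2 - p2; r <- p1 - p2
  a <- sum(d1 * d1); e <- sum(d2 * d2); f <- sum(d2 * r)
  if (a < 1e-14 && e < 1e-14) return(vnorm(r))
  if (a < 1e-14) {
    t <- max(0, min(1, f / e))
    return(vnorm(p1 - (p2 + t * d2)))
  }
  c_ <- sum(d1 * r)
  if (e < 1e-14) {
    s <- max(0, min(1, -c_ / a))
    return(vnorm(p1 + s * d1 - p2))
  }
  b <- sum(d1 * d2)
  denom <- a * e - b * b
  s <- if (denom > 1e-14) max(0, min(1, (b * f - c_ * e) / denom)) else 0
  t <- (b * s + f) / e
  if (t < 0) {
    t <- 0; s <- max(0, min(1, -c_ / a))
  } else if (t > 1) {
    t <- 1; s <- max(0, min(1, (b - c_) / a))
  }
  vnorm(p1 + s * d1 - (p2 + t * d2))
}

# project the axis segment of `axis` onto the plane (origin, e1, e2)
project_segment_2d <- function(axis, origin, e1, e2) {
  ep <- axis_endpoints(axis)
  rbind(c(sum((ep$p - origin) * e1), sum((ep$p - origin) * e2)),
        c(sum((ep$q - origin) * e1), sum((ep$q - origin) * e2)))
}

# do two 2-D segments intersect (including touching)?
segments_intersect_2d <- function(a, b) {
  d1 <- a[2, ] - a[1, ]; d2 <- b[2, ] - b[1, ]
  denom <- d1[1] * d2[2] - d1[2] * d2[1]
  w <- b[1, ] - a[1, ]
  if (abs(denom) < 1e-12) {
    # parallel: check collinear overlap
    if (abs(w[1] * d1[2] - w[2] * d1[1]) > 1e-9) return(FALSE)
    t0 <- sum(w * d1) / sum(d1 * d1)
    t1 <- t0 + sum(d2 * d1) / sum(d1 * d1)
    return(max(min(t0, t1), 0) <= min(max(t0, t1), 1))
  }
  s <- (w[1] * d2[2] - w[2] * d2[1]) / denom
  t <- (w[1] * d1[2] - w[2] * d1[1]) / denom
  s >= -1e-9 && s <= 1 + 1e-9 && t >= -1e-9 && t <= 1 + 1e-9
}

# Sutherland-Hodgman clipping of convex polygon `subject` by convex
# polygon `clip` (both counter-clockwise n x 2 matrices)
convex_clip <- function(subject, clip) {
  out <- subject
  nc <- nrow(clip)
  for (i in seq_len(nc)) {
    if (nrow(out) == 0) return(out)
    A <- clip[i, ]; B <- clip[(i %% nc) + 1, ]
    edge <- B - A
    inside <- function(p) {
      edge[1] * (p[2] - A[2]) - edge[2] * (p[1] - A[1]) >= -1e-9
    }
    inter <- function(p, q) {
      dpq <- q - p
      denom <- edge[1] * dpq[2] - edge[2] * dpq[1]
      t <- (edge[1] * (A[2] - p[2]) - edge[2] * (A[1] - p[1])) / denom
      p + t * dpq
    }
    res <- matrix(numeric(0), ncol = 2)
    np <- nrow(out)
    for (j in seq_len(np)) {
      P <- out[j, ]; Q <- out[(j %% np) + 1, ]
      pin <- inside(P); qin <- inside(Q)
      if (pin && qin) {
        res <- rbind(res, Q)
      } else if (pin && !qin) {
        res <- rbind(res, inter(P, Q))
      } else if (!pin && qin) {
        res <- rbind(res, inter(P, Q), Q)
      }
    }
    out <- res
  }
  out
}

# ensure counter-clockwise vertex order
ccw <- function(poly) {
  n <- nrow(poly)
  s <- sum(poly[, 1] * poly[c(2:n, 1), 2] - poly[c(2:n, 1), 1] * poly[, 2])
  if (s < 0) poly[n:1, , drop = FALSE] else poly
}

polygon_area <- function(poly) {
  if (is.null(poly) || nrow(poly) < 3) return(0)
  n <- nrow(poly)
  abs(sum(poly[, 1] * poly[c(2:n, 1), 2] -
            poly[c(2:n, 1), 1] * poly[, 2])) / 2
}

polygon_perimeter <- function(poly) {
  if (is.null(poly) || nrow(poly) < 2) return(0)
  n <- nrow(poly)
  sum(sqrt(rowSums((poly[c(2:n, 1), , drop = FALSE] - poly)^2)))
}

# cylinder silhouette rectangle of an axis in mid-plane coordinates
silhouette_rect <- function(axis, origin, e1, e2) {
  seg <- project_segment_2d(axis, origin, e1, e2)
  u2 <- seg[2, ] - seg[1, ]
  nu <- sqrt(sum(u2 * u2))
  if (nu < 1e-12) stop("degenerate (zero-length) projected segment")
  u2 <- u2 / nu
  w2 <- c(-u2[2], u2[1]) * axis$radius
  ccw(rbind(seg[1, ] + w2, seg[2, ] + w2, seg[2, ] - w2, seg[1, ] - w2))
}

#' Projection-intersection area and perimeter of a helical pair
#'
#' Each helix is projected onto the mid-plane (parallel to both axes,
#' halfway between their planes) as the silhouette rectangle of its
#' cylinder: length = axial segment length, width = twice the fitted
#' radius. S and P are the area and perimeter of the convex intersection
#' polygon of the two rectangles; an empty intersection gives S = P = 0.
#'
#' @param axis_a,axis_b `helix_axis` objects.
#' @return list(S = area in square Angstrom, P = perimeter in Angstrom,
#'   polygon = k x 2 vertex matrix in mid-plane coordinates).
#' @export
projection_intersection <- function(axis_a, axis_b) {
  pl <- pair_planes(axis_a, axis_b)
  origin <- axis_a$anchor + (pl$d / 2) * pl$normal
  basis <- plane_basis(pl$normal)
  ra <- silhouette_rect(axis_a, origin, basis$e1, basis$e2)
  rb <- silhouette_rect(axis_b, origin, basis$e1, basis$e2)
  poly <- convex_clip(ra, rb)
  poly <- dedup_poly(poly)
  list(S = polygon_area(poly), P = polygon_perimeter(poly), polygon = poly)
}

dedup_poly <- function(poly) {
  if (is.null(poly) || nrow(poly) < 2) return(poly)
  keep <- c(TRUE, rowSums((poly[-1, , drop = FALSE] -
                             poly[-nrow(poly), , drop = FALSE])^2) > 1e-16)
  poly <- poly[keep, , drop = FALSE]
  if (nrow(poly) > 1 && sum((poly[1, ] - poly[nrow(poly), ])^2) < 1e-16) {
    poly <- poly[-nrow(poly), , drop = FALSE]
  }
  poly
}

#' Full six-descriptor geometry of a helical pair
#'
#' @param axis_a,axis_b `helix_axis` objects (axis_a N-terminal).
#' @param eps_contact tolerance (Angstrom) for the crossing/contact flag.
#' @return A `pair_geometry`: list with `d`, `r`, `alpha`, `theta`, `S`,
#'   `P`, `crossing`, `polygon`.
#' @export
pair_geometry <- function(axis_a, axis_b, eps_contact = 0.5) {
  pl <- pair_planes(axis_a, axis_b)
  ea <- axis_endpoints(axis_a)
  eb <- axis_endpoints(axis_b)
  r <- segment_min_distance(ea$p, ea$q, eb$p, eb$q)
  ua <- axis_a$direction; ub <- axis_b$direction
  cosab <- max(-1, min(1, sum(ua * ub)))
  alpha <- rad2deg(acos(abs(cosab)))
  # signed torsion about the a->b plane normal, right-hand rule
  sin_comp <- sum(cross3(ua, ub) * pl$normal)
  theta <- rad2deg(atan2(sin_comp, cosab))
  if (theta <= -180) theta <- theta + 360
  origin <- axis_a$anchor + (pl$d / 2) * pl$normal
  basis <- plane_basis(pl$normal)
  sa <- project_segment_2d(axis_a, origin, basis$e1, basis$e2)
  sb <- project_segment_2d(axis_b, origin, basis$e1, basis$e2)
  crossing <- segments_intersect_2d(sa, sb)
  pi_ <- projection_intersection(axis_a, axis_b)
  structure(
    list(d = pl$d, r = r, alpha = alpha, theta = theta,
         S = pi_$S, P = pi_$P, crossing = crossing, polygon = pi_$polygon),
    class = "pair_geometry"
  )
}

#' @export
print.pair_geometry <- function(x, ...) {
  cat(sprintf(
    "<pair_geometry> d %.2f A, r %.2f A, alpha %.1f deg, theta %.1f deg, S %.1f A^2, P %.1f A, %s\n",
    x$d, x$r, x$alpha, x$theta, x$S, x$P,
    if (x$crossing) "crossing" else "non-crossing"))
  invisible(x)
}

#' Classify a helical pair into a supersecondary motif class
#'
#' Crossing pairs are alpha-alpha motifs: hairpins when nearly
#' antiparallel (|theta| at or above the hairpin threshold), corners
#' otherwise. Non-crossing pairs (d < r, near-null projection overlap)
#' are V-structures when the connection is short and L-structures
#' otherwise.
#'
#' @param geometry a `pair_geometry`.
#' @param connection_length residues between the helices.
#' @param hairpin_theta |theta| threshold (degrees) separating hairpins
#'   from corners.
#' @param v_max_conn maximal connection length (residues) for a
#'   V-structure.
#' @return one of `"AA_CORNER"`, `"AA_HAIRPIN"`, `"V_STRUCTURE"`,
#'   `"L_STRUCTURE"`.
#' @export
classify_motif <- function(geometry, connection_length,
                           hairpin_theta = 120, v_max_conn = 5) {
  if (geometry$crossing) {
    if (abs(geometry$theta) >= hairpin_theta) "AA_HAIRPIN" else "AA_CORNER"
  } else {
    if (connection_length <= v_max_conn) "V_STRUCTURE" else "L_STRUCTURE"
  }
}

#' Select PTM-bearing helical pairs in tight contact
#'
#' Applies the motif-selection criteria to all helix pairs of a
#' structure (any number of intervening helices): the modified residue
#' must sit on one of the pair's helices, on the connecting chain between
#' them, or within a proximity window of a helix end; the axes must be
#' well fitted (fit_rmsd below `rmsd_max`); the helices must be in tight
#' contact — minimal and inter-planar distances equal within
#' `eps_contact` and at most `r_max` (16 Angstrom by default) — with a
#' non-null projection intersection (S > 0, P > 0).
#'
#' @param structure a `ptm_structure`.
#' @param helices helix segment table from [assign_helices()].
#' @param site internal residue index of the modified residue (see
#'   [find_residue()]).
#' @param r_max maximal contact distance, Angstrom.
#' @param eps_contact |r - d| tolerance, Angstrom.
#' @param rmsd_max maximal axis fit RMSD, Angstrom.
#' @param proximity_window residues beyond a helix end still counted as
#'   "close to" the helix.
#' @param hairpin_theta,v_max_conn passed to [classify_motif()].
#' @return data.frame, one row per retained pair: helix spans, the six
#'   descriptors, fit RMSDs, and motif class; attribute `"pairs"` holds
#'   the full per-pair list (axes and geometry objects).
#' @export
select_motifs <- function(structure, helices, site, r_max = 16,
                          eps_contact = 0.5, rmsd_max = 1.0,
                          proximity_window = 2, hairpin_theta = 120,
                          v_max_conn = 5) {
  ri <- residue_index(structure)
  if (!site %in% ri$index) stop("modified residue absent from structure")
  if (nrow(helices) < 2) {
    return(empty_motif_table())
  }
  axes <- lapply(seq_len(nrow(helices)), function(i) {
    span <- helices$start_index[i]:helices$end_index[i]
    ca <- atom_coords(structure, res_index = span, elety = "CA")
    heavy <- atom_coords(structure, res_index = span, heavy_only = TRUE)
    if (nrow(ca) < 5) return(NULL)
    fit_helix_axis(ca, heavy)
  })
  rows <- list()
  pairs <- list()
  for (i in seq_len(nrow(helices) - 1)) {
    for (j in (i + 1):nrow(helices)) {
      if (helices$chain[i] != helices$chain[j]) next
      ax_i <- axes[[i]]; ax_j <- axes[[j]]
      if (is.null(ax_i) || is.null(ax_j)) next
      if (ax_i$fit_rmsd > rmsd_max || ax_j$fit_rmsd > rmsd_max) next
      # PTM residue on a helix of the pair or on the chain between them
      lo <- helices$start_index[i] - proximity_window
      hi <- helices$end_index[j] + proximity_window
      if (site < lo || site > hi) next
      geom <- pair_geometry(ax_i, ax_j, eps_contact)
      if (abs(geom$r - geom$d) > eps_contact) next
      if (geom$r > r_max) next
      if (geom$S <= 0 || geom$P <= 0) next
      conn <- helices$start_index[j] - helices$end_index[i] - 1
      cls <- classify_motif(geom, conn, hairpin_theta, v_max_conn)
      rows[[length(rows) + 1]] <- data.frame(
        chain = helices$chain[i],
        helix_a_start = helices$start_resno[i],
        helix_a_end = helices$end_resno[i],
        helix_b_start = helices$start_resno[j],
        helix_b_end = helices$end_resno[j],
        connection_length = conn,
        d = geom$d, r = geom$r, alpha = geom$alpha, theta = geom$theta,
        S = geom$S, P = geom$P,
        fit_rmsd_a = ax_i$fit_rmsd, fit_rmsd_b = ax_j$fit_rmsd,
        motif_class = cls, stringsAsFactors = FALSE
      )
      pairs[[length(pairs) + 1]] <- list(
        helix_a = i, helix_b = j, axes = list(ax_i, ax_j),
        geometry = geom, connection_length = conn, motif_class = cls)
    }
  }
  if (length(rows) == 0) return(empty_motif_table())
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "pairs") <- pairs
  out
}

empty_motif_table <- function() {
  out <- data.frame(
    chain = character(0), helix_a_start = integer(0),
    helix_a_end = integer(0), helix_b_start = integer(0),
    helix_b_end = integer(0), connection_length = integer(0),
    d = numeric(0), r = numeric(0), alpha = numeric(0),
    theta = numeric(0), S = numeric(0), P = numeric(0),
    fit_rmsd_a = numeric(0), fit_rmsd_b = numeric(0),
    motif_class = character(0), stringsAsFactors = FALSE
  )
  attr(out, "pairs") <- list()
  out
}
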