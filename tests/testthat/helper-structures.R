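# Shared generated fixtures (built once per test run).

helix20_full <- local({
  val <- NULL
  function() {
    if (is.null(val)) val <<- make_ideal_helix(20, backbone = "FULL_BACKBONE")
    val
  }
})

helix20_lys <- local({
  val <- NULL
  function() {
    if (is.null(val)) {
      val <<- make_ideal_helix(
        20, backbone = "FULL_BACKBONE",
        sequence = c(rep("ALA", 9), "LYS", rep("ALA", 10)))
    }
    val
  }
})

corner_pair <- local({
  val <- NULL
  function() {
    if (is.null(val)) {
      seq1 <- rep("ALA", 16); seq1[8] <- "LYS"
      val <<- make_helix_pair(d = 11.7, theta = -57,
                              backbone = "FULL_BACKBONE",
                              lengths = c(16, 16), sequence1 = seq1)
    }
    val
  }
})

# random helix_axis with a finite segment, for property sweeps
random_axis <- function() {
  a <- stats::rnorm(3, sd = 8)
  u <- stats::rnorm(3)
  len <- stats::runif(1, 8, 30)
  helixptm:::new_helix_axis(a, u / sqrt(sum(u^2)), 0, len,
                            radius = stats::runif(1, 1.5, 5), fit_rmsd = 0)
}

# brute-force minimal distance between two finite segments by dense
# sampling (independent of the closed-form implementation)
brute_segment_distance <- function(ax_a, ax_b, n = 400) {
  ea <- helixptm:::axis_endpoints(ax_a)
  eb <- helixptm:::axis_endpoints(ax_b)
  ta <- seq(0, 1, length.out = n)
  Pa <- outer(1 - ta, ea$p) + outer(ta, ea$q)
  Pb <- outer(1 - ta, eb$p) + outer(ta, eb$q)
  g <- tcrossprod(Pa, Pb)
  d2 <- outer(rowSums(Pa^2), rowSums(Pb^2), "+") - 2 * g
  ij <- which(d2 == min(d2), arr.ind = TRUE)[1, ]
  # polish the grid minimum with a bounded local search
  f <- function(st) {
    p <- (1 - st[1]) * ea$p + st[1] * ea$q
    q <- (1 - st[2]) * eb$p + st[2] * eb$q
    sum((p - q)^2)
  }
  opt <- stats::optim(c(ta[ij[1]], ta[ij[2]]), f, method = "L-BFGS-B",
                      lower = 0, upper = 1)
  sqrt(max(0, opt$value))
}

# brute-force distance between the two infinite lines: coarse grid plus
# Nelder-Mead polish (independent of the plane construction)
brute_line_distance <- function(ax_a, ax_b) {
  f <- function(st) {
    p <- ax_a$anchor + st[1] * ax_a$direction
    q <- ax_b$anchor + st[2] * ax_b$direction
    sum((p - q)^2)
  }
  g <- as.matrix(expand.grid(s = seq(-60, 60, length.out = 41),
                             t = seq(-60, 60, length.out = 41)))
  vals <- apply(g, 1, f)
  st0 <- g[which.min(vals), ]
  sqrt(stats::optim(st0, f, control = list(reltol = 1e-14))$value)
}

# Monte-Carlo area of the intersection of the two silhouette rectangles
mc_projection_area <- function(ax_a, ax_b, n = 1e6, seed = 1) {
  set.seed(seed)
  pl <- pair_planes(ax_a, ax_b)
  origin <- ax_a$anchor + (pl$d / 2) * pl$normal
  bs <- helixptm:::plane_basis(pl$normal)
  ra <- helixptm:::silhouette_rect(ax_a, origin, bs$e1, bs$e2)
  rb <- helixptm:::silhouette_rect(ax_b, origin, bs$e1, bs$e2)
  u <- stats::runif(n); v <- stats::runif(n)
  px <- ra[1, 1] + u * (ra[2, 1] - ra[1, 1]) + v * (ra[4, 1] - ra[1, 1])
  py <- ra[1, 2] + u * (ra[2, 2] - ra[1, 2]) + v * (ra[4, 2] - ra[1, 2])
  inside <- rep(TRUE, n)
  for (i in 1:4) {
    A <- rb[i, ]; B <- rb[(i %% 4) + 1, ]
    e <- B - A
    inside <- inside & (e[1] * (py - A[2]) - e[2] * (px - A[1]) >= 0)
  }
  p_in <- mean(inside)
  areaA <- helixptm:::polygon_area(ra)
  list(S = p_in * areaA,
       se = sqrt(p_in * (1 - p_in) / n) * areaA)
}

rigid_move_structure <- function(structure, R, t) {
  X <- as.matrix(structure$atoms[, c("x", "y", "z")])
  X <- sweep(X %*% t(R), 2, t, "+")
  structure$atoms$x <- X[, 1]
  structure$atoms$y <- X[, 2]
  structure$atoms$z <- X[, 3]
  structure
}

rigid_move_axis <- function(axis, R, t) {
  helixptm:::new_helix_axis(as.numeric(R %*% axis$anchor) + t,
                            as.numeric(R %*% axis$direction),
                            axis$seg_start, axis$seg_end,
                            axis$radius, axis$fit_rmsd)
}

random_rotation <- function() {
  u <- stats::rnorm(3)
  helixptm:::rotation_about(u / sqrt(sum(u^2)), stats::runif(1, 0, 360))
}
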