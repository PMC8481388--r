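test_that("axis fit is exact on an ideal helix and equivariant", {
  h <- make_ideal_helix(20)
  ax <- fit_helix_axis(atom_coords(h$structure))
  expect_lt(helixptm:::vec_angle(ax$direction, c(0, 0, 1)), 0.5)
  expect_equal(ax$radius, 2.30, tolerance = 0.01)
  expect_lt(ax$fit_rmsd, 0.01)
  expect_equal(ax$seg_end - ax$seg_start, 19 * 1.5, tolerance = 0.01)
  # equivariance under a known rigid motion
  set.seed(3)
  R <- random_rotation(); t <- stats::rnorm(3, sd = 15)
  moved <- rigid_move_structure(h$structure, R, t)
  ax2 <- fit_helix_axis(atom_coords(moved))
  expect_lt(helixptm:::vec_angle(ax2$direction, as.numeric(R %*% c(0, 0, 1))),
            0.5)
  expect_lt(helixptm:::vnorm(ax2$anchor - (as.numeric(R %*% ax$anchor) + t)),
            0.05)
})

test_that("axis fit recovers direction and noise level on noisy helices", {
  # oracle: the construction axis itself; 40 seeds at sigma = 0.3 A
  # (the full 200-seed sweep runs in the acceptance suite)
  errs <- sds <- excess <- numeric(40)
  for (s in 1:40) {
    set.seed(s)
    h <- make_ideal_helix(12)
    X <- atom_coords(h$structure) + matrix(stats::rnorm(36, sd = 0.3), ncol = 3)
    ax <- fit_helix_axis(X)
    errs[s] <- helixptm:::vec_angle(ax$direction, c(0, 0, 1))
    sds[s] <- ax$fit_rmsd
    # the fit must reach at least the truth's objective value
    obj <- function(a, u) stats::var(helixptm:::point_line_distance(X, a, u))
    excess[s] <- obj(ax$anchor, ax$direction) - obj(c(0, 0, 0), c(0, 0, 1))
  }
  expect_lt(stats::median(errs), 3)
  expect_true(all(excess <= 1e-10))
  expect_equal(mean(sds), 0.3, tolerance = 0.35)
  expect_error(fit_helix_axis(matrix(1:12, ncol = 3)), "at least 5")
  line <- cbind(1:6, 1:6, 1:6)
  expect_error(fit_helix_axis(line), "collinear")
})

test_that("pair_planes reproduces textbook line-to-line distances", {
  mk <- function(a, u) helixptm:::new_helix_axis(a, u, 0, 10, 2.3, 0)
  pl <- pair_planes(mk(c(0, 0, 0), c(1, 0, 0)), mk(c(0, 0, 5), c(0, 1, 0)))
  expect_equal(pl$d, 5)
  expect_equal(abs(pl$normal), c(0, 0, 1))
  # intersecting lines: d = 0
  pl0 <- pair_planes(mk(c(0, 0, 0), c(1, 0, 0)), mk(c(0, 0, 0), c(0, 1, 0)))
  expect_equal(pl0$d, 0)
  # random pairs against a brute-force infinite-line oracle
  set.seed(17)
  for (i in 1:200) {
    a <- random_axis(); b <- random_axis()
    expect_lt(abs(pair_planes(a, b)$d - brute_line_distance(a, b)), 1e-3)
  }
})

test_that("segment distance r matches brute force and never drops below d", {
  set.seed(23)
  for (i in 1:300) {
    a <- random_axis(); b <- random_axis()
    g <- pair_geometry(a, b)
    expect_lt(abs(g$r - brute_segment_distance(a, b)), 1e-2)
    expect_gte(g$r, g$d - 1e-6)
  }
})

test_that("prescribed pairs: parallel, crossing-contact, and recovery", {
  gp <- make_helix_pair(d = 10, theta = 0, crossing = TRUE)$geometry
  expect_equal(gp$d, 10, tolerance = 1e-9)
  expect_equal(gp$r, 10, tolerance = 1e-9)
  expect_equal(gp$alpha, 0, tolerance = 1e-9)
  expect_equal(gp$theta, 0, tolerance = 1e-9)
  # the crossing construction forces r = d (the tight-contact identity)
  gc <- make_helix_pair(d = 11.7, theta = -57)$geometry
  expect_equal(gc$r, gc$d, tolerance = 1e-9)
  expect_equal(gc$d, 11.7, tolerance = 1e-9)
  expect_equal(gc$theta, -57, tolerance = 1e-9)
  expect_true(gc$crossing)
  # fit from atomic coordinates recovers the construction
  pp <- corner_pair()
  ca1 <- atom_coords(pp$structure,
                     res_index = pp$span1[1]:pp$span1[2], elety = "CA")
  ca2 <- atom_coords(pp$structure,
                     res_index = helixptm::residue_index(pp$structure)$index[
                       helixptm::residue_index(pp$structure)$resno %in%
                         pp$span2[1]:pp$span2[2]], elety = "CA")
  g <- pair_geometry(fit_helix_axis(ca1), fit_helix_axis(ca2))
  expect_equal(g$d, 11.7, tolerance = 0.02 * 11.7)
  expect_equal(g$r, g$d, tolerance = 0.05)
  expect_equal(g$theta, -57, tolerance = 1)
  expect_equal(g$alpha, 57, tolerance = 1)
})

test_that("projection intersection matches closed forms and Monte Carlo", {
  mk <- function(a, u, len, rad) {
    helixptm:::new_helix_axis(a, u, 0, len, rad, 0)
  }
  # identical coincident rectangles 10 x 4.6
  a <- mk(c(0, 0, 0), c(1, 0, 0), 10, 2.3)
  self <- projection_intersection(a, a)
  expect_equal(self$S, 46.0, tolerance = 1e-9)
  expect_equal(self$P, 29.2, tolerance = 1e-9)
  # disjoint rectangles: collinear axes offset far along their direction
  b <- mk(c(100, 5, 0), c(1, 0, 0), 10, 2.3)
  far <- projection_intersection(a, b)
  expect_equal(far$S, 0)
  expect_equal(far$P, 0)
  # Monte-Carlo oracle on overlapping random pairs
  set.seed(31)
  tested <- 0
  while (tested < 12) {
    ax <- random_axis()
    bx <- random_axis()
    bx$anchor <- ax$anchor + stats::rnorm(3, sd = 3)
    pi_ <- projection_intersection(ax, bx)
    if (pi_$S < 5) next
    mc <- mc_projection_area(ax, bx, n = 2e5, seed = tested + 1)
    expect_equal(pi_$S, mc$S, tolerance = max(0.01 * pi_$S, 4 * mc$se))
    tested <- tested + 1
  }
  # S and P vanish together
  set.seed(33)
  for (i in 1:200) {
    g <- pair_geometry(random_axis(), random_axis())
    expect_identical(g$S == 0, g$P == 0)
    expect_gte(g$S, 0); expect_gte(g$P, 0)
  }
})

test_that("the six descriptors are rigid-motion invariant; theta flips under reflection and survives swap", {
  set.seed(41)
  for (i in 1:50) {
    a <- random_axis(); b <- random_axis()
    g <- pair_geometry(a, b)
    R <- random_rotation(); t <- stats::rnorm(3, sd = 10)
    g2 <- pair_geometry(rigid_move_axis(a, R, t), rigid_move_axis(b, R, t))
    expect_equal(g2$d, g$d, tolerance = 1e-3)
    expect_equal(g2$r, g$r, tolerance = 1e-3)
    expect_equal(g2$alpha, g$alpha, tolerance = 1e-3)
    expect_equal(g2$theta, g$theta, tolerance = 1e-3)
    expect_equal(g2$S, g$S, tolerance = 1e-3 * max(1, g$S))
    expect_equal(g2$P, g$P, tolerance = 1e-3 * max(1, g$P))
    # swap: normal flips, theta invariant, all unsigned features too
    gs <- pair_geometry(b, a)
    expect_equal(gs$d, g$d, tolerance = 1e-6)
    expect_equal(gs$r, g$r, tolerance = 1e-6)
    expect_equal(gs$alpha, g$alpha, tolerance = 1e-6)
    expect_equal(gs$theta, g$theta, tolerance = 1e-6)
    expect_equal(gs$S, g$S, tolerance = 1e-6 * max(1, g$S))
    # reflection (improper transform) flips the sign of theta
    refl <- function(ax) {
      helixptm:::new_helix_axis(
        ax$anchor * c(1, 1, -1), ax$direction * c(1, 1, -1),
        ax$seg_start, ax$seg_end, ax$radius, ax$fit_rmsd)
    }
    gr <- pair_geometry(refl(a), refl(b))
    if (abs(abs(g$theta) - 180) > 1e-6 && abs(g$theta) > 1e-6) {
      expect_equal(gr$theta, -g$theta, tolerance = 1e-3)
    }
  }
})

test_that("motif classification follows the crossing/torsion/connection rules", {
  g_corner <- make_helix_pair(d = 11.7, theta = -57)$geometry
  expect_equal(classify_motif(g_corner, 5), "AA_CORNER")
  g_hair <- make_helix_pair(d = 9, theta = 170)$geometry
  expect_equal(classify_motif(g_hair, 3), "AA_HAIRPIN")
  g_open <- make_helix_pair(d = 8, theta = -50, crossing = FALSE)$geometry
  expect_gt(g_open$r, g_open$d)
  expect_equal(classify_motif(g_open, 3), "V_STRUCTURE")
  expect_equal(classify_motif(g_open, 8), "L_STRUCTURE")
})

test_that("motif selection applies the tight-contact criteria", {
  build <- function(d, crossing = TRUE) {
    seq1 <- rep("ALA", 16); seq1[8] <- "LYS"
    make_helix_pair(d = d, theta = -57, crossing = crossing,
                    backbone = "FULL_BACKBONE", lengths = c(16, 16),
                    sequence1 = seq1)
  }
  run <- function(pp) {
    st <- pp$structure
    select_motifs(st, assign_helices(st), find_residue(st, "A", 8))
  }
  m12 <- run(build(12))
  expect_equal(nrow(m12), 1)
  expect_equal(m12$motif_class, "AA_CORNER")
  expect_equal(m12$r, m12$d, tolerance = 0.5)
  # beyond the 16 A tight-contact bound: empty result
  expect_equal(nrow(run(build(17))), 0)
  # non-crossing open pair (d < r): excluded from the contact selection
  expect_equal(nrow(run(build(8, crossing = FALSE))), 0)
  # a site at the helix-2 C-terminal end still counts as on the pair
  pp <- build(12)
  st <- pp$structure
  far <- select_motifs(st, assign_helices(st), find_residue(st, "A", 37))
  expect_equal(nrow(far), 1)
  expect_error(select_motifs(st, assign_helices(st), 999), "absent")
})
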