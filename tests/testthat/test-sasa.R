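single_atom <- function(x = 0, y = 0, z = 0, el = "C", resno = 1) {
  data.frame(type = "ATOM", elety = el, resid = "UNK", chain = "A",
             resno = resno, insert = "", x = x, y = y, z = z, o = 1,
             element = el, stringsAsFactors = FALSE)
}

test_that("isolated and tangent spheres match the analytic area", {
  st <- helixptm:::new_structure(single_atom())
  s <- compute_sasa(st)
  analytic <- 4 * pi * (1.76 + 1.4)^2
  expect_equal(s$per_atom, analytic, tolerance = 0.01)
  # tangent spheres: zero overlap, each keeps the isolated area
  st2 <- helixptm:::new_structure(
    rbind(single_atom(), single_atom(x = 2 * 3.16, resno = 2)))
  s2 <- compute_sasa(st2)
  expect_equal(unname(s2$per_atom), rep(analytic, 2), tolerance = 0.01)
})

test_that("two overlapping spheres match the spherical-cap solution", {
  # equal radii R at distance dist: each sphere loses a cap of height
  # h = R - dist/2, area 2*pi*R*h
  R <- 1.76 + 1.4; dist <- 3.0
  st <- helixptm:::new_structure(
    rbind(single_atom(), single_atom(x = dist, resno = 2)))
  s <- compute_sasa(st)
  analytic <- 4 * pi * R^2 - 2 * pi * R * (R - dist / 2)
  expect_equal(unname(s$per_atom[1]), analytic, tolerance = 0.01 * analytic)
  expect_equal(unname(s$per_atom[2]), analytic, tolerance = 0.01 * analytic)
})

test_that("lattice refinement and rigid motion barely change areas", {
  st <- helix20_full()$structure
  s1 <- compute_sasa(st, n_points = 960)
  s2 <- compute_sasa(st, n_points = 1920)
  # lattice convergence: within 2% or one square Angstrom per atom
  # (buried atoms with near-zero areas converge absolutely, not
  # relatively)
  expect_true(all(abs(s1$per_atom - s2$per_atom) <=
                    pmax(0.02 * s1$per_atom, 1.0)))
  set.seed(11)
  moved <- rigid_move_structure(st, random_rotation(), stats::rnorm(3, sd = 20))
  s3 <- compute_sasa(moved, n_points = 960)
  # total SASA is rotation-invariant to lattice tolerance
  expect_lt(abs(sum(s3$per_atom) - sum(s1$per_atom)) / sum(s1$per_atom),
            0.005)
  expect_true(all(abs(s3$per_atom - s1$per_atom) <=
                    pmax(0.05 * s1$per_atom, 1.5)))
})

test_that("adding an atom never increases any existing atom's area", {
  set.seed(21)
  st <- helix20_full()$structure
  base <- compute_sasa(st, n_points = 480)
  for (rep in 1:50) {
    p <- as.numeric(st$atoms[sample(nrow(st$atoms), 1), c("x", "y", "z")]) +
      stats::rnorm(3, sd = 2.5)
    cols <- c("type", "elety", "resid", "chain", "resno", "insert",
              "x", "y", "z", "o", "element")
    aug <- helixptm:::new_structure(
      rbind(st$atoms[, cols],
            single_atom(p[1], p[2], p[3], el = "O", resno = 99)))
    s_aug <- compute_sasa(aug, n_points = 480)
    keep <- s_aug$atoms$resno != 99
    expect_true(all(s_aug$per_atom[keep] <= base$per_atom + 1e-9))
  }
})

test_that("active environment matches a brute-force distance scan", {
  st <- helix20_full()$structure
  env <- active_environment(st, 10, cutoff = 6.0)
  expect_true(all(c(6:9, 11:14) %in% env$members))
  expect_false(10 %in% env$members)
  # brute force over all residue pairs
  a <- st$atoms[st$atoms$is_heavy, ]
  brute <- sort(unique(unlist(lapply(unique(a$res_index), function(j) {
    if (j == 10) return(NULL)
    Xa <- as.matrix(a[a$res_index == 10, c("x", "y", "z")])
    Xb <- as.matrix(a[a$res_index == j, c("x", "y", "z")])
    dmin <- min(apply(Xa, 1, function(p) min(sqrt(colSums((t(Xb) - p)^2)))))
    if (dmin <= 6.0) j else NULL
  }))))
  expect_identical(env$members, brute)
  expect_length(active_environment(st, 10, cutoff = 0)$members, 0)
  # isolated single residue: empty member set
  iso <- helixptm:::new_structure(single_atom())
  expect_length(active_environment(iso, 1)$members, 0)
})

test_that("delta report is zero for an unmodified twin and positive for acetyl", {
  st <- helix20_lys()$structure
  rep0 <- sasa_delta_report(st, st, 10, n_points = 480)
  expect_equal(rep0$delta_residue, 0)
  expect_equal(rep0$delta_environment, 0)
  mr <- mount_ptm(st, ptm_spec("ACETYL_K", "A", 10))
  rep1 <- sasa_delta_report(st, mr$structure, 10, n_points = 480)
  expect_gt(rep1$residue_modified, rep1$residue_intact)
  # deltas are exact differences
  expect_equal(rep1$delta_residue, rep1$residue_modified - rep1$residue_intact)
  # a structure altered beyond the moiety is rejected
  bad <- mr$structure
  bad$atoms$x[1] <- bad$atoms$x[1] + 1
  expect_error(sasa_delta_report(st, bad, 10), "beyond the moiety")
})

test_that("published-table exception count is four decreasing peptides", {
  res <- environment_decrease_count()
  expect_equal(res$n_decreasing, 4)
  expect_setequal(res$peptides$gene, c("ALBU", "CO3"))
})
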