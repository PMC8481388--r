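corner_traj <- function(n_frames = 20, jitter_sd = 0, drift = NULL,
                        seed = 1) {
  pp <- corner_pair()
  tr <- make_trajectory(pp$structure, n_frames = n_frames,
                        jitter_sd = jitter_sd, drift = drift, seed = seed)
  list(pp = pp, tr = tr)
}

test_that("zero-jitter trajectories give identical geometries and zero SDs", {
  ct <- corner_traj(10)
  ser <- track_geometry(ct$tr, ct$pp$span1, ct$pp$span2)
  expect_equal(nrow(ser), 10)
  expect_false(any(ser$flagged))
  for (f in c("d", "r", "alpha", "theta", "S", "P")) {
    expect_equal(diff(range(ser[[f]])), 0)
  }
  st <- summarize_geometry(ser)
  expect_true(all(unlist(st$sd) == 0))
})

test_that("per-frame tracking matches a naive frame-by-frame loop", {
  ct <- corner_traj(15, jitter_sd = 0.2, seed = 9)
  ser <- track_geometry(ct$tr, ct$pp$span1, ct$pp$span2)
  # oracle: independent loop over frames calling the single-frame path
  for (k in c(1, 7, 15)) {
    st <- ct$tr$frames[[k]]
    ri <- residue_index(st)
    ia <- ri$index[ri$resno %in% ct$pp$span1[1]:ct$pp$span1[2]]
    ib <- ri$index[ri$resno %in% ct$pp$span2[1]:ct$pp$span2[2]]
    g <- pair_geometry(
      fit_helix_axis(atom_coords(st, ia, elety = "CA"),
                     atom_coords(st, ia, heavy_only = TRUE)),
      fit_helix_axis(atom_coords(st, ib, elety = "CA"),
                     atom_coords(st, ib, heavy_only = TRUE)))
    expect_equal(ser$r[k], g$r, tolerance = 1e-9)
    expect_equal(ser$theta[k], g$theta, tolerance = 1e-9)
    expect_equal(ser$S[k], g$S, tolerance = 1e-9)
  }
})

test_that("a drifting helix produces monotonically increasing r", {
  pp <- corner_pair()
  ri <- residue_index(pp$structure)
  span2_idx <- ri$index[ri$resno %in% pp$span2[1]:pp$span2[2]]
  ct <- make_trajectory(pp$structure, n_frames = 20, jitter_sd = 0,
                        drift = list(res_index = span2_idx,
                                     step = c(0, 0, 0.3)), seed = 2)
  ser <- track_geometry(ct, pp$span1, pp$span2)
  expect_true(all(diff(ser$r) > 0))
})

test_that("summaries are hand-checkable, permutation-invariant, and robust to flags", {
  ser <- data.frame(frame = 1:2, time = c(0, 0.005), d = c(10, 12),
                    r = c(10, 12), alpha = c(50, 52), theta = c(-57, -55),
                    S = c(100, 110), P = c(40, 44),
                    crossing = TRUE, flagged = FALSE)
  class(ser) <- c("geometry_series", "data.frame")
  st <- summarize_geometry(ser)
  expect_equal(st$mean$d, 11)
  expect_equal(st$sd$d, 1)  # population SD of {10, 12}
  # permutation invariance
  ct <- corner_traj(12, jitter_sd = 0.15, seed = 4)
  s1 <- track_geometry(ct$tr, ct$pp$span1, ct$pp$span2)
  perm <- s1[sample(nrow(s1)), ]
  class(perm) <- class(s1)
  a <- summarize_geometry(s1); b <- summarize_geometry(perm)
  expect_equal(unlist(a$mean), unlist(b$mean))
  expect_equal(unlist(a$sd), unlist(b$sd))
  # flagged frames are excluded and counted
  s1$flagged[3] <- TRUE
  st2 <- summarize_geometry(s1)
  expect_equal(st2$n_flagged, 1)
  one <- s1[1:2, ]; one$flagged <- c(TRUE, FALSE)
  class(one) <- class(s1)
  expect_error(summarize_geometry(one), "fewer than 2")
})

test_that("verdicts: stable twins, drift rupture, and torsion-shift flagging", {
  ct <- corner_traj(10)
  ser <- track_geometry(ct$tr, ct$pp$span1, ct$pp$span2)
  st <- summarize_geometry(ser)
  rep0 <- stability_verdict(st, st, ser)
  expect_equal(rep0$verdict, "STABLE")
  expect_true(all(rep0$comparison$delta == 0))
  # constructed drift separating the helices
  pp <- corner_pair()
  ri <- residue_index(pp$structure)
  span2_idx <- ri$index[ri$resno %in% pp$span2[1]:pp$span2[2]]
  u_b <- c(cos(-57 * pi / 180), sin(-57 * pi / 180), 0)
  trd <- make_trajectory(pp$structure, n_frames = 25, jitter_sd = 0,
                         drift = list(res_index = span2_idx,
                                      step = 1.8 * u_b), seed = 3)
  serd <- track_geometry(trd, pp$span1, pp$span2)
  std <- summarize_geometry(serd)
  expect_equal(stability_verdict(std, st, serd)$verdict, "RUPTURED")
  # modified run with a large torsion shift at small SDs: flagged feature
  ppm <- make_helix_pair(d = 11.7, theta = -109,
                         backbone = "FULL_BACKBONE", lengths = c(16, 16))
  trm <- make_trajectory(ppm$structure, n_frames = 10, jitter_sd = 0.05,
                         seed = 6)
  serm <- track_geometry(trm, ppm$span1, ppm$span2)
  stm <- summarize_geometry(serm)
  repm <- stability_verdict(stm, st, serm)
  expect_true("theta" %in% repm$comparison$feature[repm$comparison$flagged])
  expect_lt(repm$comparison$delta[repm$comparison$feature == "theta"], -40)
})

test_that("the published recording schedule maps to exactly 100 frames", {
  st <- helix20_full()$structure
  tr <- make_trajectory(st, n_frames = 100, seed = 1,
                        frame_interval = 0.005)
  expect_length(tr$frames, 100)
  expect_equal(tr$duration, 0.495)
  expect_equal(tr$duration + tr$frame_interval, 0.5)
})

test_that("increasing jitter never turns a ruptured verdict stable", {
  pp <- corner_pair()
  ri <- residue_index(pp$structure)
  span2_idx <- ri$index[ri$resno %in% pp$span2[1]:pp$span2[2]]
  base <- NULL
  verdicts <- character(0)
  for (sig in c(0, 0.1, 0.3)) {
    u_b <- c(cos(-57 * pi / 180), sin(-57 * pi / 180), 0)
    tr <- make_trajectory(pp$structure, n_frames = 10, jitter_sd = sig,
                          drift = list(res_index = span2_idx,
                                       step = 4 * u_b), seed = 8)
    ser <- track_geometry(tr, pp$span1, pp$span2)
    stats <- summarize_geometry(ser)
    if (is.null(base)) base <- stats
    verdicts <- c(verdicts, stability_verdict(stats, base, ser)$verdict)
  }
  expect_true(all(verdicts == "RUPTURED"))
})
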