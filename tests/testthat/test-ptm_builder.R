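test_that("mass bookkeeping matches the monoisotopic shifts", {
  expect_equal(ptm_spec("ACETYL_K", "A", 1)$mass_shift, 42.0106,
               tolerance = 1e-3)
  expect_equal(ptm_spec("PHOSPHO_S", "A", 1)$mass_shift, 79.9663,
               tolerance = 1e-3)
  expect_equal(ptm_spec("PHOSPHO_Y", "A", 1)$mass_shift, 79.9663,
               tolerance = 1e-3)
  expect_equal(ptm_spec("GG_K", "A", 1)$mass_shift, 114.0429,
               tolerance = 1e-3)
})

test_that("mounting adds the specified heavy atoms without moving any", {
  st <- helix20_lys()$structure
  specs <- list(ACETYL_K = 3, GG_K = 6)
  for (kind in names(specs)) {
    mr <- mount_ptm(st, ptm_spec(kind, "A", 10))
    expect_equal(nrow(mr$added_atoms), specs[[kind]])
    expect_true(all(mr$added_atoms$type == "HETATM"))
    expect_true(all(mr$added_atoms$resno == 10))
    i0 <- st$atoms; i1 <- mr$structure$atoms
    m <- match(paste(i0$resno, i0$elety), paste(i1$resno, i1$elety))
    expect_false(anyNA(m))
    expect_identical(unname(as.matrix(i0[, c("x", "y", "z")])),
                     unname(as.matrix(i1[m, c("x", "y", "z")])))
  }
})

test_that("acetyl amide is planar and phosphate tetrahedral", {
  st <- helix20_lys()$structure
  mr <- mount_ptm(st, ptm_spec("ACETYL_K", "A", 10))
  a <- mr$structure$atoms
  g <- function(n) as.numeric(a[a$resno == 10 & a$elety == n,
                                c("x", "y", "z")])
  nrm <- helixptm:::unitv(helixptm:::cross3(g("CAC") - g("NZ"),
                                            g("OAC") - g("CAC")))
  expect_lt(abs(sum((g("CME") - g("CAC")) * nrm)), 0.05)
  expect_equal(helixptm:::vnorm(g("CAC") - g("NZ")), 1.33, tolerance = 1e-6)
  expect_equal(helixptm:::vnorm(g("OAC") - g("CAC")), 1.23, tolerance = 1e-6)
  ss <- make_ideal_helix(20, backbone = "FULL_BACKBONE",
                         sequence = c(rep("ALA", 9), "SER",
                                      rep("ALA", 10)))$structure
  mp <- mount_ptm(ss, ptm_spec("PHOSPHO_S", "A", 10))
  expect_equal(nrow(mp$added_atoms), 4)
  ap <- mp$structure$atoms
  gp <- function(n) as.numeric(ap[ap$resno == 10 & ap$elety == n,
                                  c("x", "y", "z")])
  for (o in c("O1P", "O2P", "O3P")) {
    expect_equal(helixptm:::vnorm(gp(o) - gp("P")), 1.52, tolerance = 0.01)
  }
  cmb <- utils::combn(c("O1P", "O2P", "O3P"), 2)
  for (i in 1:3) {
    expect_equal(helixptm:::vec_angle(gp(cmb[1, i]) - gp("P"),
                                      gp(cmb[2, i]) - gp("P")),
                 109.5, tolerance = 3)
  }
})

test_that("incompatible targets and missing anchors are rejected", {
  st <- helix20_lys()$structure
  expect_error(mount_ptm(st, ptm_spec("ACETYL_K", "A", 5)), "requires LYS")
  expect_error(mount_ptm(st, ptm_spec("PHOSPHO_S", "A", 10)), "requires SER")
  # lysine with the NZ removed
  st2 <- st
  st2$atoms <- st2$atoms[!(st2$atoms$resno == 10 & st2$atoms$elety == "NZ"), ]
  expect_error(mount_ptm(st2, ptm_spec("ACETYL_K", "A", 10)), "NZ")
})

test_that("mounting is deterministic and the grid scan tracks a fine scan", {
  st <- corner_pair()$structure
  m1 <- mount_ptm(st, ptm_spec("ACETYL_K", "A", 8))
  m2 <- mount_ptm(st, ptm_spec("ACETYL_K", "A", 8))
  expect_identical(m1$chosen_dihedral, m2$chosen_dihedral)
  expect_identical(as.matrix(m1$added_atoms[, c("x", "y", "z")]),
                   as.matrix(m2$added_atoms[, c("x", "y", "z")]))
  # fine-grid oracle: 1-degree exhaustive scan of the same objective
  fine <- mount_ptm(st, ptm_spec("ACETYL_K", "A", 8), grid_step = 1)
  dd <- abs(m1$chosen_dihedral - fine$chosen_dihedral)
  expect_lte(min(dd, 360 - dd), 30)
  # the coarse optimum can never beat the fine one, and stays close to it
  expect_lte(m1$min_clash_distance, fine$min_clash_distance + 1e-9)
  expect_gte(m1$min_clash_distance, fine$min_clash_distance - 0.5)
})

test_that("clash report distinguishes exposed, buried, and isolated sites", {
  st <- helix20_lys()$structure
  mr <- mount_ptm(st, ptm_spec("ACETYL_K", "A", 10))
  cr <- clash_report(mr, st)
  expect_gte(cr$min_distance, 2.4)
  expect_false(cr$flagged)
  # isolated residue: no non-target atoms, infinite-distance marker
  iso_atoms <- st$atoms[st$atoms$resno == 10, ]
  iso <- helixptm:::new_structure(
    iso_atoms[, c("type", "elety", "resid", "chain", "resno", "insert",
                  "x", "y", "z", "o", "element")])
  mi <- mount_ptm(iso, ptm_spec("ACETYL_K", "A", 10))
  expect_identical(clash_report(mi, iso)$min_distance, Inf)
  # deliberately buried lysine: a wall of atoms around NZ
  a <- st$atoms
  nz <- as.numeric(a[a$resno == 10 & a$elety == "NZ", c("x", "y", "z")])
  sph <- helixptm:::sphere_lattice(60) * 3.1
  wall <- do.call(rbind, lapply(seq_len(nrow(sph)), function(i) {
    data.frame(type = "ATOM", elety = "O", resid = "HOH2", chain = "B",
               resno = 500 + i, insert = "",
               x = nz[1] + sph[i, 1], y = nz[2] + sph[i, 2],
               z = nz[3] + sph[i, 3], o = 1, element = "O",
               stringsAsFactors = FALSE)
  }))
  cols <- c("type", "elety", "resid", "chain", "resno", "insert",
            "x", "y", "z", "o", "element")
  buried <- helixptm:::new_structure(rbind(a[, cols], wall))
  expect_error(mount_ptm(buried, ptm_spec("ACETYL_K", "A", 10)),
               "clash")
})
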