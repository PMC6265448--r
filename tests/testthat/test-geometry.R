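# Geometric primitives: dihedrals, attack angles, superposition.

test_that("signed dihedral reproduces cis/trans and the IUPAC sign convention", {
  b <- c(0, 0, 0); cc <- c(1.5, 0, 0)
  a <- c(-0.5, 1, 0)
  d_at <- function(t) cc + c(0.5, cos(t * pi / 180), sin(t * pi / 180))
  expect_equal(signed_dihedral(a, b, cc, d_at(0)), 0)
  expect_equal(abs(signed_dihedral(a, b, cc, d_at(180))), 180)
  expect_equal(signed_dihedral(a, b, cc, d_at(60)), 60)
  expect_equal(signed_dihedral(a, b, cc, d_at(-90)), -90)
})

test_that("a fragment built at +145 degrees mirrors to -145", {
  fr <- build_fragment(dihedral_values = list(tau_1 = 180, tau_2 = 180,
                                              tau_3 = 180, tau_4 = 180,
                                              tau_5 = 145))
  expect_equal(measure_frame(fr)$tau_5, 145, tolerance = 1e-9)
  expect_equal(measure_frame(mirror_frame(fr))$tau_5, -145, tolerance = 1e-9)
})

test_that("dihedral reversal symmetry and mirror antisymmetry hold on random quads", {
  set.seed(101)
  for (i in 1:200) {
    q <- matrix(stats::rnorm(12, sd = 2), 4)
    t1 <- signed_dihedral(q[1, ], q[2, ], q[3, ], q[4, ])
    expect_equal(signed_dihedral(q[4, ], q[3, ], q[2, ], q[1, ]), t1,
                 tolerance = 1e-9)
    qm <- q; qm[, 1] <- -qm[, 1]
    tm <- signed_dihedral(qm[1, ], qm[2, ], qm[3, ], qm[4, ])
    expect_equal(tm, -t1, tolerance = 1e-9)
  }
})

test_that("collinear triples raise a degenerate-geometry error", {
  expect_error(signed_dihedral(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), c(3, 1, 0)),
               "collinear")
})

test_that("BD angle handles analytic placements", {
  fr <- make_ideal_geometry("canonical_reactive")
  # nucleophile on the extension of O=C beyond C: angle 180
  fr180 <- fr; fr180$coords["O3p", ] <- -2 * fr$coords["Ocarb", ]
  expect_equal(bd_angle(fr180), 180)
  # perpendicular approach: 90
  fr90 <- fr; fr90$coords["O3p", ] <- c(0, 0, 3)
  expect_equal(bd_angle(fr90), 90)
  # explicit 105-degree rotation of the C->O axis
  expect_equal(bd_angle(fr), 105, tolerance = 1e-9)
})

test_that("lobe angle is tetrahedral for an ideal sp3 arrangement", {
  fr <- make_ideal_geometry("sp3_tetrahedral")
  expect_equal(lobe_angle(fr), acos(-1 / 3) * 180 / pi, tolerance = 1e-6)
  # collinear R-Nu-C with Nu between: 180
  frc <- fr
  frc$coords["C3p", ] <- 2 * frc$coords["O3p", ] - frc$coords["Ccarb", ]
  expect_equal(lobe_angle(frc), 180)
})

test_that("FL angle: symmetric perpendicular approach is 0, rotations are signed", {
  expect_equal(fl_angle(make_ideal_geometry("symmetric_carbonyl")), 0,
               tolerance = 1e-9)
  expect_equal(fl_angle(make_ideal_geometry("canonical_reactive")), 0,
               tolerance = 1e-9)
  fr17 <- make_ideal_geometry("boundary_family", "alpha_FL", 17)
  expect_equal(fl_angle(fr17), 17, tolerance = 1e-9)
  expect_equal(fl_angle(mirror_frame(fr17)), -17, tolerance = 1e-9)
})

test_that("angle primitives match the acos-dot oracle on 1000 random frames", {
  set.seed(202)
  for (i in 1:1000) {
    fr <- random_frame()
    co <- fr$coords
    expect_equal(bd_angle(fr),
                 oracle_angle(co["O3p", ], co["Ccarb", ], co["Ocarb", ]),
                 tolerance = 1e-9)
    expect_equal(lobe_angle(fr),
                 oracle_angle(co["C3p", ], co["O3p", ], co["Ccarb", ]),
                 tolerance = 1e-9)
  }
})

test_that("dihedrals match the bio3d oracle on random quads", {
  set.seed(303)
  for (i in 1:1000) {
    q <- matrix(stats::rnorm(12, sd = 2), 4)
    expect_equal(signed_dihedral(q[1, ], q[2, ], q[3, ], q[4, ]),
                 oracle_dihedral(q[1, ], q[2, ], q[3, ], q[4, ]),
                 tolerance = 1e-9)
  }
})

test_that("Kabsch RMSD: exact cases and the brute-force square value", {
  set.seed(404)
  a <- matrix(stats::rnorm(30), 10)
  expect_equal(kabsch_rmsd(a, a), 0)
  b <- a %*% t(random_rotation()) + matrix(rep(stats::rnorm(3), each = 10), 10)
  expect_lt(kabsch_rmsd(a, b), 1e-9)
  # 4-point square vs corner displaced 1 A; reference value from an
  # exhaustive rotation-grid minimisation refined to 1e-9
  sq <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0))
  sq2 <- sq; sq2[3, ] <- c(1, 1, 1)
  expect_equal(kabsch_rmsd(sq, sq2), 0.274094079, tolerance = 1e-8)
  expect_error(kabsch_rmsd(sq, sq[1:3, ]), "same number")
})

test_that("Kabsch RMSD matches the quaternion oracle on random pairs", {
  set.seed(505)
  for (i in 1:200) {
    a <- matrix(stats::rnorm(3 * 8), 8)
    b <- a + matrix(stats::rnorm(3 * 8, 0, 0.5), 8)
    expect_equal(kabsch_rmsd(a, b), oracle_rmsd(a, b), tolerance = 1e-9)
  }
})

test_that("measures are rigid-motion invariant; reflection flips only signed ones", {
  set.seed(606)
  signed_cols <- c("alpha_FL", "tau_1", "tau_2", "tau_3", "tau_4", "tau_5",
                   "tau_carbonyl")
  unsigned_cols <- c("delta_att", "alpha_BD", "alpha_Lobe",
                     "delta_SAC_OP1", "delta_SAC_OP2")
  for (i in 1:50) {
    fr <- random_frame()
    m0 <- measure_frame(fr)
    mt <- measure_frame(transform_frame(fr))
    for (cl in c(signed_cols, unsigned_cols)) {
      expect_equal(mt[[cl]], m0[[cl]], tolerance = 1e-8)
    }
    mm <- measure_frame(mirror_frame(fr))
    for (cl in unsigned_cols) expect_equal(mm[[cl]], m0[[cl]], tolerance = 1e-8)
    for (cl in signed_cols) expect_equal(mm[[cl]], -m0[[cl]], tolerance = 1e-8)
  }
})

test_that("O2' nucleophile choice switches the measured atoms", {
  fr <- make_ideal_geometry("canonical_reactive")
  m2 <- measure_frame(fr, "O2p")
  co <- fr$coords
  expect_equal(m2$delta_att, sqrt(sum((co["O2p", ] - co["Ccarb", ])^2)))
  expect_equal(m2$alpha_Lobe,
               oracle_angle(co["C2p", ], co["O2p", ], co["Ccarb", ]),
               tolerance = 1e-9)
})
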