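# Synthetic generator: internal-coordinate construction, circular sampling,
# chirality, determinism, planting.

test_that("built fragments re-measure to their input dihedrals within 1e-6", {
  set.seed(51)
  n_ok <- 0L
  while (n_ok < 20L) {
    tv <- list(tau_1 = runif(1, -180, 180), tau_2 = runif(1, -180, 180),
               tau_3 = runif(1, -180, 180), tau_4 = runif(1, -180, 180),
               tau_5 = runif(1, -180, 180))
    chir <- sample(c("L", "D"), 1)
    # a random torsion set can fold the chain onto itself; such frames are
    # correctly rejected by validation and are not round-trip material
    fr <- tryCatch(build_fragment(internal_coordinate_table(chir), tv,
                                  chirality = chir),
                   error = function(e) NULL)
    if (is.null(fr)) next
    n_ok <- n_ok + 1L
    m <- measure_frame(fr)
    for (tn in names(tv)) {
      expect_equal(m[[tn]], tv[[tn]], tolerance = 1e-6)
    }
  }
})

test_that("NeRF placement matches the rotation-composition oracle", {
  set.seed(52)
  for (i in 1:100) {
    ref <- matrix(rnorm(9, sd = 3), 3)
    # keep the reference triple well-conditioned
    if (min(abs(c(dist(ref)))) < 0.5) next
    r <- runif(1, 1, 2); th <- runif(1, 95, 125); ta <- runif(1, -179, 179)
    d_impl <- minihelix:::.nerf_place(ref[1, , drop = FALSE],
                                     ref[2, , drop = FALSE],
                                     ref[3, , drop = FALSE], r, th, ta)
    d_orac <- oracle_place(ref[1, ], ref[2, ], ref[3, ], r, th, ta)
    expect_equal(as.vector(d_impl), d_orac, tolerance = 1e-9)
  }
})

test_that("chirality is enforced and swaps under mirror reflection", {
  tv <- list(tau_1 = 180, tau_2 = 180, tau_3 = 180, tau_4 = 180, tau_5 = 145)
  l <- build_fragment(internal_coordinate_table("L"), tv, "L")
  expect_gt(chirality_improper(l), 0)
  d <- build_fragment(internal_coordinate_table("D"), tv, "D")
  expect_lt(chirality_improper(d), 0)
  # mirroring an L fragment yields a valid D frame
  m <- mirror_frame(l)
  expect_equal(m$chirality_label, "D")
  expect_silent(validate_frame(m))
})

test_that("non-physical bond tables are rejected", {
  ict <- internal_coordinate_table("L")
  ict$length[ict$role == "Ccarb"] <- 3.5
  expect_error(build_fragment(ict, list(tau_1 = 180, tau_2 = 180, tau_3 = 180,
                                        tau_4 = 180, tau_5 = 145)),
               "non-physical")
})

test_that("von Mises sampling hits its modes and concentrations", {
  set.seed(53)
  for (mu in c(-145, 0, 145)) {
    x <- minihelix:::.rvonmises(10000, mu, 10)
    expect_lt(abs(circular_mean(x - mu)), 2)
    dev <- abs(((x - mu + 180) %% 360) - 180)
    frac30 <- mean(dev < 30)
    expect_gt(frac30, 0.85); expect_lt(frac30, 0.97)
  }
  # mixture weights are respected
  model <- data.frame(mean = c(180, 0), kappa = c(10, 10), weight = c(.8, .2))
  x <- minihelix:::.sample_mixture(20000, model)
  expect_lt(abs(mean(abs(x) < 90) - 0.2), 0.02)
  bad <- data.frame(mean = 0, kappa = 10, weight = 0.7)
  expect_error(minihelix:::.sample_mixture(10, bad), "sum to 1")
})

test_that("sampling is deterministic per seed and run-structured", {
  cfg <- synthetic_config("L", n_runs = 2, frames_per_run = 50, seed = 99)
  e1 <- sample_ensemble(cfg)
  e2 <- sample_ensemble(cfg)
  expect_identical(e1$coords, e2$coords)
  e3 <- sample_ensemble(synthetic_config("L", n_runs = 2, frames_per_run = 50,
                                         seed = 100))
  expect_false(identical(e1$coords, e3$coords))
  expect_equal(n_frames(e1), 100L)
  expect_equal(e1$n_runs, 2L)
})

test_that("sampled frames carry the configured chirality", {
  set.seed(54)
  eL <- sample_ensemble(synthetic_config("L", n_runs = 1, frames_per_run = 30,
                                         seed = 5))
  eD <- sample_ensemble(synthetic_config("D", n_runs = 1, frames_per_run = 30,
                                         seed = 5))
  for (i in c(1L, 15L, 30L)) {
    expect_gt(chirality_improper(get_frame(eL, i)), 0)
    expect_lt(chirality_improper(get_frame(eD, i)), 0)
  }
})

test_that("no sampled frame violates the hard-sphere contacts", {
  e <- sample_ensemble(synthetic_config("D", n_runs = 1, frames_per_run = 300,
                                        seed = 6))
  expect_false(any(minihelix:::.clash_mask(e$coords)))
})

test_that("planted reactive frames are recovered exactly", {
  cfg <- synthetic_config("L", n_runs = 2, frames_per_run = 500, seed = 17,
                          planted_reactive_fraction = 0.02)
  e <- sample_ensemble(cfg)
  expect_type(e$planted, "logical")
  cr <- count_reactive(e)
  expect_equal(cr$total, sum(e$planted))
  # Bernoulli total within 4 sigma of its expectation
  n <- n_frames(e); p <- 0.02
  expect_lt(abs(sum(e$planted) - n * p), 4 * sqrt(n * p * (1 - p)) + 1)
  # the verdicts identify exactly the planted frames
  v <- classify(measure_ensemble(e))
  expect_equal(which(v$reactive), which(e$planted))
})

test_that("the full mirror-pipeline property holds for sampled ensembles", {
  e <- sample_ensemble(synthetic_config("L", n_runs = 1, frames_per_run = 200,
                                        seed = 23))
  m <- measure_ensemble(e)
  mm <- measure_ensemble(mirror_ensemble(e))
  expect_equal(mm$delta_att, m$delta_att, tolerance = 1e-9)
  expect_equal(mm$alpha_BD, m$alpha_BD, tolerance = 1e-9)
  expect_equal(mm$alpha_Lobe, m$alpha_Lobe, tolerance = 1e-9)
  expect_equal(mm$alpha_FL, -m$alpha_FL, tolerance = 1e-9)
  expect_equal(mm$tau_5, -m$tau_5, tolerance = 1e-9)
  expect_equal(classify(mm)$reactive, classify(m)$reactive)
})

test_that("ideal geometries expose exactly the advertised measures", {
  m <- measure_frame(make_ideal_geometry("canonical_reactive"))
  expect_equal(m$delta_att, 3.0, tolerance = 1e-9)
  expect_equal(m$alpha_BD, 105, tolerance = 1e-9)
  expect_equal(m$alpha_FL, 0, tolerance = 1e-9)
  expect_equal(m$alpha_Lobe, 109.5, tolerance = 1e-9)
  expect_equal(min(m$delta_SAC_OP1, m$delta_SAC_OP2), 3.3, tolerance = 1e-9)
  expect_true(classify(m)$reactive)
  expect_error(make_ideal_geometry("boundary_family"), "needs")
  expect_error(make_ideal_geometry("no_such_kind"))
})

test_that("boundary families vary exactly one measure", {
  base <- measure_frame(make_ideal_geometry("canonical_reactive"))
  for (spec in list(list("delta_att", 3.15, "delta_att"),
                    list("alpha_BD", 112, "alpha_BD"),
                    list("alpha_FL", -12, "alpha_FL"),
                    list("alpha_Lobe", 100, "alpha_Lobe"))) {
    m <- measure_frame(make_ideal_geometry("boundary_family", spec[[1]],
                                           spec[[2]]))
    expect_equal(m[[spec[[3]]]], spec[[2]], tolerance = 1e-9)
    others <- setdiff(c("delta_att", "alpha_BD", "alpha_FL", "alpha_Lobe"),
                      spec[[3]])
    for (o in others) expect_equal(m[[o]], base[[o]], tolerance = 1e-9)
  }
  m <- measure_frame(make_ideal_geometry("boundary_family", "delta_SAC", 3.45))
  expect_equal(min(m$delta_SAC_OP1, m$delta_SAC_OP2), 3.45, tolerance = 1e-9)
  expect_equal(m$delta_att, base$delta_att, tolerance = 1e-9)
})
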