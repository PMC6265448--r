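# Dihedral distributions, conformer groups, representatives, base pairs.

test_that("circular histograms bin correctly, including edge and wrap rules", {
  m <- data.frame(tau_5 = rep(0, 50))
  h <- dihedral_distribution(m, "tau_5", 5)
  expect_equal(sum(h$prob), 1)
  expect_equal(max(h$prob), 1)
  expect_equal(h$breaks[which.max(h$prob)], 0)   # edge value -> higher bin
  # +180 wraps into the first bin, equivalent to -180
  h2 <- dihedral_distribution(data.frame(tau_5 = 180), "tau_5", 5)
  expect_equal(h2$breaks[which.max(h2$prob)], -180)
  expect_error(dihedral_distribution(m, "tau_5", 7), "divide")
  expect_error(dihedral_distribution(m[0, , drop = FALSE], "tau_5"), "no measures")
})

test_that("the synthetic L-system tau_5 mode lies near +145 and mirrors reverse it", {
  e <- sample_ensemble(synthetic_config("L", n_runs = 1, frames_per_run = 2000,
                                        seed = 9))
  m <- measure_ensemble(e)
  h <- dihedral_distribution(m, "tau_5", 5)
  expect_lt(abs(h$mode_deg - 145), 10)
  hm <- dihedral_distribution(measure_ensemble(mirror_ensemble(e)), "tau_5", 5)
  expect_lt(abs(hm$mode_deg + 145), 10)
  # mirrored continuous samples reverse the histogram about 0
  expect_equal(rev(hm$counts), h$counts)
})

test_that("group assignment follows the dihedral windows and is disjoint", {
  g <- function(t2, t3, t4) {
    as.character(assign_group(data.frame(tau_2 = t2, tau_3 = t3, tau_4 = t4)))
  }
  expect_equal(g(180, 180, 180), "I")
  expect_equal(g(180, 180, 0), "II")
  expect_equal(g(180, 100, 180), "other")
  expect_equal(g(-150, 170, -130), "I")
  expect_equal(g(150, -150, -50), "II")
  expect_equal(g(180, 180, 90), "other")   # between the two windows
  set.seed(11)
  rnd <- data.frame(tau_2 = runif(500, -180, 180),
                    tau_3 = runif(500, -180, 180),
                    tau_4 = runif(500, -180, 180))
  gr <- assign_group(rnd)
  in_I <- abs(rnd$tau_2) >= 120 & abs(rnd$tau_3) >= 120 & abs(rnd$tau_4) >= 120
  in_II <- abs(rnd$tau_2) >= 120 & abs(rnd$tau_3) >= 120 & abs(rnd$tau_4) <= 60
  expect_false(any(in_I & in_II))
  expect_equal(gr == "I", in_I)
  expect_equal(gr == "II", in_II)
})

test_that("representative structure minimises cumulative RMSD with tie-breaks", {
  fr <- make_ideal_geometry("canonical_reactive")
  expect_equal(representative_structure(list(fr)), 1L)
  out <- fr; out$coords <- out$coords + matrix(rnorm(48, 0, 2), 16)
  expect_equal(representative_structure(list(fr, fr, out)), 1L)
  # random set: exhaustive independent O(n^2) oracle via quaternion RMSD
  set.seed(12)
  frames <- lapply(1:7, function(i) random_frame(jitter = 0.4))
  sel <- required_roles()
  n <- length(frames)
  sums <- vapply(seq_len(n), function(i) {
    sum(vapply(seq_len(n), function(j) {
      oracle_rmsd(frames[[i]]$coords[sel, ], frames[[j]]$coords[sel, ])
    }, numeric(1)))
  }, numeric(1))
  expect_equal(representative_structure(frames), which.min(sums))
})

test_that("Watson-Crick hydrogen bonds are counted per geometric criterion", {
  fx <- fixture_reference()
  expect_equal(wc_hbond_count(fx, "A3-U10"), 2L)
  expect_equal(wc_hbond_count(fx, "dT4-A9"), 2L)
  # pull the pyrimidine 5 A away: no bonds left
  far <- fx
  u10 <- grep("^U10:", rownames(far$coords))
  far$coords[u10, 1] <- far$coords[u10, 1] + 5
  expect_equal(wc_hbond_count(far, "A3-U10"), 0L)
  expect_equal(wc_hbond_count(far, "dT4-A9"), 2L)   # untouched pair intact
  # stretch one donor-acceptor pair to 3.4 A: fails the 3.0 A cutoff
  st <- fx
  co <- st$coords
  d <- co["U10:N3", ] - co["A3:N1", ]
  stretch <- (3.4 / sqrt(sum(d^2)) - 1) * d
  st$coords["U10:N3", ] <- co["U10:N3", ] + stretch
  st$coords["U10:H3", ] <- co["U10:H3", ] + stretch
  expect_equal(wc_hbond_count(st, "A3-U10"), 1L)
  # missing atoms are named
  miss <- fx
  miss$coords <- miss$coords[rownames(miss$coords) != "U10:O4", ]
  expect_error(wc_hbond_count(miss, "A3-U10"), "U10:O4")
})

test_that("RMSD to the reference is zero for rigid copies and bounded for noise", {
  fx <- fixture_reference()
  sel <- grep("^(A3|U10):", rownames(fx$coords), value = TRUE)
  sel <- sel[!grepl(":H", sel)]
  expect_equal(rmsd_to_ideal(fx, fx, sel), 0)
  rot <- transform_frame(fx)
  expect_lt(rmsd_to_ideal(rot, fx, sel), 1e-9)
  set.seed(13)
  noisy <- fx
  noisy$coords <- noisy$coords + matrix(rnorm(length(noisy$coords), 0, 0.3),
                                        nrow = nrow(noisy$coords))
  v <- rmsd_to_ideal(noisy, fx, sel)
  expect_gt(v, 0); expect_lt(v, 0.6)
  expect_equal(v, oracle_rmsd(fx$coords[sel, ], noisy$coords[sel, ]),
               tolerance = 1e-9)
})

test_that("ensemble summaries agree with independent recomputation", {
  # 6 group-I plus 2 group-II reactive frames and 2 non-reactive ones:
  # the canonical ideal geometry is all-trans (group I); a fragment built
  # with tau_4 = 0 is reactive through its other SAC oxygen (group II)
  mk <- function(t4) {
    build_fragment(dihedral_values = list(tau_1 = 180, tau_2 = 180,
                                          tau_3 = 180, tau_4 = t4,
                                          tau_5 = 145))$coords
  }
  frames <- c(lapply(1:6, function(i) {
                make_ideal_geometry("canonical_reactive")$coords
              }),
              lapply(rep(0, 2), mk),
              lapply(1:2, function(i) {
                make_ideal_geometry("boundary_family", "delta_att", 4)$coords
              }))
  e <- ensemble(frames, n_runs = 2, frames_per_run = 5, validate = FALSE)
  s <- summarize_ensemble(e)
  expect_equal(s$total_O3p, 8L)
  expect_equal(as.integer(s$group_counts[c("I", "II")]), c(6L, 2L))
  expect_equal(unname(s$group_fractions[["I"]]), 0.75)
  # cross-check against the verdicts table
  m <- measure_ensemble(e)
  v <- classify(m)
  expect_equal(s$per_run_O3p,
               as.integer(vapply(split(v$reactive, v$run_id), sum, integer(1))))
  expect_equal(s$fraction_O3p, mean(v$reactive))
  # empty reactive set: fractions are absent, not 0/0
  e0 <- ensemble(frames[9:10], n_runs = 1, frames_per_run = 2, validate = FALSE)
  s0 <- summarize_ensemble(e0)
  expect_equal(s0$total_O3p, 0L)
  expect_true(all(is.na(s0$group_fractions)))
})

test_that("summaries are invariant to frame order (up to representatives)", {
  set.seed(14)
  e <- sample_ensemble(synthetic_config("L", n_runs = 1, frames_per_run = 400,
                                        seed = 21))
  s1 <- summarize_ensemble(e)
  rev_e <- e
  rev_e$coords <- e$coords[n_frames(e):1, , , drop = FALSE]
  s2 <- summarize_ensemble(rev_e)
  expect_equal(s2$total_O3p, s1$total_O3p)
  expect_equal(s2$fraction_O3p, s1$fraction_O3p)
  expect_equal(sort(s2$per_run_O3p), sort(s1$per_run_O3p))
  expect_equal(s2$group_counts, s1$group_counts)
})
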