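# Synthetic reaction-site ensembles.
#
# The generator stands in for MD trajectories of the minihelix reaction
# site. It samples the five alanyl-phosphate backbone dihedrals from
# circular (von Mises) mixtures with the modal values observed for the L-
# and D-alanine systems, rebuilds the fragment in Cartesian space from
# internal coordinates, and holds the A3 ribose at a fixed "A-form scaffold"
# pose so that the nucleophile approach geometry emerges from the backbone
# conformation. Hard-sphere contacts between the alanine substituents
# (amino N, methyl C) and the ribose encode the steric discrimination
# between the two chiralities; clashing draws are rejected and redrawn,
# which is the hard-wall limit of the Boltzmann weight an MD ensemble
# applies.

# ---- circular sampling -----------------------------------------------------

# von Mises sampler (Best & Fisher 1979 envelope-rejection), degrees.
.rvonmises <- function(n, mu_deg, kappa) {
  if (n == 0L) return(numeric(0L))
  if (kappa < 1e-8) {
    deg <- stats::runif(n, -180, 180)
    return(deg)
  }
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(0L)
  while (length(out) < n) {
    m <- n - length(out)
    u1 <- stats::runif(m); u2 <- stats::runif(m); u3 <- stats::runif(m)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    ok <- (cc * (2 - cc) - u2 > 0) | (log(cc / u2) + 1 - cc >= 0)
    th <- sign(u3 - 0.5) * acos(pmax(-1, pmin(1, f)))
    out <- c(out, th[ok])
  }
  deg <- mu_deg + out[seq_len(n)] * 180 / pi
  deg <- ((deg + 180) %% 360) - 180
  deg[deg <= -180] <- deg[deg <= -180] + 360
  deg
}

.sample_mixture <- function(n, model) {
  w <- model$weight
  if (abs(sum(w) - 1) > 1e-9) stop("mixture weights must sum to 1", call. = FALSE)
  if (any(model$kappa <= 0)) stop("mixture concentrations must be > 0", call. = FALSE)
  comp <- sample.int(nrow(model), n, replace = TRUE, prob = w)
  out <- numeric(n)
  for (k in seq_len(nrow(model))) {
    idx <- comp == k
    out[idx] <- .rvonmises(sum(idx), model$mean[k], model$kappa[k])
  }
  out
}

#' Circular mean of angles in degrees
#'
#' @param deg Numeric vector of angles, degrees.
#' @return Circular mean in `(-180, 180]`.
#' @export
circular_mean <- function(deg) {
  th <- deg * pi / 180
  m <- atan2(mean(sin(th)), mean(cos(th))) * 180 / pi
  if (m <= -180) m <- m + 360
  m
}

# ---- configuration ---------------------------------------------------------

#' Default circular dihedral models for the alanyl-phosphate backbone
#'
#' Single von Mises components at 180 degrees for the four backbone
#' dihedrals tau_1..tau_3 and a 99:1 mixture of 180- and 0-degree components
#' for tau(P5'-Ob-Ccarb-Calpha) (the 0-degree basin is thermodynamically
#' unstable but occasionally visited), plus a single component for
#' tau(Ob-Ccarb-Calpha-N) at +145 degrees for the L system and -145 for the
#' D system -- mirror images reflecting the chirality, the only model
#' difference between the two systems. The default concentration kappa = 10
#' puts roughly 90% of each component's mass within +/-30 degrees of its
#' mode.
#'
#' @param chirality `"L"` or `"D"`.
#' @return Named list of data frames with columns `mean`, `kappa`, `weight`.
#' @export
default_dihedral_models <- function(chirality = "L") {
  chirality <- match.arg(chirality, c("L", "D"))
  one <- function(mu) data.frame(mean = mu, kappa = 10, weight = 1)
  list(
    tau_1 = one(180),
    tau_2 = one(180),
    tau_3 = one(180),
    tau_4 = data.frame(mean = c(180, 0), kappa = c(10, 10),
                       weight = c(0.99, 0.01)),
    tau_5 = one(if (chirality == "L") 145 else -145)
  )
}

#' Synthetic ensemble configuration
#'
#' @param chirality `"L"` or `"D"`.
#' @param n_runs Number of independent runs (default 30, matching 30
#'   production simulations).
#' @param frames_per_run Frames per run (default 4000, matching 20 ns
#'   sampled every 5 ps; 30 x 4000 = 120,000 frames per system).
#' @param seed Integer master seed; each run uses an independent substream
#'   derived from `(seed, run_index)`.
#' @param dihedral_models As [default_dihedral_models()].
#' @param bond_table An [internal_coordinate_table()] for the chirality.
#' @param planted_reactive_fraction Optional probability; if set, each frame
#'   is independently replaced (Bernoulli) by a jittered copy of the
#'   canonical reactive geometry, background frames are displaced out of the
#'   attack-distance window, and the planted mask is recorded as ground
#'   truth.
#' @param scaffold Scaffold parameters, see [scaffold_config()].
#' @return An object of class `SyntheticConfig`.
#' @export
synthetic_config <- function(chirality = "L", n_runs = 30L,
                             frames_per_run = 4000L, seed = 1L,
                             dihedral_models = default_dihedral_models(chirality),
                             bond_table = internal_coordinate_table(chirality),
                             planted_reactive_fraction = NULL,
                             scaffold = scaffold_config()) {
  chirality <- match.arg(chirality, c("L", "D"))
  for (nm in names(dihedral_models)) {
    m <- dihedral_models[[nm]]
    if (abs(sum(m$weight) - 1) > 1e-9) {
      stop("weights of dihedral model '", nm, "' must sum to 1", call. = FALSE)
    }
    if (any(m$kappa <= 0)) {
      stop("concentrations of dihedral model '", nm, "' must be > 0", call. = FALSE)
    }
  }
  if (!is.null(planted_reactive_fraction)) {
    stopifnot(planted_reactive_fraction >= 0, planted_reactive_fraction <= 1)
  }
  structure(list(chirality = chirality, n_runs = as.integer(n_runs),
                 frames_per_run = as.integer(frames_per_run),
                 seed = as.integer(seed), dihedral_models = dihedral_models,
                 bond_table = bond_table,
                 planted_reactive_fraction = planted_reactive_fraction,
                 scaffold = scaffold),
            class = "SyntheticConfig")
}

#' Scaffold parameters of the synthetic generator
#'
#' The A3 ribose (O3', C3', C2', O2') is held at a fixed pose emulating the
#' canonical A-form placement: at the modal backbone conformation of the L
#' system the 3'-oxygen sits `delta_att0` Angstroms from the carbonyl carbon
#' on the ideal Buergi-Dunitz approach. Per frame the ribose receives a
#' small rigid-body jitter (rotation sd `rot_sd` degrees about its centroid,
#' isotropic translation sd `trans_sd` Angstroms) emulating thermal breathing
#' of the duplex.
#'
#' @param delta_att0 Modal O3'...Ccarb distance, Angstroms.
#' @param rot_sd Rigid rotation jitter sd, degrees.
#' @param trans_sd Translation jitter sd per axis, Angstroms.
#' @return A list of class `ScaffoldConfig`.
#' @export
scaffold_config <- function(delta_att0 = 3.5, rot_sd = 4, trans_sd = 0.25) {
  structure(list(delta_att0 = delta_att0, rot_sd = rot_sd,
                 trans_sd = trans_sd), class = "ScaffoldConfig")
}

# Stereo-discriminating hard-sphere contacts (Angstroms): group van der
# Waals radii (amino N 1.64, methyl C 1.88, O 1.52, ribose C 1.70), with
# donor/acceptor N...O and O...O pairs allowed 0.4 A closer (hydrogen
# bonding). A generic 2.4 A floor keeps any other chain/ribose pair from
# interpenetrating without biasing either chirality.
.clash_cutoffs <- function() {
  ribose <- c("O3p", "C3p", "C2p", "O2p")
  cut <- matrix(2.4, nrow = 12L, ncol = 4L,
                dimnames = list(c("C4p", "C5p", "O5p", "P5p", "OP1", "OP2",
                                  "Ob", "Ccarb", "Ocarb", "Calpha",
                                  "Namino", "Cbeta"), ribose))
  cut["Namino", c("O3p", "O2p")] <- 2.76
  cut["Namino", c("C3p", "C2p")] <- 3.34
  cut["Cbeta", c("O3p", "O2p")] <- 3.40
  cut["Cbeta", c("C3p", "C2p")] <- 3.58
  cut
}

# ---- scaffold pose ---------------------------------------------------------

# Fixed ribose pose in the chain anchor frame, shared by the L and D
# systems: computed once from the L-system modal backbone, whose virtual
# internal-coordinate rows place O3' on the ideal attack path at delta0.
.scaffold_pose <- function(delta0) {
  ict <- internal_coordinate_table("L", delta_att = delta0)
  modes <- list(tau_1 = 180, tau_2 = 180, tau_3 = 180, tau_4 = 180, tau_5 = 145)
  ref <- build_fragment(ict, modes, chirality = "L")
  ref$coords[c("O3p", "C3p", "C2p", "O2p"), , drop = FALSE]
}

# rotate fixed point v (length 3) by per-frame axis/angle about origin
.rodrigues_rows <- function(v, k, th) {
  vmat <- matrix(v, nrow(k), 3L, byrow = TRUE)
  kv <- .rowcross(k, vmat)
  kdv <- .rowdot(k, vmat)
  vmat * cos(th) + kv * sin(th) + k * (kdv * (1 - cos(th)))
}

# n jittered copies of the 4 x 3 ribose pose -> n x 3 x 4 array
.jitter_pose <- function(pose, n, rot_sd, trans_sd) {
  centroid <- colMeans(pose)
  axis <- matrix(stats::rnorm(3L * n), n, 3L)
  axis <- axis / .rownorm(axis)
  th <- stats::rnorm(n, 0, rot_sd) * pi / 180
  shift <- matrix(stats::rnorm(3L * n, 0, trans_sd), n, 3L)
  out <- array(NA_real_, dim = c(n, 3L, 4L),
               dimnames = list(NULL, c("x", "y", "z"), rownames(pose)))
  for (j in seq_len(4L)) {
    out[, , j] <- .rodrigues_rows(pose[j, ] - centroid, axis, th) +
      matrix(centroid, n, 3L, byrow = TRUE) + shift
  }
  out
}

.clash_mask <- function(arr) {
  cut <- .clash_cutoffs()
  n <- dim(arr)[1L]
  bad <- rep(FALSE, n)
  for (a in rownames(cut)) for (b in colnames(cut)) {
    d2 <- (arr[, 1L, a] - arr[, 1L, b])^2 + (arr[, 2L, a] - arr[, 2L, b])^2 +
      (arr[, 3L, a] - arr[, 3L, b])^2
    bad <- bad | (d2 < cut[a, b]^2)
  }
  bad
}

# ---- ensemble sampling -----------------------------------------------------

.run_seed <- function(seed, run_index) {
  as.integer((as.numeric(seed) * 1000003 + run_index * 7919 + 12345) %% 2147483647)
}

# draw one run of n frames; returns n x 3 x 16 coordinate array
.sample_run_coords <- function(config, n, pose) {
  ict_chain <- config$bond_table[!config$bond_table$virtual, ]
  draw <- function(m) {
    taus <- lapply(config$dihedral_models, function(mod) .sample_mixture(m, mod))
    chain <- .build_chain(ict_chain, taus, n = m)
    rib <- .jitter_pose(pose, m, config$scaffold$rot_sd, config$scaffold$trans_sd)
    arr <- array(NA_real_, dim = c(m, 3L, 16L),
                 dimnames = list(NULL, c("x", "y", "z"),
                                 c(dimnames(chain)[[3L]], dimnames(rib)[[3L]])))
    arr[, , seq_len(12L)] <- chain
    arr[, , 12L + seq_len(4L)] <- rib
    arr
  }
  arr <- draw(n)
  bad <- .clash_mask(arr)
  iter <- 0L
  while (any(bad)) {
    iter <- iter + 1L
    if (iter > 500L) {
      stop("clash rejection failed to converge; scaffold and dihedral models ",
           "are mutually inconsistent", call. = FALSE)
    }
    arr[bad, , ] <- draw(sum(bad))
    bad[bad] <- .clash_mask(arr[bad, , , drop = FALSE])
  }
  arr
}

#' Sample a synthetic reaction-site ensemble
#'
#' Draws `n_runs x frames_per_run` frames. Each run uses an independent,
#' individually reproducible RNG substream derived from `(seed, run_index)`.
#' Backbone dihedrals are drawn from the configured circular mixtures, the
#' fragment is rebuilt from internal coordinates, the ribose is held at the
#' jittered scaffold pose, and frames with hard-sphere contacts between the
#' alanine substituents and the ribose are rejected and redrawn.
#'
#' With `planted_reactive_fraction` set, a Bernoulli-selected subset of
#' frames is replaced by jittered copies of the canonical reactive geometry
#' and all remaining frames are displaced out of the attack-distance window,
#' so the planted mask (stored as `$planted`) is exact ground truth for the
#' classifier.
#'
#' @param config A [synthetic_config()].
#' @return An [ensemble()] with the configured chirality.
#' @export
sample_ensemble <- function(config) {
  stopifnot(inherits(config, "SyntheticConfig"))
  pose <- .scaffold_pose(config$scaffold$delta_att0)
  fpr <- config$frames_per_run
  n_tot <- config$n_runs * fpr
  roles16 <- c(config$bond_table$role[!config$bond_table$virtual],
               rownames(pose))
  big <- array(NA_real_, dim = c(n_tot, 3L, length(roles16)),
               dimnames = list(NULL, c("x", "y", "z"), roles16))
  planted_all <- if (is.null(config$planted_reactive_fraction)) NULL else
    logical(n_tot)

  canon <- NULL
  if (!is.null(config$planted_reactive_fraction)) {
    canon <- make_ideal_geometry("canonical_reactive",
                                 chirality = config$chirality)
    canon_xyz <- canon$coords[roles16, , drop = FALSE]
  }

  for (run in seq_len(config$n_runs) - 1L) {
    set.seed(.run_seed(config$seed, run))
    idx <- run * fpr + seq_len(fpr)
    arr <- .sample_run_coords(config, fpr, pose)

    if (!is.null(config$planted_reactive_fraction)) {
      keep <- stats::runif(fpr) < config$planted_reactive_fraction
      # background frames: push the ribose out of the attack window so the
      # planted mask is exactly the reactive set
      me <- .measure_core(arr, "O3p", seq_len(fpr), run)
      shift_len <- pmax(0, 3.4 - me$delta_att)
      u <- (arr[, , "O3p"] - arr[, , "Ccarb"])
      u <- u / .rownorm(u)
      for (rb in c("O3p", "C3p", "C2p", "O2p")) {
        arr[, , rb] <- arr[, , rb] + u * shift_len
      }
      # planted frames: canonical reactive geometry with small jitter
      if (any(keep)) {
        nk <- sum(keep)
        jit <- array(stats::rnorm(nk * 3L * length(roles16), 0, 0.01),
                     dim = c(nk, 3L, length(roles16)))
        base <- array(rep(t(canon_xyz), each = nk),
                      dim = c(nk, 3L, length(roles16)))
        arr[keep, , ] <- base + jit
      }
      planted_all[idx] <- keep
    }
    big[idx, , ] <- arr
  }

  ensemble(big, n_runs = config$n_runs, frames_per_run = fpr,
           system_label = paste0(config$chirality, "-Ala (synthetic)"),
           chirality_label = config$chirality, planted = planted_all)
}

# ---- ideal geometries ------------------------------------------------------

# Closed-form construction of a complete reaction-site frame with exactly
# prescribed attack geometry. All measures are independently adjustable:
# the nucleophile entourage (C3p, C2p, O2p) and the SAC oxygen ride on the
# nucleophile, so varying one parameter leaves the others fixed.
.ideal_frame <- function(delta_att = 3.0, bd = 105, fl = 0, lobe = 109.5,
                         sac = 3.3, sub_len = c(1.36, 1.52), tau_5 = 145,
                         chirality = "L") {
  deg2rad <- pi / 180
  Cc <- c(0, 0, 0)
  Oc <- c(1.23, 0, 0)
  Ob <- sub_len[1L] * c(cos(120 * deg2rad), sin(120 * deg2rad), 0)
  Ca <- sub_len[2L] * c(cos(-120 * deg2rad), sin(-120 * deg2rad), 0)
  # nucleophile: BD polar angle from the C=O axis, FL azimuth about it
  Nu <- delta_att * c(cos(bd * deg2rad),
                      sin(bd * deg2rad) * sin(fl * deg2rad),
                      sin(bd * deg2rad) * cos(fl * deg2rad))
  # R atom: rotate the Nu->Ccarb direction by the lobe angle
  w <- (Cc - Nu) / sqrt(sum((Cc - Nu)^2))
  axis <- c(w[3L], 0, -w[1L])                      # cross(w, y-hat)
  if (sqrt(sum(axis^2)) < 1e-6) axis <- c(1, 0, 0)
  C3 <- Nu + 1.42 * as.vector(.rotation_about(axis, lobe) %*% w)
  C2 <- as.vector(.nerf_place(rbind(Cc), rbind(Nu), rbind(C3), 1.53, 109.5, 60))
  O2 <- as.vector(.nerf_place(rbind(Nu), rbind(C3), rbind(C2), 1.41, 109.5, 60))
  # phosphate: tau(P5'-Ob-Ccarb-Ocarb) ~ 0 (group-I-like carbonyl orientation)
  P5 <- as.vector(.nerf_place(rbind(Oc), rbind(Cc), rbind(Ob), 1.60, 120, 0))
  # OP1 exactly `sac` from the nucleophile, on the 1.48 A sphere around P5'
  dvec <- Nu - P5
  D <- sqrt(sum(dvec^2))
  e1 <- dvec / D
  ez <- c(0, 0, 1) - sum(c(0, 0, 1) * e1) * e1
  if (sqrt(sum(ez^2)) < 1e-6) ez <- c(1, 0, 0) - e1[1L] * e1
  e2 <- ez / sqrt(sum(ez^2))
  if (D <= sac + 1.48 && D >= abs(sac - 1.48)) {
    # on the P-O bond sphere and exactly `sac` from the nucleophile
    cphi <- (D^2 + 1.48^2 - sac^2) / (2 * D * 1.48)
    phi <- acos(pmax(-1, pmin(1, cphi)))
    OP1 <- P5 + 1.48 * (cos(phi) * e1 + sin(phi) * e2)
    phi2 <- min(phi + 115 * deg2rad, 178 * deg2rad)
    OP2 <- P5 + 1.48 * (cos(phi2) * e1 + sin(phi2) * e2)
  } else {
    # geometry too stretched for a bonded placement: translate the OP pair
    # radially from the nucleophile so the SAC distance is still exact
    OP1 <- Nu - sac * e1
    OP2 <- Nu - (sac + 1.2) * e1 + 0.8 * e2
  }
  # dT4 backbone in the trans basin
  O5 <- as.vector(.nerf_place(rbind(Cc), rbind(Ob), rbind(P5), 1.60, 102, 180))
  C5 <- as.vector(.nerf_place(rbind(Ob), rbind(P5), rbind(O5), 1.43, 120, 180))
  C4 <- as.vector(.nerf_place(rbind(P5), rbind(O5), rbind(C5), 1.52, 110, 180))
  # alanine stereocenter
  if (chirality == "D") tau_5 <- -tau_5
  cb_off <- if (chirality == "L") 120 else -120
  N <- as.vector(.nerf_place(rbind(Ob), rbind(Cc), rbind(Ca), 1.47, 109.5, tau_5))
  Cb <- as.vector(.nerf_place(rbind(Ob), rbind(Cc), rbind(Ca), 1.53, 110,
                              tau_5 + cb_off))
  co <- rbind(C4p = C4, C5p = C5, O5p = O5, P5p = P5, OP1 = OP1, OP2 = OP2,
              Ob = Ob, Ccarb = Cc, Ocarb = Oc, Calpha = Ca, Namino = N,
              Cbeta = Cb, O3p = Nu, C3p = C3, O2p = O2, C2p = C2)
  colnames(co) <- c("x", "y", "z")
  reaction_site_frame(co, chirality_label = chirality)
}

#' Construct ideal test geometries
#'
#' Deterministic, closed-form reaction-site frames used as analytic test
#' cases and for boundary scans:
#'
#' * `"canonical_reactive"`: attack distance 3.0 A, Buergi-Dunitz 105,
#'   Flippin-Lodge 0, lobe 109.5 degrees, min SAC distance exactly 3.3 A --
#'   strictly inside every criterion window.
#' * `"sp3_tetrahedral"`: as canonical but with the exact tetrahedral lobe
#'   angle acos(-1/3) = 109.4712 degrees.
#' * `"symmetric_carbonyl"`: both carbonyl substituents placed with equal
#'   bond lengths (a symmetric R' = R'' substitution); the nucleophile lies
#'   in the plane perpendicular to the carbonyl plane through C=O, so the
#'   Flippin-Lodge angle is exactly 0.
#' * `"boundary_family"`: the canonical frame with exactly one measure set
#'   to `value` (name in `measure`), all others held at their canonical
#'   values -- single-parameter families for bisection scans.
#'
#' @param kind One of the four kinds above.
#' @param measure For `"boundary_family"`: one of `"delta_att"`,
#'   `"alpha_BD"`, `"alpha_FL"`, `"alpha_Lobe"`, `"delta_SAC"`.
#' @param value For `"boundary_family"`: the value of the varied measure
#'   (Angstroms or degrees).
#' @param chirality `"L"` or `"D"` stereocenter for the alanine.
#' @return A [reaction_site_frame()].
#' @export
make_ideal_geometry <- function(kind = c("canonical_reactive", "sp3_tetrahedral",
                                         "symmetric_carbonyl", "boundary_family"),
                                measure = NULL, value = NULL, chirality = "L") {
  kind <- match.arg(kind)
  chirality <- match.arg(chirality, c("L", "D"))
  switch(kind,
    canonical_reactive = .ideal_frame(chirality = chirality),
    sp3_tetrahedral = .ideal_frame(lobe = acos(-1 / 3) * 180 / pi,
                                   chirality = chirality),
    symmetric_carbonyl = .ideal_frame(sub_len = c(1.50, 1.50),
                                      chirality = chirality),
    boundary_family = {
      if (is.null(measure) || is.null(value)) {
        stop("boundary_family needs `measure` and `value`", call. = FALSE)
      }
      measure <- match.arg(measure, c("delta_att", "alpha_BD", "alpha_FL",
                                      "alpha_Lobe", "delta_SAC"))
      args <- list(chirality = chirality)
      args[[switch(measure, delta_att = "delta_att", alpha_BD = "bd",
                   alpha_FL = "fl", alpha_Lobe = "lobe",
                   delta_SAC = "sac")]] <- value
      do.call(.ideal_frame, args)
    })
}

# ---- base-pair fixture -----------------------------------------------------

# Idealized planar base: hexagon ring of radius `r` plus exocyclic atoms.
.hexagon <- function(names, r = 1.39, start_deg = 0) {
  ang <- (start_deg + seq(0, 300, by = 60)) * pi / 180
  co <- cbind(r * cos(ang), r * sin(ang), 0)
  rownames(co) <- names
  co
}

# One Watson-Crick A:U / A:T pair in the z = 0 plane. The purine N1 sits at
# the origin-side vertex; the pyrimidine is placed so that both canonical
# hydrogen bonds (N6-H...O4 and N3-H...N1) are ~2.9 A and near-linear.
# `thymine` adds the C7 methyl. Returns role-keyed coordinates with the
# given residue prefixes (e.g. "A3", "U10").
.wc_pair <- function(pur, pyr, thymine = FALSE, n1n3 = 2.82) {
  # adenine six-ring: N1 at angle 0 (pointing +x, towards the pyrimidine)
  ade <- .hexagon(c("N1", "C2", "N3", "C4", "C5", "C6"), start_deg = 0)
  # exocyclic amino N6 on C6 (vertex at 300 deg), radially outward
  c6 <- ade["C6", ]
  ade <- rbind(ade, N6 = c6 * (1.39 + 1.34) / 1.39)
  # pyrimidine six-ring: N3 pointing back (-x) towards the purine
  pyc <- c(1.39 + n1n3 + 1.39, 0, 0)   # pyrimidine ring center
  pyr_ring <- .hexagon(c("N3", "C4", "C5", "C6", "N1", "C2"), start_deg = 180)
  pyr_ring <- sweep(pyr_ring, 2L, -pyc)   # translate to center
  # exocyclic oxygens radially outward from the ring center
  out_from <- function(v, extra) pyc + (v - pyc) * (1.39 + extra) / 1.39
  o4 <- out_from(pyr_ring["C4", ], 1.22)  # C4 at 240 deg -> below axis (-y)
  o2 <- out_from(pyr_ring["C2", ], 1.22)
  py <- rbind(pyr_ring, O4 = o4, O2 = o2)
  if (thymine) {
    py <- rbind(py, C7 = out_from(pyr_ring["C5", ], 1.50))
  }
  # polar hydrogens along the hydrogen bonds (near-linear donors)
  n6 <- ade["N6", ]
  u61 <- (o4 - n6) / sqrt(sum((o4 - n6)^2))
  ur <- (n6 - c6) / sqrt(sum((n6 - c6)^2))       # exocyclic bond direction
  h61 <- n6 + 1.01 * u61
  h62 <- n6 + 1.01 * (2 * sum(u61 * ur) * ur - u61)  # mirror of H61 across it
  ade <- rbind(ade, H61 = h61, H62 = h62)
  n3 <- py["N3", ]
  h3 <- n3 + 1.01 * (ade["N1", ] - n3) / sqrt(sum((ade["N1", ] - n3)^2))
  py <- rbind(py, H3 = h3)
  rownames(ade) <- paste0(pur, ":", rownames(ade))
  rownames(py) <- paste0(pyr, ":", rownames(py))
  rbind(ade, py)
}

#' Idealized reference frame with base-pair atoms
#'
#' A deterministic stand-in for the ideal A-form reference: the canonical
#' reactive reaction-site geometry extended with idealized, planar A3-U10
#' and dT4-A9 Watson-Crick base pairs (two well-formed hydrogen bonds each,
#' donor-acceptor ~2.9 A, near-linear), stacked with an A-form-like rise of
#' 2.81 A and twist of 32.7 degrees. Base atoms are keyed
#' `"residue:atomname"` (e.g. `"U10:O4"`); polar amino/imino hydrogens are
#' included so the angular hydrogen-bond criterion applies.
#'
#' These coordinates are synthetic idealizations for testing geometry code,
#' not a crystallographic A-form helix.
#'
#' @return A [reaction_site_frame()] with base-pair atoms attached.
#' @export
fixture_reference <- function() {
  pair1 <- .wc_pair("A3", "U10")                      # A3-U10
  pair2 <- .wc_pair("A9", "DT4", thymine = TRUE)      # dT4-A9
  # stack pair 2 below pair 1 with A-form-like rise and twist
  rot <- .rotation_about(c(0, 0, 1), 32.7)
  pair2 <- pair2 %*% t(rot)
  pair2[, 3L] <- pair2[, 3L] - 2.81
  site <- make_ideal_geometry("canonical_reactive")
  site_xyz <- site$coords
  site_xyz[, 3L] <- site_xyz[, 3L] + 8    # keep the site clear of the bases
  co <- rbind(site_xyz, pair1, pair2)
  colnames(co) <- c("x", "y", "z")
  reaction_site_frame(co, chirality_label = "L")
}
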