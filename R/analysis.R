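# Ensemble-level analyses: dihedral distributions, conformer groups,
# representative structures, Watson-Crick hydrogen bonds and RMSD to an
# ideal reference.

#' Circular histogram of a backbone dihedral
#'
#' Probability distribution of one named dihedral over frames, with circular
#' binning on `(-180, 180]`. A value falling exactly on a bin edge is
#' assigned to the higher bin (wrapping past +180 into the first bin).
#'
#' @param measures A `GeometryMeasures` data frame (non-empty).
#' @param which_tau Column name: `"tau_1"` .. `"tau_5"` or `"tau_carbonyl"`
#'   (also accepts `"alpha_FL"`).
#' @param bin_width Bin width in degrees; must divide 360.
#' @return An object of class `CircularHistogram`: list with `breaks` (bin
#'   lower edges, degrees), `mids`, `counts`, `prob` (sums to 1), `n`, and
#'   `mode_deg` (midpoint of the maximum-probability bin).
#' @export
dihedral_distribution <- function(measures, which_tau, bin_width = 5) {
  if (NROW(measures) == 0L) stop("no measures supplied", call. = FALSE)
  if (360 %% bin_width != 0) stop("bin_width must divide 360", call. = FALSE)
  v <- measures[[which_tau]]
  if (is.null(v)) stop("no dihedral column '", which_tau, "'", call. = FALSE)
  nb <- as.integer(360 / bin_width)
  idx <- (floor((v + 180) / bin_width) %% nb) + 1L
  counts <- tabulate(idx, nbins = nb)
  breaks <- -180 + bin_width * (seq_len(nb) - 1L)
  h <- list(breaks = breaks, mids = breaks + bin_width / 2,
            counts = counts, prob = counts / sum(counts),
            n = length(v), which = which_tau,
            mode_deg = (breaks + bin_width / 2)[which.max(counts)])
  class(h) <- "CircularHistogram"
  h
}

#' @export
print.CircularHistogram <- function(x, ...) {
  cat("CircularHistogram of ", x$which, ": ", length(x$breaks), " bins x ",
      x$n, " samples; mode near ", x$mode_deg, " deg\n", sep = "")
  invisible(x)
}

#' Assign conformer groups from backbone dihedrals
#'
#' Group I: all of |tau(C5'-O5'-P5'-Ob)|, |tau(O5'-P5'-Ob-Ccarb)| and
#' |tau(P5'-Ob-Ccarb-Calpha)| at least 120 degrees (the all-trans
#' combination of the most probable basins). Group II: the first two at
#' least 120 but |tau(P5'-Ob-Ccarb-Calpha)| at most 60 (the carbonyl-flipped
#' conformer distinctive of the D system). Anything else is `other`; the
#' groups are disjoint by construction.
#'
#' @param measures A `GeometryMeasures` data frame.
#' @return Factor with levels `I`, `II`, `other`, one per row.
#' @export
assign_group <- function(measures) {
  t2 <- abs(measures$tau_2); t3 <- abs(measures$tau_3); t4 <- abs(measures$tau_4)
  if (is.null(t2) || is.null(t3) || is.null(t4)) {
    stop("measures lack tau_2/tau_3/tau_4", call. = FALSE)
  }
  g <- rep("other", NROW(measures))
  backbone <- t2 >= 120 & t3 >= 120
  g[backbone & t4 >= 120] <- "I"
  g[backbone & t4 <= 60] <- "II"
  factor(g, levels = c("I", "II", "other"))
}

#' Representative structure of a conformer group
#'
#' Index (1-based) of the frame with the lowest cumulative RMSD over the
#' selected atoms with respect to every other frame, after optimal rigid
#' superposition of each pair. Ties break to the lowest index.
#'
#' @param frames A list of [reaction_site_frame()] objects or an
#'   [ensemble()].
#' @param selection Character vector of atom roles to superpose (default:
#'   all required roles).
#' @return Integer index into `frames`.
#' @export
representative_structure <- function(frames, selection = required_roles()) {
  if (inherits(frames, "Ensemble")) {
    frames <- lapply(seq_len(n_frames(frames)), function(i) get_frame(frames, i))
  }
  n <- length(frames)
  if (n == 0L) stop("no frames supplied", call. = FALSE)
  if (n == 1L) return(1L)
  xyz <- lapply(frames, function(fr) {
    miss <- setdiff(selection, rownames(fr$coords))
    if (length(miss)) {
      stop("selection role(s) absent from frame: ",
           paste(miss, collapse = ", "), call. = FALSE)
    }
    fr$coords[selection, , drop = FALSE]
  })
  rms <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    rms[i, j] <- rms[j, i] <- kabsch_rmsd(xyz[[i]], xyz[[j]])
  }
  which.min(rowSums(rms))   # which.min takes the first (lowest) index on ties
}

# canonical Watson-Crick donor/acceptor triples per base pair:
# (donor heavy atom, donor hydrogens, acceptor)
.wc_pairs <- function(basepair) {
  switch(basepair,
    "A3-U10" = list(
      list(d = "A3:N6", h = c("A3:H61", "A3:H62"), a = "U10:O4"),
      list(d = "U10:N3", h = "U10:H3", a = "A3:N1")),
    "dT4-A9" = list(
      list(d = "A9:N6", h = c("A9:H61", "A9:H62"), a = "DT4:O4"),
      list(d = "DT4:N3", h = "DT4:H3", a = "A9:N1")),
    stop("unknown base pair '", basepair, "'", call. = FALSE))
}

#' Count Watson-Crick hydrogen bonds in a base pair
#'
#' Checks the two canonical donor-acceptor pairs of an A:U / A:T
#' Watson-Crick pair (adenine N6-H to O4; N3-H of uracil/thymine to adenine
#' N1). When donor hydrogens are present, a bond requires donor-acceptor
#' distance below `dist_cutoff` and a donor-H...acceptor angle above
#' `angle_cutoff`; without hydrogens, the heavy-atom-only criterion
#' `heavy_dist_cutoff` applies. These defaults mirror common
#' trajectory-analysis practice (e.g. CPPTRAJ-style hydrogen-bond searches).
#'
#' @param frame A [reaction_site_frame()] carrying base atoms keyed
#'   `"residue:atomname"` (see [fixture_reference()]).
#' @param basepair `"A3-U10"` or `"dT4-A9"`.
#' @param dist_cutoff Donor-acceptor heavy-atom cutoff with hydrogens, A.
#' @param angle_cutoff Minimum donor-H...acceptor angle, degrees.
#' @param heavy_dist_cutoff Heavy-atom-only fallback cutoff, A.
#' @return Integer count in 0..2.
#' @export
wc_hbond_count <- function(frame, basepair = c("A3-U10", "dT4-A9"),
                           dist_cutoff = 3.0, angle_cutoff = 135,
                           heavy_dist_cutoff = 3.5) {
  basepair <- match.arg(basepair)
  co <- frame$coords
  n_hb <- 0L
  for (p in .wc_pairs(basepair)) {
    miss <- setdiff(c(p$d, p$a), rownames(co))
    if (length(miss)) {
      stop("base atom(s) missing for ", basepair, ": ",
           paste(miss, collapse = ", "), call. = FALSE)
    }
    dpos <- co[p$d, ]; apos <- co[p$a, ]
    dda <- sqrt(sum((dpos - apos)^2))
    hs <- intersect(p$h, rownames(co))
    if (length(hs)) {
      ok <- dda < dist_cutoff && any(vapply(hs, function(h) {
        .planar_angle(dpos, co[h, ], apos) > angle_cutoff
      }, logical(1L)))
    } else {
      ok <- dda < heavy_dist_cutoff
    }
    n_hb <- n_hb + as.integer(ok)
  }
  n_hb
}

#' RMSD of a frame to a reference structure
#'
#' Kabsch-superposed RMSD over a role selection present in both structures,
#' e.g. base-pair heavy atoms against an ideal A-form-like reference.
#'
#' @param frame,reference [reaction_site_frame()] objects.
#' @param selection Character vector of roles to superpose.
#' @return RMSD in Angstroms.
#' @export
rmsd_to_ideal <- function(frame, reference = fixture_reference(),
                          selection = required_roles()) {
  miss_f <- setdiff(selection, rownames(frame$coords))
  miss_r <- setdiff(selection, rownames(reference$coords))
  if (length(miss_f) || length(miss_r)) {
    stop("selection role(s) unresolvable: ",
         paste(unique(c(miss_f, miss_r)), collapse = ", "), call. = FALSE)
  }
  kabsch_rmsd(reference$coords[selection, , drop = FALSE],
              frame$coords[selection, , drop = FALSE])
}

#' Summarize an ensemble's reactive-geometry content
#'
#' Per-run and total reactive counts for both nucleophile choices, the
#' group I/II census among O3'-reactive frames, and -- when base-pair atoms
#' are present -- mean and sample standard deviation (n-1) of Watson-Crick
#' hydrogen-bond counts and RMSD to the reference over reactive frames.
#' With no reactive frames the group fractions are reported as `NA`
#' (absent), never 0/0.
#'
#' @param x An [ensemble()].
#' @param config A [criteria_config()].
#' @param measures_o3p,measures_o2p Optional precomputed measures.
#' @return A list of class `EnsembleSummary`.
#' @export
summarize_ensemble <- function(x, config = criteria_config(),
                               measures_o3p = NULL, measures_o2p = NULL) {
  if (is.null(measures_o3p)) measures_o3p <- measure_ensemble(x, "O3p")
  if (is.null(measures_o2p)) measures_o2p <- measure_ensemble(x, "O2p")
  c3 <- count_reactive(x, "O3p", config, measures = measures_o3p)
  c2 <- count_reactive(x, "O2p", config, measures = measures_o2p)
  v3 <- classify(measures_o3p, config)
  grp <- assign_group(measures_o3p[v3$reactive, , drop = FALSE])
  n_react <- sum(v3$reactive)
  group_counts <- table(grp)
  group_fractions <- if (n_react > 0L) {
    as.numeric(group_counts) / n_react
  } else rep(NA_real_, 3L)
  names(group_fractions) <- names(group_counts)

  hbonds <- rmsd <- NULL
  has_bases <- all(c("A3:N1", "U10:N3") %in% dimnames(x$coords)[[3L]])
  if (has_bases && n_react > 0L) {
    ridx <- which(v3$reactive)
    hb <- vapply(ridx, function(i) {
      fr <- get_frame(x, i)
      wc_hbond_count(fr, "A3-U10") + wc_hbond_count(fr, "dT4-A9")
    }, numeric(1L))
    hbonds <- c(mean = mean(hb), sd = stats::sd(hb))
  }

  structure(list(
    system_label = x$system_label,
    chirality = x$chirality_label,
    n_runs = x$n_runs, frames_per_run = x$frames_per_run,
    per_run_O3p = c3$per_run, total_O3p = c3$total, fraction_O3p = c3$fraction,
    per_run_O2p = c2$per_run, total_O2p = c2$total, fraction_O2p = c2$fraction,
    group_counts = group_counts, group_fractions = group_fractions,
    hbonds = hbonds, rmsd = rmsd), class = "EnsembleSummary")
}

#' @export
print.EnsembleSummary <- function(x, ...) {
  cat("EnsembleSummary '", x$system_label, "' (", x$n_runs, " x ",
      x$frames_per_run, " frames)\n", sep = "")
  cat(sprintf("  reactive (O3'): %d (%.3g%%)   reactive (O2'): %d (%.3g%%)\n",
              x$total_O3p, 100 * x$fraction_O3p,
              x$total_O2p, 100 * x$fraction_O2p))
  gc <- x$group_counts
  cat("  groups among O3'-reactive: I =", gc[["I"]], ", II =", gc[["II"]],
      ", other =", gc[["other"]], "\n")
  invisible(x)
}
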