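# Five-criterion reactive-conformation classifier.

#' Criteria thresholds for a reactive conformation
#'
#' Defaults are the printed definition of a reactive geometry:
#' attack distance below 3.2 A; Buergi-Dunitz angle within 15 degrees of
#' 105; |Flippin-Lodge| below 25 degrees; lobe angle within 15 degrees of
#' 109.5; and the nearer of the two Nu...OP distances below 3.5 A (the
#' diameter of an oxygen atom, 3.0 A, plus a 0.5 A buffer), so that a
#' non-bridging phosphate oxygen can act as the general base of
#' substrate-assisted catalysis. All comparisons are strict.
#'
#' The "criteria without the FL angle" variant is expressed as
#' `fl_halfwidth = 180` rather than a separate code path.
#'
#' @param d_att_max Maximum attack distance, Angstroms.
#' @param bd_center,bd_halfwidth Buergi-Dunitz window, degrees.
#' @param fl_halfwidth Half-width of the |FL| window, degrees.
#' @param lobe_center,lobe_halfwidth Lobe-angle window, degrees.
#' @param sac_max Maximum min(Nu...OP1, Nu...OP2) distance, Angstroms.
#' @return An object of class `CriteriaConfig`.
#' @export
criteria_config <- function(d_att_max = 3.2, bd_center = 105, bd_halfwidth = 15,
                            fl_halfwidth = 25, lobe_center = 109.5,
                            lobe_halfwidth = 15, sac_max = 3.5) {
  vals <- c(d_att_max = d_att_max, bd_center = bd_center,
            bd_halfwidth = bd_halfwidth, fl_halfwidth = fl_halfwidth,
            lobe_center = lobe_center, lobe_halfwidth = lobe_halfwidth,
            sac_max = sac_max)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all criteria parameters must be positive and finite", call. = FALSE)
  }
  if (any(c(bd_halfwidth, lobe_halfwidth) >= 180) || fl_halfwidth > 180) {
    stop("angle half-widths must be < 180 degrees (FL: <= 180)", call. = FALSE)
  }
  structure(as.list(vals), class = "CriteriaConfig")
}

#' @export
print.CriteriaConfig <- function(x, ...) {
  cat(sprintf(paste0(
    "Reactive-geometry criteria (strict inequalities):\n",
    "  1: delta_att        < %.4g A\n",
    "  2: |alpha_BD - %g|   < %g deg\n",
    "  3: |alpha_FL|        < %g deg\n",
    "  4: |alpha_Lobe - %g| < %g deg\n",
    "  5: min(delta_SAC)    < %.4g A\n"),
    x$d_att_max, x$bd_center, x$bd_halfwidth, x$fl_halfwidth,
    x$lobe_center, x$lobe_halfwidth, x$sac_max))
  invisible(x)
}

#' Classify frames as reactive or not
#'
#' Applies the five reactive-geometry criteria to per-frame measures. A frame
#' is reactive iff all five criteria hold; every inequality is strict, so a
#' measure sitting exactly on a threshold fails.
#'
#' @param measures A `GeometryMeasures` data frame from [measure_frame()] or
#'   [measure_ensemble()] (any number of rows).
#' @param config A [criteria_config()].
#' @return A data frame of class `ReactiveVerdict` with columns `frame_id`,
#'   `run_id`, `nu_choice`, logicals `c1`..`c5` and `reactive`.
#' @export
classify <- function(measures, config = criteria_config()) {
  stopifnot(inherits(config, "CriteriaConfig"))
  need <- setdiff(.measure_cols, names(measures))
  if (length(need)) {
    stop("measures lack column(s): ", paste(need, collapse = ", "), call. = FALSE)
  }
  out <- data.frame(
    frame_id = measures$frame_id,
    run_id = measures$run_id,
    nu_choice = measures$nu_choice,
    c1 = measures$delta_att < config$d_att_max,
    c2 = abs(measures$alpha_BD - config$bd_center) < config$bd_halfwidth,
    c3 = abs(measures$alpha_FL) < config$fl_halfwidth,
    c4 = abs(measures$alpha_Lobe - config$lobe_center) < config$lobe_halfwidth,
    c5 = pmin(measures$delta_SAC_OP1, measures$delta_SAC_OP2) < config$sac_max,
    stringsAsFactors = FALSE
  )
  out$reactive <- out$c1 & out$c2 & out$c3 & out$c4 & out$c5
  class(out) <- c("ReactiveVerdict", class(out))
  out
}

#' Count reactive conformations per run
#'
#' @param x An [ensemble()].
#' @param nu_choice `"O3p"` or `"O2p"`.
#' @param config A [criteria_config()].
#' @param measures Optional precomputed [measure_ensemble()] result for `x`
#'   and `nu_choice` (avoids re-measuring in scans).
#' @return A list with `per_run` (integer vector, one count per run),
#'   `total`, `n_frames`, and `fraction` (total / n_frames).
#' @export
count_reactive <- function(x, nu_choice = "O3p", config = criteria_config(),
                           measures = NULL) {
  if (n_frames(x) == 0L) stop("ensemble has no frames", call. = FALSE)
  if (is.null(measures)) measures <- measure_ensemble(x, nu_choice)
  v <- classify(measures, config)
  per_run <- vapply(split(v$reactive, v$run_id), sum, integer(1L))
  per_run <- as.integer(per_run[order(as.integer(names(per_run)))])
  list(per_run = per_run, total = sum(per_run), n_frames = n_frames(x),
       fraction = sum(per_run) / n_frames(x))
}

#' Locate a criterion's accept/reject boundary by bisection
#'
#' Uses the single-parameter ideal-geometry families of
#' [make_ideal_geometry()] (which vary exactly one measure while holding the
#' others at canonical values) to recover the classifier's decision boundary
#' empirically: the bisection brackets the value of the varied measure at
#' which the given criterion flips, to within `tol`.
#'
#' @param measure One of `"delta_att"`, `"alpha_BD"`, `"alpha_FL"`,
#'   `"alpha_Lobe"`, `"delta_SAC"`.
#' @param criterion Which criterion to watch, `"c1"`..`"c5"`.
#' @param lower,upper Bracket; the criterion must differ at the two ends.
#' @param config A [criteria_config()].
#' @param tol Bisection tolerance (same units as `measure`).
#' @param nu_choice Nucleophile choice passed to the measurement.
#' @return The boundary value of the varied measure.
#' @export
criterion_boundary <- function(measure, criterion, lower, upper,
                               config = criteria_config(), tol = 1e-6,
                               nu_choice = "O3p") {
  passes <- function(t) {
    fr <- make_ideal_geometry("boundary_family", measure = measure, value = t)
    v <- classify(measure_frame(fr, nu_choice), config)
    v[[criterion]]
  }
  p_lo <- passes(lower); p_hi <- passes(upper)
  if (p_lo == p_hi) {
    stop("criterion ", criterion, " does not change over [", lower, ", ",
         upper, "]", call. = FALSE)
  }
  while (upper - lower > tol) {
    mid <- (lower + upper) / 2
    if (passes(mid) == p_lo) lower <- mid else upper <- mid
  }
  (lower + upper) / 2
}

#' Threshold-sensitivity scan
#'
#' Reclassifies an ensemble under a grid of criteria configurations and
#' tabulates the total reactive counts, mirroring supplementary
#' buffer-variation scans: widening any window can only add frames, so
#' counts are monotone under threshold loosening.
#'
#' @param x An [ensemble()].
#' @param nu_choice `"O3p"` or `"O2p"`.
#' @param config_grid A list of [criteria_config()] objects.
#' @param measures Optional precomputed measures (measuring dominates the
#'   cost; the scan itself is arithmetic).
#' @return A data frame with one row per configuration: the seven thresholds
#'   and the resulting `total` count.
#' @export
sensitivity_scan <- function(x, nu_choice = "O3p", config_grid,
                             measures = NULL) {
  if (!length(config_grid)) stop("config_grid is empty", call. = FALSE)
  if (is.null(measures)) measures <- measure_ensemble(x, nu_choice)
  rows <- lapply(config_grid, function(cfg) {
    v <- classify(measures, cfg)
    data.frame(d_att_max = cfg$d_att_max, bd_center = cfg$bd_center,
               bd_halfwidth = cfg$bd_halfwidth, fl_halfwidth = cfg$fl_halfwidth,
               lobe_center = cfg$lobe_center, lobe_halfwidth = cfg$lobe_halfwidth,
               sac_max = cfg$sac_max, total = sum(v$reactive))
  })
  do.call(rbind, rows)
}
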