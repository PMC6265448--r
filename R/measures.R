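# Per-frame geometric measures of the attack site.
#
# measure_frame() and measure_ensemble() share one vectorised core working on
# the ensemble coordinate array, so measuring 10^5 frames costs a handful of
# matrix operations (plus one small SVD per frame for the carbonyl plane).

.measure_cols <- c("frame_id", "run_id", "nu_choice",
                   "delta_att", "alpha_BD", "alpha_FL", "alpha_Lobe",
                   "delta_SAC_OP1", "delta_SAC_OP2",
                   "tau_1", "tau_2", "tau_3", "tau_4", "tau_5", "tau_carbonyl")

# coords: n x 3 x role array; returns data.frame of measures
.measure_core <- function(coords, nu_choice, frame_id, run_id) {
  nu <- .nu_roles(nu_choice)
  at <- function(role) coords[, , role, drop = FALSE][, , 1L, drop = TRUE]
  # drop=TRUE on a 1-frame array yields a vector; normalise to matrix
  at <- function(role) {
    m <- coords[, , role]
    if (is.null(dim(m))) m <- matrix(m, nrow = 1L)
    m
  }
  Nu <- at(nu$nu); R <- at(nu$r)
  Cc <- at("Ccarb"); Oc <- at("Ocarb"); Ca <- at("Calpha"); Ob <- at("Ob")
  P5 <- at("P5p"); O5 <- at("O5p"); C5 <- at("C5p"); C4 <- at("C4p")
  OP1 <- at("OP1"); OP2 <- at("OP2"); N <- at("Namino")

  n <- nrow(Nu)
  fl <- vapply(seq_len(n), function(i) {
    .fl_angle_core(Nu[i, , drop = FALSE], Cc[i, , drop = FALSE],
                   Oc[i, , drop = FALSE], Ca[i, , drop = FALSE],
                   Ob[i, , drop = FALSE])
  }, numeric(1L))

  data.frame(
    frame_id = frame_id,
    run_id = run_id,
    nu_choice = nu_choice,
    delta_att = .rownorm(Nu - Cc),
    alpha_BD = .planar_angle(Nu, Cc, Oc),
    alpha_FL = fl,
    alpha_Lobe = .planar_angle(R, Nu, Cc),
    delta_SAC_OP1 = .rownorm(Nu - OP1),
    delta_SAC_OP2 = .rownorm(Nu - OP2),
    tau_1 = signed_dihedral(C4, C5, O5, P5),
    tau_2 = signed_dihedral(C5, O5, P5, Ob),
    tau_3 = signed_dihedral(O5, P5, Ob, Cc),
    tau_4 = signed_dihedral(P5, Ob, Cc, Ca),
    tau_5 = signed_dihedral(Ob, Cc, Ca, N),
    tau_carbonyl = signed_dihedral(P5, Ob, Cc, Oc),
    stringsAsFactors = FALSE
  )
}

#' Measure the attack geometry of one frame
#'
#' Computes every per-frame scalar the reactive-conformation criteria and the
#' dihedral analyses use: the attack distance `delta_att` (Nu...Ccarb), the
#' Buergi-Dunitz, Flippin-Lodge and lobe angles, the two
#' substrate-assisted-catalysis distances Nu...OP1 and Nu...OP2, and the five
#' named backbone dihedrals of the alanyl phosphate plus the carbonyl
#' orientation dihedral tau(P5'-Ob-Ccarb-Ocarb).
#'
#' @param frame A [reaction_site_frame()].
#' @param nu_choice `"O3p"` (attack by the 3'-oxygen, R = C3') or `"O2p"`
#'   (attack by the 2'-oxygen, R = C2').
#' @return A one-row data frame of class `GeometryMeasures`.
#' @export
measure_frame <- function(frame, nu_choice = "O3p") {
  nu_choice <- match.arg(nu_choice, c("O3p", "O2p"))
  roles <- rownames(frame$coords)
  arr <- array(NA_real_, dim = c(1L, 3L, length(roles)),
               dimnames = list(NULL, c("x", "y", "z"), roles))
  arr[1L, , ] <- t(frame$coords)
  out <- tryCatch(
    .measure_core(arr, nu_choice, frame$frame_id, frame$run_id),
    error = function(e) {
      stop("frame ", frame$frame_id, " (run ", frame$run_id, "): ",
           conditionMessage(e), call. = FALSE)
    })
  class(out) <- c("GeometryMeasures", class(out))
  out
}

#' Measure the attack geometry of every frame in an ensemble
#'
#' @param x An [ensemble()].
#' @param nu_choice `"O3p"` or `"O2p"`; which ribose oxygen is treated as
#'   the nucleophile.
#' @return A data frame with one row per frame (columns as in
#'   [measure_frame()]), in frame order.
#' @export
measure_ensemble <- function(x, nu_choice = "O3p") {
  nu_choice <- match.arg(nu_choice, c("O3p", "O2p"))
  n <- n_frames(x)
  if (n == 0L) stop("ensemble has no frames", call. = FALSE)
  out <- .measure_core(x$coords, nu_choice,
                       frame_id = (seq_len(n) - 1L) %% x$frames_per_run,
                       run_id = run_ids(x))
  class(out) <- c("GeometryMeasures", class(out))
  out
}
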