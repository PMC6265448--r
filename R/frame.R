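# Reaction-site data model.
#
# A ReactionSiteFrame holds one conformer of the reaction site, keyed by
# chemical role rather than by raw atom name, so that downstream geometry
# code never sees naming dialects. An Ensemble is a runs x frames stack of
# such conformers kept in a dense coordinate array for fast measurement.

#' Required atom roles of the reaction site
#'
#' The ribose of the terminal adenosine (A3: O3', C3', O2', C2'), the alanyl
#' carbonyl (Ccarb, Ocarb), the bridging phosphate oxygen (Ob), the phosphate
#' (P5', OP1, OP2), the alanine stereocenter (Calpha, Namino, Cbeta) and the
#' dT4 backbone atoms C4', C5', O5' needed for the backbone dihedrals.
#'
#' @return Character vector of role names.
#' @export
required_roles <- function() {
  c("C4p", "C5p", "O5p", "P5p", "OP1", "OP2", "Ob",
    "Ccarb", "Ocarb", "Calpha", "Namino", "Cbeta",
    "O3p", "C3p", "O2p", "C2p")
}

#' Construct a reaction-site frame
#'
#' @param coords Named numeric matrix (rows = atom roles, 3 columns x/y/z, in
#'   Angstroms). Must contain every role in [required_roles()]; additional
#'   rows (e.g. base heavy atoms keyed `"U10:N3"`) are allowed and used by
#'   base-pair analyses.
#' @param frame_id Integer frame index within its run (0-based internally).
#' @param run_id Integer run index (0-based internally).
#' @param chirality_label `"L"`, `"D"` or `"unknown"`. When `"L"` or `"D"`,
#'   the improper-dihedral handedness at Calpha is checked against the label.
#' @param validate Run invariant checks (default `TRUE`).
#' @return An object of class `ReactionSiteFrame`.
#' @export
reaction_site_frame <- function(coords, frame_id = 0L, run_id = 0L,
                                chirality_label = "unknown", validate = TRUE) {
  if (is.null(rownames(coords))) stop("coords must have role row names", call. = FALSE)
  storage.mode(coords) <- "double"
  fr <- structure(
    list(coords = coords,
         frame_id = as.integer(frame_id),
         run_id = as.integer(run_id),
         chirality_label = match.arg(chirality_label, c("L", "D", "unknown"))),
    class = "ReactionSiteFrame")
  if (validate) validate_frame(fr)
  fr
}

#' Improper dihedral defining the alanine stereocenter
#'
#' Signed dihedral over Namino-Ccarb-Calpha-Cbeta, i.e. the handedness of the
#' three heavy substituents viewed along Ccarb->Calpha. By this package's
#' convention a positive value corresponds to L-alanine and a negative value
#' to D-alanine; mirror reflection flips the sign.
#'
#' @param frame A [reaction_site_frame()].
#' @return Signed improper dihedral in degrees.
#' @export
chirality_improper <- function(frame) {
  signed_dihedral(.frame_xyz(frame, "Namino"), .frame_xyz(frame, "Ccarb"),
                  .frame_xyz(frame, "Calpha"), .frame_xyz(frame, "Cbeta"))
}

#' Validate a reaction-site frame
#'
#' Checks that every required role is present exactly once with finite
#' coordinates, that no two roles sit closer than 0.5 Angstrom (which traps
#' atom-mapping mistakes), and that a declared L/D label is consistent with
#' the improper-dihedral sign at Calpha.
#'
#' @param frame A [reaction_site_frame()].
#' @return The frame, invisibly; errors describe the first violated invariant.
#' @export
validate_frame <- function(frame) {
  co <- frame$coords
  rn <- rownames(co)
  missing <- setdiff(required_roles(), rn)
  if (length(missing)) {
    stop("frame ", frame$frame_id, ": missing required role(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(rn)) {
    stop("frame ", frame$frame_id, ": duplicated role(s): ",
         paste(unique(rn[duplicated(rn)]), collapse = ", "), call. = FALSE)
  }
  if (!all(is.finite(co))) {
    bad <- rn[!apply(is.finite(co), 1L, all)]
    stop("frame ", frame$frame_id, ": non-finite coordinates for ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  d <- stats::dist(co)
  if (any(d < 0.5)) {
    idx <- which(as.matrix(d) < 0.5 & upper.tri(as.matrix(d)), arr.ind = TRUE)[1L, ]
    stop("frame ", frame$frame_id, ": roles ", rn[idx[1L]], " and ", rn[idx[2L]],
         " are closer than 0.5 A (atom mapping error?)", call. = FALSE)
  }
  if (frame$chirality_label %in% c("L", "D")) {
    sgn <- sign(chirality_improper(frame))
    want <- if (frame$chirality_label == "L") 1 else -1
    if (sgn != want) {
      stop("frame ", frame$frame_id, ": chirality label ", frame$chirality_label,
           " inconsistent with improper-dihedral sign at Calpha", call. = FALSE)
    }
  }
  invisible(frame)
}

#' Mirror-reflect a frame
#'
#' Negates all x coordinates. Distances and unsigned angles are preserved;
#' every signed dihedral and the Flippin-Lodge angle change sign, and the
#' L/D label (if any) is swapped.
#'
#' @param frame A [reaction_site_frame()].
#' @return The reflected frame.
#' @export
mirror_frame <- function(frame) {
  co <- frame$coords
  co[, 1L] <- -co[, 1L]
  lab <- switch(frame$chirality_label, L = "D", D = "L", "unknown")
  reaction_site_frame(co, frame$frame_id, frame$run_id, lab, validate = FALSE)
}

#' @export
print.ReactionSiteFrame <- function(x, ...) {
  cat("ReactionSiteFrame: run", x$run_id, "frame", x$frame_id,
      "|", nrow(x$coords), "atoms | chirality:", x$chirality_label, "\n")
  invisible(x)
}

# ---- Ensemble --------------------------------------------------------------

#' Construct an ensemble of reaction-site frames
#'
#' Frames are stored as a dense `n_frames x 3 x n_roles` array so that whole
#' trajectories can be measured with vectorised geometry. Frames partition
#' into `n_runs` consecutive blocks of `frames_per_run`, mirroring
#' independent production runs of a simulation.
#'
#' @param coords Either a list of role-named coordinate matrices (one per
#'   frame, identical role sets) or an `n x 3 x n_roles` array with role
#'   dimnames on the third dimension.
#' @param n_runs,frames_per_run Run structure; `n_runs * frames_per_run` must
#'   equal the number of frames.
#' @param system_label Free-text label (e.g. `"L-Ala"`).
#' @param chirality_label `"L"`, `"D"` or `"unknown"` for all frames.
#' @param planted Optional logical vector marking frames planted as reactive
#'   by the synthetic generator (ground truth bookkeeping).
#' @param validate Validate a sample of frames (first/last of each run).
#' @return An object of class `Ensemble`.
#' @export
ensemble <- function(coords, n_runs, frames_per_run, system_label = "",
                     chirality_label = "unknown", planted = NULL,
                     validate = TRUE) {
  if (is.list(coords)) {
    roles <- rownames(coords[[1L]])
    arr <- array(NA_real_, dim = c(length(coords), 3L, length(roles)),
                 dimnames = list(NULL, c("x", "y", "z"), roles))
    for (i in seq_along(coords)) {
      m <- coords[[i]]
      if (!identical(rownames(m), roles)) m <- m[roles, , drop = FALSE]
      arr[i, , ] <- t(m)
    }
    coords <- arr
  }
  n <- dim(coords)[1L]
  n_runs <- as.integer(n_runs); frames_per_run <- as.integer(frames_per_run)
  if (n_runs * frames_per_run != n) {
    stop("frames (", n, ") do not partition into ", n_runs, " runs of ",
         frames_per_run, call. = FALSE)
  }
  if (!is.null(planted) && length(planted) != n) {
    stop("planted flag must have one entry per frame", call. = FALSE)
  }
  e <- structure(
    list(coords = coords, n_runs = n_runs, frames_per_run = frames_per_run,
         system_label = system_label,
         chirality_label = match.arg(chirality_label, c("L", "D", "unknown")),
         planted = planted),
    class = "Ensemble")
  if (validate && n > 0L) {
    probe <- unique(c(1L, frames_per_run * seq_len(n_runs)))
    for (i in probe) validate_frame(get_frame(e, i))
  }
  e
}

#' Number of frames in an ensemble
#' @param x An `Ensemble`.
#' @return Integer frame count.
#' @export
n_frames <- function(x) dim(x$coords)[1L]

#' Run index of each frame (0-based)
#' @param x An `Ensemble`.
#' @return Integer vector of length [n_frames()].
#' @export
run_ids <- function(x) rep(seq_len(x$n_runs) - 1L, each = x$frames_per_run)

#' Extract one frame from an ensemble
#'
#' @param x An `Ensemble`.
#' @param i Frame position, 1-based (as printed in reports frames are
#'   numbered like PDB MODEL records, also 1-based).
#' @return A [reaction_site_frame()].
#' @export
get_frame <- function(x, i) {
  i <- as.integer(i)
  stopifnot(i >= 1L, i <= n_frames(x))
  co <- t(x$coords[i, , ])
  colnames(co) <- c("x", "y", "z")
  reaction_site_frame(co,
                      frame_id = (i - 1L) %% x$frames_per_run,
                      run_id = (i - 1L) %/% x$frames_per_run,
                      chirality_label = x$chirality_label,
                      validate = FALSE)
}

#' Mirror-reflect every frame of an ensemble
#'
#' @param x An `Ensemble`.
#' @return The reflected ensemble, with L/D labels swapped.
#' @export
mirror_ensemble <- function(x) {
  x$coords[, 1L, ] <- -x$coords[, 1L, ]
  x$chirality_label <- switch(x$chirality_label, L = "D", D = "L", "unknown")
  x$system_label <- paste0(x$system_label, " (mirrored)")
  x
}

#' @export
print.Ensemble <- function(x, ...) {
  cat("Ensemble '", x$system_label, "': ", x$n_runs, " runs x ",
      x$frames_per_run, " frames = ", n_frames(x), " frames | chirality: ",
      x$chirality_label, "\n", sep = "")
  invisible(x)
}

#' @export
length.Ensemble <- function(x) n_frames(x)
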