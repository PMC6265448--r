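# Internal-coordinate (Z-matrix) construction of the reaction-site fragment.
#
# Atoms are placed sequentially from bond length, bond angle and dihedral
# (NeRF placement). The placement core is vectorised over frames: each step
# consumes n x 3 matrices of already-placed reference atoms, so a whole
# synthetic ensemble is built without per-frame loops.

# Place n copies of one atom. a, b, c: n x 3 references (dihedral, angle,
# bond). r, theta, tau: scalars or n-vectors (degrees). The placed atom D
# satisfies |D-c| = r, angle(D, c, b) = theta, signed_dihedral(a, b, c, D) = tau.
.nerf_place <- function(a, b, c, r, theta_deg, tau_deg) {
  th <- theta_deg * pi / 180
  ta <- tau_deg * pi / 180
  bc <- .rowunit(c - b, what = "placement bond")
  n <- .rowunit(.rowcross(b - a, bc), what = "placement plane normal")
  m <- .rowcross(n, bc)
  d2 <- r * cos(pi - th)                # along bc
  d3 <- r * sin(pi - th)                # in-plane magnitude
  c + bc * d2 + m * (d3 * cos(ta)) + n * (d3 * sin(ta))
}

#' Internal-coordinate table for the reaction-site fragment
#'
#' An ordered table of placement rules (a Z-matrix): each atom role is placed
#' from a bond length to `ref_b`, a bond angle through `ref_a`, and a
#' dihedral whose fourth atom is `ref_d`. The dihedral value is either fixed
#' (`tau_fixed`) or taken from a named sampled dihedral (`tau_name`) plus a
#' constant offset (`tau_offset`), which is how sp2/sp3 siblings (Ocarb,
#' OP1/OP2, Cbeta) ride on the sampled backbone dihedrals.
#'
#' The default table covers the dT4 backbone anchor (C4', C5', O5'), the
#' phosphate, the alanyl group, and the A3 ribose placed via virtual internal
#' coordinates relative to the carbonyl (rows flagged `virtual`, exempt from
#' the physical bond-length check). Bond lengths and angles are standard
#' organic equilibrium values. The Cbeta dihedral offset (+120 for L, -120
#' for D relative to the amino nitrogen) pins the stereocenter so that the
#' improper dihedral of [chirality_improper()] is positive for L.
#'
#' @param chirality `"L"` or `"D"`.
#' @param delta_att Virtual O3'...Ccarb distance used for the ribose rows, A.
#' @return Data frame of class `InternalCoordinateTable`.
#' @export
internal_coordinate_table <- function(chirality = "L", delta_att = 3.0) {
  chirality <- match.arg(chirality, c("L", "D"))
  cb_off <- if (chirality == "L") 120 else -120
  rw <- function(role, d, a, b, len, ang, tn, toff, tfix, virtual = FALSE) {
    data.frame(role = role, ref_d = d, ref_a = a, ref_b = b, length = len,
               angle = ang, tau_name = tn, tau_offset = toff, tau_fixed = tfix,
               virtual = virtual, stringsAsFactors = FALSE)
  }
  tab <- rbind(
    rw("C4p",   NA, NA, NA, NA, NA, NA, NA, NA),
    rw("C5p",   NA, NA, "C4p", 1.52, NA, NA, NA, NA),
    rw("O5p",   NA, "C4p", "C5p", 1.43, 110.0, NA, NA, NA),
    rw("P5p",   "C4p", "C5p", "O5p", 1.60, 120.0, "tau_1", 0, NA),
    rw("Ob",    "C5p", "O5p", "P5p", 1.60, 102.0, "tau_2", 0, NA),
    rw("OP1",   "C5p", "O5p", "P5p", 1.48, 108.0, "tau_2", 120, NA),
    rw("OP2",   "C5p", "O5p", "P5p", 1.48, 108.0, "tau_2", -120, NA),
    rw("Ccarb", "O5p", "P5p", "Ob", 1.36, 120.0, "tau_3", 0, NA),
    rw("Calpha","P5p", "Ob", "Ccarb", 1.52, 111.0, "tau_4", 0, NA),
    rw("Ocarb", "P5p", "Ob", "Ccarb", 1.23, 124.0, "tau_4", 180, NA),
    rw("Namino","Ob", "Ccarb", "Calpha", 1.47, 109.5, "tau_5", 0, NA),
    rw("Cbeta", "Ob", "Ccarb", "Calpha", 1.53, 110.0, "tau_5", cb_off, NA),
    # A3 ribose, placed via virtual internal coordinates off the carbonyl so
    # that a stand-alone fragment is complete; the ensemble generator instead
    # holds the ribose at a fixed scaffold pose (see sample_ensemble).
    rw("O3p",   "Ob", "Ocarb", "Ccarb", delta_att, 105.0, NA, NA, 90, TRUE),
    rw("C3p",   "Ocarb", "Ccarb", "O3p", 1.42, 109.47, NA, NA, 180, TRUE),
    rw("C2p",   "Ccarb", "O3p", "C3p", 1.53, 109.5, NA, NA, 60, TRUE),
    rw("O2p",   "O3p", "C3p", "C2p", 1.41, 109.5, NA, NA, 60, TRUE)
  )
  class(tab) <- c("InternalCoordinateTable", class(tab))
  tab
}

.validate_ict <- function(ict) {
  placed <- character(0L)
  for (i in seq_len(nrow(ict))) {
    row <- ict[i, ]
    refs <- stats::na.omit(c(row$ref_d, row$ref_a, row$ref_b))
    if (!all(refs %in% placed)) {
      stop("internal-coordinate table row ", i, " (", row$role,
           ") references atoms not yet placed", call. = FALSE)
    }
    if (i > 1L && !isTRUE(row$virtual)) {
      if (!is.finite(row$length) || row$length < 0.8 || row$length > 2.0) {
        stop("non-physical bond length ", row$length, " A for ", row$role,
             call. = FALSE)
      }
      if (i > 2L && (!is.finite(row$angle) || row$angle < 90 || row$angle > 130)) {
        stop("non-physical bond angle ", row$angle, " deg for ", row$role,
             call. = FALSE)
      }
    }
    placed <- c(placed, row$role)
  }
  invisible(ict)
}

# Vectorised chain construction. tau_values: named list of n-vectors (or
# scalars) for every tau_name the table references. Returns n x 3 x role array.
.build_chain <- function(ict, tau_values, n = NULL) {
  .validate_ict(ict)
  if (is.null(n)) {
    n <- max(1L, vapply(tau_values, length, integer(1L)))
  }
  roles <- ict$role
  arr <- array(NA_real_, dim = c(n, 3L, length(roles)),
               dimnames = list(NULL, c("x", "y", "z"), roles))
  at <- function(role) arr[, , role, drop = FALSE][, , 1L]
  at <- function(role) {
    m <- arr[, , role]
    if (is.null(dim(m))) m <- matrix(m, nrow = n)
    m
  }
  for (i in seq_len(nrow(ict))) {
    row <- ict[i, ]
    if (i == 1L) {
      arr[, , i] <- 0
    } else if (i == 2L) {
      arr[, , i] <- matrix(c(row$length, 0, 0), n, 3L, byrow = TRUE)
    } else if (i == 3L) {
      th <- row$angle * pi / 180
      b <- at(row$ref_b)
      prev <- at(row$ref_a)
      dir <- .rowunit(prev - b)
      # in the xy-plane, rotated off the previous bond by the bond angle
      arr[, , i] <- b + row$length *
        (dir * cos(th) + .rowcross(matrix(c(0, 0, 1), n, 3L, byrow = TRUE), dir) * sin(th))
    } else {
      if (!is.na(row$tau_name)) {
        tv <- tau_values[[row$tau_name]]
        if (is.null(tv)) {
          stop("no sampled value supplied for dihedral '", row$tau_name, "'",
               call. = FALSE)
        }
        tau <- tv + row$tau_offset
      } else {
        tau <- row$tau_fixed
      }
      arr[, , i] <- .nerf_place(at(row$ref_d), at(row$ref_a), at(row$ref_b),
                                row$length, row$angle, tau)
    }
  }
  arr
}

#' Build one reaction-site fragment from internal coordinates
#'
#' Places every atom of the internal-coordinate table, supplying the sampled
#' backbone dihedrals by name. The resulting Cartesian frame re-measures to
#' the input internal coordinates (dihedrals to ~1e-6 degree), and the
#' stereocenter obeys the requested chirality: the improper dihedral of
#' [chirality_improper()] is positive for L and negative for D.
#'
#' @param ict An [internal_coordinate_table()] (its `chirality` must match).
#' @param dihedral_values Named list/vector with entries `tau_1`..`tau_5`
#'   (degrees).
#' @param chirality `"L"` or `"D"`; stored as the frame's label.
#' @return A [reaction_site_frame()].
#' @export
build_fragment <- function(ict = internal_coordinate_table(chirality),
                           dihedral_values, chirality = "L") {
  chirality <- match.arg(chirality, c("L", "D"))
  tv <- as.list(dihedral_values)
  arr <- .build_chain(ict, tv, n = 1L)
  co <- t(arr[1L, , ])
  colnames(co) <- c("x", "y", "z")
  reaction_site_frame(co, frame_id = 0L, run_id = 0L,
                      chirality_label = chirality)
}
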