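# Pure geometric primitives. All operate in Angstroms and degrees.
#
# Vector helpers work row-wise on n x 3 matrices so that whole ensembles can
# be measured without per-frame loops.

.m3 <- function(x) {
  if (is.matrix(x)) {
    if (ncol(x) != 3L) stop("coordinates must be n x 3", call. = FALSE)
    x
  } else {
    if (length(x) != 3L) stop("a 3D position must have length 3", call. = FALSE)
    matrix(as.numeric(x), nrow = 1L)
  }
}

.rowdot <- function(a, b) rowSums(a * b)

.rowcross <- function(a, b) {
  cbind(a[, 2L] * b[, 3L] - a[, 3L] * b[, 2L],
        a[, 3L] * b[, 1L] - a[, 1L] * b[, 3L],
        a[, 1L] * b[, 2L] - a[, 2L] * b[, 1L])
}

.rownorm <- function(a) sqrt(rowSums(a * a))

.rowunit <- function(a, tol = 1e-8, what = "vector") {
  n <- .rownorm(a)
  if (any(!is.finite(n)) || any(n < tol)) {
    stop("degenerate geometry: ", what, " has near-zero length", call. = FALSE)
  }
  a / n
}

.clamp1 <- function(x) pmin(1, pmax(-1, x))

.deg <- 180 / pi

#' Signed dihedral (torsion) angle
#'
#' Dihedral angle over four linked positions `a-b-c-d`, in degrees on
#' `(-180, 180]`, using the IUPAC sign convention: looking from `b` towards
#' `c`, a clockwise rotation of the far bond relative to the near bond is
#' positive; the cis (eclipsed) arrangement is 0 and trans is 180.
#' Negating all x coordinates (a mirror reflection) negates the value.
#'
#' Inputs may be single positions (length-3 vectors) or n x 3 matrices of
#' positions, in which case a vector of n dihedrals is returned.
#'
#' @param a,b,c,d 3D positions (length-3 numeric vectors) or n x 3 matrices.
#' @return Numeric vector of dihedral angles in degrees, in `(-180, 180]`.
#' @export
#' @examples
#' signed_dihedral(c(1, 1, 0), c(0, 0, 0), c(0, 0, 1), c(1, 1, 1)) # cis, 0
#' signed_dihedral(c(1, 1, 0), c(0, 0, 0), c(0, 0, 1), c(-1, -1, 1)) # trans, 180
signed_dihedral <- function(a, b, c, d) {
  a <- .m3(a); b <- .m3(b); c <- .m3(c); d <- .m3(d)
  b1 <- b - a
  b2 <- c - b
  b3 <- d - c
  n1 <- .rowcross(b1, b2)
  n2 <- .rowcross(b2, b3)
  if (any(.rownorm(n1) < 1e-8) || any(.rownorm(n2) < 1e-8)) {
    stop("degenerate geometry: collinear atom triple in dihedral", call. = FALSE)
  }
  u2 <- .rowunit(b2, what = "central bond")
  x <- .rowdot(n1, n2)
  y <- .rowdot(.rowcross(n1, n2), u2)
  tau <- atan2(y, x) * .deg
  # atan2 yields (-180, 180]; fold the unreachable -180 representation
  tau[tau <= -180] <- tau[tau <= -180] + 360
  tau
}

# planar angle a-b-c at vertex b, degrees in [0, 180]
.planar_angle <- function(a, b, c) {
  a <- .m3(a); b <- .m3(b); c <- .m3(c)
  u <- .rowunit(a - b, what = "angle arm")
  v <- .rowunit(c - b, what = "angle arm")
  acos(.clamp1(.rowdot(u, v))) * .deg
}

#' Planar angle between three positions
#'
#' Angle at vertex `b` formed by `a-b-c`, in degrees on `[0, 180]`.
#' Accepts single positions or row-wise matrices.
#'
#' @param a,b,c 3D positions or n x 3 matrices.
#' @return Numeric vector of angles in degrees.
#' @export
planar_angle <- function(a, b, c) .planar_angle(a, b, c)

# ---- attack-geometry angles ------------------------------------------------

.frame_xyz <- function(frame, role) {
  x <- frame$coords[role, , drop = FALSE]
  if (nrow(x) != 1L || anyNA(x)) {
    stop("role '", role, "' missing from frame", call. = FALSE)
  }
  x
}

.nu_roles <- function(nu_choice) {
  nu_choice <- match.arg(nu_choice, c("O3p", "O2p"))
  if (nu_choice == "O3p") list(nu = "O3p", r = "C3p") else list(nu = "O2p", r = "C2p")
}

#' Buergi-Dunitz angle of nucleophilic attack
#'
#' The angle Nu-Ccarb-Ocarb between the nucleophile, the carbonyl carbon and
#' the carbonyl oxygen. Crystallographic surveys of nucleophile/electrophile
#' pairs place the preferred approach near 105 degrees.
#'
#' @param frame A [reaction_site_frame()].
#' @param nu_choice Which ribose oxygen acts as nucleophile, `"O3p"` or `"O2p"`.
#' @return Angle in degrees.
#' @export
bd_angle <- function(frame, nu_choice = "O3p") {
  r <- .nu_roles(nu_choice)
  .planar_angle(.frame_xyz(frame, r$nu), .frame_xyz(frame, "Ccarb"),
                .frame_xyz(frame, "Ocarb"))
}

#' Lobe angle of nucleophilic attack
#'
#' The angle R-Nu...Ccarb at the nucleophile, where R is the ribose carbon
#' bonded to the attacking hydroxyl oxygen (C3' for O3', C2' for O2'). For an
#' sp3 hydroxyl oxygen the lone-pair (HOMO) lobes point tetrahedrally, so a
#' productive approach keeps this angle near 109.5 degrees.
#'
#' @inheritParams bd_angle
#' @return Angle in degrees.
#' @export
lobe_angle <- function(frame, nu_choice = "O3p") {
  r <- .nu_roles(nu_choice)
  .planar_angle(.frame_xyz(frame, r$r), .frame_xyz(frame, r$nu),
                .frame_xyz(frame, "Ccarb"))
}

# Least-squares plane normal of a k x 3 point set (unit vector).
.ls_plane_normal <- function(p) {
  centered <- sweep(p, 2L, colMeans(p))
  sv <- svd(centered, nu = 0L)
  n <- sv$v[, 3L]
  n / sqrt(sum(n * n))
}

# Core of the FL angle given bare coordinate rows; shared by the per-frame
# and ensemble paths. All inputs 1 x 3.
.fl_angle_core <- function(nu, ccarb, ocarb, calpha, ob) {
  n <- .ls_plane_normal(rbind(ccarb, ocarb, calpha, ob))
  to_nu <- nu - ccarb
  if (sum(to_nu * n) < 0) n <- -n     # orient towards the nucleophile half-space
  u <- .rowunit(ocarb - ccarb, what = "C=O axis")
  v <- to_nu - sum(to_nu * u) * u     # azimuthal component of the approach
  nv <- sqrt(sum(v * v))
  if (!is.finite(nv) || nv < 1e-8) {
    stop("degenerate geometry: nucleophile lies on the C=O axis", call. = FALSE)
  }
  v <- v / nv
  n <- matrix(n, nrow = 1L)
  v <- matrix(v, nrow = 1L)
  s <- .rowdot(.rowcross(v, n), u)
  unname(atan2(s, .rowdot(n, v)) * .deg)
}

#' Flippin-Lodge angle of nucleophilic attack
#'
#' Signed azimuthal offset of the nucleophile's approach from the plane that
#' contains the C=O axis and is perpendicular to the carbonyl plane. The
#' carbonyl plane is taken as the least-squares plane of Ccarb, Ocarb, Calpha
#' and Ob (robust to slight pyramidalization), with its normal oriented
#' towards the nucleophile's half-space. The sign is positive when the
#' approach tilts towards the bridging phosphate oxygen (Ob) side for the
#' standard approach geometry; reflecting the coordinates flips the sign.
#' A symmetric perpendicular-plane approach gives 0.
#'
#' @inheritParams bd_angle
#' @return Signed angle in degrees, in `(-180, 180]`.
#' @export
fl_angle <- function(frame, nu_choice = "O3p") {
  r <- .nu_roles(nu_choice)
  .fl_angle_core(.frame_xyz(frame, r$nu), .frame_xyz(frame, "Ccarb"),
                 .frame_xyz(frame, "Ocarb"), .frame_xyz(frame, "Calpha"),
                 .frame_xyz(frame, "Ob"))
}

# ---- Kabsch superposition --------------------------------------------------

# Optimal proper rotation (no reflection) aligning b onto a after centering.
.kabsch_rotation <- function(a, b) {
  ac <- sweep(a, 2L, colMeans(a))
  bc <- sweep(b, 2L, colMeans(b))
  h <- crossprod(bc, ac)
  sv <- svd(h)
  d <- sign(det(sv$u %*% t(sv$v)))
  # rotation R such that (centered b) %*% R approximates centered a
  sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
}

#' Root-mean-square deviation after optimal rigid superposition
#'
#' Superposes `coords_b` onto `coords_a` with the optimal proper rotation and
#' translation (Kabsch algorithm; reflections are not allowed) and returns
#' the RMSD of the matched points. Correspondence is by row order.
#'
#' @param coords_a,coords_b n x 3 coordinate matrices, n >= 3.
#' @return RMSD in Angstroms.
#' @export
kabsch_rmsd <- function(coords_a, coords_b) {
  coords_a <- .m3(coords_a); coords_b <- .m3(coords_b)
  if (nrow(coords_a) != nrow(coords_b)) {
    stop("point sets must have the same number of rows", call. = FALSE)
  }
  if (nrow(coords_a) < 3L) stop("need at least 3 points for superposition", call. = FALSE)
  r <- .kabsch_rotation(coords_a, coords_b)
  ac <- sweep(coords_a, 2L, colMeans(coords_a))
  bc <- sweep(coords_b, 2L, colMeans(coords_b)) %*% r
  sqrt(mean(rowSums((ac - bc)^2)))
}

# ---- rigid-motion helpers (used by generator and tests) --------------------

# Rotation matrix about unit axis by angle in degrees (Rodrigues).
.rotation_about <- function(axis, angle_deg) {
  u <- axis / sqrt(sum(axis * axis))
  th <- angle_deg * pi / 180
  k <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0),
              nrow = 3L, byrow = TRUE)
  diag(3L) + sin(th) * k + (1 - cos(th)) * (k %*% k)
}
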