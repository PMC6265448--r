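# Independent oracles and generators shared across tests. Each oracle takes
# a different computational path from the implementation it checks.

# planar angle from the plain acos-of-dot-product formula
oracle_angle <- function(a, b, c) {
  u <- a - b; v <- c - b
  acos(sum(u * v) / sqrt(sum(u^2) * sum(v^2))) * 180 / pi
}

# dihedral via bio3d (third-party implementation of the same convention)
oracle_dihedral <- function(a, b, c, d) {
  bio3d::torsion.xyz(c(a, b, c, d), atm.inc = 4)
}

# RMSD after optimal superposition via the Kearsley quaternion method
# (largest-eigenvalue route, independent of the SVD-based Kabsch path)
oracle_rmsd <- function(a, b) {
  ac <- sweep(a, 2, colMeans(a))
  bc <- sweep(b, 2, colMeans(b))
  xm <- bc[, 1] - ac[, 1]; xp <- bc[, 1] + ac[, 1]
  ym <- bc[, 2] - ac[, 2]; yp <- bc[, 2] + ac[, 2]
  zm <- bc[, 3] - ac[, 3]; zp <- bc[, 3] + ac[, 3]
  k <- matrix(c(
    sum(xm^2 + ym^2 + zm^2), sum(yp * zm - ym * zp), sum(xm * zp - xp * zm), sum(xp * ym - xm * yp),
    sum(yp * zm - ym * zp), sum(yp^2 + zp^2 + xm^2), sum(xm * ym - xp * yp), sum(xm * zm - xp * zp),
    sum(xm * zp - xp * zm), sum(xm * ym - xp * yp), sum(xp^2 + zp^2 + ym^2), sum(ym * zm - yp * zp),
    sum(xp * ym - xm * yp), sum(xm * zm - xp * zp), sum(ym * zm - yp * zp), sum(xp^2 + yp^2 + zm^2)),
    4, 4, byrow = TRUE)
  lambda <- min(eigen(k, symmetric = TRUE, only.values = TRUE)$values)
  sqrt(max(0, lambda) / nrow(a))
}

# independent atom placement: start in the A-B-C plane at the bond angle
# (dihedral 0 = cis), then rotate about the B->C axis by the dihedral.
# A rotation-composition route distinct from the NeRF local-frame formula.
oracle_place <- function(a, b, c, r, theta_deg, tau_deg) {
  rot <- function(axis, ang) minihelix:::.rotation_about(axis, ang)
  cb <- b - c
  cb <- cb / sqrt(sum(cb^2))
  # in-plane normal of the A-B-C plane
  cross3 <- function(u, v) c(u[2] * v[3] - u[3] * v[2],
                             u[3] * v[1] - u[1] * v[3],
                             u[1] * v[2] - u[2] * v[1])
  n <- cross3(b - a, c - b)
  n <- n / sqrt(sum(n^2))
  d0 <- c + r * as.vector(rot(n, -theta_deg) %*% cb)   # cis position
  axis <- (c - b) / sqrt(sum((c - b)^2))
  c + as.vector(rot(axis, tau_deg) %*% (d0 - c))
}

random_rotation <- function() {
  axis <- stats::rnorm(3)
  minihelix:::.rotation_about(axis, stats::runif(1, 0, 360))
}

# apply a random rigid motion to all coordinates of a frame
transform_frame <- function(frame, rot = random_rotation(),
                            shift = stats::rnorm(3, 0, 10)) {
  co <- frame$coords %*% t(rot)
  co <- sweep(co, 2, -shift)
  colnames(co) <- c("x", "y", "z")
  reaction_site_frame(co, frame$frame_id, frame$run_id,
                      frame$chirality_label, validate = FALSE)
}

# a physically plausible random frame: jittered canonical geometry under a
# random rigid motion (jitter small enough to keep geometry non-degenerate)
random_frame <- function(jitter = 0.15) {
  fr <- make_ideal_geometry("canonical_reactive")
  fr$coords <- fr$coords + matrix(stats::rnorm(length(fr$coords), 0, jitter),
                                  nrow = nrow(fr$coords))
  transform_frame(fr)
}

# small ensemble built from an explicit list of frames (one run)
frames_to_ensemble <- function(frames, chirality = "unknown") {
  ensemble(lapply(frames, `[[`, "coords"), n_runs = 1L,
           frames_per_run = length(frames), chirality_label = chirality,
           validate = FALSE)
}
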