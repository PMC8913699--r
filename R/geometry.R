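#' Rigid-body transform
#'
#' A proper rotation plus translation, `x -> R x + t`.
#'
#' @param R 3x3 proper rotation matrix (`det = +1`, orthonormal).
#' @param t Length-3 translation (Angstrom).
#' @return A `rigid_transform` object.
#' @export
rigid_transform <- function(R = diag(3), t = c(0, 0, 0)) {
  stopifnot(all(dim(R) == c(3, 3)), length(t) == 3)
  if (max(abs(crossprod(R) - diag(3))) > 1e-8 || det(R) < 0) {
    stop("R must be a proper rotation (orthonormal, det = +1)")
  }
  structure(list(R = R, t = as.numeric(t)), class = "rigid_transform")
}

#' Rotation matrix about an arbitrary axis
#'
#' @param axis Length-3 axis (normalized internally).
#' @param angle Rotation angle in degrees, counterclockwise about `axis`.
#' @return 3x3 rotation matrix.
#' @export
rotation_about <- function(axis, angle) {
  u <- axis / sqrt(sum(axis^2))
  a <- angle * pi / 180
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(a) * K + (1 - cos(a)) * (K %*% K)
}

#' Invert a rigid transform
#' @param tf A `rigid_transform`.
#' @return The inverse transform.
#' @export
invert_transform <- function(tf) {
  rigid_transform(t(tf$R), -as.numeric(t(tf$R) %*% tf$t))
}

#' Apply a rigid transform to a model or coordinate matrix
#'
#' Positions are mapped `x -> R x + t`; all labels are untouched.
#'
#' @param model A `bead_model`, `atom_model` or an n x 3 matrix.
#' @param tf A `rigid_transform`.
#' @return Same type as `model`.
#' @export
apply_transform <- function(model, tf) {
  if (is.matrix(model)) {
    return(model %*% t(tf$R) + matrix(tf$t, nrow(model), 3, byrow = TRUE))
  }
  xyz <- .as_xyz(model) %*% t(tf$R) +
    matrix(tf$t, nrow(model), 3, byrow = TRUE)
  .set_xyz(model, xyz)
}

#' Least-squares rigid superposition (Kabsch)
#'
#' Finds the proper rotation and translation minimizing the RMSD between
#' paired points of `mobile` and `reference`.  Improper solutions are
#' never returned: the reflection branch of the SVD is corrected by sign
#' flip, so mirror-degenerate inputs still yield `det(R) = +1`.
#'
#' @param mobile,reference Bead/atom models or n x 3 matrices.
#' @param pairing Two-column integer matrix of (mobile, reference) row
#'   indices; default pairs row-by-row (models must then have equal
#'   size).
#' @return List with `transform` (a `rigid_transform` mapping mobile onto
#'   reference) and `rmsd` (Angstrom, the minimized value).
#' @export
superpose <- function(mobile, reference, pairing = NULL) {
  X <- if (is.matrix(mobile)) mobile else .as_xyz(mobile)
  Y <- if (is.matrix(reference)) reference else .as_xyz(reference)
  if (is.null(pairing)) {
    stopifnot(nrow(X) == nrow(Y))
    pairing <- cbind(seq_len(nrow(X)), seq_len(nrow(Y)))
  }
  X <- X[pairing[, 1], , drop = FALSE]
  Y <- Y[pairing[, 2], , drop = FALSE]
  if (nrow(X) < 3) stop("need at least 3 paired points")
  xm <- colMeans(X); ym <- colMeans(Y)
  Xc <- sweep(X, 2, xm); Yc <- sweep(Y, 2, ym)
  s <- svd(crossprod(Xc, Yc))
  if (min(s$d[1:2]) < 1e-10) stop("degenerate (collinear) configuration")
  d <- sign(det(s$v %*% t(s$u)))
  D <- diag(c(1, 1, d))
  R <- s$v %*% D %*% t(s$u)
  t <- ym - as.numeric(R %*% xm)
  fit <- Xc %*% t(R)
  rmsd <- sqrt(mean(rowSums((fit - Yc)^2)))
  list(transform = rigid_transform(R, t), rmsd = rmsd)
}

#' Pair beads of two models by domain label and residue index
#'
#' Standard pairing for superposing structures whose chain ids differ:
#' beads are matched on (domain, resid); residues present in only one
#' model are dropped.
#'
#' @param mobile,reference Bead models.
#' @param domains Optional subset of domain labels to use.
#' @return Two-column index matrix usable as `pairing` in [superpose()].
#' @export
pair_by_domain <- function(mobile, reference, domains = NULL) {
  km <- paste(mobile$domain, mobile$resid)
  kr <- paste(reference$domain, reference$resid)
  if (!is.null(domains)) {
    km[!(mobile$domain %in% domains)] <- NA
    kr[!(reference$domain %in% domains)] <- NA
  }
  i <- match(kr, km)
  keep <- !is.na(i) & !is.na(kr)
  cbind(mobile = i[keep], reference = which(keep))
}

#' Symmetry mates about a frame axis
#'
#' Returns `n` copies of the model rotated by `k * 360 / n` degrees
#' (k = 0..n-1) about the frame's symmetry axis through its origin.
#'
#' @param model A bead/atom model.
#' @param n Symmetry order (>= 1).
#' @param frame A [complex_frame()].
#' @return List of `n` models; the first is the input.
#' @export
symmetry_mates <- function(model, n, frame) {
  if (n < 1) stop("n must be >= 1")
  lapply(seq_len(n) - 1L, function(k) {
    if (k == 0L) return(model)
    R <- rotation_about(frame$ez, k * 360 / n)
    t <- as.numeric(frame$origin - R %*% frame$origin)
    apply_transform(model, rigid_transform(R, t))
  })
}

#' Coordinate frame of a symmetric complex
#'
#' Defines the cylindrical coordinate system used for classification:
#' origin at the core centre of mass, `ez` the symmetry axis, `ex` the
#' azimuth origin, and `z0` the reference plane (in frame coordinates)
#' given by the top plane of the component-B ring.
#'
#' @param origin Frame origin (Angstrom).
#' @param ez Symmetry-axis direction (normalized internally).
#' @param ex Azimuth-origin direction; its component along `ez` is
#'   removed.
#' @param z0 Reference-plane height in frame coordinates.
#' @return A `complex_frame` object.
#' @export
complex_frame <- function(origin, ez, ex, z0 = 0) {
  ez <- ez / sqrt(sum(ez^2))
  ex <- ex - sum(ex * ez) * ez
  if (sqrt(sum(ex^2)) < 1e-12) stop("ex parallel to ez")
  ex <- ex / sqrt(sum(ex^2))
  ey <- c(ez[2] * ex[3] - ez[3] * ex[2],
          ez[3] * ex[1] - ez[1] * ex[3],
          ez[1] * ex[2] - ez[2] * ex[1])
  structure(list(origin = as.numeric(origin), ez = ez, ex = ex, ey = ey,
                 z0 = z0), class = "complex_frame")
}

#' Derive the frame from a rigid core
#'
#' The symmetry axis is the gyration-tensor eigenvector whose eigenvalue
#' is most separated from the other two (the unique axis of an oblate or
#' prolate core), oriented from the component-C center of mass towards
#' the component-B ring.  The azimuth origin is the direction of the
#' first B-chain centre of mass; `z0` is the largest frame-z among
#' per-domain B centres of mass (the top plane of the B ring).
#'
#' @param core A `bead_model` with component labels `B` and `C`.
#' @return A `complex_frame`.
#' @export
frame_from_core <- function(core) {
  origin <- com(core)
  X <- sweep(.as_xyz(core), 2, origin)
  S <- crossprod(X * core$mass, X) / sum(core$mass)
  e <- eigen(S, symmetric = TRUE)
  gaps <- c(abs(e$values[1] - e$values[2]) + abs(e$values[1] - e$values[3]),
            abs(e$values[2] - e$values[1]) + abs(e$values[2] - e$values[3]),
            abs(e$values[3] - e$values[1]) + abs(e$values[3] - e$values[2]))
  ez <- e$vectors[, which.max(gaps)]
  isB <- core$component == "B"
  isC <- core$component == "C"
  if (any(isB) && any(isC)) {
    dirBC <- com(core, isB) - com(core, isC)
    if (sum(dirBC * ez) < 0) ez <- -ez
  }
  ex <- if (any(isB)) {
    firstB <- core$chain == core$chain[which(isB)[1]] & isB
    com(core, firstB) - origin
  } else c(1, 0, 0)
  fr <- complex_frame(origin, ez, ex, z0 = 0)
  if (any(isB)) {
    bcoms <- vapply(split(which(isB), core$chain[isB], drop = TRUE),
                    function(i) frame_coords(matrix(com(core, i), 1), fr)[3],
                    numeric(1))
    fr$z0 <- max(bcoms)
  }
  fr
}

#' Cartesian coordinates in the frame basis
#' @param xyz n x 3 matrix of lab coordinates.
#' @param frame A `complex_frame`.
#' @return n x 3 matrix of (x, y, z) in frame coordinates.
#' @export
frame_coords <- function(xyz, frame) {
  X <- sweep(xyz, 2, frame$origin)
  cbind(X %*% frame$ex, X %*% frame$ey, X %*% frame$ez)
}

#' Cylindrical coordinates of points in a complex frame
#'
#' @param xyz A length-3 vector or n x 3 matrix (lab coordinates).
#' @param frame A `complex_frame`.
#' @return Matrix with columns `r` (Angstrom, distance to the symmetry
#'   axis), `theta` (degrees in `[0, 360)`, counterclockwise from the
#'   frame azimuth origin viewed from +z; 0 on the axis by convention)
#'   and `z` (Angstrom relative to the frame origin).
#' @export
cylindrical <- function(xyz, frame) {
  if (!is.matrix(xyz)) xyz <- matrix(xyz, ncol = 3)
  F <- frame_coords(xyz, frame)
  r <- sqrt(F[, 1]^2 + F[, 2]^2)
  theta <- ifelse(r < 1e-12, 0, (atan2(F[, 2], F[, 1]) * 180 / pi) %% 360)
  cbind(r = r, theta = theta, z = F[, 3])
}

#' Cartesian lab coordinates from cylindrical frame coordinates
#' @param r,theta,z Cylindrical coordinates (`theta` in degrees).
#' @param frame A `complex_frame`.
#' @return n x 3 matrix of lab coordinates.
#' @export
from_cylindrical <- function(r, theta, z, frame) {
  a <- theta * pi / 180
  F <- cbind(r * cos(a), r * sin(a), z)
  F %*% rbind(frame$ex, frame$ey, frame$ez) +
    matrix(frame$origin, length(r), 3, byrow = TRUE)
}
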