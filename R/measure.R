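#' Rigid-body transform (proper rotation + translation)
#'
#' The result of a Kabsch fit: a rotation matrix with determinant +1 (never
#' a reflection) and a translation, applied as `x' = R x + t`.
#'
#' @slot rotation 3x3 orthonormal matrix, det = +1.
#' @slot translation numeric length 3 (nm).
#' @export
setClass("RigidTransform", representation(rotation = "matrix",
                                          translation = "numeric"))

setValidity("RigidTransform", function(object) {
  r <- object@rotation
  if (!identical(dim(r), c(3L, 3L))) return("rotation must be 3x3")
  if (max(abs(crossprod(r) - diag(3))) > 1e-8) return("rotation must be orthonormal")
  if (abs(det(r) - 1) > 1e-8) return("rotation must be proper (det = +1)")
  if (length(object@translation) != 3L) return("translation must have length 3")
  TRUE
})

#' Construct a rigid transform
#' @param rotation 3x3 proper rotation matrix.
#' @param translation numeric length 3 (nm).
#' @export
rigidTransform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  new("RigidTransform", rotation = rotation,
      translation = as.numeric(translation))
}

#' Apply a rigid transform to points
#' @param tr a [RigidTransform-class].
#' @param x N x 3 coordinate matrix (nm).
#' @return transformed N x 3 matrix.
#' @export
transformPoints <- function(tr, x) {
  sweep(as.matrix(x) %*% t(tr@rotation), 2, tr@translation, "+")
}

setMethod("show", "RigidTransform", function(object) {
  cat("RigidTransform: translation",
      sprintf("(%.4f, %.4f, %.4f) nm\n", object@translation[1],
              object@translation[2], object@translation[3]))
  print(round(object@rotation, 6))
})

# -- internal numeric cores (matrix in, value out) --------------------------

.weights <- function(w, n) {
  if (is.null(w)) w <- rep(1, n)
  if (length(w) != n) .stopUsage("weight vector length mismatch")
  tw <- sum(w)
  if (tw <= 0) .stopData("total mass/weight is zero")
  w / tw
}

.comPlain <- function(x, w) colSums(x * w)

# Periodic center of mass via the per-axis circular mean: each fractional
# coordinate is mapped to an angle on the unit circle, the mass-weighted
# mean direction is taken, and the mean angle is mapped back into the cell.
# Exact for clusters smaller than half the box; needs no bond information.
.comCircular <- function(x, w, boxObj) {
  m <- boxObj@matrix
  f <- x %*% solve(m)
  theta <- 2 * pi * f
  cs <- colSums(w * cos(theta))
  sn <- colSums(w * sin(theta))
  fbar <- (atan2(sn, cs) / (2 * pi)) %% 1
  drop(fbar %*% m)
}

.comRaw <- function(x, w, boxObj = NULL, pbc = FALSE) {
  w <- .weights(w, nrow(x))
  if (!pbc) return(.comPlain(x, w))
  if (is.null(boxObj)) .stopUsage("pbc = TRUE requires a periodic box")
  .comCircular(x, w, boxObj)
}

.kabschCore <- function(X, Y, w = NULL) {
  n <- nrow(X)
  if (nrow(Y) != n) .stopUsage("fitTransform: selections differ in size")
  if (n < 3L) .stopUsage("fitTransform: need at least 3 atoms")
  w <- .weights(w, n)
  cx <- colSums(X * w); cy <- colSums(Y * w)
  Xc <- sweep(X, 2, cx); Yc <- sweep(Y, 2, cy)
  H <- crossprod(Xc * w, Yc)           # sum_i w_i x_i y_i^T
  sv <- svd(H)
  if (sv$d[2] <= 1e-10 * max(sv$d[1], .Machine$double.xmin))
    .stopData("fitTransform: points are (nearly) collinear, rotation not unique")
  d <- sign(det(sv$v %*% t(sv$u)))
  if (d == 0) d <- 1
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  rigidTransform(R, drop(cy - R %*% cx))
}

.rmsdCore <- function(A, B) {
  if (nrow(A) != nrow(B)) .stopUsage("rmsd: selections differ in size")
  if (nrow(A) < 1L) .stopUsage("rmsd: empty input")
  sqrt(mean(rowSums((A - B)^2)))
}

.gyrationCore <- function(x, w) {
  w <- .weights(w, nrow(x))
  c0 <- colSums(x * w)
  sqrt(sum(w * rowSums(sweep(x, 2, c0)^2)))
}

# -- exported measures ------------------------------------------------------

#' Center of mass
#'
#' Mass-weighted mean position of the selected atoms. With `pbc = TRUE` the
#' center is computed per box axis as a circular mean of the fractional
#' coordinates (so a cluster straddling the periodic boundary gets the
#' physically meaningful center, inside the box, rather than the midpoint of
#' the cell); this is well-defined for clusters smaller than about half the
#' box.
#'
#' @param sel a readable [Selection-class].
#' @param pbc logical: treat coordinates periodically (requires a box).
#' @return numeric length-3 position (nm).
#' @export
centerOfMass <- function(sel, pbc = FALSE) {
  .comRaw(coords(sel), masses(sel), box(sel), pbc)
}

#' Center of geometry
#'
#' As [centerOfMass()] with unit weights.
#' @inheritParams centerOfMass
#' @export
centerOfGeometry <- function(sel, pbc = FALSE) {
  .comRaw(coords(sel), rep(1, length(sel)), box(sel), pbc)
}

#' Root-mean-square deviation between two equally sized selections
#'
#' Atoms are paired by position in the two index sets; no fitting and no
#' mass weighting is applied (superpose first with [fitTransform()] +
#' [applyTransform()] if alignment is wanted).
#'
#' @param a,b [Selection-class] objects (or N x 3 matrices) of equal size.
#' @return RMSD in nm.
#' @export
rmsd <- function(a, b) {
  A <- if (is(a, "Selection")) coords(a) else as.matrix(a)
  B <- if (is(b, "Selection")) coords(b) else as.matrix(b)
  .rmsdCore(A, B)
}

#' Optimal rigid superposition (Kabsch)
#'
#' Returns the proper rotation and translation minimizing the
#' (mass-)weighted RMSD of `mobile` onto `reference`, computed from the SVD
#' of the weighted covariance matrix with the sign of the smallest singular
#' vector flipped when needed so that the determinant is +1 — a reflection
#' is never returned, even for near-planar or mirrored configurations.
#'
#' @param mobile,reference [Selection-class] objects (or N x 3 matrices) of
#'   equal size, at least 3 atoms, not all collinear.
#' @param massWeighted logical: weight atoms by mass (masses are taken from
#'   `mobile`; ignored for matrix input unless `weights` is given).
#' @param weights optional explicit weight vector overriding `massWeighted`.
#' @return a [RigidTransform-class] mapping mobile coordinates onto the
#'   reference frame.
#' @examples
#' ref <- matrix(rnorm(30), ncol = 3)
#' th <- pi / 3
#' R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
#' mob <- sweep(ref %*% t(R), 2, c(1, 2, 3), "+")
#' tr <- fitTransform(mob, ref)
#' max(abs(transformPoints(tr, mob) - ref))   # ~ 1e-15
#' @export
fitTransform <- function(mobile, reference, massWeighted = TRUE,
                         weights = NULL) {
  if (is(mobile, "Selection")) {
    X <- coords(mobile)
    if (is.null(weights) && massWeighted) weights <- masses(mobile)
  } else X <- as.matrix(mobile)
  Y <- if (is(reference, "Selection")) coords(reference) else as.matrix(reference)
  .kabschCore(X, Y, weights)
}

#' Radius of gyration
#'
#' `sqrt(sum_i w_i |r_i - c|^2 / sum_i w_i)` with `c` the corresponding
#' (mass- or geometry-) center.
#'
#' @param sel a readable [Selection-class].
#' @param massWeighted logical: weight by atomic masses (default) or treat
#'   all atoms equally.
#' @return radius of gyration in nm.
#' @export
radiusOfGyration <- function(sel, massWeighted = TRUE) {
  w <- if (massWeighted) masses(sel) else rep(1, length(sel))
  .gyrationCore(coords(sel), w)
}
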