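#' Triclinic periodic box
#'
#' A periodic simulation cell stored as a 3x3 matrix whose rows are the box
#' vectors a, b, c in nm. The stored representation is lower-triangular
#' (a along +x, b in the xy-plane), the Gromacs convention; arbitrary input
#' vectors are rotated into it on construction. The determinant (the box
#' volume) must be positive.
#'
#' @slot matrix 3x3 numeric matrix, rows are box vectors (nm), lower-triangular.
#' @export
setClass("PeriodicBox", representation(matrix = "matrix"))

setValidity("PeriodicBox", function(object) {
  m <- object@matrix
  if (!is.numeric(m) || !identical(dim(m), c(3L, 3L)))
    return("box matrix must be numeric 3x3")
  if (any(!is.finite(m))) return("box matrix must be finite")
  if (abs(m[1, 2]) > 1e-9 || abs(m[1, 3]) > 1e-9 || abs(m[2, 3]) > 1e-9)
    return("box matrix must be lower-triangular (a along +x, b in xy-plane)")
  if (det(m) <= 0) return("box volume (determinant) must be positive")
  TRUE
})

#' Construct a periodic box
#'
#' `periodicBox()` accepts a lower-triangular 3x3 matrix of box vectors (rows,
#' nm), a single edge length (cubic box) or a length-3 vector (orthorhombic).
#' `boxFromVectors()` accepts arbitrary box vectors and rotates them into the
#' lower-triangular convention. `boxFromLengthsAngles()` builds the box from
#' cell lengths (nm) and angles (degrees).
#'
#' @param m 3x3 matrix, or numeric of length 1 or 3 (diagonal box edges, nm).
#' @return a [PeriodicBox-class] object.
#' @examples
#' b <- periodicBox(5)           # cubic, edge 5 nm
#' boxVolume(b)
#' @export
periodicBox <- function(m) {
  if (is.numeric(m) && is.null(dim(m))) {
    if (length(m) == 1L) m <- diag(rep(m, 3))
    else if (length(m) == 3L) m <- diag(m)
    else .stopUsage("periodicBox: need a 3x3 matrix or 1 or 3 edge lengths")
  }
  new("PeriodicBox", matrix = m)
}

#' @rdname periodicBox
#' @param vectors 3x3 matrix whose rows are arbitrary box vectors (nm),
#'   with positive determinant.
#' @export
boxFromVectors <- function(vectors) {
  v <- as.matrix(vectors)
  if (!identical(dim(v), c(3L, 3L))) .stopUsage("boxFromVectors: need 3x3")
  if (det(v) <= 0) .stopData("box vectors must have positive determinant")
  la <- sqrt(rowSums(v^2))
  cosg <- sum(v[1, ] * v[2, ]) / (la[1] * la[2])
  cosb <- sum(v[1, ] * v[3, ]) / (la[1] * la[3])
  cosa <- sum(v[2, ] * v[3, ]) / (la[2] * la[3])
  boxFromLengthsAngles(la[1], la[2], la[3],
                       acos(cosa) * 180 / pi,
                       acos(cosb) * 180 / pi,
                       acos(cosg) * 180 / pi)
}

#' @rdname periodicBox
#' @param a,b,c cell edge lengths in nm.
#' @param alpha,beta,gamma cell angles in degrees (angle between b and c,
#'   a and c, a and b respectively).
#' @export
boxFromLengthsAngles <- function(a, b, c, alpha = 90, beta = 90, gamma = 90) {
  ca <- cospi(alpha / 180); cb <- cospi(beta / 180)
  cg <- cospi(gamma / 180); sg <- sinpi(gamma / 180)
  m <- matrix(0, 3, 3)
  m[1, 1] <- a
  m[2, ] <- c(b * cg, b * sg, 0)
  cx <- c * cb
  cy <- c * (ca - cb * cg) / sg
  cz2 <- c^2 - cx^2 - cy^2
  if (cz2 <= 0) .stopData("degenerate cell angles: zero or negative volume")
  m[3, ] <- c(cx, cy, sqrt(cz2))
  m[abs(m) < 1e-12] <- 0
  periodicBox(m)
}

#' Box volume
#' @param box a [PeriodicBox-class].
#' @return volume in nm^3.
#' @export
boxVolume <- function(box) det(box@matrix)

#' Cell lengths and angles
#' @param box a [PeriodicBox-class].
#' @return named numeric: a, b, c (nm), alpha, beta, gamma (degrees).
#' @export
boxLengthsAngles <- function(box) {
  m <- box@matrix
  la <- sqrt(rowSums(m^2))
  ang <- function(u, v) acos(sum(u * v) / sqrt(sum(u^2) * sum(v^2))) * 180 / pi
  c(a = la[1], b = la[2], c = la[3],
    alpha = ang(m[2, ], m[3, ]), beta = ang(m[1, ], m[3, ]),
    gamma = ang(m[1, ], m[2, ]))
}

# Perpendicular heights of the cell along its three lattice directions;
# the safe cell-list cutoff is half the smallest height.
.boxHeights <- function(box) {
  m <- box@matrix
  v <- det(m)
  cr <- function(u, w) c(u[2] * w[3] - u[3] * w[2],
                         u[3] * w[1] - u[1] * w[3],
                         u[1] * w[2] - u[2] * w[1])
  c(v / sqrt(sum(cr(m[2, ], m[3, ])^2)),
    v / sqrt(sum(cr(m[1, ], m[3, ])^2)),
    v / sqrt(sum(cr(m[1, ], m[2, ])^2)))
}

.isOrthorhombic <- function(box) {
  m <- box@matrix
  abs(m[2, 1]) < 1e-12 && abs(m[3, 1]) < 1e-12 && abs(m[3, 2]) < 1e-12
}

#' Minimum-image representative of a displacement vector
#'
#' Returns the shortest vector equal to `d` modulo lattice translations of
#' `box`: exact for orthorhombic cells; for triclinic cells the fractional
#' rounding is refined by searching the 27 neighboring lattice translations.
#'
#' @param box a [PeriodicBox-class].
#' @param d numeric length-3 displacement (nm).
#' @return numeric length-3, the minimum-image displacement (nm).
#' @examples
#' boxWrapVector(periodicBox(10), c(9, 0, 0))   # -> c(-1, 0, 0)
#' @export
boxWrapVector <- function(box, d) {
  if (!is(box, "PeriodicBox")) .stopUsage("boxWrapVector: box must be a PeriodicBox")
  d <- as.numeric(d)
  if (length(d) != 3L) .stopUsage("boxWrapVector: d must have length 3")
  m <- box@matrix
  f <- drop(d %*% solve(m))
  f <- f - round(f)
  if (.isOrthorhombic(box)) return(drop(f %*% m))
  best <- NULL; bestLen <- Inf
  for (s1 in -1:1) for (s2 in -1:1) for (s3 in -1:1) {
    cand <- drop((f + c(s1, s2, s3)) %*% m)
    l <- sum(cand^2)
    if (l < bestLen) { bestLen <- l; best <- cand }
  }
  best
}

# Minimum-image squared distances between row sets Q (m x 3) and C (k x 3).
# Returns an m x k matrix. Orthorhombic boxes use the exact per-axis form;
# triclinic boxes take the minimum over the 27 neighboring translations.
.minImageDist2 <- function(Q, C, box) {
  m <- box@matrix
  inv <- solve(m)
  fQ <- Q %*% inv; fC <- C %*% inv
  d1 <- outer(fQ[, 1], fC[, 1], "-"); d1 <- d1 - round(d1)
  d2 <- outer(fQ[, 2], fC[, 2], "-"); d2 <- d2 - round(d2)
  d3 <- outer(fQ[, 3], fC[, 3], "-"); d3 <- d3 - round(d3)
  if (.isOrthorhombic(box))
    return((d1 * m[1, 1])^2 + (d2 * m[2, 2])^2 + (d3 * m[3, 3])^2)
  best <- NULL
  for (s1 in -1:1) for (s2 in -1:1) for (s3 in -1:1) {
    e1 <- d1 + s1; e2 <- d2 + s2; e3 <- d3 + s3
    cx <- e1 * m[1, 1] + e2 * m[2, 1] + e3 * m[3, 1]
    cy <- e2 * m[2, 2] + e3 * m[3, 2]
    cz <- e3 * m[3, 3]
    dd <- cx * cx + cy * cy + cz * cz
    best <- if (is.null(best)) dd else pmin(best, dd)
  }
  best
}

setMethod("show", "PeriodicBox", function(object) {
  la <- boxLengthsAngles(object)
  cat(sprintf("PeriodicBox: a=%.4f b=%.4f c=%.4f nm, angles %.2f/%.2f/%.2f deg, V=%.4f nm^3\n",
              la["a"], la["b"], la["c"], la["alpha"], la["beta"], la["gamma"],
              boxVolume(object)))
})
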