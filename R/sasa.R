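#' Solvent accessible surface area (Shrake-Rupley)
#'
#' Numeric quadrature SASA: for every atom, `nPoints` quasi-uniform points
#' (a golden-spiral lattice) are placed on the sphere of radius
#' `r_vdw + probeRadius`; a point is exposed when it lies outside every
#' neighboring atom's expanded sphere, and the atom's accessible area is the
#' exposed fraction times the full sphere area. Van der Waals radii come
#' from the bundled Bondi table ([vdwRadius()]); an atom whose element has
#' no tabulated radius is an error rather than a silent guess. Periodic
#' images are not considered.
#'
#' The quadrature error scales as ~1/nPoints; at the default 960 points the
#' two-sphere overlap case agrees with the analytic spherical-cap result to
#' well under 2%.
#'
#' @param sel a readable [Selection-class].
#' @param probeRadius probe sphere radius in nm (default 0.14, water).
#' @param nPoints number of quadrature points per atom (default 960).
#' @return list with `perAtom` (numeric vector, nm^2) and `total` (nm^2).
#' @examples
#' top <- topology(data.frame(name = "C1", resname = "LIG", resid = 1,
#'                            chain = "A"))
#' sys <- makeSystem(top, state(matrix(0, 1, 3)), "MutableSerial")
#' sasa(selectAtoms(sys, "all"))$total            # 4*pi*(0.17+0.14)^2
#' @export
sasa <- function(sel, probeRadius = 0.14, nPoints = 960L) {
  if (probeRadius < 0) .stopUsage("probeRadius must be >= 0")
  nPoints <- as.integer(nPoints)
  if (nPoints < 1L) .stopUsage("nPoints must be >= 1")
  x <- coords(sel)
  el <- atoms(sel)$element
  rv <- vdwRadius(el)
  if (anyNA(rv)) {
    bad <- which(is.na(rv))
    .stopData(sprintf("no van-der-Waals radius for atom(s) %s (element %s)",
                      paste(head(indices(sel)[bad], 5), collapse = ", "),
                      paste(unique(el[bad]), collapse = ", ")))
  }
  if (any(rv <= 0)) .stopData("non-positive van-der-Waals radius")
  R <- rv + probeRadius
  n <- nrow(x)
  pts <- .goldenSpiral(nPoints)
  # neighbor candidates: atoms whose expanded spheres can intersect
  nb <- .neighborLists(x, 2 * max(R))
  per <- numeric(n)
  for (i in seq_len(n)) {
    p <- sweep(pts * R[i], 2, x[i, ], "+")
    covered <- rep(FALSE, nPoints)
    for (j in nb[[i]]) {
      dij2 <- sum((x[i, ] - x[j, ])^2)
      if (dij2 >= (R[i] + R[j])^2) next
      d2 <- (p[, 1] - x[j, 1])^2 + (p[, 2] - x[j, 2])^2 + (p[, 3] - x[j, 3])^2
      covered <- covered | d2 < R[j]^2
      if (all(covered)) break
    }
    per[i] <- (sum(!covered) / nPoints) * 4 * pi * R[i]^2
  }
  list(perAtom = per, total = sum(per))
}

# n quasi-uniform points on the unit sphere (golden-spiral lattice).
.goldenSpiral <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  phi <- (seq_len(n) - 1) * pi * (3 - sqrt(5))
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
}
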