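# Independent oracles and fixture builders shared across the test files.
# None of these call into the package's search/fit/COM internals: they are
# deliberately naive re-derivations used to check the real implementations.

# Brute-force within-cutoff search: all-pairs distances, minimum image taken
# as the explicit minimum over lattice translations (125 when `shells = 2`).
bruteWithin <- function(xyz, query, cutoff, boxMat = NULL, includeQuery = TRUE,
                        shells = 1L) {
  n <- nrow(xyz)
  hit <- rep(FALSE, n)
  sh <- -shells:shells
  for (q in query) {
    d <- sweep(xyz, 2, xyz[q, ])
    if (is.null(boxMat)) {
      d2 <- rowSums(d^2)
    } else {
      f <- d %*% solve(boxMat)
      f <- f - round(f)
      d2 <- rep(Inf, n)
      for (s1 in sh) for (s2 in sh) for (s3 in sh) {
        cart <- (f + matrix(rep(c(s1, s2, s3), each = n), ncol = 3)) %*% boxMat
        d2 <- pmin(d2, rowSums(cart^2))
      }
    }
    hit <- hit | (d2 <= cutoff^2)
  }
  res <- which(hit)
  if (includeQuery) sort(unique(c(res, query))) else sort(setdiff(res, query))
}

# Brute-force periodic center of mass: minimize the mass-weighted sum of
# squared wrapped distances over a fine 1-D grid per axis (orthorhombic only).
bruteComPBC <- function(xyz, w, edges, gridN = 20000L) {
  vapply(1:3, function(ax) {
    L <- edges[ax]
    cand <- seq(0, L, length.out = gridN + 1L)[-(gridN + 1L)]
    cost <- vapply(cand, function(c0) {
      d <- xyz[, ax] - c0
      d <- d - L * round(d / L)
      sum(w * d^2)
    }, numeric(1))
    cand[which.min(cost)]
  }, numeric(1))
}

# Closed-form solvent accessible area of two spheres with expanded radii
# R1, R2 at center distance d (area of the union's boundary).
twoSphereArea <- function(R1, R2, d) {
  if (d >= R1 + R2) return(4 * pi * (R1^2 + R2^2))
  if (d <= abs(R1 - R2)) return(4 * pi * max(R1, R2)^2)
  h1 <- R1 - (d^2 + R1^2 - R2^2) / (2 * d)
  h2 <- R2 - (d^2 + R2^2 - R1^2) / (2 * d)
  (4 * pi * R1^2 - 2 * pi * R1 * h1) + (4 * pi * R2^2 - 2 * pi * R2 * h2)
}

# Random proper rotation from a seeded RNG (axis-angle construction).
randomRotation <- function() {
  repeat {
    v <- stats::rnorm(3); l <- sqrt(sum(v^2))
    if (l > 1e-8) { v <- v / l; break }
  }
  th <- stats::runif(1, 0, pi)
  K <- rbind(c(0, -v[3], v[2]), c(v[3], 0, -v[1]), c(-v[2], v[1], 0))
  diag(3) * cos(th) + sin(th) * K + (1 - cos(th)) * (v %o% v)
}

plainRmsd <- function(A, B) sqrt(mean(rowSums((A - B)^2)))

# Small deterministic protein-like system: 3 chains x 4 residues x 4 atoms.
toySystem <- function(kind = "MutableSerial", seed = 11L,
                      nChains = 3L, resPerChain = 4L, atomsPerRes = 4L,
                      boxEdge = 6) {
  s <- generateSystem(nChains, resPerChain, atomsPerRes, boxEdge, seed = seed)
  makeSystem(s$topology, s$state, kind)
}

# Hand-built system with explicit names/resids for grammar tests.
gridSystem <- function(kind = "MutableSerial", nRes = 3L, atomsPerRes = 7L,
                       withBox = FALSE) {
  n <- nRes * atomsPerRes
  names <- rep(c("N", "CA", "C", "O", "CB", "CG", "CD")[seq_len(atomsPerRes)],
               nRes)
  top <- topology(data.frame(
    name = names, resname = rep(c("ALA", "GLY", "SER"), length.out = n),
    resid = rep(seq_len(nRes), each = atomsPerRes), chain = "A",
    stringsAsFactors = FALSE))
  xyz <- cbind(seq_len(n) * 0.1, 0, 0)
  makeSystem(top, state(xyz, box = if (withBox) periodicBox(10) else NULL),
             kind)
}
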