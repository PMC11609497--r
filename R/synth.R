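# Deterministic synthetic systems and trajectories with known ground truth,
# so every operation is testable with no external data. "Protein-like"
# means realistic field values (atom/residue names, chains, elements,
# masses), not realistic geometry: none of the operations exercised here
# depend on stereochemistry, only on plausible particle density.

.withSeed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

.BACKBONE <- data.frame(name = c("N", "CA", "C", "O"),
                        element = c("N", "C", "C", "O"),
                        stringsAsFactors = FALSE)

.randUnit <- function() {
  repeat {
    v <- stats::rnorm(3)
    l <- sqrt(sum(v^2))
    if (l > 1e-8) return(v / l)
  }
}

#' Generate a protein-like synthetic system
#'
#' Builds chains of residues along self-avoiding random walks inside a cubic
#' box: one walk step of ~0.38 nm (the CA-CA distance in proteins) per
#' residue, a clash check of 0.25 nm between residue centers, and per-residue
#' atoms (N, CA, C, O plus carbon dummies D1, D2, ... when `atomsPerRes > 4`)
#' jittered around the walk position. Residue ids run 1..`resPerChain` within
#' each chain; chains are lettered A, B, .... Identical seeds give identical
#' systems.
#'
#' @param nChains number of chains (>= 1).
#' @param resPerChain residues per chain (>= 1).
#' @param atomsPerRes atoms per residue (>= 1).
#' @param boxEdge cubic box edge in nm.
#' @param seed integer RNG seed.
#' @return list with `topology` ([Topology-class]) and `state`
#'   ([State-class], box attached).
#' @examples
#' s <- generateSystem(1, 5, 4, 5.0, seed = 42)
#' nAtoms(s$topology)    # 20
#' @export
generateSystem <- function(nChains = 1L, resPerChain = 10L, atomsPerRes = 4L,
                           boxEdge = 5, seed = 1L) {
  nChains <- as.integer(nChains); resPerChain <- as.integer(resPerChain)
  atomsPerRes <- as.integer(atomsPerRes)
  if (nChains < 1L || resPerChain < 1L || atomsPerRes < 1L)
    .stopUsage("generateSystem: all counts must be >= 1")
  margin <- 0.4
  if (boxEdge <= 2 * margin)
    .stopData("generateSystem: box too small to place atoms")
  .withSeed(seed, {
    step <- 0.38; clash <- 0.25; maxTry <- 200L
    resNames <- c("ALA", "GLY", "SER", "VAL", "LEU", "THR", "PHE", "LYS")
    perRes <- if (atomsPerRes <= 4L) .BACKBONE[seq_len(atomsPerRes), ] else
      rbind(.BACKBONE, data.frame(name = paste0("D", seq_len(atomsPerRes - 4L)),
                                  element = "C", stringsAsFactors = FALSE))
    centers <- matrix(NA_real_, nChains * resPerChain, 3)
    nPlaced <- 0L
    for (ch in seq_len(nChains)) {
      pos <- stats::runif(3, margin, boxEdge - margin)
      for (r in seq_len(resPerChain)) {
        ok <- FALSE
        for (tries in seq_len(maxTry)) {
          cand <- if (r == 1L && tries == 1L) pos else pos + step * .randUnit()
          if (any(cand < margin) || any(cand > boxEdge - margin)) next
          if (nPlaced > 0L) {
            d2 <- colSums((t(centers[seq_len(nPlaced), , drop = FALSE]) - cand)^2)
            if (min(d2) < clash^2) next
          }
          ok <- TRUE; break
        }
        if (!ok) .stopData("generateSystem: box too small to place atoms without clashes")
        nPlaced <- nPlaced + 1L
        centers[nPlaced, ] <- cand
        pos <- cand
      }
    }
    nRes <- nChains * resPerChain
    nAt <- nRes * atomsPerRes
    resIdx <- rep(seq_len(nRes), each = atomsPerRes)
    offs <- matrix(stats::runif(nAt * 3, -0.12, 0.12), ncol = 3)
    offs[perRes$name[((seq_len(nAt) - 1L) %% atomsPerRes) + 1L] == "CA", ] <- 0
    xyz <- centers[resIdx, , drop = FALSE] + offs
    xyz <- pmin(pmax(xyz, 0.05), boxEdge - 0.05)
    atomsDf <- data.frame(
      name = rep(perRes$name, nRes),
      resname = rep(resNames[((seq_len(nRes) - 1L) %% length(resNames)) + 1L],
                    each = atomsPerRes),
      resid = rep(rep(seq_len(resPerChain), times = nChains), each = atomsPerRes),
      chain = rep(LETTERS[((seq_len(nChains) - 1L) %% 26L) + 1L],
                  each = resPerChain * atomsPerRes),
      element = rep(perRes$element, nRes),
      stringsAsFactors = FALSE)
    # bonds: consecutive atoms within a residue plus the C -> next-N link
    b1 <- cbind(seq_len(nAt - 1L), seq_len(nAt - 1L) + 1L)
    sameRes <- resIdx[b1[, 1]] == resIdx[b1[, 2]]
    sameChain <- atomsDf$chain[b1[, 1]] == atomsDf$chain[b1[, 2]]
    bondsM <- b1[sameRes | (sameChain & atomsDf$name[b1[, 1]] == "C" &
                              atomsDf$name[b1[, 2]] == "N"), , drop = FALSE]
    list(topology = topology(atomsDf, bondsM),
         state = state(xyz, box = periodicBox(boxEdge)))
  })
}

#' Motion specification for synthetic trajectories
#'
#' @slot mode `"rigid"` (per-frame rotation + translation of the whole
#'   system, recorded in the manifest), `"brownian"` (cumulative per-atom
#'   Gaussian steps) or `"mixed"` (rigid plus noise).
#' @slot seed integer RNG seed; same seed and parameters give bit-identical
#'   trajectories.
#' @slot sigma per-step Gaussian displacement sigma in nm (brownian/mixed).
#' @slot maxAngle largest per-frame rotation angle in radians (rigid/mixed).
#' @slot maxStep largest per-frame translation per axis in nm (rigid/mixed).
#' @export
setClass("MotionSpec", representation(mode = "character", seed = "integer",
                                      sigma = "numeric", maxAngle = "numeric",
                                      maxStep = "numeric"))

#' @rdname MotionSpec-class
#' @param mode,seed,sigma,maxAngle,maxStep see slots.
#' @export
motionSpec <- function(mode = c("rigid", "brownian", "mixed"), seed = 1L,
                       sigma = 0.02, maxAngle = 0.3, maxStep = 0.3) {
  mode <- match.arg(mode)
  new("MotionSpec", mode = mode, seed = as.integer(seed),
      sigma = as.numeric(sigma), maxAngle = as.numeric(maxAngle),
      maxStep = as.numeric(maxStep))
}

.axisAngleMatrix <- function(axis, angle) {
  a <- axis / sqrt(sum(axis^2))
  c0 <- cos(angle); s0 <- sin(angle)
  K <- rbind(c(0, -a[3], a[2]), c(a[3], 0, -a[1]), c(-a[2], a[1], 0))
  diag(3) * c0 + s0 * K + (1 - c0) * (a %o% a)
}

#' Generate a synthetic trajectory with known ground truth
#'
#' Writes a DCD or multi-frame XYZ trajectory whose frame 1 is exactly the
#' input state. In `"rigid"` mode every later frame is a rigid rotation +
#' translation of frame 1 about its geometric center and the exact per-frame
#' transforms are recorded in a JSON manifest, so superposition code can be
#' checked against ground truth. `"brownian"` adds cumulative Gaussian
#' displacements; `"mixed"` applies the rigid motion plus per-frame noise.
#'
#' @param sys a list with `topology` and `state` (as from
#'   [generateSystem()] or [readStructure()]) or a [MolSystem-class].
#' @param nFrames number of frames (>= 1).
#' @param motion a [MotionSpec-class].
#' @param outPath output trajectory path (`.dcd` or `.xyz`).
#' @param manifestPath JSON manifest path (default `<outPath>.manifest.json`).
#' @return the manifest, invisibly: a list with mode, seed, center and (for
#'   rigid/mixed modes) one 3x3 rotation and translation per frame.
#' @export
generateTrajectory <- function(sys, nFrames, motion = motionSpec("rigid"),
                               outPath, manifestPath = NULL) {
  nFrames <- as.integer(nFrames)
  if (nFrames < 1L) .stopUsage("generateTrajectory: nFrames must be >= 1")
  if (is(sys, "MolSystem")) {
    x0 <- coords(sys); boxObj <- box(sys)
  } else {
    x0 <- sys$state@coords; boxObj <- sys$state@box
  }
  if (is.null(manifestPath)) manifestPath <- paste0(outPath, ".manifest.json")
  ctr <- colMeans(x0)
  wr <- openTrajectoryWriter(outPath, nrow(x0), dt = 1,
                             withBox = !is.null(boxObj) &&
                               .fileFormat(outPath) == "dcd")
  transforms <- vector("list", nFrames)
  .withSeed(motion@seed, {
    x <- x0
    for (f in seq_len(nFrames)) {
      if (f == 1L) {
        R <- diag(3); tv <- c(0, 0, 0)
        x <- x0
      } else if (motion@mode %in% c("rigid", "mixed")) {
        R <- .axisAngleMatrix(.randUnit(), stats::runif(1, 0, motion@maxAngle))
        tv <- stats::runif(3, -motion@maxStep, motion@maxStep)
        x <- sweep(sweep(x0, 2, ctr) %*% t(R), 2, ctr + tv, "+")
        if (motion@mode == "mixed")
          x <- x + matrix(stats::rnorm(length(x), 0, motion@sigma), ncol = 3)
      } else {  # brownian: cumulative steps from the previous frame
        R <- diag(3); tv <- c(0, 0, 0)
        x <- x + matrix(stats::rnorm(length(x), 0, motion@sigma), ncol = 3)
      }
      transforms[[f]] <- list(rotation = R, translation = tv)
      writeFrame(wr, x, boxObj = if (wr@h$withBox %||% FALSE) boxObj else NULL,
                 time = f - 1)
    }
  })
  closeWriter(wr)
  manifest <- list(mode = motion@mode, seed = motion@seed,
                   sigma = motion@sigma, nFrames = nFrames,
                   nAtoms = nrow(x0), center = ctr,
                   transforms = lapply(transforms, function(t)
                     list(rotation = as.numeric(t$rotation),  # column-major 9
                          translation = t$translation)))
  jsonlite::write_json(manifest, manifestPath, auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
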