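#' Selection access kinds
#'
#' The four access contracts a [MolSystem-class] (and every selection made
#' from it) can carry. Each kind fixes three flags: whether selected atoms
#' may be written, whether live selections may overlap, and whether accesses
#' must be validity-checked against structural edits.
#'
#' \tabular{llll}{
#'   kind \tab data access \tab may overlap \tab validity check \cr
#'   MutableSerial \tab read/write \tab yes \tab no \cr
#'   BuilderSerial \tab read/write \tab yes \tab yes \cr
#'   ImmutableParallel \tab read only \tab yes \tab no \cr
#'   MutableParallel \tab read/write \tab no \tab no \cr
#' }
#'
#' @format character vector of the four kind names.
#' @export
ACCESS_KINDS <- c("MutableSerial", "BuilderSerial",
                  "ImmutableParallel", "MutableParallel")

.kindWritable <- function(kind) kind != "ImmutableParallel"
.kindOverlap  <- function(kind) kind != "MutableParallel"
.kindChecked  <- function(kind) kind == "BuilderSerial"
.kindSerial   <- function(kind) kind %in% c("MutableSerial", "BuilderSerial")

.checkKind <- function(kind) {
  if (!is.character(kind) || length(kind) != 1L || !(kind %in% ACCESS_KINDS))
    .stopUsage(paste("kind must be one of:", paste(ACCESS_KINDS, collapse = ", ")))
  kind
}

#' A system: shared Topology + State under one access contract
#'
#' A MolSystem takes control of a [Topology-class] and a [State-class] and
#' serves as the source of [Selection-class] views, all of which carry the
#' system's access kind. Storage lives in an internal environment so that
#' every selection sees edits immediately (reference semantics): after
#' `makeSystem()` the caller must treat the original Topology/State objects
#' as handed over and not rely on them reflecting later edits.
#'
#' For kind `"MutableParallel"` the system also maintains the used-index
#' registry: the set of atom indices claimed by live selections, kept exact
#' by [claimIndices()]/[releaseIndices()] so that mutable parallel
#' selections can never overlap.
#'
#' @slot data environment holding atoms, bonds, coords, box, time, step,
#'   the structural-edit generation counter and the used-index registry.
#' @slot kind one of [ACCESS_KINDS].
#' @export
setClass("MolSystem", representation(data = "environment", kind = "character"))

#' Create a MolSystem
#'
#' @param topology a [Topology-class].
#' @param state a [State-class] with as many coordinate rows as the topology
#'   has atoms.
#' @param kind one of [ACCESS_KINDS].
#' @return a [MolSystem-class].
#' @examples
#' top <- topology(data.frame(name = c("CA", "CB"), resname = "ALA",
#'                            resid = 1, chain = "A"))
#' st <- state(matrix(rnorm(6), ncol = 3))
#' sys <- makeSystem(top, st, "MutableSerial")
#' @export
makeSystem <- function(topology, state, kind = "MutableSerial") {
  .checkKind(kind)
  if (!is(topology, "Topology") || !is(state, "State"))
    .stopUsage("makeSystem: need a Topology and a State")
  if (nAtoms(topology) != nAtoms(state))
    .stopData(sprintf("size mismatch: topology has %d atoms, state has %d coordinate rows",
                      nAtoms(topology), nAtoms(state)))
  e <- new.env(parent = emptyenv())
  e$atoms <- topology@atoms
  e$bonds <- topology@bonds
  e$coords <- state@coords
  e$box <- state@box
  e$time <- state@time
  e$step <- state@step
  e$velocities <- state@velocities
  e$forces <- state@forces
  e$generation <- 0L
  e$used <- integer(0)
  new("MolSystem", data = e, kind = kind)
}

#' @rdname nAtoms
setMethod("nAtoms", "MolSystem", function(x) nrow(x@data$coords))
#' @rdname atoms
setMethod("atoms", "MolSystem", function(x) x@data$atoms)
#' @rdname bonds
setMethod("bonds", "MolSystem", function(x) x@data$bonds)
#' @rdname coords
setMethod("coords", "MolSystem", function(x) x@data$coords)
#' @rdname box
setMethod("box", "MolSystem", function(x) x@data$box)

#' Access kind of a system or selection
#' @param x a MolSystem or Selection.
#' @return one of [ACCESS_KINDS].
#' @export
setGeneric("accessKind", function(x) standardGeneric("accessKind"))
#' @rdname accessKind
setMethod("accessKind", "MolSystem", function(x) x@kind)

#' Structural-edit generation counter
#'
#' Incremented by every edit that can invalidate existing atom indices
#' (currently [deleteAtoms()]); appending atoms does not bump it because an
#' append preserves all existing indices. BuilderSerial selections compare
#' their birth generation against this counter on every access.
#'
#' @param x a MolSystem.
#' @return non-negative integer.
#' @export
generation <- function(x) x@data$generation

#' Current frame time / step of a system
#' @param x a MolSystem.
#' @export
frameTime <- function(x) x@data$time

#' @rdname frameTime
#' @export
frameStep <- function(x) x@data$step

#' Snapshot the system's current frame as a State
#' @param x a MolSystem.
#' @return a [State-class] copy of the current coordinates/box/time.
#' @export
currentState <- function(x) {
  state(x@data$coords, box = x@data$box, time = x@data$time, step = x@data$step)
}

## ---- used-index registry -------------------------------------------------

#' Used-index registry operations
#'
#' The registry backs the no-overlap guarantee of `MutableParallel`
#' selections: at every point it equals the union of the index sets of all
#' live MutableParallel selections on the system. `claimIndices()` adds a
#' set after checking disjointness (the check and the insertion are a single
#' uninterruptible step in R's evaluation model); `releaseIndices()` removes
#' a previously claimed set and treats a release of unclaimed indices as an
#' internal-consistency error rather than ignoring it.
#'
#' @param system a [MolSystem-class] of kind `"MutableParallel"`.
#' @param idx integer vector of 1-based atom indices.
#' @return `claimIndices()`/`releaseIndices()` return the system invisibly;
#'   `usedIndices()` returns the sorted integer vector of claimed indices.
#' @export
claimIndices <- function(system, idx) {
  idx <- sort(unique(as.integer(idx)))
  hit <- idx[idx %in% system@data$used]
  if (length(hit))
    .stopContract(sprintf("overlapping parallel selection (index %d already claimed)", hit[1]))
  system@data$used <- sort(c(system@data$used, idx))
  invisible(system)
}

#' @rdname claimIndices
#' @export
releaseIndices <- function(system, idx) {
  idx <- sort(unique(as.integer(idx)))
  if (!all(idx %in% system@data$used))
    .stopContract("internal consistency error: releasing indices that were never claimed")
  system@data$used <- setdiff(system@data$used, idx)
  invisible(system)
}

#' @rdname claimIndices
#' @export
usedIndices <- function(system) system@data$used

## ---- structural edits (BuilderSerial only) -------------------------------

#' Append atoms to a BuilderSerial system
#'
#' Only systems of kind `"BuilderSerial"` support structural edits. Appending
#' preserves all existing atom indices, so existing selections stay valid and
#' the generation counter is not bumped.
#'
#' @param system a [MolSystem-class] of kind `"BuilderSerial"`.
#' @param newAtoms data.frame of atom fields (as for [topology()]).
#' @param newCoords M x 3 matrix of positions in nm.
#' @return the system, invisibly.
#' @export
addAtoms <- function(system, newAtoms, newCoords) {
  if (system@kind != "BuilderSerial")
    .stopContract("structural edits require BuilderSerial")
  newCoords <- matrix(as.numeric(newCoords), ncol = 3)
  if (nrow(newCoords) == 0L) return(invisible(system))
  newAtoms <- .canonicalAtoms(newAtoms)
  if (nrow(newAtoms) != nrow(newCoords))
    .stopData("addAtoms: atom table and coordinate rows differ in length")
  e <- system@data
  for (col in setdiff(names(e$atoms), names(newAtoms))) newAtoms[[col]] <- NA
  e$atoms <- rbind(e$atoms[, names(e$atoms), drop = FALSE],
                   newAtoms[, names(e$atoms), drop = FALSE])
  rownames(e$atoms) <- NULL
  e$coords <- rbind(e$coords, newCoords)
  if (!is.null(e$velocities)) e$velocities <- rbind(e$velocities, matrix(0, nrow(newCoords), 3))
  if (!is.null(e$forces)) e$forces <- rbind(e$forces, matrix(0, nrow(newCoords), 3))
  invisible(system)
}

#' Delete atoms from a BuilderSerial system
#'
#' Remaining atoms are re-indexed compactly and the generation counter is
#' incremented: every selection created before the deletion becomes stale and
#' errors on its next access (after re-indexing, a plain bounds check could
#' silently address the wrong atom, so staleness is the safe contract).
#' Bonds touching a deleted atom are dropped; surviving bonds are remapped.
#'
#' @param system a [MolSystem-class] of kind `"BuilderSerial"`.
#' @param idx integer vector of 1-based atom indices to remove.
#' @return the system, invisibly.
#' @export
deleteAtoms <- function(system, idx) {
  if (system@kind != "BuilderSerial")
    .stopContract("structural edits require BuilderSerial")
  idx <- sort(unique(as.integer(idx)))
  if (length(idx) == 0L) return(invisible(system))
  e <- system@data
  n <- nrow(e$coords)
  if (any(idx < 1L) || any(idx > n)) .stopUsage("deleteAtoms: index out of range")
  keep <- setdiff(seq_len(n), idx)
  remap <- integer(n); remap[keep] <- seq_along(keep)
  e$atoms <- e$atoms[keep, , drop = FALSE]
  rownames(e$atoms) <- NULL
  e$coords <- e$coords[keep, , drop = FALSE]
  if (!is.null(e$velocities)) e$velocities <- e$velocities[keep, , drop = FALSE]
  if (!is.null(e$forces)) e$forces <- e$forces[keep, , drop = FALSE]
  if (nrow(e$bonds) > 0) {
    ok <- !(e$bonds[, 1] %in% idx) & !(e$bonds[, 2] %in% idx)
    b <- e$bonds[ok, , drop = FALSE]
    b[] <- remap[b]
    e$bonds <- b
  }
  e$generation <- e$generation + 1L
  invisible(system)
}

# Deep-copy a system's storage into a fresh environment carrying `kind`;
# used by the parallel driver to give each worker its own State buffer.
.replicateSystem <- function(system, kind = system@kind) {
  e <- system@data
  e2 <- new.env(parent = emptyenv())
  for (nm in c("atoms", "bonds", "coords", "box", "time", "step",
               "velocities", "forces", "generation"))
    assign(nm, get(nm, envir = e), envir = e2)
  e2$used <- integer(0)
  new("MolSystem", data = e2, kind = .checkKind(kind))
}

# Load a State (one trajectory frame) into a system in place.
.loadState <- function(system, st) {
  e <- system@data
  if (nrow(st@coords) != nrow(e$coords))
    .stopData(sprintf("frame has %d atoms, system has %d",
                      nrow(st@coords), nrow(e$coords)))
  e$coords <- st@coords
  if (!is.null(st@box)) e$box <- st@box
  e$time <- st@time
  e$step <- st@step
  invisible(system)
}

setMethod("show", "MolSystem", function(object) {
  cat(sprintf("MolSystem<%s>: %d atoms, generation %d, box: %s",
              object@kind, nAtoms(object), generation(object),
              if (is.null(box(object))) "none" else "present"))
  if (object@kind == "MutableParallel")
    cat(sprintf(", %d indices claimed", length(object@data$used)))
  cat("\n")
})
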