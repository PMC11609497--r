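#' Selection: a kind-tagged view over shared atoms
#'
#' A Selection points at a sorted, unique (possibly non-contiguous) set of
#' atom indices in a [MolSystem-class] and carries the system's access kind.
#' Selections hold no atom data themselves; reads and writes go through the
#' shared storage, so edits made via one selection are immediately visible
#' to every other view of the same system.
#'
#' Lifecycle: a selection is *alive* until it is consumed by
#' [intoFragments()] or released by [releaseSelection()]; any access to a
#' dead selection raises a contract error. `BuilderSerial` selections are
#' additionally checked for staleness against the system's structural-edit
#' generation on every access (see [validateAccess()]).
#'
#' @slot system the owning [MolSystem-class].
#' @slot idx sorted unique integer vector of 1-based atom indices.
#' @slot kind one of [ACCESS_KINDS] (always equal to the system's kind).
#' @slot birthGeneration the system generation at creation time.
#' @slot status environment holding the mutable `alive` flag.
#' @export
setClass("Selection", representation(system = "MolSystem", idx = "integer",
                                     kind = "character",
                                     birthGeneration = "integer",
                                     status = "environment"))

.newSelection <- function(system, idx, claim = TRUE) {
  n <- nAtoms(system)
  if (n == 0L) .stopData("cannot select from an empty system")
  idx <- sort(unique(as.integer(idx)))
  if (length(idx) == 0L) .stopData("empty selection")
  if (any(idx < 1L) || any(idx > n))
    .stopUsage(sprintf("selection index out of range (1..%d)", n))
  if (claim && system@kind == "MutableParallel") claimIndices(system, idx)
  st <- new.env(parent = emptyenv())
  st$alive <- TRUE
  new("Selection", system = system, idx = idx, kind = system@kind,
      birthGeneration = generation(system), status = st)
}

#' Create a selection from an expression
#'
#' Evaluates a selection expression (see the grammar in
#' [selection language][searchWithin]: keywords `all`, `name`, `resname`,
#' `resid`, `chain`, `index` (0-based), `within <r> of (...)`, combined with
#' `and`/`or`/`not` and parentheses) against the system's current
#' coordinates. An empty match is an error — silent empty selections hide
#' analysis bugs; use [trySelectAtoms()] when probing. On a
#' `MutableParallel` system the matched index set is claimed in the
#' used-index registry first and creation fails if it overlaps any live
#' parallel selection.
#'
#' @param system a [MolSystem-class].
#' @param expr selection expression string.
#' @param withinIncludesSelf logical: do the reference atoms of a
#'   `within` clause belong to its result (default TRUE)?
#' @return a [Selection-class].
#' @examples
#' top <- topology(data.frame(name = rep(c("N", "CA", "C", "O"), 3),
#'                            resname = "GLY", resid = rep(1:3, each = 4),
#'                            chain = "A"))
#' sys <- makeSystem(top, state(matrix(rnorm(36), ncol = 3)), "MutableSerial")
#' sel <- selectAtoms(sys, "name CA and resid 1-2")
#' indices(sel)
#' @export
selectAtoms <- function(system, expr, withinIncludesSelf = TRUE) {
  if (nAtoms(system) == 0L) .stopData("cannot select from an empty system")
  ast <- .selParse(expr)
  mask <- .selEval(ast, atoms(system), coords(system), box(system),
                   withinIncludesSelf)
  idx <- which(mask)
  if (length(idx) == 0L) .stopData(sprintf("empty selection: '%s'", expr))
  .newSelection(system, idx)
}

#' @rdname selectAtoms
#' @return `trySelectAtoms()` returns NULL instead of raising when the
#'   expression matches nothing (parse errors still raise).
#' @export
trySelectAtoms <- function(system, expr, withinIncludesSelf = TRUE) {
  ast <- .selParse(expr)
  mask <- .selEval(ast, atoms(system), coords(system), box(system),
                   withinIncludesSelf)
  idx <- which(mask)
  if (length(idx) == 0L) return(NULL)
  .newSelection(system, idx)
}

#' Create a selection from explicit indices
#' @param system a [MolSystem-class].
#' @param idx integer vector of 1-based atom indices.
#' @return a [Selection-class].
#' @export
selectIndices <- function(system, idx) .newSelection(system, idx)

#' Validate a selection before data access
#'
#' Called internally before every read or write through a selection. Dead
#' (consumed or released) selections always raise. For `BuilderSerial`
#' selections the birth generation is compared against the system's current
#' generation, so any selection created before a [deleteAtoms()] raises a
#' staleness error; for every other kind the structural immutability of the
#' system makes the check unnecessary and nothing is done.
#'
#' @param sel a [Selection-class].
#' @return TRUE, invisibly.
#' @export
validateAccess <- function(sel) {
  if (!sel@status$alive) .stopContract("selection consumed")
  if (sel@kind == "BuilderSerial" &&
      sel@birthGeneration != generation(sel@system))
    .stopContract("selection invalidated by structural edit")
  invisible(TRUE)
}

#' Is the selection still usable?
#' @param sel a [Selection-class].
#' @export
isAlive <- function(sel) sel@status$alive

#' Atom indices of a selection
#' @param sel a [Selection-class].
#' @return sorted integer vector of 1-based indices.
#' @export
indices <- function(sel) { validateAccess(sel); sel@idx }

#' @rdname nAtoms
setMethod("nAtoms", "Selection", function(x) { validateAccess(x); length(x@idx) })

setMethod("length", "Selection", function(x) { validateAccess(x); length(x@idx) })

#' @rdname atoms
setMethod("atoms", "Selection", function(x) {
  validateAccess(x)
  x@system@data$atoms[x@idx, , drop = FALSE]
})

#' @rdname coords
setMethod("coords", "Selection", function(x) {
  validateAccess(x)
  x@system@data$coords[x@idx, , drop = FALSE]
})

#' @rdname box
setMethod("box", "Selection", function(x) { validateAccess(x); x@system@data$box })

#' @rdname accessKind
setMethod("accessKind", "Selection", function(x) x@kind)

#' Masses of the selected atoms
#' @param sel a [Selection-class].
#' @return numeric vector (amu).
#' @export
masses <- function(sel) { validateAccess(sel); sel@system@data$atoms$mass[sel@idx] }

#' Replace the coordinates of the selected atoms
#'
#' @param x a [Selection-class] of a writable kind.
#' @param value |sel| x 3 numeric matrix (nm).
#' @export
setGeneric("coords<-", function(x, value) standardGeneric("coords<-"))

#' @rdname coords-set
setMethod("coords<-", "Selection", function(x, value) {
  .checkWritable(x)
  value <- as.matrix(value)
  if (!identical(dim(value), c(length(x@idx), 3L)))
    .stopUsage("replacement coordinates must be |selection| x 3")
  x@system@data$coords[x@idx, ] <- value
  x
})

.checkWritable <- function(sel) {
  validateAccess(sel)
  if (!.kindWritable(sel@kind)) .stopContract("selection kind is read-only")
  invisible(TRUE)
}

#' Release a MutableParallel selection's registry claim
#'
#' Marks the selection dead and, for kind `"MutableParallel"`, removes its
#' index set from the used-index registry so the atoms can be claimed again.
#' R has no deterministic destructors, so the release is explicit; calling
#' it on an already-dead selection is a no-op.
#'
#' @param sel a [Selection-class].
#' @return invisibly, TRUE.
#' @export
releaseSelection <- function(sel) {
  if (!sel@status$alive) return(invisible(TRUE))
  sel@status$alive <- FALSE
  if (sel@kind == "MutableParallel") releaseIndices(sel@system, sel@idx)
  invisible(TRUE)
}

## ---- sub-selections ------------------------------------------------------

#' Narrow an existing selection
#'
#' Evaluates an expression inside an existing selection: the result is the
#' subset of the parent's atoms that also satisfy `expr` (so a sub-selection
#' never widens its parent). The parent stays alive and usable. Not
#' available for `MutableParallel` selections, whose no-overlap contract a
#' coexisting subset would violate — use [intoFragments()] there.
#'
#' @param sel a live [Selection-class] of any kind except `MutableParallel`.
#' @param expr selection expression string.
#' @param withinIncludesSelf as in [selectAtoms()].
#' @return a new [Selection-class] with index set a subset of the parent's.
#' @export
subselect <- function(sel, expr, withinIncludesSelf = TRUE) {
  validateAccess(sel)
  if (sel@kind == "MutableParallel")
    .stopContract("subselect is not implemented for this kind (MutableParallel)")
  sys <- sel@system
  ast <- .selParse(expr)
  mask <- .selEval(ast, atoms(sys), coords(sys), box(sys), withinIncludesSelf)
  idx <- intersect(sel@idx, which(mask))
  if (length(idx) == 0L) .stopData(sprintf("empty selection: '%s'", expr))
  .newSelection(sys, idx)
}

# Resolve a splitting key into one key value per selected atom.
# `key` is either the name of an atom column ("resid", "chain", "resname",
# "name") or a function key(idx, atoms) returning one comparable value per
# index (idx: 1-based atom indices; atoms: the matching atom table rows).
.fragmentKeys <- function(sel, key) {
  a <- sel@system@data$atoms[sel@idx, , drop = FALSE]
  if (is.character(key) && length(key) == 1L) {
    if (key == "residue") keys <- paste(a$chain, a$resid)
    else if (key %in% names(a)) keys <- a[[key]]
    else .stopUsage(sprintf("unknown split key '%s'", key))
  } else if (is.function(key)) {
    keys <- key(sel@idx, a)
    if (length(keys) == 1L) keys <- rep(keys, length(sel@idx))
    if (length(keys) != length(sel@idx))
      .stopUsage("split key function must return one value per atom")
  } else {
    .stopUsage("split key must be a column name or a function")
  }
  keys
}

.partitionIndices <- function(sel, key) {
  keys <- .fragmentKeys(sel, key)
  split(sel@idx, factor(keys, levels = unique(keys)))
}

#' Split a selection into fragments, keeping the parent alive
#'
#' Partitions the parent's atoms by a key (one fragment per distinct key
#' value, ordered by first occurrence). Fragments are pairwise disjoint and
#' their union is the parent set. The parent remains alive and usable. Not
#' available for `MutableParallel` selections (the fragments would overlap
#' the live parent); use [intoFragments()] there.
#'
#' @param sel a live [Selection-class] of any kind except `MutableParallel`.
#' @param key column name (`"resid"`, `"chain"`, `"resname"`, `"name"`, or
#'   `"residue"` for chain+resid) or a function `key(idx, atoms)` returning
#'   one comparable value per atom.
#' @return list of [Selection-class] fragments.
#' @export
splitFragments <- function(sel, key) {
  validateAccess(sel)
  if (sel@kind == "MutableParallel")
    .stopContract("splitFragments is not implemented for this kind (MutableParallel)")
  parts <- .partitionIndices(sel, key)
  lapply(parts, function(p) .newSelection(sel@system, p))
}

#' Fragment a selection, consuming the parent
#'
#' Like [splitFragments()] but the parent is consumed: it is marked dead
#' before any fragment is handed out, so parent and fragments never coexist.
#' This is the one sub-selection route open to `MutableParallel` selections:
#' the parent's registry claim is exchanged for the per-fragment claims as
#' one indivisible step (no third party can grab those indices in between),
#' preserving the no-overlap guarantee.
#'
#' @inheritParams splitFragments
#' @param sel a live [Selection-class] of any kind.
#' @return list of [Selection-class] fragments.
#' @export
intoFragments <- function(sel, key) {
  validateAccess(sel)
  parts <- .partitionIndices(sel, key)
  sel@status$alive <- FALSE
  if (sel@kind == "MutableParallel") {
    # exchange the parent claim for fragment claims; the fragments partition
    # the parent set, so the registry's coverage is unchanged throughout
    releaseIndices(sel@system, sel@idx)
    lapply(parts, function(p) .newSelection(sel@system, p, claim = TRUE))
  } else {
    lapply(parts, function(p) .newSelection(sel@system, p))
  }
}

setMethod("show", "Selection", function(object) {
  alive <- object@status$alive
  cat(sprintf("Selection<%s>: %d atoms%s%s\n", object@kind,
              length(object@idx),
              if (alive) "" else " [dead]",
              if (alive && object@kind == "BuilderSerial" &&
                  object@birthGeneration != generation(object@system))
                " [stale]" else ""))
})
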