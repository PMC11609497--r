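# Read-write operations on selections: rigid transforms and periodic-image
# manipulation. All of them honor the access contract: ImmutableParallel
# selections refuse every write.

#' Apply a rigid transform to the selected atoms in place
#'
#' Every selected coordinate becomes `R r + t`; unselected atoms are
#' untouched.
#'
#' @param sel a writable [Selection-class] (any kind except
#'   `ImmutableParallel`).
#' @param tr a [RigidTransform-class].
#' @return the selection, invisibly.
#' @export
applyTransform <- function(sel, tr) {
  .checkWritable(sel)
  if (!is(tr, "RigidTransform")) .stopUsage("tr must be a RigidTransform")
  e <- sel@system@data
  e$coords[sel@idx, ] <- transformPoints(tr, e$coords[sel@idx, , drop = FALSE])
  invisible(sel)
}

#' Translate the selected atoms in place
#' @param sel a writable [Selection-class].
#' @param v numeric length-3 displacement (nm).
#' @return the selection, invisibly.
#' @export
translateAtoms <- function(sel, v) {
  .checkWritable(sel)
  v <- as.numeric(v)
  if (length(v) != 3L) .stopUsage("v must have length 3")
  e <- sel@system@data
  e$coords[sel@idx, ] <- sweep(e$coords[sel@idx, , drop = FALSE], 2, v, "+")
  invisible(sel)
}

#' Remove periodic-boundary jumps along a selection (make molecule whole)
#'
#' Re-images atoms sequentially in selection index order: starting from the
#' anchor atom, each atom is moved to the periodic image closest to the
#' previously processed atom (both directions from the anchor). After
#' unwrapping, no two consecutive selected atoms are separated by more than
#' half the box diagonal. The rule uses index order, not bond topology, so
#' it is meaningful for molecules whose index order follows the chain;
#' branched molecules with spatially jumping index order are a documented
#' limitation.
#'
#' @param sel a writable [Selection-class] on a system with a box.
#' @param anchor local index (1-based position within the selection) of the
#'   atom that stays fixed; default the first.
#' @return the selection, invisibly.
#' @export
unwrapAtoms <- function(sel, anchor = 1L) {
  .checkWritable(sel)
  b <- box(sel)
  if (is.null(b)) .stopData("unwrapAtoms: system has no periodic box")
  n <- length(sel@idx)
  anchor <- as.integer(anchor)
  if (anchor < 1L || anchor > n) .stopUsage("anchor out of range")
  e <- sel@system@data
  x <- e$coords[sel@idx, , drop = FALSE]
  if (anchor < n) for (k in (anchor + 1L):n)
    x[k, ] <- x[k - 1L, ] + boxWrapVector(b, x[k, ] - x[k - 1L, ])
  if (anchor > 1L) for (k in (anchor - 1L):1L)
    x[k, ] <- x[k + 1L, ] + boxWrapVector(b, x[k, ] - x[k + 1L, ])
  e$coords[sel@idx, ] <- x
  invisible(sel)
}

#' Wrap the selected atoms into the primary cell
#'
#' Maps every selected atom to fractional coordinates in [0, 1).
#'
#' @param sel a writable [Selection-class] on a system with a box.
#' @return the selection, invisibly.
#' @export
wrapAtoms <- function(sel) {
  .checkWritable(sel)
  b <- box(sel)
  if (is.null(b)) .stopData("wrapAtoms: system has no periodic box")
  m <- b@matrix
  e <- sel@system@data
  f <- e$coords[sel@idx, , drop = FALSE] %*% solve(m)
  f <- f - floor(f)
  e$coords[sel@idx, ] <- f %*% m
  invisible(sel)
}
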