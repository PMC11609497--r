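#' A per-frame analysis task
#'
#' Bundles the user logic the frame-parallel driver runs on every frame with
#' the access kind it declares. Serial kinds may only run with one worker;
#' multi-worker runs require a parallel kind (`ImmutableParallel` for
#' read-only analysis, `MutableParallel` when per-frame code writes
#' coordinates).
#'
#' @slot setup `NULL` or `function(system)` returning a per-worker context,
#'   called once per worker on its private system replica.
#' @slot perFrame `function(ctx, frame, system)` returning the frame's
#'   partial result; `frame` is the 1-based frame index and `system` a
#'   [MolSystem-class] with that frame's coordinates loaded.
#' @slot kind one of [ACCESS_KINDS].
#' @export
setClass("FrameTask", representation(setup = "ANY", perFrame = "function",
                                     kind = "character"))

setValidity("FrameTask", function(object) {
  if (!(object@kind %in% ACCESS_KINDS)) return("invalid access kind")
  if (!is.null(object@setup) && !is.function(object@setup))
    return("setup must be NULL or a function")
  TRUE
})

#' @rdname FrameTask-class
#' @param perFrame,setup,kind see slots.
#' @export
frameTask <- function(perFrame, setup = NULL, kind = "ImmutableParallel") {
  new("FrameTask", setup = setup, perFrame = perFrame, kind = .checkKind(kind))
}

#' Frame-parallel trajectory analysis
#'
#' Runs `task@perFrame` exactly once per trajectory frame and returns the
#' partial results as a list in frame order, independent of worker count or
#' completion order. With `workers > 1` the frames are dealt round-robin to
#' a pool of forked workers; each worker gets its own [MolSystem-class]
#' replica (private coordinate buffer, shared-by-copy topology) and its own
#' reopened trajectory file handle, so no two workers ever touch one State.
#' Serial access kinds are pinned to the worker that created their system:
#' submitting a serial-kind task with more than one worker is rejected up
#' front.
#'
#' Because each frame's result depends only on that frame, a 1-worker and an
#' n-worker run produce element-wise identical result lists.
#'
#' @param reader a [TrajectoryReader-class].
#' @param system a [MolSystem-class] providing the topology (and reference
#'   state) the task runs against; replicated per worker with `task@kind`.
#' @param task a [FrameTask-class].
#' @param workers number of workers (>= 1).
#' @return list of per-frame results, one per frame, in frame order.
#' @export
analyzeTrajectory <- function(reader, system, task, workers = 1L) {
  workers <- as.integer(workers)
  if (workers < 1L) .stopUsage("workers must be >= 1")
  if (!is(task, "FrameTask")) .stopUsage("task must be a FrameTask")
  if (workers > 1L && .kindSerial(task@kind))
    .stopContract(sprintf("kind %s is not usable across workers", task@kind))
  n <- nFrames(reader)
  runChunk <- function(frames) {
    sys <- .replicateSystem(system, task@kind)
    ctx <- if (is.function(task@setup)) task@setup(sys) else NULL
    lapply(frames, function(i) {
      st <- readFrame(reader, i)
      .loadState(sys, st)
      tryCatch(list(frame = i, value = task@perFrame(ctx, i, sys)),
               error = function(e) list(frame = i, failed = conditionMessage(e)))
    })
  }
  chunks <- if (workers == 1L) list(seq_len(n))
            else split(seq_len(n), rep_len(seq_len(workers), n))
  raw <- if (workers == 1L) lapply(chunks, runChunk)
         else parallel::mclapply(chunks, runChunk, mc.cores = workers,
                                 mc.preschedule = FALSE)
  failedChunk <- vapply(raw, inherits, logical(1), what = "try-error")
  if (any(failedChunk))
    .stopData(sprintf("worker failed: %s", as.character(raw[[which(failedChunk)[1]]])))
  flat <- unlist(raw, recursive = FALSE, use.names = FALSE)
  bad <- vapply(flat, function(r) !is.null(r$failed), logical(1))
  if (any(bad)) {
    f <- flat[[which(bad)[1]]]
    .stopData(sprintf("analysis failed at frame %d: %s", f$frame, f$failed))
  }
  ord <- order(vapply(flat, function(r) r$frame, integer(1)))
  lapply(flat[ord], function(r) r$value)
}

#' Process disjoint fragments of a MutableParallel selection concurrently
#'
#' The within-frame counterpart of [analyzeTrajectory()]: fragments a
#' `MutableParallel` selection with [intoFragments()] (consuming the parent
#' and exchanging its registry claim for per-fragment claims) and applies
#' `fn` to every fragment, with `workers > 1` distributing fragments over
#' forked workers. Fragment disjointness — guaranteed by the used-index
#' registry — is what makes concurrent writes sound: coordinate edits made
#' by `fn` in a worker touch only that fragment's rows and are merged back
#' into the shared system afterwards. Fragment claims are released when the
#' call returns.
#'
#' @param sel a live [Selection-class] of kind `"MutableParallel"`.
#' @param key splitting key, as in [intoFragments()].
#' @param fn `function(fragment)` applied to each fragment; may modify the
#'   fragment's coordinates.
#' @param workers number of workers (>= 1).
#' @return list of `fn` results, one per fragment, in fragment order.
#' @export
processFragments <- function(sel, key, fn, workers = 1L) {
  workers <- as.integer(workers)
  if (workers < 1L) .stopUsage("workers must be >= 1")
  if (accessKind(sel) != "MutableParallel")
    .stopContract("processFragments requires a MutableParallel selection")
  frags <- intoFragments(sel, key)
  on.exit(for (f in frags) releaseSelection(f))
  if (workers == 1L) {
    lapply(frags, fn)
  } else {
    out <- parallel::mclapply(frags, function(f) {
      v <- fn(f)
      list(value = v, idx = f@idx, coords = f@system@data$coords[f@idx, , drop = FALSE])
    }, mc.cores = workers, mc.preschedule = FALSE)
    for (o in out) {
      if (inherits(o, "try-error")) .stopData(as.character(o))
      sel@system@data$coords[o$idx, ] <- o$coords
    }
    lapply(out, function(o) o$value)
  }
}
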