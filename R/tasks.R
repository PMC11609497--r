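# The three canonical trajectory tasks, built on the frame-parallel driver.
# Each writes a CSV with a reproducibility comment header (package version
# and task parameters; deliberately nothing run-dependent, so outputs are
# byte-identical across worker counts).

.taskHeader <- function(taskName, params) {
  c(sprintf("# molkit %s", taskName),
    sprintf("# package_version=%s",
            as.character(utils::packageVersion("molkit"))),
    sprintf("# %s", paste(names(params), unname(params), sep = "=",
                          collapse = " ")))
}

.fmtNum <- function(x) sprintf("%.10g", x)

.writeTaskCsv <- function(path, headerLines, df) {
  cols <- vapply(df, function(col) {
    if (is.numeric(col) && !is.integer(col)) .fmtNum(col) else as.character(col)
  }, character(nrow(df)))
  if (nrow(df) == 1L) cols <- matrix(cols, nrow = 1)
  body <- apply(cols, 1, paste, collapse = ",")
  writeLines(c(headerLines, paste(names(df), collapse = ","), body), path)
  invisible(path)
}

.refSystem <- function(refStructure) {
  ref <- readStructure(refStructure)
  makeSystem(ref$topology, ref$state, "ImmutableParallel")
}

#' Task: align to a reference and compute per-frame RMSD
#'
#' For every trajectory frame, the `fitExpr` atoms are superposed onto the
#' same atoms of the reference structure with a (by default mass-weighted)
#' Kabsch fit, the fitted transform is applied to the `measureExpr` atoms,
#' and their unweighted RMSD against the reference is recorded — the common
#' `gmx rms` semantics (fit selection and measure selection may differ,
#' defaulting to the same).
#'
#' @param traj trajectory path (`.dcd`, `.xyz`, `.pdb`).
#' @param refStructure reference structure path (`.pdb`, `.xyz`); also
#'   supplies the topology the selections are evaluated against.
#' @param fitExpr selection expression for the fit atoms.
#' @param outCsv optional CSV output path (columns frame, time_ps, rmsd_nm).
#' @param measureExpr selection expression for the measured atoms
#'   (default: the fit selection).
#' @param workers worker count for frame-parallel execution.
#' @param massWeighted logical: mass-weight the fit.
#' @return data.frame with columns frame, time_ps, rmsd_nm, invisibly when
#'   `outCsv` is given.
#' @export
taskRmsd <- function(traj, refStructure, fitExpr = "all", outCsv = NULL,
                     measureExpr = fitExpr, workers = 1L,
                     massWeighted = TRUE) {
  refSys <- .refSystem(refStructure)
  fitSel <- selectAtoms(refSys, fitExpr)
  measSel <- selectAtoms(refSys, measureExpr)
  fitIdx <- indices(fitSel); measIdx <- indices(measSel)
  refFit <- coords(fitSel); refMeas <- coords(measSel)
  w <- if (massWeighted) masses(fitSel) else NULL
  reader <- openTrajectory(traj)
  on.exit(closeReader(reader), add = TRUE)
  if (reader@h$natom != nAtoms(refSys))
    .stopData("trajectory and reference differ in atom count")
  task <- frameTask(kind = "ImmutableParallel", perFrame = function(ctx, i, sys) {
    x <- coords(sys)
    tr <- .kabschCore(x[fitIdx, , drop = FALSE], refFit, w)
    moved <- transformPoints(tr, x[measIdx, , drop = FALSE])
    c(time = frameTime(sys), rmsd = .rmsdCore(moved, refMeas))
  })
  res <- analyzeTrajectory(reader, refSys, task, workers)
  df <- data.frame(frame = seq_along(res),
                   time_ps = vapply(res, `[[`, numeric(1), "time"),
                   rmsd_nm = vapply(res, `[[`, numeric(1), "rmsd"))
  if (!is.null(outCsv)) {
    .writeTaskCsv(outCsv, .taskHeader("task_rmsd", c(
      traj = traj, ref = refStructure, fit = fitExpr, measure = measureExpr,
      mass_weighted = massWeighted)), df)
    return(invisible(df))
  }
  df
}

#' Task: per-frame center of mass of atoms within a cutoff of a selection
#'
#' For every frame, all atoms within `cutoff` nm (minimum-image when the
#' frame has a box) of any atom of the inner selection are collected with
#' the cell-list search, and their center of mass (periodic circular-mean
#' form when boxed) is recorded. The inner selection's own atoms are part
#' of the result set by default.
#'
#' A frame in which the search comes back empty (possible only with
#' `includeQuery = FALSE`) is recorded as an NA row and the run continues.
#'
#' @param traj trajectory path.
#' @param refStructure reference structure path supplying the topology.
#' @param innerExpr selection expression for the inner (query) atoms.
#' @param cutoff distance cutoff in nm (default 1.0).
#' @param outCsv optional CSV path (columns frame, time_ps, x_nm, y_nm,
#'   z_nm, n_atoms).
#' @param workers worker count.
#' @param includeQuery logical: include the inner atoms themselves.
#' @return data.frame, invisibly when `outCsv` is given.
#' @export
taskWithinCom <- function(traj, refStructure, innerExpr, cutoff = 1.0,
                          outCsv = NULL, workers = 1L, includeQuery = TRUE) {
  refSys <- .refSystem(refStructure)
  innerIdx <- indices(selectAtoms(refSys, innerExpr))
  allMass <- atoms(refSys)$mass
  reader <- openTrajectory(traj)
  on.exit(closeReader(reader), add = TRUE)
  if (reader@h$natom != nAtoms(refSys))
    .stopData("trajectory and reference differ in atom count")
  task <- frameTask(kind = "ImmutableParallel", perFrame = function(ctx, i, sys) {
    x <- coords(sys); b <- box(sys)
    hits <- searchWithin(x, innerIdx, cutoff, box = b,
                         includeQuery = includeQuery)
    if (length(hits) == 0L)
      return(c(time = frameTime(sys), x = NA, y = NA, z = NA, n = 0))
    com <- .comRaw(x[hits, , drop = FALSE], allMass[hits], b, pbc = !is.null(b))
    c(time = frameTime(sys), x = com[1], y = com[2], z = com[3],
      n = length(hits))
  })
  res <- analyzeTrajectory(reader, refSys, task, workers)
  m <- do.call(rbind, res)
  df <- data.frame(frame = seq_along(res), time_ps = m[, 1],
                   x_nm = m[, 2], y_nm = m[, 3], z_nm = m[, 4],
                   n_atoms = as.integer(m[, 5]))
  if (!is.null(outCsv)) {
    .writeTaskCsv(outCsv, .taskHeader("task_within_com", c(
      traj = traj, ref = refStructure, inner = innerExpr, cutoff_nm = cutoff,
      include_query = includeQuery)), df)
    return(invisible(df))
  }
  df
}

#' Task: extract a selection into a new trajectory
#'
#' Reads the input trajectory and writes a new one containing only the
#' selected atoms, frame for frame, in the original relative atom order.
#'
#' @param traj input trajectory path.
#' @param expr selection expression, evaluated against the reference
#'   structure (must match at least one atom).
#' @param refStructure reference structure path supplying the topology.
#' @param outTraj output trajectory path (`.dcd` or `.xyz`).
#' @param workers worker count for the read/subset stage (frames are always
#'   written sequentially in order).
#' @return number of frames written, invisibly.
#' @export
taskExtract <- function(traj, expr, refStructure, outTraj, workers = 1L) {
  refSys <- .refSystem(refStructure)
  sel <- selectAtoms(refSys, expr)
  idx <- indices(sel)
  el <- atoms(sel)$element
  reader <- openTrajectory(traj)
  on.exit(closeReader(reader), add = TRUE)
  if (reader@h$natom != nAtoms(refSys))
    .stopData("trajectory and reference differ in atom count")
  task <- frameTask(kind = "ImmutableParallel", perFrame = function(ctx, i, sys) {
    list(xyz = coords(sys)[idx, , drop = FALSE], box = box(sys),
         time = frameTime(sys))
  })
  res <- analyzeTrajectory(reader, refSys, task, workers)
  withBox <- .fileFormat(outTraj) == "dcd" && !is.null(res[[1]]$box)
  wr <- openTrajectoryWriter(outTraj, length(idx), dt = reader@h$dt %||% 1,
                             withBox = withBox, elements = el)
  for (r in res)
    writeFrame(wr, r$xyz, boxObj = if (withBox) r$box else NULL, time = r$time)
  invisible(closeWriter(wr))
}
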