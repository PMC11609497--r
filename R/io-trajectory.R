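# Trajectory I/O with a uniform random-access reader contract.
#
# DCD: CHARMM dialect — 84-byte "CORD" header block, optional unit-cell
# record per frame, coordinates as 32-bit floats in Angstrom. Byte order is
# auto-detected from the leading record marker. Fixed-atom files are not
# supported. Frames are addressed by absolute byte offset, so readFrame(i)
# is O(1) for any i regardless of prior reads, and a reader inherited by a
# forked worker transparently reopens its own file handle.
#
# XYZ and multi-model PDB trajectories are text formats: all lines are read
# at open and frames are parsed on demand.

#' Trajectory readers
#'
#' Virtual parent of the DCD/XYZ/PDB trajectory readers returned by
#' [openTrajectory()]. All readers honor the random-access contract:
#' `readFrame(reader, i)` succeeds for any valid `i` in any order, always
#' returning the same frame for the same index, with coordinates in nm.
#'
#' @slot path source file path.
#' @slot h internal environment (frame index, offsets, connection).
#' @export
setClass("TrajectoryReader",
         representation("VIRTUAL", path = "character", h = "environment"))

#' @rdname TrajectoryReader-class
#' @export
setClass("DCDReader", contains = "TrajectoryReader")
#' @rdname TrajectoryReader-class
#' @export
setClass("XYZTrajReader", contains = "TrajectoryReader")
#' @rdname TrajectoryReader-class
#' @export
setClass("PDBTrajReader", contains = "TrajectoryReader")

#' Number of frames in a trajectory
#' @param reader a [TrajectoryReader-class].
#' @return integer frame count.
#' @export
setGeneric("nFrames", function(reader) standardGeneric("nFrames"))
setMethod("nFrames", "TrajectoryReader", function(reader) reader@h$nFrames)

#' Read one trajectory frame
#'
#' @param reader a [TrajectoryReader-class].
#' @param i frame index, 1-based, `1 <= i <= nFrames(reader)`.
#' @return a [State-class]; time is taken from the file header (`(i-1) * dt`)
#'   when available, else `i - 1`.
#' @export
setGeneric("readFrame", function(reader, i) standardGeneric("readFrame"))

#' Close a trajectory reader's file handle
#'
#' Readers reopen their file on demand, so closing is optional but polite.
#' @param reader a [TrajectoryReader-class].
#' @export
closeReader <- function(reader) {
  h <- reader@h
  if (!is.null(h$con)) { try(close(h$con), silent = TRUE); h$con <- NULL }
  invisible(TRUE)
}

.checkFrameIndex <- function(reader, i) {
  i <- as.integer(i)
  if (length(i) != 1L || is.na(i) || i < 1L || i > reader@h$nFrames)
    .stopUsage(sprintf("frame index %s out of range (1..%d)",
                       as.character(i), reader@h$nFrames))
  i
}

# per-process binary connection (fork-safe: a child inherits h but its pid
# differs, so it opens its own handle and its own seek offsets)
.binCon <- function(reader) {
  h <- reader@h
  if (is.null(h$con) || h$pid != Sys.getpid() || !isOpen(h$con)) {
    h$con <- file(reader@path, "rb")
    h$pid <- Sys.getpid()
  }
  h$con
}

setMethod("show", "TrajectoryReader", function(object) {
  cat(sprintf("%s: '%s', %d frames, %d atoms\n", class(object), object@path,
              object@h$nFrames, object@h$natom))
})

## ---- DCD reading ---------------------------------------------------------

.dcdOpen <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  raw4 <- readBin(con, "raw", 4)
  if (length(raw4) < 4) .stopData(sprintf("'%s': truncated DCD file", path))
  endian <- NULL
  for (e in c("little", "big"))
    if (readBin(raw4, "integer", 1, 4, endian = e) == 84L) endian <- e
  if (is.null(endian))
    .stopData(sprintf("'%s': not a DCD file (bad leading record marker)", path))
  magic <- rawToChar(readBin(con, "raw", 4))
  if (magic != "CORD")
    .stopData(sprintf("'%s': not a DCD file (magic '%s')", path, magic))
  icraw <- readBin(con, "raw", 80)
  ic <- readBin(icraw, "integer", 20, 4, endian = endian)
  if (readBin(con, "integer", 1, 4, endian = endian) != 84L)
    .stopData(sprintf("'%s': corrupt DCD header record", path))
  charmm <- ic[20] != 0L
  if (ic[9] != 0L)
    .stopData(sprintf("'%s': DCD files with fixed atoms are not supported", path))
  dt <- if (charmm) {
    readBin(icraw[37:40], "numeric", 1, 4, endian = endian)
  } else {
    1.0
  }
  hasCell <- charmm && ic[11] != 0L
  # title block
  m1 <- readBin(con, "integer", 1, 4, endian = endian)
  ntitle <- readBin(con, "integer", 1, 4, endian = endian)
  readBin(con, "raw", 80 * ntitle)
  readBin(con, "integer", 1, 4, endian = endian)
  # natom block
  readBin(con, "integer", 1, 4, endian = endian)
  natom <- readBin(con, "integer", 1, 4, endian = endian)
  readBin(con, "integer", 1, 4, endian = endian)
  firstOffset <- seek(con, NA)
  frameSize <- (if (hasCell) 8 + 48 else 0) + 3 * (8 + 4 * natom)
  fileSize <- file.size(path)
  nAvail <- (fileSize - firstOffset) %/% frameSize
  nFrames <- ic[1]
  if (nFrames <= 0L || nFrames > nAvail) nFrames <- as.integer(nAvail)
  if (nFrames < 1L) .stopData(sprintf("'%s': DCD file contains no frames", path))
  h <- new.env(parent = emptyenv())
  h$endian <- endian; h$natom <- natom; h$hasCell <- hasCell
  h$dt <- dt; h$firstOffset <- firstOffset; h$frameSize <- frameSize
  h$nFrames <- as.integer(nFrames); h$con <- NULL; h$pid <- -1L
  new("DCDReader", path = path, h = h)
}

.dcdCellToBox <- function(v) {
  if (all(v == 0)) return(NULL)
  lens <- v[c(1, 3, 6)]
  angv <- v[c(5, 4, 2)]            # alpha, beta, gamma
  ang <- ifelse(abs(angv) <= 1, acos(angv) * 180 / pi, angv)
  if (any(lens <= 0)) return(NULL)
  boxFromLengthsAngles(lens[1] / 10, lens[2] / 10, lens[3] / 10,
                       ang[1], ang[2], ang[3])
}

#' @rdname readFrame
setMethod("readFrame", "DCDReader", function(reader, i) {
  i <- .checkFrameIndex(reader, i)
  h <- reader@h
  con <- .binCon(reader)
  seek(con, h$firstOffset + (i - 1) * h$frameSize)
  e <- h$endian
  boxObj <- NULL
  if (h$hasCell) {
    if (readBin(con, "integer", 1, 4, endian = e) != 48L)
      .stopData("corrupt DCD frame: bad unit-cell record marker")
    cell <- readBin(con, "numeric", 6, 8, endian = e)
    readBin(con, "integer", 1, 4, endian = e)
    boxObj <- .dcdCellToBox(cell)
  }
  xyz <- matrix(0, h$natom, 3)
  for (ax in 1:3) {
    if (readBin(con, "integer", 1, 4, endian = e) != 4L * h$natom)
      .stopData("corrupt DCD frame: bad coordinate record marker")
    xyz[, ax] <- readBin(con, "numeric", h$natom, 4, endian = e)
    readBin(con, "integer", 1, 4, endian = e)
  }
  state(xyz / 10, box = boxObj, time = (i - 1) * h$dt, step = i - 1L)
})

## ---- XYZ / PDB trajectory reading ---------------------------------------

.xyzTrajOpen <- function(path) {
  con <- .openText(path)
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  starts <- integer(0)
  counts <- integer(0)
  pos <- 1L
  while (pos <= length(lines)) {
    if (!nzchar(trimws(lines[pos])) && pos == length(lines)) break
    n <- suppressWarnings(as.integer(trimws(lines[pos])))
    if (is.na(n) || n < 1L)
      .stopData(sprintf("XYZ parse error at line %d: bad atom count", pos))
    if (pos + 1L + n > length(lines))
      .stopData(sprintf("XYZ parse error: truncated frame at line %d", pos))
    starts <- c(starts, pos); counts <- c(counts, n)
    pos <- pos + n + 2L
  }
  if (length(starts) == 0L) .stopData(sprintf("'%s': no XYZ frames", path))
  if (length(unique(counts)) != 1L)
    .stopData(sprintf("'%s': frames differ in atom count", path))
  h <- new.env(parent = emptyenv())
  h$lines <- lines; h$starts <- starts; h$natom <- counts[1]
  h$nFrames <- length(starts)
  new("XYZTrajReader", path = path, h = h)
}

#' @rdname readFrame
setMethod("readFrame", "XYZTrajReader", function(reader, i) {
  i <- .checkFrameIndex(reader, i)
  h <- reader@h
  s <- h$starts[i]
  p <- .parseXyzBlock(h$lines[(s + 2L):(s + 1L + h$natom)], offset = s + 1L)
  state(p$xyzA / 10, time = i - 1, step = i - 1L)
})

.pdbTrajOpen <- function(path) {
  con <- .openText(path)
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  rec <- substr(lines, 1, 6)
  boxObj <- NULL
  ci <- which(rec == "CRYST1")
  if (length(ci)) boxObj <- .parseCryst1(lines[ci[1]])
  models <- which(trimws(rec) == "MODEL")
  h <- new.env(parent = emptyenv())
  h$lines <- lines; h$box <- boxObj
  atomRec <- rec %in% c("ATOM  ", "HETATM")
  if (length(models) == 0L) {
    h$frames <- list(which(atomRec))
  } else {
    ends <- which(trimws(rec) == "ENDMDL")
    if (length(ends) < length(models))
      ends <- c(ends, length(lines))
    h$frames <- lapply(seq_along(models), function(k) {
      rng <- seq(models[k], ends[k])
      rng[atomRec[rng]]
    })
  }
  counts <- lengths(h$frames)
  if (any(counts == 0L)) .stopData(sprintf("'%s': model without atoms", path))
  if (length(unique(counts)) != 1L)
    .stopData(sprintf("'%s': models differ in atom count", path))
  h$natom <- counts[1]
  h$nFrames <- length(h$frames)
  new("PDBTrajReader", path = path, h = h)
}

#' @rdname readFrame
setMethod("readFrame", "PDBTrajReader", function(reader, i) {
  i <- .checkFrameIndex(reader, i)
  h <- reader@h
  idx <- h$frames[[i]]
  p <- .parsePdbAtoms(h$lines[idx], idx)
  state(p$xyzA / 10, box = h$box, time = i - 1, step = i - 1L)
})

#' Open a trajectory for reading
#'
#' Supported formats: DCD (CHARMM dialect, random access by byte offset),
#' multi-frame XYZ, and multi-model PDB (each MODEL is a frame).
#'
#' @param path trajectory file path (`.dcd`, `.xyz`, `.pdb`).
#' @return a [TrajectoryReader-class].
#' @export
openTrajectory <- function(path) {
  if (!file.exists(path)) .stopData(sprintf("file not found: '%s'", path))
  switch(.fileFormat(path),
         dcd = .dcdOpen(path),
         xyz = .xyzTrajOpen(path),
         pdb = .pdbTrajOpen(path),
         .stopData(sprintf("unsupported trajectory format: '%s'", path)))
}

## ---- trajectory writing --------------------------------------------------

#' Trajectory writers
#'
#' Created by [openTrajectoryWriter()]; frames are appended in call order by
#' [writeFrame()] and [closeWriter()] flushes a consistent file (for DCD it
#' also patches the frame count in the header).
#'
#' @slot path output file path.
#' @slot h internal environment (connection, frame counter).
#' @export
setClass("TrajectoryWriter",
         representation("VIRTUAL", path = "character", h = "environment"))
#' @rdname TrajectoryWriter-class
#' @export
setClass("DCDWriter", contains = "TrajectoryWriter")
#' @rdname TrajectoryWriter-class
#' @export
setClass("XYZTrajWriter", contains = "TrajectoryWriter")

#' Open a trajectory for writing
#'
#' @param path output path (`.dcd` or `.xyz`).
#' @param nAtoms number of atoms per frame.
#' @param dt frame time spacing in ps (stored in the DCD header).
#' @param withBox logical: will frames carry a periodic box? (DCD decides
#'   its per-frame record layout up front.)
#' @param elements character vector of element symbols, used for the XYZ
#'   atom column (defaults to "C").
#' @return a [TrajectoryWriter-class].
#' @export
openTrajectoryWriter <- function(path, nAtoms, dt = 1, withBox = FALSE,
                                 elements = NULL) {
  nAtoms <- as.integer(nAtoms)
  if (nAtoms < 1L) .stopUsage("openTrajectoryWriter: need at least one atom")
  fmt <- .fileFormat(path)
  if (fmt == "dcd") .dcdWriterOpen(path, nAtoms, dt, withBox)
  else if (fmt == "xyz") {
    h <- new.env(parent = emptyenv())
    h$con <- file(path, "wt"); h$n <- 0L; h$natom <- nAtoms
    h$elements <- if (is.null(elements)) rep("C", nAtoms) else as.character(elements)
    new("XYZTrajWriter", path = path, h = h)
  } else .stopData(sprintf("unsupported trajectory output format: '%s'", path))
}

.dcdWriterOpen <- function(path, nAtoms, dt, withBox) {
  con <- file(path, "wb")
  ic <- integer(20)
  ic[2] <- 0L; ic[3] <- 1L           # first step, save interval
  ic[11] <- if (withBox) 1L else 0L  # unit-cell flag
  ic[20] <- 24L                      # CHARMM version marker
  writeBin(84L, con, 4)
  writeBin(charToRaw("CORD"), con)
  icraw <- writeBin(ic, raw(), 4)
  icraw[37:40] <- writeBin(as.numeric(dt), raw(), 4)  # delta as float32
  writeBin(icraw, con)
  writeBin(84L, con, 4)
  title <- sprintf("%-80s", "written by molkit")
  writeBin(4L + 80L, con, 4)     # title record: ntitle + one 80-char line
  writeBin(1L, con, 4)
  writeBin(charToRaw(title), con)
  writeBin(4L + 80L, con, 4)
  writeBin(4L, con, 4); writeBin(nAtoms, con, 4); writeBin(4L, con, 4)
  h <- new.env(parent = emptyenv())
  h$con <- con; h$n <- 0L; h$natom <- nAtoms; h$withBox <- withBox
  new("DCDWriter", path = path, h = h)
}

#' Append one frame to a trajectory writer
#'
#' @param writer a [TrajectoryWriter-class].
#' @param xyz N x 3 coordinate matrix in nm.
#' @param boxObj optional [PeriodicBox-class] (DCD only, and only when the
#'   writer was opened with `withBox = TRUE`).
#' @param time frame time in ps (XYZ comment line only).
#' @return the writer, invisibly.
#' @export
writeFrame <- function(writer, xyz, boxObj = NULL, time = NULL) {
  xyz <- as.matrix(xyz)
  h <- writer@h
  if (nrow(xyz) != h$natom)
    .stopData(sprintf("writeFrame: expected %d atoms, got %d", h$natom, nrow(xyz)))
  if (is(writer, "DCDWriter")) {
    con <- h$con
    if (h$withBox) {
      la <- if (is.null(boxObj)) c(a = 0, b = 0, c = 0, alpha = 90, beta = 90, gamma = 90)
            else boxLengthsAngles(boxObj)
      writeBin(48L, con, 4)
      writeBin(as.numeric(c(la["a"] * 10, la["gamma"], la["b"] * 10,
                            la["beta"], la["alpha"], la["c"] * 10)), con, 8)
      writeBin(48L, con, 4)
    } else if (!is.null(boxObj)) {
      .stopUsage("writeFrame: writer was opened with withBox = FALSE")
    }
    xyzA <- xyz * 10
    for (ax in 1:3) {
      writeBin(4L * h$natom, con, 4)
      writeBin(as.numeric(xyzA[, ax]), con, 4)
      writeBin(4L * h$natom, con, 4)
    }
  } else {
    writeLines(as.character(h$natom), h$con)
    writeLines(sprintf("frame %d t= %.4f", h$n, if (is.null(time)) h$n else time), h$con)
    xyzA <- xyz * 10
    writeLines(sprintf("%-4s %12.4f %12.4f %12.4f",
                       h$elements, xyzA[, 1], xyzA[, 2], xyzA[, 3]), h$con)
  }
  h$n <- h$n + 1L
  invisible(writer)
}

#' Finish writing a trajectory
#'
#' Flushes buffers and closes the file; for DCD the frame count fields of
#' the header are patched to the number of frames actually written.
#'
#' @param writer a [TrajectoryWriter-class].
#' @return number of frames written, invisibly.
#' @export
closeWriter <- function(writer) {
  h <- writer@h
  if (is(writer, "DCDWriter")) {
    # icntrl[1] (frame count) sits at byte 8, icntrl[4] (total steps) at 20
    seek(h$con, 8, rw = "write")
    writeBin(h$n, h$con, 4)
    seek(h$con, 20, rw = "write")
    writeBin(h$n, h$con, 4)
  }
  close(h$con)
  invisible(h$n)
}
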