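# Structure file I/O: fixed-column PDB (v3.3 ATOM/HETATM/CRYST1/MODEL) and
# XYZ. File values are Angstrom; everything is converted to nm on read and
# back on write. Text formats are transparently gzip-compressed when the
# path ends in ".gz".

.openText <- function(path, mode = "rt") {
  if (grepl("\\.gz$", path)) gzfile(path, mode) else file(path, mode)
}

.fileFormat <- function(path) {
  p <- sub("\\.gz$", "", tolower(path))
  tools::file_ext(p)
}

.substrTrim <- function(x, a, b) trimws(substr(x, a, b))

.numField <- function(x, a, b, what, lineNo) {
  v <- suppressWarnings(as.numeric(.substrTrim(x, a, b)))
  bad <- which(is.na(v))
  if (length(bad))
    .stopData(sprintf("PDB parse error at line %d: %s field is not a number",
                      lineNo[bad[1]], what))
  v
}

# Parse ATOM/HETATM records (fixed columns) into an atom table + Angstrom
# coordinates. `lineNo` carries original line numbers for error messages.
.parsePdbAtoms <- function(lines, lineNo) {
  name <- .substrTrim(lines, 13, 16)
  resname <- .substrTrim(lines, 18, 20)
  chain <- substr(lines, 22, 22)
  resid <- suppressWarnings(as.integer(.substrTrim(lines, 23, 26)))
  bad <- which(is.na(resid))
  if (length(bad))
    .stopData(sprintf("PDB parse error at line %d: residue number is not an integer",
                      lineNo[bad[1]]))
  x <- .numField(lines, 31, 38, "x coordinate", lineNo)
  y <- .numField(lines, 39, 46, "y coordinate", lineNo)
  z <- .numField(lines, 47, 54, "z coordinate", lineNo)
  occ <- suppressWarnings(as.numeric(.substrTrim(lines, 55, 60)))
  beta <- suppressWarnings(as.numeric(.substrTrim(lines, 61, 66)))
  occ[is.na(occ)] <- 1; beta[is.na(beta)] <- 0
  element <- toupper(.substrTrim(lines, 77, 78))
  atomsDf <- data.frame(name = name, resname = resname, resid = resid,
                        chain = chain, element = element,
                        occupancy = occ, beta = beta,
                        stringsAsFactors = FALSE)
  list(atoms = atomsDf, xyzA = cbind(x, y, z))
}

.parseCryst1 <- function(line) {
  a <- suppressWarnings(as.numeric(.substrTrim(line, 7, 15)))
  b <- suppressWarnings(as.numeric(.substrTrim(line, 16, 24)))
  c <- suppressWarnings(as.numeric(.substrTrim(line, 25, 33)))
  al <- suppressWarnings(as.numeric(.substrTrim(line, 34, 40)))
  be <- suppressWarnings(as.numeric(.substrTrim(line, 41, 47)))
  ga <- suppressWarnings(as.numeric(.substrTrim(line, 48, 54)))
  if (anyNA(c(a, b, c, al, be, ga)) || a <= 0 || b <= 0 || c <= 0) return(NULL)
  boxFromLengthsAngles(a / 10, b / 10, c / 10, al, be, ga)
}

.readPdbStructure <- function(path) {
  con <- .openText(path)
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  rec <- substr(lines, 1, 6)
  boxObj <- NULL
  ci <- which(rec == "CRYST1")
  if (length(ci)) boxObj <- .parseCryst1(lines[ci[1]])
  # first model only when MODEL records are present
  end <- which(trimws(rec) %in% c("ENDMDL", "END"))
  last <- if (length(end)) end[1] - 1L else length(lines)
  sel <- which(rec %in% c("ATOM  ", "HETATM") & seq_along(lines) <= last)
  if (length(sel) == 0L) .stopData(sprintf("no ATOM/HETATM records in '%s'", path))
  p <- .parsePdbAtoms(lines[sel], sel)
  top <- topology(p$atoms)
  st <- state(p$xyzA / 10, box = boxObj)
  list(topology = top, state = st)
}

.readXyzStructure <- function(path) {
  con <- .openText(path)
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  if (length(lines) < 3L) .stopData(sprintf("'%s': not an XYZ file", path))
  n <- suppressWarnings(as.integer(trimws(lines[1])))
  if (is.na(n) || n < 1L)
    .stopData(sprintf("XYZ parse error at line 1: bad atom count"))
  if (length(lines) < n + 2L)
    .stopData(sprintf("XYZ parse error: expected %d atom lines", n))
  p <- .parseXyzBlock(lines[3:(n + 2L)], offset = 2L)
  top <- topology(data.frame(name = p$el, resname = "MOL", resid = 1L,
                             chain = "A", element = p$el,
                             stringsAsFactors = FALSE))
  list(topology = top, state = state(p$xyzA / 10))
}

.parseXyzBlock <- function(lines, offset = 0L) {
  parts <- strsplit(trimws(lines), "[ \t]+")
  len <- lengths(parts)
  bad <- which(len < 4L)
  if (length(bad))
    .stopData(sprintf("XYZ parse error at line %d: expected 'element x y z'",
                      bad[1] + offset))
  m <- matrix(unlist(lapply(parts, `[`, 1:4)), ncol = 4, byrow = TRUE)
  xyz <- suppressWarnings(matrix(as.numeric(m[, 2:4]), ncol = 3))
  bad <- which(apply(is.na(xyz), 1, any))
  if (length(bad))
    .stopData(sprintf("XYZ parse error at line %d: coordinate is not a number",
                      bad[1] + offset))
  list(el = toupper(m[, 1]), xyzA = xyz)
}

#' Read a molecular structure file
#'
#' Reads a PDB (fixed-column ATOM/HETATM, CRYST1 becomes the periodic box,
#' first model of a multi-model file) or XYZ file. Coordinates are converted
#' from Angstrom to nm. Blank atom/residue name fields become `"X"`;
#' elements are taken from the element column when present and otherwise
#' inferred from the atom name; masses are assigned from the bundled element
#' table.
#'
#' @param path file path (`.pdb`, `.xyz`, optionally `.gz`-compressed).
#' @return list with components `topology` ([Topology-class]) and `state`
#'   ([State-class]).
#' @export
readStructure <- function(path) {
  if (!file.exists(path)) .stopData(sprintf("file not found: '%s'", path))
  switch(.fileFormat(path),
         pdb = .readPdbStructure(path),
         xyz = .readXyzStructure(path),
         .stopData(sprintf("unsupported structure format: '%s'", path)))
}

.formatPdbLines <- function(atomsDf, xyzA, serials) {
  name <- atomsDf$name
  # PDB convention: names up to 3 characters start in column 14
  name <- ifelse(nchar(name) <= 3, paste0(" ", name), name)
  occ <- if (!is.null(atomsDf$occupancy)) atomsDf$occupancy else rep(1, nrow(atomsDf))
  beta <- if (!is.null(atomsDf$beta)) atomsDf$beta else rep(0, nrow(atomsDf))
  el <- atomsDf$element
  # columns: serial 7-11, name 13-16, altLoc 17, resname 18-20, chain 22,
  # resid 23-26, x/y/z 31-54, occupancy 55-60, beta 61-66, element 77-78
  sprintf("ATOM  %5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serials %% 100000L, substr(name, 1, 4),
          substr(atomsDf$resname, 1, 3), substr(atomsDf$chain, 1, 1),
          atomsDf$resid %% 10000L, xyzA[, 1], xyzA[, 2], xyzA[, 3],
          occ, beta, substr(el, 1, 2))
}

.cryst1Line <- function(boxObj) {
  la <- boxLengthsAngles(boxObj)
  sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1",
          la["a"] * 10, la["b"] * 10, la["c"] * 10,
          la["alpha"], la["beta"], la["gamma"])
}

#' Write a selection to a structure file
#'
#' Writes the selected atoms to a PDB or XYZ file. PDB serial numbers are
#' renumbered from 1; residue ids, names and chains are preserved verbatim;
#' nm coordinates are converted back to Angstrom.
#'
#' @param path output path (`.pdb` or `.xyz`, optionally `.gz`).
#' @param sel a readable [Selection-class].
#' @return the path, invisibly.
#' @export
writeStructure <- function(path, sel) {
  a <- atoms(sel)
  xyzA <- coords(sel) * 10
  fmt <- .fileFormat(path)
  con <- .openText(path, "wt")
  on.exit(close(con))
  if (fmt == "pdb") {
    b <- box(sel)
    if (!is.null(b)) writeLines(.cryst1Line(b), con)
    writeLines(.formatPdbLines(a, xyzA, seq_len(nrow(a))), con)
    writeLines("END", con)
  } else if (fmt == "xyz") {
    writeLines(as.character(nrow(a)), con)
    writeLines("written by molkit", con)
    writeLines(sprintf("%-4s %12.4f %12.4f %12.4f",
                       a$element, xyzA[, 1], xyzA[, 2], xyzA[, 3]), con)
  } else {
    .stopData(sprintf("unsupported structure format: '%s'", path))
  }
  invisible(path)
}
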