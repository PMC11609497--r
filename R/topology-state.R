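#' Topology: time-independent atom identities
#'
#' Atom identities (name, residue name and id, chain, mass, charge, element)
#' plus an optional bond list. The atom table is a data.frame with one row
#' per atom; bonds are a two-column integer matrix of 1-based atom indices.
#'
#' @slot atoms data.frame with columns name, resname, resid, chain, mass,
#'   charge, element (additional columns such as occupancy/beta are carried
#'   through untouched).
#' @slot bonds integer matrix with two columns; may have zero rows.
#' @export
setClass("Topology", representation(atoms = "data.frame", bonds = "matrix"))

.ATOM_COLS <- c("name", "resname", "resid", "chain", "mass", "charge", "element")

# Fill in defaults and enforce the blank-field policy (blank names become "X").
.canonicalAtoms <- function(atoms) {
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  n <- nrow(atoms)
  if (is.null(atoms$name)) atoms$name <- rep("X", n)
  if (is.null(atoms$resname)) atoms$resname <- rep("X", n)
  if (is.null(atoms$resid)) atoms$resid <- seq_len(n)
  if (is.null(atoms$chain)) atoms$chain <- rep("A", n)
  atoms$name <- trimws(as.character(atoms$name))
  atoms$resname <- trimws(as.character(atoms$resname))
  atoms$name[atoms$name == ""] <- "X"
  atoms$resname[atoms$resname == ""] <- "X"
  atoms$chain <- substr(as.character(atoms$chain), 1L, 1L)
  atoms$chain[is.na(atoms$chain) | atoms$chain == ""] <- "A"
  atoms$resid <- as.integer(atoms$resid)
  if (is.null(atoms$element)) atoms$element <- .inferElement(atoms$name, atoms$resname)
  blank <- is.na(atoms$element) | trimws(atoms$element) == ""
  if (any(blank))
    atoms$element[blank] <- .inferElement(atoms$name[blank], atoms$resname[blank])
  atoms$element <- toupper(trimws(atoms$element))
  if (is.null(atoms$mass)) atoms$mass <- atomicMass(atoms$element)
  nm <- is.na(atoms$mass)
  if (any(nm)) atoms$mass[nm] <- atomicMass(atoms$element[nm])
  atoms$mass <- as.numeric(atoms$mass)
  if (is.null(atoms$charge)) atoms$charge <- rep(0, n)
  atoms$charge <- as.numeric(atoms$charge)
  extra <- setdiff(names(atoms), .ATOM_COLS)
  atoms[, c(.ATOM_COLS, extra), drop = FALSE]
}

setValidity("Topology", function(object) {
  a <- object@atoms
  n <- nrow(a)
  if (!all(.ATOM_COLS %in% names(a)))
    return(paste("atoms must have columns", paste(.ATOM_COLS, collapse = ", ")))
  if (any(a$name == "" | a$resname == "")) return("blank atom/residue names")
  if (any(a$mass < 0)) return("negative mass")
  b <- object@bonds
  if (ncol(b) != 2L) return("bonds must have two columns")
  if (nrow(b) > 0) {
    if (any(b < 1L) || any(b > n)) return("bond index out of range")
    if (any(b[, 1] == b[, 2])) return("self-bond")
  }
  TRUE
})

#' Construct a Topology
#'
#' @param atoms data.frame of per-atom fields; missing columns get defaults
#'   (blank names become "X", elements are inferred from atom names, masses
#'   come from the element table).
#' @param bonds optional two-column matrix of 1-based atom index pairs.
#' @return a [Topology-class].
#' @export
topology <- function(atoms, bonds = NULL) {
  atoms <- .canonicalAtoms(atoms)
  if (is.null(bonds)) bonds <- matrix(integer(0), ncol = 2)
  bonds <- matrix(as.integer(bonds), ncol = 2)
  new("Topology", atoms = atoms, bonds = bonds)
}

#' State: one trajectory frame
#'
#' Coordinates (nm), an optional periodic box, time (ps) and step number.
#' Velocities and forces are optional passthrough slots; no operation in
#' this package computes with them.
#'
#' @slot coords N x 3 numeric matrix (nm).
#' @slot box a [PeriodicBox-class] or NULL.
#' @slot time numeric scalar (ps).
#' @slot step integer scalar.
#' @slot velocities,forces N x 3 matrix or NULL.
#' @export
setClass("State", representation(coords = "matrix", box = "ANY",
                                 time = "numeric", step = "integer",
                                 velocities = "ANY", forces = "ANY"))

setValidity("State", function(object) {
  x <- object@coords
  if (!is.numeric(x) || ncol(x) != 3L) return("coords must be an N x 3 numeric matrix")
  if (any(!is.finite(x))) return("coords must be finite")
  if (!is.null(object@box) && !is(object@box, "PeriodicBox"))
    return("box must be a PeriodicBox or NULL")
  for (s in c("velocities", "forces")) {
    v <- slot(object, s)
    if (!is.null(v) && (!is.numeric(v) || !identical(dim(v), dim(x))))
      return(sprintf("%s must be NULL or an N x 3 matrix", s))
  }
  TRUE
})

#' Construct a State
#'
#' @param coords N x 3 numeric matrix of positions in nm.
#' @param box optional [PeriodicBox-class].
#' @param time time in ps.
#' @param step MD step number.
#' @param velocities,forces optional N x 3 matrices (passthrough only).
#' @return a [State-class].
#' @export
state <- function(coords, box = NULL, time = 0, step = 0L,
                  velocities = NULL, forces = NULL) {
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  dimnames(coords) <- NULL
  new("State", coords = coords, box = box, time = as.numeric(time),
      step = as.integer(step), velocities = velocities, forces = forces)
}

#' Number of atoms
#' @param x a Topology, State, MolSystem or Selection.
#' @export
setGeneric("nAtoms", function(x) standardGeneric("nAtoms"))

#' @rdname nAtoms
setMethod("nAtoms", "Topology", function(x) nrow(x@atoms))
#' @rdname nAtoms
setMethod("nAtoms", "State", function(x) nrow(x@coords))

#' Atom table accessor
#' @param x a Topology, MolSystem or Selection.
#' @return data.frame of per-atom fields.
#' @export
setGeneric("atoms", function(x) standardGeneric("atoms"))
#' @rdname atoms
setMethod("atoms", "Topology", function(x) x@atoms)

#' Bond list accessor
#' @param x a Topology or MolSystem.
#' @return two-column integer matrix of 1-based atom indices.
#' @export
setGeneric("bonds", function(x) standardGeneric("bonds"))
#' @rdname bonds
setMethod("bonds", "Topology", function(x) x@bonds)

#' Coordinate accessor
#' @param x a State, MolSystem or Selection.
#' @return numeric matrix of positions (nm).
#' @export
setGeneric("coords", function(x) standardGeneric("coords"))
#' @rdname coords
setMethod("coords", "State", function(x) x@coords)

#' Periodic box accessor
#' @param x a State, MolSystem or Selection.
#' @return a [PeriodicBox-class] or NULL.
#' @export
setGeneric("box", function(x) standardGeneric("box"))
#' @rdname box
setMethod("box", "State", function(x) x@box)

setMethod("show", "Topology", function(object) {
  a <- object@atoms
  cat(sprintf("Topology: %d atoms, %d residues, %d chains, %d bonds\n",
              nrow(a), length(unique(paste(a$chain, a$resid))),
              length(unique(a$chain)), nrow(object@bonds)))
})

setMethod("show", "State", function(object) {
  cat(sprintf("State: %d atoms, t=%.3f ps, step %d, box: %s\n",
              nrow(object@coords), object@time, object@step,
              if (is.null(object@box)) "none" else "present"))
})
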