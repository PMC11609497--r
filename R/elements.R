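# Element data: atomic masses (amu) and Bondi van-der-Waals radii (nm).
# PDB and XYZ carry no masses, so center-of-mass work needs this table.

.MASS_TABLE <- c(
  H = 1.008, D = 2.014, C = 12.011, N = 14.007, O = 15.999, F = 18.998,
  NA. = 22.990, MG = 24.305, P = 30.974, S = 32.06, CL = 35.45,
  K = 39.098, CA = 40.078, MN = 54.938, FE = 55.845, CU = 63.546,
  ZN = 65.38, SE = 78.971, BR = 79.904, I = 126.904
)
names(.MASS_TABLE)[names(.MASS_TABLE) == "NA."] <- "NA"

# Bondi (1964) radii for the common elements; ions use commonly adopted
# extensions. Unknown elements have no radius: sasa() refuses to guess.
.VDW_TABLE <- c(
  H = 0.120, C = 0.170, N = 0.155, O = 0.152, F = 0.147, P = 0.180,
  S = 0.180, CL = 0.175, BR = 0.185, I = 0.198, NA. = 0.227, K = 0.275,
  MG = 0.173, CA = 0.231, ZN = 0.139, FE = 0.194, MN = 0.205, SE = 0.190
)
names(.VDW_TABLE)[names(.VDW_TABLE) == "NA."] <- "NA"

# Monoatomic-ion residue names for which the atom name IS the element.
.ION_RESNAMES <- c("NA", "CL", "K", "MG", "CA", "ZN", "FE", "MN", "BR", "CU")

#' Atomic mass lookup
#'
#' @param element character vector of element symbols (upper case).
#' @return numeric vector of masses in amu. Unknown elements get 12.0 with a
#'   warning (a carbon-like placeholder so dummy atoms do not break sums).
#' @export
atomicMass <- function(element) {
  element <- toupper(as.character(element))
  m <- unname(.MASS_TABLE[element])
  if (anyNA(m)) {
    bad <- unique(element[is.na(m)])
    warning(sprintf("unknown element(s) %s: assigning mass 12.0",
                    paste(bad, collapse = ", ")), call. = FALSE)
    m[is.na(m)] <- 12.0
  }
  m
}

#' Van der Waals radius lookup
#'
#' @param element character vector of element symbols.
#' @return numeric vector of Bondi radii in nm; `NA` for unknown elements.
#' @export
vdwRadius <- function(element) {
  unname(.VDW_TABLE[toupper(as.character(element))])
}

# Infer an element symbol from an atom name (and residue name for ions).
# PDB columns often omit the element field; the leading alphabetic character
# of the atom name is the element for organic atoms ("CA" in a protein is a
# carbon), while ion residues ("NA", "CL", ...) use the full name.
.inferElement <- function(name, resname) {
  name <- toupper(trimws(as.character(name)))
  resname <- toupper(trimws(as.character(resname)))
  out <- character(length(name))
  ion <- resname %in% .ION_RESNAMES & name == resname
  out[ion] <- name[ion]
  rest <- which(!ion)
  if (length(rest)) {
    stripped <- gsub("[^A-Z]", "", name[rest])
    stripped[stripped == ""] <- "X"
    out[rest] <- substr(stripped, 1L, 1L)
  }
  out
}
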