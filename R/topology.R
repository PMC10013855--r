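#' Construct a molecular topology
#'
#' A topology records atom identities and their residue assignment; it carries
#' no chemistry (bonds, charges). Coordinates live in [trajectory()] objects.
#'
#' @param atom_id Integer vector of unique atom identifiers.
#' @param atom_name Character vector of atom names (PDB convention, e.g. "CA").
#' @param element Character vector of element symbols ("C", "N", "H", ...).
#' @param resno Integer vector of residue numbers (PDB author numbering).
#' @param resname Character vector of residue names ("ALA", "LIG", ...).
#' @param chain Character vector of chain identifiers.
#' @return An object of class `topology`: a data.frame with one row per atom
#'   and the columns above.
#' @export
topology <- function(atom_id, atom_name, element, resno, resname, chain) {
  n <- length(atom_id)
  stopifnot(
    n >= 1,
    length(atom_name) == n, length(element) == n,
    length(resno) == n, length(resname) == n, length(chain) == n
  )
  atom_id <- as.integer(atom_id)
  if (anyDuplicated(atom_id)) stop("atom_id values must be unique")
  if (any(resno < 0)) stop("residue numbers must be non-negative")
  top <- data.frame(
    atom_id = atom_id,
    atom_name = as.character(atom_name),
    element = as.character(element),
    resno = as.integer(resno),
    resname = as.character(resname),
    chain = as.character(chain),
    stringsAsFactors = FALSE
  )
  # every atom maps to exactly one residue (resno+chain); enforce a single
  # resname per residue
  key <- paste(top$chain, top$resno)
  if (any(tapply(top$resname, key, function(x) length(unique(x))) > 1L)) {
    stop("inconsistent residue names within a residue (same chain and resno)")
  }
  class(top) <- c("topology", "data.frame")
  top
}

#' @export
print.topology <- function(x, ...) {
  cat(sprintf("topology: %d atoms, %d residues, chains: %s\n",
              nrow(x), n_residues(x),
              paste(unique(x$chain), collapse = " ")))
  invisible(x)
}

#' Number of residues in a topology
#' @param top A [topology()].
#' @return Integer count of distinct (chain, resno) pairs.
#' @export
n_residues <- function(top) {
  length(unique(paste(top$chain, top$resno)))
}

# element symbol from a PDB atom name when the element column is blank
.element_from_name <- function(atom_name) {
  nm <- gsub("[^A-Za-z]", "", atom_name)
  first <- toupper(substr(nm, 1, 1))
  ifelse(first %in% c("C", "N", "O", "S", "P", "H", "F", "K", "I"), first,
         toupper(nm))
}

#' Read a structure file (PDB)
#'
#' Parses a PDB file into a topology and its single frame of coordinates.
#' ATOM and HETATM records are both kept so ligands are selectable.
#'
#' @param path Path to a PDB file.
#' @param format Only "pdb" is supported.
#' @return A list with elements `topology` (a [topology()]) and `coords`
#'   (natoms x 3 numeric matrix, Angstrom).
#' @export
read_structure <- function(path, format = c("pdb")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  pdb <- tryCatch(
    bio3d::read.pdb(path, verbose = FALSE),
    error = function(e) stop("failed to parse PDB '", path, "': ",
                             conditionMessage(e))
  )
  a <- pdb$atom
  if (nrow(a) == 0) stop("no atoms in PDB file: ", path)
  if (anyNA(a$x) || anyNA(a$y) || anyNA(a$z)) {
    stop("missing coordinates in PDB file: ", path)
  }
  elem <- a$elesy
  blank <- is.na(elem) | !nzchar(trimws(elem))
  elem[blank] <- .element_from_name(a$elety[blank])
  chain <- a$chain
  chain[is.na(chain) | !nzchar(chain)] <- "A"
  top <- topology(
    atom_id = a$eleno, atom_name = a$elety, element = trimws(elem),
    resno = a$resno, resname = a$resid, chain = chain
  )
  coords <- cbind(a$x, a$y, a$z)
  dimnames(coords) <- NULL
  list(topology = top, coords = coords)
}

#' Write a structure (single frame) as PDB
#'
#' @param top A [topology()].
#' @param coords natoms x 3 coordinate matrix (Angstrom).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(top, coords, path) {
  stopifnot(inherits(top, "topology"),
            is.matrix(coords), nrow(coords) == nrow(top), ncol(coords) == 3)
  bio3d::write.pdb(
    file = path,
    xyz = as.numeric(t(coords)),
    resno = top$resno, resid = top$resname, eleno = top$atom_id,
    elety = top$atom_name, chain = top$chain
  )
  invisible(path)
}
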