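#' @keywords internal
"_PACKAGE"

# Atom names that belong to the protein backbone: N, CA, C, O (plus the
# C-terminal OXT) and the amide/alpha hydrogens. Everything else -- starting
# at CB -- is side chain.
.main_chain_names <- c("N", "CA", "C", "O", "OXT",
                       "H", "H1", "H2", "H3", "HA", "HA2", "HA3")

#' Construct a structure model
#'
#' A structure model is the unit all geometry in this package operates on:
#' an ordered table of atoms with their residue identity and Cartesian
#' coordinates in Angstrom. The B-factor field is retained on parsing and is
#' reused as the output channel when displacements are exported for
#' colouring (see [colored_structure()]).
#'
#' @param atoms data frame with columns `serial` (integer), `atom_name`
#'   (PDB atom name, e.g. `"CA"`), `element`, `residue_name` (3-letter
#'   code), `residue_number` (integer, >= 1, taken verbatim from the source
#'   file), `chain_id`, `x`, `y`, `z` (Angstrom) and `b_factor`.
#' @param label free-text label for the model.
#'
#' @return An object of class `structure_model`.
#'
#' @details The key `(chain_id, residue_number, atom_name)` must be unique
#'   across atoms, and all coordinates must be finite; violations raise a
#'   validation error.
#'
#' @seealso [parse_pdb()], [write_pdb()], [generate_chain()]
#' @export
structure_model <- function(atoms, label = "") {
  required <- c("serial", "atom_name", "element", "residue_name",
                "residue_number", "chain_id", "x", "y", "z", "b_factor")
  missing_cols <- setdiff(required, names(atoms))
  if (length(missing_cols) > 0L) {
    stop_validation(sprintf("atoms table lacks column(s): %s",
                            paste(missing_cols, collapse = ", ")))
  }
  atoms <- as.data.frame(atoms)[required]
  atoms$atom_name <- as.character(atoms$atom_name)
  atoms$element <- as.character(atoms$element)
  atoms$residue_name <- as.character(atoms$residue_name)
  atoms$chain_id <- as.character(atoms$chain_id)
  atoms$residue_number <- as.integer(atoms$residue_number)
  rownames(atoms) <- NULL
  if (nrow(atoms) == 0L) {
    stop_validation("structure model contains no atoms")
  }
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  if (!all(is.finite(xyz))) {
    stop_validation("non-finite coordinates in structure model")
  }
  if (any(atoms$residue_number < 1L)) {
    stop_validation("residue numbers must be >= 1")
  }
  key <- atom_key(atoms)
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)][1L]
    stop_validation(sprintf("duplicate atom key: %s", dup))
  }
  out <- list(atoms = atoms, label = as.character(label))
  class(out) <- "structure_model"
  out
}

atom_key <- function(atoms) {
  paste(atoms$chain_id, atoms$residue_number, atoms$atom_name, sep = "|")
}

#' Number of atoms in a structure model
#' @param model a `structure_model`.
#' @return Integer atom count.
#' @export
n_atoms <- function(model) {
  nrow(model$atoms)
}

#' Coordinate matrix of a structure model
#' @param model a `structure_model`.
#' @return Numeric matrix with one row per atom and columns x, y, z (Angstrom).
#' @export
coords <- function(model) {
  as.matrix(model$atoms[, c("x", "y", "z")])
}

`coords<-` <- function(model, value) {
  stopifnot(nrow(value) == nrow(model$atoms), ncol(value) == 3L)
  model$atoms$x <- value[, 1L]
  model$atoms$y <- value[, 2L]
  model$atoms$z <- value[, 3L]
  model
}

#' Classify atoms as main chain or side chain
#'
#' The main chain (protein backbone) comprises the alpha carbon together
#' with the amide group, the carbonyl group and their hydrogens: atom names
#' N, CA, C, O, OXT, H, H1-H3, HA, HA2, HA3. Every other atom name --
#' beginning with CB -- is classed as side chain, including atom names not
#' in the standard PDB vocabulary.
#'
#' @param atom_name character vector of PDB atom names.
#' @return Character vector of `"main_chain"` / `"side_chain"`, same length
#'   as the input.
#' @examples
#' classify_atom(c("CA", "CB", "OD1"))
#' @export
classify_atom <- function(atom_name) {
  ifelse(atom_name %in% .main_chain_names, "main_chain", "side_chain")
}

#' @export
print.structure_model <- function(x, ...) {
  cls <- classify_atom(x$atoms$atom_name)
  cat(sprintf("structure_model%s: %d atoms, %d residues, %d chain(s)\n",
              if (nzchar(x$label)) paste0(" '", x$label, "'") else "",
              nrow(x$atoms),
              length(unique(paste(x$atoms$chain_id, x$atoms$residue_number))),
              length(unique(x$atoms$chain_id))))
  cat(sprintf("  main chain: %d atoms, side chain: %d atoms\n",
              sum(cls == "main_chain"), sum(cls == "side_chain")))
  invisible(x)
}

# Condition helpers: validation errors carry class "idspert_validation_error"
# and parse errors "idspert_parse_error" so the command-line wrapper can map
# them onto distinct exit codes.
stop_validation <- function(msg, call. = FALSE) {
  stop(errorCondition(msg, class = c("idspert_validation_error", "error")))
}

stop_parse <- function(msg) {
  stop(errorCondition(msg, class = c("idspert_parse_error",
                                     "idspert_validation_error", "error")))
}
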