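.aa1 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

#' Parse protein-level missense notation
#'
#' Decomposes HGVS-style protein notation `p.<WT><position><MUT>` (e.g.
#' `"p.D45N"`) into its wild-type residue, position and substituted
#' residue. The `p.` prefix is case-insensitive; the amino-acid letters
#' must be valid one-letter codes.
#'
#' @param notation character vector of notations.
#' @return Data frame with columns `wt_aa`, `position`, `mut_aa`.
#' @examples
#' parse_mutation("p.D45N")
#' @export
parse_mutation <- function(notation) {
  m <- regmatches(notation,
                  regexec("^[pP]\\.([A-Za-z])([0-9]+)([A-Za-z])$", notation))
  bad <- which(lengths(m) != 4L)
  if (length(bad) > 0L) {
    stop_parse(sprintf("malformed mutation notation: '%s'",
                       notation[bad[1L]]))
  }
  wt_aa <- toupper(vapply(m, `[`, "", 2L))
  position <- as.integer(vapply(m, `[`, "", 3L))
  mut_aa <- toupper(vapply(m, `[`, "", 4L))
  invalid <- which(!(wt_aa %in% .aa1) | !(mut_aa %in% .aa1))
  if (length(invalid) > 0L) {
    stop_parse(sprintf("invalid amino-acid code in notation: '%s'",
                       notation[invalid[1L]]))
  }
  data.frame(wt_aa = wt_aa, position = position, mut_aa = mut_aa,
             stringsAsFactors = FALSE)
}

#' Load and validate a missense-mutation table
#'
#' Reads a CSV with columns `mutation`, `phenotype`, `main_chain`,
#' `side_chain`, `active_site`, `rmsd`, `asa`, `reference`, validates
#' every row (parseable notation with distinct wild-type and mutant
#' residues, phenotype severe/attenuated, non-negative counts and
#' metrics, unique notations) and attaches the parsed notation fields.
#'
#' @param path path to a CSV file, or a data frame with the same columns.
#' @return A data frame of class `mutation_table` with the source columns
#'   plus `wt_aa`, `position`, `mut_aa`; `phenotype` normalised to
#'   `"Severe"` / `"Attenuated"`.
#' @details Validation failures name the offending row.
#' @seealso [ids_mutations()] for the packaged IDS catalogue.
#' @export
load_mutation_table <- function(path) {
  d <- if (is.data.frame(path)) as.data.frame(path) else {
    utils::read.csv(path, stringsAsFactors = FALSE)
  }
  required <- c("mutation", "phenotype", "main_chain", "side_chain",
                "active_site", "rmsd", "asa", "reference")
  missing_cols <- setdiff(required, names(d))
  if (length(missing_cols) > 0L) {
    stop_validation(sprintf("mutation table lacks column(s): %s",
                            paste(missing_cols, collapse = ", ")))
  }
  ph <- tolower(trimws(d$phenotype))
  bad <- which(!ph %in% c("severe", "attenuated"))
  if (length(bad) > 0L) {
    stop_validation(sprintf("row %d: unknown phenotype '%s'",
                            bad[1L], d$phenotype[bad[1L]]))
  }
  d$phenotype <- ifelse(ph == "severe", "Severe", "Attenuated")
  parsed <- parse_mutation(d$mutation)
  same <- which(parsed$wt_aa == parsed$mut_aa)
  if (length(same) > 0L) {
    stop_validation(sprintf("row %d: wild-type and mutant residue identical in '%s'",
                            same[1L], d$mutation[same[1L]]))
  }
  if (anyDuplicated(d$mutation)) {
    stop_validation(sprintf("duplicate mutation notation: '%s'",
                            d$mutation[duplicated(d$mutation)][1L]))
  }
  for (col in c("main_chain", "side_chain", "active_site", "rmsd", "asa")) {
    v <- d[[col]]
    bad <- which(!is.finite(v) | v < 0)
    if (length(bad) > 0L) {
      stop_validation(sprintf("row %d: invalid %s value '%s'",
                              bad[1L], col, v[bad[1L]]))
    }
  }
  d$wt_aa <- parsed$wt_aa
  d$position <- parsed$position
  d$mut_aa <- parsed$mut_aa
  class(d) <- c("mutation_table", "data.frame")
  d
}

#' The packaged IDS missense-mutation catalogue
#'
#' 131 missense mutations in the IDS gene with clearly described MPS II
#' phenotypes, compiled from the case-report literature (see the
#' `reference` column): for each mutation the phenotype label
#' (severe/attenuated), the numbers of affected main-chain, side-chain and
#' active-site atoms of the modelled mutant enzyme, the all-atom RMSD
#' against the wild-type model (Angstrom), and the wild-type residue's
#' accessible surface area (square Angstrom). The catalogue contains 68
#' severe and 63 attenuated entries.
#'
#' @return A `mutation_table` (see [load_mutation_table()]).
#' @examples
#' tab <- ids_mutations()
#' table(tab$phenotype)
#' @export
ids_mutations <- function() {
  load_mutation_table(system.file("extdata", "ids_mutations.csv",
                                  package = "idspert", mustWork = TRUE))
}

#' Filter a mutation table
#'
#' Select catalogue records by phenotype, residue position, or an
#' arbitrary predicate. Querying by position returns every substitution
#' observed at that residue, which is how multi-allelic residues (several
#' different substitutions at one position) are discovered.
#'
#' @param table a `mutation_table`.
#' @param phenotype optional `"Severe"` or `"Attenuated"`
#'   (case-insensitive).
#' @param position optional residue number(s).
#' @param predicate optional function taking the table and returning a
#'   logical row mask.
#' @return The filtered `mutation_table` (possibly empty).
#' @examples
#' filter_mutations(ids_mutations(), position = 88)
#' @export
filter_mutations <- function(table, phenotype = NULL, position = NULL,
                             predicate = NULL) {
  keep <- rep(TRUE, nrow(table))
  if (!is.null(phenotype)) {
    keep <- keep & tolower(table$phenotype) %in% tolower(phenotype)
  }
  if (!is.null(position)) {
    keep <- keep & table$position %in% position
  }
  if (!is.null(predicate)) {
    keep <- keep & predicate(table)
  }
  out <- table[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("mutation_table", "data.frame")
  out
}
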