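#' Parse PDB-format coordinate text
#'
#' Reads fixed-width ATOM records (PDB v3.3 columns). HETATM records,
#' waters and alternate locations other than blank or \"A\" are skipped; in
#' multi-MODEL files only the first model is kept. Residue numbers are taken
#' verbatim from columns 23-26 and coordinates from columns 31-54; no
#' renumbering is performed.
#'
#' @param text character: either a single path to a PDB file, or a character
#'   vector of PDB lines.
#' @param label label to attach to the model (defaults to the file name, or
#'   empty for in-memory text).
#' @return A [structure_model()].
#' @examples
#' line <- paste0("ATOM      1  CA  ALA A   1       0.000   0.000   0.000",
#'                "  1.00  0.00           C")
#' parse_pdb(line)
#' @export
parse_pdb <- function(text, label = NULL) {
  if (length(text) == 1L && !grepl("\n", text) && file.exists(text)) {
    if (is.null(label)) label <- basename(text)
    lines <- readLines(text, warn = FALSE)
  } else {
    if (is.null(label)) label <- ""
    lines <- unlist(strsplit(text, "\n", fixed = TRUE), use.names = FALSE)
  }
  rec <- substr(lines, 1L, 6L)
  endmdl <- which(trimws(rec) == "ENDMDL")
  if (length(endmdl) > 0L) {
    lines <- lines[seq_len(endmdl[1L] - 1L)]
    rec <- rec[seq_len(endmdl[1L] - 1L)]
  }
  is_atom <- rec == "ATOM  "
  if (!any(is_atom)) {
    stop_parse("no ATOM records found (empty structure)")
  }
  idx <- which(is_atom)
  ln <- lines[idx]

  altloc <- substr(ln, 17L, 17L)
  keep <- altloc %in% c(" ", "", "A")
  idx <- idx[keep]
  ln <- ln[keep]
  if (length(ln) == 0L) {
    stop_parse("no ATOM records left after alternate-location filtering")
  }

  num_field <- function(s, from, to, what) {
    v <- suppressWarnings(as.numeric(substr(s, from, to)))
    bad <- which(!is.finite(v))
    if (length(bad) > 0L) {
      stop_parse(sprintf("malformed %s field in ATOM record at line %d",
                         what, idx[bad[1L]]))
    }
    v
  }

  serial <- num_field(ln, 7L, 11L, "serial")
  resno <- num_field(ln, 23L, 26L, "residue number")
  x <- num_field(ln, 31L, 38L, "x coordinate")
  y <- num_field(ln, 39L, 46L, "y coordinate")
  z <- num_field(ln, 47L, 54L, "z coordinate")
  bcol <- trimws(substr(ln, 61L, 66L))
  b <- suppressWarnings(as.numeric(bcol))
  b[!nzchar(bcol)] <- 0
  bad_b <- which(!is.finite(b))
  if (length(bad_b) > 0L) {
    stop_parse(sprintf("malformed B-factor field in ATOM record at line %d",
                       idx[bad_b[1L]]))
  }

  atom_name <- trimws(substr(ln, 13L, 16L))
  res_name <- trimws(substr(ln, 18L, 20L))
  chain <- substr(ln, 22L, 22L)
  element <- trimws(substr(ln, 77L, 78L))
  element[!nzchar(element)] <- guess_element(atom_name[!nzchar(element)])

  structure_model(data.frame(serial = as.integer(serial),
                             atom_name = atom_name,
                             element = element,
                             residue_name = res_name,
                             residue_number = as.integer(resno),
                             chain_id = chain,
                             x = x, y = y, z = z,
                             b_factor = b,
                             stringsAsFactors = FALSE),
                  label = label)
}

# Fallback element assignment when columns 77-78 are blank: strip leading
# digits, then take the first character (covers C/N/O/S/H names used here).
guess_element <- function(atom_name) {
  stripped <- sub("^[0-9]+", "", atom_name)
  toupper(substr(stripped, 1L, 1L))
}

#' Write a structure model as PDB-format text
#'
#' Emits fixed-width ATOM records. The B-factor is written to columns 61-66
#' with two decimals, which is the channel [colored_structure()] uses to
#' export displacements. Writing then re-parsing is lossless for all
#' retained fields.
#'
#' @param model a [structure_model()].
#' @param file optional path; when given the lines are written there.
#' @return Character vector of PDB lines (invisibly when `file` is given).
#' @export
write_pdb <- function(model, file = NULL) {
  a <- model$atoms
  if (nrow(a) == 0L) stop_validation("cannot write an empty model")
  if (any(abs(c(a$x, a$y, a$z)) >= 10000)) {
    stop_validation("coordinate magnitude >= 10000 Angstrom does not fit PDB fixed-width fields")
  }
  # Atom-name column convention: names of up to 3 characters start in
  # column 14; 4-character names occupy columns 13-16.
  name_field <- ifelse(nchar(a$atom_name) >= 4L,
                       substr(a$atom_name, 1L, 4L),
                       sprintf(" %-3s", a$atom_name))
  lines <- sprintf(
    "ATOM  %5d %4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    a$serial %% 100000L, name_field, a$residue_name, a$chain_id,
    a$residue_number, a$x, a$y, a$z, 1.00, a$b_factor,
    toupper(substr(a$element, 1L, 2L)))
  lines <- c(lines, "END")
  if (!is.null(file)) {
    writeLines(lines, file)
    return(invisible(lines))
  }
  lines
}
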