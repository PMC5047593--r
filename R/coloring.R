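#' Displacement colour binning
#'
#' Five half-open displacement intervals used to colour affected atoms:
#' by default 0.15 <= cyan < 0.30, 0.30 <= green < 0.45, 0.45 <= yellow
#' < 0.60, 0.60 <= orange < 0.75, and red for 0.75 and above (Angstrom).
#' Displacements below the first edge are "uncolored".
#'
#' @param edges strictly increasing bin edges in Angstrom.
#' @param labels one label per edge.
#' @return An object of class `color_bins`.
#' @export
color_bins <- function(edges = c(0.15, 0.30, 0.45, 0.60, 0.75),
                       labels = c("cyan", "green", "yellow", "orange",
                                  "red")) {
  if (length(edges) != length(labels)) {
    stop_validation("edges and labels must have equal length")
  }
  if (any(diff(edges) <= 0)) {
    stop_validation("bin edges must be strictly increasing")
  }
  out <- list(edges = as.numeric(edges), labels = as.character(labels))
  class(out) <- "color_bins"
  out
}

#' Assign displacements to colour bins
#'
#' Left-closed, right-open intervals: a displacement d gets label i when
#' `edges[i] <= d < edges[i + 1]`, the last label when `d >= last edge`,
#' and `"uncolored"` when `d < edges[1]`.
#'
#' @param displacement numeric vector of displacements (Angstrom, >= 0).
#' @param bins a [color_bins()] specification.
#' @return Character vector of bin labels.
#' @examples
#' classify_bin(c(0.10, 0.20, 0.80), color_bins())
#' @export
classify_bin <- function(displacement, bins = color_bins()) {
  idx <- findInterval(displacement, bins$edges)
  c("uncolored", bins$labels)[idx + 1L]
}

#' Export a displacement-coloured structure
#'
#' Writes each paired atom's displacement into the B-factor column of the
#' wild-type model (unpaired atoms get -1.00), so that any molecular
#' viewer can colour the structure by B-factor, and tabulates per-atom
#' displacements with their bin labels.
#'
#' @param wt the wild-type `structure_model`.
#' @param pert a [perturbation()] result for `wt` against a mutant.
#' @param bins a [color_bins()] specification.
#' @param pdb_file,csv_file optional output paths.
#' @return List with `pdb` (character vector of PDB lines), `model` (the
#'   B-factor-encoded `structure_model`) and `table` (data frame: chain,
#'   residue number, atom name, displacement, bin label).
#' @export
colored_structure <- function(wt, pert, bins = color_bins(),
                              pdb_file = NULL, csv_file = NULL) {
  b <- rep(-1, nrow(wt$atoms))
  b[pert$wt_index] <- pert$displacements$displacement
  model <- wt
  model$atoms$b_factor <- b
  tab <- pert$displacements[, c("chain_id", "residue_number", "atom_name",
                                "displacement")]
  tab$bin <- classify_bin(tab$displacement, bins)
  pdb <- write_pdb(model, file = pdb_file)
  if (!is.null(csv_file)) {
    utils::write.csv(tab, csv_file, row.names = FALSE)
  }
  invisible(list(pdb = pdb, model = model, table = tab))
}
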