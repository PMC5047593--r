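#' Default active-site residues of iduronate 2-sulfatase
#'
#' Residue numbers (on the 550-residue precursor) of the putative IDS
#' active site: D45, D46, C84 (converted to formylglycine in vivo), K135
#' and D334.
#' @return Integer vector of residue numbers.
#' @export
ids_active_site <- function() {
  c(45L, 46L, 84L, 135L, 334L)
}

#' Tally affected atoms by region
#'
#' An atom counts as affected when its displacement exceeds the cutoff
#' distance strictly (`displacement > cutoff`); an atom displaced by
#' exactly the cutoff is not affected. Affected atoms are tallied into
#' main-chain and side-chain counts via [classify_atom()], and the
#' active-site count is the number of affected atoms (of either class)
#' whose residue number belongs to the active-site set.
#'
#' @param displacements data frame from [compute_displacements()] (columns
#'   `wt_index`, `displacement`), or a bare numeric vector accompanied by
#'   `wt_index`.
#' @param wt the wild-type `structure_model` the indices refer to.
#' @param cutoff displacement cutoff in Angstrom (default 0.15).
#' @param active_site integer vector of active-site residue numbers
#'   (default [ids_active_site()]).
#' @param wt_index atom indices when `displacements` is a bare vector.
#' @return List with integer elements `n_main_chain`, `n_side_chain`,
#'   `n_active_site`.
#' @export
count_affected <- function(displacements, wt, cutoff = 0.15,
                           active_site = ids_active_site(),
                           wt_index = NULL) {
  if (is.data.frame(displacements)) {
    wt_index <- displacements$wt_index
    d <- displacements$displacement
  } else {
    d <- as.numeric(displacements)
    if (is.null(wt_index)) wt_index <- seq_along(d)
  }
  if (cutoff <= 0) stop_validation("cutoff must be positive")
  affected <- d > cutoff
  cls <- classify_atom(wt$atoms$atom_name[wt_index])
  resno <- wt$atoms$residue_number[wt_index]
  list(n_main_chain = sum(affected & cls == "main_chain"),
       n_side_chain = sum(affected & cls == "side_chain"),
       n_active_site = sum(affected & resno %in% active_site))
}

#' All-atom root-mean-square distance
#'
#' `sqrt(mean(d^2))` over the per-atom displacements of all paired atoms.
#'
#' @param displacements numeric vector of displacements (Angstrom), or a
#'   data frame with a `displacement` column.
#' @return RMSD in Angstrom.
#' @export
rmsd_all_atoms <- function(displacements) {
  if (is.data.frame(displacements)) displacements <- displacements$displacement
  if (length(displacements) == 0L) {
    stop_validation("cannot compute RMSD of an empty displacement set")
  }
  sqrt(mean(displacements^2))
}

#' Structural perturbation of a mutant model relative to the wild type
#'
#' The central analysis: pairs atoms between the two models, fits the
#' optimal rigid transform on the C-alpha atoms ([superpose()]), brings the
#' mutant into the wild-type frame, measures per-atom displacements, and
#' summarises them as the affected-atom counts (main chain / side chain /
#' active site, displacement strictly greater than `cutoff`) and the
#' all-atom RMSD. Deterministic for fixed inputs.
#'
#' @param wt wild-type `structure_model`.
#' @param mut mutant `structure_model`.
#' @param cutoff displacement cutoff in Angstrom (default 0.15).
#' @param active_site active-site residue numbers (default
#'   [ids_active_site()]).
#' @return An object of class `perturbation` with elements
#'   \describe{
#'     \item{n_main_chain, n_side_chain, n_active_site}{affected-atom counts}
#'     \item{rmsd_all_atoms}{RMSD over all paired atoms (Angstrom)}
#'     \item{n_pairs, n_unpaired}{paired-atom count and atoms without a
#'       counterpart (excluded from fit, displacements and RMSD)}
#'     \item{displacements}{per-atom table: chain, residue, atom name,
#'       class, displacement, affected flag}
#'     \item{superposition}{the fitted [superpose()] result}
#'     \item{cutoff, active_site}{the configuration used}
#'   }
#' @examples
#' wt <- generate_chain(8, seed = 1)
#' mut <- perturb_structure(wt, data.frame(residue_number = 4,
#'                                         atom_class = "side_chain",
#'                                         magnitude = 0.3))$model
#' perturbation(wt, mut)
#' @export
perturbation <- function(wt, mut, cutoff = 0.15,
                         active_site = ids_active_site()) {
  pairing <- pair_atoms(wt, mut)
  sp <- superpose(wt, mut, pairing)
  mut_fit <- apply_transform(mut, sp)
  disp <- compute_displacements(wt, mut_fit, pairing)
  counts <- count_affected(disp, wt, cutoff = cutoff,
                           active_site = active_site)
  cls <- classify_atom(wt$atoms$atom_name[disp$wt_index])
  tab <- data.frame(
    chain_id = wt$atoms$chain_id[disp$wt_index],
    residue_number = wt$atoms$residue_number[disp$wt_index],
    atom_name = wt$atoms$atom_name[disp$wt_index],
    atom_class = cls,
    displacement = disp$displacement,
    affected = disp$displacement > cutoff,
    stringsAsFactors = FALSE)
  out <- list(n_main_chain = counts$n_main_chain,
              n_side_chain = counts$n_side_chain,
              n_active_site = counts$n_active_site,
              rmsd_all_atoms = rmsd_all_atoms(disp),
              n_pairs = nrow(disp),
              n_unpaired = attr(pairing, "n_unpaired_wt") +
                attr(pairing, "n_unpaired_mut"),
              displacements = tab,
              superposition = sp,
              wt_index = disp$wt_index,
              cutoff = cutoff,
              active_site = active_site,
              labels = c(wt = wt$label, mut = mut$label))
  class(out) <- "perturbation"
  out
}

#' @export
print.perturbation <- function(x, ...) {
  cat("Structural perturbation",
      if (any(nzchar(x$labels))) sprintf("(%s vs %s)", x$labels["wt"],
                                         x$labels["mut"]) else "", "\n")
  cat(sprintf("  paired atoms: %d (%d unpaired, excluded)\n",
              x$n_pairs, x$n_unpaired))
  cat(sprintf("  affected atoms (> %.2f Angstrom): main chain %d, side chain %d, active site %d\n",
              x$cutoff, x$n_main_chain, x$n_side_chain, x$n_active_site))
  cat(sprintf("  all-atom RMSD: %.4f Angstrom\n", x$rmsd_all_atoms))
  invisible(x)
}

#' @export
summary.perturbation <- function(object, bins = color_bins(), ...) {
  lab <- classify_bin(object$displacements$displacement, bins)
  out <- list(report = as.data.frame(object),
              bin_counts = table(factor(lab, levels = c("uncolored",
                                                        bins$labels))),
              fit_rmsd_ca = object$superposition$fit_rmsd_ca)
  class(out) <- "summary.perturbation"
  out
}

#' @export
print.summary.perturbation <- function(x, ...) {
  print(x$report, row.names = FALSE)
  cat(sprintf("C-alpha fit RMSD: %.4f Angstrom\n", x$fit_rmsd_ca))
  cat("displacement bins:\n")
  print(x$bin_counts)
  invisible(x)
}

#' @export
as.data.frame.perturbation <- function(x, ...) {
  data.frame(main_chain = x$n_main_chain,
             side_chain = x$n_side_chain,
             active_site = x$n_active_site,
             rmsd = x$rmsd_all_atoms,
             n_pairs = x$n_pairs,
             n_unpaired = x$n_unpaired)
}

#' @export
residuals.perturbation <- function(object, ...) {
  object$displacements$displacement
}

#' Plot a perturbation profile
#'
#' Per-atom displacement against atom index, coloured by the displacement
#' bins used for structure colouring, with the cutoff drawn as a dashed
#' line.
#'
#' @param x a `perturbation` object.
#' @param bins a [color_bins()] specification.
#' @param ... further arguments passed to [graphics::plot()].
#' @export
plot.perturbation <- function(x, bins = color_bins(), ...) {
  d <- x$displacements$displacement
  lab <- classify_bin(d, bins)
  col <- ifelse(lab == "uncolored", "grey70", lab)
  graphics::plot(seq_along(d), d, col = col, pch = 16, cex = 0.6,
                 xlab = "paired atom index",
                 ylab = "displacement (Angstrom)", ...)
  graphics::abline(h = x$cutoff, lty = 2)
  invisible(x)
}
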