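#' Match atoms between two structure models
#'
#' Atoms are paired on the identity key `(chain_id, residue_number,
#' atom_name)`. Atoms present in only one model -- typically the chemically
#' distinct side-chain atoms of the substituted residue -- are left
#' unpaired; their counts are reported and they take no part in either the
#' superposition fit or the displacement profile.
#'
#' @param wt,mut `structure_model` objects for the wild type and the mutant.
#' @return An object of class `atom_pairing`: a data frame with columns
#'   `wt_index` and `mut_index` (row indices into the two models, each used
#'   at most once), with attributes `n_unpaired_wt`, `n_unpaired_mut` and
#'   `matched_on`.
#' @export
pair_atoms <- function(wt, mut) {
  key_wt <- atom_key(wt$atoms)
  key_mut <- atom_key(mut$atoms)
  m <- match(key_wt, key_mut)
  wt_index <- which(!is.na(m))
  if (length(wt_index) == 0L) {
    stop_validation("no atoms in common between the two models")
  }
  pairs <- data.frame(wt_index = wt_index, mut_index = m[wt_index])
  attr(pairs, "n_unpaired_wt") <- nrow(wt$atoms) - nrow(pairs)
  attr(pairs, "n_unpaired_mut") <- nrow(mut$atoms) - nrow(pairs)
  attr(pairs, "matched_on") <- "chain_id|residue_number|atom_name"
  class(pairs) <- c("atom_pairing", "data.frame")
  pairs
}

# Kabsch: rotation R (det +1) and translation t minimizing
# sum |R q_i + t - p_i|^2 over paired points (rows of P and Q).
kabsch <- function(P, Q) {
  stopifnot(nrow(P) == nrow(Q), ncol(P) == 3L, ncol(Q) == 3L)
  cp <- colMeans(P)
  cq <- colMeans(Q)
  Pc <- sweep(P, 2L, cp)
  Qc <- sweep(Q, 2L, cq)
  H <- crossprod(Qc, Pc)           # 3x3 covariance, mutant -> wild type
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)
  t_vec <- unname(cp - as.vector(R %*% cq))
  Qfit <- Qc %*% t(R)
  rmsd <- sqrt(mean(rowSums((Qfit - Pc)^2)))
  list(rotation = R, translation = t_vec, rmsd = rmsd)
}

#' Superpose a mutant model onto the wild type
#'
#' Fits the optimal rigid transform (rotation + translation) of the mutant
#' onto the wild type by least squares over the paired C-alpha atoms, using
#' the closed-form Kabsch/SVD solution with reflection correction. The fit
#' uses C-alpha pairs only; displacements for all atoms are then measured
#' in the fixed wild-type frame (see [compute_displacements()]).
#'
#' @param wt,mut `structure_model` objects.
#' @param pairing an [pair_atoms()] result; computed from `wt` and `mut`
#'   when omitted.
#' @return An object of class `superposition` with elements `rotation`
#'   (3x3, orthonormal, det +1), `translation` (length-3, Angstrom),
#'   `fit_rmsd_ca` (RMSD over the C-alpha atoms used in the fit), `n_ca`
#'   and `pairing`.
#' @details At least three non-collinear C-alpha pairs are required;
#'   fewer, or a collinear set, raises a degenerate-fit error.
#' @export
superpose <- function(wt, mut, pairing = NULL) {
  if (is.null(pairing)) pairing <- pair_atoms(wt, mut)
  is_ca <- wt$atoms$atom_name[pairing$wt_index] == "CA"
  ca <- pairing[is_ca, , drop = FALSE]
  if (nrow(ca) < 3L) {
    stop_validation(sprintf("degenerate fit: %d C-alpha pairs (need >= 3)",
                            nrow(ca)))
  }
  P <- coords(wt)[ca$wt_index, , drop = FALSE]
  Q <- coords(mut)[ca$mut_index, , drop = FALSE]
  Pc <- sweep(P, 2L, colMeans(P))
  sv <- svd(Pc)
  if (sv$d[2L] < 1e-8 * max(sv$d[1L], 1)) {
    stop_validation("degenerate fit: C-alpha atoms are collinear")
  }
  fit <- kabsch(P, Q)
  out <- list(rotation = fit$rotation, translation = fit$translation,
              fit_rmsd_ca = fit$rmsd, n_ca = nrow(ca), pairing = pairing)
  class(out) <- "superposition"
  out
}

#' @export
print.superposition <- function(x, ...) {
  cat(sprintf("superposition: fit on %d C-alpha pairs, RMSD %.4f Angstrom\n",
              x$n_ca, x$fit_rmsd_ca))
  cat(sprintf("  rotation angle %.2f deg, translation norm %.3f Angstrom\n",
              rotation_angle(x$rotation) * 180 / pi,
              sqrt(sum(x$translation^2))))
  invisible(x)
}

rotation_angle <- function(R) {
  acos(max(-1, min(1, (sum(diag(R)) - 1) / 2)))
}

#' Apply a rigid transform to a structure model
#'
#' Replaces every coordinate x by `rotation %*% x + translation`; all
#' non-coordinate fields are unchanged.
#'
#' @param model a `structure_model`.
#' @param s a `superposition` (or any list with `rotation` and
#'   `translation`).
#' @return The transformed `structure_model`.
#' @export
apply_transform <- function(model, s) {
  xyz <- coords(model) %*% t(s$rotation)
  xyz <- sweep(xyz, 2L, s$translation, `+`)
  coords(model) <- xyz
  model
}

#' Per-atom displacements between superposed models
#'
#' Euclidean distance between each paired wild-type atom and its mutant
#' counterpart, the mutant already transformed into the wild-type frame.
#'
#' @param wt wild-type `structure_model`.
#' @param mut_superposed mutant `structure_model` after [apply_transform()].
#' @param pairing an [pair_atoms()] result.
#' @return Data frame with columns `wt_index` and `displacement`
#'   (Angstrom, >= 0), in pairing order.
#' @export
compute_displacements <- function(wt, mut_superposed, pairing) {
  P <- coords(wt)[pairing$wt_index, , drop = FALSE]
  Q <- coords(mut_superposed)[pairing$mut_index, , drop = FALSE]
  data.frame(wt_index = pairing$wt_index,
             displacement = sqrt(rowSums((P - Q)^2)))
}
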