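#' Default van der Waals radii (Angstrom)
#' @return Named numeric vector for elements C, N, O, S.
#' @export
default_radii <- function() {
  c(C = 1.70, N = 1.55, O = 1.52, S = 1.80)
}

# Quasi-uniform points on the unit sphere by the golden-spiral (Fibonacci)
# construction; deterministic, no randomness.
golden_spiral_points <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  phi <- (seq_len(n) - 1) * pi * (3 - sqrt(5))
  cbind(r * cos(phi), r * sin(phi), z)
}

# Canonical molecular frame: principal axes of the heavy-atom cloud with
# signs fixed by the third moment (largest-magnitude eigenvector component
# as tie-break) and a right-handed completion. Orienting the test-point
# lattice in this frame makes the finite-point ASA exactly covariant with
# rigid motion of the structure, hence invariant in value.
canonical_frame <- function(xyz) {
  if (nrow(xyz) < 2L) return(diag(3))
  centered <- sweep(xyz, 2L, colMeans(xyz))
  eg <- eigen(crossprod(centered) / nrow(xyz), symmetric = TRUE)
  V <- eg$vectors
  for (k in 1:2) {
    proj <- centered %*% V[, k]
    s <- sum(proj^3)
    if (abs(s) < 1e-9) {
      s <- V[which.max(abs(V[, k])), k]
    }
    if (s < 0) V[, k] <- -V[, k]
  }
  V[, 3] <- c(V[2, 1] * V[3, 2] - V[3, 1] * V[2, 2],
              V[3, 1] * V[1, 2] - V[1, 1] * V[3, 2],
              V[1, 1] * V[2, 2] - V[2, 1] * V[1, 2])
  V
}

#' Solvent-accessible surface area by the Shrake-Rupley method
#'
#' For every heavy atom, `n_sphere_points` quasi-uniform test points are
#' placed on the probe-expanded sphere of radius `r_atom + probe_radius`
#' (golden-spiral construction, deterministic; the point lattice is
#' oriented along the molecule's principal axes so the computed areas are
#' invariant under rigid motion of the structure). A point is exposed when it
#' lies outside the expanded sphere of every neighbouring atom; the atom's
#' ASA is the exposed fraction times `4 * pi * (r_atom + probe)^2`.
#' Hydrogens are ignored.
#'
#' @param model a `structure_model`.
#' @param probe_radius solvent probe radius in Angstrom (default 1.4, a
#'   water molecule).
#' @param n_sphere_points test points per atom (default 960).
#' @param radii named vector mapping element symbols to van der Waals
#'   radii in Angstrom (default [default_radii()]).
#' @return An object of class `asa_result` with `per_atom` (one row per
#'   heavy atom: indices, identity and `asa` in square Angstrom),
#'   `per_residue` (chain, residue number, residue name, summed `asa`),
#'   `probe_radius` and `n_sphere_points`.
#' @details An element without an entry in `radii` raises an error naming
#'   the element.
#' @examples
#' m <- generate_chain(5, seed = 1)
#' shrake_rupley(m)
#' @export
shrake_rupley <- function(model, probe_radius = 1.4, n_sphere_points = 960L,
                          radii = default_radii()) {
  a <- model$atoms
  heavy <- which(toupper(a$element) != "H")
  if (length(heavy) == 0L) stop_validation("no heavy atoms in model")
  el <- toupper(a$element[heavy])
  unknown <- setdiff(unique(el), names(radii))
  if (length(unknown) > 0L) {
    stop_validation(sprintf("no van der Waals radius for element(s): %s",
                            paste(unknown, collapse = ", ")))
  }
  r <- unname(radii[el]) + probe_radius
  xyz <- coords(model)[heavy, , drop = FALSE]
  frame <- canonical_frame(xyz)
  sph <- golden_spiral_points(n_sphere_points) %*% t(frame)
  n <- length(heavy)
  asa <- numeric(n)
  # neighbour cut: atoms can only occlude each other within r_i + r_j
  d2 <- as.matrix(stats::dist(xyz))^2
  for (i in seq_len(n)) {
    nb <- which(d2[i, ] < (r[i] + r)^2 & seq_len(n) != i)
    if (length(nb) == 0L) {
      asa[i] <- 4 * pi * r[i]^2
      next
    }
    pts <- sph * r[i]
    pts <- sweep(pts, 2L, xyz[i, ], `+`)
    exposed <- rep(TRUE, n_sphere_points)
    for (j in nb) {
      if (!any(exposed)) break
      dx <- pts[exposed, 1L] - xyz[j, 1L]
      dy <- pts[exposed, 2L] - xyz[j, 2L]
      dz <- pts[exposed, 3L] - xyz[j, 3L]
      exposed[exposed] <- dx * dx + dy * dy + dz * dz > r[j]^2
    }
    asa[i] <- sum(exposed) / n_sphere_points * 4 * pi * r[i]^2
  }
  per_atom <- data.frame(atom = heavy,
                         chain_id = a$chain_id[heavy],
                         residue_number = a$residue_number[heavy],
                         residue_name = a$residue_name[heavy],
                         atom_name = a$atom_name[heavy],
                         asa = asa,
                         stringsAsFactors = FALSE)
  agg <- stats::aggregate(asa ~ chain_id + residue_number + residue_name,
                          data = per_atom, FUN = sum)
  agg <- agg[order(agg$chain_id, agg$residue_number), ]
  rownames(agg) <- NULL
  out <- list(per_atom = per_atom, per_residue = agg,
              probe_radius = probe_radius,
              n_sphere_points = as.integer(n_sphere_points))
  class(out) <- "asa_result"
  out
}

#' @export
print.asa_result <- function(x, ...) {
  cat(sprintf("Shrake-Rupley ASA: %d heavy atoms, %d residues (probe %.2f Angstrom, %d points)\n",
              nrow(x$per_atom), nrow(x$per_residue), x$probe_radius,
              x$n_sphere_points))
  cat(sprintf("  total ASA: %.1f sq. Angstrom\n", sum(x$per_atom$asa)))
  invisible(x)
}

#' Accessible surface area of one residue
#'
#' @param result an [shrake_rupley()] result.
#' @param chain_id chain identifier.
#' @param residue_number residue number.
#' @return The residue's ASA in square Angstrom (sum over its heavy atoms).
#' @export
residue_asa <- function(result, chain_id, residue_number) {
  hit <- result$per_residue$chain_id == chain_id &
    result$per_residue$residue_number == residue_number
  if (!any(hit)) {
    stop_validation(sprintf("residue %s/%d not present in ASA result",
                            chain_id, residue_number))
  }
  result$per_residue$asa[hit]
}
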