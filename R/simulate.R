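#' Generate a synthetic polypeptide-like chain
#'
#' Builds a poly-alanine-like model (atoms N, CA, C, O, CB per residue)
#' with idealised geometry: an extended (beta-strand-like) zig-zag with
#' consecutive C-alpha atoms 3.8 Angstrom apart, or an ideal alpha-helix
#' (2.3 Angstrom radius, 1.5 Angstrom rise and 100 degrees twist per
#' residue). A small seeded jitter (< 0.002 Angstrom per coordinate)
#' makes every chain generic (no exact collinearity) while keeping the
#' idealised distances; output is fully deterministic per seed.
#'
#' @param n_residues number of residues (>= 3).
#' @param geometry `"extended"` or `"helix"`.
#' @param seed integer seed.
#' @param chain_id chain identifier.
#' @return A `structure_model` with residues numbered 1..n.
#' @export
generate_chain <- function(n_residues, geometry = c("extended", "helix"),
                           seed = 1L, chain_id = "A") {
  geometry <- match.arg(geometry)
  if (n_residues < 3L) stop_validation("need at least 3 residues")
  i <- seq_len(n_residues)
  if (geometry == "extended") {
    dx <- sqrt(3.8^2 - 1)             # alternating y = +/- 0.5 keeps CA-CA at 3.8
    ca <- cbind((i - 1) * dx, 0.5 * (-1)^i, 0)
  } else {
    theta <- (i - 1) * 100 * pi / 180
    ca <- cbind(2.3 * cos(theta), 2.3 * sin(theta), (i - 1) * 1.5)
  }
  offsets <- rbind(N = c(-0.9, 0.9, 0.5),
                   CA = c(0, 0, 0),
                   C = c(0.9, 0.9, -0.5),
                   O = c(1.2, 2.05, -0.3),
                   CB = c(0.2, -1.1, 1.0))
  atom_names <- rownames(offsets)
  n_per <- length(atom_names)
  xyz <- ca[rep(i, each = n_per), ] + offsets[rep(seq_len(n_per), n_residues), ]
  set.seed(seed)
  xyz <- xyz + matrix(stats::runif(length(xyz), -0.002, 0.002), ncol = 3L)
  atoms <- data.frame(serial = seq_len(n_residues * n_per),
                      atom_name = rep(atom_names, n_residues),
                      element = substr(rep(atom_names, n_residues), 1L, 1L),
                      residue_name = "ALA",
                      residue_number = rep(i, each = n_per),
                      chain_id = chain_id,
                      x = xyz[, 1L], y = xyz[, 2L], z = xyz[, 3L],
                      b_factor = 0,
                      stringsAsFactors = FALSE)
  structure_model(atoms, label = sprintf("synthetic-%s-%d", geometry,
                                         n_residues))
}

#' Apply a controlled displacement field to a model
#'
#' Creates a "mutant" copy of a model by displacing selected atoms by
#' known magnitudes, and returns the ground-truth perturbation report
#' computed by direct bookkeeping on the final coordinates -- the oracle
#' against which [perturbation()] is verified. When displaced C-alpha
#' atoms leave a net rigid component, the best-fit rigid motion of the
#' C-alpha set is removed so that a subsequent superposition is the
#' identity; when no C-alpha atom is touched the intended magnitudes are
#' realised exactly.
#'
#' @param model the wild-type `structure_model`.
#' @param targets data frame with columns `residue_number`, `magnitude`
#'   (Angstrom) and optionally `atom_class` (`"main_chain"`,
#'   `"side_chain"` or `"any"`; default any), `chain_id` (default: all
#'   chains) and `direction` (`"random"` unit vectors, the default, or
#'   `"x"`). Each row displaces all matching atoms by its magnitude.
#' @param seed integer seed for the random directions.
#' @param cutoff,active_site configuration used for the ground-truth
#'   report (defaults 0.15 Angstrom and [ids_active_site()]).
#' @param remove_rigid remove the net rigid component of the C-alpha set
#'   (default TRUE).
#' @return List with `model` (the perturbed copy), `truth` (list:
#'   `n_main_chain`, `n_side_chain`, `n_active_site`, `rmsd_all_atoms`,
#'   `n_pairs`, `n_unpaired`) and `displacement` (the realised per-atom
#'   displacements, in atom order).
#' @export
perturb_structure <- function(model, targets, seed = 1L, cutoff = 0.15,
                              active_site = ids_active_site(),
                              remove_rigid = TRUE) {
  set.seed(seed)
  a <- model$atoms
  xyz <- coords(model)
  touched_ca <- FALSE
  if (nrow(targets) > 0L) {
    for (k in seq_len(nrow(targets))) {
      tg <- targets[k, ]
      sel <- a$residue_number == tg$residue_number
      if (!is.null(tg$chain_id) && !is.na(tg$chain_id)) {
        sel <- sel & a$chain_id == tg$chain_id
      }
      cls_filter <- if (is.null(tg$atom_class) || is.na(tg$atom_class)) "any" else tg$atom_class
      if (cls_filter != "any") {
        sel <- sel & classify_atom(a$atom_name) == cls_filter
      }
      idx <- which(sel)
      if (length(idx) == 0L) {
        stop_validation(sprintf("perturbation target %d matches no atoms (residue %s)",
                                k, tg$residue_number))
      }
      dir_mode <- if (is.null(tg$direction) || is.na(tg$direction)) "random" else tg$direction
      for (j in idx) {
        u <- if (dir_mode == "x") c(1, 0, 0) else {
          v <- stats::rnorm(3)
          v / sqrt(sum(v^2))
        }
        xyz[j, ] <- xyz[j, ] + tg$magnitude * u
      }
      touched_ca <- touched_ca || any(a$atom_name[idx] == "CA")
    }
  }
  mut <- model
  coords(mut) <- xyz
  mut$label <- paste0(model$label, "-perturbed")
  if (remove_rigid && touched_ca) {
    sp <- superpose(model, mut)
    mut <- apply_transform(mut, sp)
  }
  # ground truth by direct bookkeeping on the final coordinates: plain
  # Euclidean distances, no superposition in the counting path
  d <- sqrt(rowSums((coords(mut) - coords(model))^2))
  cls <- classify_atom(a$atom_name)
  truth <- list(n_main_chain = sum(d > cutoff & cls == "main_chain"),
                n_side_chain = sum(d > cutoff & cls == "side_chain"),
                n_active_site = sum(d > cutoff &
                                      a$residue_number %in% active_site),
                rmsd_all_atoms = sqrt(mean(d^2)),
                n_pairs = nrow(a),
                n_unpaired = 0L)
  list(model = mut, truth = truth, displacement = d)
}

#' Simulate a mutation table with a known group effect
#'
#' Draws a synthetic severe/attenuated mutation catalogue whose columns
#' mimic the statistical shape of the packaged IDS data: affected-atom
#' counts from a right-skewed lognormal (rounded; counts are non-negative
#' and their SD exceeds the mean in both observed groups), side-chain
#' counts proportional to main-chain counts, RMSD increasing with the
#' total count, and ASA drawn independently of phenotype (the observed
#' data show no group difference in ASA). `effect_shift` displaces the
#' severe group's location on the log scale; 0 gives a null table.
#'
#' @param n_severe,n_attenuated group sizes (>= 2 each).
#' @param effect_shift log-scale shift of the severe group's count
#'   distribution; the default `log(106/63)` reproduces the observed
#'   severe/attenuated mean ratio of the packaged catalogue.
#' @param seed integer seed; output is fully deterministic per seed.
#' @param meanlog,sdlog baseline lognormal parameters of the main-chain
#'   count; the defaults (3.74, 0.9) match the attenuated group's
#'   observed mean 63 and coefficient of variation ~1.2.
#' @return A validated `mutation_table`.
#' @export
simulate_mutation_table <- function(n_severe = 67L, n_attenuated = 64L,
                                    effect_shift = log(106 / 63),
                                    seed = 1L, meanlog = 3.74,
                                    sdlog = 0.9) {
  if (n_severe < 2L || n_attenuated < 2L) {
    stop_validation("need at least two records per group")
  }
  set.seed(seed)
  n <- n_severe + n_attenuated
  phen <- c(rep("Severe", n_severe), rep("Attenuated", n_attenuated))
  shift <- ifelse(phen == "Severe", effect_shift, 0)
  main <- round(stats::rlnorm(n, meanlog + shift, sdlog))
  side <- round(main * stats::rlnorm(n, 0.15, 0.2))
  rmsd <- round((main + side + 20) * 2e-4 *
                  stats::rlnorm(n, 0, 0.25), 4)
  asa <- round(stats::rlnorm(n, 2.2, 1.6), 1)
  involved <- stats::rbinom(n, 1L, 0.35) == 1L & (main + side) > 0
  active <- ifelse(involved,
                   pmin(stats::rpois(n, 10) + 1L, main + side), 0L)
  position <- sample(10:540, n)
  wt_aa <- sample(.aa1, n, replace = TRUE)
  mut_aa <- vapply(wt_aa, function(w) sample(setdiff(.aa1, w), 1L), "")
  d <- data.frame(mutation = sprintf("p.%s%d%s", wt_aa, position, mut_aa),
                  phenotype = phen,
                  main_chain = main, side_chain = side,
                  active_site = active, rmsd = rmsd, asa = asa,
                  reference = "synthetic",
                  stringsAsFactors = FALSE)
  load_mutation_table(d)
}
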