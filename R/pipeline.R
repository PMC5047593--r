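#' Compare a wild-type/mutant model pair and write report files
#'
#' Runs [perturbation()] on two PDB files and writes the per-mutation
#' report (CSV and JSON, one row with the affected-atom counts and RMSD),
#' the displacement-coloured structure (displacements in the B-factor
#' column) and the per-atom displacement table. Re-running with identical
#' inputs and configuration produces byte-identical outputs.
#'
#' @param wt_file,mut_file paths to PDB files.
#' @param out_dir output directory (created if needed).
#' @param cutoff displacement cutoff in Angstrom.
#' @param active_site active-site residue numbers.
#' @param bins a [color_bins()] specification.
#' @return Invisibly, a named list of the written paths plus the
#'   `perturbation` object.
#' @export
run_compare <- function(wt_file, mut_file, out_dir = ".",
                        cutoff = 0.15, active_site = ids_active_site(),
                        bins = color_bins()) {
  for (f in c(wt_file, mut_file)) {
    if (!file.exists(f)) stop_validation(sprintf("file not found: %s", f))
  }
  wt <- parse_pdb(wt_file)
  mut <- parse_pdb(mut_file)
  pert <- perturbation(wt, mut, cutoff = cutoff, active_site = active_site)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  report_csv <- file.path(out_dir, "report.csv")
  report_json <- file.path(out_dir, "report.json")
  colored_pdb <- file.path(out_dir, "colored.pdb")
  disp_csv <- file.path(out_dir, "displacements.csv")
  report <- as.data.frame(pert)
  utils::write.csv(report, report_csv, row.names = FALSE)
  jsonlite::write_json(c(as.list(report),
                         list(cutoff = cutoff, active_site = active_site)),
                       report_json, auto_unbox = TRUE, digits = NA)
  colored_structure(wt, pert, bins, pdb_file = colored_pdb,
                    csv_file = disp_csv)
  invisible(list(report_csv = report_csv, report_json = report_json,
                 colored_pdb = colored_pdb, displacements_csv = disp_csv,
                 perturbation = pert))
}

#' Run the phenotype-group statistics on a mutation table
#'
#' Loads and validates a mutation catalogue, runs
#' [phenotype_comparison()] and writes the aggregate report as JSON and
#' as human-readable text.
#'
#' @param table_file CSV path or `mutation_table`.
#' @param out_dir output directory.
#' @param alpha significance level.
#' @return Invisibly, list of written paths plus the
#'   `phenotype_comparison` object.
#' @export
run_stats <- function(table_file, out_dir = ".", alpha = 0.05) {
  tab <- if (inherits(table_file, "mutation_table")) table_file else {
    load_mutation_table(table_file)
  }
  comp <- phenotype_comparison(tab, alpha = alpha)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  json_file <- file.path(out_dir, "group_stats.json")
  txt_file <- file.path(out_dir, "group_stats.txt")
  flat <- list(
    n_severe = comp$n_severe, n_attenuated = comp$n_attenuated,
    metrics = lapply(comp$metrics, function(m) {
      list(severe_mean = m$severe$mean, severe_sd = m$severe$sd,
           attenuated_mean = m$attenuated$mean,
           attenuated_sd = m$attenuated$sd,
           welch_t = m$welch$t, welch_df = m$welch$df, welch_p = m$welch$p,
           significant = m$significant)
    }),
    severe_main_ge_threshold = comp$severe_main_ge_threshold,
    attenuated_main_lt_threshold = comp$attenuated_main_lt_threshold,
    active_site_involved = comp$active_site_involved)
  jsonlite::write_json(flat, json_file, auto_unbox = TRUE, digits = NA)
  txt <- utils::capture.output(print(comp))
  writeLines(txt, txt_file)
  invisible(list(json = json_file, txt = txt_file, comparison = comp))
}

#' Per-residue accessible surface area of a model file
#'
#' @param pdb_file path to a PDB file.
#' @param out_file output CSV path (chain, residue number, residue name,
#'   ASA in square Angstrom).
#' @param probe_radius,n_sphere_points passed to [shrake_rupley()].
#' @return Invisibly, the `asa_result`.
#' @export
run_asa <- function(pdb_file, out_file = "asa.csv", probe_radius = 1.4,
                    n_sphere_points = 960L) {
  if (!file.exists(pdb_file)) {
    stop_validation(sprintf("file not found: %s", pdb_file))
  }
  model <- parse_pdb(pdb_file)
  res <- shrake_rupley(model, probe_radius = probe_radius,
                       n_sphere_points = n_sphere_points)
  utils::write.csv(res$per_residue, out_file, row.names = FALSE)
  invisible(res)
}
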