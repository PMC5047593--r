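#' Summary statistics of one group
#'
#' Mean, sample standard deviation (n - 1 denominator) and the five-number
#' summary with quartiles by the linear-interpolation convention
#' ([stats::quantile()] type 7).
#'
#' @param values numeric vector, nonempty.
#' @return List with `n`, `mean`, `sd` (NA when n < 2) and `five_number`
#'   (min, q1, median, q3, max).
#' @export
group_summary <- function(values) {
  values <- as.numeric(values)
  if (length(values) == 0L || any(is.na(values))) {
    stop_validation("group_summary needs a nonempty vector without NAs")
  }
  q <- unname(stats::quantile(values, c(0, 0.25, 0.5, 0.75, 1), type = 7))
  list(n = length(values),
       mean = mean(values),
       sd = if (length(values) >= 2L) stats::sd(values) else NA_real_,
       five_number = stats::setNames(q, c("min", "q1", "median", "q3",
                                          "max")))
}

#' Welch's two-sample t-test
#'
#' Two-sided location test not assuming equal variances:
#' `t = (mean(a) - mean(b)) / sqrt(var(a)/na + var(b)/nb)` with
#' Welch-Satterthwaite degrees of freedom, computed via
#' [stats::t.test()] with `var.equal = FALSE`.
#'
#' @param a,b numeric vectors, each with at least two values and nonzero
#'   variance.
#' @return An object of class `welch_result` with `t`, `df`, `p` and
#'   `two_sided = TRUE`.
#' @export
welch_test <- function(a, b) {
  if (length(a) < 2L || length(b) < 2L) {
    stop_validation("each group needs at least two values")
  }
  if (stats::var(a) == 0 || stats::var(b) == 0) {
    stop_validation("degenerate (zero-variance) group in Welch's t-test")
  }
  ht <- stats::t.test(a, b, var.equal = FALSE)
  out <- list(t = unname(ht$statistic), df = unname(ht$parameter),
              p = ht$p.value, two_sided = TRUE)
  class(out) <- "welch_result"
  out
}

#' @export
print.welch_result <- function(x, ...) {
  cat(sprintf("Welch's t-test: t = %.4f, df = %.2f, p = %.4g (two-sided)\n",
              x$t, x$df, x$p))
  invisible(x)
}

#' Count values beyond a threshold
#'
#' @param values numeric vector, nonempty.
#' @param op `">="` or `"<="`.
#' @param threshold the threshold.
#' @return List with `count` and `fraction` (= count / n).
#' @export
threshold_count <- function(values, op = c(">=", "<="), threshold) {
  op <- match.arg(op)
  if (length(values) == 0L) stop_validation("empty value vector")
  count <- if (op == ">=") sum(values >= threshold) else {
    sum(values <= threshold)
  }
  list(count = count, fraction = count / length(values))
}

#' Phenotype-group comparison of structural metrics
#'
#' Reproduces the group-level analysis of a mutation catalogue: for each
#' metric (main-chain count, side-chain count, RMSD, ASA) the per-group
#' mean, SD and five-number summary plus a two-sided Welch t-test between
#' the severe and attenuated groups; the proportion of severe cases with
#' 50 or more affected main-chain atoms and of attenuated cases with 49
#' or fewer; and the proportion of cases in each group with any
#' active-site atom affected (active-site count > 0).
#'
#' @param table a `mutation_table` (e.g. [ids_mutations()]).
#' @param alpha significance level for the `significant` flags
#'   (default 0.05).
#' @param main_threshold main-chain atom threshold for the proportion
#'   summaries (default 50).
#' @return An object of class `phenotype_comparison`.
#' @examples
#' comp <- phenotype_comparison(ids_mutations())
#' comp
#' @export
phenotype_comparison <- function(table, alpha = 0.05, main_threshold = 50) {
  sev <- table[table$phenotype == "Severe", , drop = FALSE]
  att <- table[table$phenotype == "Attenuated", , drop = FALSE]
  if (nrow(sev) < 2L || nrow(att) < 2L) {
    stop_validation("need at least two records per phenotype group")
  }
  metrics <- c(main_chain = "main_chain", side_chain = "side_chain",
               rmsd = "rmsd", asa = "asa")
  per_metric <- lapply(metrics, function(col) {
    wt <- welch_test(sev[[col]], att[[col]])
    list(severe = group_summary(sev[[col]]),
         attenuated = group_summary(att[[col]]),
         welch = wt,
         significant = wt$p < alpha)
  })
  thr_sev <- threshold_count(sev$main_chain, ">=", main_threshold)
  thr_att <- threshold_count(att$main_chain, "<=", main_threshold - 1)
  act_sev <- threshold_count(sev$active_site, ">=", 1)
  act_att <- threshold_count(att$active_site, ">=", 1)
  out <- list(n_severe = nrow(sev), n_attenuated = nrow(att),
              metrics = per_metric,
              main_chain_threshold = main_threshold,
              severe_main_ge_threshold = thr_sev,
              attenuated_main_lt_threshold = thr_att,
              active_site_involved = list(severe = act_sev,
                                          attenuated = act_att),
              alpha = alpha)
  class(out) <- "phenotype_comparison"
  out
}

#' @export
print.phenotype_comparison <- function(x, ...) {
  cat(sprintf("Phenotype-group comparison: %d severe vs %d attenuated\n",
              x$n_severe, x$n_attenuated))
  for (nm in names(x$metrics)) {
    m <- x$metrics[[nm]]
    cat(sprintf("  %-10s severe %8.3f (+/- %7.3f)  attenuated %8.3f (+/- %7.3f)  Welch p = %-8.3g%s\n",
                nm, m$severe$mean, m$severe$sd, m$attenuated$mean,
                m$attenuated$sd, m$welch$p,
                if (m$significant) " *" else ""))
  }
  cat(sprintf("  severe with >= %d main-chain atoms affected: %d/%d (%.0f%%)\n",
              x$main_chain_threshold, x$severe_main_ge_threshold$count,
              x$n_severe, 100 * x$severe_main_ge_threshold$fraction))
  cat(sprintf("  attenuated with <= %d: %d/%d (%.0f%%)\n",
              x$main_chain_threshold - 1,
              x$attenuated_main_lt_threshold$count, x$n_attenuated,
              100 * x$attenuated_main_lt_threshold$fraction))
  cat(sprintf("  active site involved: severe %d/%d (%.0f%%), attenuated %d/%d (%.0f%%)\n",
              x$active_site_involved$severe$count, x$n_severe,
              100 * x$active_site_involved$severe$fraction,
              x$active_site_involved$attenuated$count, x$n_attenuated,
              100 * x$active_site_involved$attenuated$fraction))
  invisible(x)
}

#' Boxplots of the four structural metrics by phenotype group
#'
#' @param x a `phenotype_comparison` built from a table that is still
#'   available; pass the table itself.
#' @param table the `mutation_table` the comparison was built from.
#' @param ... passed to [graphics::boxplot()].
#' @export
plot.phenotype_comparison <- function(x, table, ...) {
  if (missing(table)) stop_validation("plot needs the source mutation_table")
  old <- graphics::par(mfrow = c(2, 2))
  on.exit(graphics::par(old))
  labs <- c(main_chain = "affected main-chain atoms",
            side_chain = "affected side-chain atoms",
            rmsd = "RMSD (Angstrom)", asa = "ASA (sq. Angstrom)")
  for (nm in names(labs)) {
    graphics::boxplot(table[[nm]] ~ table$phenotype, xlab = "",
                      ylab = labs[[nm]], ...)
  }
  invisible(x)
}
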