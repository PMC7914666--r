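#' Mann-Whitney-Wilcoxon rank-sum test
#'
#' Two-sided rank-sum comparison of two SSC samples, used at harvest to
#' compare destructively measured and model-predicted SSC, whose
#' distributions need not be normal. Small untied samples are tested
#' exactly (the p-value enumerates all orderings); larger or tied samples
#' use midranks and the normal approximation with continuity correction.
#'
#' @param a,b Numeric % SSC vectors.
#' @return A one-row tibble: `u` (the U statistic of `a`), `u_other`
#'   (`length(a) * length(b) - u`), `p_value`, `exact` (whether the exact
#'   distribution was used) and the sample sizes.
#' @examples
#' mann_whitney(c(10.2, 11.1, 10.8), c(11.6, 12.0, 11.9))
#' @export
mann_whitney <- function(a, b) {
  if (length(a) == 0 || length(b) == 0) abort("both samples must be non-empty.")
  ties <- anyDuplicated(c(a, b)) > 0
  exact <- !ties && length(a) <= 20 && length(b) <= 20
  wt <- suppressWarnings(
    wilcox.test(a, b, exact = exact, correct = TRUE,
                alternative = "two.sided"))
  tibble::tibble(u = unname(wt$statistic),
                 u_other = length(a) * length(b) - unname(wt$statistic),
                 p_value = wt$p.value, exact = exact,
                 n_a = length(a), n_b = length(b))
}

#' Agreement between destructive and non-destructive SSC at harvest
#'
#' Summarises harvest samples measured by both methods: overall mean and sd
#' per method, the per-treatment-level mean difference between methods
#' (destructive minus non-destructive, reported both signed and in absolute
#' value), the grand means of those differences, and the two-sided
#' Mann-Whitney test over all values of the two methods. Treatment levels
#' observed under only one method are excluded (their count is reported).
#'
#' @param samples A tibble with columns `method` (`"destructive"` /
#'   `"nondestructive"`), `treatment_level` and `ssc`.
#' @return An `ssc_method_comparison` object: `by_method` and `per_level`
#'   tibbles, `grand_mean_abs_difference`, `grand_mean_signed_difference`,
#'   `mann_whitney` row, `n_excluded_levels`.
#' @export
method_difference <- function(samples) {
  need <- c("method", "treatment_level", "ssc")
  if (!all(need %in% names(samples))) {
    abort(paste("samples must contain columns:", paste(need, collapse = ", ")))
  }
  bad <- setdiff(unique(samples$method), c("destructive", "nondestructive"))
  if (length(bad)) abort(paste("unknown method:", paste(bad, collapse = ", ")))

  by_method <- dplyr::summarise(
    dplyr::group_by(samples, .data$method),
    mean_ssc = mean(.data$ssc), sd_ssc = sd(.data$ssc),
    n = dplyr::n(), .groups = "drop")
  if (nrow(by_method) < 2) abort("both methods must be represented.")

  level_means <- tidyr::pivot_wider(
    dplyr::summarise(
      dplyr::group_by(samples, .data$treatment_level, .data$method),
      mean_ssc = mean(.data$ssc), .groups = "drop"),
    names_from = "method", values_from = "mean_ssc")
  incomplete <- !stats::complete.cases(level_means)
  if (any(incomplete)) {
    warn(paste(sum(incomplete),
               "treatment level(s) observed under one method only; excluded."))
  }
  per_level <- dplyr::mutate(
    level_means[!incomplete, , drop = FALSE],
    difference = .data$destructive - .data$nondestructive,
    abs_difference = abs(.data$difference))

  structure(
    list(by_method = by_method, per_level = per_level,
         grand_mean_abs_difference = mean(per_level$abs_difference),
         grand_mean_signed_difference = mean(per_level$difference),
         mann_whitney = mann_whitney(
           samples$ssc[samples$method == "destructive"],
           samples$ssc[samples$method == "nondestructive"]),
         n_excluded_levels = sum(incomplete)),
    class = "ssc_method_comparison")
}

#' @exportS3Method base::print
print.ssc_method_comparison <- function(x, ...) {
  cat("<ssc_method_comparison>\n")
  print(x$by_method)
  cat(sprintf("mean |difference| per level: %.2f %%SSC (signed: %+.2f)\n",
              x$grand_mean_abs_difference, x$grand_mean_signed_difference))
  cat(sprintf("Mann-Whitney p = %.3g (%s)\n", x$mann_whitney$p_value,
              if (x$mann_whitney$exact) "exact" else "normal approximation"))
  if (x$n_excluded_levels > 0) {
    cat(x$n_excluded_levels, "level(s) excluded (single method).\n")
  }
  invisible(x)
}

#' @rdname method_difference
#' @param x An `ssc_method_comparison`.
#' @param ... Unused.
#' @export
glance.ssc_method_comparison <- function(x, ...) {
  tibble::tibble(
    grand_mean_abs_difference = x$grand_mean_abs_difference,
    grand_mean_signed_difference = x$grand_mean_signed_difference,
    p_value = x$mann_whitney$p_value,
    n_levels = nrow(x$per_level),
    n_excluded_levels = x$n_excluded_levels)
}
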