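#' Percent reduction between group means with bootstrap CI
#'
#' `100 x (mean(reference) - mean(comparison)) / mean(reference)`, with a
#' seeded percentile bootstrap confidence interval (both groups resampled
#' independently). Positive values mean the comparison group is lower.
#'
#' @param reference Activity vector of the reference group (e.g. F-type
#'   carriers).
#' @param comparison Activity vector of the comparison group.
#' @param reps Bootstrap replicates.
#' @param conf Confidence level.
#' @param seed Optional seed for the bootstrap.
#' @return List with `percent`, `ci`, `reps`.
#' @examples
#' percent_reduction(rep(100, 5), rep(69, 5), reps = 0)$percent
#' @export
percent_reduction <- function(reference, comparison, reps = 2000L,
                              conf = 0.95, seed = NULL) {
  if (length(reference) < 3L || length(comparison) < 3L) {
    abort("at least 3 values per group are required")
  }
  if (mean(reference) <= 0) abort("non-positive reference mean")
  pct <- function(a, b) 100 * (mean(a) - mean(b)) / mean(a)
  point <- pct(reference, comparison)
  ci <- c(NA_real_, NA_real_)
  if (reps > 0L) {
    boot <- function() {
      pct(sample(reference, replace = TRUE), sample(comparison, replace = TRUE))
    }
    draws <- if (is.null(seed)) replicate(reps, boot())
             else withr::with_seed(seed, replicate(reps, boot()))
    alpha <- (1 - conf) / 2
    ci <- unname(stats::quantile(draws, c(alpha, 1 - alpha)))
  }
  list(percent = point, ci = ci, reps = as.integer(reps))
}

#' Nonparametric sex-by-mitotype tests on an enzyme activity
#'
#' The study's stated test suite: a Kruskal-Wallis test across the four
#' sex-by-mitotype groups, pairwise Wilcoxon rank-sum post hoc comparisons
#' with Holm adjustment, and the two marginal Wilcoxon contrasts (mitotype
#' pooled over sex; sex pooled over mitotype). Groups with fewer than two
#' observations are flagged and excluded from the post hoc matrix.
#'
#' @param table Phenotype tibble with columns `sex`, `mitotype` and the
#'   endpoint.
#' @param endpoint Column name of the activity to test (`"ETS"`, `"COX"`,
#'   `"CS"`, ...).
#' @return An object of class `effect_report`: `endpoint`,
#'   `group_summary` (tibble of group n and means), `kw` (statistic, df,
#'   p), `posthoc` (Holm-adjusted pairwise Wilcoxon p matrix),
#'   `marginal` (tibble: factor, statistic, p), `flagged_groups`.
#' @examples
#' ph <- simulate_phenotypes(synth_config(seed = 7), n_per_group = 30)
#' factorial_tests(ph, "ETS")$marginal
#' @export
factorial_tests <- function(table, endpoint) {
  table <- as_tibble(table)
  if (!endpoint %in% names(table)) abort(sprintf("no column '%s'", endpoint))
  stopifnot(all(c("sex", "mitotype") %in% names(table)))
  y <- table[[endpoint]]
  if (any(!is.finite(y)) || any(y <= 0)) abort("activities must be positive")
  group <- interaction(table$sex, table$mitotype, drop = TRUE, sep = ":")
  if (nlevels(group) < 2L) abort("at least 2 non-empty groups are required")

  sizes <- table(group)
  flagged <- names(sizes)[sizes < 2L]
  ok <- group %in% names(sizes)[sizes >= 2L]

  kw <- stats::kruskal.test(y ~ group)
  ph <- stats::pairwise.wilcox.test(y[ok], droplevels(group[ok]),
                                    p.adjust.method = "holm", exact = FALSE)

  marginal <- dplyr::bind_rows(
    marginal_row("mitotype", y, table$mitotype),
    marginal_row("sex", y, table$sex)
  )
  grp <- dplyr::group_by(table, .data$sex, .data$mitotype)
  summ <- dplyr::summarise(grp, n = dplyr::n(),
                           mean = mean(.data[[endpoint]]),
                           median = stats::median(.data[[endpoint]]),
                           .groups = "drop")
  structure(
    list(endpoint = endpoint, group_summary = summ,
         kw = list(statistic = unname(kw$statistic),
                   df = unname(kw$parameter), p = kw$p.value),
         posthoc = ph$p.value, marginal = marginal,
         flagged_groups = flagged),
    class = "effect_report"
  )
}

marginal_row <- function(factor_name, y, f) {
  f <- as.factor(f)
  if (nlevels(droplevels(f)) != 2L) {
    return(tibble(factor = factor_name, statistic = NA_real_, p = NA_real_))
  }
  w <- stats::wilcox.test(y ~ f, exact = FALSE)
  tibble(factor = factor_name, statistic = unname(w$statistic), p = w$p.value)
}

#' @export
print.effect_report <- function(x, ...) {
  cat(sprintf("<effect_report> %s\n", x$endpoint))
  cat(sprintf("  Kruskal-Wallis: chi2 = %.3f, df = %d, p = %.3g\n",
              x$kw$statistic, x$kw$df, x$kw$p))
  for (i in seq_len(nrow(x$marginal))) {
    cat(sprintf("  marginal %s: W = %.1f, p = %.3g\n",
                x$marginal$factor[i], x$marginal$statistic[i], x$marginal$p[i]))
  }
  if (length(x$flagged_groups)) {
    cat("  flagged groups (<2 obs):", paste(x$flagged_groups, collapse = ", "), "\n")
  }
  invisible(x)
}
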