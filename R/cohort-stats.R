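# Cohort-level statistics: Pearson chi-square tests on contingency tables,
# two-sample t-tests (from summary statistics or raw samples), one-way ANOVA
# with Tukey-Kramer post-hoc comparisons, and the inter-observer comparison
# of CTCAE grade distributions. Significance convention: alpha = 0.05,
# two-sided throughout.

.new_cohort_test <- function(method, statistic, df, p_value,
                             estimate = NA_real_, conf_low = NA_real_,
                             conf_high = NA_real_, conf_level = NA_real_,
                             warnings = character(), extra = list()) {
  structure(
    list(method = method, statistic = statistic, df = df, p_value = p_value,
         estimate = estimate, conf_low = conf_low, conf_high = conf_high,
         conf_level = conf_level, warnings = warnings, extra = extra),
    class = "cohort_test"
  )
}

#' @export
print.cohort_test <- function(x, ...) {
  cat("<cohort_test>", x$method, "\n")
  cat(sprintf("  statistic = %.4g, df = %s, p = %.4g\n",
              x$statistic, paste(signif(x$df, 4), collapse = ", "), x$p_value))
  if (!is.na(x$estimate)) {
    cat(sprintf("  estimate = %.4g, %g%% CI [%.4g, %.4g]\n",
                x$estimate, 100 * x$conf_level, x$conf_low, x$conf_high))
  }
  for (w in x$warnings) cat("  warning:", w, "\n")
  invisible(x)
}

#' Tidy a cohort test result
#' @param x A `cohort_test`.
#' @param ... Unused.
#' @return A one-row tibble with `method`, `statistic`, `df`, `p_value` and,
#'   where applicable, `estimate`, `conf_low`, `conf_high`.
#' @method tidy cohort_test
#' @export
tidy.cohort_test <- function(x, ...) {
  tibble::tibble(method = x$method, statistic = x$statistic, df = x$df[1],
                 p_value = x$p_value, estimate = x$estimate,
                 conf_low = x$conf_low, conf_high = x$conf_high)
}

#' @rdname tidy.cohort_test
#' @method glance cohort_test
#' @export
glance.cohort_test <- function(x, ...) tidy(x, ...)

#' Pearson chi-square test on a contingency table
#'
#' Pearson's chi-square without continuity correction (the variant that
#' reproduces classical SPSS output for r x c tables), with
#' `df = (r - 1)(c - 1)`. A warning is attached when any expected count
#' falls below 5; with Yates' continuity correction available behind
#' `correct = TRUE` for 2 x 2 tables.
#'
#' @param counts An `r x c` matrix (or data frame) of nonnegative counts,
#'   at least 2 x 2, with strictly positive row and column sums.
#' @param correct Apply Yates' continuity correction (2 x 2 only). Default
#'   `FALSE`.
#' @return A `cohort_test`; `$extra$expected` holds the expected counts.
#' @export
#' @examples
#' skin_type <- rbind(bepanthen = c(22, 39, 5), r1r2 = c(10, 21, 3))
#' chi_square_test(skin_type) # p = 0.91, printed as 0.92 after rounding
chi_square_test <- function(counts, correct = FALSE) {
  counts <- as.matrix(counts)
  if (any(counts < 0) || anyNA(counts)) {
    stop("counts must be nonnegative and complete", call. = FALSE)
  }
  if (nrow(counts) < 2L || ncol(counts) < 2L) {
    stop("contingency table must be at least 2 x 2", call. = FALSE)
  }
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0)) {
    stop("contingency table has a zero marginal (empty row or column)",
         call. = FALSE)
  }
  ht <- suppressWarnings(stats::chisq.test(counts, correct = correct))
  warnings <- character()
  if (any(ht$expected < 5)) {
    warnings <- sprintf("%d expected cell count(s) below 5; chi-square approximation may be inaccurate",
                        sum(ht$expected < 5))
  }
  .new_cohort_test(
    method = if (correct) "Pearson chi-square (Yates-corrected)" else "Pearson chi-square",
    statistic = unname(ht$statistic), df = unname(ht$parameter),
    p_value = unname(ht$p.value), warnings = warnings,
    extra = list(observed = counts, expected = ht$expected)
  )
}

#' Two-sample t-test from summary statistics or raw samples
#'
#' Student's pooled-variance two-sided t-test, computable directly from the
#' printed group summaries (mean, SD, n) of a published table; a Welch
#' variant is available behind `var_equal = FALSE`. Raw samples may be
#' passed instead via `x` and `y` (their mean and sample SD are then used).
#'
#' @param x,y Optional raw samples (numeric vectors, each of length >= 2);
#'   when given, the summary arguments are ignored.
#' @param mean1,sd1,n1 Summary statistics of group 1.
#' @param mean2,sd2,n2 Summary statistics of group 2.
#' @param var_equal Pool the variances (Student, the default) or not
#'   (Welch-Satterthwaite df).
#' @param conf_level Confidence level of the interval on `mean1 - mean2`.
#' @return A `cohort_test` with `estimate` = mean difference and its CI.
#' @export
#' @examples
#' # group summaries of untreated-skin lightness: p = 0.87
#' two_sample_t(mean1 = 66.74, sd1 = 6.43, n1 = 66,
#'              mean2 = 66.5, sd2 = 8.05, n2 = 34)
two_sample_t <- function(x = NULL, y = NULL, mean1, sd1, n1, mean2, sd2, n2,
                         var_equal = TRUE, conf_level = 0.95) {
  if (!is.null(x) || !is.null(y)) {
    if (is.null(x) || is.null(y) || length(x) < 2L || length(y) < 2L) {
      stop("both `x` and `y` must be samples of length >= 2", call. = FALSE)
    }
    mean1 <- mean(x); sd1 <- stats::sd(x); n1 <- length(x)
    mean2 <- mean(y); sd2 <- stats::sd(y); n2 <- length(y)
  }
  if (n1 < 2L || n2 < 2L) stop("both groups need n >= 2", call. = FALSE)
  if (sd1 < 0 || sd2 < 0) stop("SDs must be nonnegative", call. = FALSE)
  diff <- mean1 - mean2
  warnings <- character()
  if (var_equal) {
    sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
    method <- "Two-sample t-test (pooled variance)"
  } else {
    se <- sqrt(sd1^2 / n1 + sd2^2 / n2)
    df <- se^4 / ((sd1^2 / n1)^2 / (n1 - 1) + (sd2^2 / n2)^2 / (n2 - 1))
    method <- "Welch two-sample t-test"
  }
  if (se == 0) {
    if (diff == 0) {
      tstat <- 0; p <- 1
    } else {
      tstat <- sign(diff) * Inf; p <- 0
      warnings <- "zero pooled variance with unequal means; p set to 0"
    }
    ci <- c(diff, diff)
  } else {
    tstat <- diff / se
    p <- 2 * stats::pt(-abs(tstat), df)
    tcrit <- stats::qt(1 - (1 - conf_level) / 2, df)
    ci <- diff + c(-1, 1) * tcrit * se
  }
  .new_cohort_test(method, statistic = tstat, df = df, p_value = p,
                   estimate = diff, conf_low = ci[1], conf_high = ci[2],
                   conf_level = conf_level, warnings = warnings)
}

#' One-way ANOVA with Tukey-Kramer post-hoc comparisons
#'
#' Fits a one-way ANOVA across the groups and, when more than two groups are
#' present (or on request), all pairwise post-hoc comparisons via Tukey's
#' HSD with the Tukey-Kramer adjustment for unequal group sizes.
#'
#' @param data A data frame with a numeric response and a grouping column,
#'   or a named list of numeric samples (one element per group).
#' @param value,group Column names (bare or quoted) of the response and the
#'   grouping variable when `data` is a data frame. Defaults `value`,
#'   `group`.
#' @param posthoc Compute pairwise Tukey-Kramer comparisons (default `TRUE`).
#' @param conf_level Confidence level of the post-hoc intervals.
#' @return A `cohort_anova` with `$anova` (one-row tibble: `statistic` F,
#'   `df`, `df_resid`, `p_value`) and `$posthoc` (tibble: `comparison`,
#'   `estimate`, `conf_low`, `conf_high`, `p_adj`).
#' @export
anova_posthoc <- function(data, value = "value", group = "group",
                          posthoc = TRUE, conf_level = 0.95) {
  if (is.list(data) && !is.data.frame(data)) {
    if (is.null(names(data)) || any(names(data) == "")) {
      stop("group list must be named", call. = FALSE)
    }
    data <- tibble::tibble(
      value = unlist(data, use.names = FALSE),
      group = rep(names(data), lengths(data))
    )
    value <- "value"; group <- "group"
  }
  value <- rlang::as_name(rlang::ensym(value))
  group <- rlang::as_name(rlang::ensym(group))
  y <- data[[value]]
  g <- factor(data[[group]])
  if (nlevels(g) < 2L) stop("at least 2 groups are required", call. = FALSE)
  if (any(table(g) < 2L)) stop("every group needs n >= 2", call. = FALSE)
  warnings <- character()
  vars <- tapply(y, g, stats::var)
  if (any(vars == 0)) {
    warnings <- sprintf("group(s) with zero variance: %s",
                        paste(names(vars)[vars == 0], collapse = ", "))
  }
  fit <- stats::aov(y ~ g)
  tab <- summary(fit)[[1]]
  anova_row <- tibble::tibble(
    statistic = tab[["F value"]][1],
    df = tab[["Df"]][1], df_resid = tab[["Df"]][2],
    p_value = tab[["Pr(>F)"]][1]
  )
  ph <- NULL
  if (posthoc) {
    tk <- stats::TukeyHSD(fit, conf.level = conf_level)$g
    ph <- tibble::tibble(
      comparison = rownames(tk),
      estimate = unname(tk[, "diff"]), conf_low = unname(tk[, "lwr"]),
      conf_high = unname(tk[, "upr"]), p_adj = unname(tk[, "p adj"])
    )
  }
  structure(list(anova = anova_row, posthoc = ph, warnings = warnings,
                 conf_level = conf_level),
            class = "cohort_anova")
}

#' @export
print.cohort_anova <- function(x, ...) {
  cat("<cohort_anova> one-way ANOVA\n")
  cat(sprintf("  F(%d, %d) = %.4g, p = %.4g\n",
              x$anova$df, x$anova$df_resid, x$anova$statistic,
              x$anova$p_value))
  if (!is.null(x$posthoc)) {
    cat("  Tukey-Kramer post-hoc comparisons:\n")
    print(as.data.frame(x$posthoc), digits = 4)
  }
  for (w in x$warnings) cat("  warning:", w, "\n")
  invisible(x)
}

#' Tidy an ANOVA result
#' @param x A `cohort_anova`.
#' @param ... Unused.
#' @return `tidy()`: the post-hoc comparison tibble (or the ANOVA row when
#'   post-hoc was skipped); `glance()`: the one-row ANOVA tibble.
#' @method tidy cohort_anova
#' @export
tidy.cohort_anova <- function(x, ...) {
  if (is.null(x$posthoc)) x$anova else x$posthoc
}

#' @rdname tidy.cohort_anova
#' @method glance cohort_anova
#' @export
glance.cohort_anova <- function(x, ...) x$anova

#' Compare the grade distributions of two observers
#'
#' Tests whether two observers assign CTCAE grades with the same marginal
#' distribution: the observer-by-grade contingency table of grade counts is
#' tested with [chi_square_test()]. The paired observer1 x observer2
#' cross-tabulation is also returned for inspection of where the
#' disagreement lies (the marginal test ignores pairing).
#'
#' @param records A data frame with one row per patient and one grade column
#'   per observer (integer CTCAE grades 0-4).
#' @param obs1,obs2 Names of the two grade columns (default `grade_obs1`,
#'   `grade_obs2`).
#' @return A list of class `interobserver_comparison`: `test` (a
#'   `cohort_test`), `marginal_table` (2 x grades counts), `cross_tab`
#'   (paired counts).
#' @export
interobserver_comparison <- function(records, obs1 = "grade_obs1",
                                     obs2 = "grade_obs2") {
  g1 <- records[[obs1]]
  g2 <- records[[obs2]]
  if (is.null(g1) || is.null(g2)) {
    stop("grade columns not found: ", obs1, ", ", obs2, call. = FALSE)
  }
  missing <- is.na(g1) | is.na(g2)
  if (any(missing)) {
    ids <- if (!is.null(records$patient_id)) {
      records$patient_id[missing]
    } else {
      which(missing)
    }
    stop("missing grades for patients: ", paste(ids, collapse = ", "),
         call. = FALSE)
  }
  grades <- sort(unique(c(g1, g2)))
  counts <- rbind(
    obs1 = as.integer(table(factor(g1, levels = grades))),
    obs2 = as.integer(table(factor(g2, levels = grades)))
  )
  colnames(counts) <- paste0("grade_", grades)
  rownames(counts) <- c(obs1, obs2)
  if (length(grades) < 2L) {
    test <- .new_cohort_test(
      "Pearson chi-square", statistic = 0, df = 0, p_value = 1,
      warnings = "both observers used a single grade; test is degenerate",
      extra = list(observed = counts))
  } else {
    test <- chi_square_test(counts)
  }
  cross <- table(factor(g1, levels = grades), factor(g2, levels = grades),
                 dnn = c(obs1, obs2))
  structure(list(test = test, marginal_table = counts, cross_tab = cross,
                 significant = test$p_value < 0.05),
            class = "interobserver_comparison")
}

#' @export
print.interobserver_comparison <- function(x, ...) {
  cat("<interobserver_comparison>\n  marginal grade counts:\n")
  print(x$marginal_table)
  cat(sprintf("  chi-square = %.4g, df = %s, p = %.4g (%ssignificant at 0.05)\n",
              x$test$statistic, paste(x$test$df, collapse = ","),
              x$test$p_value, if (x$significant) "" else "not "))
  invisible(x)
}

#' @method tidy interobserver_comparison
#' @export
tidy.interobserver_comparison <- function(x, ...) tidy(x$test, ...)
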