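#' Welch two-sample comparison of mean costs
#'
#' Unequal-variance t statistic with Satterthwaite degrees of freedom,
#' two-sided p-value and 95\% confidence interval on the mean difference.
#' The reported difference is oriented as \code{mean(b) - mean(a)}; calling
#' \code{welch_test(integrated, standard)} therefore reports the saving
#' from integrated care as a positive number, matching the reporting
#' convention for per-visit cost tables.
#'
#' @param a,b numeric samples (e.g. integrated-arm and standard-arm visit
#'   costs), each of length >= 2.
#' @param conf_level confidence level, default 0.95.
#' @return one-row data.frame of class \code{comparison_result}: n_a, n_b,
#'   mean_a, mean_b, diff, se, df, ci_low, ci_high, p_value, estimable.
#' @export
welch_test <- function(a, b, conf_level = 0.95) {
  if (length(a) < 2L || length(b) < 2L) {
    stop("insufficient data: both samples need n >= 2", call. = FALSE)
  }
  welch_summary_test(mean(a), stats::sd(a), length(a),
                     mean(b), stats::sd(b), length(b), conf_level)
}

#' Welch comparison from group summary statistics
#'
#' Same test as \code{\link{welch_test}} but computed from (mean, sd, n)
#' summaries, so published table rows can be compared directly.
#'
#' @param mean_a,sd_a,n_a,mean_b,sd_b,n_b group summaries.
#' @param conf_level confidence level, default 0.95.
#' @export
welch_summary_test <- function(mean_a, sd_a, n_a, mean_b, sd_b, n_b,
                               conf_level = 0.95) {
  if (n_a < 2L || n_b < 2L) {
    stop("insufficient data: both groups need n >= 2", call. = FALSE)
  }
  va <- sd_a^2 / n_a
  vb <- sd_b^2 / n_b
  se <- sqrt(va + vb)
  diff <- mean_b - mean_a
  if (se == 0) {
    # both groups constant: difference is known exactly
    t_stat <- if (diff == 0) 0 else sign(diff) * Inf
    df <- Inf
    p <- if (diff == 0) 1 else 0
    ci <- c(diff, diff)
  } else {
    t_stat <- diff / se
    df <- (va + vb)^2 / (va^2 / (n_a - 1) + vb^2 / (n_b - 1))
    p <- 2 * stats::pt(-abs(t_stat), df)
    crit <- stats::qt(1 - (1 - conf_level) / 2, df)
    ci <- diff + c(-1, 1) * crit * se
  }
  structure(data.frame(n_a = n_a, n_b = n_b, mean_a = mean_a, mean_b = mean_b,
                       diff = diff, se = se, df = df,
                       ci_low = ci[1], ci_high = ci[2], p_value = p,
                       estimable = TRUE),
            class = c("comparison_result", "data.frame"))
}

not_estimable_row <- function(n_a, n_b) {
  structure(data.frame(n_a = n_a, n_b = n_b, mean_a = NA_real_,
                       mean_b = NA_real_, diff = NA_real_, se = NA_real_,
                       df = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                       p_value = NA_real_, estimable = FALSE),
            class = c("comparison_result", "data.frame"))
}

#' All arm comparisons and pooled contrasts
#'
#' Computes, for each perspective supplied (provider, patient, societal),
#' the integrated-vs-standard comparison in every (country, profile) cell,
#' pooled single-condition and multimorbid arm comparisons, and pooled
#' descriptive contrasts (HIV vs HTN, HIV vs DM, multimorbid vs single,
#' Uganda vs Tanzania). Cells with fewer than two observations in either
#' group are flagged not estimable and the pipeline continues.
#'
#' @param cost_tables named list of per-visit cost tables; each must have
#'   columns country, arm, profile and a total column.
#' @param total_col name of the value column (default \code{"total"};
#'   \code{societal_total} is used automatically if present).
#' @return data.frame with perspective, contrast, group columns and the
#'   \code{\link{welch_test}} fields.
#' @export
compare_all <- function(cost_tables, total_col = "total") {
  rows <- list()
  add <- function(perspective, contrast, group, res) {
    res$perspective <- perspective; res$contrast <- contrast; res$group <- group
    rows[[length(rows) + 1L]] <<- res
  }
  cell_test <- function(df, val, sel_a, sel_b) {
    a <- df[[val]][sel_a]; b <- df[[val]][sel_b]
    if (length(a) < 2L || length(b) < 2L) {
      not_estimable_row(length(a), length(b))
    } else welch_test(a, b)
  }
  for (persp in names(cost_tables)) {
    df <- cost_tables[[persp]]
    val <- if (total_col %in% names(df)) total_col else
      if ("societal_total" %in% names(df)) "societal_total" else
        stop("no total column in ", persp, " table", call. = FALSE)
    int <- df$arm == "integrated"; std <- df$arm == "standard"
    # per (country, profile) arm comparison: diff = standard - integrated
    for (co in unique(df$country)) {
      for (pf in intersect(PROFILES, unique(df$profile[df$country == co]))) {
        sel <- df$country == co & df$profile == pf
        add(persp, "arm", paste(co, pf),
            cell_test(df, val, sel & int, sel & std))
      }
    }
    multi <- is_multimorbid(df$profile)
    add(persp, "arm", "pooled single",
        cell_test(df, val, !multi & int, !multi & std))
    add(persp, "arm", "pooled multimorbid",
        cell_test(df, val, multi & int, multi & std))
    # pooled descriptive contrasts over both arms; diff = first - second
    add(persp, "condition", "HIV vs HTN",
        cell_test(df, val, df$profile == "HTN", df$profile == "HIV"))
    add(persp, "condition", "HIV vs DM",
        cell_test(df, val, df$profile == "DM", df$profile == "HIV"))
    add(persp, "condition", "multimorbid vs single",
        cell_test(df, val, !multi, multi))
    add(persp, "country", "Uganda vs Tanzania",
        cell_test(df, val, df$country == "Tanzania", df$country == "Uganda"))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[, c("perspective", "contrast", "group", "n_a", "n_b", "mean_a", "mean_b",
          "diff", "se", "df", "ci_low", "ci_high", "p_value", "estimable")]
}
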