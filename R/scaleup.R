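#' National scale-up scenario
#'
#' Inputs for projecting annual national provider costs per arm: for each
#' condition profile, the national prevalent count, the proportion of that
#' prevalence attributed to the profile, the service coverage level, and
#' the mean monthly provider cost per participant under each arm (2021
#' Int$). Alternatively, precomputed per-profile annual totals may be
#' supplied directly (columns \code{annual_integrated},
#' \code{annual_standard}), e.g. to reconcile a published table.
#'
#' @param profiles data.frame keyed by \code{profile} covering all seven
#'   profiles, with either (\code{prevalent_count}, \code{proportion},
#'   \code{coverage}, \code{monthly_integrated}, \code{monthly_standard})
#'   or (\code{annual_integrated}, \code{annual_standard}).
#' @param country country name.
#' @param che,gdp current health expenditure and gross domestic product,
#'   2021 Int$ (numeric or money); optional, required for budget impact.
#' @return object of class \code{scaleup_scenario}.
#' @export
scaleup_scenario <- function(profiles, country, che = NULL, gdp = NULL) {
  missing_p <- setdiff(PROFILES, profiles$profile)
  if (length(missing_p)) {
    stop("scenario error: missing profile(s) ",
         paste(missing_p, collapse = ", "), call. = FALSE)
  }
  direct <- all(c("annual_integrated", "annual_standard") %in% names(profiles))
  if (!direct) {
    need <- c("prevalent_count", "proportion", "coverage",
              "monthly_integrated", "monthly_standard")
    if (!all(need %in% names(profiles))) {
      stop("scenario error: need either annual totals or columns ",
           paste(need, collapse = ", "), call. = FALSE)
    }
    if (any(profiles$prevalent_count < 0)) {
      stop("scenario error: prevalent_count must be >= 0", call. = FALSE)
    }
    if (any(profiles$proportion < 0 | profiles$proportion > 1) ||
        any(profiles$coverage < 0 | profiles$coverage > 1)) {
      stop("scenario error: proportion and coverage must lie in [0, 1]",
           call. = FALSE)
    }
  }
  for (nm in c("che", "gdp")) {
    v <- get(nm)
    if (!is.null(v) && as.numeric(v) <= 0) {
      stop("parameter error: ", nm, " must be positive", call. = FALSE)
    }
  }
  structure(list(profiles = profiles, country = country,
                 che = if (!is.null(che)) as.numeric(che),
                 gdp = if (!is.null(gdp)) as.numeric(gdp),
                 direct = direct),
            class = "scaleup_scenario")
}

#' Annual cost of care at national scale
#'
#' \code{mean_monthly * 12 * prevalent_count * proportion * coverage}.
#'
#' @param mean_monthly mean monthly provider cost per participant (Int$).
#' @param prevalent_count national prevalent count for the condition group.
#' @param proportion share of that prevalence attributed to the profile.
#' @param coverage service coverage level in [0, 1].
#' @return annual cost, Int$ per year (vectorised).
#' @export
annual_cost_at_scale <- function(mean_monthly, prevalent_count, proportion,
                                 coverage) {
  if (any(mean_monthly < 0) || any(prevalent_count < 0) ||
      any(proportion < 0) || any(coverage < 0)) {
    stop("parameter error: scale-up inputs must be non-negative", call. = FALSE)
  }
  mean_monthly * 12 * prevalent_count * proportion * coverage
}

#' National annual totals per arm, differences and budget impact
#'
#' Per-profile annual totals per arm, grand totals, integrated-minus-
#' standard differences, and (when CHE and GDP are present) each total and
#' the difference as a percentage of current health expenditure and GDP.
#'
#' @param scenario a \code{\link{scaleup_scenario}}.
#' @return object of class \code{scaleup_result}: list with
#'   \code{per_profile} (profile, integrated, standard, difference),
#'   \code{totals} (named: integrated, standard, difference) and optional
#'   \code{budget_impact}.
#' @export
national_totals <- function(scenario) {
  stopifnot(inherits(scenario, "scaleup_scenario"))
  p <- scenario$profiles
  if (scenario$direct) {
    int <- p$annual_integrated
    std <- p$annual_standard
  } else {
    int <- annual_cost_at_scale(p$monthly_integrated, p$prevalent_count,
                                p$proportion, p$coverage)
    std <- annual_cost_at_scale(p$monthly_standard, p$prevalent_count,
                                p$proportion, p$coverage)
  }
  per_profile <- data.frame(profile = p$profile, integrated = int,
                            standard = std, difference = int - std,
                            stringsAsFactors = FALSE)
  totals <- c(integrated = sum(int), standard = sum(std),
              difference = sum(int) - sum(std))
  res <- list(country = scenario$country, per_profile = per_profile,
              totals = totals)
  if (!is.null(scenario$che) && !is.null(scenario$gdp)) {
    res$budget_impact <- budget_impact(totals, scenario$che, scenario$gdp)
  }
  structure(res, class = "scaleup_result")
}

#' @export
print.scaleup_result <- function(x, ...) {
  cat("National annual provider costs (2021 Int$), ", x$country, ":\n", sep = "")
  print(transform(x$per_profile,
                  integrated = round(integrated), standard = round(standard),
                  difference = round(difference)), row.names = FALSE)
  cat(sprintf("  Total: integrated %s, standard %s, difference %s\n",
              format(round(x$totals["integrated"]), big.mark = ","),
              format(round(x$totals["standard"]), big.mark = ","),
              format(round(x$totals["difference"]), big.mark = ",")))
  if (!is.null(x$budget_impact)) print(x$budget_impact, row.names = FALSE)
  invisible(x)
}

#' Budget impact as percentage of CHE and GDP
#'
#' Expresses each arm's national total and the integrated-minus-standard
#' difference as percentages of current health expenditure and GDP. The
#' rendered difference is computed from the arm percentages rounded to two
#' decimals, matching how such tables are printed (so the difference row
#' is always internally consistent with the displayed arm rows).
#'
#' @param totals named numeric with \code{integrated} and \code{standard}
#'   annual totals (Int$); a \code{difference} element is recomputed.
#' @param che,gdp denominators, 2021 Int$, positive.
#' @return data.frame: denominator, integrated_pct, standard_pct,
#'   difference_pct (full precision) and the \code{printed_*} columns
#'   rounded to 2 decimals.
#' @export
budget_impact <- function(totals, che, gdp) {
  che <- as.numeric(che); gdp <- as.numeric(gdp)
  if (che <= 0 || gdp <= 0) {
    stop("parameter error: CHE and GDP must be positive", call. = FALSE)
  }
  out <- do.call(rbind, lapply(
    list(c(name = "CHE", denom = che), c(name = "GDP", denom = gdp)),
    function(row) {
      denom <- as.numeric(row["denom"])
      pi <- 100 * totals[["integrated"]] / denom
      ps <- 100 * totals[["standard"]] / denom
      data.frame(denominator = row[["name"]],
                 integrated_pct = pi, standard_pct = ps,
                 difference_pct = pi - ps,
                 printed_integrated = round(pi, 2),
                 printed_standard = round(ps, 2),
                 printed_difference = printed_difference(pi, ps),
                 stringsAsFactors = FALSE)
    }))
  rownames(out) <- NULL
  out
}

#' Difference of two percentages at printed precision
#'
#' Rounds each percentage to \code{digits} decimals before differencing,
#' reproducing the arithmetic of a printed table whose difference row must
#' agree with its displayed arm rows.
#'
#' @param pct_integrated,pct_standard arm-level percentages.
#' @param digits decimals displayed, default 2.
#' @export
printed_difference <- function(pct_integrated, pct_standard, digits = 2) {
  round(round(pct_integrated, digits) - round(pct_standard, digits), digits)
}

#' Reference national scale-up table
#'
#' Loads the published-magnitude reference table of annual national
#' provider costs per profile and arm for Uganda and Tanzania at current
#' coverage (2021 Int$), together with the printed grand totals, row
#' differences and budget-impact percentages, shipped as plain text with
#' the package. Used for reconciliation: feeding the per-profile totals
#' through \code{\link{national_totals}} must reproduce the printed grand
#' totals (exactly for Uganda and Tanzania integrated; Tanzania standard
#' carries a documented +/-2 Int$ printed-rounding discrepancy).
#'
#' @return list with \code{profiles} (country, profile, per-arm totals and
#'   printed differences) and \code{summary} (printed grand totals and
#'   percentage rows).
#' @export
reference_scaleup <- function() {
  path <- system.file("extdata", package = "intecost")
  profiles <- utils::read.csv(file.path(path, "scaleup_reference.csv"),
                              stringsAsFactors = FALSE)
  summary <- utils::read.csv(file.path(path, "scaleup_reference_summary.csv"),
                             stringsAsFactors = FALSE)
  for (cl in c("integrated", "standard", "printed_difference")) {
    profiles[[cl]] <- as.numeric(profiles[[cl]])
  }
  for (cl in c("integrated", "standard", "difference")) {
    summary[[cl]] <- as.numeric(summary[[cl]])
  }
  list(profiles = profiles, summary = summary)
}
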