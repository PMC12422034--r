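#' Uplift integrated-care personnel and overhead costs
#'
#' Stress-tests the assumption that integrated-care facility costs for
#' multimorbid participants equal those of the shared clinic alone, by
#' scaling the integrated arm's personnel and overhead components (and
#' optionally capital) by a factor such as 1.10, 1.20 or 1.50.
#' Medication and diagnostic components are never touched. A factor of 1
#' returns the input unchanged.
#'
#' @param provider_costs output of \code{\link{provider_visit_costs}}.
#' @param factor multiplicative uplift, > 0.
#' @param include_capital also scale the capital component (default FALSE:
#'   the stated variation targets personnel and overheads).
#' @return provider cost table with rescaled components and totals.
#' @export
apply_uplift <- function(provider_costs, factor, include_capital = FALSE) {
  if (!is.numeric(factor) || length(factor) != 1L || factor <= 0) {
    stop("parameter error: uplift factor must be a positive number",
         call. = FALSE)
  }
  out <- provider_costs
  int <- out$arm == "integrated"
  out$personnel[int] <- out$personnel[int] * factor
  out$overhead[int] <- out$overhead[int] * factor
  if (include_capital) out$capital[int] <- out$capital[int] * factor
  out$total <- out$personnel + out$overhead + out$capital +
    out$medication + out$diagnostic
  out
}

#' Uplift scenario sweep with arm comparisons
#'
#' Re-runs the pooled multimorbid (and single-condition) arm comparison
#' after each uplift factor.
#'
#' @param provider_costs output of \code{\link{provider_visit_costs}}.
#' @param factors uplift factors, default \code{c(1, 1.10, 1.20, 1.50)}.
#' @param include_capital see \code{\link{apply_uplift}}.
#' @return data.frame of comparison rows with a \code{factor} column.
#' @export
uplift_sweep <- function(provider_costs, factors = c(1, 1.10, 1.20, 1.50),
                         include_capital = FALSE) {
  out <- do.call(rbind, lapply(factors, function(f) {
    cc <- compare_all(list(provider = apply_uplift(provider_costs, f,
                                                   include_capital)))
    cc <- cc[cc$contrast == "arm" &
               cc$group %in% c("pooled single", "pooled multimorbid"), ]
    cc$factor <- f
    cc
  }))
  rownames(out) <- NULL
  out
}

#' Two-way sensitivity grid for costs at scale
#'
#' Varies (1) the proportions of total prevalence by profile and (2) the
#' mean monthly provider costs per participant, each across
#' \{low, point, high\} levels of their 95\% confidence intervals, giving a
#' 3x3 grid of national totals. Perturbed proportions are renormalised
#' within each prevalence-sharing group so they still sum to the original
#' mass. Degenerate intervals (low = point = high) reproduce the base case
#' in every cell.
#'
#' @param scenario a \code{\link{scaleup_scenario}} with full scale-up
#'   columns (not direct annual totals).
#' @param cost_ci data.frame(profile, integrated_low, integrated_high,
#'   standard_low, standard_high): CI bounds on mean monthly costs.
#' @param proportion_ci data.frame(profile, low, high): CI bounds on the
#'   prevalence proportions.
#' @return list with \code{grid} (cost_level, proportion_level, totals and
#'   difference per cell) and \code{summary} (min/max difference,
#'   \code{all_cost_saving} flag).
#' @export
two_way_grid <- function(scenario, cost_ci, proportion_ci) {
  stopifnot(inherits(scenario, "scaleup_scenario"))
  if (scenario$direct) {
    stop("two-way grid needs a full scale-up scenario, not direct totals",
         call. = FALSE)
  }
  p <- scenario$profiles
  cost_ci <- cost_ci[match(p$profile, cost_ci$profile), ]
  proportion_ci <- proportion_ci[match(p$profile, proportion_ci$profile), ]
  if (any(cost_ci$integrated_low > cost_ci$integrated_high) ||
      any(cost_ci$standard_low > cost_ci$standard_high) ||
      any(proportion_ci$low > proportion_ci$high)) {
    stop("parameter error: interval low exceeds high", call. = FALSE)
  }
  levels <- c("low", "point", "high")
  cells <- expand.grid(cost_level = levels, proportion_level = levels,
                       stringsAsFactors = FALSE)
  grid <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    q <- p
    cl <- cells$cost_level[i]; pl <- cells$proportion_level[i]
    if (cl != "point") {
      q$monthly_integrated <- cost_ci[[paste0("integrated_", cl)]]
      q$monthly_standard <- cost_ci[[paste0("standard_", cl)]]
    }
    if (pl != "point") {
      prop <- proportion_ci[[pl]]
      # renormalise so perturbed proportions keep the original total mass
      q$proportion <- prop * sum(p$proportion) / sum(prop)
    }
    sc <- scaleup_scenario(q, scenario$country, scenario$che, scenario$gdp)
    res <- national_totals(sc)
    data.frame(cost_level = cl, proportion_level = pl,
               integrated = res$totals[["integrated"]],
               standard = res$totals[["standard"]],
               difference = res$totals[["difference"]],
               stringsAsFactors = FALSE)
  }))
  list(grid = grid,
       summary = list(min_difference = min(grid$difference),
                      max_difference = max(grid$difference),
                      all_cost_saving = all(grid$difference < 0)))
}

#' Patient-cost comparisons under alternative time-valuation policies
#'
#' Recomputes the patient cost pipeline and pooled arm comparisons under
#' each supplied time-valuation policy (e.g. the conservative 30-working-
#' day consumption base, a 22-day variant, and a median-salary base) and
#' reports a concordance table of significance categories against the
#' first (base-case) policy.
#'
#' @param questionnaires,participants,economy as in
#'   \code{\link{patient_visit_costs}}.
#' @param policies named list of \code{\link{time_policy}} objects; the
#'   first is the base case.
#' @param alpha significance level, default 0.05.
#' @param ... passed to \code{\link{patient_visit_costs}}.
#' @return list with \code{comparisons} (per-policy pooled comparisons)
#'   and \code{concordance} (policy, group, significant, agrees_with_base).
#' @export
time_valuation_variants <- function(questionnaires, participants, economy,
                                    policies = list(
                                      base = time_policy(30, 8, "consumption"),
                                      days22 = time_policy(22, 8, "consumption"),
                                      median_salary = time_policy(30, 8, "median_salary")),
                                    alpha = 0.05, ...) {
  if (length(policies) == 0L) stop("policies list must be nonempty", call. = FALSE)
  comp <- do.call(rbind, lapply(names(policies), function(nm) {
    pc <- patient_visit_costs(questionnaires, participants, economy,
                              policy = policies[[nm]], ...)
    cc <- compare_all(list(patient = pc))
    cc <- cc[cc$contrast == "arm" &
               cc$group %in% c("pooled single", "pooled multimorbid"), ]
    cc$policy <- nm
    cc
  }))
  rownames(comp) <- NULL
  base <- comp[comp$policy == names(policies)[1], ]
  comp$significant <- comp$estimable & comp$p_value < alpha
  base_sig <- stats::setNames(base$estimable & base$p_value < alpha, base$group)
  concordance <- data.frame(policy = comp$policy, group = comp$group,
                            significant = comp$significant,
                            agrees_with_base =
                              comp$significant == base_sig[comp$group],
                            stringsAsFactors = FALSE)
  list(comparisons = comp, concordance = concordance)
}
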