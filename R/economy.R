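#' National economic parameters
#'
#' Per-country inputs shared across the pipeline: the 2021 purchasing-power
#' parity conversion rate (local currency units per international dollar),
#' a CPI series for inflating historical amounts to 2021 prices, the
#' monthly monetary bases used to value time, and the national denominators
#' for budget impact (current health expenditure and GDP, 2021 Int$).
#'
#' The PPP rates default to the World Bank 2021 values used for reporting
#' (Int$1 = UGX 1310.6 = TZS 890.58). The CPI series, consumption, salary,
#' CHE and GDP defaults are editable placeholders of realistic magnitude:
#' CHE and GDP were chosen so the shipped scale-up scenario yields budget
#' impacts of the published order; override them for real analyses.
#'
#' @param countries named list overriding/extending per-country entries.
#'   Each entry is a list with fields \code{currency}, \code{ppp_rate_2021},
#'   \code{cpi} (named numeric, years), \code{monthly_consumption} (money),
#'   \code{median_salary} (money), \code{che} and \code{gdp}
#'   (money, INTD 2021).
#' @return an object of class \code{economy_parameters}.
#' @export
economy_parameters <- function(countries = list()) {
  defaults <- list(
    Uganda = list(
      currency = "UGX",
      ppp_rate_2021 = 1310.6,
      cpi = c("2019" = 100, "2020" = 102.8, "2021" = 105.0),
      monthly_consumption = money(120000, "UGX", 2021),
      median_salary = money(200000, "UGX", 2021),
      che = money(4.33e9, "INTD", 2021),
      gdp = money(1.175e11, "INTD", 2021)
    ),
    Tanzania = list(
      currency = "TZS",
      ppp_rate_2021 = 890.58,
      cpi = c("2019" = 100, "2020" = 103.3, "2021" = 107.1),
      monthly_consumption = money(70000, "TZS", 2021),
      median_salary = money(150000, "TZS", 2021),
      che = money(6.70e9, "INTD", 2021),
      gdp = money(1.743e11, "INTD", 2021)
    )
  )
  for (nm in names(countries)) {
    entry <- utils::modifyList(defaults[[nm]] %||% list(), countries[[nm]])
    defaults[[nm]] <- entry
  }
  for (nm in names(defaults)) {
    e <- defaults[[nm]]
    if (is.null(e$ppp_rate_2021) || e$ppp_rate_2021 <= 0) {
      stop("ppp_rate_2021 for ", nm, " must be > 0", call. = FALSE)
    }
    if (any(e$cpi <= 0)) stop("CPI values for ", nm, " must be positive", call. = FALSE)
  }
  structure(defaults, class = "economy_parameters")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

economy_country <- function(economy, country) {
  eco <- economy[[country]]
  if (is.null(eco)) {
    stop("no economy parameters for country ", country, call. = FALSE)
  }
  eco
}

country_for_currency <- function(economy, currency) {
  for (nm in names(economy)) {
    if (identical(economy[[nm]]$currency, currency)) return(nm)
  }
  stop("no country in economy parameters uses currency ", currency,
       call. = FALSE)
}

#' @export
print.economy_parameters <- function(x, ...) {
  cat("Economy parameters for:", paste(names(x), collapse = ", "), "\n")
  for (nm in names(x)) {
    cat(sprintf("  %s: 1 Int$ = %s %.2f (2021)\n",
                nm, x[[nm]]$currency, x[[nm]]$ppp_rate_2021))
  }
  invisible(x)
}
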