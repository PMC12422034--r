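#' Currency- and price-year-aware money vectors
#'
#' Costs are captured in local currency (Ugandan shilling UGX, Tanzanian
#' shilling TZS), inflated to a common price year, and reported in 2021
#' international dollars (INTD). A \code{money} vector carries its currency
#' code and price year and refuses arithmetic that mixes them, so a 2019
#' shilling can never be silently added to a 2021 international dollar.
#'
#' @param value numeric vector, finite.
#' @param currency one of \code{"UGX"}, \code{"TZS"}, \code{"INTD"}.
#' @param price_year integer price year the values are expressed in.
#' @return an object of class \code{money}.
#' @examples
#' money(100, "UGX", 2021) + money(50, "UGX", 2021)
#' @export
money <- function(value, currency, price_year) {
  if (!is.numeric(value) || any(!is.finite(value))) {
    stop("money value must be finite numeric", call. = FALSE)
  }
  currency <- match.arg(currency, c("UGX", "TZS", "INTD"))
  price_year <- as.integer(price_year)
  if (length(price_year) != 1L || is.na(price_year)) {
    stop("price_year must be a single integer", call. = FALSE)
  }
  structure(as.numeric(value), currency = currency, price_year = price_year,
            class = "money")
}

#' @export
is_money <- function(x) inherits(x, "money")

#' @rdname money
#' @param x a \code{money} object.
#' @export
currency_of <- function(x) attr(x, "currency")

#' @rdname money
#' @export
price_year_of <- function(x) attr(x, "price_year")

money_like <- function(value, template) {
  money(value, currency_of(template), price_year_of(template))
}

check_same_unit <- function(e1, e2, what) {
  if (currency_of(e1) != currency_of(e2) ||
      price_year_of(e1) != price_year_of(e2)) {
    stop(sprintf(
      "money unit mismatch in %s: %s %d vs %s %d (convert explicitly first)",
      what, currency_of(e1), price_year_of(e1),
      currency_of(e2), price_year_of(e2)), call. = FALSE)
  }
}

#' @export
Ops.money <- function(e1, e2) {
  if (nargs() == 1L) { # unary +/-
    return(money_like(get(.Generic)(unclass(e1)), e1))
  }
  both <- is_money(e1) && is_money(e2)
  if (.Generic %in% c("+", "-")) {
    if (!both) stop("money can only be added to/subtracted from money", call. = FALSE)
    check_same_unit(e1, e2, .Generic)
    return(money_like(get(.Generic)(unclass(e1), unclass(e2)), e1))
  }
  if (.Generic %in% c("*", "/")) {
    if (both) {
      if (.Generic == "*") stop("cannot multiply money by money", call. = FALSE)
      check_same_unit(e1, e2, "/")
      return(as.vector(unclass(e1)) / as.vector(unclass(e2))) # dimensionless
    }
    tmpl <- if (is_money(e1)) e1 else e2
    if (.Generic == "/" && is_money(e2)) {
      stop("cannot divide a scalar by money", call. = FALSE)
    }
    return(money_like(get(.Generic)(unclass(e1), unclass(e2)), tmpl))
  }
  if (.Generic %in% c("==", "!=", "<", ">", "<=", ">=")) {
    if (both) check_same_unit(e1, e2, .Generic)
    return(get(.Generic)(unclass(e1), unclass(e2)))
  }
  stop("operation ", .Generic, " not defined for money", call. = FALSE)
}

#' @export
Summary.money <- function(..., na.rm = FALSE) {
  args <- list(...)
  if (!.Generic %in% c("sum", "min", "max")) {
    stop(.Generic, " not defined for money", call. = FALSE)
  }
  tmpl <- args[[1]]
  for (a in args[-1]) check_same_unit(tmpl, a, .Generic)
  money_like(get(.Generic)(unlist(lapply(args, unclass)), na.rm = na.rm), tmpl)
}

#' @export
`[.money` <- function(x, i) money_like(unclass(x)[i], x)

#' @export
format.money <- function(x, ...) {
  paste0(format(unclass(x), ...), " ", currency_of(x),
         " (", price_year_of(x), ")")
}

#' @export
print.money <- function(x, ...) {
  cat(format(x, ...), sep = "\n")
  invisible(x)
}

#' @export
as.numeric.money <- function(x, ...) unclass(x)

#' Inflate a money amount to a target price year
#'
#' Scales by the ratio of consumer-price-index values
#' \code{cpi[to_year] / cpi[price_year]}; currency is unchanged.
#'
#' @param x a \code{money} vector in local currency.
#' @param cpi named numeric vector of CPI values, names are years.
#' @param to_year target price year (default 2021, the reporting year).
#' @return \code{money} at \code{to_year} prices.
#' @export
inflate_money <- function(x, cpi, to_year = 2021L) {
  stopifnot(is_money(x))
  to_year <- as.integer(to_year)
  from <- price_year_of(x)
  if (from == to_year) return(x)
  for (y in c(from, to_year)) {
    if (!as.character(y) %in% names(cpi)) {
      stop("CPI index has no value for year ", y, call. = FALSE)
    }
  }
  if (any(cpi[as.character(c(from, to_year))] <= 0)) {
    stop("CPI values must be strictly positive", call. = FALSE)
  }
  factor <- unname(cpi[as.character(to_year)] / cpi[as.character(from)])
  money(unclass(x) * factor, currency_of(x), to_year)
}

#' Convert 2021 local currency to 2021 international dollars
#'
#' Divides by the country's purchasing-power-parity conversion rate
#' (local currency units per Int$). Amounts must already be at 2021
#' prices; inflate first.
#'
#' @param x \code{money} in UGX or TZS at 2021 prices.
#' @param economy an \code{\link{economy_parameters}} object.
#' @return \code{money} in INTD at 2021 prices.
#' @export
to_int_dollars <- function(x, economy) {
  stopifnot(is_money(x))
  cur <- currency_of(x)
  if (cur == "INTD") return(x)
  if (price_year_of(x) != 2021L) {
    stop("convert to international dollars only at 2021 prices; ",
         "inflate_money() first (amount is at ", price_year_of(x), " prices)",
         call. = FALSE)
  }
  country <- country_for_currency(economy, cur)
  money(unclass(x) / economy[[country]]$ppp_rate_2021, "INTD", 2021L)
}

#' Equivalent annual cost of a capital purchase
#'
#' Converts a capital price into an annual cost over its useful life using
#' the standard annuity factor \code{(1 - (1+r)^-L) / r} (straight-line
#' when \code{rate = 0}). The default 3\% rate is the convention used for
#' facility costing in this care setting.
#'
#' @param price purchase price (\code{money} or numeric).
#' @param rate annual discount rate, fraction (default 0.03).
#' @param life_years useful life in years, > 0.
#' @return annual cost, same type as \code{price}.
#' @examples
#' annuitize(1000, rate = 0.03, life_years = 5) # ~218.35 per year
#' @export
annuitize <- function(price, rate = 0.03, life_years) {
  if (!is.numeric(rate) || length(rate) != 1L || rate < 0) {
    stop("rate must be a single non-negative number", call. = FALSE)
  }
  if (!is.numeric(life_years) || length(life_years) < 1L || any(life_years <= 0)) {
    stop("life_years must be > 0", call. = FALSE)
  }
  af <- if (rate == 0) life_years else (1 - (1 + rate)^(-life_years)) / rate
  price / af
}

#' Working-time valuation policy
#'
#' Controls how reported time losses are priced: which monthly monetary
#' basis is used (mean per-capita consumption, the conservative default, or
#' the median monthly salary) and how a month converts to working hours.
#' The base case divides the monthly amount by 30 days and then by an
#' 8-hour working day; a 22-working-day variant is the stated sensitivity.
#'
#' @param days_per_month 30 (default) or 22.
#' @param hours_per_day hours in a working day, default 8.
#' @param basis \code{"consumption"} (default) or \code{"median_salary"}.
#' @export
time_policy <- function(days_per_month = 30, hours_per_day = 8,
                        basis = c("consumption", "median_salary")) {
  basis <- match.arg(basis)
  if (!days_per_month %in% c(30, 22)) {
    stop("days_per_month must be 30 or 22", call. = FALSE)
  }
  if (hours_per_day <= 0) stop("hours_per_day must be positive", call. = FALSE)
  structure(list(days_per_month = days_per_month, hours_per_day = hours_per_day,
                 basis = basis), class = "time_policy")
}

#' Hourly value of participant time
#'
#' The policy's monthly basis amount is inflated to 2021 prices, divided by
#' working days per month and hours per day. Applied to all participants
#' regardless of employment status.
#'
#' @param economy an \code{\link{economy_parameters}} object.
#' @param country country name present in \code{economy}.
#' @param policy a \code{\link{time_policy}}.
#' @return \code{money} per hour, local currency, 2021 prices.
#' @export
hourly_time_value <- function(economy, country, policy = time_policy()) {
  eco <- economy_country(economy, country)
  basis <- switch(policy$basis,
    consumption   = eco$monthly_consumption,
    median_salary = eco$median_salary)
  if (is.null(basis)) {
    stop("economy parameters for ", country, " lack a ", policy$basis,
         " amount", call. = FALSE)
  }
  monthly <- inflate_money(basis, eco$cpi, 2021L)
  monthly / policy$days_per_month / policy$hours_per_day
}
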