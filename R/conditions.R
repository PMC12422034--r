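#' Condition profiles
#'
#' Care is costed for seven chronic-condition profiles: the three single
#' conditions (HIV, hypertension, diabetes) and their four combinations.
#' A profile label is the canonical "+"-joined subset in the fixed order
#' HIV, HTN, DM.
#'
#' @name condition-profiles
NULL

#' @rdname condition-profiles
#' @export
CONDITIONS <- c("HIV", "HTN", "DM")

#' @rdname condition-profiles
#' @export
PROFILES <- c("HIV", "HTN", "DM", "HIV+HTN", "HIV+DM", "HTN+DM", "HIV+HTN+DM")

#' Canonical profile label for a set of conditions
#'
#' @param conditions character vector, subset of \code{CONDITIONS}, nonempty.
#' @return a single label, one of \code{PROFILES}.
#' @export
profile_label <- function(conditions) {
  conditions <- unique(conditions)
  if (length(conditions) == 0L || !all(conditions %in% CONDITIONS)) {
    stop("conditions must be a nonempty subset of {HIV, HTN, DM}", call. = FALSE)
  }
  paste(CONDITIONS[CONDITIONS %in% conditions], collapse = "+")
}

#' Conditions making up a profile label
#'
#' @param label a profile label (see \code{PROFILES}).
#' @return character vector of conditions in canonical order.
#' @export
profile_conditions <- function(label) {
  if (length(label) != 1L || !label %in% PROFILES) {
    stop("unknown condition profile: ", label, call. = FALSE)
  }
  strsplit(label, "+", fixed = TRUE)[[1]]
}

#' Number of conditions in each profile label
#' @param label character vector of profile labels.
#' @export
n_conditions <- function(label) {
  lengths(strsplit(label, "+", fixed = TRUE))
}

#' Is a profile multimorbid (two or more conditions)?
#' @param label character vector of profile labels.
#' @export
is_multimorbid <- function(label) {
  n_conditions(label) >= 2L
}
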