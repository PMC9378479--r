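#' Round half away from zero
#'
#' Display rounding used throughout the package's reports: one-decimal
#' percentages are rounded half away from zero, so e.g. 41.75 renders as
#' 41.8 regardless of the banker's rounding of [base::round()].
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Numeric vector of `x` rounded half away from zero.
#' @examples
#' round_half_up(c(0.5, 1.5, -0.5))
#' round_half_up(41.75, 1)
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Normalise an event label or drug name for matching: lowercase, trimmed,
# internal whitespace squished.
normalise_label <- function(x) {
  stringr::str_squish(stringr::str_to_lower(as.character(x)))
}

# Partial or full ATC code: letter, 2 digits, letter, letter, 2 digits,
# truncatable after any complete level (lengths 1, 3, 4, 5 or 7).
ATC_PATTERN <- "^[A-Z]([0-9]{2}([A-Z]([A-Z]([0-9]{2})?)?)?)?$"

is_valid_atc <- function(x) {
  grepl(ATC_PATTERN, x)
}

stop_input <- function(...) abort(paste0(...), class = "adrtrigger_input_error")
stop_validation <- function(...) abort(paste0(...), class = "adrtrigger_validation_error")
stop_conflict <- function(...) abort(paste0(...), class = "adrtrigger_conflict_error")
stop_lookup <- function(...) abort(paste0(...), class = "adrtrigger_lookup_error")
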