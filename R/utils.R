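# Shared helpers: rounding, tristate flags, sentinel handling.

TRISTATE <- c("yes", "no", "unknown")
ENDPOINT_KINDS <- c("OS", "PFS", "ORR")
GRADE_BANDS <- c("g1_2", "g3_4")
DESIGNS <- c("superiority", "non_inferiority")

#' Round half away from zero
#'
#' Decimal rounding in which .5 always rounds away from zero, the convention
#' used when value-framework points are reported to one decimal place
#' (base [round()] rounds half to even).
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places (default 1).
#' @return Numeric vector rounded to `digits` places.
#' @examples
#' round_half_up(0.25, 1) # 0.3, where round() gives 0.2
#' @export
round_half_up <- function(x, digits = 1) {
  scale <- 10^digits
  sign(x) * trunc(abs(x) * scale + 0.5 + 1e-9) / scale
}

is_tristate <- function(x) {
  is.character(x) && length(x) == 1 && !is.na(x) && x %in% TRISTATE
}

# "not reached" is encoded as Inf internally and as the string "NR" in the
# JSON interchange; NA means the field is absent (never reported).
is_reached <- function(x) !is.na(x) & is.finite(x)

stop_oncovalue <- function(msg, class = "oncovalue_error") {
  abort(msg, class = class)
}

`%na%` <- function(x, default) if (is.null(x) || length(x) == 0 || all(is.na(x))) default else x
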