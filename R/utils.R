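# Shared error helpers and unit conversion.

#' @importFrom rlang %||%
NULL

abort_domain <- function(msg, ...) {
  rlang::abort(msg, class = c("kirchpk_domain_error", "kirchpk_error"), ...)
}

abort_input <- function(msg, ...) {
  rlang::abort(msg, class = c("kirchpk_input_error", "kirchpk_error"), ...)
}

abort_infeasible <- function(msg, class = character(), ...) {
  rlang::abort(msg, class = c(class, "kirchpk_infeasible_error", "kirchpk_error"), ...)
}

# A process that cannot define the measured total (non-positive value or
# non-positive net difference) is "non-rate-defining"; callers distinguish
# this from plain bad input because it is a modelling outcome, not a typo.
abort_non_rate_defining <- function(msg, ...) {
  abort_infeasible(msg, class = "kirchpk_non_rate_defining_error", ...)
}

check_positive <- function(x, what = "value") {
  if (length(x) == 0L) {
    abort_domain(sprintf("no processes: `%s` is empty", what))
  }
  if (!is.numeric(x) || anyNA(x)) {
    abort_domain(sprintf("`%s` must be numeric with no missing values", what))
  }
  if (any(x <= 0)) {
    abort_domain(sprintf(
      "`%s` must be strictly positive (a non-positive process is not rate-defining); got %s",
      what, paste(signif(x[x <= 0], 6), collapse = ", ")
    ))
  }
  invisible(x)
}

#' Convert between flow/clearance units
#'
#' Clearances and blood flows appear in the literature both as L/h and as
#' mL/min (1 L/h = 1000/60 mL/min). All kirchpk computations are
#' unit-agnostic as long as one unit is used consistently; this helper makes
#' the conversion explicit when mixing sources.
#'
#' @param x numeric vector of flows or clearances.
#' @param from,to unit labels, one of `"L/h"` or `"mL/min"`.
#' @return numeric vector in the `to` units.
#' @examples
#' convert_flow(1200, "mL/min", "L/h") # 72 L/h
#' convert_flow(24.3, "L/h", "mL/min")
#' @export
convert_flow <- function(x, from = c("L/h", "mL/min"), to = c("L/h", "mL/min")) {
  from <- rlang::arg_match(from)
  to <- rlang::arg_match(to)
  if (from == to) {
    return(x)
  }
  per_lh <- 1000 / 60 # mL/min in one L/h
  if (from == "L/h") x * per_lh else x / per_lh
}

flow_units <- c("1/h", "L/h", "mL/min")

kind_for_units <- function(units) {
  if (units == "1/h") "rate_constant" else "clearance"
}
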