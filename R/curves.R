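# Polyexponential curves: signed sums of exponential terms
# C(t) = sum_i coefficient_i * exp(-exponent_i * t), the working object of
# noncompartmental analysis. Moments to infinite time are closed-form:
# AUC = sum C_i/lambda_i, AUMC = sum C_i/lambda_i^2.

#' Construct a polyexponential curve
#'
#' Terms are canonicalized to strictly decreasing exponents; duplicate
#' exponents (within 1e-9 relative) are merged by summing coefficients.
#' Role `"iv_disposition"` requires all coefficients positive; role
#' `"oral_disposition"` allows the paired +/- form (zero coefficient sum,
#' i.e. C(0) = 0) but the curve must evaluate non-negative for t >= 0;
#' role `"amount_curve"` is unconstrained in sign.
#'
#' @param coefficients term coefficients (mg/L for disposition curves, mg
#'   for amount curves).
#' @param exponents positive exponents (1/h), same length.
#' @param role one of `"iv_disposition"`, `"oral_disposition"`,
#'   `"amount_curve"`.
#' @return a tibble of class `pk_curve` with columns `coefficient`,
#'   `exponent` and a `role` attribute.
#' @examples
#' pk_curve(c(15, 16), c(1.39, 0.173), role = "iv_disposition")
#' pk_curve(c(22.7, -22.7), c(0.105, 1.16), role = "oral_disposition")
#' @export
pk_curve <- function(coefficients, exponents,
                     role = c("iv_disposition", "oral_disposition", "amount_curve")) {
  role <- rlang::arg_match(role)
  if (length(coefficients) != length(exponents) || length(exponents) == 0L) {
    abort_input("coefficients and exponents must be non-empty and equal length")
  }
  check_positive(exponents, "exponents")
  ord <- order(exponents, decreasing = TRUE)
  coefficients <- coefficients[ord]
  exponents <- exponents[ord]
  # merge numerically identical exponents
  grp <- cumsum(c(TRUE, diff(exponents) < -1e-9 * exponents[-length(exponents)]))
  coefficients <- as.numeric(tapply(coefficients, grp, sum))
  exponents <- as.numeric(tapply(exponents, grp, function(x) x[1]))
  if (role == "iv_disposition" && any(coefficients <= 0)) {
    abort_domain("iv_disposition curves require all coefficients > 0")
  }
  curve <- tibble::new_tibble(
    list(coefficient = coefficients, exponent = exponents),
    nrow = length(coefficients),
    class = "pk_curve", role = role
  )
  if (role == "oral_disposition") {
    probe <- eval_curve(curve, seq(0, 5 / min(exponents), length.out = 64))
    if (any(probe < -1e-9 * max(abs(coefficients)))) {
      abort_domain("oral_disposition curve evaluates negative for some t >= 0")
    }
  }
  curve
}

curve_role <- function(curve) attr(curve, "role") %||% "iv_disposition"

check_curve <- function(curve) {
  if (!inherits(curve, "pk_curve")) {
    abort_input("expected a `pk_curve` (see pk_curve())")
  }
  invisible(curve)
}

#' Evaluate a polyexponential curve
#'
#' @param curve a [pk_curve()].
#' @param times times (h), >= 0.
#' @return numeric vector of curve values at `times`.
#' @examples
#' eval_curve(pk_curve(c(15, 16), c(1.39, 0.173)), c(0, 1, 4, 12))
#' @export
eval_curve <- function(curve, times) {
  check_curve(curve)
  drop(exp(outer(times, -curve$exponent)) %*% curve$coefficient)
}

#' Moments of a polyexponential curve to infinite time
#'
#' `auc_inf()` is the sum of coefficients over exponents; `aumc_inf()` the
#' sum of coefficients over squared exponents; `curve_mrt()` their ratio.
#' Signed terms are included as-is, so the oral paired +/- form is handled
#' without special casing.
#'
#' @param curve a [pk_curve()].
#' @return a single number: conc h (AUC), conc h^2 (AUMC), or h (MRT).
#' @examples
#' iv <- pk_curve(c(15, 16), c(1.39, 0.173))
#' auc_inf(iv)
#' aumc_inf(iv)
#' curve_mrt(iv)
#' @export
auc_inf <- function(curve) {
  check_curve(curve)
  sum(curve$coefficient / curve$exponent)
}

#' @rdname auc_inf
#' @export
aumc_inf <- function(curve) {
  check_curve(curve)
  sum(curve$coefficient / curve$exponent^2)
}

#' @rdname auc_inf
#' @export
curve_mrt <- function(curve) {
  aumc_inf(curve) / auc_inf(curve)
}

#' @export
print.pk_curve <- function(x, ...) {
  cat(sprintf("<pk_curve: %s>\n", curve_role(x)))
  terms <- sprintf(
    "%s%g e^(-%g t)",
    ifelse(x$coefficient < 0, "- ", ifelse(seq_along(x$coefficient) > 1, "+ ", "")),
    abs(x$coefficient), x$exponent
  )
  cat("C(t) =", paste(terms, collapse = " "), "\n")
  cat(sprintf(
    "AUC(0-inf) = %.4g, AUMC(0-inf) = %.4g, MRT = %.4g h\n",
    auc_inf(x), aumc_inf(x), curve_mrt(x)
  ))
  invisible(x)
}

#' @method tidy pk_curve
#' @export
tidy.pk_curve <- function(x, ...) {
  tibble::tibble(
    term = seq_len(nrow(x)),
    coefficient = x$coefficient,
    exponent = x$exponent,
    half_life_h = log(2) / x$exponent
  )
}

#' @method glance pk_curve
#' @export
glance.pk_curve <- function(x, ...) {
  tibble::tibble(
    role = curve_role(x),
    n_terms = nrow(x),
    auc_inf = auc_inf(x),
    aumc_inf = aumc_inf(x),
    mrt = curve_mrt(x),
    c0 = sum(x$coefficient)
  )
}

#' Convolve a disposition curve with first-order input
#'
#' Given an iv-bolus disposition curve (unit-impulse response scaled by the
#' iv dose) and a first-order input with rate `k_a`, returns the oral-route
#' curve for `dose_oral`:
#' `C_oral(t) = (F dose_oral / dose_iv) * sum_i C_i k_a / (k_a - l_i)
#' (e^(-l_i t) - e^(-k_a t))`. Moment additivity makes this the exact
#' oracle for mean absorption time: the convolved curve's MRT exceeds the
#' iv MRT by exactly `1/k_a`.
#'
#' @param curve_iv an iv-disposition [pk_curve()].
#' @param k_a first-order absorption rate constant (1/h); must differ from
#'   every disposition exponent.
#' @param dose_iv,dose_oral doses (mg).
#' @param F_abs fraction absorbed reaching the measurement site.
#' @return an oral-disposition [pk_curve()].
#' @examples
#' iv <- pk_curve(c(15, 16), c(1.39, 0.173))
#' oral <- convolve_first_order_input(iv, k_a = 0.3)
#' curve_mrt(oral) - curve_mrt(iv) # exactly 1/0.3
#' @export
convolve_first_order_input <- function(curve_iv, k_a, dose_iv = 1,
                                       dose_oral = dose_iv, F_abs = 1) {
  check_curve(curve_iv)
  check_positive(k_a, "k_a")
  if (any(abs(curve_iv$exponent - k_a) < 1e-9 * k_a)) {
    abort_infeasible("k_a coincides with a disposition exponent; no distinct-term form")
  }
  scale <- F_abs * dose_oral / dose_iv
  a <- scale * curve_iv$coefficient * k_a / (k_a - curve_iv$exponent)
  pk_curve(
    coefficients = c(a, -sum(a)),
    exponents = c(curve_iv$exponent, k_a),
    role = "oral_disposition"
  )
}
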