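# Noncompartmental analysis of paired iv-bolus / oral study records, and
# the oral clearance chain: treating the absorption site as an in-series
# stage ahead of systemic elimination, so
#   1/CL(oral) = 1/CL(iv) + 1/CL(absorption site),
# with bioavailability from urine (assumption-free) and from plasma AUC
# (assumes route-independent clearance, hence can exceed 1 when absorption
# is slow).

#' Assemble a paired iv/oral study record
#'
#' @param dose_iv,dose_oral administered doses (mg); oral fields may be
#'   omitted for an iv-only record.
#' @param curve_iv an iv-disposition [pk_curve()] (mg/L).
#' @param curve_oral an oral-disposition [pk_curve()], optional.
#' @param U_inf_iv,U_inf_oral cumulative unchanged drug in urine (mg),
#'   each within `[0, dose]` for its route.
#' @return an object of class `study_record`.
#' @examples
#' rec <- study_record(
#'   dose_iv = 2500, dose_oral = 5000,
#'   curve_iv = pk_curve(c(15, 16), c(1.39, 0.173)),
#'   curve_oral = pk_curve(c(22.7, -22.7), c(0.105, 1.16), role = "oral_disposition"),
#'   U_inf_iv = 1430, U_inf_oral = 220
#' )
#' nca_iv(rec)
#' @export
study_record <- function(dose_iv, curve_iv, U_inf_iv = NA_real_,
                         dose_oral = NA_real_, curve_oral = NULL,
                         U_inf_oral = NA_real_) {
  check_positive(dose_iv, "dose_iv")
  check_curve(curve_iv)
  if (!is.null(curve_oral)) check_curve(curve_oral)
  if (!is.na(dose_oral)) check_positive(dose_oral, "dose_oral")
  for (route in c("iv", "oral")) {
    u <- get(paste0("U_inf_", route))
    d <- get(paste0("dose_", route))
    if (!is.na(u) && (u < 0 || (!is.na(d) && u > d))) {
      abort_domain(sprintf("U_inf_%s must lie in [0, dose_%s]", route, route))
    }
  }
  structure(
    list(
      dose_iv = dose_iv, dose_oral = dose_oral,
      curve_iv = curve_iv, curve_oral = curve_oral,
      U_inf_iv = U_inf_iv, U_inf_oral = U_inf_oral
    ),
    class = "study_record"
  )
}

#' @export
print.study_record <- function(x, ...) {
  cat(sprintf("<study_record> iv %g mg", x$dose_iv))
  if (!is.na(x$dose_oral)) cat(sprintf(", oral %g mg", x$dose_oral))
  cat("\n")
  if (!is.na(x$U_inf_iv)) cat(sprintf("  urine: iv %g mg", x$U_inf_iv))
  if (!is.na(x$U_inf_oral)) cat(sprintf(", oral %g mg", x$U_inf_oral))
  cat("\n")
  invisible(x)
}

#' Noncompartmental analysis of the iv-bolus route
#'
#' Standard moment analysis from the fitted polyexponential:
#' `CL = dose/AUC`; `CL_R = (U_inf/dose) * CL` (renal share by fraction
#' excreted unchanged); `CL_H = CL - CL_R`; `MRT = AUMC/AUC`;
#' `Vss = CL * MRT`; `V_initial = dose / C(0)`.
#'
#' @param record a [study_record()] with an iv curve; urine-dependent
#'   fields are `NA` when `U_inf_iv` is absent.
#' @return a one-row tibble: `auc_inf`, `aumc_inf`, `mrt`, `cl`, `cl_r`,
#'   `cl_h`, `vss`, `v_initial` (L and h based units).
#' @export
nca_iv <- function(record) {
  if (!inherits(record, "study_record")) {
    abort_input("`record` must be a study_record()")
  }
  curve <- record$curve_iv
  c0 <- sum(curve$coefficient)
  if (c0 <= 0) {
    abort_domain("invalid iv curve: coefficient sum (C at t = 0) must be > 0")
  }
  auc <- auc_inf(curve)
  aumc <- aumc_inf(curve)
  cl <- record$dose_iv / auc
  fe <- record$U_inf_iv / record$dose_iv
  cl_r <- fe * cl
  tibble::tibble(
    auc_inf = auc,
    aumc_inf = aumc,
    mrt = aumc / auc,
    cl = cl,
    cl_r = cl_r,
    cl_h = cl - cl_r,
    vss = cl * (aumc / auc),
    v_initial = record$dose_iv / c0
  )
}

#' Mean absorption time
#'
#' `MAT = MRT(oral) - MRT(iv bolus)`, both by AUMC/AUC of the fitted
#' curves. A non-positive MAT (a sampling or fitting artifact) is returned
#' with a warning, not an error.
#'
#' @param record a [study_record()] with both curves.
#' @return MAT in hours.
#' @export
mean_absorption_time <- function(record) {
  if (is.null(record$curve_oral)) {
    abort_input("record has no oral curve")
  }
  mat <- curve_mrt(record$curve_oral) - curve_mrt(record$curve_iv)
  if (mat <= 0) {
    rlang::warn(sprintf(
      "non-positive MAT (%.3g h): likely a sampling or fitting artifact",
      mat
    ))
  }
  mat
}

#' Bioavailability from urine and from plasma
#'
#' `F_urine = (U_oral/U_iv) * (dose_iv/dose_oral)` uses only measured
#' amounts and carries no assumptions. `F_plasma = (AUC_oral/AUC_iv) *
#' (dose_iv/dose_oral)` additionally assumes clearance is route-
#' independent; when absorption-site clearance is slow that assumption
#' fails and `F_plasma` can exceed 1. Values are never clamped.
#'
#' @param record a [study_record()] with both routes.
#' @return a one-row tibble: `F_urine`, `F_plasma`.
#' @export
bioavailability <- function(record) {
  if (is.null(record$curve_oral) || is.na(record$dose_oral)) {
    abort_input("record has no oral route")
  }
  dose_ratio <- record$dose_iv / record$dose_oral
  f_urine <- if (is.na(record$U_inf_iv) || is.na(record$U_inf_oral)) {
    NA_real_
  } else {
    if (record$U_inf_iv == 0) {
      abort_domain("F_urine undefined: no unchanged drug in urine after iv dosing")
    }
    (record$U_inf_oral / record$U_inf_iv) * dose_ratio
  }
  tibble::tibble(
    F_urine = f_urine,
    F_plasma = (auc_inf(record$curve_oral) / auc_inf(record$curve_iv)) * dose_ratio
  )
}

#' Oral clearance chain: systemic and absorption-site clearance
#'
#' Using the urinary bioavailability (assumption-free), the clearance
#' actually operating after oral dosing is
#' `CL(oral) = F_urine * dose_oral / AUC_oral`; the absorption site then
#' follows from the in-series relation
#' `1/CL(oral) = 1/CL(iv) + 1/CL(absorption site)`. If `k_absorption` is
#' supplied, the absorption-site volume `V = CL(absorption site) /
#' k_absorption` is reported, and the flip-flop label is taken from
#' [flip_flop_rate()] against the iv elimination rate `1/MRT(iv)`.
#'
#' @param record a [study_record()] with both routes and urine data.
#' @param k_absorption optional first-order absorption rate constant
#'   (1/h).
#' @param threshold_ratio flip-flop labeling threshold, see
#'   [flip_flop_rate()].
#' @return a one-row tibble: `F_urine`, `F_plasma`, `mat`,
#'   `cl_system_oral`, `cl_absorption_site`, `k_absorption`,
#'   `v_absorption_site`, `flip_flop`.
#' @export
oral_clearance_chain <- function(record, k_absorption = NULL,
                                 threshold_ratio = 3) {
  f <- bioavailability(record)
  if (is.na(f$F_urine)) {
    abort_input("urine data for both routes are required for the clearance chain")
  }
  auc_oral <- auc_inf(record$curve_oral)
  cl_iv <- record$dose_iv / auc_inf(record$curve_iv)
  cl_oral <- f$F_urine * record$dose_oral / auc_oral
  if (cl_oral >= cl_iv) {
    abort_infeasible(
      "CL(oral) >= CL(iv): an in-series total cannot exceed a component stage"
    )
  }
  cl_abs <- 1 / (1 / cl_oral - 1 / cl_iv)
  mat <- mean_absorption_time(record)
  k_elim <- 1 / curve_mrt(record$curve_iv)
  ka <- k_absorption %||% NA_real_
  ff <- flip_flop_rate(k_elim, if (is.na(ka)) 1 / mat else ka, threshold_ratio)
  tibble::tibble(
    F_urine = f$F_urine,
    F_plasma = f$F_plasma,
    mat = mat,
    cl_system_oral = cl_oral,
    cl_absorption_site = cl_abs,
    k_absorption = ka,
    v_absorption_site = if (is.na(ka)) NA_real_ else cl_abs / ka,
    flip_flop = ff$label
  )
}

#' Flip-flop composition of absorption and elimination rates
#'
#' The measured terminal rate after oral dosing is the series combination
#' `k = k_elim * k_absorption / (k_elim + k_absorption)`: dominated by the
#' slower of the two, which is the mathematical basis of flip-flop
#' kinetics. The label calls the regime `"absorption_limited"` when
#' `k_absorption < k_elim / threshold_ratio`, `"elimination_limited"` when
#' `k_absorption > k_elim * threshold_ratio`, else `"comparable"`.
#'
#' @param k_elim iv-bolus systemic elimination rate constant (1/h).
#' @param k_absorption first-order absorption rate constant (1/h).
#' @param threshold_ratio labeling ratio (default 3).
#' @return a tibble: `k_system_oral`, `label`.
#' @examples
#' flip_flop_rate(0.2, 0.02) # controlled release: absorption-limited
#' @export
flip_flop_rate <- function(k_elim, k_absorption, threshold_ratio = 3) {
  check_positive(k_elim, "k_elim")
  check_positive(k_absorption, "k_absorption")
  tibble::tibble(
    k_system_oral = k_elim * k_absorption / (k_elim + k_absorption),
    label = dplyr::case_when(
      k_absorption < k_elim / threshold_ratio ~ "absorption_limited",
      k_absorption > k_elim * threshold_ratio ~ "elimination_limited",
      TRUE ~ "comparable"
    )
  )
}
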