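# Hepatic clearance: the three-stage series form (blood flow, net
# basolateral transport, intrinsic elimination), its two-stage reduction
# (the familiar "well-stirred" expression), the transport-limited form, and
# the differential-equation-derived alternatives (extended clearance
# concept; well-stirred/parallel-tube intrinsic-clearance back-calculation
# from perfusion data) kept for side-by-side comparison.

#' Hepatic parameter sets
#'
#' @param Q_H hepatic blood flow (> 0), L/h.
#' @param f_uB unbound fraction in blood, in (0, 1].
#' @param CL_int intrinsic elimination clearance (metabolic + biliary, >= 0).
#' @param CL_int_influx,CL_int_efflux basolateral influx / efflux intrinsic
#'   clearances (>= 0).
#' @param transport_in_scope whether the basolateral transport stage enters
#'   the series combination.
#' @param units unit label recorded with the set.
#' @return a tibble with class `hepatic_params`.
#' @examples
#' hepatic_params(Q_H = 90, f_uB = 0.1, CL_int = 500,
#'                CL_int_influx = 60, CL_int_efflux = 10)
#' @export
hepatic_params <- function(Q_H, f_uB, CL_int,
                           CL_int_influx = 0, CL_int_efflux = 0,
                           transport_in_scope = CL_int_influx > 0 | CL_int_efflux > 0,
                           units = "L/h") {
  p <- tibble::tibble(
    Q_H = Q_H, f_uB = f_uB, CL_int = CL_int,
    CL_int_influx = CL_int_influx, CL_int_efflux = CL_int_efflux,
    transport_in_scope = transport_in_scope, units = units
  )
  if (any(p$Q_H <= 0)) abort_domain("Q_H must be > 0")
  if (any(p$f_uB <= 0 | p$f_uB > 1)) abort_domain("f_uB must be in (0, 1]")
  if (any(p$CL_int < 0 | p$CL_int_influx < 0 | p$CL_int_efflux < 0)) {
    abort_domain("intrinsic clearances must be >= 0")
  }
  class(p) <- c("hepatic_params", class(p))
  p
}

#' Hepatic clearance from in-series rate-defining stages
#'
#' The full three-stage series combination
#' `1/CL_H = 1/Q_H + 1/(f_uB*(CL_int_influx - CL_int_efflux)) + 1/(f_uB*CL_int)`.
#' When the transport stage is out of scope the middle term is omitted and
#' the result reduces exactly to [well_stirred_form()]. A non-positive net
#' transport with the stage in scope is not rate-defining and errors.
#'
#' @param params a data frame with the [hepatic_params()] columns; extra
#'   columns are kept.
#' @return `params` as a tibble with a `CL_H` column added (always below
#'   `Q_H`).
#' @examples
#' hepatic_params(90, 0.1, 500, 60, 10) |> hepatic_clearance()
#' @export
hepatic_clearance <- function(params) {
  params <- tibble::as_tibble(params)
  dplyr::mutate(params, CL_H = hepatic_cl_vec(params))
}

hepatic_cl_vec <- function(p) {
  purrr::pmap_dbl(
    p[c("Q_H", "f_uB", "CL_int", "CL_int_influx", "CL_int_efflux", "transport_in_scope")],
    function(Q_H, f_uB, CL_int, CL_int_influx, CL_int_efflux, transport_in_scope) {
      if (CL_int <= 0) {
        abort_non_rate_defining("CL_int must be > 0 for an eliminating liver")
      }
      stages <- c(Q_H, f_uB * CL_int)
      if (transport_in_scope) {
        net <- CL_int_influx - CL_int_efflux
        if (net <= 0) {
          abort_non_rate_defining(sprintf(
            "net basolateral transport %s - %s <= 0 is not rate-defining",
            signif(CL_int_influx, 6), signif(CL_int_efflux, 6)
          ))
        }
        stages <- c(stages, f_uB * net)
      }
      combine_series(stages)
    }
  )
}

#' Two-stage hepatic clearance (blood flow and intrinsic elimination)
#'
#' `CL_H = Q_H * f_uB * CL_int / (Q_H + f_uB * CL_int)`: the series
#' combination of delivery and intrinsic elimination, long known as the
#' well-stirred model equation but derivable with no organ-mixing
#' assumption at all. Vectorized over its arguments.
#'
#' @param Q_H hepatic blood flow.
#' @param f_uB unbound fraction in blood.
#' @param CL_int intrinsic elimination clearance.
#' @return hepatic clearance, below `Q_H`.
#' @examples
#' well_stirred_form(90, 0.1, 500) # ~32.1 L/h
#' @export
well_stirred_form <- function(Q_H, f_uB, CL_int) {
  check_positive(Q_H, "Q_H")
  check_positive(f_uB, "f_uB")
  check_positive(CL_int, "CL_int")
  Q_H * f_uB * CL_int / (Q_H + f_uB * CL_int)
}

#' Transport/elimination series form when blood flow is not limiting
#'
#' When `Q_H` greatly exceeds the other stages, hepatic clearance reduces
#' to the series combination of net basolateral transport and intrinsic
#' elimination: `f_uB * CL_int * net / (CL_int + net)` with
#' `net = CL_int_influx - CL_int_efflux`. The smaller of the two stages is
#' rate-limiting.
#'
#' @inheritParams hepatic_clearance
#' @return `params` as a tibble with a `CL_H_no_flow` column added.
#' @examples
#' hepatic_params(1e6, 0.5, 40, 30, 10) |> hepatic_transport_limited()
#' @export
hepatic_transport_limited <- function(params) {
  params <- tibble::as_tibble(params)
  net <- params$CL_int_influx - params$CL_int_efflux
  if (any(net <= 0)) {
    abort_non_rate_defining("net basolateral transport <= 0 is not rate-defining")
  }
  if (any(params$CL_int <= 0)) {
    abort_non_rate_defining("CL_int must be > 0")
  }
  dplyr::mutate(
    params,
    CL_H_no_flow = .data$f_uB * .data$CL_int * net / (.data$CL_int + net)
  )
}

#' Extended clearance concept (ECC) hepatic clearance
#'
#' The differential-equation-derived expression carrying influx and efflux
#' as separate parameters. Full form:
#' `CL_H = Q_H * CL_int_influx * f_uB * CL_int /
#' (CL_int_influx * f_uB * CL_int + Q_H * CL_int + Q_H * CL_int_efflux)`;
#' with `simplified = TRUE` the high-blood-flow limit
#' `CL_int_influx * f_uB * CL_int / (CL_int + CL_int_efflux)` is used.
#' Unlike the Kirchhoff path, influx <= efflux is permitted here: the ECC
#' treats the two directions independently.
#'
#' @inheritParams hepatic_clearance
#' @param simplified use the high-`Q_H` limit.
#' @return `params` as a tibble with a `CL_ecc` column added.
#' @examples
#' hepatic_params(90, 0.1, 500, 60, 10) |> ecc_clearance()
#' @export
ecc_clearance <- function(params, simplified = FALSE) {
  params <- tibble::as_tibble(params)
  dplyr::mutate(params, CL_ecc = ecc_cl_vec(params, simplified))
}

ecc_cl_vec <- function(p, simplified) {
  num_core <- p$CL_int_influx * p$f_uB * p$CL_int
  denom <- if (simplified) {
    p$CL_int + p$CL_int_efflux
  } else {
    num_core + p$Q_H * p$CL_int + p$Q_H * p$CL_int_efflux
  }
  if (any(denom <= 0)) {
    abort_infeasible("degenerate ECC parameters: zero denominator")
  }
  if (simplified) num_core / denom else p$Q_H * num_core / denom
}

#' Side-by-side ECC vs Kirchhoff comparison
#'
#' Evaluates the transport/elimination Kirchhoff form (blood flow not
#' limiting) and the simplified ECC on identical parameters, flagging the
#' regions where only one framework yields a value (the ECC is finite at
#' influx = efflux, where the net-transport stage is not rate-defining).
#' Per-framework failures are recorded in the result, never thrown.
#'
#' @inheritParams hepatic_clearance
#' @param dominance_fraction passed to [classify_rate_limiting_step()].
#' @return a tibble with `CL_ecc`, `CL_kirchhoff`, `ratio`
#'   (Kirchhoff / ECC), `kirchhoff_defined`, and the Kirchhoff rate-limit
#'   label (`NA` where undefined).
#' @examples
#' hepatic_params(90, 0.1, 500, CL_int_influx = c(60, 10),
#'                CL_int_efflux = c(10, 10)) |>
#'   compare_ecc_vs_kirchhoff()
#' @export
compare_ecc_vs_kirchhoff <- function(params, dominance_fraction = 0.9) {
  params <- tibble::as_tibble(params)
  ecc <- ecc_cl_vec(params, simplified = TRUE)
  rows <- purrr::map(seq_len(nrow(params)), function(i) {
    row <- params[i, ]
    kl <- tryCatch(
      hepatic_transport_limited(row)$CL_H_no_flow,
      kirchpk_error = function(e) NA_real_
    )
    lab <- if (is.na(kl)) {
      NA_character_
    } else {
      classify_rate_limiting_step(row, dominance_fraction)$rate_limit
    }
    tibble::tibble(CL_kirchhoff = kl, rate_limit = lab)
  })
  dplyr::bind_cols(params, dplyr::bind_rows(rows)) |>
    dplyr::mutate(
      CL_ecc = ecc,
      ratio = .data$CL_kirchhoff / .data$CL_ecc,
      kirchhoff_defined = !is.na(.data$CL_kirchhoff)
    )
}

#' Classify the rate-limiting hepatic stage
#'
#' Each in-series stage contributes its reciprocal to `1/CL_H`; the stage
#' contributing at least `dominance_fraction` of the total reciprocal is
#' rate-limiting, otherwise the classification is `"mixed"`.
#'
#' @inheritParams hepatic_clearance
#' @param dominance_fraction fraction of `1/CL_H` one stage must carry to
#'   be called rate-limiting; strictly between 0.5 and 1 (default 0.9,
#'   a strict reading of "much greater").
#' @return `params` as a tibble with `rate_limit` (one of
#'   `"blood_flow_limited"`, `"net_transport_limited"`,
#'   `"elimination_limited"`, `"mixed"`) and `dominance_ratio` columns.
#' @examples
#' hepatic_params(90, 0.1, 500, 11, 10) |> classify_rate_limiting_step()
#' @export
classify_rate_limiting_step <- function(params, dominance_fraction = 0.9) {
  if (!is.numeric(dominance_fraction) || dominance_fraction <= 0.5 ||
    dominance_fraction >= 1) {
    abort_input("dominance_fraction must be strictly between 0.5 and 1")
  }
  params <- tibble::as_tibble(params)
  out <- purrr::pmap(
    params[c("Q_H", "f_uB", "CL_int", "CL_int_influx", "CL_int_efflux", "transport_in_scope")],
    function(Q_H, f_uB, CL_int, CL_int_influx, CL_int_efflux, transport_in_scope) {
      recip <- c(blood_flow_limited = 1 / Q_H, elimination_limited = 1 / (f_uB * CL_int))
      if (transport_in_scope) {
        net <- CL_int_influx - CL_int_efflux
        if (net <= 0) {
          abort_non_rate_defining("net basolateral transport <= 0 is not rate-defining")
        }
        recip <- c(recip, net_transport_limited = 1 / (f_uB * net))
      }
      share <- recip / sum(recip)
      top <- which.max(share)
      tibble::tibble(
        rate_limit = if (share[top] >= dominance_fraction) names(share)[top] else "mixed",
        dominance_ratio = unname(share[top])
      )
    }
  )
  dplyr::bind_cols(params, dplyr::bind_rows(out))
}

#' Hepatic bioavailability from clearance and blood flow
#'
#' `F_H = 1 - CL_H / Q_H`, the fraction escaping first-pass hepatic
#' extraction. Requires `0 < CL_H < Q_H` (in-series clearance cannot exceed
#' organ blood flow).
#'
#' @param CL_H hepatic clearance.
#' @param Q_H hepatic blood flow, same units.
#' @return dimensionless fraction in (0, 1).
#' @examples
#' hepatic_bioavailability(10.4, 90)
#' @export
hepatic_bioavailability <- function(CL_H, Q_H) {
  check_positive(CL_H, "CL_H")
  check_positive(Q_H, "Q_H")
  if (any(CL_H >= Q_H)) {
    abort_infeasible("CL_H must be below hepatic blood flow Q_H")
  }
  1 - CL_H / Q_H
}

# ---- perfusion steady state -----------------------------------------------

#' Steady-state perfusion records
#'
#' Single-pass organ perfusion at steady state: unbound inlet/outlet
#' concentrations, the systemic (reference) total blood concentration, and
#' the perfusate flow. An eliminating organ requires
#' `C_in_u > C_out_u > 0`.
#'
#' @param C_in_u,C_out_u unbound inlet / outlet concentrations (mg/L).
#' @param C_blood total systemic reference blood concentration (mg/L); the
#'   convention used to choose it (e.g. inlet total) is the caller's and
#'   should be recorded with the data.
#' @param Q_H perfusate flow (L/h).
#' @param f_uB unbound fraction in blood.
#' @return a tibble with class `perfusion_ss`.
#' @export
perfusion_ss <- function(C_in_u, C_out_u, C_blood, Q_H, f_uB = 1) {
  p <- tibble::tibble(
    C_in_u = C_in_u, C_out_u = C_out_u, C_blood = C_blood,
    Q_H = Q_H, f_uB = f_uB
  )
  if (any(p$C_out_u <= 0) || any(p$C_blood <= 0) || any(p$Q_H <= 0)) {
    abort_domain("concentrations and flow must be > 0")
  }
  if (any(p$C_in_u <= p$C_out_u)) {
    abort_infeasible(
      "no extraction: C_in_u must exceed C_out_u for an eliminating organ"
    )
  }
  class(p) <- c("perfusion_ss", class(p))
  p
}

#' Back-calculate intrinsic clearance from perfusion data
#'
#' The mechanistic hepatic disposition models share one steady-state
#' identity, `CL_H * C_blood = CL_int * C_ref,u`, but differ in the
#' intra-organ reference concentration: the well-stirred model (WSM) uses
#' the outlet unbound concentration, the parallel-tube model (PTM) the
#' logarithmic mean of inlet and outlet. Observed organ clearance is taken
#' as `Q_H * (C_in_u - C_out_u) / C_in_u` (extraction on the unbound inlet
#' basis). Because the log-mean always exceeds the outlet concentration,
#' `CL_int` back-calculated under the WSM is at least the PTM value.
#'
#' @param ss a data frame with the [perfusion_ss()] columns.
#' @param model `"WSM"` or `"PTM"`.
#' @return `ss` as a tibble with `E` (extraction ratio), `CL_H`, and
#'   `CL_int` columns added.
#' @examples
#' perfusion_ss(10, 1, 10, 1) |> intrinsic_clearance_from_perfusion("WSM")
#' @export
intrinsic_clearance_from_perfusion <- function(ss, model = c("WSM", "PTM")) {
  model <- rlang::arg_match(model)
  ss <- tibble::as_tibble(ss)
  if (any(ss$C_out_u >= ss$C_in_u)) {
    abort_infeasible("no extraction: C_in_u must exceed C_out_u")
  }
  E <- (ss$C_in_u - ss$C_out_u) / ss$C_in_u
  CL_H <- ss$Q_H * E
  C_ref <- if (model == "WSM") {
    ss$C_out_u
  } else {
    (ss$C_in_u - ss$C_out_u) / log(ss$C_in_u / ss$C_out_u)
  }
  dplyr::mutate(ss, E = E, CL_H = CL_H, CL_int = CL_H * .data$C_blood / C_ref)
}
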