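# Named worked-example fixtures. Everything here is defined by printed
# constants, so the whole analysis surface is testable with no external
# data.

#' Catalogue of worked-example fixtures
#'
#' Returns the constants behind the package's worked examples:
#'
#' * `scheme1`: the five-species first-order demonstration chain
#'   C1 -> C2 -> {C3, C4}, C3 -> C5 with k12 = 0.06, k23 = 0.15,
#'   k24 = 0.20, k35 = 0.50 (1/h) and 300 mg dosed into C1, plus the
#'   matching Kirchhoff stage totals and process network.
#' * `scheme2`: the same chain with a reversible, non-eliminating side
#'   exchange C1 <-> C6 (defaults k16 = 0.3, k61 = 0.1; rebuild at other
#'   values with `scheme2_network()`).
#' * `metformin`: renal parameter set (Q_R = 1200 mL/min, f_uB = 1,
#'   GFR = 120 mL/min, net secretion 1080 mL/min) and the observed renal
#'   clearance of 600 mL/min it reproduces.
#' * `kl25a`: the paired-route study record of the hypothetical drug
#'   KL25A: 2500 mg iv bolus with disposition
#'   `15 e^(-1.39 t) + 16 e^(-0.173 t)` mg/L, 5000 mg oral with
#'   `22.7 (e^(-0.105 t) - e^(-1.16 t))` mg/L, and 1430 / 220 mg of
#'   unchanged drug in urine.
#'
#' @return a named list of fixtures.
#' @examples
#' fx <- worked_examples()
#' species_moments(fx$scheme1$network)
#' nca_iv(fx$kl25a$record)
#' @export
worked_examples <- function() {
  scheme1_edges <- tibble::tibble(
    from = c("C1", "C2", "C2", "C3"),
    to = c("C2", "C3", "C4", "C5"),
    rate = c(0.06, 0.15, 0.20, 0.50)
  )
  scheme1 <- list(
    network = fo_network(scheme1_edges, initial = c(C1 = 300)),
    dose_mg = 300,
    # in-series stage totals seen by C3: k12, (k23 + k24), k35
    kirchhoff_stages = c(0.06, 0.15 + 0.20, 0.50),
    process_network = pk_series(
      pk_process(0.06, "k12"),
      pk_parallel(pk_process(0.15, "k23"), pk_process(0.20, "k24")),
      pk_process(0.50, "k35")
    )
  )
  list(
    scheme1 = scheme1,
    scheme2 = list(
      network = scheme2_network(),
      k16 = 0.3, k61 = 0.1,
      kirchhoff_stages = scheme1$kirchhoff_stages
    ),
    metformin = list(
      params = renal_params(
        Q_R = 1200, f_uB = 1, GFR = 120, CL_sec = 1080, CL_reab = 0,
        units = "mL/min"
      ),
      CL_R_observed = 600
    ),
    kl25a = list(
      record = study_record(
        dose_iv = 2500,
        curve_iv = pk_curve(c(15, 16), c(1.39, 0.173), role = "iv_disposition"),
        U_inf_iv = 1430,
        dose_oral = 5000,
        curve_oral = pk_curve(c(22.7, -22.7), c(0.105, 1.16),
          role = "oral_disposition"
        ),
        U_inf_oral = 220
      ),
      # default synthetic sampling grid spanning both disposition phases
      sampling_times_h = c(
        0.25, 0.5, 1, 1.5, 2, 3, 4, 6, 8, 10, 12, 16, 20, 24
      )
    )
  )
}

#' @rdname worked_examples
#' @param k16,k61 exchange rate constants (1/h) between C1 and the
#'   non-eliminating side species C6.
#' @export
scheme2_network <- function(k16 = 0.3, k61 = 0.1) {
  check_positive(c(k16, k61), "k16/k61")
  fo_network(
    tibble::tibble(
      from = c("C1", "C2", "C2", "C3", "C1", "C6"),
      to = c("C2", "C3", "C4", "C5", "C6", "C1"),
      rate = c(0.06, 0.15, 0.20, 0.50, k16, k61)
    ),
    initial = c(C1 = 300)
  )
}
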