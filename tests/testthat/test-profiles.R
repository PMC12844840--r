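# Polyexponential NCA and the oral/iv bioavailability calculus.

kl25a <- function() worked_examples()$kl25a$record

test_that("curve construction canonicalizes and enforces role invariants", {
  cv <- pk_curve(c(16, 15), c(0.173, 1.39))
  expect_equal(cv$exponent, c(1.39, 0.173)) # decreasing
  expect_equal(cv$coefficient, c(15, 16))
  # duplicate exponents merge
  m <- pk_curve(c(1, 2, 3), c(0.5, 0.5, 0.1), role = "amount_curve")
  expect_equal(nrow(m), 2)
  expect_equal(m$coefficient, c(3, 3))
  expect_error(pk_curve(c(-1, 2), c(1, 0.1)), class = "kirchpk_domain_error")
  expect_error(
    pk_curve(c(-5, 1), c(0.1, 1), role = "oral_disposition"),
    class = "kirchpk_domain_error"
  )
  expect_error(pk_curve(1, -0.5), class = "kirchpk_domain_error")
})

test_that("AUC and AUMC are signed coefficient-over-exponent sums", {
  expect_equal(auc_inf(pk_curve(12, 0.4)), 30)
  expect_equal(aumc_inf(pk_curve(12, 0.4)), 75)
  iv <- kl25a()$curve_iv
  expect_equal(auc_inf(iv), 15 / 1.39 + 16 / 0.173, tolerance = 1e-12)
  expect_equal(signif(auc_inf(iv), 3), 103)
  expect_equal(signif(aumc_inf(iv), 3), 542)
  oral <- kl25a()$curve_oral
  expect_equal(auc_inf(oral), 22.7 / 0.105 - 22.7 / 1.16, tolerance = 1e-12)
  expect_equal(signif(auc_inf(oral), 3), 197)
  expect_equal(aumc_inf(oral), 22.7 / 0.105^2 - 22.7 / 1.16^2, tolerance = 1e-12)
})

test_that("iv NCA reproduces the paired-study worked values", {
  nca <- nca_iv(kl25a())
  expect_equal(nca$cl, 24.3, tolerance = 0.005)
  expect_equal(nca$cl_r, 13.9, tolerance = 0.005)
  expect_equal(nca$cl_h, 10.4, tolerance = 0.01)
  expect_equal(nca$mrt, 5.26, tolerance = 0.005)
  expect_equal(nca$vss, 127.8, tolerance = 0.01)
  expect_equal(nca$v_initial, 2500 / 31, tolerance = 1e-12)
  expect_equal(signif(nca$v_initial, 3), 80.6)
  # internal identities hold exactly
  expect_equal(nca$vss, nca$cl * nca$mrt, tolerance = 1e-12)
  expect_equal(nca$cl_h + nca$cl_r, nca$cl, tolerance = 1e-12)
})

test_that("one-compartment identities hold for a monoexponential record", {
  withr::with_seed(122, {
    for (i in 1:10) {
      D <- runif(1, 100, 1000)
      C0 <- runif(1, 1, 50)
      lam <- exp(rnorm(1, -1))
      rec <- study_record(dose_iv = D, curve_iv = pk_curve(C0, lam))
      nca <- nca_iv(rec)
      expect_equal(nca$cl, D * lam / C0, tolerance = 1e-12)
      expect_equal(nca$mrt, 1 / lam, tolerance = 1e-12)
      expect_equal(nca$vss, D / C0, tolerance = 1e-12)
      expect_equal(nca$v_initial, D / C0, tolerance = 1e-12)
    }
  })
})

test_that("synthetic biexponential built from chosen CL/V recovers them", {
  # two-compartment disposition with known micro-constants
  withr::with_seed(132, {
    for (i in 1:10) {
      V1 <- runif(1, 20, 100)
      k10 <- exp(rnorm(1, -1, 0.3))
      k12 <- exp(rnorm(1, -1.5, 0.3))
      k21 <- exp(rnorm(1, -1.5, 0.3))
      D <- 1000
      s <- k10 + k12 + k21
      l1 <- (s + sqrt(s^2 - 4 * k10 * k21)) / 2
      l2 <- (s - sqrt(s^2 - 4 * k10 * k21)) / 2
      A <- D / V1 * (l1 - k21) / (l1 - l2)
      B <- D / V1 * (k21 - l2) / (l1 - l2)
      rec <- study_record(D, pk_curve(c(A, B), c(l1, l2)))
      expect_equal(nca_iv(rec)$cl, V1 * k10, tolerance = 1e-9)
      expect_equal(nca_iv(rec)$v_initial, V1, tolerance = 1e-9)
    }
  })
})

test_that("bioavailability from urine and plasma matches the worked study", {
  f <- bioavailability(kl25a())
  expect_equal(f$F_urine, (220 / 1430) * (2500 / 5000), tolerance = 1e-12)
  expect_equal(signif(f$F_urine, 3), 0.0769)
  expect_equal(f$F_plasma, 0.956, tolerance = 0.005)
  # identical dose-normalized exposure and recovery: the two measures agree
  rec <- study_record(
    dose_iv = 100, curve_iv = pk_curve(c(4, 6), c(1, 0.2)), U_inf_iv = 40,
    dose_oral = 200, curve_oral = pk_curve(c(8, 12), c(1, 0.2)), U_inf_oral = 80
  )
  f2 <- bioavailability(rec)
  expect_equal(f2$F_urine, f2$F_plasma, tolerance = 1e-12)
})

test_that("mean absorption time follows moment additivity", {
  expect_equal(mean_absorption_time(kl25a()), 5.13, tolerance = 0.005)
  # identical curves: zero MAT, flagged as artifact
  iv <- pk_curve(c(4, 6), c(1, 0.2))
  same <- study_record(100, iv,
    dose_oral = 100,
    curve_oral = pk_curve(c(4, 6), c(1, 0.2), role = "oral_disposition")
  )
  expect_warning(mat0 <- mean_absorption_time(same), "non-positive")
  expect_equal(mat0, 0)
  # first-order-input convolution: MAT is exactly 1/k_a
  withr::with_seed(142, {
    for (i in 1:10) {
      ka <- exp(rnorm(1, -0.5, 0.7))
      oral <- convolve_first_order_input(iv, ka, dose_iv = 100, dose_oral = 250)
      rec <- study_record(100, iv, dose_oral = 250, curve_oral = oral)
      expect_equal(mean_absorption_time(rec), 1 / ka, tolerance = 1e-6)
    }
  })
})

test_that("oral clearance chain reproduces the worked example and round-trips", {
  chain <- oral_clearance_chain(kl25a())
  expect_equal(chain$cl_system_oral, 1.95, tolerance = 0.005)
  expect_equal(chain$cl_absorption_site, 2.12, tolerance = 0.01)
  # MAT (5.13 h) and iv MRT (5.26 h) are close: absorption and elimination
  # proceed at comparable rates
  expect_equal(chain$flip_flop, "comparable")
  expect_true(is.na(chain$v_absorption_site))
  with_ka <- oral_clearance_chain(kl25a(), k_absorption = 0.105)
  expect_equal(
    with_ka$v_absorption_site,
    with_ka$cl_absorption_site / 0.105,
    tolerance = 1e-12
  )

  # randomized round trip: choose CL_iv and CL_abs, build the record that
  # realizes them, and invert
  withr::with_seed(152, {
    for (i in 1:20) {
      iv <- pk_curve(c(4, 6) * runif(1, 0.5, 2), c(1, 0.2))
      dose_iv <- 500
      cl_iv <- dose_iv / auc_inf(iv)
      cl_abs <- cl_iv * runif(1, 0.02, 0.8)
      cl_oral <- combine_series(c(cl_iv, cl_abs))
      dose_oral <- 1000
      f_true <- runif(1, 0.05, 0.9) # true absorbed fraction
      auc_oral <- f_true * dose_oral / cl_oral
      shape <- pk_curve(c(1, -1), c(0.08, 0.9), role = "oral_disposition")
      oral <- pk_curve(
        shape$coefficient * auc_oral / auc_inf(shape), shape$exponent,
        role = "oral_disposition"
      )
      fe <- 0.4 # fraction excreted unchanged, route-independent
      rec <- study_record(
        dose_iv, iv,
        U_inf_iv = fe * dose_iv,
        dose_oral = dose_oral, curve_oral = oral,
        U_inf_oral = fe * f_true * dose_oral
      )
      out <- oral_clearance_chain(rec)
      expect_equal(out$F_urine, f_true, tolerance = 1e-9)
      expect_equal(out$cl_system_oral, cl_oral, tolerance = 1e-9)
      expect_equal(out$cl_absorption_site, cl_abs, tolerance = 1e-9)
    }
  })
})

test_that("slow absorption-site clearance inflates plasma bioavailability above 1", {
  iv <- pk_curve(c(10, 8), c(1.2, 0.15))
  dose_iv <- 1000
  cl_iv <- dose_iv / auc_inf(iv)
  cl_abs <- cl_iv / 50 # very slow delivery
  cl_oral <- combine_series(c(cl_iv, cl_abs))
  f_true <- 0.9
  dose_oral <- 1000
  auc_oral <- f_true * dose_oral / cl_oral
  oral <- pk_curve(c(1, -1) * auc_oral / auc_inf(pk_curve(c(1, -1), c(0.05, 1),
    role = "oral_disposition"
  )), c(0.05, 1), role = "oral_disposition")
  rec <- study_record(dose_iv, iv,
    U_inf_iv = 500, dose_oral = dose_oral,
    curve_oral = oral, U_inf_oral = 500 * f_true
  )
  f <- bioavailability(rec)
  expect_lte(f$F_urine, 1)
  expect_gt(f$F_plasma, 1) # never clamped
  expect_gt(f$F_plasma, f$F_urine)
})

test_that("infeasible oral chains error rather than return negatives", {
  iv <- pk_curve(c(4, 6), c(1, 0.2))
  # oral clearance apparently above iv clearance
  rec <- study_record(
    dose_iv = 100, curve_iv = iv, U_inf_iv = 50,
    dose_oral = 100,
    curve_oral = pk_curve(c(1, -1) * 0.5, c(0.2, 1), role = "oral_disposition"),
    U_inf_oral = 90
  )
  expect_error(
    suppressWarnings(oral_clearance_chain(rec)),
    class = "kirchpk_infeasible_error"
  )
})

test_that("flip-flop composition is a series combination with labels", {
  expect_equal(flip_flop_rate(0.2, 0.2)$k_system_oral, 0.1)
  expect_equal(flip_flop_rate(0.2, 0.2)$label, "comparable")
  expect_equal(flip_flop_rate(0.2, 200)$k_system_oral, 0.2, tolerance = 1e-3)
  expect_equal(flip_flop_rate(0.2, 200)$label, "elimination_limited")
  expect_equal(flip_flop_rate(0.2, 0.002)$k_system_oral, 0.002, tolerance = 1e-2)
  expect_equal(flip_flop_rate(0.2, 0.002)$label, "absorption_limited")
  # agrees with the generic series combination
  expect_equal(
    flip_flop_rate(0.31, 0.07)$k_system_oral,
    combine_series(c(0.31, 0.07)),
    tolerance = 1e-12
  )
})

test_that("tidy and glance summarise curves and records", {
  iv <- kl25a()$curve_iv
  td <- tidy(iv)
  expect_equal(nrow(td), 2)
  expect_equal(td$half_life_h, log(2) / c(1.39, 0.173))
  g <- glance(iv)
  expect_equal(g$c0, 31)
  expect_equal(g$role, "iv_disposition")
})
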