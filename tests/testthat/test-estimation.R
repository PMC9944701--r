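test_that("scan-midpoint offset shifts nominal times once and only once", {
  d <- data.frame(tissue = "lung", time_min = c(5, 30, 60),
                  pct_dose = c(1, 2, 3))
  ds <- observation_dataset(d)
  expect_equal(ds$time_min, ds$nominal_min)
  ds10 <- apply_scan_offset(ds, 10)
  expect_equal(ds10$time_min, c(15, 40, 70))
  expect_equal(ds10$nominal_min, c(5, 30, 60))
  expect_error(apply_scan_offset(ds10, 10), "already applied")
  ds0 <- apply_scan_offset(ds, 0)
  expect_equal(ds0$time_min, ds0$nominal_min)
})

test_that("biexponential fit recovers exact generating parameters", {
  tt <- c(0.083, 0.25, 0.5, 1, 2, 4, 8, 24)
  cv <- 25.98 * exp(-0.3004 * tt) + 0.3530 * exp(-3.533 * tt)
  ff <- fit_biexponential(tt, cv)
  expect_equal(ff$coef, c(25.98, 0.3530), tolerance = 1e-3)
  expect_equal(ff$rate, c(0.3004, 3.533), tolerance = 1e-3)
  # back-extrapolated intercept is the sum of the coefficients
  expect_equal(eval_forcing(ff, 0), 26.333, tolerance = 1e-3)
  expect_true(all(eval_forcing(ff, tt) > 0))
})

test_that("single-exponential data drive the second phase to zero", {
  tt <- c(5, 15, 30, 60, 120, 240)
  cv <- 10 * exp(-0.02 * tt)
  ff <- fit_biexponential(tt, cv)
  slow <- which.max(ff$coef)
  expect_equal(ff$coef[slow], 10, tolerance = 1e-3)
  expect_equal(ff$rate[slow], 0.02, tolerance = 1e-3)
  expect_lt(min(ff$coef) / max(ff$coef), 1e-4)
})

test_that("open-loop fits recover parameters from matching-forcing data", {
  phys <- adult_phys(); drug <- adult_drug()
  ff <- structure(list(coef = c(0.25, 0.55), rate = c(0.001, 0.035),
                       time_unit = "min"), class = "forcing_function")
  tms <- c(15, 40, 70, 130, 250, 490, 1450)

  # perfusion-limited tissue with known Kp = 8, generated from the same
  # open-loop equations the fit uses (lung Kp fixed at its default)
  kp_true <- 8
  cart <- tetrodose:::arterial_mixture(ff, phys, drug$kp[["lung"]])
  Qt <- phys$Q[["thyroid"]]; Vt <- phys$V[["thyroid"]]
  amt <- tetrodose:::mix_through(
    tetrodose:::mix_scale(cart, Qt),
    Qt * drug$blood_plasma_ratio / (kp_true * Vt))
  d_th <- data.frame(tissue = "thyroid", time_min = tms,
                     pct_dose = eval_forcing(amt, tms))
  ds <- observation_dataset(d_th)
  ds$time_min <- ds$nominal_min  # times already final
  est <- fit_open_loop("thyroid", ds, ff, phys, drug, variant = "perfusion")
  expect_equal(est$estimates[["kp_thyroid"]], kp_true, tolerance = 0.02)

  # lung directly against the venous forcing
  a <- phys$Q[["lung"]] / (drug$kp[["lung"]] * phys$V[["lung"]])
  lungmix <- tetrodose:::mix_through(
    tetrodose:::mix_scale(ff, phys$Q[["lung"]]), a)
  d_lu <- data.frame(tissue = "lung", time_min = tms,
                     pct_dose = eval_forcing(lungmix, tms))
  est <- fit_open_loop("lung", observation_dataset(d_lu), ff, phys, drug)
  expect_equal(est$estimates[["kp_lung"]], drug$kp[["lung"]],
               tolerance = 0.01)
})

test_that("zero-noise hepatic open-loop data return the clearance within 1%", {
  phys <- adult_phys(); drug <- adult_drug()
  ff <- structure(list(coef = c(0.25, 0.55), rate = c(0.001, 0.035),
                       time_unit = "min"), class = "forcing_function")
  tms <- c(15, 40, 70, 130, 250, 490, 1450)
  cart <- tetrodose:::arterial_mixture(ff, phys, drug$kp[["lung"]])
  cart_fun <- function(t) eval_forcing(cart, t)
  V <- phys$V; Q <- phys$Q; R <- drug$blood_plasma_ratio
  rhs <- function(t, y, p) {
    ca <- cart_fun(t)
    out_l <- R * y[1] / (drug$kp[["liver"]] * V[["liver"]])
    out_g <- R * y[3] / (drug$kp[["gi"]] * V[["gi_tissue"]])
    out_s <- R * y[5] / (drug$kp[["spleen"]] * V[["spleen"]])
    out_p <- R * y[6] / (drug$kp[["pancreas"]] * V[["pancreas"]])
    bile <- drug$cl[["liver"]] * y[1] / V[["liver"]]
    gb <- drug$k_gb * y[2] / V[["gallbladder"]]
    list(c(-Q[["liver"]] * out_l + Q[["hepatic_artery"]] * ca - bile +
             Q[["gi"]] * out_g + Q[["pancreas"]] * out_p +
             Q[["spleen"]] * out_s,
           bile - gb, Q[["gi"]] * (ca - out_g), gb,
           Q[["spleen"]] * (ca - out_s), Q[["pancreas"]] * (ca - out_p)))
  }
  out <- deSolve::lsoda(numeric(6), c(0, tms), rhs, NULL,
                        rtol = 1e-10, atol = 1e-12)[-1, ]
  ds <- observation_dataset(rbind(
    data.frame(tissue = "liver", time_min = tms, pct_dose = out[, 2]),
    data.frame(tissue = "gi", time_min = tms,
               pct_dose = out[, 4] + out[, 5])))
  est <- fit_open_loop("liver", ds, ff, phys, drug)
  expect_equal(est$estimates[["cl_liver"]], drug$cl[["liver"]],
               tolerance = 0.01)
  expect_equal(est$estimates[["kp_liver"]], drug$kp[["liver"]],
               tolerance = 0.01)
})

test_that("pooled R2 behaves as a coefficient of determination", {
  y <- c(1, 3, 5, 9)
  expect_equal(compute_r2(y, y), 1)
  expect_equal(compute_r2(y, rep(mean(y), 4)), 0)
  expect_error(compute_r2(rep(2, 4), y), "constant")
})

test_that("concentrated and explicit-sigma likelihoods agree at the profile", {
  set.seed(3)
  tissue <- rep(c("a", "b"), each = 6)
  f <- stats::runif(12, 1, 10)
  y <- f * (1 + stats::rnorm(12, 0, 0.2))
  sig <- vapply(split(seq_len(12), tissue), function(ix) {
    sqrt(mean(((y[ix] - f[ix]) / f[ix])^2))
  }, numeric(1))
  expect_equal(tetrodose:::neg2ll_concentrated(y, f, tissue),
               tetrodose:::neg2ll_full(y, f, tissue, sig),
               tolerance = 1e-12)
})

test_that("closed-loop refit of noise-free data recovers all 11 parameters", {
  fit <- noise_free_fit()
  truth <- truth_vector()
  expect_true(all(abs(fit$estimates[names(truth)] - truth) / truth < 0.01))
  # objective at the optimum does not exceed the starting objective, and
  # the accepted-step trace is monotone non-increasing
  expect_true(all(diff(fit$trace) <= 0))
  expect_lte(fit$neg2ll, fit$trace[1])
  expect_equal(fit$r2, 1, tolerance = 1e-6)
})

test_that("structural identifiability is guarded by tissue coverage", {
  phys <- adult_phys()
  ds <- noise_free_dataset()
  one <- ds[ds$tissue == "heart", ]
  attributes(one)[c("dose", "lag_min")] <- attributes(ds)[c("dose", "lag_min")]
  class(one) <- class(ds)
  expect_error(fit_closed_loop(one, phys, drug = adult_drug()),
               "two tissues")

  two <- ds[ds$tissue %in% c("heart", "blood"), ]
  attributes(two)[c("dose", "lag_min")] <- attributes(ds)[c("dose", "lag_min")]
  class(two) <- class(ds)
  expect_warning(
    fit2 <- fit_closed_loop(two, phys, drug = adult_drug(),
                            control = list(iter.max = 20)),
    "non-identifiable")
  expect_true("kp_thyroid" %in% fit2$non_identifiable)
  # parameters of unobserved organs stay at their initial values
  expect_equal(fit2$estimates[["kp_thyroid"]],
               adult_drug()$kp[["thyroid"]])
})

test_that("standard errors are positive with consistent relative errors", {
  fit <- compute_standard_errors(noise_free_fit())
  expect_true(all(fit$se[fit$free] > 0))
  expect_equal(fit$rse_pct, 100 * fit$se / fit$estimates)
  expect_true(isSymmetric(unname(fit$cov_log), tol = 1e-8))
  # sandwich variant runs and is recorded
  fit_sw <- compute_standard_errors(noise_free_fit(), type = "sandwich")
  expect_identical(fit_sw$se_type, "sandwich")
})
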