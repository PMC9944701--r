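# Synthetic observation datasets, structural S-value fixtures, and
# parameter-recovery experiments.

#' Specification for a synthetic imaging dataset
#'
#' Mirrors the design of the source imaging study: 7 nominal time points
#' over 24 h (5, 30 min, 1, 2, 4, 8, 24 h) for every tissue, an extra 48 h
#' point for urine, a scan-midpoint lag, and multiplicative proportional
#' noise with a separate SD per tissue.
#'
#' @param age_label Physiology age.
#' @param sigma Named per-tissue proportional error SDs; defaults to the
#'   adult residual error estimates of the bundled model.
#' @param times Nominal scan times (min).
#' @param urine_extra Extra nominal times for urine (min).
#' @param lag_min Scan-midpoint lag (min).
#' @param seed Random seed fixing all generator randomness.
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(age_label = "adult",
                           sigma = default_sigma(),
                           times = c(5, 30, 60, 120, 240, 480, 1440),
                           urine_extra = 2880, lag_min = 10, seed = 1) {
  stopifnot(all(sigma >= 0), !is.unsorted(times, strictly = TRUE),
            lag_min >= 0)
  structure(list(age_label = age_label, sigma = sigma, times = times,
                 urine_extra = urine_extra, lag_min = lag_min,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Adult per-tissue proportional residual error SDs
#'
#' The residual error estimates of the bundled adult model fit,
#' interpreted as SDs of the proportional error.
#'
#' @return Named numeric vector over the observable tissues.
#' @export
default_sigma <- function() {
  c(blood = 0.409, heart = 0.128, kidney = 0.285, liver = 0.629,
    lung = 0.785, thyroid = 0.777, gi = 0.222, urine = 0.045)
}

#' Generate a synthetic observation dataset
#'
#' Simulates the closed-loop model, evaluates the observables at the
#' offset (scan-midpoint) times, and perturbs them multiplicatively:
#' `Y = F (1 + eps)`, `eps ~ N(0, sigma_t^2)`, truncated at zero so that
#' observations are non-negative (the truncation rate is recorded as an
#' attribute).  Deterministic given the spec seed.
#'
#' @param spec A `synthetic_spec`.
#' @param phys Physiology; defaults to the bundled table for the spec age.
#' @param drug Drug parameters; default bundled adult estimates (scale
#'   first for paediatric generation).
#' @param dose Administered dose (percent scale).
#' @return A `pbpk_dataset` with nominal times and the spec lag applied;
#'   attributes `truth` (the generating drug parameters), `noise_free`
#'   (the exact predictions) and `truncated` (count of clipped draws).
#' @export
generate_dataset <- function(spec, phys = NULL, drug = NULL, dose = 100) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (is.null(phys)) phys <- load_physiology(spec$age_label)
  if (is.null(drug)) drug <- default_drug_params()
  tissues <- observable_tissues()
  des <- do.call(rbind, lapply(tissues, function(tis) {
    tms <- spec$times
    if (tis == "urine") tms <- sort(c(tms, spec$urine_extra))
    data.frame(tissue = tis, time_min = tms)
  }))
  ds <- observation_dataset(cbind(des, pct_dose = 0), dose = dose)
  ds <- apply_scan_offset(ds, spec$lag_min)
  f <- predict_dataset(ds, phys, drug)
  set.seed(spec$seed)
  eps <- stats::rnorm(nrow(ds), 0, spec$sigma[ds$tissue])
  y <- f * (1 + eps)
  truncated <- sum(y < 0)
  ds$pct_dose <- pmax(y, 0)
  attr(ds, "truth") <- drug
  attr(ds, "noise_free") <- f
  attr(ds, "truncated") <- truncated
  attr(ds, "seed") <- spec$seed
  ds
}

#' Structural S-value fixture
#'
#' Random positive target x source matrix with self-dose dominance
#' (diagonal at least as large as every entry in its column) and a global
#' inverse-mass scale factor, mimicking how S values grow as phantom mass
#' shrinks.  Deterministic given the seed.
#'
#' @param organs Character vector used as both targets and sources.
#' @param scale Global scale factor (e.g. larger for younger phantoms).
#' @param seed Random seed.
#' @return An `svalue_matrix`.
#' @export
generate_svalue_fixture <- function(organs, scale = 1, seed = 1) {
  stopifnot(length(organs) >= 1, scale > 0)
  set.seed(seed)
  n <- length(organs)
  S <- matrix(stats::runif(n * n, 1e-5, 5e-4), n, n,
              dimnames = list(organs, organs))
  diag(S) <- apply(S, 2, max) * stats::runif(n, 2, 10)
  svalue_matrix(S * scale, age_label = sprintf("fixture_x%g", scale))
}

#' Parameter-recovery experiment
#'
#' For each replicate: generate a synthetic dataset from known truth, fit
#' the closed-loop model (initialized at the truth, as the stage-one
#' workflow would provide), compute standard errors, and record relative
#' bias and whether each estimate falls within 2 SEs of the truth.
#' Replicates are seeded `seed + 1 .. seed + n`; individual fit failures
#' are logged and excluded.
#'
#' @param spec A `synthetic_spec` (its seed is overridden per replicate).
#' @param n_replicates Number of replicates (>= 1).
#' @param seed Base seed.
#' @param phys,drug Generating physiology and truth parameters.
#' @param ... Passed to [fit_closed_loop()].
#' @return A `recovery_report`: list with `bias` (replicates x parameters
#'   relative errors), `covered` (logical matrix), `summary` (bias, RMSE,
#'   coverage per parameter), `n_failed`.
#' @export
recovery_experiment <- function(spec, n_replicates = 10, seed = 1,
                                phys = NULL, drug = NULL, ...) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (n_replicates < 1) stop("need at least one replicate")
  if (is.null(phys)) phys <- load_physiology(spec$age_label)
  if (is.null(drug)) drug <- default_drug_params()
  truth <- c(kp_lung = drug$kp[["lung"]], kp_heart = drug$kp[["heart"]],
             ps_heart = drug$ps[["heart"]], kp_kidney = drug$kp[["kidney"]],
             ps_kidney = drug$ps[["kidney"]], kp_liver = drug$kp[["liver"]],
             kp_thyroid = drug$kp[["thyroid"]], kp_other = drug$kp[["other"]],
             cl_renal = drug$cl[["renal"]], cl_liver = drug$cl[["liver"]],
             k_gb = drug$k_gb)[fitted_parameters()]
  bias <- covered <- se_mat <- matrix(NA_real_, n_replicates, length(truth),
                                      dimnames = list(NULL, names(truth)))
  failures <- character(0)
  for (r in seq_len(n_replicates)) {
    sp <- spec; sp$seed <- seed + r
    ds <- generate_dataset(sp, phys, drug)
    fit <- try({
      f <- fit_closed_loop(ds, phys, init = truth, drug = drug,
                           seed = seed + r, ...)
      compute_standard_errors(f)
    }, silent = TRUE)
    if (inherits(fit, "try-error")) {
      failures <- c(failures, sprintf("replicate %d: %s", r,
                                      conditionMessage(attr(fit, "condition"))))
      next
    }
    est <- fit$estimates[names(truth)]
    bias[r, ] <- (est - truth) / truth
    se_mat[r, ] <- fit$se[names(truth)]
    covered[r, ] <- abs(est - truth) <= 2 * fit$se[names(truth)]
  }
  ok <- stats::complete.cases(bias)
  summ <- data.frame(
    parameter = names(truth), truth = unname(truth),
    bias = colMeans(bias[ok, , drop = FALSE]),
    rmse = sqrt(colMeans(bias[ok, , drop = FALSE]^2)),
    coverage = colMeans(covered[ok, , drop = FALSE] == 1))
  structure(list(bias = bias, covered = covered, se = se_mat,
                 summary = summ,
                 n_failed = sum(!ok), failures = failures,
                 truth = truth, seed = seed),
            class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat(sprintf("<recovery_report> %d replicates (%d failed)\n",
              nrow(x$bias), x$n_failed))
  print(transform(x$summary, bias = signif(bias, 3), rmse = signif(rmse, 3)),
        row.names = FALSE)
  invisible(x)
}
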