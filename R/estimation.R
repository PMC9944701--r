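# Stage-two estimation: closed-loop simultaneous maximum-likelihood fit
# with per-tissue proportional error.

#' Names of the structural parameters estimated from data
#' @return Character vector (length 11), in reporting order.
#' @export
fitted_parameters <- function() {
  c("kp_lung", "kp_heart", "ps_heart", "kp_kidney", "ps_kidney",
    "kp_liver", "kp_thyroid", "kp_other", "cl_renal", "cl_liver", "k_gb")
}

apply_estimates <- function(drug, est) {
  for (nm in names(est)) {
    v <- unname(est[[nm]])
    switch(nm,
           kp_lung = , kp_heart = , kp_kidney = , kp_liver = ,
           kp_thyroid = , kp_other = {
             drug$kp[[sub("^kp_", "", nm)]] <- v
           },
           ps_heart = { drug$ps[["heart"]] <- v },
           ps_kidney = { drug$ps[["kidney"]] <- v },
           cl_renal = { drug$cl[["renal"]] <- v },
           cl_liver = { drug$cl[["liver"]] <- v },
           k_gb = { drug$k_gb <- v },
           stop("unknown parameter: ", nm))
  }
  drug
}

#' Model predictions at the observation design
#'
#' Simulates the closed-loop model and returns the predicted observable for
#' every row of the dataset (offset times).
#'
#' @param dataset A `pbpk_dataset`.
#' @param phys `pbpk_physiology`.
#' @param drug `drug_params`.
#' @param rtol,atol Solver tolerances.
#' @return Numeric vector aligned with `dataset` rows.
#' @export
predict_dataset <- function(dataset, phys, drug, rtol = 1e-8, atol = 1e-10) {
  tms <- sort(unique(dataset$time_min))
  sim <- simulate_closed_loop(phys, drug, dose = attr(dataset, "dose"),
                              t_grid = c(0, tms), rtol = rtol, atol = atol)
  obs <- observables(sim)
  ix_t <- match(dataset$time_min, tms) + 1L
  obs[cbind(ix_t, match(dataset$tissue, colnames(obs)))]
}

# concentrated -2LL over tissues (sigma_t profiled analytically);
# includes all constants so values are comparable across calls
neg2ll_concentrated <- function(y, f, tissue) {
  f <- pmax(f, 1e-12)
  total <- length(y) * log(2 * pi) + 2 * sum(log(f)) + length(y)
  for (tis in unique(tissue)) {
    ix <- tissue == tis
    s2 <- max(mean(((y[ix] - f[ix]) / f[ix])^2), 1e-10)
    total <- total + sum(ix) * log(s2)
  }
  total
}

# full -2LL at explicit sigma (used by tests as an algebraic cross-check)
neg2ll_full <- function(y, f, tissue, sigma) {
  f <- pmax(f, 1e-12)
  s <- sigma[tissue]
  sum(log(2 * pi * s^2 * f^2) + (y - f)^2 / (s^2 * f^2))
}

param_tissue_map <- function() {
  list(kp_lung = "lung", kp_heart = "heart", ps_heart = "heart",
       kp_kidney = "kidney", ps_kidney = "kidney",
       kp_liver = "liver", kp_thyroid = "thyroid",
       kp_other = "blood", cl_renal = c("kidney", "urine"),
       cl_liver = c("liver", "gi"), k_gb = "gi")
}

#' Closed-loop simultaneous maximum-likelihood fit
#'
#' Re-estimates the 11 structural parameters by fitting the whole-body
#' model to all tissues simultaneously under the proportional error model
#' `Y = F (1 + eps)`, `eps ~ N(0, sigma_t^2)` with a separate error SD per
#' tissue.  The per-tissue SDs are profiled out analytically, and the
#' concentrated -2 log-likelihood is minimized over the log-transformed
#' structural parameters with `nlminb`, optionally from several perturbed
#' starts.  Gallbladder observations, if present, are excluded from the
#' objective.  Parameters whose associated tissues are absent from the
#' dataset are flagged non-identifiable and held at their initial values.
#'
#' @param dataset A `pbpk_dataset` with at least two tissues (offset times
#'   applied).
#' @param phys `pbpk_physiology`.
#' @param init Named vector of initial values for (a subset of) the 11
#'   parameters, typically from [open_loop_estimates()]; missing entries
#'   are taken from `drug`.
#' @param drug Baseline `drug_params` supplying the fixed parameters
#'   (mechanistic Kp values, blood:plasma ratio).
#' @param n_starts Number of optimizer starts (the first is `init`, the
#'   rest are log-normally jittered around it).
#' @param seed Seed for the jittered starts.
#' @param rtol,atol Solver tolerances used inside the objective.
#' @param control `nlminb` control list.
#' @return A `pbpk_fit` object: `estimates`, per-tissue `sigma`,
#'   `neg2ll`, `r2`, `convergence`, `trace` (accepted objective values),
#'   `non_identifiable`, the updated `drug`, and the fit inputs.
#' @export
fit_closed_loop <- function(dataset, phys, init = NULL, drug = NULL,
                            n_starts = 1, seed = 1, rtol = 1e-8,
                            atol = 1e-10,
                            control = list(rel.tol = 1e-10, iter.max = 400,
                                           eval.max = 1200)) {
  stopifnot(inherits(dataset, "pbpk_dataset"))
  if (is.null(drug)) drug <- default_drug_params()
  ds <- dataset[dataset$tissue != "gallbladder", ]
  attributes(ds)[c("dose", "lag_min")] <-
    attributes(dataset)[c("dose", "lag_min")]
  class(ds) <- class(dataset)
  tissues <- unique(ds$tissue)
  if (length(tissues) < 2) stop("need observations from at least two tissues")

  theta0 <- stats::setNames(numeric(11), fitted_parameters())
  base <- c(kp_lung = drug$kp[["lung"]], kp_heart = drug$kp[["heart"]],
            ps_heart = drug$ps[["heart"]], kp_kidney = drug$kp[["kidney"]],
            ps_kidney = drug$ps[["kidney"]], kp_liver = drug$kp[["liver"]],
            kp_thyroid = drug$kp[["thyroid"]], kp_other = drug$kp[["other"]],
            cl_renal = drug$cl[["renal"]], cl_liver = drug$cl[["liver"]],
            k_gb = drug$k_gb)
  theta0[] <- base
  if (!is.null(init)) theta0[names(init)] <- init

  ident <- vapply(param_tissue_map()[fitted_parameters()],
                  function(ts) any(ts %in% tissues), logical(1))
  free <- names(theta0)[ident]
  if (!all(ident)) {
    warning("non-identifiable (tissue absent), held fixed: ",
            paste(names(theta0)[!ident], collapse = ", "))
  }

  predfun <- function(lp) {
    th <- theta0
    th[free] <- exp(lp)
    f <- try(predict_dataset(ds, phys, apply_estimates(drug, th),
                             rtol = rtol, atol = atol), silent = TRUE)
    if (inherits(f, "try-error") || any(!is.finite(f))) return(NULL)
    pmax(f, 1e-12)
  }
  trace_env <- new.env(); trace_env$best <- Inf; trace_env$trace <- numeric(0)
  objective <- function(lp) {
    f <- predfun(lp)
    if (is.null(f)) return(1e10)
    val <- neg2ll_concentrated(ds$pct_dose, f, ds$tissue)
    if (val < trace_env$best) {
      trace_env$best <- val
      trace_env$trace <- c(trace_env$trace, val)
    }
    val
  }
  # central-difference gradient with a step wide enough to stay clear of
  # solver noise in the objective
  gradient <- function(lp, h = 1e-4) {
    vapply(seq_along(lp), function(i) {
      up <- lp; up[i] <- up[i] + h
      dn <- lp; dn[i] <- dn[i] - h
      (objective(up) - objective(dn)) / (2 * h)
    }, numeric(1))
  }
  # stage A: iteratively reweighted Levenberg-Marquardt on the scaled
  # proportional residuals (Gauss-Newton handles the correlated Kp/PS
  # valleys); stage B: quasi-Newton polish of the concentrated -2LL
  lo <- log(theta0[free]) - log(1e4)
  hi <- log(theta0[free]) + log(1e4)
  run_one <- function(start) {
    cur <- pmin(pmax(start, lo), hi)
    w <- rep(1, nrow(ds))
    best_lp <- cur; best_val <- objective(cur)
    for (sweep in 1:3) {
      res_fn <- function(lp) {
        f <- predfun(lp)
        if (is.null(f)) return(rep(1e6, nrow(ds)))
        (ds$pct_dose - f) / f * w
      }
      lmfit <- try(minpack.lm::nls.lm(
        cur, fn = res_fn, lower = lo, upper = hi,
        control = minpack.lm::nls.lm.control(
          maxiter = 300, maxfev = 20000, ftol = 1e-14, ptol = 1e-13,
          gtol = 1e-14, epsfcn = 1e-8)), silent = TRUE)
      if (inherits(lmfit, "try-error")) break
      cur <- lmfit$par
      val <- objective(cur)
      if (val < best_val) { best_val <- val; best_lp <- cur }
      f <- predfun(cur)
      if (is.null(f)) break
      s_t <- sqrt(tapply(((ds$pct_dose - f) / f)^2, ds$tissue, mean))
      if (all(s_t < 1e-4)) break  # essentially interpolating: done
      w <- 1 / pmax(s_t[as.character(ds$tissue)], 1e-3)
    }
    op <- stats::nlminb(best_lp, objective, gradient = gradient,
                        lower = lo, upper = hi, control = control)
    if (op$objective < best_val) {
      best_val <- op$objective; best_lp <- op$par
    }
    list(par = best_lp, objective = best_val,
         convergence = op$convergence, message = op$message)
  }

  set.seed(seed)
  starts <- matrix(rep(log(theta0[free]), n_starts), nrow = n_starts,
                   byrow = TRUE)
  if (n_starts > 1) {
    starts[-1, ] <- starts[-1, ] +
      matrix(stats::rnorm((n_starts - 1) * length(free), 0, 0.3),
             nrow = n_starts - 1)
  }
  best <- NULL
  for (s in seq_len(n_starts)) {
    op <- run_one(starts[s, ])
    if (is.null(best) || op$objective < best$objective) best <- op
  }
  if (!is.finite(best$objective) || best$objective >= 1e10) {
    stop("closed-loop fit did not converge; trace: ",
         paste(signif(trace_env$trace, 6), collapse = " "))
  }

  est <- theta0
  est[free] <- exp(best$par)
  drug_hat <- apply_estimates(drug, est)
  f_hat <- predict_dataset(ds, phys, drug_hat, rtol = rtol, atol = atol)
  sigma <- vapply(split(seq_len(nrow(ds)), ds$tissue), function(ix) {
    sqrt(max(mean(((ds$pct_dose[ix] - f_hat[ix]) / f_hat[ix])^2), 1e-10))
  }, numeric(1))

  structure(list(estimates = est, free = free, sigma = sigma,
                 neg2ll = best$objective,
                 r2 = compute_r2(ds$pct_dose, f_hat),
                 convergence = best$convergence,
                 message = best$message,
                 trace = trace_env$trace,
                 non_identifiable = names(theta0)[!ident],
                 drug = drug_hat, phys = phys, dataset = ds,
                 init = theta0, rtol = rtol, atol = atol),
            class = "pbpk_fit")
}

#' @export
print.pbpk_fit <- function(x, ...) {
  cat("<pbpk_fit> closed-loop maximum-likelihood fit\n")
  tab <- data.frame(estimate = signif(x$estimates, 4))
  if (!is.null(x$se)) {
    tab$se <- signif(x$se, 3)
    tab$rse_pct <- signif(x$rse_pct, 3)
  }
  print(tab)
  cat(sprintf("-2LL = %.3f, R2 = %.4f, sigma: %s\n", x$neg2ll, x$r2,
              paste(sprintf("%s=%.3g", names(x$sigma), x$sigma),
                    collapse = " ")))
  invisible(x)
}

#' Standard errors of the closed-loop estimates
#'
#' Differentiates the concentrated -2 log-likelihood numerically at the
#' optimum (over the log-transformed free parameters).  With
#' `type = "hessian"` (default) the covariance is `2 H^-1`; with
#' `type = "sandwich"` it is `H^-1 (sum_i g_i g_i') H^-1` with
#' per-observation score vectors `g_i` evaluated at the profiled error
#' SDs.  Standard errors are reported on the natural scale by the
#' delta method together with relative standard errors
#' (%RSE = 100 SE / estimate).
#'
#' @param fit A `pbpk_fit`.
#' @param type `"sandwich"` or `"hessian"`.
#' @return The fit, augmented with `se`, `rse_pct`, `cov_log`, `se_type`
#'   and `hessian_pd` (FALSE when the Hessian was not positive definite,
#'   in which case a pseudo-inverse is used and a warning is raised).
#' @export
compute_standard_errors <- function(fit, type = c("hessian", "sandwich")) {
  type <- match.arg(type)
  stopifnot(inherits(fit, "pbpk_fit"))
  ds <- fit$dataset; phys <- fit$phys
  theta <- fit$estimates; free <- fit$free
  predfun <- function(lp) {
    th <- theta
    th[free] <- exp(lp)
    pmax(predict_dataset(ds, phys, apply_estimates(fit$drug, th),
                         rtol = fit$rtol, atol = fit$atol), 1e-12)
  }
  objective <- function(lp) {
    neg2ll_concentrated(ds$pct_dose, predfun(lp), ds$tissue)
  }
  lp_hat <- log(theta[free])
  H <- pracma::hessian(objective, lp_hat)
  ev <- eigen(H, symmetric = TRUE)
  pd <- all(ev$values > 0)
  if (!pd) {
    warning("Hessian not positive definite; pseudo-inverse used")
    inv_v <- ifelse(abs(ev$values) > 1e-10 * max(abs(ev$values)),
                    1 / ev$values, 0)
  } else inv_v <- 1 / ev$values
  Hinv <- ev$vectors %*% diag(inv_v, length(inv_v)) %*% t(ev$vectors)
  if (type == "hessian") {
    cov_log <- 2 * Hinv
  } else {
    # per-observation scores of the -2LL pieces at the profiled sigmas,
    # via central differences of the predictions
    y <- ds$pct_dose
    f0 <- predfun(lp_hat)
    s <- fit$sigma[as.character(ds$tissue)]
    dfdlp <- vapply(seq_along(lp_hat), function(j) {
      up <- lp_hat; up[j] <- up[j] + 1e-4
      dn <- lp_hat; dn[j] <- dn[j] - 1e-4
      (predfun(up) - predfun(dn)) / 2e-4
    }, numeric(length(y)))
    dl_df <- 2 / f0 - 2 * (y - f0) / (s^2 * f0^2) -
      2 * (y - f0)^2 / (s^2 * f0^3)
    G <- dfdlp * dl_df                      # n x p score matrix
    B <- crossprod(G)
    cov_log <- Hinv %*% B %*% Hinv
  }
  se_log <- sqrt(pmax(diag(cov_log), 0))
  se <- stats::setNames(rep(NA_real_, length(theta)), names(theta))
  se[free] <- theta[free] * se_log   # delta method to natural scale
  fit$se <- se
  fit$rse_pct <- 100 * se / theta
  fit$cov_log <- cov_log
  fit$se_type <- type
  fit$hessian_pd <- pd
  fit
}

#' Pooled coefficient of determination
#'
#' `R^2 = 1 - SS_res / SS_tot` over observation-prediction pairs pooled
#' across tissues.
#'
#' @param observed,predicted Numeric vectors of equal length.
#' @return R-squared.
#' @export
compute_r2 <- function(observed, predicted) {
  stopifnot(length(observed) == length(predicted))
  sst <- sum((observed - mean(observed))^2)
  if (sst == 0) stop("R2 undefined: observed vector is constant")
  1 - sum((observed - predicted)^2) / sst
}

#' Write a fit report to JSON
#'
#' Estimates, standard errors, per-tissue error SDs, -2LL, R2 and the
#' configuration snapshot.
#'
#' @param fit A `pbpk_fit` (ideally after [compute_standard_errors()]).
#' @param file Output JSON path.
#' @return Invisibly, `file`.
#' @export
write_fit_report <- function(fit, file) {
  rep <- list(estimates = as.list(fit$estimates),
              se = if (!is.null(fit$se)) as.list(fit$se),
              rse_pct = if (!is.null(fit$rse_pct)) as.list(fit$rse_pct),
              sigma = as.list(fit$sigma),
              neg2ll = fit$neg2ll, r2 = fit$r2,
              convergence = fit$convergence,
              non_identifiable = fit$non_identifiable,
              config = list(dose = attr(fit$dataset, "dose"),
                            lag_min = attr(fit$dataset, "lag_min"),
                            rtol = fit$rtol, atol = fit$atol,
                            age_label = fit$phys$age_label))
  jsonlite::write_json(rep, file, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(file)
}
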