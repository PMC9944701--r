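# Stage-one estimation: empirical blood forcing function and open-loop
# per-organ fits driven by it.

#' Fit a biexponential forcing function to venous blood data
#'
#' Fits `C_ven(t) = c1 exp(-k1 t) + c2 exp(-k2 t)` (concentration in
#' percent of dose per litre) to the venous blood series by least squares
#' on a multistart curve-peeling initialization.  Rates are per minute.
#'
#' @param time Times (min).
#' @param conc Venous concentrations (% dose / L); for a blood amount
#'   series divide by the venous volume first.
#' @return A `forcing_function`: list with `coef` (c1, c2), `rate` (k1,
#'   k2, 1/min) and `time_unit`.
#' @export
fit_biexponential <- function(time, conc) {
  stopifnot(length(time) == length(conc), length(time) >= 5,
            all(conc > 0))
  df <- data.frame(t = time, y = conc)
  # curve peeling: terminal slope from the tail, fast phase from residual
  tail_ix <- time >= stats::median(time)
  sl <- stats::lm(log(y) ~ t, df[tail_ix, ])
  k1 <- max(-unname(stats::coef(sl)[2]), 1e-6)
  c1 <- unname(exp(stats::coef(sl)[1]))
  resid <- df$y - c1 * exp(-k1 * df$t)
  head_ix <- which(resid > 0 & !tail_ix)
  if (length(head_ix) >= 2) {
    s2 <- stats::lm(log(resid[head_ix]) ~ df$t[head_ix])
    k2 <- max(-unname(stats::coef(s2)[2]), 2 * k1)
    c2 <- unname(exp(stats::coef(s2)[1]))
  } else {
    k2 <- 10 * k1
    c2 <- max(df$y[1] - c1, 0.01 * c1)
  }
  fit <- try(minpack.lm::nlsLM(
    y ~ c1 * exp(-k1 * t) + c2 * exp(-k2 * t),
    data = df,
    start = list(c1 = c1, k1 = k1, c2 = max(c2, 1e-8), k2 = k2),
    lower = c(0, 1e-9, 0, 1e-9),
    control = minpack.lm::nls.lm.control(maxiter = 500)), silent = TRUE)
  if (inherits(fit, "try-error")) {
    # fall back to a single exponential (nested limit c2 -> 0)
    fit <- try(minpack.lm::nlsLM(y ~ c1 * exp(-k1 * t), data = df,
                                 start = list(c1 = c1, k1 = k1),
                                 lower = c(0, 1e-9)), silent = TRUE)
    if (inherits(fit, "try-error")) {
      stop("biexponential fit did not converge; best peeling start: c1=",
           signif(c1, 4), " k1=", signif(k1, 4), " c2=", signif(c2, 4),
           " k2=", signif(k2, 4))
    }
    cf <- c(stats::coef(fit), c2 = 0, k2 = 10 * stats::coef(fit)[["k1"]])
  } else cf <- stats::coef(fit)
  ord <- order(cf[c("k1", "k2")])  # slow phase first
  co <- cf[c("c1", "c2")][ord]
  ra <- cf[c("k1", "k2")][ord]
  structure(list(coef = unname(co), rate = unname(ra), time_unit = "min"),
            class = "forcing_function")
}

#' Evaluate a forcing function
#' @param ff A `forcing_function` (or any exponential mixture with `coef`
#'   and `rate`).
#' @param t Times (min).
#' @return Concentrations.
#' @export
eval_forcing <- function(ff, t) {
  drop(exp(-outer(t, ff$rate)) %*% ff$coef)
}

#' @export
print.forcing_function <- function(x, ...) {
  cat(sprintf("<forcing_function> C(t) = %.4g e^(-%.4g t) + %.4g e^(-%.4g t)  [1/%s]\n",
              x$coef[1], x$rate[1], x$coef[2], x$rate[2], x$time_unit))
  invisible(x)
}

# --- analytic exponential-mixture algebra -------------------------------
# A mixture is list(coef, rate) meaning sum_i coef_i exp(-rate_i t).
# Passing a mixture input u(t) through dX/dt = u(t) - a X (X(0)=0) yields
# another mixture; rates equal to a are nudged to keep the closed form.
mix_through <- function(mix, a) {
  r <- mix$rate
  r[abs(r - a) < 1e-10 * max(a, 1)] <- a * (1 + 1e-7)
  co <- mix$coef / (a - r)
  list(coef = c(co, -sum(co)), rate = c(r, a))
}

mix_scale <- function(mix, s) list(coef = mix$coef * s, rate = mix$rate)

# Arterial concentration mixture implied by a venous forcing function:
# venous -> lung (perfusion limited) -> arterial blood.
arterial_mixture <- function(forcing, phys, kp_lung) {
  Q <- phys$Q[["lung"]]
  a_lung <- Q / (kp_lung * phys$V[["lung"]])
  a_art <- Q / phys$V[["arterial_blood"]]
  lung_amt <- mix_through(mix_scale(forcing, Q), a_lung)   # A_lung(t)
  art_amt <- mix_through(mix_scale(lung_amt, a_lung), a_art)
  mix_scale(art_amt, 1 / phys$V[["arterial_blood"]])       # C_art(t)
}

# proportional-error objective (concentrated -2 log-likelihood, up to an
# additive constant) for a single error stratum
prop_obj <- function(y, f) {
  f <- pmax(f, 1e-12)
  n <- length(y)
  s2 <- max(mean(((y - f) / f)^2), 1e-10)
  n * log(s2) + 2 * sum(log(f))
}

#' Fit one organ in open-loop mode
#'
#' Fits the kinetic sub-model of a single tissue driven by the empirical
#' blood forcing function: the arterial input is derived by passing the
#' forcing through the lung equation, and the tissue parameters are
#' estimated by maximum likelihood under proportional error.  The lung is
#' fitted directly against the venous forcing.  Variants: perfusion-limited
#' (one compartment, estimates Kp) or permeability-limited (vascular +
#' extravascular, estimates Kp and PS).  The liver sub-model additionally
#' estimates the hepatic clearance and gallbladder emptying constant from
#' the liver and GI series; the kidney sub-model estimates the renal
#' clearance from the kidney and urine series.
#'
#' @param tissue One of `lung, heart, kidney, liver, thyroid, gi`, or a
#'   perfusion-limited single-tissue name.
#' @param dataset A `pbpk_dataset` (offset times applied).
#' @param forcing A `forcing_function` for venous blood concentration.
#' @param phys `pbpk_physiology`.
#' @param drug `drug_params` providing fixed parameters (notably the
#'   mechanistically predicted Kp values and, for non-lung organs, the lung
#'   Kp used to derive the arterial input).
#' @param variant `"perfusion"` or `"permeability"` where both are
#'   meaningful (heart, kidney).
#' @return List with `estimates` (named, natural scale), `objective`,
#'   `diagnostics` (convergence code, flat-objective warning).
#' @export
fit_open_loop <- function(tissue, dataset, forcing, phys, drug,
                          variant = c("permeability", "perfusion")) {
  variant <- match.arg(variant)
  stopifnot(inherits(dataset, "pbpk_dataset"))
  get_obs <- function(tis) {
    d <- dataset[dataset$tissue == tis, ]
    if (!nrow(d)) stop("no observations for tissue: ", tis)
    d
  }
  Q <- phys$Q; V <- phys$V; R <- drug$blood_plasma_ratio

  if (tissue == "lung") {
    d <- get_obs("lung")
    obj <- function(lp) {
      kp <- exp(lp)
      a <- Q[["lung"]] / (kp * V[["lung"]])
      lung <- mix_through(mix_scale(forcing, Q[["lung"]]), a)
      prop_obj(d$pct_dose, eval_forcing(lung, d$time_min))
    }
    op <- stats::optim(log(drug$kp[["lung"]]), obj, method = "Brent",
                       lower = log(1e-3), upper = log(1e3))
    return(ol_result(c(kp_lung = exp(op$par)), op, flat = FALSE))
  }

  cart <- arterial_mixture(forcing, phys, drug$kp[["lung"]])

  if (tissue %in% c("thyroid", "muscle", "adipose", "spleen", "pancreas") ||
      (tissue == "heart" && variant == "perfusion")) {
    d <- get_obs(tissue)
    Qt <- Q[[if (tissue == "heart") "heart" else tissue]]
    Vt <- V[[if (tissue == "heart") "heart_extravascular" else tissue]]
    obj <- function(lp) {
      kp <- exp(lp)
      amt <- mix_through(mix_scale(cart, Qt), Qt * R / (kp * Vt))
      prop_obj(d$pct_dose, eval_forcing(amt, d$time_min))
    }
    op <- stats::optim(log(drug$kp[[tissue]]), obj, method = "Brent",
                       lower = log(1e-3), upper = log(1e4))
    est <- stats::setNames(exp(op$par), paste0("kp_", tissue))
    return(ol_result(est, op, flat = FALSE))
  }

  # remaining sub-models are driven numerically by the arterial mixture
  cart_fun <- function(t) eval_forcing(cart, t)
  cven_fun <- function(t) eval_forcing(forcing, t)

  if (tissue == "heart") {
    d <- get_obs("heart")
    vch <- V[["heart_chambers"]]
    model <- function(kp, ps) {
      rhs <- function(t, y, p) {
        flux <- ps * (R * y[2] / (kp * V[["heart_extravascular"]]) -
                        y[1] / V[["heart_vascular"]])
        list(c(Q[["heart"]] * (cart_fun(t) - y[1] / V[["heart_vascular"]]) +
                 flux, -flux))
      }
      out <- deSolve::lsoda(c(0, 0), c(0, d$time_min), rhs, NULL,
                            rtol = 1e-8, atol = 1e-10)
      rowSums(out[-1, 2:3, drop = FALSE]) +
        vch * (cven_fun(d$time_min) + cart_fun(d$time_min))
    }
    obj <- function(lp) prop_obj(d$pct_dose, model(exp(lp[1]), exp(lp[2])))
    start <- log(c(drug$kp[["heart"]], drug$ps[["heart"]]))
    op <- stats::optim(start, obj, method = "L-BFGS-B",
                       lower = start - log(100), upper = start + log(100),
                       control = list(maxit = 200, factr = 1e4))
    est <- c(kp_heart = exp(op$par[1]), ps_heart = exp(op$par[2]))
    return(ol_result(est, op, flat = is_flat(obj, op$par)))
  }

  if (tissue == "kidney") {
    d_k <- get_obs("kidney"); d_u <- get_obs("urine")
    tms <- sort(unique(c(d_k$time_min, d_u$time_min)))
    model <- function(kp, ps, cl) {
      rhs <- function(t, y, p) {
        ckv <- y[1] / V[["kidney_vascular"]]
        flux <- ps * (R * y[2] / (kp * V[["kidney_extravascular"]]) - ckv)
        list(c(Q[["kidney"]] * (cart_fun(t) - ckv) - cl * ckv + flux,
               -flux, cl * ckv))
      }
      out <- deSolve::lsoda(c(0, 0, 0), c(0, tms), rhs, NULL,
                            rtol = 1e-8, atol = 1e-10)
      out <- out[-1, , drop = FALSE]
      list(kidney = (out[, 2] + out[, 3])[match(d_k$time_min, tms)],
           urine = out[, 4][match(d_u$time_min, tms)])
    }
    obj <- function(lp) {
      f <- model(exp(lp[1]), exp(lp[2]), exp(lp[3]))
      prop_obj(d_k$pct_dose, f$kidney) + prop_obj(d_u$pct_dose, f$urine)
    }
    start <- log(c(drug$kp[["kidney"]], drug$ps[["kidney"]],
                   drug$cl[["renal"]]))
    op <- stats::optim(start, obj, method = "L-BFGS-B",
                       lower = start - log(100), upper = start + log(100),
                       control = list(maxit = 200, factr = 1e4))
    est <- c(kp_kidney = exp(op$par[1]), ps_kidney = exp(op$par[2]),
             cl_renal = exp(op$par[3]))
    return(ol_result(est, op, flat = is_flat(obj, op$par)))
  }

  if (tissue %in% c("liver", "gi")) {
    d_l <- get_obs("liver"); d_g <- get_obs("gi")
    tms <- sort(unique(c(d_l$time_min, d_g$time_min)))
    kp_gi <- drug$kp[["gi"]]; kp_sp <- drug$kp[["spleen"]]
    kp_pa <- drug$kp[["pancreas"]]
    model <- function(kp_l, cl_l, k_gb) {
      rhs <- function(t, y, p) {
        ca <- cart_fun(t)
        out_l <- R * y[1] / (kp_l * V[["liver"]])
        out_g <- R * y[3] / (kp_gi * V[["gi_tissue"]])
        out_s <- R * y[5] / (kp_sp * V[["spleen"]])
        out_p <- R * y[6] / (kp_pa * V[["pancreas"]])
        bile <- cl_l * y[1] / V[["liver"]]
        gb <- k_gb * y[2] / V[["gallbladder"]]
        list(c(-Q[["liver"]] * out_l + Q[["hepatic_artery"]] * ca - bile +
                 Q[["gi"]] * out_g + Q[["pancreas"]] * out_p +
                 Q[["spleen"]] * out_s,
               bile - gb,
               Q[["gi"]] * (ca - out_g),
               gb,
               Q[["spleen"]] * (ca - out_s),
               Q[["pancreas"]] * (ca - out_p)))
      }
      out <- deSolve::lsoda(numeric(6), c(0, tms), rhs, NULL,
                            rtol = 1e-8, atol = 1e-10)
      out <- out[-1, , drop = FALSE]
      list(liver = out[, 2][match(d_l$time_min, tms)],
           gi = (out[, 4] + out[, 5])[match(d_g$time_min, tms)])
    }
    obj <- function(lp) {
      f <- model(exp(lp[1]), exp(lp[2]), exp(lp[3]))
      prop_obj(d_l$pct_dose, f$liver) + prop_obj(d_g$pct_dose, f$gi)
    }
    start <- log(c(drug$kp[["liver"]], drug$cl[["liver"]], drug$k_gb))
    op <- stats::optim(start, obj, method = "L-BFGS-B",
                       lower = start - log(100), upper = start + log(100),
                       control = list(maxit = 200, factr = 1e4))
    est <- c(kp_liver = exp(op$par[1]), cl_liver = exp(op$par[2]),
             k_gb = exp(op$par[3]))
    return(ol_result(est, op, flat = is_flat(obj, op$par)))
  }

  stop("no open-loop sub-model for tissue: ", tissue)
}

ol_result <- function(est, op, flat) {
  if (flat) warning("flat objective: estimates may be non-identifiable")
  list(estimates = est, objective = op$value,
       diagnostics = list(convergence = op$convergence,
                          flat_objective = flat))
}

# crude flatness probe: relative objective change under 1% parameter moves
is_flat <- function(obj, par) {
  f0 <- obj(par)
  dmax <- max(vapply(seq_along(par), function(i) {
    pp <- par; pp[i] <- pp[i] + 0.01
    abs(obj(pp) - f0)
  }, numeric(1)))
  dmax < 1e-8 * max(1, abs(f0))
}

#' Stage-one estimates for all fitted parameters
#'
#' Runs the open-loop fits in the order of the modelling workflow (lung
#' first, then heart, kidney, liver/GI and thyroid with the arterial input
#' derived from the fitted lung) and assembles initial values for the
#' closed-loop fit.  `kp_other` has no open-loop sub-model (the remainder
#' compartment is unobserved) and is carried over from `drug`.
#'
#' @inheritParams fit_open_loop
#' @return Named vector of the 11 structural parameters.
#' @export
open_loop_estimates <- function(dataset, forcing, phys, drug) {
  est <- c()
  lung <- fit_open_loop("lung", dataset, forcing, phys, drug)
  drug$kp[["lung"]] <- lung$estimates[["kp_lung"]]
  est <- c(est, lung$estimates)
  for (tis in c("heart", "kidney", "liver", "thyroid")) {
    r <- fit_open_loop(tis, dataset, forcing, phys, drug,
                       variant = if (tis %in% c("heart", "kidney"))
                         "permeability" else "perfusion")
    est <- c(est, r$estimates)
  }
  est <- c(est, kp_other = unname(drug$kp[["other"]]))
  est[fitted_parameters()]
}
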