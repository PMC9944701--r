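# MIRD dosimetry chain: activity simulation with voiding, residence
# times, absorbed doses, effective dose and maximum administered activity.

#' Default emptying schedule
#'
#' Urinary bladder voids every 3 h; the GI contents empty every 24 h.
#' Periods are in minutes; a period of `Inf` disables the event.
#'
#' @return Named list with `bladder` and `gi_contents` periods (min).
#' @export
default_emptying_schedule <- function() {
  list(bladder = 180, gi_contents = 1440)
}

#' Simulate the Tc99m activity profile
#'
#' Integrates the PBPK system in the activity domain: every compartment
#' additionally decays with the Tc99m decay constant, and the urinary
#' bladder content and GI contents are instantaneously reset to zero at
#' their emptying times.  Between resets the total activity equals the
#' total amount times `exp(-lambda t)`.
#'
#' @param phys `pbpk_physiology`.
#' @param drug `drug_params`.
#' @param dose Administered activity (1 = per unit administered).
#' @param lambda Decay constant (1/min); default `ln 2 / 361.2` (half-life
#'   6.02 h).
#' @param schedule Emptying schedule, see [default_emptying_schedule()].
#' @param horizon Simulation horizon (min); default 3600 (60 h, ~10
#'   half-lives).
#' @param dt Output resolution (min).
#' @param rtol,atol Solver tolerances.
#' @return A `pbpk_sim` with `lambda > 0`; attribute `events` holds the
#'   reset table.
#' @export
simulate_activity <- function(phys, drug, dose = 1,
                              lambda = TC99M_LAMBDA,
                              schedule = default_emptying_schedule(),
                              horizon = 3600, dt = 1,
                              rtol = 1e-8, atol = 1e-12) {
  stopifnot(lambda >= 0, horizon > 0)
  ev <- NULL
  ev_rows <- list()
  mk <- function(var, period) {
    if (is.finite(period) && period < horizon) {
      data.frame(var = var, time = seq(period, horizon - 1e-9, by = period),
                 value = 0, method = "rep")
    }
  }
  ev_rows$bladder <- mk("bladder", schedule$bladder)
  ev_rows$gi <- mk("gi_contents", schedule$gi_contents)
  ev_tab <- do.call(rbind, ev_rows)
  if (!is.null(ev_tab)) ev_tab <- ev_tab[order(ev_tab$time), ]
  t_grid <- seq(0, horizon, by = dt)
  if (!is.null(ev_tab) && nrow(ev_tab)) {
    # sample just before and after each reset so the sawtooth is
    # integrated fairly (the solver reports the pre-event state at the
    # event time itself)
    t_grid <- sort(unique(c(t_grid, ev_tab$time - 1e-3, ev_tab$time,
                            ev_tab$time + 1e-3)))
    t_grid <- t_grid[t_grid <= horizon]
    ev <- list(data = ev_tab)
  }
  sim <- simulate_closed_loop(phys, drug, dose = dose, t_grid = t_grid,
                              rtol = rtol, atol = atol, lambda = lambda,
                              events = ev)
  attr(sim, "events") <- ev_tab
  attr(sim, "schedule") <- schedule
  sim
}

#' Residence times (cumulated activity per unit administered)
#'
#' Integrates each source compartment's activity over time: trapezoidal
#' quadrature on the simulation grid plus an analytic exponential tail
#' (`a(T)/lambda`) beyond the horizon.  Returns hours.
#'
#' @param activity A `pbpk_sim` from [simulate_activity()].
#' @param tail_warn Warn when the tail estimate exceeds this fraction of
#'   the integral (default 0.1%).
#' @return Named vector of residence times (h) per model state, with
#'   attribute `tail_fraction`.
#' @export
residence_times <- function(activity, tail_warn = 1e-3) {
  stopifnot(inherits(activity, "pbpk_sim"))
  if (activity$lambda <= 0) stop("activity simulation must have lambda > 0")
  tt <- activity$time
  st <- activity$state
  dt <- diff(tt)
  trap <- 0.5 * crossprod(dt, st[-1, , drop = FALSE] +
                            st[-nrow(st), , drop = FALSE])
  n_min <- drop(trap)
  tail <- st[nrow(st), ] / activity$lambda
  # the urine state is cumulative bookkeeping, not a physical region
  tail[["urine"]] <- 0
  n_min <- n_min + tail
  tot <- sum(n_min[setdiff(model_states(), "urine")])
  if (tot > (1 + 1e-6) * activity$dose / activity$lambda) {
    stop("total residence time exceeds the total-decay bound")
  }
  tf <- sum(tail[setdiff(model_states(), "urine")]) / max(tot, 1e-300)
  if (tf > tail_warn) {
    warning(sprintf("tail estimate is %.2g of the integral; extend horizon",
                    tf))
  }
  structure(n_min / 60, tail_fraction = tf)
}

#' Load the bundled compartment-to-source mapping
#' @param file Optional JSON mapping (source region -> model compartments);
#'   defaults to the bundled mapping.
#' @return Named list.
#' @export
default_source_mapping <- function(file = NULL) {
  if (is.null(file)) file <- tetrodose_file("source_mapping.json")
  jsonlite::read_json(file, simplifyVector = TRUE)
}

#' Aggregate residence times into S-value source regions
#'
#' Every model compartment must be mapped to exactly one source region (or
#' listed under `excluded`, used for the cumulative-urine bookkeeping
#' state).  Sums are preserved over the mapped compartments.
#'
#' @param n_states Named residence times per model state (h), from
#'   [residence_times()].
#' @param mapping Named list source-region -> character vector of model
#'   compartments; see [default_source_mapping()].
#' @return Named vector of residence times per source region (h).
#' @export
map_sources <- function(n_states, mapping = default_source_mapping()) {
  all_mapped <- unlist(mapping, use.names = FALSE)
  if (any(duplicated(all_mapped))) {
    stop("compartment mapped twice: ",
         paste(unique(all_mapped[duplicated(all_mapped)]), collapse = ", "))
  }
  miss <- setdiff(names(n_states), all_mapped)
  if (length(miss)) {
    stop("unmapped compartment(s): ", paste(miss, collapse = ", "))
  }
  regions <- setdiff(names(mapping), "excluded")
  out <- vapply(regions, function(r) {
    sum(n_states[intersect(mapping[[r]], names(n_states))])
  }, numeric(1))
  out
}

#' Absorbed doses per administered activity
#'
#' `H_T = sum_S N_S S(T <- S)`, in mGy/MBq.
#'
#' @param n_sources Named residence times per source region (h).
#' @param sv An `svalue_matrix`.
#' @return Named vector of absorbed doses per target (mGy/MBq).
#' @export
absorbed_doses <- function(n_sources, sv) {
  stopifnot(inherits(sv, "svalue_matrix"))
  miss <- setdiff(names(n_sources), sv$sources)
  if (length(miss)) {
    stop("source region(s) not in S-value matrix: ",
         paste(miss, collapse = ", "))
  }
  drop(sv$S[, names(n_sources), drop = FALSE] %*% n_sources)
}

#' Effective dose
#'
#' ICRP-103 weighted sum of target absorbed doses, `E = sum_T W_T H_T`,
#' in mSv/MBq (1 mGy taken as 1 mSv for the low-LET Tc99m emissions).
#' The `remainder` weight is applied to the mean absorbed dose of the
#' targets not named explicitly in the weight table.
#'
#' @param h_targets Named absorbed doses (mGy/MBq).
#' @param weights A `tissue_weights` vector (with a `remainder` entry).
#' @return Effective dose (mSv/MBq).
#' @export
effective_dose <- function(h_targets, weights = read_tissue_weights()) {
  named <- setdiff(names(weights), "remainder")
  miss <- setdiff(named, names(h_targets))
  if (length(miss)) {
    stop("weighted target(s) missing from absorbed doses: ",
         paste(miss, collapse = ", "))
  }
  e <- sum(weights[named] * h_targets[named])
  if ("remainder" %in% names(weights)) {
    rem <- setdiff(names(h_targets), named)
    if (!length(rem)) stop("no remainder targets available")
    e <- e + weights[["remainder"]] * mean(h_targets[rem])
  }
  unname(e)
}

#' Maximum administered activity for a child
#'
#' The activity whose effective dose equals the effective dose of the
#' adult activity limit: `adult_limit * E_adult / E_child`.
#'
#' @param e_child,e_adult Effective doses (mSv/MBq).
#' @param adult_limit Adult activity limit (MBq), default 1200.
#' @return Activity (MBq).
#' @export
max_activity <- function(e_child, e_adult, adult_limit = 1200) {
  if (e_child <= 0) stop("child effective dose must be positive")
  if (e_adult <= 0) stop("adult effective dose must be positive")
  adult_limit * e_adult / e_child
}

#' Interpolate a maximum activity between age anchors
#'
#' Piecewise-linear interpolation in age between the anchored maximum
#' activities; extrapolation outside the anchor range is an error.
#'
#' @param age_years Age to interpolate at.
#' @param anchors data.frame with `age_years` and `max_activity_mbq`.
#' @return Activity (MBq).
#' @export
interpolate_max_activity <- function(age_years, anchors) {
  stopifnot(all(c("age_years", "max_activity_mbq") %in% names(anchors)))
  anchors <- anchors[order(anchors$age_years), ]
  if (age_years < min(anchors$age_years) ||
      age_years > max(anchors$age_years)) {
    stop(sprintf("age %.3g outside anchor range [%g, %g]", age_years,
                 min(anchors$age_years), max(anchors$age_years)))
  }
  stats::approx(anchors$age_years, anchors$max_activity_mbq,
                xout = age_years)$y
}

#' Run the dosimetry chain for one age
#'
#' Activity simulation with voiding, residence times, source aggregation,
#' absorbed doses and effective dose.
#'
#' @param phys `pbpk_physiology`.
#' @param drug `drug_params` for that age (scaled for children).
#' @param sv `svalue_matrix` for that age; defaults to the bundled
#'   synthetic table.
#' @param weights Tissue weighting factors.
#' @param mapping Compartment-to-source mapping.
#' @param lambda,schedule,horizon Passed to [simulate_activity()].
#' @return A `dose_report`: list with `age_label`, `residence_h` (per
#'   source), `absorbed_mgy_per_mbq` (per target), `effective_msv_per_mbq`.
#' @export
run_dosimetry <- function(phys, drug, sv = NULL,
                          weights = read_tissue_weights(),
                          mapping = default_source_mapping(),
                          lambda = TC99M_LAMBDA,
                          schedule = default_emptying_schedule(),
                          horizon = 3600) {
  if (is.null(sv)) sv <- bundled_svalues(phys$age_label)
  act <- simulate_activity(phys, drug, dose = 1, lambda = lambda,
                           schedule = schedule, horizon = horizon)
  n_states <- residence_times(act)
  n_src <- map_sources(n_states, mapping)
  h <- absorbed_doses(n_src, sv)
  e <- effective_dose(h, weights)
  structure(list(age_label = phys$age_label, residence_h = n_src,
                 absorbed_mgy_per_mbq = h, effective_msv_per_mbq = e,
                 lambda = lambda, schedule = schedule,
                 tail_fraction = attr(n_states, "tail_fraction")),
            class = "dose_report")
}

#' @export
print.dose_report <- function(x, ...) {
  cat(sprintf("<dose_report> %s: E = %.4g mSv/MBq\n", x$age_label,
              x$effective_msv_per_mbq))
  cat("  top absorbed doses (mGy/MBq):\n")
  h <- sort(x$absorbed_mgy_per_mbq, decreasing = TRUE)
  for (i in seq_len(min(5, length(h)))) {
    cat(sprintf("    %-22s %.4g\n", names(h)[i], h[i]))
  }
  invisible(x)
}

#' Paediatric dosimetry study across ages
#'
#' Scales the adult drug parameters to each paediatric physiology, runs
#' the dosimetry chain per age and derives maximum administered
#' activities from the adult activity limit.
#'
#' @param adult_drug Adult `drug_params`.
#' @param ages Ages to include (adult always included as reference).
#' @param adult_limit Adult activity limit (MBq).
#' @param sv_tables Optional named list of `svalue_matrix` per age;
#'   defaults to the bundled synthetic tables.
#' @param ... Passed to [run_dosimetry()].
#' @return data.frame with one row per age: effective dose, ratio to
#'   adult, maximum activity and activity per body weight.
#' @export
dosimetry_study <- function(adult_drug = default_drug_params(),
                            ages = supported_ages(), adult_limit = 1200,
                            sv_tables = NULL, ...) {
  ages <- union("adult", ages)
  phys_adult <- load_physiology("adult")
  reports <- list()
  bw <- numeric(0)
  for (a in ages) {
    phys <- load_physiology(a)
    drug <- if (a == "adult") adult_drug else
      scale_drug_params(adult_drug, phys_adult, phys)
    sv <- if (!is.null(sv_tables)) sv_tables[[a]] else NULL
    reports[[a]] <- run_dosimetry(phys, drug, sv = sv, ...)
    bw[a] <- phys$body_weight
  }
  e <- vapply(reports, `[[`, numeric(1), "effective_msv_per_mbq")
  max_act <- vapply(e, max_activity, numeric(1), e_adult = e[["adult"]],
                    adult_limit = adult_limit)
  out <- data.frame(age_label = ages,
                    effective_msv_per_mbq = unname(e),
                    ratio_to_adult = unname(e / e[["adult"]]),
                    max_activity_mbq = unname(max_act),
                    max_activity_mbq_per_kg = unname(max_act / bw[ages]))
  attr(out, "reports") <- reports
  out
}
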