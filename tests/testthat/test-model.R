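# independent flux-ledger right-hand side: every transport route is a
# (from, to, flux) triple; each flux is added to exactly one destination
# and removed from exactly one source ("urine" has no further outflow,
# "dose" feeds nothing here).
ledger_rhs <- function(phys, drug, y) {
  V <- phys$V; Q <- phys$Q; R <- drug$blood_plasma_ratio
  kp <- drug$kp
  a <- function(nm) y[[nm]]
  conc_art <- a("arterial_blood") / V[["arterial_blood"]]
  out <- function(nm, kpn, vn) R * a(nm) / (kp[[kpn]] * V[[vn]])
  flux <- list(
    list("venous_blood", "lung", Q[["lung"]] * a("venous_blood") / V[["venous_blood"]]),
    list("lung", "arterial_blood",
         Q[["lung"]] * a("lung") / (kp[["lung"]] * V[["lung"]])),
    list("arterial_blood", "heart_vascular", Q[["heart"]] * conc_art),
    list("heart_vascular", "venous_blood",
         Q[["heart"]] * a("heart_vascular") / V[["heart_vascular"]]),
    list("heart_vascular", "heart_extravascular",
         drug$ps[["heart"]] * a("heart_vascular") / V[["heart_vascular"]]),
    list("heart_extravascular", "heart_vascular",
         drug$ps[["heart"]] * out("heart_extravascular", "heart",
                                  "heart_extravascular")),
    list("arterial_blood", "brain_vascular", Q[["brain"]] * conc_art),
    list("brain_vascular", "venous_blood",
         Q[["brain"]] * a("brain_vascular") / V[["brain_vascular"]]),
    list("arterial_blood", "muscle", Q[["muscle"]] * conc_art),
    list("muscle", "venous_blood", Q[["muscle"]] * out("muscle", "muscle", "muscle")),
    list("arterial_blood", "liver", Q[["hepatic_artery"]] * conc_art),
    list("liver", "venous_blood", Q[["liver"]] * out("liver", "liver", "liver")),
    list("liver", "gallbladder", drug$cl[["liver"]] * a("liver") / V[["liver"]]),
    list("gallbladder", "gi_contents",
         drug$k_gb * a("gallbladder") / V[["gallbladder"]]),
    list("arterial_blood", "gi_tissue", Q[["gi"]] * conc_art),
    list("gi_tissue", "liver", Q[["gi"]] * out("gi_tissue", "gi", "gi_tissue")),
    list("arterial_blood", "spleen", Q[["spleen"]] * conc_art),
    list("spleen", "liver", Q[["spleen"]] * out("spleen", "spleen", "spleen")),
    list("arterial_blood", "pancreas", Q[["pancreas"]] * conc_art),
    list("pancreas", "liver", Q[["pancreas"]] * out("pancreas", "pancreas", "pancreas")),
    list("arterial_blood", "kidney_vascular", Q[["kidney"]] * conc_art),
    list("kidney_vascular", "venous_blood",
         Q[["kidney"]] * a("kidney_vascular") / V[["kidney_vascular"]]),
    list("kidney_vascular", "kidney_extravascular",
         drug$ps[["kidney"]] * a("kidney_vascular") / V[["kidney_vascular"]]),
    list("kidney_extravascular", "kidney_vascular",
         drug$ps[["kidney"]] * R * a("kidney_extravascular") /
           (kp[["kidney"]] * V[["kidney_extravascular"]])),
    list("kidney_vascular", "urine",
         drug$cl[["renal"]] * a("kidney_vascular") / V[["kidney_vascular"]]),
    list("arterial_blood", "adipose", Q[["adipose"]] * conc_art),
    list("adipose", "venous_blood", Q[["adipose"]] * out("adipose", "adipose", "adipose")),
    list("arterial_blood", "thyroid", Q[["thyroid"]] * conc_art),
    list("thyroid", "venous_blood", Q[["thyroid"]] * out("thyroid", "thyroid", "thyroid")),
    list("arterial_blood", "other", Q[["other"]] * conc_art),
    list("other", "venous_blood", Q[["other"]] * out("other", "other", "other")))
  dy <- stats::setNames(numeric(20), model_states())
  for (fl in flux) {
    dy[[fl[[1]]]] <- dy[[fl[[1]]]] - fl[[3]]
    dy[[fl[[2]]]] <- dy[[fl[[2]]]] + fl[[3]]
  }
  # bladder mirrors the renal excretion flux without draining anything
  dy[["bladder"]] <- drug$cl[["renal"]] * a("kidney_vascular") / V[["kidney_vascular"]]
  dy
}

test_that("derivatives match an independent flux-ledger bookkeeping oracle", {
  phys <- adult_phys(); drug <- adult_drug()
  rhs <- build_rhs(phys, drug)
  set.seed(42)
  for (i in 1:5) {
    y <- stats::setNames(stats::runif(20, 0, 10), model_states())
    expect_equal(rhs(0, y)[[1]], ledger_rhs(phys, drug, y),
                 tolerance = 1e-12)
  }
})

test_that("the derivative field conserves mass and vanishes at zero", {
  phys <- adult_phys(); drug <- adult_drug()
  rhs <- build_rhs(phys, drug)
  zero <- stats::setNames(numeric(20), model_states())
  expect_equal(rhs(0, zero)[[1]], zero)
  bolus <- zero; bolus[["venous_blood"]] <- 1
  d <- rhs(0, bolus)[[1]]
  expect_equal(sum(d[setdiff(model_states(), "bladder")]), 0,
               tolerance = 1e-14)
  set.seed(1)
  y <- stats::setNames(stats::runif(20, 0, 5), model_states())
  expect_equal(sum(rhs(0, y)[[1]][setdiff(model_states(), "bladder")]), 0,
               tolerance = 1e-12)
})

test_that("compiled and R right-hand sides integrate identically", {
  phys <- adult_phys(); drug <- adult_drug()
  s1 <- simulate_closed_loop(phys, drug, t_grid = c(0, 30, 240, 1440))
  s2 <- simulate_closed_loop(phys, drug, t_grid = c(0, 30, 240, 1440),
                             use_compiled = FALSE)
  expect_equal(s1$state, s2$state, tolerance = 1e-8)
})

test_that("mass is conserved to 1e-6 over 48 h for all five ages", {
  adult <- adult_phys(); drug <- adult_drug()
  for (age in c("adult", "15y", "10y", "5y", "1y")) {
    phys <- load_physiology(age)
    d <- if (age == "adult") drug else scale_drug_params(drug, adult, phys)
    sim <- simulate_closed_loop(phys, d, t_grid = seq(0, 2880, by = 60))
    expect_lt(mass_balance_report(sim), 1e-6)
    expect_true(all(sim$state > -1e-6))
    # total at 48 h equals the dose to 1e-6 relative
    tot <- sum(sim$state[nrow(sim$state), setdiff(model_states(), "bladder")])
    expect_equal(tot, sim$dose, tolerance = 1e-6)
  }
})

test_that("the system is linear: doubling the dose doubles every state", {
  phys <- adult_phys(); drug <- adult_drug()
  tg <- c(0, 15, 240, 2880)
  s1 <- simulate_closed_loop(phys, drug, dose = 100, t_grid = tg)
  s2 <- simulate_closed_loop(phys, drug, dose = 200, t_grid = tg)
  expect_equal(s2$state, 2 * s1$state, tolerance = 1e-7)
  s0 <- simulate_closed_loop(phys, drug, dose = 0, t_grid = tg)
  expect_true(all(s0$state == 0))
})

test_that("stationarity recovers Kp/R for perfusion-limited tissues", {
  # hold the arterial concentration fixed and solve the muscle balance
  # for its stationary amount: Q (C_art - R A / (Kp V)) = 0 implies
  # (A/V) / C_art = Kp / R
  phys <- adult_phys(); drug <- adult_drug()
  cart <- 2.5
  for (tis in c("muscle", "adipose", "thyroid")) {
    f <- function(amt) {
      cart - drug$blood_plasma_ratio * amt / (drug$kp[[tis]] * phys$V[[tis]])
    }
    a_star <- stats::uniroot(f, c(0, 1e6), tol = 1e-12)$root
    expect_equal((a_star / phys$V[[tis]]) / cart,
                 drug$kp[[tis]] / drug$blood_plasma_ratio,
                 tolerance = 1e-6)
  }
})

test_that("observables map states to reported tissues", {
  phys <- adult_phys()
  zero <- stats::setNames(numeric(20), model_states())
  expect_true(all(observables(zero, phys) == 0))

  gi_only <- zero; gi_only[["gi_contents"]] <- 5
  obs <- observables(gi_only, phys)
  expect_equal(obs[["gi"]], 5)
  expect_true(all(obs[setdiff(names(obs), "gi")] == 0))

  # heart includes chamber blood whenever the blood pools are filled
  sim <- simulate_closed_loop(phys, adult_drug(),
                              t_grid = seq(0, 480, by = 30))
  om <- observables(sim)
  hv_ev <- sim$state[, "heart_vascular"] + sim$state[, "heart_extravascular"]
  expect_true(all(om[-1, "heart"] > hv_ev[-1]))
})

test_that("mass-balance report flags a leaking system", {
  phys <- adult_phys(); drug <- adult_drug()
  sim <- simulate_closed_loop(phys, drug, t_grid = seq(0, 1440, by = 60))
  broken <- sim
  broken$state[, "liver"] <- broken$state[, "liver"] * 0.9  # 10% leak
  expect_gt(mass_balance_report(broken), 1e-3)
})
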