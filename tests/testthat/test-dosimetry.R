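lambda_tc <- log(2) / 361.2

# wrap a decayed single-compartment trace in a minimal simulation object
fake_activity_sim <- function(tt, lambda = lambda_tc) {
  st <- matrix(0, length(tt), 20, dimnames = list(NULL, model_states()))
  st[, "liver"] <- exp(-lambda * tt)
  structure(list(time = tt, state = st, dose = 1, lambda = lambda,
                 phys = adult_phys(), drug = adult_drug(),
                 rtol = 1e-8, atol = 1e-12),
            class = "pbpk_sim")
}

test_that("residence time of a pure exponential equals 1/lambda", {
  sim <- fake_activity_sim(seq(0, 3600, by = 0.5))
  n <- residence_times(sim)
  expect_equal(n[["liver"]], 1 / lambda_tc / 60, tolerance = 1e-4)
  expect_true(all(n[setdiff(names(n), "liver")] == 0))
})

test_that("decay halves the total activity every 361.2 minutes", {
  phys <- adult_phys(); drug <- adult_drug()
  act <- simulate_activity(phys, drug, lambda = lambda_tc,
                           schedule = list(bladder = Inf, gi_contents = Inf),
                           horizon = 1806, dt = 0.2)
  tot <- rowSums(act$state[, setdiff(model_states(), "bladder")])
  ix <- vapply(c(0, 361.2, 722.4, 1444.8),
               function(tv) which.min(abs(act$time - tv)), integer(1))
  expect_lt(max(abs(act$time[ix] - c(0, 361.2, 722.4, 1444.8))), 1e-6)
  expect_equal(tot[ix], c(1, 0.5, 0.25, 0.0625), tolerance = 1e-5)
  # between-event identity: total activity = amount x exp(-lambda t)
  expect_lt(mass_balance_report(act), 1e-6)
})

test_that("activity simulation with lambda=0 reproduces the amount domain", {
  phys <- adult_phys(); drug <- adult_drug()
  act <- simulate_activity(phys, drug, lambda = 0,
                           schedule = list(bladder = Inf, gi_contents = Inf),
                           horizon = 720, dt = 60)
  kin <- simulate_closed_loop(phys, drug, dose = 1,
                              t_grid = seq(0, 720, by = 60),
                              atol = 1e-12)
  expect_equal(act$state[match(kin$time, act$time), ], kin$state,
               tolerance = 1e-8)
})

test_that("bladder voiding empties the bladder on schedule", {
  phys <- adult_phys(); drug <- adult_drug()
  act <- simulate_activity(phys, drug, horizon = 900)
  for (tv in c(180, 360, 540, 720)) {
    # the solver reports the pre-void state at the event time itself;
    # the sample just after shows the emptied bladder
    after <- act$state[which(act$time > tv)[1], "bladder"]
    before <- act$state[max(which(act$time < tv)), "bladder"]
    expect_lt(after, 1e-5 * before)
    expect_gt(before, 0)
  }
  expect_equal(sum(act$state[act$time <= 180, "gi_contents"] == 0), 1)
})

test_that("voided-bladder residence agrees with a brute-force fine grid", {
  phys <- adult_phys(); drug <- adult_drug()
  n1 <- residence_times(simulate_activity(phys, drug, horizon = 3600,
                                          dt = 1))
  n2 <- residence_times(simulate_activity(phys, drug, horizon = 3600,
                                          dt = 0.25))
  expect_equal(n1[["bladder"]], n2[["bladder"]], tolerance = 1e-3)
  expect_equal(unclass(n1), unclass(n2), tolerance = 1e-3)
  # total-decay bound in consistent units
  expect_lt(sum(n1[setdiff(model_states(), "urine")]),
            1 / lambda_tc / 60)
})

test_that("source mapping preserves totals and flags gaps", {
  n <- stats::setNames(numeric(20), model_states())
  n[] <- seq(0.01, 0.2, length.out = 20)

  mapped <- map_sources(n)
  keep <- setdiff(model_states(), "urine")
  expect_equal(sum(mapped), sum(n[keep]), tolerance = 1e-12)

  # identity mapping on a toy set
  toy <- stats::setNames(c(1, 2, 3), c("a", "b", "c"))
  idm <- list(a = "a", b = "b", c = "c")
  expect_equal(map_sources(toy, idm), c(a = 1, b = 2, c = 3))

  # splits conserve the total; unmapped compartments are named
  expect_error(map_sources(c(gi = 8), list(r1 = "x")), "unmapped")
  quarter <- list(q1 = "gi", q2 = character(0), q3 = character(0),
                  q4 = character(0))
  expect_equal(sum(map_sources(c(gi = 8), quarter)), 8)

  expect_error(map_sources(toy, list(a = c("a", "b"), b = "b", c = "c")),
               "twice")
})

test_that("absorbed doses are the S-matrix contraction of residence times", {
  sv <- svalue_matrix(matrix(c(0.003, 1e-4, 2e-4,
                               1e-4, 0.004, 1e-4,
                               2e-4, 1e-4, 0.005),
                             3, 3, byrow = TRUE,
                             dimnames = list(c("a", "b", "c"),
                                             c("a", "b", "c"))))
  n0 <- c(a = 0, b = 0, c = 0)
  expect_true(all(absorbed_doses(n0, sv) == 0))
  n1 <- c(a = 2, b = 0, c = 0)
  expect_equal(absorbed_doses(n1, sv)[["a"]], 0.006)
  n <- c(a = 1.5, b = 2.5, c = 0.5)
  hand <- c(a = 0.003 * 1.5 + 1e-4 * 2.5 + 2e-4 * 0.5,
            b = 1e-4 * 1.5 + 0.004 * 2.5 + 1e-4 * 0.5,
            c = 2e-4 * 1.5 + 1e-4 * 2.5 + 0.005 * 0.5)
  expect_equal(absorbed_doses(n, sv), hand)
  expect_error(absorbed_doses(c(zz = 1), sv), "zz")
})

test_that("effective dose is the ICRP-weighted mean with remainder rule", {
  w <- read_tissue_weights()
  expect_equal(sum(w), 1)
  sv <- bundled_svalues("adult")
  h <- stats::setNames(rep(0.007, length(sv$targets)), sv$targets)
  expect_equal(effective_dose(h, w), 0.007, tolerance = 1e-12)
  h2 <- h[setdiff(names(h), "thyroid")]
  expect_error(effective_dose(h2, w), "thyroid")
})

test_that("maximum activities follow the iso-effective-dose rule", {
  expect_equal(max_activity(0.006, 0.006), 1200)
  expect_equal(max_activity(0.012, 0.006), 600)
  expect_error(max_activity(0, 0.006), "positive")

  anchors <- data.frame(age_years = c(1, 5, 10, 15, 18),
                        max_activity_mbq = c(248, 466, 694, 1011, 1200))
  expect_equal(interpolate_max_activity(10, anchors), 694)
  expect_equal(interpolate_max_activity(7.5, anchors), (466 + 694) / 2)
  expect_equal(interpolate_max_activity(3, anchors),
               248 + (466 - 248) / 2)
  expect_error(interpolate_max_activity(0.5, anchors), "outside")
})

test_that("the paediatric study is internally consistent", {
  study <- default_study()
  e <- study$effective_msv_per_mbq[match(c("1y", "5y", "10y", "15y", "adult"),
                                         study$age_label)]
  # effective dose per activity never increases with age
  expect_true(all(diff(e) <= 0))
  # iso-dose construction: max activity x E constant to machine precision
  prod <- study$max_activity_mbq * study$effective_msv_per_mbq
  expect_equal(max(prod) - min(prod), 0, tolerance = 1e-9 * max(prod))
  expect_equal(study$ratio_to_adult[study$age_label == "adult"], 1)
})

test_that("S-value ingestion normalizes units and validates entries", {
  f <- tempfile(fileext = ".csv")
  d <- data.frame(target = c("a", "a", "b", "b"),
                  source = c("a", "b", "a", "b"),
                  svalue = c(0.003, 1e-4, 2e-7 / 3600, 0.004),
                  unit = c("mGy/MBq/h", "mGy/MBq/h", "mGy/MBq/s",
                           "mGy/MBq/h"))
  utils::write.csv(d, f, row.names = FALSE)
  sv <- read_svalue_matrix(f)
  expect_equal(sv$S["b", "a"], 2e-7, tolerance = 1e-12)
  d$unit[1] <- "rad/uCi"
  utils::write.csv(d, f, row.names = FALSE)
  expect_error(read_svalue_matrix(f), "unknown S-value unit")
})
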