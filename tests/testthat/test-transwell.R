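test_that("calibration hits the anchored 24-h fractions for all conditions", {
  cases <- list(
    list("A549", particle_spec(18), 0.020),
    list("A549", particle_spec(2), 0.542),
    list("MLE12", particle_spec(2), 0.710),
    list("A549", particle_spec(NA, is_ionic = TRUE), 0.750),
    list("MLE12", particle_spec(NA, is_ionic = TRUE), 0.750)
  )
  for (cs in cases) {
    des <- transwell_design(cs[[1]], cs[[2]])
    kin <- calibrate_kinetics(des)
    expect_equal(model_translocation_fraction(kin, 24), cs[[3]],
                 tolerance = 1e-3 / cs[[3]])
    # closed form and matrix-exponential disposition agree
    st <- simulate_transwell(kin, des, times = c(0, 2, 8, 24, 48, 72))
    D <- des$dose * des$insert_area
    expect_equal(st$basolateral / D,
                 model_translocation_fraction(kin, st$time_h),
                 tolerance = 1e-9)
  }
})

test_that("size response is monotone decreasing and lag delays MLE-12", {
  sizes <- c(2, 7, 18, 46, 80)
  for (cl in c("A549", "MLE12")) {
    f24 <- vapply(sizes, function(d) {
      kin <- calibrate_kinetics(transwell_design(cl, particle_spec(d)))
      model_translocation_fraction(kin, 24)
    }, numeric(1))
    expect_true(all(diff(f24) < 0))
  }
  # a non-monotone anchor table is rejected
  bad <- default_anchor_table()
  bad$fraction[bad$cell_line == "A549"] <- c(0.02, 0.542)
  expect_error(calibrate_kinetics(transwell_design("A549", particle_spec(7)),
                                  anchor_table = bad), "decreasing")

  # with identical kinetics apart from the 2-h contact lag, the murine
  # monolayer has translocated less at 2 h
  kinA <- calibrate_kinetics(transwell_design("A549", particle_spec(2)))
  kinM <- kinA; kinM$lag <- 2
  expect_lt(model_translocation_fraction(kinM, 2),
            model_translocation_fraction(kinA, 2))
  expect_equal(model_translocation_fraction(kinM, 2), 0)
})

test_that("dose response: invariant up to 100 ng/cm2, A549 penalty above", {
  f <- function(cl, dose) {
    kin <- calibrate_kinetics(transwell_design(cl, particle_spec(18),
                                               dose = dose))
    model_translocation_fraction(kin, 24)
  }
  low <- vapply(c(25, 50, 100), function(d) f("A549", d), numeric(1))
  expect_lt(max(abs(low - low[1])), 1e-6)
  expect_lt(f("A549", 200), f("A549", 100))
  expect_lt(f("A549", 150), f("A549", 100))
  # MLE-12 shows no dose penalty over the tested range
  expect_equal(f("MLE12", 200), f("MLE12", 100), tolerance = 1e-9)
})

test_that("disposition conserves mass and is biphasic at default calibration", {
  des <- transwell_design("A549", particle_spec(18))
  kin <- calibrate_kinetics(des)
  st <- simulate_transwell(kin, des, times = c(0, 1, 2, 8, 24, 48, 72))
  D <- des$dose * des$insert_area
  expect_lt(max(abs(rowSums(st[, -1]) - D)), 1e-9 * D)

  # everything stays in the surface liquid if transfer is off
  kin0 <- kin; kin0$k_sc <- 0
  st0 <- simulate_transwell(kin0, des, times = c(0, 24, 72))
  expect_equal(st0$surface_liquid, rep(D, 3))
  expect_true(all(st0$basolateral == 0))

  # biphasic translocation: early rate at least 10x the late rate
  h <- 0.05
  rate_at <- function(t) {
    (model_translocation_fraction(kin, t + h) -
       model_translocation_fraction(kin, t - h)) / (2 * h)
  }
  expect_gte(rate_at(1) / rate_at(48), 10)
})

test_that("generator: exact without noise, bookkeeping, censoring, seeds", {
  des <- transwell_design("A549", particle_spec(18), seed = 21)
  kin <- calibrate_kinetics(des)

  # noise-free, full recovery: observations equal the model exactly
  ds0 <- generate_dataset(des, kin, noise_cv = 0, recovery = 1)
  st <- simulate_transwell(kin, des, times = des$timepoints)
  for (T in des$timepoints) {
    i <- match(T, des$timepoints)
    sub <- ds0[ds0$time_h == T & ds0$replicate == 1, ]
    expect_equal(sub$amount_ng[sub$compartment == "surface_liquid"],
                 st$surface_liquid[i], tolerance = 1e-9)
    expect_equal(sum(sub$amount_ng[sub$compartment == "basolateral"]),
                 st$basolateral[i], tolerance = 1e-9)
  }
  # daily increments sum to the cumulative basolateral amount (pre-noise)
  b72 <- ds0[ds0$time_h == 72 & ds0$compartment == "basolateral" &
               ds0$replicate == 2, ]
  expect_equal(nrow(b72), 3)           # one aliquot per 24-h medium window
  expect_equal(sort(b72$sample_time_h), c(24, 48, 72))
  expect_equal(sum(b72$amount_ng), st$basolateral[match(72, des$timepoints)],
               tolerance = 1e-9)

  # settled-dose empty wells: triplicate at the nominal settled dose
  empty <- ds0[ds0$compartment == "settled_dose", ]
  expect_equal(nrow(empty), 3)
  expect_equal(empty$amount_ng, rep(des$dose * des$insert_area, 3))

  # below the 25 ng/cm2 detection limit the basolateral data are censored
  low <- transwell_design("A549", particle_spec(18), dose = 20, seed = 3)
  dsl <- generate_dataset(low, calibrate_kinetics(low))
  expect_true(all(dsl$censored[dsl$compartment == "basolateral"]))
  expect_false(any(dsl$censored[dsl$compartment == "surface_liquid"]))

  # reproducibility: same seed bit-identical, different seed different
  d1 <- generate_dataset(des, kin, seed = 11)
  d2 <- generate_dataset(des, kin, seed = 11)
  expect_identical(as.data.frame(d1), as.data.frame(d2))
  d3 <- generate_dataset(des, kin, seed = 12)
  expect_false(identical(d1$amount_ng, d3$amount_ng))
})

test_that("estimator: exact on clean data, unbiased under noise and recovery", {
  des <- transwell_design("A549", particle_spec(2))
  kin <- calibrate_kinetics(des)

  ds0 <- generate_dataset(des, kin, noise_cv = 0, recovery = 1)
  for (t in c(2, 24, 72)) {
    expect_equal(estimate_fraction(ds0, t)$fraction,
                 model_translocation_fraction(kin, t), tolerance = 1e-9)
  }

  # recovery losses cancel through the recovery correction (still noise-free)
  dsr <- generate_dataset(des, kin, noise_cv = 0, recovery = 0.8)
  expect_equal(estimate_fraction(dsr, 24)$fraction,
               model_translocation_fraction(kin, 24), tolerance = 1e-9)
  # ... and bias the literal estimator by exactly the recovery factor
  expect_equal(estimate_fraction(dsr, 24, correct_recovery = FALSE)$fraction,
               0.8 * model_translocation_fraction(kin, 24), tolerance = 1e-9)

  # parameter recovery: across seeds at CV 10%, the mean estimate sits
  # within 2 standard errors of the generator truth
  truth <- model_translocation_fraction(kin, 24)
  ests <- vapply(1:20, function(s) {
    estimate_fraction(generate_dataset(des, kin, noise_cv = 0.10, seed = s),
                      24)$fraction
  }, numeric(1))
  se <- sd(ests) / sqrt(length(ests))
  expect_lt(abs(mean(ests) - truth), 2 * se + 1e-12)

  # all-censored conditions refuse to estimate
  low <- transwell_design("A549", particle_spec(18), dose = 20)
  expect_error(estimate_fraction(generate_dataset(low), 24), "censored")
})

test_that("two-group comparison matches the t-distribution and edge cases", {
  eq <- compare_groups(c(1, 2, 3), c(1, 2, 3))
  expect_equal(eq$t, 0)
  expect_equal(eq$p, 1)
  expect_false(eq$significant)

  # hand-computed pooled-variance case against stats::t.test
  a <- c(0.021, 0.019, 0.023); b <- c(0.031, 0.034, 0.029)
  got <- compare_groups(a, b)
  ref <- stats::t.test(a, b, var.equal = TRUE)
  expect_equal(got$t, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(got$p, ref$p.value, tolerance = 1e-12)
  expect_true(got$significant)

  # zero variance, equal means -> p = 1 by convention
  z <- compare_groups(c(2, 2, 2), c(2, 2, 2))
  expect_equal(z$p, 1)

  # power: groups separated by 10 SD are detected essentially always
  hits <- vapply(1:200, function(s) {
    set.seed(s)
    compare_groups(rnorm(3, 0, 0.01), rnorm(3, 0.1, 0.01))$significant
  }, logical(1))
  expect_gte(mean(hits), 0.99)

  expect_error(compare_groups(1, c(1, 2)), "replicates")
})
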