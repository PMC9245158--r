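test_that("scenario configurations satisfy the design constraints", {
  for (nm in c("exp.small", "exp.large", "weibull", "cov.eff.pos",
               "cov.eff.neg")) {
    cfg <- make_scenario(nm)
    expect_equal(cfg$sex_prob, 0.5)
    expect_equal(cfg$year_range, c(1990, 2000))
    expect_equal(cfg$max_follow, 10)
    expect_equal(cfg$excess_dar$beta, 0) # never an age effect on excess DaR
  }
  expect_gt(make_scenario("cov.eff.pos")$relapse$beta, 0)
  expect_gt(make_scenario("cov.eff.pos")$excess_nrm$beta, 0)
  expect_lt(make_scenario("cov.eff.neg")$relapse$beta, 0)
  expect_gt(make_scenario("cov.eff.neg")$excess_nrm$beta, 0)
  # old cohort in exp.large, young elsewhere
  expect_gte(make_scenario("exp.large")$age_range[1], 60)
  expect_lte(make_scenario("exp.small")$age_range[2], 50)
  expect_error(make_scenario("bogus"))
})

test_that("left-truncated Weibull sampler matches its closed forms", {
  set.seed(201)
  # shape 1: T - L is exponential(rate)
  x <- sample_weibull_lt(10000, rate = 0.5, shape = 1, L = 3)
  expect_true(all(x >= 3))
  expect_lt(abs(mean(x - 3) - 2), 3 * 2 / sqrt(10000))
  # L = 0: plain Weibull, KS against the closed-form CDF
  y <- sample_weibull_lt(5000, rate = 0.4, shape = 1.7, L = 0)
  ks <- stats::ks.test(y, function(t) 1 - exp(-0.4 * t^1.7))
  expect_gt(ks$p.value, 0.01)
  # left-truncated conditional law: P(T > t | T > L) = exp(-a (t^b - L^b))
  z <- sample_weibull_lt(5000, rate = 0.4, shape = 1.7, L = 2)
  ks2 <- stats::ks.test(z, function(t) 1 - exp(-0.4 * (t^1.7 - 2^1.7)))
  expect_gt(ks2$p.value, 0.01)
})

test_that("cohorts are reproducible and internally consistent", {
  cfg <- make_scenario("exp.large")
  a <- simulate_cohort(cfg, 200, seed = 501)
  b <- simulate_cohort(cfg, 200, seed = 501)
  expect_identical(a$data$records, b$data$records)
  expect_identical(a$latent, b$latent)
  expect_equal(nrow(validate_msm_data(a$data)), 0)
  # observed records are reconstructable from the latent times
  lt <- a$latent
  tau <- years_to_days(cfg$max_follow)
  first <- pmin(lt$t_relapse, lt$t_exc_nrm, lt$t_pop_nrm)
  exit1 <- pmin(first, lt$t_censor, tau)
  r1 <- a$data$records[a$data$records$trans == 1, ]
  expect_equal(r1$Tstop, exit1)
  expect_equal(r1$status,
               as.integer(lt$t_relapse == first & first < pmin(lt$t_censor, tau)))
  # cause labels never leak into the observed dataset
  expect_false(any(c("death_cause", "t_pop_nrm") %in% names(a$data$records)))
  # relapse rows carry delayed entry at the relapse time
  r3 <- a$data$records[a$data$records$trans == 3, ]
  expect_true(all(r3$Tstart > 0))
  expect_equal(sort(r3$Tstart),
               sort(lt$t_relapse[lt$relapse_observed]))
})

test_that("no events means everyone is administratively censored", {
  cfg <- make_scenario("exp.small", ratetable = constant_ratetable(0))
  cfg$relapse$rate <- 1e-12
  cfg$excess_nrm$rate <- 1e-12
  cfg$censor_rate <- 1e-12
  coh <- simulate_cohort(cfg, 50, seed = 8)
  expect_true(all(coh$data$records$status == 0))
  expect_true(all(coh$data$records$Tstop == years_to_days(10)))
})

test_that("censoring calibration hits its target", {
  cfg <- make_scenario("exp.small")
  # no-event case has the closed-form solution -log(1 - 0.2) / 10
  cfg0 <- make_scenario("exp.small", ratetable = constant_ratetable(0))
  cfg0$relapse$rate <- 1e-12
  cfg0$excess_nrm$rate <- 1e-12
  r0 <- calibrate_censoring(cfg0, n = 20000)
  expect_lt(abs(r0 - (-log(0.8) / 10)), 1e-3)
  expect_equal(calibrate_censoring(cfg, target = 0), 0)
  # calibrated rate reproduces ~20% censoring on a fresh seed
  r <- calibrate_censoring(cfg)
  cfg$censor_rate <- r
  f <- censored_fraction(simulate_cohort(cfg, 10000, seed = 902))
  expect_gt(f, 0.17)
  expect_lt(f, 0.23)
  # stored scenario defaults were produced by this calibration
  expect_equal(make_scenario("exp.small")$censor_rate, r, tolerance = 0.02)
})

test_that("truth integrator matches closed forms and is grid-converged", {
  cfg <- make_scenario("exp.small", ratetable = constant_ratetable(0))
  tv <- true_values(cfg, times = c(1, 5, 10))
  lr <- cfg$relapse$rate; le <- cfg$excess_nrm$rate; lt <- lr + le
  # competing-risks closed form for the excess-NRM state
  for (t in c(1, 5, 10)) {
    expect_equal(tv$truth[tv$measure == "P" & tv$to == "NRM.e" & tv$time == t],
                 le / lt * (1 - exp(-lt * t)), tolerance = 1e-6)
  }
  # occupation probabilities sum to one
  s <- tapply(tv$truth[tv$measure == "P"], tv$time[tv$measure == "P"], sum)
  expect_equal(as.vector(s), rep(1, 3), tolerance = 1e-4)
  # identical population hazard for everyone: truth equals the trajectory
  cfgc <- make_scenario("exp.small", ratetable = constant_ratetable(0.0001))
  tvc <- true_values(cfgc, times = c(1, 5))
  expect_equal(tvc$truth[tvc$measure == "H" & tvc$to == "NRM.p"],
               0.0001 * years_to_days(c(1, 5)), tolerance = 1e-6)
  # true cumulative hazards are non-decreasing in time
  hz <- subset(tv, measure == "H")
  for (tr in unique(hz$to)) {
    expect_true(all(diff(hz$truth[hz$to == tr]) >= 0))
  }
  # doubling the covariate quadrature changes nothing materially
  cfg2 <- make_scenario("exp.large")
  t1 <- true_values(cfg2, times = c(5, 10), age_points = 20, year_points = 3)
  t2 <- true_values(cfg2, times = c(5, 10), age_points = 40, year_points = 6)
  expect_lt(max(abs(t1$truth - t2$truth) / pmax(abs(t2$truth), 1)), 1e-3)
})

test_that("t = 0 occupation is a point mass in the starting state", {
  cfg <- make_scenario("exp.small")
  tv <- true_values(cfg, times = c(0, 1))
  p0 <- subset(tv, measure == "P" & time == 0)
  expect_equal(p0$truth[p0$to == "ARF"], 1)
  expect_true(all(p0$truth[p0$to != "ARF"] == 0))
})
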