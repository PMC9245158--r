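test_that("variance_of applies the split-transition rules", {
  expect_equal(variance_of(0.3, "greenwood", kind = "population"), 0)
  expect_equal(variance_of(0.3, "greenwood", greenwood = 0.02, kind = "excess"),
               0.02)
  expect_equal(variance_of(2, "bootstrap", replicates = c(1, 2, 3)), 1)
  expect_error(variance_of(2, "bootstrap"), "replicates")
  expect_error(variance_of(0.3, "greenwood", kind = "excess"), "not supplied")
})

test_that("confidence intervals match their closed forms", {
  z <- qnorm(0.975)
  ci <- confidence_interval(0.5, variance = 0.01, method = "plain.G")
  expect_equal(c(ci$lower, ci$upper), c(0.5 - z * 0.1, 0.5 + z * 0.1),
               tolerance = 1e-10)
  expect_equal(round(c(ci$lower, ci$upper), 3), c(0.304, 0.696))
  ci2 <- confidence_interval(0.5, variance = 0.01, method = "log.boot")
  expect_equal(c(ci2$lower, ci2$upper),
               0.5 * exp(c(-1, 1) * z * 0.1 / 0.5), tolerance = 1e-10)
  expect_equal(round(c(ci2$lower, ci2$upper), 3), c(0.338, 0.740))
  # zero variance: degenerate interval at the estimate
  for (m in c("plain.G", "plain.boot", "log.boot", "logit.boot",
              "cloglog.boot")) {
    ci0 <- confidence_interval(0.5, variance = 0, method = m)
    expect_equal(c(ci0$lower, ci0$upper), c(0.5, 0.5))
  }
  # logit and cloglog stay inside (0, 1); plain may leave [0, 1]
  cil <- confidence_interval(0.9, variance = 0.04, method = "logit.boot")
  expect_true(cil$lower > 0 && cil$upper < 1 && cil$lower <= cil$upper)
  cic <- confidence_interval(0.9, variance = 0.04, method = "cloglog.boot")
  expect_true(cic$lower > 0 && cic$upper < 1 && cic$lower <= cic$upper)
  cip <- confidence_interval(0.9, variance = 0.04, method = "plain.boot")
  expect_gt(cip$upper, 1)
  # scale preconditions produce informative errors
  expect_error(confidence_interval(0, variance = 1, method = "log.boot"),
               "log.boot")
  expect_error(confidence_interval(1, variance = 1, method = "logit.boot"),
               "logit.boot")
})

test_that("q.boot uses type-7 replicate quantiles and stays in range", {
  r <- c(5, 1, 4, 2, 3, 9, 7, 8, 6, 10)
  ci <- confidence_interval(5, replicates = r, method = "q.boot")
  expect_equal(c(ci$lower, ci$upper),
               unname(quantile(r, c(0.025, 0.975), type = 7)))
  expect_gte(ci$lower, min(r))
  expect_lte(ci$upper, max(r))
  # invariant under monotone relabelling given matching quantile evaluation
  ci2 <- confidence_interval(5, replicates = sort(r), method = "q.boot")
  expect_equal(ci, ci2)
})

test_that("bootstrap is reproducible and degenerates correctly", {
  st <- transition_structure(data.frame(from = "a", to = "b"))
  # n identical subjects: every resample is the same dataset
  rec <- tibble::tibble(id = 1:8, trans = 1, Tstart = 0, Tstop = 50,
                        status = 1)
  ds <- msm_data(rec, st, toy_profiles(1:8))
  smap <- extend_structure(st, character()) # no split
  tg <- msm_target("H", "a", "b", 50)
  bt <- suppressWarnings(
    bootstrap_msm(ds, constant_ratetable(0.0001), smap, tg, B = 20, seed = 1))
  expect_equal(boot_variance(bt), 0)
  # same seed, same replicates
  cfg <- make_scenario("exp.small")
  coh <- simulate_cohort(cfg, 80, seed = 4)
  smap2 <- extend_structure(illness_death_structure(), c("NRM", "DaR"))
  tg2 <- default_targets(c(2, 5))[c(1, 4, 8), ]
  b1 <- bootstrap_msm(coh$data, cfg$ratetable, smap2, tg2, B = 25, seed = 7)
  b2 <- bootstrap_msm(coh$data, cfg$ratetable, smap2, tg2, B = 25, seed = 7)
  expect_identical(b1$values, b2$values)
  expect_false(identical(
    b1$values,
    bootstrap_msm(coh$data, cfg$ratetable, smap2, tg2, B = 25, seed = 8)$values
  ))
})

test_that("population hazards: Greenwood width is zero, bootstrap is not", {
  cfg <- make_scenario("exp.large")
  coh <- simulate_cohort(cfg, 300, seed = 13)
  ds <- coh$data
  smap <- extend_structure(illness_death_structure(), c("NRM", "DaR"))
  hz <- nelson_aalen(ds)
  ext <- split_hazards(hz, ds, cfg$ratetable, smap)
  w <- tidy(ext)
  expect_true(all(w$var[w$kind == "population"] == 0))
  # excess hazard inherits the observed transition's Greenwood variance
  expect_equal(w$var[w$to == "NRM.e"], hz$var[hz$trans == 2])
  expect_equal(w$var[w$to == "DaR.e"], hz$var[hz$trans == 3])
  tg <- msm_target("H", "ARF", "NRM.p", years_to_days(5))
  bt <- bootstrap_msm(ds, cfg$ratetable, smap, tg, B = 50, seed = 3)
  expect_gt(boot_variance(bt), 0)
  # plain.G on a population hazard: zero-width interval; plain.boot: not
  theta <- w$haz[w$to == "NRM.p"][findInterval(years_to_days(5),
                                               w$time[w$to == "NRM.p"])]
  ci_g <- confidence_interval(theta, variance = 0, method = "plain.G")
  expect_equal(ci_g$upper - ci_g$lower, 0)
  ci_b <- confidence_interval(theta, variance = boot_variance(bt),
                              method = "plain.boot")
  expect_gt(ci_b$upper - ci_b$lower, 0)
})

test_that("Greenwood probability variance tracks the bootstrap on unsplit data", {
  # 500-subject illness-death cohort, zero ratetable so that no transition is
  # population-related; Greenwood and bootstrap SEs should agree within 25%
  cfg <- make_scenario("exp.small", ratetable = constant_ratetable(0))
  coh <- simulate_cohort(cfg, 500, seed = 17)
  ds <- coh$data
  smap <- extend_structure(illness_death_structure(), c("NRM", "DaR"))
  tg <- dplyr::filter(default_targets(5), measure == "P",
                      to %in% c("ARF", "Relapse", "NRM.e", "DaR.e"))
  pe <- relmsm:::estimate_targets_full(ds, cfg$ratetable, smap, tg,
                                       prob_variance = TRUE)
  bt <- bootstrap_msm(ds, cfg$ratetable, smap, tg, B = 100, seed = 19)
  bv <- boot_variance(bt)
  rel <- abs(sqrt(pe$gw_var) - sqrt(bv)) / sqrt(bv)
  expect_true(all(rel < 0.25))
})
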