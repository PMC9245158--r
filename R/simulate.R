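## hazard-law helpers: exponential handled as Weibull with shape 1; the
## covariate effect multiplies the Weibull rate, so the age-adjusted survival
## is exp(-a_i t^b) with a_i = a exp(beta * age_c).
law_rate <- function(l, age_c) l$rate * exp(l$beta * age_c)

#' Sample from a left-truncated Weibull distribution
#'
#' Draws `T` with conditional survival
#' `P(T > t | T > L) = exp(-a (t^b - L^b))` by inverse transform:
#' `T = (L^b + E / a)^(1/b)` with `E` unit exponential. With `shape = 1` the
#' excess time `T - L` is exponential(`rate`) (memorylessness).
#'
#' @param n Number of draws.
#' @param rate Weibull rate `a` (> 0), vectorised over draws.
#' @param shape Weibull shape `b` (> 0).
#' @param L Left-truncation time (>= 0), vectorised.
#' @return Draws, all `>= L`, in the time unit of `rate`.
#' @export
sample_weibull_lt <- function(n, rate, shape = 1, L = 0) {
  stopifnot(all(rate > 0), all(shape > 0), all(L >= 0))
  (L^shape + rexp(n) / rate)^(1 / shape)
}

#' Simulate a cohort under a study scenario
#'
#' Generates demographics (uniform age, Bernoulli(0.5) sex, uniform entry
#' date), latent event times (relapse and excess NRM from the scenario's
#' parametric laws; population NRM from the ratetable; after an observed
#' relapse, population DaR from the ratetable left-truncated at relapse and
#' excess DaR from the left-truncated Weibull conditional on relapse time,
#' keeping the model Markov on the study clock), applies exponential random
#' censoring plus the 10-year administrative cutoff, and assembles the
#' observed long-format records. Only the minimum of the competing latent
#' times is observed; cause-of-death labels stay in the latent table.
#'
#' @param cfg A [make_scenario()] configuration.
#' @param n Number of subjects.
#' @param seed Optional integer seed.
#' @return A list of class `sim_cohort`: `data` (an [msm_data()] on the
#'   illness-death structure), `latent` (tibble of all generated times and
#'   true cause labels), `cfg`.
#' @export
simulate_cohort <- function(cfg, n, seed = NULL) {
  stopifnot(inherits(cfg, "scenario_config"), n >= 1)
  if (!is.null(seed)) set.seed(seed)
  rt <- cfg$ratetable
  tau_d <- years_to_days(cfg$max_follow)
  profiles <- tibble::tibble(
    id = seq_len(n),
    age = runif(n, cfg$age_range[1], cfg$age_range[2]),
    sex = ifelse(rbinom(n, 1, cfg$sex_prob) == 1, "female", "male"),
    year = runif(n, cfg$year_range[1], cfg$year_range[2])
  )
  age_c <- profiles$age - mean(cfg$age_range)

  t_rel <- years_to_days(sample_weibull_lt(n, law_rate(cfg$relapse, age_c),
                                           cfg$relapse$shape))
  t_enrm <- years_to_days(sample_weibull_lt(n, law_rate(cfg$excess_nrm, age_c),
                                            cfg$excess_nrm$shape))
  t_pnrm <- sample_pop_death_time(rt, profiles, 0)
  t_cens <- years_to_days(rexp(n, cfg$censor_rate))

  t_nrm <- pmin(t_enrm, t_pnrm)
  first <- pmin(t_rel, t_nrm)
  t_stop1 <- pmin(first, t_cens, tau_d)
  rel_obs <- t_rel < t_nrm & t_rel < pmin(t_cens, tau_d)
  nrm_obs <- t_nrm < t_rel & t_nrm < pmin(t_cens, tau_d)

  t_pdar <- rep(NA_real_, n)
  t_edar <- rep(NA_real_, n)
  idx <- which(rel_obs)
  if (length(idx)) {
    t_pdar[idx] <- sample_pop_death_time(rt, profiles[idx, ], t_rel[idx])
    t_edar[idx] <- years_to_days(
      sample_weibull_lt(length(idx),
                        law_rate(cfg$excess_dar, age_c[idx]),
                        cfg$excess_dar$shape,
                        L = days_to_years(t_rel[idx])))
  }
  t_dar <- pmin(t_edar, t_pdar)
  t_stop2 <- pmin(t_dar, t_cens, tau_d)
  dar_obs <- !is.na(t_dar) & t_dar < pmin(t_cens, tau_d)

  records <- dplyr::bind_rows(
    tibble::tibble(id = profiles$id, trans = 1L, Tstart = 0,
                   Tstop = t_stop1, status = as.integer(rel_obs)),
    tibble::tibble(id = profiles$id, trans = 2L, Tstart = 0,
                   Tstop = t_stop1, status = as.integer(nrm_obs)),
    tibble::tibble(id = profiles$id[idx], trans = 3L, Tstart = t_rel[idx],
                   Tstop = t_stop2[idx], status = as.integer(dar_obs[idx]))
  ) |> dplyr::arrange(.data$id, .data$trans)

  latent <- tibble::tibble(
    id = profiles$id,
    t_relapse = t_rel, t_pop_nrm = t_pnrm, t_exc_nrm = t_enrm,
    t_pop_dar = t_pdar, t_exc_dar = t_edar, t_censor = t_cens,
    relapse_observed = rel_obs,
    death_cause = dplyr::case_when(
      nrm_obs & t_pnrm < t_enrm ~ "population NRM",
      nrm_obs ~ "excess NRM",
      dar_obs & t_pdar < t_edar ~ "population DaR",
      dar_obs ~ "excess DaR",
      .default = "none"
    )
  )
  structure(list(
    data = msm_data(records, illness_death_structure(), profiles),
    latent = latent, cfg = cfg
  ), class = "sim_cohort")
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat("<sim_cohort> scenario ", x$cfg$name, ", n = ",
      nrow(x$latent), "\n", sep = "")
  print(table(x$latent$death_cause))
  invisible(x)
}

#' Fraction of subjects ending in random censoring
#'
#' @param cohort A [simulate_cohort()] result.
#' @param count_administrative Also count subjects alive at the 10-year
#'   cutoff? Default `FALSE`: only exponential (random) censoring counts.
#' @return A proportion.
#' @export
censored_fraction <- function(cohort, count_administrative = FALSE) {
  lt <- cohort$latent
  tau_d <- years_to_days(cohort$cfg$max_follow)
  end <- ifelse(lt$relapse_observed,
                pmin(lt$t_exc_dar, lt$t_pop_dar),
                pmin(lt$t_relapse, lt$t_exc_nrm, lt$t_pop_nrm))
  if (count_administrative) {
    mean(lt$t_censor < end | end > tau_d)
  } else {
    mean(lt$t_censor < pmin(end, tau_d))
  }
}

#' Calibrate the exponential censoring rate of a scenario
#'
#' Finds, by bisection, the exponential rate for which the expected fraction
#' of subjects randomly censored within the follow-up window equals `target`.
#' One latent cohort (fixed internal seed) is simulated without censoring;
#' because the standard-exponential censoring draws are held fixed, the
#' censored fraction is monotone in the rate and the bisection is exact up to
#' Monte-Carlo error.
#'
#' @param cfg A [make_scenario()] configuration (its `censor_rate` is
#'   ignored).
#' @param target Target censored fraction (default 0.20).
#' @param n Cohort size used for calibration.
#' @param tol Tolerance on the censored fraction.
#' @param seed Internal seed for the calibration cohort.
#' @return The calibrated rate (per year).
#' @export
calibrate_censoring <- function(cfg, target = 0.20, n = 20000, tol = 0.01,
                                seed = 20201) {
  stopifnot(target >= 0, target < 1)
  if (target == 0) return(0)
  set.seed(seed)
  cfg2 <- cfg
  cfg2$censor_rate <- 1e-12 # effectively no random censoring in the latent draw
  coh <- simulate_cohort(cfg2, n)
  lt <- coh$latent
  tau <- cfg$max_follow
  first <- pmin(lt$t_relapse, lt$t_exc_nrm, lt$t_pop_nrm)
  end_d <- ifelse(lt$relapse_observed,
                  pmin(lt$t_exc_dar, lt$t_pop_dar), first)
  end <- pmin(days_to_years(end_d), tau)
  e <- rexp(n) # fixed standard-exponential censoring draws
  frac <- function(rate) mean(e / rate < end)
  lo <- 0; hi <- 1
  while (frac(hi) < target && hi < 50) hi <- hi * 2
  if (frac(hi) < target) {
    stop("target censored fraction unreachable; attainable maximum ~ ",
         round(frac(hi), 3))
  }
  for (it in 1:60) {
    mid <- (lo + hi) / 2
    if (abs(frac(mid) - target) <= tol / 4) return(mid)
    if (frac(mid) < target) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}
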