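## ---------------------------------------------------------------------------
## Simulation scenario constants. All numeric defaults for the five study
## scenarios live here and nowhere else, so they can be audited or substituted
## in one place. Rates are per year; age effects are log-linear per year of
## age centred at the middle of the age range. The censoring rates were
## produced by calibrate_censoring() (target: 20% of subjects randomly
## censored within 10 years) and can be re-derived at any time.
## ---------------------------------------------------------------------------

law <- function(dist, rate, shape = 1, beta = 0) {
  list(dist = dist, rate = rate, shape = shape, beta = beta)
}

SCENARIOS <- list(
  exp.small = list(
    age_range = c(25, 45),
    relapse = law("exp", 0.08),
    excess_nrm = law("exp", 0.06),
    excess_dar = law("exp", 0.50),
    censor_rate = 0.03809
  ),
  exp.large = list(
    age_range = c(65, 85),
    relapse = law("exp", 0.08),
    excess_nrm = law("exp", 0.06),
    excess_dar = law("exp", 0.50),
    censor_rate = 0.04590
  ),
  weibull = list(
    age_range = c(25, 45),
    relapse = law("weibull", 0.10, 0.8),
    excess_nrm = law("weibull", 0.05, 1.2),
    excess_dar = law("weibull", 0.45, 0.9),
    censor_rate = 0.03809
  ),
  cov.eff.pos = list(
    age_range = c(25, 45),
    relapse = law("exp", 0.08, beta = 0.03),
    excess_nrm = law("exp", 0.06, beta = 0.03),
    excess_dar = law("exp", 0.50, beta = 0),
    censor_rate = 0.03906
  ),
  cov.eff.neg = list(
    age_range = c(25, 45),
    relapse = law("exp", 0.08, beta = -0.03),
    excess_nrm = law("exp", 0.06, beta = 0.03),
    excess_dar = law("exp", 0.50, beta = 0),
    censor_rate = 0.03809
  )
)

#' Built-in simulation scenarios
#'
#' Returns the configuration of one of the five study scenarios. Common to
#' all: sex is Bernoulli(0.5); the diagnosis date is Uniform over
#' [1990-01-01, 2000-01-01]; follow-up is administratively cut at 10 years;
#' the exponential censoring rate is calibrated so that about 20% of subjects
#' are randomly censored. The scenarios differ in the event-time laws of the
#' relapse, excess-NRM and excess-DaR transitions and in the age range, which
#' controls the share of population deaths:
#'
#' * `exp.small` — constant hazards, young cohort (few population deaths);
#' * `exp.large` — constant hazards, old cohort (population deaths comparable
#'   to excess deaths);
#' * `weibull` — Weibull hazards, young cohort;
#' * `cov.eff.pos` — constant baselines with positive age effects on relapse
#'   and excess NRM (none on excess DaR);
#' * `cov.eff.neg` — negative age effect on relapse, positive on excess NRM.
#'
#' @param name Scenario name.
#' @param ratetable Population ratetable used for population death times
#'   (default [synthetic_ratetable()]).
#' @return A `scenario_config` list: `name`, `age_range` (years),
#'   `sex_prob`, `year_range`, `relapse` / `excess_nrm` / `excess_dar`
#'   parametric laws (`dist`, `rate`, `shape`, `beta`), `censor_rate` (per
#'   year), `max_follow` (years), `ratetable`.
#' @export
make_scenario <- function(name = c("exp.small", "exp.large", "weibull",
                                   "cov.eff.pos", "cov.eff.neg"),
                          ratetable = synthetic_ratetable()) {
  name <- match.arg(name)
  sc <- SCENARIOS[[name]]
  structure(
    list(name = name, age_range = sc$age_range, sex_prob = 0.5,
         year_range = c(1990, 2000),
         relapse = sc$relapse, excess_nrm = sc$excess_nrm,
         excess_dar = sc$excess_dar,
         censor_rate = sc$censor_rate, max_follow = 10,
         ratetable = ratetable),
    class = "scenario_config"
  )
}

#' @export
print.scenario_config <- function(x, ...) {
  cat("<scenario_config> ", x$name, "\n", sep = "")
  cat("  age ~ U[", x$age_range[1], ", ", x$age_range[2], "], sex ~ Bern(",
      x$sex_prob, "), entry year ~ U[", x$year_range[1], ", ",
      x$year_range[2], ")\n", sep = "")
  fmt <- function(l, nm) {
    cat(sprintf("  %-10s %s(rate=%.3g%s)%s\n", nm, l$dist, l$rate,
                if (l$dist == "weibull") sprintf(", shape=%.3g", l$shape) else "",
                if (l$beta != 0) sprintf(" x exp(%.3g * age_c)", l$beta) else ""))
  }
  fmt(x$relapse, "relapse"); fmt(x$excess_nrm, "excess NRM")
  fmt(x$excess_dar, "excess DaR")
  cat("  censoring Exp(", x$censor_rate, "/yr), admin cutoff ",
      x$max_follow, " yr\n", sep = "")
  invisible(x)
}
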