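#' Number of simulation replications for a target coverage-probability SE
#'
#' The Monte-Carlo standard error of an estimated coverage probability `p`
#' over `nsim` replications is `sqrt(p (1 - p) / nsim)`; the smallest integer
#' achieving a required SE is `ceiling(p (1 - p) / se^2)`.
#'
#' @param p Expected coverage probability (0 < p < 1).
#' @param se Required standard error of the coverage estimate.
#' @return Integer number of replications.
#' @examples
#' nsim_for_cp_se(0.95, 0.005) # 1900
#' nsim_for_cp_se(0.95, 0.01)  # 475
#' @export
nsim_for_cp_se <- function(p, se) {
  stopifnot(p > 0, p < 1, se > 0)
  # tolerate floating-point fuzz so that exact ratios stay exact
  as.integer(ceiling(p * (1 - p) / se^2 - 1e-9))
}

#' Default evaluation targets: all occupation probabilities and hazards
#'
#' @param times Evaluation times in years.
#' @return Target tibble (times converted to days) for [bootstrap_msm()] /
#'   [run_replications()].
#' @export
default_targets <- function(times = c(1, 2, 5, 10)) {
  states <- c("ARF", "Relapse", "NRM.p", "NRM.e", "DaR.p", "DaR.e")
  haz <- tibble::tribble(
    ~from, ~to,
    "ARF", "Relapse",
    "ARF", "NRM.p",
    "ARF", "NRM.e",
    "Relapse", "DaR.p",
    "Relapse", "DaR.e"
  )
  dplyr::bind_rows(
    tidyr::expand_grid(measure = "P", from = "ARF", to = states,
                       time_years = times),
    tidyr::expand_grid(haz, time_years = times) |>
      dplyr::mutate(measure = "H", .before = 1)
  ) |>
    dplyr::mutate(time = years_to_days(.data$time_years))
}

## Point estimates and Greenwood variances for a target set, via the exported
## estimation path.
estimate_targets_full <- function(ds, rt, smap, targets, prob_variance = TRUE) {
  hz <- nelson_aalen(ds, times = unique(targets$time))
  ext <- split_hazards(hz, ds, rt, smap)
  pt <- aalen_johansen(ext, s = 0, variance = prob_variance)
  base <- unclass_hazards(ext)
  est <- numeric(nrow(targets))
  gwv <- rep(NA_real_, nrow(targets))
  states <- smap$extended$states
  trf <- smap$extended$transitions$from
  trt <- smap$extended$transitions$to
  for (k in seq_len(nrow(targets))) {
    if (targets$measure[k] == "P") {
      f <- match(targets$from[k], states)
      tt <- match(targets$to[k], states)
      pos <- findInterval(targets$time[k], pt$time)
      est[k] <- pt$P[f, tt, pos]
      if (!is.null(pt$var)) gwv[k] <- pt$var[f, tt, pos]
    } else {
      m <- which(states[trf] == targets$from[k] & states[trt] == targets$to[k])
      b <- base[base$trans == m, ]
      pos <- findInterval(targets$time[k], b$time)
      est[k] <- if (pos == 0) 0 else b$haz[pos]
      gwv[k] <- if (pos == 0) 0 else b$var[pos]
    }
  }
  list(est = est, gw_var = gwv)
}

CI_METHODS <- c("plain.G", "plain.boot", "log.boot", "q.boot",
                "logit.boot", "cloglog.boot")

safe_ci <- function(theta, variance, replicates, method, alpha) {
  tryCatch(
    confidence_interval(theta, variance = variance, replicates = replicates,
                        method = method, alpha = alpha),
    error = function(e) tibble::tibble(method = method, estimate = theta,
                                       lower = NA_real_, upper = NA_real_,
                                       alpha = alpha)
  )
}

#' Run a simulation performance study (bias, SE, coverage)
#'
#' Replicates the full pipeline `simulate -> estimate -> split -> transition
#' probabilities -> variances -> confidence intervals` and summarises
#' performance against the numerically integrated truth: mean estimate,
#' relative bias `(theta - mean) / theta`, empirical SE, mean Greenwood and
#' bootstrap SEs, and coverage probability per CI method. Replicate `i` uses
#' child seed `1000 * seed + i` (bootstrap stream: `10^9 + child`), so any
#' single replicate can be reproduced in isolation.
#'
#' @param cfg A [make_scenario()] configuration.
#' @param n Cohort size per replicate.
#' @param nsim Number of replications (>= 2).
#' @param B Bootstrap replicates per replication; `B = 0` skips the bootstrap
#'   (and all bootstrap-based CIs).
#' @param seed Parent seed.
#' @param times Evaluation times in years.
#' @param targets Target tibble (default [default_targets()]).
#' @param greenwood_prob_var Compute the Greenwood covariance recursion for
#'   transition probabilities (needed for `plain.G` coverage of
#'   probabilities)?
#' @param alpha CI significance level.
#' @param truth Optional precomputed [true_values()] table.
#' @return Object of class `msm_performance`: list with `summary` (one row
#'   per target), `estimates` (nsim x targets), `targets`, `nsim`, `n`,
#'   `seed`. `tidy()` returns the summary.
#' @export
run_replications <- function(cfg, n, nsim, B = 100, seed = 1,
                             times = c(1, 2, 5, 10), targets = NULL,
                             greenwood_prob_var = TRUE, alpha = 0.05,
                             truth = NULL) {
  stopifnot(nsim >= 2)
  if (is.null(targets)) targets <- default_targets(times)
  if (is.null(truth)) truth <- true_values(cfg, times = sort(unique(targets$time_years)))
  tg_truth <- dplyr::left_join(
    targets,
    dplyr::rename(truth, time_years = "time"),
    by = c("measure", "from", "to", "time_years")
  )
  if (anyNA(tg_truth$truth)) stop("no truth value for some target")
  smap <- extend_structure(illness_death_structure(), c("NRM", "DaR"))
  TT <- nrow(targets)
  est <- matrix(NA_real_, nsim, TT)
  gw_var <- matrix(NA_real_, nsim, TT)
  bt_var <- matrix(NA_real_, nsim, TT)
  cover <- array(NA, dim = c(length(CI_METHODS), nsim, TT),
                 dimnames = list(CI_METHODS, NULL, NULL))
  do_boot <- B >= 2
  n_failed <- 0L
  for (i in seq_len(nsim)) {
    child <- 1000 * seed + i
    res <- tryCatch({
      coh <- simulate_cohort(cfg, n, seed = child)
      ds <- coh$data
      eng <- make_boot_engine(ds, cfg$ratetable, smap, targets)
      det <- boot_fit_mult(eng, rep(1L, eng$n), detail = TRUE)
      gw <- engine_greenwood(eng, det, prob_variance = greenwood_prob_var)
      bvals <- NULL
      if (do_boot) {
        set.seed(10^9 + child)
        bvals <- matrix(NA_real_, B, TT)
        for (b in seq_len(B)) {
          sampled <- sample.int(eng$n, eng$n, replace = TRUE)
          bvals[b, ] <- boot_fit_mult(eng, tabulate(sampled, eng$n))
        }
      }
      list(est = det$values, gw = gw, bvals = bvals)
    }, error = function(e) NULL)
    if (is.null(res)) {
      n_failed <- n_failed + 1L
      next
    }
    est[i, ] <- res$est
    gw_var[i, ] <- res$gw
    if (do_boot) {
      bt_var[i, ] <- apply(res$bvals, 2, function(v) var(v[!is.na(v)]))
    }
    for (k in seq_len(TT)) {
      th <- est[i, k]
      tr <- tg_truth$truth[k]
      ci <- safe_ci(th, gw_var[i, k], NULL, "plain.G", alpha)
      cover["plain.G", i, k] <- !is.na(ci$lower) && ci$lower <= tr && tr <= ci$upper
      if (do_boot) {
        for (m in c("plain.boot", "log.boot", "logit.boot", "cloglog.boot")) {
          ci <- safe_ci(th, bt_var[i, k], NULL, m, alpha)
          cover[m, i, k] <- !is.na(ci$lower) && ci$lower <= tr && tr <= ci$upper
        }
        ci <- safe_ci(th, NULL, res$bvals[, k], "q.boot", alpha)
        cover["q.boot", i, k] <- !is.na(ci$lower) && ci$lower <= tr && tr <= ci$upper
      }
    }
  }
  cm <- function(x) colMeans(x, na.rm = TRUE)
  summary <- tg_truth |>
    dplyr::mutate(
      mean_est = cm(est),
      rel_bias = (.data$truth - .data$mean_est) / .data$truth,
      emp_se = apply(est, 2, stats::sd, na.rm = TRUE),
      mean_gw_se = cm(sqrt(gw_var)),
      mean_boot_se = if (do_boot) cm(sqrt(bt_var)) else NA_real_,
      nsim = nsim - n_failed, n = n, seed = seed
    )
  for (m in CI_METHODS) {
    summary[[paste0("cp_", gsub("\\.", "_", m))]] <-
      apply(cover[m, , , drop = FALSE], 3, mean, na.rm = TRUE)
  }
  structure(list(summary = summary, estimates = est, gw_var = gw_var,
                 boot_var = bt_var, cover = cover, targets = tg_truth,
                 nsim = nsim, n = n, seed = seed, n_failed = n_failed),
            class = "msm_performance")
}

#' @export
tidy.msm_performance <- function(x, ...) x$summary

#' @export
glance.msm_performance <- function(x, ...) {
  tibble::tibble(nsim = x$nsim, n = x$n, seed = x$seed, n_failed = x$n_failed,
                 max_abs_rel_bias = max(abs(x$summary$rel_bias)))
}

#' @export
print.msm_performance <- function(x, ...) {
  cat("<msm_performance> ", x$nsim, " replications, n = ", x$n,
      ", ", nrow(x$summary), " targets",
      if (x$n_failed) paste0(", ", x$n_failed, " failed") else "", "\n",
      sep = "")
  print(dplyr::select(x$summary, "measure", "from", "to", "time_years",
                      "truth", "mean_est", "rel_bias", "emp_se"))
  invisible(x)
}
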