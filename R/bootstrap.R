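#' Describe bootstrap / evaluation targets
#'
#' A target is either a transition probability `P(from -> to at time t)` from
#' start time 0 (state occupation probability when all subjects start in the
#' first state), or a cumulative transition hazard at time `t` for an extended
#' transition.
#'
#' @param measure `"P"` (probability) or `"H"` (cumulative hazard).
#' @param from,to State labels in the extended state space.
#' @param time Evaluation time in days.
#' @return A tibble usable as the `targets` argument of [bootstrap_msm()].
#' @export
msm_target <- function(measure, from, to, time) {
  tibble::tibble(measure = measure, from = from, to = to, time = time)
}

## ---- fast estimation path -------------------------------------------------
## Minimal-overhead re-estimation used inside the bootstrap loop. A resample
## of subjects is represented by a multiplicity vector (how often each
## subject was drawn); since risk intervals, event times and each subject's
## daily population-hazard trajectory are all invariant under resampling,
## every replicate reduces to weighted aggregations of precomputed
## structures (one matrix-vector product per split departure state). The
## estimates are evaluated on the pooled event-time grid of the original
## dataset (a superset of each replicate's own event times, which leaves all
## cumulative quantities at target times unchanged). With multiplicities all
## equal to one this path reproduces nelson_aalen() + split_hazards() +
## aalen_johansen() exactly (asserted in the test suite).

## Precompute everything that is invariant under resampling of subjects.
make_boot_engine <- function(ds, rt, smap, targets) {
  st_orig <- smap$original
  st_ext <- smap$extended
  rec <- ds$records
  prof <- ds$profiles
  subj <- match(rec$id, prof$id)
  if (anyNA(subj)) stop("record subject without a profile")
  n <- nrow(prof)
  grid <- sort(unique(c(rec$Tstop[rec$status == 1], targets$time)))
  grid <- grid[grid > 0]
  G <- length(grid)
  n_days <- ceiling(max(grid))
  M <- nrow(st_orig$transitions)
  per_trans <- lapply(seq_len(M), function(m) {
    r <- which(rec$trans == m)
    tstart <- rec$Tstart[r]; tstop <- rec$Tstop[r]
    ev <- which(rec$status[r] == 1)
    list(
      subj = subj[r],
      # risk-interval bounds on the grid: at risk at grid g iff a <= g <= b
      a = findInterval(tstart, grid) + 1L,
      b = findInterval(tstop, grid),
      ev_subj = subj[r][ev],
      ev_gidx = match(tstop[ev], grid)
    )
  })
  split_from <- unique(st_orig$transitions$from[
    unique(smap$map$orig_trans[smap$map$kind != "observed"])])
  rep_trans <- vapply(split_from, function(h) {
    st_orig$transitions$trans[st_orig$transitions$from == h][1]
  }, numeric(1))
  pop_pre <- lapply(rep_trans, function(m) {
    r <- which(rec$trans == m)
    tstart <- rec$Tstart[r]; tstop <- rec$Tstop[r]
    s <- subj[r]
    # day-level at-risk bounds: whole days ceil(tstart) .. floor(tstop - 1)
    d0 <- pmax(ceiling(tstart), 0)
    d1 <- pmin(floor(tstop - 1), n_days - 1)
    Hmask <- cpp_masked_hazard(
      prof$age[s] * DAYS_PER_YEAR, prof$year[s],
      sex_index(rt, prof$sex[s]) - 1L,
      as.integer(d0), as.integer(d1),
      as.vector(rt$hazard), length(rt$ages), length(rt$years),
      rt$ages[1], rt$years[1], n_days, DAYS_PER_YEAR
    )
    list(subj = s, d0 = d0, d1 = d1, Hmask = Hmask)
  })
  names(pop_pre) <- as.character(split_from)
  gmap <- day_to_grid(n_days, grid)
  tf <- match(targets$from, st_ext$states)
  tt <- match(targets$to, st_ext$states)
  if (anyNA(tf) || anyNA(tt)) stop("target uses unknown extended state")
  ext_from_label <- st_ext$states[st_ext$transitions$from]
  ext_to_label <- st_ext$states[st_ext$transitions$to]
  h_target_trans <- rep(NA_integer_, nrow(targets))
  ish <- targets$measure == "H"
  h_target_trans[ish] <- vapply(which(ish), function(k) {
    m <- which(ext_from_label == targets$from[k] & ext_to_label == targets$to[k])
    if (length(m) != 1) stop("hazard target does not match one extended transition")
    m
  }, integer(1))
  list(
    n = n, grid = grid, G = G, n_days = n_days, gmap = gmap,
    per_trans = per_trans, pop_pre = pop_pre,
    st_orig = st_orig, st_ext = st_ext, map = smap$map,
    split_from = split_from, rep_trans = rep_trans,
    targets = targets, tf = tf, tt = tt, h_target_trans = h_target_trans,
    tpos = match(targets$time, grid)
  )
}

## weighted interval counts via the difference trick
interval_count <- function(a, b, w, len) {
  d <- numeric(len + 1)
  ok <- a <= b & w > 0
  if (any(ok)) {
    up <- rowsum(w[ok], a[ok])
    d[as.integer(rownames(up))] <- up[, 1]
    dn <- rowsum(w[ok], b[ok] + 1L)
    i <- as.integer(rownames(dn))
    d[i] <- d[i] - dn[, 1]
  }
  cumsum(d[seq_len(len)])
}

## Estimate all targets for one multiplicity vector (length n subjects).
## With detail = TRUE, also return the grid-level internals needed for the
## Greenwood variance computations.
boot_fit_mult <- function(eng, mult, detail = FALSE) {
  G <- eng$G
  M <- length(eng$per_trans)
  obs_haz <- matrix(0, G, M)
  obs_dN <- matrix(0, G, M)
  obs_Y <- matrix(0, G, M)
  for (m in seq_len(M)) {
    pt <- eng$per_trans[[m]]
    w <- mult[pt$subj]
    Y <- interval_count(pt$a, pt$b, w, G)
    dN <- numeric(G)
    wev <- mult[pt$ev_subj]
    if (length(wev)) {
      agg <- rowsum(wev, pt$ev_gidx)
      dN[as.integer(rownames(agg))] <- agg[, 1]
    }
    obs_dN[, m] <- dN
    obs_Y[, m] <- Y
    obs_haz[, m] <- cumsum(ifelse(dN > 0, dN / Y, 0))
  }
  pop_haz <- lapply(eng$pop_pre, function(pp) {
    w <- mult[pp$subj]
    num <- as.vector(pp$Hmask %*% w)
    den <- interval_count(pp$d0 + 1L, pp$d1 + 1L, w, eng$n_days)
    inc_day <- ifelse(den > 0, num / den, 0)
    ok <- !is.na(eng$gmap) & inc_day != 0
    inc_grid <- numeric(G)
    if (any(ok)) {
      agg <- rowsum(inc_day[ok], eng$gmap[ok])
      inc_grid[as.integer(rownames(agg))] <- agg[, 1]
    }
    cumsum(inc_grid)
  })
  Mx <- nrow(eng$map)
  ext_haz <- matrix(0, G, Mx)
  for (k in seq_len(Mx)) {
    ot <- eng$map$orig_trans[k]
    kind <- eng$map$kind[k]
    if (kind == "observed") {
      ext_haz[, k] <- obs_haz[, ot]
    } else {
      pop <- pop_haz[[as.character(eng$st_orig$transitions$from[ot])]]
      ext_haz[, k] <- if (kind == "population") pop else obs_haz[, ot] - pop
    }
  }
  K <- length(eng$st_ext$states)
  dL <- rbind(ext_haz[1, ], diff(ext_haz))
  P <- cpp_prod_integral(dL, eng$st_ext$transitions$from,
                         eng$st_ext$transitions$to, K)
  tg <- eng$targets
  out <- numeric(nrow(tg))
  for (k in seq_len(nrow(tg))) {
    out[k] <- if (tg$measure[k] == "P") {
      P[eng$tf[k], eng$tt[k], eng$tpos[k]]
    } else {
      ext_haz[eng$tpos[k], eng$h_target_trans[k]]
    }
  }
  if (detail) {
    return(list(values = out, ext_haz = ext_haz, dL = dL,
                obs_dN = obs_dN, obs_Y = obs_Y, P = P))
  }
  out
}

## Greenwood variances for all targets, from the detail of boot_fit_mult():
## population transitions have zero variance; excess transitions inherit the
## Greenwood series of their observed counterpart; transition probabilities
## use the covariance recursion of the product integral.
engine_greenwood <- function(eng, det, prob_variance = TRUE) {
  Mx <- nrow(eng$map)
  kind <- eng$map$kind
  ot <- eng$map$orig_trans
  gw_haz <- matrix(0, eng$G, Mx)
  dN_ext <- matrix(0, eng$G, Mx)
  Y_ext <- matrix(0, eng$G, Mx)
  for (k in seq_len(Mx)) {
    if (kind[k] != "population") {
      dN_ext[, k] <- det$obs_dN[, ot[k]]
      Y_ext[, k] <- det$obs_Y[, ot[k]]
      gw_haz[, k] <- cumsum(greenwood_increments(det$obs_dN[, ot[k]],
                                                 det$obs_Y[, ot[k]]))
    }
  }
  Varr <- NULL
  if (prob_variance) {
    Varr <- probtrans_var_recursion(det$dL, dN_ext, Y_ext, kind,
                                    eng$st_ext$transitions$from,
                                    eng$st_ext$transitions$to,
                                    length(eng$st_ext$states))
  }
  tg <- eng$targets
  out <- rep(NA_real_, nrow(tg))
  for (k in seq_len(nrow(tg))) {
    if (tg$measure[k] == "H") {
      out[k] <- gw_haz[eng$tpos[k], eng$h_target_trans[k]]
    } else if (prob_variance) {
      out[k] <- Varr[eng$tf[k], eng$tt[k], eng$tpos[k]]
    }
  }
  out
}

#' Non-parametric bootstrap over subjects for split multi-state estimates
#'
#' Resamples subjects (all their records and their demographic profile travel
#' together) with replacement, re-runs the full estimation pipeline
#' (Nelson-Aalen, population/excess split, extended product integral) and
#' records each target quantity per replicate. Replicates for which a target
#' is undefined (empty risk sets) are recorded as `NA` and the count reported.
#'
#' @param ds An [msm_data()] with profiles.
#' @param rt A [ratetable_grid()].
#' @param smap A [extend_structure()] split map.
#' @param targets Target descriptors from [msm_target()].
#' @param B Number of bootstrap replicates (default 100).
#' @param seed Optional integer seed for reproducibility.
#' @return Object of class `msm_bootstrap`: list with `targets`, `values`
#'   (B x n_targets matrix), `B`, `seed`, `n_missing` per target.
#' @export
bootstrap_msm <- function(ds, rt, smap, targets, B = 100, seed = NULL) {
  stopifnot(B >= 2, inherits(ds, "msm_data"))
  if (!is.null(seed)) set.seed(seed)
  eng <- make_boot_engine(ds, rt, smap, targets)
  values <- matrix(NA_real_, B, nrow(targets))
  for (b in seq_len(B)) {
    sampled <- sample.int(eng$n, eng$n, replace = TRUE)
    values[b, ] <- boot_fit_mult(eng, tabulate(sampled, eng$n))
  }
  structure(list(targets = targets, values = values, B = B, seed = seed,
                 n_missing = colSums(is.na(values))),
            class = "msm_bootstrap")
}

#' @export
print.msm_bootstrap <- function(x, ...) {
  cat("<msm_bootstrap> B = ", x$B, ", ", nrow(x$targets), " target(s), ",
      sum(x$n_missing), " missing replicate value(s)\n", sep = "")
  invisible(x)
}

#' @export
tidy.msm_bootstrap <- function(x, ...) {
  tg <- x$targets
  dplyr::bind_rows(lapply(seq_len(nrow(tg)), function(k) {
    tibble::tibble(measure = tg$measure[k], from = tg$from[k], to = tg$to[k],
                   time = tg$time[k], replicate = seq_len(x$B),
                   value = x$values[, k])
  }))
}

#' Bootstrap variance per target
#'
#' Sample variance of the replicate values (denominator `B - 1`), `NA`
#' replicates excluded.
#'
#' @param x An `msm_bootstrap` object (or a numeric vector of replicates).
#' @return Numeric vector of variances, one per target.
#' @export
boot_variance <- function(x) {
  if (is.numeric(x)) return(var(x[!is.na(x)]))
  apply(x$values, 2, function(v) var(v[!is.na(v)]))
}
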