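## Map each whole day (u, u+1] (u = 0-based) to the first grid point >= u + 1.
## Days beyond the last grid point are dropped (NA).
day_to_grid <- function(n_days, grid) {
  idx <- findInterval(seq_len(n_days), grid, left.open = TRUE) + 1L
  idx[idx > length(grid)] <- NA_integer_
  idx
}

## Population cumulative hazard increments on the grid for one departure
## state, from the daily lattice: d(u) = sum_i Y_i(u) dLambda_Pi(u) / Y(u),
## lumped onto the next grid point. subj0 is the 0-based row of each record's
## subject in `profiles`.
pop_hazard_on_grid <- function(tstart, tstop, subj0, rt, profiles, grid) {
  n_days <- ceiling(max(grid))
  daily <- cpp_pop_daily(
    tstart, tstop, subj0,
    profiles$age * DAYS_PER_YEAR, profiles$year,
    sex_index(rt, profiles$sex) - 1L,
    as.vector(rt$hazard), length(rt$ages), length(rt$years),
    rt$ages[1], rt$years[1], n_days, DAYS_PER_YEAR
  )
  inc_day <- ifelse(daily$den > 0, daily$num / daily$den, 0)
  gmap <- day_to_grid(n_days, grid)
  ok <- !is.na(gmap) & inc_day > 0
  inc_grid <- numeric(length(grid))
  if (any(ok)) {
    agg <- rowsum(inc_day[ok], gmap[ok])
    inc_grid[as.integer(rownames(agg))] <- agg[, 1]
  }
  cumsum(inc_grid)
}

#' Population cumulative hazard for the transitions out of one state
#'
#' Estimates `Lambda_P(t) = int_0^t sum_i Y_i(u) dLambda_Pi(u) / Y(u)` for the
#' departure state `from`, where each subject's daily population hazard
#' `dLambda_Pi(u)` follows their own attained age and calendar date at study
#' time `u` (ratetable matching), and `Y_i` is the subject's at-risk indicator
#' for that state. Accumulation is on the daily lattice; the result is
#' reported on `grid`, with between-grid mass lumped onto the next grid point.
#'
#' @param ds An [msm_data()] object with profiles.
#' @param rt A [ratetable_grid()].
#' @param from Departure state label.
#' @param grid Evaluation times (days, sorted).
#' @return A tibble `time`, `haz` (cumulative population hazard).
#' @export
population_hazard <- function(ds, rt, from, grid) {
  stopifnot(inherits(ds, "msm_data"), !is.null(ds$profiles))
  st <- ds$structure
  h <- match(from, st$states)
  if (is.na(h)) stop("unknown state: ", from)
  m <- st$transitions$trans[st$transitions$from == h][1]
  if (is.na(m)) stop("state ", from, " has no outgoing transition")
  rec <- ds$records[ds$records$trans == m, ]
  subj <- match(rec$id, ds$profiles$id)
  if (anyNA(subj)) stop("subject at risk without a demographic profile")
  tibble::tibble(time = grid,
                 haz = pop_hazard_on_grid(rec$Tstart, rec$Tstop, subj - 1L,
                                          rt, ds$profiles, grid))
}

#' Split transition hazards into population and excess parts
#'
#' Implements the additive decomposition for every transition into a split
#' death state: the population part is the risk-set-weighted ratetable hazard
#' accumulated on the daily lattice, and the excess part is the Nelson-Aalen
#' estimate minus the population part, so that
#' `haz_population + haz_excess = haz_observed` holds exactly at every grid
#' point. Excess increments may be negative (population hazard exceeding the
#' observed one); they are retained by default.
#'
#' Under the Greenwood variance option the population transitions are treated
#' as fixed (variance zero) and each excess transition inherits the Greenwood
#' variance of its observed counterpart.
#'
#' @param hz An `msm_hazards` object from [nelson_aalen()] on the original
#'   structure.
#' @param ds The [msm_data()] the hazards were estimated from (with profiles).
#' @param rt A [ratetable_grid()].
#' @param smap A [extend_structure()] split map.
#' @param eval `"event"` (default) evaluates on the pooled event-time grid;
#'   `"daily"` adds the whole daily lattice to the grid.
#' @param clamp_negative If `TRUE`, cumulative excess hazards are clamped at 0
#'   and a message reports how many grid values were raised. Default `FALSE`
#'   (negative values retained, to be interpreted with caution).
#' @return An `msm_hazards` tibble on the extended structure with `kind` in
#'   `"observed"`, `"population"`, `"excess"`.
#' @export
split_hazards <- function(hz, ds, rt, smap, eval = c("event", "daily"),
                          clamp_negative = FALSE) {
  eval <- match.arg(eval)
  stopifnot(inherits(hz, "msm_hazards"), inherits(smap, "split_map"),
            !is.null(ds$profiles))
  grid <- attr(hz, "grid")
  ev_times <- unique(ds$records$Tstop[ds$records$status == 1])
  if (!all(ev_times %in% grid)) {
    stop("hazard grid must contain all event times of the dataset")
  }
  if (eval == "daily") {
    grid2 <- sort(unique(c(grid, seq_len(ceiling(max(grid))))))
    hz <- regrid_hazards(hz, grid2)
    grid <- grid2
  }
  st_orig <- smap$original
  st_ext <- smap$extended
  split_orig <- unique(smap$map$orig_trans[smap$map$kind != "observed"])
  from_states <- unique(st_orig$transitions$from[split_orig])
  pop_by_state <- lapply(from_states, function(h) {
    m <- st_orig$transitions$trans[st_orig$transitions$from == h][1]
    rec <- ds$records[ds$records$trans == m, ]
    subj <- match(rec$id, ds$profiles$id)
    if (anyNA(subj)) stop("subject at risk without a demographic profile")
    pop_hazard_on_grid(rec$Tstart, rec$Tstop, subj - 1L, rt, ds$profiles, grid)
  })
  names(pop_by_state) <- as.character(from_states)

  base <- unclass_hazards(hz)
  rows <- lapply(seq_len(nrow(smap$map)), function(k) {
    et <- smap$map$ext_trans[k]
    ot <- smap$map$orig_trans[k]
    kind <- smap$map$kind[k]
    obs <- base[base$trans == ot, ]
    out <- obs
    out$trans <- et
    out$from <- st_ext$states[st_ext$transitions$from[et]]
    out$to <- st_ext$states[st_ext$transitions$to[et]]
    out$kind <- kind
    if (kind != "observed") {
      pop <- pop_by_state[[as.character(st_orig$transitions$from[ot])]]
      if (kind == "population") {
        out$haz <- pop
        out$var <- 0
        out$n_event <- NA_integer_
        out$n_risk <- NA_integer_
      } else {
        exc <- obs$haz - pop
        if (clamp_negative) {
          n_neg <- sum(exc < 0)
          if (n_neg > 0) {
            message("clamped ", n_neg, " negative cumulative excess hazard values to 0")
            exc <- pmax(exc, 0)
          }
        }
        out$haz <- exc
      }
    }
    out
  })
  new_msm_hazards(dplyr::bind_rows(rows), st_ext, grid, smap = smap)
}

## Re-express a hazards object on a finer grid (step interpolation; the new
## grid must contain the old one).
regrid_hazards <- function(hz, grid2) {
  st <- attr(hz, "structure")
  grid <- attr(hz, "grid")
  stopifnot(all(grid %in% grid2))
  pos <- findInterval(grid2, grid)
  base <- unclass_hazards(hz)
  rows <- lapply(unique(base$trans), function(m) {
    b <- base[base$trans == m, ]
    out <- b[rep(1, length(grid2)), ]
    out$time <- grid2
    out$haz <- c(0, b$haz)[pos + 1]
    out$var <- c(0, b$var)[pos + 1]
    out$n_event <- 0L
    out$n_event[match(grid, grid2)] <- b$n_event
    Y <- count_lt_rec(hz, m, grid2)
    out$n_risk <- Y
    out
  })
  new_msm_hazards(dplyr::bind_rows(rows), st, grid2, smap = attr(hz, "smap"))
}

## risk-set size is not recoverable from the hazard object alone; carry the
## old values forward (exact at old grid points, last-value elsewhere).
count_lt_rec <- function(hz, m, grid2) {
  base <- unclass_hazards(hz)
  b <- base[base$trans == m, ]
  pos <- findInterval(grid2, b$time)
  c(b$n_risk[1], b$n_risk)[pos + 1]
}
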