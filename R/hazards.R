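new_msm_hazards <- function(df, structure, grid, smap = NULL) {
  tibble::new_tibble(df, structure = structure, grid = grid, smap = smap,
                     class = "msm_hazards")
}

#' @export
tidy.msm_hazards <- function(x, ...) {
  tibble::as_tibble(unclass_hazards(x))
}

unclass_hazards <- function(x) {
  attr(x, "structure") <- NULL
  attr(x, "grid") <- NULL
  attr(x, "smap") <- NULL
  class(x) <- c("tbl_df", "tbl", "data.frame")
  x
}

#' @export
glance.msm_hazards <- function(x, ...) {
  st <- attr(x, "structure")
  tibble::tibble(
    n_states = length(st$states),
    n_transitions = dplyr::n_distinct(x$trans),
    n_grid = length(attr(x, "grid")),
    max_time = max(x$time),
    kinds = paste(sort(unique(x$kind)), collapse = ",")
  )
}

## dN and Y on the common grid for one transition's records
risk_on_grid <- function(tstart, tstop, status, grid) {
  ev <- tstop[status == 1]
  dN <- integer(length(grid))
  if (length(ev)) {
    idx <- match(ev, grid)
    if (anyNA(idx)) stop("grid does not contain all event times")
    tab <- table(idx)
    dN[as.integer(names(tab))] <- as.integer(tab)
  }
  Y <- count_lt(tstart, grid) - count_lt(tstop, grid)
  list(dN = dN, Y = as.integer(Y))
}

## Greenwood increments for a cumulative hazard; Y == dN increments fall back
## to the Aalen form 1/Y with a warning.
greenwood_increments <- function(dN, Y) {
  inc <- numeric(length(dN))
  pos <- dN > 0
  deg <- pos & (Y == dN)
  ok <- pos & !deg
  inc[ok] <- dN[ok] / (Y[ok] * (Y[ok] - dN[ok]))
  if (any(deg)) {
    warning("risk set exhausted at ", sum(deg),
            " event time(s); Aalen-form variance increment 1/Y used")
    inc[deg] <- 1 / Y[deg]
  }
  inc
}

#' Nelson-Aalen cumulative transition hazards
#'
#' Estimates the cumulative hazard of every transition as the sum of
#' `dN(u) / Y(u)` over event times, with the Greenwood variance
#' `sum dN / (Y (Y - dN))`. All transitions are reported on the pooled grid of
#' distinct event times (plus any requested extra times), constant between
#' their own events.
#'
#' @param ds An [msm_data()] object.
#' @param times Optional extra evaluation times to include in the grid.
#' @return An `msm_hazards` tibble: `trans`, `from`, `to` (state labels),
#'   `time`, `haz`, `var`, `n_event`, `n_risk`, `kind = "observed"`.
#' @examples
#' ds <- msm_data(
#'   tibble::tibble(id = 1:3, trans = 1, Tstart = 0, Tstop = c(1, 2, 3),
#'                  status = c(1, 1, 0)),
#'   transition_structure(data.frame(from = "alive", to = "dead"))
#' )
#' nelson_aalen(ds)
#' @export
nelson_aalen <- function(ds, times = NULL) {
  stopifnot(inherits(ds, "msm_data"))
  rec <- ds$records
  st <- ds$structure
  grid <- sort(unique(c(rec$Tstop[rec$status == 1], times)))
  grid <- grid[grid > 0]
  rows <- lapply(st$transitions$trans, function(m) {
    r <- rec[rec$trans == m, ]
    rg <- risk_on_grid(r$Tstart, r$Tstop, r$status, grid)
    inc <- ifelse(rg$dN > 0, rg$dN / rg$Y, 0)
    tibble::tibble(
      trans = m,
      from = st$states[st$transitions$from[m]],
      to = st$states[st$transitions$to[m]],
      time = grid,
      haz = cumsum(inc),
      var = cumsum(greenwood_increments(rg$dN, rg$Y)),
      n_event = rg$dN,
      n_risk = rg$Y,
      kind = "observed"
    )
  })
  new_msm_hazards(dplyr::bind_rows(rows), st, grid)
}

#' Greenwood variance of a Nelson-Aalen cumulative hazard
#'
#' Convenience wrapper applying the Greenwood formula
#' `sum_{u <= t} dN(u) / (Y(u) (Y(u) - dN(u)))` to a risk-set series as
#' produced by [risk_sets()].
#'
#' @param rs A data frame with columns `time`, `n_risk`, `n_event`.
#' @return A tibble `time`, `var` (cumulative variance).
#' @export
greenwood_var_hazard <- function(rs) {
  tibble::tibble(time = rs$time,
                 var = cumsum(greenwood_increments(rs$n_event, rs$n_risk)))
}
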