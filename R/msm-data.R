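#' Bundle long-format multi-state records with a structure and profiles
#'
#' @param records Data frame with one row per subject x possible transition:
#'   columns `id`, `trans` (transition number), `Tstart`, `Tstop` (days),
#'   `status` (1 if the transition happened at `Tstop`, 0 otherwise). Rows for
#'   transitions sharing a departure state must carry identical
#'   `(Tstart, Tstop)` per subject.
#' @param structure A [transition_structure()].
#' @param profiles Optional data frame of demographic profiles: `id`, `age`
#'   (years at study entry), `sex`, `year` (decimal calendar year of entry).
#'   Required for any relative-survival splitting.
#' @return An object of class `msm_data`.
#' @export
msm_data <- function(records, structure, profiles = NULL) {
  records <- tibble::as_tibble(records)
  stopifnot(all(c("id", "trans", "Tstart", "Tstop", "status") %in% names(records)))
  if (!is.null(profiles)) {
    profiles <- tibble::as_tibble(profiles)
    stopifnot(all(c("id", "age", "sex", "year") %in% names(profiles)))
  }
  out <- structure(list(records = records, structure = structure,
                        profiles = profiles),
                   class = "msm_data")
  out
}

#' @export
print.msm_data <- function(x, ...) {
  cat("<msm_data> ", dplyr::n_distinct(x$records$id), " subjects, ",
      nrow(x$records), " records, ",
      sum(x$records$status), " events\n", sep = "")
  invisible(x)
}

#' Check a multi-state dataset against its structural rules
#'
#' Reports (rather than errors on) violations of the long-format contract:
#' valid transition numbers, `Tstart < Tstop`, at most one event per subject
#' per departure state, and identical risk intervals across the competing
#' transitions out of one state.
#'
#' @param ds An [msm_data()] object.
#' @return A tibble with columns `id`, `trans`, `rule`; zero rows when the
#'   dataset is well formed.
#' @export
validate_msm_data <- function(ds) {
  rec <- ds$records
  tr <- ds$structure$transitions
  out <- list()
  bad <- !(rec$trans %in% tr$trans)
  if (any(bad)) {
    out[[length(out) + 1]] <- tibble::tibble(
      id = rec$id[bad], trans = rec$trans[bad], rule = "unknown transition number")
  }
  bad <- !(rec$Tstart < rec$Tstop)
  if (any(bad)) {
    out[[length(out) + 1]] <- tibble::tibble(
      id = rec$id[bad], trans = rec$trans[bad], rule = "Tstart must be < Tstop")
  }
  rec2 <- dplyr::inner_join(rec, tr, by = "trans")
  ev <- rec2 |>
    dplyr::group_by(.data$id, .data$from) |>
    dplyr::summarise(n_event = sum(.data$status),
                     n_interval = dplyr::n_distinct(.data$Tstart, .data$Tstop),
                     .groups = "drop")
  bad <- ev$n_event > 1
  if (any(bad)) {
    out[[length(out) + 1]] <- tibble::tibble(
      id = ev$id[bad], trans = NA_integer_,
      rule = "more than one event out of a departure state")
  }
  bad <- ev$n_interval > 1
  if (any(bad)) {
    out[[length(out) + 1]] <- tibble::tibble(
      id = ev$id[bad], trans = NA_integer_,
      rule = "competing transitions with differing (Tstart, Tstop]")
  }
  if (!is.null(ds$profiles)) {
    bad <- !(rec$id %in% ds$profiles$id)
    if (any(bad)) {
      out[[length(out) + 1]] <- tibble::tibble(
        id = unique(rec$id[bad]), trans = NA_integer_,
        rule = "record without a demographic profile")
    }
  }
  if (length(out) == 0) {
    return(tibble::tibble(id = integer(), trans = integer(), rule = character()))
  }
  dplyr::distinct(dplyr::bind_rows(out))
}

## count of v strictly below each t (v sorted not required)
count_lt <- function(v, t) findInterval(t, sort(v), left.open = TRUE)

#' Risk sets and event counts for one transition
#'
#' Event times are the distinct `Tstop` with `status = 1` for the transition;
#' the risk set counts records with `Tstart < u <= Tstop` (delayed entry
#' excluded at the entry time, events included at the exit time).
#'
#' @param ds An [msm_data()] object.
#' @param trans Transition number.
#' @return A tibble `time`, `n_risk`, `n_event`; zero rows if the transition
#'   has no events.
#' @export
risk_sets <- function(ds, trans) {
  stopifnot(trans %in% ds$structure$transitions$trans)
  rec <- ds$records[ds$records$trans == trans, ]
  times <- sort(unique(rec$Tstop[rec$status == 1]))
  if (length(times) == 0) {
    return(tibble::tibble(time = numeric(), n_risk = integer(), n_event = integer()))
  }
  n_event <- vapply(times, function(t) sum(rec$status == 1 & rec$Tstop == t),
                    integer(1))
  n_risk <- count_lt(rec$Tstart, times) - count_lt(rec$Tstop, times)
  tibble::tibble(time = times, n_risk = as.integer(n_risk), n_event = n_event)
}
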