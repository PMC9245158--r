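#' Transition structure of a multi-state model
#'
#' Defines the state space and the numbered transitions of a Markov
#' multi-state model. States are ordered labels; transitions are ordered
#' `from -> to` pairs numbered densely `1..M`. States with no outgoing
#' transition are absorbing.
#'
#' @param transitions A data frame with columns `from` and `to` holding state
#'   labels (or a two-column matrix). Transition numbers are row order.
#' @param states Optional character vector fixing the state order; defaults to
#'   the order of first appearance in `transitions`.
#' @return An object of class `transition_structure`: list with `states`,
#'   `transitions` (tibble `trans`, `from`, `to` as integer state indices),
#'   and `absorbing` (logical per state).
#' @examples
#' illness_death_structure()
#' @export
transition_structure <- function(transitions, states = NULL) {
  transitions <- tibble::as_tibble(as.data.frame(transitions))
  stopifnot(all(c("from", "to") %in% names(transitions)))
  if (is.null(states)) {
    states <- unique(c(rbind(as.character(transitions$from),
                             as.character(transitions$to))))
  }
  from <- match(as.character(transitions$from), states)
  to <- match(as.character(transitions$to), states)
  if (anyNA(from) || anyNA(to)) stop("transition uses a state not in `states`")
  if (any(from == to)) stop("self-transitions are not allowed")
  tr <- tibble::tibble(trans = seq_along(from), from = from, to = to)
  if (anyDuplicated(tr[c("from", "to")])) stop("duplicated transition")
  absorbing <- !(seq_along(states) %in% from)
  out <- structure(list(states = states, transitions = tr, absorbing = absorbing),
                   class = "transition_structure")
  out
}

#' @export
print.transition_structure <- function(x, ...) {
  cat("<transition_structure> ", length(x$states), " states, ",
      nrow(x$transitions), " transitions\n", sep = "")
  for (k in seq_len(nrow(x$transitions))) {
    cat(sprintf("  %d: %s -> %s\n", k,
                x$states[x$transitions$from[k]], x$states[x$transitions$to[k]]))
  }
  cat("  absorbing:", paste(x$states[x$absorbing], collapse = ", "), "\n")
  invisible(x)
}

#' The illness-death structure with separate pre- and post-relapse death
#'
#' Four states: alive relapse-free (ARF), relapse, non-relapse mortality
#' (NRM) and death after relapse (DaR); three transitions ARF->Relapse,
#' ARF->NRM, Relapse->DaR.
#'
#' @return A [transition_structure()].
#' @export
illness_death_structure <- function() {
  transition_structure(
    tibble::tribble(
      ~from, ~to,
      "ARF", "Relapse",
      "ARF", "NRM",
      "Relapse", "DaR"
    ),
    states = c("ARF", "Relapse", "NRM", "DaR")
  )
}

#' Split death states into population and excess counterparts
#'
#' Builds the extended state space in which every selected (absorbing) death
#' state is replaced by a population and an excess death state, and every
#' transition into it by a pair of transitions carrying the population and
#' excess parts of the hazard. Non-split transitions map to themselves.
#'
#' @param structure A [transition_structure()].
#' @param death_states Character vector of state labels to split. Each must be
#'   absorbing.
#' @return An object of class `split_map`: list with `original`, `extended`
#'   (both [transition_structure()]), and `map`, a tibble with one row per
#'   extended transition: `ext_trans`, `orig_trans`, and
#'   `kind` in `"observed"`, `"population"`, `"excess"`.
#' @examples
#' extend_structure(illness_death_structure(), c("NRM", "DaR"))
#' @export
extend_structure <- function(structure, death_states = character()) {
  stopifnot(inherits(structure, "transition_structure"))
  di <- match(death_states, structure$states)
  if (anyNA(di)) stop("unknown death state(s)")
  if (any(!structure$absorbing[di])) {
    stop("death state(s) not absorbing: ",
         paste(death_states[!structure$absorbing[di]], collapse = ", "))
  }
  ext_states <- unlist(lapply(seq_along(structure$states), function(s) {
    if (s %in% di) paste0(structure$states[s], c(".p", ".e")) else structure$states[s]
  }))
  state_of <- function(s) { # original index -> extended index of same label
    match(structure$states[s], ext_states)
  }
  rows <- list()
  for (k in seq_len(nrow(structure$transitions))) {
    from <- structure$transitions$from[k]
    to <- structure$transitions$to[k]
    if (to %in% di) {
      rows[[length(rows) + 1]] <- tibble::tibble(
        orig_trans = k,
        from = structure$states[from],
        to = paste0(structure$states[to], c(".p", ".e")),
        kind = c("population", "excess")
      )
    } else {
      rows[[length(rows) + 1]] <- tibble::tibble(
        orig_trans = k,
        from = structure$states[from],
        to = structure$states[to],
        kind = "observed"
      )
    }
  }
  rows <- dplyr::bind_rows(rows)
  extended <- transition_structure(rows[c("from", "to")], states = ext_states)
  map <- tibble::tibble(
    ext_trans = extended$transitions$trans,
    orig_trans = rows$orig_trans,
    kind = rows$kind
  )
  structure(list(original = structure, extended = extended, map = map),
            class = "split_map")
}

#' @export
print.split_map <- function(x, ...) {
  cat("<split_map>\n original: ", length(x$original$states), " states / ",
      nrow(x$original$transitions), " transitions\n extended: ",
      length(x$extended$states), " states / ", nrow(x$extended$transitions),
      " transitions\n", sep = "")
  print(x$map)
  invisible(x)
}
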