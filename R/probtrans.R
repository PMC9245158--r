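#' Aalen-Johansen transition probabilities
#'
#' Plug-in product-integral estimator `P(s, t) = prod_{u in (s, t]}
#' (I + dLambda(u))`, with diagonal increments `-sum_{j != h} dLambda_hj(u)`,
#' over the hazard grid. Works for ordinary Nelson-Aalen hazards and for the
#' extended (split) hazard set, where population increments enter the matrix
#' at every grid point and excess increments may be negative.
#'
#' The optional variance is the Greenwood-type recursive covariance
#' propagation of the product integral: at each grid point the covariance of
#' the hazard increments (multinomial form `(delta_jk Y dN_j - dN_j dN_k) /
#' Y^3`, which reproduces the classical Greenwood Kaplan-Meier variance in the
#' pure-survival case) is propagated through the matrix product. Population
#' transitions are treated as fixed and contribute zero variance and
#' covariance; excess transitions carry the counting-process quantities of
#' their observed counterparts.
#'
#' @param hz An `msm_hazards` object ([nelson_aalen()] or [split_hazards()]).
#' @param s Start time (days); `P(s, s) = I`.
#' @param variance Compute the Greenwood covariance recursion? (Adds the
#'   per-entry variance series.)
#' @return An object of class `msm_probtrans`: list with `s`, `time` (grid
#'   including `s`), `P` (K x K x length(time) array), `var` (same shape, or
#'   `NULL`), `structure`. Use [tidy()] for a long tibble.
#' @export
aalen_johansen <- function(hz, s = 0, variance = TRUE) {
  stopifnot(inherits(hz, "msm_hazards"), s >= 0)
  st <- attr(hz, "structure")
  grid <- attr(hz, "grid")
  K <- length(st$states)
  base <- unclass_hazards(hz)
  M <- nrow(st$transitions)
  haz <- matrix(0, length(grid), M)
  dN <- matrix(0L, length(grid), M)
  Y <- matrix(0L, length(grid), M)
  for (m in seq_len(M)) {
    b <- base[base$trans == m, ]
    stopifnot(nrow(b) == length(grid))
    haz[, m] <- b$haz
    dN[, m] <- ifelse(is.na(b$n_event), 0L, b$n_event)
    Y[, m] <- ifelse(is.na(b$n_risk), 0L, b$n_risk)
  }
  kind <- vapply(seq_len(M), function(m) base$kind[base$trans == m][1], character(1))
  keep <- grid > s
  dL <- apply(haz, 2, function(x) diff(c(0, x)))[keep, , drop = FALSE]
  dNk <- dN[keep, , drop = FALSE]
  Yk <- Y[keep, , drop = FALSE]
  times <- grid[keep]
  from <- st$transitions$from
  to <- st$transitions$to
  # pathological-increment guard: 1 + dLambda_hh >= -1
  out_by_state <- vapply(seq_len(K), function(h) {
    cols <- which(from == h)
    if (length(cols) == 0) return(0)
    max(rowSums(dL[, cols, drop = FALSE]))
  }, numeric(1))
  if (any(out_by_state > 2)) {
    stop("pathological hazard increment: 1 + dLambda_hh < -1 at some time")
  }
  Parr <- cpp_prod_integral(dL, from, to, K)
  Pfull <- array(0, dim = c(K, K, length(times) + 1))
  Pfull[, , 1] <- diag(K)
  if (length(times)) Pfull[, , -1] <- Parr
  Varr <- NULL
  if (variance) {
    Varr <- probtrans_var_recursion(dL, dNk, Yk, kind, from, to, K)
    V0 <- array(0, dim = c(K, K, length(times) + 1))
    if (length(times)) V0[, , -1] <- Varr
    Varr <- V0
  }
  structure(list(s = s, time = c(s, times), P = Pfull, var = Varr,
                 structure = st),
            class = "msm_probtrans")
}

## Greenwood-type forward covariance recursion for the product integral.
## Returns a K x K x n array of variances of the entries of P(s, t).
probtrans_var_recursion <- function(dL, dN, Y, kind, from, to, K) {
  n <- nrow(dL)
  M <- ncol(dL)
  V <- matrix(0, K * K, K * K)
  P <- diag(K)
  IK <- diag(K)
  out <- array(0, dim = c(K, K, n))
  stochastic <- kind != "population"
  for (g in seq_len(n)) {
    A <- IK
    for (m in seq_len(M)) {
      d <- dL[g, m]
      if (d != 0) {
        A[from[m], to[m]] <- A[from[m], to[m]] + d
        A[from[m], from[m]] <- A[from[m], from[m]] - d
      }
    }
    V <- kronecker(t(A), IK) %*% V %*% kronecker(A, IK)
    act <- which(stochastic & dN[g, ] > 0)
    if (length(act)) {
      m_act <- length(act)
      Sig <- matrix(0, m_act, m_act)
      for (a in seq_len(m_act)) {
        for (b in seq_len(m_act)) {
          ma <- act[a]; mb <- act[b]
          if (from[ma] == from[mb]) {
            Yh <- Y[g, ma]
            Sig[a, b] <- ((ma == mb) * Yh * dN[g, ma] -
                            dN[g, ma] * dN[g, mb]) / Yh^3
          }
        }
      }
      # U = (I_K kron P) B: column a of B is vec(E_a) with +1 at
      # (from, to), -1 at (from, from); so U[, a] = vec(P E_a)
      U <- matrix(0, K * K, m_act)
      for (a in seq_len(m_act)) {
        f <- from[act[a]]; tt <- to[act[a]]
        U[(tt - 1) * K + seq_len(K), a] <- U[(tt - 1) * K + seq_len(K), a] + P[, f]
        U[(f - 1) * K + seq_len(K), a] <- U[(f - 1) * K + seq_len(K), a] - P[, f]
      }
      V <- V + U %*% Sig %*% t(U)
    }
    P <- P %*% A
    out[, , g] <- matrix(diag(V), K, K)
  }
  out
}

#' @export
print.msm_probtrans <- function(x, ...) {
  cat("<msm_probtrans> P(s = ", x$s, ", t), ", length(x$time), " times, ",
      length(x$structure$states), " states\n", sep = "")
  invisible(x)
}

#' @export
tidy.msm_probtrans <- function(x, ...) {
  K <- length(x$structure$states)
  n <- length(x$time)
  out <- tibble::tibble(
    time = rep(x$time, each = K * K),
    from = rep(rep(x$structure$states, times = K), times = n),
    to = rep(rep(x$structure$states, each = K), times = n),
    prob = as.vector(x$P)
  )
  if (!is.null(x$var)) out$var <- as.vector(x$var)
  out
}

#' @export
glance.msm_probtrans <- function(x, ...) {
  tibble::tibble(
    s = x$s, n_times = length(x$time), max_time = max(x$time),
    n_states = length(x$structure$states),
    has_variance = !is.null(x$var),
    max_row_sum_error = max(abs(apply(x$P, 3, rowSums) - 1))
  )
}

#' Interpolate transition probabilities at arbitrary times
#'
#' Step interpolation (right-continuous, last value carried forward).
#'
#' @param x An `msm_probtrans` object.
#' @param times Times at which to evaluate.
#' @param from,to State labels (defaults: all combinations).
#' @return A tibble `time`, `from`, `to`, `prob` (and `var` when available).
#' @export
probtrans_at <- function(x, times, from = NULL, to = NULL) {
  stopifnot(inherits(x, "msm_probtrans"))
  states <- x$structure$states
  fi <- if (is.null(from)) seq_along(states) else match(from, states)
  ti <- if (is.null(to)) seq_along(states) else match(to, states)
  stopifnot(!anyNA(fi), !anyNA(ti))
  pos <- findInterval(times, x$time)
  pos[pos == 0] <- 1 # before s: P = I, row of the first slice
  combo <- expand.grid(f = fi, t = ti)
  rows <- lapply(seq_len(nrow(combo)), function(k) {
    f <- combo$f[k]; tt <- combo$t[k]
    out <- tibble::tibble(
      time = times, from = states[f], to = states[tt],
      prob = x$P[f, tt, pos]
    )
    if (!is.null(x$var)) out$var <- x$var[f, tt, pos]
    out
  })
  dplyr::bind_rows(rows)
}
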