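# Brute-force oracles and small dataset builders shared across tests.
# The oracles are written from first principles (explicit loops, Reduce over
# matrix products) and deliberately share no code with the package internals.

toy_survival_ds <- function() {
  # 3 subjects, one alive -> dead transition, events at 1 and 2, censor at 3
  msm_data(
    tibble::tibble(id = 1:3, trans = 1, Tstart = 0, Tstop = c(1, 2, 3),
                   status = c(1, 1, 0)),
    transition_structure(data.frame(from = "alive", to = "dead"))
  )
}

toy_profiles <- function(ids, age = 40, sex = "male", year = 1995) {
  tibble::tibble(id = ids, age = age, sex = sex, year = year)
}

# naive risk set / counting computation by explicit enumeration
brute_risk <- function(records, trans, t) {
  r <- records[records$trans == trans, ]
  list(
    Y = sum(r$Tstart < t & t <= r$Tstop),
    dN = sum(r$status == 1 & r$Tstop == t)
  )
}

# brute-force Aalen-Johansen: product of (I + dLambda(u)) over event times,
# hazard increments recomputed by enumeration
brute_aj <- function(records, structure, s, t_eval) {
  K <- length(structure$states)
  times <- sort(unique(records$Tstop[records$status == 1]))
  times <- times[times > s & times <= t_eval]
  mats <- lapply(times, function(u) {
    A <- diag(K)
    for (m in structure$transitions$trans) {
      rc <- brute_risk(records, m, u)
      if (rc$dN > 0) {
        h <- structure$transitions$from[m]
        j <- structure$transitions$to[m]
        A[h, j] <- A[h, j] + rc$dN / rc$Y
        A[h, h] <- A[h, h] - rc$dN / rc$Y
      }
    }
    A
  })
  Reduce(`%*%`, mats, init = diag(K))
}

# brute-force extended product integral: takes precomputed extended hazard
# increment matrices (one K x K increment per grid time) and multiplies
brute_prod <- function(inc_list, K) {
  Reduce(function(P, dL) P %*% (diag(K) + dL), inc_list, init = diag(K))
}

# ratetable with different constant daily hazards per sex
two_level_ratetable <- function(h_male, h_female, ages = 0:110,
                                years = 1980:2015) {
  grid <- tidyr::expand_grid(age = ages, year = years,
                             sex = c("male", "female"))
  grid$value <- ifelse(grid$sex == "male", h_male, h_female)
  ratetable_grid(grid, value = "daily_hazard")
}

expect_row_sums_one <- function(pt, tol = 1e-10) {
  rs <- apply(pt$P, 3, rowSums)
  testthat::expect_lt(max(abs(rs - 1)), tol)
}
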