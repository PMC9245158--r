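test_that("extending the structure splits death states per the diagram", {
  smap <- extend_structure(illness_death_structure(), c("NRM", "DaR"))
  expect_equal(length(smap$extended$states), 6)
  expect_equal(nrow(smap$extended$transitions), 5)
  expect_equal(smap$extended$states,
               c("ARF", "Relapse", "NRM.p", "NRM.e", "DaR.p", "DaR.e"))
  expect_equal(smap$map$kind,
               c("observed", "population", "excess", "population", "excess"))
  expect_true(all(smap$extended$absorbing[3:6]))
  # no split: identity mapping
  id0 <- extend_structure(illness_death_structure(), character())
  expect_equal(id0$extended$states, id0$original$states)
  expect_true(all(id0$map$kind == "observed"))
  # splitting one of two death states
  one <- extend_structure(illness_death_structure(), "NRM")
  expect_equal(length(one$extended$states), 5)
  # non-absorbing state refused
  expect_error(extend_structure(illness_death_structure(), "Relapse"),
               "absorbing")
})

test_that("population hazard reproduces hand-computed weighted daily sums", {
  # identical profiles: weights cancel, 0.001 * t exactly
  st <- transition_structure(data.frame(from = "a", to = "b"))
  rec <- tibble::tibble(id = 1:4, trans = 1, Tstart = 0,
                        Tstop = c(100, 150, 200, 200), status = c(1, 1, 0, 0))
  ds <- msm_data(rec, st, toy_profiles(1:4))
  rt <- constant_ratetable(0.001)
  ph <- population_hazard(ds, rt, "a", grid = c(50, 100, 150, 200))
  expect_equal(ph$haz, 0.001 * c(50, 100, 150, 200), tolerance = 1e-12)
  # zero table
  ph0 <- population_hazard(ds, constant_ratetable(0), "a", grid = c(100, 200))
  expect_true(all(ph0$haz == 0))
  # two subjects with hazards 0.001 and 0.003/day; the first leaves after
  # day 10; at t = 20: 10 * 0.002 + 10 * 0.003 = 0.05
  rt2 <- two_level_ratetable(0.001, 0.003)
  prof <- tibble::tibble(id = 1:2, age = 40, sex = c("male", "female"),
                         year = 1995)
  rec2 <- tibble::tibble(id = 1:2, trans = 1, Tstart = 0, Tstop = c(10, 25),
                         status = c(0, 1))
  ds2 <- msm_data(rec2, st, prof)
  ph2 <- population_hazard(ds2, rt2, "a", grid = c(10, 20, 25))
  expect_equal(ph2$haz[2], 10 * 0.002 + 10 * 0.003, tolerance = 1e-12)
  # left truncation: entry at day 5 contributes only days 6..
  rec3 <- tibble::tibble(id = 1:2, trans = 1, Tstart = c(5, 0),
                         Tstop = c(20, 20), status = 0)
  ph3 <- population_hazard(msm_data(rec3, st, prof), rt2, "a", grid = 20)
  expect_equal(ph3$haz, 15 * 0.002 + 5 * 0.003, tolerance = 1e-12)
})

test_that("split hazards are additive and reduce correctly at a zero table", {
  cfg <- make_scenario("exp.large")
  coh <- simulate_cohort(cfg, 300, seed = 21)
  ds <- coh$data
  smap <- extend_structure(illness_death_structure(), c("NRM", "DaR"))
  hz <- nelson_aalen(ds)
  ext <- split_hazards(hz, ds, cfg$ratetable, smap)
  w <- tidy(ext)
  pop <- w[w$kind == "population", ]
  exc <- w[w$kind == "excess", ]
  obs_nrm <- hz$haz[hz$trans == 2]
  obs_dar <- hz$haz[hz$trans == 3]
  expect_equal(pop$haz[pop$to == "NRM.p"] + exc$haz[exc$to == "NRM.e"],
               obs_nrm, tolerance = 1e-12)
  expect_equal(pop$haz[pop$to == "DaR.p"] + exc$haz[exc$to == "DaR.e"],
               obs_dar, tolerance = 1e-12)
  # population parts are non-decreasing and start at >= 0
  expect_true(all(dplyr::group_by(pop, .data$trans) |>
                    dplyr::summarise(ok = all(diff(c(0, haz)) >= 0)) |>
                    dplyr::pull(ok)))
  # zero ratetable: excess equals observed, population identically zero
  ext0 <- split_hazards(hz, ds, constant_ratetable(0), smap)
  w0 <- tidy(ext0)
  expect_true(all(w0$haz[w0$kind == "population"] == 0))
  expect_equal(w0$haz[w0$kind == "excess" & w0$to == "NRM.e"], obs_nrm)
})

test_that("excess hazards may go negative when population mortality dominates", {
  # healthy-cohort effect: population hazard far above observed mortality
  st <- transition_structure(data.frame(from = "alive", to = "dead"))
  rec <- tibble::tibble(id = 1:20, trans = 1, Tstart = 0,
                        Tstop = c(500, rep(1000, 19)),
                        status = c(1, rep(0, 19)))
  ds <- msm_data(rec, st, toy_profiles(1:20))
  rt <- constant_ratetable(0.001) # ~0.5 expected deaths by day 500 per subject
  smap <- extend_structure(st, "dead")
  ext <- split_hazards(nelson_aalen(ds), ds, rt, smap)
  exc <- tidy(ext)
  exc <- exc$haz[exc$kind == "excess"]
  expect_lt(min(exc), 0) # retained, no error
  # optional clamping raises them to zero with a message
  expect_message(
    ext2 <- split_hazards(nelson_aalen(ds), ds, rt, smap,
                          clamp_negative = TRUE),
    "clamped")
  w2 <- tidy(ext2)
  expect_true(all(w2$haz[w2$kind == "excess"] >= 0))
})

test_that("extended product integral matches a brute-force matrix product", {
  rt2 <- two_level_ratetable(0.0005, 0.002)
  st <- illness_death_structure()
  smap <- extend_structure(st, c("NRM", "DaR"))
  prof <- tibble::tibble(id = 1:4, age = c(40, 50, 60, 70),
                         sex = c("male", "female", "male", "female"),
                         year = 1992:1995)
  # 4 event times: relapse at 40 (id 1), NRM at 100 (id 2),
  # DaR at 160 (id 1), censoring at 200 (ids 3, 4)
  rec <- dplyr::bind_rows(
    tibble::tibble(id = 1, trans = 1:2, Tstart = 0, Tstop = 40,
                   status = c(1, 0)),
    tibble::tibble(id = 1, trans = 3, Tstart = 40, Tstop = 160, status = 1),
    tibble::tibble(id = 2, trans = 1:2, Tstart = 0, Tstop = 100,
                   status = c(0, 1)),
    tibble::tibble(id = 3, trans = 1:2, Tstart = 0, Tstop = 200, status = 0),
    tibble::tibble(id = 4, trans = 1:2, Tstart = 0, Tstop = 200, status = 0)
  )
  ds <- msm_data(rec, st, prof)
  # (suppress the expected exhausted-risk-set variance warning: the single
  # subject in Relapse dies, Y = dN = 1)
  ext <- split_hazards(suppressWarnings(nelson_aalen(ds)), ds, rt2, smap)
  pt <- aalen_johansen(ext, variance = FALSE)
  # brute force: rebuild increment matrices from the tidy hazard table
  w <- tidy(ext)
  grid <- attr(ext, "grid")
  stx <- smap$extended
  inc_list <- lapply(seq_along(grid), function(g) {
    dL <- matrix(0, 6, 6)
    for (m in seq_len(5)) {
      hzm <- w$haz[w$trans == m]
      d <- hzm[g] - if (g == 1) 0 else hzm[g - 1]
      f <- stx$transitions$from[m]; j <- stx$transitions$to[m]
      dL[f, j] <- dL[f, j] + d
      dL[f, f] <- dL[f, f] - d
    }
    dL
  })
  oracle <- brute_prod(inc_list, 6)
  expect_equal(pt$P[, , length(pt$time)], oracle, tolerance = 1e-12)
  expect_row_sums_one(pt, 1e-10)
})

test_that("split-state probabilities sum to the unsplit model's exactly", {
  cfg <- make_scenario("exp.large")
  coh <- simulate_cohort(cfg, 250, seed = 31)
  ds <- coh$data
  smap <- extend_structure(illness_death_structure(), c("NRM", "DaR"))
  hz <- nelson_aalen(ds)
  ext <- split_hazards(hz, ds, cfg$ratetable, smap)
  pt_ext <- aalen_johansen(ext, variance = FALSE)
  pt_orig <- aalen_johansen(hz, variance = FALSE)
  # P(ARF -> NRM.p) + P(ARF -> NRM.e) == P(ARF -> NRM), all times
  expect_equal(pt_ext$P[1, 3, ] + pt_ext$P[1, 4, ], pt_orig$P[1, 3, ],
               tolerance = 1e-10)
  expect_equal(pt_ext$P[1, 5, ] + pt_ext$P[1, 6, ], pt_orig$P[1, 4, ],
               tolerance = 1e-10)
  expect_equal(pt_ext$P[1, 1, ], pt_orig$P[1, 1, ], tolerance = 1e-10)
  expect_row_sums_one(pt_ext, 1e-10)
  # zero ratetable: population-state probabilities identically zero
  ext0 <- split_hazards(hz, ds, constant_ratetable(0), smap)
  pt0 <- aalen_johansen(ext0, variance = FALSE)
  expect_true(all(pt0$P[1, c(3, 5), ] == 0))
})

test_that("daily evaluation refines the event-time grid consistently", {
  cfg <- make_scenario("exp.large")
  coh <- simulate_cohort(cfg, 150, seed = 41)
  ds <- coh$data
  smap <- extend_structure(illness_death_structure(), c("NRM", "DaR"))
  hz <- nelson_aalen(ds)
  ext_ev <- split_hazards(hz, ds, cfg$ratetable, smap, eval = "event")
  ext_day <- split_hazards(hz, ds, cfg$ratetable, smap, eval = "daily")
  # at shared (event) grid points the cumulative population hazard agrees to
  # within the largest single-day increment (lumping direction differs by at
  # most the partial day at the event time itself)
  wev <- tidy(ext_ev); wd <- tidy(ext_day)
  for (tr in c("NRM.p", "DaR.p")) {
    a <- wev[wev$to == tr, ]
    b <- wd[wd$to == tr, ]
    shared <- intersect(a$time, b$time)
    amax <- max(abs(a$haz[match(shared, a$time)] -
                      b$haz[match(shared, b$time)]))
    max_daily_inc <- max(diff(c(0, b$haz[order(b$time)])))
    expect_lte(amax, max_daily_inc + 1e-12)
  }
})
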