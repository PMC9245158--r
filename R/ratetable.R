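#' Population mortality ratetable on an age x calendar-year x sex grid
#'
#' A `ratetable_grid` stores a daily mortality hazard for every combination of
#' attained age (whole years, contiguous from the youngest age), calendar year
#' (contiguous) and sex. Lookups beyond the last age or year are clamped to the
#' last available cell; there is no extrapolation.
#'
#' @param data A data frame with columns `age` (integer years), `year`
#'   (integer calendar years), `sex`, and `value`.
#' @param value Either `"annual_prob"` (annual death probability `q`, converted
#'   to a constant daily hazard `-log(1 - q) / 365.241`) or `"daily_hazard"`.
#' @return An object of class `ratetable_grid` with fields `hazard` (3-d array
#'   age x year x sex of daily hazards), `ages`, `years`, `sex_levels`.
#' @examples
#' rt <- ratetable_grid(
#'   tidyr::expand_grid(age = 0:2, year = 2000:2001, sex = c("male", "female")) |>
#'     dplyr::mutate(value = 0.001),
#'   value = "daily_hazard"
#' )
#' daily_hazard_at(rt, age = 1, sex = "male", year = 2000.5, u = 10)
#' @export
ratetable_grid <- function(data, value = c("annual_prob", "daily_hazard")) {
  value <- match.arg(value)
  stopifnot(all(c("age", "year", "sex", "value") %in% names(data)))
  ages <- sort(unique(as.integer(data$age)))
  years <- sort(unique(as.integer(data$year)))
  sexes <- sort(unique(as.character(data$sex)))
  if (length(sexes) != 2L) {
    stop("ratetable must have exactly two sex levels, got: ",
         paste(sexes, collapse = ", "))
  }
  if (length(ages) > 1L && !all(diff(ages) == 1L)) {
    stop("age axis must be contiguous with unit step")
  }
  if (length(years) > 1L && !all(diff(years) == 1L)) {
    stop("year axis must be contiguous with unit step")
  }
  full <- nrow(data) == length(ages) * length(years) * 2L &&
    !anyDuplicated(data[c("age", "year", "sex")])
  if (!full) {
    grid <- tidyr::expand_grid(age = ages, year = years, sex = sexes)
    missing <- dplyr::anti_join(grid, data, by = c("age", "year", "sex"))
    stop("ratetable grid has ", nrow(missing), " missing age x year x sex cells, e.g. ",
         paste(utils::capture.output(print(utils::head(missing, 3))), collapse = "\n"))
  }
  if (value == "annual_prob") {
    if (any(data$value < 0 | data$value >= 1)) {
      stop("annual death probabilities must lie in [0, 1)")
    }
    haz <- -log(1 - data$value) / DAYS_PER_YEAR
  } else {
    if (any(data$value < 0) || any(!is.finite(data$value))) {
      stop("daily hazards must be finite and >= 0")
    }
    haz <- data$value
  }
  arr <- array(NA_real_,
               dim = c(length(ages), length(years), 2L),
               dimnames = list(age = ages, year = years, sex = sexes))
  arr[cbind(match(as.integer(data$age), ages),
            match(as.integer(data$year), years),
            match(as.character(data$sex), sexes))] <- haz
  structure(
    list(hazard = arr, ages = ages, years = years, sex_levels = sexes),
    class = "ratetable_grid"
  )
}

#' @export
print.ratetable_grid <- function(x, ...) {
  cat("<ratetable_grid> daily hazards\n")
  cat("  ages  ", min(x$ages), "-", max(x$ages), "\n")
  cat("  years ", min(x$years), "-", max(x$years), "\n")
  cat("  sex   ", paste(x$sex_levels, collapse = ", "), "\n")
  invisible(x)
}

#' Read a population mortality table from a text file
#'
#' Two tabular layouts are supported: the package's CSV layout with columns
#' `age,year,sex,value` and an optional first metadata line
#' `# value: annual_prob` (or `daily_hazard`); and HMD-style period life-table
#' text with whitespace-separated columns `Year`, `Age`, `qx` (read per sex
#' from two files is not supported; such files carry one sex, supplied via
#' `sex`).
#'
#' @param path File path.
#' @param format One of `"auto"`, `"annual_prob"`, `"daily_hazard"`,
#'   `"hmd_lifetable"`. `"auto"` requires the metadata line.
#' @param sex For `"hmd_lifetable"` only: the sex label of the file, and a
#'   second file `path2` for the other sex.
#' @param path2 Second HMD file (other sex).
#' @param sex2 Sex label for `path2`.
#' @return A [ratetable_grid()].
#' @export
read_ratetable <- function(path, format = c("auto", "annual_prob", "daily_hazard",
                                            "hmd_lifetable"),
                           sex = "male", path2 = NULL, sex2 = "female") {
  format <- match.arg(format)
  if (format == "hmd_lifetable") {
    read_one <- function(p, s) {
      tab <- utils::read.table(p, header = TRUE, stringsAsFactors = FALSE)
      stopifnot(all(c("Year", "Age", "qx") %in% names(tab)))
      tibble::tibble(
        age = as.integer(sub("\\+$", "", tab$Age)),
        year = as.integer(tab$Year),
        sex = s,
        value = as.numeric(tab$qx)
      )
    }
    stopifnot(!is.null(path2))
    data <- dplyr::bind_rows(read_one(path, sex), read_one(path2, sex2))
    return(ratetable_grid(data, value = "annual_prob"))
  }
  first <- readLines(path, n = 1L)
  skip <- 0L
  if (grepl("^#", first)) {
    m <- regmatches(first, regexec("value:\\s*(\\w+)", first))[[1]]
    if (length(m) == 2L && format == "auto") format <- m[2]
    skip <- 1L
  }
  if (format == "auto") {
    stop("no '# value: ...' metadata line in ", path,
         "; pass format = \"annual_prob\" or \"daily_hazard\"")
  }
  data <- utils::read.csv(path, skip = skip, stringsAsFactors = FALSE)
  ratetable_grid(data, value = format)
}

#' Write a ratetable to the package's CSV layout
#'
#' Emits daily hazards with the `# value: daily_hazard` metadata line, so that
#' reading the file back reproduces the table exactly.
#'
#' @param rt A [ratetable_grid()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_ratetable <- function(rt, path) {
  df <- tidy(rt)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# value: daily_hazard", con)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
tidy.ratetable_grid <- function(x, ...) {
  grid <- tidyr::expand_grid(sex = x$sex_levels, year = x$years, age = x$ages)
  grid$value <- as.vector(x$hazard)
  dplyr::select(grid, "age", "year", "sex", "value")
}

sex_index <- function(rt, sex) {
  idx <- match(as.character(sex), rt$sex_levels)
  if (anyNA(idx)) {
    stop("unknown sex level(s): ",
         paste(unique(sex[is.na(idx)]), collapse = ", "),
         "; ratetable levels are ", paste(rt$sex_levels, collapse = ", "))
  }
  idx
}

#' Look up the daily population hazard for one subject
#'
#' Returns the ratetable cell for the attained age
#' `floor((age_at_entry_days + u) / 365.241)` and the calendar year of
#' `entry + u` days, clamped at the table boundaries.
#'
#' @param rt A [ratetable_grid()].
#' @param age Age at entry in years.
#' @param sex Sex label (one of the table's levels).
#' @param year Entry date as a decimal calendar year (e.g. `1995.4`).
#' @param u Days since entry (vectorised).
#' @return Daily hazard, same length as `u`.
#' @export
daily_hazard_at <- function(rt, age, sex, year, u) {
  stopifnot(length(age) == 1L, length(sex) == 1L, length(year) == 1L, all(u >= 0))
  age_days <- age * DAYS_PER_YEAR
  ai <- pmin(pmax(floor((age_days + u) / DAYS_PER_YEAR) - rt$ages[1] + 1, 1),
             length(rt$ages))
  yi <- pmin(pmax(floor(year + u / DAYS_PER_YEAR) - rt$years[1] + 1, 1),
             length(rt$years))
  rt$hazard[cbind(ai, yi, sex_index(rt, sex))]
}

#' Cumulative population hazard over follow-up for one subject
#'
#' Accumulates the daily hazard with left-aligned daily rectangles:
#' `Lambda_P(t) = sum_{u=1..t} h(u - 1)`, with a fractional last day when `t`
#' is not an integer. The result is non-decreasing and piecewise linear with
#' daily knots.
#'
#' @inheritParams daily_hazard_at
#' @param t Days since entry (vectorised, `>= 0`).
#' @return Cumulative hazard at `t`.
#' @export
pop_cum_hazard <- function(rt, age, sex, year, t) {
  stopifnot(all(t >= 0))
  tmax <- max(t)
  if (tmax == 0) return(rep(0, length(t)))
  h <- daily_hazard_at(rt, age, sex, year, seq_len(ceiling(tmax)) - 1)
  cum <- c(0, cumsum(h))
  fl <- floor(t)
  cum[fl + 1] + (t - fl) * c(h, 0)[fl + 1]
}

## Daily hazard matrix for a set of subjects: H[u + 1, i] is subject i's
## hazard over the day interval (u, u + 1], u = 0 .. n_days - 1.
subject_hazard_matrix <- function(rt, profiles, n_days) {
  u <- seq_len(n_days) - 1
  n <- nrow(profiles)
  age_days <- profiles$age * DAYS_PER_YEAR
  si <- sex_index(rt, profiles$sex)
  ai <- floor(outer(u, age_days, "+") / DAYS_PER_YEAR)
  ai <- pmin(pmax(ai - rt$ages[1] + 1, 1), length(rt$ages))
  yi <- floor(outer(u / DAYS_PER_YEAR, profiles$year, "+"))
  yi <- pmin(pmax(yi - rt$years[1] + 1, 1), length(rt$years))
  H <- rt$hazard[cbind(as.vector(ai), as.vector(yi), rep(si, each = n_days))]
  dim(H) <- c(n_days, n)
  H
}

## Piecewise-constant hazard segments for one block of subjects, used by the
## population death-time sampler. Returns breakpoints (integer days) at which
## the attained age or the calendar year can roll over.
pop_segment_breaks <- function(age_days, year, max_years = 200) {
  m0 <- floor(age_days / DAYS_PER_YEAR)
  age_breaks <- ceiling((m0 + seq_len(max_years)) * DAYS_PER_YEAR - age_days)
  y0 <- floor(year)
  year_breaks <- ceiling((y0 + seq_len(max_years) - year) * DAYS_PER_YEAR)
  sort(unique(c(0, age_breaks, year_breaks)))
}

#' Sample population death times from a ratetable
#'
#' Draws death times with conditional law
#' `P(T > t | T > L) = exp(-(Lambda_P(t) - Lambda_P(L)))` by inverting each
#' subject's piecewise-linear cumulative population hazard against a unit
#' exponential deviate. If the clamped table hazard cannot absorb the deviate
#' within 200 attained years, `Inf` is returned.
#'
#' @param rt A [ratetable_grid()].
#' @param profiles Data frame with columns `age` (years at entry), `sex`,
#'   `year` (decimal entry year).
#' @param left_truncation Days already survived (scalar or per subject).
#' @return Death times in days since entry, one per profile row.
#' @export
sample_pop_death_time <- function(rt, profiles, left_truncation = 0) {
  n <- nrow(profiles)
  L <- rep(left_truncation, length.out = n)
  stopifnot(all(L >= 0))
  e <- rexp(n) # target increment Lambda_P(T) - Lambda_P(L)
  age_days <- profiles$age * DAYS_PER_YEAR
  si <- sex_index(rt, profiles$sex)
  out <- rep(Inf, n)
  horizon <- 200 * DAYS_PER_YEAR
  for (i in seq_len(n)) {
    br <- pop_segment_breaks(age_days[i], profiles$year[i])
    br <- br[br <= horizon]
    a <- br
    b <- c(br[-1], horizon)
    keep <- b > L[i]
    a <- pmax(a[keep], L[i])
    b <- b[keep]
    ai <- pmin(pmax(floor((age_days[i] + a) / DAYS_PER_YEAR) - rt$ages[1] + 1, 1),
               length(rt$ages))
    yi <- pmin(pmax(floor(profiles$year[i] + a / DAYS_PER_YEAR) - rt$years[1] + 1, 1),
               length(rt$years))
    h <- rt$hazard[cbind(ai, yi, si[i])]
    cum <- cumsum(h * (b - a))
    k <- which(cum >= e[i])[1]
    if (!is.na(k)) {
      rem <- e[i] - (if (k == 1) 0 else cum[k - 1])
      out[i] <- a[k] + rem / h[k]
    }
  }
  out
}

#' Synthetic Gompertz-shaped population mortality table
#'
#' A bundled synthetic ratetable emulating the shape of a Central European
#' national life table: adult mortality rises exponentially with age
#' (Gompertz), women experience about 55% of male mortality, and rates drift
#' slowly downward over calendar time. It is generated in code, not measured
#' data, and exists so that simulations need no external downloads.
#'
#' Annual hazard: `0.0001 + 0.000034 * exp(0.095 * age) * 0.55^(sex == "female")
#' * exp(-0.005 * (year - 1990))`, capped at 0.7 per year, converted to a
#' constant daily hazard.
#'
#' @param ages Integer age axis (years).
#' @param years Integer calendar-year axis.
#' @return A [ratetable_grid()].
#' @export
synthetic_ratetable <- function(ages = 0:110, years = 1980:2015) {
  grid <- tidyr::expand_grid(age = ages, year = years, sex = c("male", "female"))
  annual <- 0.0001 + 0.000034 * exp(0.095 * grid$age) *
    ifelse(grid$sex == "female", 0.55, 1) *
    exp(-0.005 * (grid$year - 1990))
  grid$value <- pmin(annual, 0.7) / DAYS_PER_YEAR
  ratetable_grid(grid, value = "daily_hazard")
}

#' Constant-hazard ratetable (mainly for tests and examples)
#'
#' @param daily_hazard Single daily hazard applied to every cell.
#' @param ages,years Axes.
#' @return A [ratetable_grid()].
#' @export
constant_ratetable <- function(daily_hazard, ages = 0:110, years = 1980:2015) {
  grid <- tidyr::expand_grid(age = ages, year = years, sex = c("male", "female"))
  grid$value <- daily_hazard
  ratetable_grid(grid, value = "daily_hazard")
}
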