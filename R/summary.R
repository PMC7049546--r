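#' @title Life expectancy, healthy and unhealthy life years
#' @description Computes period (Sullivan) and cohort expectancies from
#'   projection aggregates. The Sullivan method builds a period life table
#'   from one calendar year's death probabilities and combines it with that
#'   year's cross-sectional disability prevalence; the cohort method sums the
#'   person-years a followed cohort actually lives. Deaths are mid-interval
#'   (L = N - D/2) and the open 95+ class is closed with the constant-hazard
#'   expectation 1/m, m = deaths / person-years.
#' @name summary
NULL

# Period life-table expansion shared by the Sullivan and cohort-continuation
# paths: q and pi are vectors over ages start..95, m95 the open-class hazard.
# Returns total and disabled expectancies per person alive at the first age.
period_table <- function(q, pi, m95) {
  n <- length(q)
  l <- numeric(n)
  l[1L] <- 1
  if (n > 1L) {
    for (i in 1:(n - 1L)) l[i + 1L] <- l[i] * (1 - q[i])
  }
  d <- l * q
  L <- l - d / 2
  if (!is.finite(m95) || m95 <= 0) {
    stop("open-class hazard must be positive and finite")
  }
  L[n] <- l[n] / m95
  list(le = sum(L), uly = sum(L * pi))
}

#' Sullivan (cross-sectional) expectancies for one year
#'
#' Builds a period life table from the aggregates of a single calendar year:
#' death probabilities `q(a) = deaths / N` per cell (equivalently the
#' survival difference between the year and the next for the closed cohorts
#' below the open class), disability prevalence
#' `pi(a) = disabled person-years / person-years`, mid-interval deaths, and
#' open-class closure `e95 = 1/m95` with `m95 = deaths / person-years` at
#' 95+.
#'
#' @param agg An `hia_aggregates` data frame.
#' @param year Calendar year present in the aggregates.
#' @param start_age Age from which the expectancies are computed.
#' @param sex `"male"` or `"female"`.
#' @return A one-row data frame `year`, `age`, `sex`, `LE`, `HLY`, `ULY`
#'   (years; `HLY + ULY = LE`).
#' @export
sullivan_expectancies <- function(agg, year, start_age = 15L, sex) {
  sub <- agg[agg$year == year & agg$sex == sex & agg$age >= start_age, ]
  if (nrow(sub) == 0L) stop(sprintf("year %d not present in aggregates", year))
  sub <- sub[order(sub$age), ]
  empty <- which(sub$N <= 0 | sub$person_years <= 0)
  if (length(empty) > 0L) {
    stop(sprintf("empty cell (age %d, %s, year %d) in the Sullivan range",
                 sub$age[empty[[1L]]], sex, year))
  }
  q <- sub$deaths / sub$N
  pi <- sub$disabled_py / sub$person_years
  open <- nrow(sub)
  m95 <- sub$deaths[open] / sub$person_years[open]
  pt <- period_table(q, pi, m95)
  data.frame(year = year, age = start_age, sex = sex,
             LE = pt$le, HLY = pt$le - pt$uly, ULY = pt$uly,
             stringsAsFactors = FALSE)
}

#' Cohort expectancies for the baseline cohort aged `start_age`
#'
#' Follows the baseline cohort along its diagonal (age `start_age + i` in
#' year `baseline + i`) through the projection horizon, summing person-years
#' and disabled person-years. Cohorts still alive at the horizon (the usual
#' case) are closed by continuing them deterministically under the final
#' year's age-specific rates: the remaining expectancies come from a period
#' table built at the final year, applied to the survivors. The share of life
#' expectancy contributed by the continuation is attached as attribute
#' `truncation_share`.
#'
#' @param agg An `hia_aggregates` data frame.
#' @param start_age Cohort age at baseline; the cohort must not reach the
#'   open 95+ class within the horizon (its identity would merge with the
#'   standing pool).
#' @param sex `"male"` or `"female"`.
#' @return A one-row data frame `cohort`, `age`, `sex`, `LE`, `HLY`, `ULY`.
#' @export
cohort_expectancies <- function(agg, start_age = 15L, sex) {
  b <- attr(agg, "baseline_year")
  horizon <- attr(agg, "horizon")
  if (is.null(b) || is.null(horizon)) {
    stop("aggregates lack baseline_year/horizon attributes")
  }
  if (start_age + horizon >= HIA_OPEN_AGE) {
    warning("cohort reaches the open 95+ class within the horizon; ",
            "pooled open-class rates are used from that point")
  }
  steps <- 0:horizon
  ages <- pmin(start_age + steps, HIA_OPEN_AGE)
  yrs <- b + steps
  key <- paste(agg$year, agg$age, agg$sex)
  rows <- match(paste(yrs, ages, sex), key)
  if (anyNA(rows)) stop("cohort diagonal missing from aggregates")
  sub <- agg[rows, ]
  base <- sub$N[[1L]]
  if (base <= 0) stop("zero baseline cohort count")
  py <- sum(sub$person_years)
  dis <- sum(sub$disabled_py)
  last <- nrow(sub)
  l_end <- sub$N[[last]] - sub$deaths[[last]]
  cont_le <- 0
  cont_uly <- 0
  if (l_end > 0) {
    next_age <- min(ages[[last]] + 1L, HIA_OPEN_AGE)
    fin <- agg[agg$year == yrs[[last]] & agg$sex == sex &
                 agg$age >= next_age, ]
    fin <- fin[order(fin$age), ]
    if (any(fin$N <= 0 | fin$person_years <= 0)) {
      stop("empty cell in the final-year continuation range")
    }
    q <- fin$deaths / fin$N
    pi <- fin$disabled_py / fin$person_years
    open <- nrow(fin)
    m95 <- fin$deaths[open] / fin$person_years[open]
    pt <- period_table(q, pi, m95)
    cont_le <- l_end * pt$le
    cont_uly <- l_end * pt$uly
  }
  le <- (py + cont_le) / base
  uly <- (dis + cont_uly) / base
  out <- data.frame(cohort = sprintf("age %d in %d", start_age, b),
                    age = start_age, sex = sex,
                    LE = le, HLY = le - uly, ULY = uly,
                    stringsAsFactors = FALSE)
  attr(out, "truncation_share") <- cont_le / (le * base)
  out
}

#' Expectancy report over scenarios
#'
#' Sullivan expectancies for every scenario x report year x report age x sex,
#' plus cohort expectancies for the baseline cohorts at the report ages.
#'
#' @param agg_map Named list of `hia_aggregates`, one per scenario.
#' @param cfg `hia_config` providing `report_years` and `report_ages`.
#' @return Data frame with columns `scenario`, `measure_type`
#'   (`"sullivan"`/`"cohort"`), `year` (calendar year or cohort label),
#'   `age`, `sex`, `LE`, `HLY`, `ULY`.
#' @export
expectancy_report <- function(agg_map, cfg) {
  rows <- list()
  for (sc in names(agg_map)) {
    agg <- agg_map[[sc]]
    for (yr in cfg$report_years) {
      for (aa in cfg$report_ages) {
        for (s in HIA_SEXES) {
          r <- sullivan_expectancies(agg, yr, aa, s)
          rows[[length(rows) + 1L]] <- data.frame(
            scenario = sc, measure_type = "sullivan",
            year = as.character(yr), age = aa, sex = s,
            LE = r$LE, HLY = r$HLY, ULY = r$ULY, stringsAsFactors = FALSE)
        }
      }
    }
    for (aa in cfg$report_ages) {
      for (s in HIA_SEXES) {
        r <- cohort_expectancies(agg, aa, s)
        rows[[length(rows) + 1L]] <- data.frame(
          scenario = sc, measure_type = "cohort",
          year = r$cohort, age = aa, sex = s,
          LE = r$LE, HLY = r$HLY, ULY = r$ULY, stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

#' Scenario-minus-reference difference table
#'
#' @param results Expectancy data frame (from [expectancy_report()]) for the
#'   alternative scenarios; may include the reference.
#' @param reference Expectancy data frame for the reference scenario.
#' @return Data frame in the shape of the headline results table: reference
#'   rows in levels, alternative rows as differences (`LE`, `HLY`, `ULY`
#'   minus the reference value at the same year/age/sex key).
#' @export
difference_table <- function(results, reference) {
  key <- function(df) paste(df$measure_type, df$year, df$age, df$sex)
  rk <- key(reference)
  out <- results[results$scenario != unique(reference$scenario)[[1L]], ]
  m <- match(key(out), rk)
  if (anyNA(m)) stop("key mismatch between results and reference")
  for (col in c("LE", "HLY", "ULY")) {
    out[[col]] <- out[[col]] - reference[[col]][m]
  }
  ref <- reference
  ref$scenario <- paste0(ref$scenario, " (level)")
  rbind(ref, out)
}

#' Write a difference table with 2-decimal formatting
#' @param diff Data frame from [difference_table()].
#' @param path Output file path.
#' @export
write_differences <- function(diff, path) {
  out <- diff
  for (col in c("LE", "HLY", "ULY")) out[[col]] <- sprintf("%.2f", diff[[col]])
  utils::write.table(out, path, sep = ",", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}
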