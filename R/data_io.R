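#' @title Grid conventions and tabular input/output
#' @description Every table in the package lives on a common age-by-sex grid:
#'   one-year age classes 0..95, where 95 denotes the open-ended class "95+",
#'   fully crossed with sex in \{male, female\}. All models and projections are
#'   stratified by sex throughout.
#' @name data_io
NULL

# Grid constants. Age a covers the half-open interval [a, a+1); 95 is open.
HIA_AGES <- 0:95
HIA_OPEN_AGE <- 95L
HIA_SEXES <- c("male", "female")
HIA_SMOKING <- c("never", "current", "former")
HIA_GALI <- c("none", "not_severe", "severe")

#' Age-by-sex grid
#'
#' @return A data frame with columns `age` (0..95) and `sex`
#'   (`"male"`, `"female"`), one row per cell, 192 rows, age varying fastest.
#' @export
age_sex_grid <- function() {
  data.frame(
    age = rep(HIA_AGES, times = length(HIA_SEXES)),
    sex = rep(HIA_SEXES, each = length(HIA_AGES)),
    stringsAsFactors = FALSE
  )
}

# Order a grid data frame canonically (sex blocks, age ascending) after
# verifying completeness; errors name the first offending cell.
check_grid <- function(df, what) {
  if (!all(c("age", "sex") %in% names(df))) {
    stop(sprintf("%s: required columns 'age' and 'sex' are missing", what))
  }
  if (!all(df$sex %in% HIA_SEXES)) {
    bad <- setdiff(unique(df$sex), HIA_SEXES)
    stop(sprintf("%s: unknown sex value '%s'", what, bad[[1L]]))
  }
  key <- paste(df$age, df$sex)
  dup <- key[duplicated(key)]
  if (length(dup) > 0L) {
    stop(sprintf("%s: duplicate cell (%s)", what, dup[[1L]]))
  }
  grid <- age_sex_grid()
  want <- paste(grid$age, grid$sex)
  miss <- setdiff(want, key)
  if (length(miss) > 0L) {
    stop(sprintf("%s: missing cell (%s)", what, miss[[1L]]))
  }
  extra <- setdiff(key, want)
  if (length(extra) > 0L) {
    stop(sprintf("%s: cell outside the 0..95 x male/female grid (%s)",
                 what, extra[[1L]]))
  }
  df[match(want, key), , drop = FALSE]
}

check_values <- function(df, cols, kind, what) {
  for (col in cols) {
    v <- df[[col]]
    if (!is.numeric(v) || anyNA(v) || any(!is.finite(v))) {
      stop(sprintf("%s: column '%s' contains non-finite values", what, col))
    }
    bad <- if (kind == "probability") which(v < 0 | v > 1) else which(v < 0)
    if (length(bad) > 0L) {
      i <- bad[[1L]]
      stop(sprintf(
        "%s: value %g in column '%s' at cell (%d, %s) outside the %s domain",
        what, v[[i]], col, df$age[[i]], df$sex[[i]],
        if (kind == "probability") "[0,1]" else "[0,Inf)"
      ))
    }
  }
  invisible(df)
}

# Fixed decimal formatting used by every writer: 12 significant digits.
fmt_num <- function(x) formatC(x, digits = 12L, format = "g", flag = "-")

write_hia_csv <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1L)) & names(df) != "age" &
    names(df) != "year"
  out <- df
  for (col in names(df)[num]) out[[col]] <- trimws(fmt_num(df[[col]]))
  utils::write.table(out, path, sep = ",", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a rate or probability table
#'
#' Reads a CSV with columns `age`, `sex`, `value` covering the full grid.
#'
#' @param path File path.
#' @param kind Either `"probability"` (values in \[0,1\]) or `"rate"`
#'   (nonnegative values; used for counts as well).
#' @return A validated data frame `age`, `sex`, `value` in canonical grid
#'   order, with attribute `kind`.
#' @export
read_rate_table <- function(path, kind = c("probability", "rate")) {
  kind <- match.arg(kind)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("age", "sex", "value") %in% names(df))) {
    stop(sprintf("%s: expected columns age, sex, value", path))
  }
  df <- check_grid(df[c("age", "sex", "value")], path)
  check_values(df, "value", kind, path)
  rownames(df) <- NULL
  attr(df, "kind") <- kind
  df
}

#' Write a rate or probability table
#'
#' @param tab Data frame with columns `age`, `sex`, `value`.
#' @param path Output file path.
#' @export
write_rate_table <- function(tab, path) {
  write_hia_csv(tab[c("age", "sex", "value")], path)
}

#' Read a smoking-state prevalence table
#'
#' Columns `age`, `sex`, `never`, `current`, `former`. Rows whose sum deviates
#' from 1 by no more than 1e-6 are renormalized; larger deviations or negative
#' entries are errors.
#'
#' @param path File path.
#' @return A validated prevalence data frame in canonical grid order.
#' @export
read_prevalence_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("age", "sex", HIA_SMOKING)
  if (!all(need %in% names(df))) {
    stop(sprintf("%s: expected columns %s", path, paste(need, collapse = ", ")))
  }
  df <- check_grid(df[need], path)
  check_values(df, HIA_SMOKING, "probability", path)
  validate_prevalence(df, path)
}

#' Validate (and renormalize) a prevalence table held in memory
#'
#' @param df Data frame with columns `age`, `sex`, `never`, `current`,
#'   `former` covering the full grid.
#' @param what Label used in error messages.
#' @return The renormalized table.
#' @export
validate_prevalence <- function(df, what = "prevalence table") {
  df <- check_grid(df[c("age", "sex", HIA_SMOKING)], what)
  check_values(df, HIA_SMOKING, "probability", what)
  s <- df$never + df$current + df$former
  bad <- which(abs(s - 1) > 1e-6)
  if (length(bad) > 0L) {
    i <- bad[[1L]]
    stop(sprintf("%s: smoking-state probabilities at cell (%d, %s) sum to %g",
                 what, df$age[[i]], df$sex[[i]], s[[i]]))
  }
  for (col in HIA_SMOKING) df[[col]] <- df[[col]] / s
  rownames(df) <- NULL
  df
}

#' Write a smoking-state prevalence table
#' @param tab Prevalence data frame.
#' @param path Output file path.
#' @export
write_prevalence_table <- function(tab, path) {
  write_hia_csv(tab[c("age", "sex", HIA_SMOKING)], path)
}

#' Read per-state relative risks or odds ratios
#'
#' Reads a CSV with columns `sex`, `state`, `value` holding the
#' current/former effect sizes per sex; the never state is the reference and
#' is fixed at 1 (rows for it are optional and must equal 1 if present).
#'
#' @param path File path.
#' @return A list with one named vector `c(never = 1, current, former)` per
#'   sex.
#' @export
read_state_effects <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("sex", "state", "value") %in% names(df))) {
    stop(sprintf("%s: expected columns sex, state, value", path))
  }
  if (!all(df$sex %in% HIA_SEXES) || !all(df$state %in% HIA_SMOKING)) {
    stop(sprintf("%s: sex must be male/female and state never/current/former",
                 path))
  }
  if (any(!is.finite(df$value)) || any(df$value <= 0)) {
    stop(sprintf("%s: effect sizes must be finite and > 0", path))
  }
  out <- lapply(HIA_SEXES, function(s) {
    sub <- df[df$sex == s, ]
    v <- c(never = 1, current = NA_real_, former = NA_real_)
    for (st in c("current", "former")) {
      row <- sub[sub$state == st, ]
      if (nrow(row) != 1L) {
        stop(sprintf("%s: need exactly one %s value for sex %s", path, st, s))
      }
      v[[st]] <- row$value
    }
    nv <- sub[sub$state == "never", ]
    if (nrow(nv) > 0L && any(nv$value != 1)) {
      stop(sprintf("%s: never state must have value 1 (reference)", path))
    }
    v
  })
  names(out) <- HIA_SEXES
  out
}

#' Write per-state effect sizes
#' @param effects List as returned by [read_state_effects()].
#' @param path Output file path.
#' @export
write_state_effects <- function(effects, path) {
  df <- do.call(rbind, lapply(HIA_SEXES, function(s) {
    data.frame(sex = s, state = c("current", "former"),
               value = unname(effects[[s]][c("current", "former")]),
               stringsAsFactors = FALSE)
  }))
  write_hia_csv(df, path)
}

#' Read a projected newborn series
#'
#' Columns `year`, `sex`, `value` (births entering at age 0 that year).
#'
#' @param path File path.
#' @return Data frame `year`, `sex`, `value`, all values positive.
#' @export
read_newborns <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("year", "sex", "value") %in% names(df))) {
    stop(sprintf("%s: expected columns year, sex, value", path))
  }
  if (!all(df$sex %in% HIA_SEXES)) stop(sprintf("%s: unknown sex", path))
  if (any(!is.finite(df$value)) || any(df$value <= 0)) {
    stop(sprintf("%s: newborn counts must be positive", path))
  }
  df[order(df$year, match(df$sex, HIA_SEXES)), c("year", "sex", "value")]
}

#' Write a newborn series
#' @param df Data frame `year`, `sex`, `value`.
#' @param path Output file path.
#' @export
write_newborns <- function(df, path) write_hia_csv(df, path)

#' Read survey microdata
#'
#' Columns `age`, `sex`, `smoking` (never/current/former), `gali`
#' (none/not_severe/severe), `weight` (> 0; defaults to 1 when absent).
#'
#' @param path File path.
#' @return A validated microdata data frame.
#' @export
read_survey <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("age", "sex", "smoking", "gali")
  if (!all(need %in% names(df))) {
    stop(sprintf("%s: expected columns %s", path, paste(need, collapse = ", ")))
  }
  if (is.null(df$weight)) df$weight <- 1
  if (!all(df$sex %in% HIA_SEXES)) stop(sprintf("%s: unknown sex", path))
  if (!all(df$smoking %in% HIA_SMOKING)) {
    stop(sprintf("%s: smoking must be one of %s", path,
                 paste(HIA_SMOKING, collapse = "/")))
  }
  if (!all(df$gali %in% HIA_GALI)) {
    stop(sprintf("%s: gali must be one of %s", path,
                 paste(HIA_GALI, collapse = "/")))
  }
  if (any(df$weight <= 0)) stop(sprintf("%s: weights must be > 0", path))
  df[c("age", "sex", "smoking", "gali", "weight")]
}

#' Write survey microdata
#' @param df Microdata data frame.
#' @param path Output file path.
#' @export
write_survey <- function(df, path) {
  write_hia_csv(df[c("age", "sex", "smoking", "gali", "weight")], path)
}

#' Parse a run configuration file
#'
#' A YAML key/value file with optional keys `baseline_year`, `horizon_years`,
#' `n_per_class`, `seed`, `report_ages`, `report_years` and `scenarios` (a
#' list of scenario names from [scenario_names()]). Absent keys take the
#' defaults below; an empty file yields the reference-only default run.
#'
#' @param path File path, or `NULL` for pure defaults.
#' @return A list of class `hia_config` with fields `baseline_year` (2018),
#'   `horizon_years` (30), `n_per_class` (2500), `seed` (1), `scenarios`
#'   (`"reference"`), `report_ages` (15), `report_years`
#'   (baseline + 10, baseline + 30).
#' @export
parse_config <- function(path = NULL) {
  raw <- list()
  if (!is.null(path)) {
    raw <- yaml::read_yaml(path)
    if (is.null(raw)) raw <- list()
  }
  known <- c("baseline_year", "horizon_years", "n_per_class", "seed",
             "scenarios", "report_ages", "report_years")
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0L) {
    stop(sprintf("config: unknown key '%s'", unknown[[1L]]))
  }
  cfg <- list(
    baseline_year = raw$baseline_year %||% 2018L,
    horizon_years = raw$horizon_years %||% 30L,
    n_per_class = raw$n_per_class %||% 2500L,
    seed = raw$seed %||% 1L,
    scenarios = unlist(raw$scenarios) %||% "reference",
    report_ages = unlist(raw$report_ages) %||% 15L
  )
  if (!is.numeric(cfg$seed) || cfg$seed != as.integer(cfg$seed)) {
    stop("config: seed must be an integer")
  }
  if (cfg$horizon_years < 1) stop("config: horizon_years must be >= 1")
  if (cfg$n_per_class < 1) stop("config: n_per_class must be >= 1")
  cfg$report_years <- unlist(raw$report_years) %||%
    (cfg$baseline_year + c(10L, 30L))
  bad <- setdiff(cfg$scenarios, scenario_names())
  if (length(bad) > 0L) {
    stop(sprintf("config: unknown scenario '%s'; valid names: %s",
                 bad[[1L]], paste(scenario_names(), collapse = ", ")))
  }
  cfg$baseline_year <- as.integer(cfg$baseline_year)
  cfg$horizon_years <- as.integer(cfg$horizon_years)
  cfg$n_per_class <- as.integer(cfg$n_per_class)
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = "hia_config")
}

#' Construct a run configuration in code
#'
#' @param baseline_year First projected calendar year.
#' @param horizon_years Number of years projected beyond the baseline.
#' @param n_per_class Simulated individuals per one-year age class and sex.
#' @param seed Root random seed.
#' @param scenarios Character vector of scenario names.
#' @param report_ages Ages at which expectancies are reported.
#' @param report_years Calendar years at which Sullivan expectancies are
#'   reported; defaults to baseline + 10 and baseline + 30.
#' @return An `hia_config` list.
#' @export
hia_config <- function(baseline_year = 2018L, horizon_years = 30L,
                       n_per_class = 2500L, seed = 1L,
                       scenarios = "reference", report_ages = 15L,
                       report_years = NULL) {
  cfg <- list(baseline_year = baseline_year, horizon_years = horizon_years,
              n_per_class = n_per_class, seed = seed, scenarios = scenarios,
              report_ages = report_ages,
              report_years = report_years %||% (baseline_year + c(10L, 30L)))
  bad <- setdiff(cfg$scenarios, scenario_names())
  if (length(bad) > 0L) {
    stop(sprintf("unknown scenario '%s'; valid names: %s", bad[[1L]],
                 paste(scenario_names(), collapse = ", ")))
  }
  if (cfg$horizon_years < 1) stop("horizon_years must be >= 1")
  if (cfg$n_per_class < 1) stop("n_per_class must be >= 1")
  cfg$baseline_year <- as.integer(cfg$baseline_year)
  cfg$horizon_years <- as.integer(cfg$horizon_years)
  cfg$n_per_class <- as.integer(cfg$n_per_class)
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = "hia_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
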