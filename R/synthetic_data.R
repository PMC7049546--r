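#' @title Synthetic survey and demography generator
#' @description Generates cross-sectional health-survey microdata (age, sex,
#'   smoking state, activity limitation) and demographic schedules (population
#'   counts, all-cause mortality, projected newborns) with the statistical
#'   structure the projection model assumes: smoking prevalence with a
#'   mid-adulthood peak among current smokers, disability prevalence rising in
#'   age and elevated among (ex-)smokers, and Gompertz adult mortality.
#' @name synthetic_data
NULL

#' Default generating truth
#'
#' Deterministic parameter set used by all generators. Smoking is
#' parameterized per sex by a strictly decreasing logistic never-smoker curve
#' and a decreasing logistic share of ever-smokers who still smoke; the
#' decreasing never curve guarantees that the net start probabilities implied
#' by the curves are nonnegative at every age, so the stationarity property of
#' the projection holds without clipping. Disability follows a logistic
#' baseline (never-smoker) log-odds curve, shifted by log odds ratios for
#' current and former smokers. Mortality is Gompertz,
#' q(a) = 1 - exp(-level * exp(slope * a)).
#'
#' @return A list of class `hia_truth` with components `smoking`,
#'   `disability`, `rr`, `gompertz` and `births` (all per sex).
#' @export
default_truth <- function() {
  structure(list(
    smoking = list(
      # logit scale, age entering as u = age / 10
      male = list(never = c(intercept = 1.70, slope = -0.21),
                  current_share = c(intercept = 2.20, slope = -0.42)),
      female = list(never = c(intercept = 1.80, slope = -0.20),
                    current_share = c(intercept = 2.00, slope = -0.40))
    ),
    disability = list(
      male = list(base = c(intercept = -5.00, slope = 0.55),
                  or_current = 1.8, or_former = 1.3),
      female = list(base = c(intercept = -5.10, slope = 0.57),
                    or_current = 2.0, or_former = 1.4)
    ),
    rr = list(male = c(never = 1, current = 2.0, former = 1.4),
              female = c(never = 1, current = 1.9, former = 1.3)),
    gompertz = list(male = c(level = 4.4e-05, slope = 0.094),
                    female = c(level = 2.2e-05, slope = 0.098)),
    births = list(male = 61500, female = 58500, annual_change = -0.003)
  ), class = "hia_truth")
}

#' Generating smoking-state probabilities
#'
#' Evaluates the truth's smoking curves. Ages below 15 are never-smokers by
#' convention.
#'
#' @param truth An `hia_truth` list.
#' @param age Integer vector of ages.
#' @param sex A single sex, `"male"` or `"female"`.
#' @return A matrix with columns `never`, `current`, `former`, rows matching
#'   `age`, rows summing to 1.
#' @export
truth_smoking_probs <- function(truth, age, sex) {
  u <- age / 10
  par <- truth$smoking[[sex]]
  p_never <- stats::plogis(par$never[["intercept"]] + par$never[["slope"]] * u)
  share <- stats::plogis(par$current_share[["intercept"]] +
                           par$current_share[["slope"]] * u)
  out <- cbind(never = p_never,
               current = (1 - p_never) * share,
               former = (1 - p_never) * (1 - share))
  young <- age < 15
  out[young, ] <- rep(c(1, 0, 0), each = sum(young))
  out
}

#' Generating state-specific disability probabilities
#'
#' @param truth An `hia_truth` list.
#' @param age Integer vector of ages.
#' @param sex A single sex.
#' @param state Smoking state, recycled against `age`.
#' @return Probability vector; 0 below age 15.
#' @export
truth_disability_probs <- function(truth, age, sex,
                                   state = c("never", "current", "former")) {
  par <- truth$disability[[sex]]
  state <- rep(match.arg(state, several.ok = TRUE), length.out = length(age))
  lor <- log(c(never = 1, current = par$or_current,
               former = par$or_former))[state]
  p <- stats::plogis(par$base[["intercept"]] + par$base[["slope"]] * age / 10 +
                       lor)
  p[age < 15] <- 0
  p
}

#' Smoking prevalence table implied by the truth
#'
#' @param truth An `hia_truth` list.
#' @return A prevalence data frame on the full grid (ages < 15 are
#'   `(1, 0, 0)`).
#' @export
truth_prevalence <- function(truth) {
  grid <- age_sex_grid()
  rows <- lapply(HIA_SEXES, function(s) truth_smoking_probs(truth, HIA_AGES, s))
  m <- do.call(rbind, rows)
  cbind(grid, as.data.frame(m))
}

#' Overall disability prevalence table implied by the truth
#'
#' Mixes the state-specific disability probabilities over the truth's smoking
#' prevalence.
#'
#' @param truth An `hia_truth` list.
#' @return A rate table (`age`, `sex`, `value`).
#' @export
truth_disability_prevalence <- function(truth) {
  grid <- age_sex_grid()
  value <- unlist(lapply(HIA_SEXES, function(s) {
    p <- truth_smoking_probs(truth, HIA_AGES, s)
    rowSums(vapply(HIA_SMOKING, function(k) {
      p[, k] * truth_disability_probs(truth, HIA_AGES, s, k)
    }, numeric(length(HIA_AGES))))
  }))
  out <- cbind(grid, value = value)
  attr(out, "kind") <- "probability"
  out
}

truth_mortality_q <- function(truth, age, sex) {
  g <- truth$gompertz[[sex]]
  pmin(1 - exp(-g[["level"]] * exp(g[["slope"]] * age)), 1)
}

#' Generate demographic schedules
#'
#' Population counts are the stationary population implied by the mortality
#' schedule and the baseline birth counts; the newborn series declines
#' geometrically at the truth's annual rate.
#'
#' @param truth An `hia_truth` list.
#' @param baseline_year First projected calendar year.
#' @param horizon_years Years of projection the newborn series must cover
#'   (the series is generated with a 5-year margin).
#' @return A list with `population` (counts rate table), `mortality`
#'   (probability rate table) and `newborns` (data frame `year`, `sex`,
#'   `value`).
#' @export
generate_demography <- function(truth, baseline_year = 2018L,
                                horizon_years = 30L) {
  grid <- age_sex_grid()
  q <- unlist(lapply(HIA_SEXES, function(s) truth_mortality_q(truth, HIA_AGES, s)))
  mortality <- cbind(grid, value = q)
  attr(mortality, "kind") <- "probability"
  pop <- unlist(lapply(HIA_SEXES, function(s) {
    qs <- truth_mortality_q(truth, HIA_AGES, s)
    surv <- cumprod(c(1, (1 - qs)[-length(qs)]))
    truth$births[[s]] * surv
  }))
  population <- cbind(grid, value = pop)
  attr(population, "kind") <- "rate"
  years <- baseline_year + 0:(horizon_years + 5L)
  newborns <- do.call(rbind, lapply(HIA_SEXES, function(s) {
    data.frame(year = years, sex = s,
               value = truth$births[[s]] *
                 (1 + truth$births$annual_change)^(years - baseline_year),
               stringsAsFactors = FALSE)
  }))
  newborns <- newborns[order(newborns$year, match(newborns$sex, HIA_SEXES)), ]
  rownames(newborns) <- NULL
  list(population = population, mortality = mortality, newborns = newborns)
}

#' Generate survey microdata
#'
#' Draws `n` records aged 15+ from the stationary population age structure,
#' assigns a smoking state from the generating curves and an activity
#' limitation (GALI) with state-specific odds; disabled records are split
#' 70/30 into not-severely / severely limited. All weights are 1.
#'
#' @param truth An `hia_truth` list.
#' @param n Number of records (>= 1).
#' @param seed Integer seed; identical inputs give identical output.
#' @return A microdata data frame with columns `age`, `sex`, `smoking`,
#'   `gali`, `weight`.
#' @export
generate_survey <- function(truth, n, seed) {
  stopifnot(n >= 1)
  set.seed(seed)
  demo <- generate_demography(truth)
  pop <- demo$population
  pop <- pop[pop$age >= 15, ]
  idx <- sample.int(nrow(pop), n, replace = TRUE, prob = pop$value)
  age <- pop$age[idx]
  sex <- pop$sex[idx]
  smoking <- character(n)
  disabled <- logical(n)
  for (s in HIA_SEXES) {
    sel <- which(sex == s)
    if (length(sel) == 0L) next
    probs <- truth_smoking_probs(truth, age[sel], s)
    u <- stats::runif(length(sel))
    st <- ifelse(u < probs[, "never"], "never",
                 ifelse(u < probs[, "never"] + probs[, "current"],
                        "current", "former"))
    smoking[sel] <- st
    pd <- truth_disability_probs(truth, age[sel], s, st)
    disabled[sel] <- stats::runif(length(sel)) < pd
  }
  gali <- rep("none", n)
  sev <- stats::runif(n) < 0.30
  gali[disabled] <- ifelse(sev[disabled], "severe", "not_severe")
  data.frame(age = age, sex = sex, smoking = smoking, gali = gali,
             weight = 1, stringsAsFactors = FALSE)
}

#' Low-smoking alternative prevalence table
#'
#' A counterfactual prevalence table emulating a low-smoking European
#' population: at every age 15+, current-smoker prevalence is reduced to 45%
#' of the default truth's, with 30% of the removed mass moved to former
#' smokers and the remainder to never smokers. Ages below 15 are unchanged
#' (all never smokers).
#'
#' @param truth An `hia_truth` list.
#' @return A valid prevalence data frame with current prevalence strictly
#'   below the truth's at every age 15+.
#' @export
low_smoking_prevalence <- function(truth) {
  base <- truth_prevalence(truth)
  adult <- base$age >= 15
  removed <- base$current[adult] * 0.55
  base$current[adult] <- base$current[adult] - removed
  base$former[adult] <- base$former[adult] + 0.30 * removed
  base$never[adult] <- 1 - base$current[adult] - base$former[adult]
  validate_prevalence(base, "low-smoking prevalence")
}
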