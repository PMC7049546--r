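# Lazily built, cached pipeline objects shared across test files. Everything
# derives from the default synthetic truth; heavy objects (the 200k survey,
# the fitted prevalence models, the full-size microsimulation) are built once
# per test run.

.hia_cache <- new.env(parent = emptyenv())

hx <- function(name, expr) {
  if (!exists(name, envir = .hia_cache)) {
    assign(name, force(expr), envir = .hia_cache)
  }
  get(name, envir = .hia_cache)
}

hx_truth <- function() hx("truth", default_truth())
hx_demo <- function() hx("demo", generate_demography(hx_truth()))
hx_prev <- function() hx("prev", truth_prevalence(hx_truth()))

hx_or_set <- function() hx("or_set", {
  truth <- hx_truth()
  out <- lapply(HIA_SEXES_T(), function(s) {
    c(never = 1, current = truth$disability[[s]]$or_current,
      former = truth$disability[[s]]$or_former)
  })
  names(out) <- HIA_SEXES_T()
  out
})

HIA_SEXES_T <- function() c("male", "female")
HIA_SMOKING_T <- function() c("never", "current", "former")

hx_sm <- function() hx("sm", partition_mortality(hx_demo()$mortality,
                                                 hx_prev(), hx_truth()$rr))
hx_ts <- function() hx("ts", derive_net_transitions(hx_prev(), hx_sm()))
hx_pi <- function() hx("pi", truth_disability_prevalence(hx_truth()))
hx_dis <- function() hx("dis", solve_disability(hx_prev(), hx_pi(),
                                                hx_or_set()))

hx_cfg <- function(...) hia_config(...)

hx_specs <- function() hx("specs", {
  lapply(scenario_names(), function(nm) {
    if (nm == "low_prevalence") {
      make_scenario(nm, list(prevalence = low_smoking_prevalence(hx_truth())))
    } else {
      make_scenario(nm)
    }
  })
})

# Deterministic reference projection over the full 30-year horizon.
hx_ref_det <- function() hx("ref_det", {
  run_deterministic(hx_prev(), hx_ts(), hx_sm(), hx_dis(), hx_cfg(),
                    hx_demo()$population, hx_demo()$newborns)
})

# Full-size reference microsimulation (2500 per age class and sex).
hx_ref_micro <- function() hx("ref_micro", {
  simulate_population(hx_prev(), hx_ts(), hx_sm(), hx_dis(),
                      hx_cfg(seed = 20180501), hx_demo()$population,
                      hx_demo()$newborns)
})

hx_survey <- function() hx("survey", generate_survey(hx_truth(), 200000L,
                                                     424242L))
hx_smoking_fit <- function() hx("smoking_fit",
                                estimate_smoking_prevalence(hx_survey()))
hx_disability_fit <- function() hx("disability_fit",
                                   estimate_disability_model(hx_survey()))

# Nine deterministic scenario runs at the default horizon.
hx_scenario_runs <- function() hx("scenario_runs", {
  deterministic_runs(hx_specs(), hx_prev(), hx_ts(), hx_sm(), hx_dis(),
                     hx_cfg(), hx_demo()$population, hx_demo()$newborns)
})

# Constant-valued grid tables used by unit tests.
flat_prevalence <- function(never, current, former) {
  grid <- age_sex_grid()
  cbind(grid, never = never, current = current, former = former)
}

flat_rate <- function(value, kind = "probability") {
  grid <- age_sex_grid()
  out <- cbind(grid, value = value)
  attr(out, "kind") <- kind
  out
}

flat_effects <- function(current, former) {
  out <- lapply(HIA_SEXES_T(), function(s) c(never = 1, current = current,
                                             former = former))
  names(out) <- HIA_SEXES_T()
  out
}

max_prevalence_drift <- function(agg) {
  pp <- prevalence_projection(agg)
  base <- pp[pp$year == min(pp$year), c("never", "current", "former")]
  err <- 0
  for (yr in unique(pp$year)) {
    sub <- pp[pp$year == yr, c("never", "current", "former")]
    err <- max(err, max(abs(as.matrix(sub) - as.matrix(base))))
  }
  err
}
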