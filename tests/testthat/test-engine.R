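test_that("the default design instantiates 480,000 individuals", {
  cfg <- hx_cfg(n_per_class = 2500L, horizon_years = 2L, seed = 1L)
  agg <- simulate_population(hx_prev(), hx_ts(), hx_sm(), hx_dis(), cfg,
                             hx_demo()$population, hx_demo()$newborns)
  expect_identical(attr(agg, "n_individuals_baseline"), 480000L)
})

test_that("microsimulation is deterministic given the seed", {
  cfg <- hx_cfg(n_per_class = 50L, horizon_years = 5L, seed = 42L)
  a <- simulate_population(hx_prev(), hx_ts(), hx_sm(), hx_dis(), cfg,
                           hx_demo()$population, hx_demo()$newborns)
  b <- simulate_population(hx_prev(), hx_ts(), hx_sm(), hx_dis(), cfg,
                           hx_demo()$population, hx_demo()$newborns)
  expect_identical(a, b)
  cfg$seed <- 43L
  c <- simulate_population(hx_prev(), hx_ts(), hx_sm(), hx_dis(), cfg,
                           hx_demo()$population, hx_demo()$newborns)
  expect_false(identical(a$N_current, c$N_current))
})

test_that("zero mortality and zero transitions conserve state composition", {
  prev <- flat_prevalence(0.5, 0.3, 0.2)
  sm <- partition_mortality(flat_rate(0), prev, flat_effects(1, 1))
  ts <- derive_net_transitions(prev, sm)
  dis <- solve_disability(prev, flat_rate(0.1), flat_effects(1, 1))
  cfg <- hx_cfg(horizon_years = 5L)
  agg <- run_deterministic(prev, ts, sm, dis, cfg, hx_demo()$population,
                           hx_demo()$newborns)
  expect_true(all(agg$deaths == 0))
  # each cohort keeps its baseline composition as it ages
  base <- agg[agg$year == 2018, ]
  for (i in 1:5) {
    shifted <- agg[agg$year == 2018 + i & agg$age %in% (i:(94 + i)), ]
    for (s in HIA_SEXES_T()) {
      b <- base[base$sex == s & base$age <= 94 - i + 0, ]
      sh <- shifted[shifted$sex == s & shifted$age <= 94, ]
      expect_equal(sh$N[sh$age >= i], b$N[seq_len(sum(sh$age >= i))],
                   tolerance = 1e-9)
    }
  }
  # shares stay at the baseline mixture everywhere above the newborn ages
  old <- agg$age > agg$year - 2018
  expect_equal(agg$N_current[old] / agg$N[old],
               rep(0.3, sum(old)), tolerance = 1e-9)
})

test_that("population accounting closes for cohorts below the open class", {
  for (agg in list(hx_ref_det(),
                   simulate_population(hx_prev(), hx_ts(), hx_sm(), hx_dis(),
                                       hx_cfg(n_per_class = 100L,
                                              horizon_years = 8L, seed = 2L),
                                       hx_demo()$population,
                                       hx_demo()$newborns))) {
    yrs <- sort(unique(agg$year))
    for (t in head(yrs, -1L)) {
      now <- agg[agg$year == t, ]
      nxt <- agg[agg$year == t + 1L, ]
      for (s in HIA_SEXES_T()) {
        a <- now[now$sex == s & now$age <= 93, ]
        b <- nxt[nxt$sex == s & nxt$age %in% (a$age + 1L), ]
        expect_equal(b$N, a$N - a$deaths, tolerance = 1e-9)
      }
    }
  }
})

test_that("microsimulation converges to the deterministic recursion", {
  # max absolute prevalence error shrinks like n^(-1/2)
  det <- run_deterministic(hx_prev(), hx_ts(), hx_sm(), hx_dis(),
                           hx_cfg(horizon_years = 10L),
                           hx_demo()$population, hx_demo()$newborns)
  det_share <- det$N_current / det$N
  adult <- det$age >= 15
  err_at <- function(n, seed) {
    agg <- simulate_population(hx_prev(), hx_ts(), hx_sm(), hx_dis(),
                               hx_cfg(n_per_class = n, horizon_years = 10L,
                                      seed = seed),
                               hx_demo()$population, hx_demo()$newborns)
    max(abs(agg$N_current[adult] / agg$N[adult] - det_share[adult]))
  }
  errs <- vapply(c(100L, 400L, 1600L), function(n) {
    mean(vapply(1:3, function(r) err_at(n, 1000L + r), numeric(1L)))
  }, numeric(1L))
  expect_true(all(diff(errs) < 0))
  expect_gt(errs[[1L]] / errs[[3L]], 2)
})

test_that("cohort life expectancy matches the geometric closed form", {
  # constant q = 0.5, no transitions, mid-interval deaths: LE = (1 - q/2)/q
  prev <- flat_prevalence(1, 0, 0)
  q <- flat_rate(0.5)
  sm <- partition_mortality(q, prev, flat_effects(1, 1))
  ts <- derive_net_transitions(prev, sm)
  dis <- solve_disability(prev, flat_rate(0), flat_effects(1, 1))
  cfg <- hx_cfg(horizon_years = 30L)
  agg <- run_deterministic(prev, ts, sm, dis, cfg, hx_demo()$population,
                           hx_demo()$newborns)
  le <- cohort_expectancies(agg, 0L, "male")$LE
  expect_equal(le, 1.5, tolerance = 1e-6)
  expect_equal(sullivan_expectancies(agg, 2020, 0L, "female")$LE, 1.5,
               tolerance = 1e-6)
})

test_that("common random numbers cancel noise in scenario differences", {
  specs <- list(make_scenario("reference"), make_scenario("all_quit"))
  cfg0 <- hx_cfg(n_per_class = 100L, horizon_years = 10L)
  run_pair <- function(seed, common) {
    cfg <- cfg0
    cfg$seed <- seed
    if (common) {
      runs <- common_random_runs(specs, hx_prev(), hx_ts(), hx_sm(), hx_dis(),
                                 cfg, hx_demo()$population,
                                 hx_demo()$newborns)
    } else {
      runs <- lapply(seq_along(specs), function(i) {
        cfg$seed <- seed + 1000L * i
        ap <- apply_scenario(specs[[i]], hx_prev(), hx_ts(), hx_sm())
        simulate_population(ap$prev, ap$ts, hx_sm(), hx_dis(), cfg,
                            hx_demo()$population, hx_demo()$newborns)
      })
      names(runs) <- c("reference", "all_quit")
    }
    sullivan_expectancies(runs$all_quit, 2028, 15, "male")$LE -
      sullivan_expectancies(runs$reference, 2028, 15, "male")$LE
  }
  seeds <- 1:12
  d_common <- vapply(seeds, run_pair, numeric(1L), common = TRUE)
  d_indep <- vapply(seeds, run_pair, numeric(1L), common = FALSE)
  expect_lt(var(d_common), var(d_indep))

  # identical scenario under common draws: difference exactly zero
  runs <- common_random_runs(list(make_scenario("reference"),
                                  make_scenario("reference")),
                             hx_prev(), hx_ts(), hx_sm(), hx_dis(), cfg0,
                             hx_demo()$population, hx_demo()$newborns)
  expect_identical(runs[[1L]]$N_current, runs[[2L]]$N_current)
  expect_identical(runs[[1L]]$disabled_py, runs[[2L]]$disabled_py)
})

test_that("a horizon beyond the newborn series is rejected", {
  cfg <- hx_cfg(horizon_years = 60L, n_per_class = 10L)
  expect_error(
    run_deterministic(hx_prev(), hx_ts(), hx_sm(), hx_dis(), cfg,
                      hx_demo()$population, hx_demo()$newborns),
    "newborn"
  )
})
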