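test_that("mortality partition honors relative risks and the mixture identity", {
  prev <- flat_prevalence(0.5, 0.3, 0.2)
  q <- flat_rate(0.01)

  null_sm <- partition_mortality(q, prev, flat_effects(1, 1))
  expect_equal(null_sm$q_never, rep(0.01, 192), tolerance = 1e-15)
  expect_equal(null_sm$q_current, null_sm$q_never, tolerance = 1e-15)

  degen <- partition_mortality(flat_rate(0.02), flat_prevalence(1, 0, 0),
                               flat_effects(3, 2))
  expect_equal(degen$q_never, rep(0.02, 192), tolerance = 1e-15)

  sm <- partition_mortality(q, prev, flat_effects(2, 1.5))
  expect_equal(sm$q_never[[1L]], 0.01 / 1.4, tolerance = 1e-12)
  expect_equal(sm$q_current[[1L]], 2 * 0.01 / 1.4, tolerance = 1e-12)
  expect_equal(sm$q_former[[1L]], 1.5 * 0.01 / 1.4, tolerance = 1e-12)
  mixture <- prev$never * sm$q_never + prev$current * sm$q_current +
    prev$former * sm$q_former
  expect_equal(mixture, q$value, tolerance = 1e-14)

  expect_warning(
    partition_mortality(flat_rate(0.9), prev, flat_effects(2, 1.5)),
    "capped"
  )
})

test_that("net transitions vanish in the stationary homogeneous case", {
  prev <- flat_prevalence(0.5, 0.3, 0.2)
  sm <- partition_mortality(flat_rate(0.01), prev, flat_effects(1, 1))
  ts <- derive_net_transitions(prev, sm)
  expect_equal(ts$start, rep(0, 192), tolerance = 1e-12)
  expect_equal(ts$net_cf, rep(0, 192), tolerance = 1e-12)
})

test_that("a pure never-share drop maps to the matching start probability", {
  sol <- smokehia:::solve_transition_cell(
    p = c(1, 0, 0), q = rep(0.01, 3), target = c(0.9, 0.1, 0))
  expect_equal(sol[["start"]], 0.1, tolerance = 1e-12)
  expect_equal(sol[["clipped"]], 0)
})

test_that("derived transitions reproduce the next-age prevalence exactly", {
  p <- c(0.5, 0.3, 0.2)
  q <- c(1, 2, 1.5) * 0.01 / 1.4
  target <- c(0.48, 0.28, 0.24)
  sol <- smokehia:::solve_transition_cell(p, q, target)
  out <- project_prevalence_one_step(p, q, sol[["start"]], sol[["net_cf"]])
  expect_lt(max(abs(out - target)), 1e-10)
})

test_that("one-step projection handles the degenerate flows", {
  p <- c(0.5, 0.3, 0.2)
  out <- project_prevalence_one_step(p, rep(0.2, 3), 0, 0)
  expect_equal(unname(out), p, tolerance = 1e-15)
  out2 <- project_prevalence_one_step(c(1, 0, 0), rep(0, 3), 1, 0)
  expect_equal(unname(out2), c(0, 1, 0), tolerance = 1e-15)
})

test_that("transition solver agrees with a nested numerical root-finder", {
  # forward-construct feasible targets, then invert: closed-form solution,
  # one-step projection and a uniroot-based solver must all agree
  set.seed(2024)
  n_cells <- 1000L
  for (i in seq_len(n_cells)) {
    p <- as.numeric(rmultinom(1, 1000, runif(3, 0.05, 1))) / 1000
    q <- runif(3, 0, 0.3)
    s_true <- runif(1, 0, 0.5)
    cf_true <- runif(1, -0.5, 0.5)
    target <- project_prevalence_one_step(p, q, s_true, cf_true)
    sol <- smokehia:::solve_transition_cell(p, q, target)
    round_trip <- project_prevalence_one_step(p, q, sol[["start"]],
                                              sol[["net_cf"]])
    expect_lt(max(abs(round_trip - target)), 1e-10)
    if (i <= 200L && p[[1L]] > 0.05) {
      s_oracle <- uniroot(function(s) {
        project_prevalence_one_step(p, q, s, 0)[[1L]] - target[[1L]]
      }, c(0, 1), tol = 1e-14)$root
      cf_oracle <- uniroot(function(cf) {
        project_prevalence_one_step(p, q, s_oracle, cf)[[2L]] - target[[2L]]
      }, c(-1, 1), tol = 1e-14)$root
      expect_lt(abs(sol[["start"]] - s_oracle), 1e-8)
      expect_lt(abs(sol[["net_cf"]] - cf_oracle), 1e-8)
    }
  }
})

test_that("projecting the baseline curve age-by-age reproduces it", {
  prev <- hx_prev()
  sm <- hx_sm()
  ts <- hx_ts()
  for (s in HIA_SEXES_T()) {
    pm <- as.matrix(prev[prev$sex == s, HIA_SMOKING_T()])
    qm <- as.matrix(sm[sm$sex == s, c("q_never", "q_current", "q_former")])
    tm <- ts[ts$sex == s, ]
    for (i in 1:95) {
      out <- project_prevalence_one_step(pm[i, ], qm[i, ], tm$start[i],
                                         tm$net_cf[i])
      expect_lt(max(abs(out - pm[i + 1L, ])), 1e-10)
    }
  }
})

test_that("disability inversion recovers a forward-constructed baseline", {
  # homogeneous odds: every state's probability equals the overall prevalence
  pi_flat <- flat_rate(0.2)
  prev <- flat_prevalence(0.5, 0.3, 0.2)
  hom <- solve_disability(prev, pi_flat, flat_effects(1, 1))
  expect_equal(hom$d_never, rep(0.2, 192), tolerance = 1e-10)
  expect_equal(hom$d_current, rep(0.2, 192), tolerance = 1e-10)

  only_never <- solve_disability(flat_prevalence(1, 0, 0), pi_flat,
                                 flat_effects(2, 1.5))
  expect_equal(only_never$d_never, rep(0.2, 192), tolerance = 1e-10)

  # beta0 = log 0.1 with OR (1, 2, 1.5) over p = (0.5, 0.3, 0.2)
  pi_val <- 0.5 * 0.1 / 1.1 + 0.3 * 0.2 / 1.2 + 0.2 * 0.15 / 1.15
  dis <- solve_disability(prev, flat_rate(pi_val), flat_effects(2, 1.5))
  expect_equal(dis$d_never, rep(0.1 / 1.1, 192), tolerance = 1e-10)
  expect_equal(dis$beta0, rep(log(0.1), 192), tolerance = 1e-10)

  # boundary prevalences map to all-0 / all-1
  edge <- solve_disability(prev, flat_rate(c(0, rep(0.3, 190), 1)),
                           flat_effects(2, 1.5))
  expect_identical(edge$d_current[[1L]], 0)
  expect_identical(edge$d_former[[192L]], 1)
})

test_that("disability inversion matches uniroot and is monotone in prevalence", {
  set.seed(77)
  prev <- flat_prevalence(0.5, 0.3, 0.2)
  prev$never <- runif(192, 0.2, 0.8)
  prev$current <- (1 - prev$never) * runif(192)
  prev$former <- 1 - prev$never - prev$current
  pi_tab <- flat_rate(runif(192, 0.01, 0.9))
  eff <- flat_effects(1.8, 1.3)
  dis <- solve_disability(prev, pi_tab, eff)
  # independent scalar root-finder per cell
  for (i in sample.int(192, 50)) {
    b0 <- uniroot(function(b) {
      prev$never[i] * plogis(b) + prev$current[i] * plogis(b + log(1.8)) +
        prev$former[i] * plogis(b + log(1.3)) - pi_tab$value[i]
    }, c(-50, 50), tol = 1e-14)$root
    expect_lt(abs(dis$beta0[i] - b0), 1e-9)
  }
  # exact odds ratios by construction
  odds <- function(x) x / (1 - x)
  expect_equal(odds(dis$d_current) / odds(dis$d_never), rep(1.8, 192),
               tolerance = 1e-9)
  # mixture conservation
  mix <- prev$never * dis$d_never + prev$current * dis$d_current +
    prev$former * dis$d_former
  expect_equal(mix, pi_tab$value, tolerance = 1e-10)
  # beta0 strictly increasing in pi
  pis <- seq(0.05, 0.95, by = 0.05)
  b0s <- vapply(pis, function(p) {
    solve_disability(flat_prevalence(0.5, 0.3, 0.2), flat_rate(p),
                     eff)$beta0[[1L]]
  }, numeric(1L))
  expect_true(all(diff(b0s) > 0))
})

test_that("pipeline mixtures conserve baseline mortality and disability", {
  prev <- hx_prev()
  sm <- hx_sm()
  dis <- hx_dis()
  q <- hx_demo()$mortality$value
  mix_q <- prev$never * sm$q_never + prev$current * sm$q_current +
    prev$former * sm$q_former
  expect_equal(mix_q, q, tolerance = 1e-12)
  mix_d <- prev$never * dis$d_never + prev$current * dis$d_current +
    prev$former * dis$d_former
  expect_equal(mix_d, hx_pi()$value, tolerance = 1e-10)
})
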