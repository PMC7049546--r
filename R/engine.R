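#' @title Population projection engines
#' @description Projects the population forward under a scenario, either by
#'   partial microsimulation (stochastic smoking histories, deterministic
#'   fractional survival weights -- no random death events) or by the exact
#'   deterministic multistate recursion that is the microsimulation's
#'   expectation. Both produce identical bookkeeping: weighted person counts
#'   by calendar year, age, sex and smoking state, with death flows,
#'   person-years (mid-interval deaths) and expected disabled person-years.
#' @name engine
NULL

# Pack canonical-grid tables into [age+1, sex] / [age+1, sex, state] arrays.
engine_arrays <- function(prev, ts, sm, dis, population) {
  list(
    prev = array(c(prev$never, prev$current, prev$former), c(96L, 2L, 3L)),
    q = array(c(sm$q_never, sm$q_current, sm$q_former), c(96L, 2L, 3L)),
    d = array(c(dis$d_never, dis$d_current, dis$d_former), c(96L, 2L, 3L)),
    start = array(ts$start, c(96L, 2L)),
    cf = array(ts$net_cf, c(96L, 2L)),
    pop = array(population$value, c(96L, 2L))
  )
}

newborn_lookup <- function(newborns, years) {
  lut <- matrix(NA_real_, nrow = length(years), ncol = 2L,
                dimnames = list(years, HIA_SEXES))
  for (j in seq_along(HIA_SEXES)) {
    sub <- newborns[newborns$sex == HIA_SEXES[[j]], ]
    lut[, j] <- sub$value[match(years, sub$year)]
  }
  if (anyNA(lut)) {
    stop("projection horizon exceeds the newborn series")
  }
  lut
}

aggregates_frame <- function(years, N, D, L, DIS) {
  grid <- age_sex_grid()
  ny <- length(years)
  df <- data.frame(
    year = rep(years, each = nrow(grid)),
    age = rep(grid$age, times = ny),
    sex = rep(grid$sex, times = ny),
    stringsAsFactors = FALSE
  )
  df$N <- as.numeric(vapply(seq_len(ny), function(t) rowSums(N[[t]], dims = 2L),
                            numeric(192L)))
  df$N_never <- as.numeric(vapply(seq_len(ny), function(t) N[[t]][, , 1L],
                                  numeric(192L)))
  df$N_current <- as.numeric(vapply(seq_len(ny), function(t) N[[t]][, , 2L],
                                    numeric(192L)))
  df$N_former <- as.numeric(vapply(seq_len(ny), function(t) N[[t]][, , 3L],
                                   numeric(192L)))
  df$deaths <- as.numeric(vapply(seq_len(ny), function(t) D[[t]],
                                 numeric(192L)))
  df$person_years <- as.numeric(vapply(seq_len(ny), function(t) L[[t]],
                                       numeric(192L)))
  df$disabled_py <- as.numeric(vapply(seq_len(ny), function(t) DIS[[t]],
                                      numeric(192L)))
  df
}

#' Deterministic multistate projection
#'
#' Exact expectation of the microsimulation: a matrix recursion on
#' state-count vectors. Each year, state-specific mortality is applied, then
#' the simultaneous net flows, then ages advance (the 95+ class retains its
#' survivors) and a newborn cohort of never smokers enters at age 0.
#'
#' @param prev Scenario prevalence table (already transformed).
#' @param ts Scenario transition schedule.
#' @param sm `state_mortality`.
#' @param dis `disability_model`.
#' @param cfg `hia_config`.
#' @param population Baseline population counts rate table.
#' @param newborns Newborn series (`year`, `sex`, `value`).
#' @return A data frame of class `hia_aggregates` with one row per
#'   year x age x sex: `N`, `N_never`, `N_current`, `N_former`, `deaths`,
#'   `person_years` (N - deaths/2) and `disabled_py` (expected disabled
#'   person-years).
#' @export
run_deterministic <- function(prev, ts, sm, dis, cfg, population, newborns) {
  a <- engine_arrays(prev, ts, sm, dis, population)
  years <- cfg$baseline_year + 0:cfg$horizon_years
  nb <- newborn_lookup(newborns, years[-1L])
  M <- a$prev * as.numeric(a$pop)
  quit <- pmax(a$cf, 0)
  restart <- pmax(-a$cf, 0)
  N <- D <- L <- DIS <- vector("list", length(years))
  for (t in seq_along(years)) {
    Dk <- M * a$q
    Lk <- M - Dk / 2
    N[[t]] <- M
    D[[t]] <- rowSums(Dk, dims = 2L)
    L[[t]] <- rowSums(Lk, dims = 2L)
    DIS[[t]] <- rowSums(Lk * a$d, dims = 2L)
    if (t == length(years)) break
    S <- M - Dk
    pool <- S[, , 2L] + a$start * S[, , 1L]
    Tn <- S[, , 1L] * (1 - a$start)
    Tc <- pool * (1 - quit) + restart * S[, , 3L]
    Tf <- S[, , 3L] * (1 - restart) + pool * quit
    M2 <- array(0, dim(M))
    M2[2:96, , 1L] <- Tn[1:95, ]
    M2[2:96, , 2L] <- Tc[1:95, ]
    M2[2:96, , 3L] <- Tf[1:95, ]
    M2[96L, , 1L] <- M2[96L, , 1L] + Tn[96L, ]
    M2[96L, , 2L] <- M2[96L, , 2L] + Tc[96L, ]
    M2[96L, , 3L] <- M2[96L, , 3L] + Tf[96L, ]
    M2[1L, , 1L] <- nb[t, ]
    M <- M2
  }
  out <- aggregates_frame(years, N, D, L, DIS)
  structure(out, class = c("hia_aggregates", "data.frame"),
            baseline_year = cfg$baseline_year, horizon = cfg$horizon_years,
            engine = "deterministic")
}

# Individual roster + pre-drawn uniforms shared across scenarios.
make_draws <- function(cfg) {
  npc <- cfg$n_per_class
  base <- expand.grid(age0 = HIA_AGES, sexi = 1:2, rep = seq_len(npc))
  entry <- rep(cfg$baseline_year, nrow(base))
  age0 <- base$age0
  sexi <- base$sexi
  if (cfg$horizon_years >= 1L) {
    nb_years <- cfg$baseline_year + 1:cfg$horizon_years
    nb <- expand.grid(year = nb_years, sexi = 1:2, rep = seq_len(npc))
    entry <- c(entry, nb$year)
    age0 <- c(age0, rep(0L, nrow(nb)))
    sexi <- c(sexi, nb$sexi)
  }
  n <- length(entry)
  list(
    entry = entry, age0 = age0, sexi = sexi,
    n_baseline = nrow(base), n_total = n,
    u0 = stats::runif(n),
    U = matrix(stats::runif(n * cfg$horizon_years), nrow = n)
  )
}

#' Stochastic partial microsimulation
#'
#' Simulates `n_per_class` individuals per one-year age class (0--95) and sex
#' (480,000 at the default 2500), each representing
#' `population / n_per_class` persons. Smoking histories are stochastic
#' (initial state drawn from the scenario prevalence; one start/quit/restart
#' draw per year from the net schedule); survival is deterministic via a
#' fractional alive-weight multiplied by `1 - q_state` each year, and
#' disability enters as the expected fraction `d_state` of each lived year.
#' Newborn cohorts of `n_per_class` never smokers per sex enter every year,
#' weighted by the newborn series.
#'
#' @inheritParams run_deterministic
#' @param draws Optional pre-drawn uniforms (internal; used by
#'   [common_random_runs()] to share draws across scenarios). When `NULL`,
#'   draws are generated from `cfg$seed`.
#' @return An `hia_aggregates` data frame (same layout as
#'   [run_deterministic()]), with attributes `n_individuals_baseline` and
#'   `n_individuals_total`.
#' @export
simulate_population <- function(prev, ts, sm, dis, cfg, population, newborns,
                                draws = NULL) {
  a <- engine_arrays(prev, ts, sm, dis, population)
  years <- cfg$baseline_year + 0:cfg$horizon_years
  nb <- newborn_lookup(newborns, years[-1L])
  if (is.null(draws)) {
    set.seed(cfg$seed)
    draws <- make_draws(cfg)
  }
  npc <- cfg$n_per_class
  n_total <- draws$n_total
  entry <- draws$entry
  age0 <- draws$age0
  sexi <- draws$sexi
  is_base <- seq_len(n_total) <= draws$n_baseline

  wgt <- numeric(n_total)
  cell_w <- a$pop / npc
  wgt[is_base] <- cell_w[cbind(age0[is_base] + 1L, sexi[is_base])]
  if (any(!is_base)) {
    nbi <- which(!is_base)
    wgt[nbi] <- nb[cbind(match(entry[nbi], years[-1L]), sexi[nbi])] / npc
  }

  state <- rep(1L, n_total)
  bi <- which(is_base)
  cn <- a$prev[cbind(age0[bi] + 1L, sexi[bi], 1L)]
  cc <- cn + a$prev[cbind(age0[bi] + 1L, sexi[bi], 2L)]
  u0 <- draws$u0[bi]
  state[bi] <- 1L + (u0 >= cn) + (u0 >= cc)

  w <- rep(1, n_total)
  quit <- pmax(a$cf, 0)
  restart <- pmax(-a$cf, 0)
  qv <- as.numeric(a$q)
  dv <- as.numeric(a$d)
  N <- D <- L <- DIS <- vector("list", length(years))
  for (t in seq_along(years)) {
    yr <- years[[t]]
    idx <- which(entry <= yr)
    age <- pmin(age0[idx] + (yr - entry[idx]), 95L)
    i <- age + 1L
    j <- sexi[idx]
    k <- state[idx]
    cell <- i + 96L * (j - 1L)
    li <- cell + 192L * (k - 1L)
    acc <- numeric(576L)
    rs <- rowsum(w[idx] * wgt[idx], li)
    acc[as.integer(rownames(rs))] <- rs
    Nk <- array(acc, c(96L, 2L, 3L))
    Dk <- Nk * a$q
    Lk <- Nk - Dk / 2
    N[[t]] <- Nk
    D[[t]] <- rowSums(Dk, dims = 2L)
    L[[t]] <- rowSums(Lk, dims = 2L)
    DIS[[t]] <- rowSums(Lk * a$d, dims = 2L)
    if (t == length(years)) break
    q_i <- qv[li]
    w[idx] <- w[idx] * (1 - q_i)
    # One uniform per individual-year encodes the sequential flows: a never
    # smoker starts when u < start, and a new starter also quits within the
    # year when u < start * quit; a current smoker quits when u < quit; a
    # former smoker restarts when u < restart.
    u <- draws$U[idx, t]
    s_i <- a$start[cell]
    q_i2 <- quit[cell]
    r_i <- restart[cell]
    new_k <- k
    new_k[k == 1L & u < s_i] <- 2L
    new_k[k == 1L & u < s_i * q_i2] <- 3L
    new_k[k == 2L & u < q_i2] <- 3L
    new_k[k == 3L & u < r_i] <- 2L
    state[idx] <- new_k
  }
  out <- aggregates_frame(years, N, D, L, DIS)
  structure(out, class = c("hia_aggregates", "data.frame"),
            baseline_year = cfg$baseline_year, horizon = cfg$horizon_years,
            engine = "microsim",
            n_individuals_baseline = draws$n_baseline,
            n_individuals_total = draws$n_total)
}

#' Run several scenarios with common random numbers
#'
#' All scenarios reuse the same simulated individuals and the same
#' per-individual uniform draws (initial state and one transition draw per
#' year), so scenario differences are not dominated by Monte Carlo noise.
#'
#' @param specs List of `scenario_spec`s (see [make_scenario()]).
#' @param prev Baseline prevalence table.
#' @param ts Baseline transition schedule.
#' @inheritParams run_deterministic
#' @return Named list of `hia_aggregates`, one per scenario.
#' @export
common_random_runs <- function(specs, prev, ts, sm, dis, cfg, population,
                               newborns) {
  stopifnot(length(specs) >= 1L)
  set.seed(cfg$seed)
  draws <- make_draws(cfg)
  out <- lapply(specs, function(spec) {
    ap <- apply_scenario(spec, prev, ts, sm)
    simulate_population(ap$prev, ap$ts, sm, dis, cfg, population, newborns,
                        draws = draws)
  })
  names(out) <- vapply(specs, function(s) s$name, character(1L))
  out
}

#' Run several scenarios with the deterministic engine
#'
#' @inheritParams common_random_runs
#' @return Named list of `hia_aggregates`, one per scenario.
#' @export
deterministic_runs <- function(specs, prev, ts, sm, dis, cfg, population,
                               newborns) {
  out <- lapply(specs, function(spec) {
    ap <- apply_scenario(spec, prev, ts, sm)
    run_deterministic(ap$prev, ap$ts, sm, dis, cfg, population, newborns)
  })
  names(out) <- vapply(specs, function(s) s$name, character(1L))
  out
}

#' Projected smoking prevalence from aggregates
#'
#' @param agg An `hia_aggregates` data frame.
#' @return Data frame `year`, `age`, `sex`, `never`, `current`, `former`
#'   (state shares; cells with N = 0 give NA).
#' @export
prevalence_projection <- function(agg) {
  data.frame(
    year = agg$year, age = agg$age, sex = agg$sex,
    never = agg$N_never / agg$N,
    current = agg$N_current / agg$N,
    former = agg$N_former / agg$N,
    stringsAsFactors = FALSE
  )
}
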