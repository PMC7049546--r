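#' @title State-specific mortality, net transitions and disability linkage
#' @description Converts baseline all-cause mortality, smoking prevalence,
#'   relative risks of death and disability odds ratios into the schedules
#'   the projection engine consumes: state-specific death probabilities that
#'   mix back to the baseline, net start/quit/restart probabilities that hold
#'   the age-specific smoking prevalence stationary over calendar time, and
#'   state-specific disability probabilities that honor the odds ratios while
#'   mixing back to the overall disability prevalence.
#' @name rates
NULL

#' Partition baseline mortality into state-specific death probabilities
#'
#' Given baseline one-year death probability q, prevalence p_k and relative
#' risks RR_k (never = 1), sets
#' `q_never = q / (p_never + p_current RR_current + p_former RR_former)` and
#' `q_k = RR_k q_never`, so the prevalence-weighted mixture reproduces q.
#' Values exceeding 1 are capped with a warning.
#'
#' @param q Baseline mortality rate table (`age`, `sex`, `value`,
#'   probabilities).
#' @param prev Smoking-state prevalence table on the same grid.
#' @param rr Per-sex relative-risk vectors `c(never = 1, current, former)`.
#' @return A data frame of class `state_mortality` with columns `age`, `sex`,
#'   `q_never`, `q_current`, `q_former`.
#' @export
partition_mortality <- function(q, prev, rr) {
  q <- check_grid(q, "baseline mortality")
  prev <- check_grid(prev, "prevalence")
  out <- prev[c("age", "sex")]
  rrc <- vapply(out$sex, function(s) rr[[s]][["current"]], numeric(1L))
  rrf <- vapply(out$sex, function(s) rr[[s]][["former"]], numeric(1L))
  denom <- prev$never + prev$current * rrc + prev$former * rrf
  if (any(denom <= 0)) stop("internal error: mortality partition denominator <= 0")
  out$q_never <- q$value / denom
  out$q_current <- rrc * out$q_never
  out$q_former <- rrf * out$q_never
  capped <- out$q_never > 1 | out$q_current > 1 | out$q_former > 1
  if (any(capped)) {
    warning(sprintf(
      "state-specific death probability capped at 1 in %d cell(s), e.g. (%d, %s)",
      sum(capped), out$age[capped][[1L]], out$sex[capped][[1L]]
    ))
    out$q_never <- pmin(out$q_never, 1)
    out$q_current <- pmin(out$q_current, 1)
    out$q_former <- pmin(out$q_former, 1)
  }
  structure(out, class = c("state_mortality", "data.frame"))
}

# Solve the one-step balance for a single cell: survivors of each state
# (p_k (1 - q_k)) must redistribute to the target shares. Flows compose
# sequentially within the year: `start` drains never into current first, then
# the signed `net_cf` acts as a quit probability on the post-start current
# pool (positive) or a restart probability on former (negative). The
# sequential order lets a cohort entering with zero current/former mass reach
# any target (new starters can quit within the year), which keeps the
# derived schedule clip-free wherever never-prevalence is non-increasing.
solve_transition_cell <- function(p, q, target) {
  n <- p * (1 - q)
  total <- sum(n)
  if (total <= 0) return(c(start = 0, net_cf = 0, clipped = 0))
  clipped <- FALSE
  clip01 <- function(x) {
    if (x < 0 || x > 1) clipped <<- TRUE
    min(max(x, 0), 1)
  }
  start <- if (n[[1L]] > 0) clip01(1 - target[[1L]] * total / n[[1L]]) else 0
  pool <- n[[2L]] + start * n[[1L]]
  # current balance: pool (1 - quit) + restart n_f = target_c total
  needed <- target[[2L]] * total - pool
  if (needed <= 0) {
    net_cf <- if (pool > 0) clip01(-needed / pool) else 0
  } else {
    net_cf <- -(if (n[[3L]] > 0) clip01(needed / n[[3L]]) else 0)
  }
  c(start = start, net_cf = net_cf, clipped = as.numeric(clipped))
}

#' Derive net transition probabilities keeping prevalence stationary
#'
#' For each sex and age a < 95, solves the one-step balance so that survivors
#' of age a (under state-specific mortality), after a net start flow
#' (never to current) and a signed net current/former flow, have exactly the
#' state shares observed at age a + 1. The open class solves the same balance
#' with its own shares as the target (a stationary self-map), so the standing
#' 95+ pool does not drift. Solutions outside \[0, 1\] are clipped with a
#' warning listing the affected cells.
#'
#' @param prev Prevalence table.
#' @param sm `state_mortality` from [partition_mortality()].
#' @return Data frame of class `transition_schedule` with columns `age`,
#'   `sex`, `start`, `net_cf` (positive = quit probability on current,
#'   negative = restart probability on former).
#' @export
derive_net_transitions <- function(prev, sm) {
  prev <- check_grid(prev, "prevalence")
  out <- prev[c("age", "sex")]
  out$start <- 0
  out$net_cf <- 0
  clipped_cells <- character(0)
  for (s in HIA_SEXES) {
    ps <- as.matrix(prev[prev$sex == s, HIA_SMOKING])
    qs <- as.matrix(sm[sm$sex == s, c("q_never", "q_current", "q_former")])
    sel <- which(out$sex == s)
    for (i in seq_along(HIA_AGES)) {
      target <- if (i < length(HIA_AGES)) ps[i + 1L, ] else ps[i, ]
      sol <- solve_transition_cell(ps[i, ], qs[i, ], target)
      out$start[sel[i]] <- sol[["start"]]
      out$net_cf[sel[i]] <- sol[["net_cf"]]
      if (sol[["clipped"]] > 0) {
        clipped_cells <- c(clipped_cells, sprintf("(%d, %s)", HIA_AGES[i], s))
      }
    }
  }
  if (length(clipped_cells) > 0L) {
    warning(sprintf("net transition clipped to [0,1] in cell(s): %s",
                    paste(clipped_cells, collapse = ", ")))
  }
  structure(out, class = c("transition_schedule", "data.frame"))
}

#' Project state shares one step forward
#'
#' Applies state-specific mortality, then the net flows in their within-year
#' order (start first, then the signed current/former flow on the post-start
#' pools), and renormalizes among survivors.
#'
#' @param p Length-3 state share vector (never, current, former).
#' @param q Length-3 state-specific death probabilities.
#' @param start Never-to-current probability.
#' @param net_cf Signed current/former flow (positive = quit probability on
#'   the post-start current pool, negative = restart probability on former).
#' @return Length-3 share vector summing to 1.
#' @export
project_prevalence_one_step <- function(p, q, start, net_cf) {
  n <- p * (1 - q)
  quit <- max(net_cf, 0)
  restart <- max(-net_cf, 0)
  pool <- n[[2L]] + start * n[[1L]]
  out <- c(
    never = n[[1L]] * (1 - start),
    current = pool * (1 - quit) + restart * n[[3L]],
    former = n[[3L]] * (1 - restart) + pool * quit
  )
  total <- sum(out)
  if (total <= 0) return(c(never = 1, current = 0, former = 0))
  out / total
}

#' Solve state-specific disability probabilities from overall prevalence
#'
#' Per cell, finds the baseline log-odds `beta0` such that
#' `sum_k p_k plogis(beta0 + log OR_k)` equals the overall disability
#' prevalence, by bisection on \[-50, 50\] to a tolerance of 1e-12; the
#' state-specific probabilities are `d_k = plogis(beta0 + log OR_k)`, so the
#' pairwise odds ratios are honored exactly. Overall prevalence of exactly 0
#' or 1 maps to all-0 / all-1.
#'
#' @param prev Prevalence table.
#' @param pi Overall disability prevalence rate table.
#' @param or_set Per-sex odds-ratio vectors `c(never = 1, current, former)`.
#' @return Data frame of class `disability_model` with columns `age`, `sex`,
#'   `d_never`, `d_current`, `d_former`, `beta0`.
#' @export
solve_disability <- function(prev, pi, or_set) {
  prev <- check_grid(prev, "prevalence")
  pi <- check_grid(pi, "disability prevalence")
  if (any(pi$value < 0 | pi$value > 1)) {
    stop("overall disability prevalence must lie in [0, 1]")
  }
  n <- nrow(prev)
  lor_c <- log(vapply(prev$sex, function(s) or_set[[s]][["current"]], numeric(1L)))
  lor_f <- log(vapply(prev$sex, function(s) or_set[[s]][["former"]], numeric(1L)))
  target <- pi$value
  mix <- function(b0) {
    prev$never * stats::plogis(b0) +
      prev$current * stats::plogis(b0 + lor_c) +
      prev$former * stats::plogis(b0 + lor_f)
  }
  lo <- rep(-50, n)
  hi <- rep(50, n)
  if (any(mix(lo) > target + 1e-15 & target > 0) ||
      any(mix(hi) < target - 1e-15 & target < 1)) {
    stop("no root in bracket for the disability baseline log-odds")
  }
  while (max(hi - lo) > 1e-12) {
    mid <- (lo + hi) / 2
    below <- mix(mid) < target
    lo[below] <- mid[below]
    hi[!below] <- mid[!below]
  }
  b0 <- (lo + hi) / 2
  out <- prev[c("age", "sex")]
  out$beta0 <- b0
  out$d_never <- stats::plogis(b0)
  out$d_current <- stats::plogis(b0 + lor_c)
  out$d_former <- stats::plogis(b0 + lor_f)
  zero <- target == 0
  one <- target == 1
  out$beta0[zero] <- -Inf
  out$beta0[one] <- Inf
  for (col in c("d_never", "d_current", "d_former")) {
    out[[col]][zero] <- 0
    out[[col]][one] <- 1
  }
  structure(out, class = c("disability_model", "data.frame"))
}
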