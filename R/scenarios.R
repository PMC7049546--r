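#' @title Tobacco-control scenario registry
#' @description The reference ("business-as-usual") projection and eight
#'   alternatives, each a declarative transform of the baseline prevalence
#'   table and/or the net transition schedule. Prevalence transforms apply
#'   once at simulation start; transition transforms apply to the schedule
#'   used in every projection year. All transforms are idempotent.
#' @name scenarios
NULL

#' Scenario registry names
#'
#' @return Character vector of the nine valid scenario names: `reference`,
#'   `smoking_free`, `zero_restart`, `all_quit`, `zero_restart_all_quit`,
#'   `low_prevalence`, `no_init_under_18`, `quit_x1_3`, `quit_x2`.
#' @export
scenario_names <- function() {
  c("reference", "smoking_free", "zero_restart", "all_quit",
    "zero_restart_all_quit", "low_prevalence", "no_init_under_18",
    "quit_x1_3", "quit_x2")
}

#' Construct a scenario specification
#'
#' \describe{
#'   \item{reference}{Identity transforms: current prevalence and transitions.}
#'   \item{smoking_free}{Everyone a never smoker; start forced to 0 so the
#'     never share stays 100\% throughout.}
#'   \item{zero_restart}{Start probabilities 0 at all ages and restart flows
#'     (negative net flows) set to 0: nobody (re)starts.}
#'   \item{all_quit}{Every positive quit probability becomes 1; restart flows
#'     are unchanged, so a small residual current-smoker prevalence can
#'     remain where the baseline flow is a net restart.}
#'   \item{zero_restart_all_quit}{Start 0 and quit probability 1 everywhere
#'     (restarts 0).}
#'   \item{low_prevalence}{Swap in a supplied alternative prevalence table
#'     (`params$prevalence`) and re-derive net transitions from it so the
#'     alternative prevalence is itself stationary.}
#'   \item{no_init_under_18}{Zero smoking prevalence below age 18 and start
#'     probability 0 below 18; ages 18+ untouched.}
#'   \item{quit_x1_3, quit_x2}{Positive quit probabilities multiplied by 1.3
#'     or 2.0, capped at 1.}
#' }
#'
#' @param name A name from [scenario_names()].
#' @param params Optional list; `low_prevalence` requires
#'   `params$prevalence`, an alternative prevalence table.
#' @return A list of class `scenario_spec` with `name`,
#'   `prevalence_transform`, `transition_transform` (functions or `NULL`) and
#'   `rederive_transitions` (flag).
#' @export
make_scenario <- function(name, params = list()) {
  if (!name %in% scenario_names()) {
    stop(sprintf("unknown scenario '%s'; valid names: %s", name,
                 paste(scenario_names(), collapse = ", ")))
  }
  prev_tf <- NULL
  ts_tf <- NULL
  rederive <- FALSE
  if (name == "smoking_free") {
    prev_tf <- function(prev) {
      prev$never <- 1; prev$current <- 0; prev$former <- 0; prev
    }
    ts_tf <- function(ts) { ts$start <- 0; ts }
  } else if (name == "zero_restart") {
    ts_tf <- function(ts) {
      ts$start <- 0; ts$net_cf <- pmax(ts$net_cf, 0); ts
    }
  } else if (name == "all_quit") {
    ts_tf <- function(ts) { ts$net_cf[ts$net_cf > 0] <- 1; ts }
  } else if (name == "zero_restart_all_quit") {
    ts_tf <- function(ts) { ts$start <- 0; ts$net_cf <- 1; ts }
  } else if (name == "low_prevalence") {
    alt <- params$prevalence
    if (is.null(alt)) {
      stop("scenario low_prevalence requires params$prevalence")
    }
    alt <- validate_prevalence(alt, "low_prevalence table")
    prev_tf <- function(prev) alt
    rederive <- TRUE
  } else if (name == "no_init_under_18") {
    prev_tf <- function(prev) {
      young <- prev$age < 18
      prev$never[young] <- 1; prev$current[young] <- 0
      prev$former[young] <- 0; prev
    }
    ts_tf <- function(ts) { ts$start[ts$age < 18] <- 0; ts }
  } else if (name == "quit_x1_3" || name == "quit_x2") {
    k <- if (name == "quit_x2") 2.0 else 1.3
    ts_tf <- function(ts) {
      pos <- ts$net_cf > 0
      ts$net_cf[pos] <- pmin(k * ts$net_cf[pos], 1)
      ts
    }
  }
  structure(list(name = name, prevalence_transform = prev_tf,
                 transition_transform = ts_tf,
                 rederive_transitions = rederive),
            class = "scenario_spec")
}

#' Apply a scenario to baseline inputs
#'
#' Applies the prevalence transform once (at baseline), optionally re-derives
#' net transitions from the transformed prevalence, applies the transition
#' transform, and re-validates both outputs.
#'
#' @param spec A `scenario_spec`.
#' @param prev Baseline prevalence table.
#' @param ts Baseline `transition_schedule`.
#' @param sm `state_mortality`; required when the scenario re-derives
#'   transitions (`low_prevalence`).
#' @return A list with elements `prev` and `ts`.
#' @export
apply_scenario <- function(spec, prev, ts, sm = NULL) {
  stopifnot(inherits(spec, "scenario_spec"))
  # idempotence: re-applying a scenario to its own output is a no-op (the
  # quit-multiplier scenarios would otherwise compound)
  if (identical(attr(prev, "hia_scenario"), spec$name) &&
      identical(attr(ts, "hia_scenario"), spec$name)) {
    return(list(prev = prev, ts = ts))
  }
  if (!is.null(spec$prevalence_transform)) {
    prev <- validate_prevalence(spec$prevalence_transform(prev),
                                sprintf("scenario %s prevalence", spec$name))
  }
  if (spec$rederive_transitions) {
    if (is.null(sm)) {
      stop(sprintf("scenario %s needs state mortality to re-derive transitions",
                   spec$name))
    }
    ts <- derive_net_transitions(prev, sm)
  }
  if (!is.null(spec$transition_transform)) {
    ts <- spec$transition_transform(ts)
    if (any(ts$start < 0 | ts$start > 1) ||
        any(abs(ts$net_cf) > 1)) {
      stop(sprintf("scenario %s produced an invalid transition schedule",
                   spec$name))
    }
  }
  attr(prev, "hia_scenario") <- spec$name
  attr(ts, "hia_scenario") <- spec$name
  list(prev = prev, ts = ts)
}
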