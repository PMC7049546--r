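#' @title Prevalence and odds-ratio estimation from survey microdata
#' @description Smooths smoking-state and disability prevalence over age with
#'   fractional-polynomial (FP) logistic regression, fitted separately by sex,
#'   and estimates disability odds ratios by smoking state from an
#'   age-adjusted logistic model. The three smoking-state curves are fitted as
#'   independent binary models and renormalized so they sum to one at every
#'   age, mirroring the internal-normalization convention of multistate
#'   prevalence inputs.
#' @name estimation
NULL

# Fixed FP power set; 0 denotes log. Candidates are all degree-1 models and
# all degree-2 combinations including repeated powers (the repeated power p
# contributes u^p and u^p * log u, the standard FP convention).
FP_POWERS <- c(-2, -1, -0.5, 0, 0.5, 1, 2, 3)

fp_candidates <- function() {
  deg1 <- lapply(FP_POWERS, function(p) p)
  deg2 <- list()
  for (i in seq_along(FP_POWERS)) {
    for (j in i:length(FP_POWERS)) {
      deg2[[length(deg2) + 1L]] <- c(FP_POWERS[[i]], FP_POWERS[[j]])
    }
  }
  c(deg1, deg2)
}

# Design matrix of FP terms in u = age/10 (u > 0 on ages >= 1).
fp_design <- function(u, powers) {
  one_term <- function(p) if (p == 0) log(u) else u^p
  if (length(powers) == 2L && powers[[1L]] == powers[[2L]]) {
    t1 <- one_term(powers[[1L]])
    X <- cbind(t1, t1 * log(u))
  } else {
    X <- vapply(powers, one_term, numeric(length(u)))
    if (is.null(dim(X))) X <- matrix(X, ncol = length(powers))
  }
  colnames(X) <- paste0("fp", seq_len(ncol(X)))
  X
}

#' Fit a fractional-polynomial logistic model
#'
#' Fits a binary logistic regression of `outcome` on FP transforms of
#' `age / 10`, trying every degree-1 and degree-2 power combination from
#' \{-2, -1, -0.5, 0, 0.5, 1, 2, 3\} (0 = log; repeated powers give the
#' `u^p`, `u^p log u` pair). Within each degree the lowest-deviance fit wins
#' (ties within 1e-8 broken by lexicographic power order); following the
#' standard fractional-polynomial function-selection convention, the best
#' degree-2 model replaces the best degree-1 model only when it improves the
#' deviance by more than the chi-square(2) critical value at the 0.05 level,
#' so a truly low-order truth is recovered as such rather than being
#' out-fitted by noise. Records are aggregated to binomial counts per
#' (age, weight-sum) before fitting, so the fit cost is independent of sample
#' size.
#'
#' @param records Microdata data frame (`age`, `sex`, `weight`).
#' @param outcome Logical or 0/1 vector, one element per record.
#' @param sex Which sex stratum to fit.
#' @return An object of class `fp_model` with fields `powers`, `coef`
#'   (intercept first), `deviance`, `sex`.
#' @export
fit_fp_logistic <- function(records, outcome, sex) {
  stopifnot(length(outcome) == nrow(records))
  sel <- records$sex == sex
  if (sum(sel) < 50L) {
    stop(sprintf("fewer than 50 records for sex %s", sex))
  }
  y <- as.numeric(outcome[sel])
  if (all(y == 0) || all(y == 1)) {
    stop(sprintf("outcome is constant for sex %s; both classes are required",
                 sex))
  }
  w <- records$weight[sel]
  age <- records$age[sel]
  # aggregate to one binomial observation per age
  trials <- tapply(w, age, sum)
  events <- tapply(w * y, age, sum)
  ages <- as.numeric(names(trials))
  u <- ages / 10
  prop <- as.numeric(events / trials)
  trials <- as.numeric(trials)

  best1 <- best2 <- NULL
  for (powers in fp_candidates()) {
    X <- cbind(1, fp_design(u, powers))
    fit <- tryCatch(
      suppressWarnings(stats::glm.fit(X, prop, weights = trials,
                                      family = stats::binomial())),
      error = function(e) NULL
    )
    if (is.null(fit) || !fit$converged || anyNA(fit$coefficients)) next
    cand <- list(powers = powers, coef = fit$coefficients,
                 deviance = fit$deviance, fitted = fit$fitted.values)
    if (length(powers) == 1L) {
      if (is.null(best1) || better_fp(cand, best1)) best1 <- cand
    } else {
      if (is.null(best2) || better_fp(cand, best2)) best2 <- cand
    }
  }
  if (is.null(best1) && is.null(best2)) {
    stop("no fractional-polynomial candidate converged")
  }
  crit <- stats::qchisq(0.95, df = 2L)
  best <- if (is.null(best2)) best1
    else if (is.null(best1)) best2
    else if (best1$deviance - best2$deviance > crit) best2
    else best1
  eps <- 1e-8
  if (all(best$fitted < eps) || all(best$fitted > 1 - eps)) {
    stop("separation: fitted probabilities are all 0/1; a larger sample is needed")
  }
  names(best$coef) <- c("(Intercept)",
                        paste0("fp", seq_along(best$coef[-1L])))
  structure(list(powers = best$powers, coef = best$coef,
                 deviance = best$deviance, sex = sex),
            class = "fp_model")
}

# Is candidate a better than b under (deviance, n terms, lexicographic)?
better_fp <- function(a, b, tol = 1e-8) {
  if (a$deviance < b$deviance - tol) return(TRUE)
  if (a$deviance > b$deviance + tol) return(FALSE)
  if (length(a$powers) != length(b$powers)) {
    return(length(a$powers) < length(b$powers))
  }
  for (i in seq_along(a$powers)) {
    if (a$powers[[i]] != b$powers[[i]]) return(a$powers[[i]] < b$powers[[i]])
  }
  FALSE
}

#' Predict from a fractional-polynomial logistic model
#'
#' @param object An `fp_model`.
#' @param ages Ages at which to predict (>= 1).
#' @param ... Unused.
#' @return Predicted probabilities.
#' @export
predict.fp_model <- function(object, ages, ...) {
  X <- cbind(1, fp_design(ages / 10, object$powers))
  as.numeric(stats::plogis(X %*% object$coef))
}

#' Estimate smoothed smoking-state prevalence
#'
#' Fits three binary FP-logistic models per sex (current vs rest, former vs
#' rest, never vs rest), predicts each on ages 15..95 and renormalizes the
#' three predictions to sum to one per cell. Ages below 15 are set to
#' `(never, current, former) = (1, 0, 0)`.
#'
#' @param records Survey microdata covering ages 15+ for both sexes.
#' @return A prevalence data frame on the full grid, with the fitted
#'   `fp_model`s in attribute `models`.
#' @export
estimate_smoking_prevalence <- function(records) {
  grid <- age_sex_grid()
  out <- cbind(grid, never = 1, current = 0, former = 0)
  models <- list()
  for (s in HIA_SEXES) {
    fits <- lapply(HIA_SMOKING, function(k) {
      fit_fp_logistic(records, records$smoking == k, s)
    })
    names(fits) <- HIA_SMOKING
    models[[s]] <- fits
    adult <- 15:95
    pred <- vapply(fits, function(m) predict(m, adult),
                   numeric(length(adult)))
    pred <- pred / rowSums(pred)
    sel <- out$sex == s & out$age >= 15
    out$never[sel] <- pred[, "never"]
    out$current[sel] <- pred[, "current"]
    out$former[sel] <- pred[, "former"]
  }
  out <- validate_prevalence(out, "estimated smoking prevalence")
  attr(out, "models") <- models
  out
}

#' Estimate the disability inputs
#'
#' Dichotomizes the activity-limitation item (any limitation counts as
#' disabled) and estimates, per sex: (i) overall disability prevalence over
#' age by an FP-logistic fit, and (ii) odds ratios of disability for current
#' and former smokers (reference: never) from a logistic regression adjusting
#' for age and age squared.
#'
#' @param records Survey microdata.
#' @return A list of class `disability_inputs` with `pi` (overall prevalence
#'   rate table; 0 below age 15), `or` (per-sex named vectors
#'   `c(never = 1, current, former)`) and `models`.
#' @export
estimate_disability_model <- function(records) {
  disabled <- records$gali != "none"
  grid <- age_sex_grid()
  pi_tab <- cbind(grid, value = 0)
  or <- list()
  models <- list()
  for (s in HIA_SEXES) {
    m <- fit_fp_logistic(records, disabled, s)
    models[[s]] <- list(prevalence = m)
    sel <- pi_tab$sex == s & pi_tab$age >= 15
    pi_tab$value[sel] <- predict(m, 15:95)
    sub <- records[records$sex == s, ]
    if (!all(HIA_SMOKING %in% unique(sub$smoking))) {
      stop(sprintf("smoking category absent in the %s stratum", s))
    }
    sub$disabled <- as.numeric(disabled[records$sex == s])
    sub$smoking <- factor(sub$smoking, levels = HIA_SMOKING)
    sub$u <- sub$age / 10
    fit <- suppressWarnings(stats::glm(
      disabled ~ smoking + u + I(u^2), family = stats::binomial(),
      data = sub, weights = sub$weight
    ))
    mu <- fit$fitted.values
    if (all(mu < 1e-8) || all(mu > 1 - 1e-8)) {
      stop("separation in the disability odds-ratio model")
    }
    cf <- stats::coef(fit)
    or[[s]] <- c(never = 1,
                 current = unname(exp(cf[["smokingcurrent"]])),
                 former = unname(exp(cf[["smokingformer"]])))
    models[[s]]$or_fit <- fit
  }
  attr(pi_tab, "kind") <- "probability"
  structure(list(pi = pi_tab, or = or, models = models),
            class = "disability_inputs")
}
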