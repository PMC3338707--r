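#' Treatment-effect estimate container
#'
#' Standardized output of every analysis function: the treatment effect on the
#' link scale with a Wald-type confidence interval and a convergence flag.
#' Estimators must never throw on degenerate data — they return
#' `converged = FALSE` instead, and such replicates are excluded from the
#' power denominator (but counted in the failure rate).
#'
#' @param theta_hat estimated treatment effect (link scale).
#' @param se standard error of `theta_hat`.
#' @param ci_low,ci_high two-sided confidence bounds.
#' @param converged logical, did the fit succeed.
#' @param model_label identifier of the estimator used.
#' @param message optional diagnostic (reason for failure).
#' @return object of class `effect_estimate`.
#' @export
effect_estimate <- function(theta_hat = NA_real_, se = NA_real_,
                            ci_low = NA_real_, ci_high = NA_real_,
                            converged = FALSE, model_label = "",
                            message = NULL) {
  if (isTRUE(converged)) {
    stopifnot(is.finite(se), se > 0,
              ci_low <= theta_hat, theta_hat <= ci_high)
  }
  structure(list(theta_hat = theta_hat, se = se, ci_low = ci_low,
                 ci_high = ci_high, converged = isTRUE(converged),
                 model_label = model_label, message = message),
            class = "effect_estimate")
}

failed_estimate <- function(model_label, message) {
  effect_estimate(converged = FALSE, model_label = model_label,
                  message = message)
}

#' @export
print.effect_estimate <- function(x, ...) {
  if (x$converged)
    cat(sprintf("%s: theta_hat = %.4f (SE %.4f), CI [%.4f, %.4f]\n",
                x$model_label, x$theta_hat, x$se, x$ci_low, x$ci_high))
  else
    cat(sprintf("%s: fit failed (%s)\n", x$model_label,
                x$message %||% "unknown reason"))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# run a glm/lm fit, capturing errors and warnings; warnings are treated as a
# convergence problem (separation, non-convergence, rank issues) except for
# known-benign ones
.benign_warnings <- "essentially perfect fit"

quiet_fit <- function(expr) {
  warn <- NULL
  fit <- withCallingHandlers(
    tryCatch(expr, error = function(e) e),
    warning = function(w) {
      msg <- conditionMessage(w)
      if (!grepl(.benign_warnings, msg)) warn <<- msg
      invokeRestart("muffleWarning")
    }
  )
  list(fit = fit, warning = warn)
}

# extract the treatment coefficient, with z or t critical value
wald_estimate <- function(fit, warn, label, alpha, use_t) {
  if (inherits(fit, "error"))
    return(failed_estimate(label, conditionMessage(fit)))
  if (!is.null(warn))
    return(failed_estimate(label, warn))
  if (inherits(fit, "glm") && !fit$converged)
    return(failed_estimate(label, "IRLS did not converge"))
  cf <- stats::coef(fit)
  if (!"treatment" %in% names(cf) || anyNA(cf))
    return(failed_estimate(label, "treatment effect not identifiable (rank deficiency)"))
  sm <- suppressWarnings(summary(fit))  # e.g. "essentially perfect fit"
  est <- sm$coefficients["treatment", 1:2]
  if (!all(is.finite(est)) || est[2] <= 0)
    return(failed_estimate(label, "non-finite standard error"))
  crit <- if (use_t) stats::qt(1 - alpha / 2, stats::df.residual(fit))
          else stats::qnorm(1 - alpha / 2)
  if (!is.finite(crit))
    return(failed_estimate(label, "no residual degrees of freedom"))
  effect_estimate(theta_hat = unname(est[1]), se = unname(est[2]),
                  ci_low = unname(est[1] - crit * est[2]),
                  ci_high = unname(est[1] + crit * est[2]),
                  converged = TRUE, model_label = label)
}

#' Cluster-level fixed-effects analysis (crossover designs)
#'
#' Fits, to the cluster-period summaries, a generalized linear model with one
#' fixed intercept per cluster, the treatment indicator, and optionally J - 1
#' period indicators. Within-cluster contrasts identify the treatment effect,
#' so at least two periods are required. Count family:
#' `log E[events] = log(exposure) + gamma_k + [delta_j] + theta X` (Poisson,
#' log-exposure offset); binary: logistic model on (successes, n); continuous:
#' Gaussian model on cluster-period means weighted by their denominators.
#'
#' Confidence intervals are Wald on the link scale: normal quantiles for the
#' Poisson and binomial fits (fixed dispersion), Student-t quantiles with the
#' residual degrees of freedom for the Gaussian fit (estimated dispersion).
#' A Poisson fit is declared failed when any cluster has zero events in every
#' period (its intercept diverges); fit failures of any kind return
#' `converged = FALSE` rather than throwing.
#'
#' @param summaries cluster-period summaries from [aggregate.simulated_trial()]
#'   (columns `cluster`, `period`, `treatment` plus family-specific columns).
#' @param family one of `"gaussian"`, `"binomial"`, `"poisson"`.
#' @param include_period_effect add fixed period indicators (adjusts for a
#'   secular trend).
#' @param alpha two-sided type-I error for the confidence interval.
#' @return an [effect_estimate()].
#' @export
fit_cluster_fixed <- function(summaries,
                              family = c("gaussian", "binomial", "poisson"),
                              include_period_effect = FALSE, alpha = 0.05) {
  family <- match.arg(family)
  label <- paste0("fixed.effect.cluster.level",
                  if (include_period_effect) ".period" else "")
  J <- length(unique(summaries$period))
  if (J < 2L)
    stop("cluster fixed effects need within-cluster contrasts: requires >= 2 periods")
  if (length(unique(summaries$cluster)) < 2L)
    stop("at least two clusters are required")

  d <- data.frame(cl = factor(summaries$cluster),
                  pd = factor(summaries$period),
                  treatment = summaries$treatment)
  rhs <- if (include_period_effect) ~ 0 + cl + pd + treatment
         else ~ 0 + cl + treatment
  if (family == "poisson") {
    if (any(tapply(summaries$events, summaries$cluster, sum) == 0))
      return(failed_estimate(label,
        "cluster with zero events in all periods (intercept diverges)"))
    d$y <- summaries$events
    q <- quiet_fit(stats::glm(stats::update(rhs, y ~ .), stats::poisson(),
                              data = d, offset = log(summaries$exposure)))
  } else if (family == "binomial") {
    d$s <- summaries$successes
    d$f <- summaries$n - summaries$successes
    q <- quiet_fit(stats::glm(stats::update(rhs, cbind(s, f) ~ .),
                              stats::binomial(), data = d))
  } else {
    d$y <- summaries$mean
    q <- quiet_fit(stats::glm(stats::update(rhs, y ~ .), stats::gaussian(),
                              data = d, weights = summaries$n))
  }
  wald_estimate(q$fit, q$warning, label, alpha, use_t = family == "gaussian")
}

#' Single-period (parallel-arm) analysis
#'
#' For a one-period cluster-randomized trial. Binary outcomes: a pooled
#' fixed-effects logistic regression of outcome on treatment (individuals
#' pooled across clusters), with a normal-quantile Wald interval — note this
#' model ignores clustering and is only calibrated when the between-cluster
#' variance is negligible. Continuous and count outcomes: a between-cluster
#' comparison of cluster-level summaries — cluster means weighted by cluster
#' size, or cluster log incidence rates weighted by exposure — with a
#' Student-t interval on K - 2 degrees of freedom, which respects the
#' clustering.
#'
#' @inheritParams fit_cluster_fixed
#' @return an [effect_estimate()].
#' @export
fit_single_period <- function(summaries,
                              family = c("gaussian", "binomial", "poisson"),
                              alpha = 0.05) {
  family <- match.arg(family)
  label <- "single_period"
  if (length(unique(summaries$period)) != 1L)
    stop("single-period analysis requires exactly one period")
  d <- data.frame(treatment = summaries$treatment)
  if (length(unique(d$treatment)) != 2L)
    return(failed_estimate(label, "both arms must be present"))

  if (family == "binomial") {
    s_arm <- tapply(summaries$successes, summaries$treatment, sum)
    n_arm <- tapply(summaries$n, summaries$treatment, sum)
    if (any(s_arm == 0) || any(s_arm == n_arm))
      return(failed_estimate(label, "zero cell in the pooled 2x2 table"))
    d$s <- summaries$successes
    d$f <- summaries$n - summaries$successes
    q <- quiet_fit(stats::glm(cbind(s, f) ~ treatment, stats::binomial(),
                              data = d))
    return(wald_estimate(q$fit, q$warning, label, alpha, use_t = FALSE))
  }
  if (family == "poisson") {
    if (any(summaries$events == 0))
      return(failed_estimate(label, "zero-event cluster: log rate undefined"))
    d$y <- log(summaries$events / summaries$exposure)
    d$w <- summaries$exposure
  } else {
    d$y <- summaries$mean
    d$w <- summaries$n
  }
  q <- quiet_fit(stats::lm(y ~ treatment, data = d, weights = w))
  wald_estimate(q$fit, q$warning, label, alpha, use_t = TRUE)
}

#' Confidence-interval rejection rule
#'
#' The null hypothesis of no treatment effect is rejected exactly when the
#' (closed) confidence interval does not cover zero; an endpoint exactly at
#' zero counts as covering, hence no rejection.
#'
#' @param estimate a converged [effect_estimate()].
#' @return logical.
#' @export
reject_null <- function(estimate) {
  stopifnot(inherits(estimate, "effect_estimate"))
  if (!estimate$converged)
    stop("cannot apply the rejection rule to a non-converged estimate")
  !(estimate$ci_low <= 0 && estimate$ci_high >= 0)
}

## ---- estimator registry -------------------------------------------------

.estimators <- new.env(parent = emptyenv())

#' Register a custom estimator
#'
#' An estimator is a function `(trial, alpha)` returning an
#' [effect_estimate()]; it must return `converged = FALSE` on degenerate data
#' rather than raising. Registered names can be passed to [estimate_power()],
#' [power_sweep()] and the command line.
#'
#' @param name estimator label (must be unused).
#' @param fn function of `(trial, alpha)`.
#' @param overwrite replace an existing registration.
#' @export
register_estimator <- function(name, fn, overwrite = FALSE) {
  stopifnot(is.character(name), length(name) == 1L, is.function(fn))
  if (!overwrite && exists(name, envir = .estimators, inherits = FALSE))
    stop("an estimator named '", name, "' is already registered")
  assign(name, fn, envir = .estimators)
  invisible(name)
}

#' Look up a registered estimator by name
#' @param name estimator label.
#' @return the estimator function, with the label attached as attribute.
#' @export
get_estimator <- function(name) {
  if (!exists(name, envir = .estimators, inherits = FALSE))
    stop("unknown estimator '", name, "'; see list_estimators()")
  fn <- get(name, envir = .estimators, inherits = FALSE)
  attr(fn, "label") <- name
  fn
}

#' List registered estimator names
#' @return character vector.
#' @export
list_estimators <- function() sort(ls(.estimators))

## built-in estimators (registered in .onLoad)

est_cluster_fixed <- function(trial, alpha = 0.05)
  fit_cluster_fixed(aggregate(trial), trial$family,
                    include_period_effect = FALSE, alpha = alpha)

est_cluster_fixed_period <- function(trial, alpha = 0.05)
  fit_cluster_fixed(aggregate(trial), trial$family,
                    include_period_effect = TRUE, alpha = alpha)

est_single_period <- function(trial, alpha = 0.05)
  fit_single_period(aggregate(trial), trial$family, alpha = alpha)

# random-intercept GLMM fit of the generating model (needs lme4)
est_glmm_random_intercept <- function(trial, alpha = 0.05) {
  label <- "glmm_random_intercept"
  if (!requireNamespace("lme4", quietly = TRUE))
    stop("the 'glmm_random_intercept' estimator requires the lme4 package")
  s <- aggregate(trial)
  d <- data.frame(cl = factor(s$cluster), pd = factor(s$period),
                  treatment = s$treatment)
  multi <- trial$design$n_periods > 1L
  rhs <- if (multi) "pd + treatment + (1 | cl)" else "treatment + (1 | cl)"
  q <- quiet_fit(switch(trial$family,
    poisson = {
      d$y <- s$events
      lme4::glmer(stats::as.formula(paste("y ~", rhs)), data = d,
                  family = stats::poisson(), offset = log(s$exposure))
    },
    binomial = {
      d$s <- s$successes; d$f <- s$n - s$successes
      lme4::glmer(stats::as.formula(paste("cbind(s, f) ~", rhs)), data = d,
                  family = stats::binomial())
    },
    gaussian = {
      dd <- data.frame(y = trial$outcomes, cl = factor(trial$cluster),
                       pd = factor(trial$period), treatment = trial$treatment)
      rhs_i <- if (multi) "pd + treatment + (1 | cl)" else "treatment + (1 | cl)"
      lme4::lmer(stats::as.formula(paste("y ~", rhs_i)), data = dd)
    }))
  fit <- q$fit
  if (inherits(fit, "error"))
    return(failed_estimate(label, conditionMessage(fit)))
  if (!is.null(q$warning))
    return(failed_estimate(label, q$warning))
  cf <- lme4::fixef(fit)
  sm <- tryCatch(summary(fit)$coefficients, error = function(e) NULL)
  if (is.null(sm) || !"treatment" %in% rownames(sm))
    return(failed_estimate(label, "treatment effect not estimated"))
  est <- sm["treatment", 1:2]
  if (!all(is.finite(est)) || est[2] <= 0)
    return(failed_estimate(label, "non-finite standard error"))
  crit <- stats::qnorm(1 - alpha / 2)
  effect_estimate(unname(est[1]), unname(est[2]),
                  unname(est[1] - crit * est[2]),
                  unname(est[1] + crit * est[2]),
                  converged = TRUE, model_label = label)
}

register_builtin_estimators <- function() {
  builtin <- list(
    "fixed.effect.cluster.level" = est_cluster_fixed,
    "cluster_fixed" = est_cluster_fixed,
    "fixed.effect.cluster.level.period" = est_cluster_fixed_period,
    "cluster_fixed_period" = est_cluster_fixed_period,
    "single_period" = est_single_period,
    "glmm_random_intercept" = est_glmm_random_intercept
  )
  for (nm in names(builtin))
    register_estimator(nm, builtin[[nm]], overwrite = TRUE)
}
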