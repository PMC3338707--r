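#' Draw period effects
#'
#' Period effects are normal with mean `period_effect` (recycled to length J if
#' scalar) and variance `period_var`; with `period_var = 0` the stated values
#' are returned verbatim, i.e. fixed period effects.
#'
#' @param n_periods number of periods J.
#' @param period_effect scalar or length-J vector of period-effect centers.
#' @param period_var variance of the random period effects (>= 0).
#' @return numeric vector of length J.
#' @export
draw_period_effects <- function(n_periods, period_effect, period_var = 0) {
  J <- as.integer(n_periods)
  if (!length(period_effect) %in% c(1L, J))
    stop("'period_effect' must be a scalar or have length n_periods = ", J)
  if (period_var < 0) stop("'period_var' must be >= 0")
  mu <- rep_len(as.numeric(period_effect), J)
  if (period_var == 0) mu else stats::rnorm(J, mu, sqrt(period_var))
}

#' Draw random cluster effects
#'
#' Cluster intercepts are iid N(0, `btw_clust_var`); a zero variance returns
#' exact zeros.
#'
#' @param n_clusters number of clusters K.
#' @param btw_clust_var between-cluster variance (>= 0).
#' @return numeric vector of length K.
#' @export
draw_cluster_effects <- function(n_clusters, btw_clust_var) {
  if (btw_clust_var < 0) stop("'btw_clust_var' must be >= 0")
  if (btw_clust_var == 0) rep(0, n_clusters)
  else stats::rnorm(n_clusters, 0, sqrt(btw_clust_var))
}

#' Sample participant at-risk times
#'
#' Fixed specification: every participant gets the same positive time.
#' Negative-binomial specification: draws with mean `mean` and variance
#' `mean + mean^2 / size`. Zero draws are replaced by 1 (smallest positive
#' support value); the number replaced is attached as attribute
#' `n_zero_replaced`.
#'
#' @param at_risk a positive scalar time or `list(mean =, size =)` (also
#'   accepts the normalized form produced by [poisson_params()]).
#' @param n number of participants.
#' @return numeric vector of length `n`, all values > 0.
#' @export
sample_at_risk_times <- function(at_risk, n) {
  if (!(is.list(at_risk) && !is.null(at_risk$type)))
    at_risk <- normalize_at_risk(at_risk)
  if (at_risk$type == "fixed") {
    out <- rep(at_risk$time, n)
    attr(out, "n_zero_replaced") <- 0L
    return(out)
  }
  out <- stats::rnbinom(n, mu = at_risk$mean, size = at_risk$size)
  zero <- out == 0
  out[zero] <- 1
  out <- as.numeric(out)
  attr(out, "n_zero_replaced") <- sum(zero)
  out
}

#' Simulate one trial from the generalized linear mixed model
#'
#' Generates individual-level outcomes with linear predictor
#' `eta_ijk = pi_j + theta * X_jk + b_k`:
#' Gaussian `Y = eta + e`, `e ~ N(0, sigma_w^2)`; binomial
#' `Y ~ Bernoulli(plogis(eta))`; Poisson `Y ~ Poisson(T_ijk * exp(eta))` with
#' at-risk times `T_ijk`. Randomness is consumed in a fixed order (period
#' effects, cluster effects, at-risk times, outcomes) so a seeded stream is
#' reproducible.
#'
#' @param design a [make_design()] object (randomize it first if desired).
#' @param params an outcome-parameter object from [gaussian_params()],
#'   [binomial_params()] or [poisson_params()].
#' @return An object of class `simulated_trial`: individual-level `outcomes`,
#'   index vectors `cluster`, `period`, `treatment`, `exposures` (count family
#'   only), and the realized period/cluster effects for diagnostics.
#' @export
simulate_trial <- function(design, params) {
  validate_design(design)
  if (!inherits(params, "outcome_params"))
    stop("'params' must come from gaussian_params(), binomial_params() or poisson_params()")
  K <- design$n_clusters; J <- design$n_periods
  n_cell <- as.vector(design$cluster_size)          # column-major: k fastest
  cl <- rep(rep(seq_len(K), J), times = n_cell)
  pd <- rep(rep(seq_len(J), each = K), times = n_cell)
  x  <- rep(as.vector(design$assignment), times = n_cell)
  total <- length(cl)

  pi_j <- draw_period_effects(J, params$period_effect, params$period_var)
  b_k  <- draw_cluster_effects(K, params$btw_clust_var)
  eta  <- pi_j[pd] + params$effect_size * x + b_k[cl]

  exposures <- NULL
  n_zero <- 0L
  y <- switch(params$family,
    gaussian = eta + if (params$variances$indiv_var > 0)
      stats::rnorm(total, 0, sqrt(params$variances$indiv_var)) else 0,
    binomial = stats::rbinom(total, 1L, stats::plogis(eta)),
    poisson  = {
      exposures <- sample_at_risk_times(params$at_risk, total)
      n_zero <- attr(exposures, "n_zero_replaced")
      stats::rpois(total, as.numeric(exposures) * exp(eta))
    }
  )

  structure(
    list(design = design, family = params$family, outcomes = as.numeric(y),
         exposures = if (is.null(exposures)) NULL else as.numeric(exposures),
         cluster = cl, period = pd, treatment = x,
         realized_period_effects = pi_j, realized_cluster_effects = b_k,
         n_zero_exposure_replaced = n_zero),
    class = "simulated_trial"
  )
}

#' @export
print.simulated_trial <- function(x, ...) {
  cat(sprintf("simulated %s trial: %d observations, %d clusters x %d period(s)\n",
              x$family, length(x$outcomes), x$design$n_clusters,
              x$design$n_periods))
  invisible(x)
}

#' Aggregate a simulated trial to cluster-period summaries
#'
#' Reduces individual-level data to one row per cluster-period — the scale at
#' which the cluster-level analysis models operate. Count family: total events
#' and total at-risk time; binomial: successes and denominator; Gaussian:
#' mean, SD and denominator. Totals are preserved exactly.
#'
#' @param x a [simulate_trial()] result.
#' @param ... unused.
#' @return data.frame with columns `cluster`, `period`, `treatment` plus the
#'   family-specific summaries; the outcome family is attached as attribute
#'   `family`.
#' @export
aggregate.simulated_trial <- function(x, ...) {
  K <- x$design$n_clusters; J <- x$design$n_periods
  cell <- (x$period - 1L) * K + x$cluster        # 1..K*J, all present
  out <- data.frame(
    cluster = rep(seq_len(K), J),
    period = rep(seq_len(J), each = K),
    treatment = as.vector(x$design$assignment)
  )
  n <- as.vector(x$design$cluster_size)
  if (x$family == "poisson") {
    out$events <- as.vector(rowsum(x$outcomes, cell))
    out$exposure <- as.vector(rowsum(x$exposures, cell))
  } else if (x$family == "binomial") {
    out$successes <- as.vector(rowsum(x$outcomes, cell))
    out$n <- n
  } else {
    sums <- as.vector(rowsum(x$outcomes, cell))
    sq   <- as.vector(rowsum(x$outcomes^2, cell))
    out$mean <- sums / n
    out$sd <- ifelse(n > 1, sqrt(pmax(sq - n * (sums / n)^2, 0) / (n - 1)), NA_real_)
    out$n <- n
  }
  attr(out, "family") <- x$family
  out
}
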