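# Outcome-model parameter containers. One constructor per GLMM family; all
# share the linear predictor eta_ijk = pi_j + theta * X_jk + b_k with
# b_k ~ N(0, sigma_b^2) and period effects pi_j drawn around `period_effect`
# with variance `period_var` (zero variance = fixed period effects).

check_common <- function(period_effect, effect_size, period_var) {
  if (!is.numeric(period_effect) || length(period_effect) < 1L ||
      any(!is.finite(period_effect)))
    stop("'period_effect' must be a finite numeric scalar or vector")
  if (!is.numeric(effect_size) || length(effect_size) != 1L ||
      !is.finite(effect_size))
    stop("'effect_size' must be a finite numeric scalar")
  if (!is.numeric(period_var) || length(period_var) != 1L || period_var < 0)
    stop("'period_var' must be a single value >= 0")
}

# normalize the at-risk-time specification for count models: either a fixed
# positive time per participant, or (mean, size) of a negative binomial
normalize_at_risk <- function(at_risk) {
  if (is.list(at_risk) ||
      (!is.null(names(at_risk)) && length(at_risk) == 2L)) {
    at_risk <- as.list(at_risk)
    if (!all(c("mean", "size") %in% names(at_risk)))
      stop("negative-binomial at-risk spec needs named elements 'mean' and 'size'")
    mu <- as.numeric(at_risk$mean); s <- as.numeric(at_risk$size)
    if (!is.finite(mu) || mu <= 0 || !is.finite(s) || s <= 0)
      stop("negative-binomial at-risk 'mean' and 'size' must be positive")
    return(list(type = "negbin", mean = mu, size = s))
  }
  if (is.numeric(at_risk) && length(at_risk) == 1L && is.finite(at_risk) &&
      at_risk > 0)
    return(list(type = "fixed", time = as.numeric(at_risk)))
  stop("'at_risk' must be a positive scalar time or list(mean =, size =)")
}

#' Parameters for the Gaussian (continuous outcome) model
#'
#' Continuous outcomes are generated as
#' `Y = pi_j + theta * X_jk + b_k + e_ijk` with `b_k ~ N(0, sigma_b^2)` and
#' `e_ijk ~ N(0, sigma_w^2)`; all fixed effects are on the outcome scale.
#' Supply any two of `icc`, `btw_clust_var`, `indiv_var` (or a ready
#' [complete_variances()] object via `variances`); the third is completed from
#' ICC = sigma_b^2 / (sigma_b^2 + sigma_w^2).
#'
#' @param period_effect scalar or length-J vector of period means (outcome
#'   scale).
#' @param effect_size treatment effect theta (outcome scale).
#' @param period_var variance of random period effects (0 = fixed periods).
#' @param icc,btw_clust_var,indiv_var variance components, two of three.
#' @param variances optionally a `variance_spec` instead of the three above.
#' @return object of class `c("gaussian_params", "outcome_params")`.
#' @export
gaussian_params <- function(period_effect, effect_size, period_var = 0,
                            icc = NULL, btw_clust_var = NULL, indiv_var = NULL,
                            variances = NULL) {
  check_common(period_effect, effect_size, period_var)
  if (is.null(variances))
    variances <- complete_variances(icc, btw_clust_var, indiv_var)
  stopifnot(inherits(variances, "variance_spec"))
  structure(list(family = "gaussian", period_effect = period_effect,
                 period_var = period_var, effect_size = effect_size,
                 variances = variances,
                 btw_clust_var = variances$btw_clust_var),
            class = c("gaussian_params", "outcome_params"))
}

#' Parameters for the binomial (binary outcome) model
#'
#' Binary outcomes are Bernoulli with
#' `logit P(Y = 1) = pi_j + theta * X_jk + b_k`; the period effects and the
#' treatment effect theta are on the log-odds scale and `btw_clust_var` is the
#' variance of the cluster effects on the log-odds scale.
#'
#' @inheritParams gaussian_params
#' @param btw_clust_var between-cluster variance (log-odds scale squared).
#' @return object of class `c("binomial_params", "outcome_params")`.
#' @export
binomial_params <- function(period_effect, effect_size, btw_clust_var,
                            period_var = 0) {
  check_common(period_effect, effect_size, period_var)
  if (!is.numeric(btw_clust_var) || btw_clust_var < 0)
    stop("'btw_clust_var' must be >= 0")
  structure(list(family = "binomial", period_effect = period_effect,
                 period_var = period_var, effect_size = effect_size,
                 btw_clust_var = btw_clust_var),
            class = c("binomial_params", "outcome_params"))
}

#' Parameters for the Poisson (count outcome) model
#'
#' Counts are Poisson with `E[Y] = T_ijk * exp(pi_j + theta * X_jk + b_k)`,
#' where `T_ijk` is the participant's at-risk time (an offset in the analysis).
#' `theta` is a log rate ratio. At-risk times are either a fixed time per
#' participant or negative-binomial draws with the given mean and size
#' (variance mean + mean^2 / size); zero draws are bumped to 1, the smallest
#' positive support value, since a participant with no at-risk time carries no
#' information and breaks the log-exposure offset.
#'
#' @inheritParams gaussian_params
#' @param btw_clust_var between-cluster variance (log-rate scale squared).
#' @param at_risk fixed positive at-risk time per participant, or
#'   `list(mean =, size =)` for negative-binomial at-risk times.
#' @return object of class `c("poisson_params", "outcome_params")`.
#' @examples
#' poisson_params(period_effect = log(0.004), effect_size = log(0.75),
#'                btw_clust_var = 0.5, at_risk = 10)
#' @export
poisson_params <- function(period_effect, effect_size, btw_clust_var,
                           at_risk, period_var = 0) {
  check_common(period_effect, effect_size, period_var)
  if (!is.numeric(btw_clust_var) || btw_clust_var < 0)
    stop("'btw_clust_var' must be >= 0")
  structure(list(family = "poisson", period_effect = period_effect,
                 period_var = period_var, effect_size = effect_size,
                 btw_clust_var = btw_clust_var,
                 at_risk = normalize_at_risk(at_risk)),
            class = c("poisson_params", "outcome_params"))
}

#' @export
print.outcome_params <- function(x, ...) {
  cat(sprintf("%s outcome model: effect_size = %g, period_effect = %s, period_var = %g\n",
              x$family, x$effect_size,
              paste(signif(x$period_effect, 4), collapse = ", "),
              x$period_var))
  if (x$family == "gaussian")
    cat(sprintf("  variances: btw %g, indiv %g (ICC %.4g)\n",
                x$variances$btw_clust_var, x$variances$indiv_var,
                x$variances$icc))
  else
    cat(sprintf("  btw_clust_var: %g\n", x$btw_clust_var))
  if (x$family == "poisson")
    cat("  at-risk:",
        if (x$at_risk$type == "fixed") sprintf("fixed %g", x$at_risk$time)
        else sprintf("negative binomial (mean %g, size %g)",
                     x$at_risk$mean, x$at_risk$size), "\n")
  invisible(x)
}
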