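#' Wilson score interval for a binomial proportion
#'
#' Used for the Monte-Carlo uncertainty of an empirical power estimate; it has
#' better small-count coverage than the Wald interval and never leaves [0, 1].
#'
#' @param x number of successes.
#' @param n number of trials (> 0).
#' @param conf.level confidence level.
#' @return named numeric vector `c(low, high)`.
#' @export
wilson_ci <- function(x, n, conf.level = 0.95) {
  stopifnot(n > 0, x >= 0, x <= n)
  z <- stats::qnorm(1 - (1 - conf.level) / 2)
  p <- x / n
  denom <- 1 + z^2 / n
  center <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  c(low = max(0, center - half), high = min(1, center + half))
}

resolve_estimator <- function(estimator, design) {
  if (is.null(estimator))
    estimator <- if (design$n_periods >= 2L) "fixed.effect.cluster.level"
                 else "single_period"
  if (is.character(estimator)) {
    fn <- get_estimator(estimator)
    list(fn = fn, label = estimator)
  } else if (is.function(estimator)) {
    list(fn = estimator, label = attr(estimator, "label") %||% "custom")
  } else stop("'estimator' must be a registered name or a function(trial, alpha)")
}

# per-replicate substream seeds derived from one master seed, so replicates
# are exchangeable and sweeps reproduce regardless of execution order
replicate_seeds <- function(master_seed, n) {
  set.seed(master_seed)
  sample.int(2147483646L, n)
}

#' Estimate empirical power by Monte-Carlo simulation
#'
#' Runs `n_sim` independent replicates of the simulate-analyze-decide loop:
#' randomize the allocation, generate a trial from the outcome model, fit the
#' estimator, and reject the null when the confidence interval excludes zero.
#' Empirical power is the rejected fraction among converged replicates; failed
#' fits are excluded from the denominator but reported as a failure rate (a
#' warning is raised when it exceeds 1%). Each replicate runs on its own
#' substream seeded from `master_seed`, so results are bit-reproducible.
#'
#' @param design a [make_design()] object.
#' @param params an outcome-parameter object; its family must match the
#'   estimator's expectations.
#' @param estimator a registered estimator name (see [list_estimators()]) or a
#'   function `(trial, alpha)`; default: cluster fixed effects for crossover
#'   designs, single-period comparison otherwise.
#' @param n_sim number of simulated trials.
#' @param alpha two-sided type-I error rate of the rejection rule.
#' @param master_seed integer seed for the whole run.
#' @param randomize re-randomize the cluster allocation in every replicate
#'   (default TRUE).
#' @return An object of class `power_result` with elements `n_sim`,
#'   `n_converged`, `n_rejected`, `power`, `mc_ci` (95% Wilson interval),
#'   `alpha`, `estimates` (per-replicate treatment effects of converged fits),
#'   `failure_rate`, `failure_reasons`, `estimator`, `master_seed`.
#' @examples
#' d <- make_design(10, 2, 25)
#' p <- poisson_params(log(0.05), log(0.5), 0.1, at_risk = 10)
#' estimate_power(d, p, n_sim = 50, master_seed = 1)
#' @export
estimate_power <- function(design, params, estimator = NULL, n_sim = 1000,
                           alpha = 0.05, master_seed = 1L, randomize = TRUE) {
  validate_design(design)
  stopifnot(n_sim >= 1, alpha > 0, alpha < 1)
  est <- resolve_estimator(estimator, design)
  seeds <- replicate_seeds(master_seed, n_sim)

  thetas <- rep(NA_real_, n_sim)
  rejected <- rep(NA, n_sim)
  reasons <- character(0)
  for (i in seq_len(n_sim)) {
    set.seed(seeds[i])
    d <- if (randomize) randomize_assignment(design) else design
    fit <- tryCatch(est$fn(simulate_trial(d, params), alpha),
                    error = function(e) failed_estimate(est$label,
                                                        conditionMessage(e)))
    if (fit$converged) {
      thetas[i] <- fit$theta_hat
      rejected[i] <- reject_null(fit)
    } else {
      reasons <- c(reasons, fit$message %||% "unknown")
    }
  }

  n_converged <- sum(!is.na(rejected))
  if (n_converged == 0L)
    stop("all ", n_sim, " replicates failed to converge; check the configuration")
  n_rejected <- sum(rejected, na.rm = TRUE)
  failure_rate <- 1 - n_converged / n_sim
  if (failure_rate > 0.01)
    warning(sprintf("%.1f%% of replicates failed to converge (most common: %s)",
                    100 * failure_rate, names(sort(table(reasons),
                                                   decreasing = TRUE))[1]))

  structure(list(
    n_sim = n_sim, n_converged = n_converged, n_rejected = n_rejected,
    power = n_rejected / n_converged,
    mc_ci = wilson_ci(n_rejected, n_converged),
    alpha = alpha, estimates = thetas[!is.na(thetas)],
    failure_rate = failure_rate,
    failure_reasons = if (length(reasons)) table(reasons) else NULL,
    estimator = est$label, master_seed = master_seed
  ), class = "power_result")
}

#' @export
print.power_result <- function(x, ...) {
  cat(sprintf("empirical power: %.3f  (95%% MC CI %.3f-%.3f)\n",
              x$power, x$mc_ci["low"], x$mc_ci["high"]))
  cat(sprintf("  %d/%d replicates rejected at alpha = %g; estimator '%s'\n",
              x$n_rejected, x$n_converged, x$alpha, x$estimator))
  if (x$failure_rate > 0)
    cat(sprintf("  failure rate %.1f%% (%d replicates excluded)\n",
                100 * x$failure_rate, x$n_sim - x$n_converged))
  invisible(x)
}

# rebuild design/params with one parameter replaced (used by sweeps)
apply_sweep_value <- function(design, params, param_name, value) {
  switch(param_name,
    n_clusters = {
      if (is.matrix(design$size_input))
        stop("sweeping 'n_clusters' requires a scalar cluster size")
      design <- make_design(value, design$n_periods, design$size_input)
    },
    cluster_size = {
      design <- make_design(design$n_clusters, design$n_periods, value)
    },
    effect_size = { params$effect_size <- value },
    btw_clust_var = {
      if (params$family == "gaussian") {
        params$variances <- complete_variances(
          btw_clust_var = value, indiv_var = params$variances$indiv_var)
        params$btw_clust_var <- value
      } else params$btw_clust_var <- value
    },
    icc = {
      if (params$family != "gaussian")
        stop("'icc' can only be swept for the gaussian family")
      params$variances <- complete_variances(
        icc = value, indiv_var = params$variances$indiv_var)
      params$btw_clust_var <- params$variances$btw_clust_var
    },
    stop("unsupported sweep parameter '", param_name, "'")
  )
  list(design = design, params = params)
}

#' Sweep a design or model parameter and estimate power at each value
#'
#' Re-estimates power over a grid of one parameter, each grid point on an
#' independent substream of `master_seed`. Errors at individual grid points
#' (e.g. an invalid design) are recorded and do not abort the sweep. When the
#' varied parameter is `n_clusters` or `cluster_size`, a monotone
#' (isotonic, pool-adjacent-violators) smoothing of the power curve is
#' included, since true power is nondecreasing in those parameters and the
#' smoothed curve is what the minimum-cluster search thresholds.
#'
#' @inheritParams estimate_power
#' @param param_name one of `"n_clusters"`, `"cluster_size"`,
#'   `"effect_size"`, `"btw_clust_var"`, `"icc"`.
#' @param grid strictly increasing numeric vector of parameter values.
#' @return An object of class `power_sweep`: `summary` data.frame (columns
#'   `grid_value`, `power`, `ci_low`, `ci_high`, `n_converged`,
#'   `failure_rate`, and `smoothed` when applicable), the per-point
#'   `results`, `param_name`, `grid`, `master_seed`.
#' @export
power_sweep <- function(design, params, estimator = NULL, param_name, grid,
                        n_sim = 1000, alpha = 0.05, master_seed = 1L,
                        randomize = TRUE) {
  stopifnot(length(grid) >= 1, !is.unsorted(grid, strictly = TRUE))
  point_seeds <- replicate_seeds(master_seed, length(grid))

  results <- vector("list", length(grid))
  for (g in seq_along(grid)) {
    results[[g]] <- tryCatch({
      cfg <- apply_sweep_value(design, params, param_name, grid[g])
      estimate_power(cfg$design, cfg$params, estimator, n_sim = n_sim,
                     alpha = alpha, master_seed = point_seeds[g],
                     randomize = randomize)
    }, error = function(e) e)
  }

  pull <- function(r, what, default = NA_real_)
    if (inherits(r, "power_result")) r[[what]] else default
  summary_df <- data.frame(
    grid_value = grid,
    power = vapply(results, pull, 0, "power"),
    ci_low = vapply(results, function(r)
      if (inherits(r, "power_result")) r$mc_ci[["low"]] else NA_real_, 0),
    ci_high = vapply(results, function(r)
      if (inherits(r, "power_result")) r$mc_ci[["high"]] else NA_real_, 0),
    n_converged = vapply(results, function(r)
      if (inherits(r, "power_result")) r$n_converged else NA_integer_, 0L),
    failure_rate = vapply(results, pull, 0, "failure_rate")
  )
  if (param_name %in% c("n_clusters", "cluster_size")) {
    ok <- !is.na(summary_df$power)
    summary_df$smoothed <- NA_real_
    if (sum(ok) >= 2)
      summary_df$smoothed[ok] <-
        stats::isoreg(grid[ok], summary_df$power[ok])$yf
    else summary_df$smoothed[ok] <- summary_df$power[ok]
  }

  structure(list(param_name = param_name, grid = grid, results = results,
                 summary = summary_df, master_seed = master_seed),
            class = "power_sweep")
}

#' @export
print.power_sweep <- function(x, ...) {
  cat(sprintf("power sweep over '%s' (%d grid points)\n",
              x$param_name, length(x$grid)))
  print(x$summary, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Smallest number of clusters reaching a target power
#'
#' Sweeps the number of clusters over `k_grid`, smooths the simulated power
#' curve isotonically (power is nondecreasing in the number of clusters; the
#' smoothing removes Monte-Carlo wiggles), and returns the smallest grid value
#' whose smoothed power reaches the target. If no grid value qualifies the
#' result is flagged `grid exhausted` — no extrapolation beyond the grid is
#' attempted.
#'
#' @inheritParams estimate_power
#' @param target_power required power, in (0, 1).
#' @param k_grid strictly increasing cluster counts (even values for
#'   balanced crossover designs).
#' @return An object of class `min_k_result`: `min_clusters` (NA when the grid
#'   is exhausted), `reached`, `target_power`, and the underlying `sweep`.
#' @export
min_clusters_for_power <- function(design, params, estimator = NULL,
                                   target_power, k_grid, n_sim = 1000,
                                   alpha = 0.05, master_seed = 1L,
                                   randomize = TRUE) {
  stopifnot(target_power >= 0, target_power < 1)
  sweep <- power_sweep(design, params, estimator, "n_clusters", k_grid,
                       n_sim = n_sim, alpha = alpha,
                       master_seed = master_seed, randomize = randomize)
  sm <- sweep$summary$smoothed
  hit <- which(!is.na(sm) & sm >= target_power)
  structure(list(
    min_clusters = if (length(hit)) as.integer(k_grid[hit[1]]) else NA_integer_,
    reached = length(hit) > 0, target_power = target_power, sweep = sweep
  ), class = "min_k_result")
}

#' @export
print.min_k_result <- function(x, ...) {
  if (x$reached)
    cat(sprintf("smallest cluster count with smoothed power >= %.2f: %d\n",
                x$target_power, x$min_clusters))
  else
    cat(sprintf("grid exhausted: smoothed power never reached %.2f (max %.3f)\n",
                x$target_power, max(x$sweep$summary$smoothed, na.rm = TRUE)))
  invisible(x)
}

#' Write a power result (plus its resolved configuration) to JSON
#'
#' @param x a `power_result` or `min_k_result`.
#' @param path output file.
#' @param config optional resolved configuration to embed for reproducibility.
#' @export
write_power_json <- function(x, path, config = NULL) {
  payload <- if (inherits(x, "power_result")) {
    list(power = x$power, mc_ci = as.list(x$mc_ci), n_sim = x$n_sim,
         n_converged = x$n_converged, n_rejected = x$n_rejected,
         alpha = x$alpha, failure_rate = x$failure_rate,
         estimator = x$estimator, master_seed = x$master_seed)
  } else if (inherits(x, "min_k_result")) {
    list(min_clusters = x$min_clusters, reached = x$reached,
         target_power = x$target_power, sweep = x$sweep$summary,
         master_seed = x$sweep$master_seed)
  } else stop("unsupported object")
  payload$config <- config
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, dataframe = "rows")
  invisible(path)
}

#' Write a sweep summary to CSV
#'
#' One row per grid point (`grid_value`, `power`, `ci_low`, `ci_high`,
#' `n_converged`, `failure_rate`, plus `smoothed` for cluster-count or
#' cluster-size sweeps). The resolved configuration and master seed are
#' embedded as a leading `#` comment line so the file is self-describing;
#' read it back with `read.csv(path, comment.char = "#")`.
#'
#' @param x a `power_sweep`.
#' @param path output file.
#' @param config optional resolved configuration to embed.
#' @export
write_sweep_csv <- function(x, path, config = NULL) {
  stopifnot(inherits(x, "power_sweep"))
  meta <- list(param_name = x$param_name, master_seed = x$master_seed,
               config = config)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", jsonlite::toJSON(meta, auto_unbox = TRUE,
                                           digits = NA)), con)
  utils::write.csv(x$summary, con, row.names = FALSE)
  invisible(path)
}
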