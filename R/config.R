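# Run-configuration schema: snake_case keys mirroring the data-generating
# parameters (n_clusters, n_periods, cluster_size, effect_size, period_effect,
# period_var, btw_clust_var, icc, indiv_var, at_risk_params, n_sim, alpha,
# estimation_function, master_seed). Dotted spellings (btw.clust.var, ...) are
# accepted as aliases. Keys are validated against the outcome family:
# icc/indiv_var are Gaussian-only, at_risk_params is count-only.

.config_aliases <- c(
  "n.sim" = "n_sim", "n.clusters" = "n_clusters", "n.periods" = "n_periods",
  "cluster.size" = "cluster_size", "clust.size" = "cluster_size",
  "effect.size" = "effect_size", "btw.clust.var" = "btw_clust_var",
  "indiv.var" = "indiv_var", "ICC" = "icc",
  "period.effect" = "period_effect", "period.var" = "period_var",
  "at.risk.params" = "at_risk_params", "at.risk" = "at_risk_params",
  "at_risk" = "at_risk_params",
  "estimation.function" = "estimation_function",
  "seed" = "master_seed", "master.seed" = "master_seed"
)

.config_keys <- c("family", "n_sim", "effect_size", "alpha", "n_clusters",
                  "n_periods", "cluster_size", "btw_clust_var", "icc",
                  "indiv_var", "at_risk_params", "period_effect",
                  "period_var", "estimation_function", "master_seed")

.config_defaults <- list(alpha = 0.05, period_var = 0, n_sim = 1000,
                         master_seed = 1L)

#' Load and validate a run configuration
#'
#' Accepts a YAML or JSON file path, or a named list. Keys are the snake_case
#' data-generating parameter names (dotted aliases such as `btw.clust.var` and
#' `at.risk.params` are accepted). Unknown keys and family/parameter
#' mismatches are rejected: `icc`/`indiv_var` apply only to the gaussian
#' family, `at_risk_params` only to the poisson family, and the gaussian
#' variance components must satisfy the two-of-three ICC rule. Defaults
#' (`alpha` 0.05, `period_var` 0, `n_sim` 1000, `master_seed` 1, and a
#' design-appropriate `estimation_function`) are applied and logged via
#' `message()`.
#'
#' @param x file path (`.yaml`, `.yml`, `.json`) or a named list.
#' @return object of class `run_config` (a validated named list); the names of
#'   defaulted fields are attached as attribute `"defaulted"`.
#' @export
load_config <- function(x) {
  if (is.character(x) && length(x) == 1L) {
    if (!file.exists(x)) stop("config file not found: ", x)
    x <- if (grepl("\\.json$", x, ignore.case = TRUE))
      jsonlite::fromJSON(x, simplifyVector = TRUE)
    else yaml::read_yaml(x)
  }
  if (!is.list(x) ||
      (length(x) > 0 && (is.null(names(x)) || any(names(x) == ""))))
    stop("configuration must be a named list / mapping")

  nm <- names(x)
  hit <- nm %in% names(.config_aliases)
  nm[hit] <- .config_aliases[nm[hit]]
  names(x) <- nm
  if (anyDuplicated(nm))
    stop("duplicate configuration keys after alias resolution: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  unknown <- setdiff(nm, .config_keys)
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))

  if (is.null(x$family) ||
      !x$family %in% c("gaussian", "binomial", "poisson"))
    stop("'family' must be one of gaussian, binomial, poisson")

  required <- c("n_clusters", "n_periods", "cluster_size", "effect_size",
                "period_effect")
  required <- c(required, switch(x$family,
    poisson = c("btw_clust_var", "at_risk_params"),
    binomial = "btw_clust_var",
    gaussian = character(0)))
  missing <- setdiff(required, nm)
  if (x$family == "gaussian" &&
      sum(c("icc", "btw_clust_var", "indiv_var") %in% nm) < 2L)
    missing <- c(missing, "two of {icc, btw_clust_var, indiv_var}")
  if (length(missing))
    stop("missing required configuration key(s): ",
         paste(missing, collapse = ", "))

  forbidden <- switch(x$family,
    gaussian = "at_risk_params",
    binomial = c("icc", "indiv_var", "at_risk_params"),
    poisson = c("icc", "indiv_var"))
  bad <- intersect(forbidden, nm)
  if (length(bad))
    stop("key(s) not applicable to family '", x$family, "': ",
         paste(bad, collapse = ", "))

  defaulted <- character(0)
  for (key in names(.config_defaults)) {
    if (is.null(x[[key]])) {
      x[[key]] <- .config_defaults[[key]]
      defaulted <- c(defaulted, key)
    }
  }
  if (is.null(x$estimation_function)) {
    x$estimation_function <- if (x$n_periods >= 2) "fixed.effect.cluster.level"
                             else "single_period"
    defaulted <- c(defaulted, "estimation_function")
  }
  for (key in defaulted)
    message("config: using default ", key, " = ",
            paste(format(x[[key]]), collapse = ", "))

  stopifnot(x$n_sim >= 1, x$alpha > 0, x$alpha < 1)
  # construct design and params now so value errors surface at load time
  design_from_config(x)
  params_from_config(x)

  structure(x, class = "run_config", defaulted = defaulted)
}

#' Build the trial design described by a configuration
#' @param config a [load_config()] result (or equivalent list).
#' @return a `trial_design`.
#' @export
design_from_config <- function(config) {
  size <- config$cluster_size
  if (is.list(size) || length(size) > 1L) size <- do.call(rbind, size)
  make_design(config$n_clusters, config$n_periods, size)
}

#' Build the outcome-parameter object described by a configuration
#' @inheritParams design_from_config
#' @return an `outcome_params` object.
#' @export
params_from_config <- function(config) {
  pv <- config$period_var %||% 0
  switch(config$family,
    gaussian = gaussian_params(config$period_effect, config$effect_size,
                               period_var = pv, icc = config$icc,
                               btw_clust_var = config$btw_clust_var,
                               indiv_var = config$indiv_var),
    binomial = binomial_params(config$period_effect, config$effect_size,
                               config$btw_clust_var, period_var = pv),
    poisson = poisson_params(config$period_effect, config$effect_size,
                             config$btw_clust_var, config$at_risk_params,
                             period_var = pv))
}

#' Run the power simulation described by a configuration
#' @inheritParams design_from_config
#' @return a `power_result` (see [estimate_power()]).
#' @export
run_power_config <- function(config) {
  if (!inherits(config, "run_config")) config <- load_config(config)
  estimate_power(design_from_config(config), params_from_config(config),
                 estimator = config$estimation_function,
                 n_sim = config$n_sim, alpha = config$alpha,
                 master_seed = config$master_seed)
}
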