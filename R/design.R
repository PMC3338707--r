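#' Construct a cluster-randomized (crossover) trial design
#'
#' Defines the geometry of a trial with `n_clusters` clusters observed over
#' `n_periods` periods, together with a canonical treatment allocation.
#' A single period (`n_periods = 1`) is an ordinary parallel-arm
#' cluster-randomized trial; two or more periods give a crossover in which
#' every cluster receives both conditions.
#'
#' The canonical allocation is deterministic: for one period the first
#' `ceiling(K/2)` clusters are assigned to treatment; for crossover designs the
#' first half of the clusters follow the sequence (1, 0, 1, ...) and the rest
#' the complementary sequence (0, 1, 0, ...). Use [randomize_assignment()] to
#' permute cluster labels under the current RNG state. Balanced crossover
#' allocation requires an even number of clusters.
#'
#' @param n_clusters integer, number of clusters K (at least 2).
#' @param n_periods integer, number of study periods J (at least 1).
#' @param cluster_size participants per cluster-period: a single integer
#'   applied everywhere, or a K x J matrix of positive integers.
#' @return An object of class `trial_design`: a list with elements
#'   `n_clusters`, `n_periods`, `cluster_size` (K x J matrix), `assignment`
#'   (K x J 0/1 matrix, 1 = treatment) and `size_input` (the original
#'   `cluster_size` argument, kept for design sweeps).
#' @examples
#' make_design(10, 2, 210)   # 5 clusters per crossover sequence
#' make_design(20, 1, 40)    # 10 treated, 10 control clusters
#' @seealso [randomize_assignment()], [estimate_power()]
#' @export
make_design <- function(n_clusters, n_periods = 1L, cluster_size) {
  K <- as.integer(n_clusters)
  J <- as.integer(n_periods)
  if (is.na(K) || K < 2L)
    stop("'n_clusters' must be an integer >= 2 (no between-cluster contrast otherwise)")
  if (is.na(J) || J < 1L)
    stop("'n_periods' must be an integer >= 1")
  if (J >= 2L && K %% 2L != 0L)
    stop("balanced crossover allocation requires an even number of clusters")

  size_input <- cluster_size
  if (is.matrix(cluster_size)) {
    if (!all(dim(cluster_size) == c(K, J)))
      stop("'cluster_size' matrix must be ", K, " x ", J)
    sizes <- cluster_size
  } else {
    if (length(cluster_size) != 1L)
      stop("'cluster_size' must be a scalar or a K x J matrix")
    sizes <- matrix(cluster_size, K, J)
  }
  if (any(!is.finite(sizes)) || any(sizes < 1) || any(sizes != floor(sizes)))
    stop("all cluster-period sizes must be integers >= 1")
  storage.mode(sizes) <- "integer"

  if (J == 1L) {
    assignment <- matrix(0L, K, 1L)
    assignment[seq_len(ceiling(K / 2)), 1L] <- 1L
  } else {
    seq_a <- rep_len(c(1L, 0L), J)    # treatment first
    assignment <- rbind(
      matrix(seq_a, K / 2L, J, byrow = TRUE),
      matrix(1L - seq_a, K / 2L, J, byrow = TRUE)
    )
  }

  structure(
    list(n_clusters = K, n_periods = J, cluster_size = sizes,
         assignment = assignment, size_input = size_input),
    class = "trial_design"
  )
}

#' @export
print.trial_design <- function(x, ...) {
  kind <- if (x$n_periods == 1L) "parallel cluster-randomized"
          else "cluster-randomized crossover"
  cat(sprintf("%s design: %d clusters x %d period(s), %d participants total\n",
              kind, x$n_clusters, x$n_periods, sum(x$cluster_size)))
  cat("treated cluster-periods per period:",
      paste(colSums(x$assignment), collapse = ", "), "\n")
  invisible(x)
}

# internal sanity check used by the simulator
validate_design <- function(design) {
  stopifnot(inherits(design, "trial_design"))
  A <- design$assignment
  if (!all(A %in% c(0L, 1L)) ||
      !all(dim(A) == c(design$n_clusters, design$n_periods)))
    stop("invalid assignment matrix")
  if (design$n_periods >= 2L &&
      (any(rowSums(A) == 0L) || any(rowSums(A) == design$n_periods)))
    stop("in a crossover design every cluster needs a treated and a control period")
  invisible(design)
}

#' Randomly permute the treatment allocation of a design
#'
#' Reassigns clusters to the canonical arms/sequences by a uniform random
#' permutation of the cluster labels, so the number of clusters per sequence
#' is unchanged. Draws from the current RNG state; call `set.seed()` first for
#' a reproducible allocation.
#'
#' @param design a [make_design()] object.
#' @return A `trial_design` with permuted `assignment` rows (cluster sizes stay
#'   attached to their clusters).
#' @export
randomize_assignment <- function(design) {
  validate_design(design)
  design$assignment <-
    design$assignment[sample.int(design$n_clusters), , drop = FALSE]
  design
}

#' Complete the Gaussian variance-component triple
#'
#' For continuous outcomes the intraclass correlation is
#' ICC = sigma_b^2 / (sigma_b^2 + sigma_w^2), where sigma_b^2 is the
#' between-cluster variance and sigma_w^2 the individual (within-cluster)
#' variance. Any two of the three determine the third; this completes the
#' triple, or checks consistency if all three are supplied.
#'
#' @param icc intraclass correlation in `[0, 1)`, or `NULL`.
#' @param btw_clust_var between-cluster variance (outcome scale squared), or
#'   `NULL`.
#' @param indiv_var individual-level variance (outcome scale squared), or
#'   `NULL`.
#' @param tol consistency tolerance when all three are supplied.
#' @return An object of class `variance_spec`: list with `icc`,
#'   `btw_clust_var`, `indiv_var` satisfying the ICC relation to within 1e-12.
#' @examples
#' complete_variances(btw_clust_var = 1, indiv_var = 3)  # ICC 0.25
#' complete_variances(icc = 0.2, indiv_var = 4)          # sigma_b^2 = 1
#' @export
complete_variances <- function(icc = NULL, btw_clust_var = NULL,
                               indiv_var = NULL, tol = 1e-8) {
  given <- !c(is.null(icc), is.null(btw_clust_var), is.null(indiv_var))
  if (sum(given) < 2L)
    stop("supply at least two of 'icc', 'btw_clust_var', 'indiv_var'")
  if (!is.null(icc) && (icc < 0 || icc >= 1))
    stop("'icc' must lie in [0, 1); icc = 1 implies infinite between-cluster variance")
  if (!is.null(btw_clust_var) && btw_clust_var < 0)
    stop("'btw_clust_var' must be >= 0")
  if (!is.null(indiv_var) && indiv_var <= 0)
    stop("'indiv_var' must be > 0")

  if (all(given)) {
    implied <- btw_clust_var / (btw_clust_var + indiv_var)
    if (abs(implied - icc) > tol)
      stop(sprintf(
        "over-specified variance components are inconsistent: ICC implied by the variances is %.6g, got %.6g",
        implied, icc))
    icc <- implied
  } else if (is.null(icc)) {
    icc <- btw_clust_var / (btw_clust_var + indiv_var)
  } else if (is.null(btw_clust_var)) {
    btw_clust_var <- icc * indiv_var / (1 - icc)
  } else {                                    # indiv_var missing
    if (icc == 0)
      stop("icc = 0 with only 'btw_clust_var' leaves 'indiv_var' undetermined")
    indiv_var <- btw_clust_var * (1 - icc) / icc
  }

  structure(list(icc = icc, btw_clust_var = btw_clust_var,
                 indiv_var = indiv_var),
            class = "variance_spec")
}

#' Calibrate the between-cluster variance against a rate ceiling
#'
#' A common way to elicit the between-cluster variance of a log-linear count
#' model is to require that a stated fraction of clusters fall below a ceiling
#' on the baseline event rate. With cluster effects b ~ N(0, v), the fraction
#' of clusters with rate exp(log(baseline) + b) below `threshold_rate` is
#' Phi(log(threshold_rate / baseline_rate) / sqrt(v)). This returns the largest
#' variance on a grid that still meets the requested fraction.
#'
#' @param baseline_rate baseline event rate (events per unit at-risk time).
#' @param threshold_rate rate ceiling that a fraction `prob` of clusters must
#'   stay below.
#' @param prob required fraction of clusters below the ceiling (default 0.9).
#' @param grid candidate variances, strictly increasing (default 0.1 to 1.0 by
#'   0.1, i.e. precision to the nearest tenth).
#' @return list with `variance` (largest qualifying grid value), `grid` and
#'   `prob_below` (the fraction below the ceiling at each grid value).
#' @examples
#' calibrate_btw_cluster_var(0.004, 0.010)$variance  # 0.5
#' @export
calibrate_btw_cluster_var <- function(baseline_rate, threshold_rate,
                                      prob = 0.9, grid = seq(0.1, 1, by = 0.1)) {
  if (baseline_rate <= 0 || threshold_rate <= baseline_rate)
    stop("'threshold_rate' must exceed 'baseline_rate', both positive")
  if (any(grid <= 0) || is.unsorted(grid, strictly = TRUE))
    stop("'grid' must be positive and strictly increasing")
  p <- stats::pnorm(log(threshold_rate / baseline_rate) / sqrt(grid))
  ok <- p >= prob
  if (!any(ok))
    stop("no grid value keeps the required fraction of clusters below the ceiling")
  list(variance = max(grid[ok]), grid = grid, prob_below = p)
}
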