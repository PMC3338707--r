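# The small simulation sizes here (n_sim 20-300) keep the unit suite fast;
# the full-scale study configurations live in test-acceptance.R.

small_design <- function() make_design(6, 2, 30)
small_params <- function(theta = log(0.6))
  poisson_params(log(0.05), theta, 0.1, at_risk = 10)

test_that("identical master seed and configuration reproduce bit-identically", {
  r1 <- estimate_power(small_design(), small_params(), n_sim = 100,
                       master_seed = 42)
  r2 <- estimate_power(small_design(), small_params(), n_sim = 100,
                       master_seed = 42)
  expect_identical(r1, r2)
  r3 <- estimate_power(small_design(), small_params(), n_sim = 100,
                       master_seed = 43)
  expect_false(identical(r1$estimates, r3$estimates))
})

test_that("power result bookkeeping: counts, Wilson interval, failures", {
  r <- estimate_power(small_design(), small_params(), n_sim = 200,
                      master_seed = 7)
  expect_lte(r$n_rejected, r$n_converged)
  expect_lte(r$n_converged, r$n_sim)
  expect_gte(r$power, r$mc_ci[["low"]])
  expect_lte(r$power, r$mc_ci[["high"]])
  expect_equal(r$failure_rate, 1 - r$n_converged / r$n_sim)
  expect_length(r$estimates, r$n_converged)

  # wilson interval sanity against prop.test's score interval
  pt <- prop.test(80, 100, correct = FALSE)$conf.int
  w <- wilson_ci(80, 100)
  expect_equal(unname(w), as.numeric(pt), tolerance = 1e-10)

  # a half-failing estimator triggers the failure warning but not an error
  flaky <- local({
    i <- 0
    function(trial, alpha) {
      i <<- i + 1
      if (i %% 2 == 0) effect_estimate(1, 0.1, 0.8, 1.2, TRUE, "flaky")
      else effect_estimate(converged = FALSE, model_label = "flaky",
                           message = "odd replicate")
    }
  })
  expect_warning(
    rf <- estimate_power(small_design(), small_params(), flaky, n_sim = 20,
                         master_seed = 1),
    "failed to converge")
  expect_equal(rf$n_converged, 10)

  # every replicate failing is an error
  broken <- function(trial, alpha) effect_estimate(converged = FALSE,
                                                   model_label = "broken")
  expect_error(estimate_power(small_design(), small_params(), broken,
                              n_sim = 5, master_seed = 1), "all 5 replicates")
})

test_that("a length-1 sweep equals the single run on the same substream", {
  sw <- power_sweep(small_design(), small_params(), param_name = "n_clusters",
                    grid = 6, n_sim = 100, master_seed = 9)
  single <- estimate_power(small_design(), small_params(), n_sim = 100,
                           master_seed = replicate_seeds_for_test(9, 1))
  expect_equal(sw$results[[1]]$power, single$power)
  expect_equal(sw$results[[1]]$estimates, single$estimates)
})

test_that("sweeps vary the requested parameter and smooth monotone curves", {
  # binomial, few clusters, pooled analysis: power grows with cluster size
  d <- make_design(8, 1, 20)
  p <- binomial_params(0, log(1.5), 0.01)
  sw <- power_sweep(d, p, "single_period", "cluster_size", c(20, 100, 400),
                    n_sim = 200, master_seed = 11)
  expect_equal(sw$summary$grid_value, c(20, 100, 400))
  expect_false(is.unsorted(sw$summary$smoothed))
  expect_gt(sw$summary$power[3], sw$summary$power[1])

  # power increases with |theta| (rate ratios 0.5, 0.75, 0.9)
  d2 <- make_design(10, 2, 100)
  grid <- log(c(0.5, 0.75, 0.9))
  sw2 <- suppressWarnings(
    power_sweep(d2, poisson_params(log(0.01), log(0.75), 0.3, 10),
                "cluster_fixed", "effect_size", grid,
                n_sim = 200, master_seed = 12))
  expect_true(all(diff(sw2$summary$power) <= 0))  # |theta| shrinks along grid

  # invalid grid points are recorded, not fatal
  sw3 <- suppressWarnings(
    power_sweep(small_design(), small_params(), param_name = "n_clusters",
                grid = c(5, 6), n_sim = 50, master_seed = 13))
  expect_true(inherits(sw3$results[[1]], "error"))
  expect_true(is.na(sw3$summary$power[1]))
  expect_false(is.na(sw3$summary$power[2]))
})

test_that("minimum-cluster search thresholds the smoothed curve", {
  mk <- min_clusters_for_power(small_design(), small_params(log(0.5)),
                               target_power = 0, k_grid = c(6, 8, 10),
                               n_sim = 20, master_seed = 14)
  expect_equal(mk$min_clusters, 6L)   # target 0: smallest grid value
  expect_true(mk$reached)

  mk2 <- min_clusters_for_power(small_design(),
                                small_params(log(0.99)),
                                target_power = 0.99, k_grid = c(6, 8),
                                n_sim = 50, master_seed = 15)
  expect_false(mk2$reached)
  expect_true(is.na(mk2$min_clusters))
})

test_that("results serialize with their configuration embedded", {
  r <- estimate_power(small_design(), small_params(), n_sim = 50,
                      master_seed = 16)
  f <- tempfile(fileext = ".json")
  write_power_json(r, f, config = list(family = "poisson", master_seed = 16))
  js <- jsonlite::fromJSON(f)
  expect_equal(js$power, r$power)
  expect_equal(js$config$master_seed, 16)

  sw <- power_sweep(small_design(), small_params(),
                    param_name = "cluster_size", grid = c(20, 40),
                    n_sim = 20, master_seed = 17)
  fc <- tempfile(fileext = ".csv")
  write_sweep_csv(sw, fc, config = list(family = "poisson"))
  first <- readLines(fc, n = 1)
  expect_match(first, "^# \\{")
  back <- read.csv(fc, comment.char = "#")
  expect_equal(back$grid_value, c(20, 40))
  expect_equal(back$power, sw$summary$power)
})
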