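test_that("cluster fixed-effects Poisson fit matches closed form and oracle", {
  s <- table2_summaries()
  e <- fit_cluster_fixed(s, "poisson")
  expect_true(e$converged)
  # equal offsets, no period effect: MLE is log(total treated / total control)
  expect_equal(e$theta_hat, log(68 / 106), tolerance = 1e-6)
  expect_equal(e$theta_hat,
               oracle_poisson_fe_theta(s$events, s$exposure, s$cluster,
                                       s$treatment),
               tolerance = 1e-6)
  expect_true(e$ci_low <= e$theta_hat && e$theta_hat <= e$ci_high)
})

test_that("oracle equivalence on random small count datasets", {
  set.seed(21)
  for (i in 1:200) {
    s <- random_count_summaries(K = sample(c(2, 4, 6), 1))
    e <- fit_cluster_fixed(s, "poisson")
    expect_true(e$converged)
    expect_lt(abs(e$theta_hat -
                  oracle_poisson_fe_theta(s$events, s$exposure, s$cluster,
                                          s$treatment)), 1e-6)
  }
})

test_that("symmetric data give a zero effect; J = 1 is rejected", {
  s <- random_count_summaries(K = 2)
  s$events <- rep(c(7L, 12L), 2)   # identical treated and control counts
  s$exposure <- 100
  e <- fit_cluster_fixed(s, "poisson")
  expect_equal(e$theta_hat, 0, tolerance = 1e-10)

  s1 <- data.frame(cluster = 1:4, period = 1, treatment = c(1, 1, 0, 0),
                   events = 5, exposure = 10)
  expect_error(fit_cluster_fixed(s1, "poisson"), "periods")
})

test_that("relabeling clusters and swapping periods leave theta unchanged", {
  set.seed(22)
  s <- random_count_summaries(K = 6)
  base <- fit_cluster_fixed(s, "poisson", include_period_effect = TRUE)
  perm <- sample(6)
  s2 <- s; s2$cluster <- perm[s$cluster]
  expect_equal(fit_cluster_fixed(s2, "poisson", TRUE)$theta_hat,
               base$theta_hat, tolerance = 1e-10)
  s3 <- s; s3$period <- 3 - s$period
  expect_equal(fit_cluster_fixed(s3, "poisson", TRUE)$theta_hat,
               base$theta_hat, tolerance = 1e-10)
})

test_that("degenerate data fail gracefully instead of throwing", {
  s <- table2_summaries()
  s$events[s$cluster == 4] <- 0     # whole cluster without events
  e <- fit_cluster_fixed(s, "poisson")
  expect_false(e$converged)
  expect_match(e$message, "zero events")

  # binomial single-period with an empty cell
  sb <- data.frame(cluster = 1:4, period = 1, treatment = c(1, 1, 0, 0),
                   successes = c(0, 0, 5, 6), n = 10)
  expect_false(fit_single_period(sb, "binomial")$converged)

  # poisson single-period with a zero-event cluster
  sp <- data.frame(cluster = 1:4, period = 1, treatment = c(1, 1, 0, 0),
                   events = c(0, 3, 4, 5), exposure = 10)
  expect_false(fit_single_period(sp, "poisson")$converged)
})

test_that("single-period estimators match their closed forms", {
  # pooled logistic: 50/100 in each control cluster, 60/100 in each treated
  sb <- data.frame(cluster = 1:4, period = 1, treatment = c(1, 1, 0, 0),
                   successes = c(60, 60, 50, 50), n = 100)
  e <- fit_single_period(sb, "binomial")
  expect_true(e$converged)
  expect_equal(e$theta_hat, log((120 / 80) / (100 / 100)), tolerance = 1e-8)

  # gaussian: equal cluster means -> zero effect, symmetric CI
  sg <- data.frame(cluster = 1:6, period = 1, treatment = rep(c(1, 0), 3),
                   mean = 2.5, sd = 1, n = 10)
  eg <- fit_single_period(sg, "gaussian")
  expect_equal(eg$theta_hat, 0, tolerance = 1e-12)
  expect_equal(eg$ci_low, -eg$ci_high, tolerance = 1e-12)

  # poisson: identical arm totals and exposures -> zero effect
  sp <- data.frame(cluster = 1:4, period = 1, treatment = c(1, 1, 0, 0),
                   events = c(8, 12, 8, 12), exposure = c(50, 60, 50, 60))
  expect_equal(fit_single_period(sp, "poisson")$theta_hat, 0,
               tolerance = 1e-10)
})

test_that("rejection rule: CI covers zero iff no rejection, boundary included", {
  mk <- function(lo, hi) effect_estimate((lo + hi) / 2, 1, lo, hi, TRUE, "x")
  expect_true(reject_null(mk(-0.5, -0.1)))
  expect_false(reject_null(mk(-0.1, 0.2)))
  expect_false(reject_null(mk(0, 0.4)))     # endpoint exactly at 0
  expect_error(reject_null(effect_estimate(converged = FALSE)), "non-converged")
})

test_that("estimator registry: lookup, duplicates, referential transparency", {
  expect_true(all(c("fixed.effect.cluster.level", "cluster_fixed",
                    "single_period") %in% list_estimators()))
  expect_error(register_estimator("single_period", function(trial, alpha) NULL),
               "already registered")

  register_estimator("my_cluster_fixed", get_estimator("cluster_fixed"),
                     overwrite = TRUE)
  d <- make_design(6, 2, 30)
  p <- poisson_params(log(0.05), log(0.6), 0.1, at_risk = 10)
  r1 <- estimate_power(d, p, "cluster_fixed", n_sim = 50, master_seed = 3)
  r2 <- estimate_power(d, p, "my_cluster_fixed", n_sim = 50, master_seed = 3)
  expect_equal(r1$power, r2$power)
  expect_equal(r1$estimates, r2$estimates)

  # an estimator that never rejects and one that always rejects
  never <- function(trial, alpha) effect_estimate(0, 1, -Inf, Inf, TRUE, "never")
  always <- function(trial, alpha) effect_estimate(1, 0.1, 0.8, 1.2, TRUE, "always")
  expect_equal(estimate_power(d, p, never, n_sim = 20, master_seed = 1)$power, 0)
  expect_equal(estimate_power(d, p, always, n_sim = 20, master_seed = 1)$power, 1)
})

test_that("Wald CI width scales as 1 / sqrt(K) at fixed per-cluster information", {
  width_at <- function(K) {
    d <- make_design(K, 2, 50)
    p <- poisson_params(log(0.02), 0, 0, at_risk = 10)
    set.seed(100 + K)
    mean(replicate(40, {
      e <- fit_cluster_fixed(aggregate(simulate_trial(d, p)), "poisson")
      e$ci_high - e$ci_low
    }))
  }
  w <- vapply(c(10, 40, 160), width_at, 0)
  expect_equal(w[1] / w[2], 2, tolerance = 0.1)
  expect_equal(w[2] / w[3], 2, tolerance = 0.1)
})
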