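# Shared fixtures and independent oracles.

# 10-cluster, 2-period count table used as a worked example (one simulated
# dataset of the crossover design, with its crude incidence rate ratios)
table2 <- function() {
  read.csv(system.file("extdata", "table2_counts.csv", package = "crxopower"))
}

table2_summaries <- function(exposure = 2100) {
  tab <- table2()
  data.frame(cluster = rep(tab$unit, 2),
             period = rep(1:2, each = nrow(tab)),
             treatment = rep(c(0, 1), each = nrow(tab)),
             events = c(tab$control, tab$treatment),
             exposure = exposure)
}

# brute-force oracle for the cluster-fixed-effects Poisson MLE: profile out
# the cluster intercepts (closed form given theta) and maximize the profile
# log-likelihood over theta by 1-D numerical optimization
oracle_poisson_fe_theta <- function(events, exposure, cluster, treat) {
  nll <- function(theta) {
    mu0 <- exposure * exp(theta * treat)
    gamma <- log(tapply(events, cluster, sum) / tapply(mu0, cluster, sum))
    mu <- mu0 * exp(gamma[as.character(cluster)])
    -sum(stats::dpois(events, mu, log = TRUE))
  }
  stats::optimize(nll, c(-8, 8), tol = 1e-10)$minimum
}

# random small count dataset on a crossover design (always positive counts so
# the likelihood is well-behaved for the oracle comparison)
random_count_summaries <- function(K = 4, J = 2) {
  data.frame(cluster = rep(seq_len(K), J),
             period = rep(seq_len(J), each = K),
             treatment = as.vector(make_design(K, J, 1)$assignment),
             events = stats::rpois(K * J, lambda = stats::runif(K * J, 3, 30)) + 1L,
             exposure = stats::runif(K * J, 50, 150))
}

# the engine's documented substream derivation, re-stated independently:
# the master seed seeds R's RNG, substream seeds are sampled from it
replicate_seeds_for_test <- function(master_seed, n) {
  set.seed(master_seed)
  sample.int(2147483646L, n)
}

# closed-form power of a two-sample z comparison with known SE
normal_approx_power <- function(theta, se, alpha = 0.05) {
  z <- stats::qnorm(1 - alpha / 2)
  stats::pnorm(theta / se - z) + stats::pnorm(-theta / se - z)
}

# exact power of the cluster-mean two-sample t comparison (noncentral t)
t_power <- function(theta, se, df, alpha = 0.05) {
  crit <- stats::qt(1 - alpha / 2, df)
  ncp <- theta / se
  1 - stats::pt(crit, df, ncp) + stats::pt(-crit, df, ncp)
}
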