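test_that("mcmc_config validates and retention arithmetic holds", {
  expect_error(mcmc_config(100, 100), "burn_in")
  expect_error(mcmc_config(100, 50, thin = 0), "thin")
  # n_samples = burn_in + thin -> exactly one retained draw
  cohort <- small_cohort(4, 15, seed = 2)
  fit <- fit_hierarchical_ddm(cohort, mcmc_config(103, 100, 3, 1, seed = 1))
  expect_equal(dim(fit$group)[1], 1L)
})

test_that("fit_hierarchical_ddm validates its inputs", {
  cohort <- small_cohort(4, 15, seed = 2)
  expect_error(fit_hierarchical_ddm(cohort[cohort$participant_id ==
                                             cohort$participant_id[1], ]),
               ">= 2 subjects")
  expect_error(fit_hierarchical_ddm(cohort[c(1:5, 16:30), ]),
               ">= 10 trials")
  bad <- cohort; bad$rt[3] <- -1
  expect_error(fit_hierarchical_ddm(bad), "rt must be finite")
  expect_error(fit_hierarchical_ddm(data.frame(participant_id = 1, rt = 2)),
               "response")
})

test_that("hdi finds the shortest mass interval", {
  expect_error(hdi(numeric(0)), "empty")
  expect_error(hdi(rnorm(5)), "at least 10")
  expect_error(hdi(rnorm(20), mass = 1), "mass")
  h <- hdi(rep(3, 12), 0.95) # degenerate draws
  expect_equal(c(h$lower, h$upper), c(3, 3))
  set.seed(8)
  hn <- hdi(rnorm(1e6), 0.95)
  # the window's width is tightly pinned; its position wanders more because
  # the width objective is flat around the optimum
  expect_lt(abs((hn$upper - hn$lower) - 2 * 1.959964), 0.01)
  expect_lt(abs(hn$lower + 1.959964), 0.03)
  expect_lt(abs(hn$upper - 1.959964), 0.03)
  hu <- hdi(runif(1e6), 0.95)
  expect_lt(abs((hu$upper - hu$lower) - 0.95), 0.005)
  # asymmetric density: HDI hugs the mode, narrower than equal-tail
  he <- hdi(rexp(1e5), 0.9)
  expect_lt(he$lower, 0.01)
})

test_that("gelman_rubin follows the variance-ratio formula", {
  expect_error(gelman_rubin(matrix(rnorm(100), ncol = 1)), "2 chains")
  x <- rnorm(500)
  expect_equal(gelman_rubin(cbind(x, x)), 1.0) # identical chains
  set.seed(9)
  far <- cbind(rnorm(500, 0), rnorm(500, 100)) # disjoint chains
  expect_gt(gelman_rubin(far), 10)
  # direct formula oracle on arbitrary chains
  y <- matrix(rnorm(400, rep(c(0, 1), each = 200)), ncol = 2)
  w <- mean(apply(y, 2, var)); b <- var(colMeans(y))
  expect_equal(gelman_rubin(y), sqrt((w + b) / w))
  expect_gte(gelman_rubin(y), 1)
})

test_that("compare_groups pairs pooled draws and flags credibility", {
  set.seed(10)
  base <- rnorm(2000, 0.5, 0.05)
  pa <- fake_posterior(base)
  expect_false(compare_groups(pa, pa, "mu_v")$credible) # identical posteriors
  shifted <- fake_posterior(base + 0.3)
  cmp <- compare_groups(shifted, pa, "mu_v")
  expect_true(cmp$credible)
  expect_equal(cmp$mean_diff, 0.3, tolerance = 1e-9) # paired shift is exact
  expect_lt(cmp$hdi$upper - cmp$hdi$lower, 0.01)
  expect_error(compare_groups(pa, pa, "nu"), "unknown group parameter")
})

test_that("hierarchical fit recovers generating group means (self-consistency)", {
  mu <- list(v = 0.3, a = 2.2, z = 0.5, t0 = 6.8)
  cohort <- small_cohort(20, 60, seed = 42, mu = mu)
  fit <- fit_hierarchical_ddm(cohort, mcmc_config(1200, 400, 1, 1, seed = 3))
  summ <- group_summary(fit)
  for (par in c("v", "a", "z", "t0")) {
    row <- summ[paste0("mu_", par), ]
    expect_lt(abs(row["mean"] - mu[[par]]) / row["sd"], 4)
  }
  # posterior draws respect parameter domains
  expect_true(all(fit$group[, , "mu_a"] > 0))
  expect_true(all(fit$group[, , "mu_z"] > 0 & fit$group[, , "mu_z"] < 1))
  expect_true(all(fit$group[, , "sigma_v"] > 0))
  expect_true(all(fit$subject[, "z", , ] > 0 & fit$subject[, "z", , ] < 1))
})

test_that("posterior contracts as subjects and trials double", {
  f1 <- fit_hierarchical_ddm(small_cohort(10, 30, seed = 13),
                             mcmc_config(800, 300, 1, 1, seed = 4))
  f2 <- fit_hierarchical_ddm(small_cohort(40, 60, seed = 13),
                             mcmc_config(800, 300, 1, 1, seed = 4))
  expect_lt(sd(shareddm:::pooled_draws(f2, "mu_v")),
            sd(shareddm:::pooled_draws(f1, "mu_v")))
  expect_lt(sd(shareddm:::pooled_draws(f2, "mu_a")),
            sd(shareddm:::pooled_draws(f1, "mu_a")))
})

test_that("with no data the sampler returns the prior (moment check)", {
  # two subjects with zero trials: the stationary distribution is the prior;
  # group means are then uniform over their bounds
  sj <- matrix(c(0, 0, 2, 2, 0, 0, 6, 6), 2)
  g0 <- c(0, 1, 2, 1, 0, 1, 6, 1)
  set.seed(11)
  out <- shareddm:::hddm_mcmc_cpp(numeric(0), integer(0), c(0L, 0L, 0L),
                                  sj, g0, 20000L, 5000L, 5L, 50L)
  mu_v <- out$group[, 1] # prior: U[-5, 5] -> mean 0, sd 10/sqrt(12)
  expect_lt(abs(mean(mu_v)), 0.8)
  expect_lt(abs(sd(mu_v) - 10 / sqrt(12)), 0.6)
  sd_v <- out$group[, 2] # prior: U(0.01, 5] -> mean ~2.5
  expect_lt(abs(mean(sd_v) - 2.5), 0.6)
})

test_that("identical (data, config) fits are bit-identical", {
  cohort <- small_cohort(5, 15, seed = 21)
  cfg <- mcmc_config(200, 100, 1, 2, seed = 17)
  f1 <- fit_hierarchical_ddm(cohort, cfg)
  f2 <- fit_hierarchical_ddm(cohort, cfg)
  expect_identical(f1$group, f2$group)
  expect_identical(f1$data_hash, f2$data_hash)
})
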