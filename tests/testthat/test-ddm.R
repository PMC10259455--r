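# parameter grid reused across density properties
param_grid <- expand.grid(v = c(-0.5, 0, 0.216, 1), a = c(1, 2.403, 4),
                          z = c(0.3, 0.48, 0.7))

test_that("ddm_params validates domains", {
  expect_error(ddm_params(0.1, -1, 0.5, 0), "boundary")
  expect_error(ddm_params(0.1, 2, 1.2, 0), "\\(0, 1\\)")
  expect_error(ddm_params(0.1, 2, 0.5, -1), "t0")
  expect_error(ddm_params(Inf, 2, 0.5, 0), "finite")
})

test_that("defective densities are symmetric, mirror-invariant and normalized", {
  # v=0, z=0.5: upper and lower densities coincide for every t
  p0 <- ddm_params(0, 2, 0.5, 0)
  tt <- c(0.1, 0.5, 1, 2, 5)
  expect_equal(wfpt_density(tt, p0, "upper"), wfpt_density(tt, p0, "lower"))

  for (i in seq_len(nrow(param_grid))) {
    p <- ddm_params(param_grid$v[i], param_grid$a[i], param_grid$z[i], 0)
    pm <- ddm_params(-param_grid$v[i], param_grid$a[i], 1 - param_grid$z[i], 0)
    # mirror symmetry is exact
    expect_equal(wfpt_density(tt, p, "upper"), wfpt_density(tt, pm, "lower"))
    # both boundaries integrate to 1 (tolerance 1e-4)
    tot <- integrate(function(t) wfpt_density(t, p, "upper") +
                       wfpt_density(t, p, "lower"), 0, Inf)$value
    expect_lt(abs(tot - 1), 1e-4)
  }
  expect_error(wfpt_density(-1, p0), "t_dec")
})

test_that("choice probability is exact at v=0, monotone in v, and matches the density mass", {
  expect_identical(choice_probability(ddm_params(0, 2, 0.5, 0)), 0.5)
  expect_identical(choice_probability(ddm_params(0, 2, 0.3, 0)), 0.3)
  vs <- seq(-1, 1, by = 0.1)
  ps <- vapply(vs, function(v) choice_probability(ddm_params(v, 2.4, 0.48, 0)),
               numeric(1))
  expect_true(all(diff(ps) > 0))
  for (i in c(1, 8, 14)) {
    p <- ddm_params(param_grid$v[i], param_grid$a[i], param_grid$z[i], 0)
    mass <- integrate(function(t) wfpt_density(t, p, "upper"), 0, Inf,
                      rel.tol = 1e-9)$value
    expect_equal(choice_probability(p), mass, tolerance = 1e-6)
  }
})

test_that("simulator respects rt > t0, determinism and boundary frequencies", {
  p <- ddm_params(0.216, 2.403, 0.48, 6.681)
  set.seed(3); sim <- simulate_trials(p, 2000)
  expect_true(all(sim$rt > p$t0))
  set.seed(3); expect_identical(sim, simulate_trials(p, 2000))
  # symmetric process: upper fraction 0.5 within 3 MC standard errors
  set.seed(4); s0 <- simulate_trials(ddm_params(0, 2, 0.5, 0), 1e5)
  expect_lt(abs(mean(s0$boundary == "upper") - 0.5), 0.005)
  # drifting process matches the closed-form absorption probability
  frac <- mean(sim$boundary == "upper")
  expect_lt(abs(frac - choice_probability(p)), 3 * sqrt(0.25 / 2000))
})

test_that("simulated decision times follow the density (KS oracle)", {
  p <- ddm_params(0.216, 2.403, 0.48, 0)
  set.seed(5)
  sim <- simulate_trials(p, 3e4)
  dt_step <- 1e-3
  for (b in c("upper", "lower")) {
    x <- sim$decision_time[sim$boundary == b]
    x <- x - runif(length(x)) * dt_step # de-grid the Euler time lattice
    ks <- suppressWarnings(ks.test(x, shareddm:::wfpt_cdf_fun(p, b)))
    expect_gt(ks$p.value, 0.01)
  }
})

test_that("trial_loglik matches the density, handles rt <= t0 and is additive", {
  p <- ddm_params(0.3, 2, 0.45, 6.5)
  expect_identical(trial_loglik("upper", p$t0, p), -Inf)
  expect_identical(trial_loglik("lower", p$t0 - 1, p), -Inf)
  p0 <- ddm_params(0, 2, 0.5, 6.5)
  expect_equal(trial_loglik("upper", p0$t0 + 1, p0),
               trial_loglik("lower", p0$t0 + 1, p0))
  set.seed(6); sim <- simulate_trials(p, 50)
  ll <- trial_loglik(sim$boundary, sim$rt, p)
  expect_equal(ll, log(wfpt_density(sim$rt[1:50] - p$t0, p, "upper")) *
                 (sim$boundary == "upper") +
                 log(wfpt_density(sim$rt - p$t0, p, "lower")) *
                 (sim$boundary == "lower"),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(sum(ll), sum(vapply(seq_len(50), function(i)
    trial_loglik(sim$boundary[i], sim$rt[i], p), numeric(1))))
  expect_error(trial_loglik("upper", NaN, p), "finite")
  expect_error(trial_loglik("share", 7, p), "choice")
})

test_that("time-axis conversion round-trips", {
  expect_equal(rt_from_model_axis(rt_to_model_axis(c(500, 2000))), c(500, 2000))
  expect_error(rt_to_model_axis(-1), "> 0")
})
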