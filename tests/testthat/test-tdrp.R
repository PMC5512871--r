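test_that("fit_power_law recovers a noiseless power law exactly", {
  S <- c(0.5, 1, 2, 4, 8)
  f <- fit_power_law(S, 10 * S^2)
  expect_equal(f$alpha, 1, tolerance = 1e-10)
  expect_equal(f$beta, 2, tolerance = 1e-10)
  expect_equal(f$adjusted_r2, 1, tolerance = 1e-10)
})

test_that("fit_power_law validates its domain", {
  expect_error(fit_power_law(c(1, 2), c(1, 2)), ">= 3 points")
  expect_error(fit_power_law(c(1, 2, 0), c(1, 2, 3)), "> 0")
  expect_error(fit_power_law(c(1, 2, 3), c(1, -2, 3)), "> 0")
})

test_that("fit on the foamy-virus host-calibrated medians matches the known model", {
  cal <- fv_calibration_points()
  f <- fit_power_law(cal$s_median, cal$t_median)
  expect_equal(f$n_points, 9L)
  expect_equal(f$alpha, 2.6128, tolerance = 1e-3)
  expect_equal(f$beta, 1.6289, tolerance = 1e-3)
  ## fit to the medians; the reference value 0.954 is a posterior median
  expect_equal(f$adjusted_r2, 0.954, tolerance = 0.015)
  ## agreement with lm() on the log10-transformed data
  lmfit <- lm(log10(cal$t_median) ~ log10(cal$s_median))
  expect_equal(unname(coef(lmfit)), c(f$alpha, f$beta), tolerance = 1e-10)
  expect_equal(summary(lmfit)$adj.r.squared, f$adjusted_r2, tolerance = 1e-10)
})

test_that("extrapolation reproduces the deep-node ages from the calibrated fit", {
  cal <- fv_calibration_points()
  f <- fit_power_law(cal$s_median, cal$t_median)
  ## identity model sanity
  f0 <- structure(list(alpha = 0, beta = 1), class = "power_law_fit")
  expect_equal(extrapolate_age(f0, 7), 7)
  ## deep nodes X-XII
  expect_equal(extrapolate_age(f, 0.764), 263, tolerance = 0.03)
  expect_equal(extrapolate_age(f, 0.908), 348, tolerance = 0.03)
  expect_equal(extrapolate_age(f, 1.071), 455, tolerance = 0.03)
  expect_error(extrapolate_age(f, -1), "> 0")
})

test_that("fit is scale-equivariant and extrapolation monotone in S", {
  cal <- fv_calibration_points()
  f <- fit_power_law(cal$s_median, cal$t_median)
  for (c0 in c(0.1, 3, 100)) {
    fc <- fit_power_law(cal$s_median * c0, cal$t_median)
    expect_equal(fc$beta, f$beta, tolerance = 1e-9)
    expect_equal(fc$adjusted_r2, f$adjusted_r2, tolerance = 1e-9)
    expect_equal(fc$alpha, f$alpha - f$beta * log10(c0), tolerance = 1e-9)
  }
  S <- sort(runif(20, 0.01, 2))
  expect_true(all(diff(extrapolate_age(f, S)) > 0))
})

test_that("a calibrated node fed back through extrapolation returns its fitted residual", {
  cal <- fv_calibration_points()
  f <- fit_power_law(cal$s_median, cal$t_median)
  back <- extrapolate_age(f, cal$s_median)
  expect_equal(log10(cal$t_median) - log10(back), f$residuals, tolerance = 1e-10)
})

test_that("hpd_interval matches the exhaustive window-scan oracle", {
  expect_equal(hpd_interval(rep(3.5, 10)), c(3.5, 3.5))
  expect_equal(diff(hpd_interval(1:100)), 94)
  expect_equal(hpd_interval(1:100)[1], 1)  # tie broken to smallest low endpoint
  expect_error(hpd_interval(numeric(0)), "empty")
  set.seed(5)
  for (rep in 1:20) {
    x <- switch(1 + rep %% 3,
                rnorm(sample(5:200, 1)),
                rexp(sample(5:200, 1)),
                rlnorm(sample(5:200, 1)))
    m <- sample(c(0.5, 0.8, 0.95), 1)
    expect_equal(hpd_interval(x, m), oracle_hpd(x, m))
  }
})

test_that("hpd_interval width matches the uniform-sample expectation", {
  set.seed(123)
  x <- runif(10000)
  w <- diff(hpd_interval(x, 0.95))
  expect_equal(w, 0.95, tolerance = 0.02 / 0.95)
})

test_that("posterior_dating degenerates correctly for 1 tree and identical trees", {
  cal <- fv_calibration_points()
  sim <- simulate_tdrp_posterior(2.61, 1.63, cal$s_median, rel_noise_sd = 0,
                                 n_trees = 1, seed = 1, calib_idx = 1:8)
  est <- posterior_dating(sim$trees, sim$focal_tip, sim$calibration,
                          sim$specs, sim$specs["node_9"])
  expect_equal(est$summary$n_samples, 1L)
  expect_equal(est$summary$median, est$summary$hpd_low)
  expect_equal(est$summary$median, est$summary$hpd_high)
  ## noiseless: held-out node recovered exactly
  expect_equal(est$summary$median, sim$truth$T[9], tolerance = 1e-9)

  ## 50 identical copies: zero-width HPD
  trees <- rep(sim$trees, 50)
  est50 <- posterior_dating(trees, sim$focal_tip, sim$calibration,
                            sim$specs, sim$specs["node_9"])
  expect_equal(est50$summary$hpd_high - est50$summary$hpd_low, 0)
  expect_equal(est50$summary$n_samples, 50L)
})

test_that("posterior_dating flags extrapolation and rejects off-lineage nodes", {
  cal <- fv_calibration_points()
  sim <- simulate_tdrp_posterior(2.61, 1.63, cal$s_median, rel_noise_sd = 0,
                                 n_trees = 2, seed = 1, calib_idx = 1:8)
  est <- posterior_dating(sim$trees, sim$focal_tip, sim$calibration,
                          sim$specs, sim$specs["node_9"])
  expect_true(est$summary$extrapolation)  # node_9 is beyond nodes 1-8
  est2 <- posterior_dating(sim$trees, sim$focal_tip, sim$calibration,
                           sim$specs, sim$specs["node_5"])
  expect_false(est2$summary$extrapolation)
  ## an off-lineage MRCA (a cherry on the other side of the root) is a
  ## structural error naming tree and node
  tr <- parse_newick("(((FOCAL:0.1,OG1:0.1)n1:0.2,OG2:0.3)n2:0.3,(X1:0.2,X2:0.2)off:0.4);")
  calib3 <- data.frame(node = c("node_1", "node_2", "node_3"),
                       t_median = c(1, 10, 100),
                       t_low = c(0.5, 5, 50), t_high = c(2, 20, 200))
  specs3 <- list(node_1 = c("FOCAL", "OG1"), node_2 = c("FOCAL", "OG2"),
                 node_3 = c("FOCAL", "X1"))
  expect_error(
    posterior_dating(tr, "FOCAL", calib3, specs3,
                     list(node_bad = c("X1", "X2"))),
    "not on the focal lineage")
})

test_that("interval T-sampling is seeded and reproducible", {
  cal <- fv_calibration_points()
  sim <- simulate_tdrp_posterior(2.61, 1.63, cal$s_median, rel_noise_sd = 0.05,
                                 n_trees = 20, seed = 2, calib_idx = 1:8)
  a <- posterior_dating(sim$trees, sim$focal_tip, sim$calibration, sim$specs,
                        sim$specs["node_9"], t_sampling = "interval", seed = 99)
  b <- posterior_dating(sim$trees, sim$focal_tip, sim$calibration, sim$specs,
                        sim$specs["node_9"], t_sampling = "interval", seed = 99)
  d <- posterior_dating(sim$trees, sim$focal_tip, sim$calibration, sim$specs,
                        sim$specs["node_9"], t_sampling = "interval", seed = 100)
  expect_identical(a$samples, b$samples)
  expect_false(identical(a$samples, d$samples))
  ## interval sampling widens the HPD relative to fixed medians
  m <- posterior_dating(sim$trees, sim$focal_tip, sim$calibration, sim$specs,
                        sim$specs["node_9"], t_sampling = "median")
  expect_gt(diff(c(a$summary$hpd_low, a$summary$hpd_high)),
            diff(c(m$summary$hpd_low, m$summary$hpd_high)) - 1e-9)
})

test_that("known (alpha, beta) are recovered within their 95% CIs across seeds", {
  alpha <- 2.61; beta <- 1.63
  cal <- fv_calibration_points()
  hits <- 0L
  n_rep <- 40L
  for (s in seq_len(n_rep)) {
    set.seed(1000 + s)
    x <- log10(cal$s_median)
    y <- alpha + beta * x + rnorm(length(x), 0, 0.1)
    f <- fit_power_law(cal$s_median, 10^y)
    ci <- confint(lm(y ~ x))
    expect_equal(unname(coef(lm(y ~ x))), c(f$alpha, f$beta), tolerance = 1e-10)
    if (ci[1, 1] <= alpha && alpha <= ci[1, 2] &&
        ci[2, 1] <= beta && beta <= ci[2, 2]) hits <- hits + 1L
  }
  expect_gte(hits / n_rep, 0.9)
})
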