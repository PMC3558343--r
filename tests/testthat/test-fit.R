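test_that("common smoothing moment estimator matches worked values", {
  d <- design_two_group(2, 2, normalize = TRUE)
  # ||t(Xo) d||^2 = 8, q = 2, sigma2 = 1  ->  8/2 - 1 = 3
  expect_equal(estimate_common_tau(c(2, 2, 0, 0), d, 1), 3)
  # at the boundary ||b||^2 = q sigma2 the positive part hits zero
  expect_equal(estimate_common_tau(c(1, 0, 1, 0) * sqrt(2) / 2 * 2, d, 1), 0)
  b_sq_1 <- c(1, 0, 0, 0)  # ||t(Xo) d||^2 = 1/2 < q sigma2
  expect_equal(estimate_common_tau(b_sq_1, d, 1), 0)
  expect_error(estimate_common_tau(c(1, 1, 1, 1), d, 0), "positive")
  expect_error(
    estimate_common_tau(c(1, 1, 1, 1),
                        design_two_group(2, 2, normalize = FALSE), 1),
    "normalized")
})

test_that("Gauss-Seidel sweep has the no-signal fixed point", {
  d <- design_two_group(2, 2, normalize = TRUE)
  # orthogonal to both columns: sum zero and equal group sums
  v <- c(1, -1, 1, -1)
  st <- gauss_seidel_update(v, d, list(tau = 0, sigma2 = 5))
  expect_equal(st$sigma2, sum(v^2) / 4)
  expect_equal(st$tau, 0)
  # huge signal: shrinkage approaches 1 under iteration
  v2 <- d$Xo %*% c(100, 80)
  st2 <- list(tau = 0, sigma2 = 1)
  for (i in 1:50) st2 <- gauss_seidel_update(v2, d, st2)
  expect_gt(st2$tau / (1 + st2$tau), 0.999)
})

test_that("the MML fixed point matches a dense 2-D grid search", {
  set.seed(3)
  d <- design_two_group(4, 4, normalize = TRUE)
  n_checked <- 0
  for (rep in 1:12) {
    beta <- rnorm(2, sd = 2)
    v <- drop(d$Xo %*% beta) + rnorm(8, sd = 0.7)
    st <- list(tau = 1, sigma2 = 1)
    for (i in 1:200) st <- gauss_seidel_update(v, d, st)
    grid <- mml_grid_oracle(v, d$Xo, n_tau = 600, n_sig = 600)
    if (grid$tau == 0 || st$tau == 0) {
      expect_equal(st$tau, grid$tau)
      next
    }
    n_checked <- n_checked + 1
    expect_lt(abs(st$tau - grid$tau) / grid$tau, 0.05)
    expect_lt(abs(st$sigma2 - grid$sigma2) / grid$sigma2, 0.05)
    # the fixed point never scores below the grid optimum
    expect_gte(mml_loglik(v, d$Xo, st$tau, st$sigma2),
               grid$loglik - 1e-6)
  }
  expect_gte(n_checked, 5)
})

test_that("fixed point is a stationary point regardless of start", {
  set.seed(8)
  d <- design_poly(rep(1:3, each = 2), normalize = TRUE)
  for (rep in 1:20) {
    v <- drop(d$Xo %*% rnorm(3, sd = 3)) + rnorm(6)
    ends <- lapply(list(list(tau = 0, sigma2 = 10),
                        list(tau = 50, sigma2 = 0.01)), function(st) {
      for (i in 1:300) st <- gauss_seidel_update(v, d, st)
      st
    })
    expect_equal(ends[[1]]$tau, ends[[2]]$tau, tolerance = 1e-4)
    expect_equal(ends[[1]]$sigma2, ends[[2]]$sigma2, tolerance = 1e-4)
  }
})

test_that("noise-free signals are recovered almost exactly", {
  d <- design_two_group(3, 3)
  sim <- simulate_tiling(d, n_probes = 256, noise_sd = 1e-6, baseline = 5,
    effects = list(list(role = "group_diff", from = 65, to = 128,
                        amplitude = 2)), seed = 5)
  fit <- wfm(sim$Y, d)
  expect_lt(max(abs(coef(fit) - sim$truth$B)), 0.05)
})

test_that("pure noise drives the common smoothing parameter to zero", {
  set.seed(21)
  d <- design_two_group(3, 3, normalize = TRUE)
  Y <- matrix(rnorm(6 * 2048), 6, 2048)
  fit <- wfm(Y, d, smoothing = "common")
  expect_equal(median(fit$tau), 0)
  # tau = 0 means full shrinkage: posterior mean identically zero there
  expect_true(all(fit$coef_w[, fit$tau[1, ] == 0] == 0))
})

test_that("posterior means are shrunken least-squares coefficients", {
  set.seed(31)
  d <- design_helmert(c(2, 2, 2), normalize = TRUE)
  sim <- simulate_tiling(d, n_probes = 200, noise_sd = 0.5,
    effects = list(list(role = "helmert_1", from = 50, to = 120,
                        amplitude = 1)), seed = 31)
  for (sm in c("per_effect", "common")) {
    fit <- wfm(sim$Y, d, smoothing = sm)
    expect_true(all(abs(fit$coef_w) <= abs(fit$b) + 1e-12))
    expect_true(all(fit$var_w >= 0))
    expect_true(all(fit$tau >= 0))
    expect_true(all(fit$sigma2 > 0))
    expect_true(fit$converged)
  }
})

test_that("no-shrinkage fit equals probe-wise ordinary least squares", {
  set.seed(13)
  for (Tn in c(16, 21)) {   # power of two and padded case
    d <- design_poly(rep(1:3, each = 2), normalize = FALSE)
    Y <- matrix(rnorm(6 * Tn, sd = 1), 6, Tn) +
      d$X %*% matrix(rnorm(3 * Tn), 3, Tn)
    fit <- wfm(Y, d, tau_fixed = Inf)
    ols <- probewise_ols(Y, d$X)
    expect_equal(unname(coef(fit)), unname(t(ols)), tolerance = 1e-8)
  }
})

test_that("custom-design back-transform reproduces OLS on the original X", {
  set.seed(14)
  X <- two_factor_design_matrix()
  d <- design_custom(X)
  Y <- X %*% matrix(rnorm(6 * 16), 6, 16) + matrix(rnorm(96, sd = 0.2), 6)
  fit <- wfm(Y, d, tau_fixed = Inf)
  expect_equal(unname(coef(fit)), unname(t(probewise_ols(Y, X))),
               tolerance = 1e-8)
})

test_that("zero data give zero tracks with nonnegative variances", {
  d <- design_two_group(2, 2)
  fit <- wfm(matrix(0, 4, 32), d)
  expect_equal(unname(coef(fit)), matrix(0, 2, 32))
  expect_true(all(coef(fit, what = "var") >= 0))
})

test_that("two-group parameter recovery hits the planted effect size", {
  d <- design_two_group(3, 3)
  inreg <- numeric(0)
  outreg <- numeric(0)
  for (r in 1:20) {
    sim <- simulate_tiling(d, n_probes = 1024, noise_sd = 0.3,
      effects = list(list(role = "group_diff", from = 101, to = 228,
                          amplitude = 1)), seed = 100 + r)
    fit <- wfm(sim$Y, d, probes = sim$probes)
    tr <- wfm_effect(fit, "compare", pair = c(1, 2))
    inreg <- c(inreg, mean(tr$mean[101:228]))
    outreg <- c(outreg, mean(abs(tr$mean[-(81:248)])))
  }
  expect_gte(mean(inreg), 0.8)
  expect_lte(mean(inreg), 1.1)
  expect_lt(mean(outreg), 0.1)
})

test_that("null data rarely reach high posterior effect probabilities", {
  set.seed(77)
  d <- design_two_group(3, 3)
  frac <- replicate(5, {
    Y <- matrix(rnorm(6 * 1024, sd = 0.3), 6, 1024)
    fit <- wfm(Y, d)
    tr <- wfm_effect(fit, "compare", pair = c(1, 2))
    f <- wfm_fdr(tr, delta = 0.2, alpha = 0.05)
    mean(f$locfdr < 0.05)   # P(effect > delta | Y) > 0.95
  })
  expect_lt(mean(frac), 0.01)
})

test_that("configuration and data errors are raised", {
  d <- design_two_group(2, 2, normalize = FALSE)
  Y <- matrix(rnorm(4 * 16), 4, 16)
  expect_error(wfm(Y, d, smoothing = "common"), "normalized design")
  Yb <- Y; Yb[1, 1] <- NA
  expect_error(wfm(Yb, d), "finite")
  expect_error(wfm(Y[1:3, ], d), "arrays")
})
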