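test_that("pairwise contrast matrices enumerate all group pairs", {
  Z <- pairwise_contrasts(3, c(1, 1, 1))
  expect_equal(unname(Z), matrix(c(1, -1, 0,
                                   1, 0, -1,
                                   0, 1, -1), 3, 3, byrow = TRUE))
  Z2 <- pairwise_contrasts(2, c(2, 2))
  expect_equal(unname(Z2), matrix(c(0.5, 0.5, -0.5, -0.5), 1))
  expect_equal(nrow(pairwise_contrasts(6, rep(3, 6))), 15)
  expect_error(pairwise_contrasts(1, 1), ">= 2")
  # Z X B evaluates fitted mean differences: with identical rows per group,
  # row (a,b) of Z %*% X is x_a - x_b
  d <- design_helmert(c(2, 3), normalize = FALSE)
  ZX <- pairwise_contrasts(2, c(2, 3)) %*% d$X
  expect_equal(drop(ZX), d$X[1, ] - d$X[3, ])
})

test_that("two-group comparison equals twice the contrast coefficient", {
  d <- design_two_group(3, 3)
  sim <- simulate_tiling(d, n_probes = 64, noise_sd = 0, baseline = 4,
    effects = list(list(role = "group_diff", from = 17, to = 48,
                        amplitude = 1)))
  fit <- wfm(sim$Y, d)
  tr <- wfm_effect(fit, "compare", pair = c(1, 2))
  b2 <- coef(fit)[2, ]
  expect_equal(tr$mean, 2 * b2, tolerance = 1e-8)
  expect_equal(tr$mean[17:48], rep(1, 32), tolerance = 1e-6)
})

test_that("means mode recovers group mean functions on noise-free data", {
  d <- design_helmert(c(2, 2, 2), normalize = TRUE)
  sim <- simulate_tiling(d, n_probes = 128, noise_sd = 0, baseline = 3,
    effects = list(list(role = "helmert_2", from = 33, to = 96,
                        amplitude = 0.8)))
  fit <- wfm(sim$Y, d)
  for (g in 1:3) {
    tr <- wfm_effect(fit, "means", group = g)
    true_mean <- colMeans(sim$Y[d$groups == g, , drop = FALSE])
    expect_lt(max(abs(tr$mean - true_mean)), 0.05)
  }
})

test_that("effects mode returns the de-normalized polynomial coefficient", {
  d <- design_poly(rep(1:3, each = 2), normalize = TRUE)
  B <- matrix(0, 3, 64)
  B[2, 20:40] <- 1.5                      # linear effect, original coding
  Y <- d$Xo %*% (d$tri %*% B)             # signal X %*% B in the raw coding
  fit <- wfm(Y, d, tau_fixed = Inf)
  tr <- wfm_effect(fit, "effects", degree = 1)
  expect_equal(tr$mean, B[2, ], tolerance = 1e-8)
  expect_equal(tr$label, "linear")
  expect_error(wfm_effect(fit, "effects", degree = 3), "degree must be in")
  # effects mode is gated to time-course fits
  d2 <- design_two_group(2, 2)
  fit2 <- wfm(matrix(rnorm(4 * 16), 4, 16), d2)
  expect_error(wfm_effect(fit2, "effects", degree = 1), "time-course")
  expect_error(wfm_effect(fit2, "circadian"), "circadian")
})

test_that("circadian amplitude combines sine and cosine components", {
  tt <- rep(0:5 * 4, each = 2)
  d <- design_circadian(tt, period = 24)
  B <- matrix(0, 3, 32)
  B[2, ] <- 3
  B[3, ] <- 4
  Y <- d$X %*% B
  fit <- wfm(Y, d, tau_fixed = Inf)
  tr <- wfm_effect(fit, "circadian")
  expect_equal(tr$mean, rep(5, 32), tolerance = 1e-6)   # 3-4-5
  expect_true(all(tr$mean >= 0))
  expect_equal(tr$comp$sin_mean, rep(3, 32), tolerance = 1e-6)
  expect_equal(tr$comp$cos_mean, rep(4, 32), tolerance = 1e-6)
})

test_that("local FDR probabilities follow the Gaussian posterior", {
  mk_track <- function(mean, sd) {
    structure(list(mode = "compare", label = "toy", mean = mean, sd = sd,
                   comp = NULL, n_probes = length(mean), probes = NULL),
              class = "wfm_track")
  }
  delta <- 0.5
  tr <- mk_track(c(delta, delta + 5 * 0.1, -2), c(0.2, 0.1, 0.3))
  f <- wfm_fdr(tr, delta = delta, alpha = 0.05, side = "above")
  expect_equal(f$locfdr[1], 0.5)
  expect_equal(f$locfdr[2], pnorm(-5), tolerance = 1e-10)
  expect_gt(f$locfdr[3], 0.999)

  # degenerate posteriors collapse to point masses
  f0 <- wfm_fdr(mk_track(c(1, 0.2), c(0, 0)), delta = 0.5, alpha = 0.2)
  expect_equal(f0$locfdr, c(0, 1))

  # under-expression is over-expression of the negated track
  m <- rnorm(50); s <- rexp(50)
  f_below <- wfm_fdr(mk_track(m, s), delta = delta, side = "below")
  f_above_neg <- wfm_fdr(mk_track(-m, s), delta = delta, side = "above")
  expect_equal(f_below$locfdr, f_above_neg$locfdr, tolerance = 1e-12)

  # monotone in delta
  f1 <- wfm_fdr(mk_track(m, s), delta = 0.2)
  f2 <- wfm_fdr(mk_track(m, s), delta = 0.8)
  expect_true(all(f2$locfdr >= f1$locfdr - 1e-12))

  # two-sided output carries the per-direction probabilities
  f2s <- wfm_fdr(mk_track(m, s), delta = delta, side = "two_sided")
  expect_equal(f2s$locfdr, pmin(f2s$locfdr_above, f2s$locfdr_below))
  expect_true(all(f2s$direction %in% c("up", "down")))

  expect_error(wfm_fdr(mk_track(m, s), delta = 0.5, alpha = 1.2), "alpha")
  expect_error(wfm_fdr(mk_track(m, s), delta = -1), "nonnegative")
  tr_means <- mk_track(m, s); tr_means$mode <- "means"
  expect_error(wfm_fdr(tr_means), "no default threshold")
})

test_that("the prefix rule declares the right significant sets", {
  # choose means so that pnorm((delta - m) / 1) equals the wanted local prob
  mk_track <- function(p) structure(
    list(mode = "compare", label = "t", mean = 0.5 - qnorm(p),
         sd = rep(1, length(p)), comp = NULL, n_probes = length(p),
         probes = NULL), class = "wfm_track")
  # all local probs 0.2: nothing at alpha 0.05, everything at 0.25
  tr <- mk_track(rep(0.2, 10))
  expect_equal(sum(wfm_fdr(tr, delta = 0.5, alpha = 0.05)$mask), 0)
  expect_equal(sum(wfm_fdr(tr, delta = 0.5, alpha = 0.25)$mask), 10)
})

test_that("prefix rule equals exhaustive subset search for small T", {
  set.seed(99)
  for (rep in 1:8) {
    p <- round(runif(11), 3)
    alpha <- runif(1, 0.05, 0.5)
    mask <- tilewave:::bfdr_mask(p, alpha)
    ref <- bfdr_exhaustive(p, alpha)
    expect_equal(sum(mask), sum(ref))
    if (any(mask)) {
      expect_lte(mean(p[mask]), alpha + 1e-12)
      expect_equal(sort(p[mask]), sort(p[ref]))
    }
  }
})

test_that("circadian Monte-Carlo FDR matches the chi-square closed form", {
  set.seed(5)
  n_probes <- 50
  s <- 0.4
  m2 <- rnorm(n_probes); m3 <- rnorm(n_probes)
  tr <- structure(list(
    mode = "circadian", label = "amplitude",
    mean = sqrt(m2^2 + m3^2), sd = rep(NA_real_, n_probes),
    comp = list(sin_mean = m2, sin_sd = rep(s, n_probes),
                cos_mean = m3, cos_sd = rep(s, n_probes)),
    n_probes = n_probes, probes = NULL), class = "wfm_track")
  delta <- 0.8
  f <- wfm_fdr_circadian(tr, delta = delta, alpha = 0.05, n_sim = 10000,
                         seed = 42)
  # equal component variances: (A/s)^2 ~ noncentral chi^2_2
  exact <- pchisq((delta / s)^2, df = 2, ncp = (m2^2 + m3^2) / s^2)
  se <- sqrt(pmax(exact * (1 - exact), 1e-12) / 10000)
  expect_true(all(abs(f$locfdr - exact) <= 3 * se + 1e-9))

  # standard-normal components, delta = 1: P(chi^2_2 < 1) = 1 - exp(-1/2)
  tr0 <- tr
  tr0$comp <- list(sin_mean = rep(0, n_probes), sin_sd = rep(1, n_probes),
                   cos_mean = rep(0, n_probes), cos_sd = rep(1, n_probes))
  f0 <- wfm_fdr_circadian(tr0, delta = 1, alpha = 0.05, n_sim = 10000,
                          seed = 43)
  expect_equal(mean(f0$locfdr), 1 - exp(-0.5), tolerance = 0.01)

  # identical seeds are bit-identical; degenerate posteriors give 0
  f_rep <- wfm_fdr_circadian(tr, delta = delta, alpha = 0.05, n_sim = 10000,
                             seed = 42)
  expect_identical(f$locfdr, f_rep$locfdr)
  tr_d <- tr
  tr_d$comp <- list(sin_mean = rep(3, n_probes), sin_sd = rep(1e-12, n_probes),
                    cos_mean = rep(4, n_probes), cos_sd = rep(1e-12, n_probes))
  fd <- wfm_fdr_circadian(tr_d, delta = 1, alpha = 0.05, n_sim = 200,
                          seed = 1)
  expect_equal(fd$locfdr, rep(0, n_probes))

  expect_error(wfm_fdr_circadian(tr, n_sim = 50, seed = 1), "at least 100")
  expect_error(wfm_fdr_circadian(tr, n_sim = 1000), "seed")
})

test_that("compare and contrast modes agree on the two-factor design", {
  X <- two_factor_design_matrix()
  d <- design_custom(X, groups = 1:6)
  B <- matrix(rnorm(6 * 16), 6, 16)
  fit <- wfm(X %*% B, d, tau_fixed = Inf)
  # imbibition effect in aba2 mutants: beta1 + beta4 = row5 - row2 of X B
  tr_c <- wfm_effect(fit, "contrast", contrast = c(0, 1, 0, 0, 1, 0))
  tr_p <- wfm_effect(fit, "compare", pair = c(5, 2))
  expect_equal(tr_c$mean, tr_p$mean, tolerance = 1e-8)
  expect_equal(tr_c$mean, B[2, ] + B[5, ], tolerance = 1e-8)
})
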