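# Effect functions and Bayesian FDR detection.
#
# Every inference mode reduces to a linear functional F beta(t) = lambda' beta
# of the original-coding effect functions (except the circadian amplitude,
# which is the norm of two of them). In the orthonormal fitting basis the
# posterior is independent across effects, so the functional's posterior is
# Gaussian per probe with mean and variance obtained by the linear inverse
# DWT; for QR designs the mapping through solve(tri) carries the posterior
# covariance along automatically.

#' Pairwise-comparison contrast matrix
#'
#' Builds the `q*(q-1)/2 x N` matrix Z whose rows pick out all pairwise
#' group-mean differences: the row for pair (a, b), a < b, has `+1/N_a` on
#' the arrays of group a and `-1/N_b` on the arrays of group b, so
#' `Z %*% X %*% B` evaluates the fitted mean-difference function for every
#' pair. Arrays are assumed in group-block order.
#'
#' @param q Number of groups (>= 2).
#' @param group_sizes Integer vector of length `q`.
#' @return Numeric matrix with `choose(q, 2)` rows; rownames label the pairs.
#' @examples
#' pairwise_contrasts(3, c(1, 1, 1))
#' @export
pairwise_contrasts <- function(q, group_sizes) {
  q <- as.integer(q)
  if (is.na(q) || q < 2L) stop("q must be an integer >= 2", call. = FALSE)
  check_counts(group_sizes, "group sizes")
  if (length(group_sizes) != q)
    stop("group_sizes must have length q", call. = FALSE)
  grp <- rep(seq_len(q), group_sizes)
  pairs <- utils::combn(q, 2L)
  Z <- matrix(0, ncol(pairs), length(grp))
  for (r in seq_len(ncol(pairs))) {
    a <- pairs[1L, r]; b <- pairs[2L, r]
    Z[r, grp == a] <- 1 / group_sizes[a]
    Z[r, grp == b] <- -1 / group_sizes[b]
  }
  rownames(Z) <- apply(pairs, 2L, function(p) paste0(p[1L], "-", p[2L]))
  Z
}

group_design_row <- function(design, g) {
  idx <- which(design$groups == g)
  if (length(idx) == 0L) stop("no arrays in group ", g, call. = FALSE)
  colMeans(design$X[idx, , drop = FALSE])
}

#' Extract an effect function track from a fit
#'
#' Computes the probe-wise posterior mean and standard deviation of the
#' effect of interest `F beta(t)`:
#' \describe{
#'   \item{compare}{difference of two group/time-point mean functions
#'     (select with `pair = c(a, b)`, a minus b, by group index).}
#'   \item{means}{fitted mean expression function of one group/time point
#'     (`group =`), for annotation-free transcript discovery.}
#'   \item{effects}{a polynomial trend coefficient function on the original
#'     de-normalized coding (`degree =`; time-course fits only), so the
#'     fitted effect at probe t is `beta_d(t)` times the degree-d
#'     polynomial of time.}
#'   \item{circadian}{the rhythm amplitude
#'     `A(t) = sqrt(beta_sin(t)^2 + beta_cos(t)^2)` (circadian fits only);
#'     the sine/cosine component posteriors are retained for Monte-Carlo
#'     FDR via [wfm_fdr_circadian()].}
#'   \item{contrast}{a user-supplied linear combination of the
#'     original-coding effect functions (`contrast =`, length q), e.g.
#'     main effect plus interaction in a multi-factor design.}
#' }
#' Modes are gated by the fit subclass: `effects` needs a time-course fit,
#' `circadian` a circadian fit, and `compare`/`means` a design with group
#' structure.
#'
#' @param fit A `"wfm"` object.
#' @param mode One of `"compare"`, `"means"`, `"effects"`, `"circadian"`,
#'   `"contrast"`.
#' @param pair,group,degree,contrast Mode selectors (see above).
#' @param label Optional track label; a default is derived from the mode.
#' @return An object of class `"wfm_track"`: list with `mode`, `label`,
#'   `mean` and `sd` (length-T numeric), and for circadian mode the
#'   component posteriors `comp` (means/sds of the sine and cosine effect
#'   functions).
#' @examples
#' d <- design_two_group(3, 3)
#' sim <- simulate_tiling(d, n_probes = 128,
#'   effects = list(list(role = "group_diff", from = 30, to = 60,
#'                       amplitude = 0.5)),
#'   noise_sd = 0.2, seed = 1)
#' fit <- wfm(sim$Y, d)
#' tr <- wfm_effect(fit, "compare", pair = c(1, 2))
#' @export
wfm_effect <- function(fit,
                       mode = c("compare", "means", "effects", "circadian",
                                "contrast"),
                       pair = NULL, group = NULL, degree = NULL,
                       contrast = NULL, label = NULL) {
  mode <- match.arg(mode)
  if (!inherits(fit, "wfm")) stop("fit must be a wfm object", call. = FALSE)
  design <- fit$design
  A <- solve(design$tri)     # original coding <- orthonormal basis
  q <- design$q

  comp <- NULL
  if (mode == "compare" || mode == "means") {
    if (is.null(design$groups))
      stop(mode, " mode needs a design with group structure ",
           "(supply groups= for custom designs)", call. = FALSE)
    ngrp <- length(design$group_sizes)
    if (mode == "compare") {
      if (is.null(pair) || length(pair) != 2L)
        stop("compare mode needs pair = c(a, b)", call. = FALSE)
      pair <- as.integer(pair)
      if (any(is.na(pair)) || any(pair < 1L) || any(pair > ngrp) ||
          pair[1L] == pair[2L])
        stop("pair must select two distinct groups in 1..", ngrp,
             call. = FALSE)
      lam_orig <- group_design_row(design, pair[1L]) -
        group_design_row(design, pair[2L])
      if (is.null(label))
        label <- paste(design$group_labels[pair[1L]], "vs",
                       design$group_labels[pair[2L]])
    } else {
      if (is.null(group) || length(group) != 1L)
        stop("means mode needs group = <index>", call. = FALSE)
      group <- as.integer(group)
      if (is.na(group) || group < 1L || group > ngrp)
        stop("group must be in 1..", ngrp, call. = FALSE)
      lam_orig <- group_design_row(design, group)
      if (is.null(label)) label <- design$group_labels[group]
    }
  } else if (mode == "effects") {
    if (!inherits(fit, "wfm_time"))
      stop("effects mode is only available for time-course ",
           "(orthogonal polynomial) fits", call. = FALSE)
    if (is.null(degree) || length(degree) != 1L)
      stop("effects mode needs degree = <polynomial degree>", call. = FALSE)
    degree <- as.integer(degree)
    if (is.na(degree) || degree < 1L || degree > q - 1L)
      stop("degree must be in 1..", q - 1L, call. = FALSE)
    lam_orig <- as.numeric(seq_len(q) == degree + 1L)
    if (is.null(label)) label <- c("linear", "quadratic",
                                   paste0("degree", 3:25))[degree]
  } else if (mode == "contrast") {
    if (is.null(contrast) || length(contrast) != q)
      stop("contrast mode needs a numeric contrast of length ", q,
           call. = FALSE)
    lam_orig <- as.numeric(contrast)
    if (is.null(label)) label <- "contrast"
  } else {                                  # circadian
    if (!inherits(fit, "wfm_circadian"))
      stop("circadian mode is only available for circadian (Fourier) fits",
           call. = FALSE)
    i_sin <- which(design$roles == "sine")
    i_cos <- which(design$roles == "cosine")
    lam_sin <- drop(A[i_sin, ])
    lam_cos <- drop(A[i_cos, ])
    cs <- functional_track(fit, lam_sin)
    cc <- functional_track(fit, lam_cos)
    comp <- list(sin_mean = cs$mean, sin_sd = cs$sd,
                 cos_mean = cc$mean, cos_sd = cc$sd)
    out <- list(mode = mode,
                label = if (is.null(label)) "amplitude" else label,
                mean = sqrt(cs$mean^2 + cc$mean^2),
                sd = rep(NA_real_, length(cs$mean)),
                comp = comp, n_probes = length(cs$mean),
                probes = fit$probes)
    class(out) <- "wfm_track"
    return(out)
  }

  lam <- drop(lam_orig %*% A)    # functional in the orthonormal basis
  tr <- functional_track(fit, lam)
  out <- list(mode = mode, label = label, mean = tr$mean, sd = tr$sd,
              comp = NULL, n_probes = length(tr$mean), probes = fit$probes)
  class(out) <- "wfm_track"
  out
}

# posterior of lambda' beta_orth per coefficient, mapped to probe space
functional_track <- function(fit, lam) {
  m_w <- drop(lam %*% fit$coef_w)
  v_w <- drop(lam^2 %*% fit$var_w)
  list(mean = wt_inverse(m_w, fit$plan),
       sd = sqrt(pmax(wt_var(v_w, fit$plan), 0)))
}

# Bayesian FDR prefix rule: among probes whose posterior odds favour a true
# call (local probability < 0.5), declare the largest prefix of the sorted
# local probabilities whose running mean stays at or below alpha. The
# candidate restriction keeps the running mean from absorbing probes that
# are more likely null than not.
bfdr_mask <- function(p, alpha) {
  mask <- logical(length(p))
  cand <- which(p < 0.5)
  if (!length(cand)) return(mask)
  o <- cand[order(p[cand])]
  running <- cumsum(p[o]) / seq_along(o)
  k <- which(running <= alpha)
  if (length(k)) mask[o[seq_len(max(k))]] <- TRUE
  mask
}

#' Bayesian FDR track for a Gaussian effect function
#'
#' Per probe, the local false discovery probability of calling the effect
#' beyond the threshold `delta`: for over-expression (`side = "above"`)
#' `P(F beta(t) < delta | Y)`, for under-expression (`side = "below"`)
#' `P(F beta(t) > -delta | Y)`, both from the Gaussian posterior of the
#' track. Significance is assigned by the direct posterior probability
#' (Bayesian FDR) rule: probes are sorted by local probability and the
#' largest prefix whose running mean stays at or below `alpha` is declared
#' significant; only probes whose posterior odds favour a true call (local
#' probability below 0.5) are eligible, so the running mean cannot absorb
#' probes that are more likely null than not. `side = "two_sided"`
#' evaluates both directions and combines them by their minimum, recording
#' the direction per probe.
#'
#' @param track A `"wfm_track"` with Gaussian posteriors (not circadian;
#'   use [wfm_fdr_circadian()] for amplitudes).
#' @param delta Effect threshold (>= 0, log2 units). Defaults to
#'   `log2(1.2)` for compare/contrast tracks; means-mode tracks have no
#'   default and require an explicit value.
#' @param alpha Target Bayesian FDR level in (0, 1).
#' @param side `"above"`, `"below"` or `"two_sided"`.
#' @return An object of class `"wfm_fdr"`: list with `locfdr` (local false
#'   discovery probabilities in `[0, 1]`), `mask` (significant probes),
#'   `alpha`, `delta`, `side`, and for two-sided calls `direction`
#'   (`"up"`/`"down"`) plus the per-direction probabilities.
#' @examples
#' d <- design_two_group(3, 3)
#' sim <- simulate_tiling(d, n_probes = 128,
#'   effects = list(list(role = "group_diff", from = 30, to = 60,
#'                       amplitude = 1)),
#'   noise_sd = 0.2, seed = 1)
#' f <- wfm_fdr(wfm_effect(wfm(sim$Y, d), "compare", pair = c(1, 2)),
#'              delta = log2(1.2), alpha = 0.05)
#' sum(f$mask)
#' @export
wfm_fdr <- function(track, delta = NULL, alpha = 0.05,
                    side = c("above", "below", "two_sided")) {
  side <- match.arg(side)
  if (!inherits(track, "wfm_track"))
    stop("track must be a wfm_track", call. = FALSE)
  if (track$mode == "circadian")
    stop("circadian amplitude tracks need the Monte-Carlo procedure; ",
         "use wfm_fdr_circadian()", call. = FALSE)
  if (is.null(delta)) {
    if (track$mode == "means")
      stop("means-mode tracks have no default threshold; supply delta ",
           "explicitly (see ?delta_quantile for an empirical helper)",
           call. = FALSE)
    delta <- log2(1.2)
  }
  if (!is.numeric(delta) || length(delta) != 1L || is.na(delta) || delta < 0)
    stop("delta must be a single nonnegative number", call. = FALSE)
  if (!is.numeric(alpha) || length(alpha) != 1L || is.na(alpha) ||
      alpha <= 0 || alpha >= 1)
    stop("alpha must be in (0, 1)", call. = FALSE)
  if (!all(is.finite(track$sd)))
    stop("track has non-finite posterior sd", call. = FALSE)

  p_above <- local_prob(track$mean, track$sd, delta, "above")
  p_below <- local_prob(track$mean, track$sd, delta, "below")
  locfdr <- switch(side, above = p_above, below = p_below,
                   two_sided = pmin(p_above, p_below))
  mask <- bfdr_mask(locfdr, alpha)
  out <- list(locfdr = locfdr, mask = mask, alpha = alpha, delta = delta,
              side = side, mode = track$mode, label = track$label,
              n_probes = track$n_probes, probes = track$probes,
              track_mean = track$mean)
  if (side == "two_sided") {
    out$direction <- ifelse(p_above <= p_below, "up", "down")
    out$locfdr_above <- p_above
    out$locfdr_below <- p_below
  }
  class(out) <- "wfm_fdr"
  out
}

local_prob <- function(m, s, delta, side) {
  if (side == "above") {
    # P(F < delta | Y); degenerate posteriors collapse to a point mass
    ifelse(s > 0, stats::pnorm((delta - m) / s), as.numeric(m < delta))
  } else {
    # P(F > -delta | Y)
    ifelse(s > 0, stats::pnorm((m + delta) / s), as.numeric(m > -delta))
  }
}

#' Monte-Carlo Bayesian FDR for circadian amplitude tracks
#'
#' The amplitude `A(t)` depends non-linearly on the sine and cosine effect
#' functions, so its posterior tail probability is approximated by
#' simulation: per probe, `n_sim` pairs are drawn from the independent
#' Gaussian posteriors of the two component functions, and the local false
#' discovery probability is the proportion of draws with
#' `sqrt(bs^2 + bc^2) < delta`. The same prefix rule as [wfm_fdr()] then
#' assigns significance.
#'
#' @param track A circadian `"wfm_track"` from [wfm_effect()].
#' @param delta Amplitude threshold (default `log2(1.1)`).
#' @param alpha Target Bayesian FDR level in (0, 1).
#' @param n_sim Number of posterior draws per probe (>= 100).
#' @param seed Integer seed; required, so repeated runs are bit-identical.
#' @return A `"wfm_fdr"` object (with `n_sim` and `seed` recorded).
#' @export
wfm_fdr_circadian <- function(track, delta = log2(1.1), alpha = 0.05,
                              n_sim = 10000L, seed) {
  if (!inherits(track, "wfm_track") || track$mode != "circadian")
    stop("track must be a circadian wfm_track", call. = FALSE)
  n_sim <- as.integer(n_sim)
  if (is.na(n_sim) || n_sim < 100L)
    stop("n_sim must be at least 100", call. = FALSE)
  if (missing(seed) || !is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("a single integer seed is required", call. = FALSE)
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1)
    stop("alpha must be in (0, 1)", call. = FALSE)
  if (!is.numeric(delta) || length(delta) != 1L || delta < 0)
    stop("delta must be a single nonnegative number", call. = FALSE)

  cm <- track$comp
  T_ <- track$n_probes
  locfdr <- numeric(T_)
  with_seed(seed, {
    chunk <- max(1L, floor(2e6 / n_sim))
    for (from in seq.int(1L, T_, by = chunk)) {
      to <- min(from + chunk - 1L, T_)
      idx <- from:to
      nb <- length(idx)
      bs <- matrix(stats::rnorm(nb * n_sim), nb, n_sim) *
        cm$sin_sd[idx] + cm$sin_mean[idx]
      bc <- matrix(stats::rnorm(nb * n_sim), nb, n_sim) *
        cm$cos_sd[idx] + cm$cos_mean[idx]
      locfdr[idx] <- rowMeans(sqrt(bs^2 + bc^2) < delta)
    }
  })
  mask <- bfdr_mask(locfdr, alpha)
  structure(list(locfdr = locfdr, mask = mask, alpha = alpha, delta = delta,
                 side = "above", mode = "circadian", label = track$label,
                 n_probes = T_, probes = track$probes,
                 track_mean = track$mean,
                 n_sim = n_sim, seed = as.integer(seed)),
            class = "wfm_fdr")
}

# run code under a given seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  force(code)
  invisible(NULL)
}

#' Empirical-quantile threshold helper for transcript discovery
#'
#' A convenience for choosing a means-mode threshold when no externally
#' motivated expression cutoff is available: the `prob` quantile of the
#' fitted mean-expression track, i.e. treat the bulk of the genome as
#' background and call the upper tail. This is a pragmatic device, not a
#' calibrated background model.
#'
#' @param track A means-mode `"wfm_track"`.
#' @param prob Background quantile (default 0.95).
#' @return A single number usable as `delta` in [wfm_fdr()].
#' @export
delta_quantile <- function(track, prob = 0.95) {
  if (!inherits(track, "wfm_track"))
    stop("track must be a wfm_track", call. = FALSE)
  as.numeric(stats::quantile(track$mean, prob))
}

#' @export
print.wfm_track <- function(x, ...) {
  cat("Effect track [", x$mode, "]: ", x$label, ", ", x$n_probes,
      " probes\n", sep = "")
  cat("  mean range: ", paste(signif(range(x$mean), 4), collapse = " .. "),
      "\n", sep = "")
  invisible(x)
}

#' @export
print.wfm_fdr <- function(x, ...) {
  cat("Bayesian FDR track [", x$mode, "]: ", x$label, "\n", sep = "")
  cat("  delta = ", signif(x$delta, 4), ", alpha = ", x$alpha,
      ", side = ", x$side,
      if (!is.null(x$n_sim)) paste0(", n_sim = ", x$n_sim), "\n", sep = "")
  cat("  significant probes: ", sum(x$mask), " / ", x$n_probes, "\n",
      sep = "")
  invisible(x)
}
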