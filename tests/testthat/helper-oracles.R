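# Independent oracles used across the suite.

# Closed-form orthonormal Haar synthesis matrix (P a power of two, full
# depth), columns ordered like the package's coefficient layout:
# scaling vector first, then wavelets coarse to fine, left to right.
haar_synthesis_oracle <- function(P) {
  J <- round(log2(P))
  cols <- list(rep(1 / sqrt(P), P))
  for (j in seq_len(J)) {
    K <- 2^(j - 1)
    s <- P / K
    for (k in seq_len(K)) {
      v <- numeric(P)
      idx <- ((k - 1) * s + 1):(k * s)
      v[idx[1:(s / 2)]] <- 1 / sqrt(s)
      v[idx[(s / 2 + 1):s]] <- -1 / sqrt(s)
      cols[[length(cols) + 1]] <- v
    }
  }
  do.call(cbind, cols)
}

# synthesis matrix of any plan, built coefficient by coefficient
synthesis_matrix <- function(plan) {
  P <- plan$padded
  sapply(seq_len(P), function(c) {
    e <- numeric(P); e[c] <- 1
    wt_inverse(e, plan, keep_pad = TRUE)
  })
}

# dense 2-D grid search of the common-smoothing marginal log likelihood
mml_grid_oracle <- function(d, Xo, n_tau = 400, n_sig = 400,
                            tau_range = c(1e-4, 1e4),
                            sig_range = NULL) {
  N <- nrow(Xo); q <- ncol(Xo)
  b2 <- sum(crossprod(Xo, d)^2)
  ssd <- sum(d^2)
  if (is.null(sig_range)) sig_range <- c(ssd / N / 50, ssd / N * 5)
  taus <- c(0, exp(seq(log(tau_range[1]), log(tau_range[2]),
                       length.out = n_tau)))
  sig2 <- exp(seq(log(sig_range[1]), log(sig_range[2]), length.out = n_sig))
  ll <- outer(taus, sig2, function(tau, s2)
    -0.5 * (N * log(s2) + q * log1p(tau) +
              ((ssd - b2) + b2 / (1 + tau)) / s2))
  best <- arrayInd(which.max(ll), dim(ll))
  list(tau = taus[best[1]], sigma2 = sig2[best[2]], loglik = max(ll))
}

mml_loglik <- function(d, Xo, tau, sigma2) {
  N <- nrow(Xo); q <- ncol(Xo)
  b2 <- sum(crossprod(Xo, d)^2)
  ssd <- sum(d^2)
  -0.5 * (N * log(sigma2) + q * log1p(tau) +
            ((ssd - b2) + b2 / (1 + tau)) / sigma2)
}

# exhaustive Bayesian-FDR reference: the largest subset of eligible probes
# (local probability < 0.5, i.e. posterior odds favour a true call) whose
# average local probability stays <= alpha (ties resolved to smallest mean)
bfdr_exhaustive <- function(p, alpha) {
  n <- length(p)
  best <- logical(n)
  best_size <- 0L
  best_mean <- Inf
  for (code in 0:(2^n - 1)) {
    sel <- as.logical(bitwAnd(rep(code, n), 2^(0:(n - 1))))
    if (!any(sel)) next
    if (any(p[sel] >= 0.5)) next
    m <- mean(p[sel])
    if (m <= alpha &&
        (sum(sel) > best_size || (sum(sel) == best_size && m < best_mean))) {
      best <- sel
      best_size <- sum(sel)
      best_mean <- m
    }
  }
  best
}

# probe-wise ordinary least squares on the original design coding
probewise_ols <- function(Y, X) {
  t(solve(crossprod(X), crossprod(X, Y)))  # T x q
}

# the printed two-factor (dry/imbibed x wild-type/aba2/cyp707) model matrix
two_factor_design_matrix <- function() {
  matrix(c(1, 0, 0, 0, 0, 0,
           1, 0, 1, 0, 0, 0,
           1, 0, 0, 1, 0, 0,
           1, 1, 0, 0, 0, 0,
           1, 1, 1, 0, 1, 0,
           1, 1, 0, 1, 0, 1),
         nrow = 6, byrow = TRUE)
}

make_annotation <- function(chrom, start0, end, strand = "+", id = NULL) {
  gr <- GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = start0 + 1L, end = end),
    strand = strand)
  if (!is.null(id)) gr$gene_id <- id
  gr
}
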