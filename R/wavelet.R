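# Orthonormal discrete wavelet transform along the probe coordinate.
#
# Signals of arbitrary length T are reflection-padded to the next power of
# two; the periodized pyramid transform on the padded signal is then exactly
# orthonormal, so Parseval holds and the inverse is the transpose. Padded
# positions are dropped again on reconstruction and never enter inference.

wt_filters <- function(family) {
  h <- switch(family,
    haar = c(1, 1) / sqrt(2),
    d4   = {
      s <- sqrt(3)
      c(1 + s, 3 + s, 3 - s, 1 - s) / (4 * sqrt(2))
    },
    stop("unknown wavelet family: ", family, call. = FALSE)
  )
  # quadrature-mirror highpass: g_k = (-1)^k h_{L-1-k}
  g <- rev(h) * (-1)^(seq_along(h) - 1)
  list(h = h, g = g)
}

#' Build a wavelet transform plan for a probe signal
#'
#' Prepares the bookkeeping for an orthonormal discrete wavelet transform
#' (DWT) of a signal of `n_probes` values: the padded (power-of-two) length,
#' the filter family, the decomposition depth, the (scale, location) index of
#' every coefficient, and the mask of synthetic padded positions.
#'
#' Scale 0 is the coarse approximation block; scales `1..levels` index the
#' detail blocks from coarsest to finest, with locations `k = 1..K_j` within
#' each scale.
#'
#' @param n_probes Number of probes T in the signal (>= 2).
#' @param family Wavelet family: `"haar"` (default, hand-checkable, exactly
#'   localized) or `"d4"` (Daubechies extremal-phase, 4 taps).
#' @param levels Decomposition depth J; defaults to the full depth
#'   `log2(padded length)`.
#' @return An object of class `"wavelet_plan"`: a list with elements
#'   `n_probes`, `padded`, `levels`, `family`, `h`, `g`,
#'   `index` (data frame with columns `scale`, `loc`), and `pad_mask`.
#' @examples
#' p <- wavelet_plan(6)
#' p$padded      # 8
#' table(p$index$scale)
#' @export
wavelet_plan <- function(n_probes, family = c("haar", "d4"), levels = NULL) {
  family <- match.arg(family)
  n_probes <- as.integer(n_probes)
  if (length(n_probes) != 1L || is.na(n_probes) || n_probes < 2L)
    stop("n_probes must be a single integer >= 2", call. = FALSE)
  padded <- 2L^as.integer(ceiling(log2(n_probes)))
  jmax <- as.integer(round(log2(padded)))
  if (is.null(levels)) levels <- jmax
  levels <- as.integer(levels)
  if (levels < 1L || levels > jmax)
    stop("levels must be in 1..", jmax, " for padded length ", padded,
         call. = FALSE)
  filt <- wt_filters(family)
  # coefficient layout: [approx (scale 0), detail scale 1 (coarsest), ...,
  # detail scale `levels` (finest)]
  block_len <- c(padded / 2^levels, padded / 2^(levels:1))
  scale <- rep.int(0:levels, block_len)
  loc <- unlist(lapply(block_len, seq_len), use.names = FALSE)
  plan <- list(
    n_probes = n_probes, padded = padded, levels = levels, family = family,
    h = filt$h, g = filt$g,
    index = data.frame(scale = scale, loc = loc),
    pad_mask = c(rep(FALSE, n_probes), rep(TRUE, padded - n_probes)),
    cache = new.env(parent = emptyenv())
  )
  class(plan) <- "wavelet_plan"
  plan
}

# one periodized analysis step: v (even length) -> approx + detail
dwt_step <- function(v, h, g) {
  n <- length(v)
  L <- length(h)
  pos <- (outer(seq.int(0L, n - 2L, by = 2L), 0:(L - 1L), `+`) %% n) + 1L
  V <- matrix(v[pos], nrow = n %/% 2L)
  list(a = drop(V %*% h), d = drop(V %*% g))
}

# one periodized synthesis step (transpose of dwt_step)
idwt_step <- function(a, d, h, g) {
  m <- length(a)
  n <- 2L * m
  L <- length(h)
  pos <- (outer(seq.int(0L, n - 2L, by = 2L), 0:(L - 1L), `+`) %% n) + 1L
  contrib <- outer(a, h) + outer(d, g)
  as.vector(rowsum(as.vector(contrib), group = as.vector(pos)))
}

pad_reflect <- function(x, padded) {
  p <- padded - length(x)
  if (p == 0L) return(x)
  c(x, rev(x)[seq_len(p)])
}

#' Forward discrete wavelet transform
#'
#' Projects a probe-ordered signal onto the orthonormal wavelet basis of its
#' plan. The signal is reflection-padded to the plan's power-of-two length
#' first; the returned coefficient vector has the padded length and satisfies
#' Parseval's identity with respect to the padded signal.
#'
#' @param x Numeric vector of length `plan$n_probes`.
#' @param plan A [wavelet_plan()].
#' @return Numeric vector of wavelet coefficients, length `plan$padded`,
#'   ordered approximation block first, then detail blocks coarse to fine
#'   (see `plan$index`).
#' @examples
#' p <- wavelet_plan(4)
#' wt_forward(c(1, 1, 1, 1), p)  # all energy in the coarse coefficient
#' @export
wt_forward <- function(x, plan) {
  if (!inherits(plan, "wavelet_plan")) stop("plan must be a wavelet_plan",
                                            call. = FALSE)
  if (length(x) != plan$n_probes)
    stop("signal length ", length(x), " does not match plan for ",
         plan$n_probes, " probes", call. = FALSE)
  v <- pad_reflect(as.numeric(x), plan$padded)
  details <- vector("list", plan$levels)
  for (l in seq_len(plan$levels)) {
    s <- dwt_step(v, plan$h, plan$g)
    details[[l]] <- s$d
    v <- s$a
  }
  c(v, unlist(rev(details), use.names = FALSE))
}

split_coeffs <- function(w, plan) {
  block_len <- c(plan$padded / 2^plan$levels, plan$padded / 2^(plan$levels:1))
  ends <- cumsum(block_len)
  starts <- c(1L, head(ends, -1L) + 1L)
  lapply(seq_along(block_len), function(i) w[starts[i]:ends[i]])
}

#' Inverse discrete wavelet transform
#'
#' Reconstructs the probe-space signal from a full coefficient vector; the
#' synthetic padded positions are dropped unless `keep_pad = TRUE`.
#'
#' @param w Numeric coefficient vector of length `plan$padded`.
#' @param plan A [wavelet_plan()].
#' @param keep_pad Return the full padded reconstruction instead of the first
#'   `n_probes` values.
#' @return Numeric vector of length `plan$n_probes` (or `plan$padded`).
#' @export
wt_inverse <- function(w, plan, keep_pad = FALSE) {
  if (!inherits(plan, "wavelet_plan")) stop("plan must be a wavelet_plan",
                                            call. = FALSE)
  if (length(w) != plan$padded)
    stop("coefficient length ", length(w), " does not match padded length ",
         plan$padded, call. = FALSE)
  blocks <- split_coeffs(as.numeric(w), plan)
  a <- blocks[[1L]]
  for (i in seq.int(2L, length(blocks)))
    a <- idwt_step(a, blocks[[i]], plan$h, plan$g)
  if (keep_pad) a else a[!plan$pad_mask]
}

# squared synthesis matrix (padded x padded), cached on the plan
wt_synth_sq <- function(plan) {
  if (!is.null(plan$cache$synth_sq)) return(plan$cache$synth_sq)
  P <- plan$padded
  M <- matrix(0, P, P)
  e <- numeric(P)
  for (c in seq_len(P)) {
    e[c] <- 1
    M[, c] <- wt_inverse(e, plan, keep_pad = TRUE)^2
    e[c] <- 0
  }
  plan$cache$synth_sq <- M
  M
}

#' Back-propagate coefficient variances to probe space
#'
#' Given per-coefficient variances of mutually independent wavelet
#' coefficients, returns the implied variance of the reconstructed signal at
#' every probe: `var(t) = sum_c w_{t,c}^2 var_c`, with `w` the synthesis
#' matrix of the plan. For the Haar family each coefficient reaches a probe
#' through a single filter path, so the computation runs through the fast
#' synthesis pyramid with squared taps; other families use the explicit
#' squared synthesis matrix (built once per plan and cached).
#'
#' @param v Nonnegative numeric vector of coefficient variances, length
#'   `plan$padded`.
#' @param plan A [wavelet_plan()].
#' @return Nonnegative numeric vector of probe variances, length
#'   `plan$n_probes`.
#' @export
wt_var <- function(v, plan) {
  if (!inherits(plan, "wavelet_plan")) stop("plan must be a wavelet_plan",
                                            call. = FALSE)
  if (length(v) != plan$padded)
    stop("variance length ", length(v), " does not match padded length ",
         plan$padded, call. = FALSE)
  v <- as.numeric(v)
  if (anyNA(v) || any(v < 0))
    stop("coefficient variances must be nonnegative", call. = FALSE)
  if (plan$family == "haar") {
    h2 <- plan$h^2
    g2 <- plan$g^2
    blocks <- split_coeffs(v, plan)
    a <- blocks[[1L]]
    for (i in seq.int(2L, length(blocks)))
      a <- idwt_step(a, blocks[[i]], h2, g2)
    return(a[!plan$pad_mask])
  }
  drop(wt_synth_sq(plan) %*% v)[!plan$pad_mask]
}

#' @export
print.wavelet_plan <- function(x, ...) {
  cat("Wavelet plan: ", x$n_probes, " probes, padded to ", x$padded,
      ", family ", x$family, ", ", x$levels, " levels\n", sep = "")
  invisible(x)
}
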