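# Standard modelling methods for "wfm" fits.

#' @export
print.wfm <- function(x, ...) {
  cat("Wavelet-based functional model fit (", class(x)[1L], ")\n", sep = "")
  cat("  design: ", x$design$kind, ", ", x$design$N, " arrays, ",
      x$design$q, " effect functions\n", sep = "")
  cat("  probes: ", ncol(x$Y), " (padded to ", x$plan$padded,
      "), wavelet family ", x$plan$family, ", ", x$plan$levels,
      " levels\n", sep = "")
  cat("  smoothing: ", x$smoothing,
      if (!is.null(x$tau_fixed)) paste0(" (tau fixed at ", x$tau_fixed, ")"),
      "; ", if (x$converged) "converged" else "NOT converged", " in ",
      x$iterations, " sweeps\n", sep = "")
  invisible(x)
}

#' @export
summary.wfm <- function(object, ...) {
  tracks <- wfm_tracks(object)
  res <- residuals(object)
  out <- list(
    fit = object,
    effect_range = t(apply(tracks$coef, 1L, range)),
    shrinkage = 1 - mean(object$tau / (1 + object$tau) == 0),
    residual_sd = stats::sd(res),
    sigma2_by_scale = tapply(object$sigma2, object$plan$index$scale,
                             stats::median))
  class(out) <- "summary.wfm"
  out
}

#' @export
print.summary.wfm <- function(x, ...) {
  print(x$fit)
  cat("  residual sd: ", signif(x$residual_sd, 4), "\n", sep = "")
  cat("  fraction of coefficient posteriors not fully shrunk to 0: ",
      signif(x$shrinkage, 3), "\n", sep = "")
  cat("  effect function ranges (original coding):\n")
  er <- x$effect_range
  colnames(er) <- c("min", "max")
  print(signif(er, 4))
  cat("  median noise variance by wavelet scale (0 = coarse):\n")
  print(signif(x$sigma2_by_scale, 3))
  invisible(x)
}

#' Posterior-mean effect functions
#'
#' @param object A `"wfm"` fit.
#' @param coding `"original"` (the design's interpretable coding, default)
#'   or `"orthonormal"` (the fitting basis).
#' @param what `"mean"` for the posterior-mean effect functions, `"var"`
#'   for their probe-wise posterior variances.
#' @param ... Unused.
#' @return A q x T matrix, rows named by effect role.
#' @export
coef.wfm <- function(object, coding = c("original", "orthonormal"),
                     what = c("mean", "var"), ...) {
  what <- match.arg(what)
  tr <- wfm_tracks(object, coding = match.arg(coding))
  if (what == "mean") tr$coef else tr$var
}

#' Fitted (denoised) expression values
#'
#' @param object A `"wfm"` fit.
#' @param ... Unused.
#' @return N x T matrix of fitted log2 expression values `X %*% B(t)`.
#' @export
fitted.wfm <- function(object, ...) {
  object$design$X %*% coef(object)
}

#' @export
residuals.wfm <- function(object, ...) {
  object$Y - fitted(object)
}

#' Predict fitted expression for new design rows
#'
#' @param object A `"wfm"` fit.
#' @param newdesign Matrix (rows in the design's original coding) or
#'   omitted for the fitted values.
#' @param ... Unused.
#' @return Matrix with one row of fitted probe values per input row.
#' @export
predict.wfm <- function(object, newdesign = NULL, ...) {
  if (is.null(newdesign)) return(fitted(object))
  newdesign <- matrix(as.numeric(newdesign), ncol = object$design$q)
  newdesign %*% coef(object)
}

#' Plot observed and fitted probe signals
#'
#' Base-graphics view of a probe window: observed log2 values per array
#' (colored by group where the design has groups) with the fitted group or
#' array curves overlaid.
#'
#' @param x A `"wfm"` fit.
#' @param window Probe index range to show (default the first 512 probes).
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.wfm <- function(x, window = NULL, ...) {
  T_ <- ncol(x$Y)
  if (is.null(window)) window <- c(1L, min(512L, T_))
  idx <- seq(max(1L, window[1L]), min(T_, window[2L]))
  groups <- x$design$groups
  col <- if (is.null(groups)) seq_len(nrow(x$Y)) else groups
  fv <- fitted(x)
  graphics::matplot(idx, t(x$Y[, idx, drop = FALSE]), pch = 16,
                    cex = 0.3, col = grDevices::adjustcolor(col, 0.35),
                    xlab = "probe index", ylab = "log2 expression", ...)
  graphics::matlines(idx, t(fv[, idx, drop = FALSE]), lty = 1, col = col)
  invisible(x)
}

#' Plot an effect track with its uncertainty band
#'
#' @param x A `"wfm_track"`.
#' @param fdr Optional `"wfm_fdr"`; significant probes are marked along the
#'   axis.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.wfm_track <- function(x, fdr = NULL, ...) {
  idx <- seq_len(x$n_probes)
  graphics::plot(idx, x$mean, type = "l", xlab = "probe index",
                 ylab = x$label, ...)
  if (all(is.finite(x$sd))) {
    graphics::polygon(c(idx, rev(idx)),
                      c(x$mean + 2 * x$sd, rev(x$mean - 2 * x$sd)),
                      border = NA,
                      col = grDevices::adjustcolor("steelblue", 0.3))
    graphics::lines(idx, x$mean)
  }
  if (!is.null(fdr))
    graphics::rug(idx[fdr$mask], col = "firebrick")
  invisible(x)
}
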