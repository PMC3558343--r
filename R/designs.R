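# Design-matrix constructors for the supported study types.
#
# Every design carries three coupled matrices: X, the interpretable coding
# (dummy/Helmert/polynomial/Fourier/custom); Xo, an orthonormal basis of the
# same column space with positive-diagonal triangular factor; and tri, the
# q x q upper-triangular matrix with Xo %*% tri == X. The model is always
# fitted on Xo and posteriors are mapped back through solve(tri), which is
# exactly the QR route for non-orthogonal multi-factor designs and reduces
# to column rescaling when X is already orthogonal.

new_wfm_design <- function(kind, X, roles, normalized,
                           groups = NULL, group_labels = NULL,
                           times = NULL, period = NULL) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  qrx <- qr(X)
  q <- ncol(X)
  if (qrx$rank < q) {
    dep <- rank_deficient_column(X)
    stop("design matrix is rank deficient: column ", dep,
         if (!is.null(colnames(X))) paste0(" (", colnames(X)[dep], ")"),
         " is linearly dependent on earlier columns", call. = FALSE)
  }
  Qm <- qr.Q(qrx)
  Rm <- qr.R(qrx)
  sgn <- sign(diag(Rm))
  sgn[sgn == 0] <- 1
  Xo <- Qm %*% diag(sgn, q)
  tri <- diag(sgn, q) %*% Rm
  dimnames(Xo) <- dimnames(X)
  structure(list(
    kind = kind, X = X, Xo = Xo, tri = tri, roles = roles,
    normalized = normalized, groups = groups, group_labels = group_labels,
    group_sizes = if (!is.null(groups)) as.integer(table(groups)) else NULL,
    times = times, period = period, N = nrow(X), q = q
  ), class = "wfm_design")
}

rank_deficient_column <- function(X) {
  for (j in seq_len(ncol(X)))
    if (qr(X[, seq_len(j), drop = FALSE])$rank < j) return(j)
  ncol(X)
}

check_counts <- function(x, what) {
  if (anyNA(x) || any(x < 1) || any(x != round(x)))
    stop(what, " must be positive integers", call. = FALSE)
}

#' Two-group design matrix
#'
#' The basic two-condition coding: an intercept column of ones (overall mean
#' expression, used for transcript discovery) and a contrast column that is
#' +1 for the `n1` arrays of condition 1 and -1 for the `n2` arrays of
#' condition 2 (differential expression). For a balanced design the columns
#' are orthogonal with `t(X) %*% X = diag(N, N)`.
#'
#' @param n1,n2 Number of arrays in each condition (>= 1).
#' @param normalize Scale columns to unit norm so that
#'   `t(X) %*% X = I` (required for common smoothing in [wfm()]); the
#'   interpretable +/-1 coding stays available as `$X`.
#' @return A `"wfm_design"` object.
#' @examples
#' design_two_group(2, 2)$X
#' @export
design_two_group <- function(n1, n2, normalize = TRUE) {
  check_counts(c(n1, n2), "group counts")
  n1 <- as.integer(n1); n2 <- as.integer(n2)
  X <- cbind(intercept = 1, group = c(rep(1, n1), rep(-1, n2)))
  new_wfm_design("two_group", X,
                 roles = c("overall_mean", "group_diff"),
                 normalized = normalize,
                 groups = rep(1:2, c(n1, n2)),
                 group_labels = c("group1", "group2"))
}

# canonical "raw" scaling of an orthonormal column: divide by the smallest
# nonzero |entry|, which recovers the classical integer orthogonal-polynomial
# contrasts on equidistant designs (e.g. (-1,0,1), (1,-2,1))
descale_column <- function(v) {
  a <- abs(v)
  nz <- a > 1e-8 * max(a)
  v / min(a[nz])
}

#' Orthogonal-polynomial time-course design matrix
#'
#' Columns are the degree `0..q-1` orthogonal polynomials evaluated at each
#' array's time, where `q` is the number of distinct time points. Column
#' `d+1` carries the degree-`d` trend (linear, quadratic, ...) and the
#' columns are mutually orthogonal over the design points, including
#' unbalanced and non-equidistant designs (built by Gram-Schmidt / QR of the
#' Vandermonde matrix of centered times). With `normalize = TRUE` the
#' columns have unit norm (`t(X) %*% X = I`); otherwise each column is
#' scaled canonically so equidistant designs reproduce the classical integer
#' contrasts.
#'
#' @param times Numeric vector of length N: the time point of each array.
#'   At least two distinct values are required.
#' @param normalize Return the orthonormal coding.
#' @return A `"wfm_design"` object; the group structure (for pairwise
#'   comparisons and per-time means) follows the sorted distinct times.
#' @examples
#' round(crossprod(as.matrix(design_poly(c(1, 2, 3)))), 10)  # diag(3, 2, 6)
#' @export
design_poly <- function(times, normalize = TRUE) {
  times <- as.numeric(times)
  if (anyNA(times) || length(times) < 2L)
    stop("times must be a numeric vector of length >= 2", call. = FALSE)
  lev <- sort(unique(times))
  q <- length(lev)
  if (q < 2L)
    stop("time-course design needs at least 2 distinct time points",
         call. = FALSE)
  tc <- times - mean(times)
  V <- outer(tc, 0:(q - 1L), `^`)
  qrv <- qr(V)
  sgn <- sign(diag(qr.R(qrv)))
  sgn[sgn == 0] <- 1
  Xn <- qr.Q(qrv) %*% diag(sgn, q)        # orthonormal polynomial columns
  X <- apply(Xn, 2, descale_column)       # canonical integer-style coding
  colnames(X) <- c("intercept", paste0("poly", seq_len(q - 1L)))
  new_wfm_design("time_polynomial", X,
                 roles = c("overall_mean", paste0("poly_degree_",
                                                 seq_len(q - 1L))),
                 normalized = normalize,
                 groups = match(times, lev),
                 group_labels = paste0("t", lev),
                 times = times)
}

#' Helmert-contrast design matrix for unordered groups
#'
#' Intercept plus `q - 1` Helmert contrasts: contrast `j` assigns -1 to the
#' arrays of groups `1..j`, the value `j` to group `j + 1`, and 0 afterwards,
#' comparing each group with the mean of all preceding groups. For balanced
#' designs the unnormalized cross-product is diagonal with entries
#' `N, sum(N_i, i<=2), 2*sum(N_i, i<=3), ..., (q-1)*sum(N_i, i<=q)`.
#'
#' @param group_sizes Positive integer vector of length `q >= 2`: number of
#'   arrays per group, in array (block) order.
#' @param normalize Scale columns to unit norm.
#' @return A `"wfm_design"` object.
#' @examples
#' round(crossprod(as.matrix(design_helmert(c(1, 1, 1)))), 10)  # diag(3, 2, 6)
#' @export
design_helmert <- function(group_sizes, normalize = TRUE) {
  check_counts(group_sizes, "group sizes")
  group_sizes <- as.integer(group_sizes)
  q <- length(group_sizes)
  if (q < 2L)
    stop("Helmert design needs at least 2 groups", call. = FALSE)
  grp <- rep(seq_len(q), group_sizes)
  X <- matrix(0, length(grp), q)
  X[, 1L] <- 1
  for (j in seq_len(q - 1L)) {
    X[grp <= j, j + 1L] <- -1
    X[grp == j + 1L, j + 1L] <- j
  }
  colnames(X) <- c("intercept", paste0("helmert", seq_len(q - 1L)))
  new_wfm_design("factor_helmert", X,
                 roles = c("overall_mean", paste0("helmert_", seq_len(q - 1L))),
                 normalized = normalize,
                 groups = grp,
                 group_labels = paste0("group", seq_len(q)))
}

#' Fourier design matrix for circadian rhythms
#'
#' One harmonic: `[1, sin(2*pi*t/period), cos(2*pi*t/period)]` per array.
#' For equally spaced designs covering full cycles the cross-product is
#' `diag(N, N/2, N/2)` (equal to `diag(N, q, q)` when there are two arrays
#' per time point). The sine and cosine effect functions combine into the
#' rhythm amplitude `A(t) = sqrt(beta_sin(t)^2 + beta_cos(t)^2)`.
#'
#' @param times Numeric time of each array (same units as `period`); at
#'   least 3 distinct values.
#' @param period Oscillation period (> 0), e.g. 24 for hourly circadian data.
#' @param normalize Scale columns to unit norm.
#' @return A `"wfm_design"` object.
#' @examples
#' round(crossprod(as.matrix(design_circadian(0:3 * 6, period = 24))), 10)
#' @export
design_circadian <- function(times, period, normalize = TRUE) {
  times <- as.numeric(times)
  if (anyNA(times) || length(unique(times)) < 3L)
    stop("circadian design needs at least 3 distinct time points",
         call. = FALSE)
  if (!is.numeric(period) || length(period) != 1L || is.na(period) ||
      period <= 0)
    stop("period must be a single positive number", call. = FALSE)
  ang <- 2 * pi * times / period
  X <- cbind(intercept = 1, sin = sin(ang), cos = cos(ang))
  lev <- sort(unique(times))
  new_wfm_design("circadian", X,
                 roles = c("overall_mean", "sine", "cosine"),
                 normalized = normalize,
                 groups = match(times, lev),
                 group_labels = paste0("t", lev),
                 times = times, period = period)
}

#' Orthogonalize a custom design matrix
#'
#' QR decomposition of an arbitrary full-column-rank design into an
#' orthonormal matrix `Xo` (used for fitting) and an upper-triangular factor
#' `tri` with `Xo %*% tri` reproducing the input. The sign convention fixes
#' the diagonal of `tri` positive so results are reproducible across linear
#' algebra backends. Fitted coefficients are mapped back to the original
#' coding by premultiplying with `solve(tri)`.
#'
#' @param X Numeric N x q matrix with full column rank (typically a
#'   multi-factor model matrix with interactions).
#' @param roles Optional character vector naming each column's role.
#' @param groups Optional integer/factor of length N assigning arrays to
#'   groups, enabling `compare` and `means` inference on the fit.
#' @return A `"wfm_design"` object of kind `"custom"`; `as.matrix()` returns
#'   the orthonormal `Xo`.
#' @examples
#' d <- design_custom(cbind(1, c(1, 0)))
#' as.matrix(d)            # 1/sqrt(2) * [[1, 1], [1, -1]]
#' d$Xo %*% d$tri          # reproduces the input
#' @export
design_custom <- function(X, roles = NULL, groups = NULL) {
  X <- as.matrix(X)
  if (!is.numeric(X) || anyNA(X)) stop("X must be a numeric matrix",
                                       call. = FALSE)
  if (nrow(X) < 2L) stop("design needs at least 2 arrays", call. = FALSE)
  if (is.null(roles)) {
    roles <- c("overall_mean", paste0("effect_", seq_len(ncol(X) - 1L)))
    if (!all(X[, 1L] == X[1L, 1L])) roles[1L] <- "effect_0"
  }
  if (length(roles) != ncol(X))
    stop("roles must have one entry per column", call. = FALSE)
  group_labels <- NULL
  if (!is.null(groups)) {
    groups <- as.factor(groups)
    group_labels <- levels(groups)
    groups <- as.integer(groups)
  }
  new_wfm_design("custom", X, roles = roles, normalized = TRUE,
                 groups = groups, group_labels = group_labels)
}

#' Build a design from a configuration list or file
#'
#' Reads the structured design specification used by [wfm_pipeline()]: a
#' list (or JSON/YAML file) with a `kind` field (`two_group`,
#' `factor_helmert`, `time_polynomial`, `circadian`, `custom`) and the
#' fields that kind needs (`n1`/`n2`, `group_sizes`, `times`, `period`,
#' `normalize`, `matrix`).
#'
#' @param config A named list, or the path of a `.json`/`.yaml`/`.yml` file.
#' @return A `"wfm_design"` object.
#' @export
design_from_config <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- read_config_file(config)
  if (!is.list(config) || is.null(config$kind))
    stop("design config must be a list with a 'kind' field", call. = FALSE)
  norm <- isTRUE(config$normalize) || is.null(config$normalize)
  switch(config$kind,
    two_group = design_two_group(need(config, "n1"), need(config, "n2"),
                                 normalize = norm),
    time_polynomial = design_poly(unlist(need(config, "times")),
                                  normalize = norm),
    factor_helmert = design_helmert(unlist(need(config, "group_sizes")),
                                    normalize = norm),
    circadian = design_circadian(unlist(need(config, "times")),
                                 need(config, "period"), normalize = norm),
    custom = design_custom(
      do.call(rbind, lapply(need(config, "matrix"), unlist)),
      roles = config$roles,
      groups = if (!is.null(config$groups)) unlist(config$groups)),
    stop("unknown design kind: ", config$kind, call. = FALSE)
  )
}

need <- function(config, field) {
  if (is.null(config[[field]]))
    stop("design config is missing field '", field, "'", call. = FALSE)
  config[[field]]
}

#' @export
as.matrix.wfm_design <- function(x, ...) {
  if (x$normalized) x$Xo else x$X
}

#' @export
print.wfm_design <- function(x, ...) {
  cat("Design (", x$kind, "): ", x$N, " arrays x ", x$q, " effects",
      if (x$normalized) ", orthonormal coding", "\n", sep = "")
  cat("  roles:", paste(x$roles, collapse = ", "), "\n")
  if (!is.null(x$groups))
    cat("  groups:", paste(x$group_labels, "(n=", x$group_sizes, ")",
                           sep = "", collapse = ", "), "\n")
  invisible(x)
}

#' Write the resolved design matrix to TSV for audit
#'
#' @param design A `"wfm_design"`.
#' @param path Output file.
#' @param array_ids Optional row identifiers.
#' @return `path`, invisibly.
#' @export
write_design_tsv <- function(design, path, array_ids = NULL) {
  M <- as.matrix(design)
  colnames(M) <- design$roles
  df <- data.frame(
    array = if (is.null(array_ids)) paste0("array", seq_len(nrow(M)))
            else array_ids,
    M, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
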