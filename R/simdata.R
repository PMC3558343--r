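# Synthetic tiling experiments with known ground truth.
#
# The generator realizes the working model exactly: Y = X B + E with
# E iid N(0, sigma^2) across probes and arrays, B built as a baseline on the
# overall-mean effect plus boxcar (or half-cosine-tapered) bumps on chosen
# effect roles. Equally spaced probes along one chromosome x strand.

#' Simulate a tiling experiment under a design
#'
#' @param design A `"wfm_design"`.
#' @param n_probes Number of probes T.
#' @param effects List of effect bumps; each element is a list with fields
#'   `role` (one of `design$roles`), `from`, `to` (1-based probe interval),
#'   `amplitude` (log2 units), and optionally `shape` (`"boxcar"`, the
#'   default, or `"taper"` for half-cosine edges over 1/8 of the bump).
#'   For the two-group `group_diff` role the amplitude is the
#'   between-condition log2 difference (the +/-1 coding makes the
#'   coefficient half of it); every other role takes the amplitude as the
#'   effect-function coefficient itself.
#' @param baseline Constant added to the overall-mean effect function.
#' @param noise_sd Error standard deviation sigma (>= 0; log2 units).
#' @param spacing Probe spacing in bp.
#' @param probe_length Probe length in bp.
#' @param chrom,strand,start0 Genomic placement of the probe grid.
#' @param seed Optional integer seed; identical seeds give identical output
#'   and the caller's RNG state is untouched.
#' @return An object of class `"tiling_sim"`: list with `Y` (N x T matrix),
#'   `probes` (a [probe_annotation()]), and `truth` (`$B`, the q x T true
#'   effect-function matrix in the design's original coding, and
#'   `$regions`, a data frame of the planted intervals).
#' @examples
#' d <- design_two_group(2, 2)
#' sim <- simulate_tiling(d, n_probes = 64, noise_sd = 0,
#'   effects = list(list(role = "group_diff", from = 17, to = 32,
#'                       amplitude = 0.5)))
#' all(sim$Y == d$X %*% sim$truth$B)
#' @export
simulate_tiling <- function(design, n_probes = 1024L, effects = list(),
                            baseline = 2, noise_sd = 0.3,
                            spacing = 35L, probe_length = 25L,
                            chrom = "chr1", strand = "+", start0 = 0L,
                            seed = NULL) {
  if (!inherits(design, "wfm_design"))
    stop("design must be a wfm_design object", call. = FALSE)
  n_probes <- as.integer(n_probes)
  if (is.na(n_probes) || n_probes < 2L)
    stop("n_probes must be an integer >= 2", call. = FALSE)
  if (!is.numeric(noise_sd) || noise_sd < 0)
    stop("noise_sd must be nonnegative", call. = FALSE)

  q <- design$q
  B <- matrix(0, q, n_probes)
  rownames(B) <- design$roles
  i_mean <- match("overall_mean", design$roles)
  if (!is.na(i_mean)) B[i_mean, ] <- baseline

  truth_regions <- data.frame(role = character(0), from = integer(0),
                              to = integer(0), amplitude = numeric(0))
  for (ef in effects) {
    if (is.null(ef$role) || is.null(ef$from) || is.null(ef$to) ||
        is.null(ef$amplitude))
      stop("each effect needs fields role, from, to, amplitude",
           call. = FALSE)
    row <- match(ef$role, design$roles)
    if (is.na(row))
      stop("unknown effect role '", ef$role, "'; design roles are: ",
           paste(design$roles, collapse = ", "), call. = FALSE)
    from <- as.integer(ef$from); to <- as.integer(ef$to)
    if (is.na(from) || is.na(to) || from < 1L || to > n_probes || from > to)
      stop("effect interval [", ef$from, ", ", ef$to,
           "] is not inside 1..", n_probes, call. = FALSE)
    len <- to - from + 1L
    # group_diff amplitude = condition difference; +/-1 coding -> halve
    coef_amp <- if (identical(ef$role, "group_diff"))
      as.numeric(ef$amplitude) / 2 else as.numeric(ef$amplitude)
    bump <- rep(coef_amp, len)
    if (identical(ef$shape, "taper")) {
      edge <- max(1L, len %/% 8L)
      ramp <- (1 - cos(pi * seq_len(edge) / (edge + 1))) / 2
      bump[seq_len(edge)] <- bump[seq_len(edge)] * ramp
      bump[len - edge + seq_len(edge)] <- bump[len - edge + seq_len(edge)] *
        rev(ramp)
    }
    B[row, from:to] <- B[row, from:to] + bump
    truth_regions <- rbind(truth_regions,
                           data.frame(role = ef$role, from = from, to = to,
                                      amplitude = as.numeric(ef$amplitude)))
  }

  signal <- design$X %*% B
  E <- matrix(0, design$N, n_probes)
  if (noise_sd > 0) {
    draw <- function() {
      E <<- matrix(stats::rnorm(design$N * n_probes, sd = noise_sd),
                   design$N, n_probes)
    }
    if (is.null(seed)) draw() else with_seed(seed, draw())
  }
  Y <- signal + E
  rownames(Y) <- paste0("array", seq_len(design$N))

  probes <- probe_annotation(
    chrom = rep(chrom, n_probes),
    start = as.integer(start0) + (seq_len(n_probes) - 1L) * as.integer(spacing),
    strand = rep(strand, n_probes),
    probe_length = as.integer(probe_length))

  structure(list(Y = Y, probes = probes,
                 truth = list(B = B, regions = truth_regions),
                 design = design, noise_sd = noise_sd, seed = seed),
            class = "tiling_sim")
}

#' @export
print.tiling_sim <- function(x, ...) {
  cat("Simulated tiling experiment: ", nrow(x$Y), " arrays x ", ncol(x$Y),
      " probes, sigma = ", x$noise_sd, "\n", sep = "")
  if (nrow(x$truth$regions))
    print(x$truth$regions)
  else cat("  (null: no planted effects)\n")
  invisible(x)
}

# linear functional of the original-coding effects for a given mode,
# shared between inference on fits and ground-truth evaluation
effect_lambda_orig <- function(design, mode, pair = NULL, group = NULL,
                               degree = NULL, contrast = NULL) {
  switch(mode,
    compare = group_design_row(design, pair[1L]) -
      group_design_row(design, pair[2L]),
    means = group_design_row(design, group),
    effects = as.numeric(seq_len(design$q) == degree + 1L),
    contrast = as.numeric(contrast),
    stop("unsupported mode for ground-truth evaluation: ", mode,
         call. = FALSE))
}

true_effect_track <- function(sim, mode, ...) {
  design <- sim$design
  if (mode == "circadian") {
    i_s <- which(design$roles == "sine")
    i_c <- which(design$roles == "cosine")
    sqrt(sim$truth$B[i_s, ]^2 + sim$truth$B[i_c, ]^2)
  } else {
    lam <- effect_lambda_orig(design, mode, ...)
    drop(lam %*% sim$truth$B)
  }
}

#' Benchmark the fit-and-detect pipeline on simulated data
#'
#' Repeatedly simulates an experiment, runs the full pipeline
#' (fit, effect track, Bayesian FDR, region calling) and scores the probe
#' calls against the planted truth: probe-level sensitivity, observed false
#' discovery proportion, and (for a single planted region) the boundary
#' error of the best-matching called region in probes.
#'
#' @param design A `"wfm_design"`.
#' @param effects Planted effects, as in [simulate_tiling()] (may be empty
#'   for null calibration runs).
#' @param mode,pair,group,degree,contrast Inference selector passed to
#'   [wfm_effect()].
#' @param n_replicates Number of simulated replicates.
#' @param delta,alpha Detection threshold and Bayesian FDR level.
#' @param noise_sd,n_probes,baseline Generator settings.
#' @param smoothing Passed to [wfm()].
#' @param min_probes,max_gap_bp Region-calling settings.
#' @param n_sim Posterior draws for circadian mode.
#' @param seed Integer seed; replicate r uses `seed + r`.
#' @return A data frame with one row per replicate (`sensitivity`, `fdp`,
#'   `n_called`, `boundary_error`) and a `summary` attribute with means and
#'   sds.
#' @export
benchmark_pipeline <- function(design, effects = list(),
                               mode = "compare", pair = c(1L, 2L),
                               group = NULL, degree = NULL, contrast = NULL,
                               n_replicates = 20L, delta = log2(1.2),
                               alpha = 0.05, noise_sd = 0.3,
                               n_probes = 1024L, baseline = 2,
                               smoothing = "common",
                               min_probes = 4L, max_gap_bp = NULL,
                               n_sim = 1000L, seed = 1L) {
  n_replicates <- as.integer(n_replicates)
  if (is.na(n_replicates) || n_replicates < 1L)
    stop("n_replicates must be >= 1", call. = FALSE)

  rows <- vector("list", n_replicates)
  for (r in seq_len(n_replicates)) {
    sim <- simulate_tiling(design, n_probes = n_probes, effects = effects,
                           baseline = baseline, noise_sd = noise_sd,
                           seed = seed + r)
    fit <- wfm(sim$Y, design, probes = sim$probes, smoothing = smoothing)
    track <- wfm_effect(fit, mode, pair = pair, group = group,
                        degree = degree, contrast = contrast)
    fdr <- if (mode == "circadian")
      wfm_fdr_circadian(track, delta = delta, alpha = alpha, n_sim = n_sim,
                        seed = seed + r)
    else
      wfm_fdr(track, delta = delta, alpha = alpha)
    regs <- call_regions(fdr, min_probes = min_probes,
                         max_gap_bp = max_gap_bp)

    truth <- abs(true_effect_track(sim, mode, pair = pair, group = group,
                                   degree = degree, contrast = contrast))
    truth_mask <- truth > 1e-12
    called <- fdr$mask
    sens <- if (any(truth_mask))
      sum(called & truth_mask) / sum(truth_mask) else NA_real_
    fdp <- if (any(called))
      sum(called & !truth_mask) / sum(called) else 0

    be <- NA_real_
    tr <- sim$truth$regions
    if (nrow(tr) == 1L && length(regs$gr)) {
      starts <- sim$probes$start
      true_start <- starts[tr$from]
      true_end <- starts[tr$to] + sim$probes$probe_length[tr$to]
      rs <- GenomicRanges::start(regs$gr) - 1L
      re <- GenomicRanges::end(regs$gr)
      best <- which.max(pmin(re, true_end) - pmax(rs, true_start))
      spacing <- stats::median(diff(starts))
      be <- max(abs(rs[best] - true_start), abs(re[best] - true_end)) /
        spacing
    }
    rows[[r]] <- data.frame(replicate = r, sensitivity = sens, fdp = fdp,
                            n_called = sum(called), boundary_error = be)
  }
  out <- do.call(rbind, rows)
  attr(out, "summary") <- data.frame(
    metric = c("sensitivity", "fdp", "boundary_error"),
    mean = c(mean(out$sensitivity), mean(out$fdp),
             mean(out$boundary_error, na.rm = TRUE)),
    sd = c(stats::sd(out$sensitivity), stats::sd(out$fdp),
           stats::sd(out$boundary_error, na.rm = TRUE)))
  out
}
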