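# Configuration-driven pipeline and fit archives.
#
# The analysis flow is the two-step one the model implies: fit once, then
# run as many inference passes as there are research questions on the saved
# fit. Every pipeline run writes a JSON provenance record (task, resolved
# config, package and R versions, seed).

read_config_file <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path,
                               call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) yaml::read_yaml(path)
  else if (ext == "json") jsonlite::read_json(path, simplifyVector = FALSE)
  else stop("config must be .json, .yaml or .yml: ", path, call. = FALSE)
}

#' Save a fitted model as a plain-text archive
#'
#' Writes every component of a `"wfm"` fit (wavelet-domain posteriors,
#' smoothing and noise parameters, design matrices, expression data, probe
#' annotation) as TSV tables plus a JSON metadata file, so any number of
#' inference runs can reuse the fit without refitting. Doubles are stored
#' with 17 significant digits; [wfm_load()] restores the fit exactly.
#'
#' @param fit A `"wfm"` object.
#' @param dir Directory to create/populate.
#' @return `dir`, invisibly.
#' @export
wfm_save <- function(fit, dir) {
  if (!inherits(fit, "wfm")) stop("fit must be a wfm object", call. = FALSE)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(dir, f)
  write_num_tsv(fit$b, p("b.tsv"))
  write_num_tsv(fit$coef_w, p("coef_w.tsv"))
  write_num_tsv(fit$var_w, p("var_w.tsv"))
  write_num_tsv(fit$tau, p("tau.tsv"))
  write_num_tsv(matrix(fit$sigma2, nrow = 1L), p("sigma2.tsv"))
  write_num_tsv(fit$Y, p("Y.tsv"))
  d <- fit$design
  write_num_tsv(d$X, p("design_X.tsv"))
  write_num_tsv(d$Xo, p("design_Xo.tsv"))
  write_num_tsv(d$tri, p("design_tri.tsv"))
  if (!is.null(fit$probes))
    utils::write.table(fit$probes, p("probes.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  meta <- list(
    class = class(fit), smoothing = fit$smoothing, noise = fit$noise,
    iterations = fit$iterations, converged = fit$converged,
    tau_fixed = fit$tau_fixed,
    plan = list(n_probes = fit$plan$n_probes, family = fit$plan$family,
                levels = fit$plan$levels),
    design = list(kind = d$kind, roles = d$roles, normalized = d$normalized,
                  groups = d$groups, group_labels = d$group_labels,
                  times = d$times, period = d$period, N = d$N, q = d$q),
    package_version = as.character(utils::packageVersion("tilewave")))
  jsonlite::write_json(meta, p("meta.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(dir)
}

#' Load a fitted model from a [wfm_save()] archive
#'
#' @param dir Archive directory.
#' @return The restored `"wfm"` object.
#' @export
wfm_load <- function(dir) {
  p <- function(f) file.path(dir, f)
  if (!file.exists(p("meta.json")))
    stop("not a wfm archive (no meta.json): ", dir, call. = FALSE)
  meta <- jsonlite::read_json(p("meta.json"), simplifyVector = TRUE)
  dm <- meta$design
  design <- structure(list(
    kind = dm$kind,
    X = unname(read_num_tsv(p("design_X.tsv"), header = FALSE)),
    Xo = unname(read_num_tsv(p("design_Xo.tsv"), header = FALSE)),
    tri = unname(read_num_tsv(p("design_tri.tsv"), header = FALSE)),
    roles = dm$roles, normalized = dm$normalized,
    groups = dm$groups, group_labels = dm$group_labels,
    group_sizes = if (!is.null(dm$groups))
      as.integer(table(dm$groups)) else NULL,
    times = dm$times, period = dm$period,
    N = as.integer(dm$N), q = as.integer(dm$q)), class = "wfm_design")
  plan <- wavelet_plan(meta$plan$n_probes, family = meta$plan$family,
                       levels = meta$plan$levels)
  probes <- NULL
  if (file.exists(p("probes.tsv")))
    probes <- probe_annotation(utils::read.table(p("probes.tsv"),
                                                 sep = "\t", header = TRUE))
  fit <- structure(list(
    design = design, plan = plan, smoothing = meta$smoothing,
    noise = meta$noise,
    b = unname(read_num_tsv(p("b.tsv"), header = FALSE)),
    coef_w = unname(read_num_tsv(p("coef_w.tsv"), header = FALSE)),
    var_w = unname(read_num_tsv(p("var_w.tsv"), header = FALSE)),
    tau = unname(read_num_tsv(p("tau.tsv"), header = FALSE)),
    sigma2 = drop(unname(read_num_tsv(p("sigma2.tsv"), header = FALSE))),
    iterations = meta$iterations, converged = meta$converged,
    tau_fixed = meta$tau_fixed,
    Y = unname(read_num_tsv(p("Y.tsv"), header = FALSE)),
    probes = probes, call = NULL), class = meta$class)
  fit
}

#' Run one pipeline task from a configuration
#'
#' Executes one of the tasks `simulate`, `fit`, `infer`, `regions` or
#' `benchmark` described by a configuration list or JSON/YAML file, reading
#' and writing the documented interchange formats in `out_dir` and
#' recording a JSON provenance file (`<task>_provenance.json`). A saved fit
#' archive produced by the `fit` task feeds any number of `infer` runs.
#' On failure, files created by the failing run are removed.
#'
#' Inference modes are gated by the fit's design, mirroring the model's
#' class pairing: `compare`/`means` need group structure, `effects` a
#' time-course fit, `circadian` a circadian fit.
#'
#' @param config Named list or path to a `.json`/`.yaml` config. Required
#'   fields: `task`; per task see the vignette. Stochastic tasks
#'   (`simulate`, circadian `infer`, `benchmark`) require a `seed`.
#' @param out_dir Output directory (created if missing); defaults to
#'   `config$out_dir`.
#' @return A named list of the paths/objects the task produced, invisibly.
#' @export
wfm_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config) && length(config) == 1L)
    config <- read_config_file(config)
  if (!is.list(config)) stop("config must be a list or a file path",
                             call. = FALSE)
  task <- need(config, "task")
  if (is.null(out_dir)) out_dir <- need(config, "out_dir")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  created <- character(0)
  note <- function(path) { created <<- c(created, path); path }
  ok <- FALSE
  on.exit(if (!ok) unlink(created, recursive = TRUE), add = TRUE)

  result <- switch(task,
    simulate = pipeline_simulate(config, out_dir, note),
    fit = pipeline_fit(config, out_dir, note),
    infer = pipeline_infer(config, out_dir, note),
    regions = pipeline_regions(config, out_dir, note),
    benchmark = pipeline_benchmark(config, out_dir, note),
    stop("unknown task '", task, "'; expected simulate, fit, infer, ",
         "regions or benchmark", call. = FALSE))

  prov <- list(task = task, config = config,
               package_version =
                 as.character(utils::packageVersion("tilewave")),
               r_version = as.character(getRversion()),
               seed = config$seed,
               timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  prov_path <- note(file.path(out_dir, paste0(task, "_provenance.json")))
  jsonlite::write_json(prov, prov_path, auto_unbox = TRUE, digits = NA,
                       null = "null", force = TRUE)
  result$provenance <- prov_path
  ok <- TRUE
  invisible(result)
}

pipeline_simulate <- function(config, out_dir, note) {
  design <- design_from_config(need(config, "design"))
  seed <- need(config, "seed")
  sim <- simulate_tiling(
    design,
    n_probes = config$n_probes %||% 1024L,
    effects = config$effects %||% list(),
    baseline = config$baseline %||% 2,
    noise_sd = config$noise_sd %||% 0.3,
    spacing = config$spacing %||% 35L,
    probe_length = config$probe_length %||% 25L,
    chrom = config$chrom %||% "chr1",
    strand = config$strand %||% "+",
    seed = seed)
  ep <- note(file.path(out_dir, "expression.tsv"))
  bp <- note(file.path(out_dir, "probes.bed"))
  tb <- note(file.path(out_dir, "truth_B.tsv"))
  tr <- note(file.path(out_dir, "truth_regions.tsv"))
  write_expression_tsv(sim$Y, ep)
  write_probes_bed(sim$probes, bp)
  write_num_tsv(sim$truth$B, tb)
  utils::write.table(sim$truth$regions, tr, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  list(sim = sim, expression = ep, probes = bp)
}

pipeline_fit <- function(config, out_dir, note) {
  design <- design_from_config(need(config, "design"))
  Y <- read_expression_tsv(need(config, "expression"))
  probes <- if (!is.null(config$probes)) read_probes_bed(config$probes)
  fit <- wfm(Y, design, probes = probes,
             smoothing = config$smoothing %||% "common",
             noise = config$noise %||% "scale",
             family = config$family %||% "haar",
             levels = config$levels,
             tol = config$tol %||% 1e-6,
             max_iter = config$max_iter %||% 100L)
  fdir <- note(file.path(out_dir, config$fit_dir %||% "fit"))
  wfm_save(fit, fdir)
  list(fit = fit, fit_dir = fdir)
}

pipeline_infer <- function(config, out_dir, note) {
  fit <- wfm_load(need(config, "fit_dir"))
  mode <- need(config, "mode")
  track <- wfm_effect(fit, mode,
                      pair = unlist(config$pair),
                      group = config$group, degree = config$degree,
                      contrast = unlist(config$contrast))
  if (mode == "circadian") {
    fdr <- wfm_fdr_circadian(track,
                             delta = config$delta %||% log2(1.1),
                             alpha = config$alpha %||% 0.05,
                             n_sim = config$n_sim %||% 10000L,
                             seed = need(config, "seed"))
  } else {
    fdr <- wfm_fdr(track, delta = config$delta,
                   alpha = config$alpha %||% 0.05,
                   side = config$side %||% "above")
  }
  tp <- note(file.path(out_dir, "track.tsv"))
  bg <- note(file.path(out_dir, "track.bedgraph"))
  write_track_tsv(track, tp, fdr = fdr, probes = fit$probes)
  write_track_bedgraph(track, bg, probes = fit$probes)
  list(track = track, fdr = fdr, track_tsv = tp)
}

pipeline_regions <- function(config, out_dir, note) {
  tt <- utils::read.table(need(config, "track"), sep = "\t", header = TRUE)
  if (is.null(tt$significant))
    stop("track file has no 'significant' column; run an infer task first",
         call. = FALSE)
  probes <- read_probes_bed(need(config, "probes"))
  fake_fdr <- structure(list(
    mask = tt$significant == 1L, locfdr = tt$locfdr,
    track_mean = tt$mean, label = config$label %||% "regions",
    probes = probes, n_probes = nrow(tt)), class = "wfm_fdr")
  regs <- call_regions(fake_fdr,
                       min_probes = config$min_probes %||% 4L,
                       max_gap_bp = config$max_gap_bp)
  rb <- note(file.path(out_dir, "regions.bed"))
  rg <- note(file.path(out_dir, "regions.gff3"))
  write_regions_bed(regs, rb)
  write_regions_gff3(regs, rg)
  out <- list(regions = regs, bed = rb, gff3 = rg)
  if (!is.null(config$annotation)) {
    ann <- read_annotation(config$annotation,
                           feature_types = config$feature_types)
    hits <- map_to_annotation(regs, ann,
                              min_overlap_fraction =
                                config$min_overlap_fraction %||% 0.15)
    gh <- note(file.path(out_dir, "gene_hits.tsv"))
    write_gene_hits(hits, gh)
    un <- unannotated_regions(regs, ann,
                              min_length_bp = config$min_length_bp %||% 200L,
                              exclusion_margin_bp =
                                config$exclusion_margin_bp %||% 500L)
    ub <- note(file.path(out_dir, "unannotated.bed"))
    write_regions_bed(un, ub)
    out$gene_hits <- hits
    out$unannotated <- un
  }
  out
}

pipeline_benchmark <- function(config, out_dir, note) {
  design <- design_from_config(need(config, "design"))
  metrics <- benchmark_pipeline(
    design,
    effects = config$effects %||% list(),
    mode = config$mode %||% "compare",
    pair = unlist(config$pair) %||% c(1L, 2L),
    group = config$group, degree = config$degree,
    contrast = unlist(config$contrast),
    n_replicates = config$n_replicates %||% 20L,
    delta = config$delta %||% log2(1.2),
    alpha = config$alpha %||% 0.05,
    noise_sd = config$noise_sd %||% 0.3,
    n_probes = config$n_probes %||% 1024L,
    seed = need(config, "seed"))
  mp <- note(file.path(out_dir, "metrics.tsv"))
  utils::write.table(metrics, mp, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  list(metrics = metrics, metrics_tsv = mp)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
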