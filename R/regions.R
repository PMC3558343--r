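# Genomic region extraction and annotation mapping.
#
# Internal coordinates are 0-based half-open (BED convention); GRanges
# objects used for the interval arithmetic are 1-based closed and converted
# at the boundary. Strands are never merged: forward and reverse probes are
# analyzed as independent signals.

#' Probe genomic annotation
#'
#' Validates and classes a table of probe coordinates: chromosome, 0-based
#' 5' start position, strand, and probe length in bp. Positions must be
#' strictly increasing within each chromosome x strand, in the same order
#' as the columns of the expression matrix.
#'
#' @param chrom Character vector (or a data frame with columns `chrom`,
#'   `start`, `strand` and optionally `probe_length`, in which case the
#'   other arguments are ignored).
#' @param start Integer 0-based start positions.
#' @param strand `"+"` or `"-"` per probe.
#' @param probe_length Probe length in bp (single value or per probe).
#' @return A data frame of class `"probe_annotation"`.
#' @export
probe_annotation <- function(chrom, start = NULL, strand = "+",
                             probe_length = 25L) {
  if (inherits(chrom, "probe_annotation")) return(chrom)
  if (is.data.frame(chrom)) {
    df <- chrom
    if (is.null(df$probe_length)) df$probe_length <- probe_length
  } else {
    df <- data.frame(chrom = as.character(chrom), start = as.integer(start),
                     strand = as.character(strand),
                     probe_length = as.integer(probe_length))
  }
  for (col in c("chrom", "start", "strand")) {
    if (is.null(df[[col]])) stop("probe annotation needs a '", col,
                                 "' column", call. = FALSE)
  }
  df$chrom <- as.character(df$chrom)
  df$start <- as.integer(df$start)
  df$strand <- as.character(df$strand)
  df$probe_length <- as.integer(df$probe_length)
  if (!all(df$strand %in% c("+", "-")))
    stop("strand must be '+' or '-'", call. = FALSE)
  if (anyNA(df$start) || any(df$start < 0))
    stop("probe starts must be nonnegative integers", call. = FALSE)
  key <- paste(df$chrom, df$strand)
  for (k in unique(key)) {
    s <- df$start[key == k]
    if (any(diff(s) <= 0))
      stop("probe positions must be strictly increasing within ",
           "chromosome x strand (", k, ")", call. = FALSE)
  }
  class(df) <- c("probe_annotation", "data.frame")
  df
}

probes_granges <- function(probes) {
  GenomicRanges::GRanges(
    seqnames = probes$chrom,
    ranges = IRanges::IRanges(start = probes$start + 1L,
                              width = probes$probe_length),
    strand = probes$strand)
}

#' Call transcriptionally affected regions from a significance mask
#'
#' Converts per-probe significance calls into maximal genomic intervals:
#' runs of significant probes are merged across insignificant gaps of at
#' most `max_gap_bp` (measured between probe intervals), and merged runs
#' with fewer than `min_probes` significant probes are dropped. Region
#' spans run from the first probe's start to the last probe's end.
#'
#' @param x Logical mask of length T, or a `"wfm_fdr"` object (its mask is
#'   used and local FDRs are summarized per region).
#' @param probes A [probe_annotation()] (defaults to the one carried by a
#'   `"wfm_fdr"` input).
#' @param track Optional `"wfm_track"` supplying per-probe effect sizes for
#'   the region summaries (defaults to the track mean stored in the fdr
#'   object).
#' @param min_probes Minimum significant probes per region (default 4).
#' @param max_gap_bp Maximum insignificant gap to bridge, in bp; defaults
#'   to twice the median probe spacing.
#' @param split_gap_bp Runs are split where consecutive probes are further
#'   apart than this, so regions never span large unprobed genomic holes;
#'   defaults to ten times the median probe spacing (never less than
#'   `max_gap_bp`).
#' @return An object of class `"wfm_regions"`: a list with a `GRanges`
#'   (`$gr`) whose metadata columns hold per-region probe counts, mean and
#'   max-absolute effect, and minimum local FDR, plus the calling
#'   parameters. Probes belonging to dropped (too short) runs are counted
#'   in `$dropped_probes`.
#' @export
call_regions <- function(x, probes = NULL, track = NULL,
                         min_probes = 4L, max_gap_bp = NULL,
                         split_gap_bp = NULL) {
  effect <- NULL
  locfdr <- NULL
  label <- "regions"
  if (inherits(x, "wfm_fdr")) {
    if (is.null(probes)) probes <- x$probes
    mask <- x$mask
    locfdr <- x$locfdr
    effect <- x$track_mean
    label <- x$label
  } else {
    mask <- as.logical(x)
  }
  if (!is.null(track)) effect <- track$mean
  if (is.null(probes))
    stop("probe annotation is required to call regions", call. = FALSE)
  probes <- probe_annotation(probes)
  if (length(mask) != nrow(probes))
    stop("mask length ", length(mask), " does not match ", nrow(probes),
         " probes", call. = FALSE)
  min_probes <- as.integer(min_probes)
  if (is.na(min_probes) || min_probes < 1L)
    stop("min_probes must be a positive integer", call. = FALSE)
  key <- paste(probes$chrom, probes$strand)
  spacing <- unlist(lapply(split(probes$start, key), diff),
                    use.names = FALSE)
  med_sp <- if (length(spacing)) stats::median(spacing) else 0L
  if (is.null(max_gap_bp)) max_gap_bp <- 2L * med_sp
  max_gap_bp <- as.integer(max_gap_bp)
  if (is.null(split_gap_bp)) split_gap_bp <- 10L * med_sp
  split_gap_bp <- max(as.integer(split_gap_bp), max_gap_bp)

  # group significant probes into runs per chromosome x strand: adjacent
  # significant probes share a run unless separated by more than
  # split_gap_bp of unprobed sequence; runs merge across insignificant
  # stretches when the genomic gap between probe intervals is at most
  # max_gap_bp
  rows <- list()
  dropped <- 0L
  for (k in unique(key)) {
    sel <- which(key == k)
    sig <- sel[mask[sel]]
    if (length(sig) == 0L) next
    starts <- probes$start[sig]
    ends <- probes$start[sig] + probes$probe_length[sig]
    gap <- starts[-1L] - ends[-length(ends)]
    # consecutive-in-index probes have gap < spacing; break a region only
    # where the significant probes are separated by more than max_gap_bp
    # of insignificant sequence AND are not index-adjacent
    adjacent <- diff(sig) == 1L
    new_region <- c(TRUE, !(adjacent | gap <= max_gap_bp) |
                      gap > split_gap_bp)
    region_id <- cumsum(new_region)
    for (r in unique(region_id)) {
      idx <- sig[region_id == r]
      n <- length(idx)
      if (n < min_probes) { dropped <- dropped + n; next }
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = probes$chrom[idx[1L]],
        start = probes$start[idx[1L]],
        end = probes$start[idx[n]] + probes$probe_length[idx[n]],
        strand = probes$strand[idx[1L]],
        n_probes = n,
        mean_effect = if (is.null(effect)) NA_real_ else mean(effect[idx]),
        max_abs_effect = if (is.null(effect)) NA_real_
                         else max(abs(effect[idx])),
        min_fdr = if (is.null(locfdr)) NA_real_ else min(locfdr[idx]))
    }
  }
  if (length(rows)) {
    df <- do.call(rbind, rows)
    df <- df[order(df$chrom, df$strand, df$start), , drop = FALSE]
    regions <- GenomicRanges::GRanges(
      seqnames = df$chrom,
      ranges = IRanges::IRanges(start = df$start + 1L, end = df$end),
      strand = df$strand)
    S4Vectors::mcols(regions) <- S4Vectors::DataFrame(
      n_probes = df$n_probes, mean_effect = df$mean_effect,
      max_abs_effect = df$max_abs_effect, min_fdr = df$min_fdr)
  } else {
    regions <- GenomicRanges::GRanges()
    S4Vectors::mcols(regions) <- S4Vectors::DataFrame(
      n_probes = integer(0), mean_effect = numeric(0),
      max_abs_effect = numeric(0), min_fdr = numeric(0))
  }
  structure(list(gr = regions, label = label, min_probes = min_probes,
                 max_gap_bp = max_gap_bp, dropped_probes = dropped,
                 probes = probes),
            class = "wfm_regions")
}

#' @export
print.wfm_regions <- function(x, ...) {
  cat("Region set [", x$label, "]: ", length(x$gr), " regions (min_probes = ",
      x$min_probes, ", max_gap_bp = ", x$max_gap_bp, ")\n", sep = "")
  if (length(x$gr)) {
    df <- as.data.frame(x$gr)
    print(utils::head(df, 10L))
    if (nrow(df) > 10L) cat("  ...\n")
  }
  invisible(x)
}

as_annotation_granges <- function(annotation) {
  if (is.character(annotation) && length(annotation) == 1L)
    annotation <- read_annotation(annotation)
  if (!methods::is(annotation, "GRanges"))
    stop("annotation must be a GRanges or a GFF3 file path", call. = FALSE)
  annotation
}

annotation_ids <- function(gr) {
  mc <- S4Vectors::mcols(gr)
  for (col in c("gene_id", "ID", "Name", "locus_tag"))
    if (!is.null(mc[[col]])) return(as.character(mc[[col]]))
  paste0("feature_", seq_along(gr))
}

#' Map detected regions to gene annotation
#'
#' For every annotated gene, computes the fraction of the gene covered by
#' detected regions (strand-aware) and retains genes whose overlap reaches
#' `min_overlap_fraction` (default 0.15, i.e. at least 15 % of the gene).
#'
#' @param regions A `"wfm_regions"` object.
#' @param annotation A `GRanges` of gene intervals or a GFF3 file path.
#' @param min_overlap_fraction Fraction of the gene length that must be
#'   covered, in (0, 1].
#' @return A data frame with one row per gene that overlaps any region:
#'   `gene_id`, coordinates, `overlap_bp`, `overlap_fraction` and a
#'   `retained` flag.
#' @export
map_to_annotation <- function(regions, annotation,
                              min_overlap_fraction = 0.15) {
  if (!inherits(regions, "wfm_regions"))
    stop("regions must be a wfm_regions object", call. = FALSE)
  if (!is.numeric(min_overlap_fraction) || length(min_overlap_fraction) != 1L ||
      min_overlap_fraction <= 0 || min_overlap_fraction > 1)
    stop("min_overlap_fraction must be in (0, 1]", call. = FALSE)
  genes <- as_annotation_granges(annotation)
  ids <- annotation_ids(genes)
  cov <- GenomicRanges::reduce(regions$gr)
  hits <- GenomicRanges::findOverlaps(genes, cov)
  if (length(hits) == 0L)
    return(data.frame(gene_id = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), gene_length = integer(0),
                      overlap_bp = integer(0), overlap_fraction = numeric(0),
                      retained = logical(0)))
  ov <- GenomicRanges::pintersect(genes[S4Vectors::queryHits(hits)],
                                  cov[S4Vectors::subjectHits(hits)])
  ov_bp <- tapply(GenomicRanges::width(ov),
                  S4Vectors::queryHits(hits), sum)
  gi <- as.integer(names(ov_bp))
  out <- data.frame(
    gene_id = ids[gi],
    chrom = as.character(GenomicRanges::seqnames(genes)[gi]),
    start = GenomicRanges::start(genes)[gi] - 1L,
    end = GenomicRanges::end(genes)[gi],
    strand = as.character(GenomicRanges::strand(genes)[gi]),
    gene_length = GenomicRanges::width(genes)[gi],
    overlap_bp = as.integer(ov_bp),
    row.names = NULL)
  out$overlap_fraction <- out$overlap_bp / out$gene_length
  out$retained <- out$overlap_fraction >= min_overlap_fraction
  out[order(-out$overlap_fraction), , drop = FALSE]
}

#' Extract unannotated transcriptionally affected regions
#'
#' Candidate novel transcribed units: detected regions that have zero
#' overlap with any annotated feature after padding the annotation by
#' `exclusion_margin_bp` on both sides (operationalizing "not in or near a
#' gene or its promoter"; the check ignores strand), and whose length is at
#' least `min_length_bp`.
#'
#' @param regions A `"wfm_regions"` object.
#' @param annotation A `GRanges` or GFF3 file path.
#' @param min_length_bp Minimum region length in bp (default 200).
#' @param exclusion_margin_bp Padding added to each annotated feature
#'   (default 500).
#' @return A `"wfm_regions"` object containing the surviving regions.
#' @export
unannotated_regions <- function(regions, annotation, min_length_bp = 200L,
                                exclusion_margin_bp = 500L) {
  if (!inherits(regions, "wfm_regions"))
    stop("regions must be a wfm_regions object", call. = FALSE)
  min_length_bp <- as.integer(min_length_bp)
  if (is.na(min_length_bp) || min_length_bp < 1L)
    stop("min_length_bp must be a positive integer", call. = FALSE)
  genes <- as_annotation_granges(annotation)
  padded <- GenomicRanges::trim(suppressWarnings(
    genes + as.integer(exclusion_margin_bp)))
  keep <- GenomicRanges::countOverlaps(regions$gr, padded,
                                       ignore.strand = TRUE) == 0L &
    GenomicRanges::width(regions$gr) >= min_length_bp
  out <- regions
  out$gr <- regions$gr[keep]
  out$label <- paste0(regions$label, " (unannotated)")
  out
}

#' Read gene annotation from GFF3
#'
#' Thin wrapper around `rtracklayer::import()` that optionally restricts to
#' given feature types (e.g. `"gene"`).
#'
#' @param path GFF3 file.
#' @param feature_types Optional character vector of `type` values to keep.
#' @return A `GRanges`.
#' @export
read_annotation <- function(path, feature_types = NULL) {
  if (!file.exists(path))
    stop("annotation file not found: ", path, call. = FALSE)
  gr <- tryCatch(rtracklayer::import(path, format = "gff3"),
                 error = function(e)
                   stop("failed to parse annotation '", path, "': ",
                        conditionMessage(e), call. = FALSE))
  if (!is.null(feature_types) && !is.null(gr$type))
    gr <- gr[as.character(gr$type) %in% feature_types]
  gr
}
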