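# Interchange formats: TSV expression, BED6 probes and regions, bedGraph
# tracks, GFF3 region export. Numeric TSVs are written with 17 significant
# digits so doubles round-trip exactly.

fmt_num <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.na(x)] <- "NA"
  out
}

# headerless numeric matrix round trip at full double precision
write_num_tsv <- function(m, path) {
  m <- as.matrix(m)
  txt <- matrix(fmt_num(m), nrow(m), ncol(m))
  utils::write.table(txt, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

read_num_tsv <- function(path, header = FALSE) {
  unname(as.matrix(utils::read.table(path, sep = "\t", header = header,
                                     check.names = FALSE)))
}

#' Write a probe-level expression matrix as TSV
#'
#' The interchange layout is probes x arrays: a `probe_id` column joining to
#' the probe BED file, then one column per array.
#'
#' @param Y N x T matrix (arrays x probes, the in-memory layout).
#' @param path Output file.
#' @param probe_ids Optional probe identifiers (default `probe_<i>`).
#' @return `path`, invisibly.
#' @export
write_expression_tsv <- function(Y, path, probe_ids = NULL) {
  Y <- as.matrix(Y)
  if (is.null(probe_ids)) probe_ids <- paste0("probe_", seq_len(ncol(Y)))
  if (is.null(rownames(Y))) rownames(Y) <- paste0("array", seq_len(nrow(Y)))
  M <- t(Y)
  txt <- matrix(fmt_num(M), nrow(M), ncol(M))
  df <- cbind(probe_id = probe_ids, as.data.frame(txt))
  colnames(df) <- c("probe_id", rownames(Y))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a probe-level expression matrix from TSV
#'
#' @param path File written by [write_expression_tsv()] (probes x arrays
#'   with a `probe_id` first column).
#' @return N x T numeric matrix (arrays x probes) with array rownames and
#'   a `probe_ids` attribute.
#' @export
read_expression_tsv <- function(path) {
  if (!file.exists(path)) stop("expression file not found: ", path,
                               call. = FALSE)
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE)
  if (colnames(df)[1L] != "probe_id")
    stop("expression TSV must have a probe_id first column", call. = FALSE)
  Y <- t(as.matrix(df[, -1L, drop = FALSE]))
  if (!is.numeric(Y) || anyNA(Y))
    stop("expression TSV contains non-numeric values", call. = FALSE)
  attr(Y, "probe_ids") <- df$probe_id
  Y
}

#' Write probe coordinates as BED6
#'
#' 0-based half-open probe intervals, one line per probe, name = probe id.
#'
#' @param probes A [probe_annotation()].
#' @param path Output file.
#' @param probe_ids Optional names (default `probe_<i>`).
#' @return `path`, invisibly.
#' @export
write_probes_bed <- function(probes, path, probe_ids = NULL) {
  probes <- probe_annotation(probes)
  if (is.null(probe_ids)) probe_ids <- paste0("probe_", seq_len(nrow(probes)))
  df <- data.frame(probes$chrom, probes$start,
                   probes$start + probes$probe_length,
                   probe_ids, 0L, probes$strand)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read probe coordinates from a BED file
#'
#' @param path BED file (at least 6 columns for stranded probes).
#' @return A [probe_annotation()], in file order.
#' @export
read_probes_bed <- function(path) {
  if (!file.exists(path)) stop("probe BED file not found: ", path,
                               call. = FALSE)
  gr <- rtracklayer::import(path, format = "BED")
  strand <- as.character(GenomicRanges::strand(gr))
  strand[strand == "*"] <- "+"
  probe_annotation(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    strand = strand,
    probe_length = GenomicRanges::width(gr))
}

#' Export an effect or FDR track as bedGraph
#'
#' One interval per probe with the selected track value.
#'
#' @param track A `"wfm_track"` or `"wfm_fdr"`.
#' @param path Output file.
#' @param probes Probe annotation (defaults to the one carried by the
#'   track).
#' @param what Which value to write: `"mean"`, `"sd"` (tracks) or
#'   `"locfdr"` (FDR tracks).
#' @return `path`, invisibly.
#' @export
write_track_bedgraph <- function(track, path, probes = NULL,
                                 what = c("mean", "sd", "locfdr")) {
  what <- match.arg(what)
  if (is.null(probes)) probes <- track$probes
  if (is.null(probes)) stop("probe annotation required", call. = FALSE)
  probes <- probe_annotation(probes)
  v <- switch(what,
    mean = if (!is.null(track$mean)) track$mean else track$track_mean,
    sd = track$sd,
    locfdr = track$locfdr)
  if (is.null(v)) stop("track has no '", what, "' component", call. = FALSE)
  df <- data.frame(probes$chrom, probes$start,
                   probes$start + probes$probe_length, fmt_num(v))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("track type=bedGraph name=\"%s %s\"",
                     track$label, what), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Export a full inference track as TSV
#'
#' Per-probe table: coordinates, posterior mean and sd, local FDR and the
#' significance call (the latter two when an FDR object is supplied).
#'
#' @param track A `"wfm_track"`.
#' @param path Output file.
#' @param fdr Optional matching `"wfm_fdr"`.
#' @param probes Probe annotation override.
#' @return `path`, invisibly.
#' @export
write_track_tsv <- function(track, path, fdr = NULL, probes = NULL) {
  if (is.null(probes)) probes <- track$probes
  if (is.null(probes)) stop("probe annotation required", call. = FALSE)
  probes <- probe_annotation(probes)
  df <- data.frame(chrom = probes$chrom, start = probes$start,
                   end = probes$start + probes$probe_length,
                   strand = probes$strand,
                   mean = fmt_num(track$mean), sd = fmt_num(track$sd))
  if (!is.null(fdr)) {
    df$locfdr <- fmt_num(fdr$locfdr)
    df$significant <- as.integer(fdr$mask)
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write called regions as BED6
#'
#' Score is `-10 * log10(min local FDR)` capped at 1000 (0 when no FDR
#' summary is available).
#'
#' @param regions A `"wfm_regions"`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_regions_bed <- function(regions, path) {
  if (!inherits(regions, "wfm_regions"))
    stop("regions must be a wfm_regions object", call. = FALSE)
  gr <- regions$gr
  mf <- S4Vectors::mcols(gr)$min_fdr
  score <- ifelse(is.na(mf), 0,
                  pmin(round(-10 * log10(pmax(mf, 1e-100))), 1000))
  df <- data.frame(as.character(GenomicRanges::seqnames(gr)),
                   GenomicRanges::start(gr) - 1L,
                   GenomicRanges::end(gr),
                   sprintf("region_%d", seq_along(gr)),
                   as.integer(score),
                   as.character(GenomicRanges::strand(gr)))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write called regions as GFF3 (1-based closed coordinates)
#'
#' @param regions A `"wfm_regions"`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_regions_gff3 <- function(regions, path) {
  if (!inherits(regions, "wfm_regions"))
    stop("regions must be a wfm_regions object", call. = FALSE)
  gr <- regions$gr
  mc <- S4Vectors::mcols(gr)
  attrs <- sprintf(
    "ID=region_%d;n_probes=%d;mean_effect=%s;min_fdr=%s",
    seq_along(gr), mc$n_probes,
    signif(mc$mean_effect, 6), signif(mc$min_fdr, 6))
  lines <- c("##gff-version 3",
             sprintf("%s\ttilewave\ttranscribed_region\t%d\t%d\t.\t%s\t.\t%s",
                     as.character(GenomicRanges::seqnames(gr)),
                     GenomicRanges::start(gr), GenomicRanges::end(gr),
                     as.character(GenomicRanges::strand(gr)), attrs))
  writeLines(lines, path)
  invisible(path)
}

#' Write a gene hit table as TSV
#'
#' @param hits Data frame from [map_to_annotation()].
#' @param path Output file.
#' @param retained_only Keep only genes passing the overlap fraction.
#' @return `path`, invisibly.
#' @export
write_gene_hits <- function(hits, path, retained_only = FALSE) {
  if (retained_only) hits <- hits[hits$retained, , drop = FALSE]
  utils::write.table(hits, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
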