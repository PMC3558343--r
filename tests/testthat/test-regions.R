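probes_grid <- function(n, spacing = 100L, len = 50L, chrom = "chr1",
                        strand = "+") {
  probe_annotation(chrom = rep(chrom, n),
                   start = (seq_len(n) - 1L) * spacing,
                   strand = rep(strand, n), probe_length = len)
}

test_that("runs of significant probes become regions", {
  pr <- probes_grid(5)
  r <- call_regions(c(FALSE, TRUE, TRUE, TRUE, FALSE), pr, min_probes = 2,
                    max_gap_bp = 0)
  expect_equal(length(r$gr), 1L)
  expect_equal(GenomicRanges::start(r$gr) - 1L, 100L)   # 0-based start
  expect_equal(GenomicRanges::end(r$gr), 350L)          # last start + length
  expect_equal(S4Vectors::mcols(r$gr)$n_probes, 3L)

  expect_equal(length(call_regions(rep(FALSE, 5), pr)$gr), 0L)
})

test_that("gap merging and the minimum-probe filter behave as specified", {
  pr <- probes_grid(3)  # probes 100 bp apart, 50 bp long: interval gap 50
  mask <- c(TRUE, FALSE, TRUE)
  merged <- call_regions(mask, pr, min_probes = 1, max_gap_bp = 150)
  expect_equal(length(merged$gr), 1L)
  expect_equal(S4Vectors::mcols(merged$gr)$n_probes, 2L)

  split <- call_regions(mask, pr, min_probes = 1, max_gap_bp = 20)
  expect_equal(length(split$gr), 2L)

  dropped <- call_regions(mask, pr, min_probes = 2, max_gap_bp = 20)
  expect_equal(length(dropped$gr), 0L)
  expect_equal(dropped$dropped_probes, 2L)
})

test_that("probe conservation and idempotence hold", {
  set.seed(4)
  pr <- probes_grid(200, spacing = 35L, len = 25L)
  mask <- runif(200) < 0.3
  r <- call_regions(mask, pr, min_probes = 3)
  counts <- S4Vectors::mcols(r$gr)$n_probes
  expect_equal(sum(counts) + r$dropped_probes, sum(mask))

  # recalling from the regions' own probes reproduces the set
  in_region <- GenomicRanges::countOverlaps(
    tilewave:::probes_granges(pr), r$gr) > 0
  r2 <- call_regions(in_region, pr, min_probes = 3,
                     max_gap_bp = r$max_gap_bp)
  expect_equal(GenomicRanges::start(r2$gr), GenomicRanges::start(r$gr))
  expect_equal(GenomicRanges::end(r2$gr), GenomicRanges::end(r$gr))
})

test_that("strands are never merged", {
  pr <- probe_annotation(chrom = rep("chr1", 6),
                         start = c(0, 100, 200, 0, 100, 200),
                         strand = rep(c("+", "-"), each = 3),
                         probe_length = 50L)
  r <- call_regions(rep(TRUE, 6), pr, min_probes = 1, max_gap_bp = 100)
  expect_equal(length(r$gr), 2L)
  expect_setequal(as.character(GenomicRanges::strand(r$gr)), c("+", "-"))
})

test_that("probe annotation validation catches malformed input", {
  expect_error(probe_annotation(chrom = c("c1", "c1"), start = c(10, 10),
                                strand = "+"), "strictly increasing")
  expect_error(probe_annotation(chrom = c("c1", "c1"), start = c(20, 10),
                                strand = "+"), "strictly increasing")
  expect_error(probe_annotation(chrom = "c1", start = 0, strand = "x"),
               "strand")
  pr <- probes_grid(4)
  expect_error(call_regions(c(TRUE, TRUE), pr), "does not match")
})

test_that("annotation overlap applies the 15 percent rule at the boundary", {
  pr <- probes_grid(40, spacing = 10L, len = 10L)
  mask <- rep(FALSE, 40)
  mask[11:25] <- TRUE          # region spanning 100..250
  r <- call_regions(mask, pr, min_probes = 2, max_gap_bp = 0)
  expect_equal(GenomicRanges::start(r$gr) - 1L, 100L)
  expect_equal(GenomicRanges::end(r$gr), 250L)

  # gene of 1000 bp with exactly 150 bp covered: fraction 0.15
  gene <- make_annotation("chr1", start0 = 100L, end = 1100L,
                          id = "gene150")
  hits <- map_to_annotation(r, gene, min_overlap_fraction = 0.15)
  expect_equal(hits$overlap_bp, 150L)
  expect_true(hits$retained)
  hits2 <- map_to_annotation(r, gene, min_overlap_fraction = 0.151)
  expect_false(hits2$retained)

  # opposite strand: no hit by default
  gene_rev <- make_annotation("chr1", 100L, 1100L, strand = "-", id = "rev")
  expect_equal(nrow(map_to_annotation(r, gene_rev)), 0L)
  expect_error(map_to_annotation(r, gene, min_overlap_fraction = 0),
               "min_overlap_fraction")
})

test_that("unannotated regions respect length and proximity filters", {
  pr <- probe_annotation(chrom = rep("chr1", 60),
                         start = c(seq(0, 240, by = 10),
                                   seq(20000, 20140, by = 10),
                                   seq(40000, 40190, by = 10)),
                         strand = "+", probe_length = 10L)
  mask <- rep(TRUE, 60)
  r <- call_regions(mask, pr, min_probes = 2, max_gap_bp = 0)
  expect_equal(length(r$gr), 3L)   # 250, 150 and 200 bp regions

  far_gene <- make_annotation("chr1", 100000L, 101000L, id = "far")
  un <- unannotated_regions(r, far_gene, min_length_bp = 200,
                            exclusion_margin_bp = 500)
  expect_equal(GenomicRanges::width(un$gr), c(250L, 200L))  # 150 bp dropped

  # a gene 100 bp from the third region: excluded by the 500 bp margin
  near_gene <- make_annotation("chr1", 40290L, 41000L, id = "near")
  un2 <- unannotated_regions(r, c(far_gene, near_gene),
                             min_length_bp = 200,
                             exclusion_margin_bp = 500)
  expect_equal(GenomicRanges::width(un2$gr), 250L)
  # the margin check ignores strand: the 200 bp region is still excluded
  # by the opposite-strand gene, leaving only the far 250 bp region
  near_rev <- make_annotation("chr1", 40290L, 41000L, strand = "-")
  un3 <- unannotated_regions(r, near_rev, min_length_bp = 200)
  expect_equal(GenomicRanges::width(un3$gr), 250L)
})

test_that("GFF3 annotation files are parsed and filtered", {
  gff <- tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\ttest\tgene\t101\t1100\t.\t+\t.\tID=g1;Name=GENE1",
    "chr1\ttest\texon\t101\t400\t.\t+\t.\tID=g1.e1;Parent=g1"), gff)
  ann <- read_annotation(gff, feature_types = "gene")
  expect_equal(length(ann), 1L)
  expect_equal(GenomicRanges::start(ann), 101L)
  expect_error(read_annotation("/nonexistent.gff3"), "not found")
})

test_that("region export formats are well formed", {
  pr <- probes_grid(20, spacing = 10L, len = 10L)
  fdr <- structure(list(mask = c(rep(FALSE, 5), rep(TRUE, 10), rep(FALSE, 5)),
                        locfdr = rep(c(0.5, 0.001, 0.5), c(5, 10, 5)),
                        track_mean = rep(c(0, 1.5, 0), c(5, 10, 5)),
                        label = "toy", probes = pr, n_probes = 20),
                   class = "wfm_fdr")
  r <- call_regions(fdr, min_probes = 2)
  expect_equal(S4Vectors::mcols(r$gr)$min_fdr, 0.001)
  expect_equal(S4Vectors::mcols(r$gr)$mean_effect, 1.5)

  bed <- tempfile(fileext = ".bed")
  write_regions_bed(r, bed)
  b <- read.table(bed, sep = "\t")
  expect_equal(ncol(b), 6L)
  expect_equal(b$V2, 50L)          # 0-based start
  expect_equal(b$V5, 30L)          # -10 log10(0.001)

  gff <- tempfile(fileext = ".gff3")
  write_regions_gff3(r, gff)
  g <- readLines(gff)
  expect_equal(g[1], "##gff-version 3")
  expect_match(g[2], "\t51\t150\t")          # 1-based closed
  reread <- rtracklayer::import(gff, format = "gff3")
  expect_equal(GenomicRanges::start(reread), 51L)
})
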