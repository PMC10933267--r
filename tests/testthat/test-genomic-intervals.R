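tss3 <- data.frame(gene_id = c("gA", "gB", "gC"),
                   chrom = c("chr1", "chr1", "chr2"),
                   tss_position = c(10000L, 50000L, 20000L),
                   strand = c("+", "-", "+"),
                   stringsAsFactors = FALSE)

peak_at <- function(mid, chrom = "chr1", width = 200L, name = "pk") {
  data.frame(chrom = chrom, start = mid - width %/% 2L,
             end = mid + width %/% 2L, name = name,
             stringsAsFactors = FALSE)
}

test_that("TSS distances are signed by gene strand and categorized by window", {
  # midpoint exactly at the TSS
  at <- annotate_peaks(peak_at(10000L), tss3)
  expect_identical(at$peaks$tss_distance, 0L)
  expect_identical(at$peaks$category, "promoter_0-1kb")
  # 500 bp upstream of a + gene: negative distance, proximal promoter
  up <- annotate_peaks(peak_at(9500L), tss3)
  expect_identical(up$peaks$tss_distance, -500L)
  expect_identical(up$peaks$category, "promoter_0-1kb")
  # 2500 bp upstream: outer promoter window, not proximal
  mid <- annotate_peaks(peak_at(7500L), tss3)
  expect_identical(mid$peaks$tss_distance, -2500L)
  expect_identical(mid$peaks$category, "promoter_1-3kb")
  # on a - strand gene, upstream lies to the right
  minus_up <- annotate_peaks(peak_at(50400L), tss3)
  expect_identical(minus_up$peaks$nearest_gene, "gB")
  expect_identical(minus_up$peaks$tss_distance, -400L)
  # 10 kb from every TSS, no features -> intergenic
  far <- annotate_peaks(peak_at(30000L), tss3)
  expect_identical(far$peaks$category, "intergenic")
})

test_that("peaks on chromosomes without a TSS are intergenic and flagged", {
  ann <- annotate_peaks(peak_at(5000L, chrom = "chrX"), tss3)
  expect_true(ann$peaks$no_tss)
  expect_identical(ann$peaks$category, "intergenic")
})

test_that("gene-body and downstream categories use the feature annotation", {
  features <- data.frame(chrom = "chr1", start = 20000L, end = 25000L,
                         strand = "+", stringsAsFactors = FALSE)
  body <- annotate_peaks(peak_at(22000L), tss3, features)
  expect_identical(body$peaks$category, "gene_body")
  down <- annotate_peaks(peak_at(26000L), tss3, features)
  expect_identical(down$peaks$category, "downstream_0-3kb")
  cls <- data.frame(chrom = "chr1", start = 20000L, end = 25000L,
                    strand = "+", class = "exon", stringsAsFactors = FALSE)
  expect_identical(annotate_peaks(peak_at(22000L), tss3,
                                  cls)$peaks$category, "exon")
})

test_that("category proportions sum to 100 and ignore peak order", {
  g <- generate_genome_fixtures(seed = 14)
  a1 <- annotate_peaks(g$peaks, g$tss)
  expect_equal(sum(a1$proportions), 100, tolerance = 1e-9)
  set.seed(3)
  shuffled <- g$peaks[sample(nrow(g$peaks)), ]
  a2 <- annotate_peaks(shuffled, g$tss)
  key <- function(a) a$peaks[order(a$peaks$name),
                             c("name", "tss_distance", "category")]
  k1 <- key(a1); k2 <- key(a2)
  rownames(k1) <- rownames(k2) <- NULL
  expect_identical(k1, k2)
})

test_that("enhancer overlap uses half-open arithmetic", {
  peaks <- data.frame(chrom = "chr1", start = 100L, end = 200L)
  inside <- data.frame(chrom = "chr1", start = 150L, end = 160L)
  abut <- data.frame(chrom = "chr1", start = 200L, end = 300L)
  expect_true(enhancer_overlap(peaks, inside)$overlaps)
  expect_false(enhancer_overlap(peaks, abut)$overlaps)
  expect_error(enhancer_overlap(peaks[0, ], inside), "empty peak set")
  # empty enhancer set -> proportion 0
  expect_equal(enhancer_overlap(peaks, inside[0, ])$proportion, 0)
  # 2 of 20 peaks overlapping -> 10%
  many <- data.frame(chrom = "chr1",
                     start = seq(0L, by = 1000L, length.out = 20L),
                     end = seq(200L, by = 1000L, length.out = 20L))
  enh <- data.frame(chrom = "chr1", start = c(100L, 1100L),
                    end = c(150L, 1150L))
  expect_equal(enhancer_overlap(many, enh)$proportion, 10)
})

test_that("peak-set comparison counts shared peaks from both sides", {
  a <- data.frame(chrom = "chr1", start = c(0L, 1000L, 5000L),
                  end = c(200L, 1200L, 5200L))
  expect_identical(compare_peak_sets(a, a),
                   c(a_only = 0L, shared_a = 3L, shared_b = 3L,
                     b_only = 0L))
  b_disjoint <- data.frame(chrom = "chr9", start = 0L, end = 200L)
  got <- compare_peak_sets(a, b_disjoint)
  expect_identical(unname(got["shared_a"]), 0L)
  # one A peak spanning two B peaks counts once on A's side
  wide <- data.frame(chrom = "chr1", start = 0L, end = 2000L)
  two <- data.frame(chrom = "chr1", start = c(100L, 1500L),
                    end = c(200L, 1600L))
  got2 <- compare_peak_sets(wide, two)
  expect_identical(got2, c(a_only = 0L, shared_a = 1L, shared_b = 2L,
                           b_only = 0L))
  # empty B -> all A exclusive
  expect_identical(compare_peak_sets(a, two[0, ])["a_only"],
                   c(a_only = 3L))
})

test_that("interval operations agree with an all-pairs brute-force oracle", {
  set.seed(25)
  for (trial in 1:3) {
    a <- data.frame(chrom = sample(c("chr1", "chr2"), 120, TRUE),
                    start = sample.int(10000, 120))
    a$end <- a$start + sample.int(500, 120)
    b <- data.frame(chrom = sample(c("chr1", "chr2"), 80, TRUE),
                    start = sample.int(10000, 80))
    b$end <- b$start + sample.int(500, 80)
    expect_identical(enhancer_overlap(a, b)$overlaps, oracle_overlaps(a, b))
    got <- compare_peak_sets(a, b)
    expect_identical(unname(got["shared_a"]),
                     sum(oracle_overlaps(a, b)))
    expect_identical(unname(got["shared_b"]),
                     sum(oracle_overlaps(b, a)))
  }
})

test_that("BED files round-trip through the readers", {
  g <- generate_genome_fixtures(seed = 44)
  path <- withr::local_tempfile(fileext = ".bed")
  write_bed(g$peaks, path)
  back <- read_bed(path)
  expect_identical(back$start, g$peaks$start)
  expect_identical(back$end, g$peaks$end)
  expect_identical(back$name, g$peaks$name)
})
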