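test_that("VAF is derived from AD and multi-allelic records are split", {
  path <- write_test_vcf(c(
    "chr1\t100\t.\tA\tG\t.\tPASS\t.\tGT:AD\t0/1:60,40",
    "chr1\t200\t.\tC\tG,T\t.\tPASS\t.\tGT:AD\t0/1:50,30,20",
    "chr1\t300\t.\tCT\tC\t.\tPASS\t.\tGT:AD\t0/1:90,10"))
  v <- read_vcf(path, sample_id = "s1")
  expect_equal(nrow(v), 4L)                      # (record, alt) pairs conserved
  expect_equal(v$vaf[v$pos == 100], 0.4)
  two <- v[v$pos == 200, ]
  expect_equal(nrow(two), 2L)
  expect_equal(sort(two$alt), c("G", "T"))
  expect_equal(sort(two$vaf), c(0.2, 0.3))
  del <- v[v$pos == 300, ]
  expect_equal(del$var_class, "DEL")
  expect_equal(del$ref, "CT")
})

test_that("FORMAT/VAF takes precedence and INFO keys are a fallback", {
  path <- write_test_vcf(c(
    "chr1\t100\t.\tA\tG\t.\tPASS\t.\tGT:AD:VAF\t0/1:60,40:0.25",
    "chr1\t200\t.\tA\tC\t.\tPASS\tTVAF=0.33\tGT\t0/1"))
  v <- read_vcf(path)
  expect_equal(v$vaf[v$pos == 100], 0.25)
  expect_equal(v$vaf[v$pos == 200], 0.33)
})

test_that("FILTER handling excludes failed records unless overridden", {
  path <- write_test_vcf(c(
    "chr1\t100\t.\tA\tG\t.\tPASS\t.\tGT:AD\t0/1:60,40",
    "chr1\t200\t.\tA\tC\t.\tLOWQ\t.\tGT:AD\t0/1:60,40",
    "chr1\t300\t.\tA\tC\t.\t.\t.\tGT:AD\t0/1:60,40"))
  v <- read_vcf(path)
  expect_equal(sort(v$pos), c(100L, 300L))
  expect_equal(attr(v, "n_filtered"), 1L)
  v2 <- read_vcf(path, keep_filtered = TRUE)
  expect_equal(nrow(v2), 3L)
})

test_that("records without VAF evidence are skipped with a warning and counted", {
  path <- write_test_vcf(c(
    "chr1\t100\t.\tA\tG\t.\tPASS\t.\tGT\t0/1",
    "chr1\t200\t.\tA\tC\t.\tPASS\t.\tGT:AD\t0/1:60,40"))
  expect_warning(v <- read_vcf(path), "skipped")
  expect_equal(nrow(v), 1L)
  expect_equal(attr(v, "n_skipped"), 1L)
})

test_that("VCF write/read round trip reproduces variants exactly", {
  set.seed(31)
  n <- 40L
  depth <- sample(40:120, n, replace = TRUE)
  alt_reads <- pmax(1L, rbinom(n, depth, 0.3))
  refs <- sample(c("A", "C"), n, replace = TRUE)
  alts <- ifelse(refs == "A", sample(c("G", "T", "AT"), n, replace = TRUE),
                 sample(c("A", "CTT"), n, replace = TRUE))
  v <- variant_table("s1", "chrS", sample.int(5000, n), refs, alts,
                     vaf = alt_reads / depth, depth = depth)
  path <- tempfile(fileext = ".vcf")
  write_vcf(v, path)
  v2 <- read_vcf(path, sample_id = "s1")
  key <- function(x) do.call(order, x[c("chrom", "pos", "ref", "alt")])
  a <- v[key(v), c("chrom", "pos", "ref", "alt", "vaf")]
  b <- v2[key(v2), c("chrom", "pos", "ref", "alt", "vaf")]
  rownames(a) <- rownames(b) <- NULL
  expect_equal(a, b)
})

test_that("variant classes follow the allele arithmetic", {
  expect_identical(classify_var_class(c("A", "C", "CT", "GAT", "AT", "GA"),
                                      c("G", "CTT", "C", "G", "GC", "TG")),
                   c("SNV", "INS", "DEL", "DEL", "OTHER", "OTHER"))
})

test_that("variant_table rejects invalid alleles and VAFs", {
  expect_error(variant_table("s", "1", 1, "A", "A", 0.5), "invalid alleles")
  expect_error(variant_table("s", "1", 1, "A", "N", 0.5), "invalid alleles")
  expect_error(variant_table("s", "1", 1, "A", "G", 1.5), "vaf")
})

test_that("reference windows respect bounds and orientation", {
  fx <- tiny_reference()
  ref <- fx$ref
  w <- read_reference_window(ref, "chrS", 1000, 1002)
  expect_equal(nchar(w), 3L)
  expect_equal(read_reference_window(ref, "chrS", 1000, 1000),
               substr(w, 1, 1))
  expect_error(read_reference_window(ref, "chrS", 10, 5), "start")
  expect_error(read_reference_window(ref, "chrS", 0, 5), "out of bounds")
  expect_error(read_reference_window(ref, "chrS", 1, 1e9), "out of bounds")
  expect_error(read_reference_window(ref, "chrZ", 1, 5), "unknown contig")
})

test_that("panel BED parsing merges per-gene overlaps and validates input", {
  bed <- tempfile(fileext = ".bed")
  writeLines(c("chr1\t100\t200\tTP53",
               "chr1\t150\t300\tTP53",
               "chr1\t500\t600\tEGFR"), bed)
  p <- read_panel(bed)
  tp53 <- p[p$gene == "TP53"]
  expect_length(tp53, 1L)
  expect_equal(GenomicRanges::start(tp53), 101L)  # 0-based BED converted
  expect_equal(GenomicRanges::end(tp53), 300L)

  empty <- tempfile(fileext = ".bed")
  writeLines(character(0), empty)
  expect_length(read_panel(empty), 0L)

  bad3 <- tempfile(fileext = ".bed")
  writeLines("chr1\t100\t200", bad3)
  expect_error(read_panel(bad3), "BED4")

  badrange <- tempfile(fileext = ".bed")
  writeLines(c("chr1\t100\t200\tA", "chr1\t300\t300\tB"), badrange)
  expect_error(read_panel(badrange), "line 2")
})
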