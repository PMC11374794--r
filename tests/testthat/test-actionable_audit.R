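make_panel <- function(lines) {
  bed <- tempfile(fileext = ".bed")
  writeLines(lines, bed)
  read_panel(bed)
}

test_that("panel flagging is positional and fragmentation-invariant", {
  panel <- make_panel(c("chr1\t100\t200\tGENE1"))          # 1-based 101..200
  v <- variant_table("s", "chr1", c(150L, 100L, 199L, 201L),
                     c("A", "C", "ACGTA", "G"),
                     c("G", "T", "A", "C"), 0.3, 80)
  fl <- annotate_panel(v, panel)
  expect_equal(fl$gene, c("GENE1", NA, "GENE1", NA))
  # deletion spanning the interval boundary is flagged
  vdel <- variant_table("s", "chr1", 198L, "GACGT", "G", 0.3, 80)
  expect_equal(annotate_panel(vdel, panel)$gene, "GENE1")
  # fragmented vs merged panel intervals give identical flags
  frag <- make_panel(c("chr1\t100\t150\tGENE1", "chr1\t150\t200\tGENE1"))
  expect_equal(annotate_panel(v, frag)$gene, fl$gene)
  expect_error(annotate_panel(v, make_panel(character(0))), "empty")
})

test_that("hotspot lookup matches exact alleles", {
  hs <- data.frame(chrom = "chr7", pos = 55259515L, ref = "T", alt = "G",
                   label = "EGFR_L858R", stringsAsFactors = FALSE)
  v <- variant_table("s", "chr7", c(55259515L, 55259515L),
                     c("T", "T"), c("G", "A"), 0.2, 100)
  out <- annotate_hotspots(v, hs)
  expect_equal(out$hotspot, c("EGFR_L858R", NA))
})

test_that("the VAF-filter audit counts what a naive filter would discard", {
  panel <- make_panel("chr1\t0\t10000\tG")
  v <- variant_table("s", "chr1", 1:10, "A", "G",
                     c(0.05, 0.08, rep(0.3, 8)), 80)
  audit <- vaf_filter_audit(annotate_panel(v, panel), threshold = 0.1)
  expect_equal(audit$n_panel_variants, 10L)
  expect_equal(audit$n_below_threshold, 2L)
  expect_equal(audit$frac_below, 0.2)
  expect_error(vaf_filter_audit(annotate_panel(v, panel), threshold = 0),
               "threshold")
  expect_error(vaf_filter_audit(v), "annotate_panel")
})

test_that("audit counts match brute-force enumeration on beta-distributed VAFs", {
  panel <- make_panel(c("chr1\t0\t5000\tA", "chr1\t8000\t9000\tB"))
  set.seed(77)
  pos <- sample.int(12000, 400)
  vafs <- rbeta(400, 2, 6)
  v <- variant_table("s", "chr1", pos, "A", "G", vafs, 90)
  fl <- annotate_panel(v, panel)
  audit <- vaf_filter_audit(fl, threshold = 0.1)
  inside <- (pos >= 1 & pos <= 5000) | (pos >= 8001 & pos <= 9000)
  expect_equal(audit$n_panel_variants, sum(inside))
  expect_equal(audit$n_below_threshold, sum(inside & vafs < 0.1))
  expect_equal(sum(audit$per_gene$n), sum(inside))
  expect_equal(sum(audit$per_gene$n_below), audit$n_below_threshold)
})

test_that("VAF/purity Spearman correlation matches a rank-then-Pearson oracle", {
  meta <- data.frame(sample_id = paste0("s", 1:20),
                     purity = seq(0.2, 0.9, length.out = 20))
  v <- variant_table(paste0("s", 1:20), "chr1", 1:20, "A", "G",
                     vaf = seq(0.1, 0.45, length.out = 20), depth = 80)
  r <- vaf_purity_correlation(v, meta)
  expect_equal(r$rho, 1.0)
  v$vaf <- rev(v$vaf)
  expect_equal(vaf_purity_correlation(v, meta)$rho, -1.0)
  set.seed(3)
  v$vaf <- pmin(0.99, pmax(0.01, meta$purity / 2 + rnorm(20, 0, 0.08)))
  r2 <- vaf_purity_correlation(v, meta)
  expect_equal(r2$rho, oracle_spearman(v$vaf, meta$purity), tolerance = 1e-12)
  v$vaf <- rep(0.3, 20)
  expect_warning(r3 <- vaf_purity_correlation(v, meta), "constant")
  expect_true(is.na(r3$rho))
  expect_error(vaf_purity_correlation(v[1:3, ], meta), "at least 5")
})

test_that("exposure concordance captures agreement between matched pairs", {
  sigs <- c("S1", "S2")
  mk <- function(id, e1, e2) make_exposure_set(id, c(S1 = e1, S2 = e2))
  ff <- lapply(1:8, function(i) mk(paste0("p", i), i * 10, 100 - i * 10))
  conc <- exposure_concordance(ff, ff)
  expect_true(all(conc$rho == 1))
  expect_true(all(conc$complementarity == 1))
  # permuted exposures give the permutation's rank correlation
  ffpe <- ff[c(2, 1, 4, 3, 6, 5, 8, 7)]
  for (i in seq_along(ffpe)) ffpe[[i]]$sample_id <- paste0("p", i)
  conc2 <- exposure_concordance(ff, ffpe)
  want <- oracle_spearman(sapply(ff, function(e) e$exposures["S1"]),
                          sapply(ffpe, function(e) e$exposures["S1"]))
  expect_equal(conc2$rho[conc2$signature == "S1"], want, tolerance = 1e-12)
  # unmatched ids error
  bad <- ff; bad[[1]]$sample_id <- "other"
  expect_error(exposure_concordance(ff, bad), "unmatched")
})

test_that("concordance is high for shared exposures with Poisson noise", {
  set.seed(15)
  truth <- matrix(runif(12 * 3, 100, 2000), 12, 3,
                  dimnames = list(NULL, c("S1", "S2", "S3")))
  mk <- function(mu, id) make_exposure_set(id, setNames(rpois(3, mu),
                                                        colnames(truth)))
  ff <- lapply(1:12, function(i) mk(truth[i, ], paste0("p", i)))
  ffpe <- lapply(1:12, function(i) mk(truth[i, ], paste0("p", i)))
  conc <- exposure_concordance(ff, ffpe)
  expect_true(all(conc$rho > 0.9))
})
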