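test_that("synthetic references honour GC content and determinism", {
  p1 <- tempfile(fileext = ".fa")
  r1 <- make_reference(1e6, gc = 0.5, seed = 3, path = p1)
  expect_gte(r1$gc, 0.49)
  expect_lte(r1$gc, 0.51)
  p2 <- tempfile(fileext = ".fa")
  r2 <- make_reference(1e6, gc = 0.5, seed = 3, path = p2)
  expect_identical(readLines(p1), readLines(p2))
  expect_error(make_reference(5000, 0.5, 1), ">= 10,000")
  # engineered tracts are present at their recorded positions
  ref <- load_reference(p1)
  tr <- r1$tracts[r1$tracts$kind == "homopolymer", ][1, ]
  run <- read_reference_window(ref, "chrS", tr$start, tr$start + tr$len - 1L)
  expect_equal(run, paste(rep(tr$unit, tr$len), collapse = ""))
})

test_that("test signature profiles are normalised with the documented peaks", {
  sbs <- make_test_signatures("SBS96")
  id <- make_test_signatures("ID83")
  expect_true(all(abs(colSums(sbs) - 1) < 1e-8))
  expect_true(all(abs(colSums(id) - 1) < 1e-8))
  peaks <- c("A[T>C]A", "A[T>C]C", "C[T>C]T", "T[T>C]T",
             "A[C>T]A", "A[C>T]T", "T[C>T]T")
  expect_gte(sum(sbs[peaks, "SBS_FFPE"]), 0.6)
  id_peaks <- c("1:Del:T:5", "1:Del:T:6+", "1:Ins:T:4", "1:Ins:T:5+",
                "2:Del:R:4", "2:Del:R:5", "2:Del:R:6+", "5+:Ins:R:0")
  expect_gte(sum(id[id_peaks, "ID_FFPE"]), 0.6)
  flat96 <- rep(1 / 96, 96)
  flat83 <- rep(1 / 83, 83)
  expect_lt(cosine_similarity(sbs[, "SBS_FFPE"], flat96), 0.6)
  expect_lt(cosine_similarity(sbs[, "SBS57"], flat96), 0.6)
  expect_lt(cosine_similarity(id[, "ID_FFPE"], flat83), 0.6)
})

test_that("samples without artefact weight emit no artefact mutations", {
  co <- standard_cohort()
  sim <- simulate_sample("ff_only", "FF", 0.7, n_sbs = 300L, n_id = 30L,
                         sbs_mixture = c(BIO_A = 0.5, BIO_B = 0.5),
                         id_mixture = c(ID_BIO_A = 1),
                         sbs_signatures = co$signatures$SBS96,
                         id_signatures = co$signatures$ID83,
                         indexes = co$indexes, seed = 5)
  expect_equal(sim$truth$artefact_fraction, 0)
  expect_equal(sim$truth$sbs_artefact + sim$truth$id_artefact, 0)
  expect_false(any(sim$variants$signature %in% default_artefact_signatures()))
})

test_that("catalogues rebuilt from the emitted VCF match the drawn counts exactly", {
  co <- standard_cohort()
  vcf <- tempfile(fileext = ".vcf")
  sim <- simulate_sample("rt", "FFPE", 0.6, n_sbs = 500L, n_id = 300L,
                         sbs_mixture = c(BIO_A = 0.6, SBS_FFPE = 0.4),
                         id_mixture = c(ID_BIO_B = 0.3, ID_FFPE = 0.7),
                         sbs_signatures = co$signatures$SBS96,
                         id_signatures = co$signatures$ID83,
                         indexes = co$indexes, seed = 8, vcf_path = vcf)
  v <- read_vcf(vcf, sample_id = "rt")
  ref <- co$indexes$reference
  sbs <- build_catalogue(v, ref, "SBS96")
  id <- build_catalogue(v, ref, "ID83")
  expect_equal(as.numeric(sbs), as.numeric(sim$channel_counts$SBS96))
  expect_equal(as.numeric(id), as.numeric(sim$channel_counts$ID83))
})

test_that("simulation is byte-identical under a fixed seed", {
  co <- standard_cohort()
  args <- list("det", "FFPE", 0.5, 200L, 100L,
               c(BIO_A = 0.7, SBS57 = 0.3), c(ID_BIO_A = 0.4, ID_FFPE = 0.6),
               co$signatures$SBS96, co$signatures$ID83, co$indexes)
  v1 <- tempfile(fileext = ".vcf"); v2 <- tempfile(fileext = ".vcf")
  do.call(simulate_sample, c(args, list(seed = 99, vcf_path = v1)))
  do.call(simulate_sample, c(args, list(seed = 99, vcf_path = v2)))
  expect_identical(readLines(v1), readLines(v2))
})

test_that("PCR-exposed preparations carry an order-of-magnitude indel excess", {
  co <- standard_cohort()
  tr <- co$truth
  med_ff <- median(tr$id_total[tr$preparation == "FF"])
  med_ffpe <- median(tr$id_total[tr$preparation == "FFPE"])
  ratio <- med_ffpe / med_ff
  expect_gt(ratio, 6)
  expect_lt(ratio, 16)
  # substitution burdens are not systematically inflated
  sbs_ratio <- median(tr$sbs_total[tr$preparation == "FFPE"]) /
    median(tr$sbs_total[tr$preparation == "FF"])
  expect_lt(sbs_ratio, 2)
})

test_that("truth tables are internally consistent", {
  co <- standard_cohort()
  tr <- co$truth
  sbs_cols <- grep("^sbs_(BIO|SBS)", names(tr), value = TRUE)
  id_cols <- grep("^id_ID", names(tr), value = TRUE)
  expect_equal(rowSums(tr[, sbs_cols]), tr$sbs_total, ignore_attr = TRUE)
  expect_equal(rowSums(tr[, id_cols]), tr$id_total, ignore_attr = TRUE)
  art <- tr$sbs_SBS57 + tr$sbs_SBS_FFPE + tr$id_ID_FFPE
  expect_equal(art / (tr$sbs_total + tr$id_total), tr$artefact_fraction,
               ignore_attr = TRUE)
  # FF samples carry no artefact weight
  expect_true(all(tr$artefact_fraction[tr$preparation == "FF"] == 0))
})

test_that("unsatisfiable channels raise a named error", {
  co <- standard_cohort()
  bad_mix <- c(ID_BIO_A = 1)
  sigs <- co$signatures$ID83
  # request far more long-homopolymer deletions than the reference can host
  expect_error(
    simulate_sample("boom", "FFPE", 0.6, n_sbs = 0L, n_id = 200000L,
                    sbs_mixture = c(BIO_A = 1), id_mixture = c(ID_FFPE = 1),
                    sbs_signatures = co$signatures$SBS96,
                    id_signatures = sigs, indexes = co$indexes, seed = 1),
    "unsatisfiable ID channel")
})
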