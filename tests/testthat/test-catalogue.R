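test_that("substitutions collapse onto the pyrimidine strand", {
  # FFPE-associated C>T and T>C contexts
  expect_equal(classify_sbs("C", "T", "ACA"), "A[C>T]A")
  expect_equal(classify_sbs("G", "A", "TGT"), "A[C>T]A")  # reverse strand
  expect_equal(classify_sbs("T", "C", "ATA"), "A[T>C]A")
  expect_error(classify_sbs("C", "T", "AGA"), "reference mismatch")
})

test_that("1bp indels land in homopolymer-length channels with complement collapsing", {
  fx <- tiny_reference()
  ref <- fx$ref; seq <- ref[["chrS"]]
  # deletion of one T from an engineered run of >= 6 Ts
  tr <- fx$info$tracts
  t6 <- tr[tr$kind == "homopolymer" & tr$unit == "T" & tr$len >= 6, ][1, ]
  anchor <- t6$start - 1L
  lab <- classify_indel_at(ref, "chrS", anchor,
                           paste0(substr(seq, anchor, anchor), "T"),
                           substr(seq, anchor, anchor))
  expect_equal(lab, "1:Del:T:6+")
  # same event via an A-run maps to the T channel too
  a6 <- tr[tr$kind == "homopolymer" & tr$unit == "A" & tr$len >= 6, ][1, ]
  anchor <- a6$start - 1L
  lab <- classify_indel_at(ref, "chrS", anchor,
                           paste0(substr(seq, anchor, anchor), "A"),
                           substr(seq, anchor, anchor))
  expect_equal(lab, "1:Del:T:6+")
  # insertion of A next to zero existing As: unit-count class 0
  expect_equal(classify_indel("G", "GA", "CGTCGC", "CCGTCG"), "1:Ins:T:0")
})

test_that("microhomology and repeat precedence follow the scheme", {
  # 4bp deletion whose 3' flank begins with 3 of its 4 bases, no full copy
  expect_equal(classify_indel("GACGT", "G",
                              flank5 = "TTGGCCTTGGCCTTGGCCTTGGCCG",
                              flank3 = "ACGGGTTTCCGGAATTCCGGAATTCC"),
               "4:Del:M:3")
  # deletion of one unit with two more adjacent copies: repeat classification
  # takes precedence and the deleted copy itself is counted (3 units)
  expect_equal(classify_indel("GAT", "G", "CCGCCGCCGCCG", "ATATGCGCGCGC"),
               "2:Del:R:3")
  # insertion next to an existing tandem run counts existing copies only
  expect_equal(classify_indel("G", "GAT", "CCGCCGCCGCCG", "ATATGCGCGCGC"),
               "2:Ins:R:2")
  expect_error(classify_indel("GACGT", "G", "AC", "ACGT"), "flanks shorter")
})

test_that("channel assignment is invariant to indel representation", {
  fx <- tiny_reference()
  ref <- fx$ref; seq <- ref[["chrS"]]
  tr <- fx$info$tracts
  t8 <- tr[tr$kind == "homopolymer" & tr$unit == "T" & tr$len >= 8, ][1, ]
  # delete one T from the middle of the run instead of its left edge
  mid <- t8$start + 3L
  la <- left_align_indel("chrS", mid, paste0(substr(seq, mid, mid), "T"),
                         substr(seq, mid, mid), ref)
  expect_equal(la$pos, t8$start - 1L)
  lab_mid <- classify_indel_at(ref, "chrS", mid,
                               paste0(substr(seq, mid, mid), "T"),
                               substr(seq, mid, mid))
  lab_left <- classify_indel_at(ref, "chrS", t8$start - 1L,
                                paste0(substr(seq, t8$start - 1L, t8$start - 1L), "T"),
                                substr(seq, t8$start - 1L, t8$start - 1L))
  expect_equal(lab_mid, lab_left)
})

test_that("classify_indel agrees with the brute-force scanning oracle", {
  fx <- tiny_reference()
  ref <- fx$ref
  chars <- strsplit(ref[["chrS"]], "", fixed = TRUE)[[1]]
  tracts <- fx$info$tracts
  set.seed(99)
  rng_pos <- 200:(length(chars) - 200)
  for (i in seq_len(1000)) {
    ev <- random_indel(chars, rng_pos, tracts)
    got <- classify_indel_at(ref, "chrS", ev$pos, ev$ref, ev$alt)
    want <- oracle_classify_indel(chars, ev$pos, ev$ref, ev$alt)
    if (!identical(got, want)) {
      fail(sprintf("mismatch at pos %d %s>%s: got %s, oracle %s",
                   ev$pos, ev$ref, ev$alt, got, want))
    }
  }
  succeed()
})

test_that("catalogues count classifiable variants and tally the rest", {
  fx <- tiny_reference()
  ref <- fx$ref; seq <- ref[["chrS"]]
  empty <- variant_table(character(0), character(0), integer(0),
                         character(0), character(0), numeric(0))
  cat0 <- build_catalogue(empty, ref, "SBS96")
  expect_equal(sum(cat0), 0)
  expect_length(cat0, 96L)

  # 100 identical C>T at an ACA context
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  aca <- which(chars[1:(length(chars) - 2)] == "A" &
                 chars[2:(length(chars) - 1)] == "C" &
                 chars[3:length(chars)] == "A")[1] + 1L
  v <- variant_table("s", "chrS", rep(aca, 100), "C", "T", 0.4, 80)
  cat1 <- build_catalogue(v, ref, "SBS96")
  expect_equal(unname(cat1["A[C>T]A"]), 100)
  expect_equal(sum(cat1), 100)

  # conservation: SNVs + indels + OTHER split across the two schemes
  v2 <- variant_table("s", "chrS",
                      c(aca, aca + 10L, aca + 20L),
                      c("C", substr(seq, aca + 10L, aca + 11L), "AT"),
                      c("T", substr(seq, aca + 10L, aca + 10L), "GC"),
                      0.3, 60)
  sbs <- build_catalogue(v2, ref, "SBS96")
  id <- build_catalogue(v2, ref, "ID83")
  expect_equal(sum(sbs) + attr(sbs, "n_excluded"), nrow(v2))
  expect_equal(sum(id) + attr(id, "n_excluded"), nrow(v2))
  expect_equal(sum(sbs), 1)
  expect_equal(sum(id), 1)
})

test_that("catalogue channel frequencies match the generating profile", {
  co <- standard_cohort()
  ref <- co$indexes$reference
  sigs <- co$signatures$SBS96
  set.seed(12)
  sim <- simulate_sample("chisq", "FF", 0.6, n_sbs = 2000L, n_id = 0L,
                         sbs_mixture = c(BIO_A = 1),
                         id_mixture = c(ID_BIO_A = 1),
                         sbs_signatures = sigs,
                         id_signatures = co$signatures$ID83,
                         indexes = co$indexes, seed = 314)
  cat <- build_catalogue(sim$variants, ref, "SBS96")
  p <- sigs[, "BIO_A"]
  ct <- suppressWarnings(stats::chisq.test(as.numeric(cat), p = p))
  expect_gt(ct$p.value, 0.01)
})

test_that("catalogue TSV round-trips in canonical channel order", {
  fx <- tiny_reference()
  cat1 <- new_catalogue("s1", "ID83",
                        c("1:Del:T:6+" = 5, "2:Del:R:4" = 3))
  cat2 <- new_catalogue("s2", "ID83", c("3:Del:M:1" = 7))
  path <- tempfile(fileext = ".tsv")
  write_catalogue_tsv(list(cat1, cat2), path)
  back <- read_catalogue_tsv(path, "ID83")
  expect_equal(as.numeric(back$s1), as.numeric(cat1))
  expect_equal(as.numeric(back$s2), as.numeric(cat2))
  expect_identical(names(back$s1), id83_channels())
})
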