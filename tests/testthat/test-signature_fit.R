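# two orthogonal-peaked SBS96 test profiles
disjoint_profiles <- function() {
  a <- setNames(numeric(96), sbs96_channels())
  b <- a
  a[1:10] <- 0.1
  b[21:30] <- 0.1
  signature_matrix(cbind(A = a, B = b), "SBS96")
}

test_that("noise-free mixtures are recovered exactly", {
  sigs <- disjoint_profiles()
  m <- new_catalogue("s", "SBS96", round(100 * sigs[, "A"]))
  fit <- fit_exposures(m, sigs)
  expect_equal(unname(fit$exposures["A"]), 100, tolerance = 1e-9)
  expect_equal(unname(fit$exposures["B"]), 0, tolerance = 1e-9)
  expect_equal(fit$reconstruction_cosine, 1, tolerance = 1e-12)

  m2 <- new_catalogue("s", "SBS96", round(70 * sigs[, "A"] + 30 * sigs[, "B"]))
  fit2 <- fit_exposures(m2, sigs)
  want <- oracle_lsq(unclass(sigs), as.numeric(m2))
  expect_equal(unname(fit2$exposures), want, tolerance = 1e-6)
  expect_equal(unname(fit2$exposures), c(70, 30), tolerance = 1e-6)
})

test_that("exposures are non-negative and account for the catalogue total", {
  sigs <- make_test_signatures("SBS96")
  set.seed(8)
  for (i in 1:20) {
    w <- as.numeric(rmultinom(1, 500, rep(0.2, 5)))
    m <- new_catalogue("s", "SBS96", rpois(96, as.numeric(sigs %*% w)))
    fit <- fit_exposures(m, sigs)
    expect_true(all(fit$exposures >= 0))
    expect_equal(sum(fit$exposures) + fit$unassigned, sum(m), tolerance = 0.5)
    # fitted objective never exceeds that of the all-zero solution
    r_fit <- sum((as.numeric(m) - as.numeric(sigs %*% fit$exposures))^2)
    expect_lte(r_fit, sum(as.numeric(m)^2) + 1e-8)
  }
})

test_that("Poisson-noised 500-mutation mixtures are recovered with small error", {
  sigs <- make_test_signatures("SBS96")
  S3 <- signature_matrix(unclass(sigs)[, c("BIO_A", "BIO_B", "SBS_FFPE")],
                         "SBS96")
  truth <- c(0.6, 0.3, 0.1)
  set.seed(256)
  maes <- vapply(seq_len(100), function(r) {
    m <- new_catalogue("r", "SBS96",
                       rpois(96, as.numeric(S3 %*% (500 * truth))))
    fit <- fit_exposures(m, S3)
    mean(abs(fit$exposures / sum(m) - truth))
  }, numeric(1))
  expect_lt(mean(maes), 0.05)
})

test_that("adding an unused signature never increases the residual norm", {
  sigs <- make_test_signatures("SBS96")
  set.seed(17)
  m <- new_catalogue("s", "SBS96",
                     rpois(96, as.numeric(sigs[, 1:2] %*% c(300, 200))))
  rnorm2 <- function(fit, S) {
    sum((as.numeric(m) - as.numeric(S %*% fit$exposures))^2)
  }
  f2 <- fit_exposures(m, signature_matrix(sigs[, 1:2], "SBS96"))
  f3 <- fit_exposures(m, signature_matrix(sigs[, 1:3], "SBS96"))
  expect_lte(rnorm2(f3, sigs[, 1:3]), rnorm2(f2, sigs[, 1:2]) + 1e-6)
})

test_that("bootstrap sparsity zeroes signatures without support", {
  sigs <- disjoint_profiles()
  set.seed(4)
  m <- new_catalogue("s", "SBS96", rpois(96, 400 * sigs[, "A"]))
  fit <- fit_exposures(m, sigs, sparsity = "bootstrap", seed = 21)
  expect_equal(unname(fit$exposures["B"]), 0)
  expect_gt(unname(fit$exposures["A"]), 300)
})

test_that("degenerate inputs are handled explicitly", {
  sigs <- disjoint_profiles()
  zero <- new_catalogue("s", "SBS96")
  fit <- fit_exposures(zero, sigs)
  expect_true(all(fit$exposures == 0))
  expect_true(is.na(fit$reconstruction_cosine))
  id_cat <- new_catalogue("s", "ID83", c("1:Del:T:1" = 5))
  expect_error(fit_exposures(id_cat, sigs), "channel-set mismatch")
})

test_that("subtraction removes fitted signatures and clamps at zero", {
  sigs <- disjoint_profiles()
  m <- new_catalogue("s", "SBS96", round(100 * sigs[, "A"]))
  fit <- fit_exposures(m, sigs)
  res <- subtract_signatures(m, fit, sigs, "A")
  expect_true(all(res == 0))
  # empty subset is the identity
  expect_equal(as.numeric(subtract_signatures(m, fit, sigs, character(0))),
               as.numeric(m))
  # clamping: inflate one channel's expected count beyond the observation
  fit2 <- fit
  fit2$exposures["A"] <- 1e5
  res2 <- subtract_signatures(m, fit2, sigs, "A")
  expect_true(all(res2 >= 0))
  expect_gt(attr(res2, "negative_mass"), 0)
  expect_lte(sum(res2), sum(m))
  expect_error(subtract_signatures(m, fit, sigs, "missing"), "unknown")
})

test_that("cosine similarity matches hand computations", {
  expect_equal(cosine_similarity(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(cosine_similarity(c(1, 1, 0), c(0, 0, 5)), 0)
  expect_equal(cosine_similarity(c(1, 1, 0), c(1, 0, 1)), 0.5)
  expect_error(cosine_similarity(c(0, 0), c(1, 1)), "zero vector")
  expect_error(cosine_similarity(c(1, 0), c(1, 1, 1)), "length")
})

test_that("signature matrices validate normalisation and channel order", {
  sigs <- make_test_signatures("SBS96")
  expect_true(all(abs(colSums(sigs) - 1) < 1e-8))
  shuffled <- unclass(sigs)[sample(96), , drop = FALSE]
  back <- signature_matrix(shuffled, "SBS96")
  expect_identical(rownames(back), sbs96_channels())
  expect_warning(signature_matrix(cbind(a = sigs[, 1], b = sigs[, 1]),
                                  "SBS96"),
                 "collinear")
  path <- tempfile(fileext = ".tsv")
  write_signature_tsv(sigs, path)
  expect_equal(unclass(read_signature_tsv(path, "SBS96")), unclass(sigs),
               tolerance = 1e-12)
})
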