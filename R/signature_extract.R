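# generalised Kullback-Leibler divergence between V and WH
.kl_div <- function(V, WH) {
  eps <- 1e-12
  sum(V * log((V + eps) / (WH + eps)) - V + WH)
}

#' Non-negative matrix factorisation with the generalised KL objective
#'
#' Multiplicative updates (Poisson-appropriate for count catalogues), with
#' the basis columns renormalised to sum to 1 at each step.
#'
#' @param V non-negative matrix (channels x samples).
#' @param k rank.
#' @param max_iter maximum iterations (default 5000).
#' @param tol relative tolerance on the KL objective (default 1e-6).
#' @param W0,H0 optional initial factors; random uniform if omitted (uses the
#'   current RNG state).
#' @return list with `W` (channels x k, columns summing to 1), `H`
#'   (k x samples) and `divergence`.
#' @export
nmf_kl <- function(V, k, max_iter = 5000L, tol = 1e-6, W0 = NULL, H0 = NULL) {
  V <- as.matrix(V)
  n <- nrow(V); m <- ncol(V)
  eps <- 1e-12
  W <- if (is.null(W0)) matrix(stats::runif(n * k, 0.1, 1), n, k) else as.matrix(W0)
  H <- if (is.null(H0)) matrix(stats::runif(k * m, 0.1, 1), k, m) else as.matrix(H0)
  W <- sweep(W, 2, colSums(W) + eps, "/")
  prev <- Inf
  for (it in seq_len(max_iter)) {
    WH <- W %*% H
    H <- H * (t(W) %*% (V / (WH + eps))) / (colSums(W) + eps)
    WH <- W %*% H
    W <- W * ((V / (WH + eps)) %*% t(H)) /
      matrix(rowSums(H) + eps, n, k, byrow = TRUE)
    s <- colSums(W) + eps
    W <- sweep(W, 2, s, "/")
    H <- H * s
    if (it %% 10L == 0L || it == max_iter) {
      d <- .kl_div(V, W %*% H)
      if (is.finite(prev) && abs(prev - d) <= tol * max(1, abs(prev))) {
        prev <- d
        break
      }
      prev <- d
    }
  }
  list(W = W, H = H, divergence = .kl_div(V, W %*% H))
}

# greedy one-to-one matching of columns of A to columns of B by cosine;
# returns data.frame(a, b, cosine)
.greedy_match <- function(A, B) {
  cm <- matrix(0, ncol(A), ncol(B))
  for (i in seq_len(ncol(A))) for (j in seq_len(ncol(B))) {
    cm[i, j] <- cosine_similarity(A[, i], B[, j])
  }
  res <- data.frame(a = integer(0), b = integer(0), cosine = numeric(0))
  while (nrow(res) < min(dim(cm)) && any(is.finite(cm))) {
    ij <- arrayInd(which.max(cm), dim(cm))
    res <- rbind(res, data.frame(a = ij[1], b = ij[2], cosine = cm[ij]))
    cm[ij[1], ] <- -Inf
    cm[, ij[2]] <- -Inf
  }
  res[order(res$a), , drop = FALSE]
}

#' Extract recurrent artefact signatures from residual catalogues
#'
#' Runs seeded multi-restart KL-NMF on the residual catalogue matrix for each
#' rank in `k_range`, measures per-signature stability as the mean matched
#' cosine between each random restart's solution and the best-objective
#' solution, and selects the largest rank for which (a) every extracted
#' signature has stability of at least `stability_min`, (b) is non-degenerate — no two
#' extracted profiles with cosine above `max_pair_cosine`, the fingerprint of
#' one process being split across components — and (c) lowers the KL
#' reconstruction error by at least a fraction `elbow_min_gain` relative to
#' the best smaller accepted rank: stability is the primary criterion, the
#' reconstruction-error elbow decides among stable ranks. One extra restart
#' per rank is warm-started from the previous rank's solution, so
#' reconstruction error is non-increasing in k.
#'
#' Samples whose residual total exceeds 10x the cohort median
#' ("hypermutators") are down-weighted to the 90th-percentile total during
#' extraction; exposures are then refit at full scale by NNLS.
#'
#' @param residuals list of `mutational_catalogue` objects (>= 10 with
#'   nonzero totals).
#' @param k_range candidate ranks (within `[1, n_samples/2]`).
#' @param n_restarts random restarts per rank (default 10).
#' @param seed integer seed; extraction is deterministic given the seed and
#'   input order.
#' @param stability_min stability threshold for rank selection (default 0.8).
#' @param elbow_min_gain minimum relative KL-divergence improvement required
#'   to accept a larger stable rank (default 0.05).
#' @param max_pair_cosine ranks whose best solution contains two profiles
#'   with cosine above this are treated as degenerate (default 0.9).
#' @param max_iter,tol passed to [nmf_kl()].
#' @return list of class `extraction_result`: `k`, `profiles`
#'   (a `signature_matrix`, names `X1..Xk`), `sample_exposures` (list of
#'   `exposure_set`), `stability` (per signature), `divergences` (best KL per
#'   rank), `stability_by_k`.
#' @export
extract_signatures <- function(residuals, k_range, n_restarts = 10L, seed = 1L,
                               stability_min = 0.8, elbow_min_gain = 0.05,
                               max_pair_cosine = 0.9, max_iter = 5000L,
                               tol = 1e-6) {
  if (inherits(residuals, "mutational_catalogue")) residuals <- list(residuals)
  totals <- vapply(residuals, sum, numeric(1))
  if (all(totals == 0)) stop("nothing to extract: all residual catalogues are zero")
  if (length(residuals) < 10L) {
    stop("need >= 10 residual catalogues, got ", length(residuals))
  }
  k_range <- sort(unique(as.integer(k_range)))
  if (min(k_range) < 1L || max(k_range) > length(residuals) / 2) {
    stop("k_range must lie within [1, n_samples/2]")
  }
  channel_set <- attr(residuals[[1]], "channel_set")
  V <- do.call(cbind, lapply(residuals, as.numeric))
  colnames(V) <- vapply(residuals, function(x) {
    s <- attr(x, "sample_id"); if (is.null(s) || is.na(s)) "" else s
  }, character(1))
  # hypermutator down-weighting
  med <- stats::median(totals[totals > 0])
  cap <- stats::quantile(totals, 0.9, names = FALSE)
  Vw <- V
  hyper <- totals > 10 * med
  if (any(hyper)) {
    for (j in which(hyper)) Vw[, j] <- Vw[, j] * (cap / totals[j])
  }
  keep_cols <- totals > 0
  Vw_fit <- Vw[, keep_cols, drop = FALSE]

  set.seed(seed)
  run_seeds <- sample.int(.Machine$integer.max - 1L,
                          length(k_range) * n_restarts)
  dim(run_seeds) <- c(length(k_range), n_restarts)

  best_by_k <- vector("list", length(k_range))
  stab_by_k <- vector("list", length(k_range))
  div_by_k <- numeric(length(k_range))
  prev_best <- NULL
  for (ki in seq_along(k_range)) {
    k <- k_range[ki]
    runs <- vector("list", n_restarts + 1L)
    for (r in seq_len(n_restarts)) {
      set.seed(run_seeds[ki, r])
      runs[[r]] <- nmf_kl(Vw_fit, k, max_iter = max_iter, tol = tol)
    }
    # warm start from the previous rank's best solution (+ random column)
    if (!is.null(prev_best) && ncol(prev_best$W) == k - 1L) {
      set.seed(run_seeds[ki, 1] + 1L)
      W0 <- cbind(prev_best$W, stats::runif(nrow(Vw_fit), 0.1, 1))
      H0 <- rbind(prev_best$H, matrix(stats::runif(ncol(Vw_fit), 0, 0.1), 1))
      runs[[n_restarts + 1L]] <- nmf_kl(Vw_fit, k, max_iter = max_iter,
                                        tol = tol, W0 = W0, H0 = H0)
    } else {
      runs[[n_restarts + 1L]] <- NULL
    }
    runs <- Filter(Negate(is.null), runs)
    divs <- vapply(runs, `[[`, numeric(1), "divergence")
    best <- runs[[which.min(divs)]]
    # stability: mean matched cosine of each *random* restart against the
    # best run (the warm-started run is excluded; it is biased toward the
    # previous rank's solution)
    rand_runs <- runs[seq_len(min(n_restarts, length(runs)))]
    stab <- matrix(NA_real_, length(rand_runs), k)
    for (r in seq_along(rand_runs)) {
      mt <- .greedy_match(best$W, rand_runs[[r]]$W)
      stab[r, mt$a] <- mt$cosine
    }
    best_by_k[[ki]] <- best
    stab_by_k[[ki]] <- colMeans(stab, na.rm = TRUE)
    div_by_k[ki] <- min(divs)
    prev_best <- best
  }
  mean_stab <- vapply(stab_by_k, mean, numeric(1))
  stable <- vapply(stab_by_k, min, numeric(1)) >= stability_min
  degenerate <- vapply(best_by_k, function(b) {
    k <- ncol(b$W)
    if (k < 2L) return(FALSE)
    for (i in 1:(k - 1L)) for (j in (i + 1L):k) {
      if (cosine_similarity(b$W[, i], b$W[, j]) > max_pair_cosine) return(TRUE)
    }
    FALSE
  }, logical(1))
  ki_sel <- NULL
  for (ki in seq_along(k_range)) {
    if (!stable[ki] || degenerate[ki]) next
    if (is.null(ki_sel) ||
        div_by_k[ki] < (1 - elbow_min_gain) * div_by_k[ki_sel]) {
      ki_sel <- ki
    }
  }
  if (is.null(ki_sel)) ki_sel <- which.max(mean_stab)
  k_sel <- k_range[ki_sel]
  best <- best_by_k[[ki_sel]]
  profiles <- signature_matrix(best$W, channel_set,
                               names = paste0("X", seq_len(k_sel)))
  # refit exposures at full scale on all samples
  sample_exposures <- lapply(residuals, function(res) {
    fit_exposures(res, profiles, sparsity = "none")
  })
  structure(list(k = k_sel,
                 profiles = profiles,
                 sample_exposures = sample_exposures,
                 stability = stats::setNames(stab_by_k[[ki_sel]],
                                             colnames(profiles)),
                 divergences = stats::setNames(div_by_k, k_range),
                 stability_by_k = stats::setNames(mean_stab, k_range),
                 seed = seed),
            class = "extraction_result")
}

#' Match extracted signatures to a reference set by cosine similarity
#'
#' Greedy best-match: repeatedly pair the extracted/reference columns with
#' the highest remaining cosine. Matches below `min_cosine` are labelled
#' `"novel"`.
#'
#' @param extracted,reference `signature_matrix` objects on the same channel
#'   set.
#' @param min_cosine annotation threshold (default 0.8).
#' @return data.frame with columns `extracted`, `reference` (or `"novel"`)
#'   and `cosine`.
#' @export
match_to_reference <- function(extracted, reference, min_cosine = 0.8) {
  if (!identical(attr(extracted, "channel_set"), attr(reference, "channel_set"))) {
    stop("channel-set mismatch between extracted and reference signatures")
  }
  mt <- .greedy_match(unclass(extracted), unclass(reference))
  out <- data.frame(extracted = colnames(extracted),
                    reference = NA_character_,
                    cosine = NA_real_, stringsAsFactors = FALSE)
  out$reference[mt$a] <- colnames(reference)[mt$b]
  out$cosine[mt$a] <- mt$cosine
  novel <- is.na(out$cosine) | out$cosine < min_cosine
  out$reference[novel] <- "novel"
  out
}

#' Write an extraction result (profiles TSV + JSON sidecar)
#'
#' @param result an `extraction_result`.
#' @param profiles_path signature TSV path.
#' @param json_path sidecar path for stability and matches.
#' @param matches optional output of [match_to_reference()].
#' @export
write_extraction_result <- function(result, profiles_path, json_path,
                                    matches = NULL) {
  write_signature_tsv(result$profiles, profiles_path)
  side <- list(k = result$k,
               seed = result$seed,
               stability = as.list(result$stability),
               stability_by_k = as.list(result$stability_by_k),
               divergences = as.list(result$divergences))
  if (!is.null(matches)) side$matches <- matches
  jsonlite::write_json(side, json_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(json_path)
}
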