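#' Construct a signature matrix
#'
#' A signature matrix holds column-normalised non-negative profiles over a
#' channel set, rows in the canonical channel order.
#'
#' @param profiles numeric matrix (channels x signatures), non-negative.
#' @param channel_set `"SBS96"` or `"ID83"`.
#' @param names optional signature names (defaults to `colnames(profiles)`).
#' @return matrix of class `signature_matrix` with canonical rownames and
#'   columns summing to 1.
#' @export
signature_matrix <- function(profiles, channel_set = c("SBS96", "ID83"),
                             names = NULL) {
  channel_set <- match.arg(channel_set)
  labels <- channel_labels(channel_set)
  profiles <- as.matrix(profiles)
  if (nrow(profiles) != length(labels)) {
    stop("expected ", length(labels), " channels, got ", nrow(profiles))
  }
  if (!is.null(rownames(profiles)) && !identical(rownames(profiles), labels)) {
    if (!all(labels %in% rownames(profiles))) {
      stop("profile rownames do not match the canonical ", channel_set, " labels")
    }
    profiles <- profiles[labels, , drop = FALSE]
  }
  rownames(profiles) <- labels
  if (!is.null(names)) colnames(profiles) <- names
  if (is.null(colnames(profiles))) {
    colnames(profiles) <- paste0("S", seq_len(ncol(profiles)))
  }
  if (any(profiles < 0)) stop("signature profiles must be non-negative")
  cs <- colSums(profiles)
  if (any(cs <= 0)) stop("all-zero signature column: ",
                         paste(colnames(profiles)[cs <= 0], collapse = ", "))
  profiles <- sweep(profiles, 2, cs, "/")
  # near-collinear columns are kept but flagged
  if (ncol(profiles) > 1L) {
    cm <- crossprod(sweep(profiles, 2, sqrt(colSums(profiles^2)), "/"))
    diag(cm) <- 0
    if (any(cm > 0.99)) {
      idx <- which(cm > 0.99, arr.ind = TRUE)[1, ]
      warning("signature columns nearly collinear (cosine > 0.99): ",
              colnames(profiles)[idx[1]], " vs ", colnames(profiles)[idx[2]],
              "; keeping both")
    }
  }
  structure(profiles, channel_set = channel_set,
            class = c("signature_matrix", "matrix"))
}

#' Read a signature matrix from TSV (channels x signatures, header row)
#'
#' @param path TSV path; first column holds channel labels.
#' @param channel_set channel set of the file.
#' @return a `signature_matrix`.
#' @export
read_signature_tsv <- function(path, channel_set = c("SBS96", "ID83")) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  signature_matrix(m, match.arg(channel_set))
}

#' Write a signature matrix to TSV
#'
#' @param signatures a `signature_matrix`.
#' @param path output path.
#' @export
write_signature_tsv <- function(signatures, path) {
  df <- data.frame(channel = rownames(signatures), stringsAsFactors = FALSE,
                   check.names = FALSE)
  for (nm in colnames(signatures)) df[[nm]] <- signatures[, nm]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Cosine similarity between two non-negative channel vectors
#'
#' @param a,b equal-length non-negative vectors, each with at least one
#'   nonzero entry.
#' @return `a.b / (|a||b|)`, in `[0, 1]`.
#' @export
cosine_similarity <- function(a, b) {
  if (length(a) != length(b)) stop("length mismatch")
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) stop("cosine similarity undefined for a zero vector")
  min(1, max(0, sum(a * b) / (na * nb)))
}

.nnls <- function(S, m) {
  # Lawson-Hanson active-set NNLS
  pracma::lsqnonneg(as.matrix(S), as.numeric(m))$x
}

#' Fit non-negative signature exposures to a catalogue
#'
#' Solves `min || m - S e ||_2` subject to `e >= 0` on the raw count vector,
#' so exposures are mutation counts. With `sparsity = "bootstrap"`, the
#' catalogue is resampled `n_boot` times (multinomial over channels),
#' exposures are refit per replicate, and any signature whose 5th-percentile
#' bootstrap exposure falls below `max(min_mutations, min_prop * total)` is
#' zeroed before a final refit on the retained set.
#'
#' @param catalogue a `mutational_catalogue`.
#' @param signatures a `signature_matrix` on the same channel set.
#' @param sparsity `"none"` or `"bootstrap"`.
#' @param n_boot bootstrap replicates (default 100).
#' @param min_mutations,min_prop sparsity threshold components (defaults 10
#'   mutations, 1% of total).
#' @param seed optional seed for the bootstrap resampling.
#' @return list of class `exposure_set` with elements `sample_id`,
#'   `exposures` (named counts), `unassigned`, `total` and
#'   `reconstruction_cosine` (NA for an all-zero catalogue).
#' @export
fit_exposures <- function(catalogue, signatures,
                          sparsity = c("none", "bootstrap"),
                          n_boot = 100L, min_mutations = 10, min_prop = 0.01,
                          seed = NULL) {
  sparsity <- match.arg(sparsity)
  if (!identical(attr(catalogue, "channel_set"), attr(signatures, "channel_set"))) {
    stop("channel-set mismatch between catalogue and signatures")
  }
  if (ncol(signatures) < 1L) stop("need at least one signature")
  m <- as.numeric(catalogue)
  total <- sum(m)
  nms <- colnames(signatures)
  if (total == 0) {
    return(structure(list(sample_id = attr(catalogue, "sample_id"),
                          exposures = stats::setNames(numeric(length(nms)), nms),
                          unassigned = 0, total = 0,
                          reconstruction_cosine = NA_real_),
                     class = "exposure_set"))
  }
  e <- .nnls(signatures, m)
  if (sparsity == "bootstrap") {
    if (!is.null(seed)) set.seed(seed)
    p <- m / total
    boot <- matrix(0, nrow = n_boot, ncol = length(nms))
    for (b in seq_len(n_boot)) {
      mb <- as.numeric(stats::rmultinom(1, size = round(total), prob = p))
      boot[b, ] <- .nnls(signatures, mb)
    }
    q5 <- apply(boot, 2, stats::quantile, probs = 0.05, names = FALSE)
    thr <- max(min_mutations, min_prop * total)
    keep <- q5 >= thr
    if (!any(keep)) keep[which.max(q5)] <- TRUE
    e <- numeric(length(nms))
    e[keep] <- .nnls(signatures[, keep, drop = FALSE], m)
  }
  # exposures are counts: cap their sum at the catalogue total
  if (sum(e) > total) e <- e * (total / sum(e))
  fitted <- as.numeric(signatures %*% e)
  cosine <- if (sum(fitted) > 0) cosine_similarity(m, fitted) else NA_real_
  structure(list(sample_id = attr(catalogue, "sample_id"),
                 exposures = stats::setNames(e, nms),
                 unassigned = max(0, total - sum(e)),
                 total = total,
                 reconstruction_cosine = cosine),
            class = "exposure_set")
}

#' Subtract fitted signatures from a catalogue
#'
#' Residual counts are `round(m - sum_k e_k s_k)` over the chosen subset,
#' clamped at zero per channel; any clamped (negative) mass is recorded in
#' `attr(,"negative_mass")`.
#'
#' @param catalogue a `mutational_catalogue`.
#' @param exposures the `exposure_set` fitted to it.
#' @param signatures the `signature_matrix` used in the fit.
#' @param subset signature names to subtract (must all have been fitted).
#' @return residual `mutational_catalogue`.
#' @export
subtract_signatures <- function(catalogue, exposures, signatures, subset) {
  if (length(subset) == 0L) return(catalogue)
  unknown <- setdiff(subset, names(exposures$exposures))
  if (length(unknown) > 0L) stop("unknown signature name(s) in subset: ",
                                 paste(unknown, collapse = ", "))
  expected <- as.numeric(signatures[, subset, drop = FALSE] %*%
                           exposures$exposures[subset])
  resid <- round(as.numeric(catalogue) - expected)
  neg <- -sum(resid[resid < 0])
  resid <- pmax(resid, 0)
  out <- new_catalogue(attr(catalogue, "sample_id"),
                       attr(catalogue, "channel_set"), resid)
  attr(out, "negative_mass") <- neg
  out
}

#' Write exposure sets to TSV (samples x signatures + unassigned + cosine)
#'
#' @param exposure_sets list of `exposure_set` objects over the same
#'   signatures.
#' @param path output path.
#' @export
write_exposures_tsv <- function(exposure_sets, path) {
  if (inherits(exposure_sets, "exposure_set")) exposure_sets <- list(exposure_sets)
  nms <- names(exposure_sets[[1]]$exposures)
  df <- do.call(rbind, lapply(exposure_sets, function(e) {
    row <- as.data.frame(as.list(e$exposures[nms]), check.names = FALSE)
    cbind(data.frame(sample_id = e$sample_id, stringsAsFactors = FALSE), row,
          data.frame(unassigned = e$unassigned,
                     reconstruction_cosine = e$reconstruction_cosine))
  }))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
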