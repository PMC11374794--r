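.comp <- function(b) chartr("ACGT", "TGCA", b)

#' Generate a synthetic reference sequence
#'
#' Writes a random FASTA contig (`chrS`) with the requested GC content,
#' seeded with engineered homopolymer tracts (A/T, lengths 6-12) and
#' dinucleotide-repeat tracts (2-8 copies) at recorded positions, so that
#' long-homopolymer and long-repeat ID83 channels are populatable by the
#' variant simulator. Each tract is isolated by breaker bases so its run
#' length is exact.
#'
#' @param length contig length in bases (>= 10,000).
#' @param gc target GC fraction; the realised sequence is within ~0.01.
#' @param seed integer seed; the same seed yields a byte-identical FASTA.
#' @param path output FASTA path (a `.fai` index is written alongside).
#' @return list with `path`, `chrom`, `length`, `gc` (realised) and
#'   `tracts` (data.frame: kind, base, unit, len, copies, start).
#' @export
make_reference <- function(length, gc = 0.41, seed = 1L,
                           path = tempfile(fileext = ".fa")) {
  if (length < 10000) stop("reference length must be >= 10,000 bases")
  set.seed(seed)
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  chars <- sample(names(p), length, replace = TRUE, prob = p)

  # engineered tract templates
  homo <- expand.grid(base = c("A", "T"), len = 6:12,
                      stringsAsFactors = FALSE)
  homo <- homo[rep(seq_len(nrow(homo)), each = 60), ]
  homo$kind <- "homopolymer"; homo$unit <- homo$base; homo$copies <- homo$len
  di_units <- c("AC", "TG", "CA", "GT")
  di_copies <- c(rep(3, 40), rep(4, 300), rep(5, 300),
                 rep(6, 130), rep(7, 130), rep(8, 130))
  di <- data.frame(kind = "repeat",
                   base = NA_character_,
                   unit = di_units[(seq_along(di_copies) - 1L) %% 4L + 1L],
                   len = 2L, copies = di_copies,
                   stringsAsFactors = FALSE)
  homo$len <- as.integer(homo$len)
  tmpl <- rbind(homo[, c("kind", "base", "unit", "len", "copies")],
                di[, c("kind", "base", "unit", "len", "copies")])
  tmpl <- tmpl[sample.int(nrow(tmpl)), ]
  tract_nchar <- ifelse(tmpl$kind == "homopolymer", tmpl$len,
                        tmpl$len * tmpl$copies)
  spacing <- 400L
  n_fit <- max(1L, min(nrow(tmpl), floor((length - 200L) / spacing)))
  if (n_fit < nrow(tmpl)) {
    keep <- round(seq(1, nrow(tmpl), length.out = n_fit))
    tmpl <- tmpl[keep, , drop = FALSE]
    tract_nchar <- tract_nchar[keep]
  }
  starts <- 100L + (seq_len(nrow(tmpl)) - 1L) * spacing
  tmpl$start <- starts + 1L  # first tract base (after the 5' breaker)
  for (i in seq_len(nrow(tmpl))) {
    s <- starts[i]
    if (tmpl$kind[i] == "homopolymer") {
      b <- tmpl$unit[i]
      tr <- rep(b, tmpl$len[i])
      brk <- if (b %in% c("A", "T")) c("C", "G") else c("A", "T")
    } else {
      u <- strsplit(tmpl$unit[i], "", fixed = TRUE)[[1]]
      tr <- rep(u, tmpl$copies[i])
      others <- setdiff(c("A", "C", "G", "T"), u)
      brk <- c(others[1], others[2])  # != both unit bases on each side
    }
    span <- s:(s + length(tr) + 1L)
    if (max(span) > length) break
    chars[s] <- brk[1]
    chars[s + seq_along(tr)] <- tr
    chars[s + length(tr) + 1L] <- brk[2]
  }
  seq <- paste(chars, collapse = "")
  dss <- Biostrings::DNAStringSet(seq)
  names(dss) <- "chrS"
  Biostrings::writeXStringSet(dss, path, width = 70L)
  try(Rsamtools::indexFa(path), silent = TRUE)
  list(path = path, chrom = "chrS", length = length,
       gc = mean(chars %in% c("C", "G")), tracts = tmpl)
}

#' Deterministic TEST-ONLY signature profiles
#'
#' Returns a fixed, clearly synthetic signature set for pipeline testing:
#' three smooth "biological" profiles plus artefact stand-ins. The SBS96 set
#' carries `BIO_A/B/C`, an `SBS57` stand-in (T>G peaked) and an `SBS_FFPE`
#' stand-in peaked at the FFPE-associated channels (T>C at A[T>C]A, A[T>C]C,
#' C[T>C]T, T[T>C]T; C>T at A[C>T]A, A[C>T]T, T[C>T]T; >= 60% of mass). The
#' ID83 set carries `ID_BIO_A/B/C` and an `ID_FFPE` stand-in concentrated on
#' 1bp T insertions/deletions at long homopolymers, dinucleotide deletions at
#' long repeats, and long insertions at non-repeats. These are stand-ins for
#' testing only; real published profiles should be loaded from TSV with
#' [read_signature_tsv()].
#'
#' @param channel_set `"SBS96"` or `"ID83"`.
#' @return a `signature_matrix`.
#' @export
make_test_signatures <- function(channel_set = c("SBS96", "ID83")) {
  channel_set <- match.arg(channel_set)
  labels <- channel_labels(channel_set)
  if (channel_set == "SBS96") {
    sub_of <- sub("^.\\[([ACGT]>[ACGT])\\].$", "\\1", labels)
    w <- function(base) stats::setNames(rep(base, 96), labels)
    bio_a <- w(0.5); bio_a[sub_of == "C>A"] <- 3
    bio_b <- w(0.3); bio_b[sub_of == "C>T"] <- 1
    bio_b[grepl("^[ACGT]\\[C>T\\]G$", labels)] <- 5
    bio_c <- w(0.4); bio_c[sub_of == "T>A"] <- 2; bio_c[sub_of == "T>G"] <- 1.5
    sbs57 <- w(0)
    sbs57[c("A[T>G]A", "C[T>G]T", "T[T>G]T", "A[T>G]G")] <- 0.15
    sbs57[sub_of == "T>A"] <- 0.4 / 16
    ffpe <- w(0)
    tc_peaks <- c("A[T>C]A" = 0.12, "A[T>C]C" = 0.11, "C[T>C]T" = 0.11,
                  "T[T>C]T" = 0.12)
    ct_peaks <- c("A[C>T]A" = 0.08, "A[C>T]T" = 0.08, "T[C>T]T" = 0.08)
    ffpe[names(tc_peaks)] <- tc_peaks
    ffpe[names(ct_peaks)] <- ct_peaks
    rest <- setdiff(labels[sub_of %in% c("T>C", "C>T")],
                    c(names(tc_peaks), names(ct_peaks)))
    ffpe[rest] <- (1 - sum(tc_peaks) - sum(ct_peaks)) / length(rest)
    m <- cbind(BIO_A = bio_a, BIO_B = bio_b, BIO_C = bio_c,
               SBS57 = sbs57, SBS_FFPE = ffpe)
  } else {
    prof <- function(x) {
      v <- stats::setNames(numeric(83), labels)
      v[names(x)] <- x
      v
    }
    bio_a <- prof(c("1:Ins:T:0" = 0.10, "1:Ins:T:1" = 0.22, "1:Ins:T:2" = 0.18,
                    "1:Ins:C:0" = 0.15, "1:Ins:C:1" = 0.10,
                    "1:Del:T:1" = 0.10, "1:Del:C:1" = 0.15))
    bio_b <- prof(c("2:Del:M:1" = 0.18, "3:Del:M:1" = 0.20, "3:Del:M:2" = 0.12,
                    "4:Del:M:1" = 0.15, "4:Del:M:2" = 0.10, "4:Del:M:3" = 0.05,
                    "2:Del:R:1" = 0.10, "3:Del:R:1" = 0.10))
    bio_c <- prof(c("1:Del:C:1" = 0.20, "1:Del:C:2" = 0.18, "1:Del:C:3" = 0.12,
                    "1:Del:T:1" = 0.15, "1:Del:T:2" = 0.15, "1:Del:T:3" = 0.10,
                    "1:Ins:C:0" = 0.10))
    ffpe <- prof(c("1:Del:T:4" = 0.05, "1:Del:T:5" = 0.08, "1:Del:T:6+" = 0.20,
                   "1:Ins:T:4" = 0.07, "1:Ins:T:5+" = 0.20,
                   "2:Del:R:4" = 0.07, "2:Del:R:5" = 0.07, "2:Del:R:6+" = 0.08,
                   "5+:Ins:R:0" = 0.15, "4:Ins:R:0" = 0.03))
    m <- cbind(ID_BIO_A = bio_a, ID_BIO_B = bio_b, ID_BIO_C = bio_c,
               ID_FFPE = ffpe)
  }
  signature_matrix(m, channel_set)
}

# ---- simulation indexes ----------------------------------------------------

# positions grouped by pyrimidine-collapsed trinucleotide context
.sbs_context_index <- function(reference, chrom) {
  seq <- reference[[chrom]]
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  L <- length(chars)
  tri <- paste0(chars[1:(L - 2L)], chars[2:(L - 1L)], chars[3:L])
  all_tri <- apply(expand.grid(DNA_BASES, DNA_BASES, DNA_BASES,
                               stringsAsFactors = FALSE)[, 3:1], 1, paste,
                   collapse = "")
  mid <- substr(all_tri, 2, 2)
  collapsed <- ifelse(mid %in% c("C", "T"), all_tri, revcomp(all_tri))
  map <- stats::setNames(collapsed, all_tri)
  split(2:(L - 1L), map[tri])
}

.parse_id_channel <- function(channel) {
  parts <- strsplit(channel, ":", fixed = TRUE)[[1]]
  list(size = parts[1], type = parts[2], ctx = parts[3], cls = parts[4])
}

# candidate (pos, ref, alt) events for one ID83 channel, verified by
# classification; capped at pool_target
.channel_candidates <- function(reference, chrom, chars, runs, tracts,
                                channel, pool_target, probe_cap = 60000L) {
  ch <- .parse_id_channel(channel)
  L <- length(chars)
  margin <- 80L
  cand <- NULL
  if (ch$size == "1") {
    bases <- if (ch$ctx == "T") c("A", "T") else c("C", "G")
    if (ch$type == "Del") {
      need <- ch$cls
      sel <- runs$base %in% bases &
        (if (need == "6+") runs$len >= 6L else runs$len == as.integer(need))
    } else {
      need <- ch$cls
      sel <- runs$base %in% bases &
        (if (need == "5+") runs$len >= 5L else runs$len == as.integer(need))
    }
    if (ch$type == "Ins" && ch$cls == "0") {
      # insert b between two non-b bases
      b <- bases[1]
      ok <- which(chars[-L] != b & chars[-1] != b &
                    chars[-L] != .comp(b) & chars[-1] != .comp(b))
      ok <- ok[ok > margin & ok < L - margin]
      if (length(ok) > 0L) {
        take <- ok[sample.int(length(ok), min(length(ok), pool_target * 2L))]
        cand <- data.frame(pos = take, ref = chars[take],
                           alt = paste0(chars[take], b),
                           stringsAsFactors = FALSE)
      }
    } else {
      rr <- runs[sel & runs$start > margin &
                   runs$start + runs$len < L - margin, , drop = FALSE]
      if (nrow(rr) > pool_target * 2L) {
        rr <- rr[sample.int(nrow(rr), pool_target * 2L), , drop = FALSE]
      }
      if (nrow(rr) > 0L) {
        anchor <- rr$start - 1L
        if (ch$type == "Del") {
          cand <- data.frame(pos = anchor,
                             ref = paste0(chars[anchor], rr$base),
                             alt = chars[anchor], stringsAsFactors = FALSE)
        } else {
          cand <- data.frame(pos = anchor, ref = chars[anchor],
                             alt = paste0(chars[anchor], rr$base),
                             stringsAsFactors = FALSE)
        }
      }
    }
  } else if (ch$ctx == "R" && ch$size %in% c("2") &&
             !(ch$type == "Del" && ch$cls == "1") &&
             !(ch$type == "Ins" && ch$cls == "0")) {
    tr <- tracts[tracts$kind == "repeat" & tracts$len == 2L, , drop = FALSE]
    if (ch$type == "Del") {
      sel <- if (ch$cls == "6+") tr$copies >= 6L else tr$copies == as.integer(ch$cls)
    } else {
      sel <- if (ch$cls == "5+") tr$copies >= 5L else tr$copies == as.integer(ch$cls)
    }
    tr <- tr[sel, , drop = FALSE]
    if (nrow(tr) > 0L) {
      anchor <- tr$start - 1L
      if (ch$type == "Del") {
        cand <- data.frame(pos = anchor, ref = paste0(chars[anchor], tr$unit),
                           alt = chars[anchor], stringsAsFactors = FALSE)
      } else {
        cand <- data.frame(pos = anchor, ref = chars[anchor],
                           alt = paste0(chars[anchor], tr$unit),
                           stringsAsFactors = FALSE)
      }
    }
  } else {
    # probed channels: microhomology / no-repeat deletions, non-repeat
    # insertions, and any repeat class without an engineered tract
    probed <- TRUE
    n <- switch(ch$size, "2" = 2L, "3" = 3L, "4" = 4L, "5+" = 6L)
    got <- list(); n_got <- 0L; tried <- 0L
    while (n_got < pool_target && tried < probe_cap) {
      batch <- 2000L
      tried <- tried + batch
      pos <- sample.int(L - 2L * margin, batch) + margin
      for (p in pos) {
        if (n_got >= pool_target) break
        if (ch$type == "Del") {
          ref <- paste0(chars[p - 1L],
                        substr(reference[[chrom]], p, p + n - 1L))
          alt <- chars[p - 1L]
          ev_pos <- p - 1L
        } else {
          unit <- paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
          ref <- chars[p]
          alt <- paste0(ref, unit)
          ev_pos <- p
        }
        lab <- tryCatch(classify_indel_at(reference, chrom, ev_pos, ref, alt),
                        error = function(e) NA_character_)
        if (identical(lab, channel)) {
          n_got <- n_got + 1L
          got[[n_got]] <- c(ev_pos, ref, alt)
        }
      }
    }
    if (n_got > 0L) {
      m <- do.call(rbind, got)
      cand <- data.frame(pos = as.integer(m[, 1]), ref = m[, 2], alt = m[, 3],
                         stringsAsFactors = FALSE)
    }
  }
  if (is.null(cand) || nrow(cand) == 0L) {
    return(data.frame(pos = integer(0), ref = character(0),
                      alt = character(0), stringsAsFactors = FALSE))
  }
  if (exists("probed", inherits = FALSE)) {
    # probe loop already classified each candidate
    cand <- cand[!duplicated(paste(cand$pos, cand$ref, cand$alt)), , drop = FALSE]
    if (nrow(cand) > pool_target) cand <- cand[seq_len(pool_target), , drop = FALSE]
    return(cand)
  }
  # verify every candidate by classification; left-align is part of the check
  keep <- vapply(seq_len(nrow(cand)), function(i) {
    lab <- tryCatch(classify_indel_at(reference, chrom, cand$pos[i],
                                      cand$ref[i], cand$alt[i]),
                    error = function(e) NA_character_)
    identical(lab, channel)
  }, logical(1))
  cand <- cand[keep, , drop = FALSE]
  cand <- cand[!duplicated(paste(cand$pos, cand$ref, cand$alt)), , drop = FALSE]
  if (nrow(cand) > pool_target) cand <- cand[seq_len(pool_target), , drop = FALSE]
  cand
}

#' Precompute simulation indexes for a synthetic reference
#'
#' Builds the trinucleotide-context position index (for substitution
#' placement) and verified per-channel indel candidate pools (for indel
#' placement) once per reference, for reuse across simulated samples.
#'
#' @param ref_info list returned by [make_reference()].
#' @param id_signatures ID83 `signature_matrix` whose supported channels need
#'   candidate pools.
#' @param pool_target maximum candidates per channel (default 900).
#' @param seed seed for candidate subsampling/probing.
#' @return list with `reference` (accessor), `chrom`, `ctx_index`, `pools`.
#' @export
prepare_simulation_indexes <- function(ref_info, id_signatures,
                                       pool_target = 900L, seed = 1L) {
  reference <- load_reference(ref_info$path)
  chrom <- ref_info$chrom
  set.seed(seed)
  ctx_index <- .sbs_context_index(reference, chrom)
  chars <- strsplit(reference[[chrom]], "", fixed = TRUE)[[1]]
  r <- rle(chars)
  ends <- cumsum(r$lengths)
  runs <- data.frame(base = r$values, len = r$lengths,
                     start = ends - r$lengths + 1L, stringsAsFactors = FALSE)
  needed <- rownames(id_signatures)[rowSums(id_signatures > 0) > 0]
  pools <- lapply(needed, function(chnl) {
    .channel_candidates(reference, chrom, chars, runs, ref_info$tracts,
                        chnl, pool_target)
  })
  names(pools) <- needed
  list(reference = reference, chrom = chrom, ctx_index = ctx_index,
       pools = pools)
}

# ---- VAF models ------------------------------------------------------------

#' Simulate clonal heterozygous VAFs
#'
#' Read depths are binomial around the mean coverage; alternate read counts
#' are binomial with success probability `purity / 2` (clonal heterozygous
#' diploid), truncated to at least one supporting read.
#'
#' @param n number of variants.
#' @param purity cancer cell content in (0, 1].
#' @param depth mean coverage (default 90).
#' @return data.frame with `depth`, `alt_reads`, `vaf`.
#' @export
simulate_clonal_vafs <- function(n, purity, depth = 90) {
  dp <- pmax(1L, stats::rbinom(n, 2L * depth, 0.5))
  p <- purity / 2
  alt <- stats::rbinom(n, dp, p)
  redo <- which(alt < 1L)
  while (length(redo) > 0L) {
    alt[redo] <- stats::rbinom(length(redo), dp[redo], p)
    redo <- redo[alt[redo] < 1L]
  }
  data.frame(depth = dp, alt_reads = alt, vaf = alt / dp)
}

#' Simulate low-VAF artefact variant VAFs
#'
#' Per-variant success probabilities are normal around `mean` (default 0.08,
#' s.d. 0.03), truncated to be positive; alternate read counts are binomial
#' and truncated to at least one supporting read. This reproduces the
#' characteristic low-VAF artefact peak without asserting a damage mechanism.
#'
#' @param n number of variants.
#' @param depth mean coverage (default 90).
#' @param mean,sd parameters of the success-probability distribution.
#' @return data.frame with `depth`, `alt_reads`, `vaf`.
#' @export
simulate_artefact_vafs <- function(n, depth = 90, mean = 0.08, sd = 0.03) {
  dp <- pmax(1L, stats::rbinom(n, 2L * depth, 0.5))
  draw_p <- function(k) {
    p <- stats::rnorm(k, mean, sd)
    while (any(p <= 0)) p[p <= 0] <- stats::rnorm(sum(p <= 0), mean, sd)
    pmin(p, 1)
  }
  p <- draw_p(n)
  alt <- stats::rbinom(n, dp, p)
  redo <- which(alt < 1L)
  while (length(redo) > 0L) {
    alt[redo] <- stats::rbinom(length(redo), dp[redo], p[redo])
    redo <- redo[alt[redo] < 1L]
  }
  data.frame(depth = dp, alt_reads = alt, vaf = alt / dp)
}

# ---- per-sample simulation -------------------------------------------------

#' Simulate one sample's somatic variants
#'
#' Channel-first simulation: mutation counts are allocated to signatures
#' (multinomial over the mixture), channels are drawn from each signature's
#' profile, and each mutation is realised as a concrete (pos, ref, alt) at a
#' reference position whose context yields exactly that channel, without
#' positional collisions. VAFs follow the clonal model for biological
#' signatures and the low-VAF artefact model for artefact signatures.
#' Rebuilding catalogues from the emitted VCF reproduces the drawn
#' per-channel counts exactly.
#'
#' @param sample_id sample name.
#' @param preparation `"FF"`, `"FF_PCR"` or `"FFPE"`.
#' @param purity cancer cell content.
#' @param n_sbs,n_id substitution and indel mutation counts.
#' @param sbs_mixture,id_mixture named signature weights (each sums to 1).
#' @param sbs_signatures,id_signatures `signature_matrix` objects covering
#'   the mixture names.
#' @param indexes output of [prepare_simulation_indexes()].
#' @param artefact_names signatures whose mutations follow the artefact VAF
#'   model.
#' @param depth mean coverage.
#' @param artefact_vaf_mean,artefact_vaf_sd artefact VAF model parameters.
#' @param seed integer seed (full determinism).
#' @param vcf_path optional path; when given, a VCF 4.2 file is written.
#' @return list with `variants` (a `variant_table`), `truth` (one-row
#'   data.frame with per-signature counts, totals and the true artefact
#'   fraction) and `channel_counts` (list of drawn SBS96/ID83 count vectors).
#' @export
simulate_sample <- function(sample_id, preparation, purity, n_sbs, n_id,
                            sbs_mixture, id_mixture,
                            sbs_signatures, id_signatures, indexes,
                            artefact_names = default_artefact_signatures(),
                            depth = 90, artefact_vaf_mean = 0.08,
                            artefact_vaf_sd = 0.03, seed = 1L,
                            vcf_path = NULL) {
  set.seed(seed)
  chrom <- indexes$chrom
  reference <- indexes$reference
  L <- .contig_length(reference, chrom)
  used <- logical(L)

  draw_counts <- function(n, mixture, signatures) {
    if (n == 0L) {
      return(list(sig = stats::setNames(integer(length(mixture)), names(mixture)),
                  by_sig = list()))
    }
    if (abs(sum(mixture) - 1) > 1e-6) stop("mixture weights must sum to 1")
    missing <- setdiff(names(mixture), colnames(signatures))
    if (length(missing) > 0L) stop("mixture names absent from signatures: ",
                                   paste(missing, collapse = ", "))
    sig_n <- as.integer(stats::rmultinom(1, n, mixture))
    names(sig_n) <- names(mixture)
    by_sig <- lapply(names(mixture), function(s) {
      if (sig_n[s] == 0L) return(NULL)
      as.integer(stats::rmultinom(1, sig_n[s], signatures[, s]))
    })
    names(by_sig) <- names(mixture)
    list(sig = sig_n, by_sig = by_sig)
  }

  sbs_draw <- draw_counts(n_sbs, sbs_mixture, sbs_signatures)
  id_draw <- draw_counts(n_id, id_mixture, id_signatures)

  rows <- list()
  sbs_labels <- rownames(sbs_signatures)
  for (s in names(sbs_draw$by_sig)) {
    cnt <- sbs_draw$by_sig[[s]]
    if (is.null(cnt)) next
    for (ci in which(cnt > 0L)) {
      lab <- sbs_labels[ci]
      k <- cnt[ci]
      ctx <- paste0(substr(lab, 1, 1), substr(lab, 3, 3), substr(lab, 7, 7))
      avail <- indexes$ctx_index[[ctx]]
      avail <- avail[!used[avail]]
      if (length(avail) < k) {
        stop("unsatisfiable SBS channel ", lab, ": need ", k,
             " positions, only ", length(avail), " available")
      }
      pos <- avail[sample.int(length(avail), k)]
      used[pos] <- TRUE
      mid <- vapply(pos, function(p) substr(reference[[chrom]], p, p),
                    character(1))
      ch_ref <- substr(lab, 3, 3); ch_alt <- substr(lab, 5, 5)
      alt <- ifelse(mid == ch_ref, ch_alt, .comp(ch_alt))
      rows[[length(rows) + 1L]] <- data.frame(
        pos = pos, ref = mid, alt = alt, signature = s,
        stringsAsFactors = FALSE)
    }
  }
  id_labels <- rownames(id_signatures)
  for (s in names(id_draw$by_sig)) {
    cnt <- id_draw$by_sig[[s]]
    if (is.null(cnt)) next
    for (ci in which(cnt > 0L)) {
      lab <- id_labels[ci]
      k <- cnt[ci]
      pool <- indexes$pools[[lab]]
      if (is.null(pool)) stop("no candidate pool for ID channel ", lab)
      free <- which(!used[pool$pos])
      if (length(free) < k) {
        stop("unsatisfiable ID channel ", lab, ": need ", k,
             " events, only ", length(free), " candidates available")
      }
      take <- free[sample.int(length(free), k)]
      used[pool$pos[take]] <- TRUE
      rows[[length(rows) + 1L]] <- data.frame(
        pos = pool$pos[take], ref = pool$ref[take], alt = pool$alt[take],
        signature = s, stringsAsFactors = FALSE)
    }
  }
  ev <- if (length(rows) > 0L) do.call(rbind, rows) else
    data.frame(pos = integer(0), ref = character(0), alt = character(0),
               signature = character(0), stringsAsFactors = FALSE)
  is_art <- ev$signature %in% artefact_names
  n_art <- sum(is_art); n_bio <- sum(!is_art)
  vaf_bio <- simulate_clonal_vafs(n_bio, purity, depth)
  vaf_art <- simulate_artefact_vafs(n_art, depth, artefact_vaf_mean,
                                    artefact_vaf_sd)
  ev$depth <- NA_real_; ev$vaf <- NA_real_
  ev$depth[!is_art] <- vaf_bio$depth; ev$vaf[!is_art] <- vaf_bio$vaf
  ev$depth[is_art] <- vaf_art$depth; ev$vaf[is_art] <- vaf_art$vaf

  variants <- variant_table(sample_id, chrom, ev$pos, ev$ref, ev$alt,
                            ev$vaf, ev$depth)
  variants$signature <- ev$signature
  if (!is.null(vcf_path)) {
    contigs <- stats::setNames(L, chrom)
    write_vcf(variants, vcf_path, contigs = contigs)
  }
  sbs_art <- sum(sbs_draw$sig[intersect(names(sbs_draw$sig), artefact_names)])
  id_art <- sum(id_draw$sig[intersect(names(id_draw$sig), artefact_names)])
  truth <- data.frame(sample_id = sample_id, preparation = preparation,
                      purity = purity, sbs_total = n_sbs, id_total = n_id,
                      sbs_artefact = sbs_art, id_artefact = id_art,
                      artefact_fraction =
                        if (n_sbs + n_id > 0) (sbs_art + id_art) / (n_sbs + n_id)
                        else 0,
                      stringsAsFactors = FALSE)
  for (s in names(sbs_draw$sig)) truth[[paste0("sbs_", s)]] <- sbs_draw$sig[s]
  for (s in names(id_draw$sig)) truth[[paste0("id_", s)]] <- id_draw$sig[s]

  sbs_counts <- stats::setNames(numeric(96), sbs_labels)
  for (cnts in sbs_draw$by_sig) if (!is.null(cnts)) sbs_counts <- sbs_counts + cnts
  id_counts <- stats::setNames(numeric(83), id_labels)
  for (cnts in id_draw$by_sig) if (!is.null(cnts)) id_counts <- id_counts + cnts
  list(variants = variants, truth = truth,
       channel_counts = list(SBS96 = sbs_counts, ID83 = id_counts))
}

# ---- cohort ----------------------------------------------------------------

#' Specification of a synthetic cohort
#'
#' Default values define the package's standard synthetic cohort, emulating
#' the statistical structure of FF / FF(PCR) / FFPE whole-genome cohorts:
#' clonal heterozygous variants peaking at nVAF 0.5, low-VAF artefact
#' variants peaking near nVAF 0.1, indel burdens inflated by an order of
#' magnitude in PCR-exposed preparations, and mutation spectra drawn from
#' mixtures of biological and artefact signature profiles.
#'
#' @param n_samples cohort size (default 50).
#' @param prep_mix preparation fractions (FF, FF_PCR, FFPE).
#' @param sbs_burden lognormal (meanlog, sdlog) of substitution burden.
#' @param id_burden lognormal (meanlog, sdlog) of the baseline indel burden.
#' @param ffpe_indel_inflation indel burden multiplier for FF_PCR/FFPE
#'   preparations (default 10).
#' @param sbs_mixtures,id_mixtures per-preparation named signature weights.
#'   The `SBS_FFPE` entry of the FFPE mixture is treated as a base weight:
#'   the signature is idiosyncratic, carried only by a `sbs_ffpe_prevalence`
#'   fraction of FFPE samples, in which it takes a per-sample weight drawn
#'   from `sbs_ffpe_weight` and the remaining weights are rescaled.
#' @param sbs_ffpe_prevalence fraction of FFPE samples carrying SBS_FFPE
#'   (default 0.2).
#' @param sbs_ffpe_weight range of the per-sample SBS_FFPE mixture weight in
#'   carriers, where it dominates the substitution landscape (default
#'   0.45-0.7).
#' @param hypermutator_boost range of the substitution-burden multiplier for
#'   SBS_FFPE carriers, which present as hypermutators (default 3-6).
#' @param purity_beta shape parameters of the purity distribution.
#' @param depth mean coverage (default 90).
#' @param artefact_vaf_mean,artefact_vaf_sd artefact VAF model parameters.
#' @param reference_length,gc synthetic reference parameters.
#' @param seed integer master seed.
#' @return list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_samples = 50L,
                        prep_mix = c(FF = 0.4, FF_PCR = 0.1, FFPE = 0.5),
                        sbs_burden = c(meanlog = log(1500), sdlog = 0.35),
                        id_burden = c(meanlog = log(150), sdlog = 0.35),
                        ffpe_indel_inflation = 10,
                        sbs_mixtures = list(
                          FF = c(BIO_A = 0.45, BIO_B = 0.35, BIO_C = 0.20),
                          FF_PCR = c(BIO_A = 0.43, BIO_B = 0.33, BIO_C = 0.19,
                                     SBS57 = 0.05),
                          FFPE = c(BIO_A = 0.35, BIO_B = 0.30, BIO_C = 0.17,
                                   SBS57 = 0.10, SBS_FFPE = 0.08)),
                        id_mixtures = list(
                          FF = c(ID_BIO_A = 0.40, ID_BIO_B = 0.30,
                                 ID_BIO_C = 0.30),
                          FF_PCR = c(ID_BIO_A = 0.06, ID_BIO_B = 0.05,
                                     ID_BIO_C = 0.04, ID_FFPE = 0.85),
                          FFPE = c(ID_BIO_A = 0.06, ID_BIO_B = 0.05,
                                   ID_BIO_C = 0.04, ID_FFPE = 0.85)),
                        sbs_ffpe_prevalence = 0.2,
                        sbs_ffpe_weight = c(0.45, 0.7),
                        hypermutator_boost = c(3, 6),
                        purity_beta = c(6, 4),
                        depth = 90,
                        artefact_vaf_mean = 0.08, artefact_vaf_sd = 0.03,
                        reference_length = 8e5, gc = 0.41,
                        seed = 1L) {
  spec <- list(n_samples = as.integer(n_samples), prep_mix = prep_mix,
               sbs_burden = sbs_burden, id_burden = id_burden,
               ffpe_indel_inflation = ffpe_indel_inflation,
               sbs_mixtures = sbs_mixtures, id_mixtures = id_mixtures,
               sbs_ffpe_prevalence = sbs_ffpe_prevalence,
               sbs_ffpe_weight = sbs_ffpe_weight,
               hypermutator_boost = hypermutator_boost,
               purity_beta = purity_beta, depth = depth,
               artefact_vaf_mean = artefact_vaf_mean,
               artefact_vaf_sd = artefact_vaf_sd,
               reference_length = reference_length, gc = gc,
               seed = as.integer(seed))
  for (p in names(spec$sbs_mixtures)) {
    if (abs(sum(spec$sbs_mixtures[[p]]) - 1) > 1e-6 ||
        abs(sum(spec$id_mixtures[[p]]) - 1) > 1e-6) {
      stop("mixture weights for ", p, " must sum to 1")
    }
  }
  art <- default_artefact_signatures()
  if (any(art %in% names(spec$sbs_mixtures$FF)) ||
      any(art %in% names(spec$id_mixtures$FF))) {
    stop("FF mixtures must not contain artefact signatures")
  }
  class(spec) <- "cohort_spec"
  spec
}

#' Simulate a full synthetic cohort
#'
#' Generates the reference, per-sample VCFs, a sample-metadata TSV and a
#' truth TSV under `dir`. Fully deterministic: the same spec and seed yield
#' byte-identical outputs.
#'
#' @param spec a [cohort_spec()].
#' @param dir output directory (created if needed).
#' @return list with `dir`, `ref_info`, `indexes`, `signatures` (list of the
#'   SBS96/ID83 test matrices), `meta`, `truth`, `vcfs` (named paths).
#' @export
simulate_cohort <- function(spec, dir) {
  stopifnot(inherits(spec, "cohort_spec"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sbs_sigs <- make_test_signatures("SBS96")
  id_sigs <- make_test_signatures("ID83")
  ref_info <- make_reference(spec$reference_length, spec$gc,
                             seed = spec$seed,
                             path = file.path(dir, "reference.fa"))
  indexes <- prepare_simulation_indexes(ref_info, id_sigs, seed = spec$seed)

  set.seed(spec$seed)
  n <- spec$n_samples
  n_per <- round(spec$prep_mix * n)
  while (sum(n_per) > n) n_per[which.max(n_per)] <- n_per[which.max(n_per)] - 1L
  while (sum(n_per) < n) n_per[which.min(n_per)] <- n_per[which.min(n_per)] + 1L
  preparation <- rep(names(n_per), n_per)
  sample_ids <- sprintf("%s_%02d", preparation, seq_len(n))
  purity <- pmin(0.99, pmax(0.1, stats::rbeta(n, spec$purity_beta[1],
                                              spec$purity_beta[2])))
  n_sbs <- pmax(1L, round(stats::rlnorm(n, spec$sbs_burden["meanlog"],
                                        spec$sbs_burden["sdlog"])))
  n_id_base <- pmax(1L, round(stats::rlnorm(n, spec$id_burden["meanlog"],
                                            spec$id_burden["sdlog"])))
  inflate <- ifelse(preparation %in% c("FF_PCR", "FFPE"),
                    spec$ffpe_indel_inflation, 1)
  n_id <- pmax(1L, round(n_id_base * inflate))
  # SBS_FFPE is idiosyncratic: carried by a subset of FFPE samples, where it
  # dominates and inflates the substitution burden (hypermutator phenotype)
  carries_ffpe <- preparation == "FFPE" &
    stats::runif(n) < spec$sbs_ffpe_prevalence
  ffpe_w <- stats::runif(n, spec$sbs_ffpe_weight[1], spec$sbs_ffpe_weight[2])
  boost <- stats::runif(n, spec$hypermutator_boost[1],
                        spec$hypermutator_boost[2])
  n_sbs[carries_ffpe] <- round(n_sbs[carries_ffpe] * boost[carries_ffpe])
  sample_seeds <- sample.int(.Machine$integer.max - 1L, n)

  sbs_mix_for <- function(i) {
    prep <- preparation[i]
    base <- spec$sbs_mixtures[[prep]]
    if (!"SBS_FFPE" %in% names(base)) return(base)
    rest <- base[setdiff(names(base), "SBS_FFPE")]
    rest <- rest / sum(rest)
    if (!carries_ffpe[i]) return(rest)
    c(rest * (1 - ffpe_w[i]), SBS_FFPE = unname(ffpe_w[i]))
  }

  truth <- list(); vcfs <- character(n)
  for (i in seq_len(n)) {
    prep <- preparation[i]
    vcfs[i] <- file.path(dir, paste0(sample_ids[i], ".vcf"))
    sim <- simulate_sample(sample_ids[i], prep, purity[i], n_sbs[i], n_id[i],
                           sbs_mix_for(i), spec$id_mixtures[[prep]],
                           sbs_sigs, id_sigs, indexes,
                           depth = spec$depth,
                           artefact_vaf_mean = spec$artefact_vaf_mean,
                           artefact_vaf_sd = spec$artefact_vaf_sd,
                           seed = sample_seeds[i], vcf_path = vcfs[i])
    truth[[i]] <- sim$truth
  }
  all_cols <- unique(unlist(lapply(truth, names)))
  truth <- do.call(rbind, lapply(truth, function(df) {
    for (cc in setdiff(all_cols, names(df))) df[[cc]] <- 0
    df[, all_cols, drop = FALSE]
  }))
  meta <- data.frame(sample_id = sample_ids, purity = purity,
                     preparation = preparation, stringsAsFactors = FALSE)
  utils::write.table(meta, file.path(dir, "meta.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_signature_tsv(sbs_sigs, file.path(dir, "signatures_sbs96.tsv"))
  write_signature_tsv(id_sigs, file.path(dir, "signatures_id83.tsv"))
  names(vcfs) <- sample_ids
  list(dir = dir, ref_info = ref_info, indexes = indexes,
       signatures = list(SBS96 = sbs_sigs, ID83 = id_sigs),
       meta = meta, truth = truth, vcfs = vcfs)
}
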