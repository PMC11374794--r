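#' Classify a single-base substitution into its SBS96 channel
#'
#' Substitutions are collapsed onto the pyrimidine strand: if the reference
#' base is a purine, the alternate allele and the trinucleotide context are
#' reverse-complemented before lookup, so the central base of the returned
#' channel is always C or T.
#'
#' @param ref,alt single reference/alternate bases.
#' @param context reference trinucleotide centred on the variant position;
#'   its middle base must equal `ref`.
#' @return channel label, e.g. `"A[C>T]A"`.
#' @export
classify_sbs <- function(ref, alt, context) {
  if (nchar(ref) != 1L || nchar(alt) != 1L) stop("classify_sbs expects an SNV")
  if (nchar(context) != 3L) stop("context must be a trinucleotide")
  context <- toupper(context); ref <- toupper(ref); alt <- toupper(alt)
  if (substr(context, 2, 2) != ref) {
    stop("reference mismatch: context '", context, "' middle base != ref '",
         ref, "' (wrong genome build?)")
  }
  if (ref %in% c("A", "G")) {
    context <- revcomp(context)
    ref <- substr(context, 2, 2)
    alt <- revcomp(alt)
  }
  paste0(substr(context, 1, 1), "[", ref, ">", alt, "]", substr(context, 3, 3))
}

# longest prefix of `s` that matches the start of `x`
.prefix_match <- function(s, x) {
  n <- min(nchar(s), nchar(x))
  k <- 0L
  while (k < n && substr(s, k + 1L, k + 1L) == substr(x, k + 1L, k + 1L)) {
    k <- k + 1L
  }
  k
}

# number of complete copies of `unit` at the start of `x`
.count_copies <- function(unit, x) {
  n <- nchar(unit); k <- 0L
  while (nchar(x) >= n && substr(x, 1L, n) == unit) {
    k <- k + 1L
    x <- substr(x, n + 1L, nchar(x))
  }
  k
}

# run length of base b at the start of x
.run_len <- function(b, x) {
  k <- 0L
  while (k < nchar(x) && substr(x, k + 1L, k + 1L) == b) k <- k + 1L
  k
}

.size_class <- function(n) if (n >= 5L) "5+" else as.character(n)

#' Classify an insertion or deletion into its ID83 channel
#'
#' Implements the 83-channel COSMIC-style scheme. The event must be
#' left-aligned (see [left_align_indel()]); `flank5`/`flank3` are reference
#' sequence immediately 5'/3' of the inserted/deleted bases and must each be
#' at least 6 times the indel length.
#'
#' Conventions: 1bp events in A/G are complement-collapsed onto the T/C
#' channels; the homopolymer length for 1bp deletions counts the deleted base
#' plus identical adjacent bases on both sides, for insertions the existing
#' identical adjacent bases only. For >=2bp events the repeat unit count is
#' the number of complete copies of the indel sequence adjacent in the
#' reference (deletions count the deleted copy itself); microhomology is only
#' assigned to deletions with no adjacent full copy.
#'
#' @param ref,alt VCF-style anchored alleles (one a strict prefix of the
#'   other), or a 1-row `variant_table`.
#' @param flank5,flank3 flanking reference sequence.
#' @return channel label, e.g. `"1:Del:T:6+"`.
#' @export
classify_indel <- function(ref, alt, flank5, flank3) {
  if (is.data.frame(ref)) {
    v <- ref
    if (nrow(v) != 1L) stop("classify_indel expects a single variant")
    alt <- v$alt; ref <- v$ref
  }
  ref <- toupper(ref); alt <- toupper(alt)
  cls <- classify_var_class(ref, alt)
  if (!cls %in% c("INS", "DEL")) stop("classify_indel expects INS or DEL, got ", cls)
  seq <- if (cls == "INS") substr(alt, nchar(ref) + 1L, nchar(alt))
         else substr(ref, nchar(alt) + 1L, nchar(ref))
  n <- nchar(seq)
  flank5 <- toupper(flank5); flank3 <- toupper(flank3)
  if (nchar(flank5) < 6L * n || nchar(flank3) < 6L * n) {
    stop("flanks shorter than required: need >= ", 6L * n,
         " bases each side for a ", n, "bp indel")
  }
  rev5 <- paste(rev(strsplit(flank5, "", fixed = TRUE)[[1]]), collapse = "")

  if (n == 1L) {
    b <- seq
    cb <- if (b %in% c("A", "T")) "T" else "C"
    adj <- .run_len(b, rev5) + .run_len(b, flank3)
    if (cls == "DEL") {
      len <- adj + 1L
      label_len <- if (len >= 6L) "6+" else as.character(len)
      return(paste0("1:Del:", cb, ":", label_len))
    } else {
      label_len <- if (adj >= 5L) "5+" else as.character(adj)
      return(paste0("1:Ins:", cb, ":", label_len))
    }
  }

  size <- .size_class(n)
  rev_seq <- paste(rev(strsplit(seq, "", fixed = TRUE)[[1]]), collapse = "")
  copies <- .count_copies(seq, flank3) + .count_copies(rev_seq, rev5)
  if (cls == "INS") {
    label_cnt <- if (copies >= 5L) "5+" else as.character(copies)
    return(paste0(size, ":Ins:R:", label_cnt))
  }
  units <- copies + 1L
  if (units >= 2L) {
    label_cnt <- if (units >= 6L) "6+" else as.character(units)
    return(paste0(size, ":Del:R:", label_cnt))
  }
  mh <- max(.prefix_match(seq, flank3), .prefix_match(rev_seq, rev5))
  if (mh >= 1L) {
    mh_label <- if (n >= 5L && mh >= 5L) "5+" else as.character(min(mh, n - 1L))
    return(paste0(size, ":Del:M:", mh_label))
  }
  paste0(size, ":Del:R:1")
}

#' Left-align an indel against the reference
#'
#' Shifts a VCF-style anchored insertion/deletion to its leftmost equivalent
#' representation, so channel assignment is invariant to how the caller
#' emitted the event.
#'
#' @param chrom,pos,ref,alt one anchored indel record.
#' @param reference a `reference_sequence`.
#' @return list with elements `pos`, `ref`, `alt`.
#' @export
left_align_indel <- function(chrom, pos, ref, alt, reference) {
  cls <- classify_var_class(ref, alt)
  if (!cls %in% c("INS", "DEL")) stop("left_align_indel expects INS or DEL")
  short <- if (cls == "INS") ref else alt
  seq <- if (cls == "INS") substr(alt, nchar(ref) + 1L, nchar(alt))
         else substr(ref, nchar(alt) + 1L, nchar(ref))
  # pos points at the anchor base; shift while the anchor base equals the
  # last base of the indel sequence
  while (pos > 1L) {
    anchor <- read_reference_window(reference, chrom, pos, pos)
    if (anchor != substr(seq, nchar(seq), nchar(seq))) break
    seq <- paste0(anchor, substr(seq, 1L, nchar(seq) - 1L))
    pos <- pos - 1L
  }
  anchor <- read_reference_window(reference, chrom, pos, pos)
  if (cls == "INS") {
    list(pos = pos, ref = anchor, alt = paste0(anchor, seq))
  } else {
    list(pos = pos, ref = paste0(anchor, seq), alt = anchor)
  }
}

#' Classify an anchored indel record against the reference
#'
#' Convenience wrapper: left-aligns the event, extracts flanks of 6x the
#' indel length from the reference and calls [classify_indel()].
#'
#' @param reference a `reference_sequence`.
#' @param chrom,pos,ref,alt one anchored INS/DEL record.
#' @return ID83 channel label.
#' @export
classify_indel_at <- function(reference, chrom, pos, ref, alt) {
  la <- left_align_indel(chrom, pos, ref, alt, reference)
  n <- abs(nchar(la$ref) - nchar(la$alt))
  w <- 6L * n
  ev_start <- la$pos + 1L
  ev_end <- la$pos + nchar(la$ref) - 1L
  clen <- .contig_length(reference, chrom)
  f5_start <- max(1L, ev_start - w)
  flank5 <- read_reference_window(reference, chrom, f5_start, ev_start - 1L)
  flank3 <- if (ev_end + 1L > clen) "" else
    read_reference_window(reference, chrom, ev_end + 1L, min(clen, ev_end + w))
  classify_indel(la$ref, la$alt, flank5, flank3)
}

#' Construct an empty mutational catalogue
#'
#' @param sample_id sample identifier.
#' @param channel_set `"SBS96"` or `"ID83"`.
#' @param counts optional named or canonical-order count vector.
#' @return named integer vector of class `mutational_catalogue` with
#'   attributes `sample_id` and `channel_set`.
#' @export
new_catalogue <- function(sample_id, channel_set = c("SBS96", "ID83"),
                          counts = NULL) {
  channel_set <- match.arg(channel_set)
  labels <- channel_labels(channel_set)
  x <- stats::setNames(numeric(length(labels)), labels)
  if (!is.null(counts)) {
    if (!is.null(names(counts))) {
      if (!all(names(counts) %in% labels)) {
        stop("unknown channel label(s): ",
             paste(setdiff(names(counts), labels), collapse = ", "))
      }
      x[names(counts)] <- counts
    } else {
      if (length(counts) != length(labels)) stop("counts length mismatch")
      x[] <- counts
    }
  }
  if (any(x < 0)) stop("catalogue counts must be non-negative")
  structure(x, sample_id = sample_id, channel_set = channel_set,
            class = "mutational_catalogue")
}

#' Build a per-sample mutational catalogue from variants
#'
#' Substitutions are classified via their reference trinucleotide context
#' into SBS96 channels; insertions/deletions are left-aligned and classified
#' into ID83 channels. Variants of the other class (and `OTHER`-class
#' events) are excluded and tallied in `attr(,"n_excluded")`, so that
#' `sum(catalogue) + n_excluded == nrow(variants)`.
#'
#' @param variants a `variant_table` for one sample.
#' @param reference a `reference_sequence`.
#' @param channel_set `"SBS96"` or `"ID83"`.
#' @return a `mutational_catalogue`.
#' @export
build_catalogue <- function(variants, reference,
                            channel_set = c("SBS96", "ID83")) {
  channel_set <- match.arg(channel_set)
  sid <- unique(variants$sample_id)
  if (length(sid) > 1L) stop("variants must belong to one sample")
  if (length(sid) == 0L) sid <- NA_character_
  cat <- new_catalogue(sid, channel_set)
  if (nrow(variants) == 0L) {
    attr(cat, "n_excluded") <- 0L
    return(cat)
  }
  wanted <- if (channel_set == "SBS96") "SNV" else c("INS", "DEL")
  keep <- variants$var_class %in% wanted
  n_excluded <- sum(!keep)
  v <- variants[keep, , drop = FALSE]
  for (i in seq_len(nrow(v))) {
    ch <- tryCatch({
      if (channel_set == "SBS96") {
        ctx <- read_reference_window(reference, v$chrom[i],
                                     v$pos[i] - 1L, v$pos[i] + 1L)
        classify_sbs(v$ref[i], v$alt[i], ctx)
      } else {
        classify_indel_at(reference, v$chrom[i], v$pos[i], v$ref[i], v$alt[i])
      }
    }, error = function(e) {
      stop("classification failed at ", v$chrom[i], ":", v$pos[i], " ",
           v$ref[i], ">", v$alt[i], ": ", conditionMessage(e))
    })
    cat[ch] <- cat[ch] + 1
  }
  attr(cat, "sample_id") <- sid
  attr(cat, "n_excluded") <- n_excluded
  cat
}

#' Write catalogues to TSV
#'
#' First column `channel` in the fixed canonical order, one column per
#' sample.
#'
#' @param catalogues a `mutational_catalogue` or list of them (same channel
#'   set).
#' @param path output path.
#' @export
write_catalogue_tsv <- function(catalogues, path) {
  if (inherits(catalogues, "mutational_catalogue")) catalogues <- list(catalogues)
  labels <- channel_labels(attr(catalogues[[1]], "channel_set"))
  df <- data.frame(channel = labels, stringsAsFactors = FALSE)
  for (cat in catalogues) {
    stopifnot(identical(names(cat), labels))
    df[[attr(cat, "sample_id")]] <- as.numeric(cat)
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read catalogues from TSV
#'
#' @param path TSV written by [write_catalogue_tsv()].
#' @param channel_set channel set of the file.
#' @return named list of `mutational_catalogue` objects.
#' @export
read_catalogue_tsv <- function(path, channel_set = c("SBS96", "ID83")) {
  channel_set <- match.arg(channel_set)
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  labels <- channel_labels(channel_set)
  if (!identical(df[[1]], labels)) stop("channel column does not match the canonical ",
                                        channel_set, " order")
  out <- lapply(names(df)[-1], function(s) {
    new_catalogue(s, channel_set, stats::setNames(df[[s]], labels))
  })
  stats::setNames(out, names(df)[-1])
}
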