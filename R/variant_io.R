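#' Build a variant table
#'
#' The internal variant model is a plain `data.frame` with one row per
#' (sample, position, alt allele): columns `sample_id`, `chrom`, `pos`
#' (1-based), `ref`, `alt`, `vaf`, `depth` and `var_class`. `var_class` is
#' derived from the alleles: `SNV` for 1bp/1bp substitutions, `INS`/`DEL` for
#' pure anchored insertions/deletions, `OTHER` for multi-nucleotide or complex
#' events (retained but excluded from catalogues).
#'
#' @param sample_id,chrom,pos,ref,alt,vaf,depth vectors, recycled to a common
#'   length. `depth` may be `NA`.
#' @return a `data.frame` of class `variant_table`.
#' @export
variant_table <- function(sample_id, chrom, pos, ref, alt, vaf, depth = NA_real_) {
  n <- length(pos)
  df <- data.frame(sample_id = rep_len(as.character(sample_id), n),
                   chrom = rep_len(as.character(chrom), n),
                   pos = as.integer(pos),
                   ref = rep_len(toupper(as.character(ref)), n),
                   alt = rep_len(toupper(as.character(alt)), n),
                   vaf = rep_len(as.numeric(vaf), n),
                   depth = rep_len(as.numeric(depth), n),
                   stringsAsFactors = FALSE)
  bad <- !grepl("^[ACGT]+$", df$ref) | !grepl("^[ACGT]+$", df$alt) | df$ref == df$alt
  if (any(bad)) {
    stop("invalid alleles (must be non-empty A/C/G/T strings with ref != alt) at rows: ",
         paste(utils::head(which(bad), 5), collapse = ", "))
  }
  if (any(df$vaf < 0 | df$vaf > 1, na.rm = TRUE)) {
    stop("vaf outside [0,1]")
  }
  df$var_class <- classify_var_class(df$ref, df$alt)
  class(df) <- c("variant_table", "data.frame")
  df
}

#' Classify allele pairs into SNV/INS/DEL/OTHER
#'
#' @param ref,alt character vectors of alleles.
#' @return character vector over `{SNV, INS, DEL, OTHER}`.
#' @export
classify_var_class <- function(ref, alt) {
  nr <- nchar(ref); na <- nchar(alt)
  out <- rep("OTHER", length(ref))
  out[nr == 1L & na == 1L] <- "SNV"
  ins <- na > nr & substr(alt, 1L, nr) == ref
  out[ins] <- "INS"
  del <- nr > na & substr(ref, 1L, na) == alt
  out[del] <- "DEL"
  out
}

#' Read somatic variants from a VCF file
#'
#' Reads a VCF 4.x file (via \pkg{vcfR}), splits multi-allelic records into
#' one row per alternate allele, drops records failing FILTER (unless
#' `keep_filtered`), and derives a VAF per allele using a configurable key
#' precedence: `FORMAT/VAF` if present, else `FORMAT/AD`
#' (alt / (sum of allele depths)), else INFO-level keys such as `TVAF`.
#' Records with no usable VAF evidence, or with non-ACGT/symbolic alleles,
#' are skipped with a warning and counted in `attr(,"n_skipped")`.
#' Multi-nucleotide/complex substitutions are retained with
#' `var_class = "OTHER"`.
#'
#' @param path VCF file path.
#' @param sample_id sample column to read (defaults to the first genotype
#'   column); also used as `sample_id` in the output.
#' @param vaf_keys character vector giving the VAF evidence precedence.
#' @param keep_filtered if `TRUE`, records failing FILTER are kept.
#' @return a `variant_table`, with attributes `n_skipped` and `n_filtered`.
#' @export
read_vcf <- function(path, sample_id = NULL,
                     vaf_keys = c("VAF", "AD", "TVAF"),
                     keep_filtered = FALSE) {
  if (!file.exists(path)) stop("VCF not found: ", path)
  v <- tryCatch(vcfR::read.vcfR(path, verbose = FALSE),
                error = function(e) stop("malformed VCF '", path, "': ",
                                         conditionMessage(e)))
  fix <- v@fix
  if (is.null(fix) || nrow(fix) == 0L) {
    out <- variant_table(character(0), character(0), integer(0),
                         character(0), character(0), numeric(0))
    attr(out, "n_skipped") <- 0L
    attr(out, "n_filtered") <- 0L
    return(out)
  }
  filt <- fix[, "FILTER"]
  pass <- is.na(filt) | filt %in% c("PASS", ".")
  n_filtered <- sum(!pass)
  if (keep_filtered) pass <- rep(TRUE, nrow(fix))

  gt <- v@gt
  has_gt <- !is.null(gt) && ncol(gt) >= 2L
  if (has_gt) {
    samp_cols <- colnames(gt)[-1]
    col <- if (!is.null(sample_id) && sample_id %in% samp_cols) sample_id else samp_cols[1]
    if (is.null(sample_id)) sample_id <- col
    fmt <- gt[, "FORMAT"]
    smp <- gt[, col]
  } else {
    if (is.null(sample_id)) sample_id <- "sample"
    fmt <- smp <- rep(NA_character_, nrow(fix))
  }
  info <- fix[, "INFO"]

  get_fmt <- function(i, key) {
    if (is.na(fmt[i]) || is.na(smp[i])) return(NA_character_)
    keys <- strsplit(fmt[i], ":", fixed = TRUE)[[1]]
    j <- match(key, keys)
    if (is.na(j)) return(NA_character_)
    vals <- strsplit(smp[i], ":", fixed = TRUE)[[1]]
    if (j > length(vals)) NA_character_ else vals[j]
  }
  get_info <- function(i, key) {
    m <- regmatches(info[i],
                    regexpr(paste0("(?:^|;)", key, "=([^;]+)"), info[i], perl = TRUE))
    if (length(m) == 0L) return(NA_character_)
    sub(paste0("^;?", key, "="), "", m)
  }

  rows <- vector("list", nrow(fix))
  n_skipped <- 0L
  for (i in which(pass)) {
    ref <- toupper(fix[i, "REF"])
    alts <- strsplit(toupper(fix[i, "ALT"]), ",", fixed = TRUE)[[1]]
    if (is.na(ref) || !grepl("^[ACGT]+$", ref)) { n_skipped <- n_skipped + length(alts); next }
    ad <- get_fmt(i, "AD")
    ad_vals <- if (!is.na(ad)) suppressWarnings(as.numeric(strsplit(ad, ",", fixed = TRUE)[[1]])) else NULL
    dp <- suppressWarnings(as.numeric(get_fmt(i, "DP")))
    depth <- if (!is.na(dp)) dp else if (!is.null(ad_vals)) sum(ad_vals, na.rm = TRUE) else NA_real_
    for (ai in seq_along(alts)) {
      alt <- alts[ai]
      if (!grepl("^[ACGT]+$", alt) || identical(alt, ref)) { n_skipped <- n_skipped + 1L; next }
      vaf <- NA_real_
      for (key in vaf_keys) {
        if (key == "AD") {
          if (!is.null(ad_vals) && length(ad_vals) >= ai + 1L &&
              sum(ad_vals, na.rm = TRUE) > 0) {
            vaf <- ad_vals[ai + 1L] / sum(ad_vals, na.rm = TRUE)
          }
        } else {
          val <- get_fmt(i, key)
          if (is.na(val)) val <- get_info(i, key)
          if (!is.na(val)) {
            parts <- suppressWarnings(as.numeric(strsplit(val, ",", fixed = TRUE)[[1]]))
            cand <- if (length(parts) >= ai) parts[ai] else parts[1]
            if (!is.na(cand)) vaf <- cand
          }
        }
        if (!is.na(vaf)) break
      }
      if (is.na(vaf) || vaf < 0 || vaf > 1) { n_skipped <- n_skipped + 1L; next }
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = sample_id, chrom = fix[i, "CHROM"],
        pos = as.integer(fix[i, "POS"]), ref = ref, alt = alt,
        vaf = vaf, depth = depth, stringsAsFactors = FALSE)
    }
  }
  rows <- Filter(Negate(is.null), rows)
  if (n_skipped > 0L) {
    warning(n_skipped, " record/allele(s) skipped in '", basename(path),
            "' (missing VAF evidence or non-ACGT alleles)")
  }
  if (length(rows) == 0L) {
    out <- variant_table(character(0), character(0), integer(0),
                         character(0), character(0), numeric(0))
  } else {
    df <- do.call(rbind, rows)
    out <- variant_table(df$sample_id, df$chrom, df$pos, df$ref, df$alt,
                         df$vaf, df$depth)
  }
  attr(out, "n_skipped") <- n_skipped
  attr(out, "n_filtered") <- n_filtered
  out
}

#' Write a variant table to a single-sample VCF 4.2 file
#'
#' Emits plain-text VCF with `DP`, `AD` and `VAF` FORMAT fields. `VAF` is
#' written at full double precision so that a write/read round trip
#' reproduces `(chrom, pos, ref, alt, vaf)` exactly; `AD` is derived from
#' `vaf * depth` when depth is available.
#'
#' @param variants a `variant_table` for a single sample.
#' @param path output path.
#' @param contigs optional named integer vector of contig lengths for the
#'   header.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(variants, path, contigs = NULL) {
  sid <- unique(variants$sample_id)
  if (length(sid) > 1L) stop("write_vcf expects a single sample, got: ",
                             paste(sid, collapse = ", "))
  if (length(sid) == 0L) sid <- "sample"
  hdr <- c("##fileformat=VCFv4.2",
           "##source=ffpesig")
  if (!is.null(contigs)) {
    hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>",
                          names(contigs), as.integer(contigs)))
  }
  hdr <- c(hdr,
           "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
           "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allele depths\">",
           "##FORMAT=<ID=VAF,Number=A,Type=Float,Description=\"Variant allele fraction\">",
           paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
                 "FORMAT", sid, sep = "\t"))
  if (nrow(variants) > 0L) {
    ord <- order(variants$chrom, variants$pos, variants$ref, variants$alt)
    v <- variants[ord, , drop = FALSE]
    dp <- ifelse(is.na(v$depth), ".", as.character(as.integer(round(v$depth))))
    alt_reads <- ifelse(is.na(v$depth), NA_integer_,
                        as.integer(round(v$vaf * v$depth)))
    ad <- ifelse(is.na(alt_reads), ".",
                 paste0(as.integer(round(v$depth)) - alt_reads, ",", alt_reads))
    body <- paste(v$chrom, v$pos, ".", v$ref, v$alt, ".", "PASS", ".",
                  "DP:AD:VAF",
                  paste0(dp, ":", ad, ":", sprintf("%.17g", v$vaf)),
                  sep = "\t")
  } else body <- character(0)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Export a variant table to TSV
#'
#' Columns: sample_id, chrom, pos, ref, alt, vaf, class.
#' @param variants a `variant_table`.
#' @param path output path.
#' @export
write_variants_tsv <- function(variants, path) {
  df <- as.data.frame(variants)[, c("sample_id", "chrom", "pos", "ref",
                                    "alt", "vaf", "var_class")]
  names(df)[names(df) == "var_class"] <- "class"
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Load a FASTA reference into an in-memory accessor
#'
#' @param path FASTA path (an accompanying `.fai` index is created if absent).
#' @return named list of uppercase contig sequences, class
#'   `reference_sequence`.
#' @export
load_reference <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  out <- lapply(seq_along(seqs), function(i) toupper(as.character(seqs[[i]])))
  names(out) <- names(seqs)
  if (!file.exists(paste0(path, ".fai"))) {
    try(Rsamtools::indexFa(path), silent = TRUE)
  }
  attr(out, "lengths") <- vapply(out, nchar, integer(1))
  class(out) <- "reference_sequence"
  out
}

# contig length with cached lookup (nchar on megabase strings is slow)
.contig_length <- function(reference, chrom) {
  lens <- attr(reference, "lengths")
  if (!is.null(lens) && chrom %in% names(lens)) return(lens[[chrom]])
  nchar(reference[[chrom]])
}

#' Extract a reference window
#'
#' @param reference a `reference_sequence` (or named list/vector of contig
#'   strings).
#' @param chrom contig name.
#' @param start,end 1-based inclusive coordinates, `start <= end`.
#' @return uppercase sequence string of length `end - start + 1`.
#' @export
read_reference_window <- function(reference, chrom, start, end) {
  if (!chrom %in% names(reference)) stop("unknown contig: ", chrom)
  if (start > end) stop("invalid window on ", chrom, ": start (", start,
                        ") > end (", end, ")")
  len <- .contig_length(reference, chrom)
  if (start < 1 || end > len) {
    stop("window out of bounds on ", chrom, ": ", start, "-", end,
         " (contig length ", len, ")")
  }
  substr(reference[[chrom]], start, end)
}

#' Read an actionable-gene panel from BED4
#'
#' Parses a 4+ column BED (chrom, start, end, gene; 0-based half-open),
#' converts to 1-based inclusive coordinates and merges overlapping intervals
#' per gene.
#'
#' @param path BED file path.
#' @return a `GRanges` with a `gene` metadata column, one row per merged
#'   interval.
#' @export
read_panel <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^(#|track|browser)", lines) & nzchar(lines)]
  if (length(lines) == 0L) {
    gr <- GenomicRanges::GRanges()
    S4Vectors::mcols(gr)$gene <- character(0)
    return(gr)
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ncols <- vapply(parts, length, integer(1))
  if (any(ncols < 4L)) {
    stop("BED4 required (chrom, start, end, gene); line ",
         which(ncols < 4L)[1], " has ", min(ncols), " columns")
  }
  chrom <- vapply(parts, `[`, character(1), 1L)
  start0 <- as.numeric(vapply(parts, `[`, character(1), 2L))
  end0 <- as.numeric(vapply(parts, `[`, character(1), 3L))
  gene <- vapply(parts, `[`, character(1), 4L)
  bad <- which(!(start0 < end0))
  if (length(bad) > 0L) {
    stop("BED interval with start >= end at line ", bad[1])
  }
  gr <- GenomicRanges::GRanges(chrom,
                               IRanges::IRanges(start = start0 + 1, end = end0),
                               gene = gene)
  merged <- lapply(split(gr, gr$gene), function(g) {
    r <- GenomicRanges::reduce(g)
    S4Vectors::mcols(r)$gene <- rep(g$gene[1], length(r))
    r
  })
  out <- sort(unname(do.call(c, unname(merged))))
  out
}
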