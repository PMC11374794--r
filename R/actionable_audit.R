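#' Flag variants that intersect an actionable-gene panel
#'
#' Membership is positional: an SNV is flagged when its position lies inside
#' a panel interval; an indel when any inserted/deleted base or its anchor
#' base does. Flagging is invariant to panel interval fragmentation.
#'
#' @param variants a `variant_table`.
#' @param panel a `GRanges` with a `gene` column, as from [read_panel()].
#' @return `variants` with an added `gene` column (`NA` when outside the
#'   panel).
#' @export
annotate_panel <- function(variants, panel) {
  if (length(panel) == 0L) stop("panel is empty")
  if (nrow(variants) == 0L) {
    variants$gene <- character(0)
    return(variants)
  }
  start <- variants$pos
  end <- variants$pos + pmax(nchar(variants$ref), 1L) - 1L
  end <- pmax(end, start + ifelse(variants$var_class == "INS", 1L, 0L))
  vr <- GenomicRanges::GRanges(variants$chrom,
                               IRanges::IRanges(start = start, end = end))
  hits <- GenomicRanges::findOverlaps(vr, panel)
  gene <- rep(NA_character_, nrow(variants))
  q <- S4Vectors::queryHits(hits)
  first <- !duplicated(q)
  gene[q[first]] <- panel$gene[S4Vectors::subjectHits(hits)[first]]
  variants$gene <- gene
  variants
}

#' Look up named hotspot variants
#'
#' Matches variants against a hotspot table (chrom, pos, ref, alt, label),
#' e.g. EGFR L858R or BRAF V600E, without requiring a consequence annotator.
#'
#' @param variants a `variant_table`.
#' @param hotspots data.frame with columns `chrom`, `pos`, `ref`, `alt`,
#'   `label` (or a TSV path with these columns).
#' @return `variants` with an added `hotspot` column (`NA` when unmatched).
#' @export
annotate_hotspots <- function(variants, hotspots) {
  if (is.character(hotspots)) {
    hotspots <- utils::read.table(hotspots, sep = "\t", header = TRUE,
                                  stringsAsFactors = FALSE)
  }
  key <- function(df) paste(df$chrom, df$pos, df$ref, df$alt, sep = ":")
  variants$hotspot <- hotspots$label[match(key(variants), key(hotspots))]
  variants
}

#' Audit what a naive VAF filter would discard from panel variants
#'
#' Counts panel-flagged variants with `vaf < threshold`, overall and per
#' gene — the clinical cost of the historical "filter FFPE variants below
#' 10% VAF" practice.
#'
#' @param variants a `variant_table` annotated by [annotate_panel()].
#' @param threshold VAF threshold in `(0, 1)` (default 0.1).
#' @return list of class `audit_result`: `n_panel_variants`,
#'   `n_below_threshold`, `frac_below`, `threshold` and `per_gene`
#'   (data.frame gene / n / n_below).
#' @export
vaf_filter_audit <- function(variants, threshold = 0.1) {
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0, 1)")
  if (is.null(variants$gene)) stop("variants must be annotated with annotate_panel()")
  flagged <- variants[!is.na(variants$gene), , drop = FALSE]
  n_panel <- nrow(flagged)
  below <- flagged$vaf < threshold
  per_gene <- if (n_panel > 0) {
    agg <- stats::aggregate(cbind(n = rep(1L, n_panel), n_below = as.integer(below)),
                            by = list(gene = flagged$gene), FUN = sum)
    agg[order(agg$gene), , drop = FALSE]
  } else data.frame(gene = character(0), n = integer(0), n_below = integer(0))
  structure(list(n_panel_variants = n_panel,
                 n_below_threshold = sum(below),
                 frac_below = if (n_panel > 0) sum(below) / n_panel else 0,
                 threshold = threshold,
                 per_gene = per_gene),
            class = "audit_result")
}

#' Spearman correlation of VAF against cancer cell content
#'
#' True somatic variants correlate with tumour purity; artefacts do not.
#' Ties are handled by average ranks.
#'
#' @param variants a `variant_table` (typically panel/hotspot-flagged).
#' @param meta data.frame with columns `sample_id` and `purity`.
#' @return list with `rho`, `p_value` and `n`. `rho` is `NA` (with a
#'   warning) when either vector is constant.
#' @export
vaf_purity_correlation <- function(variants, meta) {
  purity <- meta$purity[match(variants$sample_id, meta$sample_id)]
  keep <- !is.na(purity) & !is.na(variants$vaf)
  vaf <- variants$vaf[keep]; purity <- purity[keep]
  if (length(vaf) < 5L) stop("need at least 5 (vaf, purity) pairs, got ",
                             length(vaf))
  if (length(unique(vaf)) == 1L || length(unique(purity)) == 1L) {
    warning("constant vector: Spearman correlation undefined")
    return(list(rho = NA_real_, p_value = NA_real_, n = length(vaf)))
  }
  ct <- suppressWarnings(stats::cor.test(vaf, purity, method = "spearman",
                                         exact = FALSE,
                                         alternative = "two.sided"))
  list(rho = unname(ct$estimate), p_value = ct$p.value, n = length(vaf))
}

#' Rank concordance of signature exposures between matched sample pairs
#'
#' For matched FF/FFPE pairs, computes the per-signature Spearman
#' correlation of exposures across pairs, plus a complementarity fraction:
#' the proportion of FFPE-positive signature calls (exposure > 0) that are
#' also positive in the matched FF sample.
#'
#' @param ff_exposures,ffpe_exposures lists of `exposure_set` objects; pairs
#'   are matched by `sample_id`.
#' @param min_pairs minimum matched pairs per signature (default 5).
#' @return data.frame with columns `signature`, `rho`, `p_value`,
#'   `complementarity`, `n_pairs`.
#' @export
exposure_concordance <- function(ff_exposures, ffpe_exposures, min_pairs = 5L) {
  ids_ff <- vapply(ff_exposures, `[[`, character(1), "sample_id")
  ids_ffpe <- vapply(ffpe_exposures, `[[`, character(1), "sample_id")
  unmatched <- c(setdiff(ids_ff, ids_ffpe), setdiff(ids_ffpe, ids_ff))
  if (length(unmatched) > 0L) {
    stop("unmatched sample ids: ", paste(unique(unmatched), collapse = ", "))
  }
  ffpe_exposures <- ffpe_exposures[match(ids_ff, ids_ffpe)]
  sigs <- names(ff_exposures[[1]]$exposures)
  n <- length(ff_exposures)
  if (n < min_pairs) stop("need at least ", min_pairs, " matched pairs, got ", n)
  mat <- function(lst) t(vapply(lst, function(e) e$exposures[sigs],
                                numeric(length(sigs))))
  F <- mat(ff_exposures); P <- mat(ffpe_exposures)
  out <- lapply(sigs, function(s) {
    f <- F[, s]; p <- P[, s]
    if (length(unique(f)) == 1L || length(unique(p)) == 1L) {
      rho <- NA_real_; pv <- NA_real_
    } else {
      ct <- suppressWarnings(stats::cor.test(f, p, method = "spearman",
                                             exact = FALSE))
      rho <- unname(ct$estimate); pv <- ct$p.value
    }
    pos <- p > 0
    comp <- if (any(pos)) mean(f[pos] > 0) else NA_real_
    data.frame(signature = s, rho = rho, p_value = pv,
               complementarity = comp, n_pairs = n,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
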