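#' Default artefact signature names
#'
#' The artefact set used by [compute_ffpeimpact()] when none is given:
#' SBS57, SBS_FFPE (substitutions) and ID_FFPE (indels). The set is a plain
#' character vector so newly characterised artefact signatures can be added
#' by configuration.
#'
#' @return character vector.
#' @export
default_artefact_signatures <- function() c("SBS57", "SBS_FFPE", "ID_FFPE")

#' Compute the per-sample FFPEimpact score
#'
#' FFPEimpact quantifies the proportion of a sample's mutations attributed
#' to FFPE/PCR artefact signatures. Two combining rules are implemented and
#' both are always reported: `pooled` (default)
#' `(sbs_artefact + id_artefact) / (sbs_total + id_total)`, which is
#' invariant to splitting a sample into batches, and `mean`, the average of
#' the substitution and indel artefact proportions.
#'
#' @param sbs_exposures,id_exposures `exposure_set` objects for the same
#'   sample, fitted on the SBS96 and ID83 catalogues.
#' @param artefact_names signature names counted as artefact (default
#'   [default_artefact_signatures()]); must appear in at least one exposure
#'   set.
#' @param mode `"pooled"` or `"mean"` — which rule populates `score`.
#' @return list of class `ffpeimpact_result`: `sample_id`,
#'   `sbs_artefact_count`, `sbs_total`, `id_artefact_count`, `id_total`,
#'   `sbs_artefact_prop`, `id_artefact_prop`, `score`, `score_pooled`,
#'   `score_mean`, `mode`.
#' @export
compute_ffpeimpact <- function(sbs_exposures, id_exposures,
                               artefact_names = default_artefact_signatures(),
                               mode = c("pooled", "mean")) {
  mode <- match.arg(mode)
  if (!identical(sbs_exposures$sample_id, id_exposures$sample_id)) {
    stop("sample_id mismatch: '", sbs_exposures$sample_id, "' vs '",
         id_exposures$sample_id, "'")
  }
  present <- c(names(sbs_exposures$exposures), names(id_exposures$exposures))
  if (!any(artefact_names %in% present)) {
    stop("none of the artefact signatures (",
         paste(artefact_names, collapse = ", "), ") appear in the exposures")
  }
  sbs_total <- sbs_exposures$total
  id_total <- id_exposures$total
  if (sbs_total == 0 && id_total == 0) stop("both catalogue totals are zero")
  art <- function(e) sum(e$exposures[intersect(artefact_names,
                                               names(e$exposures))])
  sbs_art <- min(art(sbs_exposures), sbs_total)
  id_art <- min(art(id_exposures), id_total)
  sbs_prop <- if (sbs_total > 0) sbs_art / sbs_total else 0
  id_prop <- if (id_total > 0) id_art / id_total else 0
  pooled <- (sbs_art + id_art) / (sbs_total + id_total)
  mean_score <- (sbs_prop + id_prop) / 2
  structure(list(sample_id = sbs_exposures$sample_id,
                 sbs_artefact_count = sbs_art, sbs_total = sbs_total,
                 id_artefact_count = id_art, id_total = id_total,
                 sbs_artefact_prop = sbs_prop, id_artefact_prop = id_prop,
                 score = if (mode == "pooled") pooled else mean_score,
                 score_pooled = pooled, score_mean = mean_score,
                 mode = mode),
            class = "ffpeimpact_result")
}

#' Normalise a VAF by cancer cell content
#'
#' `nVAF = min(vaf / purity, 1)`: clonal heterozygous diploid variants
#' centre at nVAF 0.5 regardless of tumour purity. Values above 1 (amplified
#' loci, purity misestimates) are clamped.
#'
#' @param vaf variant allele fraction(s) in `[0, 1]`.
#' @param purity cancer cell content in `(0, 1]`.
#' @return nVAF value(s) in `[0, 1]`.
#' @export
normalise_vaf <- function(vaf, purity) {
  if (any(is.na(purity)) || any(purity <= 0) || any(purity > 1)) {
    stop("purity must be in (0, 1]; sample excluded from nVAF analysis")
  }
  if (any(vaf < 0 | vaf > 1, na.rm = TRUE)) stop("vaf must be in [0, 1]")
  pmin(vaf / purity, 1)
}

#' Purity-normalised VAF histogram and mode bin
#'
#' Bins nVAF values over `[0, 1]` and reports the centre of the tallest bin
#' (ties broken toward the lower bin, with a message).
#'
#' @param variants a `variant_table` (or numeric vector of VAFs) with at
#'   least one valid VAF.
#' @param purity cancer cell content of the sample.
#' @param bin_width histogram bin width (default 0.05).
#' @return list with `breaks`, `counts`, `mids` and `mode_bin_centre`.
#' @export
nvaf_histogram <- function(variants, purity, bin_width = 0.05) {
  vaf <- if (is.data.frame(variants)) variants$vaf else as.numeric(variants)
  vaf <- vaf[!is.na(vaf)]
  if (length(vaf) == 0L) stop("need at least one variant with a valid VAF")
  nvaf <- normalise_vaf(vaf, purity)
  breaks <- seq(0, 1, by = bin_width)
  if (breaks[length(breaks)] < 1) breaks <- c(breaks, 1)
  bin <- findInterval(nvaf, breaks, rightmost.closed = TRUE,
                      all.inside = TRUE)
  counts <- tabulate(bin, nbins = length(breaks) - 1L)
  mids <- (breaks[-length(breaks)] + breaks[-1]) / 2
  top <- which(counts == max(counts))
  if (length(top) > 1L) {
    message("nvaf_histogram: tied mode bins; reporting the lower bin")
  }
  list(breaks = breaks, counts = counts, mids = mids,
       mode_bin_centre = mids[top[1]])
}

#' Assemble the per-sample WGS report block
#'
#' @param impact an `ffpeimpact_result`.
#' @param preparation sample preparation label (`FF`, `FF_PCR`, `FFPE`).
#' @param sbs_exposures,id_exposures the underlying `exposure_set`s.
#' @param nvaf_mode optional nVAF mode bin centre.
#' @return a list ready for JSON serialisation.
#' @export
sample_report_block <- function(impact, preparation = NA_character_,
                                sbs_exposures = NULL, id_exposures = NULL,
                                nvaf_mode = NULL) {
  block <- list(sample_id = impact$sample_id,
                preparation = preparation,
                FFPEimpact = impact$score,
                mode = impact$mode,
                components = list(
                  score_pooled = impact$score_pooled,
                  score_mean = impact$score_mean,
                  sbs_artefact_count = impact$sbs_artefact_count,
                  sbs_total = impact$sbs_total,
                  sbs_artefact_prop = impact$sbs_artefact_prop,
                  id_artefact_count = impact$id_artefact_count,
                  id_total = impact$id_total,
                  id_artefact_prop = impact$id_artefact_prop))
  if (!is.null(sbs_exposures)) {
    block$sbs_exposures <- as.list(sbs_exposures$exposures)
    block$sbs_unassigned <- sbs_exposures$unassigned
  }
  if (!is.null(id_exposures)) {
    block$id_exposures <- as.list(id_exposures$exposures)
    block$id_unassigned <- id_exposures$unassigned
  }
  if (!is.null(nvaf_mode)) block$nvaf_mode <- nvaf_mode
  block
}
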