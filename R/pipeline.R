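#' Assemble and validate a pipeline run configuration
#'
#' @param reference FASTA path.
#' @param vcfs named character vector of VCF paths (names are sample ids).
#' @param sbs_signatures,id_signatures `signature_matrix` objects or TSV
#'   paths.
#' @param meta data.frame (or TSV path) with `sample_id`, `purity`,
#'   `preparation`.
#' @param panel optional BED path or `GRanges` panel.
#' @param artefact_signatures artefact name set for the FFPEimpact score.
#' @param biological_signatures names subtracted to form residuals before
#'   extraction (default: all non-artefact signatures).
#' @param score_mode `"pooled"` or `"mean"`.
#' @param sparsity exposure-fit sparsity (`"none"` or `"bootstrap"`).
#' @param extract run cohort artefact-signature extraction on residuals.
#' @param k_range,n_restarts extraction settings.
#' @param vaf_threshold VAF-filter audit threshold.
#' @param seed integer seed recorded in (and used by) the run.
#' @param outdir output directory.
#' @return validated config list of class `run_config`.
#' @export
run_config <- function(reference, vcfs, sbs_signatures, id_signatures, meta,
                       panel = NULL,
                       artefact_signatures = default_artefact_signatures(),
                       biological_signatures = NULL,
                       score_mode = c("pooled", "mean"),
                       sparsity = c("none", "bootstrap"),
                       extract = FALSE, k_range = 1:3, n_restarts = 10L,
                       vaf_threshold = 0.1, seed = 1L, outdir = tempfile()) {
  score_mode <- match.arg(score_mode)
  sparsity <- match.arg(sparsity)
  if (!file.exists(reference)) stop("config error: reference not found: ", reference)
  missing <- vcfs[!file.exists(vcfs)]
  if (length(missing) > 0L) stop("config error: VCF(s) not found: ",
                                 paste(missing, collapse = ", "))
  if (is.null(names(vcfs)) || any(!nzchar(names(vcfs)))) {
    stop("config error: vcfs must be named by sample id")
  }
  if (is.character(sbs_signatures)) sbs_signatures <- read_signature_tsv(sbs_signatures, "SBS96")
  if (is.character(id_signatures)) id_signatures <- read_signature_tsv(id_signatures, "ID83")
  if (is.character(meta)) meta <- utils::read.table(meta, sep = "\t", header = TRUE,
                                                    stringsAsFactors = FALSE)
  if (!all(c("sample_id", "purity") %in% names(meta))) {
    stop("config error: meta needs sample_id and purity columns")
  }
  if (is.character(panel)) panel <- read_panel(panel)
  structure(list(reference = reference, vcfs = vcfs,
                 sbs_signatures = sbs_signatures,
                 id_signatures = id_signatures, meta = meta, panel = panel,
                 artefact_signatures = artefact_signatures,
                 biological_signatures = biological_signatures,
                 score_mode = score_mode, sparsity = sparsity,
                 extract = extract, k_range = k_range,
                 n_restarts = as.integer(n_restarts),
                 vaf_threshold = vaf_threshold, seed = as.integer(seed),
                 outdir = outdir),
            class = "run_config")
}

#' Run the FFPE artefact-characterisation pipeline on a cohort
#'
#' Per sample: read variants, build SBS96/ID83 catalogues, fit signature
#' exposures, compute the FFPEimpact score and (when a panel is configured)
#' the VAF-filter audit. Cohort level: subtract biological signatures to
#' form residual catalogues and, optionally, extract recurrent artefact
#' signatures from them. All intermediate tables (catalogues, exposures,
#' residuals, per-sample reports) are written under `config$outdir`, along
#' with a machine-readable run manifest; every number in the report is
#' recomputable from the emitted intermediates. Per-sample failures are
#' isolated, reported in the manifest and do not abort the cohort.
#'
#' @param config a [run_config()].
#' @return list of class `pipeline_result` with `samples` (per-sample
#'   blocks), `impact` (data.frame), `residuals`, `extraction` (or NULL),
#'   `audit`, `failures`, `outdir`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  reference <- load_reference(config$reference)
  art <- config$artefact_signatures
  bio_sbs <- config$biological_signatures
  if (is.null(bio_sbs)) {
    bio_sbs <- setdiff(c(colnames(config$sbs_signatures),
                         colnames(config$id_signatures)), art)
  }
  samples <- names(config$vcfs)
  blocks <- list(); impact_rows <- list(); failures <- list()
  sbs_cats <- list(); id_cats <- list(); sbs_res <- list(); id_res <- list()
  sbs_exp <- list(); id_exp <- list()
  set.seed(config$seed)
  fit_seeds <- sample.int(.Machine$integer.max - 1L, length(samples))
  for (i in seq_along(samples)) {
    sid <- samples[i]
    res <- tryCatch({
      variants <- read_vcf(config$vcfs[[sid]], sample_id = sid)
      sbs_cat <- build_catalogue(variants, reference, "SBS96")
      id_cat <- build_catalogue(variants, reference, "ID83")
      se <- fit_exposures(sbs_cat, config$sbs_signatures,
                          sparsity = config$sparsity, seed = fit_seeds[i])
      ie <- fit_exposures(id_cat, config$id_signatures,
                          sparsity = config$sparsity, seed = fit_seeds[i])
      imp <- compute_ffpeimpact(se, ie, artefact_names = art,
                                mode = config$score_mode)
      m <- config$meta[match(sid, config$meta$sample_id), ]
      nvaf_mode <- if (!is.na(m$purity) && nrow(variants) > 0) {
        nvaf_histogram(variants, m$purity)$mode_bin_centre
      } else NULL
      prep <- if ("preparation" %in% names(m)) m$preparation else NA_character_
      block <- sample_report_block(imp, preparation = prep,
                                   sbs_exposures = se, id_exposures = ie,
                                   nvaf_mode = nvaf_mode)
      if (!is.null(config$panel)) {
        flagged <- annotate_panel(variants, config$panel)
        audit <- vaf_filter_audit(flagged, config$vaf_threshold)
        block$audit <- list(n_panel_variants = audit$n_panel_variants,
                            n_below_threshold = audit$n_below_threshold,
                            frac_below = audit$frac_below,
                            threshold = audit$threshold)
      }
      list(block = block, sbs_cat = sbs_cat, id_cat = id_cat,
           se = se, ie = ie, imp = imp)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures[[sid]] <- conditionMessage(res)
      next
    }
    blocks[[sid]] <- res$block
    sbs_cats[[sid]] <- res$sbs_cat; id_cats[[sid]] <- res$id_cat
    sbs_exp[[sid]] <- res$se; id_exp[[sid]] <- res$ie
    sbs_res[[sid]] <- subtract_signatures(
      res$sbs_cat, res$se, config$sbs_signatures,
      intersect(bio_sbs, colnames(config$sbs_signatures)))
    id_res[[sid]] <- subtract_signatures(
      res$id_cat, res$ie, config$id_signatures,
      intersect(bio_sbs, colnames(config$id_signatures)))
    imp <- res$imp
    impact_rows[[sid]] <- data.frame(
      sample_id = sid, FFPEimpact = imp$score, mode = imp$mode,
      score_pooled = imp$score_pooled, score_mean = imp$score_mean,
      sbs_artefact_count = imp$sbs_artefact_count, sbs_total = imp$sbs_total,
      id_artefact_count = imp$id_artefact_count, id_total = imp$id_total,
      stringsAsFactors = FALSE)
  }
  impact <- if (length(impact_rows) > 0) do.call(rbind, impact_rows) else NULL

  extraction <- NULL
  if (isTRUE(config$extract) && length(sbs_res) >= 10L) {
    extraction <- tryCatch(
      extract_signatures(unname(sbs_res), config$k_range,
                         n_restarts = config$n_restarts, seed = config$seed),
      error = function(e) { failures[["extraction"]] <- conditionMessage(e); NULL })
  }

  out <- config$outdir
  if (length(sbs_cats) > 0) {
    write_catalogue_tsv(sbs_cats, file.path(out, "catalogues_sbs96.tsv"))
    write_catalogue_tsv(id_cats, file.path(out, "catalogues_id83.tsv"))
    write_catalogue_tsv(sbs_res, file.path(out, "residuals_sbs96.tsv"))
    write_catalogue_tsv(id_res, file.path(out, "residuals_id83.tsv"))
    write_exposures_tsv(sbs_exp, file.path(out, "exposures_sbs96.tsv"))
    write_exposures_tsv(id_exp, file.path(out, "exposures_id83.tsv"))
    utils::write.table(impact, file.path(out, "ffpeimpact.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  if (!is.null(extraction)) {
    write_extraction_result(extraction,
                            file.path(out, "extracted_signatures.tsv"),
                            file.path(out, "extraction.json"))
  }
  jsonlite::write_json(blocks, file.path(out, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  manifest <- list(package = "ffpesig",
                   version = as.character(utils::packageVersion("ffpesig")),
                   seed = config$seed,
                   reference = config$reference,
                   vcfs = as.list(config$vcfs),
                   n_samples = length(samples),
                   n_failed = length(failures),
                   failures = failures,
                   score_mode = config$score_mode,
                   artefact_signatures = config$artefact_signatures)
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  structure(list(samples = blocks, impact = impact,
                 catalogues = list(SBS96 = sbs_cats, ID83 = id_cats),
                 exposures = list(SBS96 = sbs_exp, ID83 = id_exp),
                 residuals = list(SBS96 = sbs_res, ID83 = id_res),
                 extraction = extraction, failures = failures,
                 outdir = out),
            class = "pipeline_result")
}
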