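# Shared fixtures, built once per test run and cached.
.fixtures <- new.env(parent = emptyenv())

# small synthetic reference with engineered tracts
tiny_reference <- function() {
  if (is.null(.fixtures$tiny)) {
    path <- file.path(tempdir(), "ffpesig-tiny-ref.fa")
    info <- make_reference(60000, gc = 0.45, seed = 71, path = path)
    .fixtures$tiny <- list(info = info, ref = load_reference(path))
  }
  .fixtures$tiny
}

# standard synthetic cohort (the package's default study conditions)
standard_cohort <- function() {
  if (is.null(.fixtures$cohort)) {
    spec <- cohort_spec(seed = 20260901)
    dir <- file.path(tempdir(), "ffpesig-standard-cohort")
    .fixtures$cohort <- simulate_cohort(spec, dir)
  }
  .fixtures$cohort
}

# full pipeline result on the standard cohort
standard_pipeline <- function() {
  if (is.null(.fixtures$pipeline)) {
    co <- standard_cohort()
    cfg <- run_config(reference = co$ref_info$path, vcfs = co$vcfs,
                      sbs_signatures = co$signatures$SBS96,
                      id_signatures = co$signatures$ID83,
                      meta = co$meta, seed = 7,
                      outdir = file.path(tempdir(), "ffpesig-standard-out"))
    .fixtures$pipeline <- run_pipeline(cfg)
  }
  .fixtures$pipeline
}

# small cohort for end-to-end determinism checks
small_cohort_spec <- function(seed = 404) {
  cohort_spec(n_samples = 12L, reference_length = 3e5,
              sbs_burden = c(meanlog = log(600), sdlog = 0.3),
              id_burden = c(meanlog = log(60), sdlog = 0.3),
              seed = seed)
}

# hand-built exposure set fixture
make_exposure_set <- function(sample_id, exposures, total = sum(exposures)) {
  structure(list(sample_id = sample_id,
                 exposures = exposures,
                 unassigned = max(0, total - sum(exposures)),
                 total = total,
                 reconstruction_cosine = NA_real_),
            class = "exposure_set")
}

# write a small VCF from raw lines
write_test_vcf <- function(body, path = tempfile(fileext = ".vcf"),
                           format_def = TRUE) {
  hdr <- c("##fileformat=VCFv4.2")
  if (format_def) {
    hdr <- c(hdr,
             "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
             "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allele depths\">",
             "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Depth\">",
             "##FORMAT=<ID=VAF,Number=A,Type=Float,Description=\"VAF\">")
  }
  hdr <- c(hdr, paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", "TUMOUR", sep = "\t"))
  writeLines(c(hdr, body), path)
  path
}
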