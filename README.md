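# ffpesig

Characterisation and quantification of FFPE/PCR artefacts in cancer
whole-genome sequencing.

## The problem

Routine tumour biopsies are formalin-fixed and paraffin-embedded (FFPE),
which damages DNA and injects artefactual calls into somatic whole-genome
sequencing: low-VAF substitution artefacts and an indel burden inflated by
roughly an order of magnitude wherever PCR touches the library. The
historical remedy — discarding every variant with VAF < 10% — also discards
genuine, clinically actionable mutations. This package is for analysts of
tumour WGS who want the alternative: **characterise the artefact, keep the
data**.

## What it computes

* **Mutational catalogues.** Somatic VCFs are turned into per-sample SBS96
  catalogues (pyrimidine-collapsed trinucleotide contexts, labels like
  `A[C>T]A`) and ID83 indel catalogues (left-aligned; type, size,
  homopolymer/repeat context, microhomology), with conventions pinned and
  documented.
* **Signature refitting.** Exposures solve `min ||m − S·e||, e ≥ 0`
  (active-set NNLS on raw counts), with optional bootstrap sparsity.
  Fitted biological signatures can be subtracted to leave residual
  catalogues — also the hand-off point for downstream algorithms such as
  HRD classifiers.
* **De novo artefact extraction.** Stability-selected KL-NMF
  (multiplicative updates) on cohort residuals, with rank chosen by restart
  stability, a collinearity guard and a reconstruction-error elbow;
  extracted profiles are annotated against references by cosine matching.
* **FFPEimpact.** A per-sample score: the proportion of mutations assigned
  to artefact signatures (default set `{SBS57, SBS_FFPE, ID_FFPE}`), pooled
  over substitutions and indels —
  `(sbs_artefact + id_artefact) / (sbs_total + id_total)` — with a
  mean-of-proportions variant reported alongside.
* **nVAF and the filter audit.** VAF normalised by cancer cell content
  (`nVAF = min(vaf/purity, 1)`; clonal heterozygous diploid variants centre
  at 0.5, artefacts near 0.1) and an audit of what a naive VAF threshold
  would discard from an actionable-gene panel.
* **Synthetic cohorts.** A fully deterministic generator (reference FASTA
  with engineered homopolymer/repeat tracts, signature-driven variants with
  preparation-dependent VAF/burden structure, truth tables) so the whole
  pipeline is testable without controlled-access data.

## Worked example

Simulate a small mixed cohort and run the full pipeline:

```r
library(ffpesig)

spec <- cohort_spec(n_samples = 12, reference_length = 3e5,
                    sbs_burden = c(meanlog = log(600), sdlog = 0.3),
                    id_burden = c(meanlog = log(60), sdlog = 0.3), seed = 7)
co <- simulate_cohort(spec, file.path(tempdir(), "cohort"))

cfg <- run_config(reference = co$ref_info$path, vcfs = co$vcfs,
                  sbs_signatures = co$signatures$SBS96,
                  id_signatures = co$signatures$ID83,
                  meta = co$meta, seed = 1,
                  outdir = file.path(tempdir(), "run"))
res <- run_pipeline(cfg)

out <- merge(res$impact, co$meta, by = "sample_id")
out[order(out$sample_id),
    c("sample_id", "preparation", "FFPEimpact", "sbs_total", "id_total")]
```

```
 sample_id preparation FFPEimpact sbs_total id_total
     FF_01          FF    0.00774       690       72
     FF_02          FF    0.00000       459       45
     FF_03          FF    0.04801       547       55
     FF_04          FF    0.00000       599       46
     FF_05          FF    0.00913       807       74
 FF_PCR_06      FF_PCR    0.41072       772      620
   FFPE_07        FFPE    0.43612       741      590
   FFPE_08        FFPE    0.63221      3207      530
   FFPE_09        FFPE    0.73390      2001      510
   FFPE_10        FFPE    0.45724       879      810
   FFPE_11        FFPE    0.42104       634      430
   FFPE_12        FFPE    0.42530       752      570
```

Reading the output: FF samples carry essentially no artefact (scores ≈ 0);
PCR-exposed preparations show ten-fold indel inflation (`id_total`) and
FFPEimpact scores dominated by the indel artefact; `FFPE_08`/`FFPE_09` are
SBS_FFPE "hypermutator" carriers — inflated substitution totals and the
highest scores. Against the generator's truth table, the scores track the
true artefact fraction with mean absolute error 0.008 here. `run_pipeline()`
also writes all intermediates (catalogues, exposures, residuals, per-sample
JSON report blocks and a run manifest) under `outdir`.

The numbered scripts under `analysis/` walk the same workflow at full scale
(50-sample standard cohort): simulation, catalogues, fitting/subtraction, de
novo extraction of the artefact signatures from residuals, FFPEimpact, and
the VAF-filter audit, writing their tables under `results/`.

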