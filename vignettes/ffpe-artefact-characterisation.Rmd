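---
title: "Characterising FFPE artefacts in cancer whole-genome sequencing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Characterising FFPE artefacts in cancer whole-genome sequencing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Formalin fixation and paraffin embedding (FFPE) is the default preservation
for diagnostic tumour tissue, but it damages DNA: cytosine deamination,
fragmentation and cross-linking inject artefactual variant calls into
whole-genome sequencing (WGS) data, and PCR during library preparation adds
an indel artefact load of roughly an order of magnitude. The historical
remedy — discarding all variants below 10% variant allele fraction (VAF) —
also discards genuine, clinically actionable mutations that sit at low VAF
because of low tumour purity or subclonality.

`ffpesig` takes the opposite approach: **characterise the artefact instead of
filtering the data**. The pipeline

1. builds per-sample mutational catalogues (SBS96 substitutions, ID83
   indels) from somatic VCFs,
2. fits known signature exposures by non-negative least squares (NNLS),
3. subtracts biological signatures and extracts recurrent artefact
   signatures from the cohort residuals by stability-selected NMF,
4. summarises each sample's artefact load as a single **FFPEimpact** score
   suitable for a WGS report, and
5. audits what a naive VAF filter would have discarded from an
   actionable-gene panel.

All stages run end-to-end on a synthetic cohort generator, so every claim in
the test suite is checked against a known truth table.

## Mutational catalogues

**SBS96.** Substitutions are classified by the pyrimidine-collapsed
substitution class (C>A, C>G, C>T, T>A, T>C, T>G) and the flanking reference
bases: 6 x 16 = 96 channels, labels like `A[C>T]A`. If the reference base is
a purine, both the alternate allele and the trinucleotide context are
reverse-complemented first, so strand symmetry holds by construction (the
test suite checks all 192 raw combinations exhaustively). A mismatch between
the VCF REF and the reference genome raises an error immediately — it is the
signature of a wrong genome build.

**ID83.** Indels are left-aligned and classified into the 83-channel
COSMIC-style scheme: 1 bp deletions/insertions in C or T homopolymers (A/G
events complement-collapsed), larger events at tandem repeats by repeat-unit
count, and deletions with flanking microhomology. Public implementations
differ in small conventions, so this package pins them explicitly:

* homopolymer length for a 1 bp deletion counts the deleted base plus
  identical neighbours on both sides (classes 1..6+); for a 1 bp insertion,
  existing identical neighbours only (classes 0..5+);
* the repeat-unit count for a >=2 bp event is the number of complete copies
  of the indel sequence adjacent in the reference, and deletions count the
  deleted copy itself (so a deletion with one extra adjacent copy is class 2);
* microhomology (the longest flank-shared prefix or suffix of the deleted
  sequence) is assigned only when a deletion has no adjacent full copy;
* deletions with neither repeats nor microhomology land in the repeat class
  with unit count 1.

Left-alignment before classification makes channel assignment invariant to
how the caller represented the event; a brute-force string-scanning oracle
in the test suite confirms agreement on 1,000 random indels.

## Signature fitting and subtraction

Exposures solve `min || m − S e ||` subject to `e >= 0` on the **raw count
vector** (Lawson–Hanson active-set NNLS), so exposures are mutation counts
and divide by the catalogue total to give proportions. An optional
bootstrap-sparsity mode resamples the catalogue (multinomial over channels,
100 replicates) and zeroes any signature whose 5th-percentile exposure falls
below `max(10 mutations, 1% of total)` before refitting — thresholds are
explicit arguments because published assignment pipelines do not print
theirs. Tissue-specific "common signature" lists are configuration, not
code.

Subtraction forms `round(m − Σ e_k s_k)` over a chosen subset, clamped at
zero per channel (clamped mass is recorded). Subtracting the biological
signatures leaves residual catalogues in which recurrent artefact patterns
concentrate; the residuals are also the designed hand-off to downstream
algorithms (HRD classifiers and similar) that should not see artefact
mutations.

Numerical notes: if the NNLS solution's total slightly exceeds the catalogue
total it is rescaled down so that exposures + unassigned always account for
the catalogue exactly; near-collinear signature pairs (cosine > 0.99) are
kept but warned about rather than merged silently; an all-zero catalogue
yields all-zero exposures with an undefined (NA) reconstruction cosine.

## De novo artefact extraction

Residual catalogues across the cohort are factorised by NMF under the
generalised Kullback–Leibler objective (the natural choice for Poisson
counts) with multiplicative updates, at most 5,000 iterations and relative
tolerance 1e-6. For each candidate rank k the package runs `n_restarts`
seeded random initialisations plus one restart warm-started from the best
rank-(k−1) solution — the warm start guarantees the reconstruction error is
non-increasing in k, which the tests assert.

Rank selection was a genuinely open design point; the rule implemented is:

1. **stability** — every extracted signature must reach mean matched cosine
   >= 0.8 between the random restarts and the best-objective run (the
   warm-started run is excluded from this measurement as it is biased toward
   the previous rank);
2. **non-degeneracy** — a rank is rejected if any two of its profiles have
   cosine > 0.9; empirically this is the fingerprint of one process being
   split across components (overfit ranks on single-process data produce
   pairwise cosines of 0.93–0.97, genuinely distinct processes sit near 0);
3. **elbow** — among surviving ranks, a larger rank is accepted only if it
   improves the KL divergence by at least 5% over the last accepted one.

Samples whose residual total exceeds 10x the cohort median are down-weighted
to the 90th-percentile total during factorisation — hypermutator-like
samples would otherwise dominate the objective — and all exposures are then
refit at full scale by NNLS against the extracted profiles. Extracted
profiles are annotated against a reference set by greedy best cosine
matching; matches below 0.8 are labelled `novel`.

## FFPEimpact

FFPEimpact is the proportion of a sample's mutations attributed to the
artefact signature set (default `SBS57`, `SBS_FFPE`, `ID_FFPE`; a plain
configuration list, so newly characterised artefacts can be added). Two
combining rules are implemented and always reported side by side:

* **pooled** (default): `(sbs_artefact + id_artefact) / (sbs_total +
  id_total)` — invariant to splitting a sample into batches, which is why it
  is the default;
* **mean**: the average of the substitution and indel artefact proportions —
  retained for sensitivity analysis.

VAFs are normalised by cancer cell content, `nVAF = min(vaf / purity, 1)`,
clamped because amplified loci and purity misestimates can exceed 1. Clonal
heterozygous diploid variants centre at nVAF 0.5; the low-VAF artefact
population peaks near 0.1. The histogram helper reports the tallest-bin
centre with ties broken toward the lower bin (logged).

## Actionable-variant audit

Panel membership is purely positional (SNV position, or any deleted/inserted
base including the anchor, intersecting a panel interval) — consequence
annotation is deliberately out of scope, and the audit is invariant to how
panel intervals are fragmented. Named hotspots (e.g. specific EGFR or BRAF
alleles) are matched from a plain TSV. The audit counts panel variants below
a VAF threshold (default 0.1) — the variants a naive filter would discard —
and Spearman-correlates VAF against cancer cell content (average ranks for
ties): genuine clonal variants track purity, artefacts do not. For matched
FF/FFPE pairs, per-signature exposure concordance is the Spearman
correlation across pairs plus the fraction of FFPE-positive calls also
positive in FF.

## The synthetic cohort generator

The generator exists so that every pipeline stage is testable without
controlled-access patient data. It emulates the statistical structure of
FF / FF(PCR) / FFPE WGS cohorts:

* **reference**: a random contig (default 800 kb, GC 0.41) seeded with
  engineered homopolymer tracts (A/T, lengths 6–12) and dinucleotide-repeat
  tracts (2–8 copies) at recorded, breaker-isolated positions, so
  long-homopolymer and long-repeat indel channels have enough distinct
  placement sites;
* **burdens**: per-sample lognormal substitution (meanlog log 1500, sdlog
  0.35) and indel (meanlog log 150, sdlog 0.35) burdens, with the indel
  burden multiplied by 10 in PCR-exposed preparations (FF_PCR, FFPE) —
  the order-of-magnitude indel excess;
* **spectra**: channel-first simulation — each mutation draws a signature
  from the preparation's mixture, a channel from that signature's profile,
  and only then a concrete (pos, ref, alt) realising exactly that channel,
  so the truth spectrum matches the mixture draw exactly and catalogue
  round-trips are sharp (bit-exact in the tests). Candidate indel events are
  verified by the classifier itself before entering the placement pools;
* **artefact structure**: `SBS57` is carried at a fixed mixture weight by
  FFPE (0.10) and FF_PCR (0.05) samples; `SBS_FFPE` is idiosyncratic —
  carried by a 0.2 fraction of FFPE samples, where it takes a 0.45–0.7
  mixture weight and multiplies the substitution burden by 3–6
  (hypermutator phenotype); `ID_FFPE` takes 0.85 of the inflated indel
  mixture in PCR-exposed preparations. FF samples carry no artefact weight
  at all. This prevalence structure is what makes the two substitution
  artefacts separable by de novo extraction: with identical mixtures in
  every sample their combination would be unidentifiable;
* **VAFs**: read depths binomial around mean coverage 90; clonal variants
  draw alternate reads at success probability purity/2; artefact variants at
  a per-variant probability ~ Normal(0.08, 0.03) truncated positive, both
  truncated to >= 1 supporting read. With purity ~ Beta(6, 4) this
  reproduces the clonal nVAF peak at 0.5 and the artefact peak near 0.1;
* **signatures**: `make_test_signatures()` returns deterministic TEST-ONLY
  stand-ins — three smooth biological profiles plus artefact profiles with
  the characteristic peaks (T>C at A[T>C]A/A[T>C]C/C[T>C]T/T[T>C]T and C>T
  at A[C>T]A/A[C>T]T/T[C>T]T for the substitution artefact; 1 bp T
  insertions/deletions at long homopolymers, dinucleotide deletions at long
  repeats and long insertions at non-repeats for the indel artefact). Real
  published profiles should be loaded from TSV instead.

Everything is driven by one integer seed: the same spec and seed produce
byte-identical FASTA, VCFs and truth tables.

**What the generator does not emulate** — and hence what passing tests do
not show about real data: read-level artefact structure (strand bias, PCR
duplicates, fragmentation-length effects), copy-number and its interaction
with VAF, subclonality, sequence-context biases of real deamination beyond
the injected profiles, caller-specific error modes, and structural
variants. Recovery results on the synthetic cohort are a correctness check
of the machinery, not a clinical validation.

## Problem sizes and numerical choices in the test suite

The standard synthetic cohort used by the tests is 50 samples (20 FF, 5
FF_PCR, 25 FFPE) on an 800 kb reference — sizes chosen so the whole suite
exercises every stage, including two full pipeline runs, in a few minutes.
On this cohort the pooled FFPEimpact score tracks the generator's true
artefact fraction with mean absolute error well under 0.03, and fitted
exposure proportions recover the truth with median per-sample maximum error
under 0.05. NNLS recovery precision depends on burden: with the smooth,
partially overlapping test profiles, a (0.6, 0.3, 0.1) mixture is recovered
within ±0.05 in 78% of replicates at 500 mutations, 90% at 1,000 and 98% at
2,000 — the property-style test therefore runs at 2,000 mutations, the
pipeline's typical per-sample substitution burden, and the 500-mutation case
is asserted on mean absolute error (< 0.05, measured ≈ 0.023).

## Known limitations

* The FFPEimpact combining rule is implemented in two labelled variants
  (pooled, mean) because the printed definition does not fix one; pooled is
  the default for its batch invariance.
* Panel flagging is positional; transcript consequence is out of scope.
* The ID83 conventions above are one self-consistent choice among public
  variants; catalogues built here should not be mixed with catalogues from
  implementations using different repeat-counting conventions.
* NNLS separation of flat, featureless signatures is intrinsically unstable
  at low mutation burden — the same behaviour that causes HR-deficiency
  signature misassignment in real cohorts; exposures of such signatures
  should be interpreted with care (or constrained via the sparsity mode).
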