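#!/usr/bin/env Rscript

# Step 6 — actionable-variant audit: what would a naive VAF filter discard?
#
# A virtual panel of "actionable" intervals is placed on the synthetic
# reference; panel variants are then audited against the historical
# "filter FFPE variants below 10% VAF" practice. Because artefact variants
# sit at low VAF but so do some genuine clonal variants (low purity), the
# filter discards real panel calls — the audit quantifies how many. VAF is
# also correlated against cancer cell content: genuine clonal variants track
# purity, artefacts do not.

suppressMessages(library(ffpesig))

meta <- read.table("scratch/cohort/meta.tsv", sep = "\t", header = TRUE)
ref_info_len <- 8e5

# virtual panel: 40 evenly spaced 10 kb "genes"
bed <- "scratch/panel.bed"
starts <- seq(0, ref_info_len - 2e4, length.out = 40)
writeLines(sprintf("chrS\t%d\t%d\tGENE%02d", round(starts),
                   round(starts) + 10000L, seq_along(starts)), bed)
panel <- read_panel(bed)

all_v <- list()
for (sid in meta$sample_id) {
  v <- read_vcf(file.path("scratch/cohort", paste0(sid, ".vcf")),
                sample_id = sid)
  all_v[[sid]] <- annotate_panel(v, panel)
}
flagged <- do.call(rbind, all_v)

audit <- vaf_filter_audit(flagged, threshold = 0.1)
cat("Panel variants:", audit$n_panel_variants,
    "; below VAF 0.1:", audit$n_below_threshold,
    sprintf("(%.1f%%)", 100 * audit$frac_below), "\n")

# clonal variants only (biological signatures): correlation with purity
ffpe_ids <- meta$sample_id[meta$preparation == "FFPE"]
ffpe_v <- flagged[flagged$sample_id %in% ffpe_ids & !is.na(flagged$gene), ]
corr <- vaf_purity_correlation(ffpe_v, meta)
cat("Spearman rho (panel VAF vs cancer cell content, FFPE):",
    round(corr$rho, 3), " p =", signif(corr$p_value, 3), "\n")

res <- data.frame(n_panel = audit$n_panel_variants,
                  n_below_0.1 = audit$n_below_threshold,
                  frac_below = audit$frac_below,
                  spearman_rho = corr$rho, p = corr$p_value)
write.table(res, "results/actionable_audit.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("A naive VAF<0.1 filter would discard genuine panel variants alongside\n")
cat("artefact; characterising artefact instead preserves them.\n")
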