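#!/usr/bin/env Rscript

# Stage 3: chromatin occupancy analytics.
#
# Venn overlaps of the peak sets (NONO vs TET1, TET1 WT vs KO), promoter
# target-gene assignment (TSS +/- 2 kb) and the common / WT-specific /
# KO-specific target partition, reduced-peak calls (knockout keeps at most
# half the wild-type signal, pseudocounted), genome-binned NONO-TET1
# Pearson correlation at 10-kb resolution, and TSS / gene-body metagene
# profiles of TET1 and 5hmC.
#
# Input: results/sim/   Output: results/chromatin/

suppressPackageStartupMessages(library(nonotet))

b <- load_inputs("results/sim")
cfg <- pipeline_config()
out <- "results/chromatin"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
wt <- function(df, f) write.table(df, file.path(out, f), sep = "\t",
                                  quote = FALSE, row.names = FALSE)

ov <- intersect_peaks(b$peaks$nono_wt, b$peaks$tet1_wt)
cat(sprintf("NONO peaks on TET1 peaks: %d of %d (%s)\n",
            ov$n_overlap_a, ov$n_a, fmt_pct(ov$n_overlap_a, ov$n_a)))
ov2 <- intersect_peaks(b$peaks$tet1_wt, b$peaks$tet1_ko)
cat(sprintf("TET1 WT peaks with a KO peak: %d of %d (%s)\n",
            ov2$n_overlap_a, ov2$n_a, fmt_pct(ov2$n_overlap_a, ov2$n_a)))

tw <- promoter_targets(b$peaks$tet1_wt, b$genes, cfg$promoter_flank_bp)
tk <- promoter_targets(b$peaks$tet1_ko, b$genes, cfg$promoter_flank_bp)
venn <- target_gene_venn(tw, tk)
cat(sprintf("promoter target genes: %d common, %d WT-specific, %d KO-specific\n",
            length(venn$common), length(venn$a_specific), length(venn$b_specific)))
wt(data.frame(gene_id = c(venn$common, venn$a_specific, venn$b_specific),
              group = rep(c("common", "WT_specific", "KO_specific"),
                          c(length(venn$common), length(venn$a_specific),
                            length(venn$b_specific)))),
   "target_gene_venn.tsv")

red <- identify_reduced_peaks(b$peaks$tet1_wt, b$tracks$tet1_wt,
                              b$tracks$tet1_ko, cfg)
cat(sprintf("reduced TET1 peaks: %d of %d (%s)\n",
            sum(red$reduced), nrow(red), fmt_pct(sum(red$reduced), nrow(red))))
wt(red, "reduced_tet1_peaks.tsv")

corr <- binned_correlation(rebin_track(b$tracks$nono_wt, cfg$bin_size_bp),
                           rebin_track(b$tracks$tet1_wt, cfg$bin_size_bp))
cat(sprintf("NONO-TET1 Pearson r over %d bins of %d bp: %.4f\n",
            corr$n_bins, cfg$bin_size_bp, corr$pearson_r))
wt(corr$bins, "nono_tet1_10kb_bins.tsv")

for (sel in list(c("tet1_wt", "tss"), c("hmc_wt", "tss"), c("hmc_ko", "tss"),
                  c("hmc_wt", "genebody"), c("hmc_ko", "genebody"))) {
  pr <- metagene_profile(b$tracks[[sel[1]]], b$genes, sel[2], cfg)
  wt(data.frame(position = pr$positions, mean_signal = pr$mean_signal),
     sprintf("metagene_%s_%s.tsv", sel[1], sel[2]))
  cat(sprintf("metagene %s (%s): max %.2f at position %s over %d genes\n",
              sel[1], sel[2], max(pr$mean_signal),
              format(pr$positions[which.max(pr$mean_signal)]), pr$n_genes))
}
cat("wrote", out, "\n")
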