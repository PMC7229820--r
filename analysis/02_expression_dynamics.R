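#!/usr/bin/env Rscript

# Stage 2: expression dynamics and the two-stage 9-square selection.
#
# Normalizes FPKM to TPM, computes day-12-vs-day-0 differential expression
# in each genotype (Welch test on log2 pseudocounted FPKM), classifies
# genes on the 9-square fold-change grid (WT on x, KO on y), and validates
# the stage-1 NONO-sensitive genes against the rescue genotype (KO + WT on
# x, KO on y). Scores the recovered dependent sets against the planted
# truth and writes scaled trajectories for the dependent-up genes.
#
# Input: results/sim/   Output: results/expression/

suppressPackageStartupMessages(library(nonotet))

b <- load_inputs("results/sim")
cfg <- pipeline_config()
dir.create("results/expression", recursive = TRUE, showWarnings = FALSE)
wt <- function(df, f) write.table(df, file.path("results/expression", f),
                                  sep = "\t", quote = FALSE, row.names = FALSE)

tpm <- fpkm_to_tpm(b$expression)
cat(sprintf("TPM columns sum to 1e6 within %.2g relative error\n",
            max(abs(colSums(tpm$values) - 1e6)) / 1e6))

de_for <- function(gt) {
  differential_expression(b$expression, samples_of(b$expression, gt, 0L),
                          samples_of(b$expression, gt, 12L), cfg)
}
de <- list(WT = de_for("WT"), KO = de_for("KO"), KO_WT = de_for("KO_WT"))
for (gt in names(de)) {
  wt(de[[gt]], sprintf("de_day12_vs_day0_%s.tsv", gt))
  cat(sprintf("%-5s day12 vs day0: %d up, %d down of %d genes\n", gt,
              sum(de[[gt]]$status == "up"), sum(de[[gt]]$status == "down"),
              nrow(de[[gt]])))
}

sel <- select_dependent_genes(de$WT, de$KO, de$KO_WT, cfg)
cat(sprintf("stage 1 (WT vs KO grid): %d up (F&I), %d down (A&D)\n",
            length(sel$stage1_up), length(sel$stage1_down)))
cat(sprintf("stage 2 (rescue-validated): %d of %d up (%s), %d of %d down (%s)\n",
            length(sel$up_dependent), length(sel$stage1_up),
            fmt_pct(length(sel$up_dependent), length(sel$stage1_up)),
            length(sel$down_dependent), length(sel$stage1_down),
            fmt_pct(length(sel$down_dependent), length(sel$stage1_down))))
wt(sel$stage1, "nine_square_stage1.tsv")
wt(sel$stage2, "nine_square_stage2.tsv")
wt(data.frame(gene_id = sel$up_dependent), "dependent_up.tsv")
wt(data.frame(gene_id = sel$down_dependent), "dependent_down.tsv")

# recovery against the planted truth
score <- function(called, planted) {
  c(sensitivity = mean(planted %in% called), precision = mean(called %in% planted))
}
up_true <- b$truth$gene_id[b$truth$class == "dep_up"]
dn_true <- b$truth$gene_id[b$truth$class == "dep_down"]
cat("dependent-up recovery: ",
    paste(sprintf("%s %.3f", names(score(sel$up_dependent, up_true)),
                  score(sel$up_dependent, up_true)), collapse = ", "), "\n")
cat("dependent-down recovery: ",
    paste(sprintf("%s %.3f", names(score(sel$down_dependent, dn_true)),
                  score(sel$down_dependent, dn_true)), collapse = ", "), "\n")

traj <- scale_trajectories(b$expression, sel$up_dependent)
wt(traj, "trajectories_dependent_up.tsv")
wt(data.frame(rank = 1:50, gene_id = top_differential(de$WT, 50L)),
   "top50_differential_WT.tsv")
cat("wrote results/expression\n")
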