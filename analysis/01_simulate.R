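#!/usr/bin/env Rscript

# Stage 1: generate the synthetic study.
#
# Builds a two-chromosome toy genome with 5000 genes, RNA-seq FPKM for the
# rescue design (WT, Nono KO, KO + re-expressed WT NONO; days 0/3/6/12 with
# 3+2+2+2 replicates per genotype), and coupled TET1 / NONO / 5hmC peak
# sets and signal tracks with planted ground truth: 500 dependent-up and
# 300 dependent-down genes, half the genes TET1-bound at the promoter, 60%
# of TET1 peaks reduced in the knockout, 85% of NONO peaks on TET1 peaks.
# Tracks are tiled at 500 bp here to keep the bedGraph files readable; the
# planted signal is broad relative to either tiling.
#
# Output: results/sim/ (BED / bedGraph / TSV + truth labels + md5 manifest).

suppressPackageStartupMessages(library(nonotet))

seed <- 20260921L %% 100000L
cfg <- simulation_config(seed = seed, track_bin_bp = 500L)
out <- "results/sim"

bundle <- simulate_all(cfg, out_dir = out, force = TRUE)

cat(sprintf("genome: %d genes on %d chromosomes of %g bp\n",
            nrow(bundle$genes), cfg$n_chroms, cfg$chrom_len_bp))
cat(sprintf("expression: %d x %d FPKM, planted %d up / %d down dependent genes\n",
            nrow(bundle$expression$values), ncol(bundle$expression$values),
            cfg$n_dep_up, cfg$n_dep_down))
cat(sprintf("chromatin: %d TET1 peaks (%d promoter-bound genes), %d NONO peaks\n",
            nrow(bundle$peaks$tet1_wt), sum(bundle$truth$tet1_bound),
            nrow(bundle$peaks$nono_wt)))
cat("wrote", out, "\n")
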