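#' Format a fraction as an integer percentage
#'
#' Rounds half away from zero, so 4948/5848 prints as "85%", 851/2005 as
#' "42%" and 513/1949 as "26%".
#'
#' @param num,den numerator and denominator.
#' @return Character scalar like "85%".
#' @export
fmt_pct <- function(num, den) {
  if (den == 0) return(ifelse(num == 0, "0%", "NA%"))
  sprintf("%d%%", as.integer(round_half_up(100 * num / den)))
}

#' Load a simulator-layout input directory
#'
#' Reads the files written by [simulate_all()] (annotation, expression,
#' peak BEDs, bedGraph tracks, chromosome sizes, optional truth labels and
#' gene sets) back into memory. Track bin size is inferred from the
#' bedGraph record widths.
#'
#' @param dir input directory.
#' @return A bundle list shaped like the [simulate_all()] return value.
#' @export
load_inputs <- function(dir) {
  p <- function(f) file.path(dir, f)
  need <- c("annotation.bed", "expression_fpkm.tsv", "chrom_sizes.tsv",
            "tet1_wt.bed", "tet1_ko.bed", "nono_wt.bed", "hmc_wt.bed", "hmc_ko.bed",
            "tet1_wt.bedgraph", "tet1_ko.bedgraph", "nono_wt.bedgraph",
            "hmc_wt.bedgraph", "hmc_ko.bedgraph")
  miss <- need[!file.exists(p(need))]
  if (length(miss)) stop("missing input file(s): ", paste(miss, collapse = ", "))
  cs <- utils::read.table(p("chrom_sizes.tsv"), sep = "\t", header = TRUE)
  chrom_sizes <- stats::setNames(as.integer(cs$length), cs$chrom)
  genes <- read_bed(p("annotation.bed"), kind = "genes")
  expr <- read_expression_tsv(p("expression_fpkm.tsv"))
  pk_names <- c("tet1_wt", "tet1_ko", "nono_wt", "hmc_wt", "hmc_ko")
  peaks <- lapply(pk_names, function(nm) read_bed(p(paste0(nm, ".bed")), kind = "peaks"))
  names(peaks) <- pk_names
  tracks <- lapply(pk_names, function(nm) {
    f <- p(paste0(nm, ".bedgraph"))
    first <- utils::read.table(f, sep = "\t", nrows = 50, header = FALSE)
    bs <- max(first[[3]] - first[[2]])
    read_bedgraph(f, bs, chrom_sizes)
  })
  names(tracks) <- pk_names
  bundle <- list(genes = genes, expression = expr, peaks = peaks,
                 tracks = tracks, chrom_sizes = chrom_sizes)
  if (file.exists(p("truth_labels.tsv"))) {
    bundle$truth <- utils::read.table(p("truth_labels.tsv"), sep = "\t",
                                      header = TRUE, stringsAsFactors = FALSE)
  }
  if (file.exists(p("gene_sets.tsv"))) {
    bundle$gene_sets <- read_gene_sets(p("gene_sets.tsv"), genes$gene_id)
  }
  bundle
}

#' Run the full integrative analysis
#'
#' Executes, in order: TPM normalization, day-12-vs-day-0 differential
#' expression in each genotype, two-stage 9-square selection of
#' rescue-validated NONO-dependent genes, trajectory scaling, top-gene
#' ranking, peak overlap Venn analyses (TET1 WT vs KO, NONO vs TET1),
#' promoter target assignment and target-gene Venn, reduced-peak calls,
#' genome-binned NONO-TET1 correlation, TSS and gene-body metagene
#' profiles, day-0 TET1-bound expression stratification, the chi-squared
#' association of day-0 differential expression with promoter binding loss,
#' and (when gene sets are supplied) hypergeometric over-representation of
#' the dependent-up set. Fully deterministic given its inputs.
#'
#' @param bundle an input bundle from [simulate_all()] or [load_inputs()].
#' @param cfg a [pipeline_config()].
#' @return A named list of stage results (see [write_report()]).
#' @export
run_pipeline <- function(bundle, cfg = pipeline_config()) {
  genes <- bundle$genes
  expr <- bundle$expression
  res <- list(config = cfg)

  log_msg("TPM normalization")
  res$tpm <- fpkm_to_tpm(expr)

  log_msg("differential expression day 12 vs day 0, three genotypes")
  de_for <- function(gt) {
    differential_expression(expr, samples_of(expr, gt, 0L),
                            samples_of(expr, gt, 12L), cfg)
  }
  res$de <- list(WT = de_for("WT"), KO = de_for("KO"), KO_WT = de_for("KO_WT"))

  log_msg("two-stage 9-square dependent-gene selection")
  res$dependent <- select_dependent_genes(res$de$WT, res$de$KO, res$de$KO_WT, cfg)

  log_msg("trajectory scaling for the dependent-up set")
  traj_genes <- res$dependent$up_dependent
  res$trajectories <- if (length(traj_genes)) scale_trajectories(expr, traj_genes) else NULL

  res$top50 <- top_differential(res$de$WT, min(50L, nrow(res$de$WT)))

  log_msg("peak overlap Venn analyses")
  res$overlap_tet1_wt_ko <- intersect_peaks(bundle$peaks$tet1_wt, bundle$peaks$tet1_ko)
  res$overlap_nono_tet1 <- intersect_peaks(bundle$peaks$nono_wt, bundle$peaks$tet1_wt)

  log_msg("promoter target assignment")
  res$targets_wt <- promoter_targets(bundle$peaks$tet1_wt, genes, cfg$promoter_flank_bp)
  res$targets_ko <- promoter_targets(bundle$peaks$tet1_ko, genes, cfg$promoter_flank_bp)
  res$target_venn <- target_gene_venn(res$targets_wt, res$targets_ko)

  log_msg("reduced TET1 peaks")
  res$reduced <- identify_reduced_peaks(bundle$peaks$tet1_wt,
                                        bundle$tracks$tet1_wt,
                                        bundle$tracks$tet1_ko, cfg)

  log_msg("binned NONO-TET1 correlation")
  coarse <- function(tr) {
    if (tr$bin_size < cfg$bin_size_bp) rebin_track(tr, cfg$bin_size_bp) else tr
  }
  res$correlation <- binned_correlation(coarse(bundle$tracks$nono_wt),
                                        coarse(bundle$tracks$tet1_wt))

  log_msg("metagene profiles")
  res$metagene <- list(
    tet1_tss = metagene_profile(bundle$tracks$tet1_wt, genes, "tss", cfg),
    hmc_wt_tss = metagene_profile(bundle$tracks$hmc_wt, genes, "tss", cfg),
    hmc_ko_tss = metagene_profile(bundle$tracks$hmc_ko, genes, "tss", cfg),
    hmc_wt_body = metagene_profile(bundle$tracks$hmc_wt, genes, "genebody", cfg),
    hmc_ko_body = metagene_profile(bundle$tracks$hmc_ko, genes, "genebody", cfg)
  )

  log_msg("day-0 stratification by promoter TET1 binding")
  res$stratification <- stratify_expression_by_binding(
    genes, res$targets_wt, bundle$tracks, expr, cfg)

  log_msg("chi-squared association of day-0 DE with binding loss")
  de0 <- differential_expression(expr, samples_of(expr, "WT", 0L),
                                 samples_of(expr, "KO", 0L), cfg)
  res$de_day0 <- de0
  reduced_genes <- genes_with_reduced_promoter(genes, bundle$peaks$tet1_wt,
                                               res$reduced, cfg)
  res$reduced_genes <- reduced_genes
  res$association <- chi_squared_association(
    de0$gene_id[de0$status != "ns"], reduced_genes, genes$gene_id)

  if (!is.null(bundle$gene_sets) && length(res$dependent$up_dependent)) {
    log_msg("over-representation of the dependent-up set")
    res$ora <- ora_hypergeometric(res$dependent$up_dependent, bundle$gene_sets)
  }
  res
}

#' Genes whose promoter carries at least one reduced peak
#'
#' @param genes gene models.
#' @param peaks the reference peak set used for the reduced-peak call.
#' @param reduced the [identify_reduced_peaks()] table for `peaks`.
#' @param cfg a [pipeline_config()].
#' @return Character vector of gene ids.
#' @export
genes_with_reduced_promoter <- function(genes, peaks, reduced, cfg = pipeline_config()) {
  stopifnot(nrow(peaks) == nrow(reduced))
  assign <- promoter_targets(peaks, genes, cfg$promoter_flank_bp)
  hit <- vapply(assign$assignments, function(idx) any(reduced$reduced[idx]), logical(1))
  names(assign$assignments)[hit]
}

#' Write the pipeline report bundle
#'
#' One TSV per stage plus a plain-text `summary.txt` whose headline
#' percentages are printed as round-half-away-from-zero integers alongside
#' the raw fractions; every number in the summary is traceable to a stage
#' file.
#'
#' @param res a [run_pipeline()] result.
#' @param out_dir output directory (created if needed).
#' @return Invisibly, the path of the summary file.
#' @export
write_report <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(out_dir, f)
  wt <- function(df, f) utils::write.table(df, p(f), sep = "\t", quote = FALSE,
                                           row.names = FALSE)
  for (gt in names(res$de)) wt(res$de[[gt]], sprintf("de_day12_vs_day0_%s.tsv", gt))
  wt(res$de_day0, "de_day0_KO_vs_WT.tsv")
  wt(res$dependent$stage1, "nine_square_stage1.tsv")
  wt(res$dependent$stage2, "nine_square_stage2.tsv")
  wt(data.frame(gene_id = res$dependent$up_dependent), "dependent_up.tsv")
  wt(data.frame(gene_id = res$dependent$down_dependent), "dependent_down.tsv")
  if (!is.null(res$trajectories)) wt(res$trajectories, "trajectories_scaled.tsv")
  wt(data.frame(rank = seq_along(res$top50), gene_id = res$top50), "top_differential.tsv")
  wt(res$reduced, "reduced_peaks.tsv")
  wt(res$correlation$bins, "correlation_bins.tsv")
  for (nm in names(res$metagene)) {
    wt(data.frame(position = res$metagene[[nm]]$positions,
                  mean_signal = res$metagene[[nm]]$mean_signal),
       sprintf("metagene_%s.tsv", nm))
  }
  wt(res$stratification$per_gene, "stratification_per_gene.tsv")
  wt(res$stratification$group_means, "stratification_groups.tsv")
  if (!is.null(res$ora)) wt(res$ora, "ora_dependent_up.tsv")

  ov <- res$overlap_nono_tet1
  ov2 <- res$overlap_tet1_wt_ko
  nred <- sum(res$reduced$reduced)
  s1u <- length(res$dependent$stage1_up)
  s1d <- length(res$dependent$stage1_down)
  lines <- c(
    "integrative NONO/TET1/5hmC pipeline summary",
    "",
    sprintf("genes: %d   samples: %d", nrow(res$de$WT), nrow(res$tpm$samples)),
    sprintf("stage-1 up (F&I): %d   rescue-validated up-dependent (F'&I'): %d of %d (%s)",
            s1u, length(res$dependent$up_dependent), s1u,
            fmt_pct(length(res$dependent$up_dependent), s1u)),
    sprintf("stage-1 down (A&D): %d   rescue-validated down-dependent (A''&D''): %d of %d (%s)",
            s1d, length(res$dependent$down_dependent), s1d,
            fmt_pct(length(res$dependent$down_dependent), s1d)),
    sprintf("NONO peaks on TET1 peaks: %d of %d (%s)",
            ov$n_overlap_a, ov$n_a, fmt_pct(ov$n_overlap_a, ov$n_a)),
    sprintf("TET1 WT peaks overlapping a KO peak: %d of %d (%s)",
            ov2$n_overlap_a, ov2$n_a, fmt_pct(ov2$n_overlap_a, ov2$n_a)),
    sprintf("reduced TET1 peaks: %d of %d (%s)",
            nred, nrow(res$reduced), fmt_pct(nred, nrow(res$reduced))),
    sprintf("promoter target genes: common %d, WT-specific %d, KO-specific %d",
            length(res$target_venn$common), length(res$target_venn$a_specific),
            length(res$target_venn$b_specific)),
    sprintf("NONO-TET1 Pearson r over %d bins of %d bp: %.4f",
            res$correlation$n_bins, res$config$bin_size_bp,
            res$correlation$pearson_r),
    sprintf("day-0 DE (KO vs WT): %d genes (%d up, %d down)",
            sum(res$de_day0$status != "ns"), sum(res$de_day0$status == "up"),
            sum(res$de_day0$status == "down")),
    sprintf("DE x reduced-binding association: chi2 = %.2f, p = %.3g",
            res$association$chi2, res$association$p_value),
    sprintf("stratified day-0 log2(KO/WT) [bound | not bound]: binding %.3f | %.3f, 5hmC %.3f | %.3f, expression %.3f | %.3f",
            res$stratification$group_means$binding[1],
            res$stratification$group_means$binding[2],
            res$stratification$group_means$hmc[1],
            res$stratification$group_means$hmc[2],
            res$stratification$group_means$expression[1],
            res$stratification$group_means$expression[2])
  )
  if (!is.null(res$ora)) {
    lines <- c(lines, sprintf("top enriched set: %s (k=%d/%d, p=%.3g, q=%.3g)",
                              res$ora$set_name[1], res$ora$k[1], res$ora$K[1],
                              res$ora$p_value[1], res$ora$q_value[1]))
  }
  writeLines(lines, p("summary.txt"))
  invisible(p("summary.txt"))
}
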