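#' Normalize FPKM to TPM
#'
#' TPM for gene g in sample s is `FPKM_gs / sum_g(FPKM_gs) * 1e6`, so every
#' sample column sums to one million and abundances are comparable across
#' samples.
#'
#' @param m an [expression_matrix()] with unit FPKM.
#' @return An [expression_matrix()] with unit TPM.
#' @export
fpkm_to_tpm <- function(m) {
  stopifnot(inherits(m, "expression_matrix"))
  if (m$unit != "FPKM") stop("input unit must be FPKM")
  cs <- colSums(m$values)
  if (any(cs <= 0)) {
    stop("all-zero sample column: ", paste(colnames(m$values)[cs <= 0], collapse = ", "))
  }
  expression_matrix(sweep(m$values, 2, cs, "/") * 1e6, m$samples, unit = "TPM")
}

#' Two-group differential expression
#'
#' For each gene, the log2 fold-change of condition B over condition A on
#' pseudocounted replicate means, and a Welch two-sample t-test on
#' `log2(value + pseudocount)`. A gene is called `up` when
#' `log2fc > log2(fc_cutoff)` and `p < p_cutoff` (strict inequalities),
#' `down` symmetrically, otherwise `ns`. Degenerate genes whose replicates
#' are identical within each group get p = 1 when the group means agree and
#' p = 0 otherwise.
#'
#' @param m an [expression_matrix()].
#' @param samples_a,samples_b sample ids of the two conditions (>= 2 each).
#' @param cfg a [pipeline_config()].
#' @return A data frame with columns gene_id, log2fc, p_value, mean_a,
#'   mean_b, status.
#' @export
differential_expression <- function(m, samples_a, samples_b, cfg = pipeline_config()) {
  stopifnot(inherits(m, "expression_matrix"))
  if (length(samples_a) < 2 || length(samples_b) < 2) {
    stop("need >= 2 replicates per condition")
  }
  miss <- setdiff(c(samples_a, samples_b), colnames(m$values))
  if (length(miss)) stop("unknown sample: ", paste(miss, collapse = ", "))
  a <- m$values[, samples_a, drop = FALSE]
  b <- m$values[, samples_b, drop = FALSE]
  pc <- cfg$pseudocount
  mean_a <- rowMeans(a)
  mean_b <- rowMeans(b)
  log2fc <- log2((mean_b + pc) / (mean_a + pc))
  la <- log2(a + pc)
  lb <- log2(b + pc)
  p <- vapply(seq_len(nrow(a)), function(i) {
    welch_p(la[i, ], lb[i, ])
  }, numeric(1))
  status <- rep("ns", length(p))
  up <- log2fc > log2(cfg$fc_cutoff) & p < cfg$p_cutoff
  down <- log2fc < -log2(cfg$fc_cutoff) & p < cfg$p_cutoff
  status[up] <- "up"
  status[down] <- "down"
  data.frame(gene_id = rownames(m$values), log2fc = log2fc, p_value = p,
             mean_a = mean_a, mean_b = mean_b, status = status,
             row.names = NULL, stringsAsFactors = FALSE)
}

welch_p <- function(x, y) {
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    return(if (isTRUE(all.equal(mean(x), mean(y)))) 1 else 0)
  }
  stats::t.test(x, y)$p.value
}

#' Classify genes on a 9-square fold-change grid
#'
#' Genes are placed on a 3 x 3 grid by thresholding two log2 fold-changes
#' at `+/- cutoff_log2`. With rows the y category (top to bottom up / ns /
#' down) and columns the x category (left to right down / ns / up), the
#' cells are lettered row-major:
#' \preformatted{
#'        x down  x ns  x up
#'  y up    A      B     C
#'  y ns    D      E     F
#'  y down  G      H     I
#' }
#' so F + I collects genes up on x but not up on y, and A + D genes down on
#' x but not down on y. Placement uses fold-change alone; significance lives
#' in the DE status, not the grid.
#'
#' @param fc_x,fc_y named numeric vectors of per-gene log2 fold-changes over
#'   the same gene universe.
#' @param cutoff_log2 grid threshold on |log2 fold-change|
#'   (default log2(1.5)).
#' @return A data frame (gene_id, group) with attributes `cutoff_log2`,
#'   `x_axis`, `y_axis`.
#' @export
classify_nine_square <- function(fc_x, fc_y, cutoff_log2 = log2(1.5)) {
  if (is.null(names(fc_x)) || is.null(names(fc_y))) {
    stop("fold-change vectors must be named by gene_id")
  }
  if (!setequal(names(fc_x), names(fc_y))) stop("gene universes differ between axes")
  fc_y <- fc_y[names(fc_x)]
  bad <- !is.finite(fc_x) | !is.finite(fc_y)
  if (any(bad)) {
    stop("non-finite fold-change for: ", paste(names(fc_x)[bad], collapse = ", "))
  }
  cat3 <- function(v) ifelse(v > cutoff_log2, 3L, ifelse(v < -cutoff_log2, 1L, 2L))
  xc <- cat3(fc_x)  # 1 down, 2 ns, 3 up
  yc <- cat3(fc_y)
  grid <- matrix(c("A", "B", "C",
                   "D", "E", "F",
                   "G", "H", "I"), nrow = 3, byrow = TRUE)
  group <- grid[cbind(4L - yc, xc)]
  out <- data.frame(gene_id = names(fc_x), group = group,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "cutoff_log2") <- cutoff_log2
  out
}

nine_square_groups <- function(ns, letters) {
  ns$gene_id[ns$group %in% letters]
}

#' Select rescue-validated NONO-dependent genes
#'
#' Two-stage 9-square selection. Stage 1 classifies the day-12 versus day-0
#' log2 fold-changes with WT on x and KO on y: groups F and I are genes up
#' in WT but not up in KO, groups A and D genes down in WT but not down in
#' KO. Stage 2 re-classifies the stage-1 genes with the rescue genotype
#' (KO + WT) on x and KO on y: stage-1 up genes that are again up in the
#' rescue but not in KO are the rescue-validated up-dependent set, and
#' symmetrically for down. Dependence on NONO is thus required twice: loss
#' in the knockout and restoration by re-expression.
#'
#' @param de_wt,de_ko,de_rescue DE tables (day 12 vs day 0) for WT, KO and
#'   KO + WT over the same gene universe, as returned by
#'   [differential_expression()].
#' @param cfg a [pipeline_config()]; `fc_cutoff` sets the grid threshold.
#' @return list(up_dependent, down_dependent, stage1_up, stage1_down) of
#'   gene-id vectors, plus the two 9-square tables (`stage1`, `stage2`).
#' @export
select_dependent_genes <- function(de_wt, de_ko, de_rescue, cfg = pipeline_config()) {
  u <- de_wt$gene_id
  if (!setequal(u, de_ko$gene_id) || !setequal(u, de_rescue$gene_id)) {
    stop("DE tables cover different gene universes")
  }
  fc <- function(de) stats::setNames(de$log2fc, de$gene_id)
  cut <- log2(cfg$fc_cutoff)
  s1 <- classify_nine_square(fc(de_wt), fc(de_ko), cut)
  stage1_up <- nine_square_groups(s1, c("F", "I"))
  stage1_down <- nine_square_groups(s1, c("A", "D"))
  s2 <- classify_nine_square(fc(de_rescue), fc(de_ko), cut)
  up_dep <- intersect(stage1_up, nine_square_groups(s2, c("F", "I")))
  down_dep <- intersect(stage1_down, nine_square_groups(s2, c("A", "D")))
  list(up_dependent = up_dep, down_dependent = down_dep,
       stage1_up = stage1_up, stage1_down = stage1_down,
       stage1 = s1, stage2 = s2)
}

#' Per-genotype scaled expression trajectories
#'
#' For each gene and genotype, replicate FPKM are averaged per timepoint and
#' the resulting trajectory is min-max scaled to [0, 1]; a constant
#' trajectory maps to all zeros.
#'
#' @param m an [expression_matrix()].
#' @param genes optional gene ids to restrict to (default: all).
#' @return A data frame with columns gene_id, genotype, timepoint, mean_value,
#'   scaled.
#' @export
scale_trajectories <- function(m, genes = NULL) {
  stopifnot(inherits(m, "expression_matrix"))
  ids <- genes %||% rownames(m$values)
  miss <- setdiff(ids, rownames(m$values))
  if (length(miss)) stop("unknown gene: ", paste(miss, collapse = ", "))
  sm <- m$samples
  out <- list()
  for (gt in unique(sm$genotype)) {
    tps <- sort(unique(sm$timepoint[sm$genotype == gt]))
    means <- sapply(tps, function(tp) {
      cols <- sm$sample_id[sm$genotype == gt & sm$timepoint == tp]
      rowMeans(m$values[ids, cols, drop = FALSE])
    })
    means <- matrix(means, nrow = length(ids),
                    dimnames = list(ids, as.character(tps)))
    rng <- apply(means, 1, range)
    span <- rng[2, ] - rng[1, ]
    scaled <- (means - rng[1, ]) / ifelse(span == 0, 1, span)
    scaled[span == 0, ] <- 0
    out[[gt]] <- data.frame(
      gene_id = rep(ids, times = length(tps)),
      genotype = gt,
      timepoint = rep(tps, each = length(ids)),
      mean_value = as.vector(means),
      scaled = as.vector(scaled),
      stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Rank the most differential genes
#'
#' Orders by |log2fc| descending; ties broken by ascending p-value, then by
#' gene id.
#'
#' @param records a DE table from [differential_expression()].
#' @param k number of genes to return (`k <=` universe size).
#' @return Character vector of the top `k` gene ids.
#' @export
top_differential <- function(records, k) {
  if (k > nrow(records)) stop("k exceeds the gene universe")
  o <- order(-abs(records$log2fc), records$p_value, records$gene_id)
  records$gene_id[o][seq_len(k)]
}

#' Sample ids of a genotype/timepoint cell
#'
#' @param m an [expression_matrix()].
#' @param genotype,timepoint the cell to select.
#' @return Character vector of sample ids.
#' @export
samples_of <- function(m, genotype, timepoint) {
  sm <- m$samples
  sm$sample_id[sm$genotype == genotype & sm$timepoint == timepoint]
}
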