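#' Peak set overlap (Venn) analysis
#'
#' Counts, by a linear merge sweep over the two sorted sets, how many peaks
#' of A overlap at least one peak of B (>= 1 bp shared, same chromosome) and
#' vice versa. Inputs must already be sorted by (chrom, start); unsorted
#' input is an error, never silently sorted.
#'
#' @param a,b [peak_set()]s sorted by (chrom, start).
#' @return list(n_a = |A|, n_b = |B|, n_overlap_a, n_a_only, n_overlap_b,
#'   n_b_only, pct_a_overlapping (rounded to nearest integer),
#'   a_overlapping, a_only (logical index into A), b_overlapping (into B)).
#' @export
intersect_peaks <- function(a, b) {
  if (!is_sorted_peaks(a) || !is_sorted_peaks(b)) {
    stop("peak sets must be sorted by (chrom, start)")
  }
  hit_a <- sweep_hits(a, b)
  hit_b <- sweep_hits(b, a)
  n_a <- nrow(a); n_b <- nrow(b)
  res <- list(
    n_a = n_a, n_b = n_b,
    n_overlap_a = sum(hit_a), n_a_only = sum(!hit_a),
    n_overlap_b = sum(hit_b), n_b_only = sum(!hit_b),
    pct_a_overlapping = if (n_a > 0) round_half_up(100 * sum(hit_a) / n_a) else NA_real_,
    a_overlapping = hit_a, a_only = !hit_a, b_overlapping = hit_b
  )
  res
}

# logical vector: which intervals of q overlap >=1 interval of r.
# Both sorted by (chrom, start); classic two-pointer sweep per chromosome,
# advancing the reference pointer only past intervals that can no longer
# overlap any later query (max running end tracked to handle containment).
sweep_hits <- function(q, r) {
  hit <- rep(FALSE, nrow(q))
  if (nrow(q) == 0 || nrow(r) == 0) return(hit)
  for (ch in unique(q$chrom)) {
    qi <- which(q$chrom == ch)
    ri <- which(r$chrom == ch)
    if (length(ri) == 0) next
    rs <- r$start[ri]; re <- r$end[ri]
    j <- 1L
    nr <- length(ri)
    for (k in qi) {
      qs <- q$start[k]; qe <- q$end[k]
      while (j <= nr && re[j] <= qs) j <- j + 1L
      # scan forward from j; sorted starts let us stop once rs >= qe
      jj <- j
      while (jj <= nr && rs[jj] < qe) {
        if (re[jj] > qs) { hit[k] <- TRUE; break }
        jj <- jj + 1L
      }
    }
  }
  hit
}

round_half_up <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Assign peaks to promoter target genes
#'
#' A gene is a target when at least one peak intersects its promoter window
#' `[tss - flank, tss + flank)`, clipped at zero. Windows respect strand
#' through the TSS definition (start on "+", end - 1 on "-").
#'
#' @param peaks a [peak_set()].
#' @param genes gene models.
#' @param flank promoter half-width in bp (> 0).
#' @return list(assignments = named list gene_id -> integer indices of
#'   overlapping peaks (row numbers in `peaks`), target_genes = character
#'   vector of targeted gene ids).
#' @export
promoter_targets <- function(peaks, genes, flank = 2000L) {
  stopifnot(flank > 0)
  win <- data.frame(chrom = genes$chrom,
                    start = pmax(0L, as.integer(genes$tss - flank)),
                    end = as.integer(pmax(genes$tss + flank, genes$tss + 1L)),
                    stringsAsFactors = FALSE)
  assignments <- stats::setNames(vector("list", nrow(genes)), genes$gene_id)
  for (ch in unique(win$chrom)) {
    gi <- which(win$chrom == ch)
    pi <- which(peaks$chrom == ch)
    if (length(pi) == 0) next
    ps <- peaks$start[pi]; pe <- peaks$end[pi]
    for (g in gi) {
      ov <- pi[ps < win$end[g] & pe > win$start[g]]
      if (length(ov)) assignments[[genes$gene_id[g]]] <- ov
    }
  }
  targeted <- genes$gene_id[lengths(assignments) > 0]
  list(assignments = assignments[lengths(assignments) > 0],
       target_genes = targeted)
}

#' Venn partition of two promoter target-gene sets
#'
#' @param assign_a,assign_b results of [promoter_targets()] over the same
#'   annotation (e.g. WT and KO peak sets).
#' @return list(common, a_specific, b_specific) of gene-id vectors.
#' @export
target_gene_venn <- function(assign_a, assign_b) {
  a <- assign_a$target_genes
  b <- assign_b$target_genes
  list(common = intersect(a, b),
       a_specific = setdiff(a, b),
       b_specific = setdiff(b, a))
}

#' Mean track signal over a set of intervals
#'
#' Length-weighted mean of the binned values across each interval's span.
#'
#' @param track a [signal_track()].
#' @param df data frame with chrom, start, end.
#' @return Numeric vector, one mean per interval.
#' @export
interval_track_means <- function(track, df) {
  miss <- setdiff(unique(df$chrom), names(track$values))
  if (length(miss)) stop("chromosome absent from track: ", miss[1])
  bs <- track$bin_size
  vapply(seq_len(nrow(df)), function(i) {
    ch <- df$chrom[i]
    s <- df$start[i]
    e <- min(df$end[i], track$chrom_sizes[[ch]])
    v <- track$values[[ch]]
    b0 <- s %/% bs
    b1 <- (e - 1L) %/% bs
    bins <- b0:b1
    lo <- pmax(s, bins * bs)
    hi <- pmin(e, (bins + 1) * bs)
    sum(v[bins + 1] * (hi - lo)) / (e - s)
  }, numeric(1))
}

#' Identify peaks with reduced occupancy in the knockout
#'
#' For each reference peak the signal in each condition is the
#' length-weighted mean track value over the peak span; the peak is flagged
#' reduced when `log2((KO + pc) / (WT + pc)) <= reduced_log2_cutoff`
#' (default -1: the knockout retains at most half the wild-type signal).
#'
#' @param peaks_ref reference [peak_set()] (typically the WT call set).
#' @param track_wt,track_ko [signal_track()]s sharing bin size and
#'   chromosome sizes.
#' @param cfg a [pipeline_config()].
#' @return A data frame (chrom, start, end, signal_wt, signal_ko,
#'   log2_ratio, reduced) in `peaks_ref` order.
#' @export
identify_reduced_peaks <- function(peaks_ref, track_wt, track_ko, cfg = pipeline_config()) {
  if (!same_binning(track_wt, track_ko)) {
    stop("tracks must share bin size and chromosome sizes")
  }
  s_wt <- interval_track_means(track_wt, peaks_ref)
  s_ko <- interval_track_means(track_ko, peaks_ref)
  pc <- cfg$pseudocount
  lr <- log2((s_ko + pc) / (s_wt + pc))
  data.frame(chrom = peaks_ref$chrom, start = peaks_ref$start,
             end = peaks_ref$end, signal_wt = s_wt, signal_ko = s_ko,
             log2_ratio = lr, reduced = lr <= cfg$reduced_log2_cutoff,
             stringsAsFactors = FALSE)
}

#' Genome-wide binned correlation of two tracks
#'
#' Pearson correlation over all genome bins of two identically binned
#' tracks, zero-signal bins included (the read-count-in-fixed-windows
#' convention). Set `nonzero_only = TRUE` to restrict to bins where either
#' track is non-zero.
#'
#' @param track_a,track_b [signal_track()]s with identical binning.
#' @param nonzero_only drop bins that are zero in both tracks.
#' @return list(pearson_r, n_bins, bins = data.frame(chrom, bin, a, b)).
#' @export
binned_correlation <- function(track_a, track_b, nonzero_only = FALSE) {
  if (!same_binning(track_a, track_b)) {
    stop("tracks must share bin size and chromosome sizes")
  }
  bins <- do.call(rbind, lapply(names(track_a$values), function(ch) {
    data.frame(chrom = ch, bin = seq_along(track_a$values[[ch]]) - 1L,
               a = track_a$values[[ch]], b = track_b$values[[ch]],
               stringsAsFactors = FALSE)
  }))
  if (nonzero_only) bins <- bins[bins$a > 0 | bins$b > 0, , drop = FALSE]
  if (nrow(bins) < 3) stop("need at least 3 bins")
  if (stats::var(bins$a) == 0 || stats::var(bins$b) == 0) {
    stop("constant track: correlation undefined")
  }
  list(pearson_r = stats::cor(bins$a, bins$b), n_bins = nrow(bins), bins = bins)
}

#' Metagene signal profile at TSSs or across gene bodies
#'
#' TSS mode samples the track at its own bin resolution at offsets
#' `-flank ... +flank` around each TSS (flank must be a multiple of the bin
#' size, giving `2 * flank / bin + 1` positions); gene-body mode rescales
#' each gene body to `nbins` equal-length fractions and takes the
#' length-weighted mean per fraction. Minus-strand genes are reversed so
#' position runs 5' to 3'. The profile is the per-position mean over genes;
#' genes whose window leaves the chromosome are dropped in TSS mode.
#'
#' @param track a [signal_track()].
#' @param genes gene models (non-empty).
#' @param mode "tss" or "genebody".
#' @param cfg a [pipeline_config()]; uses `metagene_flank_bp` and
#'   `genebody_nbins`.
#' @return list(mode, positions, mean_signal, n_genes).
#' @export
metagene_profile <- function(track, genes, mode = c("tss", "genebody"),
                             cfg = pipeline_config()) {
  mode <- match.arg(mode)
  if (nrow(genes) == 0) stop("empty gene list")
  miss <- setdiff(unique(genes$chrom), names(track$values))
  if (length(miss)) stop("chromosome absent from track: ", miss[1])
  bs <- track$bin_size
  if (mode == "tss") {
    flank <- cfg$metagene_flank_bp
    if (flank %% bs != 0) stop("metagene_flank_bp must be a multiple of the track bin size")
    offs <- seq(-flank, flank, by = bs)
    prof <- matrix(NA_real_, nrow(genes), length(offs))
    for (i in seq_len(nrow(genes))) {
      ch <- genes$chrom[i]
      pos <- genes$tss[i] + offs
      if (pos[1] < 0 || pos[length(pos)] >= track$chrom_sizes[[ch]]) next
      v <- track$values[[ch]][pos %/% bs + 1]
      if (genes$strand[i] == "-") v <- rev(v)
      prof[i, ] <- v
    }
    keep <- !is.na(prof[, 1])
    if (!any(keep)) stop("no gene window fits inside the genome")
    list(mode = "tss", positions = offs,
         mean_signal = colMeans(prof[keep, , drop = FALSE]),
         n_genes = sum(keep))
  } else {
    nb <- cfg$genebody_nbins
    prof <- matrix(NA_real_, nrow(genes), nb)
    for (i in seq_len(nrow(genes))) {
      bounds <- genes$start[i] + (genes$end[i] - genes$start[i]) * (0:nb) / nb
      seg <- data.frame(chrom = genes$chrom[i],
                        start = bounds[-(nb + 1)], end = bounds[-1])
      v <- fractional_track_means(track, seg)
      if (genes$strand[i] == "-") v <- rev(v)
      prof[i, ] <- v
    }
    list(mode = "genebody", positions = (seq_len(nb) - 0.5) / nb * 100,
         mean_signal = colMeans(prof), n_genes = nrow(genes))
  }
}

# length-weighted track means over (possibly fractional-bp) segments
fractional_track_means <- function(track, df) {
  bs <- track$bin_size
  vapply(seq_len(nrow(df)), function(i) {
    ch <- df$chrom[i]
    s <- df$start[i]
    e <- min(df$end[i], track$chrom_sizes[[ch]])
    v <- track$values[[ch]]
    b0 <- floor(s / bs)
    b1 <- ceiling(e / bs) - 1
    bins <- b0:b1
    lo <- pmax(s, bins * bs)
    hi <- pmin(e, (bins + 1) * bs)
    sum(v[bins + 1] * (hi - lo)) / (e - s)
  }, numeric(1))
}

#' Stratify knockout-vs-WT changes by promoter TET1 binding
#'
#' Partitions genes into TET1-bound (>= 1 promoter peak, per `assignment`)
#' and not-bound, then averages per group the log2((KO + pc) / (WT + pc))
#' of three quantities per gene: promoter-window mean TET1 signal,
#' promoter-window mean 5hmC signal, and mean day-0 FPKM.
#'
#' @param genes gene models.
#' @param assignment a [promoter_targets()] result defining the bound group.
#' @param tracks named list with elements tet1_wt, tet1_ko, hmc_wt, hmc_ko.
#' @param expr an [expression_matrix()] containing WT and KO day-0 samples.
#' @param cfg a [pipeline_config()].
#' @return list(per_gene = data frame with the three per-gene log2 ratios
#'   and the bound flag, group_means = data frame group x quantity).
#' @export
stratify_expression_by_binding <- function(genes, assignment, tracks, expr,
                                           cfg = pipeline_config()) {
  need <- c("tet1_wt", "tet1_ko", "hmc_wt", "hmc_ko")
  stopifnot(all(need %in% names(tracks)))
  for (gt in c("WT", "KO")) {
    if (length(samples_of(expr, gt, 0L)) == 0) stop("missing day-0 samples for genotype ", gt)
  }
  flank <- cfg$promoter_flank_bp
  win <- data.frame(chrom = genes$chrom,
                    start = pmax(0L, as.integer(genes$tss - flank)),
                    end = as.integer(genes$tss + flank), stringsAsFactors = FALSE)
  pc <- cfg$pseudocount
  lr <- function(ko, wt) log2((ko + pc) / (wt + pc))
  bind_lr <- lr(interval_track_means(tracks$tet1_ko, win),
                interval_track_means(tracks$tet1_wt, win))
  hmc_lr <- lr(interval_track_means(tracks$hmc_ko, win),
               interval_track_means(tracks$hmc_wt, win))
  e_wt <- rowMeans(expr$values[genes$gene_id, samples_of(expr, "WT", 0L), drop = FALSE])
  e_ko <- rowMeans(expr$values[genes$gene_id, samples_of(expr, "KO", 0L), drop = FALSE])
  expr_lr <- lr(e_ko, e_wt)
  bound <- genes$gene_id %in% assignment$target_genes
  per_gene <- data.frame(gene_id = genes$gene_id, tet1_bound = bound,
                         binding_log2fc = bind_lr, hmc_log2fc = hmc_lr,
                         expression_log2fc = expr_lr, stringsAsFactors = FALSE)
  gm <- do.call(rbind, lapply(c(TRUE, FALSE), function(bb) {
    sub <- per_gene[per_gene$tet1_bound == bb, ]
    data.frame(group = if (bb) "TET1_bound" else "not_TET1_bound",
               n = nrow(sub),
               binding = mean(sub$binding_log2fc),
               hmc = mean(sub$hmc_log2fc),
               expression = mean(sub$expression_log2fc))
  }))
  list(per_gene = per_gene, group_means = gm)
}

#' Chi-squared association of differential expression with binding loss
#'
#' Builds the 2 x 2 table (DE vs not) x (reduced promoter binding vs not)
#' over a gene universe and computes the Pearson chi-squared statistic
#' `sum((O - E)^2 / E)` with one degree of freedom, no continuity
#' correction. An expected cell below 1 is recorded as a warning flag, not
#' an error.
#'
#' @param de_genes,reduced_genes gene-id vectors, subsets of `universe`.
#' @param universe all gene ids under consideration.
#' @return list(table = 2 x 2 matrix, chi2, p_value, warning).
#' @export
chi_squared_association <- function(de_genes, reduced_genes, universe) {
  if (length(setdiff(de_genes, universe)) || length(setdiff(reduced_genes, universe))) {
    stop("gene sets must be subsets of the universe")
  }
  de <- universe %in% de_genes
  red <- universe %in% reduced_genes
  obs <- matrix(c(sum(de & red), sum(de & !red),
                  sum(!de & red), sum(!de & !red)),
                nrow = 2, byrow = TRUE,
                dimnames = list(c("DE", "not_DE"), c("reduced", "not_reduced")))
  n <- sum(obs)
  expd <- outer(rowSums(obs), colSums(obs)) / n
  if (any(expd == 0)) {
    return(list(table = obs, chi2 = 0, p_value = 1,
                warning = "degenerate margin (expected cell = 0)"))
  }
  chi2 <- sum((obs - expd)^2 / expd)
  list(table = obs, chi2 = chi2,
       p_value = stats::pchisq(chi2, df = 1, lower.tail = FALSE),
       warning = if (any(expd < 1)) "expected cell < 1" else NA_character_)
}
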