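#' Gene models
#'
#' A gene annotation is a data frame with columns `gene_id`, `chrom`,
#' `start`, `end` (0-based half-open), `strand` and the derived `tss`
#' (`start` on the plus strand, `end - 1` on the minus strand). All
#' coordinates in this package are BED-native 0-based half-open.
#'
#' @param gene_id character gene identifiers, unique.
#' @param chrom character chromosome names (taken verbatim, no "chr"
#'   normalization).
#' @param start,end integer coordinates, `start < end`.
#' @param strand "+" or "-".
#' @return A data frame of gene models, sorted by (chrom, start).
#' @export
gene_models <- function(gene_id, chrom, start, end, strand) {
  g <- data.frame(
    gene_id = as.character(gene_id),
    chrom = as.character(chrom),
    start = as.integer(start),
    end = as.integer(end),
    strand = as.character(strand),
    stringsAsFactors = FALSE
  )
  validate_gene_models(g)
}

validate_gene_models <- function(g) {
  stopifnot(is.data.frame(g), all(c("gene_id", "chrom", "start", "end", "strand") %in% names(g)))
  if (anyDuplicated(g$gene_id)) {
    stop("duplicate gene_id: ", paste(unique(g$gene_id[duplicated(g$gene_id)]), collapse = ", "))
  }
  if (any(g$start < 0)) stop("negative gene start coordinate")
  if (any(g$start >= g$end)) stop("gene with start >= end: ", paste(g$gene_id[g$start >= g$end], collapse = ", "))
  if (!all(g$strand %in% c("+", "-"))) stop("unknown strand symbol: ", paste(setdiff(g$strand, c("+", "-")), collapse = ", "))
  g$tss <- ifelse(g$strand == "+", g$start, g$end - 1L)
  g <- g[order(g$chrom, g$start, g$end), , drop = FALSE]
  rownames(g) <- NULL
  g
}

#' Peak sets
#'
#' A named collection of genomic intervals with per-peak signal. Stored as a
#' data frame (`chrom`, `start`, `end`, `signal`, optionally `score_p`)
#' sorted by (chrom, start), with the set label in attribute `name`.
#'
#' @param chrom,start,end interval coordinates (0-based half-open).
#' @param signal non-negative per-peak signal (mean occupancy); defaults 0.
#' @param score_p optional per-peak p-value of the call.
#' @param name label of the set, e.g. "TET1_WT".
#' @return A `peak_set` data frame.
#' @export
peak_set <- function(chrom, start, end, signal = NULL, score_p = NULL, name = "peaks") {
  p <- data.frame(
    chrom = as.character(chrom),
    start = as.integer(start),
    end = as.integer(end),
    stringsAsFactors = FALSE
  )
  p$signal <- if (is.null(signal)) rep(0, nrow(p)) else as.numeric(signal)
  if (!is.null(score_p)) p$score_p <- as.numeric(score_p)
  validate_peak_set(p, name = name)
}

validate_peak_set <- function(p, name = attr(p, "name") %||% "peaks") {
  stopifnot(is.data.frame(p), all(c("chrom", "start", "end") %in% names(p)))
  if (is.null(p$signal)) p$signal <- rep(0, nrow(p))
  if (nrow(p) > 0) {
    if (any(p$start < 0)) stop("negative peak coordinate in set '", name, "'")
    if (any(p$start >= p$end)) stop("peak with start >= end in set '", name, "'")
    if (any(p$signal < 0)) stop("negative peak signal in set '", name, "'")
    p <- p[order(p$chrom, p$start, p$end), , drop = FALSE]
  }
  rownames(p) <- NULL
  attr(p, "name") <- name
  class(p) <- c("peak_set", "data.frame")
  p
}

is_sorted_peaks <- function(p) {
  if (nrow(p) < 2) return(TRUE)
  o <- order(p$chrom, p$start, p$end)
  all(o == seq_len(nrow(p)))
}

#' Sample metadata
#'
#' One row per RNA-seq library: genotype in {WT, KO, KO_WT}, timepoint in
#' days {0, 3, 6, 12}, replicate index. The (genotype, timepoint, replicate)
#' triple must be unique.
#'
#' @param sample_id character sample identifiers.
#' @param genotype one of "WT", "KO", "KO_WT".
#' @param timepoint integer day, one of 0, 3, 6, 12.
#' @param replicate positive integer replicate index.
#' @return A data frame of sample metadata.
#' @export
sample_meta <- function(sample_id, genotype, timepoint, replicate) {
  s <- data.frame(
    sample_id = as.character(sample_id),
    genotype = as.character(genotype),
    timepoint = as.integer(timepoint),
    replicate = as.integer(replicate),
    stringsAsFactors = FALSE
  )
  stopifnot(all(s$genotype %in% c("WT", "KO", "KO_WT")))
  stopifnot(all(s$timepoint %in% c(0L, 3L, 6L, 12L)), all(s$replicate >= 1L))
  if (anyDuplicated(s[, c("genotype", "timepoint", "replicate")])) {
    stop("duplicate (genotype, timepoint, replicate) triple")
  }
  if (anyDuplicated(s$sample_id)) stop("duplicate sample_id")
  s
}

#' The study's replicate layout
#'
#' Three biological replicates at day 0 and two at days 3, 6 and 12, for
#' each of the three genotypes (27 samples).
#'
#' @return A sample metadata data frame.
#' @export
default_sample_layout <- function() {
  tp <- c(0L, 3L, 6L, 12L)
  nrep <- c(3L, 2L, 2L, 2L)
  rows <- do.call(rbind, lapply(c("WT", "KO", "KO_WT"), function(gt) {
    do.call(rbind, lapply(seq_along(tp), function(i) {
      data.frame(
        genotype = gt, timepoint = tp[i], replicate = seq_len(nrep[i]),
        stringsAsFactors = FALSE
      )
    }))
  }))
  rows$sample_id <- sprintf("%s_d%d_r%d", rows$genotype, rows$timepoint, rows$replicate)
  sample_meta(rows$sample_id, rows$genotype, rows$timepoint, rows$replicate)
}

#' Expression matrices
#'
#' A gene x sample abundance matrix with its sample metadata and unit
#' ("FPKM" or "TPM"). When the unit is TPM every sample column sums to 1e6.
#'
#' @param values numeric matrix, genes in rows (rownames = gene ids),
#'   samples in columns (colnames = sample ids).
#' @param samples sample metadata (see [sample_meta()]), one row per column
#'   of `values`, in column order.
#' @param unit "FPKM" or "TPM".
#' @return An `expression_matrix` (a list with elements `values`, `samples`,
#'   `unit`).
#' @export
expression_matrix <- function(values, samples, unit = c("FPKM", "TPM")) {
  unit <- match.arg(unit)
  stopifnot(is.matrix(values), !is.null(rownames(values)), !is.null(colnames(values)))
  if (anyDuplicated(rownames(values))) stop("duplicate gene_id in expression matrix")
  if (any(values < 0)) stop("negative abundance value")
  if (!identical(colnames(values), samples$sample_id)) {
    stop("sample columns do not match sample metadata order")
  }
  if (unit == "TPM") {
    cs <- colSums(values)
    if (any(abs(cs - 1e6) > 1e-6 * 1e6)) stop("TPM columns must sum to 1e6")
  }
  structure(list(values = values, samples = samples, unit = unit),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d genes x %d samples [%s]\n",
              nrow(x$values), ncol(x$values), x$unit))
  invisible(x)
}

#' Binned signal tracks
#'
#' Fixed-bin genome-wide coverage: a bin size, chromosome lengths, and one
#' numeric vector of bin values per chromosome (`ceiling(length / bin_size)`
#' bins; the last bin may be partial).
#'
#' @param values named list of non-negative numeric vectors, one per
#'   chromosome.
#' @param bin_size bin width in bp.
#' @param chrom_sizes named integer vector of chromosome lengths in bp.
#' @return A `signal_track`.
#' @export
signal_track <- function(values, bin_size, chrom_sizes) {
  bin_size <- as.integer(bin_size)
  stopifnot(bin_size > 0, is.list(values), !is.null(names(chrom_sizes)))
  stopifnot(setequal(names(values), names(chrom_sizes)))
  for (ch in names(values)) {
    nb <- ceiling(chrom_sizes[[ch]] / bin_size)
    if (length(values[[ch]]) != nb) {
      stop("chromosome ", ch, ": expected ", nb, " bins, got ", length(values[[ch]]))
    }
    if (any(values[[ch]] < 0)) stop("negative track value on ", ch)
  }
  structure(list(bin_size = bin_size,
                 chrom_sizes = chrom_sizes,
                 values = values[names(chrom_sizes)]),
            class = "signal_track")
}

#' @export
print.signal_track <- function(x, ...) {
  cat(sprintf("signal_track: %d chrom(s), bin %d bp, %d bins\n",
              length(x$values), x$bin_size, sum(lengths(x$values))))
  invisible(x)
}

same_binning <- function(a, b) {
  identical(a$bin_size, b$bin_size) &&
    identical(names(a$chrom_sizes), names(b$chrom_sizes)) &&
    all(unlist(a$chrom_sizes) == unlist(b$chrom_sizes))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
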