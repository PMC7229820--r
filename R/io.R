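#' Read a BED file as peaks or gene models
#'
#' Accepts BED3-BED6 (tab-separated). For `kind = "genes"` column 4 is the
#' gene id, column 6 the strand (defaulting to "+" when absent) and the TSS
#' is derived (start on "+", end - 1 on "-"). For `kind = "peaks"` column 5
#' is parsed into the per-peak `signal` when numeric. Records are returned
#' sorted by (chrom, start); coordinates are 0-based half-open as in the
#' file.
#'
#' @param path path to a BED file.
#' @param kind "peaks" or "genes".
#' @return A [peak_set()] or a gene-model data frame.
#' @export
read_bed <- function(path, kind = c("peaks", "genes")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    return(if (kind == "peaks") {
      peak_set(character(), integer(), integer(), name = basename(path))
    } else {
      gene_models(character(), character(), integer(), integer(), character())
    })
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncol <- lengths(fields)
  if (any(ncol < 3)) {
    stop("line ", which(ncol < 3)[1], ": fewer than 3 tab-separated columns")
  }
  getcol <- function(i) vapply(fields, function(f) if (length(f) >= i) f[i] else NA_character_, "")
  chrom <- getcol(1)
  start <- suppressWarnings(as.integer(getcol(2)))
  end <- suppressWarnings(as.integer(getcol(3)))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad)) stop("line ", bad[1], ": non-integer coordinate")
  bad <- which(start >= end)
  if (length(bad)) stop("line ", bad[1], ": start >= end")
  bad <- which(start < 0)
  if (length(bad)) stop("line ", bad[1], ": negative coordinate")
  name <- getcol(4)
  score <- getcol(5)
  strand <- getcol(6)

  if (kind == "genes") {
    strand[is.na(strand)] <- "+"
    bad <- which(!strand %in% c("+", "-"))
    if (length(bad)) stop("line ", bad[1], ": unknown strand symbol '", strand[bad[1]], "'")
    if (anyNA(name)) name <- ifelse(is.na(name), sprintf("gene_%06d", seq_along(chrom)), name)
    gene_models(name, chrom, start, end, strand)
  } else {
    signal <- suppressWarnings(as.numeric(score))
    signal[is.na(signal)] <- 0
    peak_set(chrom, start, end, signal = signal, name = basename(path))
  }
}

#' Write peaks or gene models to BED
#'
#' Peaks are written as BED5 (name column `peak_<i>`, signal in the score
#' column); gene models as BED6. Round-trips through [read_bed()] preserve
#' coordinates, names, strands and signal.
#'
#' @param records a `peak_set` or gene-model data frame.
#' @param path output path.
#' @export
write_bed <- function(records, path) {
  if (inherits(records, "peak_set")) {
    df <- data.frame(records$chrom, records$start, records$end,
                     if (nrow(records)) sprintf("peak_%d", seq_len(nrow(records))) else character(),
                     records$signal)
  } else {
    df <- data.frame(records$chrom, records$start, records$end,
                     records$gene_id, 0L, records$strand)
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a bedGraph into a fixed-bin signal track
#'
#' Each bin's value is the length-weighted mean of the bedGraph values over
#' that bin; base pairs not covered by any record contribute 0. Record
#' boundaries need not align to bins. Overlapping records or records beyond
#' the stated chromosome length are errors.
#'
#' @param path path to a bedGraph file (chrom, start, end, value).
#' @param bin_size bin width in bp.
#' @param chrom_sizes named vector of chromosome lengths in bp.
#' @return A [signal_track()].
#' @export
read_bedgraph <- function(path, bin_size, chrom_sizes) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- tryCatch(
    utils::read.table(path, sep = "\t", header = FALSE,
                      col.names = c("chrom", "start", "end", "value"),
                      colClasses = c("character", "integer", "integer", "numeric")),
    error = function(e) {
      if (grepl("no lines available", conditionMessage(e))) NULL else stop(e)
    })
  if (is.null(df)) df <- data.frame(chrom = character(), start = integer(),
                                    end = integer(), value = numeric())
  track_from_intervals(df, bin_size, chrom_sizes)
}

#' Build a signal track from value-bearing intervals
#'
#' The in-memory counterpart of [read_bedgraph()]: bins get the
#' length-weighted mean of overlapping interval values, uncovered bp
#' contribute 0.
#'
#' @param df data frame with columns chrom, start, end, value.
#' @param bin_size bin width in bp.
#' @param chrom_sizes named vector of chromosome lengths.
#' @return A [signal_track()].
#' @export
track_from_intervals <- function(df, bin_size, chrom_sizes) {
  bin_size <- as.integer(bin_size)
  unknown <- setdiff(unique(df$chrom), names(chrom_sizes))
  if (length(unknown)) stop("interval on unknown chromosome: ", unknown[1])
  vals <- lapply(names(chrom_sizes), function(ch) {
    len <- chrom_sizes[[ch]]
    nb <- ceiling(len / bin_size)
    acc <- numeric(nb)
    sub <- df[df$chrom == ch, , drop = FALSE]
    if (nrow(sub)) {
      if (any(sub$start < 0) || any(sub$start >= sub$end)) {
        stop("malformed interval on ", ch)
      }
      if (any(sub$end > len)) stop("interval beyond chromosome length on ", ch)
      sub <- sub[order(sub$start), , drop = FALSE]
      if (nrow(sub) > 1 && any(sub$start[-1] < sub$end[-nrow(sub)])) {
        stop("overlapping intervals on ", ch)
      }
      for (i in seq_len(nrow(sub))) {
        s <- sub$start[i]; e <- sub$end[i]; v <- sub$value[i]
        b <- s %/% bin_size
        while (b * bin_size < e) {
          lo <- max(s, b * bin_size)
          hi <- min(e, (b + 1) * bin_size)
          acc[b + 1] <- acc[b + 1] + v * (hi - lo)
          b <- b + 1
        }
      }
      # divide by effective bin length (last bin may be partial)
      w <- rep(bin_size, nb)
      w[nb] <- len - (nb - 1) * bin_size
      acc <- acc / w
    }
    acc
  })
  names(vals) <- names(chrom_sizes)
  signal_track(vals, bin_size, chrom_sizes)
}

#' Write a signal track as bedGraph
#'
#' One record per bin (zero bins included) so the file round-trips exactly
#' through [read_bedgraph()] at the same bin size.
#'
#' @param track a [signal_track()].
#' @param path output path.
#' @export
write_bedgraph <- function(track, path) {
  parts <- lapply(names(track$values), function(ch) {
    v <- track$values[[ch]]
    nb <- length(v)
    start <- (seq_len(nb) - 1L) * track$bin_size
    end <- pmin(start + track$bin_size, track$chrom_sizes[[ch]])
    data.frame(chrom = ch, start = start, end = end,
               value = format(v, digits = 10, scientific = FALSE, trim = TRUE))
  })
  df <- do.call(rbind, parts)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read an expression table with embedded sample metadata
#'
#' The format written by [write_expression_tsv()]: leading
#' `#sample<TAB>id<TAB>genotype<TAB>timepoint<TAB>replicate` lines, then a
#' header row (`gene_id` plus sample ids), then one row per gene. Values are
#' FPKM. Duplicate gene ids, negative values and samples without metadata
#' are rejected.
#'
#' @param path path to the TSV.
#' @return An [expression_matrix()] with unit FPKM.
#' @export
read_expression_tsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  meta_lines <- grep("^#sample\t", lines, value = TRUE)
  body <- lines[!startsWith(lines, "#")]
  if (length(body) < 1) stop("no header row in ", path)
  header <- strsplit(body[1], "\t", fixed = TRUE)[[1]]
  sample_ids <- header[-1]
  if (length(meta_lines) == 0) stop("no sample metadata (#sample lines) in ", path)
  mf <- do.call(rbind, strsplit(meta_lines, "\t", fixed = TRUE))
  meta <- sample_meta(mf[, 2], mf[, 3], as.integer(mf[, 4]), as.integer(mf[, 5]))
  missing <- setdiff(sample_ids, meta$sample_id)
  if (length(missing)) stop("sample without metadata: ", paste(missing, collapse = ", "))
  meta <- meta[match(sample_ids, meta$sample_id), , drop = FALSE]
  rownames(meta) <- NULL

  rows <- strsplit(body[-1], "\t", fixed = TRUE)
  gene_ids <- vapply(rows, `[`, "", 1)
  if (anyDuplicated(gene_ids)) {
    stop("duplicate gene_id: ", gene_ids[duplicated(gene_ids)][1])
  }
  values <- matrix(NA_real_, nrow = length(rows), ncol = length(sample_ids),
                   dimnames = list(gene_ids, sample_ids))
  for (i in seq_along(rows)) {
    v <- as.numeric(rows[[i]][-1])
    if (length(v) != length(sample_ids)) stop("row ", i, ": wrong number of fields")
    values[i, ] <- v
  }
  if (anyNA(values)) stop("non-numeric abundance value")
  if (any(values < 0)) stop("negative abundance value")
  expression_matrix(values, meta, unit = "FPKM")
}

#' Write an expression matrix with embedded sample metadata
#'
#' @param m an [expression_matrix()] (unit FPKM).
#' @param path output path.
#' @export
write_expression_tsv <- function(m, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#sample\t%s\t%s\t%d\t%d",
                     m$samples$sample_id, m$samples$genotype,
                     m$samples$timepoint, m$samples$replicate), con)
  writeLines(paste(c("gene_id", colnames(m$values)), collapse = "\t"), con)
  body <- apply(m$values, 1, function(v) {
    paste(format(v, digits = 10, scientific = FALSE, trim = TRUE), collapse = "\t")
  })
  writeLines(paste(rownames(m$values), body, sep = "\t"), con)
  invisible(path)
}
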