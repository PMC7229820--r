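#' Pipeline configuration
#'
#' Collects every tunable threshold of the analysis pipeline in one object.
#' Defaults follow the study design: differential expression is called at
#' fold-change > 1.5 and p < 0.05 (strict inequalities), promoters are
#' TSS +/- 2 kb, a TET1 peak counts as "reduced" when its knockout signal is
#' at most half the wild-type signal (log2 ratio <= -1, pseudocounted), and
#' genome-wide track correlation uses non-overlapping 10-kb bins.
#'
#' @param fc_cutoff fold-change threshold for differential-expression status.
#' @param p_cutoff p-value threshold for differential-expression status.
#' @param promoter_flank_bp promoter half-width around the TSS, bp.
#' @param reduced_log2_cutoff log2(KO/WT) at or below which a peak is flagged
#'   reduced; must be negative.
#' @param bin_size_bp genome bin width for track correlation, bp.
#' @param metagene_flank_bp half-width of TSS metagene profiles, bp.
#' @param genebody_nbins number of equal-length fractions a gene body is
#'   rescaled to in gene-body metagene profiles.
#' @param pseudocount added to every numerator and denominator of a log-ratio;
#'   shared across expression and chromatin signal for coherence.
#' @param seed integer seed for any stochastic step.
#' @return A list with class `pipeline_config`.
#' @export
pipeline_config <- function(fc_cutoff = 1.5,
                            p_cutoff = 0.05,
                            promoter_flank_bp = 2000L,
                            reduced_log2_cutoff = -1.0,
                            bin_size_bp = 10000L,
                            metagene_flank_bp = 2500L,
                            genebody_nbins = 100L,
                            pseudocount = 0.1,
                            seed = 1L) {
  cfg <- list(
    fc_cutoff = fc_cutoff,
    p_cutoff = p_cutoff,
    promoter_flank_bp = as.integer(promoter_flank_bp),
    reduced_log2_cutoff = reduced_log2_cutoff,
    bin_size_bp = as.integer(bin_size_bp),
    metagene_flank_bp = as.integer(metagene_flank_bp),
    genebody_nbins = as.integer(genebody_nbins),
    pseudocount = pseudocount,
    seed = as.integer(seed)
  )
  stopifnot(
    cfg$fc_cutoff > 0, cfg$p_cutoff > 0, cfg$promoter_flank_bp > 0,
    cfg$bin_size_bp > 0, cfg$metagene_flank_bp > 0, cfg$genebody_nbins > 0,
    cfg$pseudocount > 0
  )
  if (cfg$reduced_log2_cutoff >= 0) {
    stop("reduced_log2_cutoff must be negative (a loss of signal)")
  }
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a key=value configuration file
#'
#' Plain `key = value` lines (comments start with `#`); keys match the
#' arguments of [pipeline_config()]. Unknown keys are an error so typos do
#' not silently fall back to defaults.
#'
#' @param path path to the configuration file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  args <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2) stop("malformed config line: ", ln)
    key <- trimws(kv[1])
    if (!key %in% names(formals(pipeline_config))) {
      stop("unknown config key: ", key)
    }
    args[[key]] <- as.numeric(trimws(kv[2]))
  }
  do.call(pipeline_config, args)
}

#' Emit a log message to stderr
#'
#' Silenced when `options(nonotet.quiet = TRUE)` is set.
#' @param ... passed to [message()].
#' @export
log_msg <- function(...) {
  if (!isTRUE(getOption("nonotet.quiet", FALSE))) {
    message("[nonotet] ", ...)
  }
  invisible(NULL)
}
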