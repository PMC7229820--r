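#' Simulation configuration
#'
#' Parameters of the synthetic study: a toy genome, expression across three
#' genotypes (WT, Nono KO, KO with re-expressed WT NONO) and four
#' differentiation timepoints (days 0/3/6/12), and coupled TET1 / NONO /
#' 5hmC chromatin occupancy with planted ground truth.
#'
#' Key planted structure: `n_dep_up` / `n_dep_down` genes ramp up / down
#' by `effect_log2fc` log2 units over the 12-day course in WT and the
#' rescue genotype but stay flat in the knockout (the rescue-validated
#' NONO-dependent sets); `n_null_up` / `n_null_down` genes change in all
#' three genotypes; the rest are flat. A fraction `frac_tet1_bound` of
#' genes carry a promoter TET1 peak, `frac_reduced_in_ko` of TET1 peaks
#' lose most of their signal in the knockout (and their genes are
#' transcriptionally repressed in KO by `ko_expr_effect_log2` log2 units,
#' planting the association between binding loss and differential
#' expression), `frac_nono_cobound` of NONO peaks sit on TET1 peaks, and
#' 5hmC mirrors TET1 with multiplicative noise.
#'
#' @param n_chroms number of chromosomes.
#' @param chrom_len_bp chromosome length, bp.
#' @param n_genes number of genes (length uniform 2-20 kb, spacing >= 1 kb).
#' @param n_dep_up,n_dep_down planted rescue-validated dependent genes.
#' @param n_null_up,n_null_down genes changing in all genotypes.
#' @param frac_tet1_bound fraction of genes with a promoter TET1 peak in WT.
#' @param frac_reduced_in_ko fraction of TET1 peaks losing >= half their
#'   signal in KO.
#' @param frac_nono_cobound fraction of NONO peaks placed on TET1 peaks.
#' @param effect_log2fc planted differentiation log2 fold-change magnitude.
#' @param noise_sd_log2 replicate noise SD on the log2 scale.
#' @param ko_expr_effect_log2 log2 repression of reduced-binding genes in KO.
#' @param baseline_log2_mean,baseline_log2_sd baseline log2 FPKM distribution.
#' @param peak_signal_shape,peak_signal_scale Gamma parameters of per-peak
#'   signal (mean = shape * scale).
#' @param background_peaks_per_mb Poisson rate of intergenic background peaks.
#' @param nono_per_tet1 number of NONO peaks as a fraction of TET1 WT peaks.
#' @param hmc_coupling_sd_log2 SD of the multiplicative (log2) noise coupling
#'   5hmC to TET1 signal.
#' @param track_bin_bp bin width of the generated signal tracks, bp.
#' @param track_bg_mean mean of the Exponential per-bin track background.
#' @param seed integer seed; every generator is deterministic given it.
#' @return A list with class `simulation_config`.
#' @export
simulation_config <- function(n_chroms = 2L,
                              chrom_len_bp = 5e7,
                              n_genes = 5000L,
                              n_dep_up = 500L,
                              n_dep_down = 300L,
                              n_null_up = 500L,
                              n_null_down = 300L,
                              frac_tet1_bound = 0.5,
                              frac_reduced_in_ko = 0.6,
                              frac_nono_cobound = 0.85,
                              effect_log2fc = 2.0,
                              noise_sd_log2 = 0.25,
                              ko_expr_effect_log2 = 1.0,
                              baseline_log2_mean = 4,
                              baseline_log2_sd = 1.5,
                              peak_signal_shape = 4,
                              peak_signal_scale = 2.5,
                              background_peaks_per_mb = 3,
                              nono_per_tet1 = 0.6,
                              hmc_coupling_sd_log2 = 0.2,
                              track_bin_bp = 100L,
                              track_bg_mean = 0.05,
                              seed = 1L) {
  cfg <- as.list(environment())
  cfg$n_chroms <- as.integer(n_chroms)
  cfg$n_genes <- as.integer(n_genes)
  cfg$track_bin_bp <- as.integer(track_bin_bp)
  cfg$seed <- as.integer(seed)
  fr <- c(cfg$frac_tet1_bound, cfg$frac_reduced_in_ko, cfg$frac_nono_cobound)
  if (any(fr < 0 | fr > 1)) stop("fractions must be in [0, 1]")
  if (cfg$n_dep_up + cfg$n_dep_down + cfg$n_null_up + cfg$n_null_down > cfg$n_genes) {
    stop("planted gene classes exceed n_genes")
  }
  class(cfg) <- "simulation_config"
  cfg
}

sim_chrom_sizes <- function(cfg) {
  stats::setNames(rep(as.integer(cfg$chrom_len_bp), cfg$n_chroms),
                  sprintf("chr%d", seq_len(cfg$n_chroms)))
}

#' Simulate a toy gene annotation
#'
#' Places `n_genes` non-overlapping genes (length uniform 2-20 kb, >= 1 kb
#' apart, random strand) on `n_chroms` chromosomes, splitting the genes
#' evenly and distributing the leftover space randomly between them.
#' Deterministic given `cfg$seed`.
#'
#' @param cfg a [simulation_config()].
#' @return A gene-model data frame sorted by (chrom, start).
#' @export
simulate_genome <- function(cfg) {
  set.seed(cfg$seed)
  sizes <- sim_chrom_sizes(cfg)
  n_per <- diff(round(seq(0, cfg$n_genes, length.out = cfg$n_chroms + 1)))
  out <- list()
  for (ci in seq_len(cfg$n_chroms)) {
    nc <- n_per[ci]
    if (nc == 0) next
    len <- sizes[ci]
    glen <- round(stats::runif(nc, 2000, 20000))
    need <- sum(glen) + (nc + 1) * 1000
    if (need > len) {
      stop("cannot place ", nc, " genes in ", len,
           " bp; increase chrom_len_bp (need >= ", need, ")")
    }
    slack <- len - need
    cuts <- sort(stats::runif(nc, 0, slack))
    gaps <- 1000 + round(diff(c(0, cuts)))
    starts <- cumsum(gaps) + c(0, cumsum(glen[-nc]))
    out[[ci]] <- data.frame(
      chrom = names(sizes)[ci],
      start = as.integer(starts),
      end = as.integer(starts + glen),
      strand = sample(c("+", "-"), nc, replace = TRUE),
      stringsAsFactors = FALSE
    )
  }
  g <- do.call(rbind, out)
  if (is.null(g) || nrow(g) == 0) {
    return(gene_models(character(), character(), integer(), integer(), character()))
  }
  g$gene_id <- sprintf("gene_%05d", seq_len(nrow(g)))
  gene_models(g$gene_id, g$chrom, g$start, g$end, g$strand)
}

assign_truth <- function(genes, cfg) {
  n <- nrow(genes)
  cls <- rep("flat", n)
  idx <- sample.int(n)
  k <- c(cfg$n_dep_up, cfg$n_dep_down, cfg$n_null_up, cfg$n_null_down)
  ends <- cumsum(k)
  cls[idx[seq_len(ends[1])]] <- "dep_up"
  if (k[2]) cls[idx[(ends[1] + 1):ends[2]]] <- "dep_down"
  if (k[3]) cls[idx[(ends[2] + 1):ends[3]]] <- "null_up"
  if (k[4]) cls[idx[(ends[3] + 1):ends[4]]] <- "null_down"
  bound <- rep(FALSE, n)
  bound[sample.int(n, round(cfg$frac_tet1_bound * n))] <- TRUE
  reduced <- rep(FALSE, n)
  bidx <- which(bound)
  reduced[sample(bidx, round(cfg$frac_reduced_in_ko * length(bidx)))] <- TRUE
  data.frame(gene_id = genes$gene_id, class = cls,
             tet1_bound = bound, reduced_in_ko = reduced,
             stringsAsFactors = FALSE)
}

#' Simulate the rescue-design expression matrix
#'
#' Generates FPKM for 27 samples (3 genotypes x days 0/3/6/12; three
#' replicates at day 0, two elsewhere) with the planted structure described
#' in [simulation_config()]. Baseline log2 FPKM is Normal(4, 1.5^2);
#' trajectories ramp linearly in time on the log2 scale; replicate noise is
#' Normal(0, noise_sd_log2^2) on log2 and then exponentiated. Genes whose
#' TET1 peak is reduced in KO are additionally repressed in KO samples at
#' every timepoint. Deterministic given `cfg$seed`.
#'
#' @param genes gene models from [simulate_genome()].
#' @param cfg a [simulation_config()].
#' @return list(expression = [expression_matrix()] (FPKM), truth = per-gene
#'   truth labels with columns gene_id, class, tet1_bound, reduced_in_ko).
#' @export
simulate_expression <- function(genes, cfg) {
  if (nrow(genes) == 0) stop("genes must be non-empty")
  set.seed(cfg$seed + 1L)
  truth <- assign_truth(genes, cfg)
  samples <- default_sample_layout()
  n <- nrow(genes)
  baseline <- stats::rnorm(n, cfg$baseline_log2_mean, cfg$baseline_log2_sd)
  # per-gene ramp direction in each genotype
  dir_all <- ifelse(truth$class %in% c("dep_up", "null_up"), 1,
                    ifelse(truth$class %in% c("dep_down", "null_down"), -1, 0))
  dep <- truth$class %in% c("dep_up", "dep_down")
  logm <- matrix(0, n, nrow(samples),
                 dimnames = list(genes$gene_id, samples$sample_id))
  for (j in seq_len(nrow(samples))) {
    f <- samples$timepoint[j] / 12
    ramp <- dir_all
    if (samples$genotype[j] == "KO") ramp[dep] <- 0  # dependence: no ramp in KO
    mu <- baseline + ramp * cfg$effect_log2fc * f
    if (samples$genotype[j] == "KO") {
      mu <- mu - cfg$ko_expr_effect_log2 * truth$reduced_in_ko
    }
    logm[, j] <- mu
  }
  noise <- matrix(stats::rnorm(length(logm), 0, cfg$noise_sd_log2), n)
  expr <- expression_matrix(2^(logm + noise), samples, unit = "FPKM")
  list(expression = expr, truth = truth)
}

gamma_signal <- function(n, cfg) {
  stats::rgamma(n, shape = cfg$peak_signal_shape, scale = cfg$peak_signal_scale)
}

place_background <- function(n, sizes, avoid, width_fun) {
  # uniform placement rejecting overlap with 'avoid' (data.frame chrom/start/end)
  out <- vector("list", 0)
  placed <- 0
  guard <- 0
  res <- data.frame(chrom = character(), start = integer(), end = integer())
  while (placed < n && guard < 50) {
    guard <- guard + 1
    m <- (n - placed) * 2
    ch <- sample(names(sizes), m, replace = TRUE)
    w <- width_fun(m)
    st <- floor(stats::runif(m, 0, sizes[ch] - w))
    cand <- data.frame(chrom = ch, start = as.integer(st),
                       end = as.integer(st + w), stringsAsFactors = FALSE)
    ok <- !overlaps_any(cand, avoid)
    cand <- cand[ok, , drop = FALSE]
    if (nrow(cand) > n - placed) cand <- cand[seq_len(n - placed), , drop = FALSE]
    res <- rbind(res, cand)
    placed <- nrow(res)
  }
  res
}

overlaps_any <- function(q, ref) {
  # TRUE per row of q if it overlaps any interval of ref (same chrom, >=1 bp)
  if (nrow(ref) == 0 || nrow(q) == 0) return(rep(FALSE, nrow(q)))
  hit <- rep(FALSE, nrow(q))
  for (ch in unique(q$chrom)) {
    qi <- which(q$chrom == ch)
    r <- ref[ref$chrom == ch, , drop = FALSE]
    if (nrow(r) == 0) next
    r <- r[order(r$start), , drop = FALSE]
    # an interval overlaps none iff it fits between consecutive ref intervals
    for (i in qi) {
      hit[i] <- any(q$start[i] < r$end & r$start < q$end[i])
    }
  }
  hit
}

#' Simulate coupled TET1 / NONO / 5hmC peaks and signal tracks
#'
#' Every TET1-bound gene receives a TET1 WT peak centred on its TSS (width
#' uniform 600-1200 bp, Gamma signal); intergenic background peaks are added
#' at a Poisson rate. In the knockout the reduced peaks keep only a
#' Uniform(0.05, 0.45) fraction of their signal, the others a
#' Uniform(0.8, 1.2) fraction; background peaks lose signal at the same rate
#' `frac_reduced_in_ko` so that binding loss is a genome-wide property of
#' the peak set. NONO peaks are placed on a `frac_nono_cobound` Bernoulli
#' subset of TET1 peaks (jittered but guaranteed to overlap) plus
#' independent background. 5hmC mirrors TET1 with multiplicative log-normal
#' coupling noise and shares the reduction flags. Tracks paint the per-peak
#' signal onto fixed bins (length-weighted) and add Exponential background.
#' Deterministic given `cfg$seed`.
#'
#' @param genes gene models.
#' @param truth per-gene truth labels from [simulate_expression()].
#' @param cfg a [simulation_config()].
#' @return list(peaks = named list of [peak_set()]s (tet1_wt, tet1_ko,
#'   nono_wt, hmc_wt, hmc_ko), tracks = named list of [signal_track()]s,
#'   peak_truth = per-TET1-peak labels (gene_id, is_background, reduced),
#'   nono_truth = per-NONO-peak labels (cobound)).
#' @export
simulate_chromatin <- function(genes, truth, cfg) {
  stopifnot(identical(genes$gene_id, truth$gene_id))
  set.seed(cfg$seed + 2L)
  sizes <- sim_chrom_sizes(cfg)
  width_fun <- function(m) round(stats::runif(m, 600, 1200))

  bidx <- which(truth$tet1_bound)
  w <- width_fun(length(bidx))
  st <- pmax(0L, as.integer(genes$tss[bidx] - w %/% 2))
  en <- pmin(as.integer(sizes[genes$chrom[bidx]]), as.integer(st + w))
  tet1 <- data.frame(chrom = genes$chrom[bidx], start = st, end = en,
                     signal = gamma_signal(length(bidx), cfg),
                     gene_id = genes$gene_id[bidx],
                     is_background = FALSE,
                     reduced = truth$reduced_in_ko[bidx],
                     stringsAsFactors = FALSE)

  promoters <- data.frame(chrom = genes$chrom,
                          start = pmax(0L, genes$tss - 3000L),
                          end = genes$tss + 3000L)
  n_bg <- stats::rpois(1, cfg$background_peaks_per_mb * sum(sizes) / 1e6)
  bg <- place_background(n_bg, sizes, promoters, width_fun)
  if (nrow(bg)) {
    bg$signal <- gamma_signal(nrow(bg), cfg)
    bg$gene_id <- NA_character_
    bg$is_background <- TRUE
    bg$reduced <- stats::runif(nrow(bg)) < cfg$frac_reduced_in_ko
    tet1 <- rbind(tet1, bg)
  }
  o <- order(tet1$chrom, tet1$start, tet1$end)
  tet1 <- tet1[o, , drop = FALSE]
  rownames(tet1) <- NULL

  red_factor <- function(flag) {
    ifelse(flag, stats::runif(length(flag), 0.05, 0.45),
           stats::runif(length(flag), 0.8, 1.2))
  }
  tet1_ko_sig <- tet1$signal * red_factor(tet1$reduced)

  # NONO: Bernoulli co-binding on TET1 peaks plus independent background
  n_nono <- round(cfg$nono_per_tet1 * nrow(tet1))
  cobound <- stats::runif(n_nono) < cfg$frac_nono_cobound
  n_co <- sum(cobound)
  host <- sample.int(nrow(tet1), n_co, replace = FALSE)
  ctr <- (tet1$start[host] + tet1$end[host]) %/% 2 + round(stats::runif(n_co, -200, 200))
  wn <- width_fun(n_co)
  nono_co <- data.frame(chrom = tet1$chrom[host],
                        start = pmax(0L, as.integer(ctr - wn %/% 2)))
  nono_co$end <- as.integer(nono_co$start + wn)
  avoid <- tet1[, c("chrom", "start", "end")]
  nono_bg <- place_background(n_nono - n_co, sizes, avoid, width_fun)
  nono <- rbind(
    data.frame(nono_co, cobound = TRUE, stringsAsFactors = FALSE),
    if (nrow(nono_bg)) data.frame(nono_bg, cobound = FALSE) else NULL
  )
  nono$signal <- gamma_signal(nrow(nono), cfg)
  o <- order(nono$chrom, nono$start, nono$end)
  nono <- nono[o, , drop = FALSE]
  rownames(nono) <- NULL

  # 5hmC mirrors TET1 with multiplicative coupling noise; reductions shared
  hmc_wt_sig <- tet1$signal * 2^stats::rnorm(nrow(tet1), 0, cfg$hmc_coupling_sd_log2)
  hmc_ko_sig <- hmc_wt_sig * red_factor(tet1$reduced)

  mk <- function(df, sig, name) {
    peak_set(df$chrom, df$start, df$end, signal = sig, name = name)
  }
  peaks <- list(
    tet1_wt = mk(tet1, tet1$signal, "TET1_WT"),
    tet1_ko = mk(tet1, tet1_ko_sig, "TET1_KO"),
    nono_wt = mk(nono, nono$signal, "NONO_WT"),
    hmc_wt = mk(tet1, hmc_wt_sig, "hmC_WT"),
    hmc_ko = mk(tet1, hmc_ko_sig, "hmC_KO")
  )
  tracks <- lapply(peaks, function(p) {
    paint_track(p, cfg$track_bin_bp, sizes, bg_mean = cfg$track_bg_mean)
  })
  list(peaks = peaks, tracks = tracks,
       peak_truth = tet1[, c("chrom", "start", "end", "gene_id",
                             "is_background", "reduced")],
       nono_truth = nono[, c("chrom", "start", "end", "cobound")])
}

#' Paint a peak set onto a binned track
#'
#' Each bin receives the length-weighted sum of overlapping peak signals
#' (so a peak fully covering a bin contributes its full signal there) plus
#' an Exponential background draw per bin.
#'
#' @param peaks a [peak_set()].
#' @param bin_size bin width, bp.
#' @param chrom_sizes named chromosome lengths.
#' @param bg_mean mean of the per-bin Exponential background (0 disables).
#' @return A [signal_track()].
#' @export
paint_track <- function(peaks, bin_size, chrom_sizes, bg_mean = 0) {
  bin_size <- as.integer(bin_size)
  vals <- lapply(names(chrom_sizes), function(ch) {
    len <- chrom_sizes[[ch]]
    nb <- ceiling(len / bin_size)
    acc <- numeric(nb)
    sub <- peaks[peaks$chrom == ch, , drop = FALSE]
    for (i in seq_len(nrow(sub))) {
      s <- sub$start[i]; e <- min(sub$end[i], len); v <- sub$signal[i]
      b <- s %/% bin_size
      while (b * bin_size < e) {
        lo <- max(s, b * bin_size)
        hi <- min(e, (b + 1) * bin_size)
        acc[b + 1] <- acc[b + 1] + v * (hi - lo)
        b <- b + 1
      }
    }
    w <- rep(bin_size, nb)
    w[nb] <- len - (nb - 1) * bin_size
    acc <- acc / w
    if (bg_mean > 0) acc <- acc + stats::rexp(nb, rate = 1 / bg_mean)
    acc
  })
  names(vals) <- names(chrom_sizes)
  signal_track(vals, bin_size, chrom_sizes)
}

#' Aggregate a track into larger bins
#'
#' `new_bin` must be a multiple of the track's bin size; coarse bins take
#' the length-weighted mean of their fine bins.
#'
#' @param track a [signal_track()].
#' @param new_bin new bin width, bp.
#' @return A [signal_track()] at the coarser resolution.
#' @export
rebin_track <- function(track, new_bin) {
  new_bin <- as.integer(new_bin)
  if (new_bin %% track$bin_size != 0) stop("new_bin must be a multiple of bin_size")
  k <- new_bin %/% track$bin_size
  vals <- lapply(names(track$values), function(ch) {
    v <- track$values[[ch]]
    len <- track$chrom_sizes[[ch]]
    w <- rep(track$bin_size, length(v))
    w[length(v)] <- len - (length(v) - 1) * track$bin_size
    grp <- (seq_along(v) - 1) %/% k
    as.numeric(tapply(v * w, grp, sum) / tapply(w, grp, sum))
  })
  names(vals) <- names(track$values)
  signal_track(vals, new_bin, track$chrom_sizes)
}

#' Simulate enriched and null gene sets for over-representation analysis
#'
#' Emits two "pathway" sets drawing mostly from the planted dependent-up and
#' dependent-down genes plus six random sets over the whole annotation.
#'
#' @param truth per-gene truth labels.
#' @param cfg a [simulation_config()].
#' @return A [gene_set_collection()].
#' @export
simulate_gene_sets <- function(truth, cfg) {
  set.seed(cfg$seed + 3L)
  universe <- truth$gene_id
  pick <- function(pool, other, n_pool, n_other) {
    unique(c(sample(pool, min(n_pool, length(pool))),
             sample(other, min(n_other, length(other)))))
  }
  up <- truth$gene_id[truth$class == "dep_up"]
  down <- truth$gene_id[truth$class == "dep_down"]
  sets <- list(
    pathway_dep_up = pick(up, setdiff(universe, up), 150, 50),
    pathway_dep_down = pick(down, setdiff(universe, down), 100, 50)
  )
  for (i in 1:6) {
    sets[[sprintf("pathway_random_%d", i)]] <-
      sample(universe, min(200, length(universe)))
  }
  gene_set_collection(sets, universe)
}

#' Generate the full synthetic bundle
#'
#' Runs genome, expression, chromatin and gene-set generators under one
#' seed; optionally writes everything (BED / bedGraph / TSV plus truth
#' labels and an md5 manifest) to a directory.
#'
#' @param cfg a [simulation_config()].
#' @param out_dir optional output directory; must be empty or absent unless
#'   `force = TRUE`.
#' @param force overwrite a non-empty `out_dir`.
#' @return Invisibly, list(genes, expression, truth, peaks, tracks,
#'   peak_truth, nono_truth, gene_sets, chrom_sizes, config).
#' @export
simulate_all <- function(cfg = simulation_config(), out_dir = NULL, force = FALSE) {
  genes <- simulate_genome(cfg)
  ex <- simulate_expression(genes, cfg)
  chrom <- simulate_chromatin(genes, ex$truth, cfg)
  sets <- simulate_gene_sets(ex$truth, cfg)
  bundle <- list(genes = genes, expression = ex$expression, truth = ex$truth,
                 peaks = chrom$peaks, tracks = chrom$tracks,
                 peak_truth = chrom$peak_truth, nono_truth = chrom$nono_truth,
                 gene_sets = sets, chrom_sizes = sim_chrom_sizes(cfg),
                 config = cfg)
  if (!is.null(out_dir)) {
    if (dir.exists(out_dir) && length(list.files(out_dir)) > 0 && !force) {
      stop("output directory not empty (use force = TRUE): ", out_dir)
    }
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_bundle(bundle, out_dir)
  }
  invisible(bundle)
}

write_bundle <- function(bundle, out_dir) {
  p <- function(f) file.path(out_dir, f)
  write_bed(bundle$genes, p("annotation.bed"))
  write_expression_tsv(bundle$expression, p("expression_fpkm.tsv"))
  for (nm in names(bundle$peaks)) write_bed(bundle$peaks[[nm]], p(paste0(nm, ".bed")))
  for (nm in names(bundle$tracks)) write_bedgraph(bundle$tracks[[nm]], p(paste0(nm, ".bedgraph")))
  utils::write.table(bundle$truth, p("truth_labels.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(bundle$peak_truth, p("peak_truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(bundle$nono_truth, p("nono_truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  sets_df <- do.call(rbind, lapply(names(bundle$gene_sets$sets), function(s) {
    data.frame(set_name = s, gene_id = bundle$gene_sets$sets[[s]])
  }))
  utils::write.table(sets_df, p("gene_sets.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(chrom = names(bundle$chrom_sizes),
               length = as.integer(bundle$chrom_sizes)),
    p("chrom_sizes.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  files <- setdiff(list.files(out_dir), "manifest.tsv")
  manifest <- data.frame(file = files,
                         md5 = unname(tools::md5sum(file.path(out_dir, files))))
  manifest <- manifest[order(manifest$file), ]
  utils::write.table(manifest, p("manifest.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(out_dir)
}
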