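test_that("fpkm_to_tpm rescales columns to one million", {
  v <- matrix(c(5, 2, 3, 5, 1, 1), nrow = 3,
              dimnames = list(c("g1", "g2", "g3"), NULL))
  m <- make_expr(v, c("WT", "WT"), c(0L, 0L))
  tpm <- fpkm_to_tpm(m)
  expect_equal(unname(tpm$values[, 1]), c(5e5, 2e5, 3e5))
  expect_equal(unname(tpm$values[, 2]), c(5e6 / 7, 1e6 / 7, 1e6 / 7))
  expect_equal(unname(colSums(tpm$values)), c(1e6, 1e6))
  expect_equal(tpm$unit, "TPM")

  one <- make_expr(matrix(5, 1, 2, dimnames = list("g1", NULL)),
                   c("WT", "WT"), c(0L, 0L))
  expect_equal(unname(fpkm_to_tpm(one)$values[1, ]), c(1e6, 1e6))

  v[, 2] <- 0
  expect_error(fpkm_to_tpm(make_expr(v, c("WT", "WT"), c(0L, 0L))),
               "all-zero sample")
})

test_that("differential expression applies strict cutoffs and handles degeneracy", {
  cfg <- pipeline_config()
  # identical replicate vectors on both sides: fc 0, ns
  v <- matrix(c(4, 8, 2, 4, 8, 2, 4, 8, 2, 4, 8, 2), nrow = 3,
              dimnames = list(c("g1", "g2", "g3"), NULL))
  m <- make_expr(v, rep("WT", 4), c(0L, 0L, 12L, 12L))
  de <- differential_expression(m, samples_of(m, "WT", 0L), samples_of(m, "WT", 12L), cfg)
  expect_equal(de$log2fc, rep(0, 3))
  expect_equal(de$status, rep("ns", 3))
  expect_equal(de$p_value, rep(1, 3))

  # a mean ratio of exactly 1.5 on pseudocounted means stays ns (strict >)
  pc <- cfg$pseudocount
  a <- 10
  b <- 1.5 * (a + pc) - pc
  v2 <- matrix(c(a, a, b, b), nrow = 1, dimnames = list("g1", NULL))
  m2 <- make_expr(v2, rep("WT", 4), c(0L, 0L, 12L, 12L))
  de2 <- differential_expression(m2, samples_of(m2, "WT", 0L),
                                 samples_of(m2, "WT", 12L), cfg)
  expect_equal(de2$log2fc, log2(1.5))
  expect_equal(de2$status, "ns")
  # while a clear constant shift above the cutoff is up with p = 0
  v3 <- matrix(c(a, a, 4 * a, 4 * a), nrow = 1, dimnames = list("g1", NULL))
  m3 <- make_expr(v3, rep("WT", 4), c(0L, 0L, 12L, 12L))
  expect_equal(differential_expression(m3, samples_of(m3, "WT", 0L),
                                       samples_of(m3, "WT", 12L), cfg)$status, "up")

  expect_error(differential_expression(m, samples_of(m, "WT", 0L), "WT_d12_r1", cfg),
               "2 replicates")
})

test_that("planted effects are detected with high power at the study design", {
  # 200 independent replications of a dependent-up gene: day 0 (3 reps) vs
  # day 12 (2 reps), log2 effect 2, log2 noise SD 0.25. A 20k-run
  # Monte-Carlo reference puts the Welch power of this design at
  # 0.855 +/- 0.003 (the 2-replicate group leaves ~2 error df), so the
  # detection rate here must clear 0.78 (3 binomial SD below at n = 200).
  set.seed(1234)
  nrun <- 200
  base <- rnorm(nrun, 4, 1.5)
  d0 <- matrix(2^(base + rnorm(nrun * 3, 0, 0.25)), nrun, 3)
  d12 <- matrix(2^(base + 2 + rnorm(nrun * 2, 0, 0.25)), nrun, 2)
  v <- cbind(d0, d12)
  rownames(v) <- sprintf("run_%03d", seq_len(nrun))
  m <- make_expr(v, rep("KO_WT", 5), c(0L, 0L, 0L, 12L, 12L))
  de <- differential_expression(m, samples_of(m, "KO_WT", 0L),
                                samples_of(m, "KO_WT", 12L))
  expect_gte(mean(de$status == "up"), 0.78)
  # and the rate is consistent with the reference power, not just above floor
  expect_lt(abs(mean(de$status == "up") - 0.855), 3 * sqrt(0.855 * 0.145 / nrun))
})

test_that("nine-square letters follow the fixed grid", {
  cut <- log2(1.5)
  nm <- function(x) setNames(x, sprintf("g%d", seq_along(x)))
  ns <- classify_nine_square(nm(0), nm(0), cut)
  expect_equal(ns$group, "E")
  expect_equal(classify_nine_square(nm(2), nm(0), cut)$group, "F")
  expect_equal(classify_nine_square(nm(2), nm(-2), cut)$group, "I")

  # exhaustive 9-point probe: each sign combination hits its own letter once
  probe <- expand.grid(x = c(-2, 0, 2), y = c(-2, 0, 2))
  fx <- setNames(probe$x, sprintf("p%d", 1:9))
  fy <- setNames(probe$y, sprintf("p%d", 1:9))
  ns <- classify_nine_square(fx, fy, cut)
  # expand.grid varies x fastest with y = -2 first
  expect_equal(ns$group, c("G", "H", "I", "D", "E", "F", "A", "B", "C"))
  expect_setequal(ns$group, LETTERS[1:9])

  expect_error(classify_nine_square(nm(c(1, NA)), nm(c(0, 0)), cut), "non-finite")
  expect_error(classify_nine_square(setNames(1, "a"), setNames(1, "b"), cut),
               "universes differ")
})

test_that("nine-square labels partition the universe and tighten monotonically", {
  set.seed(99)
  for (rep in 1:20) {
    n <- 200
    fx <- setNames(rnorm(n, 0, 1.5), sprintf("g%d", 1:n))
    fy <- setNames(rnorm(n, 0, 1.5), sprintf("g%d", 1:n))
    ns1 <- classify_nine_square(fx, fy, log2(1.5))
    expect_equal(nrow(ns1), n)
    expect_true(all(ns1$group %in% LETTERS[1:9]))
    ns2 <- classify_nine_square(fx, fy, 1.5)  # stricter cutoff
    # raising the cutoff never moves a gene out of the centre cell
    expect_true(all(ns2$group[ns1$group == "E"] == "E"))
  }
})

test_that("dependent-gene selection obeys its subset invariants on random tables", {
  set.seed(7)
  cfg <- pipeline_config()
  mk_de <- function(n) data.frame(gene_id = sprintf("g%d", 1:n),
                                  log2fc = rnorm(n, 0, 1.5),
                                  p_value = runif(n))
  for (rep in 1:300) {
    n <- sample(20:80, 1)
    sel <- select_dependent_genes(mk_de(n), mk_de(n), mk_de(n), cfg)
    expect_true(all(sel$up_dependent %in% sel$stage1_up))
    expect_true(all(sel$down_dependent %in% sel$stage1_down))
    expect_length(intersect(sel$up_dependent, sel$down_dependent), 0)
    # stage-1 sets plus the remaining letters partition the universe
    s1 <- sel$stage1
    expect_equal(length(sel$stage1_up) + length(sel$stage1_down) +
                   sum(!s1$group %in% c("F", "I", "A", "D")), n)
  }
})

test_that("selection recovers the definitional cases", {
  cfg <- pipeline_config()
  de <- function(fc) data.frame(gene_id = c("dep", "shared"),
                                log2fc = fc, p_value = c(1e-4, 1e-4))
  # 'dep' is up in WT and rescue, flat in KO -> up-dependent;
  # 'shared' is up everywhere -> excluded at stage 1 (lands in C)
  sel <- select_dependent_genes(de(c(2, 2)), de(c(0, 2)), de(c(2, 2)), cfg)
  expect_equal(sel$up_dependent, "dep")
  expect_equal(sel$stage1_up, "dep")
})

test_that("trajectory scaling maps means to [0, 1] with constant rows at zero", {
  v <- matrix(c(2, 4, 6, 10,
                3, 3, 3, 3), nrow = 2, byrow = TRUE,
              dimnames = list(c("gA", "gB"), NULL))
  m <- make_expr(v, rep("WT", 4), c(0L, 3L, 6L, 12L))
  tr <- scale_trajectories(m)
  a <- tr[tr$gene_id == "gA", ]
  expect_equal(a$scaled[order(a$timepoint)], c(0, 0.25, 0.5, 1))
  b <- tr[tr$gene_id == "gB", ]
  expect_equal(b$scaled, rep(0, 4))
})

test_that("noise-free dependent-up genes scale to a monotone WT ramp and flat KO", {
  cfg <- small_sim_cfg(seed = 3, noise_sd_log2 = 0)
  g <- simulate_genome(cfg)
  ex <- simulate_expression(g, cfg)
  up <- ex$truth$gene_id[ex$truth$class == "dep_up"][1:5]
  tr <- scale_trajectories(ex$expression, up)
  for (gid in up) {
    wt <- tr[tr$gene_id == gid & tr$genotype == "WT", ]
    wt <- wt[order(wt$timepoint), ]
    expect_true(all(diff(wt$scaled) > 0))
    expect_equal(wt$scaled[c(1, 4)], c(0, 1))
    ko <- tr[tr$gene_id == gid & tr$genotype == "KO", ]
    expect_equal(ko$scaled, rep(0, 4))
  }
})

test_that("top_differential ranks by |fc|, then p, then gene id", {
  rec <- data.frame(gene_id = c("g1", "g2", "g3", "g4"),
                    log2fc = c(3, -2, 2, -3),
                    p_value = c(0.01, 0.001, 0.0005, 0.01))
  expect_equal(top_differential(rec, 1), "g1")  # |fc| ties broken by gene id
  expect_equal(top_differential(rec, 4), c("g1", "g4", "g3", "g2"))
  expect_error(top_differential(rec, 5), "exceeds")
  tie <- data.frame(gene_id = c("a", "b"), log2fc = c(2, -2),
                    p_value = c(0.02, 0.01))
  expect_equal(top_differential(tie, 2), c("b", "a"))
})
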