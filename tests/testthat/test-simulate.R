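small_cfg <- function(.seed, ...) {
  # first formal deliberately dot-prefixed: a caller's `s = ...` must reach
  # sim_config's selection coefficient, not partially match a `seed` formal
  sim_config(n_diploid = 30, n_generations = 20, split_generation = 10,
             n_sites = 80, region_length = 1e5, rho = 1e-3,
             n_sample_focal = 20, n_sample_ref = 20, seed = .seed, ...)
}

test_that("the same seed reproduces a fixture byte for byte", {
  cfg <- small_cfg(123)
  d1 <- file.path(tempdir(), "fx_a")
  d2 <- file.path(tempdir(), "fx_b")
  f1 <- make_fixture(d1, cfg)
  f2 <- make_fixture(d2, cfg)
  for (nm in c("vcf", "phenotypes", "genes", "counts", "design",
               "known_genes", "truth_json")) {
    expect_identical(readLines(f1[[nm]]), readLines(f2[[nm]]),
                     label = paste("file", nm))
  }
})

test_that("offspring haplotypes are parental copies when rho = mu = 0", {
  set.seed(91)
  pop <- matrix(rbinom(20 * 30, 1, 0.5), 20, 30)
  nxt <- gradsweep:::wf_generation(pop, rep(1, 10), mu = 0, rho = 0)
  parent_rows <- apply(nxt, 1, function(g) {
    any(apply(pop, 1, function(p) all(p == g)))
  })
  expect_true(all(parent_rows))
})

test_that("offspring are parental mosaics under recombination", {
  set.seed(92)
  # two fully distinguishable parental haplotype pools
  pop <- rbind(matrix(0L, 10, 40), matrix(1L, 10, 40))
  pop <- pop[rep(1:20), ]
  # one diploid parent per deme arrangement: make each diploid 0-hap + 1-hap
  pop <- matrix(0L, 20, 40)
  pop[seq(2, 20, by = 2), ] <- 1L  # every sample is het at every site
  nxt <- gradsweep:::wf_generation(pop, rep(1, 10), mu = 0, rho = 0.05)
  # every gamete must be a 0/1 step mosaic: runs of constant allele
  n_switches <- apply(nxt, 1, function(g) sum(diff(g) != 0))
  expect_true(all(n_switches < 40))
  expect_true(all(nxt %in% c(0L, 1L)))
})

test_that("allele frequencies remain bounded and sites are conserved", {
  cfg <- small_cfg(321)
  sim <- simulate_panel(cfg)
  expect_equal(n_sites(sim$focal), cfg$n_sites)
  expect_equal(n_sites(sim$ref), cfg$n_sites)
  f <- colMeans(sim$combined$haplotypes)
  expect_true(all(f >= 0 & f <= 1))
})

test_that("neutral drift preserves the mean and decays heterozygosity", {
  # single biallelic site at exact frequency 0.5, no mutation/recombination
  N <- 50; T_gen <- 50; reps <- 200
  freqs <- vapply(seq_len(reps), function(i) {
    cfg <- sim_config(n_diploid = N, n_generations = T_gen,
                      split_generation = 0, n_sites = 1,
                      region_length = 1000, mu = 0, rho = 0, s = 0,
                      sel_init_freq = 0.5, selected_site = 1,
                      condition_establishment = FALSE,
                      sel_final_range = NULL,
                      n_sample_focal = N, n_sample_ref = N, seed = 5000 + i)
    sim <- simulate_panel(cfg)
    sim$truth$freq_focal_deme
  }, numeric(1))
  se <- stats::sd(freqs) / sqrt(reps)
  expect_lt(abs(mean(freqs) - 0.5), 3 * se)       # drift martingale
  H <- mean(2 * freqs * (1 - freqs))
  H_expected <- 0.5 * (1 - 1 / (2 * N))^T_gen
  se_H <- stats::sd(2 * freqs * (1 - freqs)) / sqrt(reps)
  expect_lt(abs(H - H_expected), 3 * se_H)
})

test_that("selection drives the focal deme above the neutral deme", {
  wins <- vapply(1:50, function(i) {
    cfg <- sim_config(n_diploid = 100, n_generations = 50,
                      split_generation = 0, n_sites = 1,
                      region_length = 1000, mu = 0, rho = 0, s = 0.1,
                      sel_init_freq = 0.2, selected_site = 1,
                      condition_establishment = FALSE,
                      sel_final_range = NULL,
                      n_sample_focal = 100, n_sample_ref = 100,
                      seed = 7000 + i)
    sim <- simulate_panel(cfg)
    sim$truth$freq_focal_deme >= sim$truth$freq_ref_deme
  }, logical(1))
  expect_gte(mean(wins), 0.9)
})

test_that("phenotype records follow the dosage model exactly when noiseless", {
  cfg <- small_cfg(77, beta = 1, sigma_env = 0, mu_gl_focal = 114,
                   mu_gl_ref = 115)
  sim <- simulate_panel(cfg)
  ph <- simulate_phenotypes(sim$combined, sim$truth, cfg)
  d <- as_dosage(sim$combined)[, sim$truth$selected_site]
  focal <- ph$breed == "QP"
  expect_equal(ph$mean_gl[focal], unname(114 - d[focal]))
  expect_true(all(ph$mean_gl[!focal] == 115))
  expect_true(all(vapply(ph$records[focal], function(r)
    length(unique(r)) == 1, logical(1))))
})

test_that("higher dosage lowers mean gestation length with noise", {
  neg <- vapply(1:40, function(i) {
    cfg <- small_cfg(900 + i, beta = 1.5, sigma_env = 0.8,
                     sel_init_freq = 0.5, s = 0,
                     condition_establishment = FALSE, sel_final_range = NULL)
    sim <- simulate_panel(cfg)
    ph <- simulate_phenotypes(sim$combined, sim$truth, cfg)
    d <- as_dosage(sim$combined)[, sim$truth$selected_site]
    focal <- ph$breed == "QP"
    if (stats::var(d[focal]) == 0) return(NA)
    stats::cor(ph$mean_gl[focal], d[focal]) < 0
  }, logical(1))
  expect_gte(mean(neg, na.rm = TRUE), 0.95)
})

test_that("simulated counts carry the planted block structure", {
  cfg <- small_cfg(55, n_genes = 500, n_breed_genes = 40, n_stage_genes = 40)
  rna <- simulate_counts(cfg)
  expect_equal(dim(rna$counts), c(500L, 12L))
  expect_equal(length(rna$truth$breed_genes), 40L)
  # planted breed genes differ in mean between breeds at both stages
  qp <- rna$samples$breed == "QP"
  ratio <- rowMeans(rna$counts[rna$truth$breed_genes, qp]) /
    (rowMeans(rna$counts[rna$truth$breed_genes, !qp]) + 0.5)
  expect_gt(mean(abs(log2(ratio + 1e-9)) > 1.5), 0.9)
  # near-Poisson limit: variance tracks the mean
  cfg2 <- small_cfg(56, n_genes = 300, n_breed_genes = 0, n_stage_genes = 0,
                    dispersion = 0)
  rna2 <- simulate_counts(cfg2)
  ratio2 <- apply(rna2$counts, 1, stats::var) / rowMeans(rna2$counts)
  expect_lt(abs(median(ratio2) - 1), 0.25)
})

test_that("null counts produce near-nominal raw false-positive rates", {
  cfg <- small_cfg(58, n_genes = 1500, n_breed_genes = 0, n_stage_genes = 0)
  rna <- simulate_counts(cfg)
  pre <- rna$samples$stage == "PRE"
  res <- simple_de(rna$counts[, pre], rna$samples$breed[pre],
                   contrast = c("QP", "LW"))
  rate <- mean(res$pvalue < 0.05)
  expect_lt(abs(rate - 0.05), 4 * sqrt(0.05 * 0.95 / 1500) + 0.01)
  expect_lte(length(de_call(res)), 2L)
})

test_that("stage exclusion recovers planted breed genes at the derived ceiling", {
  # Independent normal-theory oracle for the Welch stand-in's detection
  # ceiling: per-gene log2-scale noise implied by the NB model, effect 3,
  # n = 3 per cell, Satterthwaite df, BH at the strict call threshold.
  set.seed(95)
  cfg <- sim_config(seed = 95)
  expected_rate <- local({
    reps <- 4000
    sd_lg <- sqrt(1 / exp(6) + cfg$dispersion) / log(2)
    v1 <- sd_lg^2 * stats::rchisq(reps, 2) / 2
    v2 <- sd_lg^2 * stats::rchisq(reps, 2) / 2
    se2 <- v1 / 3 + v2 / 3
    tt <- (cfg$log2_effect + stats::rnorm(reps, 0, sqrt(se2))) / sqrt(se2)
    df <- se2^2 / ((v1 / 3)^2 / 2 + (v2 / 3)^2 / 2)
    p <- 2 * stats::pt(-abs(tt), df)
    # BH threshold when ~n_breed planted genes carry most small p-values
    mean(p < 0.001 * cfg$n_breed_genes / cfg$n_genes)
  })
  rna <- simulate_counts(cfg)
  de <- run_expression_arm(rna$counts, rna$samples)
  rec <- mean(rna$truth$breed_genes %in% de$stage_excluded$final)
  # within a reasonable band of the derived ceiling, and far above the
  # background rate
  expect_gt(rec, expected_rate - 0.2)
  expect_gt(rec, 0.3)
  fp <- mean(setdiff(rownames(rna$counts),
                     c(rna$truth$breed_genes, rna$truth$stage_genes)) %in%
               de$stage_excluded$final)
  expect_lt(fp, 0.02)
  # the final set never intersects stage genes (asserted by construction)
  expect_length(intersect(de$stage_excluded$final,
                          de$stage_excluded$stage_genes), 0)
})
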