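toy_pheno <- function(means, breed = "QP", ref_means = c(114, 115)) {
  tibble::tibble(
    sample_id = c(sprintf("f%02d", seq_along(means)),
                  sprintf("r%02d", seq_along(ref_means))),
    breed = c(rep(breed, length(means)), rep("LW", length(ref_means))),
    mean_gl = c(means, ref_means)
  )
}

test_that("pairs nest strictly under strict thresholds", {
  ph <- toy_pheno(c(112, 113, 114, 115))
  pp <- build_pairs(ph, "QP", thresholds = c(114, 113))
  expect_equal(pp$n_focal, c(4L, 2L, 1L))         # strict <
  expect_false("f03" %in% pp$focal[[2]])          # exactly 114 excluded
  expect_true(all(pp$focal[[3]] %in% pp$focal[[2]]))
  expect_true(all(pp$focal[[2]] %in% pp$focal[[1]]))
  expect_equal(attr(pp, "reference"), c("r01", "r02"))
  expect_error(build_pairs(ph, "QP", thresholds = c(114, 110)), "empty")
})

test_that("a synthetic 100-sow table reproduces brute-force nested counts", {
  set.seed(71)
  means <- round(rnorm(100, 113.5, 1.3), 2)
  ph <- toy_pheno(means)
  pp <- build_pairs(ph, "QP", thresholds = c(114, 113))
  expect_equal(pp$n_focal[2], sum(means < 114))
  expect_equal(pp$n_focal[3], sum(means < 113))
})

test_that("top-tail selection counts, keeps ties, matches sort-and-slice", {
  v <- sample(seq_len(1000))
  expect_equal(sum(select_top(v, 0.01, "upper")), 10L)
  v2 <- c(rep(5, 12), runif(988, 0, 1))
  expect_equal(sum(select_top(v2, 0.01, "upper")), 12L)  # ties included
  set.seed(72)
  v3 <- rnorm(500)
  sel <- select_top(v3, 0.02, "upper")
  brute <- v3 >= sort(v3, decreasing = TRUE)[ceiling(0.02 * 500)]
  expect_equal(sel, brute)
  two <- select_top(v3, 0.02, "two_way")
  brute2 <- brute | v3 <= sort(v3)[ceiling(0.02 * 500)]
  expect_equal(two, brute2)
  expect_warning(select_top(rnorm(10), 0.01), "coarse")
  expect_warning(empty <- select_top(rep(NA_real_, 5), 0.01), "no valid")
  expect_false(any(empty))
})

test_that("the gradient filter reproduces its pass/fail truth table", {
  tbl <- tibble::tibble(
    signal_1 = c(2.0, 2.0, 2.1, 2.0, 2.0, NA, 2.0),
    signal_2 = c(3.0, 3.0, 2.4, 2.0, 3.0, 3.0, 3.0),
    signal_3 = c(4.0, 2.5, 2.9, 2.0, 4.0, 4.0, 4.0),
    sign_1 = c(1, 1, 1, 1, 1, 1, 1),
    sign_2 = c(1, 1, 1, 1, 1, 1, 1),
    sign_3 = c(1, 1, -1, 1, 1, 1, 1),
    selected_pair1 = c(TRUE, TRUE, TRUE, TRUE, FALSE, TRUE, TRUE)
  )
  res <- gradient_filter(tbl)
  # pass; non-monotone; sign flip; flat under strict; not selected;
  # missing pair value; pass
  expect_equal(res$gradient_pass,
               c(TRUE, FALSE, FALSE, FALSE, FALSE, FALSE, TRUE))
  res_ns <- gradient_filter(tbl, strict = FALSE)
  expect_true(res_ns$gradient_pass[4])  # equal values pass non-strict
  expect_error(gradient_filter(tbl[, -1]), "signal")
})

test_that("gradient output is a subset of the pair-1 selection", {
  set.seed(73)
  tbl <- tibble::tibble(
    signal_1 = rnorm(200), signal_2 = rnorm(200), signal_3 = rnorm(200),
    selected_pair1 = select_top(rnorm(200), 0.05)
  )
  res <- gradient_filter(tbl)
  expect_true(all(res$selected_pair1[res$gradient_pass]))
})

test_that("identical nested groups defeat the strict gradient", {
  set.seed(74)
  panel <- random_panel(n_hap = 40, n_site = 60, max_pos = 60000,
                        breed = "QP")
  panel$breed <- rep(c("QP", "LW"), each = 10)
  ph <- tibble::tibble(sample_id = panel$sample_id, breed = panel$breed,
                       mean_gl = c(rep(100, 10), rep(114, 10)))
  # thresholds far above every mean: all three focal groups identical
  pp <- build_pairs(ph, "QP", thresholds = c(150, 149))
  expect_equal(pp$n_focal, rep(10L, 3))
  sc <- suppressWarnings(sweep_scan(panel, pp, region_length = 60000,
                                    stats = c("pi_ratio", "fst")))
  expect_equal(sum(sc$pi_ratio$gradient_pass), 0L)
  expect_equal(sum(sc$fst$gradient_pass), 0L)
})

test_that("neutral scans rarely pass the strict gradient", {
  set.seed(75)
  frac <- replicate(8, {
    panel <- random_panel(n_hap = 80, n_site = 100, max_pos = 2e5,
                          breed = "QP")
    panel$breed <- rep(c("QP", "LW"), each = 20)
    means <- rnorm(20, 114, 1)
    ph <- tibble::tibble(sample_id = panel$sample_id, breed = panel$breed,
                         mean_gl = c(means, rep(114, 20)))
    pp <- build_pairs(ph, "QP",
                      thresholds = stats::quantile(means, c(0.7, 0.3)))
    sc <- suppressWarnings(sweep_scan(panel, pp, region_length = 2e5,
                                      stats = "fst", window_size = 10000))
    sel <- sum(sc$fst$selected_pair1, na.rm = TRUE)
    if (sel == 0) return(NA_real_)
    sum(sc$fst$gradient_pass) / sel
  })
  # under the null, a selected window passes the strict two-step increase
  # well below 25% of the time (random-order argument)
  expect_lt(mean(frac, na.rm = TRUE), 0.25)
})

test_that("candidate combination reports per-statistic sets and the union", {
  genes <- tibble::tibble(
    gene_id = c("A", "B", "C"), symbol = c("A", "B", "C"),
    chrom = "1", start = c(0, 30000, 60000),
    end = c(20000, 50000, 80000), strand = "unknown"
  )
  # fabricate a minimal scan object
  w <- make_windows(90000)
  mk <- function(pass_idx) {
    tbl <- w
    tbl$signal_1 <- 0; tbl$signal_2 <- 0; tbl$signal_3 <- 0
    tbl$selected_pair1 <- FALSE
    tbl$gradient_pass <- seq_len(nrow(w)) %in% pass_idx
    tbl
  }
  scan <- structure(list(windows = w, pi_ratio = mk(1), fst = mk(4),
                         xpehh = NULL), class = "sweep_scan")
  scan$xpehh <- tibble::tibble(site = 1L, pos = 65000L, gradient_pass = TRUE)
  cand <- candidate_genes(scan, genes)
  expect_equal(cand$per_stat$pi_ratio, "A")
  expect_equal(cand$per_stat$fst, "B")
  expect_equal(cand$per_stat$xpehh, "C")
  expect_equal(cand$union, c("A", "B", "C"))
  expect_equal(sum(cand$venn$count), 3L)
})

test_that("scan export writes per-statistic TSVs and BED5 window tracks", {
  set.seed(76)
  panel <- random_panel(n_hap = 40, n_site = 60, max_pos = 60000,
                        breed = "QP")
  panel$breed <- rep(c("QP", "LW"), each = 10)
  ph <- tibble::tibble(sample_id = panel$sample_id, breed = panel$breed,
                       mean_gl = c(rnorm(10, 113, 1), rep(114, 10)))
  pp <- build_pairs(ph, "QP", thresholds = c(114, 113.5))
  sc <- suppressWarnings(sweep_scan(panel, pp, region_length = 60000))
  files <- export_scan(sc, file.path(tempdir(), "scan_out"))
  expect_true(all(file.exists(files)))
  fst_back <- readr::read_tsv(files["fst_tsv"], show_col_types = FALSE)
  expect_equal(nrow(fst_back), nrow(sc$fst))
  bed <- readr::read_tsv(files["fst_selected_bed"], col_names = FALSE,
                         show_col_types = FALSE)
  expect_equal(nrow(bed), sum(sc$fst$selected_pair1, na.rm = TRUE))
  expect_true(all(bed$X5 >= 0 & bed$X5 <= 1000))
})
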