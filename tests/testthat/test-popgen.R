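test_that("site_pi equals the discordant-pair fraction", {
  expect_equal(site_pi(2, 4), 2 / 3)  # 4 discordant pairs of 6
  expect_equal(site_pi(0, 10), 0)
  expect_equal(site_pi(10, 10), 0)
  expect_error(site_pi(0, 1), "2 haplotypes")
  set.seed(11)
  for (i in 1:50) {
    n <- sample(2:12, 1)
    alleles <- rbinom(n, 1, runif(1))
    expect_equal(site_pi(sum(alleles), n), oracle_site_pi(alleles))
  }
})

test_that("window_pi divides by span, uses half-open windows", {
  # two SNPs inside one 10-kb window: value is the site_pi sum over the span
  p <- hap_panel(matrix(c(0, 1, 0, 1), 2, 2), positions = c(5000, 9999))
  w <- make_windows(10000)
  res <- window_pi(p, windows = w)
  expect_equal(res$pi[1], (site_pi(1, 2) + site_pi(1, 2)) / 10000)
  expect_equal(res$n_snps[1], 2L)
  # a SNP at position exactly = end belongs to the next window
  p2 <- hap_panel(matrix(c(0, 1), 2, 1), positions = 10000)
  res2 <- window_pi(p2, windows = make_windows(20000))
  expect_equal(res2$n_snps, c(0L, 1L))
  expect_equal(res2$pi[1], 0)
})

test_that("window_pi matches the all-pairs Hamming oracle", {
  set.seed(12)
  for (i in 1:30) {
    panel <- random_panel(n_hap = sample(c(4, 6, 8), 1), n_site = 20,
                          max_pos = 30000)
    w <- make_windows(30000, size = 10000)
    res <- window_pi(panel, windows = w)
    for (k in seq_len(nrow(w))) {
      expect_equal(res$pi[k],
                   oracle_window_pi(panel$haplotypes, panel$positions,
                                    w$start[k], w$end[k]))
    }
  }
})

test_that("window_pi is invariant to haplotype row permutation", {
  set.seed(13)
  panel <- random_panel(n_hap = 10, n_site = 30, max_pos = 20000)
  w <- make_windows(20000)
  perm <- sample(5)
  expect_equal(window_pi(panel, samples = perm, windows = w)$pi,
               window_pi(panel, samples = 1:5, windows = w)$pi)
})

test_that("pi ratio signal handles identity, decades and zeros", {
  expect_equal(pi_ratio_signal(1e-4, 1e-4)$signal, 0)
  expect_equal(pi_ratio_signal(1e-5, 1e-4, mode = "low_tail")$signal, 1)
  z <- pi_ratio_signal(0, 1e-4)
  expect_true(is.infinite(z$signal) && z$signal > 0)
  expect_equal(z$sign, -1)
  expect_false(pi_ratio_signal(1e-4, 0)$valid)
  # ranking under the two-tailed mode equals ranking by |log ratio|
  set.seed(14)
  pf <- runif(50, 1e-5, 1e-3)
  pr <- runif(50, 1e-5, 1e-3)
  sig <- pi_ratio_signal(pf, pr)$signal
  expect_equal(order(sig), order(abs(log10(pf / pr))))
})

test_that("Weir-Cockerham site components match the ANOVA-route oracle", {
  # fixed difference, no heterozygotes
  comp <- wc_fst_site(10, 0, 0, 0, 0, 10)
  expect_equal(unname(comp["a"] / sum(comp)), 1)
  # identical genotype counts: no among-population variance
  comp2 <- wc_fst_site(5, 3, 2, 5, 3, 2)
  expect_equal(unname(comp2["a"]) <= 0, TRUE)
  expect_lte(sum(comp2["a"]) / sum(comp2), 0)
  # one worked table against the independently derived mean-square route
  expect_equal(unname(wc_fst_site(6, 3, 1, 2, 5, 3)),
               unname(oracle_wc_fst(6, 3, 1, 2, 5, 3)), tolerance = 1e-12)
  set.seed(15)
  for (i in 1:100) {
    cnt <- c(sample(0:8, 3, replace = TRUE), sample(0:8, 3, replace = TRUE))
    if (sum(cnt[1:3]) == 0 || sum(cnt[4:6]) == 0) next
    expect_equal(unname(do.call(wc_fst_site, as.list(cnt))),
                 unname(do.call(oracle_wc_fst, as.list(cnt))),
                 tolerance = 1e-10)
  }
})

test_that("windowed FST is the ratio of sums with the documented edge cases", {
  # a window of fixed differences gives exactly 1
  haps <- rbind(matrix(1L, 4, 3), matrix(0L, 4, 3))
  p <- hap_panel(haps, positions = c(100, 200, 300),
                 sample_id = paste0("s", 1:4), breed = rep(c("A", "B"), each = 2))
  w <- make_windows(10000)
  res <- window_fst(p, c("s1", "s2"), c("s3", "s4"), w)
  expect_equal(res$fst, 1)
  # single-site window reduces to the site ratio
  p1 <- hap_panel(matrix(c(1, 1, 1, 0, 0, 1, 0, 0), 8, 1),
                  positions = 50, breed = rep(c("A", "B"), each = 2))
  comp <- wc_fst_site(1, 1, 0, 0, 1, 1)
  expect_equal(window_fst(p1, 1:2, 3:4, w)$fst[1],
               unname(comp["a"] / sum(comp)))
  # zero usable sites -> NA, excluded
  pmono <- hap_panel(matrix(1L, 8, 2), positions = c(10, 20),
                     breed = rep(c("A", "B"), each = 2))
  expect_true(is.na(window_fst(pmono, 1:2, 3:4, w)$fst[1]))
})

test_that("ratio-of-sums differs from mean-of-ratios on a constructed window", {
  # two sites with very different information content
  g1 <- list(c(9, 1, 0), c(4, 2, 4))
  g2 <- list(c(0, 1, 9), c(4, 2, 4))
  comps <- lapply(1:2, function(i) {
    wc_fst_site(g1[[i]][1], g1[[i]][2], g1[[i]][3],
                g2[[i]][1], g2[[i]][2], g2[[i]][3])
  })
  ratio_of_sums <- sum(vapply(comps, `[`, numeric(1), "a")) /
    sum(vapply(comps, sum, numeric(1)))
  mean_of_ratios <- mean(vapply(comps, function(x) x["a"] / sum(x), numeric(1)))
  expect_false(isTRUE(all.equal(ratio_of_sums, mean_of_ratios)))
  # the package reports the weighted (ratio-of-sums) value
  haps <- matrix(0L, 20, 2)
  # site 1: pop1 9 AA (dosage 2), 1 Aa; pop2 1 Aa, 9 aa
  d1 <- c(rep(2, 9), 1, 1, rep(0, 9))
  d2 <- c(rep(2, 4), rep(1, 2), rep(0, 4), rep(2, 4), rep(1, 2), rep(0, 4))
  to_haps <- function(d) rbind(as.integer(d >= 1), as.integer(d == 2))
  h <- matrix(0L, 40, 2)
  for (i in 1:20) h[c(2 * i - 1, 2 * i), ] <- cbind(to_haps(d1[i]), to_haps(d2[i]))
  p <- hap_panel(h, positions = c(100, 200), breed = rep(c("A", "B"), each = 10))
  expect_equal(window_fst(p, 1:10, 11:20, make_windows(10000))$fst[1],
               ratio_of_sums)
})

test_that("windowed FST never exceeds 1 and splits of one pool sit near 0", {
  set.seed(16)
  fsts <- replicate(30, {
    panel <- random_panel(n_hap = 40, n_site = 30, max_pos = 9000,
                          breed = "X")
    window_fst(panel, 1:10, 11:20, make_windows(10000))$fst[1]
  })
  fsts <- fsts[!is.na(fsts)]
  expect_true(all(fsts <= 1))
  # random halves of one panmictic pool: mean near 0
  expect_lt(abs(mean(fsts)), 0.02)
})

test_that("merged-group diversity is not systematically below subgroup minimum", {
  set.seed(17)
  diffs <- replicate(60, {
    panel <- random_panel(n_hap = 16, n_site = 25, max_pos = 9000)
    w <- make_windows(10000)
    pi_all <- window_pi(panel, windows = w)$pi[1]
    pi_a <- window_pi(panel, samples = 1:4, windows = w)$pi[1]
    pi_b <- window_pi(panel, samples = 5:8, windows = w)$pi[1]
    pi_all - min(pi_a, pi_b)
  })
  # sanity, not a pointwise identity: on average the pooled group is at
  # least as diverse as its least diverse half
  expect_gte(mean(diffs), 0)
  expect_gte(mean(diffs >= 0), 0.5)
})
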