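# Independent brute-force oracles. These deliberately share no code with
# the package implementations: pair enumeration instead of closed forms,
# the ANOVA mean-square route for the variance components, direct factorial
# enumeration for the exact HWE test.

# mean pairwise difference at one site by enumerating haplotype pairs
oracle_site_pi <- function(alleles) {
  n <- length(alleles)
  pairs <- utils::combn(n, 2)
  mean(alleles[pairs[1, ]] != alleles[pairs[2, ]])
}

# per-bp window diversity via all-pairs Hamming distance over in-window sites
oracle_window_pi <- function(haps, positions, start, end) {
  span <- end - start
  in_w <- positions >= start & positions < end
  if (!any(in_w)) return(0)
  sub <- haps[, in_w, drop = FALSE]
  n <- nrow(sub)
  pairs <- utils::combn(n, 2)
  total <- 0
  for (k in seq_len(ncol(pairs))) {
    total <- total + sum(sub[pairs[1, k], ] != sub[pairs[2, k], ])
  }
  total / ncol(pairs) / span
}

# Weir-Cockerham components through the ANOVA mean-square formulation:
# a = (MSP - MSI) / (2 nc), b = (MSI - MSG) / 2, c = MSG
oracle_wc_fst <- function(n_AA1, n_Aa1, n_aa1, n_AA2, n_Aa2, n_aa2) {
  expand <- function(nAA, nAa, naa) {
    c(rep(1, nAA), rep(0.5, nAa), rep(0, naa))  # per-individual allele mean
  }
  pops <- list(expand(n_AA1, n_Aa1, n_aa1), expand(n_AA2, n_Aa2, n_aa2))
  hets <- c(n_Aa1, n_Aa2)
  n_i <- lengths(pops)
  r <- 2
  p_i <- vapply(pops, mean, numeric(1))
  pbar <- sum(n_i * p_i) / sum(n_i)
  SSP <- sum(2 * n_i * (p_i - pbar)^2)
  MSP <- SSP / (r - 1)
  SSI <- sum(unlist(lapply(seq_len(r), function(k) {
    2 * (pops[[k]] - p_i[k])^2
  })))
  MSI <- SSI / sum(n_i - 1)
  SSG <- sum(hets) / 2  # each het individual contributes 2 * (1/2)^2
  MSG <- SSG / sum(n_i)
  nbar <- mean(n_i)
  nc <- (r * nbar - sum(n_i^2) / (r * nbar)) / (r - 1)
  c(a = (MSP - MSI) / (2 * nc), b = (MSI - MSG) / 2, c = MSG)
}

# EHHS at each flanking marker by explicit pair counting
oracle_ehhs <- function(haps, core, t) {
  n <- nrow(haps)
  pairs <- utils::combn(n, 2)
  span <- seq(min(core, t), max(core, t))
  same_span <- vapply(seq_len(ncol(pairs)), function(k) {
    all(haps[pairs[1, k], span] == haps[pairs[2, k], span])
  }, logical(1))
  same_core <- haps[pairs[1, ], core] == haps[pairs[2, ], core]
  sum(same_span) / sum(same_core)
}

# trapezoid integral by dense midpoint Riemann sum on the interpolated curve
oracle_integral <- function(pos, val, n_grid = 20000) {
  if (length(pos) < 2) return(0)
  o <- order(pos)
  f <- stats::approxfun(pos[o], val[o])
  width <- (max(pos) - min(pos)) / n_grid
  mids <- min(pos) + (seq_len(n_grid) - 0.5) * width
  sum(f(mids)) * width
}

# exact HWE by direct factorial enumeration (valid for 2n <= 170)
oracle_hwe <- function(nAA, nAa, naa) {
  n <- nAA + nAa + naa
  n_a <- 2 * naa + nAa
  n_rare <- min(n_a, 2 * n - n_a)
  if (n_rare == 0) return(1)
  hets <- seq(n_rare %% 2, n_rare, by = 2)
  probs <- vapply(hets, function(h) {
    hom_r <- (n_rare - h) / 2
    hom_c <- n - h - hom_r
    factorial(n) / (factorial(hom_r) * factorial(h) * factorial(hom_c)) *
      2^h * factorial(n_rare) * factorial(2 * n - n_rare) / factorial(2 * n)
  }, numeric(1))
  sum(probs[probs <= probs[hets == nAa] * (1 + 1e-12)])
}

# Benjamini-Hochberg by the step-up definition
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(m)
  out[o] <- pmin(adj, 1)
  out
}

# quartet topology by the four-point condition: returns the pair grouped
# with taxon 1 (2, 3 or 4)
oracle_quartet <- function(d) {
  s12 <- d[1, 2] + d[3, 4]
  s13 <- d[1, 3] + d[2, 4]
  s14 <- d[1, 4] + d[2, 3]
  which.min(c(s12, s13, s14)) + 1L
}

# a random phased panel for property tests
random_panel <- function(n_hap = 8, n_site = 20, max_pos = 100000,
                         breed = "pop") {
  haps <- matrix(rbinom(n_hap * n_site, 1, runif(1, 0.2, 0.8)),
                 n_hap, n_site)
  # ensure at least one polymorphic site
  if (all(colSums(haps) %in% c(0, n_hap))) {
    haps[1, 1] <- 1L - haps[1, 1]
  }
  hap_panel(haps, positions = sort(sample.int(max_pos, n_site)),
            breed = breed)
}
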