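#' Tile a region into non-overlapping windows
#'
#' Windows are 0-based half-open tiles of `size` bp. A site with position
#' `pos` belongs to the window with `start <= pos < end`.
#'
#' @param region_length span to tile, bp.
#' @param size window span in bp (default 10 kb, the scan's window and step).
#' @param chrom chromosome label.
#' @return tibble: `chrom`, `start`, `end`, `window` (index).
#' @export
make_windows <- function(region_length, size = 10000, chrom = "1") {
  starts <- seq(0L, max(0L, as.integer(region_length) - 1L), by = as.integer(size))
  tibble::tibble(chrom = chrom, start = starts,
                 end = starts + as.integer(size),
                 window = seq_along(starts))
}

window_index <- function(pos, windows) {
  size <- windows$end[1] - windows$start[1]
  idx <- pos %/% size + 1L
  idx[idx < 1L | idx > nrow(windows)] <- NA_integer_
  idx
}

#' Per-site nucleotide diversity
#'
#' Mean pairwise difference at a biallelic site among `n` haplotypes with
#' `c` copies of the alternate allele: `2 c (n - c) / (n (n - 1))`, i.e. the
#' fraction of discordant haplotype pairs.
#'
#' @param alt_count alternate-allele count(s) `c`.
#' @param hap_count haplotype count(s) `n` (>= 2).
#' @return numeric vector of per-site diversity values.
#' @export
site_pi <- function(alt_count, hap_count) {
  if (any(hap_count < 2)) stop("site_pi needs at least 2 haplotypes")
  stopifnot(all(alt_count >= 0), all(alt_count <= hap_count))
  2 * alt_count * (hap_count - alt_count) / (hap_count * (hap_count - 1))
}

#' Windowed nucleotide diversity per bp
#'
#' Sums [site_pi()] over the SNPs falling in each window and divides by the
#' window span in bp (not by the SNP count), so empty windows score 0.
#'
#' @param panel a [hap_panel()].
#' @param samples samples to use (ids or indices; default all).
#' @param windows tibble from [make_windows()].
#' @return `windows` with `n_snps` and `pi` (per-bp diversity) added.
#' @export
window_pi <- function(panel, samples = NULL, windows) {
  rows <- if (is.null(samples)) seq_len(nrow(panel$haplotypes)) else hap_rows(panel, samples)
  h <- panel$haplotypes[rows, , drop = FALSE]
  n <- nrow(h)
  sp <- site_pi(colSums(h), n)
  idx <- window_index(panel$positions, windows)
  keep <- !is.na(idx)
  span <- windows$end - windows$start
  pi_sum <- rep(0, nrow(windows))
  n_snps <- rep(0L, nrow(windows))
  if (any(keep)) {
    agg <- rowsum(sp[keep], idx[keep])
    pi_sum[as.integer(rownames(agg))] <- agg[, 1]
    cnt <- table(idx[keep])
    n_snps[as.integer(names(cnt))] <- as.integer(cnt)
  }
  dplyr::mutate(windows, n_snps = n_snps, pi = pi_sum / span)
}

#' Diversity-ratio signal for sweep ranking
#'
#' Converts focal/reference per-window diversities into the ranking signal.
#' `two_tailed_abs_log` returns `|log10(pi_focal / pi_ref)|` with the sign of
#' the log ratio kept as metadata (both diversity losses and gains rank
#' high); `low_tail` returns `-log10(pi_focal / pi_ref)` so only diversity
#' loss in the focal group ranks high. Windows with `pi_ref = 0` are invalid
#' (ratio undefined); `pi_focal = 0` with positive `pi_ref` yields an `Inf`
#' sentinel that outranks all finite signals.
#'
#' @param pi_focal,pi_ref per-window diversities (same length).
#' @param mode `"two_tailed_abs_log"` or `"low_tail"`.
#' @return tibble: `signal`, `sign` (of the log ratio; -1 means reduced
#'   focal diversity), `valid`.
#' @export
pi_ratio_signal <- function(pi_focal, pi_ref,
                            mode = c("two_tailed_abs_log", "low_tail")) {
  mode <- match.arg(mode)
  valid <- pi_ref > 0
  lr <- rep(NA_real_, length(pi_focal))
  lr[valid] <- log10(pi_focal[valid] / pi_ref[valid])  # -Inf when pi_focal = 0
  sgn <- sign(lr)
  sgn[valid & pi_focal == 0] <- -1
  signal <- switch(mode,
                   two_tailed_abs_log = abs(lr),
                   low_tail = -lr)
  signal[valid & pi_focal == 0] <- Inf
  tibble::tibble(signal = signal, sign = sgn, valid = valid)
}

#' Weir-Cockerham variance components at one site
#'
#' Two-population components (a: among populations, b: among individuals
#' within populations, c: within individuals) computed from genotype counts
#' with observed heterozygosity. The site estimate is `a / (a + b + c)`; the
#' windowed estimate sums components before dividing.
#'
#' @param n_AA1,n_Aa1,n_aa1 genotype counts in population 1.
#' @param n_AA2,n_Aa2,n_aa2 genotype counts in population 2.
#' @return named numeric vector `c(a, b, c)`.
#' @export
wc_fst_site <- function(n_AA1, n_Aa1, n_aa1, n_AA2, n_Aa2, n_aa2) {
  comp <- wc_components(n_AA1, n_Aa1, n_aa1, n_AA2, n_Aa2, n_aa2)
  c(a = comp$a, b = comp$b, c = comp$c)
}

# vectorized Weir & Cockerham (1984) two-population components; alt allele
# plays the role of A. All arguments are per-site count vectors.
wc_components <- function(n_AA1, n_Aa1, n_aa1, n_AA2, n_Aa2, n_aa2) {
  if (any(c(n_AA1, n_Aa1, n_aa1, n_AA2, n_Aa2, n_aa2) < 0)) {
    stop("genotype counts must be non-negative")
  }
  n1 <- n_AA1 + n_Aa1 + n_aa1
  n2 <- n_AA2 + n_Aa2 + n_aa2
  if (any(n1 < 1) || any(n2 < 1)) {
    stop("each population needs at least one genotyped individual")
  }
  r <- 2
  p1 <- (2 * n_AA1 + n_Aa1) / (2 * n1)
  p2 <- (2 * n_AA2 + n_Aa2) / (2 * n2)
  h1 <- n_Aa1 / n1
  h2 <- n_Aa2 / n2
  nbar <- (n1 + n2) / r
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- nbar / nc *
    (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- nbar / (nbar - 1) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  list(a = a, b = b, c = cc)
}

# per-site genotype counts (AA = alt hom) for a sample subset of a panel
genotype_counts <- function(panel, samples) {
  d <- as_dosage(subset_panel(panel, samples))
  list(n_AA = colSums(d == 2L, na.rm = TRUE),
       n_Aa = colSums(d == 1L, na.rm = TRUE),
       n_aa = colSums(d == 0L, na.rm = TRUE))
}

#' Windowed Weir-Cockerham FST
#'
#' The weighted (ratio-of-sums) estimator: per-site components are summed
#' over the SNPs in each window and the window value is
#' `sum(a) / sum(a + b + c)`. Sites monomorphic across both populations
#' contribute nothing; windows with no usable site are `NA` (excluded from
#' ranking). Negative per-site components are kept, not truncated, to avoid
#' biasing the windowed estimate.
#'
#' @param panel a [hap_panel()].
#' @param pop1,pop2 sample ids or indices of the two populations.
#' @param windows tibble from [make_windows()].
#' @return `windows` with `n_snps_used` and `fst` added.
#' @export
window_fst <- function(panel, pop1, pop2, windows) {
  g1 <- genotype_counts(panel, pop1)
  g2 <- genotype_counts(panel, pop2)
  comp <- wc_components(g1$n_AA, g1$n_Aa, g1$n_aa, g2$n_AA, g2$n_Aa, g2$n_aa)
  denom_site <- comp$a + comp$b + comp$c
  usable <- is.finite(denom_site) & denom_site != 0
  idx <- window_index(panel$positions, windows)
  keep <- usable & !is.na(idx)
  num <- rep(0, nrow(windows))
  den <- rep(0, nrow(windows))
  n_used <- rep(0L, nrow(windows))
  if (any(keep)) {
    agg <- rowsum(cbind(comp$a[keep], denom_site[keep]), idx[keep])
    w <- as.integer(rownames(agg))
    num[w] <- agg[, 1]
    den[w] <- agg[, 2]
    cnt <- table(idx[keep])
    n_used[as.integer(names(cnt))] <- as.integer(cnt)
  }
  fst <- ifelse(den > 0, num / den, NA_real_)
  dplyr::mutate(windows, n_snps_used = n_used, fst = fst)
}
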