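#' Minor allele frequency of one site
#'
#' Alt-allele frequency over non-missing dosages, folded to the minor
#' allele: `maf = min(p, 1 - p)`.
#'
#' @param dosages vector of 0/1/2 with `NA` for missing genotypes.
#' @return minor allele frequency in `[0, 0.5]`.
#' @export
site_maf <- function(dosages) {
  ok <- !is.na(dosages)
  if (!any(ok)) stop("all genotypes missing: MAF undefined")
  p <- sum(dosages[ok]) / (2 * sum(ok))
  min(p, 1 - p)
}

#' Exact Hardy-Weinberg equilibrium test
#'
#' Exact two-sided p-value for a biallelic site: conditional on the observed
#' allele counts, the p-value is the summed probability of all heterozygote
#' counts whose conditional probability does not exceed that of the observed
#' count (no mid-p correction). Monomorphic sites have a single attainable
#' configuration and p = 1.
#'
#' @param n_AA,n_Aa,n_aa genotype counts (non-negative, total >= 1).
#' @return exact p-value in `(0, 1]`.
#' @export
hwe_exact_p <- function(n_AA, n_Aa, n_aa) {
  if (any(c(n_AA, n_Aa, n_aa) < 0)) stop("genotype counts must be non-negative")
  n <- n_AA + n_Aa + n_aa
  if (n < 1) stop("at least one genotyped individual required")
  n_a <- 2 * n_aa + n_Aa
  n_A <- 2 * n_AA + n_Aa
  n_rare <- min(n_A, n_a)
  if (n_rare == 0) return(1)
  hets <- seq(n_rare %% 2, n_rare, by = 2)
  # log P(het = h | allele counts), up to the shared normalising constant
  logp <- vapply(hets, function(h) {
    hom_rare <- (n_rare - h) / 2
    hom_common <- n - h - hom_rare
    lfactorial(n) - lfactorial(hom_rare) - lfactorial(h) -
      lfactorial(hom_common) + h * log(2)
  }, numeric(1))
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  p_obs <- p[hets == n_Aa]
  min(1, sum(p[p <= p_obs * (1 + 1e-12)]))
}

#' Apply the site quality filters
#'
#' Retains sites with MAF strictly above `maf_min`, call rate strictly above
#' `call_rate_min`, and exact Hardy-Weinberg p strictly above `hwe_alpha`
#' (all boundaries fail, matching the literal thresholds
#' MAF > 0.05, call rate > 90\%, HWE p > 1e-6).
#'
#' @param dosage samples x sites dosage matrix (0/1/2, `NA` missing).
#' @param maf_min,call_rate_min,hwe_alpha filter thresholds.
#' @return list: `dosage` (retained columns), `report` (tibble with one row
#'   per input site: `site`, `maf`, `call_rate`, `hwe_p`, `pass`).
#' @export
apply_site_filters <- function(dosage, maf_min = 0.05, call_rate_min = 0.90,
                               hwe_alpha = 1e-6) {
  L <- ncol(dosage)
  n <- nrow(dosage)
  called <- colSums(!is.na(dosage))
  call_rate <- called / n
  maf <- vapply(seq_len(L), function(j) {
    if (called[j] == 0) NA_real_ else site_maf(dosage[, j])
  }, numeric(1))
  hwe_p <- vapply(seq_len(L), function(j) {
    if (called[j] == 0) return(NA_real_)
    d <- dosage[, j]
    hwe_exact_p(sum(d == 2, na.rm = TRUE), sum(d == 1, na.rm = TRUE),
                sum(d == 0, na.rm = TRUE))
  }, numeric(1))
  pass <- !is.na(maf) & maf > maf_min & call_rate > call_rate_min &
    !is.na(hwe_p) & hwe_p > hwe_alpha
  report <- tibble::tibble(site = seq_len(L), maf = maf,
                           call_rate = call_rate, hwe_p = hwe_p, pass = pass)
  list(dosage = dosage[, pass, drop = FALSE], report = report)
}

#' Per-sample missingness
#'
#' Fraction of missing genotypes per sample; samples at or above
#' `flag_rate` are flagged (advisory: removal is the caller's choice, since
#' downstream haplotype statistics assume complete phased panels).
#'
#' @param dosage samples x sites dosage matrix.
#' @param flag_rate flag threshold (default 0.10; the boundary is flagged).
#' @return tibble: `sample_id`, `missing_rate`, `flagged`.
#' @export
sample_missing_rates <- function(dosage, flag_rate = 0.10) {
  rate <- rowMeans(is.na(dosage))
  tibble::tibble(
    sample_id = if (!is.null(rownames(dosage))) rownames(dosage) else
      paste0("s", seq_len(nrow(dosage))),
    missing_rate = rate,
    flagged = rate >= flag_rate
  )
}
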