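#' Phased haplotype panel
#'
#' A `hap_panel` holds a phased, biallelic SNP panel: a 0/1 haplotype matrix
#' with one row per haploid genome (two consecutive rows per diploid sample,
#' the sample's first and second haplotype) and one column per site, plus the
#' physical positions, alleles and per-sample metadata. All downstream
#' statistics (diversity, FST, EHH) operate on this container.
#'
#' @param haplotypes integer/numeric matrix of 0/1 (NA allowed only for
#'   panels read from incompletely genotyped VCFs), `2 * length(sample_id)`
#'   rows.
#' @param positions 1-based physical positions in bp, strictly increasing.
#' @param chrom chromosome name (single string).
#' @param ref,alt single-base reference / alternate alleles per site.
#' @param sample_id per-sample identifiers (half the number of haplotype
#'   rows).
#' @param breed per-sample population/breed labels.
#'
#' @return An object of class `hap_panel`.
#' @export
hap_panel <- function(haplotypes, positions, chrom = "1",
                      ref = NULL, alt = NULL,
                      sample_id = NULL, breed = NULL) {
  haplotypes <- as.matrix(haplotypes)
  storage.mode(haplotypes) <- "integer"
  n_hap <- nrow(haplotypes)
  n_site <- ncol(haplotypes)
  if (n_hap %% 2L != 0L) {
    stop("haplotype row count must be even (two rows per diploid sample)")
  }
  n_sample <- n_hap %/% 2L
  if (is.null(sample_id)) sample_id <- paste0("s", seq_len(n_sample))
  if (is.null(breed)) breed <- rep("pop", n_sample)
  if (length(breed) == 1L) breed <- rep(breed, n_sample)
  if (is.null(ref)) ref <- rep("A", n_site)
  if (is.null(alt)) alt <- rep("G", n_site)
  positions <- as.integer(positions)
  x <- structure(
    list(chrom = as.character(chrom)[1], positions = positions,
         ref = as.character(ref), alt = as.character(alt),
         haplotypes = haplotypes,
         sample_id = as.character(sample_id), breed = as.character(breed)),
    class = "hap_panel"
  )
  validate_hap_panel(x)
}

validate_hap_panel <- function(x) {
  h <- x$haplotypes
  if (nrow(h) != 2L * length(x$sample_id)) {
    stop("row count must be 2 x sample count")
  }
  if (length(x$breed) != length(x$sample_id)) {
    stop("breed labels must match sample count")
  }
  if (length(x$positions) != ncol(h) || length(x$ref) != ncol(h) ||
      length(x$alt) != ncol(h)) {
    stop("positions/alleles must have one entry per site")
  }
  vals <- h[!is.na(h)]
  if (length(vals) && !all(vals %in% c(0L, 1L))) {
    stop("haplotype entries must be 0 or 1")
  }
  if (ncol(h) > 1L && any(diff(x$positions) <= 0L)) {
    stop("positions must be strictly increasing")
  }
  x
}

#' @export
print.hap_panel <- function(x, ...) {
  cat(sprintf("<hap_panel> %d samples (%d haplotypes) x %d sites on %s\n",
              length(x$sample_id), nrow(x$haplotypes),
              ncol(x$haplotypes), x$chrom))
  if (length(x$positions)) {
    cat(sprintf("  positions %s..%s bp; breeds: %s\n",
                format(min(x$positions), big.mark = ","),
                format(max(x$positions), big.mark = ","),
                paste(unique(x$breed), collapse = ", ")))
  }
  invisible(x)
}

#' @export
dim.hap_panel <- function(x) dim(x$haplotypes)

n_samples <- function(panel) length(panel$sample_id)
n_sites <- function(panel) ncol(panel$haplotypes)

#' Diploid dosage matrix from a phased panel
#'
#' Collapses the two haplotype rows of each sample into an alt-allele dosage
#' in `{0, 1, 2}` (`NA` where either haplotype is missing). Rows are samples,
#' columns sites.
#'
#' @param panel a [hap_panel()].
#' @return integer matrix, `sample_id` as rownames.
#' @export
as_dosage <- function(panel) {
  h <- panel$haplotypes
  d <- h[seq(1L, nrow(h), by = 2L), , drop = FALSE] +
    h[seq(2L, nrow(h), by = 2L), , drop = FALSE]
  rownames(d) <- panel$sample_id
  colnames(d) <- as.character(panel$positions)
  d
}

#' Subset a panel by samples and/or sites
#'
#' @param panel a [hap_panel()].
#' @param samples sample identifiers or indices to keep (default all).
#' @param sites site indices to keep (default all).
#' @return a [hap_panel()].
#' @export
subset_panel <- function(panel, samples = NULL, sites = NULL) {
  if (is.null(samples)) {
    si <- seq_along(panel$sample_id)
  } else if (is.character(samples)) {
    si <- match(samples, panel$sample_id)
    if (anyNA(si)) stop("unknown sample id: ", samples[is.na(si)][1])
  } else {
    si <- as.integer(samples)
  }
  if (is.null(sites)) sites <- seq_len(n_sites(panel))
  rows <- as.vector(rbind(2L * si - 1L, 2L * si))
  hap_panel(panel$haplotypes[rows, sites, drop = FALSE],
            positions = panel$positions[sites], chrom = panel$chrom,
            ref = panel$ref[sites], alt = panel$alt[sites],
            sample_id = panel$sample_id[si], breed = panel$breed[si])
}

# haplotype row indices for a set of sample ids/indices
hap_rows <- function(panel, samples) {
  if (is.character(samples)) {
    si <- match(samples, panel$sample_id)
    if (anyNA(si)) stop("unknown sample id: ", samples[is.na(si)][1])
  } else {
    si <- as.integer(samples)
  }
  as.vector(rbind(2L * si - 1L, 2L * si))
}

#' Site summary of a panel as a tibble
#'
#' One row per site: position, alleles, alt-allele count and frequency over
#' all haplotypes.
#'
#' @param x a [hap_panel()].
#' @param ... unused.
#' @return a tibble.
#' @export
tidy.hap_panel <- function(x, ...) {
  h <- x$haplotypes
  tibble::tibble(
    chrom = x$chrom,
    pos = x$positions,
    ref = x$ref,
    alt = x$alt,
    alt_count = colSums(h, na.rm = TRUE),
    n_called = colSums(!is.na(h)),
    alt_freq = colSums(h, na.rm = TRUE) / pmax(colSums(!is.na(h)), 1L)
  )
}
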