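#' Haplotype r-squared between two sites
#'
#' `r2 = D^2 / (p_i (1 - p_i) p_j (1 - p_j))` with `D` estimated directly
#' from phased haplotypes as `freq(1,1) - p_i p_j`. Equals the squared
#' Pearson correlation of the two binary haplotype columns.
#'
#' @param hap_i,hap_j 0/1 vectors of equal length (>= 2), both polymorphic.
#' @return r-squared in `[0, 1]`, or `NA` if either site is monomorphic.
#' @export
hap_r2 <- function(hap_i, hap_j) {
  stopifnot(length(hap_i) == length(hap_j), length(hap_i) >= 2)
  p1 <- mean(hap_i)
  p2 <- mean(hap_j)
  if (p1 %in% c(0, 1) || p2 %in% c(0, 1)) return(NA_real_)
  D <- mean(hap_i == 1 & hap_j == 1) - p1 * p2
  D^2 / (p1 * (1 - p1) * p2 * (1 - p2))
}

# pairwise r2 matrix for a haplotype matrix (columns = sites); monomorphic
# sites give NA rows/cols
r2_matrix <- function(h) {
  n <- nrow(h)
  p <- colMeans(h)
  co <- crossprod(h) / n
  D <- co - outer(p, p)
  pq <- p * (1 - p)
  denom <- outer(pq, pq)
  r2 <- D^2 / denom
  r2[, pq == 0] <- NA_real_
  r2[pq == 0, ] <- NA_real_
  r2
}

#' Linkage-disequilibrium decay curve
#'
#' Computes r-squared for every pair of polymorphic SNPs no more than
#' `max_dist` bp apart, bins the pairs by inter-SNP distance and reports the
#' arithmetic mean r-squared per bin. Empty bins are absent from the output.
#'
#' @param panel a [hap_panel()].
#' @param samples samples to use (default all).
#' @param max_dist maximum pair distance in bp (default 300 kb).
#' @param bin_width distance-bin width in bp.
#' @return tibble: `bin_start`, `bin_mid`, `n_pairs`, `mean_r2`.
#' @export
ld_decay <- function(panel, samples = NULL, max_dist = 300000,
                     bin_width = 10000) {
  rows <- if (is.null(samples)) seq_len(nrow(panel$haplotypes)) else hap_rows(panel, samples)
  h <- panel$haplotypes[rows, , drop = FALSE]
  pos <- panel$positions
  L <- ncol(h)
  if (L < 2L) {
    return(tibble::tibble(bin_start = integer(), bin_mid = numeric(),
                          n_pairs = integer(), mean_r2 = numeric()))
  }
  r2 <- r2_matrix(h)
  ut <- which(upper.tri(r2), arr.ind = TRUE)
  d <- pos[ut[, 2]] - pos[ut[, 1]]
  keep <- d <= max_dist & !is.na(r2[ut])
  if (!any(keep)) {
    return(tibble::tibble(bin_start = integer(), bin_mid = numeric(),
                          n_pairs = integer(), mean_r2 = numeric()))
  }
  tibble::tibble(dist = d[keep], r2 = r2[ut][keep]) |>
    dplyr::mutate(bin_start = (dist - 1L) %/% bin_width * bin_width) |>
    dplyr::group_by(bin_start) |>
    dplyr::summarise(bin_mid = bin_start[1] + bin_width / 2,
                     n_pairs = dplyr::n(), mean_r2 = mean(r2),
                     .groups = "drop") |>
    dplyr::select(bin_start, bin_mid, n_pairs, mean_r2)
}

#' Greedy sliding-window LD pruning
#'
#' Scans windows of `window_sites` SNPs advancing by `step_sites`; within a
#' window, site pairs are visited in position order and whenever a pair of
#' still-retained sites has `r2 >= r2_max` the later site is dropped. The
#' retained set therefore satisfies the pairwise bound within every window
#' and is deterministic for a fixed site order.
#'
#' @param panel a [hap_panel()].
#' @param samples samples to use (default all).
#' @param r2_max pruning threshold (drop at `r2 >= r2_max`; default 0.2).
#' @param window_sites,step_sites window size and step, in sites.
#' @return integer vector of retained site indices.
#' @export
ld_prune <- function(panel, samples = NULL, r2_max = 0.2,
                     window_sites = 50, step_sites = 25) {
  rows <- if (is.null(samples)) seq_len(nrow(panel$haplotypes)) else hap_rows(panel, samples)
  h <- panel$haplotypes[rows, , drop = FALSE]
  L <- ncol(h)
  keep <- rep(TRUE, L)
  starts <- seq(1L, max(1L, L), by = step_sites)
  for (w0 in starts) {
    idx <- seq(w0, min(w0 + window_sites - 1L, L))
    idx <- idx[keep[idx]]
    if (length(idx) < 2L) next
    r2 <- r2_matrix(h[, idx, drop = FALSE])
    for (i in seq_along(idx)[-length(idx)]) {
      if (!keep[idx[i]]) next
      for (j in seq(i + 1L, length(idx))) {
        if (!keep[idx[j]]) next
        if (!is.na(r2[i, j]) && r2[i, j] >= r2_max) keep[idx[j]] <- FALSE
      }
    }
    if (w0 + window_sites - 1L >= L) break
  }
  which(keep)
}

#' Principal component analysis of genotype dosages
#'
#' Patterson-style PCA: each site is centred by twice its allele frequency
#' and scaled by `sqrt(2 p (1 - p))`, monomorphic sites are dropped, and the
#' sample covariance of the scaled dosages is eigen-decomposed. Variance
#' fractions are eigenvalues over the trace.
#'
#' @param dosage complete samples x sites dosage matrix (0/1/2), e.g. from
#'   [as_dosage()].
#' @param n_components number of PCs to return.
#' @param groups optional per-sample labels carried into the scores.
#' @return object of class `gt_pca`: list with `scores` (tibble),
#'   `var_explained` (fractions), `values` (eigenvalues).
#' @export
gt_pca <- function(dosage, n_components = 2, groups = NULL) {
  if (anyNA(dosage)) stop("PCA requires a complete dosage matrix")
  p <- colMeans(dosage) / 2
  poly <- p > 0 & p < 1
  if (!any(poly)) stop("no polymorphic sites")
  X <- dosage[, poly, drop = FALSE]
  p <- p[poly]
  Z <- sweep(X, 2, 2 * p) / rep(sqrt(2 * p * (1 - p)), each = nrow(X))
  G <- tcrossprod(Z) / ncol(Z)
  eig <- eigen(G, symmetric = TRUE)
  vals <- pmax(eig$values, 0)
  k <- min(n_components, ncol(eig$vectors))
  scores <- eig$vectors[, seq_len(k), drop = FALSE] %*%
    diag(sqrt(vals[seq_len(k)]), k)
  colnames(scores) <- paste0("PC", seq_len(k))
  sc <- tibble::as_tibble(scores)
  sc$sample_id <- if (!is.null(rownames(dosage))) rownames(dosage) else
    paste0("s", seq_len(nrow(dosage)))
  if (!is.null(groups)) sc$group <- groups
  structure(list(scores = sc,
                 var_explained = vals / sum(vals),
                 values = vals),
            class = "gt_pca")
}

#' @export
print.gt_pca <- function(x, ...) {
  cat(sprintf("<gt_pca> %d samples; PC1 %.2f%%, PC2 %.2f%% of variance\n",
              nrow(x$scores), 100 * x$var_explained[1],
              100 * ifelse(length(x$var_explained) > 1, x$var_explained[2], 0)))
  invisible(x)
}

#' @export
tidy.gt_pca <- function(x, ...) x$scores

#' @export
glance.gt_pca <- function(x, ...) {
  tibble::tibble(n_samples = nrow(x$scores),
                 pc1_var = x$var_explained[1],
                 pc2_var = if (length(x$var_explained) > 1) x$var_explained[2] else NA_real_)
}

#' Allele-sharing (1 - IBS) distance between samples
#'
#' IBS between two samples is the mean shared-allele fraction per site
#' (1 for identical genotypes, 0.5 for het vs homozygote, 0 for opposite
#' homozygotes), so the distance is the mean of `|d_i - d_j| / 2`.
#'
#' @param dosage complete samples x sites dosage matrix.
#' @return a symmetric distance matrix with zero diagonal.
#' @export
ibs_dist <- function(dosage) {
  if (anyNA(dosage)) stop("IBS distance requires a complete dosage matrix")
  d <- as.matrix(stats::dist(dosage, method = "manhattan")) / (2 * ncol(dosage))
  rownames(d) <- colnames(d) <- rownames(dosage)
  d
}

#' Neighbour-joining tree from a distance matrix
#'
#' Saitou-Nei neighbour joining (via \pkg{ape}) on a symmetric,
#' zero-diagonal distance matrix, typically the allele-sharing distance from
#' [ibs_dist()]. Returns the tree in Newick form.
#'
#' @param d symmetric distance matrix (n >= 3) with zero diagonal.
#' @param labels optional taxon labels (default rownames of `d`).
#' @return single Newick string.
#' @export
nj_tree <- function(d, labels = NULL) {
  d <- as.matrix(d)
  if (anyNA(d)) stop("distance matrix contains NA")
  if (nrow(d) < 3L) stop("neighbour joining needs at least 3 taxa")
  if (!is.null(labels)) rownames(d) <- colnames(d) <- labels
  if (is.null(rownames(d))) {
    rownames(d) <- colnames(d) <- paste0("t", seq_len(nrow(d)))
  }
  tree <- ape::nj(stats::as.dist(d))
  ape::write.tree(tree)
}
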