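#' Genes overlapping candidate windows
#'
#' A gene is annotated when its 0-based half-open interval intersects any
#' candidate window by at least 1 bp on the same chromosome.
#'
#' @param windows tibble with `chrom`, `start`, `end` (0-based half-open).
#' @param genes gene tibble from [read_genes()].
#' @return character vector of unique gene symbols.
#' @export
annotate_windows <- function(windows, genes) {
  if (nrow(windows) == 0 || nrow(genes) == 0) return(character(0))
  hits <- purrr::map_lgl(seq_len(nrow(genes)), function(g) {
    any(genes$chrom[g] == windows$chrom &
          genes$start[g] < windows$end &
          genes$end[g] > windows$start)
  })
  sort(unique(genes$symbol[hits]))
}

#' Genes assigned to candidate SNPs
#'
#' A SNP is assigned to every gene whose body contains it and, failing
#' that, to every gene whose nearest boundary lies within `flank_bp` of the
#' SNP (no nearest-only rule: an intergenic SNP between two genes within
#' flank distance reports both).
#'
#' @param snps tibble with `chrom`, `pos` (same coordinate frame as gene
#'   intervals).
#' @param genes gene tibble from [read_genes()].
#' @param flank_bp flank distance in bp (default 10 kb; a SNP exactly
#'   `flank_bp` away is included, one bp further is not).
#' @return character vector of unique gene symbols.
#' @export
annotate_snps <- function(snps, genes, flank_bp = 10000) {
  if (nrow(snps) == 0 || nrow(genes) == 0) return(character(0))
  hits <- purrr::map_lgl(seq_len(nrow(genes)), function(g) {
    same <- snps$chrom == genes$chrom[g]
    any(same &
          snps$pos >= genes$start[g] - flank_bp &
          snps$pos < genes$end[g] + flank_bp)
  })
  sort(unique(genes$symbol[hits]))
}

#' Simple differential-expression test
#'
#' A deliberately simple DE engine for exercising the downstream set logic:
#' median-of-ratios size factors (against the per-gene geometric-mean
#' pseudo-reference, genes containing any zero excluded from the median),
#' log2 fold changes from shifted normalized means, a two-sided Welch t-test
#' on `log2(normalized + 1)`, and Benjamini-Hochberg adjustment. Externally
#' produced DE tables (e.g. from a negative-binomial model) can be used in
#' its place anywhere downstream.
#'
#' @param counts gene x sample matrix of non-negative integer counts with
#'   gene rownames.
#' @param groups per-sample labels (exactly two levels).
#' @param contrast `c(test, reference)` group labels; log2 fold change is
#'   test over reference. Default: second level vs first.
#' @return tibble: `gene`, `base_mean`, `log2fc`, `pvalue`, `padj`, with
#'   the contrast label as attribute `contrast`.
#' @export
simple_de <- function(counts, groups, contrast = NULL) {
  groups <- as.character(groups)
  lev <- unique(groups)
  if (length(lev) != 2) stop("simple_de needs exactly two groups")
  if (is.null(contrast)) contrast <- c(lev[2], lev[1])
  i_test <- which(groups == contrast[1])
  i_ref <- which(groups == contrast[2])
  if (length(i_test) < 2 || length(i_ref) < 2) {
    stop("each group needs at least 2 samples")
  }
  counts <- as.matrix(counts)
  # median-of-ratios size factors
  log_geo <- rowMeans(log(counts))
  usable <- is.finite(log_geo)
  sf <- apply(counts, 2, function(col) {
    stats::median((col / exp(log_geo))[usable])
  })
  if (any(!is.finite(sf) | sf <= 0)) {
    stop("size factors undefined: too many zero counts")
  }
  norm <- sweep(counts, 2, sf, "/")
  m_test <- rowMeans(norm[, i_test, drop = FALSE])
  m_ref <- rowMeans(norm[, i_ref, drop = FALSE])
  all_zero <- rowSums(counts) == 0
  log2fc <- log2((m_test + 0.5) / (m_ref + 0.5))
  log2fc[all_zero] <- 0
  ln <- log2(norm + 1)
  pvalue <- vapply(seq_len(nrow(counts)), function(g) {
    x <- ln[g, i_test]
    y <- ln[g, i_ref]
    v1 <- stats::var(x); v2 <- stats::var(y)
    se2 <- v1 / length(x) + v2 / length(y)
    d <- mean(x) - mean(y)
    if (se2 == 0) return(if (d == 0) 1 else 0)
    tt <- d / sqrt(se2)
    df <- se2^2 / ((v1 / length(x))^2 / (length(x) - 1) +
                     (v2 / length(y))^2 / (length(y) - 1))
    2 * stats::pt(-abs(tt), df)
  }, numeric(1))
  pvalue[all_zero] <- 1
  out <- tibble::tibble(
    gene = rownames(counts),
    base_mean = unname(rowMeans(norm)),
    log2fc = unname(log2fc),
    pvalue = pvalue,
    padj = stats::p.adjust(pvalue, method = "BH")
  )
  attr(out, "contrast") <- paste0(contrast[1], "_vs_", contrast[2])
  out
}

#' Call differentially expressed genes
#'
#' Strict thresholds: `|log2fc| > log2(fc_min)` and `padj < alpha`; genes
#' exactly at either boundary are not called.
#'
#' @param table DE tibble with `gene`, `log2fc`, `padj` (from [simple_de()]
#'   or an external tool).
#' @param fc_min minimum fold change (default 2, i.e. `|log2fc| > 1`).
#' @param alpha adjusted-p threshold (default 0.001).
#' @return character vector of called gene symbols.
#' @export
de_call <- function(table, fc_min = 2, alpha = 0.001) {
  stopifnot(all(c("gene", "log2fc", "padj") %in% names(table)))
  called <- abs(table$log2fc) > log2(fc_min) & table$padj < alpha
  called[is.na(called)] <- FALSE
  sort(unique(table$gene[called]))
}

#' Stage-exclusion set logic for breed-specific expression
#'
#' Removes gestational-stage genes from the breed contrasts: the stage gene
#' set is the union of the within-breed late-pregnancy-versus-parturition
#' DE sets; each stage's short-gestation gene set is the corresponding
#' between-breed DE set minus the stage genes; the final set is the union
#' over stages. By construction the result never intersects the stage
#' genes.
#'
#' @param breed_sets named list of between-breed DE gene sets, one per
#'   stage (e.g. `list(PRE = ..., PAR = ...)`).
#' @param stage_sets list of within-breed stage DE gene sets (one per
#'   breed).
#' @return list: `stage_genes`, `per_stage` (named list), `final`.
#' @export
stage_exclusion <- function(breed_sets, stage_sets) {
  stage_genes <- sort(unique(unlist(stage_sets, use.names = FALSE)))
  per_stage <- lapply(breed_sets, function(s) sort(setdiff(s, stage_genes)))
  list(stage_genes = stage_genes,
       per_stage = per_stage,
       final = sort(unique(unlist(per_stage, use.names = FALSE))))
}

# 7 disjoint Venn regions of three sets
venn3_counts <- function(a, b, c, names = c("A", "B", "C")) {
  a <- unique(a); b <- unique(b); c <- unique(c)
  all_sym <- unique(c(a, b, c))
  in_a <- all_sym %in% a
  in_b <- all_sym %in% b
  in_c <- all_sym %in% c
  region <- function(x, y, z) sum(in_a == x & in_b == y & in_c == z)
  tibble::tibble(
    region = c(paste0(names[1], "_only"), paste0(names[2], "_only"),
               paste0(names[3], "_only"),
               paste(names[1], names[2], sep = "_"),
               paste(names[1], names[3], sep = "_"),
               paste(names[2], names[3], sep = "_"),
               paste(names, collapse = "_")),
    count = c(region(TRUE, FALSE, FALSE), region(FALSE, TRUE, FALSE),
              region(FALSE, FALSE, TRUE), region(TRUE, TRUE, FALSE),
              region(TRUE, FALSE, TRUE), region(FALSE, TRUE, TRUE),
              region(TRUE, TRUE, TRUE))
  )
}

#' Known-gene overlap of the candidate sets
#'
#' Harmonises symbols case-insensitively, computes the 7 disjoint Venn
#' regions of the sweep, DE and known-gene sets, and reports the overlap of
#' interest: `(sweep union DE) intersect known`.
#'
#' @param sweep_genes,de_genes,known_genes character vectors of symbols.
#' @return list: `venn` (tibble of disjoint region counts), `overlap`
#'   (candidate genes that are known genes), `sets` (the harmonised sets).
#' @export
known_gene_venn <- function(sweep_genes, de_genes, known_genes) {
  harmonise <- function(x, nm) {
    x <- toupper(x)
    if (anyDuplicated(x)) {
      warning("duplicate symbols in ", nm, " set collapsed")
    }
    unique(x)
  }
  s <- harmonise(sweep_genes, "sweep")
  d <- harmonise(de_genes, "DE")
  k <- harmonise(known_genes, "known")
  list(
    venn = venn3_counts(s, d, k, names = c("sweep", "de", "known")),
    overlap = sort(intersect(union(s, d), k)),
    sets = list(sweep = s, de = d, known = k)
  )
}
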