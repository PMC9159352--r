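#' Read a phased VCF into a haplotype panel
#'
#' Parses a VCF 4.x file (via \pkg{vcfR}), keeps biallelic single-base SNP
#' records only (others are dropped with a message), and transcribes the GT
#' field into a 0/1 haplotype matrix ordered sampleA_hap1, sampleA_hap2,
#' sampleB_hap1, ... Missing genotypes become `NA` haplotypes; with
#' `require_phased = TRUE` any unphased ("/") non-missing genotype raises an
#' error naming the first offending record.
#'
#' @param path VCF file (plain or gzipped).
#' @param require_phased error on unphased genotypes (default TRUE).
#' @param breed optional per-sample breed labels.
#' @return a [hap_panel()].
#' @export
read_vcf <- function(path, require_phased = TRUE, breed = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  n_rec <- nrow(fix)
  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]
  snp <- !is.na(ref) & !is.na(alt) & nchar(ref) == 1L & nchar(alt) == 1L &
    !grepl(",", alt, fixed = TRUE) & ref %in% c("A", "C", "G", "T") &
    alt %in% c("A", "C", "G", "T")
  n_drop <- sum(!snp)
  if (n_drop > 0) {
    message(n_drop, " non-biallelic-SNP record(s) dropped")
  }
  if (!any(snp)) {
    gt_samples <- colnames(v@gt)[-1]
    return(hap_panel(matrix(integer(), 2L * length(gt_samples), 0L),
                     positions = integer(), chrom = "1",
                     ref = character(), alt = character(),
                     sample_id = gt_samples, breed = breed))
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = n_rec)
  gt <- gt[snp, , drop = FALSE]
  fix <- fix[snp, , drop = FALSE]
  pos <- as.integer(fix[, "POS"])
  if (length(pos) > 1L && any(diff(pos) <= 0L)) {
    stop("VCF positions are not strictly increasing")
  }
  samples <- colnames(gt)
  if (require_phased) {
    unphased <- grepl("/", gt, fixed = TRUE) & !grepl("^\\.", gt)
    if (any(unphased)) {
      w <- arrayInd(which(unphased)[1], dim(gt))
      stop(sprintf("unphased genotype at %s:%s sample %s",
                   fix[w[1], "CHROM"], fix[w[1], "POS"], samples[w[2]]))
    }
  }
  a1 <- substr(gt, 1, 1)
  a2 <- substr(gt, 3, 3)
  to_int <- function(a) {
    out <- suppressWarnings(as.integer(a))
    out
  }
  # interleave: rows are sites here; build 2S x L with sample-major hap rows
  h1 <- to_int(a1)
  h2 <- to_int(a2)
  L <- nrow(gt)
  S <- length(samples)
  haps <- matrix(NA_integer_, 2L * S, L)
  for (s in seq_len(S)) {
    haps[2L * s - 1L, ] <- h1[(s - 1L) * L + seq_len(L)]
    haps[2L * s, ] <- h2[(s - 1L) * L + seq_len(L)]
  }
  hap_panel(haps, positions = pos, chrom = fix[1, "CHROM"],
            ref = fix[, "REF"], alt = fix[, "ALT"],
            sample_id = samples, breed = breed)
}

#' Write a haplotype panel as a VCF 4.2 file
#'
#' Emits a minimal VCF with phased GT genotypes; `read_vcf()` of the result
#' reproduces the panel exactly on positions, alleles and haplotypes.
#'
#' @param panel a [hap_panel()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(panel, path) {
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=gradsweep",
    sprintf("##contig=<ID=%s>", panel$chrom),
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", panel$sample_id), collapse = "\t")
  )
  L <- n_sites(panel)
  if (L == 0L) {
    writeLines(header, path)
    return(invisible(path))
  }
  h <- panel$haplotypes
  gt_chr <- matrix(as.character(h), nrow(h), ncol(h))
  gt_chr[is.na(gt_chr)] <- "."
  S <- length(panel$sample_id)
  gt_cols <- vapply(seq_len(S), function(s) {
    paste0(gt_chr[2L * s - 1L, ], "|", gt_chr[2L * s, ])
  }, character(L))
  if (L == 1L) gt_cols <- matrix(gt_cols, nrow = 1L)
  body <- paste(panel$chrom, panel$positions, ".", panel$ref, panel$alt,
                ".", "PASS", ".", "GT",
                apply(gt_cols, 1L, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a gestation-length phenotype table
#'
#' Accepts a TSV with header and either one row per recorded parity
#' (`sample_id`, `breed`, `gestation_length`) or per-sample means
#' (`sample_id`, `breed`, `mean_gl`), or a mixture (rows may use either
#' column). Parity records are aggregated per sample into a list-column and
#' `mean_gl` is the arithmetic mean of the records.
#'
#' @param path TSV file.
#' @return tibble: `sample_id`, `breed`, `records` (list-column),
#'   `n_records`, `mean_gl`.
#' @export
read_phenotypes <- function(path) {
  raw <- readr::read_tsv(path, show_col_types = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  if (!all(c("sample_id", "breed") %in% names(raw))) {
    stop("phenotype table needs sample_id and breed columns")
  }
  has_rec <- "gestation_length" %in% names(raw)
  has_mean <- "mean_gl" %in% names(raw)
  if (!has_rec && !has_mean) {
    stop("phenotype table needs a gestation_length or mean_gl column")
  }
  parse_num <- function(x, col) {
    out <- suppressWarnings(as.numeric(x))
    bad <- which(!is.na(x) & x != "" & is.na(out))
    if (length(bad)) {
      stop(sprintf("non-numeric %s at row %d: '%s'", col, bad[1], x[bad[1]]))
    }
    out
  }
  gl <- if (has_rec) parse_num(raw$gestation_length, "gestation_length") else
    rep(NA_real_, nrow(raw))
  mg <- if (has_mean) parse_num(raw$mean_gl, "mean_gl") else
    rep(NA_real_, nrow(raw))
  rec_rows <- !is.na(gl)
  if ("parity" %in% names(raw) &&
      anyDuplicated(raw[rec_rows, c("sample_id", "parity")])) {
    warning("duplicate (sample, parity) phenotype rows found; all kept")
  }
  recs <- tibble::tibble(sample_id = raw$sample_id[rec_rows],
                         breed = raw$breed[rec_rows],
                         gl = gl[rec_rows]) |>
    dplyr::group_by(sample_id, breed) |>
    dplyr::summarise(records = list(gl), n_records = dplyr::n(),
                     mean_gl = mean(gl), .groups = "drop")
  means <- tibble::tibble(sample_id = raw$sample_id[!rec_rows & !is.na(mg)],
                          breed = raw$breed[!rec_rows & !is.na(mg)],
                          records = list(numeric(0)), n_records = 0L,
                          mean_gl = mg[!rec_rows & !is.na(mg)])
  dplyr::bind_rows(recs, means)
}

#' Read gene features from BED or GFF3
#'
#' Normalises coordinates to the package-wide 0-based half-open convention:
#' BED intervals pass through unchanged; GFF3 `gene` records (1-based
#' inclusive) have their start decremented by 1. Records whose end does not
#' exceed their start after normalisation are rejected with a warning.
#'
#' @param path annotation file.
#' @param dialect `"bed"` or `"gff3"` (default guessed from the extension).
#' @return tibble: `gene_id`, `symbol`, `chrom`, `start`, `end`, `strand`.
#' @export
read_genes <- function(path, dialect = NULL) {
  if (is.null(dialect)) {
    dialect <- if (grepl("\\.gff3?(\\.gz)?$", path, ignore.case = TRUE))
      "gff3" else "bed"
  }
  dialect <- match.arg(dialect, c("bed", "gff3"))
  if (dialect == "gff3") {
    lines <- readLines(path)
    body <- !startsWith(lines, "#") & nzchar(lines)
    fields <- strsplit(lines[body], "\t", fixed = TRUE)
    ok <- vapply(fields, function(f) {
      length(f) >= 9 && !is.na(suppressWarnings(as.numeric(f[4]))) &&
        !is.na(suppressWarnings(as.numeric(f[5]))) &&
        as.numeric(f[4]) <= as.numeric(f[5])
    }, logical(1))
    if (any(!ok)) {
      warning(sum(!ok), " malformed GFF3 record(s) rejected")
      tmp <- tempfile(fileext = ".gff3")
      writeLines(c(lines[startsWith(lines, "#")], lines[body][ok]), tmp)
      path <- tmp
      on.exit(unlink(tmp), add = TRUE)
    }
    gr <- rtracklayer::import(path, format = "gff3")
    if ("type" %in% names(S4Vectors::mcols(gr))) {
      gr <- gr[as.character(gr$type) == "gene"]
    }
    id <- if (!is.null(gr$ID)) as.character(gr$ID) else
      if (!is.null(gr$gene_id)) as.character(gr$gene_id) else
        paste0("gene", seq_along(gr))
    sym <- if (!is.null(gr$Name)) as.character(gr$Name) else id
    out <- tibble::tibble(
      gene_id = id, symbol = sym,
      chrom = as.character(GenomicRanges::seqnames(gr)),
      start = GenomicRanges::start(gr) - 1L,
      end = GenomicRanges::end(gr),
      strand = as.character(GenomicRanges::strand(gr))
    )
  } else {
    gr <- rtracklayer::import(path, format = "bed")
    nm <- if (!is.null(gr$name)) as.character(gr$name) else
      paste0("gene", seq_along(gr))
    out <- tibble::tibble(
      gene_id = nm, symbol = nm,
      chrom = as.character(GenomicRanges::seqnames(gr)),
      start = GenomicRanges::start(gr) - 1L,
      end = GenomicRanges::end(gr),
      strand = as.character(GenomicRanges::strand(gr))
    )
  }
  out$strand[!out$strand %in% c("+", "-")] <- "unknown"
  bad <- out$end <= out$start
  if (any(bad)) {
    warning(sum(bad), " gene record(s) with end <= start rejected")
    out <- out[!bad, , drop = FALSE]
  }
  out
}

#' Read a known-gene list
#'
#' One gene symbol per line (a dbPTB-style catalogue); blank lines are
#' skipped and duplicates collapsed.
#'
#' @param path text file.
#' @return character vector of symbols.
#' @export
read_known_genes <- function(path) {
  x <- trimws(readLines(path))
  unique(x[nzchar(x)])
}
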