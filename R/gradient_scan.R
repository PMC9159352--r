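#' Build the nested phenotype-gradient population pairs
#'
#' Pair 1 contrasts all focal-breed samples against the fixed reference
#' (every non-focal sample); each further pair keeps only focal samples
#' whose mean gestation length falls strictly below the next threshold, so
#' the focal groups are strictly nested while the reference never changes.
#' With the default thresholds `c(114, 113)` this mirrors the three-step
#' design: all sows, sows under 114 d, sows under 113 d.
#'
#' @param phenotypes tibble from [read_phenotypes()] or
#'   [simulate_phenotypes()] (`sample_id`, `breed`, `mean_gl`).
#' @param focal_breed breed label of the focal group.
#' @param thresholds decreasing gestation-length cutoffs in days, one per
#'   additional pair.
#' @return object of class `pop_pairs`: tibble with `label`, `threshold`,
#'   `n_focal`, `focal` (list-column of sample ids), and attribute
#'   `reference` (the fixed reference sample ids).
#' @export
build_pairs <- function(phenotypes, focal_breed, thresholds = c(114, 113)) {
  stopifnot(all(c("sample_id", "breed", "mean_gl") %in% names(phenotypes)))
  focal_all <- phenotypes[phenotypes$breed == focal_breed, ]
  if (nrow(focal_all) == 0) stop("no samples of focal breed ", focal_breed)
  if (anyNA(focal_all$mean_gl)) {
    stop("every focal-breed sample needs a mean gestation length")
  }
  reference <- phenotypes$sample_id[phenotypes$breed != focal_breed]
  if (length(reference) == 0) stop("no reference samples")
  sets <- list(focal_all$sample_id)
  labels <- focal_breed
  for (thr in thresholds) {
    keep <- focal_all$sample_id[focal_all$mean_gl < thr]
    if (length(keep) == 0) {
      stop("threshold ", thr, " d leaves an empty focal group")
    }
    sets <- c(sets, list(keep))
    labels <- c(labels, paste0(focal_breed, thr))
  }
  sizes <- lengths(sets)
  if (any(diff(sizes) > 0)) {
    stop("thresholds must produce nested (non-increasing) focal groups")
  }
  out <- tibble::tibble(pair = seq_along(sets), label = labels,
                        threshold = c(NA_real_, thresholds),
                        n_focal = sizes, focal = sets)
  structure(out, reference = reference,
            class = c("pop_pairs", class(out)))
}

#' @export
print.pop_pairs <- function(x, ...) {
  cat(sprintf("<pop_pairs> %d nested pairs vs %d reference samples\n",
              nrow(x), length(attr(x, "reference"))))
  print(tibble::as_tibble(x[, c("pair", "label", "threshold", "n_focal")]))
  invisible(x)
}

#' Select the empirical top tail(s)
#'
#' `upper` keeps units whose value is at least the `(1 - q)` empirical
#' cutoff (the `ceiling(q * n)`-th largest value); ties at the cutoff are
#' all included. `two_way` unions the upper and lower tails, each at `q`.
#' `NA`/invalid values are never selected; `Inf` sentinels outrank all
#' finite values.
#'
#' @param values numeric signal per unit.
#' @param q tail fraction (default 0.01).
#' @param tail `"upper"` or `"two_way"`.
#' @return logical vector, `TRUE` for selected units.
#' @export
select_top <- function(values, q = 0.01, tail = c("upper", "two_way")) {
  tail <- match.arg(tail)
  ok <- !is.na(values)
  n_valid <- sum(ok)
  if (n_valid == 0) {
    warning("no valid values: empty selection")
    return(rep(FALSE, length(values)))
  }
  if (n_valid < 1 / q) {
    warning("fewer than 1/q valid units; tail selection is coarse")
  }
  k <- max(1L, ceiling(q * n_valid))
  sel <- rep(FALSE, length(values))
  hi <- sort(values[ok], decreasing = TRUE)[k]
  sel[ok] <- values[ok] >= hi
  if (tail == "two_way") {
    lo <- sort(values[ok])[k]
    sel[ok] <- sel[ok] | values[ok] <= lo
  }
  sel
}

#' Gradient-increase filter across the three population pairs
#'
#' A unit passes when (1) it was selected in the first pair's top tail,
#' (2) its signal increases across the nested pairs
#' (`signal_1 < signal_2 < signal_3`; non-strict `<=` when
#' `strict = FALSE`), and (3) for signed statistics the sign is identical
#' across the pairs. Units missing any pair's signal fail.
#'
#' @param data tibble with columns `signal_1`, `signal_2`, `signal_3`,
#'   `selected_pair1`, and optionally `sign_1`, `sign_2`, `sign_3`.
#' @param strict require strictly increasing signals (default TRUE).
#' @return `data` with a logical `gradient_pass` column.
#' @export
gradient_filter <- function(data, strict = TRUE) {
  need <- c("signal_1", "signal_2", "signal_3", "selected_pair1")
  if (!all(need %in% names(data))) {
    stop("gradient_filter needs three pairs of signals: columns ",
         paste(setdiff(need, names(data)), collapse = ", "), " missing")
  }
  s1 <- data$signal_1; s2 <- data$signal_2; s3 <- data$signal_3
  complete <- !is.na(s1) & !is.na(s2) & !is.na(s3)
  inc <- if (strict) s1 < s2 & s2 < s3 else s1 <= s2 & s2 <= s3
  pass <- data$selected_pair1 & complete & inc
  if (all(c("sign_1", "sign_2", "sign_3") %in% names(data))) {
    same_sign <- data$sign_1 == data$sign_2 & data$sign_2 == data$sign_3
    same_sign[is.na(same_sign)] <- FALSE
    pass <- pass & same_sign
  }
  pass[is.na(pass)] <- FALSE
  dplyr::mutate(data, gradient_pass = pass)
}

#' Phenotype-gradient selective-sweep scan
#'
#' Runs the full scan over the nested population pairs: windowed diversity
#' ratios and Weir-Cockerham FST per 10-kb tile, and per-SNP unstandardized
#' XP-EHH; selects the top `q` tail in the first pair (two-way for XP-EHH
#' and for the two-tailed diversity-ratio mode), and applies the
#' gradient-increase filter across the pairs.
#'
#' @param panel combined [hap_panel()] holding focal and reference samples.
#' @param pairs a [build_pairs()] result.
#' @param region_length region span used to tile windows (default: past the
#'   last site).
#' @param window_size window/step span in bp (default 10 kb).
#' @param stats statistics to run, subset of `c("pi_ratio", "fst",
#'   "xpehh")`.
#' @param q top-tail fraction (default 0.01).
#' @param pi_mode diversity-ratio mode, see [pi_ratio_signal()].
#' @param ehh_cutoff,ehh_maf XP-EHH decay cutoff and core MAF filter.
#' @param ehh_max_extent maximum EHH scan extent per side, bp.
#' @param strict strict monotone gradient (default TRUE).
#' @return object of class `sweep_scan`: list of per-statistic tibbles (one
#'   row per window or SNP, with per-pair signals, `selected_pair1`,
#'   `gradient_pass`), plus `windows` and the `pairs` used.
#' @export
sweep_scan <- function(panel, pairs, region_length = NULL,
                       window_size = 10000,
                       stats = c("pi_ratio", "fst", "xpehh"),
                       q = 0.01,
                       pi_mode = c("two_tailed_abs_log", "low_tail"),
                       ehh_cutoff = 0.05, ehh_maf = 0.05,
                       ehh_max_extent = 300000, strict = TRUE) {
  stats <- match.arg(stats, several.ok = TRUE)
  pi_mode <- match.arg(pi_mode)
  reference <- attr(pairs, "reference")
  if (is.null(region_length)) region_length <- max(panel$positions)
  windows <- make_windows(region_length, window_size, chrom = panel$chrom)
  n_pairs <- nrow(pairs)
  if (n_pairs < 3) stop("the gradient design needs 3 nested pairs")
  out <- list(windows = windows, pairs = pairs, q = q, pi_mode = pi_mode)

  if ("pi_ratio" %in% stats || "fst" %in% stats) {
    pi_ref <- window_pi(panel, reference, windows)$pi
    per_pair_pi <- lapply(pairs$focal, function(f) window_pi(panel, f, windows)$pi)
    if ("pi_ratio" %in% stats) {
      sig <- lapply(per_pair_pi, pi_ratio_signal, pi_ref = pi_ref, mode = pi_mode)
      tbl <- windows
      for (k in seq_len(n_pairs)) {
        tbl[[paste0("pi_focal_", k)]] <- per_pair_pi[[k]]
        tbl[[paste0("signal_", k)]] <- ifelse(sig[[k]]$valid, sig[[k]]$signal, NA_real_)
        # sign consistency only constrains the two-tailed (signed) mode
        if (pi_mode == "two_tailed_abs_log") {
          tbl[[paste0("sign_", k)]] <- sig[[k]]$sign
        }
      }
      tbl$pi_ref <- pi_ref
      tbl$selected_pair1 <- select_top(tbl$signal_1, q, tail = "upper")
      out$pi_ratio <- gradient_filter(tbl, strict = strict)
    }
    if ("fst" %in% stats) {
      tbl <- windows
      for (k in seq_len(n_pairs)) {
        tbl[[paste0("signal_", k)]] <-
          window_fst(panel, pairs$focal[[k]], reference, windows)$fst
      }
      tbl$selected_pair1 <- select_top(tbl$signal_1, q, tail = "upper")
      out$fst <- gradient_filter(tbl, strict = strict)
    }
  }

  if ("xpehh" %in% stats) {
    # cores fixed once from the pair-1 (whole-panel) pooled MAF, so the
    # three pairs are evaluated on identical cores and the reference-group
    # scan is shared across pairs
    f_all <- colMeans(panel$haplotypes[hap_rows(panel, c(pairs$focal[[1]],
                                                         reference)), ,
                                       drop = FALSE])
    cores <- which(pmin(f_all, 1 - f_all) > ehh_maf)
    ref_ies <- ies_scan(panel, reference, cores, ehh_cutoff, ehh_max_extent)
    tbl <- ref_ies[, c("site", "pos")]
    for (k in seq_len(n_pairs)) {
      fi <- ies_scan(panel, pairs$focal[[k]], cores, ehh_cutoff,
                     ehh_max_extent)
      valid <- fi$ies > 0 & ref_ies$ies > 0
      v <- ifelse(valid, log(fi$ies / ref_ies$ies), NA_real_)
      # gradient compares signal magnitudes; sign carries the direction
      tbl[[paste0("xpehh_", k)]] <- v
      tbl[[paste0("signal_", k)]] <- abs(v)
      tbl[[paste0("sign_", k)]] <- sign(v)
    }
    tbl$selected_pair1 <- select_top(tbl$xpehh_1, q, tail = "two_way")
    out$xpehh <- gradient_filter(tbl, strict = strict)
  }
  structure(out, class = "sweep_scan")
}

#' @export
print.sweep_scan <- function(x, ...) {
  cat("<sweep_scan>\n")
  for (stat in intersect(c("pi_ratio", "fst", "xpehh"), names(x))) {
    tbl <- x[[stat]]
    cat(sprintf("  %-9s %6d units; %4d in pair-1 top tail; %4d gradient\n",
                stat, nrow(tbl), sum(tbl$selected_pair1, na.rm = TRUE),
                sum(tbl$gradient_pass)))
  }
  invisible(x)
}

#' Long per-unit view of a sweep scan
#'
#' @param x a `sweep_scan`.
#' @param ... unused.
#' @return tibble: `statistic`, unit coordinates, per-pair signals,
#'   selection and gradient flags.
#' @export
tidy.sweep_scan <- function(x, ...) {
  purrr::map_dfr(intersect(c("pi_ratio", "fst", "xpehh"), names(x)), function(stat) {
    tbl <- x[[stat]]
    tbl$statistic <- stat
    if (!"pos" %in% names(tbl)) tbl$pos <- NA_integer_
    cols <- intersect(c("statistic", "chrom", "start", "end", "window", "site",
                        "pos", "signal_1", "signal_2", "signal_3",
                        "selected_pair1", "gradient_pass"), names(tbl))
    tbl[, cols]
  })
}

#' One-row scan summary per statistic
#'
#' @param x a `sweep_scan`.
#' @param ... unused.
#' @return tibble: `statistic`, `n_units`, `n_selected`, `n_gradient`.
#' @export
glance.sweep_scan <- function(x, ...) {
  purrr::map_dfr(intersect(c("pi_ratio", "fst", "xpehh"), names(x)), function(stat) {
    tbl <- x[[stat]]
    tibble::tibble(statistic = stat, n_units = nrow(tbl),
                   n_selected = sum(tbl$selected_pair1, na.rm = TRUE),
                   n_gradient = sum(tbl$gradient_pass))
  })
}

#' Candidate genes from a gradient scan
#'
#' Annotates the gradient-passing windows (diversity ratio and FST) and
#' SNPs (XP-EHH) with overlapping genes and reports the per-statistic gene
#' sets, their union, and the Venn region counts of the three sets.
#'
#' @param scan a [sweep_scan()] result.
#' @param genes gene tibble from [read_genes()].
#' @param flank_bp flank used for SNP-to-gene assignment (default 10 kb).
#' @return list: `per_stat` (named list of gene-symbol vectors), `union`,
#'   `venn` (tibble of the 7 disjoint region counts).
#' @export
candidate_genes <- function(scan, genes, flank_bp = 10000) {
  sets <- list()
  for (stat in c("pi_ratio", "fst")) {
    if (!is.null(scan[[stat]])) {
      w <- scan[[stat]][scan[[stat]]$gradient_pass, c("chrom", "start", "end")]
      sets[[stat]] <- annotate_windows(w, genes)
    }
  }
  if (!is.null(scan$xpehh)) {
    snp <- scan$xpehh[scan$xpehh$gradient_pass, ]
    sets$xpehh <- annotate_snps(
      tibble::tibble(chrom = scan$windows$chrom[1], pos = snp$pos),
      genes, flank_bp = flank_bp)
  }
  all3 <- lapply(c("pi_ratio", "fst", "xpehh"), function(s) {
    if (is.null(sets[[s]])) character(0) else sets[[s]]
  })
  list(per_stat = sets,
       union = sort(unique(unlist(sets, use.names = FALSE))),
       venn = venn3_counts(all3[[1]], all3[[2]], all3[[3]],
                           names = c("pi_ratio", "fst", "xpehh")))
}

#' Export scan tables as TSV and selected windows as BED
#'
#' Writes one TSV per computed statistic (all per-unit columns) and, for the
#' windowed statistics, BED5 files of the pair-1 top-tail windows and of the
#' gradient-passing windows (score = pair-1 signal scaled to 0-1000).
#'
#' @param scan a [sweep_scan()] result.
#' @param dir output directory (created if needed).
#' @return named character vector of the files written, invisibly.
#' @export
export_scan <- function(scan, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  for (stat in intersect(c("pi_ratio", "fst", "xpehh"), names(scan))) {
    tbl <- scan[[stat]]
    tsv <- file.path(dir, paste0(stat, ".tsv"))
    readr::write_tsv(tbl, tsv)
    written[paste0(stat, "_tsv")] <- tsv
    if (all(c("start", "end") %in% names(tbl))) {
      score <- tbl$signal_1
      rng <- range(score[is.finite(score)], na.rm = TRUE)
      span <- max(rng[2] - rng[1], .Machine$double.eps)
      bedify <- function(rows, suffix) {
        bed <- tibble::tibble(
          chrom = tbl$chrom[rows], start = tbl$start[rows],
          end = tbl$end[rows],
          name = paste0(stat, "_w", tbl$window[rows]),
          score = as.integer(round(1000 * pmin(pmax(
            (score[rows] - rng[1]) / span, 0), 1)))
        )
        path <- file.path(dir, paste0(stat, "_", suffix, ".bed"))
        readr::write_tsv(bed, path, col_names = FALSE)
        written[paste0(stat, "_", suffix, "_bed")] <<- path
      }
      bedify(which(tbl$selected_pair1), "selected")
      bedify(which(tbl$gradient_pass), "gradient")
    }
  }
  invisible(written)
}
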