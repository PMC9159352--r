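#' Site-EHH decay profile from a core SNP
#'
#' At each flanking marker t, haplotypes are partitioned into identity
#' classes over the inclusive span core..t and the site homozygosity is
#' `h(t) = sum_k n_k (n_k - 1) / (n (n - 1))`. EHHS(t) = h(t) / h(core),
#' where h(core) is computed from the two core-allele classes, so the
#' profile starts at 1 and can only decrease as classes refine. The scan
#' stops at the first marker with EHHS below `cutoff` (kept in the profile)
#' or at the panel edge, which sets the truncation flag for that side.
#'
#' @param panel a [hap_panel()] (phased, complete).
#' @param core site index of the core SNP (must be polymorphic in the
#'   subset).
#' @param samples samples to use (default all).
#' @param cutoff decay cutoff ending the scan (default 0.05).
#' @return object of class `ehh_profile`: tibble with `site`, `pos`,
#'   `distance` (signed bp from the core), `ehhs`, plus attributes
#'   `core`, `truncated_left`, `truncated_right`.
#' @export
ehhs_profile <- function(panel, core, samples = NULL, cutoff = 0.05) {
  rows <- if (is.null(samples)) seq_len(nrow(panel$haplotypes)) else hap_rows(panel, samples)
  h <- panel$haplotypes[rows, , drop = FALSE]
  if (anyNA(h)) stop("EHH requires a complete (no-missing) panel")
  n <- nrow(h)
  core_col <- h[, core]
  n1 <- sum(core_col)
  if (n1 == 0L || n1 == n) stop("monomorphic core site: EHHS undefined")
  h_core <- (n1 * (n1 - 1) + (n - n1) * (n - n1 - 1)) / (n * (n - 1))
  if (h_core == 0) stop("core homozygosity is zero: EHHS undefined")

  scan_side <- function(step) {
    L <- ncol(h)
    ids <- core_col + 1L
    out_site <- integer(0)
    out_ehhs <- numeric(0)
    truncated <- TRUE
    t <- core + step
    while (t >= 1L && t <= L) {
      key <- ids * 2L + h[, t]
      ids <- match(key, unique(key))
      nk <- tabulate(ids)
      ehhs <- sum(nk * (nk - 1)) / (n * (n - 1)) / h_core
      out_site <- c(out_site, t)
      out_ehhs <- c(out_ehhs, ehhs)
      if (ehhs < cutoff) {
        truncated <- FALSE
        break
      }
      t <- t + step
    }
    list(site = out_site, ehhs = out_ehhs, truncated = truncated)
  }
  left <- scan_side(-1L)
  right <- scan_side(1L)
  prof <- tibble::tibble(
    site = c(rev(left$site), core, right$site),
    ehhs = c(rev(left$ehhs), 1, right$ehhs)
  )
  prof$pos <- panel$positions[prof$site]
  prof$distance <- prof$pos - panel$positions[core]
  prof <- prof[, c("site", "pos", "distance", "ehhs")]
  structure(prof, core = core, core_pos = panel$positions[core],
            truncated_left = left$truncated, truncated_right = right$truncated,
            class = c("ehh_profile", class(prof)))
}

#' Integrated EHHS (iES) of a decay profile
#'
#' Trapezoid integral of EHHS against physical position, summed over the two
#' sides of the core. Each side ends at the first marker with EHHS below the
#' decay cutoff (that marker contributes the final trapezoid endpoint at its
#' actual EHHS value) or at the panel edge. A core with no flanking marker
#' integrates to 0.
#'
#' @param profile an `ehh_profile` from [ehhs_profile()].
#' @return integral in bp.
#' @export
ies <- function(profile) {
  pos <- profile$pos
  e <- profile$ehhs
  if (length(pos) < 2L) return(0)
  sum((e[-1] + e[-length(e)]) / 2 * diff(pos))
}

# iES at many cores for one haplotype subset; returns a tibble.
# Shares the incremental identity-class partition with ehhs_profile but
# avoids per-core object construction.
ies_scan <- function(panel, samples = NULL, cores, cutoff = 0.05,
                     max_extent = 300000) {
  rows <- if (is.null(samples)) seq_len(nrow(panel$haplotypes)) else hap_rows(panel, samples)
  h <- panel$haplotypes[rows, , drop = FALSE]
  if (anyNA(h)) stop("EHH requires a complete (no-missing) panel")
  n <- nrow(h)
  L <- ncol(h)
  pos <- panel$positions
  denom <- n * (n - 1)
  n_c <- length(cores)
  ies_out <- numeric(n_c)
  tl <- logical(n_c)
  tr <- logical(n_c)
  for (ci in seq_len(n_c)) {
    core <- cores[ci]
    core_col <- h[, core]
    n1 <- sum(core_col)
    # a core fixed within this group still has a defined allele-pooled
    # homozygosity (h_core = 1); only the pooled MAF filter gates cores
    h_core <- (n1 * (n1 - 1) + (n - n1) * (n - n1 - 1)) / denom
    total <- 0
    for (step in c(-1L, 1L)) {
      ids <- core_col + 1L
      nid <- 2L
      prev_e <- 1
      prev_pos <- pos[core]
      truncated <- TRUE
      t <- core + step
      while (t >= 1L && t <= L &&
             abs(pos[t] - pos[core]) <= max_extent) {
        # refine identity classes with the next marker: relabel through a
        # tabulate/cumsum pass (cheaper than match/unique at every marker)
        key <- ids * 2L - 1L + h[, t]
        cnt <- tabulate(key, 2L * nid)
        e <- sum(cnt * (cnt - 1L)) / denom / h_core
        total <- total + (prev_e + e) / 2 * abs(pos[t] - prev_pos)
        prev_e <- e
        prev_pos <- pos[t]
        if (e < cutoff) {
          truncated <- FALSE
          break
        }
        relabel <- cumsum(cnt > 0L)
        ids <- relabel[key]
        nid <- relabel[2L * nid]
        t <- t + step
      }
      if (step == -1L) tl[ci] <- truncated else tr[ci] <- truncated
    }
    ies_out[ci] <- total
  }
  tibble::tibble(site = cores, pos = pos[cores], ies = ies_out,
                 truncated_left = tl, truncated_right = tr)
}

#' Cross-population XP-EHH scan (unstandardized)
#'
#' For each core SNP, computes the integrated site-EHH (iES) separately in
#' the focal and reference groups and reports
#' `xpehh = ln(iES_focal / iES_ref)`. Positive values indicate longer shared
#' haplotypes (an ongoing or recent sweep) in the focal group. Values are
#' left unstandardized; candidate SNPs are taken from the two-way top tails
#' downstream.
#'
#' @param panel a [hap_panel()] (phased, complete).
#' @param focal,ref sample ids or indices of the two groups (each
#'   contributing at least 2 haplotypes).
#' @param cutoff EHHS decay cutoff (default 0.05).
#' @param maf_min minimum pooled minor-allele frequency for a core SNP
#'   (default 0.05, strict `>`); cores failing it are skipped.
#' @param max_extent maximum scan extent per side in bp (default 300 kb);
#   a profile still above the cutoff there is treated as truncated.
#' @param drop_truncated drop cores whose EHHS never decays below the cutoff
#'   before the panel edge in some group (default keeps them, flagged).
#' @return tibble: `site`, `pos`, `ies_focal`, `ies_ref`, `xpehh`,
#'   truncation flags per group, `valid`.
#' @export
xpehh_scan <- function(panel, focal, ref, cutoff = 0.05, maf_min = 0.05,
                       max_extent = 300000, drop_truncated = FALSE) {
  rows_f <- hap_rows(panel, focal)
  rows_r <- hap_rows(panel, ref)
  if (length(rows_f) < 2L || length(rows_r) < 2L) {
    stop("both groups need at least 2 haplotypes")
  }
  pooled <- panel$haplotypes[c(rows_f, rows_r), , drop = FALSE]
  f <- colMeans(pooled)
  maf <- pmin(f, 1 - f)
  cores <- which(maf > maf_min)
  if (!length(cores)) {
    warning("no core SNP passes the MAF filter")
    return(tibble::tibble(site = integer(), pos = integer(),
                          ies_focal = numeric(), ies_ref = numeric(),
                          xpehh = numeric(), truncated_focal = logical(),
                          truncated_ref = logical(), valid = logical()))
  }
  tf <- ies_scan(panel, focal, cores, cutoff, max_extent)
  tr <- ies_scan(panel, ref, cores, cutoff, max_extent)
  out <- tibble::tibble(
    site = tf$site, pos = tf$pos,
    ies_focal = tf$ies, ies_ref = tr$ies,
    truncated_focal = tf$truncated_left | tf$truncated_right,
    truncated_ref = tr$truncated_left | tr$truncated_right
  )
  out$valid <- !is.na(out$ies_focal) & !is.na(out$ies_ref) &
    out$ies_focal > 0 & out$ies_ref > 0
  out$xpehh <- ifelse(out$valid, log(out$ies_focal / out$ies_ref), NA_real_)
  if (drop_truncated) {
    out$valid <- out$valid & !(out$truncated_focal | out$truncated_ref)
  }
  out
}
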