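#' Mask low-quality calls
#'
#' Sets individual genotype calls with quality score at or below
#' `threshold` to missing; only calls with score strictly greater than
#' the threshold are retained. Panels without quality scores are
#' returned unchanged with a warning.
#'
#' @param panel a [genotype_panel()].
#' @param threshold quality score cutoff in \[0, 1\]; default 0.70.
#' @return The panel with sub-threshold calls set to `NA`.
#' @export
apply_gc_filter <- function(panel, threshold = 0.70) {
  if (threshold < 0 || threshold > 1) stop("threshold must be in [0, 1]")
  if (is.null(panel$call_quality)) {
    warning("panel has no call_quality scores; returning unchanged")
    return(panel)
  }
  low <- !is.na(panel$call_quality) & panel$call_quality <= threshold
  panel$dosage[low] <- NA
  panel
}

#' Remove markers sharing map coordinates
#'
#' Every marker at a duplicated (chromosome, position) coordinate is
#' removed — all members of the clash, not one survivor per
#' coordinate, since co-mapped assay pairs are both suspect.
#'
#' @param panel a [genotype_panel()].
#' @return Panel without co-located markers.
#' @export
remove_duplicate_positions <- function(panel) {
  key <- paste(panel$chrom, panel$pos_bp, sep = ":")
  dup <- key %in% key[duplicated(key)]
  if (!any(dup)) return(panel)
  subset_markers(panel, !dup)
}

# per-marker summaries on the dosage matrix
marker_call_rate <- function(panel) colMeans(!is.na(panel$dosage))

marker_maf <- function(panel) {
  p <- colMeans(panel$dosage, na.rm = TRUE) / 2
  pmin(p, 1 - p)
}

#' Hardy-Weinberg chi-square p-values per marker
#'
#' One-degree-of-freedom goodness-of-fit chi-square on the observed
#' genotype counts against expectations from the allele frequency, no
#' continuity correction. Monomorphic markers get p = 1 (a perfect
#' fit with zero degrees of information).
#'
#' @param panel a [genotype_panel()].
#' @return Numeric vector of p-values.
#' @export
hwe_pvalues <- function(panel) {
  d <- panel$dosage
  n0 <- colSums(d == 0, na.rm = TRUE)
  n1 <- colSums(d == 1, na.rm = TRUE)
  n2 <- colSums(d == 2, na.rm = TRUE)
  n <- n0 + n1 + n2
  p <- (n1 + 2 * n2) / (2 * pmax(n, 1))
  q <- 1 - p
  e0 <- n * q^2; e1 <- 2 * n * p * q; e2 <- n * p^2
  chi <- rep(0, length(n))
  ok <- p > 0 & q > 0 & n > 0
  chi[ok] <- (n0[ok] - e0[ok])^2 / e0[ok] +
    (n1[ok] - e1[ok])^2 / e1[ok] +
    (n2[ok] - e2[ok])^2 / e2[ok]
  ifelse(ok, pchisq(chi, df = 1, lower.tail = FALSE), 1)
}

#' Marker-level filters: call rate, MAF and HWE
#'
#' Retains markers with call rate strictly above `cr_min`, minor
#' allele frequency strictly above `maf_min` and HWE chi-square
#' p-value strictly above `hwe_p_min` (frequencies computed from
#' non-missing calls).
#'
#' @param panel a [genotype_panel()].
#' @param cr_min minimum call rate (exclusive); default 0.98.
#' @param maf_min minimum MAF (exclusive); default 0.02.
#' @param hwe_p_min minimum HWE p-value (exclusive); default 1e-5.
#' @return list with `panel` (filtered) and `removed`, a named vector
#'   of removal counts for `call_rate`, `maf`, `hwe` (a marker failing
#'   several rules is attributed to the first that catches it, in that
#'   order).
#' @export
marker_filters <- function(panel, cr_min = 0.98, maf_min = 0.02,
                           hwe_p_min = 1e-5) {
  if (nrow(panel$dosage) < 1) stop("panel has no samples")
  if (ncol(panel$dosage) < 1) stop("panel has no markers")
  cr <- marker_call_rate(panel)
  maf <- marker_maf(panel)
  maf[is.nan(maf)] <- 0  # zero calls
  hwe <- hwe_pvalues(panel)
  fail_cr <- cr <= cr_min
  fail_maf <- !fail_cr & maf <= maf_min
  fail_hwe <- !fail_cr & !fail_maf & hwe <= hwe_p_min
  keep <- !(fail_cr | fail_maf | fail_hwe)
  list(panel = subset_markers(panel, keep),
       removed = c(call_rate = sum(fail_cr), maf = sum(fail_maf),
                   hwe = sum(fail_hwe)))
}

#' Prune near-duplicate markers by local LD
#'
#' Scans each chromosome left to right. For every syntenic marker pair
#' within a window of `window` neighbouring markers whose
#' genotype-dosage r-squared exceeds `r2_max`, the later marker (by
#' position, ties broken towards the lexicographically larger id) is
#' dropped. A marker already dropped cannot trigger further removals.
#' r-squared is computed on mean-imputed dosages, matching the
#' centering convention used for the genomic relationship matrix.
#'
#' @param panel a [genotype_panel()].
#' @param window number of neighbouring markers scanned; default 100.
#' @param r2_max exclusive r-squared threshold; default 0.995.
#' @return The pruned panel.
#' @export
ld_prune <- function(panel, window = 100, r2_max = 0.995) {
  m <- ncol(panel$dosage)
  if (m < 2) return(panel)
  # mean-impute and center once
  X <- panel$dosage
  mu <- colMeans(X, na.rm = TRUE)
  for (j in seq_len(m)) {
    nas <- is.na(X[, j])
    if (any(nas)) X[nas, j] <- mu[j]
  }
  X <- scale(X, center = TRUE, scale = FALSE)
  sds <- sqrt(colMeans(X^2))
  keep <- rep(TRUE, m)
  for (chr in unique(panel$chrom)) {
    idx <- which(panel$chrom == chr)
    # ensure deterministic later-marker rule: position then id
    ord <- order(panel$pos_bp[idx],
                 panel$marker_ids[idx], method = "radix")
    idx <- idx[ord]
    for (a in seq_along(idx)) {
      ja <- idx[a]
      if (!keep[ja] || sds[ja] == 0) next
      upper <- min(a + window, length(idx))
      if (upper <= a) next
      for (b in seq((a + 1), upper)) {
        jb <- idx[b]
        if (!keep[jb] || sds[jb] == 0) next
        r <- mean(X[, ja] * X[, jb]) / (sds[ja] * sds[jb])
        if (r * r > r2_max) keep[jb] <- FALSE
      }
    }
  }
  subset_markers(panel, keep)
}

#' Remove low call-rate samples
#'
#' Samples whose non-missing fraction is strictly below
#' `sample_cr_min` are excluded; a sample exactly at the threshold is
#' retained.
#'
#' @param panel a [genotype_panel()].
#' @param sample_cr_min minimum sample call rate; default 0.90.
#' @return The filtered panel.
#' @export
sample_filter <- function(panel, sample_cr_min = 0.90) {
  if (ncol(panel$dosage) < 1) stop("panel has no markers")
  cr <- rowMeans(!is.na(panel$dosage))
  keep <- cr >= sample_cr_min
  if (!any(keep)) stop("sample filter would remove every sample")
  subset_samples(panel, keep)
}

#' Iterative genotype quality control
#'
#' Runs the full QC sequence: quality-score masking and
#' duplicate-coordinate removal once, then marker filters (call rate,
#' MAF, HWE), LD pruning and the sample call-rate filter repeatedly
#' until a pass removes nothing. Iteration matters because removing a
#' poorly called sample can lift a marker back above the MAF or
#' call-rate threshold — each round re-evaluates every rule on the
#' current panel.
#'
#' @param panel a [genotype_panel()].
#' @param gc_min call-quality threshold (strictly-greater rule).
#' @param cr_min,maf_min,hwe_p_min marker thresholds, see
#'   [marker_filters()].
#' @param ld_window,ld_r2_max LD pruning parameters, see [ld_prune()].
#' @param sample_cr_min sample call-rate threshold.
#' @return list with `panel` (the QC'd panel) and `report`, a
#'   `qc_report` recording rounds and per-rule removal counts.
#' @export
iterate_qc <- function(panel, gc_min = 0.70, cr_min = 0.98, maf_min = 0.02,
                       hwe_p_min = 1e-5, ld_window = 100, ld_r2_max = 0.995,
                       sample_cr_min = 0.90) {
  n0 <- nrow(panel$dosage); m0 <- ncol(panel$dosage)
  removed <- c(gc = 0, duplicate_position = 0, call_rate = 0, maf = 0,
               hwe = 0, ld_prune = 0, sample_call_rate = 0)
  if (!is.null(panel$call_quality)) panel <- apply_gc_filter(panel, gc_min)
  m <- ncol(panel$dosage)
  panel <- remove_duplicate_positions(panel)
  removed["duplicate_position"] <- m - ncol(panel$dosage)
  rounds <- 0L
  repeat {
    rounds <- rounds + 1L
    n_before <- nrow(panel$dosage); m_before <- ncol(panel$dosage)
    mf <- marker_filters(panel, cr_min, maf_min, hwe_p_min)
    panel <- mf$panel
    removed[names(mf$removed)] <- removed[names(mf$removed)] + mf$removed
    m_mid <- ncol(panel$dosage)
    panel <- ld_prune(panel, ld_window, ld_r2_max)
    removed["ld_prune"] <- removed["ld_prune"] + (m_mid - ncol(panel$dosage))
    if (ncol(panel$dosage) == 0)
      stop("QC removed every marker")
    n_mid <- nrow(panel$dosage)
    panel <- sample_filter(panel, sample_cr_min)
    removed["sample_call_rate"] <-
      removed["sample_call_rate"] + (n_mid - nrow(panel$dosage))
    if (nrow(panel$dosage) == n_before && ncol(panel$dosage) == m_before)
      break
  }
  report <- structure(
    list(rounds = rounds, removed_by_rule = removed,
         input_samples = n0, input_markers = m0,
         retained_samples = nrow(panel$dosage),
         retained_markers = ncol(panel$dosage)),
    class = "qc_report")
  list(panel = panel, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("QC report: %d round(s)\n", x$rounds))
  cat(sprintf("  samples: %d -> %d | markers: %d -> %d\n",
              x$input_samples, x$retained_samples,
              x$input_markers, x$retained_markers))
  for (nm in names(x$removed_by_rule))
    cat(sprintf("  removed by %-18s %d\n", nm, x$removed_by_rule[[nm]]))
  invisible(x)
}
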