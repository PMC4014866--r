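#' Construct a genotype panel
#'
#' The central container of the package: a samples-by-markers dosage
#' matrix with map positions and (optionally) per-call quality scores.
#' Dosages count copies of the "counted" allele (allele 2), coded 0, 1
#' or 2; missing calls are `NA`. The counted allele is fixed per marker
#' when the panel is built and shared by every downstream train/test
#' split, so marker-effect signs stay consistent.
#'
#' @param dosage integer matrix, samples in rows, markers in columns;
#'   entries in \{0, 1, 2, NA\}.
#' @param sample_ids character vector of unique sample labels.
#' @param marker_ids character vector of unique marker labels.
#' @param chrom chromosome label per marker.
#' @param pos_bp 1-based physical position per marker.
#' @param call_quality optional matrix of per-call quality scores in
#'   \[0, 1\] (a GenCall-style score), same shape as `dosage`.
#' @return An object of class `genotype_panel`.
#' @export
genotype_panel <- function(dosage, sample_ids, marker_ids, chrom, pos_bp,
                           call_quality = NULL) {
  dosage <- as.matrix(dosage)
  if (nrow(dosage) != length(sample_ids))
    stop("dosage rows must match sample_ids")
  if (ncol(dosage) != length(marker_ids))
    stop("dosage columns must match marker_ids")
  if (anyDuplicated(sample_ids)) stop("duplicate sample ids")
  if (anyDuplicated(marker_ids)) stop("duplicate marker ids")
  if (length(chrom) != length(marker_ids) || length(pos_bp) != length(marker_ids))
    stop("chrom/pos_bp must have one entry per marker")
  bad <- !(dosage %in% c(0L, 1L, 2L, NA))
  if (any(bad)) stop("dosage codes must be 0, 1, 2 or NA")
  if (!is.null(call_quality)) {
    call_quality <- as.matrix(call_quality)
    if (!all(dim(call_quality) == dim(dosage)))
      stop("call_quality must match dosage dimensions")
    if (any(call_quality < 0 | call_quality > 1, na.rm = TRUE))
      stop("call_quality must lie in [0, 1]")
  }
  dimnames(dosage) <- list(sample_ids, marker_ids)
  p <- structure(
    list(dosage = dosage,
         sample_ids = as.character(sample_ids),
         marker_ids = as.character(marker_ids),
         chrom = as.character(chrom),
         pos_bp = as.integer(pos_bp),
         call_quality = call_quality),
    class = "genotype_panel")
  sort_panel_markers(p)
}

# internal: keep markers sorted by (chrom, pos)
sort_panel_markers <- function(panel) {
  ord <- order(panel$chrom, panel$pos_bp)
  subset_markers(panel, ord)
}

#' Subset a panel by marker index or id
#' @param panel a `genotype_panel`.
#' @param j integer/logical index or character marker ids to keep.
#' @return A `genotype_panel` restricted to the selected markers.
#' @export
subset_markers <- function(panel, j) {
  if (is.character(j)) j <- match(j, panel$marker_ids)
  structure(
    list(dosage = panel$dosage[, j, drop = FALSE],
         sample_ids = panel$sample_ids,
         marker_ids = panel$marker_ids[j],
         chrom = panel$chrom[j],
         pos_bp = panel$pos_bp[j],
         call_quality = if (!is.null(panel$call_quality))
           panel$call_quality[, j, drop = FALSE]),
    class = "genotype_panel")
}

#' Subset a panel by sample index or id
#' @inheritParams subset_markers
#' @param i integer/logical index or character sample ids to keep.
#' @export
subset_samples <- function(panel, i) {
  if (is.character(i)) i <- match(i, panel$sample_ids)
  structure(
    list(dosage = panel$dosage[i, , drop = FALSE],
         sample_ids = panel$sample_ids[i],
         marker_ids = panel$marker_ids,
         chrom = panel$chrom,
         pos_bp = panel$pos_bp,
         call_quality = if (!is.null(panel$call_quality))
           panel$call_quality[i, , drop = FALSE]),
    class = "genotype_panel")
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat(sprintf("genotype_panel: %d samples x %d markers (%d chromosomes)\n",
              nrow(x$dosage), ncol(x$dosage), length(unique(x$chrom))))
  miss <- mean(is.na(x$dosage))
  cat(sprintf("  missing calls: %.3f%%; call_quality: %s\n",
              100 * miss, if (is.null(x$call_quality)) "absent" else "present"))
  invisible(x)
}

#' @export
dim.genotype_panel <- function(x) dim(x$dosage)
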