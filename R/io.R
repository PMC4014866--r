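#' Read genotypes from PLINK ped/map or VCF
#'
#' PLINK: space/tab-delimited .ped with the six pedigree columns and
#' two allele columns per marker; the counted allele (allele 2) is
#' fixed per marker as the lexicographically larger observed allele
#' (so "B" counts against "A"), and "0" means a missing call. VCF:
#' biallelic records only, dosage from the GT field; multi-allelic
#' records are skipped with a warning. Non-autosomal markers
#' (chromosome labels X, Y, MT and synonyms) are dropped at read
#' time.
#'
#' @param path file path (.ped — with its .map next to it — or .vcf).
#' @param format "plink" or "vcf" (guessed from the extension by
#'   default).
#' @return A [genotype_panel()].
#' @export
read_genotypes <- function(path, format = c("auto", "plink", "vcf")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.vcf(\\.gz)?$", path)) "vcf" else "plink"
  if (!file.exists(path)) stop("file not found: ", path)
  if (file.size(path) == 0) stop("empty file: ", path)
  if (format == "plink") read_plink(path) else read_vcf_panel(path)
}

non_autosomal <- c("X", "Y", "MT", "M", "XY", "chrX", "chrY", "chrM")

read_plink <- function(ped_path) {
  map_path <- sub("\\.ped$", ".map", ped_path)
  if (!file.exists(map_path)) stop("missing .map beside ", ped_path)
  map <- data.table::fread(map_path, header = FALSE,
                           colClasses = "character")
  if (ncol(map) < 4) stop("map file needs 4 columns")
  data.table::setnames(map, 1:4, c("chrom", "id", "cm", "pos"))
  ped <- data.table::fread(ped_path, header = FALSE,
                           colClasses = "character")
  m <- nrow(map)
  if (ncol(ped) != 6 + 2 * m)
    stop("ped/map mismatch: expected ", 6 + 2 * m, " columns, found ",
         ncol(ped), " (line widths in ", ped_path, ")")
  ids <- ped[[2]]
  al1 <- as.matrix(ped[, seq(7, 6 + 2 * m, by = 2), with = FALSE])
  al2 <- as.matrix(ped[, seq(8, 6 + 2 * m, by = 2), with = FALSE])
  dosage <- matrix(NA_integer_, nrow(ped), m)
  for (j in seq_len(m)) {
    a <- al1[, j]; b <- al2[, j]
    miss <- a == "0" | b == "0"
    obs <- sort(unique(c(a[!miss], b[!miss])))
    if (length(obs) > 2)
      stop("marker ", map$id[j], " has >2 alleles in ", ped_path)
    # A/B-coded files keep "B" as the counted allele even when a
    # marker is monomorphic, so write/read round-trips exactly
    counted <- if (all(obs %in% c("A", "B"))) "B"
      else if (length(obs)) obs[length(obs)] else "B"
    dosage[, j] <- (a == counted) + (b == counted)
    dosage[miss, j] <- NA_integer_
  }
  keep <- !(map$chrom %in% non_autosomal)
  genotype_panel(dosage[, keep, drop = FALSE], ids, map$id[keep],
                 map$chrom[keep], as.integer(map$pos[keep]))
}

read_vcf_panel <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  alt <- fix[, "ALT"]
  multi <- grepl(",", alt) | is.na(alt)
  if (any(multi))
    warning(sum(multi), " multi-allelic record(s) skipped")
  gt <- vcfR::extract.gt(v, element = "GT")
  keep <- !multi & !(fix[, "CHROM"] %in% non_autosomal)
  gt <- gt[keep, , drop = FALSE]
  fix <- fix[keep, , drop = FALSE]
  count_alt <- function(g) {
    g <- sub("\\|", "/", g)
    ifelse(is.na(g) | g %in% c("./.", "."), NA_integer_,
           (substr(g, 1, 1) == "1") + (substr(g, 3, 3) == "1"))
  }
  dosage <- t(apply(gt, 1, count_alt))
  mids <- fix[, "ID"]
  mids[is.na(mids) | mids == "."] <-
    paste0(fix[is.na(mids) | mids == ".", "CHROM"], ":",
           fix[is.na(mids) | mids == ".", "POS"])
  genotype_panel(t(dosage) * 1L, colnames(gt), mids, fix[, "CHROM"],
                 as.integer(fix[, "POS"]))
}

#' Write a simulated dataset as pipeline-ready fixture files
#'
#' Emits PLINK .ped/.map (alleles coded A/B, missing "0"), a pedigree
#' CSV (id, sire, dam, birth_year; "0" = unknown parent), one trait
#' CSV per snapshot (id, trait, ebv, accuracy, snapshot_year) and a
#' truth CSV with TBV and subgroup labels. The files round-trip
#' through [read_genotypes()] and the CSV readers.
#'
#' @param dir output directory (created if needed).
#' @param pedigree pedigree data.frame.
#' @param panel a [genotype_panel()] (must be non-empty).
#' @param snapshots list of snapshot data.frames (e.g. from
#'   [simulate_ebv_snapshots()]).
#' @param truth optional truth list with `tbv` and
#'   `subgroup_labels`.
#' @param basename file stem; default "synthetic".
#' @return Invisibly, the named vector of file paths written.
#' @export
write_fixture <- function(dir, pedigree, panel, snapshots = list(),
                          truth = NULL, basename = "synthetic") {
  if (nrow(panel$dosage) == 0 || ncol(panel$dosage) == 0)
    stop("refusing to write an empty panel")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  stem <- file.path(dir, basename)
  paths <- c(ped = paste0(stem, ".ped"), map = paste0(stem, ".map"),
             pedigree = paste0(stem, "_pedigree.csv"),
             traits = paste0(stem, "_traits.csv"),
             truth = paste0(stem, "_truth.csv"))
  map <- data.frame(panel$chrom, panel$marker_ids, 0,
                    panel$pos_bp)
  data.table::fwrite(map, paths["map"], sep = " ", col.names = FALSE)
  n <- nrow(panel$dosage); m <- ncol(panel$dosage)
  allele <- function(d, first) {
    # dosage counts "B"; first haplotype allele then second
    out <- matrix("0", n, m)
    out[d == 0] <- "A"
    out[d == 2] <- "B"
    out[d == 1] <- if (first) "A" else "B"
    out
  }
  d <- panel$dosage
  ped_geno <- matrix("0", n, 2 * m)
  ped_geno[, seq(1, 2 * m, 2)] <- allele(d, TRUE)
  ped_geno[, seq(2, 2 * m, 2)] <- allele(d, FALSE)
  ped_df <- data.frame(fid = "FAM", iid = panel$sample_ids,
                       pat = 0, mat = 0, sex = 0, phe = -9,
                       ped_geno)
  data.table::fwrite(ped_df, paths["ped"], sep = " ",
                     col.names = FALSE)
  data.table::fwrite(
    pedigree[, c("id", "sire", "dam",
                 intersect("birth_year", names(pedigree)))],
    paths["pedigree"])
  if (length(snapshots))
    data.table::fwrite(do.call(rbind, snapshots), paths["traits"])
  else paths <- paths[names(paths) != "traits"]
  if (!is.null(truth) && !is.null(truth$tbv)) {
    data.table::fwrite(
      data.frame(id = names(truth$tbv), tbv = truth$tbv,
                 subgroup = truth$subgroup_labels[names(truth$tbv)]),
      paths["truth"])
  } else paths <- paths[names(paths) != "truth"]
  invisible(paths)
}

#' Read a pedigree CSV
#' @param path CSV with columns id, sire, dam (and optionally
#'   birth_year); "0" or empty = unknown parent.
#' @return data.frame with character id columns.
#' @export
read_pedigree <- function(path) {
  ped <- data.table::fread(path, colClasses = list(
    character = c("id", "sire", "dam")))
  as.data.frame(ped)
}

#' Read a trait snapshot CSV
#' @param path CSV with columns id, trait, ebv, accuracy,
#'   snapshot_year.
#' @return data.frame.
#' @export
read_traits <- function(path) {
  as.data.frame(data.table::fread(path,
                                  colClasses = list(character = "id")))
}
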