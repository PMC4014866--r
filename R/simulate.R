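#' Configuration for the synthetic population simulator
#'
#' Defaults emulate the bull population the pipeline is designed for:
#' a multi-generation pedigree (up to four generations) with
#' son-sire pairs and paternal half-sib families of mean size 4.7, a
#' 30 Morgan genome, founder allele frequencies with mean minor
#' allele frequency near 0.226 and adjacent-marker LD r-squared near
#' 0.29, and (optionally) two genetic subgroups.
#'
#' @param n_founders founder individuals in generation 0.
#' @param n_generations total generations including founders.
#' @param sires_per_generation sires drawn from the previous
#'   generation for each new one.
#' @param offspring_per_sire mean paternal half-sib family size.
#' @param n_markers total biallelic markers.
#' @param n_chromosomes chromosomes (markers split evenly).
#' @param genome_length_morgans total map length in Morgans.
#' @param target_maf_mean target mean minor allele frequency.
#' @param target_adjacent_r2 target mean adjacent-marker LD
#'   r-squared.
#' @param n_qtl number of QTL for [simulate_trait()].
#' @param h2 trait heritability in \[0, 1\].
#' @param subgroup_split fraction of founders in subgroup 1; 0 or 1
#'   disables subgroup structure.
#' @param subgroup_fst Balding-Nichols differentiation between the
#'   founder pools; default 0.15.
#' @param seed master seed; every random draw in the simulator flows
#'   from it.
#' @return A validated `simulation_config` list.
#' @export
simulation_config <- function(n_founders = 120, n_generations = 4,
                              sires_per_generation = 15,
                              offspring_per_sire = 4.7,
                              n_markers = 2000, n_chromosomes = 10,
                              genome_length_morgans = 30,
                              target_maf_mean = 0.226,
                              target_adjacent_r2 = 0.293,
                              n_qtl = 100, h2 = 0.3,
                              subgroup_split = 0, subgroup_fst = 0.15,
                              seed = 1) {
  stopifnot(n_founders >= 1, n_generations >= 1,
            sires_per_generation >= 1, offspring_per_sire >= 1,
            n_markers >= 2, n_chromosomes >= 1,
            genome_length_morgans > 0,
            h2 >= 0, h2 <= 1, subgroup_split >= 0, subgroup_split <= 1,
            target_adjacent_r2 >= 0, target_adjacent_r2 < 1)
  if (n_generations > 1 && n_founders < 2)
    stop("offspring requested but fewer than two founders available")
  structure(as.list(environment()), class = "simulation_config")
}

# Founder allele frequencies: latent AR(1) in normal space mapped
# through a symmetric Beta quantile so the mean minor allele frequency
# lands near the target while adjacent markers keep similar
# frequencies (which preserves the achievable adjacent correlation).
# Shape 0.70 on p = 0.02 + 0.96 * Beta(a, a) yields mean MAF ~ 0.226.
founder_freqs <- function(m_chr, shape = 0.70, phi = 0.9) {
  z <- numeric(m_chr)
  z[1] <- rnorm(1)
  if (m_chr > 1)
    for (j in 2:m_chr) z[j] <- phi * z[j - 1] + sqrt(1 - phi^2) * rnorm(1)
  0.02 + 0.96 * qbeta(pnorm(z), shape, shape)
}

# Largest correlation achievable for adjacent Bernoulli marginals
frechet_rho_max <- function(p1, p2) {
  lo <- pmin(p1, p2); hi <- pmax(p1, p2)
  (lo - lo * hi) / sqrt(lo * (1 - lo) * hi * (1 - hi))
}

# Per-chromosome haplotype sampler: first-order Markov chain over
# allele indicators with per-pair correlation rho (clamped to the
# Frechet bound). Returns an n_hap x m 0/1 matrix.
sample_haplotypes <- function(n_hap, p, rho) {
  m <- length(p)
  H <- matrix(0L, n_hap, m)
  H[, 1] <- rbinom(n_hap, 1, p[1])
  if (m > 1) for (j in 2:m) {
    r <- rho[j - 1]
    p1 <- p[j - 1]; p2 <- p[j]
    c11 <- p2 + r * sqrt(p2 * (1 - p2) * (1 - p1) / p1)
    c01 <- p2 - r * sqrt(p2 * (1 - p2) * p1 / (1 - p1))
    c11 <- min(max(c11, 0), 1); c01 <- min(max(c01, 0), 1)
    prev <- H[, j - 1]
    H[, j] <- rbinom(n_hap, 1, ifelse(prev == 1L, c11, c01))
  }
  H
}

# choose a scalar boost c so that mean(min(c*rho_t, rho_max)^2) over
# adjacent pairs equals the target r2 (compensates Frechet clamping)
calibrate_rho <- function(p, target_r2) {
  if (length(p) < 2 || target_r2 <= 0)
    return(rep(sqrt(max(target_r2, 0)), max(length(p) - 1, 0)))
  rho_t <- sqrt(target_r2)
  rmax <- frechet_rho_max(p[-length(p)], p[-1])
  f <- function(cc) mean(pmin(cc * rho_t, rmax)^2) - target_r2
  if (f(1) >= 0) return(pmin(rho_t, rmax))
  hi <- 1
  while (f(hi) < 0 && hi < 3) hi <- hi + 0.1
  cc <- tryCatch(stats::uniroot(f, c(1, hi))$root, error = function(e) hi)
  pmin(cc * rho_t, rmax)
}

# one meiosis: recombine two parental haplotype vectors (Haldane,
# uniform spacing between adjacent markers)
meiosis <- function(h1, h2, rec_prob) {
  m <- length(h1)
  if (m == 1) return(if (runif(1) < 0.5) h1 else h2)
  cross <- rbinom(m - 1, 1, rec_prob)
  phase <- cumsum(c(sample(0:1, 1), cross)) %% 2
  ifelse(phase == 0L, h1, h2)
}

#' Simulate a pedigreed, LD-structured population
#'
#' Founder haplotypes are built as a first-order Markov chain along
#' each chromosome, tuned so the mean adjacent-marker r-squared and
#' mean MAF land near their configured targets. Descendant
#' generations are produced by gene-dropping with Haldane
#' recombination over a uniformly spaced map. Each generation draws
#' `sires_per_generation` sires from the previous one; every sire
#' founds a paternal half-sib family whose dams are new unrelated
#' founder females (recorded in the pedigree with unknown parents).
#' When `subgroup_split` is strictly inside (0, 1), founders come
#' from two pools with Balding-Nichols-perturbed frequencies and
#' matings stay within pools, producing a two-cluster structure in
#' the genomic PCA.
#'
#' @param config a [simulation_config()].
#' @return list with `pedigree` (id, sire, dam, birth_year, sex,
#'   generation), `panel` (a [genotype_panel()] over all
#'   individuals), `truth` (subgroup labels; QTL fields are filled by
#'   [simulate_trait()]) and the `config`.
#' @export
simulate_population <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  m_per_chr <- diff(round(seq(0, config$n_markers,
                              length.out = config$n_chromosomes + 1)))
  m_per_chr <- m_per_chr[m_per_chr > 0]
  chr_len <- config$genome_length_morgans / length(m_per_chr)

  two_pools <- config$subgroup_split > 0 && config$subgroup_split < 1
  freqs <- lapply(m_per_chr, founder_freqs)
  rhos <- lapply(freqs, calibrate_rho,
                 target_r2 = config$target_adjacent_r2)
  pool_freqs <- lapply(seq_along(freqs), function(cc) {
    p <- freqs[[cc]]
    if (!two_pools) return(list(p, p))
    F <- config$subgroup_fst
    lapply(1:2, function(k)
      pmin(pmax(rbeta(length(p), p * (1 - F) / F,
                      (1 - p) * (1 - F) / F), 0.01), 0.99))
  })
  rec_probs <- lapply(m_per_chr, function(mm) {
    d <- chr_len / max(mm - 1, 1)
    rep(0.5 * (1 - exp(-2 * d)), max(mm - 1, 1))
  })
  n_chr <- length(m_per_chr)

  # growing per-individual stores (lists: O(1) append)
  H1 <- list(); H2 <- list()   # H1[[i]]: list of per-chrom vectors
  rec <- list()                # pedigree rows

  # batch founder generation: one Markov-chain sweep per chromosome
  batch_founders <- function(n_ind, pool)
    lapply(seq_len(n_chr), function(cc)
      list(h1 = sample_haplotypes(n_ind, pool_freqs[[cc]][[pool]],
                                  rhos[[cc]]),
           h2 = sample_haplotypes(n_ind, pool_freqs[[cc]][[pool]],
                                  rhos[[cc]])))

  add_ind <- function(h1, h2, sire, dam, g, sex, pool) {
    i <- length(H1) + 1L
    H1[[i]] <<- h1; H2[[i]] <<- h2
    rec[[i]] <<- list(id = sprintf("ID%05d", i), sire = sire, dam = dam,
                      generation = g, sex = sex, pool = pool)
    i
  }
  add_founder_batch <- function(n_ind, pool, g, sex) {
    if (n_ind == 0) return(integer(0))
    B <- batch_founders(n_ind, pool)
    vapply(seq_len(n_ind), function(r)
      add_ind(lapply(B, function(b) b$h1[r, ]),
              lapply(B, function(b) b$h2[r, ]),
              "0", "0", g, sex, pool), integer(1))
  }

  n1 <- if (two_pools)
    min(max(round(config$subgroup_split * config$n_founders), 1),
        config$n_founders - 1) else config$n_founders
  add_founder_batch(n1, 1L, 0L, "M")
  add_founder_batch(config$n_founders - n1, 2L, 0L, "M")

  if (config$n_generations > 1) {
    prev <- seq_len(config$n_founders)
    for (g in seq_len(config$n_generations - 1)) {
      cur <- integer(0)
      pool_ids <- vapply(rec[prev], `[[`, integer(1), "pool")
      sex_prev <- vapply(rec[prev], `[[`, character(1), "sex")
      for (pool in sort(unique(pool_ids))) {
        cand <- prev[pool_ids == pool & sex_prev == "M"]
        if (!length(cand)) cand <- prev[pool_ids == pool]
        sires_g <- sample(cand, min(config$sires_per_generation,
                                    length(cand)))
        fams <- pmax(1L, rpois(length(sires_g),
                               config$offspring_per_sire - 1) + 1L)
        dam_rows <- add_founder_batch(sum(fams), pool, g, "F")
        di <- 0L
        for (si in seq_along(sires_g)) {
          s <- sires_g[si]
          for (k in seq_len(fams[si])) {
            di <- di + 1L
            d_row <- dam_rows[di]
            gs <- lapply(seq_len(n_chr), function(cc)
              meiosis(H1[[s]][[cc]], H2[[s]][[cc]], rec_probs[[cc]]))
            gd <- lapply(seq_len(n_chr), function(cc)
              meiosis(H1[[d_row]][[cc]], H2[[d_row]][[cc]],
                      rec_probs[[cc]]))
            o <- add_ind(gs, gd, rec[[s]]$id, rec[[d_row]]$id, g,
                         sample(c("M", "F"), 1, prob = c(0.8, 0.2)),
                         pool)
            cur <- c(cur, o)
          }
        }
      }
      prev <- cur
    }
  }

  n_ind <- length(H1)
  dosage <- matrix(0L, n_ind, sum(m_per_chr))
  for (i in seq_len(n_ind))
    dosage[i, ] <- unlist(H1[[i]], use.names = FALSE) +
      unlist(H2[[i]], use.names = FALSE)
  ids <- vapply(rec, `[[`, character(1), "id")
  ped <- data.frame(
    id = ids,
    sire = vapply(rec, `[[`, character(1), "sire"),
    dam = vapply(rec, `[[`, character(1), "dam"),
    birth_year = 1998L + 3L * vapply(rec, `[[`, integer(1),
                                     "generation"),
    sex = vapply(rec, `[[`, character(1), "sex"),
    generation = vapply(rec, `[[`, integer(1), "generation"),
    stringsAsFactors = FALSE)
  marker_ids <- sprintf("M%05d", seq_len(sum(m_per_chr)))
  chrom <- rep(sprintf("%d", seq_len(n_chr)), m_per_chr)
  pos_bp <- unlist(lapply(m_per_chr, function(mm)
    seq(10000L, by = 10000L, length.out = mm)))
  panel <- genotype_panel(dosage, ids, marker_ids, chrom, pos_bp)
  truth <- list(subgroup_labels = stats::setNames(
    vapply(rec, `[[`, integer(1), "pool"), ids),
    qtl_indices = integer(0), qtl_effects = numeric(0), tbv = NULL)
  list(pedigree = ped, panel = panel, truth = truth, config = config)
}

#' Attach a trait architecture and true breeding values
#'
#' Samples `n_qtl` QTL without replacement among polymorphic markers,
#' draws their allele-substitution effects from a standard normal and
#' scales them so the variance of the true breeding values equals
#' `genetic_var`. TBV are the centered QTL dosages times the effects.
#'
#' @param panel a [genotype_panel()].
#' @param n_qtl number of QTL (0 gives identically zero TBV).
#' @param genetic_var target variance of the TBV.
#' @param effect_sd optional per-QTL raw effect scale before the
#'   variance rescaling (sets relative QTL sizes); length `n_qtl`.
#' @param seed integer seed.
#' @return list (a `simulation_truth`) with qtl_indices, qtl_effects,
#'   tbv (named by sample id).
#' @export
simulate_trait <- function(panel, n_qtl, genetic_var = 1,
                           effect_sd = NULL, seed = 1) {
  set.seed(seed)
  n <- nrow(panel$dosage)
  if (n_qtl == 0)
    return(list(qtl_indices = integer(0), qtl_effects = numeric(0),
                tbv = stats::setNames(rep(0, n), panel$sample_ids)))
  p <- allele_frequencies(panel)
  poly <- which(p > 0 & p < 1)
  if (n_qtl > length(poly))
    stop("n_qtl exceeds the number of polymorphic markers (",
         length(poly), ")")
  qtl <- sort(sample(poly, n_qtl))
  eff <- rnorm(n_qtl)
  if (!is.null(effect_sd)) {
    stopifnot(length(effect_sd) == n_qtl)
    eff <- eff * effect_sd
  }
  W <- centered_dosages(subset_markers(panel, qtl))
  tbv <- as.numeric(W %*% eff)
  v <- var(tbv)
  if (v > 0 && genetic_var > 0) {
    sc <- sqrt(genetic_var / v)
    eff <- eff * sc
    tbv <- tbv * sc
  }
  list(qtl_indices = qtl, qtl_effects = eff,
       tbv = stats::setNames(tbv, panel$sample_ids))
}

#' Simulate two EBV evaluation snapshots at target accuracies
#'
#' For each animal, EBV = r * standardized TBV + sqrt(1 - r^2) *
#' noise, rescaled so that the expected correlation between EBV and
#' TBV among animals sharing a target accuracy r equals r and the EBV
#' variance equals r^2 times the TBV variance — the shrinkage
#' property of a BLUP evaluation, which makes the regression of TBV
#' on EBV (and of deregressed proofs on TBV) have slope one. The two
#' snapshots emulate an early evaluation (training) and a later one
#' (validation) in which previously young animals have gained
#' accuracy.
#'
#' @param tbv named true breeding values.
#' @param accuracy_early,accuracy_late per-animal target accuracies
#'   in \[0, 1\] (recycled if scalar).
#' @param years the two snapshot years; default c(2007, 2011).
#' @param trait trait label; default "T1".
#' @param seed integer seed.
#' @return list of two data.frames (early, late) with columns id,
#'   trait, ebv, accuracy, snapshot_year.
#' @export
simulate_ebv_snapshots <- function(tbv, accuracy_early, accuracy_late,
                                   years = c(2007L, 2011L),
                                   trait = "T1", seed = 1) {
  n <- length(tbv)
  accuracy_early <- rep_len(accuracy_early, n)
  accuracy_late <- rep_len(accuracy_late, n)
  if (any(c(accuracy_early, accuracy_late) < 0) ||
      any(c(accuracy_early, accuracy_late) > 1))
    stop("target accuracies must lie in [0, 1]")
  set.seed(seed)
  mu <- mean(tbv); s <- sd(tbv)
  if (is.na(s) || s == 0) s <- 1
  z <- (tbv - mu) / s
  mk <- function(acc, yr) {
    noise <- rnorm(n)
    # BLUP shrinkage: sd(EBV) = r * sd(TBV), cor(EBV, TBV) = r
    ebv <- mu + acc * s * (acc * z + sqrt(1 - acc^2) * noise)
    data.frame(id = names(tbv), trait = trait, ebv = ebv,
               accuracy = acc, snapshot_year = yr,
               stringsAsFactors = FALSE)
  }
  list(early = mk(accuracy_early, years[1]),
       late = mk(accuracy_late, years[2]))
}

#' Mean adjacent-marker LD
#'
#' Mean squared correlation between genotype dosages of adjacent
#' markers within each chromosome (monomorphic pairs skipped); the
#' summary the simulator is calibrated against.
#'
#' @param panel a [genotype_panel()].
#' @return Mean adjacent r-squared.
#' @export
adjacent_r2 <- function(panel) {
  X <- impute_missing(panel, "mean")
  vals <- numeric(0)
  for (chr in unique(panel$chrom)) {
    j <- which(panel$chrom == chr)
    if (length(j) < 2) next
    a <- X[, j[-length(j)], drop = FALSE]
    b <- X[, j[-1], drop = FALSE]
    for (k in seq_len(ncol(a))) {
      if (sd(a[, k]) == 0 || sd(b[, k]) == 0) next
      vals <- c(vals, cor(a[, k], b[, k])^2)
    }
  }
  mean(vals)
}
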