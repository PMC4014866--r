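test_that("allele frequencies and mean imputation follow 2p", {
  d <- matrix(c(2L, 2L, 2L,
                0L, 1L, 2L,
                0L, 0L, NA,
                1L, NA, NA), 3, 4)
  panel <- make_panel(d)
  p <- allele_frequencies(panel)
  expect_equal(unname(p), c(1, 0.5, 0, 0.5))
  X <- impute_missing(panel, "mean")
  expect_equal(X[3, 3], 0)      # 2p = 0
  expect_equal(X[2, 4], 1)      # 2p = 1
  expect_equal(X[is.finite(panel$dosage)],
               as.numeric(panel$dosage[is.finite(panel$dosage)]))
  d[, 1] <- NA
  expect_error(allele_frequencies(make_panel(d)), "zero non-missing")
})

test_that("pedigree imputation uses the Mendelian expectation", {
  d <- matrix(c(2L, 0L, NA,
                1L, 1L, NA,
                2L, 2L, 2L), 3, 3, byrow = FALSE)
  # samples S01..S03; S03 is offspring of S01 x S02
  panel <- make_panel(d)
  ped <- data.frame(id = c("S01", "S02", "S03"),
                    sire = c("0", "0", "S01"),
                    dam = c("0", "0", "S02"))
  X <- impute_missing(panel, "pedigree", pedigree = ped)
  expect_equal(X[3, 1], 1)      # parents 2 and 0 -> 1.0
  expect_equal(X[3, 2], 1)      # parents 1 and 1
  # no parents genotyped: falls back to 2p
  ped2 <- data.frame(id = c("S01", "S02", "S03"),
                     sire = c("0", "0", "X99"),
                     dam = c("0", "0", "X98"))
  X2 <- impute_missing(panel, "pedigree", pedigree = ped2)
  p <- allele_frequencies(panel)
  expect_equal(X2[3, 1], 2 * p[[1]])
})

test_that("G matches the hand-worked single-marker case and VanRaden scaling", {
  # one marker, p = 0.5, dosages 0 and 2: centered scores -1 and +1,
  # denominator 2*0.5*0.5 = 0.5, so G = [[2,-2],[-2,2]]
  d <- matrix(c(0L, 2L), 2, 1)
  panel <- make_panel(d)
  G <- build_G(panel)
  expect_equal(unname(G$values),
               matrix(c(2, -2, -2, 2), 2), tolerance = 1e-12)
  # identical genotypes: off-diagonal equals the diagonals
  d2 <- matrix(rbinom(40, 2, 0.4), 2, 20, byrow = TRUE)
  d2[2, ] <- d2[1, ]
  G2 <- build_G(make_panel(d2))
  expect_equal(G2$values[1, 2], G2$values[1, 1])
  # mean diagonal near 1 under Hardy-Weinberg
  rnd <- random_panel(300, 2000, seed = 5)
  G3 <- build_G(rnd)
  expect_lt(abs(mean(diag(G3$values)) - 1), 0.05)
  # symmetric, and invariant to allele-label swap
  expect_lt(max(abs(G3$values - t(G3$values))), 1e-12)
  flipped <- rnd
  flipped$dosage <- 2L - flipped$dosage
  G4 <- build_G(flipped)
  expect_equal(G4$values, G3$values, tolerance = 1e-10)
  mono <- make_panel(matrix(c(0L, 0L, 2L, 2L), 2, 2))
  expect_error(build_G(mono), "monomorphic")
})

# recursive kinship oracle, memoised: independent of the tabular loop
kinship_oracle <- function(ped) {
  memo <- new.env()
  par_of <- function(i) {
    r <- ped[ped$id == i, ]
    c(if (r$sire == "0") NA else r$sire,
      if (r$dam == "0") NA else r$dam)
  }
  depth <- function(i) {
    if (is.na(i)) return(0)
    ps <- par_of(i)
    1 + max(depth(ps[1]), depth(ps[2]))
  }
  a <- function(i, j) {
    if (is.na(i) || is.na(j)) return(0)
    key <- paste(sort(c(i, j)), collapse = "|")
    if (!is.null(memo[[key]])) return(memo[[key]])
    val <- if (i == j) {
      ps <- par_of(i)
      1 + 0.5 * a(ps[1], ps[2])
    } else {
      # recurse on the individual with the deeper pedigree
      if (depth(i) < depth(j)) { tmp <- i; i <- j; j <- tmp }
      ps <- par_of(i)
      0.5 * (a(ps[1], j) + a(ps[2], j))
    }
    memo[[key]] <- val
    val
  }
  ids <- ped$id
  outer(ids, ids, Vectorize(function(x, y) a(x, y)))
}

test_that("A reproduces textbook values and the recursive oracle", {
  ped <- data.frame(id = c("F1", "F2", "C1", "C2"),
                    sire = c("0", "0", "F1", "F1"),
                    dam = c("0", "0", "F2", "F2"))
  A <- build_A(ped)
  expect_equal(A$values["F1", "C1"], 0.5)      # parent-offspring
  expect_equal(A$values["C1", "C2"], 0.5)      # full sibs
  expect_equal(unname(diag(A$values)), rep(1, 4))
  # founders only: identity
  ped0 <- data.frame(id = c("X", "Y"), sire = "0", dam = "0")
  expect_equal(unname(build_A(ped0)$values), diag(2))
  # deeper pedigree with inbreeding vs oracle
  ped2 <- data.frame(
    id = c("A", "B", "C", "D", "E", "F", "G"),
    sire = c("0", "0", "A", "A", "C", "C", "E"),
    dam = c("0", "0", "B", "B", "D", "D", "F"))
  A2 <- build_A(ped2)
  expect_equal(unname(A2$values), kinship_oracle(ped2),
               tolerance = 1e-12)
  expect_gt(A2$values["G", "G"], 1)  # inbred: full-sib parents
  # subsetting after recursion keeps ancestor-routed relationships
  A3 <- build_A(ped2, ids = c("E", "F", "G"))
  expect_equal(A3$values["E", "F"], A2$values["E", "F"])
  # cycle detection
  bad <- data.frame(id = c("P", "Q"), sire = c("Q", "P"),
                    dam = c("0", "0"))
  expect_error(build_A(bad), "cycle")
})

test_that("G* blending is the exact convex combination", {
  pop <- shared_pop()
  # pick sired animals so A carries real relationships
  sired <- pop$pedigree$id[pop$pedigree$sire != "0"]
  sub <- subset_samples(pop$panel, head(sired, 60))
  G <- build_G(sub)
  A <- build_A(pop$pedigree, sub$sample_ids)
  expect_equal(combine_G_star(G, A, 0)$values, G$values)
  expect_equal(combine_G_star(G, A, 1)$values, A$values)
  Gs <- combine_G_star(G, A, 0.20)
  expect_equal(Gs$values, 0.8 * G$values + 0.2 * A$values)
  expect_equal(Gs$blend_weight, 0.20)
  # worked entry: 0.8*0.30 + 0.2*0.25 = 0.29
  expect_equal(0.8 * 0.30 + 0.2 * 0.25, 0.29)
  expect_error(combine_G_star(G, A, 1.2), "0, 1")
  # G and A correlate positively on pedigree-simulated data
  lt <- lower.tri(G$values)
  expect_gt(cor(G$values[lt], A$values[lt]), 0)
})

test_that("relatedness statistics order and average correctly", {
  ids <- c("T1", "A", "B", "C")
  V <- diag(4); dimnames(V) <- list(ids, ids)
  V["T1", c("A", "B", "C")] <- c(0.5, 0.2, 0.1)
  V[c("A", "B", "C"), "T1"] <- c(0.5, 0.2, 0.1)
  rel <- structure(list(ids = ids, values = V, kind = "G"),
                   class = "relationship_matrix")
  st <- relatedness_stats(rel, train_ids = c("A", "B", "C"),
                          test_ids = "T1")
  expect_equal(st$maxr, 0.5)
  expect_equal(st$ave5, mean(c(0.5, 0.2, 0.1)), tolerance = 1e-12)
  expect_true(st$short_set)
  # aveK non-increasing in K on a real panel
  pop <- shared_pop()
  G <- build_G(subset_samples(pop$panel, 1:120))
  st2 <- relatedness_stats(G, G$ids[1:100], G$ids[101:120])
  expect_true(all(st2$ave5 >= st2$ave10 - 1e-12))
  expect_true(all(st2$ave10 >= st2$ave20 - 1e-12))
  expect_true(all(st2$maxr >= st2$ave5 - 1e-12))
  expect_error(relatedness_stats(G, character(0), G$ids[1]), "empty")
})

test_that("genomic PCA separates simulated subgroups and flags homogeneity", {
  pop <- shared_pop_subgroups()
  G <- cached("G_subgroups", build_G(pop$panel))
  pc <- pca_subgroups(G)
  truth <- pop$truth$subgroup_labels
  agree <- max(mean((pc$labels == 1) == (truth == 1)),
               mean((pc$labels == 2) == (truth == 1)))
  expect_gt(agree, 0.9)
  expect_true(pc$structured)
  # homogeneous population: low leading-eigenvalue share
  rnd <- random_panel(150, 1500, seed = 6)
  pc2 <- pca_subgroups(build_G(rnd))
  expect_false(pc2$structured)
  # permutation invariance of grouping
  perm <- sample(length(G$ids))
  Gp <- structure(list(ids = G$ids[perm],
                       values = G$values[perm, perm], kind = "G"),
                  class = "relationship_matrix")
  set.seed(1); pcp <- pca_subgroups(Gp)
  same <- mean(pcp$labels[match(G$ids, Gp$ids)] == pc$labels)
  expect_true(same > 0.95 || same < 0.05)  # labels defined up to swap
})

test_that("relationship matrices round-trip through TSV", {
  panel <- random_panel(15, 80, seed = 90)
  G <- build_G(panel)
  ped <- data.frame(id = panel$sample_ids, sire = "0", dam = "0")
  Gs <- combine_G_star(G, build_A(ped, panel$sample_ids), 0.2)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_relmatrix(Gs, path)
  back <- read_relmatrix(path)
  expect_equal(back$ids, Gs$ids)
  expect_equal(back$values, Gs$values, tolerance = 1e-10)
  expect_equal(back$kind, "G_star")
  expect_equal(back$blend_weight, 0.2)
})
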