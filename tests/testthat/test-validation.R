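test_that("forward split applies the accuracy rule per animal", {
  early <- data.frame(id = c("a", "b", "c", "d"),
                      accuracy = c(0.4, 0.6, 0.4, 0.55), ebv = 0)
  late <- data.frame(id = c("a", "b", "c", "d"),
                     accuracy = c(0.8, 0.9, 0.45, 0.9), ebv = 0)
  plan <- forward_split(early, late)
  expect_setequal(plan$folds[[1]]$train, c("b", "d"))
  expect_setequal(plan$folds[[1]]$test, "a")   # c accurate in neither
  # animal absent early but accurate late joins the test set
  late2 <- rbind(late, data.frame(id = "e", accuracy = 0.7, ebv = 0))
  plan2 <- forward_split(early, late2)
  expect_true("e" %in% plan2$folds[[1]]$test)
  # all accurate early: no test set left
  early3 <- data.frame(id = c("a", "b"), accuracy = c(0.9, 0.9),
                       ebv = 0)
  late3 <- data.frame(id = c("a", "b"), accuracy = c(0.9, 0.9),
                      ebv = 0)
  expect_error(forward_split(early3, late3), "empty testing")
})

test_that("forward split recovers planned membership on a built fixture", {
  set.seed(60)
  ids <- sprintf("A%03d", 1:650)
  planned_train <- ids[1:500]
  planned_test <- ids[501:650]
  early <- data.frame(id = ids,
                      accuracy = c(runif(500, 0.6, 0.95),
                                   runif(150, 0.1, 0.5)), ebv = 0)
  late <- data.frame(id = ids,
                     accuracy = runif(650, 0.55, 0.95), ebv = 0)
  plan <- forward_split(early, late)
  expect_setequal(plan$folds[[1]]$train, planned_train)
  expect_setequal(plan$folds[[1]]$test, planned_test)
})

test_that("random folds partition evenly and reproducibly", {
  ids <- sprintf("x%02d", 1:10)
  plan <- random_folds(ids, k = 5, seed = 3)
  sizes <- vapply(plan$folds, function(f) length(f$test), integer(1))
  expect_equal(sizes, rep(2L, 5))
  tests <- unlist(lapply(plan$folds, `[[`, "test"))
  expect_setequal(tests, ids)
  expect_equal(anyDuplicated(tests), 0L)
  for (f in plan$folds)
    expect_length(intersect(f$train, f$test), 0)
  plan2 <- random_folds(ids, k = 5, seed = 3)
  expect_identical(plan$folds, plan2$folds)
  expect_error(random_folds(ids[1:3], k = 5), "fewer ids")
})

test_that("k-means folds follow genetic structure", {
  pop <- shared_pop_subgroups()
  G <- cached("G_subgroups", build_G(pop$panel))
  plan <- kmeans_folds(G, k = 2, seed = 4)
  truth <- pop$truth$subgroup_labels
  f1 <- plan$folds[[1]]$test
  agree <- max(mean(truth[f1] == 1), mean(truth[f1] == 2))
  expect_gt(agree, 0.9)
  # between-fold relationships smaller than within-fold
  plan5 <- kmeans_folds(G, k = 5, seed = 4)
  V <- G$values
  within <- between <- c()
  cl <- rep(NA_integer_, length(G$ids))
  names(cl) <- G$ids
  for (f in seq_along(plan5$folds)) cl[plan5$folds[[f]]$test] <- f
  same <- outer(cl, cl, "==")
  lt <- lower.tri(V)
  expect_gt(mean(V[lt & same]), mean(V[lt & !same]))
  # fold sizes vary more than under random splits
  sz_km <- vapply(plan5$folds, function(f) length(f$test), integer(1))
  sz_rd <- vapply(random_folds(G$ids, 5, seed = 4)$folds,
                  function(f) length(f$test), integer(1))
  expect_gt(var(sz_km), var(sz_rd))
  expect_error(kmeans_folds(G, k = length(G$ids) + 1), "folds")
})

test_that("comparison metrics match their definitions", {
  set.seed(5)
  x <- rnorm(20)
  expect_equal(empirical_accuracy(x, x, 0.8), 1.25)
  expect_equal(inflation_slope(x, x), 1, tolerance = 1e-12)
  expect_equal(prediction_mse(x, x), 0)
  expect_equal(inflation_slope(2 * x, x), 2, tolerance = 1e-12)
  expect_equal(prediction_mse(x + 2, x), 4, tolerance = 1e-12)
  # deflation direction: noisy half-scale proofs
  y <- 0.5 * x + rnorm(20, sd = 1e-3)
  expect_lt(abs(inflation_slope(y, x) - 0.5), 0.01)
  # hand 3-vector MSE
  expect_equal(prediction_mse(c(1, 2, 3), c(2, 2, 5)), (1 + 0 + 4) / 3)
  # independence gives near-zero accuracy
  set.seed(6)
  expect_lt(abs(empirical_accuracy(rnorm(500), rnorm(500), 0.8)), 0.2)
  # degenerate input flagged
  expect_warning(v <- empirical_accuracy(rep(1, 5), rnorm(5), 0.8),
                 "zero variance")
  expect_true(is.na(v))
})

test_that("run_design aggregates folds and audits forward leakage", {
  pop <- shared_pop()
  panel <- pop$panel
  tr <- cached("trait_default",
               simulate_trait(panel, 100, genetic_var = 1, seed = 3))
  # young animals are inaccurate early and gain accuracy late
  old <- pop$pedigree$generation <= 1
  acc_early <- ifelse(old, 0.85, 0.35)
  snaps <- simulate_ebv_snapshots(tr$tbv, acc_early, 0.85, seed = 61)
  debv_e <- deregress(snaps$early, h2 = 0.3)
  debv_l <- deregress(snaps$late, h2 = 0.3)
  plan <- forward_split(snaps$early, snaps$late)
  # forward training table only holds early-snapshot proofs
  debv_fwd <- rbind(debv_e[debv_e$id %in% plan$folds[[1]]$train, ],
                    debv_l[debv_l$id %in% plan$folds[[1]]$test, ])
  train_rows <- debv_fwd[debv_fwd$id %in% plan$folds[[1]]$train, ]
  expect_true(all(train_rows$debv ==
                    debv_e$debv[match(train_rows$id, debv_e$id)]))
  G <- build_G(panel)
  eng <- list(gblup0 = engine_gblup(panel, (1 - 0.3) / 0.3, w = 0))
  rep_f <- run_design(plan, eng, debv_fwd, G = G)
  expect_equal(nrow(rep_f), 1)
  expect_true(is.finite(rep_f$accuracy))
  expect_gt(rep_f$accuracy, 0)
  expect_true(rep_f$maxr > 0 && rep_f$ave5 <= rep_f$maxr)
  # cv aggregation: mean of fold metrics equals the report
  plan_cv <- random_folds(debv_l$id, k = 5, seed = 62)
  rep_cv <- run_design(plan_cv, eng, debv_l, G = G)
  pf <- attr(rep_cv, "folds")$gblup0
  expect_equal(rep_cv$accuracy, mean(pf$accuracy), tolerance = 1e-12)
  # fold processing order does not matter
  plan_rev <- plan_cv
  plan_rev$folds <- rev(plan_rev$folds)
  rep_rev <- run_design(plan_rev, eng, debv_l, G = G)
  expect_equal(rep_rev$accuracy, rep_cv$accuracy, tolerance = 1e-12)
})

test_that("accuracy rises with relatedness to the training set", {
  # weaker LD separates the pedigree-driven signal from the
  # LD-tagging baseline that unrelated test animals retain; per-bin
  # accuracies are averaged over trait replicates to tame the
  # sampling noise of within-bin correlations
  cfg <- simulation_config(n_markers = 1500, target_adjacent_r2 = 0.10,
                           seed = 64)
  pop <- simulate_population(cfg)
  panel <- pop$panel
  n <- nrow(panel$dosage)
  h2 <- 0.5
  ped <- pop$pedigree
  test_ids <- ped$id[ped$generation == 3]
  train_ids <- setdiff(panel$sample_ids, test_ids)
  G <- build_G(panel)
  st <- relatedness_stats(G, train_ids, test_ids)
  bins <- cut(st$ave5, quantile(st$ave5, 0:3 / 3),
              include.lowest = TRUE)
  accs <- matrix(NA_real_, 6, 3)
  fit <- NULL
  for (r in 1:6) {
    tr <- simulate_trait(panel, 100, genetic_var = 1, seed = 400 + r)
    set.seed(500 + r)
    y_all <- tr$tbv + rnorm(n, sd = sqrt((1 - h2) / h2))
    fit <- fit_gblup(stats::setNames(
      y_all[match(train_ids, panel$sample_ids)], train_ids), G,
      var_ratio = (1 - h2) / h2)
    accs[r, ] <- tapply(seq_along(test_ids), bins, function(i)
      cor(fit$gebv[test_ids[i]], tr$tbv[test_ids[i]]))
  }
  expect_gt(cor(1:3, colMeans(accs), method = "spearman"), 0)
  # estimated individual accuracies track relatedness tightly
  expect_gt(cor(fit$rpev[test_ids], st$ave5), 0.5)
  expect_gt(cor(fit$rpev[test_ids], st$maxr), 0.5)
})
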