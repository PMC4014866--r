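#' Forward-prediction split from two evaluation snapshots
#'
#' Training animals are those already accurately evaluated in the
#' early snapshot (accuracy strictly above the threshold); testing
#' animals are those that were not, but became accurate by the late
#' snapshot. Animals accurate in neither are excluded. Training on
#' early-snapshot proofs only is what prevents information from the
#' testing animals leaking into training.
#'
#' @param snap_early,snap_late snapshot data.frames (id, ebv,
#'   accuracy, ...).
#' @param acc_threshold accuracy cutoff; default 0.50.
#' @return A `split_plan` with design "forward" and one fold.
#' @export
forward_split <- function(snap_early, snap_late, acc_threshold = 0.50) {
  acc_e <- stats::setNames(snap_early$accuracy, snap_early$id)
  acc_l <- stats::setNames(snap_late$accuracy, snap_late$id)
  train <- snap_early$id[snap_early$accuracy > acc_threshold]
  late_ok <- snap_late$id[snap_late$accuracy > acc_threshold]
  not_early <- setdiff(late_ok, train)
  test <- not_early[is.na(acc_e[not_early]) |
                      acc_e[not_early] <= acc_threshold]
  if (!length(train)) stop("empty training set under forward split")
  if (!length(test)) stop("empty testing set under forward split")
  structure(list(design = "forward", k = 1L,
                 folds = list(list(train = train, test = test))),
            class = "split_plan")
}

#' Random k-fold cross-validation plan
#'
#' Seeded shuffle into k folds of near-equal size (sizes differ by at
#' most one); each fold is a test set, the remainder trains.
#'
#' @param ids animal ids.
#' @param k number of folds; default 5.
#' @param seed integer seed.
#' @return A `split_plan` with design "random_cv".
#' @export
random_folds <- function(ids, k = 5, seed = 1) {
  if (length(ids) < k) stop("fewer ids than folds")
  set.seed(seed)
  perm <- sample(ids)
  grp <- sort(rep(seq_len(k), length.out = length(ids)))
  folds <- lapply(seq_len(k), function(f) {
    test <- perm[grp == f]
    list(train = setdiff(ids, test), test = test)
  })
  structure(list(design = "random_cv", k = as.integer(k), seed = seed,
                 folds = folds),
            class = "split_plan")
}

#' Genomic-clustering (k-means) cross-validation plan
#'
#' Embeds animals by the top principal coordinates of the genomic
#' relationship matrix (enough components for at least 90% of the
#' positive spectrum), runs seeded k-means with 25 restarts, and
#' makes each cluster one test fold. Clusters follow genetic
#' structure, so relationships between train and test are minimized;
#' fold sizes are free to vary.
#'
#' @param G a `relationship_matrix` (kind "G" or "G_star").
#' @param k number of folds; default 5.
#' @param seed integer seed.
#' @return A `split_plan` with design "kmeans_cv".
#' @export
kmeans_folds <- function(G, k = 5, seed = 1) {
  n <- length(G$ids)
  if (k > n) stop("more folds than animals")
  V <- G$values
  J <- diag(n) - matrix(1 / n, n, n)
  e <- eigen(J %*% V %*% J, symmetric = TRUE)
  pos <- pmax(e$values, 0)
  ncomp <- which(cumsum(pos) / sum(pos) >= 0.90)[1]
  ncomp <- max(2L, min(ncomp, n - 1L))
  scores <- e$vectors[, seq_len(ncomp), drop = FALSE] %*%
    diag(sqrt(pos[seq_len(ncomp)]), ncomp)
  set.seed(seed)
  km <- kmeans(scores, centers = k, nstart = 25, iter.max = 100)
  folds <- lapply(seq_len(k), function(f) {
    test <- G$ids[km$cluster == f]
    list(train = setdiff(G$ids, test), test = test)
  })
  structure(list(design = "kmeans_cv", k = as.integer(k), seed = seed,
                 folds = folds),
            class = "split_plan")
}

#' @export
print.split_plan <- function(x, ...) {
  sizes <- vapply(x$folds, function(f) length(f$test), integer(1))
  cat(sprintf("split_plan [%s]: %d fold(s); test sizes: %s\n",
              x$design, length(x$folds),
              paste(sizes, collapse = ", ")))
  invisible(x)
}

#' Empirical accuracy of genomic predictions
#'
#' Pearson correlation between DGV and validation dEBV divided by the
#' mean dEBV accuracy — a proxy for the correlation of the DGV with
#' the true breeding value. Because of the division it can exceed 1
#' and is deliberately not clamped.
#'
#' @param dgv,debv aligned numeric vectors (n >= 3).
#' @param debv_accuracies per-animal dEBV accuracies (or a scalar
#'   mean).
#' @return Empirical accuracy (scalar); NA with a warning if either
#'   vector is constant.
#' @export
empirical_accuracy <- function(dgv, debv, debv_accuracies) {
  if (length(dgv) != length(debv)) stop("dgv and debv must align")
  if (length(dgv) < 3) stop("need at least 3 animals")
  if (sd(dgv) == 0 || sd(debv) == 0) {
    warning("zero variance: empirical accuracy undefined")
    return(NA_real_)
  }
  cor(dgv, debv) / mean(debv_accuracies)
}

#' Inflation/deflation slope
#'
#' OLS slope of validation dEBV on DGV (with intercept). Values above
#' 1 mean the DGV are compressed relative to the proofs (deflated
#' predictions); below 1, over-dispersed (inflated).
#'
#' @param debv,dgv aligned numeric vectors.
#' @return The slope b1.
#' @export
inflation_slope <- function(debv, dgv) {
  if (length(dgv) < 3) stop("need at least 3 animals")
  if (var(dgv) == 0) {
    warning("zero DGV variance: slope undefined")
    return(NA_real_)
  }
  unname(coef(lm(debv ~ dgv))[2])
}

#' Mean squared error of prediction
#'
#' @param dgv,debv aligned numeric vectors.
#' @return mean((dgv - debv)^2).
#' @export
prediction_mse <- function(dgv, debv) {
  if (length(dgv) != length(debv)) stop("dgv and debv must align")
  mean((dgv - debv)^2)
}

#' Run prediction engines across a validation plan
#'
#' For every fold of the plan and every engine, trains on the fold's
#' training dEBV, scores the test animals, and computes empirical
#' accuracy, slope and MSE, plus per-fold relatedness summaries
#' (pooled mean maxr and ave5 of test animals to their training set).
#' Cross-validation metrics are averaged over folds with their
#' standard errors; a forward plan reports its single split.
#'
#' @param plan a `split_plan`.
#' @param engines named list of fitting functions; each is called as
#'   `fn(y, weights, train_ids, test_ids)` and must return a named
#'   DGV vector covering the test ids. See [engine_gblup()] /
#'   [engine_bayes()] for ready-made constructors.
#' @param debv data.frame from [deregress()] (id, debv, reliability,
#'   weight).
#' @param G optional `relationship_matrix` for relatedness summaries.
#' @return A `validation_report` data.frame: one row per engine with
#'   accuracy, slope, mse, their fold standard errors, mean maxr and
#'   ave5, plus a `folds` attribute with fold-level rows.
#' @export
run_design <- function(plan, engines, debv, G = NULL) {
  rows <- list()
  for (eng_name in names(engines)) {
    fn <- engines[[eng_name]]
    per_fold <- lapply(seq_along(plan$folds), function(f) {
      fold <- plan$folds[[f]]
      tr <- intersect(fold$train, debv$id)
      te <- intersect(fold$test, debv$id)
      d_tr <- debv[match(tr, debv$id), ]
      d_te <- debv[match(te, debv$id), ]
      y <- stats::setNames(d_tr$debv, d_tr$id)
      res <- tryCatch(fn(y = y, weights = d_tr$weight, train_ids = tr,
                         test_ids = te),
                      error = function(e) e)
      if (inherits(res, "error"))
        return(data.frame(fold = f, accuracy = NA, slope = NA,
                          mse = NA, maxr = NA, ave5 = NA,
                          n_train = length(tr), n_test = length(te),
                          error = conditionMessage(res)))
      dgv <- res[d_te$id]
      acc <- empirical_accuracy(dgv, d_te$debv,
                                sqrt(d_te$reliability))
      rel <- if (!is.null(G))
        relatedness_stats(G, tr, te) else NULL
      data.frame(fold = f, accuracy = acc,
                 slope = inflation_slope(d_te$debv, dgv),
                 mse = prediction_mse(dgv, d_te$debv),
                 maxr = if (is.null(rel)) NA else mean(rel$maxr),
                 ave5 = if (is.null(rel)) NA else mean(rel$ave5),
                 n_train = length(tr), n_test = length(te),
                 error = NA_character_)
    })
    pf <- do.call(rbind, per_fold)
    pf$engine <- eng_name
    se <- function(x) if (sum(!is.na(x)) > 1) sd(x, na.rm = TRUE) /
      sqrt(sum(!is.na(x))) else NA_real_
    rows[[eng_name]] <- data.frame(
      engine = eng_name, design = plan$design,
      accuracy = mean(pf$accuracy, na.rm = TRUE),
      accuracy_se = se(pf$accuracy),
      slope = mean(pf$slope, na.rm = TRUE), slope_se = se(pf$slope),
      mse = mean(pf$mse, na.rm = TRUE),
      maxr = mean(pf$maxr, na.rm = TRUE),
      ave5 = mean(pf$ave5, na.rm = TRUE),
      n_folds = length(plan$folds),
      n_failed = sum(!is.na(pf$error)))
    attr(rows[[eng_name]], "per_fold") <- pf
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "folds") <- lapply(rows, attr, "per_fold")
  class(out) <- c("validation_report", class(out))
  out
}

#' GBLUP engine constructor for [run_design()]
#'
#' Binds a genotype panel, pedigree and blending weight into an
#' engine closure. The relationship matrix is built once over all
#' animals; each fold fits the mixed model on its training records
#' and reads test DGV straight out of the solutions.
#'
#' @param panel post-QC [genotype_panel()] covering all animals.
#' @param var_ratio sigma2_e/sigma2_g.
#' @param w pedigree blend weight (0 = pure genomic).
#' @param pedigree required when `w > 0`.
#' @return function(y, weights, train_ids, test_ids) -> named DGV.
#' @export
engine_gblup <- function(panel, var_ratio, w = 0, pedigree = NULL) {
  G <- build_G(panel)
  rel <- if (w > 0) {
    if (is.null(pedigree)) stop("w > 0 needs a pedigree")
    A <- build_A(pedigree, panel$sample_ids)
    combine_G_star(G, A, w)
  } else G
  function(y, weights, train_ids, test_ids) {
    fit <- fit_gblup(y, rel, var_ratio, weights = weights)
    fit$gebv
  }
}

#' Bayesian-regression engine constructor for [run_design()]
#'
#' @param panel post-QC [genotype_panel()] covering all animals.
#' @param method "bayesc" or "blasso".
#' @param chain a [chain_config()].
#' @param ... passed to [fit_bayesC()] / [fit_blasso()].
#' @return function(y, weights, train_ids, test_ids) -> named DGV.
#' @export
engine_bayes <- function(panel, method = c("bayesc", "blasso"),
                         chain = chain_config(reduced = TRUE), ...) {
  method <- match.arg(method)
  freqs <- allele_frequencies(panel)
  function(y, weights, train_ids, test_ids) {
    tr_panel <- subset_samples(panel, train_ids)
    fit <- if (method == "bayesc")
      fit_bayesC(y, tr_panel, chain = chain, weights = weights,
                 freqs = freqs, ...)
    else
      fit_blasso(y, tr_panel, chain = chain, weights = weights,
                 freqs = freqs, ...)
    dgv_from_effects(fit$effects,
                     subset_samples(panel, test_ids), freqs)
  }
}
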