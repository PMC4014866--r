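#' Fit weighted GBLUP through the mixed-model equations
#'
#' Solves y = 1 mu + Z g + e with g ~ N(0, G* sigma2_g) and
#' e ~ N(0, R sigma2_e), where R is a diagonal matrix of per-record
#' weights (typically (1 - r2)/r2 from deregression). Animals present
#' in G* but absent from `y` carry no data equations and are predicted
#' purely through their relationships — that is how test-set DGV are
#' produced, and it stays exact under pedigree blending (w > 0).
#' Prediction-error variances come from the g-block of the inverse
#' coefficient matrix.
#'
#' @param y named numeric vector of pseudo-phenotypes (names = animal
#'   ids, a subset of `Gstar$ids`).
#' @param Gstar a `relationship_matrix` covering all animals to
#'   predict.
#' @param var_ratio sigma2_e / sigma2_g. For deregressed proofs with
#'   weights (1 - r2)/r2 the natural choice is (1 - h2) / h2.
#' @param weights per-record residual weights R_ii aligned with `y`;
#'   default 1 (homogeneous).
#' @param var_g genetic variance sigma2_g used to scale PEV; default 1
#'   (PEV then in units of sigma2_g via `var_ratio`).
#' @param ridge diagonal jitter added to G* only if its smallest
#'   eigenvalue falls below 1e-10; default 1e-8.
#' @return A `gblup_fit` with elements mu, gebv (all animals in G*),
#'   pev, rpev, var_g, var_e, weights, relationship kind and blend
#'   weight.
#' @export
fit_gblup <- function(y, Gstar, var_ratio, weights = NULL, var_g = 1,
                      ridge = 1e-8) {
  if (var_ratio < 0) stop("var_ratio must be non-negative")
  ids <- Gstar$ids
  if (is.null(names(y))) stop("y must be named by animal id")
  obs <- match(names(y), ids)
  if (anyNA(obs)) stop("y contains ids absent from Gstar")
  n_all <- length(ids)
  n_obs <- length(y)
  if (is.null(weights)) weights <- rep(1, n_obs)
  if (any(weights <= 0)) stop("weights must be positive")
  G <- Gstar$values
  ev_min <- min(eigen(G, symmetric = TRUE, only.values = TRUE)$values)
  if (ev_min < 1e-10) G <- G + diag(ridge, n_all)
  Ginv <- tryCatch(chol2inv(chol(G)), error = function(e)
    stop("G* singular even after ridge: ", conditionMessage(e)))
  rinv <- 1 / weights
  # coefficient matrix [mu; g]
  C <- matrix(0, n_all + 1, n_all + 1)
  C[1, 1] <- sum(rinv)
  zrz <- numeric(n_all)
  zrz[obs] <- rinv
  C[1, 1 + seq_len(n_all)] <- zrz
  C[1 + seq_len(n_all), 1] <- zrz
  C[-1, -1] <- diag(zrz, n_all) + Ginv * var_ratio
  rhs <- c(sum(rinv * y), {
    v <- numeric(n_all); v[obs] <- rinv * y; v
  })
  Cinv <- tryCatch(solve(C), error = function(e)
    stop("singular mixed-model equations: ", conditionMessage(e)))
  sol <- Cinv %*% rhs
  mu <- sol[1]
  gebv <- as.numeric(sol[-1])
  names(gebv) <- ids
  var_e <- var_ratio * var_g
  pev <- diag(Cinv)[-1] * var_e
  names(pev) <- ids
  fit <- structure(
    list(mu = mu, gebv = gebv, pev = pev, var_g = var_g, var_e = var_e,
         var_ratio = var_ratio, weights = weights, obs_ids = names(y),
         relationship_kind = Gstar$kind, blend_weight = Gstar$blend_weight),
    class = "gblup_fit")
  fit$rpev <- rpev_accuracy(fit, Gstar)
  fit
}

#' Individual accuracy of DGV from prediction-error variance
#'
#' rpev_i = sqrt(max(0, 1 - PEV_i / (sigma2_g G*_ii))): the classical
#' reliability of a BLUP prediction read off the inverse coefficient
#' matrix, on the accuracy (correlation) scale.
#'
#' @param fit a `gblup_fit`.
#' @param Gstar the relationship matrix used in the fit.
#' @return Named vector of accuracies in \[0, 1\].
#' @export
rpev_accuracy <- function(fit, Gstar) {
  gii <- diag(Gstar$values)
  if (any(gii <= 0)) stop("non-positive diagonal in G*")
  rel <- 1 - fit$pev / (fit$var_g * gii)
  r <- sqrt(pmax(rel, 0))
  names(r) <- names(fit$pev)
  pmin(r, 1)
}

#' @export
print.gblup_fit <- function(x, ...) {
  cat(sprintf("gblup_fit [%s%s]: %d animals (%d with records)\n",
              x$relationship_kind,
              if (!is.null(x$blend_weight))
                sprintf(", w=%.2f", x$blend_weight) else "",
              length(x$gebv), length(x$obs_ids)))
  cat(sprintf("  mu = %.4f; var ratio = %.3f; mean rpev = %.3f\n",
              x$mu, x$var_ratio, mean(x$rpev)))
  invisible(x)
}

#' Back-solve marker effects from a GBLUP fit
#'
#' a = M' G^-1 g_hat / sum(2 p (1 - p)), with M the centered dosage
#' matrix of the fitted animals. For w = 0 the implied DGV of any new
#' animal (centered genotypes times a) reproduce the in-MME
#' predictions; under blending (w > 0) the conversion is approximate
#' and is flagged.
#'
#' @param fit a `gblup_fit`.
#' @param panel the training [genotype_panel()] (fitted animals).
#' @param freqs allele frequencies used to build G.
#' @return Named vector of per-marker effects; attribute
#'   `approximate` is TRUE when the fit used w > 0.
#' @export
backsolve_marker_effects <- function(fit, panel, freqs) {
  denom <- sum(2 * freqs * (1 - freqs))
  if (denom <= 0) stop("all markers monomorphic: backsolve undefined")
  ids <- panel$sample_ids
  M <- impute_missing(panel, "mean")
  M <- sweep(M, 2, 2 * freqs)
  G <- tcrossprod(M) / denom
  ev_min <- min(eigen(G, symmetric = TRUE, only.values = TRUE)$values)
  if (ev_min < 1e-10) G <- G + diag(1e-8, nrow(G))
  g <- fit$gebv[ids]
  a <- as.numeric(crossprod(M, solve(G, g))) / denom
  names(a) <- panel$marker_ids
  approx <- !is.null(fit$blend_weight) && fit$blend_weight > 0
  if (approx)
    warning("fit used w > 0: back-solved effects are approximate")
  attr(a, "approximate") <- approx
  a
}

#' Ridge-regression SNP-BLUP
#'
#' Direct marker-effect estimation: y = 1 mu + W a + e with
#' a ~ N(0, I sigma2_a) and heterogeneous residual weights. With
#' sigma2_a = sigma2_g / sum(2p(1-p)) this is algebraically the same
#' model as GBLUP on G = WW'/sum(2p(1-p)), which makes it the
#' independent cross-check for [fit_gblup()].
#'
#' @param y named pseudo-phenotypes.
#' @param panel training [genotype_panel()] containing the `y`
#'   animals.
#' @param var_ratio sigma2_e / sigma2_g (genomic scale, as in
#'   [fit_gblup()]).
#' @param weights per-record residual weights aligned with y.
#' @param freqs optional allele frequencies (default: computed from
#'   the panel).
#' @return list with mu, effects (per marker), dgv (per panel animal)
#'   and the frequencies used.
#' @export
snp_blup <- function(y, panel, var_ratio, weights = NULL, freqs = NULL) {
  if (is.null(freqs)) freqs <- allele_frequencies(panel)
  denom <- sum(2 * freqs * (1 - freqs))
  W <- impute_missing(panel, "mean")
  W <- sweep(W, 2, 2 * freqs)
  obs <- match(names(y), panel$sample_ids)
  if (anyNA(obs)) stop("y contains ids absent from panel")
  if (is.null(weights)) weights <- rep(1, length(y))
  rinv <- 1 / weights
  Wo <- W[obs, , drop = FALSE]
  m <- ncol(Wo)
  lambda_a <- var_ratio * denom  # sigma2_e / sigma2_a
  # augmented normal equations [mu; a]
  C <- matrix(0, m + 1, m + 1)
  C[1, 1] <- sum(rinv)
  xw <- crossprod(rinv, Wo)
  C[1, -1] <- xw
  C[-1, 1] <- xw
  C[-1, -1] <- crossprod(Wo * rinv, Wo) + diag(lambda_a, m)
  rhs <- c(sum(rinv * y), crossprod(Wo, rinv * y))
  sol <- solve(C, rhs)
  mu <- sol[1]
  a <- sol[-1]
  names(a) <- panel$marker_ids
  dgv <- as.numeric(W %*% a)
  names(dgv) <- panel$sample_ids
  list(mu = mu, effects = a, dgv = dgv, freqs = freqs)
}
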