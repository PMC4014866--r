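#' Gibbs chain settings
#'
#' Defaults follow the long production profile (100 000 iterations,
#' 20 000 burn-in, thinning 100). `reduced = TRUE` switches to a short
#' profile (5 000 / 1 000 / 10) suitable for tests and interactive
#' use.
#'
#' @param n_iter,burn_in,thin chain length, burn-in, thinning.
#' @param seed integer seed applied before sampling.
#' @param reduced use the short test profile.
#' @return A `chain_config` list.
#' @export
chain_config <- function(n_iter = 100000, burn_in = 20000, thin = 100,
                         seed = 1, reduced = FALSE) {
  if (reduced) { n_iter <- 5000; burn_in <- 1000; thin <- 10 }
  if (burn_in >= n_iter) stop("burn_in must be below n_iter")
  if (thin < 1) stop("thin must be >= 1")
  if ((n_iter - burn_in) / thin < 30)
    stop("chain settings retain fewer than 30 samples")
  structure(list(n_iter = as.integer(n_iter),
                 burn_in = as.integer(burn_in),
                 thin = as.integer(thin), seed = as.integer(seed)),
            class = "chain_config")
}

# shared design preparation: whiten by residual weights, center dosages
prepare_design <- function(y, panel, weights, freqs) {
  if (is.null(freqs)) freqs <- allele_frequencies(panel)
  obs <- match(names(y), panel$sample_ids)
  if (anyNA(obs)) stop("y contains ids absent from panel")
  if (is.null(weights)) weights <- rep(1, length(y))
  if (any(weights <= 0)) stop("weights must be positive")
  W <- impute_missing(panel, "mean")
  W <- sweep(W, 2, 2 * freqs)
  sw <- 1 / sqrt(weights)
  list(yt = as.numeric(y) * sw,
       Xt = W[obs, , drop = FALSE] * sw,
       x0 = sw, W = W, freqs = freqs)
}

#' BayesC whole-genome regression
#'
#' Mixture model: each marker has probability pi of carrying a normal
#' effect with a common variance, else exactly zero. Effects,
#' indicators, the two variances and pi are sampled by single-site
#' Gibbs; scaled inverse chi-square priors with `v` = 4 degrees of
#' freedom are used for both variances, their scales derived so the
#' prior means match the assumed genetic variance split over the
#' expected number of included markers (pi times the
#' heterozygosity sum) and the assumed residual variance. pi itself is
#' sampled from its beta posterior; with the default
#' Beta(1e8, 1e10) prior it is numerically pinned near 0.01.
#' Heterogeneous residual weights are handled by whitening rows by
#' 1/sqrt(R_ii) once, up front.
#'
#' @param y named numeric vector of pseudo-phenotypes.
#' @param panel training [genotype_panel()].
#' @param chain a [chain_config()].
#' @param weights per-record residual weights R_ii (default 1).
#' @param var_g,var_e assumed genetic and residual variances; defaults
#'   split var(y) in half.
#' @param pi_alpha,pi_beta beta prior for pi; defaults 1e8 / 1e10.
#' @param v prior degrees of freedom for both variances; default 4.
#' @param freqs optional allele frequencies.
#' @return A `bayes_fit`: posterior-mean effects, inclusion
#'   frequencies, mu, DGV for all panel animals, variance/pi chains.
#' @export
fit_bayesC <- function(y, panel, chain = chain_config(), weights = NULL,
                       var_g = NULL, var_e = NULL,
                       pi_alpha = 1e8, pi_beta = 1e10, v = 4,
                       freqs = NULL) {
  if (any(!is.finite(y))) stop("non-finite values in y")
  d <- prepare_design(y, panel, weights, freqs)
  if (is.null(var_g)) var_g <- var(y) / 2
  if (is.null(var_e)) var_e <- var(y) / 2
  pi0 <- pi_alpha / (pi_alpha + pi_beta)
  het <- sum(2 * d$freqs * (1 - d$freqs))
  # prior mean of scaled-inv-chisq(v, S) is v S/(v-2)
  S_a <- (v - 2) / v * var_g / (pi0 * het)
  S_e <- (v - 2) / v * var_e
  set.seed(chain$seed)
  res <- .bayesc_gibbs(d$yt, d$Xt, d$x0, chain$n_iter, chain$burn_in,
                       chain$thin, pi_alpha, pi_beta, v, S_a, S_e,
                       var_g / (pi0 * het), var_e, pi0)
  if (res$n_kept < 30) stop("fewer than 30 retained samples")
  effects <- stats::setNames(res$effect_mean, panel$marker_ids)
  dgv <- as.numeric(d$W %*% effects)
  names(dgv) <- panel$sample_ids
  structure(list(method = "bayesc", effects = effects,
                 inclusion_freq = stats::setNames(res$inclusion_freq,
                                                  panel$marker_ids),
                 mu = mean(res$mu_chain), dgv = dgv,
                 chains = list(var_a = res$var_a_chain,
                               var_e = res$var_e_chain,
                               pi = res$pi_chain, mu = res$mu_chain),
                 freqs = d$freqs, chain = chain),
            class = "bayes_fit")
}

#' Bayesian LASSO whole-genome regression
#'
#' Each marker effect is normal with its own variance tau2_i, and the
#' tau2_i carry an exponential prior with rate lambda^2/2 — the
#' conditional-normal parameterization of the LASSO. Full
#' conditionals: effects are normal, 1/tau2_i inverse-Gaussian,
#' lambda^2 gamma (truncated so lambda stays in (0, 1e7)), and the
#' residual variance gets a flat prior. Residual weights are whitened
#' as in [fit_bayesC()].
#'
#' @inheritParams fit_bayesC
#' @param lambda_shape,lambda_rate gamma prior for lambda^2 (weakly
#'   informative defaults 1.1 and 1e-4).
#' @param lambda_max upper bound for lambda; default 1e7.
#' @return A `bayes_fit` with effects, mu, dgv, lambda and variance
#'   chains.
#' @export
fit_blasso <- function(y, panel, chain = chain_config(), weights = NULL,
                       var_e = NULL, lambda_shape = 1.1,
                       lambda_rate = 1e-4, lambda_max = 1e7,
                       freqs = NULL) {
  if (any(!is.finite(y))) stop("non-finite values in y")
  d <- prepare_design(y, panel, weights, freqs)
  if (is.null(var_e)) var_e <- var(y) / 2
  set.seed(chain$seed)
  res <- .blasso_gibbs(d$yt, d$Xt, d$x0, chain$n_iter, chain$burn_in,
                       chain$thin, lambda_shape, lambda_rate,
                       lambda_max, var_e)
  if (res$n_kept < 30) stop("fewer than 30 retained samples")
  effects <- stats::setNames(res$effect_mean, panel$marker_ids)
  dgv <- as.numeric(d$W %*% effects)
  names(dgv) <- panel$sample_ids
  structure(list(method = "blasso", effects = effects,
                 mu = mean(res$mu_chain), dgv = dgv,
                 chains = list(var_e = res$var_e_chain,
                               lambda = res$lambda_chain,
                               mu = res$mu_chain),
                 freqs = d$freqs, chain = chain),
            class = "bayes_fit")
}

#' @export
print.bayes_fit <- function(x, ...) {
  cat(sprintf("bayes_fit [%s]: %d markers, %d animals scored\n",
              x$method, length(x$effects), length(x$dgv)))
  cat(sprintf("  mu = %.4f; retained samples = %d\n", x$mu,
              length(x$chains$mu)))
  invisible(x)
}

#' Direct genomic values from marker effects
#'
#' DGV = centered dosages times posterior-mean effects; the intercept
#' is excluded — the DGV is the genetic term only. The new panel must
#' carry exactly the training marker set (same counted alleles).
#'
#' @param effects named per-marker effects.
#' @param new_panel a [genotype_panel()] of animals to score.
#' @param freqs training allele frequencies (centering must match
#'   training).
#' @return Named numeric vector of DGV.
#' @export
dgv_from_effects <- function(effects, new_panel, freqs) {
  missing_m <- setdiff(names(effects), new_panel$marker_ids)
  extra_m <- setdiff(new_panel$marker_ids, names(effects))
  if (length(missing_m) || length(extra_m))
    stop("marker sets differ; absent from panel: ",
         paste(head(missing_m, 5), collapse = ", "),
         "; absent from effects: ",
         paste(head(extra_m, 5), collapse = ", "))
  W <- impute_missing(new_panel, "mean")
  ord <- match(names(effects), new_panel$marker_ids)
  W <- sweep(W[, ord, drop = FALSE], 2, 2 * freqs[names(effects)])
  dgv <- as.numeric(W %*% effects)
  names(dgv) <- new_panel$sample_ids
  dgv
}

#' Chain diagnostics
#'
#' Effective sample size per stored chain via the
#' initial-positive-sequence estimator (autocorrelations summed until
#' the first non-positive term), plus simple trace statistics. A
#' warning is attached when any ESS drops below 50.
#'
#' @param fit a `bayes_fit`.
#' @return data.frame with parameter, mean, sd, ess and a `low_ess`
#'   flag.
#' @export
chain_diagnostics <- function(fit) {
  chains <- fit$chains
  out <- lapply(names(chains), function(nm) {
    x <- as.numeric(chains[[nm]])
    data.frame(parameter = nm, mean = mean(x), sd = sd(x),
               ess = ess_ips(x))
  })
  res <- do.call(rbind, out)
  res$low_ess <- res$ess < 50
  if (any(res$low_ess))
    warning("low effective sample size for: ",
            paste(res$parameter[res$low_ess], collapse = ", "))
  res
}

# initial-positive-sequence ESS
ess_ips <- function(x) {
  n <- length(x)
  if (n < 3 || sd(x) == 0) return(n)
  acfs <- as.numeric(stats::acf(x, lag.max = min(n - 2, 200),
                                plot = FALSE)$acf)[-1]
  s <- 0
  for (r in acfs) {
    if (r <= 0) break
    s <- s + r
  }
  max(1, min(n, n / (1 + 2 * s)))
}

#' Imputed, centered dosage matrix
#'
#' Convenience accessor used by the engines and the validation layer:
#' mean-imputes missing calls and centers by twice the supplied
#' allele frequencies.
#'
#' @param panel a [genotype_panel()].
#' @param freqs allele frequencies (default: computed from the panel).
#' @return Real matrix, samples by markers.
#' @export
centered_dosages <- function(panel, freqs = NULL) {
  if (is.null(freqs)) freqs <- allele_frequencies(panel)
  W <- impute_missing(panel, "mean")
  sweep(W, 2, 2 * freqs)
}
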