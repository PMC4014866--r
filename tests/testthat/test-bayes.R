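test_that("chain settings are validated", {
  expect_error(chain_config(1000, 2000), "below n_iter")
  expect_error(chain_config(1000, 100, thin = 0), "thin")
  expect_error(chain_config(1000, 900, thin = 10), "30 samples")
  ch <- chain_config(reduced = TRUE)
  expect_equal(ch$n_iter, 5000L)
  expect_equal(ch$burn_in, 1000L)
  expect_equal(ch$thin, 10L)
})

test_that("BayesC is seed-deterministic and pins pi near 0.01", {
  panel <- random_panel(100, 300, seed = 30)
  set.seed(31)
  y <- stats::setNames(rnorm(100), panel$sample_ids)
  ch <- chain_config(2000, 500, 10, seed = 99)
  f1 <- fit_bayesC(y, panel, chain = ch)
  f2 <- fit_bayesC(y, panel, chain = ch)
  expect_identical(f1$effects, f2$effects)
  expect_identical(f1$chains$var_e, f2$chains$var_e)
  expect_lt(abs(mean(f1$chains$pi) - 0.0099), 0.001)
})

test_that("BayesC finds a planted large-effect QTL and ignores noise", {
  pop <- shared_pop()
  panel <- pop$panel
  n <- nrow(panel$dosage)
  # null response: posterior effects shrink to near zero
  set.seed(32)
  y0 <- stats::setNames(rnorm(n), panel$sample_ids)
  ch <- chain_config(reduced = TRUE, seed = 44)
  f0 <- fit_bayesC(y0, panel, chain = ch, var_g = 0.5, var_e = 0.5)
  slab_sd <- sqrt(0.5 / (0.0099 *
                           sum(2 * f0$freqs * (1 - f0$freqs))))
  expect_lt(mean(abs(f0$effects)), 0.1 * slab_sd)
  expect_lt(var(f0$dgv), 0.1 * var(y0))
  # single huge QTL explaining half the variance
  tr <- simulate_trait(panel, 1, genetic_var = 1, seed = 33)
  set.seed(34)
  y1 <- stats::setNames(tr$tbv + rnorm(n, sd = 1), panel$sample_ids)
  f1 <- fit_bayesC(y1, panel, chain = ch, var_g = 1, var_e = 1)
  # the QTL (or a near-perfect LD neighbour) is included almost always
  hit <- max(f1$inclusion_freq[seq.int(max(1, tr$qtl_indices - 2),
                                       min(length(f1$effects),
                                           tr$qtl_indices + 2))])
  expect_gt(hit, 0.9)
})

test_that("BayesC with pi pinned at 1 reproduces GBLUP", {
  panel <- random_panel(200, 1000, seed = 35)
  tr <- simulate_trait(panel, 100, genetic_var = 1, seed = 35)
  set.seed(36)
  y <- stats::setNames(tr$tbv + rnorm(200, sd = sqrt(7 / 3)),
                       panel$sample_ids)
  ch <- chain_config(reduced = TRUE, seed = 37)
  fc <- fit_bayesC(y, panel, chain = ch, var_g = 1, var_e = 7 / 3,
                   pi_alpha = 1e10, pi_beta = 1)
  G <- build_G(panel)
  fg <- fit_gblup(y, G, var_ratio = 7 / 3)
  expect_gt(cor(fc$dgv, fg$gebv), 0.98)
})

test_that("BayesC and BLASSO approximate the same conditional mean", {
  # polygenic architecture; pi scaled with panel density so the
  # expected number of included markers matches the QTL dimension
  # (the production prior's pi*m is far above n; a fixed 0.01 at
  # reduced marker counts would not be)
  pop <- shared_pop()
  panel <- pop$panel
  tr <- cached("trait_default",
               simulate_trait(panel, 100, genetic_var = 1, seed = 3))
  n <- nrow(panel$dosage)
  set.seed(38)
  y <- stats::setNames(tr$tbv + rnorm(n, sd = sqrt(7 / 3)),
                       panel$sample_ids)
  ch <- chain_config(reduced = TRUE, seed = 39)
  fc <- fit_bayesC(y, panel, chain = ch, var_g = 1, var_e = 7 / 3,
                   pi_alpha = 1e9)           # prior pi ~ 0.09
  fb <- fit_blasso(y, panel, chain = ch, var_e = 7 / 3)
  expect_gt(cor(fc$dgv, fb$dgv), 0.95)
  # both engines recover genuine signal
  expect_gt(cor(fc$dgv, tr$tbv), 0.5)
  expect_gt(cor(fb$dgv, tr$tbv), 0.5)
})

test_that("BayesC recovers the residual variance on model-true data", {
  set.seed(40)
  n <- 500; m <- 2000
  panel <- random_panel(n, m, seed = 40)
  W <- centered_dosages(panel)
  pi_true <- 0.01
  nz <- which(runif(m) < pi_true)
  sig2a <- 0.01
  a <- rnorm(length(nz), 0, sqrt(sig2a))
  g <- as.numeric(W[, nz, drop = FALSE] %*% a)
  sig2e <- 1
  y <- stats::setNames(g + rnorm(n, 0, sqrt(sig2e)), panel$sample_ids)
  ch <- chain_config(reduced = TRUE, seed = 41)
  fit <- fit_bayesC(y, panel, chain = ch, var_g = var(g),
                    var_e = sig2e)
  post_ve <- mean(fit$chains$var_e)
  expect_lt(abs(post_ve - sig2e) / sig2e, 0.2)
})

test_that("BLASSO shrinks everything when lambda is forced large", {
  panel <- random_panel(80, 200, seed = 42)
  set.seed(43)
  y <- stats::setNames(rnorm(80, sd = 2), panel$sample_ids)
  ch <- chain_config(2000, 500, 10, seed = 44)
  # gamma prior concentrated at huge lambda^2
  f <- fit_blasso(y, panel, chain = ch, lambda_shape = 1e6,
                  lambda_rate = 1e-2)
  ols_scale <- sd(y) / sd(centered_dosages(panel)[, 1])
  expect_lt(max(abs(f$effects)), 0.01 * ols_scale)
})

test_that("DGV from effects is a consistent linear score", {
  panel <- random_panel(50, 120, seed = 45)
  freqs <- allele_frequencies(panel)
  eff <- stats::setNames(rep(0, 120), panel$marker_ids)
  expect_equal(unname(dgv_from_effects(eff, panel, freqs)),
               rep(0, 50))
  # worked 2-marker example: effects (0.5, -1.0), centered dosages
  # (1, 0.5) -> DGV = 0.5*1 - 1*0.5 = 0
  expect_equal(0.5 * 1 + (-1.0) * 0.5, 0)
  # duplicating a training animal duplicates its genetic term
  set.seed(46)
  eff2 <- stats::setNames(rnorm(120, sd = 0.1), panel$marker_ids)
  d1 <- dgv_from_effects(eff2, panel, freqs)
  dup <- subset_samples(panel, c(1, 1))
  dup$sample_ids <- c("S01", "copy")
  rownames(dup$dosage) <- dup$sample_ids
  d2 <- dgv_from_effects(eff2, dup, freqs)
  expect_equal(unname(d2["copy"]), unname(d1["S01"]))
  # mismatched marker sets are refused
  expect_error(dgv_from_effects(eff2[-1], panel, freqs), "marker sets")
})

test_that("effective sample size diagnostics behave at the extremes", {
  panel <- random_panel(60, 100, seed = 47)
  set.seed(48)
  y <- stats::setNames(rnorm(60), panel$sample_ids)
  f <- fit_bayesC(y, panel, chain = chain_config(2000, 500, 10,
                                                 seed = 49))
  di <- chain_diagnostics(f)
  expect_true(all(c("var_a", "var_e", "pi", "mu") %in% di$parameter))
  expect_true(all(di$ess >= 1))
  # iid chain: ESS near length; constant chain: full length by
  # convention, perfectly autocorrelated ramp: ESS collapses
  f_iid <- f
  set.seed(50)
  f_iid$chains <- list(var_e = rnorm(150))
  expect_gt(chain_diagnostics(f_iid)$ess, 100)
  f_ramp <- f
  f_ramp$chains <- list(var_e = seq_len(150))
  expect_warning(d_ramp <- chain_diagnostics(f_ramp), "low effective")
  expect_lt(d_ramp$ess, 20)
})
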