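#' Effective number of chromosome segments
#'
#' Me = 2 Ne L / ln(4 Ne L), the classical approximation from
#' effective population size Ne and genome length L in Morgans. It is
#' the effective number of independently segregating genome segments
#' that genomic prediction has to estimate.
#'
#' @param Ne effective population size.
#' @param L genome length in Morgans.
#' @return Me (scalar).
#' @export
effective_segments <- function(Ne, L) {
  if (Ne <= 0 || L <= 0) stop("Ne and L must be positive")
  if (4 * Ne * L <= 1) stop("4*Ne*L must exceed 1")
  2 * Ne * L / log(4 * Ne * L)
}

#' Expected accuracy of genomic prediction
#'
#' The deterministic expectation for an animal without own phenotype
#' and without close relatives in the training set:
#' sqrt(q) * sqrt(N h2 / (N h2 + Me)), with N the training-set size,
#' h2 the heritability of the pseudo-phenotypes and Me the effective
#' number of chromosome segments. The fraction q of genetic variance
#' captured by the markers enters as the multiplier sqrt(q)
#' (an upper bound on DGV accuracy); `q_placement` exposes the
#' alternative conventions for sensitivity analysis.
#'
#' @param N training-set size.
#' @param h2_pseudo heritability of the pseudo-phenotypes in
#'   \[0, 1\].
#' @param Me effective chromosome segments (see
#'   [effective_segments()]).
#' @param q fraction of genetic variance captured by markers; default
#'   0.8.
#' @param q_placement "outside" (default: sqrt(q) multiplier),
#'   "inside" (q scales N h2 inside the ratio) or "both".
#' @return Expected accuracy in \[0, 1\].
#' @export
daetwyler_accuracy <- function(N, h2_pseudo, Me, q = 0.8,
                               q_placement = c("outside", "inside",
                                               "both")) {
  q_placement <- match.arg(q_placement)
  stopifnot(N > 0, Me > 0, h2_pseudo >= 0, h2_pseudo <= 1,
            q >= 0, q <= 1)
  core <- function(nh2) sqrt(nh2 / (nh2 + Me))
  switch(q_placement,
         outside = sqrt(q) * core(N * h2_pseudo),
         inside = core(N * h2_pseudo * q),
         both = sqrt(q) * core(N * h2_pseudo * q))
}

#' Expected accuracies for a table of traits
#'
#' For each trait row the pseudo-phenotype heritability is taken as
#' the squared mean training accuracy (the mean training reliability
#' under the squared-mean convention), Me is computed from Ne and L,
#' and the expected accuracy is evaluated per trait. Rows missing N
#' or accuracy are skipped with a warning.
#'
#' @param trait_rows data.frame with columns `trait`, `n_train`, and
#'   `mean_acc_train` (mean training-set accuracy).
#' @param Ne effective population size; default 120.
#' @param L genome length in Morgans; default 30.
#' @param q marker-captured fraction of genetic variance; default
#'   0.8.
#' @param h2_convention "squared_mean_accuracy" (default) or
#'   "mean_reliability" — the latter needs a `mean_rel_train`
#'   column.
#' @param q_placement see [daetwyler_accuracy()].
#' @return list with `table` (per-trait expected accuracies), `mean`,
#'   `sd` and `Me`.
#' @export
expectation_table <- function(trait_rows, Ne = 120, L = 30, q = 0.8,
                              h2_convention = c("squared_mean_accuracy",
                                                "mean_reliability"),
                              q_placement = "outside") {
  h2_convention <- match.arg(h2_convention)
  if (nrow(trait_rows) < 1) stop("need at least one trait row")
  Me <- effective_segments(Ne, L)
  ok <- !is.na(trait_rows$n_train) & !is.na(trait_rows$mean_acc_train)
  if (any(!ok))
    warning(sum(!ok), " trait row(s) skipped: missing N or accuracy")
  rows <- trait_rows[ok, , drop = FALSE]
  h2p <- if (h2_convention == "squared_mean_accuracy")
    rows$mean_acc_train^2 else rows$mean_rel_train
  ea <- mapply(daetwyler_accuracy, N = rows$n_train, h2_pseudo = h2p,
               MoreArgs = list(Me = Me, q = q,
                               q_placement = q_placement))
  tab <- data.frame(trait = rows$trait, n_train = rows$n_train,
                    h2_pseudo = h2p, expected_accuracy = ea)
  list(table = tab, mean = mean(ea), sd = sd(ea), Me = Me)
}
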