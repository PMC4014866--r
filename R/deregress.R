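#' Deregress EBV into pseudo-phenotypes
#'
#' Converts estimated breeding values and their accuracies into
#' deregressed proofs (dEBV) suitable as pseudo-phenotypes for
#' whole-genome regression. The parent-average (PA) contribution is
#' removed by solving the two-component information system of the
#' standard PA-removal deregression: the PA reliability is formed from
#' the parents' reliabilities, effective record contributions are
#' derived for the PA and the individual, and the individual's own
#' information yields the dEBV and its reliability. Animals with both
#' parents unknown (or no parental accuracies supplied) use the
#' classical fallback dEBV = EBV / r-squared with reliability
#' r-squared.
#'
#' @param snapshot data.frame with columns `id`, `ebv`, `accuracy`
#'   (and optionally `trait`, `snapshot_year`).
#' @param parent_accuracies optional data.frame with columns `id`,
#'   `sire_accuracy`, `dam_accuracy` (NA = unknown parent).
#' @param h2 trait heritability in (0, 1).
#' @param accuracy_floor animals with accuracy at or below this are
#'   dropped (with a message); default 0, i.e. keep all positive.
#' @return data.frame with id, debv, reliability, weight
#'   (= (1 - reliability)/reliability) and a `fallback` flag marking
#'   animals deregressed without parental information.
#' @export
deregress <- function(snapshot, parent_accuracies = NULL, h2,
                      accuracy_floor = 0) {
  if (h2 <= 0 || h2 >= 1) stop("h2 must be in (0, 1)")
  if (any(snapshot$accuracy < 0 | snapshot$accuracy > 1))
    stop("accuracies must lie in [0, 1]")
  keep <- snapshot$accuracy > accuracy_floor & snapshot$accuracy < 1
  dropped <- snapshot$id[!keep]
  if (length(dropped))
    message(length(dropped),
            " animal(s) excluded from deregression (accuracy at floor or 1)")
  snap <- snapshot[keep, , drop = FALSE]
  lambda <- (1 - h2) / h2
  n <- nrow(snap)
  debv <- rel <- numeric(n)
  fallback <- logical(n)
  pa <- NULL
  if (!is.null(parent_accuracies))
    pa <- parent_accuracies[match(snap$id, parent_accuracies$id), ]
  for (i in seq_len(n)) {
    r2 <- snap$accuracy[i]^2
    r2s <- if (!is.null(pa)) pa$sire_accuracy[i]^2 else NA_real_
    r2d <- if (!is.null(pa)) pa$dam_accuracy[i]^2 else NA_real_
    if (is.na(r2s) && is.na(r2d)) {
      debv[i] <- snap$ebv[i] / r2
      rel[i] <- r2
      fallback[i] <- TRUE
      next
    }
    r2pa <- (ifelse(is.na(r2s), 0, r2s) + ifelse(is.na(r2d), 0, r2d)) / 4
    dr <- deregress_one(snap$ebv[i], r2, r2pa, lambda)
    debv[i] <- dr$debv
    rel[i] <- dr$reliability
  }
  bad <- rel <= 0
  if (any(bad)) {
    message(sum(bad), " animal(s) excluded: non-positive deregressed ",
            "reliability")
  }
  out <- data.frame(id = snap$id[!bad], debv = debv[!bad],
                    reliability = rel[!bad],
                    weight = (1 - rel[!bad]) / rel[!bad],
                    fallback = fallback[!bad],
                    stringsAsFactors = FALSE)
  if (!is.null(snap$trait)) out$trait <- snap$trait[!bad]
  out
}

# One animal's PA-removal deregression.
# Solves the 2x2 information system linking the parent-average and the
# individual EBV; returns own-information dEBV and its reliability.
deregress_one <- function(ebv, r2, r2pa, lambda) {
  r2pa <- min(r2pa, 0.4999)      # PA reliability cannot reach the 0.5 bound
  r2 <- max(r2, r2pa)            # individual knows at least its PA
  alpha <- 1 / (0.5 - r2pa)
  delta <- (0.5 - r2pa) / (1 - r2)
  ZpZ_pa <- lambda * (0.5 * alpha - 4) +
    0.5 * lambda * sqrt(alpha^2 + 16 / delta)
  ZpZ_i <- delta * ZpZ_pa + 2 * lambda * (2 * delta - 1)
  # the PA enters the individual's proof; with PA itself unobserved here
  # the own-information right-hand side reduces to:
  rel_i <- 1 - lambda / (ZpZ_i + lambda)
  if (ZpZ_i <= 0) return(list(debv = NA_real_, reliability = 0))
  pa_hat <- 0  # centered evaluation: PA expectation at the trait mean
  rhs_i <- -2 * lambda * pa_hat + (ZpZ_i + 2 * lambda) * ebv
  list(debv = rhs_i / ZpZ_i, reliability = rel_i)
}

#' Residual weight from a reliability
#'
#' The diagonal of the residual weight matrix for a deregressed proof:
#' R = (1 - r2) / r2, so information-rich records get small residual
#' variance.
#'
#' @param reliability reliability (squared accuracy) in (0, 1).
#' @return Numeric weight(s), strictly decreasing in reliability.
#' @export
residual_weight <- function(reliability) {
  if (any(reliability <= 0 | reliability >= 1))
    stop("reliability must be strictly inside (0, 1)")
  (1 - reliability) / reliability
}
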