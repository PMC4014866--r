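#' Current allele frequencies
#'
#' Frequency of the counted allele (allele 2) per marker from all
#' non-missing calls across every genotyped animal — "current"
#' frequencies, not reconstructed base-population ones.
#'
#' @param panel a [genotype_panel()].
#' @return Named numeric vector of frequencies in \[0, 1\].
#' @export
allele_frequencies <- function(panel) {
  ncall <- colSums(!is.na(panel$dosage))
  if (any(ncall == 0))
    stop("marker(s) with zero non-missing calls: ",
         paste(head(panel$marker_ids[ncall == 0], 5), collapse = ", "))
  p <- colMeans(panel$dosage, na.rm = TRUE) / 2
  names(p) <- panel$marker_ids
  p
}

#' Impute missing dosages
#'
#' `mode = "mean"` replaces missing calls with the population mean
#' dosage 2p for the marker. `mode = "pedigree"` uses the Mendelian
#' expectation — the mean of the available parents' dosages (parents'
#' own missing calls mean-imputed first) — falling back to 2p when no
#' parent is genotyped.
#'
#' @param panel a [genotype_panel()].
#' @param mode "mean" or "pedigree".
#' @param pedigree data.frame with columns id, sire, dam ("0" =
#'   unknown); required for pedigree mode.
#' @return Real-valued dosage matrix with no missing entries.
#' @export
impute_missing <- function(panel, mode = c("mean", "pedigree"),
                           pedigree = NULL) {
  mode <- match.arg(mode)
  X <- panel$dosage
  storage.mode(X) <- "double"
  p <- allele_frequencies(panel)
  mu <- 2 * p
  fill_mean <- function(M) {
    idx <- which(is.na(M), arr.ind = TRUE)
    if (nrow(idx)) M[idx] <- mu[idx[, 2]]
    M
  }
  if (mode == "mean") return(fill_mean(X))
  if (is.null(pedigree)) stop("pedigree mode needs a pedigree")
  Xm <- fill_mean(X)  # parental lookups use mean-completed dosages
  ped <- pedigree[match(panel$sample_ids, pedigree$id), ]
  for (i in seq_len(nrow(X))) {
    nas <- which(is.na(X[i, ]))
    if (!length(nas)) next
    par_rows <- match(c(ped$sire[i], ped$dam[i]), panel$sample_ids)
    par_rows <- par_rows[!is.na(par_rows)]
    if (length(par_rows)) {
      # expected offspring dosage = mean of available parents' dosages
      X[i, nas] <- colMeans(Xm[par_rows, nas, drop = FALSE])
    } else {
      X[i, nas] <- mu[nas]
    }
  }
  X
}

#' Genomic relationship matrix (VanRaden)
#'
#' G = MM'/sum(2 p (1 - p)) where M holds dosages centered by twice
#' the current allele frequency; missing calls are mean-imputed first,
#' so they contribute exactly zero after centering.
#'
#' @param panel a post-QC [genotype_panel()] with at least two
#'   polymorphic markers.
#' @return A `relationship_matrix` of kind "G" carrying the allele
#'   frequencies used.
#' @export
build_G <- function(panel) {
  p <- allele_frequencies(panel)
  denom <- sum(2 * p * (1 - p))
  if (denom <= 0) stop("all markers monomorphic: G scale undefined")
  M <- impute_missing(panel, "mean")
  M <- sweep(M, 2, 2 * p)
  G <- tcrossprod(M) / denom
  dimnames(G) <- list(panel$sample_ids, panel$sample_ids)
  structure(list(ids = panel$sample_ids, values = G, kind = "G",
                 allele_freqs = p),
            class = "relationship_matrix")
}

#' Pedigree numerator relationship matrix
#'
#' Computes A by the tabular (recursive) method over the full pedigree
#' — unknown parents are treated as unrelated, non-inbred founders —
#' and then restricts the result to the requested ids. Restriction
#' happens after recursion so relationships routed through
#' ungenotyped ancestors are preserved.
#'
#' @param pedigree data.frame with columns id, sire, dam ("0" or NA =
#'   unknown).
#' @param ids ids to retain (default: all pedigree members).
#' @return A `relationship_matrix` of kind "A".
#' @export
build_A <- function(pedigree, ids = pedigree$id) {
  ped <- data.frame(id = as.character(pedigree$id),
                    sire = as.character(pedigree$sire),
                    dam = as.character(pedigree$dam),
                    stringsAsFactors = FALSE)
  ped$sire[ped$sire %in% c("0", "", NA)] <- NA
  ped$dam[ped$dam %in% c("0", "", NA)] <- NA
  if (anyDuplicated(ped$id)) stop("duplicate ids in pedigree")
  ord <- pedigree_order(ped)
  ped <- ped[ord, ]
  n <- nrow(ped)
  A <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  si <- match(ped$sire, ped$id)
  di <- match(ped$dam, ped$id)
  for (i in seq_len(n)) {
    s <- si[i]; d <- di[i]
    if (!is.na(s) && !is.na(d)) {
      A[i, i] <- 1 + 0.5 * A[s, d]
    } else {
      A[i, i] <- 1
    }
    if (i > 1) {
      j <- seq_len(i - 1)
      aij <- numeric(i - 1)
      if (!is.na(s)) aij <- aij + 0.5 * A[j, s]
      if (!is.na(d)) aij <- aij + 0.5 * A[j, d]
      A[i, j] <- aij
      A[j, i] <- aij
    }
  }
  ids <- as.character(ids)
  missing_ids <- setdiff(ids, ped$id)
  if (length(missing_ids))
    stop("ids not in pedigree: ", paste(head(missing_ids, 5), collapse = ", "))
  A <- A[ids, ids, drop = FALSE]
  structure(list(ids = ids, values = A, kind = "A"),
            class = "relationship_matrix")
}

# topological order; errors on cycles naming one offending id
pedigree_order <- function(ped) {
  n <- nrow(ped)
  si <- match(ped$sire, ped$id)
  di <- match(ped$dam, ped$id)
  state <- integer(n)  # 0 unvisited, 1 in stack, 2 done
  ord <- integer(0)
  visit <- function(i) {
    stack <- list(c(i, 0L))
    while (length(stack)) {
      top <- stack[[length(stack)]]
      v <- top[1]
      if (state[v] == 2L) { stack[[length(stack)]] <- NULL; next }
      if (top[2] == 0L) {
        if (state[v] == 1L)
          stop("pedigree cycle involving id '", ped$id[v], "'")
        state[v] <<- 1L
        stack[[length(stack)]][2] <- 1L
        for (pp in c(si[v], di[v])) {
          if (!is.na(pp) && state[pp] != 2L) {
            if (state[pp] == 1L)
              stop("pedigree cycle involving id '", ped$id[pp], "'")
            stack[[length(stack) + 1]] <- c(pp, 0L)
          }
        }
      } else {
        state[v] <<- 2L
        ord <<- c(ord, v)
        stack[[length(stack)]] <- NULL
      }
    }
  }
  for (i in seq_len(n)) if (state[i] == 0L) visit(i)
  ord
}

#' Blend genomic and pedigree relationships
#'
#' G* = (1 - w) G + w A on a shared id ordering. Blending in a
#' fraction of A is equivalent to fitting a residual polygenic effect
#' not captured by the markers; w = 0 is pure GBLUP, w = 0.20 the
#' usual polygenic-blend setting.
#'
#' @param G,A `relationship_matrix` objects over the same ids.
#' @param w pedigree weight in \[0, 1\].
#' @return A `relationship_matrix` of kind "G_star" recording `w`.
#' @export
combine_G_star <- function(G, A, w) {
  if (w < 0 || w > 1) stop("w must be in [0, 1]")
  if (!identical(G$ids, A$ids)) stop("G and A must share the same id order")
  V <- (1 - w) * G$values + w * A$values
  structure(list(ids = G$ids, values = V, kind = "G_star",
                 blend_weight = w, allele_freqs = G$allele_freqs),
            class = "relationship_matrix")
}

#' @export
print.relationship_matrix <- function(x, ...) {
  cat(sprintf("relationship_matrix [%s]: %d animals", x$kind,
              length(x$ids)))
  if (!is.null(x$blend_weight)) cat(sprintf(", w = %.2f", x$blend_weight))
  cat(sprintf("; mean diag = %.3f\n", mean(diag(x$values))))
  invisible(x)
}

#' Relatedness of test animals to a training set
#'
#' For each test animal: the maximum genomic relationship to any
#' training animal (maxr) and the mean of the K largest relationships
#' (aveK) for K in 5, 10, 20, 50. When fewer than K training animals
#' exist, all are averaged and the row is flagged.
#'
#' @param rel a `relationship_matrix` (G or G*).
#' @param train_ids,test_ids disjoint id sets present in `rel`.
#' @return data.frame with id, maxr, ave5, ave10, ave20, ave50 and a
#'   logical `short_set` flag.
#' @export
relatedness_stats <- function(rel, train_ids, test_ids) {
  if (!length(train_ids)) stop("empty training set")
  if (length(intersect(train_ids, test_ids)))
    stop("train and test ids overlap")
  V <- rel$values
  ks <- c(5, 10, 20, 50)
  out <- lapply(test_ids, function(id) {
    r <- sort(V[id, train_ids], decreasing = TRUE)
    aves <- vapply(ks, function(k) mean(r[seq_len(min(k, length(r)))]),
                   numeric(1))
    c(maxr = r[1], stats::setNames(aves, paste0("ave", ks)))
  })
  res <- as.data.frame(do.call(rbind, out))
  res <- cbind(id = as.character(test_ids), res,
               short_set = length(train_ids) < max(ks))
  rownames(res) <- NULL
  res
}

#' Principal-component screen for population substructure
#'
#' Eigendecomposition of the double-centered genomic relationship
#' matrix; animals are assigned to two groups by 2-means on the first
#' component. If the leading eigenvalue explains less than
#' `min_share` of the total, the population is flagged as
#' unstructured and the labels should not be over-interpreted.
#'
#' @param G a `relationship_matrix` of kind "G".
#' @param k number of components to return (default 2).
#' @param min_share leading-eigenvalue share below which the
#'   "no structure" flag is raised; default 0.05.
#' @return list with `scores` (n x k), `eig_share`, `labels` (1/2) and
#'   `structured` flag.
#' @export
pca_subgroups <- function(G, k = 2, min_share = 0.05) {
  V <- G$values
  if (any(!is.finite(V))) stop("non-finite entries in G")
  n <- nrow(V)
  J <- diag(n) - matrix(1 / n, n, n)
  Vc <- J %*% V %*% J
  e <- eigen(Vc, symmetric = TRUE)
  scores <- e$vectors[, seq_len(k), drop = FALSE] %*%
    diag(sqrt(pmax(e$values[seq_len(k)], 0)), k)
  rownames(scores) <- G$ids
  share <- e$values[1] / sum(pmax(e$values, 0))
  km <- kmeans(scores[, 1], centers = 2, nstart = 10)
  list(scores = scores, eig_share = share,
       labels = km$cluster, structured = share >= min_share)
}

#' Write / read a relationship matrix as TSV
#'
#' Tab-separated with the animal ids as header and first column;
#' kind and blend weight stored on comment lines so a round trip
#' restores the object.
#'
#' @param rel a `relationship_matrix`.
#' @param path output file.
#' @return `write_relmatrix()`: the path, invisibly;
#'   `read_relmatrix()`: a `relationship_matrix`.
#' @export
write_relmatrix <- function(rel, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# kind=%s", rel$kind), con)
  if (!is.null(rel$blend_weight))
    writeLines(sprintf("# blend_weight=%.10g", rel$blend_weight), con)
  writeLines(paste(c("id", rel$ids), collapse = "\t"), con)
  for (i in seq_along(rel$ids))
    writeLines(paste(c(rel$ids[i],
                       formatC(rel$values[i, ], format = "g",
                               digits = 12)),
                     collapse = "\t"), con)
  invisible(path)
}

#' @rdname write_relmatrix
#' @param path file written by [write_relmatrix()].
#' @export
read_relmatrix <- function(path) {
  hdr <- readLines(path, n = 3)
  kind <- sub("^# kind=", "", hdr[grepl("^# kind=", hdr)])
  wline <- hdr[grepl("^# blend_weight=", hdr)]
  w <- if (length(wline)) as.numeric(sub("^# blend_weight=", "",
                                         wline)) else NULL
  tab <- data.table::fread(path, skip = length(kind) + length(wline),
                           header = TRUE)
  ids <- as.character(tab[[1]])
  V <- as.matrix(tab[, -1, with = FALSE])
  dimnames(V) <- list(ids, ids)
  structure(list(ids = ids, values = V,
                 kind = if (length(kind)) kind else "G",
                 blend_weight = w),
            class = "relationship_matrix")
}
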