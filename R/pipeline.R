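#' Run the full genomic-prediction pipeline from a configuration
#'
#' Executes QC, relationship-matrix construction, deregression, the
#' requested prediction engines under the requested validation
#' designs, and the expected-accuracy calculation, writing
#' tab-separated reports and a JSON manifest (config hash, seeds,
#' package version) to the output directory.
#'
#' The configuration is a nested list (typically loaded from YAML
#' with [read_run_config()]) with elements:
#' \describe{
#'   \item{paths}{`genotypes` (ped or vcf), `pedigree` (CSV),
#'     `traits` (CSV with both snapshot years).}
#'   \item{h2}{named list mapping every trait label to its
#'     heritability.}
#'   \item{engines}{character subset of `gblup0`, `gblup20`,
#'     `bayesc`, `blasso`.}
#'   \item{designs}{character subset of `forward`, `rand`, `dist`.}
#'   \item{qc}{optional threshold overrides (gc_min, cr_min, maf_min,
#'     hwe_p_min, ld_window, ld_r2_max, sample_cr_min).}
#'   \item{accuracy_threshold}{forward-split cutoff, default 0.50.}
#'   \item{chain}{optional chain settings (n_iter, burn_in, thin,
#'     reduced).}
#'   \item{expectation}{optional Ne, L, q.}
#'   \item{seed}{master seed.}
#'   \item{out_dir}{output directory.}
#' }
#'
#' @param config configuration list (see Details) or a YAML path.
#' @return Invisibly, a list with the QC report, the validation
#'   report (one row per trait x engine x design), the expectation
#'   table and the manifest.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  cfg <- validate_run_config(config)
  out_dir <- cfg$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  msg <- function(...) message(sprintf(...))
  msg("[1/5] reading inputs")
  panel <- read_genotypes(cfg$paths$genotypes)
  pedigree <- read_pedigree(cfg$paths$pedigree)
  traits <- read_traits(cfg$paths$traits)
  trait_names <- unique(traits$trait)
  missing_h2 <- setdiff(trait_names, names(cfg$h2))
  if (length(missing_h2))
    stop("missing h2 for trait(s): ", paste(missing_h2, collapse = ", "))

  msg("[2/5] quality control")
  qc <- do.call(iterate_qc, c(list(panel), cfg$qc))
  panel <- qc$panel

  msg("[3/5] relationship matrices")
  G <- build_G(panel)
  A <- build_A(pedigree, panel$sample_ids)
  write_relmatrix(G, file.path(out_dir, "G.tsv"))

  years <- sort(unique(traits$snapshot_year))
  if (length(years) < 2) stop("need two snapshot years in traits file")
  rows <- list(); i <- 0
  msg("[4/5] engines x designs")
  for (tr in trait_names) {
    h2 <- cfg$h2[[tr]]
    var_ratio <- (1 - h2) / h2
    snap_e <- traits[traits$trait == tr &
                       traits$snapshot_year == years[1], ]
    snap_l <- traits[traits$trait == tr &
                       traits$snapshot_year == years[2], ]
    keep <- function(s) s[s$id %in% panel$sample_ids, ]
    snap_e <- keep(snap_e); snap_l <- keep(snap_l)
    debv_e <- deregress(snap_e, h2 = h2)
    debv_l <- deregress(snap_l, h2 = h2)
    engines <- list()
    for (eng in cfg$engines) {
      engines[[eng]] <- switch(
        eng,
        gblup0 = engine_gblup(panel, var_ratio, w = 0),
        gblup20 = engine_gblup(panel, var_ratio, w = 0.20,
                               pedigree = pedigree),
        bayesc = engine_bayes(panel, "bayesc", chain = cfg$chain),
        blasso = engine_bayes(panel, "blasso", chain = cfg$chain),
        stop("unknown engine: ", eng))
    }
    for (des in cfg$designs) {
      if (des == "forward") {
        plan <- forward_split(snap_e, snap_l, cfg$accuracy_threshold)
        # training proofs come from the early snapshot; validation
        # proofs from the late one — assemble a mixed dEBV table
        debv <- rbind(
          debv_e[debv_e$id %in% plan$folds[[1]]$train, ],
          debv_l[debv_l$id %in% plan$folds[[1]]$test, ])
      } else {
        plan <- switch(des,
                       rand = random_folds(debv_l$id, k = cfg$k,
                                           seed = cfg$seed),
                       dist = kmeans_folds(G, k = cfg$k,
                                           seed = cfg$seed),
                       stop("unknown design: ", des))
        debv <- debv_l
      }
      rep_i <- run_design(plan, engines, debv, G = G)
      rep_i$trait <- tr
      i <- i + 1
      rows[[i]] <- rep_i
    }
  }
  report <- do.call(rbind, lapply(rows, as.data.frame))

  msg("[5/5] expected accuracies")
  trait_rows <- do.call(rbind, lapply(trait_names, function(tr) {
    snap_e <- traits[traits$trait == tr &
                       traits$snapshot_year == years[1], ]
    tr_set <- snap_e[snap_e$accuracy > cfg$accuracy_threshold, ]
    data.frame(trait = tr, n_train = nrow(tr_set),
               mean_acc_train = mean(tr_set$accuracy))
  }))
  expect <- expectation_table(trait_rows, Ne = cfg$expectation$Ne,
                              L = cfg$expectation$L,
                              q = cfg$expectation$q)

  manifest <- list(package_version =
                     as.character(utils::packageVersion("indicusGP")),
                   seed = cfg$seed,
                   config_hash = config_hash(cfg),
                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  write_tsv <- function(df, name)
    utils::write.table(format(df, digits = 6),
                       file.path(out_dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  write_tsv(report, "validation_report.tsv")
  write_tsv(expect$table, "expected_accuracies.tsv")
  qcr <- qc$report
  jsonlite::write_json(
    list(rounds = qcr$rounds, removed = as.list(qcr$removed_by_rule),
         retained_samples = qcr$retained_samples,
         retained_markers = qcr$retained_markers),
    file.path(out_dir, "qc_report.json"), auto_unbox = TRUE)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE)
  invisible(list(qc_report = qc$report, report = report,
                 expectation = expect, manifest = manifest))
}

#' Load a pipeline configuration from YAML
#' @param path YAML file.
#' @return Configuration list for [run_pipeline()].
#' @export
read_run_config <- function(path) yaml::read_yaml(path)

validate_run_config <- function(cfg) {
  stopifnot(is.list(cfg), !is.null(cfg$paths), !is.null(cfg$h2))
  for (p in unlist(cfg$paths))
    if (!file.exists(p)) stop("input not found: ", p)
  cfg$engines <- cfg$engines %||% c("gblup0")
  cfg$designs <- cfg$designs %||% "forward"
  cfg$qc <- cfg$qc %||% list()
  cfg$accuracy_threshold <- cfg$accuracy_threshold %||% 0.50
  cfg$k <- cfg$k %||% 5
  cfg$seed <- cfg$seed %||% 1
  ch <- cfg$chain %||% list(reduced = TRUE)
  cfg$chain <- do.call(chain_config,
                       c(ch, list(seed = cfg$seed)[!("seed" %in%
                                                       names(ch))]))
  ex <- cfg$expectation %||% list()
  cfg$expectation <- list(Ne = ex$Ne %||% 120, L = ex$L %||% 30,
                          q = ex$q %||% 0.8)
  cfg$out_dir <- cfg$out_dir %||% "pipeline_out"
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# order-independent hash of the semantic config fields
config_hash <- function(cfg) {
  semantic <- cfg[sort(intersect(names(cfg),
                                 c("paths", "h2", "engines", "designs",
                                   "qc", "accuracy_threshold", "k",
                                   "seed", "chain", "expectation")))]
  if (!is.null(semantic$chain)) semantic$chain <- unclass(semantic$chain)
  js <- jsonlite::toJSON(semantic, auto_unbox = TRUE, digits = 12)
  # polynomial rolling hash over the serialized config; stable across
  # sessions and platforms
  bytes <- utf8ToInt(as.character(js))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}
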