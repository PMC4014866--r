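# Shared fixtures, built in code. Expensive simulations are cached in
# a session-level environment so several test files can reuse them.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, force(expr), envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

# small deterministic panel from an explicit dosage matrix
make_panel <- function(dosage, chrom = NULL, pos = NULL, quality = NULL) {
  n <- nrow(dosage); m <- ncol(dosage)
  genotype_panel(dosage,
                 sample_ids = sprintf("S%02d", seq_len(n)),
                 marker_ids = sprintf("M%02d", seq_len(m)),
                 chrom = chrom %||% rep("1", m),
                 pos_bp = pos %||% (1000L * seq_len(m)),
                 call_quality = quality)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# random unlinked panel in Hardy-Weinberg proportions
random_panel <- function(n, m, seed, maf_range = c(0.05, 0.5)) {
  set.seed(seed)
  p <- runif(m, maf_range[1], maf_range[2])
  dos <- matrix(rbinom(n * m, 2, rep(p, each = n)), n, m)
  make_panel(dos)
}

# The QC acceptance fixture: 20 samples x 50 markers with planted
# violations and hand-computed expected outcomes.
#  - markers 1-40: clean; fixed distinct permutations of
#    (0 x5, 1 x10, 2 x5)  -> perfect HWE, MAF 0.5, complete
#  - markers 41, 42: duplicated map position -> both removed
#  - marker 43: monomorphic -> MAF rule
#  - marker 44: all heterozygous -> HWE chi-square 20, p 7.7e-6
#  - marker 45: exact copy of marker 1 -> LD prune drops the later one
#  - markers 46, 47: one call each at quality 0.50 -> masked by the
#    quality filter, then call rate 19/20 = 0.95 fails CR > 0.98
#  - markers 48-50: one raw missing call each (sample 20) -> CR rule;
#    sample 20 afterwards has no missing calls among survivors, so no
#    sample is removed (the sample rule applies to the current panel)
# Expected: 40 markers and 20 samples survive, round 2 removes nothing.
qc_fixture <- function() {
  n <- 20
  base <- c(rep(0L, 5), rep(1L, 10), rep(2L, 5))
  set.seed(4242)
  cols <- list()
  seen <- character(0)
  while (length(cols) < 40) {
    cand <- sample(base)
    key <- paste(cand, collapse = "")
    if (key %in% seen) next
    seen <- c(seen, key)
    cols[[length(cols) + 1]] <- cand
  }
  d <- do.call(cbind, cols)
  d <- cbind(d,
             sample(base), sample(base),     # 41, 42: duplicate position
             rep(0L, n),                     # 43: monomorphic
             rep(1L, n),                     # 44: all heterozygous
             d[, 1],                         # 45: copy of marker 1
             sample(base), sample(base),     # 46, 47: low-quality call
             sample(base), sample(base), sample(base))  # 48-50
  d[20, 48:50] <- NA                         # raw missingness
  pos <- 1000L * 1:50
  pos[42] <- pos[41]
  qual <- matrix(1, n, 50)
  qual[1, 46] <- 0.5
  qual[2, 47] <- 0.5
  # distinct permutations of the same multiset can still collide in
  # correlation only if identical, which the loop above excludes
  make_panel(d, pos = pos, quality = qual)
}

# multi-generation population reused by several test files
shared_pop <- function() cached("pop_default", {
  simulate_population(simulation_config(n_markers = 2000, seed = 3))
})

shared_pop_subgroups <- function() cached("pop_subgroups", {
  simulate_population(simulation_config(n_markers = 2000,
                                        subgroup_split = 0.5,
                                        seed = 21))
})
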