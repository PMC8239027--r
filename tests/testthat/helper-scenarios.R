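# Shared simulated scenarios, built lazily and memoised across test files.

.scn_cache <- new.env(parent = emptyenv())

get_scn <- function(name) {
  if (!is.null(.scn_cache[[name]])) return(.scn_cache[[name]])
  scn <- switch(
    name,
    # gap-filling focus: one chromosome, no structural events
    gapfill = simulate_scenario(sim_config(
      seed = 5, n_chromosomes = 1, chromosome_length = 3e5,
      base_n_fragments = 5, n_misjoins = 0,
      bac_insert_mean = 40000, bac_insert_sd = 6000, bac_n_pairs = 500)),
    # two misplaced fragments across two chromosomes
    misjoin = simulate_scenario(sim_config(
      seed = 7, n_chromosomes = 2, chromosome_length = 5e5,
      base_n_fragments = 6, n_misjoins = 2,
      bac_insert_mean = 60000, bac_insert_sd = 10000, bac_n_pairs = 800)),
    # two inverted fragments
    inversion = simulate_scenario(sim_config(
      seed = 11, n_chromosomes = 2, chromosome_length = 5e5,
      base_n_fragments = 5, n_misjoins = 0, n_inversions = 2,
      bac_insert_mean = 50000, bac_insert_sd = 8000, bac_n_pairs = 400)),
    # one chromosome split into two scaffolds (merge evidence)
    brk = simulate_scenario(sim_config(
      seed = 18, n_chromosomes = 1, chromosome_length = 6e5,
      base_n_fragments = 6, n_misjoins = 0, n_scaffold_breaks = 1,
      bac_insert_mean = 50000, bac_insert_sd = 8000, bac_n_pairs = 400)),
    stop("unknown scenario ", name))
  .scn_cache[[name]] <- scn
  scn
}

get_recon <- function(name, seed = 1L, ...) {
  key <- paste0("rec_", name, "_", seed)
  if (!is.null(.scn_cache[[key]])) return(.scn_cache[[key]])
  scn <- get_scn(name)
  rec <- reconcile_assemblies(scn$base, scn$alternates, seed = seed, ...)
  .scn_cache[[key]] <- rec
  rec
}

# liftover of a truth genome onto itself (identity)
truth_self_liftover <- function(truth) {
  lens <- nchar(unclass(truth))
  tibble::tibble(seq_id = names(truth), seg_start = 0, seg_end = lens,
                 truth_chrom = names(truth), truth_start = 0,
                 truth_end = lens, strand = "+")
}

hybrid_liftover <- function(rec, scn) {
  compose_liftover(rec$plan, c(list(.base = scn$truth_record$liftover),
                               scn$alt_liftovers))
}

# brute-force NX: walk the sorted lengths until X% of the total is covered
nx_bruteforce <- function(lengths, X) {
  s <- sort(lengths, decreasing = TRUE)
  tot <- sum(s)
  vapply(X, function(x) {
    need <- x / 100 * tot
    acc <- 0
    for (l in s) {
      acc <- acc + l
      if (acc >= need) return(l)
    }
    s[length(s)]
  }, numeric(1))
}

# exact chain DP over all anchor pairs (no lookback cap): reference for the
# banded C++ chainer
chain_bruteforce <- function(x, y, k, gap_limit, diag_limit,
                             diag_penalty = 0.01) {
  o <- order(x, y)
  x <- x[o]; y <- y[o]
  n <- length(x)
  f <- rep(as.numeric(k), n)
  for (i in seq_len(n)) {
    for (j in seq_len(i - 1L)) {
      dx <- x[i] - x[j]; dy <- y[i] - y[j]
      if (dx <= 0 || dy <= 0) next
      if (dx - k > gap_limit || dy - k > gap_limit) next
      if (abs(dx - dy) > diag_limit) next
      cand <- f[j] + min(k, dx, dy) - diag_penalty * abs(dx - dy)
      if (cand > f[i]) f[i] <- cand
    }
  }
  max(f)
}

rand_seq <- function(n, seed = NULL) {
  gen <- function() paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                          collapse = "")
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

write_tmp_fasta <- function(seqs, dir = tempdir()) {
  path <- tempfile(tmpdir = dir, fileext = ".fasta")
  con <- file(path, "w")
  for (nm in names(seqs)) {
    writeLines(paste0(">", nm), con)
    writeLines(substring(seqs[[nm]],
                         seq(1, nchar(seqs[[nm]]), 60),
                         pmin(seq(60, nchar(seqs[[nm]]) + 59, 60),
                              nchar(seqs[[nm]]))), con)
  }
  close(con)
  path
}

# standard study-scale scenario + its reconciliation, memoised per seed
get_standard <- function(seed) {
  key <- paste0("std_", seed)
  if (!is.null(.scn_cache[[key]])) return(.scn_cache[[key]])
  scn <- simulate_scenario(standard_scenario_config(seed))
  rec <- reconcile_assemblies(scn$base, scn$alternates, seed = seed)
  out <- list(scn = scn, rec = rec)
  .scn_cache[[key]] <- out
  out
}
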