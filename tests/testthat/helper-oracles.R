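# Shared fixtures and independent oracles used across the test files.

# deterministic random DNA
rand_dna <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Brute-force semi-global primer-match oracle: best edit distance of `primer`
# against any substring of `read` with length within `primer +/- max_ed`,
# via utils::adist (Levenshtein). Returns the minimal edit distance (Inf if
# none <= max_ed) -- independent of the package's own C++ scanner.
adist_scan_oracle <- function(read, primer, max_ed) {
  m <- nchar(primer)
  n <- nchar(read)
  best <- Inf
  for (w in (m - max_ed):(m + max_ed)) {
    if (w < 1 || w > n) next
    starts <- seq_len(n - w + 1)
    subs <- substring(read, starts, starts + w - 1)
    d <- utils::adist(primer, subs)
    best <- min(best, min(d))
  }
  best
}

# Mutate a sequence with a fixed number of substitutions at given positions
substitute_at <- function(seq, pos, seed = 1) {
  set.seed(seed)
  x <- strsplit(seq, "")[[1]]
  for (p in pos) {
    x[p] <- sample(setdiff(c("A", "C", "G", "T"), x[p]), 1)
  }
  paste(x, collapse = "")
}

# A small default-architecture reference set shared by several files
small_ref <- function(n_taxa = 10, seed = 420) {
  generate_reference_set(n_taxa, 0.15, operon_model(), seed)
}

# Error-free, junk-free reads of one taxon, forced to plus orientation
clean_reads <- function(ref, taxon, n, seed = 5) {
  prof <- structure(setNames(1, taxon), class = "community_profile")
  sim <- simulate_reads(prof, ref, n, error_model(0, 0, 0), seed,
                        junk_fraction = 0, read_prefix = "clean")
  flip <- sim$truth$orientation == "-"
  sim$reads$seq[flip] <- vapply(sim$reads$seq[flip], revcomp, "")
  sim$reads
}

# Noisy plus-oriented reads of one taxon at the default 12% error model
noisy_reads <- function(ref, taxon, n, seed) {
  prof <- structure(setNames(1, taxon), class = "community_profile")
  sim <- simulate_reads(prof, ref, n, error_model(), seed,
                        junk_fraction = 0, read_prefix = paste0("nz", seed))
  flip <- sim$truth$orientation == "-"
  sim$reads$seq[flip] <- vapply(sim$reads$seq[flip], revcomp, "")
  sim$reads
}
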