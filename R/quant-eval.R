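# Evaluation layer: two-end-member mixture linear-response regression,
# rarefaction with its hypergeometric closed form, error-injection
# classification sensitivity, and replicate-consensus reproducibility.

#' Two-end-member mixture design
#'
#' @param fractions end-member-A input fractions; default the six ratios
#'   0/10/20/50/75/100 percent.
#' @param replicates replicates per ratio (default quadruplicate).
#' @return data.frame: sample_id, fraction_a, replicate.
#' @export
mixture_design <- function(fractions = c(0, 0.1, 0.2, 0.5, 0.75, 1),
                           replicates = 4) {
  if (length(unique(fractions)) < 3)
    stop("need at least 3 distinct fractions for regression")
  if (any(fractions < 0 | fractions > 1)) stop("fractions must be in [0, 1]")
  grid <- expand.grid(replicate = seq_len(replicates),
                      fraction_a = fractions)
  data.frame(sample_id = sprintf("mix%03d_rep%d",
                                 round(100 * grid$fraction_a),
                                 grid$replicate),
             fraction_a = grid$fraction_a, replicate = grid$replicate,
             stringsAsFactors = FALSE)
}

#' Linear response of one OTU's frequency to the input DNA fraction
#'
#' Ordinary least squares of normalized read frequency against the
#' end-member input percentage. The regressor polarity (fraction of A or of
#' B = 1 - A) is chosen by the sign of the covariance, so OTUs from either
#' end member regress against their own input axis; r-squared is unaffected
#' by the choice. By default the quadruplicate frequencies are averaged per
#' ratio before fitting, mirroring a mean-with-error-bars response plot;
#' `aggregate = FALSE` fits all individual samples.
#'
#' @param freqs normalized OTU x sample frequency matrix (see
#'   [normalize_otu_table]); columns must match `design$sample_id`.
#' @param design a [mixture_design].
#' @param otu_id OTU to regress.
#' @param aggregate average replicates per ratio before fitting.
#' @return data.frame: otu_id, slope, intercept, r_squared, n, polarity.
#' @export
mixture_regression <- function(freqs, design, otu_id, aggregate = TRUE) {
  if (!otu_id %in% rownames(freqs)) stop("OTU '", otu_id, "' not in table")
  idx <- match(design$sample_id, colnames(freqs))
  if (anyNA(idx)) stop("design samples missing from the frequency table")
  y <- as.numeric(freqs[otu_id, idx])
  x <- design$fraction_a
  present <- sum(y > 0)
  if (aggregate) {
    ym <- tapply(y, x, mean)
    x <- as.numeric(names(ym))
    y <- as.numeric(ym)
  }
  if (length(y) < 3) stop("need at least 3 data points")
  polarity <- if (cov(y, x) < 0) "B" else "A"
  xp <- if (polarity == "B") 100 * (1 - x) else 100 * x
  fit <- lm(y ~ xp)
  ssr <- sum((fitted(fit) - mean(y))^2)
  sst <- sum((y - mean(y))^2)
  data.frame(otu_id = otu_id, slope = unname(coef(fit)[2]),
             intercept = unname(coef(fit)[1]),
             r_squared = if (sst > 0) ssr / sst else 0,
             n = length(y), n_samples_present = present,
             polarity = polarity, stringsAsFactors = FALSE)
}

#' Regress the top-k OTUs of each end member against input fraction
#'
#' OTUs are ranked by their mean normalized frequency in the pure
#' end-member samples (fraction 1 for A, fraction 0 for B), k from each,
#' and each regressed with [mixture_regression]. OTUs whose maximum count
#' support is below `low_count_flag` reads are flagged as low-count (the
#' regime where linearity degrades).
#'
#' @param freqs normalized OTU x sample frequency matrix.
#' @param design a [mixture_design].
#' @param k OTUs per end member (default 4).
#' @param counts optional raw count matrix used for the low-count flag.
#' @param low_count_flag flag threshold (default 10 reads).
#' @param aggregate see [mixture_regression].
#' @return data.frame of regressions with `end_member` and `rank` columns.
#' @export
top_k_response <- function(freqs, design, k = 4, counts = NULL,
                           low_count_flag = 10, aggregate = TRUE) {
  idx <- match(design$sample_id, colnames(freqs))
  out <- list()
  for (em in c("A", "B")) {
    pure <- design$sample_id[design$fraction_a == (if (em == "A") 1 else 0)]
    if (!length(pure)) stop("design lacks pure end-member ", em, " samples")
    rank_freq <- rowMeans(freqs[, pure, drop = FALSE])
    top <- names(sort(rank_freq, decreasing = TRUE))[seq_len(min(k, nrow(freqs)))]
    for (r in seq_along(top)) {
      reg <- mixture_regression(freqs, design, top[r], aggregate)
      reg$end_member <- em
      reg$rank <- r
      reg$low_count <- if (!is.null(counts))
        max(counts[top[r], ]) < low_count_flag else NA
      out[[paste0(em, r)]] <- reg
    }
  }
  do.call(rbind, out)
}

#' Rarefaction curve with hypergeometric expectation
#'
#' Mean number of distinct OTUs observed in `n_resamples` random subsamples
#' (without replacement) at each depth, reported alongside the closed-form
#' expectation E[S(d)] = sum_i (1 - C(N - N_i, d) / C(N, d)).
#'
#' @param otu_ids vector of OTU assignments of the classified reads of one
#'   sample (one entry per read).
#' @param depths subsampling depths (each <= number of reads).
#' @param n_resamples resamples per depth.
#' @param seed integer seed.
#' @return data.frame: depth, mean_observed, expected.
#' @export
rarefaction_curve <- function(otu_ids, depths, n_resamples = 10, seed) {
  N <- length(otu_ids)
  if (any(depths > N)) stop("depth exceeds the number of classified reads")
  if (any(depths < 1)) stop("depths must be >= 1")
  set.seed(seed)
  counts <- table(otu_ids)
  expected <- vapply(depths, function(d) {
    sum(1 - exp(lchoose(N - counts, d) - lchoose(N, d)))
  }, 0)
  observed <- vapply(depths, function(d) {
    mean(vapply(seq_len(n_resamples), function(r)
      length(unique(sample(otu_ids, d))), 0))
  }, 0)
  data.frame(depth = depths, mean_observed = observed, expected = expected)
}

#' Classification sensitivity to injected sequence error
#'
#' For each identity level of a descending ladder, generates error-injected
#' copies (substitutions and indels 2:1:1 along the full length) of the
#' source 16S sequences, classifies every copy against the reference index,
#' and reports per-level assignment accuracy and the lowest level at which
#' every copy still maps to its source.
#'
#' @param ref a `reference_set`.
#' @param source_ids taxa whose 16S sequences are error-injected (default:
#'   three taxa spread over the set).
#' @param levels descending percent-identity levels (default 100 down to 76
#'   by 3).
#' @param n_per_level copies per level per source.
#' @param seed integer seed.
#' @param index optional prebuilt `seed_index` (defaults to indexing `ref`).
#' @param scoring a [scoring_scheme].
#' @return list: `table` (level, n, n_correct, accuracy, mean_realized),
#'   `min_perfect_identity`.
#' @export
sensitivity_run <- function(ref, source_ids = NULL,
                            levels = seq(100, 76, by = -3),
                            n_per_level = 20, seed,
                            index = NULL, scoring = scoring_scheme()) {
  if (is.unsorted(rev(levels), strictly = TRUE))
    stop("levels must be strictly descending")
  if (is.null(source_ids)) {
    pick <- unique(round(seq(1, length(ref$taxon_ids), length.out = 3)))
    source_ids <- ref$taxon_ids[pick]
  }
  if (!all(source_ids %in% ref$taxon_ids))
    stop("source taxa absent from the reference set")
  if (is.null(index)) index <- build_index(ref)
  rp_set_active_seed(seed)
  sources <- setNames(ref$sixteen_s$seq, ref$sixteen_s$id)[source_ids]
  rows <- list()
  for (li in seq_along(levels)) {
    lev <- levels[li]
    qid <- character(0); qseq <- character(0); qsrc <- character(0)
    realized <- numeric(0)
    for (si in seq_along(source_ids)) {
      for (copy in seq_len(n_per_level)) {
        s <- derive_seed(seed, "sens", lev, source_ids[si], copy)
        inj <- inject_errors_to_identity(sources[[si]], lev, s)
        qid <- c(qid, sprintf("%s_l%d_c%02d", source_ids[si], lev, copy))
        qseq <- c(qseq, inj$seq)
        qsrc <- c(qsrc, source_ids[si])
        realized <- c(realized, inj$realized_identity)
      }
    }
    asn <- classify_reads(seq_records(qid, qseq), index, scoring)
    correct <- sum(asn$classified & asn$otu_id == qsrc, na.rm = TRUE)
    rows[[li]] <- data.frame(level = lev, n = length(qid),
                             n_correct = correct,
                             accuracy = correct / length(qid),
                             mean_realized = mean(realized))
  }
  tab <- do.call(rbind, rows)
  perfect <- tab$level[tab$accuracy == 1]
  # lowest level of the uninterrupted perfect run from the top
  run <- cumprod(tab$accuracy == 1) == 1
  min_perfect <- if (any(run)) min(tab$level[run]) else NA_real_
  list(table = tab, min_perfect_identity = min_perfect,
       all_perfect_levels = perfect)
}

#' Pairwise identity of replicate consensus sequences
#'
#' Global-alignment percent identities (gap columns included) between
#' independently reconstructed consensus sequences of one OTU.
#'
#' @param consensuses list of `consensus_record`s or character sequences
#'   (>= 2).
#' @param scoring a [scoring_scheme].
#' @return list: `identity` (symmetric matrix), `all_identical` (TRUE iff
#'   every pair is 100 percent identical).
#' @export
replicate_consensus_identity <- function(consensuses,
                                         scoring = scoring_scheme()) {
  seqs <- vapply(consensuses, function(x)
    if (is.character(x)) x else x$sequence, "")
  n <- length(seqs)
  if (n < 2) stop("need at least 2 consensus sequences")
  nm <- names(seqs)
  if (is.null(nm)) nm <- paste0("rep", seq_len(n))
  m <- matrix(100, n, n, dimnames = list(nm, nm))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (seqs[i] == seqs[j]) { m[i, j] <- m[j, i] <- 100; next }
    al <- cpp_align_global(seqs[i], seqs[j], scoring$match, scoring$mismatch,
                           scoring$gap_open, scoring$gap_extend, -1L)
    m[i, j] <- m[j, i] <- al$identity
  }
  list(identity = m, all_identical = all(m == 100))
}
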