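# Discontiguous-seed best-hit OTU classification: seed template and inverted
# index, banded seed-and-extend local alignment with the 2/-3 match scheme
# and 5/2 affine gaps, best-hit assignment with the 70%/500 bp unclassified
# floor, OTU tabulation and per-sample normalization.

#' Alignment scoring scheme
#'
#' Defaults are the discontiguous megablast-style settings used throughout
#' the package: match +2, mismatch -3, affine gap cost 5 to open plus 2 per
#' gapped base.
#'
#' @param match,mismatch per-column scores (match > 0 > mismatch).
#' @param gap_open,gap_extend positive gap costs (subtracted).
#' @return a `scoring_scheme` object.
#' @export
scoring_scheme <- function(match = 2, mismatch = -3, gap_open = 5,
                           gap_extend = 2) {
  if (!(match > 0 && mismatch < 0)) stop("need match > 0 > mismatch")
  if (!(gap_open > 0 && gap_extend > 0)) stop("gap penalties must be > 0")
  structure(list(match = as.integer(match), mismatch = as.integer(mismatch),
                 gap_open = as.integer(gap_open),
                 gap_extend = as.integer(gap_extend)),
            class = "scoring_scheme")
}

#' Discontiguous seed template
#'
#' A binary mask over an 18-column span with exactly 11 care positions
#' (word size 11, seed length 18); the default is the classic coding-region
#' template `111010010100110111`.
#'
#' @param pattern character mask of 0/1.
#' @return a `seed_template` object.
#' @export
seed_template <- function(pattern = "111010010100110111") {
  bits <- strsplit(pattern, "", fixed = TRUE)[[1]]
  if (!all(bits %in% c("0", "1"))) stop("pattern must be a 0/1 mask")
  if (sum(bits == "1") != 11) stop("pattern must have exactly 11 care positions")
  if (bits[1] != "1" || bits[length(bits)] != "1")
    stop("pattern must start and end with a care position")
  structure(list(pattern = pattern, span = length(bits), weight = 11L),
            class = "seed_template")
}

#' Build the discontiguous-seed inverted index over a 16S reference set
#'
#' Every reference position contributes one template key (positions whose
#' care columns contain non-ACGT letters are skipped); references shorter
#' than the template span are skipped with a warning.
#'
#' @param refs [seq_records] of reference 16S sequences, or a `reference_set`
#'   (its extracted 16S records are used).
#' @param template a [seed_template].
#' @return a `seed_index` object.
#' @export
build_index <- function(refs, template = seed_template()) {
  if (inherits(refs, "reference_set")) refs <- refs$sixteen_s
  short <- nchar(refs$seq) < template$span
  if (any(short)) {
    warning("skipping ", sum(short), " reference(s) shorter than the seed span")
    refs <- refs[!short, , drop = FALSE]
  }
  if (nrow(refs) == 0) stop("no references long enough to index")
  ptr <- cpp_build_index(refs$seq, refs$id, template$pattern)
  structure(list(ptr = ptr, ids = refs$id, seqs = refs$seq,
                 template = template), class = "seed_index")
}

#' @export
print.seed_index <- function(x, ...) {
  info <- cpp_index_keys(x$ptr)
  cat("seed_index:", info$n_refs, "references,", info$n_keys,
      "distinct keys,", info$n_positions, "indexed positions\n")
  invisible(x)
}

#' Number of indexed seed positions
#' @param index a `seed_index`.
#' @return named list with n_keys, n_positions, n_refs.
#' @export
index_stats <- function(index) cpp_index_keys(index$ptr)

#' Gapped extension of a seed anchor into a local alignment
#'
#' Banded affine-gap local alignment of query and subject restricted to
#' diagonals near the anchor, with X-drop termination. When `anchor` is NULL
#' the densest seed-anchor diagonal between the two sequences is detected
#' first. Identity is matches divided by alignment columns, gap columns
#' included.
#'
#' @param query,subject DNA strings (or one-row [seq_records]).
#' @param anchor optional c(q_pos, s_pos), 0-based exact template match.
#' @param scoring a [scoring_scheme].
#' @param x_drop X-drop termination threshold (negative disables).
#' @param band half-width of the diagonal band around the anchor.
#' @param template seed template used when auto-detecting the anchor.
#' @return one-row data.frame in [hit_columns] layout (without query ids).
#' @export
extend_alignment <- function(query, subject, anchor = NULL,
                             scoring = scoring_scheme(), x_drop = 40,
                             band = 100, template = seed_template()) {
  q <- if (is.character(query)) query else query$seq
  s <- if (is.character(subject)) subject else subject$seq
  if (is.null(anchor)) {
    idx <- cpp_build_index(s, "subject", template$pattern)
    hit <- cpp_classify_batch(q, idx, scoring$match, scoring$mismatch,
                              scoring$gap_open, scoring$gap_extend,
                              100L, 1L, as.integer(band), as.integer(x_drop))
    if (hit$n_anchors[1] == 0) stop("no seed anchor between query and subject")
    return(as_tabular_hit(hit, 1))
  }
  diag <- as.integer(anchor[2] - anchor[1])
  res <- cpp_align_local(q, s, diag, as.integer(band), scoring$match,
                         scoring$mismatch, scoring$gap_open,
                         scoring$gap_extend, as.integer(x_drop), FALSE)
  data.frame(subject_id = NA_character_, score = res$score,
             percent_identity = res$identity,
             alignment_length = res$columns, mismatches = res$mismatches,
             gap_opens = res$gap_opens, q_start = res$q_start,
             q_end = res$q_end, s_start = res$s_start, s_end = res$s_end,
             stringsAsFactors = FALSE)
}

as_tabular_hit <- function(batch, i) {
  data.frame(subject_id = batch$subject_id[i], score = batch$score[i],
             percent_identity = batch$percent_identity[i],
             alignment_length = batch$alignment_length[i],
             mismatches = batch$mismatches[i], gap_opens = batch$gap_opens[i],
             q_start = batch$q_start[i], q_end = batch$q_end[i],
             s_start = batch$s_start[i], s_end = batch$s_end[i],
             stringsAsFactors = FALSE)
}

#' Best-hit OTU classification of query 16S sequences
#'
#' Seed anchors are gathered across the whole index, chained per subject in
#' diagonal bands, and the candidate subjects (chain weight at least 25
#' percent of the best chain, capped at `max_subjects`) scored by a banded
#' local pass; the full alignment is recomputed only for the top raw score
#' (ties: higher identity, then lexicographically smallest subject id). A query is
#' `classified` only when the best hit reaches `min_identity` percent over
#' at least `min_span` aligned columns.
#'
#' @param queries [seq_records] of query sequences (e.g. extracted 16S).
#' @param index a `seed_index` from [build_index].
#' @param scoring a [scoring_scheme].
#' @param min_identity,min_span unclassified floor (70 percent over 500 bp).
#' @param chain_band diagonal band width for anchor chaining.
#' @param max_subjects extend at most this many top-weight subjects.
#' @param x_drop X-drop threshold for extension.
#' @param sample_id optional sample label stored on every assignment.
#' @return data.frame of assignments: read_id, otu_id, score,
#'   percent_identity, alignment_length, classified, coordinates, sample_id.
#' @export
classify_reads <- function(queries, index, scoring = scoring_scheme(),
                           min_identity = 70, min_span = 500,
                           chain_band = 100, max_subjects = 12,
                           x_drop = 40, sample_id = NA_character_) {
  res <- cpp_classify_batch(queries$seq, index$ptr, scoring$match,
                            scoring$mismatch, scoring$gap_open,
                            scoring$gap_extend, as.integer(chain_band),
                            as.integer(max_subjects),
                            as.integer(chain_band + 60), as.integer(x_drop))
  classified <- res$subject_id != "" &
    res$percent_identity >= min_identity & res$alignment_length >= min_span
  data.frame(read_id = queries$id,
             otu_id = ifelse(classified, res$subject_id, NA_character_),
             score = res$score, percent_identity = res$percent_identity,
             alignment_length = res$alignment_length,
             q_start = res$q_start, q_end = res$q_end,
             s_start = res$s_start, s_end = res$s_end,
             n_anchors = res$n_anchors, classified = classified,
             sample_id = sample_id, stringsAsFactors = FALSE)
}

#' Classify a single query sequence
#'
#' @inheritParams classify_reads
#' @param query a DNA string or one-row [seq_records].
#' @return one-row assignment data.frame (see [classify_reads]).
#' @export
classify_read <- function(query, index, scoring = scoring_scheme(),
                          min_identity = 70, min_span = 500, ...) {
  if (is.character(query)) query <- seq_records("query", query)
  classify_reads(query, index, scoring, min_identity, min_span, ...)
}

#' Tabulate classified assignments into an OTU count table
#'
#' @param assignments data.frame from [classify_reads] with a `sample_id`
#'   column (possibly several samples concatenated); NA sample ids are
#'   tabulated under "sample".
#' @return integer matrix OTU x sample; the per-sample count of unclassified
#'   reads is attached as attribute `unclassified`.
#' @export
tabulate_assignments <- function(assignments) {
  assignments$sample_id[is.na(assignments$sample_id)] <- "sample"
  samples <- unique(assignments$sample_id)
  cl <- assignments[assignments$classified, , drop = FALSE]
  otus <- sort(unique(cl$otu_id))
  m <- matrix(0L, nrow = length(otus), ncol = length(samples),
              dimnames = list(otus, samples))
  if (nrow(cl)) {
    t <- table(factor(cl$otu_id, levels = otus),
               factor(cl$sample_id, levels = samples))
    m[] <- as.integer(t)
  }
  uncl <- vapply(samples, function(s)
    sum(!assignments$classified & assignments$sample_id %in% s), 0L)
  attr(m, "unclassified") <- setNames(as.integer(uncl), samples)
  m
}

#' Normalize an OTU count table to per-sample relative frequencies
#'
#' @param table integer matrix OTU x sample.
#' @return numeric matrix with columns summing to 1.
#' @export
normalize_otu_table <- function(table) {
  sums <- colSums(table)
  zero <- sums == 0
  if (any(zero))
    stop("zero-sum sample column(s): ",
         paste(colnames(table)[zero], collapse = ", "))
  sweep(table, 2, sums, "/")
}

#' Full-matrix Smith-Waterman / Needleman-Wunsch oracle
#'
#' Provably optimal affine-gap alignment via Biostrings dynamic programming,
#' used as ground truth in tests of the banded seed-and-extend path. Identity
#' is matches over alignment columns including gaps.
#'
#' @param a,b DNA strings.
#' @param scoring a [scoring_scheme].
#' @param type "local" or "global".
#' @return list: score, percent_identity, matches, columns (alignment
#'   length), and 1-based inclusive aligned spans q_start/q_end/
#'   s_start/s_end.
#' @export
sw_oracle <- function(a, b, scoring = scoring_scheme(),
                      type = c("local", "global")) {
  type <- match.arg(type)
  mat <- Biostrings::nucleotideSubstitutionMatrix(
    match = scoring$match, mismatch = scoring$mismatch, baseOnly = TRUE)
  pa <- Biostrings::pairwiseAlignment(
    a, b, type = type, substitutionMatrix = mat,
    gapOpening = scoring$gap_open, gapExtension = scoring$gap_extend)
  pq <- as.character(Biostrings::alignedPattern(pa))
  ps <- as.character(Biostrings::alignedSubject(pa))
  qc <- strsplit(pq, "")[[1]]; sc <- strsplit(ps, "")[[1]]
  matches <- sum(qc == sc & qc != "-")
  cols <- length(qc)
  list(score = Biostrings::score(pa),
       percent_identity = if (cols) 100 * matches / cols else 0,
       matches = matches, columns = cols,
       q_start = Biostrings::start(Biostrings::pattern(pa)),
       q_end = Biostrings::end(Biostrings::pattern(pa)),
       s_start = Biostrings::start(Biostrings::subject(pa)),
       s_end = Biostrings::end(Biostrings::subject(pa)))
}
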