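# Iterative batched consensus reconstruction of rRNA operons from noisy
# reads: a progressive-alignment draft from the first batch, then repeated
# independent realignment of growing read sets to the current consensus with
# per-column plurality calling (con1 -> con2 -> final, in replicates A/B/C).

CALL_ALPHABET <- c("A", "C", "G", "T", "-")

#' Select the reads used to reconstruct one OTU's consensus
#'
#' The `n` reads assigned to the OTU with the highest classification scores,
#' ties resolved by read id so the selection is stable across runs.
#'
#' @param assignments assignment data.frame from [classify_reads].
#' @param reads [seq_records] holding the (oriented) reads.
#' @param otu_id the OTU to reconstruct.
#' @param n number of reads (30 by default).
#' @return [seq_records] of the selected reads, best score first.
#' @export
select_otu_reads <- function(assignments, reads, otu_id, n = 30) {
  hits <- assignments[assignments$classified &
                        assignments$otu_id == otu_id, , drop = FALSE]
  hits <- hits[!is.na(hits$read_id), , drop = FALSE]
  if (nrow(hits) < n)
    stop("OTU '", otu_id, "' has ", nrow(hits), " assigned reads; ",
         "below the ", n, "-read reconstruction coverage")
  hits <- hits[order(-hits$score, hits$read_id), , drop = FALSE]
  sel <- hits$read_id[seq_len(n)]
  idx <- match(sel, reads$id)
  if (anyNA(idx)) stop("assigned read(s) missing from the read set")
  out <- reads[idx, , drop = FALSE]
  class(out) <- c("seq_records", "data.frame")
  out
}

# plurality call per profile column: counts over A,C,G,T,-; ties prefer a
# base over the gap, then alphabetic order (deterministic)
call_column <- function(counts) {
  ord <- order(-counts, c(1, 2, 3, 4, 5))
  CALL_ALPHABET[ord[1]]
}

#' Build a gap-free draft consensus by progressive multiple alignment
#'
#' Reads are added in order of descending length; each is globally aligned
#' (affine gaps, classifier scoring) to the plurality consensus of the
#' current profile and merged column-wise. The final per-column plurality
#' call (gap is a candidate; ties prefer a base, then alphabetic order) is
#' returned with called gap columns removed.
#'
#' @param reads [seq_records] of same-OTU, uniformly oriented reads.
#' @param scoring a [scoring_scheme].
#' @param band band half-width for the pairwise global alignments
#'   (NULL = length difference + 150).
#' @return the draft consensus sequence (single string, gap-free).
#' @export
draft_consensus <- function(reads, scoring = scoring_scheme(), band = NULL) {
  if (nrow(reads) < 1) stop("draft_consensus needs at least one read")
  ord <- order(-nchar(reads$seq), reads$id)
  seqs <- reads$seq[ord]
  prof <- matrix(strsplit(seqs[1], "")[[1]], nrow = 1)
  for (s in seqs[-1]) {
    calls <- apply_calls(prof)
    is_ref <- calls != "-"
    ref <- paste(calls[is_ref], collapse = "")
    b <- if (is.null(band)) abs(nchar(s) - nchar(ref)) + 150 else band
    al <- cpp_align_global(s, ref, scoring$match, scoring$mismatch,
                           scoring$gap_open, scoring$gap_extend,
                           as.integer(b))
    prof <- merge_profile(prof, which(is_ref), al$aln_a, al$aln_b)
  }
  calls <- apply_calls(prof)
  paste(calls[calls != "-"], collapse = "")
}

apply_calls <- function(prof) {
  n <- nrow(prof); C <- ncol(prof)
  m <- match(prof, CALL_ALPHABET)
  cnt <- matrix(tabulate((rep(seq_len(C), each = n) - 1L) * 5L + m,
                         nbins = 5L * C), 5L, C)
  # plurality; ties prefer a base over the gap, then alphabetic order --
  # identical to call_column, vectorized (first max row = smallest index)
  CALL_ALPHABET[max.col(t(cnt), ties.method = "first")]
}

# Merge one pairwise alignment (new read `aln_a` vs reference `aln_b`) into
# the profile matrix; `ref_cols` maps reference positions to profile columns.
merge_profile <- function(prof, ref_cols, aln_a, aln_b) {
  A <- strsplit(aln_a, "")[[1]]
  B <- strsplit(aln_b, "")[[1]]
  n_ref <- sum(B != "-")
  stopifnot(n_ref == length(ref_cols))
  # for each alignment column: the reference position it consumes (0 = none)
  rpos <- cumsum(B != "-")
  # read chars landing on reference positions
  on_ref <- B != "-"
  new_on_ref <- rep("-", ncol(prof))
  new_on_ref[ref_cols[rpos[on_ref]]] <- A[on_ref]
  # insertions (gap in reference), grouped by the preceding reference position
  ins_cols <- which(!on_ref)
  ins_after <- rpos[ins_cols]           # 0..n_ref
  # existing profile columns, annotated with the reference position after
  # which they sit (non-ref columns inherit the previous ref position)
  col_ref <- rep(0L, ncol(prof))
  col_ref[ref_cols] <- seq_along(ref_cols)
  col_after <- cummax(col_ref)          # ref position at or before column
  # assemble merged column order
  nr <- nrow(prof)
  out_cols <- vector("list", length(ref_cols) * 2 + 2)
  oc <- 0
  add <- function(mat_cols, new_chars) {
    oc <<- oc + 1
    out_cols[[oc]] <<- list(cols = mat_cols, new = new_chars)
  }
  ins_split <- split(ins_cols, ins_after)
  for (r in 0:length(ref_cols)) {
    # existing columns whose anchor is r, excluding the ref column itself
    if (r > 0) {
      anchored <- which(col_after == r & col_ref != r)
    } else anchored <- which(col_after == 0L)
    pre <- if (r > 0) ref_cols[r] else 0L
    if (r > 0) add(ref_cols[r], new_on_ref[ref_cols[r]])
    if (length(anchored)) add(anchored, new_on_ref[anchored])
    key <- as.character(r)
    if (!is.null(ins_split[[key]]))
      add(NULL, A[ins_split[[key]]])
  }
  total <- sum(vapply(out_cols[seq_len(oc)], function(x)
    if (is.null(x$cols)) length(x$new) else length(x$cols), 0L))
  merged <- matrix("-", nrow = nr + 1, ncol = total)
  at <- 0
  for (k in seq_len(oc)) {
    piece <- out_cols[[k]]
    if (is.null(piece$cols)) {
      w <- length(piece$new)
      merged[nr + 1, (at + 1):(at + w)] <- piece$new
      at <- at + w
    } else {
      w <- length(piece$cols)
      merged[seq_len(nr), (at + 1):(at + w)] <- prof[, piece$cols]
      merged[nr + 1, (at + 1):(at + w)] <- piece$new
      at <- at + w
    }
  }
  merged
}

#' Realign reads to a draft and call a polished consensus
#'
#' Each read is globally aligned (banded, affine gaps) to the gap-free
#' draft independently, so indels at the very ends of the draft remain
#' visible; for every draft column the covering reads vote (plurality;
#' ties keep the draft base). Indels are called repeat-aware, because pairwise alignments
#' place an indel anywhere inside a repeat and naive per-column voting
#' splits the evidence:
#'
#' * candidate insertions are insertion placements shifted to their
#'   canonical (leftmost equivalent) position whose modal inserted string
#'   (ties to the alphabetically smallest) is reported by at least 15
#'   percent of covering reads; candidate deletions are maximal
#'   single-base runs whose pooled per-read gap fraction reaches 15
#'   percent (deleting `round(gaps / coverage)` columns, those with the
#'   most gap votes first).
#' * each candidate edit is then accepted only if it increases the summed
#'   alignment score of the reads against the template over a +/- 30 bp
#'   window around the edit; accepted edits are applied largest gain
#'   first, skipping edits whose windows overlap one already applied.
#'
#' The low candidacy bar is deliberate — alignments of reads with errors
#' near a repeat absorb a genuinely missing or surplus base as mismatches,
#' so per-column vote fractions understate indel evidence — while the
#' score comparison pools the evidence of every read exactly and rejects
#' spurious candidates.
#'
#' Reads whose alignment identity to the draft falls below 55 percent are
#' excluded from the vote.
#'
#' @param draft gap-free draft consensus (single string).
#' @param reads [seq_records] to realign.
#' @param agreement_threshold a column is counted as a disagreement when
#'   fewer than this fraction of its covering reads match the called base.
#' @param scoring a [scoring_scheme].
#' @param otu_id,stage labels stored on the record.
#' @return a `consensus_record`: sequence, per_column_coverage,
#'   disagreements, n_reads, excluded reads.
#' @export
realign_and_call <- function(draft, reads, agreement_threshold = 0.5,
                             scoring = scoring_scheme(),
                             otu_id = NA_character_, stage = "consensus") {
  L <- nchar(draft)
  draft_chars <- strsplit(draft, "")[[1]]
  base_tally <- matrix(0L, nrow = 5, ncol = L)
  ins_after <- list()
  aln_store <- list()
  excluded <- character(0)
  n_used <- 0
  # inserting s after position p equals inserting rotate(s) after p-1 when
  # s ends with the template base at p; shift to the leftmost equivalent
  canonical_ins <- function(p, s) {
    n <- nchar(s)
    while (p >= 1 && substr(s, n, n) == draft_chars[p]) {
      s <- paste0(draft_chars[p], substr(s, 1, n - 1))
      p <- p - 1L
    }
    list(p = p, s = s)
  }
  for (i in seq_len(nrow(reads))) {
    rseq <- reads$seq[i]
    al <- cpp_align_global(rseq, draft, scoring$match, scoring$mismatch,
                           scoring$gap_open, scoring$gap_extend, -1L)
    if (al$identity < 55) {
      excluded <- c(excluded, reads$id[i])
      rp_log("realign_and_call: read ", reads$id[i], " failed to align")
      next
    }
    n_used <- n_used + 1
    X <- strsplit(al$aln_a, "")[[1]]
    Y <- strsplit(al$aln_b, "")[[1]]
    on_ref <- Y != "-"
    dpos <- cumsum(on_ref)                     # draft position per column
    aln_store[[n_used]] <- list(X = X, dpos = dpos)
    bidx <- match(X[on_ref], CALL_ALPHABET)
    code <- (dpos[on_ref] - 1L) * 5L + bidx
    base_tally <- base_tally + matrix(tabulate(code, nbins = 5L * L), 5L, L)
    gaps <- which(!on_ref)
    if (length(gaps)) {
      after <- dpos[gaps]
      for (grp in split(seq_along(gaps), after)) {
        can <- canonical_ins(after[grp[1]],
                             paste(X[gaps[grp]], collapse = ""))
        key <- as.character(can$p)
        ins_after[[key]] <- c(ins_after[[key]], can$s)
      }
    }
  }
  cov <- colSums(base_tally)
  run_id <- cumsum(c(TRUE, draft_chars[-1] != draft_chars[-L]))
  calls <- character(L)
  agree <- numeric(L)
  for (j in seq_len(L)) {
    if (cov[j] == 0) { calls[j] <- draft_chars[j]; agree[j] <- 1; next }
    cnt <- base_tally[seq_len(4), j]   # bases only; indels decided below
    best <- max(cnt)
    if (best == 0) { calls[j] <- draft_chars[j]; agree[j] <- 1; next }
    winners <- CALL_ALPHABET[seq_len(4)][cnt[seq_len(4)] == best]
    calls[j] <- if (draft_chars[j] %in% winners) draft_chars[j]
                else winners[1]
    agree[j] <- cnt[match(calls[j], CALL_ALPHABET)] / cov[j]
  }
  covering_at <- function(p) {
    if (p >= 1 && p < L) min(cov[p], cov[p + 1])
    else if (p == 0) cov[1] else cov[L]
  }
  ## indel candidates at a low evidence bar; each is accepted only when it
  ## raises the summed alignment score of the reads over a local window
  win <- 30L
  seg_of <- function(k, a, b) {
    st <- aln_store[[k]]
    sel <- st$dpos >= a & st$dpos <= b & st$X != "-"
    paste(st$X[sel], collapse = "")
  }
  edit_gain <- function(from, to, repl) {
    a <- max(1L, from - win); b <- min(L, to + win)
    win0 <- substr(draft, a, b)
    win1 <- paste0(substr(draft, a, from - 1), repl,
                   substr(draft, to + 1, b))
    gain <- 0
    for (k in seq_len(n_used)) {
      seg <- seg_of(k, a, b)
      if (!nchar(seg)) next
      b0 <- abs(nchar(seg) - nchar(win0)) + 12L
      s0 <- cpp_align_global(seg, win0, scoring$match, scoring$mismatch,
                             scoring$gap_open, scoring$gap_extend,
                             b0)$score
      b1 <- abs(nchar(seg) - nchar(win1)) + 12L
      s1 <- cpp_align_global(seg, win1, scoring$match, scoring$mismatch,
                             scoring$gap_open, scoring$gap_extend,
                             b1)$score
      gain <- gain + (s1 - s0)
    }
    gain
  }
  cands <- list()
  # deletion candidates: pooled gap votes per maximal single-base run
  for (run in split(seq_len(L), run_id)) {
    covm <- mean(cov[run])
    if (covm == 0) next
    ratio <- sum(base_tally[5, run]) / covm
    if (ratio < 0.15) next
    d <- min(length(run), max(1L, as.integer(floor(ratio + 0.5))))
    k0 <- min(run)
    cands[[length(cands) + 1]] <- list(
      type = "del", from = k0, to = max(run), d = d,
      repl = paste(rep(draft_chars[k0], length(run) - d), collapse = ""))
  }
  # insertion candidates: canonical positions whose modal string is
  # reported by at least 15 percent of covering reads (minimum 2)
  for (p in sort(as.integer(names(ins_after)))) {
    strings <- ins_after[[as.character(p)]]
    if (length(strings) < 2) next                # cannot reach the 15% bar
    tab <- sort(table(strings), decreasing = TRUE)
    modal <- sort(names(tab)[tab == max(tab)])[1]
    c_modal <- sum(strings == modal)
    if (c_modal < max(2, 0.15 * covering_at(p))) next
    cands[[length(cands) + 1]] <- list(
      type = "ins", from = p + 1L, to = p, d = 0L, repl = modal,
      support = c_modal)
  }
  # keep improving edits, largest score gain first, windows disjoint
  ins_call <- list()
  if (length(cands)) {
    gains <- vapply(cands, function(cd)
      edit_gain(cd$from, cd$to, cd$repl), 0)
    ord <- order(-gains, vapply(cands, `[[`, 0L, "from"))
    taken <- matrix(numeric(0), ncol = 2)
    for (idx in ord) {
      if (gains[idx] <= 0) break
      cd <- cands[[idx]]
      a <- max(1L, cd$from - win); b <- min(L, cd$to + win)
      if (nrow(taken) && any(taken[, 1] <= b & taken[, 2] >= a)) next
      taken <- rbind(taken, c(a, b))
      if (cd$type == "del") {
        run <- cd$from:cd$to
        keepc <- run[calls[run] == draft_chars[run]]
        if (!length(keepc)) next
        del <- keepc[order(-base_tally[5, keepc],
                           -keepc)][seq_len(min(cd$d, length(keepc)))]
        calls[del] <- "-"
        agree[del] <- base_tally[5, del] / pmax(cov[del], 1)
      } else {
        ins_call[[as.character(cd$to)]] <- list(
          chars = strsplit(cd$repl, "")[[1]],
          support = cd$support,
          agree = cd$support / max(covering_at(cd$to), 1))
      }
    }
  }
  emit_ins <- function(p) {
    e <- ins_call[[as.character(p)]]
    if (is.null(e)) return(NULL)
    list(chars = e$chars, cov = rep(e$support, length(e$chars)),
         agree = rep(e$agree, length(e$chars)))
  }
  pieces_seq <- vector("list", 2 * L + 2); pc <- 0
  push <- function(chs, cv, ag) {
    pc <<- pc + 1
    pieces_seq[[pc]] <<- list(s = chs, c = cv, a = ag)
  }
  ins0 <- emit_ins(0)
  if (!is.null(ins0)) push(ins0$chars, ins0$cov, ins0$agree)
  for (j in seq_len(L)) {
    if (calls[j] != "-") push(calls[j], cov[j], agree[j])
    insj <- emit_ins(j)
    if (!is.null(insj)) push(insj$chars, insj$cov, insj$agree)
  }
  pieces_seq <- pieces_seq[seq_len(pc)]
  seqv <- unlist(lapply(pieces_seq, `[[`, "s"))
  covv <- unlist(lapply(pieces_seq, `[[`, "c"))
  agv <- unlist(lapply(pieces_seq, `[[`, "a"))
  structure(list(otu_id = otu_id, stage = stage,
                 sequence = paste(seqv, collapse = ""),
                 per_column_coverage = as.integer(covv),
                 disagreements = sum(agv < agreement_threshold),
                 n_reads = n_used, excluded = excluded),
            class = "consensus_record")
}

#' @export
print.consensus_record <- function(x, ...) {
  cat("consensus_record ", x$stage,
      if (!is.na(x$otu_id)) paste0(" [", x$otu_id, "]") else "", ": ",
      nchar(x$sequence), " bp from ", x$n_reads, " reads, mean coverage ",
      round(mean(x$per_column_coverage), 1), ", ", x$disagreements,
      " disagreement column(s)\n", sep = "")
  invisible(x)
}

#' Iterative batched consensus reconstruction
#'
#' Implements the staged scheme: the selected reads (best classification
#' score first) are partitioned into consecutive batches of
#' `schedule[1]` reads. For each replicate (A, B, C, ...) a draft is built
#' from that replicate's batch, realigned against its own batch (con1X),
#' then against the first `schedule[2]` reads (con2X), and so on up to the
#' full set (finalX); the last stage is repeated until the sequence reaches
#' a fixed point (at most 5 realignments). The final consensus with the
#' highest mean per-column coverage (then length, then replicate letter) is
#' chosen.
#'
#' @param reads [seq_records], classification-score ordered (see
#'   [select_otu_reads]); `nrow` must equal the last schedule entry.
#' @param schedule ascending read counts per stage (default 10, 20, 30).
#' @param agreement_threshold see [realign_and_call].
#' @param scoring a [scoring_scheme].
#' @param otu_id label stored on every record.
#' @return list: `records` (named list of `consensus_record`s for every
#'   stage of every replicate), `final` (chosen record), `replicate`
#'   (chosen letter).
#' @export
iterative_consensus <- function(reads, schedule = c(10, 20, 30),
                                agreement_threshold = 0.5,
                                scoring = scoring_scheme(),
                                otu_id = NA_character_) {
  if (is.unsorted(schedule, strictly = TRUE))
    stop("schedule must be strictly ascending")
  n <- nrow(reads)
  if (schedule[length(schedule)] != n)
    stop("schedule must end at the number of selected reads (", n, ")")
  bs <- schedule[1]
  n_rep <- n %/% bs
  if (n_rep < 1) stop("not enough reads for one batch")
  records <- list()
  finals <- list()
  for (r in seq_len(n_rep)) {
    letter <- LETTERS[r]
    batch <- reads[((r - 1) * bs + 1):(r * bs), , drop = FALSE]
    class(batch) <- c("seq_records", "data.frame")
    draft <- draft_consensus(batch, scoring)
    cons <- realign_and_call(draft, batch, agreement_threshold, scoring,
                             otu_id, paste0("con1", letter))
    records[[cons$stage]] <- cons
    for (k in seq_along(schedule)[-1]) {
      sub <- reads[seq_len(schedule[k]), , drop = FALSE]
      class(sub) <- c("seq_records", "data.frame")
      stage <- if (k == length(schedule)) paste0("final", letter)
               else paste0("con", k, letter)
      cons <- realign_and_call(cons$sequence, sub, agreement_threshold,
                               scoring, otu_id, stage)
      if (k == length(schedule)) {
        # polish the final stage to a fixed point (bounded)
        for (it in seq_len(4)) {
          nxt <- realign_and_call(cons$sequence, sub, agreement_threshold,
                                  scoring, otu_id, stage)
          if (nxt$sequence == cons$sequence) break
          cons <- nxt
        }
      }
      records[[stage]] <- cons
    }
    finals[[letter]] <- cons
  }
  mean_cov <- vapply(finals, function(x) mean(x$per_column_coverage), 0)
  len <- vapply(finals, function(x) nchar(x$sequence), 0)
  ord <- order(-mean_cov, -len, names(finals))
  chosen <- names(finals)[ord[1]]
  list(records = records, final = finals[[chosen]], replicate = chosen)
}
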