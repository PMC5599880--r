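# Primer-site annotation on noisy long reads, length / site-count filtering,
# uniform orientation, and 16S / 23S subregion extraction.

#' Annotate approximate primer sites on reads
#'
#' Scans every primer of the panel (IUPAC codes expanded) against both
#' strands of each read with a semi-global edit-distance search; placements
#' within `floor(max_error_rate * primer_length)` edits are reported at
#' their best position, with overlapping placements of the same primer
#' merged keeping the minimal edit distance. Coordinates are 0-based
#' half-open on the read as given; strand "-" means the reverse complement
#' of the primer matched.
#'
#' @param reads a [seq_records] data.frame (one or many reads).
#' @param panel a [seq_records] of primers (length >= 10 each).
#' @param max_error_rate tolerated edit fraction of the primer length;
#'   0.25 by default so ~12 percent-error reads still reveal their sites.
#' @return data.frame: read_id, primer_name, strand, start, end,
#'   edit_distance.
#' @export
find_primer_sites <- function(reads, panel, max_error_rate = 0.25) {
  empty <- data.frame(read_id = character(), primer_name = character(),
                      strand = character(), start = integer(),
                      end = integer(), edit_distance = integer(),
                      stringsAsFactors = FALSE)
  if (is.null(panel) || nrow(panel) == 0) {
    rp_log("find_primer_sites: empty primer panel, no sites reported")
    warning("empty primer panel")
    return(empty)
  }
  if (any(nchar(panel$seq) < 10)) stop("primers must be at least 10 bp")
  max_ed <- as.integer(floor(max_error_rate * nchar(panel$seq)))
  hits <- cpp_scan_panel(reads$seq, panel$seq, max_ed)
  if (nrow(hits) == 0) return(empty)
  out <- data.frame(read_id = reads$id[hits$read_idx],
                    primer_name = panel$id[hits$primer_idx],
                    strand = hits$strand, start = hits$start, end = hits$end,
                    edit_distance = hits$edits, stringsAsFactors = FALSE)
  out[order(match(out$read_id, reads$id), out$start), , drop = FALSE]
}

#' Length and primer-site QC decision for one read
#'
#' A read is kept iff its length lies within `[min_len, max_len]` (the 4-5 kb
#' amplicon window by default) and it carries at least `min_sites` priming
#' sites; the reject reason reports the first failed criterion (length is
#' checked before primer count).
#'
#' @param read one-row [seq_records] (or list with `id` and `seq`).
#' @param sites primer sites for this read from [find_primer_sites].
#' @param min_len,max_len read length bounds in bp.
#' @param min_sites minimum number of priming sites.
#' @return list: read_id, status ("keep"/"reject"), reject_reason ("none",
#'   "length" or "primer_count"), length, n_sites.
#' @export
qc_filter <- function(read, sites, min_len = 4000, max_len = 5000,
                      min_sites = 2) {
  len <- nchar(read$seq)
  n_sites <- if (is.null(sites)) 0L else nrow(sites)
  if (len < min_len || len > max_len)
    return(list(read_id = read$id, status = "reject",
                reject_reason = "length", length = len, n_sites = n_sites))
  if (n_sites < min_sites)
    return(list(read_id = read$id, status = "reject",
                reject_reason = "primer_count", length = len,
                n_sites = n_sites))
  list(read_id = read$id, status = "keep", reject_reason = "none",
       length = len, n_sites = n_sites)
}

#' Orient a read so that primer sites lie predominantly on the plus strand
#'
#' If a strict majority of its primer sites are on the minus strand the read
#' is reverse-complemented and all site coordinates and strands are flipped;
#' ties leave the read unchanged. Idempotent.
#'
#' @param read one-row [seq_records].
#' @param sites primer sites for this read (>= 1 row).
#' @return list with `read` (possibly reverse-complemented one-row
#'   [seq_records]) and `sites` (remapped), plus `flipped` flag.
#' @export
orient_read <- function(read, sites) {
  if (is.null(sites) || nrow(sites) == 0)
    stop("orient_read requires at least one primer site; filter first")
  n_minus <- sum(sites$strand == "-")
  if (n_minus * 2 <= nrow(sites))
    return(list(read = read, sites = sites, flipped = FALSE))
  len <- nchar(read$seq)
  new_sites <- data.frame(
    read_id = sites$read_id, primer_name = sites$primer_name,
    strand = ifelse(sites$strand == "+", "-", "+"),
    start = len - sites$end, end = len - sites$start,
    edit_distance = sites$edit_distance, stringsAsFactors = FALSE)
  new_sites <- new_sites[order(new_sites$start), , drop = FALSE]
  out <- read
  out$seq <- revcomp(read$seq)
  list(read = out, sites = new_sites, flipped = TRUE)
}

#' Extract the 16S (or 23S) subregion from an oriented read
#'
#' The 16S region runs from the start of the 5'-most plus-strand site of the
#' 16S sub-panel to `min(start + cap_16s, start of the 5'-most 23S-panel
#' site)`; the 23S region runs from the 5'-most 23S-panel site to the read
#' end. Returns NULL when the anchoring site is absent.
#'
#' @param read oriented one-row [seq_records].
#' @param sites remapped primer sites on the oriented read.
#' @param subunit "16S" or "23S".
#' @param cap_16s upper bound on the extracted 16S length in bp.
#' @return one-row [seq_records], or NULL.
#' @export
extract_subunit <- function(read, sites, subunit = c("16S", "23S"),
                            cap_16s = 1600) {
  subunit <- match.arg(subunit)
  is16 <- grepl("^16S", sites$primer_name)
  is23 <- grepl("^23S", sites$primer_name)
  plus <- sites$strand == "+"
  len <- nchar(read$seq)
  first_23s <- if (any(is23 & plus)) min(sites$start[is23 & plus]) else NA
  if (subunit == "16S") {
    if (!any(is16 & plus)) {
      rp_log("no 16S-panel site on read ", read$id)
      return(NULL)
    }
    s <- min(sites$start[is16 & plus])
    e <- min(s + cap_16s, if (is.na(first_23s)) len else first_23s, len)
  } else {
    if (is.na(first_23s)) {
      rp_log("no 23S-panel site on read ", read$id)
      return(NULL)
    }
    s <- first_23s
    e <- len
  }
  if (e <= s) return(NULL)
  seq_records(read$id, substr(read$seq, s + 1, e),
              desc = paste0(subunit, ":", s, "-", e))
}

#' QC, orient and extract the 16S region for a set of reads
#'
#' Convenience wrapper running [find_primer_sites], [qc_filter],
#' [orient_read] and [extract_subunit] over a read set.
#'
#' Site annotation is two-tiered: sites within
#' `floor(max_error_rate * primer_length)` edits count toward the
#' `min_sites` QC criterion, but orientation and extraction anchoring use
#' the higher-confidence subset within
#' `floor(anchor_error_rate * primer_length)` edits, because at the
#' permissive tier chance placements occur on kilobase-scale reads and a
#' spurious 23S-panel site would truncate the extracted 16S. Permissive-tier
#' 16S-panel sites are kept as anchors: a 16S site only ever moves the
#' extraction start 5'-ward, which cannot truncate the region. Reads whose
#' anchor tier is empty fall back to the permissive tier.
#'
#' @param reads a [seq_records] data.frame.
#' @param panel primer panel [seq_records].
#' @param max_error_rate see [find_primer_sites].
#' @param anchor_error_rate stricter edit fraction for orientation and
#'   extraction anchors.
#' @param min_len,max_len,min_sites see [qc_filter].
#' @param cap_16s see [extract_subunit].
#' @return list: `kept` (oriented kept reads), `extracted_16s`
#'   ([seq_records]), `report` (data.frame: read_id, length, n_sites,
#'   status, reason).
#' @export
qc_reads <- function(reads, panel, max_error_rate = 0.25,
                     anchor_error_rate = 0.15, min_len = 4000,
                     max_len = 5000, min_sites = 2, cap_16s = 1600) {
  all_sites <- find_primer_sites(reads, panel, max_error_rate)
  lens <- nchar(reads$seq)
  n_sites <- integer(nrow(reads))
  tab <- table(factor(all_sites$read_id, levels = reads$id))
  n_sites <- as.integer(tab)
  status <- ifelse(lens < min_len | lens > max_len, "reject",
                   ifelse(n_sites < min_sites, "reject", "keep"))
  reason <- ifelse(lens < min_len | lens > max_len, "length",
                   ifelse(n_sites < min_sites, "primer_count", "none"))
  report <- data.frame(read_id = reads$id, length = lens, n_sites = n_sites,
                       status = status, reason = reason,
                       stringsAsFactors = FALSE)
  kept <- which(status == "keep")
  plen <- setNames(nchar(panel$seq), panel$id)
  is_anchor <- all_sites$edit_distance <=
    floor(anchor_error_rate * plen[all_sites$primer_name]) |
    grepl("^16S", all_sites$primer_name)
  anchor_sites <- all_sites[is_anchor, , drop = FALSE]
  site_split <- split(all_sites, factor(all_sites$read_id, levels = reads$id))
  anchor_split <- split(anchor_sites,
                        factor(anchor_sites$read_id, levels = reads$id))
  n_k <- length(kept)
  kept_seqs <- character(n_k)
  ext_seqs <- rep(NA_character_, n_k); ext_desc <- rep(NA_character_, n_k)
  for (k in seq_len(n_k)) {
    i <- kept[k]
    read <- list(id = reads$id[i], desc = reads$desc[i], seq = reads$seq[i])
    anch <- anchor_split[[read$id]]
    if (is.null(anch) || nrow(anch) == 0) anch <- site_split[[read$id]]
    ori <- orient_read(read, anch)
    kept_seqs[k] <- ori$read$seq
    ext <- extract_subunit(ori$read, ori$sites, "16S", cap_16s)
    if (!is.null(ext)) { ext_seqs[k] <- ext$seq; ext_desc[k] <- ext$desc }
  }
  has_ext <- !is.na(ext_seqs)
  list(kept = if (n_k) seq_records(reads$id[kept], kept_seqs,
                                   reads$desc[kept]) else NULL,
       extracted_16s = if (any(has_ext))
         seq_records(reads$id[kept][has_ext], ext_seqs[has_ext],
                     ext_desc[has_ext]) else NULL,
       report = report)
}
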