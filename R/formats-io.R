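# Sequence record containers and readers/writers for the plain-text formats
# the pipeline touches: FASTA, FASTQ (Phred+33), 12-column hit tables
# (outfmt-6 dialect), OTU count tables, and flat key=value run configs.

#' Construct a set of sequence records
#'
#' The package's light container for named DNA sequences: a data.frame with
#' columns `id`, `desc`, `seq` and, when qualities are present, a list column
#' `qual` of integer Phred scores. Sequences are uppercased and U is mapped
#' to T; IUPAC ambiguity codes are accepted (intended for primers).
#'
#' @param id character vector of record ids (no whitespace).
#' @param seq character vector of sequences.
#' @param desc optional descriptions.
#' @param qual optional list of integer quality vectors, one per sequence.
#' @return a `seq_records` data.frame.
#' @export
seq_records <- function(id, seq, desc = "", qual = NULL) {
  id <- as.character(id)
  seq <- toupper(as.character(seq))
  seq <- chartr("U", "T", seq)
  if (length(id) != length(seq)) stop("id and seq lengths differ")
  if (any(grepl("[[:space:]]", id))) stop("record ids must not contain whitespace")
  if (any(nchar(seq) < 1)) {
    bad <- id[nchar(seq) < 1][1]
    stop("empty sequence for record '", bad, "'")
  }
  dup <- id[duplicated(id)]
  if (length(dup)) stop("duplicate record id '", dup[1], "'")
  out <- data.frame(id = id, desc = rep_len(as.character(desc), length(id)),
                    seq = seq, stringsAsFactors = FALSE)
  if (!is.null(qual)) {
    if (length(qual) != length(id)) stop("qual must have one vector per record")
    bad <- which(vapply(qual, length, 0L) != nchar(seq))
    if (length(bad))
      stop("quality length mismatch for record '", id[bad[1]], "'")
    out$qual <- lapply(qual, as.integer)
  }
  class(out) <- c("seq_records", "data.frame")
  out
}

#' Read a FASTA file into sequence records
#'
#' Parsed with Biostrings; sequences are uppercased, U mapped to T, and
#' duplicate ids rejected.
#'
#' @param path file path (plain or gzip).
#' @return a [seq_records] data.frame.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  set <- tryCatch(Biostrings::readBStringSet(path, format = "fasta"),
                  error = function(e) stop("malformed FASTA in '", path, "': ",
                                           conditionMessage(e), call. = FALSE))
  if (length(set) == 0)
    return(seq_records(character(), character()))
  headers <- names(set)
  id <- sub("[[:space:]].*$", "", headers)
  desc <- ifelse(grepl("[[:space:]]", headers),
                 sub("^[^[:space:]]+[[:space:]]+", "", headers), "")
  seqs <- as.character(set)
  if (any(nchar(seqs) == 0))
    stop("malformed FASTA in '", path, "': empty sequence for record '",
         id[nchar(seqs) == 0][1], "'")
  seq_records(id, seqs, desc)
}

#' Write sequence records to FASTA
#'
#' @param records a [seq_records] data.frame.
#' @param path output path.
#' @param width line wrap width (0 = single line per sequence).
#' @return invisibly, `path`.
#' @export
write_fasta <- function(records, path, width = 0) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(records))) {
    hdr <- if (nzchar(records$desc[i]))
      paste(records$id[i], records$desc[i]) else records$id[i]
    writeLines(paste0(">", hdr), con)
    s <- records$seq[i]
    if (width > 0) {
      starts <- seq(1, nchar(s), by = width)
      writeLines(substring(s, starts, pmin(starts + width - 1, nchar(s))), con)
    } else writeLines(s, con)
  }
  invisible(path)
}

#' Read a FASTQ file (Phred+33) into sequence records
#'
#' @param path file path.
#' @return a [seq_records] data.frame with a `qual` list column.
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  set <- tryCatch(
    Biostrings::readBStringSet(path, format = "fastq", with.qualities = TRUE),
    error = function(e) stop("malformed FASTQ in '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  if (length(set) == 0)
    return(seq_records(character(), character(), qual = list()))
  headers <- names(set)
  id <- sub("[[:space:]].*$", "", headers)
  desc <- ifelse(grepl("[[:space:]]", headers),
                 sub("^[^[:space:]]+[[:space:]]+", "", headers), "")
  quals <- tryCatch(as.character(S4Vectors::mcols(set)$qualities),
                    error = function(e) stop("malformed FASTQ in '", path,
                                             "': ", conditionMessage(e),
                                             call. = FALSE))
  seqs <- as.character(set)
  bad <- which(nchar(quals) != nchar(seqs))
  if (length(bad))
    stop("malformed FASTQ in '", path, "': quality length mismatch for '",
         id[bad[1]], "'")
  qual <- lapply(quals, function(q) utf8ToInt(q) - 33L)
  seq_records(id, seqs, desc, qual = qual)
}

#' Write sequence records to FASTQ (Phred+33)
#'
#' Records without qualities are written with a uniform placeholder quality
#' of 20.
#'
#' @param records a [seq_records] data.frame.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_fastq <- function(records, path) {
  con <- file(path, "w")
  on.exit(close(con))
  has_qual <- "qual" %in% names(records)
  for (i in seq_len(nrow(records))) {
    q <- if (has_qual && !is.null(records$qual[[i]])) records$qual[[i]]
         else rep(20L, nchar(records$seq[i]))
    hdr <- if (nzchar(records$desc[i]))
      paste(records$id[i], records$desc[i]) else records$id[i]
    writeLines(c(paste0("@", hdr), records$seq[i], "+",
                 intToUtf8(q + 33L)), con)
  }
  invisible(path)
}

# -- hit tables --------------------------------------------------------------

hit_columns <- c("query_id", "subject_id", "percent_identity",
                 "alignment_length", "mismatches", "gap_opens",
                 "q_start", "q_end", "s_start", "s_end", "evalue", "score")

#' Write alignment hits as a 12-column tab-separated table
#'
#' Column order follows the widespread headerless 12-column tabular dialect
#' (query, subject, percent identity, alignment length, mismatches, gap
#' opens, query start/end, subject start/end, e-value, score). Ranking in
#' this package uses raw scores, so the e-value column is emitted as "NA".
#' Coordinates are 1-based inclusive.
#'
#' @param hits data.frame with the columns of [hit_columns] (evalue optional).
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_hits_tsv <- function(hits, path) {
  if (nrow(hits) == 0) { file.create(path); return(invisible(path)) }
  out <- data.frame(
    query_id = hits$query_id, subject_id = hits$subject_id,
    percent_identity = sprintf("%.2f", hits$percent_identity),
    alignment_length = hits$alignment_length, mismatches = hits$mismatches,
    gap_opens = hits$gap_opens, q_start = hits$q_start, q_end = hits$q_end,
    s_start = hits$s_start, s_end = hits$s_end, evalue = "NA",
    score = hits$score, stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a 12-column tab-separated hit table
#'
#' @param path file path.
#' @return data.frame of hits (numeric columns parsed; evalue kept as "NA").
#' @export
read_hits_tsv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (file.size(path) == 0) {
    out <- data.frame(matrix(nrow = 0, ncol = 12))
    names(out) <- hit_columns
    return(out)
  }
  out <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE,
                           na.strings = character(0),
                           colClasses = "character")
  names(out) <- hit_columns
  # The evalue column keeps its literal "NA"; numeric columns may carry NA
  # for unclassified queries.
  num_cols <- setdiff(hit_columns, c("query_id", "subject_id", "evalue"))
  for (cn in num_cols) {
    v <- suppressWarnings(if (cn == "percent_identity") as.numeric(out[[cn]])
                          else as.integer(out[[cn]]))
    bad <- which(is.na(v) & out[[cn]] != "NA")
    if (length(bad))
      stop("non-numeric value in column '", cn, "' of '", path, "' (row ",
           bad[1], ")")
    out[[cn]] <- v
  }
  bad <- with(out, q_start > q_end | s_start > s_end)
  bad[is.na(bad)] <- FALSE
  if (any(bad)) stop("invalid hit coordinates in '", path, "' (row ",
                     which(bad)[1], ")")
  out
}

# -- OTU tables --------------------------------------------------------------

#' Write an OTU count table as TSV
#'
#' @param counts integer matrix, OTU rows x sample columns, with dimnames.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_otu_table <- function(counts, path) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("OTU table needs row (otu_id) and column (sample) names")
  if (any(counts < 0)) stop("negative counts in OTU table")
  if (any(counts != round(counts))) stop("non-integer counts in OTU table")
  df <- data.frame(otu_id = rownames(counts), counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an OTU count table from TSV
#'
#' @param path file path.
#' @return integer matrix, OTU rows x sample columns.
#' @export
read_otu_table <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (names(df)[1] != "otu_id") stop("OTU table must start with an otu_id column")
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric counts in '", path, "'")
  storage.mode(m) <- "integer"
  if (any(m < 0)) stop("negative counts in '", path, "'")
  rownames(m) <- df$otu_id
  m
}

# -- run configuration -------------------------------------------------------

#' Write a run configuration as a flat key=value file
#'
#' @param config named list of scalar values.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_run_config <- function(config, path) {
  keys <- names(config)
  if (is.null(keys) || any(!nzchar(keys))) stop("config entries must be named")
  lines <- vapply(keys, function(k) {
    v <- config[[k]]
    paste0(k, "=", paste(format(v, scientific = FALSE, trim = TRUE),
                         collapse = ","))
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read a flat key=value run configuration
#'
#' Values that parse as numbers are returned numeric; comma-separated values
#' become vectors. Lines starting with '#' are ignored.
#'
#' @param path file path.
#' @return named list.
#' @export
read_run_config <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^\\s*#", lines)]
  out <- list()
  for (ln in lines) {
    eq <- regexpr("=", ln, fixed = TRUE)
    if (eq < 0) stop("malformed config line: '", ln, "'")
    k <- trimws(substr(ln, 1, eq - 1))
    v <- strsplit(trimws(substr(ln, eq + 1, nchar(ln))), ",", fixed = TRUE)[[1]]
    num <- suppressWarnings(as.numeric(v))
    out[[k]] <- if (!anyNA(num)) num else v
  }
  out
}
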