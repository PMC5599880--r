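# read_qc: primer-site annotation, filtering, orientation, 16S extraction

test_that("find_primer_sites locates exact and mutated primers", {
  primer <- "AGAGTTTGATCCTGGCTCAG"
  read <- seq_records("r1", paste0(primer, rand_dna(400, 2)))
  panel <- seq_records("p1", primer)
  sites <- find_primer_sites(read, panel)
  expect_equal(nrow(sites), 1)
  expect_equal(sites$strand, "+")
  expect_equal(sites$start, 0)
  expect_equal(sites$end, 20)
  expect_equal(sites$edit_distance, 0)
})

test_that("find_primer_sites agrees with the brute-force edit-distance oracle", {
  primer <- "AGAGTTTGATCCTGGCTCAG"
  set.seed(77)
  body <- rand_dna(5000)
  mut <- substitute_at(primer, c(3, 9, 15), seed = 78)
  read_seq <- paste0(substr(body, 1, 1234), mut, substr(body, 1235, 5000))
  read <- seq_records("r1", read_seq)
  sites <- find_primer_sites(read, seq_records("p1", primer))
  hit <- sites[sites$start >= 1224 & sites$start <= 1244, , drop = FALSE]
  expect_equal(nrow(hit), 1)
  expect_equal(hit$start, 1234)
  expect_equal(hit$end, 1254)
  expect_equal(hit$edit_distance, 3)
  expect_equal(hit$edit_distance, adist_scan_oracle(read_seq, primer, 5))
  # every reported site's edit distance matches the oracle on its window
  for (i in seq_len(nrow(sites))) {
    win <- substr(read_seq, sites$start[i] + 1 - 5, sites$end[i] + 5)
    p <- if (sites$strand[i] == "+") primer else revcomp(primer)
    expect_equal(sites$edit_distance[i], adist_scan_oracle(win, p, 5))
  }
})

test_that("find_primer_sites finds minus-strand sites and warns on empty panel", {
  primer <- "AGAGTTTGATCCTGGCTCAG"
  read <- seq_records("r1", paste0(rand_dna(300, 3), revcomp(primer),
                                   rand_dna(300, 4)))
  sites <- find_primer_sites(read, seq_records("p1", primer))
  minus <- sites[sites$strand == "-", , drop = FALSE]
  expect_equal(nrow(minus), 1)
  expect_equal(minus$start, 300)
  expect_equal(minus$edit_distance, 0)
  expect_warning(out <- find_primer_sites(read, seq_records(character(),
                                                            character())),
                 "empty primer panel")
  expect_equal(nrow(out), 0)
  expect_error(find_primer_sites(read, seq_records("p", "ACGTACGT")),
               "at least 10 bp")
})

test_that("qc_filter applies length before primer count", {
  fake_sites <- function(n) if (n == 0) NULL else
    data.frame(read_id = "r", primer_name = "p", strand = "+",
               start = seq_len(n), end = seq_len(n) + 20, edit_distance = 0)
  r <- list(id = "r", seq = rand_dna(4500, 5))
  expect_equal(qc_filter(r, fake_sites(3))$status, "keep")
  short <- list(id = "r", seq = rand_dna(3999, 6))
  expect_equal(qc_filter(short, fake_sites(5))$reject_reason, "length")
  expect_equal(qc_filter(r, fake_sites(1))$reject_reason, "primer_count")
  # pure function of (length, site count): site permutation is irrelevant
  s <- fake_sites(3)
  expect_equal(qc_filter(r, s[3:1, ])$status, qc_filter(r, s)$status)
})

test_that("orient_read flips on strict minus majority with exact remapping", {
  primer <- "AGAGTTTGATCCTGGCTCAG"
  fwd <- paste0(primer, rand_dna(200, 7), primer, rand_dna(100, 8))
  panel <- seq_records("p1", primer)
  read <- seq_records("r1", fwd)
  sites <- find_primer_sites(read, panel)
  ori <- orient_read(as.list(read[1, ]), sites)
  expect_false(ori$flipped)                      # all sites already +
  expect_identical(ori$read$seq, fwd)

  # reverse-complemented read: involution back to the same orientation
  rc <- seq_records("r1", revcomp(fwd))
  rc_sites <- find_primer_sites(rc, panel)
  ori2 <- orient_read(as.list(rc[1, ]), rc_sites)
  expect_true(ori2$flipped)
  expect_identical(ori2$read$seq, fwd)
  expect_equal(ori2$sites$start, sites$start)    # coordinates remapped
  expect_equal(ori2$sites$strand, sites$strand)

  expect_error(orient_read(as.list(read[1, ]), NULL), "at least one")
})

test_that("orientation follows the strict majority rule on mixed strands", {
  primer <- "AGAGTTTGATCCTGGCTCAG"
  other <- "CCTACGGGAGGCAGCAGTGG"
  seqv <- paste0(revcomp(primer), rand_dna(150, 9), revcomp(other),
                 rand_dna(150, 10), primer)
  read <- seq_records("r1", seqv)
  sites <- find_primer_sites(read, seq_records(c("p1", "p2"),
                                               c(primer, other)))
  expect_equal(sum(sites$strand == "-"), 2)
  ori <- orient_read(as.list(read[1, ]), sites)
  expect_true(ori$flipped)
  # hand-computed flip: start_new = len - end_old
  len <- nchar(seqv)
  expect_equal(sort(ori$sites$start),
               sort(len - find_primer_sites(read, seq_records(
                 c("p1", "p2"), c(primer, other)))$end))
})

test_that("extraction recovers the 16S region of simulated reads", {
  ref <- small_ref(4)
  reads <- clean_reads(ref, ref$taxon_ids[1], 3)
  sites <- find_primer_sites(reads, ref$panel)
  r1 <- as.list(reads[1, ])
  s1 <- sites[sites$read_id == r1$id, ]
  # as in qc_reads, 23S extraction anchors use the high-confidence tier
  # (<= 0.15 * primer length edits): a permissive-tier chance 23S hit would
  # truncate the 16S, whereas 16S sites can only move its start 5'-ward
  s1 <- s1[s1$edit_distance <= 3 | grepl("^16S", s1$primer_name), ]
  ext <- extract_subunit(r1, s1, "16S")
  # error-free read: extraction runs from the 27F site to the 1600-bp cap,
  # so the reference 16S (1500 bp) is its exact prefix
  expect_identical(substr(ext$seq, 1, 1500), ref$sixteen_s$seq[1])
  ext23 <- extract_subunit(r1, s1, "23S")
  expect_identical(ext23$seq,
                   substr(ref$operons$seq[1], 1800 + 129 + 1, 4200))

  no16 <- s1[!grepl("^16S", s1$primer_name), ]
  expect_null(extract_subunit(r1, no16, "16S"))
})

test_that("noisy-read extraction aligns to the source 16S", {
  ref <- small_ref(4)
  reads <- noisy_reads(ref, ref$taxon_ids[2], 50, seed = 15)
  qc <- qc_reads(reads, ref$panel)
  ex <- qc$extracted_16s
  expect_gt(nrow(ex), 40)
  src <- ref$sixteen_s$seq[2]
  for (i in seq_len(min(nrow(ex), 50))) {
    o <- sw_oracle(ex$seq[i], src, type = "local")
    expect_gte(o$percent_identity, 80)
    cover <- (o$s_end - o$s_start + 1) / 1500
    expect_gte(cover, 0.9)
  }
})

test_that("the 20-read QC fixture keeps exactly its 8 good reads", {
  ref <- small_ref(4)
  good <- clean_reads(ref, ref$taxon_ids[1], 8)        # length 4200, sites
  polyca <- function(n) paste(rep("CA", ceiling(n / 2)), collapse = "")
  short <- vapply(1:4, function(i) substr(good$seq[1], 1, 3000), "")
  long <- vapply(1:2, function(i) paste0(good$seq[1], polyca(1500)), "")
  nosite <- vapply(1:6, function(i) substr(polyca(4500), 1, 4500), "")
  reads <- seq_records(
    c(sprintf("good_%d", 1:8), sprintf("short_%d", 1:4),
      sprintf("long_%d", 1:2), sprintf("nosite_%d", 1:6)),
    c(good$seq, short, long, nosite))
  qc <- qc_reads(reads, ref$panel)
  expect_setequal(qc$kept$id, sprintf("good_%d", 1:8))
  rep <- qc$report
  expect_equal(sum(rep$status == "keep"), 8)
  expect_true(all(rep$reason[grepl("^short|^long", rep$read_id)] == "length"))
  expect_true(all(rep$reason[grepl("^nosite", rep$read_id)] == "primer_count"))
})

test_that("qc_reads is deterministic and reports every read once", {
  ref <- small_ref(3)
  prof <- sample_community(ref, 2, 33)
  sim <- simulate_reads(prof, ref, 40, error_model(), 34)
  qc1 <- qc_reads(sim$reads, ref$panel)
  qc2 <- qc_reads(sim$reads, ref$panel)
  expect_identical(qc1$report, qc2$report)
  expect_identical(qc1$extracted_16s, qc2$extracted_16s)
  expect_setequal(qc1$report$read_id, sim$reads$id)
})
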