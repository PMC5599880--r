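# otu_classify: scoring, seeding, extension, best-hit assignment, tabulation

test_that("scoring scheme and seed template carry the published settings", {
  sc <- scoring_scheme()
  expect_equal(sc$match, 2)
  expect_equal(sc$mismatch, -3)
  expect_equal(sc$gap_open, 5)
  expect_equal(sc$gap_extend, 2)
  tpl <- seed_template()
  expect_equal(nchar(tpl$pattern), 18)
  expect_equal(sum(strsplit(tpl$pattern, "")[[1]] == "1"), 11)
  expect_match(tpl$pattern, "^1.*1$")
  expect_error(seed_template("110"), "11")
})

test_that("the seed index is exhaustive", {
  one <- build_index(seq_records("s1", rand_dna(18, 41)))
  st1 <- index_stats(one)
  expect_equal(st1$n_positions, 1)

  idx <- build_index(seq_records("s1", rand_dna(100, 42)))
  expect_equal(index_stats(idx)$n_positions, 83)   # 100 - 18 + 1

  twin <- rand_dna(100, 43)
  both <- build_index(seq_records(c("a", "b"), c(twin, twin)))
  expect_equal(index_stats(both)$n_positions, 166) # every key lists both
  expect_warning(build_index(seq_records(c("a", "b"), c(twin, "ACGT"))),
                 "shorter than the seed span")
})

test_that("sw_oracle reproduces the hand-computed scores", {
  expect_equal(sw_oracle("ACGT", "ACGT")$score, 8)
  expect_equal(sw_oracle("AAAA", "TTTT")$score, 0)
  expect_equal(sw_oracle("ACGTACGT", "ACGGACGT")$score, 11)  # 7*2 - 3
})

test_that("extend_alignment matches hand-computed affine-gap arithmetic", {
  s <- rand_dna(100, 44)
  hit <- extend_alignment(s, s)
  expect_equal(hit$score, 200)                    # 100 matches x 2
  expect_equal(hit$percent_identity, 100)

  q <- paste0(substr(s, 1, 50), substr(s, 54, 100))  # 3-bp deletion
  hit2 <- extend_alignment(q, s)
  expect_equal(hit2$score, 97 * 2 - (5 + 3 * 2))  # 183
  expect_equal(hit2$score, sw_oracle(q, s)$score) # confirmed by the oracle
})

test_that("seed-and-extend equals the local-DP oracle on noisy pairs", {
  # scaled-down version of the acceptance property (full size in
  # test-acceptance.R): 40 random 300-bp pairs at >= 80% identity
  set.seed(45)
  agree <- 0
  for (i in 1:40) {
    a <- rand_dna(300)
    b <- inject_errors_to_identity(a, sample(c(83, 88, 93, 98), 1),
                                   seed = 4500 + i)$seq
    ours <- extend_alignment(b, a, x_drop = 40)
    oracle <- sw_oracle(b, a)
    expect_lte(ours$score, oracle$score)          # never above the optimum
    if (ours$score == oracle$score) agree <- agree + 1
  }
  expect_gte(agree / 40, 0.95)
})

test_that("every reference classifies to itself at identity 100", {
  ref <- small_ref(20)
  idx <- build_index(ref)
  asn <- classify_reads(ref$sixteen_s, idx)
  expect_true(all(asn$classified))
  expect_equal(asn$otu_id, ref$taxon_ids)
  expect_true(all(asn$percent_identity == 100))
})

test_that("classification survives heavy error injection and rejects noise", {
  ref <- small_ref(20)
  idx <- build_index(ref)
  src <- ref$sixteen_s$seq[3]
  inj <- inject_errors_to_identity(src, 79, 46)
  asn <- classify_read(inj$seq, idx)
  expect_true(asn$classified)
  expect_equal(asn$otu_id, ref$taxon_ids[3])

  junk <- classify_read(rand_dna(1500, 47), idx)
  expect_false(junk$classified)
})

test_that("classification is independent of reference order", {
  ref <- small_ref(12)
  perm <- c(7, 3, 12, 1, 9, 5, 11, 2, 8, 10, 4, 6)
  shuffled <- seq_records(ref$sixteen_s$id[perm], ref$sixteen_s$seq[perm])
  idx1 <- build_index(ref)
  idx2 <- build_index(shuffled)
  queries <- seq_records(
    c("q1", "q2"),
    c(inject_errors_to_identity(ref$sixteen_s$seq[5], 85, 48)$seq,
      inject_errors_to_identity(ref$sixteen_s$seq[9], 85, 49)$seq))
  a1 <- classify_reads(queries, idx1)
  a2 <- classify_reads(queries, idx2)
  expect_equal(a1$otu_id, a2$otu_id)
  expect_equal(a1$score, a2$score)
})

test_that("tabulation and normalization follow the counting contracts", {
  asn <- data.frame(
    read_id = c("r1", "r2", "r3", "r4"),
    otu_id = c("a", "a", "b", NA),
    classified = c(TRUE, TRUE, TRUE, FALSE),
    sample_id = c("s1", "s1", "s1", "s1"), stringsAsFactors = FALSE)
  tab <- tabulate_assignments(asn)
  expect_equal(as.integer(tab[, "s1"]), c(2L, 1L))
  expect_equal(sum(tab[, "s1"]), 3)
  expect_equal(attr(tab, "unclassified")[["s1"]], 1L)

  none <- asn; none$classified <- FALSE; none$otu_id <- NA
  tab0 <- tabulate_assignments(none)
  expect_equal(nrow(tab0), 0)
  expect_equal(attr(tab0, "unclassified")[["s1"]], 4L)

  two <- rbind(asn, within(asn, sample_id <- "s2"))
  tab2 <- tabulate_assignments(two)
  expect_equal(tab2[, "s1"], tab2[, "s2"])        # no cross-talk

  m <- matrix(c(10, 30, 60), ncol = 1, dimnames = list(letters[1:3], "s1"))
  nm <- normalize_otu_table(m)
  expect_equal(as.numeric(nm), c(0.1, 0.3, 0.6))
  expect_equal(normalize_otu_table(m * 10), nm)   # scale invariance
  expect_equal(normalize_otu_table(nm), nm)       # idempotence
  m2 <- cbind(m, bad = c(0, 0, 0))
  expect_error(normalize_otu_table(m2), "bad")
})
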