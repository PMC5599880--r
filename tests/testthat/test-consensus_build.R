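# consensus_build: read selection, drafting, realignment, iterative scheme

test_that("select_otu_reads picks the top scorers deterministically", {
  asn <- data.frame(
    read_id = sprintf("r%02d", 1:40),
    otu_id = "otu1", classified = TRUE,
    score = c(rep(100, 5), rep(90, 30), rep(80, 5)),
    stringsAsFactors = FALSE)
  reads <- seq_records(asn$read_id, replicate(40, rand_dna(50)))
  sel <- select_otu_reads(asn, reads, "otu1", 30)
  expect_equal(nrow(sel), 30)
  expect_true(all(sprintf("r%02d", 1:5) %in% sel$id))    # top scores first
  expect_false(any(sprintf("r%02d", 36:40) %in% sel$id)) # worst left out
  expect_identical(sel$id, select_otu_reads(asn, reads, "otu1", 30)$id)

  expect_error(select_otu_reads(asn[1:29, ], reads, "otu1", 30),
               "below the 30-read")
})

test_that("draft_consensus is exact on identical and error-free reads", {
  s <- rand_dna(400, 51)
  ten <- seq_records(sprintf("c%d", 1:10), rep(s, 10))
  expect_identical(draft_consensus(ten), s)

  ref <- small_ref(2)
  reads <- clean_reads(ref, ref$taxon_ids[1], 10)
  expect_identical(draft_consensus(reads), ref$operons$seq[1])
})

test_that("realign_and_call keeps a perfect draft and fixes a wrong base", {
  s <- rand_dna(500, 52)
  reads <- seq_records(sprintf("c%d", 1:10), rep(s, 10))
  cons <- realign_and_call(s, reads)
  expect_identical(cons$sequence, s)
  expect_equal(cons$disagreements, 0)
  expect_equal(length(cons$per_column_coverage), nchar(cons$sequence))
  expect_true(all(cons$per_column_coverage <= 10))

  bad <- substitute_at(s, 250, seed = 53)
  fixed <- realign_and_call(bad, reads)
  expect_identical(fixed$sequence, s)            # plurality corrects it
})

test_that("iterative_consensus is an exact fixed point on error-free reads", {
  ref <- small_ref(2)
  reads <- clean_reads(ref, ref$taxon_ids[2], 30)
  it <- iterative_consensus(reads)
  src <- ref$operons$seq[2]
  expect_identical(it$final$sequence, src)
  stages <- names(it$records)
  expect_setequal(stages, c("con1A", "con2A", "finalA", "con1B", "con2B",
                            "finalB", "con1C", "con2C", "finalC"))
  for (st in stages) expect_identical(it$records[[st]]$sequence, src)

  expect_error(iterative_consensus(reads, schedule = c(10, 30, 20)),
               "ascending")
  expect_error(iterative_consensus(reads, schedule = c(10, 20, 25)),
               "schedule must end")
})

test_that("noisy-read consensus converges to the truth (scaled operon)", {
  # 1200-bp operon keeps this property suite fast; the full-size behavior
  # is exercised by the acceptance pipeline run
  model <- operon_model(len_16s = 500, len_its = 200, len_23s = 500,
                        anchor_offsets_16s = c(150, 350),
                        anchor_offsets_23s = c(100, 300))
  ref <- generate_reference_set(2, 0.15, model, 61)
  src <- ref$operons$seq[1]
  ok_draft <- 0; ok_polish <- 0
  for (sd in 1:5) {
    reads <- noisy_reads(ref, ref$taxon_ids[1], 30, seed = 600 + sd)
    ten <- reads[1:10, ]; class(ten) <- c("seq_records", "data.frame")
    draft <- draft_consensus(ten)
    if (sw_oracle(draft, src, type = "global")$percent_identity >= 97)
      ok_draft <- ok_draft + 1
    polished <- realign_and_call(src, reads)     # truth as draft
    if (sw_oracle(polished$sequence, src,
                  type = "global")$percent_identity >= 99.5)
      ok_polish <- ok_polish + 1
  }
  expect_gte(ok_draft, 4)
  expect_equal(ok_polish, 5)
})

test_that("consensus identity is non-decreasing along the schedule", {
  model <- operon_model(len_16s = 500, len_its = 200, len_23s = 500,
                        anchor_offsets_16s = c(150, 350),
                        anchor_offsets_23s = c(100, 300))
  ref <- generate_reference_set(2, 0.15, model, 62)
  src <- ref$operons$seq[1]
  mono <- 0
  for (sd in 1:5) {
    reads <- noisy_reads(ref, ref$taxon_ids[1], 30, seed = 700 + sd)
    it <- iterative_consensus(reads)
    ids <- vapply(c("con1A", "con2A", "finalA"), function(st)
      sw_oracle(it$records[[st]]$sequence, src,
                type = "global")$percent_identity, 0)
    if (all(diff(ids) >= -1e-9)) mono <- mono + 1
  }
  expect_gte(mono, 4)                            # >= 90% of seeds
})

test_that("iterative_consensus is byte-deterministic", {
  model <- operon_model(len_16s = 500, len_its = 200, len_23s = 500,
                        anchor_offsets_16s = c(150, 350),
                        anchor_offsets_23s = c(100, 300))
  ref <- generate_reference_set(2, 0.15, model, 63)
  reads <- noisy_reads(ref, ref$taxon_ids[1], 30, seed = 64)
  a <- iterative_consensus(reads)
  b <- iterative_consensus(reads)
  expect_identical(a$final$sequence, b$final$sequence)
  expect_identical(a$replicate, b$replicate)
})

test_that("replicate_consensus_identity computes pairwise identities", {
  s <- rand_dna(4200, 65)
  dup <- replicate_consensus_identity(list(s, s))
  expect_true(dup$all_identical)
  expect_true(all(dup$identity == 100))

  onesub <- substitute_at(s, 2100, seed = 66)
  pair <- replicate_consensus_identity(list(a = s, b = onesub))
  expect_false(pair$all_identical)
  expect_equal(pair$identity["a", "b"], 100 * 4199 / 4200, tolerance = 1e-9)
  expect_error(replicate_consensus_identity(list(s)), "at least 2")
})
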