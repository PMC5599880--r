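# synthetic_community: reference sets, profiles, mixtures, reads, injection

test_that("revcomp handles plain and IUPAC bases", {
  expect_equal(revcomp("ACGT"), "ACGT")
  expect_equal(revcomp("AACGT"), "ACGTT")
  expect_equal(revcomp("ACCGCCCCAGTHAAACT"), "AGTTTDACTGGGGCGGT")  # H -> D
  expect_equal(revcomp(revcomp("AGAGTTTGATCCTGGCTCAG")),
               "AGAGTTTGATCCTGGCTCAG")
})

test_that("operon_model validates its architecture", {
  m <- operon_model()
  expect_equal(operon_length(m), 4200)
  expect_equal(m$forward_primer, "AGAGTTTGATCCTGGCTCAG")
  expect_equal(m$reverse_primer, "ACCGCCCCAGTHAAACT")
  expect_error(operon_model(forward_primer = "ACGTX"), "IUPAC")
  expect_error(operon_model(anchor_offsets_16s = 1495), "16S anchor")
})

test_that("generate_reference_set honors divergence and determinism", {
  m <- operon_model()
  r0 <- generate_reference_set(1, 0, m, 11)
  expect_equal(r0$operons$seq[1], r0$ancestor)   # divergence 0 = ancestor
  expect_equal(nchar(r0$operons$seq[1]), 4200)
  expect_equal(r0$sixteen_s$seq[1], substr(r0$operons$seq[1], 1, 1500))

  r1 <- generate_reference_set(5, 0.15, m, 12)
  r2 <- generate_reference_set(5, 0.15, m, 12)
  expect_identical(r1$operons$seq, r2$operons$seq)  # determinism
  expect_error(generate_reference_set(5, 0.31, m, 1), "divergence")

  # realized divergence to the ancestor by direct column counting
  anc <- strsplit(r1$ancestor, "")[[1]]
  for (t in 1:5) {
    tx <- strsplit(r1$operons$seq[t], "")[[1]]
    d <- mean(tx != anc)
    # only non-conserved sites mutate; binomial 4-sigma bounds
    ivs <- ribopore:::conserved_intervals(m)
    n_cons <- sum(ivs[, 2] - ivs[, 1])
    p <- 0.15 * (4200 - n_cons) / 4200
    expect_lt(abs(d - p), 4 * sqrt(p * (1 - p) / 4200))
  }

  # conserved windows intact: the primer panel matches every taxon exactly
  panel <- r1$panel
  for (t in 1:5) {
    op <- r1$operons$seq[t]
    for (k in seq_len(nrow(panel))[-c(1, nrow(panel))])  # internal windows
      expect_true(grepl(panel$seq[k], op, fixed = TRUE))
  }
})

test_that("sample_community draws normalized, skewed, reproducible profiles", {
  ids <- sprintf("t%02d", 1:50)
  p0 <- sample_community(ids, 0, 1)
  expect_equal(as.numeric(p0), rep(1 / 50, 50))  # sigma 0 = uniform
  p2 <- sample_community(ids, 2, 1)
  expect_equal(sum(p2), 1, tolerance = 1e-9)
  expect_gt(max(p2), 1 / 50)                      # skew exists
  expect_identical(p2, sample_community(ids, 2, 1))
  expect_error(sample_community(ids, 2, 1, taxa = "zz"), "unknown taxa")
})

test_that("mix_profiles is exactly linear over the taxon union", {
  a <- structure(c(x = 1), class = "community_profile")
  b <- structure(c(y = 1), class = "community_profile")
  half <- mix_profiles(a, b, 0.5)
  expect_equal(as.numeric(half[c("x", "y")]), c(0.5, 0.5))
  expect_equal(as.numeric(mix_profiles(a, b, 1)["x"]), 1)
  expect_error(mix_profiles(a, b, 1.2), "fraction_a")

  ids <- sprintf("t%02d", 1:10)
  pa <- sample_community(ids, 2, 3)
  pb <- sample_community(ids, 2, 4)
  for (f in c(0, 0.1, 0.2, 0.5, 0.75, 1)) {
    mx <- mix_profiles(pa, pb, f)
    expect_equal(as.numeric(mx[ids]),
                 f * as.numeric(pa[ids]) + (1 - f) * as.numeric(pb[ids]))
  }
})

test_that("error_model validates rates", {
  em <- error_model()
  expect_equal(em$sub_rate + em$ins_rate + em$del_rate, 0.12)
  expect_error(error_model(0.5, 0.3, 0.3), "sum")
  expect_error(error_model(-0.1, 0, 0), "rates")
})

test_that("error-free single-taxon reads are exact copies up to orientation", {
  ref <- small_ref(3)
  prof <- structure(setNames(1, ref$taxon_ids[2]), class = "community_profile")
  sim <- simulate_reads(prof, ref, 20, error_model(0, 0, 0), 9,
                        junk_fraction = 0)
  src <- ref$operons$seq[2]
  for (i in 1:20) {
    s <- sim$reads$seq[i]
    if (sim$truth$orientation[i] == "-") s <- revcomp(s)
    expect_identical(s, src)
  }
  expect_equal(sort(sim$truth$read_id), sort(sim$reads$id))  # full truth
})

test_that("simulated reads match the error model in identity and length", {
  ref <- small_ref(2)
  prof <- structure(setNames(c(0.5, 0.5), ref$taxon_ids),
                    class = "community_profile")
  sim <- simulate_reads(prof, ref, 200, error_model(), 17, junk_fraction = 0)
  # mean length within [0.95, 1.05] * 4200 * (1 + ins - del)
  expect_lt(abs(mean(nchar(sim$reads$seq)) / 4200 - 1), 0.05)

  # realized identity to source ~ 88%: banded global identity for all reads,
  # cross-checked against the independent Biostrings oracle on a subset
  ops <- setNames(ref$operons$seq, ref$operons$id)
  als <- lapply(seq_len(200), function(i) {
    s <- sim$reads$seq[i]
    if (sim$truth$orientation[i] == "-") s <- revcomp(s)
    ribopore:::cpp_align_global(s, ops[[sim$truth$taxon_id[i]]],
                                2L, -3L, 5L, 2L, -1L)
  })
  expect_lt(abs(mean(vapply(als, `[[`, 0, "identity")) - 88), 1)
  for (i in seq(1, 200, by = 40)) {
    s <- sim$reads$seq[i]
    if (sim$truth$orientation[i] == "-") s <- revcomp(s)
    o <- sw_oracle(s, ops[[sim$truth$taxon_id[i]]], type = "global")
    # same optimum; co-optimal paths may differ slightly in column count
    expect_equal(als[[i]]$score, o$score)
    expect_equal(als[[i]]$identity, o$percent_identity, tolerance = 0.01)
  }
})

test_that("source counts follow the profile multinomially", {
  ref <- small_ref(2)
  prof <- structure(setNames(c(0.7, 0.3), ref$taxon_ids),
                    class = "community_profile")
  sim <- simulate_reads(prof, ref, 1000, error_model(0, 0, 0), 21,
                        junk_fraction = 0)
  n_x <- sum(sim$truth$taxon_id == ref$taxon_ids[1])
  expect_lt(abs(n_x - 700), 3 * sqrt(1000 * 0.7 * 0.3))
})

test_that("inject_errors_to_identity reaches its target", {
  s <- rand_dna(1500, 31)
  expect_equal(inject_errors_to_identity(s, 100, 1)$realized_identity, 100)
  inj <- inject_errors_to_identity(s, 79, 2)
  expect_gte(inj$realized_identity, 77)
  expect_lte(inj$realized_identity, 80)
  expect_identical(inj, inject_errors_to_identity(s, 79, 2))
  expect_error(inject_errors_to_identity(s, 60, 1), "target_identity")
})
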