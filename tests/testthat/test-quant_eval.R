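# quant_eval: mixture regression, rarefaction, sensitivity, reproducibility

test_that("mixture_design enumerates the quadruplicate ratio grid", {
  d <- mixture_design()
  expect_equal(nrow(d), 24)
  expect_equal(sort(unique(d$fraction_a)), c(0, 0.1, 0.2, 0.5, 0.75, 1))
  expect_equal(sum(d$fraction_a == 0.5), 4)
  expect_true(all(grepl("^mix\\d{3}_rep\\d$", d$sample_id)))
  expect_error(mixture_design(c(0, 1)), "at least 3")
  expect_error(mixture_design(c(0, 0.5, 2)), "fractions")
})

test_that("mixture_regression is exact on noiseless linear input", {
  d <- mixture_design()
  # two OTUs: one tracking end member A, one tracking B, plus a flat one
  freqs <- rbind(
    otuA = 0.1 + 0.004 * (100 * d$fraction_a),
    otuB = 0.5 - 0.004 * (100 * d$fraction_a),
    flat = rep(0.2, 24))
  colnames(freqs) <- d$sample_id
  for (aggregate in c(TRUE, FALSE)) {
    ra <- mixture_regression(freqs, d, "otuA", aggregate = aggregate)
    expect_equal(ra$r_squared, 1, tolerance = 1e-12)
    expect_equal(ra$slope, 0.004, tolerance = 1e-12)
    expect_equal(ra$polarity, "A")
    rb <- mixture_regression(freqs, d, "otuB", aggregate = aggregate)
    expect_equal(rb$r_squared, 1, tolerance = 1e-12)
    expect_equal(rb$polarity, "B")
    expect_equal(rb$slope, 0.004, tolerance = 1e-12)  # on its own axis
  }
  expect_error(mixture_regression(freqs, d, "nope"), "not in table")
})

test_that("replicate aggregation averages the four replicates per ratio", {
  d <- mixture_design()
  set.seed(71)
  y <- 0.1 + 0.004 * (100 * d$fraction_a) + rnorm(24, 0, 0.01)
  freqs <- rbind(otuA = y); colnames(freqs) <- d$sample_id
  agg <- mixture_regression(freqs, d, "otuA")
  expect_equal(agg$n, 6)
  per <- mixture_regression(freqs, d, "otuA", aggregate = FALSE)
  expect_equal(per$n, 24)
  # identical fitted line either way (equal replicate counts per ratio)
  expect_equal(agg$slope, per$slope, tolerance = 1e-12)
  expect_gte(agg$r_squared, per$r_squared)
})

test_that("top_k_response ranks by pure end-member abundance", {
  d <- mixture_design(replicates = 1)
  otus <- sprintf("o%d", 1:6)
  freqs <- matrix(0, 6, nrow(d), dimnames = list(otus, d$sample_id))
  weights_a <- c(0.5, 0.3, 0.1, 0.06, 0.03, 0.01)
  weights_b <- rev(weights_a)
  for (i in seq_len(nrow(d))) {
    f <- d$fraction_a[i]
    freqs[, i] <- f * weights_a + (1 - f) * weights_b
  }
  counts <- matrix(5L, 6, nrow(d), dimnames = dimnames(freqs))
  res <- top_k_response(freqs, d, k = 3, counts = counts)
  expect_equal(res$otu_id[res$end_member == "A"], otus[1:3])
  expect_equal(res$otu_id[res$end_member == "B"], otus[6:4])
  expect_true(all(res$r_squared > 1 - 1e-9))
  expect_true(all(res$low_count))                 # max count 5 < 10
})

test_that("rarefaction matches the hypergeometric closed form", {
  otu_ids <- rep(sprintf("o%d", 1:20), times = c(200, 100, 60, 40, rep(25, 8),
                                                 rep(10, 4), rep(5, 4)))
  depths <- c(1, 10, 50, 100, 300, length(otu_ids))
  rc <- rarefaction_curve(otu_ids, depths, n_resamples = 200, seed = 72)
  expect_true(all(diff(rc$mean_observed) >= 0))   # monotone
  expect_true(all(diff(rc$expected) >= 0))
  expect_equal(rc$expected[1], 1)
  expect_equal(rc$expected[length(depths)], 20)
  # Monte-Carlo agreement: binomial-style 4-sigma envelope per depth
  expect_true(all(abs(rc$mean_observed - rc$expected) <
                    4 * sqrt(20) / sqrt(200) + 1e-9))
  expect_error(rarefaction_curve(otu_ids, 10000, seed = 1), "depth exceeds")
  expect_error(rarefaction_curve(otu_ids, 0, seed = 1), ">= 1")
})

test_that("sensitivity_run reports a descending accuracy ladder", {
  ref <- small_ref(8)
  sens <- sensitivity_run(ref, source_ids = ref$taxon_ids[c(1, 4, 8)],
                          levels = c(100, 91, 82), n_per_level = 2,
                          seed = 73)
  expect_equal(nrow(sens$table), 3)
  expect_equal(sens$table$n, rep(6, 3))
  expect_equal(sens$table$accuracy[1], 1)         # level 100 is exact copies
  expect_true(all(abs(sens$table$mean_realized - sens$table$level) < 2.5))
  expect_true(sens$min_perfect_identity %in% c(100, 91, 82))
  expect_error(sensitivity_run(ref, levels = c(82, 91), seed = 1),
               "descending")
  expect_error(sensitivity_run(ref, source_ids = "zz", seed = 1), "absent")
})
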