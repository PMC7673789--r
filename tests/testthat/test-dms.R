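test_that("scoring normalises to the WT and reproduces exact ratios", {
  # v1 has output frequency exactly twice its input frequency; WT equal
  counts <- toy_counts(freq_in = c(0.1, 0.2), freq_out = c(0.2, 0.2),
                       depth = 1e4)
  cfg <- library_config(psi_wt = 50)
  sc <- score_variants(counts, cfg)
  wt <- sc[sc$variant_id == "WT", ]
  expect_equal(wt$es_norm, 1)
  expect_equal(wt$psi, 50)
  v1 <- sc[sc$variant_id == "v1", ]
  # ratios of frequencies survive the shared normalising constants
  # (tolerance covers count rounding in the fixture)
  expect_equal(v1$es_norm, 2, tolerance = 2e-3)
  expect_equal(v1$psi, 100, tolerance = 2e-3)
})

test_that("scoring is invariant to per-replicate sequencing depth", {
  counts <- toy_counts(freq_in = c(0.3, 0.1, 0.2),
                       freq_out = c(0.15, 0.1, 0.4), depth = 2e4)
  cfg <- library_config(60)
  base <- score_variants(counts, cfg)
  scaled <- counts
  scaled$input_2 <- scaled$input_2 * 7L     # one replicate sequenced deeper
  scaled$output_1 <- scaled$output_1 * 3L
  res <- score_variants(scaled, cfg)
  expect_equal(res$es_norm, base$es_norm, tolerance = 1e-12)
})

test_that("variants with no input reads are dropped, zero-count WT is fatal", {
  counts <- toy_counts(freq_in = c(0.2, 0.2), freq_out = c(0.2, 0.1))
  counts[counts$variant_id == "v1", c("input_1", "input_2")] <- 0L
  sc <- score_variants(counts, library_config(50))
  expect_false("v1" %in% sc$variant_id)
  expect_identical(attr(sc, "n_dropped"), 1L)
  bad <- counts
  bad[bad$variant_id == "WT", "input_1"] <- 0L
  expect_error(score_variants(bad, library_config(50)), "WT")
})

test_that("bayes correction matches fine-grid and closed-form oracles", {
  set.seed(42)
  for (i in 1:100) {
    psi_wt <- runif(1, 20, 99)
    cfg <- library_config(psi_wt)
    se <- runif(1, 0.02, 0.5)
    # scores up to 2 SE outside the admissible range (beyond that the
    # measurement is junk, not a correction candidate)
    es <- runif(1, -2 * se, cfg$es_max + 2 * se)
    got <- bayes_correct(es, se, cfg)
    expect_lt(abs(got - posterior_mean_oracle(es, se, cfg$es_max)), 1e-3)
    expect_lt(abs(got - truncnorm_mean(es, se, cfg$es_max)), 2e-3)
    expect_gte(got, 0)
    expect_lte(got, cfg$es_max)
  }
})

test_that("bayes correction collapses onto precise measurements", {
  cfg <- library_config(50)
  expect_equal(cfg$es_max, 2)
  expect_equal(bayes_correct(1.0, 1e-8, cfg), 1.0, tolerance = 1e-4)
  # out-of-range measurement with moderate error lands inside (1.5, 2)
  got <- bayes_correct(2.5, 0.3, cfg)
  expect_gt(got, 1.5)
  expect_lt(got, 2)
  # shrinkage decreases monotonically as the error shrinks
  es_grid <- seq(0.2, 1.8, by = 0.2)
  for (es in es_grid) {
    shift <- vapply(c(0.5, 0.2, 0.05, 0.01),
                    function(s) abs(bayes_correct(es, s, cfg) - es),
                    numeric(1))
    expect_true(all(diff(shift) <= 1e-9))
  }
})

test_that("mode adjustment recovers an injected offset and is equivariant", {
  set.seed(7)
  ref <- c(rnorm(300, 1, 0.05), runif(100, 0.2, 0.9))
  adj <- mode_adjust(ref, wt_es = 1)
  expect_lt(abs(attr(adj, "shift")), 0.02)       # already moded at 1
  shifted <- mode_adjust(ref + 0.15, wt_es = 1)
  expect_lt(abs(attr(shifted, "shift") + 0.15), 0.02)
  expect_lt(max(abs(as.numeric(shifted) - as.numeric(adj))), 0.03)
  one <- mode_adjust(0.8, wt_es = 1)
  expect_equal(as.numeric(one), 1)
})

test_that("full pipeline recovers true PSI and keeps WT at psi_wt", {
  cfg <- sim_config(seed = 2024)
  d <- gen_dms(cfg)
  lib <- library_config(cfg$dms$psi_wt)
  sc <- dms_pipeline(d$counts, lib)
  expect_true(all(sc$psi_corrected >= 0 & sc$psi_corrected <= 100))
  m <- merge(sc, d$truth, by = "variant_id")
  expect_gt(cor(m$psi_corrected, m$true_psi), 0.95)
  expect_gt(cor(m$psi_corrected, m$true_psi, method = "spearman"), 0.95)
  wt_psi <- sc$psi_corrected[sc$variant_id == "WT"]
  expect_lt(abs(wt_psi - cfg$dms$psi_wt), 0.5)
})

test_that("pipeline bounds hold even for scores implying PSI > 100", {
  # inclusion-promoting variant at high psi_wt: raw psi exceeds 100
  counts <- toy_counts(freq_in = c(0.05, 0.05), freq_out = c(0.08, 0.05),
                       depth = 5e4)
  cfg <- library_config(95)
  sc <- dms_pipeline(counts, cfg)
  expect_gt(max(sc$psi), 100)            # uncorrected estimate overshoots
  expect_true(all(sc$psi_corrected <= 100))
})

test_that("pooled-input design reuses summed input frequencies", {
  counts <- toy_counts(freq_in = c(0.2, 0.3), freq_out = c(0.1, 0.3),
                       depth = 1e4, n_rep = 3)
  cfg_pool <- library_config(50, pool_inputs = TRUE)
  sc <- score_variants(counts, cfg_pool)
  # identical replicate frequencies: pooling must not change the scores
  sc0 <- score_variants(counts, library_config(50))
  expect_equal(sc$es_norm, sc0$es_norm, tolerance = 1e-12)
})

test_that("junction PSI applies the read threshold", {
  expect_equal(psi_from_junctions(90, 10), 90)
  expect_true(is.na(psi_from_junctions(5, 3)))
  expect_equal(psi_from_junctions(0, 50), 0)
  expect_equal(psi_from_junctions(7, 3), 70)   # exactly at the threshold
  expect_equal(psi_from_junctions(c(90, 5), c(10, 3)), c(90, NA))
  expect_error(psi_from_junctions(-1, 5), "nonnegative")
})
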