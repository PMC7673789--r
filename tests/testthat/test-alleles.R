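test_that("dosage regression matches closed-form OLS on collinear points", {
  # suppressWarnings: base R flags the exact collinear fit as "perfect"
  eff <- suppressWarnings(
    fit_allele_effect(c(50, 55, 60), c(0, 1, 2), min_samples = 3))
  expect_equal(eff$slope, 5)
  expect_equal(eff$delta_psi, 10)
  expect_equal(eff$starting_psi, 50)
  flat <- suppressWarnings(
    fit_allele_effect(c(40, 40, 40, 40), c(0, 1, 2, 1), min_samples = 3))
  expect_equal(flat$delta_psi, 0)
  # degenerate inputs are flagged, not guessed
  expect_false(fit_allele_effect(c(50, 60, 70), c(1, 1, 1),
                                 min_samples = 3)$estimable)
  expect_false(fit_allele_effect(c(50, 60), c(0, 1),
                                 min_samples = 3)$estimable)
})

test_that("planted cohort effects are recovered within tolerance", {
  cfg <- sim_config(seed = 402, cohort = list(n_variants = 60L))
  co <- gen_cohort(cfg)
  eff <- fit_all_allele_effects(co$genotypes, co$psi_by_tissue)
  m <- merge(eff, co$truth, by = "variant_id")
  expect_gt(nrow(m), 50)
  # individual estimates land within a few PSI units of the truth
  expect_lt(stats::median(abs(m$delta_psi - m$true_delta_psi)), 2)
  expect_lt(abs(mean(m$delta_psi - m$true_delta_psi)), 0.5)
  # intercept extrapolates the starting PSI
  expect_lt(stats::median(abs(m$starting_psi - m$psi_start)), 2)
})

test_that("estimator is calibrated over many planted variants", {
  cfg <- sim_config(seed = 77, cohort = list(n_variants = 500L))
  co <- gen_cohort(cfg)
  eff <- fit_all_allele_effects(co$genotypes, co$psi_by_tissue)
  m <- merge(eff, co$truth, by = "variant_id")
  expect_gt(nrow(m), 450)
  expect_lt(abs(mean(m$delta_psi - m$true_delta_psi)), 0.5)
  # 95% CI coverage of the homozygous effect (2 * slope)
  half <- 2 * m$se_slope * stats::qt(0.975, m$n_samples - 2)
  covered <- abs(m$delta_psi - m$true_delta_psi) <= half
  expect_gte(mean(covered), 0.92)
  expect_lte(mean(covered), 0.97)
})

test_that("null cohorts rarely produce large-effect calls", {
  cfg <- sim_config(seed = 55, cohort = list(n_variants = 400L,
                                             frac_null = 1))
  co <- gen_cohort(cfg)
  eff <- fit_all_allele_effects(co$genotypes, co$psi_by_tissue)
  expect_lt(mean(abs(eff$delta_psi) > 10), 0.01)
})

test_that("intercept filter removes out-of-range fits without clamping", {
  cfg <- sim_config(seed = 91, cohort = list(n_variants = 150L))
  co <- gen_cohort(cfg)
  eff <- fit_all_allele_effects(co$genotypes, co$psi_by_tissue)
  expect_true(all(eff$starting_psi >= 0 & eff$starting_psi <= 100))
  n_filtered <- attr(eff, "n_intercept_filtered")
  # total accounting: estimable fits = kept + filtered
  raw <- sum(vapply(seq_len(nrow(co$genotypes$variants)), function(i) {
    fit_allele_effect(co$psi_by_tissue[[1]][co$truth$exon_id[i], ],
                      co$genotypes$copies[i, ])$estimable
  }, logical(1)))
  expect_equal(nrow(eff) + n_filtered, raw)
})

test_that("per-event pruning keeps the smallest p and enforces cross-exclusion", {
  eff <- data.frame(
    variant_id = c("v1", "v2", "v3", "v4", "v5"),
    exon_id = c("E1", "E1", "E1", "E2", "E2"),
    tissue = "t1",
    region = c("exonic", "intronic", "exonic", "intronic", "exonic"),
    p_value = c(0.5, 0.01, 0.2, 0.03, 0.001),
    delta_psi = 1:5, starting_psi = 50,
    stringsAsFactors = FALSE)
  pr <- prune_per_event(eff)
  expect_equal(nrow(pr$pruned), 2)
  expect_equal(pr$pruned$variant_id[pr$pruned$exon_id == "E1"], "v2")
  # E1 claimed by an intronic winner: absent from the exonic analysis,
  # and conversely for E2 (exonic winner v5)
  expect_false("E1" %in% effects_for_region(pr, "exonic")$exon_id)
  expect_true("E1" %in% effects_for_region(pr, "intronic")$exon_id)
  expect_false("E2" %in% effects_for_region(pr, "intronic")$exon_id)
  expect_true("E2" %in% effects_for_region(pr, "exonic")$exon_id)
  # exact p ties resolve deterministically by the stated tie-break
  tie <- data.frame(variant_id = c("b", "a"), exon_id = "E", tissue = "t",
                    region = "exonic", p_value = 0.05,
                    position = c(10, 30), exon_midpoint = 15,
                    stringsAsFactors = FALSE)
  expect_equal(prune_per_event(tie)$pruned$variant_id, "b")  # closer to mid
  tie$position <- c(20, 10)
  expect_equal(prune_per_event(tie)$pruned$variant_id, "a")  # equidistant -> id
})

test_that("equal binning summarises effects per starting-PSI stratum", {
  eff <- data.frame(variant_id = sprintf("v%02d", 1:10),
                    starting_psi = seq(5, 95, by = 10),
                    delta_psi = c(0, 0, 15, -20, 30, -12, 4, 1, 0, 0))
  b <- bin_equal(eff, 5)
  expect_equal(b$n, rep(2, 5))
  expect_equal(b$frac_gt_threshold, c(0, 1, 1, 0, 0))
  expect_equal(b$median_abs_delta[3], 21)   # median of |30|, |-12|
  zero <- eff; zero$delta_psi <- 0
  bz <- bin_equal(zero, 5)
  expect_true(all(bz$frac_gt_threshold == 0) && all(bz$median_abs_delta == 0))
  expect_error(bin_equal(eff[1:3, ], 5), "fewer")
  # permutation invariance
  perm <- eff[sample.int(10), ]
  expect_equal(bin_equal(perm, 5), b)
})

test_that("middle starting-PSI bins carry the largest effects under the scaling law", {
  set.seed(120)
  n <- 3000
  p0 <- 100 * stats::rbeta(n, 0.4, 0.4)      # bimodal starting PSIs
  p0 <- pmin(pmax(p0, 0.5), 99.5)
  A <- stats::rlnorm(n, -0.2, 0.6)
  eff <- data.frame(variant_id = sprintf("v%04d", 1:n),
                    starting_psi = p0,
                    delta_psi = predict_final_psi(A, p0) - p0)
  b <- bin_equal(eff, 5)
  expect_gt(b$frac_gt_threshold[3], b$frac_gt_threshold[5])
  expect_gt(b$frac_gt_threshold[3], b$frac_gt_threshold[1])
})

test_that("exon classification follows the all-tissues rule", {
  psis <- matrix(c(95, 96, 97,
                   95, 85, 97,
                   NA, 92, 91,
                   10, NA, 50), nrow = 4, byrow = TRUE)
  exons <- data.frame(exon_id = paste0("e", 1:4), length = 100)
  at <- psi_atlas(exons, psis)
  cl <- classify_exons(at)
  expect_equal(as.character(cl$class),
               c("constitutive", "alternative", "constitutive", "alternative"))
  # stricter alternative definition opens a gap between the classes
  cl2 <- classify_exons(at, constitutive_min = 90, alternative_max = 60)
  expect_equal(as.character(cl2$class),
               c("constitutive", NA, "constitutive", "alternative"))
})

test_that("class comparison recovers a planted extra effect in alternative exons", {
  set.seed(300)
  n <- 2000
  cls <- sample(c("constitutive", "alternative"), n, replace = TRUE)
  p0 <- runif(n, 60, 95)
  delta <- -0.1 * p0 + rnorm(n, 0, 4)
  delta[cls == "alternative"] <- delta[cls == "alternative"] - 5
  eff <- data.frame(exon_id = paste0("e", 1:n), delta_psi = delta,
                    starting_psi = p0)
  classes <- data.frame(exon_id = eff$exon_id,
                        class = factor(cls, levels = c("constitutive",
                                                       "alternative")))
  res <- compare_exon_classes(eff, classes)
  expect_lt(abs(res$coefficient + 5), 1)
  expect_lt(res$p_value, 1e-6)
  # single-class input is an error
  expect_error(compare_exon_classes(
    eff, transform(classes, class = factor("constitutive",
      levels = levels(classes$class)))), "both")
})

test_that("class comparison is null-calibrated under random labels", {
  set.seed(11)
  n <- 400
  p0 <- runif(n, 50, 95)
  eff <- data.frame(exon_id = paste0("e", 1:n),
                    delta_psi = -0.1 * p0 + rnorm(n, 0, 5),
                    starting_psi = p0)
  pvals <- replicate(200, {
    classes <- data.frame(exon_id = eff$exon_id,
                          class = factor(sample(c("constitutive", "alternative"),
                                                n, replace = TRUE),
                                         levels = c("constitutive",
                                                    "alternative")))
    compare_exon_classes(eff, classes)$p_value
  })
  ks <- stats::ks.test(pvals, "punif")
  expect_gt(ks$p.value, 0.01)
  expect_lt(abs(mean(pvals < 0.05) - 0.05), 0.05)
})

test_that("threshold sweep yields finite coefficients where both classes exist", {
  cfg <- sim_config(seed = 19, atlas = list(n_exons = 300L, n_tissues = 3L))
  at <- gen_atlas(cfg)
  set.seed(19)
  idx <- sample(nrow(at$psi), 200, replace = TRUE)
  eff <- data.frame(exon_id = at$exons$exon_id[idx],
                    starting_psi = runif(200, 40, 99),
                    delta_psi = rnorm(200, -5, 6))
  sweep <- class_threshold_sweep(eff, at,
                                 constitutive_grid = seq(60, 95, length.out = 6),
                                 alternative_grid = seq(60, 95, length.out = 6))
  expect_equal(dim(sweep), c(6, 6))
  expect_true(any(is.finite(sweep)))
  expect_true(all(is.finite(sweep[!is.na(sweep)])))
})

test_that("condition comparison aligns constructs and drops unmatched ids", {
  a <- c(x = 50, y = 70, z = 20)
  b <- c(y = 90, x = 50, w = 10)
  cd <- condition_delta(a, b)
  expect_equal(cd$delta_psi[cd$construct_id == "x"], 0)
  expect_equal(cd$delta_psi[cd$construct_id == "y"], 20)
  expect_equal(attr(cd, "n_unmatched"), 2)
  # identical conditions: all zero
  expect_true(all(condition_delta(a, a)$delta_psi == 0))
})

test_that("a trans perturbation is strongest at intermediate starting PSI", {
  set.seed(8)
  n <- 2000
  p0 <- 100 * stats::rbeta(n, 0.5, 0.5)
  p0 <- pmin(pmax(p0, 0.5), 99.5)
  names(p0) <- paste0("c", 1:n)
  # condition B multiplies every construct's efficiency by a fixed factor
  A0 <- estimate_A(rep(0, n), p0)            # all 1, by construction
  pb <- predict_final_psi(as.numeric(A0) * 0.5, p0)
  names(pb) <- names(p0)
  cd <- condition_delta(p0, pb)
  b <- bin_equal(cd[, c("starting_psi", "delta_psi")], 5)
  mid_vs_edges <- b$median_abs_delta[3] >
    max(b$median_abs_delta[c(1, 5)])
  expect_true(mid_vs_edges)
})
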