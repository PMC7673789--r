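test_that("motif density counts overlapping windows", {
  ese <- hexamer_set("AAAAAA")
  d <- motif_density("AAAAAAA", ese)
  expect_equal(d$count, 2)
  expect_equal(d$density, 2 / 7)
  expect_equal(motif_density("ACGTACGTA", hexamer_set(character(0)))$count, 0)
  # the complete hexamer universe matches every window
  all_hex <- hexamer_set(apply(expand.grid(rep(list(c("A", "C", "G", "T")), 6)),
                               1, paste, collapse = ""))
  set.seed(1)
  s <- paste(sample(c("A", "C", "G", "T"), 200, replace = TRUE), collapse = "")
  expect_equal(motif_density(s, all_hex)$count, 195)
  expect_error(motif_density("ACGTN", ese), "6 nt|non-ACGT")
  expect_error(motif_density("ACGTNACGT", ese), "non-ACGT")
})

test_that("suboptimal set is the single-substitution neighbourhood", {
  one <- suboptimal_set(hexamer_set("AAAAAA"))
  expect_length(one, 18)
  expect_false("AAAAAA" %in% one)
  expect_setequal(as.character(one), neighbours_oracle("AAAAAA"))
  # mutual neighbours are retained
  pair <- suboptimal_set(hexamer_set(c("AAAAAA", "AAAAAT")))
  expect_true(all(c("AAAAAA", "AAAAAT") %in% pair))
  # the full universe is closed under substitution
  all_hex <- hexamer_set(apply(expand.grid(rep(list(c("A", "C", "G", "T")), 6)),
                               1, paste, collapse = ""))
  expect_length(suboptimal_set(all_hex), 4096)
})

test_that("robustness scores match the enumeration oracle on random sets", {
  expect_equal(robustness_score("AAAAAA", hexamer_set("AAAAAA")), 0)
  expect_equal(robustness_score("AAAAAA",
                                hexamer_set(c("AAAAAA", "AAAAAT", "CAAAAA"))), 2)
  expect_error(robustness_score("CCCCCC", hexamer_set("AAAAAA")), "member")
  set.seed(77)
  for (i in 1:1000) {
    motifs <- hexamer_set(random_hexamers(sample(5:60, 1)))
    h <- as.character(motifs)[sample.int(length(motifs), 1)]
    expect_identical(robustness_score(h, motifs),
                     sum(neighbours_oracle(h) %in% motifs))
  }
  # group counts over a set partition it completely
  set.seed(8)
  motifs <- gen_motif_set(80, connectivity = 0.6)
  scores <- robustness_scores(motifs)
  expect_length(scores, 80)
  expect_true(all(scores >= 0 & scores <= 18))
  expect_equal(sum(table(scores)), length(motifs))
})

test_that("mutational scan matches the recount-all-windows oracle", {
  set.seed(55)
  bases <- c("A", "C", "G", "T")
  for (rep in 1:40) {
    L <- sample(10:60, 1)
    s <- paste(sample(bases, L, replace = TRUE), collapse = "")
    ese <- hexamer_set(unique(c(random_hexamers(20),
                                substring(s, 1, 6))))  # ensure some hits
    ess <- hexamer_set(random_hexamers(15), role = "ESS")
    scan <- mutational_motif_scan(s, ese, ess)
    # oracle: recount windows before/after every possible substitution
    for (pos in seq_len(L)) {
      for (alt in setdiff(bases, substr(s, pos, pos))) {
        mut <- s
        substr(mut, pos, pos) <- alt
        n0 <- nchar(s)
        w0 <- substring(s, 1:(n0 - 5), 6:n0)
        w1 <- substring(mut, 1:(n0 - 5), 6:n0)
        lost <- sum(w0 %in% ese & !(w1 %in% ese))
        gained <- sum(!(w0 %in% ese) & w1 %in% ese)
        ess_gain <- sum(!(w0 %in% ess) & w1 %in% ess)
        row <- scan[scan$position == pos & scan$alt == alt, ]
        if (lost == 0) {
          expect_equal(nrow(row), 0)
        } else {
          expect_equal(row$ese_lost, lost)
          expect_equal(row$ese_gained, gained)
          expect_equal(row$ess_gained, ess_gain)
        }
      }
    }
  }
})

test_that("scan handles the canonical single-window and overlap cases", {
  # one ESE spanning the whole sequence: every mutation loses it, none
  # can create a shifted copy
  scan <- mutational_motif_scan("AAAAAA", hexamer_set("AAAAAA"))
  expect_equal(nrow(scan), 18)
  expect_true(all(scan$ese_lost == 1))
  expect_true(all(scan$ese_gained == 0))
  # empty motif set: nothing to disrupt
  expect_equal(nrow(mutational_motif_scan("ACGTACGTACGT",
                                          hexamer_set(character(0)))), 0)
  # planted overlapping pair sharing 5 nt: one mutation kills both
  seq <- paste0("GGG", "TACGTAC", "GGGCCCGGGCCC")  # TACGTA + ACGTAC overlap
  ese <- hexamer_set(c("TACGTA", "ACGTAC"))
  scan2 <- mutational_motif_scan(seq, ese)
  expect_gte(max(scan2$ese_lost), 2)
})

test_that("overlap counting is pairwise window intersection", {
  ese <- hexamer_set("AAAAAA")
  expect_equal(overlap_count("AAAAAAA", ese), 1)
  expect_equal(overlap_count(paste0("AAAAAA", "CCCCCC", "AAAAAA"), ese), 0)
  # triple overlap: three mutually intersecting occurrences -> 3 pairs
  expect_equal(overlap_count("AAAAAAAA", ese), 3)
  # interval-intersection oracle on random sequences
  set.seed(3)
  for (i in 1:25) {
    s <- paste(sample(c("A", "T"), 40, replace = TRUE), collapse = "")
    motifs <- hexamer_set(random_hexamers(10))
    starts <- which(substring(s, 1:35, 6:40) %in% motifs)
    oracle <- if (length(starts) < 2) 0 else
      sum(utils::combn(starts, 2)[2, ] - utils::combn(starts, 2)[1, ] < 6)
    expect_equal(overlap_count(s, motifs), oracle)
  }
})

test_that("decile enrichment detects planted density differences and nulls", {
  cfg <- sim_config(seed = 500, sequences = list(n_per_class = 250L))
  sq <- gen_sequences(cfg)
  de <- decile_enrichment(sq$exons, sq$ese)
  expect_equal(sum(de$n), nrow(sq$exons))
  expect_true(all(abs(de$n - nrow(sq$exons) / 10) <= 1))
  # constitutive exons (1.5x implant rate) dominate the top deciles
  top <- mean(de$prop_constitutive[9:10])
  bottom <- mean(de$prop_constitutive[1:2])
  expect_gt(top, bottom)
  # null: equal multipliers give a flat profile
  cfg0 <- sim_config(seed = 501, sequences = list(
    n_per_class = 250L,
    density_multiplier = c(constitutive = 1, alternative = 1)))
  sq0 <- gen_sequences(cfg0)
  # density ties break by exon id; ids must not encode the class for the
  # null to hold, so relabel them at random
  set.seed(42)
  sq0$exons$exon_id <- sprintf("r%04d", sample.int(nrow(sq0$exons)))
  de0 <- decile_enrichment(sq0$exons, sq0$ese)
  counts <- cbind(round(de0$prop_constitutive * de0$n),
                  round(de0$prop_alternative * de0$n))
  expect_gt(suppressWarnings(stats::chisq.test(counts)$p.value), 0.01)
})

test_that("decile bins stay equal-sized under massive density ties", {
  exons <- data.frame(
    exon_id = sprintf("t%02d", 1:20),
    sequence = strrep("ACGTAC", 20),     # identical density everywhere
    class = factor(rep(c("constitutive", "alternative"), 10),
                   levels = c("constitutive", "alternative")),
    stringsAsFactors = FALSE)
  de <- decile_enrichment(exons, hexamer_set("ACGTAC"))
  expect_true(all(de$n == 2))
  expect_error(decile_enrichment(exons[1:5, ], hexamer_set("ACGTAC")),
               "at least")
})

test_that("robustness profile contrasts classes per score group", {
  cfg <- sim_config(seed = 321, sequences = list(n_per_class = 80L,
                                                 connectivity = 0.7))
  sq <- gen_sequences(cfg)
  prof <- robustness_profile(sq$exons, sq$ese)
  expect_true(all(prof$score %in% 0:18))
  expect_equal(sum(prof$n_motifs), length(sq$ese))
  expect_true(all(prof$density_constitutive >= 0))
})
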