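#' Simulation configuration
#'
#' One configuration object drives every generator, so a full synthetic
#' workspace is a pure function of `(config, seed)`. Defaults describe
#' the study conditions the package's analyses assume: a doped mini-gene
#' DMS library on an exon included at intermediate levels, a strongly
#' bimodal exon-inclusion atlas, a population cohort with common alleles,
#' and exon sequences with class-dependent enhancer densities.
#'
#' @param seed integer seed (mandatory; all generators derive their
#'   randomness from it).
#' @param dms list overriding the DMS block: `exon_length` (63 nt),
#'   `psi_wt` (49), `meanlog`/`sdlog` of the log-normal efficiency-effect
#'   distribution for splice-altering mutations (-0.1, 0.5 — chosen so
#'   roughly 43% of such mutations move an exon at PSI 50 by at least 10
#'   units), `neutral_frac`/`neutral_sdlog` (0.4, 0.05 — the fraction of
#'   mutations with essentially no splicing effect, drawn tightly around
#'   A = 1; single-mutant score distributions spike at the wild-type
#'   score, which is what the mode adjustment relies on),
#'   `n_replicates` (3), `depth` (1e6 reads per replicate, matching the
#'   deep per-variant coverage of mini-gene DMS sequencing), `wt_weight`
#'   (10, the wild type's library abundance relative to one variant).
#' @param atlas list overriding the atlas block: `n_exons` (2000),
#'   `n_tissues` (5), `intermediate_mass` (0.28, the target fraction of
#'   entries with 10 < PSI < 90), `mixture` (optional explicit data frame
#'   `weight`, `shape1`, `shape2` of Beta components on \[0,1\] scale,
#'   overriding the solved default), `length_meanlog`/`length_sdlog`
#'   (log(120), 0.45), `missing_rate` (0.05).
#' @param cohort list overriding the cohort block: `n_samples` (300),
#'   `n_variants` (100), `maf_range` (c(0.05, 0.5)), `noise_sd` (5 PSI
#'   units), `meanlog`/`sdlog` of planted efficiency effects (-0.1, 0.5),
#'   `frac_null` (0; fraction of variants planted with A = 1).
#' @param sequences list overriding the sequence block: `n_per_class`
#'   (300), `length` (120 nt), `n_motifs` (120 enhancers),
#'   `connectivity` (0.5, probability a new motif is drawn as a neighbour
#'   of an existing one), `base_rate` (0.02 implants per nucleotide),
#'   `density_multiplier` (named, constitutive 1.5, alternative 1.0).
#' @return a `sim_config` list.
#' @export
sim_config <- function(seed, dms = list(), atlas = list(), cohort = list(),
                       sequences = list()) {
  if (missing(seed)) stop("a seed is mandatory", call. = FALSE)
  cfg <- list(
    seed = as.integer(seed),
    dms = utils::modifyList(list(
      exon_length = 63L, psi_wt = 49, meanlog = -0.1, sdlog = 0.5,
      neutral_frac = 0.4, neutral_sdlog = 0.05,
      n_replicates = 3L, depth = 1e6, wt_weight = 10), dms),
    atlas = utils::modifyList(list(
      n_exons = 2000L, n_tissues = 5L, intermediate_mass = 0.28,
      mixture = NULL, length_meanlog = log(120), length_sdlog = 0.45,
      missing_rate = 0.05), atlas),
    cohort = utils::modifyList(list(
      n_samples = 300L, n_variants = 100L, maf_range = c(0.05, 0.5),
      noise_sd = 5, meanlog = -0.1, sdlog = 0.5, frac_null = 0), cohort),
    sequences = utils::modifyList(list(
      n_per_class = 300L, length = 120L, n_motifs = 120L,
      connectivity = 0.5, base_rate = 0.02,
      density_multiplier = c(constitutive = 1.5, alternative = 1.0)),
      sequences))
  if (cfg$cohort$maf_range[1] < 0.05)
    stop("allele frequencies below 0.05 are out of scope (common alleles only)",
         call. = FALSE)
  structure(cfg, class = "sim_config")
}

.rand_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                      replace = TRUE), collapse = "")

#' Generate a DMS variant-count table with known ground truth
#'
#' Simulates a doped-library mutagenesis experiment on one exon: every
#' single-nucleotide substitution receives a true efficiency effect drawn
#' from the configured log-normal, its true PSI follows from the scaling
#' law at `psi_wt`, input counts are multinomial over the library, and
#' output (inclusion-band) counts are multinomial with per-variant weight
#' proportional to input frequency times `true_psi / psi_wt`.
#'
#' @param config a [sim_config()].
#' @return list with `counts` (data frame in the layout
#'   [score_variants()] reads), `truth` (data frame `variant_id`,
#'   `true_A`, `true_psi`), `sequence` (the wild-type exon),
#'   and `config_dms` (the block used).
#' @export
gen_dms <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cd <- config$dms
  set.seed(config$seed)
  L <- cd$exon_length
  wt_seq <- .rand_seq(L)
  chars <- strsplit(wt_seq, "")[[1]]
  bases <- c("A", "C", "G", "T")
  pos <- rep(seq_len(L), each = 3L)
  alt <- unlist(lapply(chars, function(r) bases[bases != r]))
  ref <- chars[pos]
  ids <- paste0(ref, pos, alt)
  nv <- length(ids)

  true_A <- stats::rlnorm(nv, cd$meanlog, cd$sdlog)
  neutral <- stats::runif(nv) < cd$neutral_frac
  true_A[neutral] <- stats::rlnorm(sum(neutral), 0, cd$neutral_sdlog)
  true_psi <- predict_final_psi(true_A, cd$psi_wt)

  lib_w <- c(cd$wt_weight, rep(1, nv))          # WT first
  in_p <- lib_w / sum(lib_w)
  out_w <- in_p * c(1, true_psi / cd$psi_wt)
  out_p <- out_w / sum(out_w)
  if (cd$depth < 10 * (nv + 1))
    warning("sequencing depth is low relative to library size", call. = FALSE)

  inm <- stats::rmultinom(cd$n_replicates, cd$depth, in_p)
  outm <- stats::rmultinom(cd$n_replicates, cd$depth, out_p)
  counts <- data.frame(variant_id = c("WT", ids),
                       position = c(NA_integer_, pos),
                       ref = c(NA_character_, ref),
                       alt = c(NA_character_, alt),
                       stringsAsFactors = FALSE)
  for (r in seq_len(cd$n_replicates)) counts[[paste0("input_", r)]] <- inm[, r]
  for (r in seq_len(cd$n_replicates)) counts[[paste0("output_", r)]] <- outm[, r]
  list(counts = counts,
       truth = data.frame(variant_id = ids, true_A = true_A,
                          true_psi = true_psi, stringsAsFactors = FALSE),
       sequence = wt_seq, config_dms = cd)
}

# solve three-component Beta mixture weights for a target 10-90 mass
.default_mixture <- function(intermediate_mass) {
  comp <- data.frame(shape1 = c(40, 1, 2), shape2 = c(1, 40, 2))
  inter <- stats::pbeta(0.9, comp$shape1, comp$shape2) -
    stats::pbeta(0.1, comp$shape1, comp$shape2)
  # weight m on the intermediate component; the remainder split 60/40
  # between the high- and low-inclusion components
  base <- 0.6 * inter[1] + 0.4 * inter[2]
  m <- (intermediate_mass - base) / (inter[3] - base)
  if (m < 0 || m > 1)
    stop("intermediate_mass outside the achievable range", call. = FALSE)
  comp$weight <- c(0.6 * (1 - m), 0.4 * (1 - m), m)
  comp
}

#' Generate a bimodal exon-by-tissue PSI atlas
#'
#' Per-exon, per-tissue PSI values are drawn from a Beta mixture (scaled
#' to 0-100) whose default components put most mass near full inclusion
#' or full skipping, with the mixture weights solved so the pooled
#' fraction of intermediate entries (10 < PSI < 90) equals the configured
#' target. Exon lengths are log-normal; a configurable fraction of
#' entries is masked missing (events under the read threshold).
#'
#' @param config a [sim_config()].
#' @return a [psi_atlas()].
#' @export
gen_atlas <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  ca <- config$atlas
  set.seed(config$seed + 1L)
  mix <- ca$mixture
  if (is.null(mix)) mix <- .default_mixture(ca$intermediate_mass)
  stopifnot(abs(sum(mix$weight) - 1) < 1e-8)
  n <- ca$n_exons * ca$n_tissues
  comp <- sample.int(nrow(mix), n, replace = TRUE, prob = mix$weight)
  psi <- 100 * stats::rbeta(n, mix$shape1[comp], mix$shape2[comp])
  psi[stats::runif(n) < ca$missing_rate] <- NA_real_
  psi <- matrix(psi, nrow = ca$n_exons, ncol = ca$n_tissues,
                dimnames = list(NULL, paste0("tissue_", seq_len(ca$n_tissues))))
  lengths <- pmax(25L, round(stats::rlnorm(ca$n_exons, ca$length_meanlog,
                                           ca$length_sdlog)))
  start <- cumsum(c(0L, lengths[-ca$n_exons] + 1000L))
  exons <- data.frame(exon_id = sprintf("exon_%05d", seq_len(ca$n_exons)),
                      chrom = "chrS", start = start, end = start + lengths,
                      strand = "+", length = lengths,
                      stringsAsFactors = FALSE)
  psi_atlas(exons, psi)
}

#' Generate a genotyped cohort with planted splicing effects
#'
#' Assigns each variant to an atlas exon with intermediate-to-high
#' inclusion, plants an efficiency effect `A` (log-normal, or `A = 1` for
#' the null fraction), and simulates per-sample PSI: a carrier of 0
#' copies sits at the exon's starting PSI, a homozygote at
#' `predict_final_psi(A, psi_start)`, a heterozygote at the midpoint
#' (matching the additive dosage model the analysis fits), plus Gaussian
#' noise. Genotypes are Hardy-Weinberg draws at the variant's allele
#' frequency. The truth table records the homozygous (two-copy) delta-PSI
#' for every variant.
#'
#' @param config a [sim_config()].
#' @param atlas a [psi_atlas()] supplying starting PSI levels (defaults
#'   to `gen_atlas(config)`).
#' @param tissue atlas tissue the cohort PSI matrices are generated for
#'   (default: first tissue).
#' @return list with `genotypes` (list: `variants` data frame, `copies`
#'   matrix variants x samples), `psi_by_tissue` (named list of one
#'   exons x samples matrix), `truth` (data frame `variant_id`,
#'   `exon_id`, `true_A`, `psi_start`, `true_delta_psi`).
#' @export
gen_cohort <- function(config, atlas = NULL, tissue = NULL) {
  stopifnot(inherits(config, "sim_config"))
  cc <- config$cohort
  if (is.null(atlas)) atlas <- gen_atlas(config)
  if (is.null(tissue)) tissue <- colnames(atlas$psi)[1]
  set.seed(config$seed + 2L)

  psi_col <- atlas$psi[, tissue]
  eligible <- which(!is.na(psi_col) & psi_col > 1 & psi_col < 99.5)
  if (length(eligible) < cc$n_variants)
    stop("atlas has too few quantifiable exons for the cohort", call. = FALSE)
  exon_idx <- sample(eligible, cc$n_variants)
  psi_start <- psi_col[exon_idx]

  af <- stats::runif(cc$n_variants, cc$maf_range[1], cc$maf_range[2])
  A <- stats::rlnorm(cc$n_variants, cc$meanlog, cc$sdlog)
  if (cc$frac_null > 0) {
    null_idx <- sample.int(cc$n_variants, round(cc$frac_null * cc$n_variants))
    A[null_idx] <- 1
  }
  delta2 <- predict_final_psi(A, psi_start) - psi_start

  copies <- matrix(stats::rbinom(cc$n_variants * cc$n_samples, 2L,
                                 rep(af, cc$n_samples)),
                   nrow = cc$n_variants, ncol = cc$n_samples)
  exon_ids <- atlas$exons$exon_id[exon_idx]
  expected <- matrix(psi_start, cc$n_variants, cc$n_samples) +
    copies / 2 * matrix(delta2, cc$n_variants, cc$n_samples)
  psi_obs <- expected + matrix(stats::rnorm(length(expected), 0, cc$noise_sd),
                               nrow = nrow(expected))
  rownames(psi_obs) <- exon_ids
  colnames(psi_obs) <- sprintf("sample_%03d", seq_len(cc$n_samples))
  colnames(copies) <- colnames(psi_obs)

  variants <- data.frame(
    variant_id = sprintf("var_%04d", seq_len(cc$n_variants)),
    exon_id = exon_ids,
    position = atlas$exons$start[exon_idx] +
      sample.int(50L, cc$n_variants, replace = TRUE),
    exon_midpoint = (atlas$exons$start[exon_idx] +
                       atlas$exons$end[exon_idx]) / 2,
    ref = "A", alt = "G",
    allele_frequency = af,
    region = sample(c("exonic", "intronic"), cc$n_variants, replace = TRUE),
    stringsAsFactors = FALSE)
  psi_list <- list(psi_obs); names(psi_list) <- tissue
  list(genotypes = list(variants = variants, copies = copies),
       psi_by_tissue = psi_list,
       truth = data.frame(variant_id = variants$variant_id,
                          exon_id = exon_ids, true_A = A,
                          psi_start = psi_start, true_delta_psi = delta2,
                          stringsAsFactors = FALSE))
}

#' Generate a motif set with controlled neighbourhood connectivity
#'
#' Builds an enhancer hexamer set by iteratively adding either a random
#' hexamer or (with probability `connectivity`) a random
#' single-substitution neighbour of a motif already in the set. Higher
#' connectivity yields higher robustness scores. A hexamer has at most 18
#' single-substitution neighbours, so any requested neighbourhood larger
#' than 18 is rejected.
#'
#' @param n_motifs set size.
#' @param connectivity probability in \[0, 1\] of growing the set by a
#'   neighbour rather than a random hexamer.
#' @param role motif role label.
#' @param max_neighbors optional cap used for validation only; requesting
#'   more than 18 mutual neighbours is combinatorially impossible.
#' @return a [hexamer_set()].
#' @export
gen_motif_set <- function(n_motifs, connectivity = 0.5, role = "ESE",
                          max_neighbors = NULL) {
  if (!is.null(max_neighbors) && max_neighbors > 18)
    stop("a hexamer has only 18 single-substitution neighbours", call. = FALSE)
  if (connectivity < 0 || connectivity > 1)
    stop("'connectivity' must be in [0, 1]", call. = FALSE)
  motifs <- character(0)
  while (length(motifs) < n_motifs) {
    if (length(motifs) > 0 && stats::runif(1) < connectivity) {
      seed_motif <- motifs[sample.int(length(motifs), 1L)]
      cand <- sample(.neighbours(seed_motif), 1L)
    } else {
      cand <- .rand_seq(6L)
    }
    if (!cand %in% motifs) motifs <- c(motifs, cand)
  }
  hexamer_set(motifs, role = role)
}

#' Generate exon sequences with class-dependent motif densities
#'
#' Random-background sequences for two exon classes, with enhancer motifs
#' implanted at non-overlapping positions at a per-class rate
#' (`base_rate * length * density_multiplier[class]` expected implants).
#' The emitted motif set is generated by [gen_motif_set()] so robustness
#' spectra are controllable.
#'
#' @param config a [sim_config()].
#' @return list with `exons` (data frame `exon_id`, `sequence`, `class`),
#'   `ese` (the implanted [hexamer_set()]), and `truth` (implants per
#'   exon).
#' @export
gen_sequences <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cs <- config$sequences
  set.seed(config$seed + 3L)
  ese <- gen_motif_set(cs$n_motifs, cs$connectivity, role = "ESE")
  # interleave classes so sequence ids (and any id-based tie-breaks
  # downstream) carry no class information
  classes <- rep(c("constitutive", "alternative"), times = cs$n_per_class)
  n <- length(classes)
  max_implants <- cs$length %/% 6L
  seqs <- character(n); n_implanted <- integer(n)
  for (i in seq_len(n)) {
    lambda <- cs$base_rate * cs$length * cs$density_multiplier[classes[i]]
    k <- stats::rpois(1L, lambda)
    if (k > max_implants)
      stop("requested motif density infeasible for sequence length",
           call. = FALSE)
    chars <- strsplit(.rand_seq(cs$length), "")[[1]]
    # greedy non-overlapping placement
    placed <- integer(0)
    starts <- sample.int(cs$length - 5L)
    for (s in starts) {
      if (length(placed) >= k) break
      if (all(abs(s - placed) >= 6L)) placed <- c(placed, s)
    }
    for (s in placed) {
      m <- strsplit(as.character(ese)[sample.int(length(ese), 1L)], "")[[1]]
      chars[s:(s + 5L)] <- m
    }
    seqs[i] <- paste(chars, collapse = "")
    n_implanted[i] <- length(placed)
  }
  exons <- data.frame(exon_id = sprintf("seq_%04d", seq_len(n)),
                      sequence = seqs,
                      class = factor(classes,
                                     levels = c("constitutive", "alternative")),
                      stringsAsFactors = FALSE)
  list(exons = exons, ese = ese,
       truth = data.frame(exon_id = exons$exon_id,
                          n_implanted = n_implanted,
                          stringsAsFactors = FALSE))
}
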