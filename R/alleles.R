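#' Estimate an allele's effect on exon inclusion by dosage regression
#'
#' Ordinary least squares of per-sample exon PSI on the number of copies
#' of the alternative allele (0, 1 or 2). The slope is the PSI change per
#' allele copy; the reported `delta_psi` is twice the slope (the change
#' associated with homozygosity), and the intercept extrapolates the
#' exon's inclusion level in the absence of the allele (`starting_psi`),
#' which is defined even when no homozygous-reference samples exist.
#'
#' @param psi numeric vector of per-sample PSI (percent); `NA` allowed.
#' @param copies integer vector of allele copies in \{0, 1, 2\}; `NA`
#'   allowed. Pairs with a missing value in either vector are dropped.
#' @param min_samples minimum complete pairs required (default 20; the
#'   mathematical minimum is 3).
#' @return one-row data frame with `delta_psi` (2 x slope),
#'   `starting_psi` (intercept), `slope`, `se_slope`, `p_value`
#'   (two-sided, for the slope), `n_samples`, `estimable`. When the copies
#'   carry no variance or too few samples remain, `estimable` is `FALSE`
#'   and the estimates are `NA`.
#' @export
fit_allele_effect <- function(psi, copies, min_samples = 20L) {
  ok <- !is.na(psi) & !is.na(copies)
  psi <- psi[ok]; copies <- copies[ok]
  n <- length(psi)
  unestimable <- data.frame(delta_psi = NA_real_, starting_psi = NA_real_,
                            slope = NA_real_, se_slope = NA_real_,
                            p_value = NA_real_, n_samples = n,
                            estimable = FALSE)
  if (n < max(3L, min_samples)) return(unestimable)
  if (length(unique(copies)) < 2L) return(unestimable)
  fit <- stats::lm(psi ~ copies)
  cf <- summary(fit)$coefficients
  data.frame(delta_psi = 2 * cf["copies", "Estimate"],
             starting_psi = cf["(Intercept)", "Estimate"],
             slope = cf["copies", "Estimate"],
             se_slope = cf["copies", "Std. Error"],
             p_value = cf["copies", "Pr(>|t|)"],
             n_samples = n, estimable = TRUE)
}

#' Fit allele effects for every variant x exon x tissue combination
#'
#' Driver over a genotype table and per-sample PSI matrices. Effects whose
#' extrapolated starting PSI falls outside \[0, 100\] are removed (not
#' clamped), mirroring the intercept filter used for population data.
#'
#' @param genotypes a `genotype_table` (see [read_genotypes_tsv()] or
#'   [gen_cohort()]): list with `variants` data frame (columns `variant_id`,
#'   `exon_id`, `region`, ...) and `copies` matrix (variants x samples).
#' @param psi_by_tissue named list of PSI matrices (exons x samples),
#'   one per tissue; sample columns aligned with the genotype matrix.
#' @param min_samples passed to [fit_allele_effect()].
#' @return data frame of allele effects with columns `variant_id`,
#'   `exon_id`, `region`, `tissue`, plus the [fit_allele_effect()] fields;
#'   `attr(, "n_intercept_filtered")` counts the removed records.
#' @export
fit_all_allele_effects <- function(genotypes, psi_by_tissue,
                                   min_samples = 20L) {
  stopifnot(is.list(psi_by_tissue), length(psi_by_tissue) >= 1L)
  vars <- genotypes$variants
  rows <- list()
  for (tissue in names(psi_by_tissue)) {
    psi_mat <- psi_by_tissue[[tissue]]
    for (i in seq_len(nrow(vars))) {
      exon <- vars$exon_id[i]
      if (!exon %in% rownames(psi_mat)) next
      eff <- fit_allele_effect(psi_mat[exon, ], genotypes$copies[i, ],
                               min_samples = min_samples)
      eff <- cbind(data.frame(variant_id = vars$variant_id[i],
                              exon_id = exon,
                              region = vars$region[i],
                              tissue = tissue,
                              stringsAsFactors = FALSE), eff)
      rows[[length(rows) + 1L]] <- eff
    }
  }
  effects <- do.call(rbind, rows)
  effects <- effects[effects$estimable, , drop = FALSE]
  bad <- effects$starting_psi < 0 | effects$starting_psi > 100
  out <- effects[!bad, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_intercept_filtered") <- sum(bad)
  out
}

#' Keep one allele per splicing event
#'
#' Linked alleles near the same exon produce redundant associations. Per
#' (event, tissue), only the allele with the smallest regression p-value
#' is kept; exact ties break by distance to the exon midpoint (needs
#' `position` and `exon_midpoint` columns; skipped when absent) and then
#' by lexical variant id. The registry of which region class (exonic vs
#' intronic) claimed each event supports the downstream cross-exclusion
#' rule: an event claimed by an exonic winner is excluded from the
#' intronic analysis, and vice versa.
#'
#' @param effects data frame of allele effects with at least `variant_id`,
#'   `exon_id`, `tissue`, `region`, `p_value`.
#' @return list with `pruned` (one row per event x tissue) and `registry`
#'   (data frame `exon_id`, `tissue`, `winner_region`).
#' @export
prune_per_event <- function(effects) {
  stopifnot(all(c("variant_id", "exon_id", "tissue", "region", "p_value")
                %in% names(effects)))
  key <- paste(effects$exon_id, effects$tissue, sep = "\r")
  has_pos <- all(c("position", "exon_midpoint") %in% names(effects))
  dist_mid <- if (has_pos) abs(effects$position - effects$exon_midpoint)
              else rep(0, nrow(effects))
  ord <- order(key, effects$p_value, dist_mid, effects$variant_id)
  effects <- effects[ord, , drop = FALSE]
  keep <- !duplicated(key[ord])
  pruned <- effects[keep, , drop = FALSE]
  rownames(pruned) <- NULL
  registry <- data.frame(exon_id = pruned$exon_id, tissue = pruned$tissue,
                         winner_region = pruned$region,
                         stringsAsFactors = FALSE)
  list(pruned = pruned, registry = registry)
}

#' Select pruned effects of one region class with cross-exclusion
#'
#' @param pruned result of [prune_per_event()].
#' @param region `"exonic"` or `"intronic"`; an event whose winning allele
#'   belongs to the other class is excluded entirely.
#' @return the subset of `pruned$pruned` whose winner matches `region`.
#' @export
effects_for_region <- function(pruned, region = c("exonic", "intronic")) {
  region <- match.arg(region)
  pruned$pruned[pruned$pruned$region == region, , drop = FALSE]
}

#' Bin effects into equally populated starting-PSI bins
#'
#' Rank-based binning: records are ordered by the binning key (ties broken
#' by original position, so bins stay equal-sized) and cut into `n_bins`
#' groups differing in size by at most one record.
#'
#' @param effects data frame with `delta_psi` and the binning key column.
#' @param n_bins number of bins (5, 10 and 25 are the conventional
#'   choices).
#' @param key name of the column to bin on (default `"starting_psi"`).
#' @param threshold effect-magnitude threshold for the per-bin fraction
#'   (default 10 PSI units, counted strictly: `|delta| > threshold`).
#' @return data frame with one row per bin: `bin`, `key_min`, `key_max`,
#'   `n`, `frac_gt_threshold`, `median_abs_delta`.
#' @export
bin_equal <- function(effects, n_bins, key = "starting_psi",
                      threshold = 10) {
  stopifnot(is.data.frame(effects), key %in% names(effects),
            "delta_psi" %in% names(effects))
  n <- nrow(effects)
  if (n < n_bins) stop("fewer records than bins", call. = FALSE)
  # ties on the key break on variant_id where available, so the binning
  # does not depend on input row order
  ord <- if ("variant_id" %in% names(effects))
    order(effects[[key]], effects$variant_id) else order(effects[[key]])
  # equal split up to +/-1: bin sizes floor(n/k) or ceiling(n/k)
  sizes <- rep(n %/% n_bins, n_bins)
  extra <- n %% n_bins
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  bin_of <- rep(seq_len(n_bins), times = sizes)
  effects <- effects[ord, , drop = FALSE]
  out <- lapply(seq_len(n_bins), function(b) {
    e <- effects[bin_of == b, , drop = FALSE]
    data.frame(bin = b,
               key_min = min(e[[key]]), key_max = max(e[[key]]),
               n = nrow(e),
               frac_gt_threshold = mean(abs(e$delta_psi) > threshold),
               median_abs_delta = stats::median(abs(e$delta_psi)))
  })
  do.call(rbind, out)
}

#' Classify exons as constitutive or alternative from an atlas
#'
#' Constitutive exons are included at or above `constitutive_min` percent
#' in every tissue with data; alternative exons fall below
#' `alternative_max` in at least one tissue. With the default thresholds
#' (both 90) the two classes partition the quantified exons; with
#' stricter definitions some exons belong to neither class and are
#' labelled `NA`.
#'
#' @param atlas a [psi_atlas()].
#' @param constitutive_min PSI threshold met in all tissues (default 90).
#' @param alternative_max below this in at least one tissue (default 90).
#' @return data frame `exon_id`, `class` (factor
#'   constitutive/alternative or `NA`), `min_psi`, `n_tissues`.
#' @export
classify_exons <- function(atlas, constitutive_min = 90,
                           alternative_max = 90) {
  stopifnot(inherits(atlas, "psi_atlas"))
  min_psi <- apply(atlas$psi, 1, function(x)
    if (all(is.na(x))) NA_real_ else min(x, na.rm = TRUE))
  n_tis <- rowSums(!is.na(atlas$psi))
  cls <- ifelse(is.na(min_psi), NA_character_,
         ifelse(min_psi >= constitutive_min, "constitutive",
         ifelse(min_psi < alternative_max, "alternative", NA_character_)))
  data.frame(exon_id = atlas$exons$exon_id,
             class = factor(cls, levels = c("constitutive", "alternative")),
             min_psi = min_psi, n_tissues = n_tis,
             stringsAsFactors = FALSE)
}

#' Compare allele effects between constitutive and alternative exons
#'
#' Fits the joint linear model `delta_psi ~ starting_psi + class` on a set
#' of (typically skipping-promoting) allele effects, so the exon-class
#' term measures the extra effect in alternative exons at matched
#' starting inclusion. Significance is the t test of the class
#' coefficient.
#'
#' @param effects data frame with `delta_psi`, `starting_psi`, `exon_id`.
#' @param classes data frame from [classify_exons()].
#' @return list with `coefficient` (PSI units, alternative relative to
#'   constitutive), `p_value`, `n_constitutive`, `n_alternative`, and the
#'   fitted `model`.
#' @export
compare_exon_classes <- function(effects, classes) {
  stopifnot(all(c("delta_psi", "starting_psi", "exon_id") %in% names(effects)))
  cls <- classes$class[match(effects$exon_id, classes$exon_id)]
  ok <- !is.na(cls)
  effects <- effects[ok, , drop = FALSE]
  cls <- droplevels(cls[ok])
  if (nlevels(cls) < 2L)
    stop("both exon classes must be represented", call. = FALSE)
  fit <- stats::lm(delta_psi ~ starting_psi + cls, data = effects)
  cf <- summary(fit)$coefficients
  row <- grep("^cls", rownames(cf))
  list(coefficient = cf[row, "Estimate"],
       p_value = cf[row, "Pr(>|t|)"],
       n_constitutive = sum(cls == "constitutive"),
       n_alternative = sum(cls == "alternative"),
       model = fit)
}

#' Sweep the exon-class definition thresholds
#'
#' Recomputes the class coefficient of [compare_exon_classes()] over a
#' grid of constitutive and alternative definitions, showing how the
#' constitutive/alternative contrast depends on where the thresholds are
#' drawn.
#'
#' @param effects as in [compare_exon_classes()].
#' @param atlas a [psi_atlas()].
#' @param constitutive_grid,alternative_grid numeric vectors of PSI
#'   thresholds (the conventional sweep uses 50 values from 50 to 99 on
#'   each axis).
#' @return matrix of class coefficients (rows: constitutive thresholds;
#'   columns: alternative thresholds); cells where a class is empty are
#'   `NA`.
#' @export
class_threshold_sweep <- function(effects, atlas,
                                  constitutive_grid = seq(50, 99, length.out = 50),
                                  alternative_grid = seq(50, 99, length.out = 50)) {
  min_psi <- apply(atlas$psi, 1, function(x)
    if (all(is.na(x))) NA_real_ else min(x, na.rm = TRUE))
  names(min_psi) <- atlas$exons$exon_id
  mp <- min_psi[effects$exon_id]
  out <- matrix(NA_real_, length(constitutive_grid), length(alternative_grid),
                dimnames = list(constitutive_grid, alternative_grid))
  for (i in seq_along(constitutive_grid)) {
    for (j in seq_along(alternative_grid)) {
      cls <- ifelse(mp >= constitutive_grid[i], "constitutive",
             ifelse(mp < alternative_grid[j], "alternative", NA_character_))
      ok <- !is.na(cls) & !is.na(effects$delta_psi)
      if (length(unique(cls[ok])) < 2L) next
      fit <- stats::lm(effects$delta_psi[ok] ~ effects$starting_psi[ok] +
                         factor(cls[ok], levels = c("constitutive", "alternative")))
      out[i, j] <- stats::coef(fit)[3]
    }
  }
  out
}

#' Per-construct PSI change between two conditions
#'
#' Matches constructs measured in two conditions (e.g. two cell types, or
#' two flanking-intron contexts) and returns the change in inclusion when
#' moving from condition A (the starting-PSI condition) to condition B.
#' The result is ready for [bin_equal()] on `starting_psi`.
#'
#' @param psi_a,psi_b named numeric vectors of per-construct PSI in the
#'   two conditions; names are construct identifiers.
#' @return data frame `construct_id`, `starting_psi` (condition A),
#'   `delta_psi` (B minus A); unmatched constructs are dropped and counted
#'   in `attr(, "n_unmatched")`.
#' @export
condition_delta <- function(psi_a, psi_b) {
  stopifnot(!is.null(names(psi_a)), !is.null(names(psi_b)))
  common <- intersect(names(psi_a), names(psi_b))
  n_unmatched <- (length(psi_a) - length(common)) +
    (length(psi_b) - length(common))
  out <- data.frame(construct_id = common,
                    starting_psi = unname(psi_a[common]),
                    delta_psi = unname(psi_b[common] - psi_a[common]),
                    stringsAsFactors = FALSE)
  attr(out, "n_unmatched") <- n_unmatched
  out
}
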