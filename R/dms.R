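#' Library configuration for DMS scoring
#'
#' @param psi_wt wild-type inclusion level of the assayed exon, percent in
#'   (0, 100]. The maximum admissible normalised enrichment score follows
#'   as `es_max = 100 / psi_wt` (a variant cannot be included above 100%).
#' @param bayes_grid_size number of grid points for the Bayesian score
#'   correction (default 1000).
#' @param min_reads minimum junction reads for PSI quantification
#'   (default 10).
#' @param pool_inputs pool counts from all input replicates before forming
#'   frequencies (the design used when input replicates are technical);
#'   default `FALSE` (per-replicate input/output ratios).
#' @param pseudocount added to every count before frequencies are formed;
#'   default 0 (variants with no input reads in any replicate are dropped
#'   instead).
#' @return a `library_config` list.
#' @export
library_config <- function(psi_wt, bayes_grid_size = 1000L, min_reads = 10L,
                           pool_inputs = FALSE, pseudocount = 0) {
  if (!is.numeric(psi_wt) || psi_wt <= 0 || psi_wt > 100)
    stop("'psi_wt' must be in (0, 100]", call. = FALSE)
  structure(list(psi_wt = psi_wt, es_max = 100 / psi_wt,
                 bayes_grid_size = as.integer(bayes_grid_size),
                 min_reads = as.integer(min_reads),
                 pool_inputs = isTRUE(pool_inputs),
                 pseudocount = pseudocount),
            class = "library_config")
}

.input_cols <- function(counts) grep("^input_", names(counts), value = TRUE)
.output_cols <- function(counts) grep("^output_", names(counts), value = TRUE)

#' Score DMS variants from replicate counts
#'
#' Converts a table of per-variant input/output read counts into
#' enrichment scores and PSI estimates. Per replicate, a variant's raw
#' enrichment score is its output frequency divided by its input
#' frequency; normalised scores divide by the wild-type's raw score, so
#' the wild type scores exactly 1. The per-variant point estimate is the
#' mean of the normalised scores over replicates, and
#' `psi = psi_wt * es_norm`.
#'
#' The standard error combines two components: the count (Poisson)
#' sampling variance of each replicate's ratio, propagated by the delta
#' method (`es^2 * (1/out_x + 1/in_x + 1/out_wt + 1/in_wt)`), and the
#' empirical between-replicate variance of the normalised scores. This is
#' the package's own simplified error model for frequency-ratio scores.
#'
#' @param counts data frame with columns `variant_id`, `position`, `ref`,
#'   `alt`, plus paired count columns `input_1..input_R` and
#'   `output_1..output_R`. The wild-type row is identified by
#'   `variant_id == "WT"` (or a missing `position`). Exactly one WT row is
#'   required, with nonzero counts in every replicate.
#' @param config a [library_config()].
#' @return data frame (one row per retained variant) with `variant_id`,
#'   `position`, `ref`, `alt`, `es_raw`, `es_norm`, `se_es`, `psi`;
#'   `attr(, "n_dropped")` counts variants dropped for having no input
#'   reads in any replicate. The WT row is retained.
#' @export
score_variants <- function(counts, config) {
  stopifnot(is.data.frame(counts), inherits(config, "library_config"))
  ic <- .input_cols(counts); oc <- .output_cols(counts)
  if (length(ic) == 0L || length(oc) == 0L)
    stop("count table needs input_* and output_* columns", call. = FALSE)
  if (length(ic) != length(oc) && !config$pool_inputs)
    stop("unpaired input/output replicates; use pool_inputs", call. = FALSE)

  wt_row <- which(counts$variant_id == "WT" | is.na(counts$position))
  if (length(wt_row) != 1L)
    stop("exactly one WT record is required", call. = FALSE)

  inm <- as.matrix(counts[ic]) + config$pseudocount
  outm <- as.matrix(counts[oc]) + config$pseudocount
  if (config$pool_inputs) {
    pooled <- rowSums(inm)
    inm <- matrix(pooled, nrow = nrow(counts), ncol = length(oc))
  }
  if (any(inm[wt_row, ] == 0) || any(outm[wt_row, ] == 0))
    stop("WT record has a zero count; cannot normalise", call. = FALSE)

  keep <- rowSums(inm) > 0
  keep[wt_row] <- TRUE
  n_dropped <- sum(!keep)
  counts <- counts[keep, , drop = FALSE]
  inm <- inm[keep, , drop = FALSE]
  outm <- outm[keep, , drop = FALSE]
  wt_row <- which(counts$variant_id == "WT" | is.na(counts$position))

  R <- ncol(outm)
  in_freq <- sweep(inm, 2, colSums(inm), "/")
  out_freq <- sweep(outm, 2, colSums(outm), "/")
  es_raw_rep <- out_freq / in_freq                 # Inf/NaN where in_freq 0
  es_raw_rep[!is.finite(es_raw_rep)] <- NA_real_
  es_norm_rep <- sweep(es_raw_rep, 2, es_raw_rep[wt_row, ], "/")

  es_raw <- rowMeans(es_raw_rep, na.rm = TRUE)
  es_norm <- rowMeans(es_norm_rep, na.rm = TRUE)

  # delta-method Poisson variance per replicate, then variance of the mean
  inv <- function(m) { x <- 1 / m; x[!is.finite(x)] <- NA_real_; x }
  pois_rel <- inv(outm) + inv(inm) +
    matrix(rep(1 / outm[wt_row, ] + 1 / inm[wt_row, ], each = nrow(outm)),
           nrow = nrow(outm))
  pois_var_rep <- es_norm_rep^2 * pois_rel
  n_rep <- rowSums(!is.na(es_norm_rep))
  pois_var <- rowSums(pois_var_rep, na.rm = TRUE) / n_rep^2
  between_var <- ifelse(n_rep > 1,
                        apply(es_norm_rep, 1, stats::var, na.rm = TRUE) / n_rep,
                        0)
  se_es <- sqrt(pois_var + between_var)

  out <- data.frame(variant_id = counts$variant_id,
                    position = counts$position,
                    ref = counts$ref, alt = counts$alt,
                    es_raw = es_raw, es_norm = es_norm, se_es = se_es,
                    psi = config$psi_wt * es_norm,
                    stringsAsFactors = FALSE)
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Bounded Bayesian correction of an enrichment score
#'
#' High enrichment scores can imply PSI estimates above 100%, which is
#' physically impossible. The correction rescales each measured score to
#' the admissible range `[0, es_max]` by treating the measurement as
#' Normal(`es_norm`, `se_es^2`), evaluating its density at
#' `bayes_grid_size` evenly spaced candidate scores `k`, and returning the
#' probability-weighted mean of the candidates, `sum(P*k) / sum(P)` — the
#' posterior mean under a flat prior on the admissible range.
#'
#' @param es_norm measured normalised enrichment score(s); vectorised.
#' @param se_es standard error(s) of the score, > 0.
#' @param config a [library_config()] (supplies `es_max` and the grid
#'   size).
#' @return corrected score(s), always inside `[0, es_max]`.
#' @export
bayes_correct <- function(es_norm, se_es, config) {
  stopifnot(inherits(config, "library_config"))
  if (config$es_max <= 0) stop("es_max must be positive", call. = FALSE)
  if (any(se_es <= 0)) stop("'se_es' must be > 0", call. = FALSE)
  k <- seq(0, config$es_max, length.out = config$bayes_grid_size)
  # trapezoid endpoint weights: the grid is a quadrature of the continuous
  # posterior mean, and full weight on the boundary points biases
  # boundary-concentrated posteriors by more than the correction itself
  qw <- rep(1, length(k)); qw[c(1L, length(k))] <- 0.5
  vapply(seq_along(es_norm), function(i) {
    p <- qw * stats::dnorm(k, mean = es_norm[i], sd = se_es[i])
    if (sum(p) == 0) {
      # error so small every grid weight underflows: the posterior is the
      # measurement itself, clamped into the admissible range
      min(max(es_norm[i], 0), config$es_max)
    } else sum(p * k) / sum(p)
  }, numeric(1))
}

#' Adjust scores so the mode of their distribution sits at the WT score
#'
#' The bounded correction shifts the bulk of the score distribution
#' slightly away from the wild-type score, around which single-mutant
#' scores are expected to concentrate. The adjustment estimates the mode
#' of the corrected scores by a Gaussian kernel density (Silverman's
#' rule-of-thumb bandwidth) and subtracts `mode - wt_es` from every score,
#' re-clipping to `[0, es_max]`.
#'
#' @param scores numeric vector of corrected scores (length >= 2 for a
#'   meaningful density; a single score is shifted trivially).
#' @param wt_es the wild-type score the mode should coincide with
#'   (default 1).
#' @param es_max upper clip bound (default `Inf`, i.e. no clipping).
#' @return adjusted scores, with the applied shift in `attr(, "shift")`.
#' @export
mode_adjust <- function(scores, wt_es = 1, es_max = Inf) {
  stopifnot(is.numeric(scores))
  if (length(unique(scores)) < 2L) {
    shift <- wt_es - scores[1]
  } else {
    d <- stats::density(scores, bw = "nrd0")
    shift <- wt_es - d$x[which.max(d$y)]
  }
  out <- pmin(pmax(scores + shift, 0), es_max)
  attr(out, "shift") <- shift
  out
}

#' Full DMS scoring pipeline: counts to corrected PSI values
#'
#' Runs [score_variants()], applies [bayes_correct()] to every variant,
#' re-centres the corrected scores on the wild type with [mode_adjust()],
#' and converts to PSI. The result satisfies `psi_corrected` in
#' `[0, 100]` for every variant.
#'
#' @inheritParams score_variants
#' @return the [score_variants()] data frame with extra columns
#'   `es_corrected` and `psi_corrected`.
#' @export
dms_pipeline <- function(counts, config) {
  scored <- score_variants(counts, config)
  # variants at zero output in every replicate have zero estimated error;
  # floor keeps the correction defined without moving any estimate
  se <- pmax(scored$se_es, 1e-6)
  es_corr <- bayes_correct(scored$es_norm, se, config)
  es_adj <- mode_adjust(es_corr, wt_es = 1, es_max = config$es_max)
  scored$es_corrected <- as.numeric(es_adj)
  scored$psi_corrected <- config$psi_wt * scored$es_corrected
  attr(scored, "mode_shift") <- attr(es_adj, "shift")
  scored
}

#' Simple junction-based PSI quantification
#'
#' @param inclusion_reads,exclusion_reads nonnegative integer vectors of
#'   junction reads supporting inclusion and exclusion of the exon.
#' @param min_reads events with fewer total reads are returned as `NA`
#'   (default 10).
#' @return PSI percent, or `NA` below the read threshold.
#' @examples
#' psi_from_junctions(90, 10)  # 90
#' psi_from_junctions(5, 3)    # NA: under 10 reads
#' @export
psi_from_junctions <- function(inclusion_reads, exclusion_reads,
                               min_reads = 10L) {
  if (any(inclusion_reads < 0, na.rm = TRUE) ||
      any(exclusion_reads < 0, na.rm = TRUE))
    stop("read counts must be nonnegative", call. = FALSE)
  total <- inclusion_reads + exclusion_reads
  ifelse(total < min_reads, NA_real_, 100 * inclusion_reads / total)
}
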