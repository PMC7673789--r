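#' Predict the final inclusion level of an exon under an efficiency effect
#'
#' The central scaling law of the package. A mutation's effect on the
#' splicing efficiency of an exon is summarised by a single nonnegative
#' multiplicative parameter `A` that does not depend on how much the exon
#' is included to begin with. Given `A` and a starting inclusion level
#' `psi_start` (percent spliced in, 0-100), the inclusion level after the
#' mutation is
#'
#' \deqn{PSI_{final} = \frac{100 \cdot A \cdot PSI_s}{100 - PSI_s + A \cdot PSI_s}}
#'
#' `A = 1` is neutral (the exon keeps its inclusion level), `A < 1`
#' promotes skipping and `A > 1` promotes inclusion. The change in
#' inclusion is `predict_final_psi(A, p) - p`; it vanishes at `p = 0` and
#' `p = 100` for every finite `A`, which is why mutations rarely move the
#' inclusion of almost-fully included (or almost-fully skipped) exons.
#'
#' @param A nonnegative numeric vector of efficiency effects.
#' @param psi_start numeric vector of starting PSI values in \[0, 100\].
#'   Recycled against `A`.
#' @return numeric vector of final PSI values, always in \[0, 100\].
#'   `psi_start` of exactly 0 or 100 is returned unchanged for any finite
#'   `A` (the boundary is a fixed point of the law).
#' @examples
#' predict_final_psi(1, 37)  # neutral: 37
#' predict_final_psi(3, 50)  # 75
#' predict_final_psi(3, 99) - 99  # tiny shift near full inclusion
#' @seealso [estimate_A()] for the inverse, [rescale_effects()] for
#'   rescaling whole distributions.
#' @export
predict_final_psi <- function(A, psi_start) {
  stopifnot(is.numeric(A), is.numeric(psi_start))
  if (any(!is.finite(A)) || any(A < 0))
    stop("'A' must be finite and >= 0", call. = FALSE)
  if (any(!is.finite(psi_start)) || any(psi_start < 0) || any(psi_start > 100))
    stop("'psi_start' must be in [0, 100]", call. = FALSE)
  n <- max(length(A), length(psi_start))
  A <- rep_len(A, n)
  p <- rep_len(psi_start, n)
  out <- 100 * A * p / (100 - p + A * p)
  # neutrality is exact, not a rounding accident of 100 * p / 100
  out[A == 1] <- p[A == 1]
  # boundaries are fixed points; guard the 0/0 at p = 100, A = 0
  boundary <- p == 0 | p == 100
  out[boundary] <- p[boundary]
  pmin(pmax(out, 0), 100)
}

#' Estimate the efficiency effect of a mutation from an observed PSI change
#'
#' Inverts the scaling law: given a change in inclusion `delta_psi`
#' observed at a starting inclusion level `psi_start`, recovers the
#' inclusion-independent efficiency effect
#'
#' \deqn{A = \frac{PSI_s^2 - 100 \cdot PSI_s + \Delta PSI \cdot PSI_s -
#'   100 \cdot \Delta PSI}{PSI_s (\Delta PSI + PSI_s - 100)}}
#'
#' which round-trips with [predict_final_psi()]. Measurement noise can
#' push `delta_psi` past the physical bounds: a final PSI below 0 inverts
#' to a negative `A`, clipped to 0 with a warning, and a final PSI at or
#' above 100 leaves `A` unbounded — such records are saturated and
#' returned as `NA` with a `"saturated"` attribute counting them.
#'
#' @param delta_psi numeric vector of observed PSI changes (percent).
#' @param psi_start numeric vector of starting PSI values, strictly inside
#'   (0, 100). Recycled.
#' @return numeric vector of `A` estimates (>= 0); saturated entries are
#'   `NA_real_` and their count is attached as `attr(, "saturated")`, the
#'   number of negative estimates clipped to zero as `attr(, "clipped")`.
#' @examples
#' estimate_A(0, 50)    # 1: no change is neutral
#' estimate_A(25, 50)   # 3
#' estimate_A(-80, 80)  # 0: complete loss
#' @export
estimate_A <- function(delta_psi, psi_start) {
  stopifnot(is.numeric(delta_psi), is.numeric(psi_start))
  if (any(!is.finite(psi_start)) || any(psi_start <= 0) || any(psi_start >= 100))
    stop("'psi_start' must be strictly inside (0, 100)", call. = FALSE)
  n <- max(length(delta_psi), length(psi_start))
  d <- rep_len(delta_psi, n)
  p <- rep_len(psi_start, n)
  final <- p + d
  # noise can push the final PSI slightly past either bound: below 0 the
  # inversion goes negative (clipped below); at or above 100 A is
  # unbounded (flagged saturated)
  saturated <- final >= 100
  A <- (p^2 - 100 * p + d * p - 100 * d) / (p * (d + p - 100))
  A[saturated] <- NA_real_
  clipped <- !saturated & A < 0
  if (any(clipped)) {
    warning(sum(clipped), " negative A estimate(s) clipped to 0", call. = FALSE)
    A[clipped] <- 0
  }
  attr(A, "saturated") <- sum(saturated)
  attr(A, "clipped") <- sum(clipped)
  A
}

#' Construct a distribution of efficiency effects
#'
#' Bundles the `A` values estimated from one source exon's mutational data
#' so they can be projected to any starting inclusion level. Saturated
#' records (`NA`) are dropped with their count recorded; all retained
#' effects must be nonnegative.
#'
#' @param effects numeric vector of efficiency effects (`A` values);
#'   `NA` entries (saturated inversions) are removed.
#' @param source_label character scalar naming the source dataset.
#' @param source_starting_psi the starting PSI at which the source effects
#'   were measured, strictly inside (0, 100).
#' @return an object of class `effect_distribution` (a list with
#'   `source_label`, `source_starting_psi`, `effects`, `n_dropped`).
#' @export
effect_distribution <- function(effects, source_label = "effects",
                                source_starting_psi = 50) {
  stopifnot(is.numeric(effects))
  if (source_starting_psi <= 0 || source_starting_psi >= 100)
    stop("'source_starting_psi' must be strictly inside (0, 100)", call. = FALSE)
  dropped <- sum(is.na(effects))
  effects <- effects[!is.na(effects)]
  if (length(effects) == 0L)
    stop("effect distribution must be nonempty", call. = FALSE)
  if (any(effects < 0))
    stop("all efficiency effects must be >= 0", call. = FALSE)
  structure(
    list(source_label = as.character(source_label)[1],
         source_starting_psi = source_starting_psi,
         effects = as.numeric(effects),
         n_dropped = dropped),
    class = "effect_distribution")
}

#' @export
print.effect_distribution <- function(x, ...) {
  cat(sprintf("<effect_distribution> %s: %d effects (source PSI %.1f, %d saturated dropped)\n",
              x$source_label, length(x$effects), x$source_starting_psi, x$n_dropped))
  invisible(x)
}

#' Estimate an effect distribution from delta-PSI measurements
#'
#' Convenience wrapper: inverts the scaling law for a vector of measured
#' PSI changes made at a common (or per-record) starting PSI and packages
#' the result as an [effect_distribution()].
#'
#' @inheritParams estimate_A
#' @inheritParams effect_distribution
#' @return an `effect_distribution`.
#' @export
effects_from_deltas <- function(delta_psi, psi_start,
                                source_label = "effects") {
  A <- suppressWarnings(estimate_A(delta_psi, psi_start))
  dist <- effect_distribution(A, source_label = source_label,
                              source_starting_psi = psi_start[1])
  dist$n_clipped <- attr(A, "clipped")
  dist
}

#' Rescale a distribution of efficiency effects to a new starting PSI
#'
#' Projects every efficiency effect in a distribution to the PSI change it
#' would cause in an exon included at `target_psi`: each `A` is mapped to
#' `predict_final_psi(A, target_psi) - target_psi`, preserving order. This
#' is how a distribution of mutation effects measured in one exon predicts
#' the effect distribution for a completely different exon, provided its
#' inclusion level is known.
#'
#' @param dist an [effect_distribution()].
#' @param target_psi target starting PSI, strictly inside (0, 100).
#' @return numeric vector of predicted delta-PSI values, one per effect.
#' @export
rescale_effects <- function(dist, target_psi) {
  stopifnot(inherits(dist, "effect_distribution"))
  if (target_psi <= 0 || target_psi >= 100)
    stop("'target_psi' must be strictly inside (0, 100)", call. = FALSE)
  if (length(dist$effects) == 0L)
    stop("effect distribution is empty", call. = FALSE)
  predict_final_psi(dist$effects, target_psi) - target_psi
}

#' Fraction of effects exceeding a delta-PSI threshold
#'
#' @param deltas numeric vector of delta-PSI values.
#' @param threshold magnitude threshold in PSI units (default 10).
#' @param strict if `FALSE` (default) counts `|delta| >= threshold`
#'   ("by at least 10 PSI units"); if `TRUE` counts `|delta| > threshold`
#'   ("by more than 10").
#' @return fraction of entries whose absolute value passes the threshold.
#' @export
fraction_exceeding <- function(deltas, threshold = 10, strict = FALSE) {
  deltas <- deltas[!is.na(deltas)]
  if (length(deltas) == 0L) stop("'deltas' must be nonempty", call. = FALSE)
  if (strict) mean(abs(deltas) > threshold) else mean(abs(deltas) >= threshold)
}

#' Pooled rescaled density with a bootstrap confidence band
#'
#' Rescales one or more effect distributions to a common target PSI,
#' estimates the pooled density of the predicted delta-PSI values with a
#' Gaussian kernel (bandwidth 5 PSI units, 512 grid points spanning the
#' pooled range plus three bandwidths on either side), and attaches a
#' pointwise percentile confidence band. Each bootstrap replicate
#' resamples every distribution with replacement, rescales, and
#' re-estimates the pooled density on the same grid; the band at each grid
#' point is the `(1-level)/2` and `1-(1-level)/2` percentile of the
#' bootstrap densities.
#'
#' @param dists a single [effect_distribution()] or a list of them.
#' @param target_psi target starting PSI, strictly inside (0, 100).
#' @param n_boot number of bootstrap replicates (default 2500).
#' @param band_level band coverage, a fraction in (0, 1); default 0.95.
#'   (Figures elsewhere sometimes quote 0.99; it is a plain parameter
#'   here.)
#' @param seed integer seed; the result is bit-reproducible given the seed.
#' @param bw kernel bandwidth in PSI units (default 5).
#' @param n_grid number of grid points (default 512).
#' @return an object of class `scaled_density`: list with `target_psi`,
#'   `grid`, `density`, `band_lower`, `band_upper`, `band_level`, `bw`,
#'   `n_boot`, `seed`.
#' @export
density_with_band <- function(dists, target_psi, n_boot = 2500,
                              band_level = 0.95, seed = 1L,
                              bw = 5, n_grid = 512L) {
  if (inherits(dists, "effect_distribution")) dists <- list(dists)
  stopifnot(length(dists) >= 1L,
            all(vapply(dists, inherits, logical(1), "effect_distribution")))
  if (band_level <= 0 || band_level >= 1)
    stop("'band_level' must be in (0, 1)", call. = FALSE)
  if (n_boot < 1) stop("'n_boot' must be >= 1", call. = FALSE)

  deltas <- lapply(dists, rescale_effects, target_psi = target_psi)
  pooled <- unlist(deltas, use.names = FALSE)
  from <- min(pooled) - 3 * bw
  to <- max(pooled) + 3 * bw
  dens <- stats::density(pooled, bw = bw, n = n_grid, from = from, to = to)

  set.seed(seed)
  boot <- matrix(NA_real_, nrow = n_boot, ncol = n_grid)
  for (b in seq_len(n_boot)) {
    resampled <- unlist(lapply(deltas, function(d)
      d[sample.int(length(d), replace = TRUE)]), use.names = FALSE)
    boot[b, ] <- stats::density(resampled, bw = bw, n = n_grid,
                                from = from, to = to)$y
  }
  alpha <- (1 - band_level) / 2
  qs <- apply(boot, 2, stats::quantile, probs = c(alpha, 1 - alpha),
              names = FALSE, type = 7)
  structure(
    list(target_psi = target_psi, grid = dens$x, density = dens$y,
         band_lower = qs[1, ], band_upper = qs[2, ],
         band_level = band_level, bw = bw, n_boot = n_boot, seed = seed),
    class = "scaled_density")
}

#' @export
print.scaled_density <- function(x, ...) {
  cat(sprintf(
    "<scaled_density> target PSI %.1f: %d grid points, %.0f%% band (%d bootstraps, bw %.1f)\n",
    x$target_psi, length(x$grid), 100 * x$band_level, x$n_boot, x$bw))
  invisible(x)
}
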