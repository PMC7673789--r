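#' Construct an exon-by-tissue PSI atlas
#'
#' @param exons data frame with columns `exon_id`, `chrom`, `start`,
#'   `end` (0-based half-open), `strand`, `length` (nucleotides, >= 1).
#' @param psi numeric matrix of mean PSI (percent, or `NA` where the event
#'   could not be quantified), rows matching `exons$exon_id`, one column
#'   per tissue.
#' @return a `psi_atlas` object.
#' @export
psi_atlas <- function(exons, psi) {
  stopifnot(is.data.frame(exons), is.matrix(psi),
            nrow(exons) == nrow(psi))
  required <- c("exon_id", "length")
  missing <- setdiff(required, names(exons))
  if (length(missing))
    stop("exon table lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (any(exons$length < 1)) stop("exon lengths must be >= 1", call. = FALSE)
  if (any(psi < 0 | psi > 100, na.rm = TRUE))
    stop("PSI values must be in [0, 100]", call. = FALSE)
  if (is.null(colnames(psi)))
    colnames(psi) <- paste0("tissue_", seq_len(ncol(psi)))
  rownames(psi) <- exons$exon_id
  structure(list(exons = exons, psi = psi), class = "psi_atlas")
}

#' @export
print.psi_atlas <- function(x, ...) {
  cat(sprintf("<psi_atlas> %d exons x %d tissues (%.1f%% quantified)\n",
              nrow(x$psi), ncol(x$psi), 100 * mean(!is.na(x$psi))))
  invisible(x)
}

#' Summarise the bimodality of exon inclusion levels
#'
#' Exon inclusion across tissues is strongly bimodal: most exons are
#' almost completely included or almost completely skipped. This
#' summarises the fraction of (exon, tissue) PSI entries at intermediate
#' inclusion, both at the exon level and at the nucleotide level (each
#' exon's PSI weighted by its length, equivalent to repeating the value
#' once per nucleotide).
#'
#' @param atlas a [psi_atlas()].
#' @param lo,hi the intermediate-inclusion window: entries with
#'   `lo < PSI < hi` count as intermediate (defaults 10 and 90).
#' @return list with `pooled` (fraction intermediate over all entries),
#'   `pooled_nt` (length-weighted), `per_tissue` and `per_tissue_nt`
#'   (named vectors), and `n_entries`.
#' @export
summarize_bimodality <- function(atlas, lo = 10, hi = 90) {
  stopifnot(inherits(atlas, "psi_atlas"))
  psi <- atlas$psi
  if (all(is.na(psi))) stop("atlas has no quantified PSI values", call. = FALSE)
  len <- atlas$exons$length
  inter <- psi > lo & psi < hi

  frac <- function(x, w) {
    ok <- !is.na(x)
    sum(w[ok] * x[ok]) / sum(w[ok])
  }
  w1 <- rep(1, nrow(psi))
  per_tissue <- apply(inter, 2, frac, w = w1)
  per_tissue_nt <- apply(inter, 2, frac, w = len)
  wmat <- matrix(1, nrow(psi), ncol(psi))
  lmat <- matrix(len, nrow(psi), ncol(psi))
  list(pooled = frac(as.vector(inter), as.vector(wmat)),
       pooled_nt = frac(as.vector(inter), as.vector(lmat)),
       per_tissue = per_tissue, per_tissue_nt = per_tissue_nt,
       n_entries = sum(!is.na(psi)))
}

# deterministic 31-bit hash of a string, for per-exon seed splitting
.hash31 <- function(s) {
  bytes <- utf8ToInt(s)
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  as.integer(h)
}

#' Predict the genome-wide distribution of mutational delta-PSI effects
#'
#' For every exon quantified in the chosen tissue, draws efficiency
#' effects with replacement from `dist` — `round(length * samples_per_nt)`
#' draws, so each exon contributes in proportion to its length (one draw
#' per nucleotide at the default rate) — and converts each draw to a
#' delta-PSI through the scaling law at that exon's inclusion level.
#' Pooling the per-exon predictions yields the transcriptome-wide
#' distribution of mutational effects on inclusion.
#'
#' Exons at PSI exactly 0 or 100 sit at the fixed points of the scaling
#' law; their predicted delta-PSI is 0 for every draw. Sampling is keyed
#' per exon (seed split on `exon_id`), so results do not depend on exon
#' order.
#'
#' @param atlas a [psi_atlas()].
#' @param dist an [effect_distribution()].
#' @param tissue tissue (column) name present in the atlas.
#' @param samples_per_nt draws per exon nucleotide (default 1; lower it
#'   for small-scale runs).
#' @param seed integer seed.
#' @param threshold summary threshold in PSI units (default 10).
#' @return a `genomewide_delta_psi` object: list with `tissue`, `deltas`
#'   (numeric vector), `exon_id` (provenance, one label per draw),
#'   `frac_below_threshold` (fraction with `|delta| < threshold`),
#'   `threshold`, `n_exons`, `n_draws`.
#' @export
predict_genomewide <- function(atlas, dist, tissue, samples_per_nt = 1,
                               seed = 1L, threshold = 10) {
  stopifnot(inherits(atlas, "psi_atlas"),
            inherits(dist, "effect_distribution"))
  if (!tissue %in% colnames(atlas$psi))
    stop("tissue '", tissue, "' not present in atlas", call. = FALSE)
  psi <- atlas$psi[, tissue]
  keep <- !is.na(psi)
  ids <- atlas$exons$exon_id[keep]
  lens <- atlas$exons$length[keep]
  psi <- psi[keep]

  n_draws <- round(lens * samples_per_nt)
  use <- n_draws > 0
  out_deltas <- vector("list", sum(use))
  out_ids <- vector("list", sum(use))
  j <- 0L
  for (i in which(use)) {
    j <- j + 1L
    set.seed((seed + .hash31(ids[i])) %% 2147483647L)
    a <- dist$effects[sample.int(length(dist$effects), n_draws[i],
                                 replace = TRUE)]
    d <- if (psi[i] <= 0 || psi[i] >= 100) rep(0, n_draws[i])
         else predict_final_psi(a, psi[i]) - psi[i]
    out_deltas[[j]] <- d
    out_ids[[j]] <- rep(ids[i], n_draws[i])
  }
  deltas <- unlist(out_deltas, use.names = FALSE)
  structure(
    list(tissue = tissue, deltas = deltas,
         exon_id = unlist(out_ids, use.names = FALSE),
         frac_below_threshold = mean(abs(deltas) < threshold),
         threshold = threshold,
         n_exons = sum(use), n_draws = length(deltas)),
    class = "genomewide_delta_psi")
}

#' @export
print.genomewide_delta_psi <- function(x, ...) {
  cat(sprintf(
    "<genomewide_delta_psi> %s: %d draws over %d exons; %.1f%% with |dPSI| < %g\n",
    x$tissue, x$n_draws, x$n_exons, 100 * x$frac_below_threshold,
    x$threshold))
  invisible(x)
}

#' Pool efficiency-effect distributions from several source datasets
#'
#' Concatenates the effects of several [effect_distribution()] objects
#' into one, for analyses that combine all available mutational datasets.
#'
#' @param dists list of `effect_distribution` objects.
#' @param source_label label for the pooled distribution.
#' @return an `effect_distribution`.
#' @export
pool_distributions <- function(dists, source_label = "pooled") {
  stopifnot(length(dists) >= 1L,
            all(vapply(dists, inherits, logical(1), "effect_distribution")))
  effect_distribution(
    unlist(lapply(dists, `[[`, "effects"), use.names = FALSE),
    source_label = source_label,
    source_starting_psi = dists[[1]]$source_starting_psi)
}
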