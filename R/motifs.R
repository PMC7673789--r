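#' Construct a hexamer motif set
#'
#' @param motifs character vector of length-6 DNA strings (A/C/G/T);
#'   duplicates are removed, case is normalised to upper.
#' @param role `"ESE"` (enhancer) or `"ESS"` (silencer).
#' @return a `hexamer_set` object (character vector with a `role`
#'   attribute).
#' @export
hexamer_set <- function(motifs, role = c("ESE", "ESS")) {
  role <- match.arg(role)
  motifs <- toupper(unique(as.character(motifs)))
  if (length(motifs) && (any(nchar(motifs) != 6L) ||
      any(grepl("[^ACGT]", motifs))))
    stop("motifs must be length-6 strings over A/C/G/T", call. = FALSE)
  structure(motifs, role = role, class = "hexamer_set")
}

#' @export
print.hexamer_set <- function(x, ...) {
  cat(sprintf("<hexamer_set> %d %s hexamers\n", length(x), attr(x, "role")))
  invisible(x)
}

.check_seq <- function(seq) {
  seq <- toupper(seq)
  if (grepl("[^ACGT]", seq))
    stop("sequence contains non-ACGT characters", call. = FALSE)
  seq
}

# all overlapping 6-nt windows of a sequence (sense strand)
.windows <- function(seq) {
  n <- nchar(seq)
  if (n < 6L) return(character(0))
  substring(seq, 1:(n - 5L), 6:n)
}

#' Count motif occurrences in a sequence
#'
#' Overlapping sliding-window count of 6-nt windows matching the motif
#' set, and the per-nucleotide density (count divided by sequence
#' length). Occurrences, not motif types, are counted: the same hexamer
#' at two positions counts twice.
#'
#' @param seq a DNA string (sense strand), length >= 6.
#' @param motifs a [hexamer_set()].
#' @return list with `count` and `density`.
#' @examples
#' motif_density("AAAAAAA", hexamer_set("AAAAAA"))  # 2 windows, density 2/7
#' @export
motif_density <- function(seq, motifs) {
  seq <- .check_seq(seq)
  if (nchar(seq) < 6L) stop("sequence must be at least 6 nt", call. = FALSE)
  count <- sum(.windows(seq) %in% motifs)
  list(count = count, density = count / nchar(seq))
}

#' Class composition across motif-density deciles
#'
#' Ranks exons by motif density into 10 equally populated bins and
#' reports the proportion of constitutive vs alternative exons in each.
#' Constitutive exons concentrating in the high-density bins is the
#' signature of enhancer redundancy. Optional restriction filters (e.g.
#' alternative exons highly included in at least one tissue, or exons in
#' the weak/strong tails of splice-site strength) are applied by
#' subsetting `exons` before the call.
#'
#' @param exons data frame with columns `exon_id`, `sequence`, `class`
#'   (factor constitutive/alternative).
#' @param motifs a [hexamer_set()].
#' @param n_bins number of density bins (default 10).
#' @return data frame per bin: `bin`, `n`, `density_min`, `density_max`,
#'   `prop_constitutive`, `prop_alternative`.
#' @export
decile_enrichment <- function(exons, motifs, n_bins = 10L) {
  stopifnot(all(c("exon_id", "sequence", "class") %in% names(exons)))
  exons <- exons[!is.na(exons$class), , drop = FALSE]
  if (nrow(exons) < n_bins)
    stop("need at least ", n_bins, " classified exons", call. = FALSE)
  if (length(unique(exons$class)) < 2L)
    stop("both exon classes must be represented", call. = FALSE)
  dens <- vapply(exons$sequence, function(s) motif_density(s, motifs)$density,
                 numeric(1), USE.NAMES = FALSE)
  ord <- order(dens, exons$exon_id)      # deterministic under ties
  n <- nrow(exons)
  sizes <- rep(n %/% n_bins, n_bins)
  extra <- n %% n_bins
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  bin_of <- rep(seq_len(n_bins), times = sizes)
  cls <- exons$class[ord]; dens <- dens[ord]
  out <- lapply(seq_len(n_bins), function(b) {
    sel <- bin_of == b
    data.frame(bin = b, n = sum(sel),
               density_min = min(dens[sel]), density_max = max(dens[sel]),
               prop_constitutive = mean(cls[sel] == "constitutive"),
               prop_alternative = mean(cls[sel] == "alternative"))
  })
  do.call(rbind, out)
}

# the 18 single-substitution neighbours of a hexamer
.neighbours <- function(h) {
  bases <- c("A", "C", "G", "T")
  chars <- strsplit(h, "")[[1]]
  out <- character(18L)
  k <- 0L
  for (i in 1:6) {
    for (b in bases[bases != chars[i]]) {
      k <- k + 1L
      tmp <- chars; tmp[i] <- b
      out[k] <- paste(tmp, collapse = "")
    }
  }
  out
}

#' The suboptimal-motif neighbourhood of a hexamer set
#'
#' A suboptimal ESE is a hexamer one nucleotide substitution away from an
#' ESE. The result is the union, over all motifs in the set, of their 18
#' single-substitution neighbours; a member of the input set appears in
#' the output exactly when it is itself one substitution from another
#' member.
#'
#' @param motifs a [hexamer_set()].
#' @return a `hexamer_set` of suboptimal motifs (same role attribute).
#' @export
suboptimal_set <- function(motifs) {
  if (length(motifs) == 0L) stop("motif set is empty", call. = FALSE)
  nb <- unique(unlist(lapply(as.character(motifs), .neighbours),
                      use.names = FALSE))
  hexamer_set(nb, role = attr(motifs, "role"))
}

#' Mutational robustness of a motif
#'
#' The robustness of an ESE hexamer is the number of its 18
#' single-substitution neighbours that are themselves ESEs: a robust
#' enhancer tends to remain an enhancer when hit by a point mutation.
#'
#' @param h a hexamer that is a member of `motifs`.
#' @param motifs a [hexamer_set()].
#' @return integer in \[0, 18\].
#' @export
robustness_score <- function(h, motifs) {
  h <- toupper(h)
  if (!h %in% motifs)
    stop("robustness is defined only for members of the motif set",
         call. = FALSE)
  sum(.neighbours(h) %in% motifs)
}

#' Robustness scores of every motif in a set
#'
#' @param motifs a [hexamer_set()].
#' @return named integer vector (one score per motif, 0..18).
#' @export
robustness_scores <- function(motifs) {
  vapply(as.character(motifs), robustness_score, integer(1), motifs = motifs)
}

#' Per-robustness-group motif density contrast between exon classes
#'
#' Groups the motifs of a set by robustness score and, for each group,
#' computes the mean occurrences-per-nucleotide of that group's motifs in
#' constitutive and in alternative exons, and their ratio (constitutive
#' over alternative enrichment).
#'
#' @param exons data frame with `sequence` and `class` columns.
#' @param motifs a [hexamer_set()].
#' @return data frame per observed score: `score`, `n_motifs`,
#'   `density_constitutive`, `density_alternative`, `ratio`.
#' @export
robustness_profile <- function(exons, motifs) {
  scores <- robustness_scores(motifs)
  cls <- exons$class
  seqs_con <- exons$sequence[cls == "constitutive"]
  seqs_alt <- exons$sequence[cls == "alternative"]
  win_con <- lapply(seqs_con, .windows)
  win_alt <- lapply(seqs_alt, .windows)
  len_con <- sum(nchar(seqs_con)); len_alt <- sum(nchar(seqs_alt))
  out <- lapply(sort(unique(scores)), function(s) {
    grp <- names(scores)[scores == s]
    dc <- sum(vapply(win_con, function(w) sum(w %in% grp), numeric(1))) / len_con
    da <- sum(vapply(win_alt, function(w) sum(w %in% grp), numeric(1))) / len_alt
    data.frame(score = s, n_motifs = length(grp),
               density_constitutive = dc, density_alternative = da,
               ratio = dc / da)
  })
  do.call(rbind, out)
}

#' Exhaustive scan of motif gains and losses under point mutation
#'
#' Enumerates all `3 * length` single-nucleotide substitutions of a
#' sequence and, for every mutation that destroys at least one enhancer
#' occurrence, records: the number of enhancer occurrences lost
#' (overlapping occurrences can be deactivated simultaneously), the
#' number of enhancer occurrences gained at windows other than the exact
#' coordinates of a destroyed occurrence (a same-window replacement does
#' not count as a cryptic gain), and the number of silencer occurrences
#' gained.
#'
#' @param seq a DNA string, length >= 6.
#' @param ese enhancer [hexamer_set()].
#' @param ess silencer [hexamer_set()] (optional; empty set allowed).
#' @return data frame with one row per disrupting mutation: `position`,
#'   `ref`, `alt`, `ese_lost`, `ese_gained`, `ess_gained`.
#' @export
mutational_motif_scan <- function(seq, ese, ess = hexamer_set(character(0), "ESS")) {
  seq <- .check_seq(seq)
  n <- nchar(seq)
  if (n < 6L) stop("sequence must be at least 6 nt", call. = FALSE)
  bases <- c("A", "C", "G", "T")
  chars <- strsplit(seq, "")[[1]]
  win0 <- .windows(seq)
  ese0 <- which(win0 %in% ese)       # occurrence start positions
  ess0 <- which(win0 %in% ess)
  rows <- list()
  for (pos in seq_len(n)) {
    # windows covering this position
    lo <- max(1L, pos - 5L); hi <- min(n - 5L, pos)
    if (lo > hi) next
    affected <- lo:hi
    for (alt in bases[bases != chars[pos]]) {
      mut <- chars; mut[pos] <- alt
      mutseq <- paste(mut, collapse = "")
      win1 <- substring(mutseq, affected, affected + 5L)
      was_ese <- affected[win0[affected] %in% ese]
      now_ese <- affected[win1 %in% ese]
      lost <- setdiff(was_ese, now_ese)
      if (length(lost) == 0L) next
      # a window that merely swaps one enhancer for another stays in the
      # set, so same-window replacements never register as gains
      gained <- setdiff(now_ese, was_ese)
      was_ess <- affected[win0[affected] %in% ess]
      now_ess <- affected[win1 %in% ess]
      ess_gained <- setdiff(now_ess, was_ess)
      rows[[length(rows) + 1L]] <- data.frame(
        position = pos, ref = chars[pos], alt = alt,
        ese_lost = length(lost), ese_gained = length(gained),
        ess_gained = length(ess_gained))
    }
  }
  if (length(rows) == 0L)
    return(data.frame(position = integer(0), ref = character(0),
                      alt = character(0), ese_lost = integer(0),
                      ese_gained = integer(0), ess_gained = integer(0)))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Count overlapping motif-occurrence pairs
#'
#' The number of unordered pairs of motif occurrences whose 6-nt windows
#' share at least one position. Overlapping enhancers are of interest
#' because a single point mutation can deactivate both at once.
#'
#' @inheritParams motif_density
#' @return integer pair count.
#' @export
overlap_count <- function(seq, motifs) {
  seq <- .check_seq(seq)
  if (nchar(seq) < 6L) stop("sequence must be at least 6 nt", call. = FALSE)
  starts <- which(.windows(seq) %in% motifs)
  if (length(starts) < 2L) return(0L)
  pairs <- utils::combn(starts, 2L)
  sum(pairs[2L, ] - pairs[1L, ] < 6L)
}
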