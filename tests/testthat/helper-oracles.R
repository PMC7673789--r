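# Independent oracles and tiny fixture builders shared across tests.

# Invert the scaling law by bisection on A (never calls estimate_A).
grid_invert_A <- function(delta_psi, psi_start, lo = 0, hi = 1e6) {
  target <- psi_start + delta_psi
  f <- function(A) 100 * A * psi_start / (100 - psi_start + A * psi_start) - target
  stats::uniroot(f, c(lo, hi), tol = 1e-12)$root
}

# Posterior mean of a Normal measurement restricted to [0, es_max],
# by fine-grid numerical integration (independent of bayes_correct).
posterior_mean_oracle <- function(es, se, es_max, n = 1e6) {
  k <- seq(0, es_max, length.out = n)
  w <- exp(-0.5 * ((k - es) / se)^2)
  sum(w * k) / sum(w)
}

# Closed-form mean of a truncated normal on [0, es_max] (second route).
truncnorm_mean <- function(es, se, es_max) {
  a <- (0 - es) / se; b <- (es_max - es) / se
  es + se * (stats::dnorm(a) - stats::dnorm(b)) /
    (stats::pnorm(b) - stats::pnorm(a))
}

# All 18 single-substitution neighbours of a hexamer, by plain loops.
neighbours_oracle <- function(h) {
  bases <- c("A", "C", "G", "T")
  out <- character(0)
  for (i in 1:6) {
    for (b in setdiff(bases, substr(h, i, i))) {
      x <- h
      substr(x, i, i) <- b
      out <- c(out, x)
    }
  }
  out
}

# Window-set recount oracle for mutational_motif_scan: for one mutated
# sequence, count motif windows before and after.
count_windows <- function(seq, motifs) {
  n <- nchar(seq)
  sum(substring(seq, 1:(n - 5), 6:n) %in% motifs)
}

random_hexamers <- function(n) {
  unique(replicate(n, paste(sample(c("A", "C", "G", "T"), 6, replace = TRUE),
                            collapse = "")))
}

# Minimal DMS count table: WT plus explicitly given variant frequencies.
# freq_in/freq_out are per-variant relative weights; depth exact.
toy_counts <- function(freq_in, freq_out, depth = 1e4, n_rep = 2) {
  stopifnot(length(freq_in) == length(freq_out))
  nv <- length(freq_in)
  counts <- data.frame(
    variant_id = c("WT", paste0("v", seq_len(nv))),
    position = c(NA_integer_, seq_len(nv)),
    ref = c(NA, rep("A", nv)), alt = c(NA, rep("G", nv)),
    stringsAsFactors = FALSE)
  p_in <- c(1, freq_in); p_out <- c(1, freq_out)
  for (r in seq_len(n_rep)) {
    counts[[paste0("input_", r)]] <- round(depth * p_in / sum(p_in))
    counts[[paste0("output_", r)]] <- round(depth * p_out / sum(p_out))
  }
  counts
}
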