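#!/usr/bin/env Rscript
# Hexamer enhancer analytics on the simulated sequences: density deciles,
# suboptimal-ESE neighbourhood, robustness profile, cryptic gain/loss scan
# and overlapping occurrences.

suppressMessages(library(psiscale))

exons <- read_exon_fasta("results/workspace/exon_sequences.fa")
cls <- utils::read.delim("results/workspace/exon_classes.tsv")
exons$class <- factor(cls$class[match(exons$exon_id, cls$exon_id)],
                      levels = c("constitutive", "alternative"))
ese <- read_hexamers("results/workspace/ese_hexamers.txt", role = "ESE")
cat(sprintf("%d exons, %d ESE hexamers\n", nrow(exons), length(ese)))

dec <- decile_enrichment(exons, ese)
utils::write.table(dec, "results/ese_density_deciles.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
cat(sprintf("ESE density deciles: constitutive proportion %.2f (bottom) -> %.2f (top)\n",
            dec$prop_constitutive[1], dec$prop_constitutive[10]))

sub <- suboptimal_set(ese)
cat(sprintf("Suboptimal-ESE set: %d hexamers one substitution from an ESE\n",
            length(sub)))
dec_sub <- decile_enrichment(exons, sub)
utils::write.table(dec_sub, "results/suboptimal_ese_deciles.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)
cat(sprintf("Suboptimal-ESE deciles: constitutive proportion %.2f (bottom) -> %.2f (top)\n",
            dec_sub$prop_constitutive[1], dec_sub$prop_constitutive[10]))

prof <- robustness_profile(exons, ese)
utils::write.table(prof, "results/ese_robustness_profile.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
cat("ESE robustness profile (score = mutable neighbours that stay ESEs):\n")
cat(sprintf("  scores observed: %s\n",
            paste(prof$score, collapse = " ")))

# cryptic gains/losses: exhaustive point-mutation scan over a subset
set.seed(1)
subset_idx <- sample.int(nrow(exons), 100)
scan_rows <- lapply(subset_idx, function(i) {
  s <- mutational_motif_scan(exons$sequence[i], ese)
  if (nrow(s) == 0) return(NULL)
  cbind(exon_id = exons$exon_id[i], class = as.character(exons$class[i]), s)
})
scan <- do.call(rbind, scan_rows)
utils::write.table(scan, "results/mutational_scan.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
cat(sprintf("Mutational scan over %d exons: %d ESE-disrupting mutations; %.1f%% create a cryptic ESE elsewhere, %.2f%% destroy >1 occurrence at once\n",
            length(subset_idx), nrow(scan),
            100 * mean(scan$ese_gained > 0),
            100 * mean(scan$ese_lost > 1)))

ov <- vapply(exons$sequence, overlap_count, integer(1), motifs = ese,
             USE.NAMES = FALSE)
cat(sprintf("Overlapping ESE occurrence pairs per exon: mean %.2f (constitutive) vs %.2f (alternative)\n",
            mean(ov[exons$class == "constitutive"]),
            mean(ov[exons$class == "alternative"])))
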