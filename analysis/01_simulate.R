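#!/usr/bin/env Rscript
# Materialise the synthetic workspace every downstream analysis consumes:
# a DMS count table with ground truth, an exon-by-tissue PSI atlas, a
# genotyped cohort with planted dosage effects, and exon sequences with
# class-dependent enhancer densities.

suppressMessages(library(psiscale))
seed <- 20260929L
ws <- "results/workspace"
dir.create(ws, recursive = TRUE, showWarnings = FALSE)

cfg <- sim_config(seed = seed,
                  atlas = list(n_exons = 5000L, n_tissues = 5L),
                  cohort = list(n_variants = 500L),
                  sequences = list(n_per_class = 400L))

dms <- gen_dms(cfg)
write_counts(dms$counts, file.path(ws, "dms_counts.tsv"))
write_effect_table(dms$truth, file.path(ws, "dms_truth.tsv"))
cat(sprintf("DMS library: %d variants + WT, %d replicates, depth %g\n",
            nrow(dms$truth), cfg$dms$n_replicates, cfg$dms$depth))

atlas <- gen_atlas(cfg)
write_atlas(atlas, file.path(ws, "psi_atlas.tsv"))
cat(sprintf("Atlas: %d exons x %d tissues (%.1f%% entries quantified)\n",
            nrow(atlas$psi), ncol(atlas$psi), 100 * mean(!is.na(atlas$psi))))

cohort <- gen_cohort(cfg, atlas)
write_genotypes_tsv(cohort$genotypes, file.path(ws, "genotypes.tsv"))
utils::write.table(cbind(exon_id = rownames(cohort$psi_by_tissue[[1]]),
                         as.data.frame(cohort$psi_by_tissue[[1]])),
                   file.path(ws, "cohort_psi_tissue_1.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")
write_effect_table(cohort$truth, file.path(ws, "cohort_truth.tsv"))
cat(sprintf("Cohort: %d variants x %d samples (planted effects recorded)\n",
            nrow(cohort$genotypes$variants), ncol(cohort$genotypes$copies)))

sq <- gen_sequences(cfg)
write_exon_fasta(sq$exons, file.path(ws, "exon_sequences.fa"))
utils::write.table(sq$exons[c("exon_id", "class")],
                   file.path(ws, "exon_classes.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
write_hexamers(sq$ese, file.path(ws, "ese_hexamers.txt"))
cat(sprintf("Sequences: %d exons (%d per class), %d ESE hexamers\n",
            nrow(sq$exons), cfg$sequences$n_per_class, length(sq$ese)))
cat("workspace written to", ws, "\n")
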