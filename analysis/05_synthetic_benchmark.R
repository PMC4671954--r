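#!/usr/bin/env Rscript
# Stage 5 - planted-structure recovery benchmark on synthetic cohorts.
# Generates seeded cohorts with the study's shape (29 vs 17 samples, 43
# region genes, 9 released miRNAs, 4 planted ceRNAs), runs the pipeline on
# each, and scores recovery against the generator's ground truth; a null
# configuration (all effects 1.0) checks type-I calibration of the screen.

suppressPackageStartupMessages(library(cernadel))
dir.create("results", showWarnings = FALSE)

n_seeds <- 50
rec <- recovery_experiment(n_seeds = n_seeds, seed = 1)
utils::write.table(rec, "results/05_recovery.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
cat(sprintf("Recovery over %d seeded cohorts (defaults):\n", n_seeds))
cat(sprintf("  released-miRNA precision %.3f, recall %.3f\n",
            mean(rec$mirna_precision, na.rm = TRUE), mean(rec$mirna_recall)))
cat(sprintf("  ceRNA-gene     precision %.3f, recall %.3f\n",
            mean(rec$cerna_precision, na.rm = TRUE), mean(rec$cerna_recall)))

null_cfg <- synthetic_config(deletion_effect = 1, cerna_effect_down = 1,
                             cerna_effect_up = 1)
null_rec <- recovery_experiment(n_seeds = n_seeds, cfg = null_cfg,
                                seed = 100000)
utils::write.table(null_rec, "results/05_null.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
cat(sprintf("Null configuration: in-region significant fraction %.4f (nominal 0.05)\n",
            mean(null_rec$region_sig_rate)))
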