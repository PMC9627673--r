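#!/usr/bin/env Rscript
# Stage 1: generate the synthetic multi-batch screen and its companion
# inputs (trait table, flux validation panel), and write them under
# results/ as plain-text artifacts.
#
# The screen emulates a pan-cancer cell line panel profiled by
# flow-injection untargeted metabolomics: 60 lines in 7 batches, two QC
# lines repeated in every batch, planted 2-3x per-ion batch effects, a
# 2x injection-order drift, per-sample size factors and two planted
# metabolic types driving pathway-level intensity differences.

library(metabotyper)

seed <- 20260923L
out <- "results/01_simulate"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

scr <- simulate_screen(n_lines = 60, n_batches = 7, n_ions = 120,
                       batch_fold_range = c(2, 3), drift_amplitude = 2,
                       seed = seed)
write_ion_table(scr$table, file.path(out, "screen"))
# artifacts stay plain text; the full truth is re-derivable from the seed
jsonlite::write_json(
  list(seed = seed,
       type = as.list(scr$truth$type),
       qc_lines = scr$truth$qc_lines),
  file.path(out, "screen_truth.json"), auto_unbox = TRUE)

traits <- simulate_traits(scr$truth$type, n_null_categorical = 200,
                          n_null_continuous = 200, n_planted = 2,
                          effect = 4, seed = seed + 1)
write_traits_tsv(traits, file.path(out, "traits.tsv"))

panel <- simulate_flux_panel(25, rep(6, 5), sigma = 0.2,
                             seed = seed + 2)
write_ion_table(panel$table, file.path(out, "flux_panel"))

message(sprintf(
  "wrote screen (%d samples x %d ions, %d batches), %d traits, flux panel",
  nrow(scr$table$intensity), ncol(scr$table$intensity),
  length(unique(scr$table$samples$batch)),
  length(unique(traits$trait_id))))
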