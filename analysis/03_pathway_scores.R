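#!/usr/bin/env Rscript
# Stage 3: validate the PC1 pathway-activity score against planted
# fluxes on the validation panel, then score the normalized screen.

library(metabotyper)

seed <- 20260923L
out <- "results/03_scores"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

# flux validation: score vs planted flux, per pathway
panel <- simulate_flux_panel(25, rep(6, 5), sigma = 0.2,
                             seed = seed + 2)
psc <- pathway_score(panel$table, truth_ion_pathway_map(panel))
val <- validate_against_flux(psc, panel$truth$flux)
write.table(val, file.path(out, "flux_validation.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
message(sprintf("flux recovery: |r| in [%.3f, %.3f] over %d pathways",
                min(val$abs_r), max(val$abs_r), nrow(val)))

# screen: normalize with the winning stack, then score
scr <- simulate_screen(n_lines = 60, n_batches = 7, n_ions = 120,
                       batch_fold_range = c(2, 3), drift_amplitude = 2,
                       seed = seed)
stack <- normalization_stack(
  list(class = "sample_variance", method = "quantile"),
  list(class = "batch_effect", method = "combat"))
norm <- apply_stack(filter_abnormal_tic(scr$table)$table, stack)
scores <- pathway_score(norm, truth_ion_pathway_map(scr))
write_pathway_scores(scores, file.path(out, "screen"))
message(sprintf("scored %d pathways for %d cell lines; PC1 explains %.0f%%-%.0f%% of variance",
                ncol(scores$scores), nrow(scores$scores),
                100 * min(scores$explained_variance),
                100 * max(scores$explained_variance)))
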