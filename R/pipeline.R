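# End-to-end orchestration: screen pipeline (QC filter -> normalize ->
# score -> cluster -> associate) and tracing pipeline (correction -> FC
# -> fractional differences -> tail enrichment), with provenance
# manifests.

write_provenance <- function(dir, stage, params, seed = NULL) {
  prov <- list(stage = stage, params = params, seed = seed,
               timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  jsonlite::write_json(prov, file.path(dir,
                                       paste0(stage, "_provenance.json")),
                       auto_unbox = TRUE, digits = NA, null = "null")
}

#' Run the screen analysis pipeline
#'
#' Executes, in order: TIC quality filtering, the configured
#' normalization stack, pathway activity scoring, Ward clustering, and
#' the branch-trait association scan. Intermediate artifacts and
#' provenance JSON are written under `out_dir`.
#'
#' @param table raw [ion_table].
#' @param map an `ion_pathway_map` (see [map_ions_to_pathways()]).
#' @param traits long-format trait table, or NULL to skip the scan.
#' @param stack a [normalization_stack()]; default quantile + ComBat.
#' @param out_dir output directory (created); NULL skips writing.
#' @param tic_k TIC filter cut-off.
#' @param fdr,min_fraction association-scan parameters.
#' @return list with `table` (normalized), `scores`, `tree`,
#'   `associations` (NULL if no traits), `tic_removed`.
#' @export
run_screen_pipeline <- function(table, map, traits = NULL,
                                stack = normalization_stack(
                                  list(class = "sample_variance",
                                       method = "quantile"),
                                  list(class = "batch_effect",
                                       method = "combat")),
                                out_dir = NULL, tic_k = 4, fdr = 0.10,
                                min_fraction = 0.10) {
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  flt <- filter_abnormal_tic(table, k = tic_k)
  norm <- apply_stack(flt$table, stack)
  scores <- pathway_score(norm, map)
  tree <- cluster_cell_lines(scores)
  assoc <- NULL
  if (!is.null(traits))
    assoc <- association_scan(tree, traits, fdr = fdr,
                              min_fraction = min_fraction)
  if (!is.null(out_dir)) {
    write_ion_table(norm, file.path(out_dir, "normalized"))
    write_pathway_scores(scores, file.path(out_dir, "pathway"))
    write_tree_newick(tree, file.path(out_dir, "tree.nwk"))
    if (!is.null(assoc))
      utils::write.table(assoc, file.path(out_dir, "associations.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    write_provenance(out_dir, "screen_pipeline",
                     list(stack = stack$label, tic_k = tic_k,
                          fdr = fdr, min_fraction = min_fraction))
  }
  list(table = norm, scores = scores, tree = tree, associations = assoc,
       tic_removed = flt$removed_samples)
}

#' Run the tracing analysis pipeline
#'
#' Natural-abundance correction and fractional contributions per
#' metabolite, type-wise fractional differences, and pathway enrichment
#' in both tails of the ranked list — per tracer, never pooled across
#' tracers.
#'
#' @param mdv_table MDV data.frame (see [simulate_mdv()]).
#' @param type_labels named vector (1/2) per cell line.
#' @param sets named list of pathway sets (metabolite ids) for the tail
#'   enrichment; NULL skips enrichment.
#' @param tail_fraction tail size for the enrichment.
#' @param correct,p_nat natural-abundance correction options.
#' @param out_dir output directory; NULL skips writing.
#' @return list with `fc`, `delta` (ranked fractional differences) and
#'   `enrichment` (per tracer, NULL if no sets).
#' @export
run_tracing_pipeline <- function(mdv_table, type_labels, sets = NULL,
                                 tail_fraction = 0.25, correct = TRUE,
                                 p_nat = 0.0107, out_dir = NULL) {
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  fc <- compute_fractional_contributions(mdv_table, correct = correct,
                                         p_nat = p_nat)
  delta <- fractional_difference(fc, type_labels)
  enrichment <- NULL
  if (!is.null(sets)) {
    enrichment <- lapply(split(delta, delta$tracer), function(d)
      tail_enrichment(stats::setNames(d$delta, d$metabolite), sets,
                      tail_fraction))
  }
  if (!is.null(out_dir)) {
    utils::write.table(fc, file.path(out_dir, "fractional_contributions.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(delta, file.path(out_dir, "fractional_differences.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(enrichment))
      for (tr in names(enrichment))
        utils::write.table(enrichment[[tr]],
                           file.path(out_dir,
                                     paste0("enrichment_", tr, ".tsv")),
                           sep = "\t", quote = FALSE, row.names = FALSE)
    write_provenance(out_dir, "tracing_pipeline",
                     list(tail_fraction = tail_fraction,
                          correct = correct, p_nat = p_nat))
  }
  list(fc = fc, delta = delta, enrichment = enrichment)
}

#' Write a trait table to TSV
#'
#' @param traits long-format trait data.frame.
#' @param path file path.
#' @return Invisibly, `path`.
#' @export
write_traits_tsv <- function(traits, path) {
  utils::write.table(traits, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_traits_tsv
#' @param path file path.
#' @return The trait data.frame (read).
#' @export
read_traits_tsv <- function(path) {
  utils::read.delim(path, colClasses = c(value = "character"))
}
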