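# Pathway activity scoring by principal components.
#
# When a pathway's flux changes, most of its intermediates shift in a
# coherent direction; the first principal component of the pathway's
# member-ion profile captures exactly such coherent, distributed
# variation and its score is used as a qualitative proxy of pathway
# activity.

#' Score pathway activity per cell line
#'
#' For every scoreable pathway: member-ion intensities are
#' log-transformed and z-scored per ion across replicate-level samples;
#' PCA is fitted jointly on all replicates; the first principal
#' component's score is oriented so that the sum of PC1 loadings is
#' positive (ties broken by requiring positive correlation of scores
#' with the mean pathway-ion level); replicate scores are averaged per
#' cell line; finally each pathway's cell-line scores are divided by
#' their maximum absolute value, mapping them to `[-1, 1]`.
#'
#' @param table a normalized [ion_table] with `cell_line` metadata.
#' @param map an [map_ions_to_pathways()] result; only scoreable
#'   pathways are used.
#' @return An object of class `pathway_scores`: list with `scores`
#'   (cell line x pathway matrix in `[-1, 1]`), `loadings` (pathway ->
#'   named loading vector, unit norm), `explained_variance` (pathway ->
#'   PC1 variance fraction), `orientation` (pathway -> +/- 1 applied),
#'   `dropped` (pathways dropped for zero variance).
#' @export
pathway_score <- function(table, map) {
  stopifnot(inherits(table, "ion_table"),
            inherits(map, "ion_pathway_map"))
  if (is.null(table$samples$cell_line))
    stop("cell_line metadata required")
  scoreable <- names(which(map$scoreable))
  if (!length(scoreable)) stop("no scoreable pathway")
  lg <- log_safe(table)$log
  lines <- sort(unique(table$samples$cell_line))
  scores <- matrix(NA_real_, length(lines), length(scoreable),
                   dimnames = list(lines, scoreable))
  loadings <- list(); expl <- c(); orient <- c(); dropped <- character()
  for (p in scoreable) {
    ii <- match(map$pathway_ions[[p]], table$ions$ion_id)
    ii <- ii[!is.na(ii)]
    x <- lg[, ii, drop = FALSE]
    sds <- apply(x, 2, stats::sd)
    keep <- sds > 0
    if (sum(keep) < 2) {
      warning("pathway ", p, " dropped: zero-variance ions")
      dropped <- c(dropped, p)
      next
    }
    x <- x[, keep, drop = FALSE]
    z <- scale(x)
    pc <- stats::prcomp(z, center = FALSE, scale. = FALSE)
    load1 <- pc$rotation[, 1]
    s1 <- pc$x[, 1]
    flip <- 1
    ssum <- sum(load1)
    if (abs(ssum) > 1e-12) {
      if (ssum < 0) flip <- -1
    } else {
      # tie: orient by correlation with the mean pathway-ion level
      r <- stats::cor(s1, rowMeans(z))
      if (is.finite(r) && r < 0) flip <- -1
    }
    s1 <- flip * s1
    load1 <- flip * load1
    cl_score <- tapply(s1, table$samples$cell_line, mean)[lines]
    mx <- max(abs(cl_score))
    if (mx > 0) cl_score <- cl_score / mx
    scores[, p] <- cl_score
    loadings[[p]] <- load1
    expl[p] <- pc$sdev[1]^2 / sum(pc$sdev^2)
    orient[p] <- flip
  }
  ok <- setdiff(scoreable, dropped)
  structure(list(scores = scores[, ok, drop = FALSE],
                 loadings = loadings,
                 explained_variance = expl, orientation = orient,
                 dropped = dropped),
            class = "pathway_scores")
}

#' @export
print.pathway_scores <- function(x, ...) {
  cat(sprintf("pathway_scores: %d cell lines x %d pathways (in [-1, 1])\n",
              nrow(x$scores), ncol(x$scores)))
  invisible(x)
}

#' Validate pathway scores against known fluxes
#'
#' Correlates each pathway's activity score with the true (planted or
#' measured) pathway flux across conditions. On a validation panel a
#' strong correlation, of either sign, indicates that the first
#' principal component tracks flux; a negative sign flags a pathway
#' whose score direction is reversed (majority of intermediates respond
#' negatively to flux).
#'
#' @param scores a [pathway_score()] result whose rows are conditions.
#' @param flux condition x pathway matrix of true fluxes (e.g.
#'   `truth$flux` from [simulate_flux_panel()]).
#' @param log_flux correlate against log fluxes (default TRUE: fluxes
#'   span orders of magnitude and metabolite levels respond as power
#'   laws, so the score is linear in log flux).
#' @return data.frame with `pathway`, `r` (Pearson, score vs flux),
#'   `abs_r`, and `sign_reversed` (TRUE when r < 0).
#' @export
validate_against_flux <- function(scores, flux, log_flux = TRUE) {
  stopifnot(inherits(scores, "pathway_scores"))
  common <- intersect(rownames(scores$scores), rownames(flux))
  if (length(common) < 3) stop("need >= 3 aligned conditions")
  pws <- intersect(colnames(scores$scores), colnames(flux))
  if (log_flux) flux <- log(flux)
  r <- vapply(pws, function(p)
    stats::cor(scores$scores[common, p], flux[common, p]), numeric(1))
  data.frame(pathway = pws, r = unname(r), abs_r = abs(unname(r)),
             sign_reversed = unname(r) < 0)
}

#' Write pathway scores to TSV (plus loadings JSON)
#'
#' @param scores a [pathway_score()] result.
#' @param prefix file path prefix; writes `<prefix>_scores.tsv` and
#'   `<prefix>_loadings.json`.
#' @return Invisibly, the paths written.
#' @export
write_pathway_scores <- function(scores, prefix) {
  stopifnot(inherits(scores, "pathway_scores"))
  paths <- paste0(prefix, c("_scores.tsv", "_loadings.json"))
  df <- data.frame(cell_line = rownames(scores$scores), scores$scores,
                   check.names = FALSE)
  utils::write.table(df, paths[1], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(lapply(scores$loadings, function(l)
    as.list(stats::setNames(unname(l), names(l)))), paths[2],
    auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
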