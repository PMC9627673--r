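# Pathway definitions: reaction-level curation and ion-to-pathway
# mapping.
#
# Database pathway definitions overlap heavily; reactions occurring in
# several pathways make their metabolites uninformative about any one of
# them. The curation removes every reaction shared by two or more
# pathways, together with its substrates and products, keeping a
# metabolite only where some surviving reaction of the same pathway
# still touches it.

#' Construct a pathway set
#'
#' @param reactions data.frame with columns `reaction_id`, `pathway_id`,
#'   `substrates`, `products` (the last two semicolon-separated
#'   metabolite formulas); one row per (reaction, pathway) membership.
#' @param pathway_info optional data.frame with columns `pathway_id`,
#'   `name`, `class`.
#' @return An object of class `pathway_set` with elements `reactions`,
#'   `pathway_info` and `membership` (named list: pathway id -> character
#'   vector of member metabolite formulas).
#' @export
pathway_set <- function(reactions, pathway_info = NULL) {
  need <- c("reaction_id", "pathway_id", "substrates", "products")
  if (!all(need %in% names(reactions)))
    stop("reactions needs columns: ", paste(need, collapse = ", "))
  if (is.null(pathway_info))
    pathway_info <- data.frame(pathway_id = unique(reactions$pathway_id),
                               name = unique(reactions$pathway_id),
                               class = NA_character_)
  membership <- compute_membership(reactions)
  structure(list(reactions = reactions, pathway_info = pathway_info,
                 membership = membership),
            class = "pathway_set")
}

split_formulas <- function(x) {
  lapply(strsplit(ifelse(is.na(x), "", x), ";"),
         function(v) v[nzchar(v)])
}

compute_membership <- function(reactions) {
  mets <- mapply(function(s, p) unique(c(s, p)),
                 split_formulas(reactions$substrates),
                 split_formulas(reactions$products), SIMPLIFY = FALSE)
  out <- lapply(split(mets, reactions$pathway_id),
                function(l) sort(unique(unlist(l))))
  out[vapply(out, length, integer(1)) > 0]
}

#' @export
print.pathway_set <- function(x, ...) {
  cat(sprintf("pathway_set: %d pathways, %d reaction memberships\n",
              length(x$membership), nrow(x$reactions)))
  invisible(x)
}

#' Curate overlapping pathway definitions
#'
#' Deletes every reaction present in two or more pathways from all of
#' them, together with its substrate and product metabolites; a
#' metabolite survives in a pathway only if some surviving reaction of
#' that pathway still touches it. Pathways left without reactions are
#' dropped.
#'
#' @param pathways a [pathway_set()].
#' @return The curated `pathway_set`; dropped pathway ids are recorded in
#'   `attr(, "dropped_pathways")`.
#' @export
curate_pathways <- function(pathways) {
  stopifnot(inherits(pathways, "pathway_set"))
  rx <- pathways$reactions
  n_pw <- tapply(rx$pathway_id, rx$reaction_id,
                 function(p) length(unique(p)))
  shared <- names(n_pw)[n_pw >= 2]
  kept <- rx[!rx$reaction_id %in% shared, , drop = FALSE]
  out <- pathway_set(kept[, c("reaction_id", "pathway_id", "substrates",
                              "products")],
                     pathways$pathway_info[
                       pathways$pathway_info$pathway_id %in%
                         unique(kept$pathway_id), , drop = FALSE])
  attr(out, "dropped_pathways") <-
    setdiff(unique(rx$pathway_id), unique(kept$pathway_id))
  out
}

#' Map measured ions to pathway metabolites
#'
#' Formula-level matching: an ion's candidate formulas are compared with
#' each pathway's member metabolite formulas; structural isomers cannot
#' be resolved, so one ion may map to several metabolites and pathways.
#' A pathway is scoreable only if at least `min_ions` mapped ions with
#' distinct m/z support it.
#'
#' @param ions ion metadata data.frame (`ion_id`, `mz`, `formulas` with
#'   semicolon-separated candidates), e.g. the `ions` element of an
#'   [ion_table].
#' @param pathways a (curated) [pathway_set()].
#' @param min_ions minimum number of unique-m/z ions for a pathway to be
#'   scoreable (default 4).
#' @return An object of class `ion_pathway_map`: list with `edges`
#'   (data.frame `ion_id`, `formula`, `pathway_id`), `pathway_ions`
#'   (pathway id -> ion ids), `scoreable` (named logical) and
#'   `n_unique_mz` (named integer).
#' @export
map_ions_to_pathways <- function(ions, pathways, min_ions = 4) {
  stopifnot(inherits(pathways, "pathway_set"))
  if (!all(c("ion_id", "formulas") %in% names(ions)))
    stop("ions needs ion_id and formulas columns")
  cand <- split_formulas(ions$formulas)
  edges <- list()
  for (p in names(pathways$membership)) {
    members <- pathways$membership[[p]]
    for (i in seq_along(cand)) {
      hits <- intersect(cand[[i]], members)
      if (length(hits))
        edges[[length(edges) + 1]] <- data.frame(
          ion_id = ions$ion_id[i], formula = hits, pathway_id = p)
    }
  }
  edges <- if (length(edges)) do.call(rbind, edges) else
    data.frame(ion_id = character(), formula = character(),
               pathway_id = character())
  pathway_ions <- lapply(split(edges$ion_id, edges$pathway_id), unique)
  mz <- stats::setNames(ions$mz, ions$ion_id)
  n_unique_mz <- vapply(pathway_ions, function(ii)
    length(unique(mz[ii])), integer(1))
  scoreable <- n_unique_mz >= min_ions
  structure(list(edges = edges, pathway_ions = pathway_ions,
                 scoreable = scoreable, n_unique_mz = n_unique_mz,
                 min_ions = min_ions),
            class = "ion_pathway_map")
}

#' @export
print.ion_pathway_map <- function(x, ...) {
  cat(sprintf("ion_pathway_map: %d pathways mapped, %d scoreable (>= %d unique-m/z ions)\n",
              length(x$pathway_ions), sum(x$scoreable), x$min_ions))
  invisible(x)
}

#' Read pathway sets from an extended GMT file
#'
#' Each line: set name, description (used as class tag), then member
#' formulas, tab-separated.
#'
#' @param path file path.
#' @return Named list of character vectors (set -> members), with a
#'   `classes` attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t")
  sets <- lapply(fields, function(f) f[-(1:2)])
  names(sets) <- vapply(fields, `[`, character(1), 1)
  attr(sets, "classes") <- stats::setNames(
    vapply(fields, `[`, character(1), 2), names(sets))
  sets
}

#' Write pathway/gene sets to a GMT file
#'
#' @param sets named list of character vectors.
#' @param path file path.
#' @param classes optional named character vector of class tags (written
#'   in the description field).
#' @return Invisibly, `path`.
#' @export
write_gmt <- function(sets, path, classes = NULL) {
  lines <- vapply(names(sets), function(nm) {
    cls <- if (!is.null(classes) && nm %in% names(classes))
      classes[[nm]] else "na"
    paste(c(nm, cls, sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
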