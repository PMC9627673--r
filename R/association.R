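# Metabolic typing and the dendrogram-branch association scan.
#
# Cell lines are clustered by Ward's method on their pathway scores;
# every internal branch holding at least a fixed fraction of the cohort
# is then tested against every trait (hypergeometric for categorical,
# two-sample t for continuous), and all p-values are pooled into one
# global Storey-Tibshirani q-value computation.

#' Cluster cell lines into metabolic types
#'
#' Ward linkage (on Euclidean distances) over the pathway score matrix.
#' Rows are sorted by cell-line id first so the result is deterministic
#' regardless of input order.
#'
#' @param scores a [pathway_score()] result or a plain cell line x
#'   pathway numeric matrix with rownames.
#' @return An object of class `cluster_tree`: list with `hclust` (the
#'   linkage), `labels` (cell-line ids in leaf order of the input) and
#'   `branches` (see [enumerate_branches()]).
#' @export
cluster_cell_lines <- function(scores) {
  m <- if (inherits(scores, "pathway_scores")) scores$scores else scores
  if (is.null(rownames(m))) stop("score matrix needs cell-line rownames")
  if (nrow(m) < 3) stop("need >= 3 cell lines")
  if (anyNA(m))
    stop("missing pathway scores; complete or drop affected pathways upstream")
  m <- m[order(rownames(m)), , drop = FALSE]
  hc <- stats::hclust(stats::dist(m), method = "ward.D2")
  structure(list(hclust = hc, labels = rownames(m)),
            class = "cluster_tree")
}

#' @export
print.cluster_tree <- function(x, ...) {
  cat(sprintf("cluster_tree: Ward linkage over %d cell lines\n",
              length(x$labels)))
  invisible(x)
}

#' Cut a cluster tree into major types
#'
#' @param tree a [cluster_cell_lines()] result.
#' @param k number of types (default 2).
#' @return Named integer vector of type labels per cell line, numbered
#'   in leaf order.
#' @export
cut_types <- function(tree, k = 2) {
  stopifnot(inherits(tree, "cluster_tree"))
  stats::cutree(tree$hclust, k = k)
}

# leaf sets of every internal node of an hclust merge matrix
merge_leaf_sets <- function(hc) {
  n <- length(hc$labels %||% hc$order)
  sets <- vector("list", nrow(hc$merge))
  for (i in seq_len(nrow(hc$merge))) {
    kids <- hc$merge[i, ]
    leaves <- integer()
    for (k in kids)
      leaves <- c(leaves, if (k < 0) -k else sets[[k]])
    sets[[i]] <- leaves
  }
  sets
}

#' Enumerate qualifying dendrogram branches
#'
#' Lists every internal branch (node) of the tree holding at least
#' `ceil(min_fraction * n_total)` cell lines, excluding the root (whose
#' complement is empty). With the default 10% rule a 180-line cohort
#' yields a minimum branch size of 18.
#'
#' @param tree a [cluster_cell_lines()] result.
#' @param min_fraction minimum branch size as a fraction of the cohort
#'   (default 0.10).
#' @return Named list of character vectors (branch id "b<node>" ->
#'   cell-line ids); branch sizes in `attr(, "sizes")`, the threshold in
#'   `attr(, "min_size")`.
#' @export
enumerate_branches <- function(tree, min_fraction = 0.10) {
  stopifnot(inherits(tree, "cluster_tree"))
  hc <- tree$hclust
  n_total <- length(tree$labels)
  min_size <- ceiling(min_fraction * n_total)
  sets <- merge_leaf_sets(hc)
  root <- nrow(hc$merge)
  keep <- which(vapply(sets, length, integer(1)) >= min_size)
  keep <- setdiff(keep, root)
  out <- lapply(sets[keep], function(ii) tree$labels[ii])
  names(out) <- sprintf("b%03d", keep)
  attr(out, "sizes") <- vapply(out, length, integer(1))
  attr(out, "min_size") <- min_size
  out
}

#' Test one branch against one trait
#'
#' Categorical traits: one-sided upper-tail hypergeometric enrichment of
#' each trait level in the branch versus the background of cell lines
#' with data; the reported p is the Bonferroni-corrected minimum over
#' levels (`min(1, L * min p)`), so that pooled null p-values stay
#' honest for the global q-value computation. For two-level
#' traits the reported level is canonicalized to the focal level (TRUE,
#' or the lexicographically larger level) and the direction is the sign
#' of that level's enrichment in the branch; for more levels the
#' minimal-p level is reported with its own enrichment sign. Continuous
#' traits: two-tailed two-sample t-test of the branch versus all other
#' cell lines with data; direction is the sign of the mean difference.
#'
#' @param branch character vector of cell-line ids.
#' @param values named vector of trait values (names = cell lines;
#'   missing values allowed as NA).
#' @param modality "categorical" or "continuous".
#' @param var_equal use the pooled-variance (classical) t statistic
#'   (default TRUE).
#' @return list with `p`, `direction` (+1/-1), `effect` (overlap count
#'   or mean difference), `level` (categorical only), `skip` (reason
#'   string when the pair cannot be tested, else NA).
#' @export
test_branch_trait <- function(branch, values, modality,
                              var_equal = TRUE) {
  values <- values[!is.na(values)]
  background <- names(values)
  inb <- intersect(branch, background)
  if (!length(inb))
    return(list(p = NA_real_, direction = NA_integer_,
                effect = NA_real_, level = NA_character_,
                skip = "branch_all_missing"))
  if (modality == "categorical") {
    v <- as.character(values)
    names(v) <- names(values)
    levels <- sort(unique(v))
    if (length(levels) < 2)
      return(list(p = NA_real_, direction = NA_integer_,
                  effect = NA_real_, level = NA_character_,
                  skip = "single_level"))
    N <- length(background); n <- length(inb)
    ps <- vapply(levels, function(l) {
      K <- sum(v == l); k <- sum(v[inb] == l)
      stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    }, numeric(1))
    enr <- vapply(levels, function(l)
      mean(v[inb] == l) - mean(v == l), numeric(1))
    # Bonferroni over levels: the plain minimum of complementary
    # upper-tail tests is anticonservative (it never exceeds ~0.6),
    # which breaks the pi0 estimate of the global q-value pool
    p_rep <- min(1, length(levels) * min(ps))
    if (length(levels) == 2) {
      focal <- levels[2]
      if ("TRUE" %in% levels) focal <- "TRUE"
      list(p = p_rep, direction = if (enr[focal] >= 0) 1L else -1L,
           effect = sum(v[inb] == focal), level = focal, skip = NA)
    } else {
      best <- names(which.min(ps))
      list(p = p_rep, direction = if (enr[best] >= 0) 1L else -1L,
           effect = sum(v[inb] == best), level = best, skip = NA)
    }
  } else {
    x <- as.numeric(values[inb])
    y <- as.numeric(values[setdiff(background, inb)])
    if (length(y) < 2 || length(x) < 2)
      return(list(p = NA_real_, direction = NA_integer_,
                  effect = NA_real_, level = NA_character_,
                  skip = "complement_too_small"))
    if (stats::sd(c(x, y)) == 0)
      return(list(p = 1, direction = 1L, effect = 0,
                  level = NA_character_, skip = NA))
    tt <- stats::t.test(x, y, var.equal = var_equal)
    d <- mean(x) - mean(y)
    list(p = tt$p.value, direction = if (d >= 0) 1L else -1L,
         effect = d, level = NA_character_, skip = NA)
  }
}

#' Storey-Tibshirani q-values
#'
#' Estimates the null proportion pi0 on the lambda grid 0, 0.05, ...,
#' 0.90 via `pi0(lambda) = #\{p > lambda\} / (m (1 - lambda))`, smooths it
#' with a cubic smoothing spline, evaluates the fit at lambda = 0.90 and
#' clips to (0, 1]; q-values are the usual step-up
#' `q_i = min_{t >= p_i} pi0 m t / #\{p <= t\}`, monotone in p.
#'
#' @param p vector of p-values in (0, 1].
#' @param lambda grid for the pi0 estimate.
#' @return list with `qvalues` (same order as `p`) and `pi0`.
#' @export
qvalues_storey <- function(p, lambda = seq(0, 0.90, by = 0.05)) {
  m <- length(p)
  if (m == 0) stop("no p-values")
  if (any(is.na(p)) || any(p <= 0 | p > 1))
    stop("p-values must be in (0, 1]")
  if (min(p) == max(p) && p[1] == 1) {
    return(list(qvalues = rep(1, m), pi0 = 1))
  }
  pi0_lambda <- vapply(lambda, function(l) mean(p > l) / (1 - l),
                       numeric(1))
  pi0 <- if (m < 100) {
    # spline smoothing is unstable for tiny families; fall back to the
    # most conservative grid estimate
    min(1, max(pi0_lambda))
  } else {
    fit <- stats::smooth.spline(lambda, pi0_lambda, df = 3)
    stats::predict(fit, x = max(lambda))$y
  }
  pi0 <- min(max(pi0, 1e-8), 1)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  q <- pi0 * m * p[o] / rank(p, ties.method = "max")[o]
  q <- pmin(cummin(q), 1)
  list(qvalues = q[ro], pi0 = pi0)
}

#' Branch-wide association scan
#'
#' Tests every qualifying branch of the tree against every trait,
#' pools all p-values into a single global Storey-Tibshirani q-value
#' computation, and reports signed q-values (direction x q) for
#' visualization. Records with `q <= fdr` are flagged significant.
#'
#' @param tree a [cluster_cell_lines()] result.
#' @param traits long-format trait data.frame (`trait_id`, `modality`,
#'   `cell_line`, `value`), e.g. from [simulate_traits()].
#' @param fdr significance threshold on q (default 0.10).
#' @param min_fraction branch inclusion rule (default 0.10 of cohort).
#' @return data.frame with one row per tested (branch, trait) pair:
#'   `branch`, `trait_id`, `modality`, `test`, `p`, `q`, `direction`,
#'   `signed_q`, `effect`, `level`, `significant`. Skipped pairs are in
#'   `attr(, "skipped")`; the pi0 estimate in `attr(, "pi0")`.
#' @export
association_scan <- function(tree, traits, fdr = 0.10,
                             min_fraction = 0.10) {
  stopifnot(inherits(tree, "cluster_tree"))
  branches <- enumerate_branches(tree, min_fraction)
  if (!length(branches)) stop("no qualifying branches")
  trait_ids <- unique(traits$trait_id)
  by_trait <- split(seq_len(nrow(traits)),
                    factor(traits$trait_id, levels = trait_ids))
  res <- vector("list", length(branches) * length(trait_ids))
  skipped <- list()
  k <- 0L
  for (tid in trait_ids) {
    tr <- traits[by_trait[[tid]], , drop = FALSE]
    modality <- tr$modality[1]
    vals <- tr$value
    if (modality == "continuous") vals <- as.numeric(vals)
    names(vals) <- tr$cell_line
    vals <- vals[names(vals) %in% tree$labels]
    for (b in names(branches)) {
      r <- if (modality == "continuous")
        test_branch_trait_fast(branches[[b]], vals)
      else test_branch_trait(branches[[b]], vals, modality)
      if (!is.na(r$skip %||% NA)) {
        skipped[[length(skipped) + 1]] <- data.frame(
          branch = b, trait_id = tid, reason = r$skip)
        next
      }
      k <- k + 1L
      res[[k]] <- data.frame(branch = b, trait_id = tid,
                             modality = modality,
                             test = if (modality == "categorical")
                               "hypergeometric" else "t",
                             p = r$p, direction = r$direction,
                             effect = r$effect,
                             level = r$level %||% NA_character_)
    }
  }
  out <- do.call(rbind, res[seq_len(k)])
  out$p <- pmax(out$p, .Machine$double.xmin)  # guard exact zeros
  qr <- qvalues_storey(out$p)
  out$q <- qr$qvalues
  out$signed_q <- out$direction * out$q
  out$significant <- out$q <= fdr
  out <- out[, c("branch", "trait_id", "modality", "test", "p", "q",
                 "direction", "signed_q", "effect", "level",
                 "significant")]
  attr(out, "skipped") <- if (length(skipped)) do.call(rbind, skipped)
    else NULL
  attr(out, "pi0") <- qr$pi0
  attr(out, "n_branches") <- length(branches)
  out
}

# pooled-variance t-test of branch vs complement without t.test()
# overhead; same contract as test_branch_trait(modality="continuous")
test_branch_trait_fast <- function(branch, values) {
  values <- values[!is.na(values)]
  inb <- names(values) %in% branch
  x <- values[inb]; y <- values[!inb]
  if (!length(x))
    return(list(p = NA_real_, direction = NA_integer_,
                effect = NA_real_, level = NA_character_,
                skip = "branch_all_missing"))
  if (length(y) < 2 || length(x) < 2)
    return(list(p = NA_real_, direction = NA_integer_,
                effect = NA_real_, level = NA_character_,
                skip = "complement_too_small"))
  nx <- length(x); ny <- length(y)
  vx <- stats::var(x); vy <- stats::var(y)
  sp2 <- ((nx - 1) * vx + (ny - 1) * vy) / (nx + ny - 2)
  d <- mean(x) - mean(y)
  if (sp2 == 0)
    return(list(p = 1, direction = 1L, effect = 0,
                level = NA_character_, skip = NA))
  tstat <- d / sqrt(sp2 * (1 / nx + 1 / ny))
  p <- 2 * stats::pt(abs(tstat), nx + ny - 2, lower.tail = FALSE)
  list(p = p, direction = if (d >= 0) 1L else -1L, effect = d,
       level = NA_character_, skip = NA)
}

#' Write a cluster tree as Newick
#'
#' Leaves are cell-line ids; internal nodes carry branch ids matching
#' [enumerate_branches()].
#'
#' @param tree a [cluster_cell_lines()] result.
#' @param path file path.
#' @return Invisibly, `path`.
#' @export
write_tree_newick <- function(tree, path) {
  stopifnot(inherits(tree, "cluster_tree"))
  phy <- ape::as.phylo(tree$hclust)
  # label each internal node with the merge row holding the same leaf set
  sets <- merge_leaf_sets(tree$hclust)
  keys <- vapply(sets, function(ii)
    paste(sort(tree$labels[ii]), collapse = "|"), character(1))
  n_tip <- length(phy$tip.label)
  labs <- character(phy$Nnode)
  for (nd in seq_len(phy$Nnode)) {
    tips <- ape::extract.clade(phy, n_tip + nd)$tip.label
    labs[nd] <- sprintf("b%03d",
                        match(paste(sort(tips), collapse = "|"), keys))
  }
  phy$node.label <- labs
  ape::write.tree(phy, file = path)
  invisible(path)
}
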