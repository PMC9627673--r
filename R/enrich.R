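# Set enrichment over ranked lists: two-tail hypergeometric enrichment
# of pathway sets in a ranked metabolite list, per-item group
# comparisons of dependency/drug scores, and pre-ranked GSEA.

#' Hypergeometric enrichment in the tails of a ranked list
#'
#' Takes the top and bottom `ceil(tail_fraction * N)` items of a ranked
#' list (descending scores; ties broken by item id, with a warning when
#' ties straddle a cut) and tests each set for over-representation in
#' each tail with an upper-tail hypergeometric test. q-values are
#' Benjamini-Hochberg within each tail family.
#'
#' @param ranked data.frame with `item` and `score` columns (e.g. the
#'   output of [fractional_difference()] with `item = metabolite`,
#'   `score = delta`), or a named numeric vector.
#' @param sets named list of character vectors (set -> member items).
#' @param tail_fraction fraction of the list per tail, in (0, 0.5].
#' @return data.frame `set`, `tail` ("top"/"bottom"), `k` (overlap),
#'   `K` (set size in universe), `n` (tail size), `N` (universe size),
#'   `p`, `q`; sets with no members in the universe are skipped and
#'   listed in `attr(, "skipped_sets")`.
#' @export
tail_enrichment <- function(ranked, sets, tail_fraction = 0.25) {
  if (tail_fraction <= 0 || tail_fraction > 0.5)
    stop("tail_fraction must be in (0, 0.5]")
  if (is.numeric(ranked) && !is.null(names(ranked)))
    ranked <- data.frame(item = names(ranked), score = unname(ranked))
  stopifnot(all(c("item", "score") %in% names(ranked)))
  if (anyDuplicated(ranked$item)) stop("item ids must be unique")
  o <- order(-ranked$score, ranked$item)
  items <- ranked$item[o]
  scores <- ranked$score[o]
  N <- length(items)
  n <- ceiling(tail_fraction * N)
  if (scores[n] == scores[n + 1] || scores[N - n] == scores[N - n + 1])
    warning("tied scores straddle a tail cut; tie-broken by item id")
  tails <- list(top = items[seq_len(n)],
                bottom = items[N - seq_len(n) + 1])
  rows <- list(); skipped <- character()
  for (s in names(sets)) {
    members <- intersect(sets[[s]], items)
    K <- length(members)
    if (K == 0) { skipped <- c(skipped, s); next }
    for (tl in names(tails)) {
      k <- length(intersect(members, tails[[tl]]))
      p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
      rows[[length(rows) + 1]] <- data.frame(
        set = s, tail = tl, k = k, K = K, n = n, N = N, p = p)
    }
  }
  out <- do.call(rbind, rows)
  out$q <- NA_real_
  for (tl in unique(out$tail))
    out$q[out$tail == tl] <- stats::p.adjust(out$p[out$tail == tl],
                                             "BH")
  attr(out, "skipped_sets") <- skipped
  out
}

#' Compare one gene's (or drug's) scores between two groups
#'
#' Classical two-sided unpaired (pooled-variance) t-test of the item's
#' per-cell-line scores between the two type groups.
#'
#' @param effects data.frame with columns `item` (gene or drug id),
#'   `cell_line`, `score`.
#' @param type_labels named vector (1/2) of types per cell line.
#' @param item the gene or drug id to test.
#' @return list with `mean_1`, `mean_2`, `difference` (type 1 - type 2),
#'   `t`, `p`, `n_1`, `n_2`.
#' @export
compare_groups <- function(effects, type_labels, item) {
  sub <- effects[effects$item == item, , drop = FALSE]
  if (!nrow(sub)) stop("no scores for item ", item)
  type <- type_labels[sub$cell_line]
  x <- sub$score[type == 1 & !is.na(type)]
  y <- sub$score[type == 2 & !is.na(type)]
  if (length(x) < 2 || length(y) < 2)
    stop("need >= 2 cell lines per group for ", item)
  if (stats::sd(c(x, y)) == 0)
    return(list(mean_1 = mean(x), mean_2 = mean(y), difference = 0,
                t = 0, p = 1, n_1 = length(x), n_2 = length(y)))
  tt <- stats::t.test(x, y, var.equal = TRUE)
  list(mean_1 = mean(x), mean_2 = mean(y),
       difference = mean(x) - mean(y),
       t = unname(tt$statistic), p = tt$p.value,
       n_1 = length(x), n_2 = length(y))
}

#' Rank genes by correlation with the two types
#'
#' Point-biserial correlation between each gene's dependency score and
#' the binary type label (type 1 coded 1, type 2 coded 0): positive
#' correlations mean higher (less negative) scores in type 1. Genes are
#' ranked by descending correlation.
#'
#' @param effects data.frame with `item`, `cell_line`, `score`.
#' @param type_labels named vector (1/2) per cell line.
#' @return data.frame `item`, `score` (the correlation), `rank`; genes
#'   with constant scores get correlation 0 with a warning.
#' @export
rank_genes_by_type <- function(effects, type_labels) {
  items <- unique(effects$item)
  r <- vapply(items, function(g) {
    sub <- effects[effects$item == g, , drop = FALSE]
    type <- type_labels[sub$cell_line]
    ok <- !is.na(type)
    x <- sub$score[ok]
    lab <- as.numeric(type[ok] == 1)
    if (length(unique(lab)) < 2) return(NA_real_)
    if (stats::sd(x) == 0) {
      warning("constant scores for ", g, "; correlation set to 0")
      return(0)
    }
    stats::cor(x, lab)
  }, numeric(1))
  if (anyNA(r)) stop("both types must be represented for every gene")
  o <- order(-r, items)
  data.frame(item = items[o], score = unname(r[o]),
             rank = seq_along(items))
}

# weighted Kolmogorov-Smirnov running-sum enrichment score
gsea_es <- function(in_set, weights_abs, weight) {
  N <- length(in_set)
  K <- sum(in_set)
  hit <- ifelse(in_set, if (weight == 0) 1 else weights_abs^weight, 0)
  if (sum(hit) == 0) return(0)
  inc <- hit / sum(hit)
  dec <- ifelse(in_set, 0, 1 / (N - K))
  rs <- cumsum(inc - dec)
  rs[which.max(abs(rs))]
}

#' Pre-ranked gene set enrichment analysis
#'
#' Classical weighted Kolmogorov-Smirnov running-sum enrichment score:
#' walking down the ranked list, set hits increment the running sum
#' proportionally to |score|^weight (normalized), misses decrement by
#' 1/(N-K); the enrichment score (ES) is the maximal deviation from
#' zero. The null distribution is obtained by permuting gene labels
#' (random sets of the same size); NES is ES divided by the mean
#' same-sign permuted ES, and p-values use the add-one rule (never 0).
#' BH q-values are computed within each sign family.
#'
#' @param ranked data.frame with `item` and `score`, sorted or not
#'   (sorted internally by descending score, ties by item id).
#' @param sets named list of gene sets (subsets of the ranked items).
#' @param n_perm number of permutations (default 1000, >= 100).
#' @param weight running-sum weight exponent (default 1; 0 gives the
#'   unweighted Kolmogorov-Smirnov statistic).
#' @param seed integer seed for the permutations.
#' @return data.frame `set`, `size`, `es`, `nes`, `p`, `q`.
#' @export
preranked_gsea <- function(ranked, sets, n_perm = 1000, weight = 1,
                           seed = 1L) {
  if (n_perm < 100) stop("n_perm must be >= 100")
  if (is.numeric(ranked) && !is.null(names(ranked)))
    ranked <- data.frame(item = names(ranked), score = unname(ranked))
  o <- order(-ranked$score, ranked$item)
  items <- ranked$item[o]
  wabs <- abs(ranked$score[o])
  N <- length(items)
  set.seed(seed)
  rows <- list()
  for (s in names(sets)) {
    members <- unique(sets[[s]])
    if (!all(members %in% items))
      stop("set ", s, " contains items outside the universe")
    K <- length(members)
    if (K >= N) stop("set ", s, " is not smaller than the universe")
    es <- gsea_es(items %in% members, wabs, weight)
    perm_es <- vapply(seq_len(n_perm), function(i) {
      idx <- sample.int(N, K)
      gsea_es(seq_len(N) %in% idx, wabs, weight)
    }, numeric(1))
    same_sign <- if (es >= 0) perm_es[perm_es >= 0] else
      perm_es[perm_es <= 0]
    nes <- if (length(same_sign) && mean(abs(same_sign)) > 0)
      es / mean(abs(same_sign)) else NA_real_
    n_extreme <- sum(sign(perm_es) == sign(es) &
                       abs(perm_es) >= abs(es))
    p <- (n_extreme + 1) / (n_perm + 1)
    rows[[length(rows) + 1]] <- data.frame(set = s, size = K, es = es,
                                           nes = nes, p = p)
  }
  out <- do.call(rbind, rows)
  out$q <- NA_real_
  for (sg in unique(sign(out$es)))
    out$q[sign(out$es) == sg] <-
      stats::p.adjust(out$p[sign(out$es) == sg], "BH")
  out
}
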