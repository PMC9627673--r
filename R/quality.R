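# Reproducibility criteria for benchmarking normalization methods.
#
# All five criteria are built on the repeated injections of the two QC
# cell lines: they decrease when replicate agreement improves, and
# score_stacks() scales each criterion to the un-normalized table so that
# 1 means "no improvement" and values below 1 mean improvement.

#' Monoisotopic formulas of the 20 proteinogenic amino acids
#'
#' Used to restrict the fold-change reproducibility criterion to
#' amino-acid ions by exact formula match.
#'
#' @return Named character vector of molecular formulas.
#' @export
amino_acid_formulas <- function() {
  c(Gly = "C2H5NO2",  Ala = "C3H7NO2",  Ser = "C3H7NO3",
    Pro = "C5H9NO2",  Val = "C5H11NO2", Thr = "C4H9NO3",
    Cys = "C3H7NO2S", Leu = "C6H13NO2", Ile = "C6H13NO2",
    Asn = "C4H8N2O3", Asp = "C4H7NO4",  Gln = "C5H10N2O3",
    Lys = "C6H14N2O2", Glu = "C5H9NO4", Met = "C5H11NO2S",
    His = "C6H9N3O2", Phe = "C9H11NO2", Arg = "C6H14N4O2",
    Tyr = "C9H11NO3", Trp = "C11H12N2O2")
}

qc_rows <- function(table, qc_line) {
  which(table$samples$cell_line == qc_line)
}

#' Batch scoring fold-change criterion
#'
#' Repeatedly draws two disjoint sets of `set_size` replicate injections
#' of one QC cell line, computes per-ion |log2 fold-changes| between the
#' set means, pools them over all resamples, and returns the
#' `1 - fdr` quantile of that pooled distribution: the fold-change
#' threshold below which `1 - fdr` of same-cell-line "changes" fall.
#' Zero for perfectly reproducible replicates.
#'
#' @param table an [ion_table].
#' @param qc_line QC cell line id with at least `2 * set_size`
#'   replicates.
#' @param set_size size of each resampled set (default 6).
#' @param n_resample number of resamples (default 1000).
#' @param fdr quantile tail (default 0.05, i.e. the 95th percentile).
#' @param seed integer seed for the resampling.
#' @return The |log2 FC| threshold (scalar, log2-fold-change units).
#' @export
batch_scoring_fc <- function(table, qc_line, set_size = 6,
                             n_resample = 1000, fdr = 0.05, seed = 1L) {
  stopifnot(inherits(table, "ion_table"))
  rows <- qc_rows(table, qc_line)
  if (length(rows) < 2 * set_size)
    stop("need >= ", 2 * set_size, " replicates of ", qc_line,
         ", have ", length(rows))
  m <- table$intensity[rows, , drop = FALSE]
  set.seed(seed)
  pooled <- matrix(NA_real_, n_resample, ncol(m))
  for (r in seq_len(n_resample)) {
    pick <- sample(length(rows), 2 * set_size)  # disjoint by construction
    a <- colMeans(m[pick[seq_len(set_size)], , drop = FALSE])
    b <- colMeans(m[pick[set_size + seq_len(set_size)], , drop = FALSE])
    pooled[r, ] <- abs(log2(a / b))
  }
  unname(stats::quantile(pooled, probs = 1 - fdr, na.rm = TRUE))
}

# per-batch log2 fold-change vectors between the mean intensities of two
# QC lines, over batches containing both
batch_fc_vectors <- function(table, qc_a, qc_b, ions = NULL) {
  m <- table$intensity
  if (!is.null(ions)) m <- m[, ions, drop = FALSE]
  batch <- as.character(table$samples$batch)
  cl <- table$samples$cell_line
  out <- list()
  for (b in unique(batch)) {
    ra <- which(batch == b & cl == qc_a)
    rb <- which(batch == b & cl == qc_b)
    if (!length(ra) || !length(rb)) next
    out[[b]] <- log2(colMeans(m[ra, , drop = FALSE]) /
                       colMeans(m[rb, , drop = FALSE]))
  }
  out
}

#' Fold-change reproducibility across batches
#'
#' Per batch, computes the per-ion log2 fold-change vector between the
#' mean intensities of two QC cell lines, and returns the mean Euclidean
#' distance between those vectors over all batch pairs. Differences
#' between the two lines should be preserved across batches, so smaller
#' is better; 0 when all batches agree exactly.
#'
#' @param table an [ion_table].
#' @param qc_a,qc_b the two QC cell line ids.
#' @param ion_subset "all" or "amino_acids" (ions whose candidate
#'   formulas match a proteinogenic amino acid).
#' @return Mean pairwise Euclidean distance (scalar).
#' @export
fc_reproducibility <- function(table, qc_a, qc_b,
                               ion_subset = c("all", "amino_acids")) {
  stopifnot(inherits(table, "ion_table"))
  ion_subset <- match.arg(ion_subset)
  ions <- NULL
  if (ion_subset == "amino_acids") {
    aa <- amino_acid_formulas()
    hit <- vapply(strsplit(table$ions$formulas %||% "", ";"),
                  function(f) any(f %in% aa), logical(1))
    if (!any(hit)) stop("no amino-acid ions found")
    ions <- which(hit)
  }
  fc <- batch_fc_vectors(table, qc_a, qc_b, ions)
  if (length(fc) < 2)
    stop("need both QC lines in >= 2 common batches")
  pairs <- utils::combn(length(fc), 2)
  mean(apply(pairs, 2, function(p)
    sqrt(sum((fc[[p[1]]] - fc[[p[2]]])^2))))
}

# Bhattacharyya distance between two Gaussian clouds
bhattacharyya <- function(mu1, S1, mu2, S2) {
  Sbar <- (S1 + S2) / 2
  dmu <- mu1 - mu2
  0.125 * drop(t(dmu) %*% solve(Sbar, dmu)) +
    0.5 * log(det(Sbar) / sqrt(det(S1) * det(S2)))
}

#' Inter-batch distance in principal component space
#'
#' Fits a PCA on all samples (log scale, ion-centered), models each
#' batch as a Gaussian in the first `n_pcs` score dimensions, and
#' returns the mean pairwise Bhattacharyya distance between batches.
#' Near 0 when batches overlap.
#'
#' @param table an [ion_table] with >= 2 batches and more samples per
#'   batch than `n_pcs`.
#' @param n_pcs number of principal components (default 2).
#' @param eps ridge added to near-singular covariance matrices.
#' @return Mean pairwise Bhattacharyya distance (scalar).
#' @export
interbatch_distance <- function(table, n_pcs = 2, eps = 1e-8) {
  stopifnot(inherits(table, "ion_table"))
  batch <- as.character(table$samples$batch)
  counts <- table(batch)
  if (length(counts) < 2) stop("need >= 2 batches")
  if (any(counts <= n_pcs))
    stop("every batch needs more samples than n_pcs")
  lg <- log_safe(table)$log
  pc <- stats::prcomp(lg, center = TRUE, scale. = FALSE)
  scores <- pc$x[, seq_len(min(n_pcs, ncol(pc$x))), drop = FALSE]
  stats_by_batch <- lapply(unique(batch), function(b) {
    s <- scores[batch == b, , drop = FALSE]
    S <- stats::cov(s)
    if (rcond_safe(S) < 1e-10) S <- S + diag(eps, ncol(S))
    if (rcond_safe(S) < 1e-10)
      stop("singular batch covariance after regularization")
    list(mu = colMeans(s), S = S)
  })
  pairs <- utils::combn(length(stats_by_batch), 2)
  mean(apply(pairs, 2, function(p)
    bhattacharyya(stats_by_batch[[p[1]]]$mu, stats_by_batch[[p[1]]]$S,
                  stats_by_batch[[p[2]]]$mu, stats_by_batch[[p[2]]]$S)))
}

rcond_safe <- function(S) {
  tryCatch(rcond(S), error = function(e) 0)
}

#' Kolmogorov-Smirnov batch-effect rate
#'
#' For every ion and every pair of batches, performs a two-sample KS
#' test on the QC cell line's intensities and returns the fraction of
#' tests with p below `alpha`. Near `alpha` in the absence of batch
#' effects.
#'
#' @param table an [ion_table].
#' @param qc_line QC cell line id present in >= 2 batches.
#' @param alpha significance level (default 0.05).
#' @return Fraction of significant tests, in `[0, 1]`.
#' @export
ks_batch_effect_rate <- function(table, qc_line, alpha = 0.05) {
  stopifnot(inherits(table, "ion_table"))
  rows <- qc_rows(table, qc_line)
  batch <- as.character(table$samples$batch[rows])
  keep <- names(which(table(batch) >= 2))
  skipped <- setdiff(unique(batch), keep)
  if (length(skipped))
    warning("batches with < 2 QC replicates skipped: ",
            paste(skipped, collapse = ", "))
  if (length(keep) < 2) stop("QC line usable in < 2 batches")
  m <- table$intensity[rows, , drop = FALSE]
  n_sig <- 0L; n_tot <- 0L
  pairs <- utils::combn(keep, 2)
  for (j in seq_len(ncol(m))) {
    x <- m[, j]
    for (p in seq_len(ncol(pairs))) {
      xa <- x[batch == pairs[1, p]]
      xb <- x[batch == pairs[2, p]]
      pv <- suppressWarnings(stats::ks.test(xa, xb)$p.value)
      n_tot <- n_tot + 1L
      if (pv < alpha) n_sig <- n_sig + 1L
    }
  }
  n_sig / n_tot
}

#' Compute all five reproducibility criteria
#'
#' @param table an [ion_table].
#' @param qc_a,qc_b the two QC cell line ids (`qc_a` is the replicate
#'   line used by the fold-change scoring and KS criteria).
#' @param set_size,n_resample,fdr,alpha,n_pcs passed to the individual
#'   criteria.
#' @param seed integer seed for the resampling criterion.
#' @param aa_subset compute the amino-acid restricted criterion (set to
#'   FALSE when the panel has no amino-acid ions; the criterion is then
#'   reported as NA).
#' @return Named numeric vector with elements `batch_scoring_fc`,
#'   `fc_reproducibility`, `fc_reproducibility_aa`,
#'   `interbatch_distance`, `ks_rate`.
#' @export
quality_criteria <- function(table, qc_a, qc_b, set_size = 6,
                             n_resample = 1000, fdr = 0.05, alpha = 0.05,
                             n_pcs = 2, seed = 1L, aa_subset = TRUE) {
  c(batch_scoring_fc = batch_scoring_fc(table, qc_a, set_size,
                                        n_resample, fdr, seed),
    fc_reproducibility = fc_reproducibility(table, qc_a, qc_b, "all"),
    fc_reproducibility_aa = if (aa_subset)
      fc_reproducibility(table, qc_a, qc_b, "amino_acids") else NA_real_,
    interbatch_distance = interbatch_distance(table, n_pcs),
    ks_rate = ks_batch_effect_rate(table, qc_a, alpha))
}

#' Benchmark normalization stacks against the baseline
#'
#' Computes the five reproducibility criteria on the un-normalized table
#' and on each stack's output, scales every criterion to the baseline
#' (baseline = 1, below 1 = improvement) and ranks stacks by their mean
#' scaled criterion.
#'
#' @param table the raw (un-normalized) [ion_table].
#' @param stacks list of [normalization_stack()] objects.
#' @inheritParams quality_criteria
#' @return A data.frame with one row per stack (the baseline first),
#'   raw criteria, scaled criteria (`scaled_*`) and `mean_scaled`,
#'   ordered as given; attribute `ranking` holds labels sorted by mean
#'   scaled criterion.
#' @export
score_stacks <- function(table, stacks, qc_a, qc_b, set_size = 6,
                         n_resample = 1000, fdr = 0.05, alpha = 0.05,
                         n_pcs = 2, seed = 1L, aa_subset = TRUE) {
  base <- quality_criteria(table, qc_a, qc_b, set_size, n_resample, fdr,
                           alpha, n_pcs, seed, aa_subset)
  rows <- list(data.frame(stack = "baseline", t(base), t(base / base),
                          check.names = FALSE))
  names(rows[[1]]) <- c("stack", names(base), paste0("scaled_",
                                                     names(base)))
  for (st in stacks) {
    tn <- apply_stack(table, st)
    crit <- quality_criteria(tn, qc_a, qc_b, set_size, n_resample, fdr,
                             alpha, n_pcs, seed, aa_subset)
    r <- data.frame(stack = st$label, t(crit), t(crit / base),
                    check.names = FALSE)
    names(r) <- names(rows[[1]])
    rows[[length(rows) + 1]] <- r
  }
  out <- do.call(rbind, rows)
  sc <- out[, grep("^scaled_", names(out)), drop = FALSE]
  out$mean_scaled <- rowMeans(sc, na.rm = TRUE)
  attr(out, "ranking") <- out$stack[order(out$mean_scaled)]
  out
}
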