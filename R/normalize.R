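# Sample-variance normalization and injection-level QC.
#
# All corrections operate on log-transformed intensities internally
# (multiplicative artifact model) and exponentiate on output. Zeros are
# treated as missing and imputed per ion with half the minimum positive
# value before any log transform; imputed cells are restored to zero
# afterwards.

log_safe <- function(table) {
  m <- table$intensity
  zero <- m <= 0
  if (any(zero)) {
    for (j in which(colSums(zero) > 0)) {
      pos <- m[, j][m[, j] > 0]
      if (!length(pos)) stop("ion with no positive intensities: ",
                             table$ions$ion_id[j])
      m[zero[, j], j] <- min(pos) / 2
    }
  }
  list(log = log(m), zero = zero)
}

restore_zeros <- function(m, zero) { m[zero] <- 0; m }

#' Remove injections with abnormal total ion current
#'
#' Computes each injection's total ion current (TIC, sum of all ion
#' intensities) and removes samples whose log-TIC deviates from the cohort
#' median by more than `k` robust standard deviations (MAD x 1.4826).
#' Cell lines losing all their replicates are dropped entirely and
#' reported.
#'
#' @param table an [ion_table].
#' @param k robust z-score cut-off (> 0); default 4.
#' @return list with `table` (filtered [ion_table]), `removed_samples`
#'   (sample ids) and `removed_cell_lines`.
#' @export
filter_abnormal_tic <- function(table, k = 4) {
  stopifnot(inherits(table, "ion_table"), k > 0)
  tic <- rowSums(table$intensity)
  if (any(tic <= 0)) stop("samples with zero TIC present")
  lt <- log(tic)
  s <- stats::mad(lt)
  if (s == 0) s <- stats::sd(lt)  # degenerate spread (tied TICs)
  z <- if (is.na(s) || s == 0) rep(0, length(lt))
       else (lt - stats::median(lt)) / s
  bad <- abs(z) > k
  if (all(bad)) stop("all samples removed by TIC filter")
  removed <- table$samples$sample_id[bad]
  out <- subset_ion_table(table, samples = !bad)
  dropped_lines <- character()
  if ("cell_line" %in% names(table$samples)) {
    before <- unique(table$samples$cell_line)
    after <- unique(out$samples$cell_line)
    dropped_lines <- setdiff(before, after)
  }
  out$provenance <- c(out$provenance, sprintf("tic_filter(k=%g)", k))
  list(table = out, removed_samples = removed,
       removed_cell_lines = dropped_lines)
}

# per-sample scaling statistics used by normalize_sample_variance
sample_statistic <- function(table, method) {
  m <- table$intensity
  switch(method,
    mean = {  # log10-mean: geometric-mean-type location
      lg <- log_safe(table)$log / log(10)
      10^rowMeans(lg)
    },
    median = apply(m, 1, stats::median),
    std = apply(m, 1, stats::sd),
    mad = apply(m, 1, stats::mad),
    tic = rowSums(m),
    confluency = {
      cf <- table$samples$confluency
      if (is.null(cf) || any(is.na(cf)) || any(cf <= 0))
        stop("confluency metadata missing or not positive")
      cf
    },
    stop("unknown statistic: ", method)
  )
}

#' Sample-variance normalization
#'
#' Corrects per-sample variation (cell amount, pipetting, injection):
#' `quantile` replaces every sample's sorted intensities by the
#' across-sample mean quantile profile (ties averaged); scaling methods
#' (`mean` = log10-mean, `median`, `std`, `mad`, `tic`, `confluency`)
#' divide each sample by its statistic and re-multiply by the cohort
#' median of that statistic, preserving the intensity scale; `pqn`
#' divides each sample by the median of its ion-wise quotients versus the
#' median reference spectrum.
#'
#' @param table an [ion_table].
#' @param method one of "quantile", "mean", "median", "std", "mad",
#'   "tic", "pqn", "confluency".
#' @return The normalized [ion_table].
#' @export
normalize_sample_variance <- function(table,
                                      method = c("quantile", "mean",
                                                 "median", "std", "mad",
                                                 "tic", "pqn",
                                                 "confluency")) {
  stopifnot(inherits(table, "ion_table"))
  method <- match.arg(method)
  m <- table$intensity
  if (method == "quantile") {
    # limma works on matrices with samples in columns
    out <- t(limma::normalizeQuantiles(t(m), ties = TRUE))
  } else if (method == "pqn") {
    ref <- apply(m, 2, stats::median)
    if (any(ref <= 0)) stop("reference spectrum has non-positive entries")
    quot <- sweep(m, 2, ref, `/`)
    q <- apply(quot, 1, stats::median)
    if (any(q <= 0)) stop("zero quotient for a sample")
    out <- m / q
  } else {
    s <- sample_statistic(table, method)
    if (any(!is.finite(s)) || any(s <= 0))
      stop("zero or non-finite ", method, " statistic for a sample")
    out <- m / s * stats::median(s)
  }
  set_intensity(table, out, paste0("sample_variance:", method))
}

#' Correct chronological signal drift
#'
#' Estimates, per ion, a smooth trend of log intensity over injection
#' time and removes it: intensities are divided by the trend and
#' re-multiplied by the ion's overall median. `moving_median` uses a
#' running median within +/- `window_min`/2 minutes; `loess` and
#' `robust_loess` use locally weighted regression (the robust variant
#' with symmetric redescending weights).
#'
#' @param table an [ion_table] with finite `injection_order` metadata.
#' @param method "moving_median" (default), "loess" or "robust_loess".
#' @param window_min moving-median window width in minutes (default 120).
#' @param span loess span.
#' @param per_batch estimate the trend within each batch separately
#'   (default TRUE; injection time restarts with every batch).
#' @return The corrected [ion_table]. Ions whose trend could not be
#'   estimated are left uncorrected and listed in
#'   `attr(, "uncorrected_ions")`.
#' @export
correct_drift <- function(table, method = c("moving_median", "loess",
                                            "robust_loess"),
                          window_min = 120, span = 0.75,
                          per_batch = TRUE) {
  stopifnot(inherits(table, "ion_table"))
  method <- match.arg(method)
  t_all <- table$samples$injection_order
  if (is.null(t_all) || any(!is.finite(t_all)))
    stop("injection_order metadata missing or not finite")
  if (length(unique(t_all)) < 5 && !per_batch)
    stop("fewer than 5 distinct injection times")
  ls <- log_safe(table)
  lm_ <- ls$log
  out <- lm_
  groups <- if (per_batch) split(seq_len(nrow(lm_)), table$samples$batch)
            else list(seq_len(nrow(lm_)))
  uncorrected <- character()
  for (idx in groups) {
    tt <- t_all[idx]
    if (length(unique(tt)) < 5)
      stop("fewer than 5 distinct injection times in a batch")
    for (j in seq_len(ncol(lm_))) {
      y <- lm_[idx, j]
      trend <- switch(method,
        moving_median = vapply(tt, function(t0)
          stats::median(y[abs(tt - t0) <= window_min / 2]), numeric(1)),
        loess = tryCatch(stats::predict(stats::loess(
          y ~ tt, span = span, degree = 2,
          family = "gaussian")), error = function(e) NULL),
        robust_loess = tryCatch(stats::predict(stats::loess(
          y ~ tt, span = span, degree = 2,
          family = "symmetric")), error = function(e) NULL))
      if (is.null(trend) || any(!is.finite(trend))) {
        uncorrected <- c(uncorrected, table$ions$ion_id[j])
        next
      }
      out[idx, j] <- y - trend + stats::median(y)
    }
  }
  res <- set_intensity(table, restore_zeros(exp(out), ls$zero),
                       paste0("signal_drift:", method))
  attr(res, "uncorrected_ions") <- unique(uncorrected)
  res
}
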