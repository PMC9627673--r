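# Empirical-Bayes batch-effect adjustment (location/scale model with
# parametric priors, the classical ComBat procedure), written against the
# log-intensity model used throughout the package. Implemented in-package
# because the pipeline needs two modes absent from off-the-shelf
# implementations: estimating batch parameters on QC samples only, and a
# no-shrinkage limit used for exact-adjustment checks.

#' Batch-effect correction by parametric empirical Bayes
#'
#' Per ion, log intensities are standardized by the pooled mean and
#' variance; per-batch location and scale are estimated and shrunk toward
#' common priors (normal prior on locations, inverse-gamma on scales,
#' hyperparameters moment-matched across ions); the batch-adjusted data
#' are returned on the original intensity scale.
#'
#' @param table an [ion_table] with >= 2 batches, each >= 2 samples.
#' @param use_qc_only if TRUE, batch locations/scales are estimated on QC
#'   samples only (`is_qc` metadata) and applied to all samples.
#' @param eb if FALSE, skip the empirical-Bayes shrinkage and use the raw
#'   per-batch estimates (the hyperprior-variance -> infinity limit);
#'   after correction every batch has exactly the pooled mean and
#'   variance per ion.
#' @return The corrected [ion_table].
#' @export
correct_batch_combat <- function(table, use_qc_only = FALSE, eb = TRUE) {
  stopifnot(inherits(table, "ion_table"))
  batch <- as.character(table$samples$batch)
  batches <- unique(batch)
  if (length(batches) < 2) stop("need >= 2 batches")
  counts <- table(batch)
  if (any(counts < 2))
    stop("batch with a single sample: ",
         paste(names(counts)[counts < 2], collapse = ", "))
  est_rows <- if (use_qc_only) {
    if (is.null(table$samples$is_qc) || !any(table$samples$is_qc))
      stop("use_qc_only requires is_qc metadata with QC samples")
    which(table$samples$is_qc)
  } else seq_len(nrow(table$intensity))
  if (use_qc_only) {
    qc_counts <- table(batch[est_rows])
    missing <- setdiff(batches, names(qc_counts)[qc_counts >= 2])
    if (length(missing))
      stop("batches without >= 2 QC samples: ",
           paste(missing, collapse = ", "))
  }

  ls <- log_safe(table)
  y <- ls$log
  n_ion <- ncol(y)
  n_batch <- length(batches)

  ye <- y[est_rows, , drop = FALSE]
  be <- batch[est_rows]
  # grand mean per ion, and pooled variance of the residuals after
  # removing per-batch means (the location/scale model's error variance)
  grand_mean <- colMeans(ye)
  batch_means <- rowsum(ye, be) / as.vector(table(be)[sort(unique(be))])
  resid <- ye - batch_means[be, , drop = FALSE]
  pooled_var <- colMeans(resid^2)
  pooled_var[pooled_var < 1e-12] <- 1e-12
  z <- sweep(ye, 2, grand_mean, `-`)
  z <- sweep(z, 2, sqrt(pooled_var), `/`)

  gamma_hat <- matrix(NA_real_, n_batch, n_ion)   # batch locations
  delta_hat <- matrix(NA_real_, n_batch, n_ion)   # batch variances
  for (b in seq_len(n_batch)) {
    zb <- z[be == batches[b], , drop = FALSE]
    gamma_hat[b, ] <- colMeans(zb)
    delta_hat[b, ] <- apply(zb, 2, function(v) sum((v - mean(v))^2) /
                              (length(v) - 1))
  }
  delta_hat[delta_hat < 1e-12] <- 1e-12

  if (eb) {
    gamma_star <- gamma_hat
    delta_star <- delta_hat
    for (b in seq_len(n_batch)) {
      g <- gamma_hat[b, ]; d <- delta_hat[b, ]
      n_b <- sum(be == batches[b])
      gbar <- mean(g); t2 <- stats::var(g)
      # inverse-gamma moment matching on the batch variances
      v <- mean(d); s2 <- stats::var(d)
      a_prior <- (2 * s2 + v^2) / s2
      b_prior <- (v * s2 + v^3) / s2
      if (!is.finite(a_prior) || !is.finite(b_prior) || s2 < 1e-12) {
        a_prior <- 2 + 1e-8; b_prior <- v
      }
      # iterative joint solution for shrunk location and scale
      g_new <- g; d_new <- d
      zb <- z[be == batches[b], , drop = FALSE]
      for (it in 1:100) {
        g_old <- g_new; d_old <- d_new
        g_new <- (n_b * t2 * g + d_new * gbar) / (n_b * t2 + d_new)
        ss <- colSums(sweep(zb, 2, g_new, `-`)^2)
        d_new <- (0.5 * ss + b_prior) / (n_b / 2 + a_prior - 1)
        if (max(abs(g_new - g_old)) + max(abs(d_new - d_old)) < 1e-8)
          break
      }
      gamma_star[b, ] <- g_new
      delta_star[b, ] <- d_new
    }
  } else {
    gamma_star <- gamma_hat
    delta_star <- delta_hat
  }

  # adjust all samples with the (possibly QC-estimated) batch parameters
  z_all <- sweep(y, 2, grand_mean, `-`)
  z_all <- sweep(z_all, 2, sqrt(pooled_var), `/`)
  adj <- z_all
  for (b in seq_len(n_batch)) {
    rows <- which(batch == batches[b])
    adj[rows, ] <- sweep(z_all[rows, , drop = FALSE], 2,
                         gamma_star[b, ], `-`)
    adj[rows, ] <- sweep(adj[rows, , drop = FALSE], 2,
                         sqrt(delta_star[b, ]), `/`)
  }
  adj <- sweep(adj, 2, sqrt(pooled_var), `*`)
  adj <- sweep(adj, 2, grand_mean, `+`)
  set_intensity(table, restore_zeros(exp(adj), ls$zero),
                paste0("batch_effect:combat",
                       if (use_qc_only) "_qc" else ""))
}

#' Build a normalization stack
#'
#' A stack is an ordered combination of at most one method per class,
#' applied in the fixed order sample_variance -> signal_drift ->
#' batch_effect.
#'
#' @param ... named method descriptors: each argument is a list with a
#'   `class` ("sample_variance", "signal_drift" or "batch_effect"), a
#'   `method` name and optional parameters, e.g.
#'   `list(class = "sample_variance", method = "quantile")`.
#' @param label optional label for reports.
#' @return An object of class `normalization_stack`.
#' @export
normalization_stack <- function(..., label = NULL) {
  steps <- list(...)
  if (length(steps) == 1 && is.null(steps[[1]]$class) &&
      is.list(steps[[1]]))
    steps <- steps[[1]]  # allow passing a plain list of steps
  classes <- vapply(steps, function(s) s$class %||% "", character(1))
  allowed <- c("sample_variance", "signal_drift", "batch_effect")
  if (!all(classes %in% allowed))
    stop("step classes must be one of: ", paste(allowed, collapse = ", "))
  if (anyDuplicated(classes))
    stop("at most one method per class")
  steps <- steps[order(match(classes, allowed))]
  if (is.null(label))
    label <- if (!length(steps)) "identity" else
      paste(vapply(steps, function(s) s$method, character(1)),
            collapse = "+")
  structure(list(steps = steps, label = label),
            class = "normalization_stack")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.normalization_stack <- function(x, ...) {
  cat("normalization_stack:", x$label, "\n")
  for (s in x$steps) cat(sprintf("  %s: %s\n", s$class, s$method))
  invisible(x)
}

#' Apply a normalization stack
#'
#' Applies the stack's methods in class order (sample_variance ->
#' signal_drift -> batch_effect), recording provenance in the result.
#' An empty stack is the identity.
#'
#' @param table an [ion_table].
#' @param stack a [normalization_stack()].
#' @return The normalized [ion_table].
#' @export
apply_stack <- function(table, stack) {
  stopifnot(inherits(table, "ion_table"),
            inherits(stack, "normalization_stack"))
  for (s in stack$steps) {
    extra <- s[setdiff(names(s), c("class", "method"))]
    table <- switch(s$class,
      sample_variance = normalize_sample_variance(table, s$method),
      signal_drift = {
        if (s$method %in% c("moving_median", "loess", "robust_loess"))
          do.call(correct_drift, c(list(table = table, method = s$method),
                                   extra))
        else do.call(get_normalizer(s$method), c(list(table), extra))
      },
      batch_effect = {
        if (s$method %in% c("combat", "combat_qc"))
          correct_batch_combat(table,
                               use_qc_only = identical(s$method,
                                                       "combat_qc"))
        else do.call(get_normalizer(s$method), c(list(table), extra))
      })
  }
  table
}

# Plug-in registry for external normalizers (e.g. RUV variants, QC-SVR).
# A plug-in is a function(ion_table, ...) -> ion_table registered under a
# class/method name; reference implementations are not bundled.
.normalizer_registry <- new.env(parent = emptyenv())

#' Register an external normalizer plug-in
#'
#' Declares a named normalization method (for example the published RUV
#' variants or QC-based support vector regression) backed by a
#' user-supplied function. Registered methods can then be referenced by
#' name in [normalization_stack()] steps of the matching class.
#'
#' @param name method name.
#' @param fun function taking and returning an [ion_table].
#' @return Invisibly, `name`.
#' @export
register_normalizer <- function(name, fun) {
  stopifnot(is.character(name), is.function(fun))
  assign(name, fun, envir = .normalizer_registry)
  invisible(name)
}

get_normalizer <- function(name) {
  if (!exists(name, envir = .normalizer_registry))
    stop("no registered normalizer named ", name)
  get(name, envir = .normalizer_registry)
}
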