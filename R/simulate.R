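# Synthetic-data generators.
#
# Every generator is deterministic given its seed and produces both the
# data object and a "truth" list against which downstream modules can be
# validated (planted fluxes, types, batch effects, labeling fractions).

#' Simulate a flux-vs-metabolite validation panel
#'
#' Generates an ion table across conditions in which every ion's level is
#' driven monotonically by the latent flux of the pathway it belongs to:
#' `L_ic = a_i * v_{p(i),c}^gamma_i * exp(eps)`, with `eps ~ N(0, sigma^2)`
#' on the log scale. A minority of ions per pathway carry negative response
#' exponents, emulating incoherent intermediates; at least 80% per pathway
#' respond positively.
#'
#' @param n_conditions number of conditions (>= 3).
#' @param pathway_sizes integer vector, ions per pathway; each >= 4 (the
#'   downstream scoring rule needs at least four ions per pathway).
#' @param sigma log-scale noise standard deviation (>= 0).
#' @param frac_negative fraction of ions per pathway with negative response
#'   exponent; must be <= 0.2.
#' @param gamma_range range the positive response exponents are drawn from.
#' @param seed integer seed.
#' @return list with `table` (an [ion_table], conditions as samples) and
#'   `truth` (fluxes, per-ion pathway, exponents, baselines, sigma).
#' @export
simulate_flux_panel <- function(n_conditions, pathway_sizes, sigma = 0.2,
                                frac_negative = 0.15,
                                gamma_range = c(0.3, 1.0), seed = 1L) {
  if (n_conditions < 3) stop("need at least 3 conditions")
  if (any(pathway_sizes < 4))
    stop("every pathway needs >= 4 ions (downstream scoring rule)")
  if (frac_negative > 0.2) stop("frac_negative must be <= 0.2")
  set.seed(seed)
  n_pw <- length(pathway_sizes)
  pw_ids <- sprintf("pw%02d", seq_len(n_pw))
  ion_pw <- rep(pw_ids, pathway_sizes)
  n_ions <- sum(pathway_sizes)
  ion_ids <- sprintf("ion%04d", seq_len(n_ions))

  # latent fluxes: positive, spread over ~an order of magnitude
  flux <- matrix(exp(stats::rnorm(n_pw * n_conditions, 0, 0.8)),
                 nrow = n_conditions, ncol = n_pw,
                 dimnames = list(sprintf("cond%02d", seq_len(n_conditions)),
                                 pw_ids))
  gamma <- stats::runif(n_ions, gamma_range[1], gamma_range[2])
  # flip a fixed minority per pathway so >= 80% stay positive
  for (p in pw_ids) {
    idx <- which(ion_pw == p)
    n_neg <- floor(frac_negative * length(idx))
    if (n_neg > 0) gamma[idx[seq_len(n_neg)]] <- -gamma[idx[seq_len(n_neg)]]
  }
  a <- exp(stats::rnorm(n_ions, 8, 1))   # ion-specific baseline intensity

  logL <- log(flux[, match(ion_pw, pw_ids), drop = FALSE])
  logL <- sweep(logL, 2, gamma, `*`)
  logL <- sweep(logL, 2, log(a), `+`)
  if (sigma > 0)
    logL <- logL + matrix(stats::rnorm(length(logL), 0, sigma), nrow(logL))
  intensity <- exp(logL)

  samples <- data.frame(sample_id = rownames(flux),
                        cell_line = rownames(flux),
                        batch = "b1", injection_order = seq_len(n_conditions),
                        is_qc = FALSE, replicate = 1L)
  ions <- data.frame(ion_id = ion_ids,
                     mz = round(100 + seq_len(n_ions) * 0.37, 4),
                     formulas = sprintf("F%04d", seq_len(n_ions)))
  truth <- list(flux = flux, ion_pathway = stats::setNames(ion_pw, ion_ids),
                gamma = stats::setNames(gamma, ion_ids),
                baseline = stats::setNames(a, ion_ids), sigma = sigma)
  list(table = ion_table(intensity, samples, ions), truth = truth)
}

#' Simulate a multi-batch cell line screen
#'
#' Emulates an untargeted metabolomics screen of a cell line panel grown
#' and measured in several batches, with two quality-control (QC) cell
#' lines replicated in every batch. Intensities are
#' biology x batch effect x injection-order drift x sample size factor x
#' log-normal noise, all multiplicative and strictly positive. Biology:
#' ions belong to pathways whose latent flux differs between two planted
#' metabolic types, plus a cell-line random effect.
#'
#' @param n_lines number of non-QC cell lines.
#' @param n_batches number of growth/measurement batches (>= 2).
#' @param n_ions total number of ions; ions are split evenly over
#'   `n_pathways` pathways.
#' @param n_pathways number of latent pathways driving the biology.
#' @param qc_replicates_per_batch replicates of each QC line per batch
#'   (> 0; quality metrics are undefined without QC samples).
#' @param replicates_per_line replicates of each non-QC line (grown in one
#'   batch).
#' @param type_effect log-scale separation of the two planted metabolic
#'   types on type-informative pathways.
#' @param batch_sd log-scale sd of per-batch per-ion multiplicative
#'   effects (0 = no batch artifact).
#' @param batch_fold_range if given (e.g. `c(2, 3)`), overrides
#'   `batch_sd`: each per-batch per-ion effect is a fold-change drawn
#'   uniformly from this range, with random direction.
#' @param batch_scale_sd log-sd of per-batch per-ion response-scale
#'   factors: biological log deviations are multiplied by
#'   `exp(N(0, batch_scale_sd))`, emulating batch-to-batch changes in
#'   detector gain/compression (0 = none).
#' @param drift_amplitude peak-to-trough fold-change of the smooth cubic
#'   injection-order drift (1 = flat).
#' @param size_factor_sd log-scale sd of per-sample size factors.
#' @param noise_sd log-scale sd of residual measurement noise.
#' @param seed integer seed.
#' @return list with `table` (an [ion_table]) and `truth` (type labels,
#'   per-batch per-ion effects, drift curves, size factors, QC line ids,
#'   pathway fluxes per type, ion pathway membership).
#' @export
simulate_screen <- function(n_lines = 60, n_batches = 7, n_ions = 120,
                            n_pathways = 6, qc_replicates_per_batch = 6,
                            replicates_per_line = 3, type_effect = 1.0,
                            batch_sd = 0.4, batch_fold_range = NULL,
                            batch_scale_sd = 0.2, drift_amplitude = 1.5,
                            size_factor_sd = 0.3, noise_sd = 0.15,
                            seed = 1L) {
  if (n_batches < 2) stop("need at least 2 batches")
  if (qc_replicates_per_batch < 1)
    stop("qc_replicates_per_batch must be >= 1: quality metrics are undefined without QC samples")
  set.seed(seed)

  qc_lines <- c("QC_A", "QC_B")
  lines <- sprintf("CL%03d", seq_len(n_lines))
  # planted types, balanced
  type <- rep(c(1L, 2L), length.out = n_lines)
  names(type) <- lines
  batch_of_line <- rep(seq_len(n_batches), length.out = n_lines)

  pw_ids <- sprintf("pw%02d", seq_len(n_pathways))
  ion_pw <- rep(pw_ids, length.out = n_ions)
  ion_ids <- sprintf("ion%04d", seq_len(n_ions))

  # type-dependent latent pathway fluxes: alternate direction per pathway
  flux_type <- matrix(1, nrow = 2, ncol = n_pathways,
                      dimnames = list(c("1", "2"), pw_ids))
  dir_pw <- rep(c(1, -1), length.out = n_pathways)
  flux_type[1, ] <- exp(+dir_pw * type_effect / 2)
  flux_type[2, ] <- exp(-dir_pw * type_effect / 2)

  gamma <- stats::runif(n_ions, 0.3, 1.0)
  neg <- stats::runif(n_ions) < 0.15
  gamma[neg] <- -gamma[neg]
  baseline <- exp(stats::rnorm(n_ions, 8, 1))

  # per-line random flux wobble around its type's pathway flux
  line_flux <- matrix(NA_real_, nrow = n_lines + 2, ncol = n_pathways,
                      dimnames = list(c(lines, qc_lines), pw_ids))
  for (cl in lines)
    line_flux[cl, ] <- flux_type[as.character(type[cl]), ] *
      exp(stats::rnorm(n_pathways, 0, 0.15))
  line_flux["QC_A", ] <- exp(stats::rnorm(n_pathways, 0, 0.3))
  line_flux["QC_B", ] <- exp(stats::rnorm(n_pathways, 0, 0.3))

  # sample layout: per batch, its lines' replicates plus QC replicates,
  # randomized injection order, ~10 min per injection
  rows <- list()
  for (b in seq_len(n_batches)) {
    bl <- lines[batch_of_line == b]
    cl <- c(rep(bl, each = replicates_per_line),
            rep(qc_lines, each = qc_replicates_per_batch))
    rep_idx <- c(rep(seq_len(replicates_per_line), times = length(bl)),
                 rep(seq_len(qc_replicates_per_batch), times = 2))
    ord <- sample.int(length(cl))
    rows[[b]] <- data.frame(cell_line = cl[ord],
                            batch = sprintf("batch%d", b),
                            injection_order = seq_along(cl) * 10,
                            is_qc = cl[ord] %in% qc_lines,
                            replicate = rep_idx[ord])
  }
  samples <- do.call(rbind, rows)
  samples$sample_id <- sprintf("s%04d", seq_len(nrow(samples)))
  samples$confluency <- round(stats::runif(nrow(samples), 0.5, 0.8), 3)
  samples <- samples[, c("sample_id", "cell_line", "batch",
                         "injection_order", "confluency", "is_qc",
                         "replicate")]
  n_samples <- nrow(samples)

  # artifacts
  batch_effect <- if (is.null(batch_fold_range)) {
    matrix(exp(stats::rnorm(n_batches * n_ions, 0, batch_sd)),
           nrow = n_batches)
  } else {
    fold <- stats::runif(n_batches * n_ions, batch_fold_range[1],
                         batch_fold_range[2])
    dir <- sample(c(-1, 1), n_batches * n_ions, replace = TRUE)
    matrix(fold^dir, nrow = n_batches)
  }
  dimnames(batch_effect) <- list(sprintf("batch%d", seq_len(n_batches)),
                                 ion_ids)
  batch_scale <- matrix(exp(stats::rnorm(n_batches * n_ions, 0,
                                         batch_scale_sd)),
                        nrow = n_batches,
                        dimnames = dimnames(batch_effect))
  # smooth cubic drift of injection order, shared shape per ion with
  # random phase; amplitude 1 means flat
  drift_coef <- matrix(stats::rnorm(n_ions * 3), ncol = 3)
  drift_fun <- function(t, i) {
    if (drift_amplitude <= 1) return(rep(1, length(t)))
    u <- (t - min(t)) / max(diff(range(t)), 1)
    raw <- drift_coef[i, 1] * u + drift_coef[i, 2] * u^2 +
      drift_coef[i, 3] * u^3
    span <- max(raw) - min(raw)
    if (span < 1e-12) return(rep(1, length(t)))
    exp((raw - mean(raw)) / span * log(drift_amplitude))
  }
  size_factor <- exp(stats::rnorm(n_samples, 0, size_factor_sd))

  # assemble intensities on the log scale
  fl <- line_flux[samples$cell_line, , drop = FALSE]
  logflux_ion <- log(fl[, match(ion_pw, pw_ids), drop = FALSE])
  bio_dev <- sweep(logflux_ion, 2, gamma, `*`)
  # batch-dependent response scale acts on the biological deviations
  logI <- bio_dev * batch_scale[samples$batch, , drop = FALSE]
  logI <- sweep(logI, 2, log(baseline), `+`)
  logI <- logI + log(batch_effect[samples$batch, , drop = FALSE])
  drift <- matrix(1, n_samples, n_ions)
  for (b in unique(samples$batch)) {
    sb <- which(samples$batch == b)
    tt <- samples$injection_order[sb]
    for (i in seq_len(n_ions)) drift[sb, i] <- drift_fun(tt, i)
  }
  logI <- logI + log(drift) + log(size_factor)
  if (noise_sd > 0)
    logI <- logI + matrix(stats::rnorm(length(logI), 0, noise_sd),
                          nrow(logI))
  intensity <- exp(logI)

  formulas <- sprintf("F%04d", seq_len(n_ions))
  # first ions carry proteinogenic amino-acid formulas so the
  # amino-acid-restricted reproducibility criterion is computable
  aa <- unique(amino_acid_formulas())
  n_aa <- min(length(aa), n_ions)
  formulas[seq_len(n_aa)] <- aa[seq_len(n_aa)]
  ions <- data.frame(ion_id = ion_ids,
                     mz = round(100 + seq_len(n_ions) * 0.53, 4),
                     formulas = formulas)
  truth <- list(type = type, qc_lines = qc_lines,
                batch_of_line = stats::setNames(batch_of_line, lines),
                batch_effect = batch_effect, batch_scale = batch_scale,
                drift = drift,
                size_factor = stats::setNames(size_factor,
                                              samples$sample_id),
                flux_type = flux_type, line_flux = line_flux,
                ion_pathway = stats::setNames(ion_pw, ion_ids),
                gamma = stats::setNames(gamma, ion_ids))
  list(table = ion_table(intensity, samples, ions), truth = truth)
}

#' Simulate a trait table with planted branch associations
#'
#' Null traits are independent of the planted type labels; planted
#' categorical traits are over-represented in type 1, planted continuous
#' traits are mean-shifted between types by `effect` within-type standard
#' deviations.
#'
#' @param type_labels named integer vector (1/2) of planted types per cell
#'   line, e.g. `truth$type` from [simulate_screen()].
#' @param n_null_categorical,n_null_continuous numbers of null traits.
#' @param n_planted number of planted trait pairs (each planted index
#'   yields one categorical and one continuous trait).
#' @param effect planted effect size (> 0): continuous shift in sd units;
#'   categorical traits match type 1 with probability
#'   `min(1, 0.5 + effect/10)` (effect >= 5 plants a perfectly aligned
#'   trait).
#' @param planted_modality which modalities to plant: "both" (default),
#'   "categorical" or "continuous".
#' @param seed integer seed.
#' @return A long-format data.frame with columns `trait_id`, `modality`
#'   ("categorical"/"continuous"), `cell_line`, `value` (character for
#'   categorical, numeric-as-character for continuous), `source`.
#' @export
simulate_traits <- function(type_labels, n_null_categorical = 50,
                            n_null_continuous = 50, n_planted = 0,
                            effect = 2, planted_modality = "both",
                            seed = 1L) {
  if (n_planted > 0 && effect <= 0) stop("effect must be > 0")
  set.seed(seed)
  lines <- names(type_labels)
  n <- length(lines)
  out <- list()
  add <- function(id, modality, values, source) {
    out[[length(out) + 1]] <<- data.frame(
      trait_id = id, modality = modality, cell_line = lines,
      value = as.character(values), source = source)
  }
  for (i in seq_len(n_null_categorical))
    add(sprintf("null_cat%04d", i), "categorical",
        sample(c("yes", "no"), n, replace = TRUE), "null")
  for (i in seq_len(n_null_continuous))
    add(sprintf("null_cont%04d", i), "continuous",
        stats::rnorm(n), "null")
  if (n_planted > 0) {
    p_match <- min(1, 0.5 + effect / 10)  # effect >= 5: perfect alignment
    for (i in seq_len(n_planted)) {
      if (planted_modality %in% c("both", "categorical")) {
        v <- ifelse(stats::runif(n) < p_match, type_labels == 1L,
                    type_labels != 1L)
        add(sprintf("planted_cat%04d", i), "categorical",
            ifelse(v, "yes", "no"), "planted")
      }
      if (planted_modality %in% c("both", "continuous"))
        add(sprintf("planted_cont%04d", i), "continuous",
            stats::rnorm(n) + effect * (type_labels == 1L), "planted")
    }
  }
  do.call(rbind, out)
}

#' Simulate isotopologue intensity vectors
#'
#' For each (metabolite, cell line) of the truth, generates replicate raw
#' isotopologue vectors from a two-population labeling model: a fraction
#' `FC*/enrichment` of molecules is tracer-labeled with per-position
#' enrichment 0.99, the rest unlabeled; the tracer pattern is then
#' convolved with the natural-abundance binomial at `p_nat` and scaled by
#' a multiplicative log-normal noise.
#'
#' @param truth a list describing the tracer experiment:
#'   `metabolites` (data.frame with `metabolite`, `n_carbons`),
#'   `fc` (data.frame with `metabolite`, `cell_line`, `tracer`, `fc_true`
#'   in `[0,1]`), `p_nat` (natural 13C abundance, default 0.0107).
#' @param n_replicates replicates per (metabolite, cell line, tracer).
#' @param noise multiplicative log-normal noise sd (>= 0).
#' @param enrichment per-position 13C enrichment of the labeled
#'   population.
#' @param seed integer seed.
#' @return An `mdv_table` data.frame: columns `metabolite`, `n_carbons`,
#'   `tracer`, `cell_line`, `replicate`, and raw intensities `I0..Imax`
#'   (NA beyond a metabolite's carbon count).
#' @export
simulate_mdv <- function(truth, n_replicates = 3, noise = 0,
                         enrichment = 0.99, seed = 1L) {
  if (noise < 0) stop("noise must be >= 0")
  p_nat <- if (!is.null(truth$p_nat)) truth$p_nat else 0.0107
  set.seed(seed)
  mets <- truth$metabolites
  fc <- truth$fc
  if (any(fc$fc_true < 0 | fc$fc_true > 1)) stop("fc_true must be in [0,1]")
  max_n <- max(mets$n_carbons)
  rows <- list()
  for (r in seq_len(nrow(fc))) {
    m <- fc$metabolite[r]
    n <- mets$n_carbons[match(m, mets$metabolite)]
    if (is.na(n) || n < 1) stop("unknown metabolite or n_carbons < 1: ", m)
    enr <- enrichment
    f <- fc$fc_true[r] / enr
    if (f > 1) {  # above the population enrichment: fully labeled pool
      f <- 1
      enr <- fc$fc_true[r]
    }
    tracer_mdv <- f * stats::dbinom(0:n, n, enr) +
      (1 - f) * c(1, rep(0, n))
    obs <- convolve_natural_abundance(tracer_mdv, p_nat)
    for (k in seq_len(n_replicates)) {
      v <- obs * 1e5
      if (noise > 0) v <- v * exp(stats::rnorm(n + 1, 0, noise))
      rows[[length(rows) + 1]] <- data.frame(
        metabolite = m, n_carbons = n, tracer = fc$tracer[r],
        cell_line = fc$cell_line[r], replicate = k,
        t(c(v, rep(NA_real_, max_n - n))))
    }
  }
  out <- do.call(rbind, rows)
  names(out)[-(1:5)] <- paste0("I", 0:max_n)
  rownames(out) <- NULL
  out
}

# forward-convolve a tracer-labeled MDV with the natural-abundance
# binomial: a molecule with k tracer carbons has n-k positions that can
# each be 13C at p_nat
convolve_natural_abundance <- function(mdv, p_nat) {
  n <- length(mdv) - 1L
  out <- numeric(n + 1L)
  for (k in 0:n) {
    if (mdv[k + 1L] == 0) next
    out[(k:n) + 1L] <- out[(k:n) + 1L] +
      mdv[k + 1L] * stats::dbinom(0:(n - k), n - k, p_nat)
  }
  out
}

#' Ion-pathway map implied by a simulated panel's truth
#'
#' Builds the [map_ions_to_pathways()]-style map directly from the truth
#' of [simulate_flux_panel()] or [simulate_screen()], so generated panels
#' can be scored without constructing a reaction-level pathway set.
#'
#' @param panel the list returned by a generator (`table` + `truth`).
#' @param min_ions scoreability threshold (default 4 unique-m/z ions).
#' @return An object of class `ion_pathway_map`.
#' @export
truth_ion_pathway_map <- function(panel, min_ions = 4) {
  tab <- panel$table; truth <- panel$truth
  edges <- data.frame(ion_id = names(truth$ion_pathway),
                      formula = tab$ions$formulas[
                        match(names(truth$ion_pathway),
                              tab$ions$ion_id)],
                      pathway_id = unname(truth$ion_pathway))
  pathway_ions <- lapply(split(edges$ion_id, edges$pathway_id), unique)
  mz <- stats::setNames(tab$ions$mz, tab$ions$ion_id)
  n_unique_mz <- vapply(pathway_ions, function(ii)
    length(unique(mz[ii])), integer(1))
  structure(list(edges = edges, pathway_ions = pathway_ions,
                 scoreable = n_unique_mz >= min_ions,
                 n_unique_mz = n_unique_mz, min_ions = min_ions),
            class = "ion_pathway_map")
}

#' Reaction-level pathway definitions for a simulated panel
#'
#' Produces a [pathway_set()] consistent with a generated panel: each
#' pathway's member formulas are chained into linear reactions, so the
#' curation and mapping steps can run on synthetic data. Optionally a
#' number of reactions shared between consecutive pathways is added to
#' exercise the curation rule.
#'
#' @param panel the list returned by a generator (`table` + `truth`).
#' @param n_shared number of extra reactions shared between pathway
#'   pairs (default 0).
#' @return A [pathway_set()].
#' @export
truth_pathway_set <- function(panel, n_shared = 0) {
  truth <- panel$truth; tab <- panel$table
  pw <- split(names(truth$ion_pathway), unname(truth$ion_pathway))
  rows <- list()
  for (p in names(pw)) {
    f <- tab$ions$formulas[match(pw[[p]], tab$ions$ion_id)]
    for (i in seq_len(length(f) - 1))
      rows[[length(rows) + 1]] <- data.frame(
        reaction_id = sprintf("%s_r%02d", p, i), pathway_id = p,
        substrates = f[i], products = f[i + 1])
  }
  if (n_shared > 0) {
    pws <- names(pw)
    for (k in seq_len(n_shared)) {
      a <- pws[(k - 1) %% length(pws) + 1]
      b <- pws[k %% length(pws) + 1]
      for (p in c(a, b))
        rows[[length(rows) + 1]] <- data.frame(
          reaction_id = sprintf("shared_r%02d", k), pathway_id = p,
          substrates = sprintf("S%03da", k),
          products = sprintf("S%03db", k))
    }
  }
  pathway_set(do.call(rbind, rows))
}
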