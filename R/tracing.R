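# 13C isotopologue analysis: natural-abundance correction, mass
# distribution vectors, fractional contributions and type-wise
# fractional differences.

#' Correct an isotopologue vector for natural 13C abundance
#'
#' Builds the (n+1) x (n+1) correction matrix whose column for a
#' tracer-labeling state with k labeled carbons is the binomial
#' distribution of additional natural 13C over the remaining n - k
#' positions, and deconvolves the measured vector by non-negative least
#' squares (plain inversion can produce negative fractions on noisy
#' data). The result is renormalized to unit sum.
#'
#' @param raw numeric vector of raw isotopologue intensities I0..In
#'   (length n+1, non-negative, not all zero).
#' @param n_carbons the metabolite's carbon count n (>= 1).
#' @param p_nat natural 13C abundance (default 0.0107).
#' @return Corrected mass distribution vector m0..mn (sums to 1).
#' @export
natural_abundance_correction <- function(raw, n_carbons,
                                         p_nat = 0.0107) {
  if (length(raw) != n_carbons + 1)
    stop("raw must have length n_carbons + 1")
  if (any(raw < 0) || any(!is.finite(raw))) stop("raw must be >= 0")
  if (sum(raw) == 0) stop("all-zero isotopologue vector")
  n <- n_carbons
  if (p_nat == 0) return(raw / sum(raw))
  cm <- matrix(0, n + 1, n + 1)
  for (k in 0:n)
    cm[(k:n) + 1, k + 1] <- stats::dbinom(0:(n - k), n - k, p_nat)
  sol <- pracma::lsqnonneg(cm, as.numeric(raw))$x
  if (sum(sol) == 0) stop("deconvolution returned the zero vector")
  sol / sum(sol)
}

#' Fractional contribution of a labeled tracer
#'
#' `FC = sum(i * m_i) / n`: the fraction of the metabolite's carbon
#' derived from the labeled substrate, computed from a corrected,
#' normalized mass distribution vector.
#'
#' @param mdv corrected mass distribution vector m0..mn.
#' @return FC in `[0, 1]`.
#' @export
fractional_contribution <- function(mdv) {
  n <- length(mdv) - 1L
  if (n == 0) stop("fractional contribution undefined for n = 0")
  s <- sum(mdv)
  if (abs(s - 1) > 1e-6) mdv <- mdv / s
  sum((0:n) * mdv) / n
}

#' Fractional contributions for an MDV table
#'
#' Applies natural-abundance correction (optional) and the FC formula to
#' every row of an MDV table, then averages replicates per
#' (metabolite, tracer, cell line).
#'
#' @param mdv_table data.frame as produced by [simulate_mdv()] or
#'   [read_mdv_csv()]: `metabolite`, `n_carbons`, `tracer`, `cell_line`,
#'   `replicate`, `I0..Imax`.
#' @param correct apply natural-abundance correction (default TRUE).
#' @param p_nat natural 13C abundance (default 0.0107).
#' @return data.frame with `metabolite`, `tracer`, `cell_line`, `fc`
#'   (replicate-averaged) and `n_replicates`.
#' @export
compute_fractional_contributions <- function(mdv_table, correct = TRUE,
                                             p_nat = 0.0107) {
  icols <- grep("^I\\d+$", names(mdv_table), value = TRUE)
  icols <- icols[order(as.integer(sub("^I", "", icols)))]
  fc_row <- vapply(seq_len(nrow(mdv_table)), function(r) {
    n <- mdv_table$n_carbons[r]
    raw <- as.numeric(mdv_table[r, icols[seq_len(n + 1)]])
    mdv <- if (correct) natural_abundance_correction(raw, n, p_nat)
           else raw / sum(raw)
    fractional_contribution(mdv)
  }, numeric(1))
  agg <- stats::aggregate(
    fc_row,
    by = list(metabolite = mdv_table$metabolite,
              tracer = mdv_table$tracer,
              cell_line = mdv_table$cell_line),
    FUN = mean)
  cnt <- stats::aggregate(
    fc_row,
    by = list(metabolite = mdv_table$metabolite,
              tracer = mdv_table$tracer,
              cell_line = mdv_table$cell_line),
    FUN = length)
  agg$n_replicates <- cnt$x
  names(agg)[names(agg) == "x"] <- "fc"
  agg
}

#' Rank metabolites by type-wise fractional difference
#'
#' Per metabolite and tracer, `delta = mean FC over type-1 cell lines -
#' mean FC over type-2 cell lines` (cell-line means first, so lines
#' weigh equally); positive values mean higher labeling in type 1. The
#' list is sorted by descending delta, ties broken by metabolite id.
#'
#' @param fc data.frame from [compute_fractional_contributions()].
#' @param type_labels named vector (1/2) of types per cell line.
#' @return data.frame `metabolite`, `tracer`, `delta`, `fc_type1`,
#'   `fc_type2`, `rank` (per tracer); metabolites absent in one type
#'   are excluded and listed in `attr(, "excluded")`.
#' @export
fractional_difference <- function(fc, type_labels) {
  fc$type <- type_labels[fc$cell_line]
  if (anyNA(fc$type)) stop("cell lines without type labels present")
  out <- list(); excluded <- character()
  for (tr in unique(fc$tracer)) {
    sub <- fc[fc$tracer == tr, , drop = FALSE]
    for (m in unique(sub$metabolite)) {
      sm <- sub[sub$metabolite == m, , drop = FALSE]
      f1 <- sm$fc[sm$type == 1]; f2 <- sm$fc[sm$type == 2]
      if (!length(f1) || !length(f2)) {
        excluded <- c(excluded, paste0(tr, ":", m))
        next
      }
      out[[length(out) + 1]] <- data.frame(
        metabolite = m, tracer = tr, delta = mean(f1) - mean(f2),
        fc_type1 = mean(f1), fc_type2 = mean(f2))
    }
  }
  out <- do.call(rbind, out)
  out <- out[order(out$tracer, -out$delta, out$metabolite), ]
  out$rank <- stats::ave(out$delta, out$tracer,
                         FUN = function(d) seq_along(d))
  rownames(out) <- NULL
  attr(out, "excluded") <- excluded
  out
}

#' Write/read MDV tables as CSV
#'
#' @param mdv_table the MDV data.frame.
#' @param path file path.
#' @return Invisibly `path` (write) or the data.frame (read).
#' @export
write_mdv_csv <- function(mdv_table, path) {
  utils::write.csv(mdv_table, path, row.names = FALSE, quote = FALSE,
                   na = "")
  invisible(path)
}

#' @rdname write_mdv_csv
#' @export
read_mdv_csv <- function(path) {
  utils::read.csv(path)
}
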