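#' Ion intensity table
#'
#' The central container of the pipeline: a samples x ions intensity matrix
#' with per-sample and per-ion metadata, as produced by a flow-injection
#' untargeted metabolomics screen after peak annotation.
#'
#' @param intensity numeric matrix, samples in rows, ions in columns.
#'   Intensities must be non-negative; zeros are treated as missing-value
#'   sentinels by the normalizers.
#' @param sample_data data.frame with one row per sample. Must contain a
#'   `sample_id` column (unique) and a `batch` column; recognised optional
#'   columns are `cell_line`, `injection_order` (minutes), `confluency`
#'   (fraction in (0, 1]), `is_qc` (logical) and `replicate`.
#' @param ion_data data.frame with one row per ion. Must contain an
#'   `ion_id` column (unique); recognised optional columns are `mz` (Da)
#'   and `formulas` (semicolon-separated candidate molecular formulas).
#'
#' @return An object of class `ion_table`: a list with elements
#'   `intensity`, `samples`, `ions` and a `provenance` character vector
#'   recording the processing steps applied so far.
#' @export
ion_table <- function(intensity, sample_data, ion_data) {
  intensity <- as.matrix(intensity)
  if (!is.numeric(intensity)) stop("intensity must be a numeric matrix")
  if (nrow(sample_data) != nrow(intensity))
    stop("sample_data rows must match intensity rows")
  if (nrow(ion_data) != ncol(intensity))
    stop("ion_data rows must match intensity columns")
  if (!"sample_id" %in% names(sample_data)) stop("sample_data needs sample_id")
  if (!"ion_id" %in% names(ion_data)) stop("ion_data needs ion_id")
  if (anyDuplicated(sample_data$sample_id))
    stop("sample ids must be unique")
  if (!"batch" %in% names(sample_data)) stop("every sample needs a batch")
  if (any(is.na(sample_data$batch))) stop("every sample needs a batch")
  if (any(!is.finite(intensity)) || any(intensity < 0))
    stop("intensities must be finite and >= 0")
  rownames(intensity) <- sample_data$sample_id
  colnames(intensity) <- ion_data$ion_id
  rownames(sample_data) <- NULL
  rownames(ion_data) <- NULL
  structure(
    list(intensity = intensity, samples = sample_data, ions = ion_data,
         provenance = character()),
    class = "ion_table"
  )
}

#' @export
print.ion_table <- function(x, ...) {
  cat(sprintf("ion_table: %d samples x %d ions\n",
              nrow(x$intensity), ncol(x$intensity)))
  cat(sprintf("  batches: %s\n",
              paste(sort(unique(as.character(x$samples$batch))),
                    collapse = ", ")))
  if ("cell_line" %in% names(x$samples))
    cat(sprintf("  cell lines: %d\n", length(unique(x$samples$cell_line))))
  if (length(x$provenance))
    cat("  steps:", paste(x$provenance, collapse = " -> "), "\n")
  invisible(x)
}

#' @export
dim.ion_table <- function(x) dim(x$intensity)

#' Subset an ion table by samples and/or ions
#'
#' @param table an [ion_table].
#' @param samples logical, integer or character (sample id) index.
#' @param ions logical, integer or character (ion id) index.
#' @return The subsetted [ion_table].
#' @export
subset_ion_table <- function(table, samples = NULL, ions = NULL) {
  stopifnot(inherits(table, "ion_table"))
  si <- seq_len(nrow(table$intensity))
  ii <- seq_len(ncol(table$intensity))
  if (!is.null(samples)) {
    si <- if (is.character(samples)) {
      match(samples, table$samples$sample_id)
    } else si[samples]
    if (anyNA(si)) stop("unknown sample ids")
  }
  if (!is.null(ions)) {
    ii <- if (is.character(ions)) match(ions, table$ions$ion_id) else ii[ions]
    if (anyNA(ii)) stop("unknown ion ids")
  }
  out <- table
  out$intensity <- table$intensity[si, ii, drop = FALSE]
  out$samples <- table$samples[si, , drop = FALSE]
  rownames(out$samples) <- NULL
  out$ions <- table$ions[ii, , drop = FALSE]
  rownames(out$ions) <- NULL
  out
}

# replace the intensity matrix, keeping metadata and appending a step label
set_intensity <- function(table, intensity, step = NULL) {
  stopifnot(identical(dim(intensity), dim(table$intensity)))
  dimnames(intensity) <- dimnames(table$intensity)
  table$intensity <- intensity
  if (!is.null(step)) table$provenance <- c(table$provenance, step)
  table
}

#' Write an ion table to plain-text files
#'
#' Writes three TSV files: `<prefix>_intensity.tsv` (samples x ions, with a
#' leading `sample_id` column), `<prefix>_samples.tsv` and
#' `<prefix>_ions.tsv`.
#'
#' @param table an [ion_table].
#' @param prefix file path prefix.
#' @return Invisibly, the paths written.
#' @export
write_ion_table <- function(table, prefix) {
  stopifnot(inherits(table, "ion_table"))
  paths <- paste0(prefix, c("_intensity.tsv", "_samples.tsv", "_ions.tsv"))
  ints <- data.frame(sample_id = table$samples$sample_id,
                     table$intensity, check.names = FALSE)
  utils::write.table(ints, paths[1], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(table$samples, paths[2], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(table$ions, paths[3], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}

#' Read an ion table written by [write_ion_table()]
#'
#' @param prefix file path prefix used when writing.
#' @return An [ion_table].
#' @export
read_ion_table <- function(prefix) {
  ints <- utils::read.delim(paste0(prefix, "_intensity.tsv"),
                            check.names = FALSE)
  samples <- utils::read.delim(paste0(prefix, "_samples.tsv"))
  ions <- utils::read.delim(paste0(prefix, "_ions.tsv"))
  mat <- as.matrix(ints[, -1, drop = FALSE])
  storage.mode(mat) <- "double"
  ion_table(mat, samples, ions)
}
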