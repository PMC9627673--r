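# Shared fixtures, all built in code.

# tiny ion table with explicit values; samples in rows
tiny_table <- function(intensity, batch = NULL, cell_line = NULL,
                       injection_order = NULL, is_qc = NULL,
                       confluency = NULL, mz = NULL, formulas = NULL) {
  n <- nrow(intensity); p <- ncol(intensity)
  samples <- data.frame(
    sample_id = sprintf("s%02d", seq_len(n)),
    cell_line = cell_line %||% sprintf("cl%02d", seq_len(n)),
    batch = batch %||% rep("b1", n),
    injection_order = injection_order %||% seq_len(n) * 10,
    is_qc = is_qc %||% rep(FALSE, n),
    replicate = 1L)
  if (!is.null(confluency)) samples$confluency <- confluency
  ions <- data.frame(ion_id = sprintf("i%02d", seq_len(p)),
                     mz = mz %||% (100 + seq_len(p)),
                     formulas = formulas %||% sprintf("F%02d", seq_len(p)))
  ion_table(intensity, samples, ions)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# small screen shared by several normalization/quality tests
small_screen <- function(seed = 42, ...) {
  simulate_screen(n_lines = 24, n_batches = 3, n_ions = 40,
                  qc_replicates_per_batch = 6,
                  replicates_per_line = 2, seed = seed, ...)
}

# the winning stack
quantile_combat <- function() {
  normalization_stack(list(class = "sample_variance", method = "quantile"),
                      list(class = "batch_effect", method = "combat"))
}

# Rand index between two labelings
rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  n <- length(a)
  s <- 0
  for (i in seq_len(n - 1))
    for (j in (i + 1):n)
      s <- s + ((a[i] == a[j]) == (b[i] == b[j]))
  s / choose(n, 2)
}
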