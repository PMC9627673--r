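# Lipidomics summary statistics: class totals, unsaturation index and
# chain-length profiles, with two-group comparisons.

# acyl-chain count convention per lipid class: 1 for lyso species,
# 2 for diacyl glycerophospholipids and sphingolipids (long-chain base
# counted as a chain), 3 for triacylglycerols, 4 for cardiolipins
lipid_chain_counts <- c(HexCer = 2, SM = 2, CL = 4, PC = 2, LPC = 1,
                        `ether PC` = 2, PE = 2, LPE = 1, PS = 2, PG = 2,
                        TAG = 3)

#' Acyl-chain counts per lipid class
#'
#' @return Named integer vector (class -> chains per species).
#' @export
acyl_chain_counts <- function() lipid_chain_counts

#' Summarize a lipid table per class and compare groups
#'
#' Computes, per sample: class totals (sum of concentrations),
#' concentration-weighted unsaturation index (average double bonds per
#' acyl chain), and the concentration distribution over total acyl
#' carbons (chain-length profile). Two-sided pooled t-tests compare the
#' groups per class on totals and unsaturation; per-species t-tests are
#' Benjamini-Hochberg adjusted across the species panel.
#'
#' @param lipids long-format data.frame with columns `species`, `class`,
#'   `carbons` (total acyl carbons), `double_bonds`, `ether` (logical),
#'   `sample`, `concentration` (internal-standard normalized, >= 0).
#' @param groups named vector mapping sample -> group label (two
#'   groups).
#' @return list with `class_totals` (sample x class), `unsaturation`
#'   (sample x class plus `overall`), `chain_profile` (long data.frame),
#'   `class_tests` (per class: totals and unsaturation t-tests),
#'   `species_tests` (per species, BH-adjusted), `missing_classes`.
#' @export
lipid_summaries <- function(lipids, groups) {
  need <- c("species", "class", "carbons", "double_bonds", "sample",
            "concentration")
  if (!all(need %in% names(lipids)))
    stop("lipids needs columns: ", paste(need, collapse = ", "))
  if (any(lipids$concentration < 0)) stop("concentrations must be >= 0")
  if (any(lipids$double_bonds > lipids$carbons))
    stop("double bonds cannot exceed carbons")
  unknown <- setdiff(unique(lipids$class), names(lipid_chain_counts))
  if (length(unknown))
    stop("unknown lipid class(es): ", paste(unknown, collapse = ", "))
  lipids$chains <- lipid_chain_counts[lipids$class]
  lipids$db_per_chain <- lipids$double_bonds / lipids$chains

  samples <- sort(unique(lipids$sample))
  classes <- sort(unique(lipids$class))
  totals <- matrix(NA_real_, length(samples), length(classes),
                   dimnames = list(samples, classes))
  unsat <- totals
  for (s in samples) for (cl in classes) {
    sub <- lipids[lipids$sample == s & lipids$class == cl, ]
    if (!nrow(sub)) next   # empty class stays missing, not zero
    totals[s, cl] <- sum(sub$concentration)
    if (totals[s, cl] > 0)
      unsat[s, cl] <- sum(sub$concentration * sub$db_per_chain) /
        sum(sub$concentration)
  }
  overall_unsat <- vapply(samples, function(s) {
    sub <- lipids[lipids$sample == s, ]
    sum(sub$concentration * sub$db_per_chain) / sum(sub$concentration)
  }, numeric(1))

  chain_profile <- stats::aggregate(
    concentration ~ sample + class + carbons, data = lipids, FUN = sum)

  g <- groups[samples]
  if (length(unique(stats::na.omit(g))) != 2)
    stop("groups must define exactly two groups over the samples")
  two_group_t <- function(v) {
    a <- v[g == unique(g)[1]]; b <- v[g == unique(g)[2]]
    a <- a[!is.na(a)]; b <- b[!is.na(b)]
    if (length(a) < 2 || length(b) < 2) return(NA_real_)
    if (stats::sd(c(a, b)) == 0) return(1)
    stats::t.test(a, b, var.equal = TRUE)$p.value
  }
  class_tests <- data.frame(
    class = classes,
    p_total = apply(totals, 2, two_group_t),
    p_unsaturation = apply(unsat, 2, two_group_t))
  species <- sort(unique(lipids$species))
  sp_mat <- matrix(NA_real_, length(samples), length(species),
                   dimnames = list(samples, species))
  for (r in seq_len(nrow(lipids)))
    sp_mat[lipids$sample[r], lipids$species[r]] <- lipids$concentration[r]
  species_tests <- data.frame(
    species = species,
    class = lipids$class[match(species, lipids$species)],
    p = apply(sp_mat, 2, two_group_t))
  species_tests$p_adj <- stats::p.adjust(species_tests$p, "BH")

  missing_classes <- classes[colSums(!is.na(totals)) == 0]
  list(class_totals = totals,
       unsaturation = cbind(unsat, overall = overall_unsat),
       chain_profile = chain_profile, class_tests = class_tests,
       species_tests = species_tests,
       missing_classes = missing_classes)
}
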