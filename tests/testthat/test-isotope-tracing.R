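# Natural-abundance correction, fractional contributions, fractional
# differences, lipid summaries.

test_that("correction is the identity at p_nat = 0 and exact on round trips", {
  raw <- c(3, 1, 0.5, 0.25)
  expect_equal(natural_abundance_correction(raw, 3, p_nat = 0),
               raw / sum(raw))
  # forward-convolve a known MDV, then correct: recovered within 1e-6
  mdv <- c(0.45, 0.2, 0.05, 0.1, 0.05, 0.05, 0.1)
  obs <- metabotyper:::convolve_natural_abundance(mdv, 0.0107)
  back <- natural_abundance_correction(obs * 3e4, 6, p_nat = 0.0107)
  expect_lt(max(abs(back - mdv)), 1e-6)
  # unlabeled 6-carbon metabolite at natural abundance
  nat <- dbinom(0:6, 6, 0.0107)
  corr <- natural_abundance_correction(nat, 6)
  expect_lt(max(abs(corr - c(1, rep(0, 6)))), 1e-6)
  expect_error(natural_abundance_correction(rep(0, 4), 3), "zero")
  expect_error(natural_abundance_correction(c(1, 2), 3), "length")
})

test_that("fractional contribution follows the closed-form definition", {
  expect_equal(fractional_contribution(c(1, 0, 0, 0)), 0)
  expect_equal(fractional_contribution(c(0, 0, 0, 1)), 1)
  expect_equal(fractional_contribution(c(0.5, 0, 0, 0.5)), 0.5)
  expect_error(fractional_contribution(1), "n = 0")
  # invariant to uniform scaling of the raw vector
  v <- c(2, 1, 1, 4)
  expect_equal(fractional_contribution(v / sum(v)),
               fractional_contribution(10 * v / sum(10 * v)))
})

tracer_truth <- function(fc_values, n_carbons = 5) {
  lines <- sprintf("L%d", seq_along(fc_values))
  list(metabolites = data.frame(metabolite = "met",
                                n_carbons = n_carbons),
       fc = data.frame(metabolite = "met", cell_line = lines,
                       tracer = "glc", fc_true = fc_values),
       p_nat = 0.0107)
}

test_that("planted FC values survive the simulate-correct-measure loop", {
  fcs <- c(0, 0.25, 0.5, 0.75, 1)
  truth <- tracer_truth(fcs)
  mdv <- simulate_mdv(truth, n_replicates = 1, noise = 0, seed = 1)
  out <- compute_fractional_contributions(mdv)
  out <- out[match(sprintf("L%d", 1:5), out$cell_line), ]
  expect_equal(out$fc, fcs, tolerance = 1e-6)
  # with 5% multiplicative noise, recovered within 0.02
  set.seed(2)
  mdv_n <- simulate_mdv(truth, n_replicates = 20, noise = 0.05,
                        seed = 3)
  out_n <- compute_fractional_contributions(mdv_n)
  out_n <- out_n[match(sprintf("L%d", 1:5), out_n$cell_line), ]
  expect_lt(max(abs(out_n$fc - fcs)), 0.02)
})

test_that("fractional differences rank metabolites with correct signs", {
  type <- c(A1 = 1, A2 = 1, B1 = 2, B2 = 2)
  fc <- expand.grid(metabolite = c("up", "flat", "down"),
                    cell_line = names(type), tracer = "glc",
                    stringsAsFactors = FALSE)
  base <- c(up = 0.2, flat = 0.5, down = 0.8)
  shift <- c(up = 0.3, flat = 0, down = -0.3)
  fc$fc <- base[fc$metabolite] +
    shift[fc$metabolite] * (type[fc$cell_line] == 1)
  d <- fractional_difference(fc, type)
  expect_identical(d$metabolite, c("up", "flat", "down"))
  expect_equal(d$delta, c(0.3, 0, -0.3), tolerance = 1e-12)
  expect_true(all(abs(d$delta) <= 1))
  # identical FC in both types -> all zero, ties broken by id
  fc0 <- fc; fc0$fc <- 0.4
  d0 <- fractional_difference(fc0, type)
  expect_equal(d0$delta, rep(0, 3))
  expect_identical(d0$metabolite, sort(c("up", "flat", "down")))
  # a metabolite absent in one type is excluded with a log entry
  fc_m <- fc[!(fc$metabolite == "down" & type[fc$cell_line] == 2), ]
  dm <- fractional_difference(fc_m, type)
  expect_false("down" %in% dm$metabolite)
  expect_identical(attr(dm, "excluded"), "glc:down")
})

test_that("type means weigh cell lines equally, not replicates", {
  type <- c(A1 = 1, B1 = 2, B2 = 2)
  # A1 has 3 replicates, B1 one, B2 one; replicate imbalance must not
  # tilt the type mean because FCs are averaged per line first
  truth <- list(metabolites = data.frame(metabolite = "m", n_carbons = 2),
                fc = data.frame(metabolite = "m",
                                cell_line = c("A1", "B1", "B2"),
                                tracer = "glc",
                                fc_true = c(0.6, 0.2, 0.4)),
                p_nat = 0)
  mdv <- simulate_mdv(truth, n_replicates = 3, noise = 0, seed = 4)
  mdv <- mdv[!(mdv$cell_line %in% c("B1", "B2") & mdv$replicate > 1), ]
  fc <- compute_fractional_contributions(mdv, correct = FALSE)
  d <- fractional_difference(fc, type)
  expect_equal(d$delta, 0.6 - 0.3, tolerance = 1e-9)
})

test_that("mdv tables round-trip through CSV", {
  truth <- tracer_truth(c(0.3, 0.7), n_carbons = 3)
  mdv <- simulate_mdv(truth, n_replicates = 2, noise = 0.02, seed = 9)
  path <- withr::local_tempfile(fileext = ".csv")
  write_mdv_csv(mdv, path)
  back <- read_mdv_csv(path)
  expect_equal(back$I0, mdv$I0, tolerance = 1e-9)
  expect_identical(back$metabolite, mdv$metabolite)
})

lipid_fixture <- function() {
  species <- data.frame(
    species = c("PC 34:1", "PC 36:4", "TAG 50:1", "LPC 18:0",
                "CL 72:4", "SM 34:1"),
    class = c("PC", "PC", "TAG", "LPC", "CL", "SM"),
    carbons = c(34, 36, 50, 18, 72, 34),
    double_bonds = c(1, 4, 1, 0, 4, 1),
    ether = FALSE)
  samples <- sprintf("s%d", 1:6)
  out <- merge(species, data.frame(sample = samples))
  set.seed(20)
  out$concentration <- rlnorm(nrow(out), 2, 0.2)
  out
}

test_that("unsaturation index is the weighted double-bond-per-chain mean", {
  # single species per class: index equals its double bonds per chain
  lip <- data.frame(species = c("PC a", "TAG b"),
                    class = c("PC", "TAG"),
                    carbons = c(34, 50), double_bonds = c(2, 3),
                    ether = FALSE,
                    sample = "s1", concentration = c(5, 7))
  lip <- rbind(lip, transform(lip, sample = "s2"),
               transform(lip, sample = "s3"),
               transform(lip, sample = "s4"))
  g <- stats::setNames(rep(c("g1", "g2"), each = 2), paste0("s", 1:4))
  res <- lipid_summaries(lip, g)
  expect_equal(unname(res$unsaturation[, "PC"]), rep(2 / 2, 4))
  expect_equal(unname(res$unsaturation[, "TAG"]), rep(3 / 3, 4))
  # 50:50 mix with 0 and 2 double bonds over 2 chains -> index 0.5
  mix <- data.frame(species = c("PC sat", "PC poly"), class = "PC",
                    carbons = 34, double_bonds = c(0, 2), ether = FALSE,
                    sample = "s1", concentration = c(10, 10))
  mix <- rbind(mix, transform(mix, sample = "s2"),
               transform(mix, sample = "s3"),
               transform(mix, sample = "s4"))
  res2 <- lipid_summaries(mix, g)
  expect_equal(unname(res2$unsaturation[, "PC"]), rep(0.5, 4))
  # identical groups: all class-level p = 1
  expect_true(all(res2$class_tests$p_total == 1))
  expect_true(all(na.omit(res2$species_tests$p) == 1))
})

test_that("class totals, chain profile and group tests are computed", {
  lip <- lipid_fixture()
  g <- stats::setNames(rep(c("t1", "t2"), each = 3), sprintf("s%d", 1:6))
  res <- lipid_summaries(lip, g)
  s1 <- lip[lip$sample == "s1", ]
  expect_equal(res$class_totals["s1", "PC"],
               sum(s1$concentration[s1$class == "PC"]))
  expect_setequal(colnames(res$class_totals),
                  c("PC", "TAG", "LPC", "CL", "SM"))
  expect_true(all(res$species_tests$p_adj >= res$species_tests$p,
                  na.rm = TRUE))
  prof <- res$chain_profile
  expect_equal(sum(prof$concentration[prof$sample == "s1"]),
               sum(s1$concentration))
  # chain-count convention fixed by class
  cc <- acyl_chain_counts()
  expect_equal(unname(cc[c("LPC", "PC", "TAG", "CL")]), c(1, 2, 3, 4))
})
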