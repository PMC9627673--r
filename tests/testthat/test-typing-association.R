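# Ward typing, branch enumeration, branch-trait tests, Storey q-values,
# and the global association scan.

test_that("Ward linkage matches a Lance-Williams recursion on 5 points", {
  set.seed(300)
  x <- matrix(rnorm(10), 5, 2, dimnames = list(letters[1:5], NULL))
  tree <- cluster_cell_lines(x)
  # independent oracle: Lance-Williams update on squared Euclidean
  # distances, heights reported on the distance scale
  n <- 5
  D <- as.matrix(dist(x))^2
  size <- rep(1, n); active <- 1:n
  heights <- numeric(n - 1)
  for (s in 1:(n - 1)) {
    sub <- D[active, active]; diag(sub) <- Inf
    ij <- which(sub == min(sub), arr.ind = TRUE)[1, ]
    i <- active[ij[1]]; j <- active[ij[2]]
    heights[s] <- sqrt(D[i, j])
    ni <- size[i]; nj <- size[j]
    for (k in setdiff(active, c(i, j))) {
      nk <- size[k]
      D[i, k] <- D[k, i] <-
        ((ni + nk) * D[i, k] + (nj + nk) * D[j, k] - nk * D[i, j]) /
        (ni + nj + nk)
    }
    size[i] <- ni + nj; active <- setdiff(active, j)
  }
  expect_equal(tree$hclust$height, heights, tolerance = 1e-10)
})

test_that("clustering recovers planted types and refuses missing scores", {
  scr <- simulate_screen(n_lines = 40, seed = 33)
  res <- run_screen_pipeline(scr$table, truth_ion_pathway_map(scr))
  types <- cut_types(res$tree, 2)
  truth <- scr$truth$type
  common <- intersect(names(types), names(truth))
  expect_gte(rand_index(types[common], truth[common]), 0.9)
  bad <- res$scores$scores
  bad[1, 1] <- NA
  expect_error(cluster_cell_lines(bad), "missing")
})

test_that("duplicating every cell line preserves the type partition", {
  set.seed(301)
  m <- matrix(rnorm(12 * 3), 12, 3,
              dimnames = list(sprintf("c%02d", 1:12), NULL))
  m[1:6, 1] <- m[1:6, 1] + 4
  base_types <- cut_types(cluster_cell_lines(m), 2)
  dup <- rbind(m, m)
  rownames(dup) <- c(sprintf("c%02d_a", 1:12), sprintf("c%02d_b", 1:12))
  dup_types <- cut_types(cluster_cell_lines(dup), 2)
  # duplicates land together and the induced partition matches
  expect_equal(unname(dup_types[sprintf("c%02d_a", 1:12)]),
               unname(dup_types[sprintf("c%02d_b", 1:12)]))
  expect_equal(rand_index(unname(dup_types[sprintf("c%02d_a", 1:12)]),
                          unname(base_types)), 1)
})

test_that("branch enumeration applies the ceil(fraction) rule without root", {
  # balanced tree over 32 leaves via perfectly separated clusters
  x <- matrix(0, 32, 1)
  x[, 1] <- rep(c(0, 100, 1e4, 1.01e4, 2e6, 2.01e6, 3e6, 3.01e6),
                each = 4) + rep(1:4, 8)
  rownames(x) <- sprintf("c%02d", 1:32)
  tree <- cluster_cell_lines(x)
  br <- enumerate_branches(tree, min_fraction = 4 / 32)
  # non-root internal branches of size >= 4: 8 + 4 + 2 = 14
  expect_length(br, 14)
  expect_equal(sort(unique(unname(attr(br, "sizes")))), c(4, 8, 16))
  expect_length(enumerate_branches(tree, min_fraction = 1.0), 0)
  # the 10% rule on a 180-line cohort -> minimum branch size 18
  y <- matrix(rnorm(180 * 2), 180, 2,
              dimnames = list(sprintf("c%03d", 1:180), NULL))
  t180 <- cluster_cell_lines(y)
  expect_equal(attr(enumerate_branches(t180, 0.10), "min_size"), 18)
})

test_that("hypergeometric branch test matches the exact example", {
  # population 10, 4 positive, branch of 5 holding all 4
  vals <- stats::setNames(c(rep("yes", 4), rep("no", 6)),
                          sprintf("c%02d", 1:10))
  branch <- sprintf("c%02d", 1:5)
  r <- test_branch_trait(branch, vals, "categorical")
  # enrichment probability C(4,4) C(6,1) / C(10,5) = 6/252, reported
  # with the two-level Bonferroni factor
  expect_equal(r$p, 2 * 6 / 252, tolerance = 1e-12)
  expect_equal(r$direction, 1L)
  # trait positive only outside the branch -> direction -1
  vals2 <- stats::setNames(c(rep("no", 5), rep("yes", 5)),
                           sprintf("c%02d", 1:10))
  r2 <- test_branch_trait(branch, vals2, "categorical")
  expect_equal(r2$direction, -1L)
  expect_identical(r2$level, "yes")
})

test_that("hypergeometric test equals exhaustive enumeration (N <= 12)", {
  set.seed(302)
  for (rep_i in 1:5) {
    N <- sample(6:12, 1)
    K <- sample(2:(N - 2), 1)
    n <- sample(2:(N - 2), 1)
    ids <- sprintf("c%02d", 1:N)
    vals <- stats::setNames(
      sample(c(rep("yes", K), rep("no", N - K))), ids)
    branch <- sample(ids, n)
    k_obs <- sum(vals[branch] == "yes")
    # enumerate all C(N, n) branch draws, count overlap >= observed
    draws <- combn(N, n)
    cnt <- sum(apply(draws, 2, function(ix)
      sum(vals[ids[ix]] == "yes") >= k_obs))
    p_exact <- cnt / ncol(draws)
    got <- stats::phyper(k_obs - 1, K, N - K, n, lower.tail = FALSE)
    expect_equal(got, p_exact, tolerance = 1e-12)
  }
})

test_that("continuous branch test handles nulls, signs and skips", {
  vals <- stats::setNames(c(1, 1, 2, 2, 1, 1, 2, 2),
                          sprintf("c%02d", 1:8))
  # branch and complement identically distributed -> t = 0, p = 1
  r <- test_branch_trait(sprintf("c%02d", c(1, 3, 5, 7)), vals,
                         "continuous")
  expect_equal(r$p, 1)
  vals2 <- stats::setNames(c(5, 6, 7, 1, 2, 3), sprintf("c%02d", 1:6))
  r2 <- test_branch_trait(sprintf("c%02d", 4:6), vals2, "continuous")
  expect_equal(r2$direction, -1L)
  expect_lt(r2$p, 0.05)
  # complement too small -> skipped with reason
  r3 <- test_branch_trait(sprintf("c%02d", 1:5), vals2, "continuous")
  expect_identical(r3$skip, "complement_too_small")
  # the fast path equals the classical pooled-variance t test
  set.seed(303)
  vals3 <- stats::setNames(rnorm(20), sprintf("c%02d", 1:20))
  br <- sprintf("c%02d", 1:8)
  ref <- stats::t.test(vals3[br], vals3[9:20], var.equal = TRUE)$p.value
  expect_equal(test_branch_trait(br, vals3, "continuous")$p, ref)
})

test_that("Storey q-values behave at the null, the boundary and in power", {
  expect_equal(qvalues_storey(rep(1, 50)),
               list(qvalues = rep(1, 50), pi0 = 1))
  set.seed(304)
  for (s in 1:5) {
    p <- runif(10000)
    q <- qvalues_storey(p)
    expect_gt(q$pi0, 0.85)
    expect_lte(q$pi0, 1)
    # q monotone in p
    o <- order(p)
    expect_true(all(diff(q$qvalues[o]) >= -1e-12))
  }
  expect_error(qvalues_storey(numeric(0)))
  expect_error(qvalues_storey(c(0.5, 0)))
})

test_that("q <= 0.10 controls empirical FDP on signal mixtures", {
  set.seed(305)
  fdp <- replicate(50, {
    m <- 2000
    is_signal <- seq_len(m) <= 0.3 * m
    p <- ifelse(is_signal, pmin(rbeta(m, 0.08, 1), 1), runif(m))
    p[p == 0] <- .Machine$double.xmin
    q <- qvalues_storey(p)$qvalues
    hits <- q <= 0.10
    if (!any(hits)) 0 else sum(hits & !is_signal) / sum(hits)
  })
  expect_lte(mean(fdp), 0.15)
})

planted_tree <- function(n = 60, seed = 310) {
  set.seed(seed)
  type <- stats::setNames(rep(1:2, each = n / 2),
                          sprintf("CL%03d", seq_len(n)))
  m <- matrix(rnorm(n * 4), n, 4,
              dimnames = list(names(type), paste0("pw", 1:4)))
  m[, 1] <- m[, 1] + 3 * (type == 1)
  m[, 2] <- m[, 2] - 3 * (type == 1)
  list(tree = cluster_cell_lines(m), type = type)
}

test_that("association scan bookkeeping and null control hold", {
  pt <- planted_tree()
  traits <- simulate_traits(pt$type, 30, 30, n_planted = 0, seed = 11)
  scan <- association_scan(pt$tree, traits, fdr = 0.10)
  n_br <- attr(scan, "n_branches")
  skipped <- attr(scan, "skipped")
  expect_equal(nrow(scan) + if (is.null(skipped)) 0 else nrow(skipped),
               n_br * 60)
  expect_equal(sum(scan$significant), 0)
  expect_gt(attr(scan, "pi0"), 0.85)
  # direction agrees with a naive mean/fraction comparison everywhere
  expect_true(all(scan$direction %in% c(-1L, 1L)))
  cont <- scan[scan$modality == "continuous", ]
  expect_true(all(sign(cont$effect) == cont$direction |
                    cont$effect == 0))
})

test_that("a perfectly aligned planted trait is found on its branch", {
  pt <- planted_tree(seed = 311)
  traits <- simulate_traits(pt$type, 30, 30, n_planted = 1, effect = 6,
                            seed = 12)
  scan <- association_scan(pt$tree, traits, fdr = 0.10)
  hit <- scan[scan$trait_id == "planted_cat0001" & scan$significant, ]
  expect_gt(nrow(hit), 0)
  # at least one significant branch is exactly a planted type
  br <- enumerate_branches(pt$tree, 0.10)
  type_sets <- split(names(pt$type), pt$type)
  jaccard <- function(a, b)
    length(intersect(a, b)) / length(union(a, b))
  match_type <- vapply(hit$branch, function(b)
    any(vapply(type_sets, jaccard, numeric(1), b = br[[b]]) >= 0.9),
    logical(1))
  expect_true(any(match_type))
})

test_that("p-values are pooling-invariant, q-values are not promised to be", {
  pt <- planted_tree(seed = 312)
  traits <- simulate_traits(pt$type, 10, 10, n_planted = 1, effect = 4,
                            seed = 13)
  full <- association_scan(pt$tree, traits, fdr = 0.10)
  keep <- unique(full$trait_id)[1:8]
  sub <- association_scan(pt$tree,
                          traits[traits$trait_id %in% keep, ],
                          fdr = 0.10)
  merged <- merge(full[full$trait_id %in% keep,
                       c("branch", "trait_id", "p")],
                  sub[, c("branch", "trait_id", "p")],
                  by = c("branch", "trait_id"))
  expect_equal(merged$p.x, merged$p.y, tolerance = 1e-12)
})

test_that("newick export labels branches consistently with enumeration", {
  pt <- planted_tree(n = 12, seed = 313)
  path <- withr::local_tempfile(fileext = ".nwk")
  write_tree_newick(pt$tree, path)
  phy <- ape::read.tree(path)
  expect_setequal(phy$tip.label, names(pt$type))
  br <- enumerate_branches(pt$tree, min_fraction = 2 / 12)
  for (b in names(br)) {
    nd <- which(phy$node.label == b) + length(phy$tip.label)
    tips <- ape::extract.clade(phy, nd)$tip.label
    expect_setequal(tips, br[[b]])
  }
})
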