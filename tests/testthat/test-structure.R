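test_that("AMOVA sums of squares decompose exactly and F_ST hits its bounds", {
  fx <- two_pop_fixture()
  am <- amova(fx$g, fx$pops, n_perm = 200, seed = 1)
  # populations fixed for different alleles: maximal differentiation
  expect_equal(am$fst, 1)
  expect_equal(unname(am$percent["among"]), 100, tolerance = 1e-9)
  expect_lt(am$p, 0.05)
  # SS_total = SS_among + SS_within on every locus
  comp <- am$components
  expect_equal(comp[, "ss_t"], comp[, "ss_a"] + comp[, "ss_w"],
               tolerance = 1e-12)
  # an identical duplicated population: SS_among is exactly zero and the
  # unbiased components give the small negative -1/(n' - 1) = -1/7 here
  calls <- list(c(1L, 1L), c(1L, 2L), c(2L, 2L), c(1L, 2L))
  gd <- toy_genotypes(c(calls, calls))
  pd <- population_map(gd$ind, rep(c("pA", "pB"), each = 4))
  am0 <- amova(gd, pd, n_perm = 50, seed = 1)
  expect_equal(unname(am0$components[, "ss_a"]), 0, tolerance = 1e-12)
  expect_equal(am0$fst, -1 / 7, tolerance = 1e-9)
  expect_gt(am0$p, 0.2)
})

test_that("panmictic samples give near-zero F_ST and calm p-values", {
  set.seed(31)
  fst <- numeric(6); pv <- numeric(6)
  for (r in 1:6) {
    n <- 40
    a1 <- matrix(sample(1:5, 3 * n, TRUE), n, 3)
    a2 <- matrix(sample(1:5, 3 * n, TRUE), n, 3)
    g <- genotypes(a1, a2, paste0("i", 1:n), toy_panel(3))
    pops <- population_map(g$ind, rep(c("x", "y"), each = n / 2))
    am <- amova(g, pops, n_perm = 60, seed = r)
    fst[r] <- am$fst; pv[r] <- am$p
  }
  expect_lt(max(abs(fst)), 0.06)
  expect_gt(mean(pv), 0.2)
})

test_that("populations of one are excluded and relabeling changes nothing", {
  x <- random_genotypes(41, n_ind = 9, miss = 0)
  pops <- population_map(x$genotypes$ind,
                         c(rep("a", 4), rep("b", 4), "single"))
  expect_warning(am <- amova(x$genotypes, pops, n_perm = 0), "single")
  # permutation p-values and estimates are invariant to relabeling
  x2 <- random_genotypes(42, n_ind = 12, miss = 0)
  am1 <- amova(x2$genotypes, x2$pops, n_perm = 100, seed = 7)
  relab <- population_map(x2$genotypes$ind,
                          c(P1 = "north", P2 = "south")[
                            paste0("P", as.integer(x2$pops))])
  am2 <- amova(x2$genotypes, relab, n_perm = 100, seed = 7)
  expect_equal(am1$fst, am2$fst)
  expect_equal(am1$p, am2$p)
})

test_that("pairwise F_ST of two populations equals the two-pop AMOVA", {
  x <- random_genotypes(51, n_ind = 12, miss = 0.05)
  pw <- pairwise_fst(x$genotypes, x$pops, n_perm = 0)
  am <- amova(x$genotypes, x$pops, n_perm = 0)
  expect_equal(pw$fst["p1", "p2"], am$fst)
  expect_equal(diag(pw$fst), c(p1 = 0, p2 = 0))
  # fixed difference pair
  fx <- two_pop_fixture()
  pwf <- pairwise_fst(fx$g, fx$pops, n_perm = 0)
  expect_equal(pwf$fst["pA", "pB"], 1)
})

test_that("DAPC separates synthetic clusters and assigns them confidently", {
  set.seed(61)
  n <- 20
  # two clusters with fixed allele differences at 4 loci
  a_a <- matrix(sample(1:2, 4 * n, TRUE), n, 4)
  b_a <- matrix(sample(5:6, 4 * n, TRUE), n, 4)
  g <- genotypes(rbind(a_a, b_a), rbind(a_a, b_a),
                 paste0("i", 1:(2 * n)), toy_panel(4))
  grp <- rep(c("A", "B"), each = n)
  d <- dapc(g, groups = grp, n_pca = 5, seed = 1)
  expect_true(all(rowSums(d$posterior) - 1 < 1e-9))
  expect_true(all(d$posterior[cbind(seq_len(2 * n),
                                    as.integer(factor(grp)))] > 0.99))
  # the first discriminant axis separates the clusters completely
  expect_true(max(d$coords[1:n, 1]) < min(d$coords[(n + 1):(2 * n), 1]) ||
                min(d$coords[1:n, 1]) > max(d$coords[(n + 1):(2 * n), 1]))
  # without priors, k-means + BIC recovers two clusters
  d2 <- dapc(g, groups = NULL, n_pca = 5, k_max = 6, seed = 2)
  expect_equal(d2$k, 2L)
})

test_that("DAPC flags a single panmictic population as unstructured", {
  set.seed(71)
  n <- 40
  a1 <- matrix(sample(1:4, 6 * n, TRUE), n, 6)
  a2 <- matrix(sample(1:4, 6 * n, TRUE), n, 6)
  g <- genotypes(a1, a2, paste0("i", 1:n), toy_panel(6))
  d <- dapc(g, groups = NULL, n_pca = 4, k_max = 5, seed = 3)
  expect_true(d$no_structure)
  expect_equal(d$k, 1L)
})

test_that("duplicated individuals land on coincident DAPC coordinates", {
  set.seed(81)
  n <- 10
  a1 <- matrix(sample(1:3, 3 * n, TRUE), n, 3)
  a2 <- matrix(sample(1:3, 3 * n, TRUE), n, 3)
  g <- genotypes(rbind(a1, a1), rbind(a2, a2), paste0("i", 1:(2 * n)),
                 toy_panel(3))
  grp <- rep(c("g1", "g2"), n)  # both groups contain both copies
  # copies i and i+n have identical dosage rows, hence identical
  # coordinates under any projection
  dd <- dapc(g, groups = grp, n_pca = 4)
  expect_equal(dd$coords[1:n, , drop = FALSE],
               dd$coords[(n + 1):(2 * n), , drop = FALSE],
               ignore_attr = TRUE)
})
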