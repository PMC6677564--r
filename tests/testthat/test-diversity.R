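test_that("allele frequencies count each gene copy once and skip missing", {
  g <- toy_genotypes(list(c(1L, 1L), c(1L, 2L)))
  fr <- allele_frequencies(g)
  expect_equal(unname(fr$L1$freq), c(0.75, 0.25))
  expect_equal(fr$L1$n_genes, 4L)
  # all-missing locus is flagged, no frequencies
  gm <- toy_genotypes(list(c(NA, NA), c(NA, NA)))
  expect_equal(allele_frequencies(gm)$L1$n_genes, 0L)
  # independent tally oracle on a random matrix
  x <- random_genotypes(21)
  fr <- allele_frequencies(x$genotypes)
  for (l in seq_len(n_loci(x$genotypes))) {
    v <- c(x$genotypes$a1[, l], x$genotypes$a2[, l])
    v <- v[!is.na(v)]
    brute <- table(v) / length(v)
    expect_equal(unname(fr[[l]]$freq), as.numeric(brute))
  }
})

test_that("gene diversity matches the closed form and a pairwise oracle", {
  # two alleles at 0.5 with 10 gene copies: 10/9 * 0.5
  g <- toy_genotypes(list(c(1L, 2L), c(1L, 2L), c(1L, 2L), c(1L, 2L),
                          c(1L, 2L)))
  expect_equal(unname(gene_diversity(allele_frequencies(g))), 10 / 9 * 0.5,
               tolerance = 1e-12)
  # monomorphic locus
  gm <- toy_genotypes(list(c(3L, 3L), c(3L, 3L)))
  expect_equal(unname(gene_diversity(allele_frequencies(gm))), 0)
  # brute force: probability that two gene copies drawn without replacement
  # differ, over all pairs
  x <- random_genotypes(31, n_ind = 8, n_loci = 3, miss = 0)
  fr <- allele_frequencies(x$genotypes)
  gd <- gene_diversity(fr)
  for (l in 1:3) {
    v <- c(x$genotypes$a1[, l], x$genotypes$a2[, l])
    diffs <- outer(v, v, "!=")
    brute <- mean(diffs[upper.tri(diffs)])
    expect_equal(unname(gd[l]), brute, tolerance = 1e-12)
  }
})

test_that("PIC follows its definition and never exceeds plug-in He", {
  g <- toy_genotypes(list(c(1L, 2L), c(1L, 2L)))
  expect_equal(unname(pic(allele_frequencies(g))), 0.375)
  gm <- toy_genotypes(list(c(3L, 3L), c(3L, 3L)))
  expect_equal(unname(pic(allele_frequencies(gm))), 0)
  # 4 equifrequent alleles: 1 - 1/4 - 2 C(4,2) (1/16)^2
  g4 <- toy_genotypes(list(c(1L, 2L), c(3L, 4L)))
  expect_equal(unname(pic(allele_frequencies(g4))),
               1 - 0.25 - 2 * choose(4, 2) * (1 / 16)^2)
  # invariant on random data
  x <- random_genotypes(41)
  fr <- allele_frequencies(x$genotypes)
  he_plug <- gene_diversity(fr, unbiased = FALSE)
  expect_true(all(pic(fr) <= he_plug + 1e-12, na.rm = TRUE))
})

test_that("rarefied allelic richness equals exhaustive subset enumeration", {
  expect_equal(allelic_richness(c(9, 1), 2), 1.2)
  # enumeration oracle: mean number of distinct alleles over all g-subsets
  cnt <- c(5, 3, 2)
  genes <- rep(1:3, cnt)
  for (g in 2:4) {
    subs <- utils::combn(length(genes), g)
    brute <- mean(apply(subs, 2, function(ix) length(unique(genes[ix]))))
    expect_equal(allelic_richness(cnt, g), brute, tolerance = 1e-12)
  }
  # monomorphic locus gives 1 for any g; g = N returns the allele count
  expect_equal(allelic_richness(c(10), 4), 1)
  expect_equal(allelic_richness(cnt, sum(cnt)), 3)
  # monotone non-decreasing in g
  ar <- vapply(2:10, function(g) allelic_richness(cnt, g), numeric(1))
  expect_true(all(diff(ar) >= -1e-12))
})

test_that("F_IS hits the heterozygote-excess bound and is null under HWE", {
  # all heterozygotes: F_IS = -1
  g <- toy_genotypes(list(c(1L, 2L), c(1L, 2L), c(1L, 2L), c(1L, 2L)))
  pops <- population_map(g$ind, rep("p1", 4))
  f <- f_is(g, pops, n_perm = 0)
  expect_equal(unname(f$per_locus), -1)
  # large sample at HWE proportions: F_IS near 0
  set.seed(61)
  n <- 400
  a1 <- matrix(sample(1:4, 2 * n, TRUE), n, 2)
  a2 <- matrix(sample(1:4, 2 * n, TRUE), n, 2)
  gh <- genotypes(a1, a2, paste0("i", 1:n), toy_panel(2))
  fh <- f_is(gh, population_map(gh$ind, rep("p", n)), n_perm = 200, seed = 2)
  expect_lt(abs(fh$overall), 0.06)
  expect_gt(fh$p_overall, 0.05)
})

test_that("null-allele estimators follow their closed forms", {
  # He = Ho gives 0 by both
  g <- toy_genotypes(list(c(1L, 2L), c(1L, 2L)))
  na <- null_allele_frequency(g)
  expect_equal(na$chakraborty, (na$He - na$Ho) / (na$He + na$Ho))
  # direct evaluation at He = 0.5, Ho = 0.4
  expect_equal((0.5 - 0.4) / (0.5 + 0.4), 0.1111, tolerance = 1e-3)
  x <- random_genotypes(71, n_ind = 20, miss = 0)
  na <- null_allele_frequency(x$genotypes)
  expect_equal(na$chakraborty, (na$He - na$Ho) / (na$He + na$Ho))
  expect_equal(na$brookfield, (na$He - na$Ho) / (1 + na$He))
})

test_that("exact HWE test reproduces the full Levene enumeration", {
  # 3 AA / 0 AB / 3 BB with margins (6, 6): the only table with probability
  # at most the observed is itself, so p = 20/924
  g <- toy_genotypes(list(c(1L, 1L), c(1L, 1L), c(1L, 1L),
                          c(2L, 2L), c(2L, 2L), c(2L, 2L)))
  h <- hwe_exact_test(g)
  expect_equal(h$p, 20 / 924, tolerance = 1e-12)
  expect_equal(h$method, "exact enumeration")
  expect_equal(h$direction, "deficit")
  # Monte-Carlo branch agrees with the enumeration on the same data
  hmc <- hwe_exact_test(g, enum_cap = 0, n_mc = 20000, seed = 9)
  expect_equal(hmc$p, 20 / 924, tolerance = 0.25)
  expect_equal(hmc$method, "monte carlo")
  # monomorphic locus: p = 1, flagged not testable
  gm <- toy_genotypes(list(c(3L, 3L), c(3L, 3L), c(3L, 3L)))
  hm <- hwe_exact_test(gm)
  expect_equal(hm$p, 1)
  expect_match(hm$method, "not testable")
  # enumeration probabilities sum to 1 over the state space
  tot <- 0
  edgepop:::enumerate_levene(c(6L, 6L), function(lp) tot <<- tot + exp(lp))
  expect_equal(tot, 1, tolerance = 1e-12)
})

test_that("HWE p is near 1 for large samples at equilibrium proportions", {
  set.seed(81)
  n <- 150
  a1 <- matrix(sample(1:2, n, TRUE, prob = c(0.6, 0.4)), n, 1)
  a2 <- matrix(sample(1:2, n, TRUE, prob = c(0.6, 0.4)), n, 1)
  g <- genotypes(a1, a2, paste0("i", 1:n), toy_panel(1))
  h <- hwe_exact_test(g, n_mc = 5000, seed = 3)
  expect_gt(h$p, 0.2)
})

test_that("Bonferroni calls use the family-size-adjusted threshold", {
  expect_true(bonferroni(0.004, m = 10))
  expect_false(bonferroni(0.006, m = 10))
  expect_equal(bonferroni(c(0.04, 0.06), m = 1), c(TRUE, FALSE))
  expect_error(bonferroni(numeric(0)), "no p-values")
})

test_that("genotypic LD test flags duplicated loci and skips degenerate input", {
  set.seed(91)
  n <- 30  # few allele states, so genotype classes repeat
  a1 <- matrix(sample(1:2, n, TRUE), n, 1)
  a2 <- matrix(sample(1:2, n, TRUE), n, 1)
  g1 <- genotypes(a1, a2, paste0("i", 1:n), toy_panel(1))
  pops <- population_map(g1$ind, rep(c("p1", "p2"), each = n / 2))
  # duplicate the locus column: maximal association
  g2 <- genotypes(cbind(g1$a1, g1$a1), cbind(g1$a2, g1$a2), g1$ind,
                  locus_panel(2, motif_length = 1, amin = 0, amax = 30))
  ld <- genotypic_ld_test(g2, pops, n_perm = 200, seed = 4)
  expect_equal(ld$p, 1 / 201, tolerance = 1e-12)
  # a single polymorphic locus yields an empty result
  mono <- genotypes(cbind(g1$a1, 7L), cbind(g1$a2, 7L), g1$ind,
                    locus_panel(2, motif_length = 1, amin = 0, amax = 30))
  expect_equal(nrow(genotypic_ld_test(mono, pops, n_perm = 50)), 0L)
})

test_that("independently generated loci give non-extreme LD p-values", {
  set.seed(101)
  ps <- replicate(8, {
    x <- random_genotypes(sample.int(1e6, 1), n_ind = 20, n_loci = 2,
                          miss = 0)
    genotypic_ld_test(x$genotypes, x$pops, n_perm = 60, seed = 5)$p
  })
  expect_gt(mean(ps), 0.2)  # uniform-ish, not systematically significant
})

test_that("private alleles match a set-membership oracle", {
  g <- toy_genotypes(list(c(1L, 2L), c(1L, 1L), c(1L, 3L), c(1L, 3L)))
  pops <- population_map(g$ind, c("p1", "p1", "p2", "p2"))
  e <- private_alleles(g, pops)
  expect_equal(unname(e), c(1L, 1L))  # allele 2 private to p1, 3 to p2
  # all alleles shared
  gs <- toy_genotypes(list(c(1L, 2L), c(1L, 2L)))
  expect_equal(unname(private_alleles(
    gs, population_map(gs$ind, c("a", "b")))), c(0L, 0L))
  # brute force on random data
  x <- random_genotypes(111, n_ind = 16, miss = 0.05)
  e <- private_alleles(x$genotypes, x$pops)
  brute <- stats::setNames(integer(2), levels(x$pops))
  for (l in seq_len(n_loci(x$genotypes))) {
    sets <- lapply(c("p1", "p2"), function(p) {
      idx <- which(x$pops == p)
      v <- c(x$genotypes$a1[idx, l], x$genotypes$a2[idx, l])
      unique(v[!is.na(v)])
    })
    brute["p1"] <- brute["p1"] + length(setdiff(sets[[1]], sets[[2]]))
    brute["p2"] <- brute["p2"] + length(setdiff(sets[[2]], sets[[1]]))
  }
  expect_equal(e, brute)
})

test_that("the diversity summary table keeps its internal consistency", {
  x <- random_genotypes(121, n_ind = 14, miss = 0.05)
  ds <- diversity_stats(x$genotypes, x$pops, n_perm = 100, seed = 6)
  tab <- ds$per_locus
  expect_true(all(tab$GD >= 0 & tab$GD <= 1, na.rm = TRUE))
  expect_true(all(tab$PIC <= tab$He + 1e-12, na.rm = TRUE))
  expect_true(all(tab$AR <= tab$A + 1e-9, na.rm = TRUE))
  expect_true(all(tab$F_IS >= -1 & tab$F_IS <= 1, na.rm = TRUE))
})
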