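test_that("pairwise TMRCA matches coalescent expectations", {
  set.seed(1)
  # constant size: E[TMRCA] = 2N for two gene copies
  t2 <- replicate(2000, sim_tmrca(2, list(start = 0, N = 1000)))
  se <- sd(t2) / sqrt(length(t2))
  expect_lt(abs(mean(t2) - 2000), 3 * se)
  # a size change at time 0 reduces to the constant small-size case
  t3 <- replicate(2000, sim_tmrca(2, list(start = c(0, 0), N = c(100, 100))))
  expect_lt(abs(mean(t3) - 200), 3 * sd(t3) / sqrt(2000))
})

test_that("two-epoch TMRCA distribution matches an independent R oracle", {
  # oracle: piecewise-exponential inverse-cdf simulation of the pairwise
  # coalescence time under (N1 until t, then N2)
  oracle <- function(n, N1, N2, t) {
    u <- runif(n)
    # survival: exp(-tau/(2 N1)) for tau <= t, then exp(-t/(2N1) - (tau-t)/(2N2))
    tau <- -2 * N1 * log(u)
    deep <- tau > t
    tau[deep] <- t + (-2 * N2 * (log(u[deep]) + t / (2 * N1)))
    tau
  }
  set.seed(2)
  sim <- replicate(2500, sim_tmrca(2, list(start = c(0, 400),
                                           N = c(200, 2000))))
  ora <- oracle(2500, 200, 2000, 400)
  ks <- suppressWarnings(stats::ks.test(sim, ora))
  expect_gt(ks$p.value, 0.001)
})

test_that("GSM branch displacement matches the event-level law", {
  # event-level oracle: m signed jumps of 1 + Geometric(p)
  set.seed(3)
  m <- 7; p <- 0.3
  events <- replicate(20000,
                      sum(sample(c(-1, 1), m, TRUE) * (1 + rgeom(m, p))))
  compound <- replicate(20000, edgepop:::gsm_displacement(m, p))
  v_theory <- m * ((1 - p) / p^2 + 1 / p^2)  # m * E[(1 + G)^2]
  expect_lt(abs(mean(compound)), 0.15)
  expect_equal(var(compound), v_theory, tolerance = 0.05)
  expect_equal(var(events), var(compound), tolerance = 0.05)
})

test_that("zero mutation rate freezes all tips at the root allele", {
  ss <- scenario_set(locus_panel(3), n_ind = 10)
  set.seed(4)
  g <- sim_dataset(ss, 1, list(Ne = 500),
                   mutation = list(mu = rep(0, 3), gsm_p = rep(0.5, 3)))
  s <- abc_summary_stats(g)
  expect_equal(unname(s), c(1, 0, 0, 1))
  mid <- (ss$panel$amin[1] + ss$panel$amax[1]) %/% 2
  expect_true(all(g$a1 == mid))
})

test_that("simulation is deterministic under a fixed seed", {
  ss <- scenario_set(locus_panel(4), n_ind = 15)
  p <- list(Ne2 = 300, Na2 = 60000, t = 800)
  set.seed(99); g1 <- sim_dataset(ss, 2, p)
  set.seed(99); g2 <- sim_dataset(ss, 2, p)
  expect_identical(g1$a1, g2$a1)
  expect_identical(g1$a2, g2$a2)
})

test_that("summary statistics follow their hand-computed conventions", {
  # one locus, gene copies {10, 10, 12, 14}: A = 3, variance (denominator n)
  # = 2.75, M = 3 / (4 + 1) = 0.6
  g <- toy_genotypes(list(c(10L, 10L), c(12L, 14L)))
  s <- abc_summary_stats(g)
  expect_equal(unname(s["mean_A"]), 3)
  expect_equal(unname(s["mean_size_var"]), 2.75)
  expect_equal(unname(s["mean_M"]), 0.6)
  # monomorphic dataset
  gm <- toy_genotypes(list(c(5L, 5L), c(5L, 5L)))
  expect_equal(unname(abc_summary_stats(gm)), c(1, 0, 0, 1))
  # cross-oracle against the diversity module on simulated data
  ss <- scenario_set(locus_panel(5), n_ind = 20)
  set.seed(5)
  gs <- sim_dataset(ss, 1, list(Ne = 2000))
  s2 <- abc_summary_stats(gs)
  fr <- allele_frequencies(gs)
  expect_equal(unname(s2["mean_A"]),
               mean(vapply(fr, function(e) length(e$freq), numeric(1))))
  expect_equal(unname(s2["mean_GD"]), mean(gene_diversity(fr)))
})

test_that("a bottleneck depresses allele counts and the M index", {
  ss <- scenario_set(locus_panel(8), n_ind = 25)
  mut <- list(mu = rep(1e-3, 8), gsm_p = rep(0.3, 8))
  set.seed(6)
  bt <- replicate(25, edgepop:::sim_stats(
    ss, 2, list(Ne2 = 100, Na2 = 80000, t = 1500), mutation = mut))
  ct <- replicate(25, edgepop:::sim_stats(
    ss, 1, list(Ne = 80000), mutation = mut))
  expect_lt(mean(bt["mean_A", ]), mean(ct["mean_A", ]))
  expect_lt(mean(bt["mean_M", ]), mean(ct["mean_M", ]))
})

test_that("prior draws respect bounds, constraints and uniformity", {
  ss <- scenario_set(locus_panel(2), n_ind = 10)
  d4 <- sample_prior(ss, 4, 2000)
  expect_true(all(d4$t1 < d4$t2))
  expect_true(all(d4$Nb < d4$Ne4 & d4$Nb < d4$Na4))
  d2 <- sample_prior(ss, 2, 2000)
  expect_true(all(d2$Ne2 < d2$Na2))
  pr <- ss$priors
  expect_true(all(d2$Ne2 >= pr$N_small[1] & d2$Ne2 <= pr$N_small[2]))
  expect_true(all(d2$Na2 >= pr$N_large[1] & d2$Na2 <= pr$N_large[2]))
  # an unconstrained marginal is uniform (Kolmogorov-Smirnov)
  set.seed(7)
  d1 <- sample_prior(ss, 1, 5000)
  ks <- suppressWarnings(stats::ks.test(d1$Ne, "punif", pr$N[1], pr$N[2]))
  expect_gt(ks$p.value, 0.001)
  # degenerate prior: constant draws
  ssd <- scenario_set(locus_panel(2), 10,
                      default_priors(N_bounds = c(100, 100.000001)))
  expect_equal(sample_prior(ssd, 1, 5)$Ne, rep(100, 5), tolerance = 1e-6)
})

test_that("allele-range folding keeps simulated alleles inside the panel", {
  ss <- scenario_set(locus_panel(3, amin = 10, amax = 20), n_ind = 20)
  set.seed(8)
  g <- sim_dataset(ss, 1, list(Ne = 50000),
                   mutation = list(mu = rep(5e-3, 3), gsm_p = rep(0.2, 3)))
  expect_true(all(g$a1 >= 10 & g$a1 <= 20))
  set.seed(8)
  gc <- sim_dataset(ss, 1, list(Ne = 50000),
                    mutation = list(mu = rep(5e-3, 3), gsm_p = rep(0.2, 3)),
                    boundary = "clamp")
  expect_true(all(gc$a1 >= 10 & gc$a1 <= 20))
})
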