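# hand-built reference table: four well-separated scenario clusters in
# summary-statistic space
fake_ref <- function(n_per = 200, sep = 6, noise = 0.3, seed = 1) {
  set.seed(seed)
  centers <- rbind(c(2, 0.2, 5, 0.9), c(6, 0.6, 20, 0.4),
                   c(10, 0.8, 40, 0.7), c(14, 0.95, 60, 0.2))
  centers[, 1] <- centers[, 1] * sep / 6
  stats <- do.call(rbind, lapply(1:4, function(s)
    sweep(matrix(rnorm(n_per * 4, sd = noise), n_per, 4), 2,
          centers[s, ], "+")))
  colnames(stats) <- c("mean_A", "mean_GD", "mean_size_var", "mean_M")
  ss <- scenario_set(locus_panel(3), n_ind = 10)
  params <- data.frame(Ne = NA_real_, Ne2 = runif(4 * n_per, 10, 1e4),
                       Na2 = runif(4 * n_per, 1e4, 5e5),
                       t = runif(4 * n_per, 10, 5e4),
                       Ne3 = NA_real_, Na3 = NA_real_, Ne4 = NA_real_,
                       Nb = NA_real_, Na4 = NA_real_, t1 = NA_real_,
                       t2 = NA_real_)
  structure(list(stats = stats, scenario = rep(1:4, each = n_per),
                 params = params,
                 center = apply(stats, 2, median),
                 scale = apply(stats, 2, mad), ss = ss, seed = seed),
            class = "abc_ref")
}

test_that("direct and logistic model choice behave on separable clusters", {
  ref <- fake_ref()
  obs <- c(mean_A = 6, mean_GD = 0.6, mean_size_var = 20, mean_M = 0.4)
  fit <- abc_fit(obs, ref, k_direct = 50, k_logistic = 400, k_est = 100)
  expect_equal(unname(fit$direct["scenario2"]), 1)
  expect_gt(fit$logistic$prob["scenario2"], 0.95)
  expect_equal(sum(fit$direct), 1, tolerance = 1e-9)
  expect_equal(sum(fit$logistic$prob), 1, tolerance = 1e-9)
  expect_equal(fit$best_scenario, 2L)
})

test_that("shuffled scenario labels give near-uniform probabilities", {
  ref <- fake_ref(seed = 2)
  set.seed(3)
  ref$scenario <- sample(ref$scenario)
  obs <- c(mean_A = 6, mean_GD = 0.6, mean_size_var = 20, mean_M = 0.4)
  fit <- abc_fit(obs, ref, k_direct = 200, k_logistic = 800, k_est = 100)
  expect_true(all(abs(fit$direct - 0.25) < 0.12))
  expect_true(all(abs(fit$logistic$prob - 0.25) < 0.12))
})

test_that("probabilities are invariant to a monotone rescaling of a statistic", {
  ref <- fake_ref(seed = 4)
  obs <- c(mean_A = 6, mean_GD = 0.6, mean_size_var = 20, mean_M = 0.4)
  fit1 <- abc_fit(obs, ref, k_direct = 50, k_logistic = 400, k_est = 100)
  ref2 <- ref
  ref2$stats[, "mean_size_var"] <- ref2$stats[, "mean_size_var"] * 37
  ref2$center <- apply(ref2$stats, 2, median)
  ref2$scale <- apply(ref2$stats, 2, mad)
  obs2 <- obs; obs2["mean_size_var"] <- obs2["mean_size_var"] * 37
  fit2 <- abc_fit(obs2, ref2, k_direct = 50, k_logistic = 400, k_est = 100)
  expect_equal(fit1$direct, fit2$direct, tolerance = 1e-9)
  expect_equal(fit1$logistic$prob, fit2$logistic$prob, tolerance = 1e-4)
})

test_that("as k grows the direct estimate approaches the prior proportions", {
  ref <- fake_ref(seed = 5)
  obs <- c(mean_A = 6, mean_GD = 0.6, mean_size_var = 20, mean_M = 0.4)
  fit <- abc_fit(obs, ref, k_direct = nrow(ref$stats), k_logistic = 400,
                 k_est = 100)
  expect_equal(unname(fit$direct), rep(0.25, 4), tolerance = 1e-9)
})

test_that("zero-information statistics reproduce the rejection posterior", {
  ref <- fake_ref(seed = 6)
  # make every scenario-2 row's statistics identical to the observation:
  # the local regression has nothing to correct
  obs <- c(mean_A = 6, mean_GD = 0.6, mean_size_var = 20, mean_M = 0.4)
  rows <- ref$scenario == 2
  ref$stats[rows, ] <- matrix(obs, sum(rows), 4, byrow = TRUE)
  est <- abc_estimate(obs, ref, scenario_id = 2, k_est = 100)
  # adjusted draws equal the accepted draws (up to the logit clamp)
  expect_equal(sort(est$samples$Ne2), sort(ref$params$Ne2[rows][1:100]),
               tolerance = 1e-6)
})

test_that("local-linear adjustment sharpens a linear toy model", {
  set.seed(7)
  n <- 2000
  th <- runif(n, 10, 1e4)          # acts as Ne2 under its prior
  stats <- cbind(mean_A = th / 1e3 + rnorm(n, sd = 0.05),
                 mean_GD = 0.5, mean_size_var = 10, mean_M = 0.5)
  ss <- scenario_set(locus_panel(3), n_ind = 10)
  params <- data.frame(Ne = NA_real_, Ne2 = th, Na2 = 2e5, t = 100,
                       Ne3 = NA_real_, Na3 = NA_real_, Ne4 = NA_real_,
                       Nb = NA_real_, Na4 = NA_real_, t1 = NA_real_,
                       t2 = NA_real_)
  ref <- structure(list(stats = stats, scenario = rep(2L, n),
                        params = params, center = apply(stats, 2, median),
                        scale = apply(stats, 2, mad), ss = ss, seed = 7),
                   class = "abc_ref")
  truth <- 4000
  obs <- c(mean_A = truth / 1e3, mean_GD = 0.5, mean_size_var = 10,
           mean_M = 0.5)
  est <- suppressWarnings(abc_estimate(obs, ref, 2, k_est = 500))
  w <- est$weights
  post_mean <- sum(est$samples$Ne2 * w) / sum(w)
  # rejection-only posterior mean over the same accepted rows
  dd <- edgepop:::ref_distances(ref, obs, warn = FALSE)
  acc <- order(dd$d)[1:500]
  rej_mean <- mean(th[acc])
  expect_lt(abs(post_mean - truth), abs(rej_mean - truth) + 30)
  expect_lt(abs(post_mean - truth), 150)
  s <- est$summary[est$summary$parameter == "Ne2", ]
  expect_true(s$q050 <= truth && truth <= s$q950)
  # the adjusted interval is tighter than the rejection interval
  expect_lt(s$q950 - s$q050, diff(quantile(th[acc], c(0.05, 0.95))))
})

test_that("posterior model checking flags statistics outside the envelope", {
  ss <- scenario_set(locus_panel(4), n_ind = 12)
  ref <- build_reference_table(ss, 400, seed = 8)
  set.seed(9)
  g <- sim_dataset(ss, 2, list(Ne2 = 200, Na2 = 50000, t = 2000))
  fit <- abc_fit(abc_summary_stats(g), ref, k_direct = 20,
                 k_logistic = 300, k_est = 100)
  ppc <- posterior_model_check(fit, ref, n_ppc = 60, seed = 10)
  expect_equal(nrow(ppc), 4)
  expect_true(all(ppc$tail_prob >= 0 & ppc$tail_prob <= 1))
  # an absurdly inflated observation lands in a tail and is flagged
  fit2 <- fit
  fit2$obs["mean_size_var"] <- 1e6
  ppc2 <- posterior_model_check(fit2, ref, n_ppc = 60, seed = 10)
  expect_true(ppc2$flagged[ppc2$statistic == "mean_size_var"])
  expect_equal(ppc2$tail_prob[ppc2$statistic == "mean_size_var"], 1)
  # degenerate single replicate emits a warning and a {0, 1} tail
  expect_warning(ppc3 <- posterior_model_check(fit, ref, n_ppc = 1,
                                               seed = 11), "degenerate")
  expect_true(all(ppc3$tail_prob %in% c(0, 1)))
})

test_that("reference tables are reproducible and scenario-stamped", {
  ss <- scenario_set(locus_panel(3), n_ind = 8)
  r1 <- build_reference_table(ss, 10, seed = 12)
  r2 <- build_reference_table(ss, 10, seed = 12)
  expect_identical(r1$stats, r2$stats)
  expect_identical(r1$params, r2$params)
  expect_equal(nrow(r1$stats), 40L)
  expect_equal(as.integer(table(r1$scenario)), rep(10L, 4))
  expect_false(any(!is.finite(r1$stats)))
})

test_that("bottlenecked reference rows show the Garza-Williamson signature", {
  ss <- scenario_set(locus_panel(4), n_ind = 15)
  ref <- build_reference_table(ss, 400, seed = 13)
  # recent, deep bottlenecks from a large ancestral pool versus
  # constant-size histories of comparable ancestral scale
  sel2 <- ref$scenario == 2 & ref$params$Na2 > 1e5 & ref$params$t < 5000
  sel1 <- ref$scenario == 1 & ref$params$Ne > 1e5
  m2 <- mean(ref$stats[sel2, "mean_M"])
  m1 <- mean(ref$stats[sel1, "mean_M"])
  expect_gt(sum(sel2), 10); expect_gt(sum(sel1), 10)
  expect_lt(m2, m1)
  expect_lt(mean(ref$stats[sel2, "mean_A"]),
            mean(ref$stats[sel1, "mean_A"]))
})
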