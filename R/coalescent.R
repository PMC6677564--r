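## Single-population coalescent under four demographic scenarios with the
## generalized stepwise mutation model (GSM).

#' Define a microsatellite locus panel
#'
#' @param n_loci number of loci.
#' @param motif_length bp per repeat unit (recycled).
#' @param amin,amax allele range in repeat units (recycled). The default
#'   40-state range matches common practice for simulated microsatellites.
#' @param names locus names.
#' @return a locus panel data frame usable as the `loci` slot of
#'   [genotypes()].
#' @export
locus_panel <- function(n_loci, motif_length = 2L, amin = 10L, amax = 49L,
                        names = paste0("L", seq_len(n_loci))) {
  data.frame(name = names,
             motif_length = rep_len(as.integer(motif_length), n_loci),
             amin = rep_len(as.integer(amin), n_loci),
             amax = rep_len(as.integer(amax), n_loci),
             offset = 0L)
}

#' Default priors for the demographic and mutational parameters
#'
#' All demographic priors are uniform. Effective sizes are diploid
#' individuals, times are generations (one generation per year). Sizes come
#' in two classes: "small" for current/bottleneck sizes of the bottleneck
#' scenarios (2's `Ne2`, 3's `Na3`, 4's `Nb`) — these species persist as few
#' tiny patches — and "large" for the ancestral/expanded sizes (`Na2`,
#' `Ne3`, `Ne4`, `Na4`), reflecting the widespread-ancestor hypothesis;
#' scenario 1's long-term `Ne` spans the full range. The GSM mean mutation
#' rate is uniform on `[1e-4, 1e-2]` per generation; per-locus rates are
#' Gamma(shape 2) around the mean, truncated to `[1e-5, 1e-2]`; the
#' per-locus geometric parameter of the GSM step size is uniform.
#'
#' @param N_bounds bounds of the scenario-1 long-term size.
#' @param N_small_bounds bounds of current/bottleneck sizes.
#' @param N_large_bounds bounds of ancestral/expanded sizes.
#' @param t_bounds bounds for every event-time parameter (generations).
#' @param mu_mean_bounds bounds of the mean mutation rate.
#' @param mu_locus_bounds truncation bounds of per-locus rates.
#' @param gsm_p_bounds bounds of the per-locus GSM geometric parameter.
#' @return a named list of bounds, class `"prior_spec"`.
#' @export
default_priors <- function(N_bounds = c(10, 5e5),
                           N_small_bounds = c(10, 1e4),
                           N_large_bounds = c(1e4, 5e5),
                           t_bounds = c(10, 5e4),
                           mu_mean_bounds = c(1e-4, 1e-2),
                           mu_locus_bounds = c(1e-5, 1e-2),
                           gsm_p_bounds = c(0.1, 0.9)) {
  stopifnot(N_bounds[1] < N_bounds[2], t_bounds[1] < t_bounds[2],
            N_small_bounds[1] < N_small_bounds[2],
            N_large_bounds[1] < N_large_bounds[2])
  structure(list(N = N_bounds, N_small = N_small_bounds,
                 N_large = N_large_bounds, t = t_bounds,
                 mu_mean = mu_mean_bounds, mu_locus = mu_locus_bounds,
                 gsm_p = gsm_p_bounds),
            class = "prior_spec")
}

# parameter names per scenario
scenario_params <- list(
  `1` = "Ne",
  `2` = c("Ne2", "Na2", "t"),
  `3` = c("Ne3", "Na3", "t"),
  `4` = c("Ne4", "Nb", "Na4", "t1", "t2"))

# prior bounds of one demographic parameter
param_bounds <- function(par_name, priors) {
  switch(par_name,
         Ne = priors$N,
         Ne2 = , Na3 = , Nb = priors$N_small,
         Na2 = , Ne3 = , Ne4 = , Na4 = priors$N_large,
         t = , t1 = , t2 = priors$t,
         stop("unknown parameter: ", par_name))
}

#' The four single-population demographic scenarios
#'
#' Scenario 1: constant size `Ne`. Scenario 2: a population still in a
#' bottleneck — current size `Ne2`, ancestral `Na2 > Ne2`, change at time `t`.
#' Scenario 3: recent expansion — current `Ne3 > Na3` since time `t`.
#' Scenario 4: transitory bottleneck — current `Ne4`, size `Nb` between
#' `t1 < t2`, ancestral `Na4`, with `Nb < Ne4` and `Nb < Na4`.
#'
#' @param panel a [locus_panel()].
#' @param n_ind number of diploid individuals sampled.
#' @param priors a [default_priors()] object.
#' @return an object of class `"scenario_set"`.
#' @export
scenario_set <- function(panel, n_ind, priors = default_priors()) {
  stopifnot(nrow(panel) >= 1, n_ind >= 1)
  structure(list(panel = panel, n_ind = as.integer(n_ind), priors = priors,
                 scenarios = 1:4),
            class = "scenario_set")
}

#' @export
print.scenario_set <- function(x, ...) {
  cat("Demographic scenario set: 4 single-population scenarios\n")
  cat("  panel:", nrow(x$panel), "loci; sample:", x$n_ind, "diploids\n")
  cat(sprintf("  priors: N ~ U(%g, %g), t ~ U(%g, %g), mu ~ U(%g, %g)\n",
              x$priors$N[1], x$priors$N[2], x$priors$t[1], x$priors$t[2],
              x$priors$mu_mean[1], x$priors$mu_mean[2]))
  invisible(x)
}

#' Sample demographic parameters from the priors
#'
#' Uniform draws with the scenario's ordering constraints enforced by
#' rejection (`Ne2 < Na2`, `Ne3 > Na3`, `Nb < Ne4`, `Nb < Na4`, `t1 < t2`).
#'
#' @param ss a [scenario_set()].
#' @param scenario_id scenario number in 1..4.
#' @param n number of draws.
#' @return data frame of `n` rows, one column per scenario parameter.
#' @export
sample_prior <- function(ss, scenario_id, n = 1) {
  pr <- ss$priors
  id <- as.character(scenario_id)
  if (!id %in% names(scenario_params)) stop("scenario_id must be in 1..4")
  pars <- scenario_params[[id]]
  rdraw <- function(n) {
    d <- lapply(pars, function(p) {
      b <- param_bounds(p, pr)
      stats::runif(n, b[1], b[2])
    })
    names(d) <- pars
    as.data.frame(d)
  }
  d <- rdraw(n)
  violates <- function(d) switch(id,
    `1` = rep(FALSE, nrow(d)),
    `2` = d$Ne2 >= d$Na2,
    `3` = d$Ne3 <= d$Na3,
    `4` = d$Nb >= d$Ne4 | d$Nb >= d$Na4 | d$t1 >= d$t2)
  repeat {
    bad <- violates(d)
    if (!any(bad)) break
    d[bad, ] <- rdraw(sum(bad))
  }
  d
}

# epochs (backwards in time) for one parameter draw
scenario_epochs <- function(scenario_id, params) {
  p <- as.list(params)
  switch(as.character(scenario_id),
    `1` = list(start = 0, N = p$Ne),
    `2` = list(start = c(0, p$t), N = c(p$Ne2, p$Na2)),
    `3` = list(start = c(0, p$t), N = c(p$Ne3, p$Na3)),
    `4` = list(start = c(0, p$t1, p$t2), N = c(p$Ne4, p$Nb, p$Na4)),
    stop("scenario_id must be in 1..4"))
}

# hierarchical mutation model: mean rate, truncated per-locus Gamma rates,
# per-locus GSM geometric parameter
draw_mutation_params <- function(L, priors) {
  mu_bar <- stats::runif(1, priors$mu_mean[1], priors$mu_mean[2])
  mu <- numeric(L)
  todo <- seq_len(L)
  while (length(todo)) {
    cand <- stats::rgamma(length(todo), shape = 2, scale = mu_bar / 2)
    ok <- cand >= priors$mu_locus[1] & cand <= priors$mu_locus[2]
    mu[todo[ok]] <- cand[ok]
    todo <- todo[!ok]
  }
  p <- stats::runif(L, priors$gsm_p[1], priors$gsm_p[2])
  list(mu_bar = mu_bar, mu = mu, gsm_p = p)
}

#' Simulate the time to the most recent common ancestor
#'
#' Coalescent TMRCA (generations) of `n_genes` gene copies under a
#' piecewise-constant demographic history.
#'
#' @param n_genes number of gene copies (>= 2).
#' @param epochs list with `start` (ascending, first 0) and `N` (diploid
#'   size per epoch), as produced by the scenario definitions.
#' @return TMRCA in generations.
#' @export
sim_tmrca <- function(n_genes, epochs) {
  cpp_sim_tmrca(as.integer(n_genes), as.numeric(epochs$start),
                as.numeric(epochs$N))
}

#' Simulate a multi-locus microsatellite dataset
#'
#' One independent genealogy per locus for `2 * n_ind` gene copies under the
#' given scenario, GSM mutation along the branches, genotypes formed by
#' pairing the (exchangeable) gene copies. Mutational parameters are redrawn
#' from their (hierarchical) priors unless supplied.
#'
#' @param ss a [scenario_set()].
#' @param scenario_id scenario number in 1..4.
#' @param params one-row data frame (or named vector/list) of demographic
#'   parameters for the scenario.
#' @param n_ind number of diploid individuals (default: the scenario set's).
#' @param mutation optional list with `mu` and `gsm_p` vectors (one entry per
#'   locus) to bypass the prior draw.
#' @param boundary `"reflect"` (fold alleles back into the locus range) or
#'   `"clamp"`.
#' @return a [genotypes()] object; attribute `"mutation"` records the rates
#'   used.
#' @export
sim_dataset <- function(ss, scenario_id, params, n_ind = ss$n_ind,
                        mutation = NULL, boundary = c("reflect", "clamp")) {
  boundary <- match.arg(boundary)
  panel <- ss$panel
  L <- nrow(panel)
  if (is.null(mutation)) mutation <- draw_mutation_params(L, ss$priors)
  ep <- scenario_epochs(scenario_id, params)
  genes <- cpp_sim_genes(2L * n_ind, ep$start, ep$N, mutation$mu,
                         mutation$gsm_p, panel$amin, panel$amax,
                         boundary == "reflect")
  odd <- seq(1, 2 * n_ind, by = 2)
  g <- genotypes(genes[odd, , drop = FALSE], genes[odd + 1, , drop = FALSE],
                 ind = paste0("sim", seq_len(n_ind)), loci = panel)
  attr(g, "mutation") <- mutation
  g
}

# fast path: simulate and return only the four summary statistics
sim_stats <- function(ss, scenario_id, params, n_ind = ss$n_ind,
                      mutation = NULL, reflect = TRUE) {
  panel <- ss$panel
  if (is.null(mutation)) mutation <- draw_mutation_params(nrow(panel),
                                                          ss$priors)
  ep <- scenario_epochs(scenario_id, params)
  s <- cpp_sim_stats(2L * n_ind, ep$start, ep$N, mutation$mu, mutation$gsm_p,
                     panel$amin, panel$amax, reflect)
  names(s) <- c("mean_A", "mean_GD", "mean_size_var", "mean_M")
  s
}

#' ABC summary statistics of a genotype set
#'
#' The four single-sample statistics averaged across loci: mean number of
#' alleles, mean unbiased gene diversity, mean variance of allele size over
#' gene copies (denominator `n`), and the mean Garza-Williamson index
#' `M = k / (r + 1)` with `k` alleles over an allele-size range of `r` repeat
#' units. Loci without at least two non-missing gene copies are skipped.
#'
#' @param g a [genotypes()] object.
#' @return named numeric vector
#'   `c(mean_A, mean_GD, mean_size_var, mean_M)`.
#' @export
abc_summary_stats <- function(g) {
  per <- vapply(seq_len(n_loci(g)), function(l) {
    v <- locus_alleles(g, l)
    n <- length(v)
    if (n < 2) return(c(NA, NA, NA, NA))
    tab <- table(v)
    p <- as.numeric(tab) / n
    k <- length(tab)
    c(k,
      n / (n - 1) * (1 - sum(p^2)),
      mean((v - mean(v))^2),
      k / (diff(range(v)) + 1))
  }, numeric(4))
  out <- rowMeans(per, na.rm = TRUE)
  names(out) <- c("mean_A", "mean_GD", "mean_size_var", "mean_M")
  out
}

# compound sampler for the summed GSM displacement of m mutations
# (R mirror of the C++ branch sampler; kept for verification)
gsm_displacement <- function(m, p) {
  if (m <= 0) return(0)
  m_up <- stats::rbinom(1, m, 0.5)
  m_dn <- m - m_up
  up <- m_up + if (m_up > 0) stats::rnbinom(1, m_up, p) else 0
  dn <- m_dn + if (m_dn > 0) stats::rnbinom(1, m_dn, p) else 0
  up - dn
}
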