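## Study-shaped synthetic data with known ground truth.

rdirichlet1 <- function(alpha) {
  x <- stats::rgamma(length(alpha), shape = alpha)
  x / sum(x)
}

random_dna <- function(n, gc = 0.30) {
  paste(sample(c("A", "T", "G", "C"), n, replace = TRUE,
               prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2)),
        collapse = "")
}

#' Island-model genotype generator with selfing
#'
#' Multi-population genotypes from a Balding-Nichols equilibrium model:
#' ancestral allele frequencies per locus are Dirichlet; each population's
#' frequencies are Dirichlet with concentration `p (1 - F) / F` around the
#' ancestral vector, so `F` per population sets its drift from the common
#' pool (and the expected F_ST scale). Within populations, genotypes carry
#' an inbreeding coefficient `F_IS = s / (2 - s)` — the classical
#' partial-selfing equilibrium for selfing rate `s` — imposed at the
#' gene-pairing stage (with that probability the two gene copies are one
#' draw duplicated).
#'
#' @param pop_sizes integer vector of individuals per population.
#' @param n_loci number of loci.
#' @param n_alleles alleles per locus (recycled); 1 forces a monomorphic
#'   locus.
#' @param fst_drift per-population drift parameter `F` (recycled; 0 gives a
#'   panmictic pool).
#' @param selfing selfing rate `s` in `[0, 1)` (recycled per population).
#' @param panel optional [locus_panel()]; default motif length 2, range
#'   padded around the used allele states.
#' @param pop_names population labels.
#' @param seed RNG seed (mandatory).
#' @return list with `genotypes`, `pops` and `truth` (the generating
#'   parameters).
#' @export
sim_island_genotypes <- function(pop_sizes, n_loci, n_alleles = 5,
                                 fst_drift = 0.05, selfing = 0,
                                 panel = NULL,
                                 pop_names = paste0("pop", seq_along(pop_sizes)),
                                 seed) {
  if (missing(seed)) stop("seed is mandatory")
  withr_seed(seed)
  P <- length(pop_sizes)
  n_alleles <- rep_len(n_alleles, n_loci)
  fst_drift <- rep_len(fst_drift, P)
  selfing <- rep_len(selfing, P)
  f_is <- selfing / (2 - selfing)
  if (is.null(panel)) panel <- locus_panel(n_loci, amin = 5L, amax = 44L)
  n_tot <- sum(pop_sizes)
  a1 <- matrix(NA_integer_, n_tot, n_loci)
  a2 <- matrix(NA_integer_, n_tot, n_loci)
  pop <- rep(pop_names, pop_sizes)
  for (l in seq_len(n_loci)) {
    k <- n_alleles[l]
    mid <- (panel$amin[l] + panel$amax[l]) %/% 2L
    states <- mid + seq_len(k) - (k %/% 2L)
    anc <- if (k == 1) 1 else rdirichlet1(rep(1.5, k))
    row0 <- 0L
    for (pi in seq_len(P)) {
      f <- fst_drift[pi]
      pf <- if (k == 1) 1
      else if (f <= 0) anc
      else rdirichlet1(anc * (1 - f) / f)
      n <- pop_sizes[pi]
      ib <- stats::runif(n) < f_is[pi]
      g1 <- states[sample.int(length(states), n, replace = TRUE, prob = pf)]
      g2 <- states[sample.int(length(states), n, replace = TRUE, prob = pf)]
      g2[ib] <- g1[ib]
      a1[row0 + seq_len(n), l] <- g1
      a2[row0 + seq_len(n), l] <- g2
      row0 <- row0 + n
    }
  }
  ind <- paste0(rep(pop_names, pop_sizes), "_",
                unlist(lapply(pop_sizes, seq_len)))
  g <- genotypes(a1, a2, ind, panel)
  list(genotypes = g, pops = population_map(ind, pop),
       truth = list(pop_sizes = pop_sizes, n_alleles = n_alleles,
                    fst_drift = fst_drift, selfing = selfing,
                    f_is = f_is, seed = seed))
}

plastid_regions <- function(ids, lengths, n_haplotypes = 1, carrier_idx = NULL,
                            gc = 0.30) {
  base <- lapply(lengths, random_dna, gc = gc)
  regions <- vector("list", length(lengths))
  for (r in seq_along(lengths)) {
    seqs <- rep(base[[r]], length(ids))
    if (n_haplotypes == 2 && r == 1 && length(carrier_idx)) {
      # one substitution defines the minor haplotype
      pos <- max(1L, lengths[r] %/% 2L)
      ch <- substr(base[[r]], pos, pos)
      alt <- setdiff(c("A", "C", "G", "T"), ch)[1]
      for (i in carrier_idx)
        substr(seqs[i], pos, pos) <- alt
    }
    regions[[r]] <- alignment_set(seqs, ids, paste0("region", r))
  }
  regions
}

#' Synthetic dataset shaped like the *Petunia mantiqueirensis* study design
#'
#' Seven small populations totalling 38 individuals, 12 microsatellite loci
#' of which exactly 2 are monomorphic, weak population structure (drift
#' calibrated to an F_ST around 0.05-0.1), no inbreeding, and a
#' 471 + 650 bp two-region plastid alignment with a single haplotype.
#'
#' @param seed RNG seed (mandatory).
#' @return list with `genotypes`, `pops`, `plastid` (list of per-region
#'   [alignment_set()]s) and `truth`.
#' @export
generate_mantiqueirensis_like <- function(seed) {
  if (missing(seed)) stop("seed is mandatory")
  sim <- sim_island_genotypes(
    pop_sizes = c(10, 8, 5, 4, 4, 4, 3), n_loci = 12,
    n_alleles = c(4, 7, 3, 3, 3, 2, 5, 3, 7, 2, 1, 1),
    fst_drift = 0.075, selfing = 0,
    pop_names = paste0("siteA", 1:7), seed = seed)
  withr_seed(seed + 101)
  sim$plastid <- plastid_regions(sim$genotypes$ind, c(471, 650),
                                 n_haplotypes = 1)
  sim$truth$n_polymorphic <- 10L
  sim$truth$plastid_haplotypes <- 1L
  sim
}

#' Synthetic dataset shaped like the *Calibrachoa elegans* study design
#'
#' Four populations totalling 81 individuals, 14 loci of which 5 are
#' polymorphic, partial selfing producing a positive inbreeding coefficient
#' (`F_IS = s/(2-s)`), one strongly diverged population, and a 445 + 746 bp
#' plastid alignment with two haplotypes at skewed frequencies (the minor
#' haplotype confined to the first population).
#'
#' @param seed RNG seed (mandatory).
#' @param selfing selfing rate (default 0.5, i.e. equilibrium F_IS = 1/3).
#' @return list with `genotypes`, `pops`, `plastid` and `truth`.
#' @export
generate_elegans_like <- function(seed, selfing = 0.5) {
  if (missing(seed)) stop("seed is mandatory")
  sim <- sim_island_genotypes(
    pop_sizes = c(30, 10, 21, 20), n_loci = 14,
    n_alleles = c(13, 6, 4, 10, 6, rep(1, 9)),
    fst_drift = c(0.04, 0.55, 0.04, 0.04), selfing = selfing,
    pop_names = paste0("siteB", 1:4), seed = seed)
  withr_seed(seed + 211)
  sim$plastid <- plastid_regions(sim$genotypes$ind, c(445, 746),
                                 n_haplotypes = 2, carrier_idx = 1:2)
  sim$truth$n_polymorphic <- 5L
  sim$truth$plastid_haplotypes <- 2L
  sim$truth$diverged_pop <- "siteB2"
  sim
}

#' Simulate a dataset with recorded demographic truth
#'
#' Wraps [sim_dataset()] for inference-recovery experiments: the returned
#' bundle records the generating scenario, parameters and mutation rates so
#' downstream scenario choice and parameter estimates can be scored.
#'
#' @param scenario_id generating scenario (1..4).
#' @param params named demographic parameters for that scenario.
#' @param panel a [locus_panel()].
#' @param n_ind number of diploid individuals.
#' @param seed RNG seed (mandatory).
#' @param priors priors used for the mutation model draw.
#' @return list with `genotypes`, `pops` (single population), `stats`
#'   (observed [abc_summary_stats()]) and `truth`.
#' @export
generate_bottleneck_truth <- function(scenario_id, params, panel, n_ind,
                                      seed, priors = default_priors()) {
  if (missing(seed)) stop("seed is mandatory")
  withr_seed(seed)
  ss <- scenario_set(panel, n_ind, priors)
  g <- sim_dataset(ss, scenario_id, params)
  list(genotypes = g,
       pops = population_map(g$ind, rep("pop1", n_ind(g))),
       stats = abc_summary_stats(g),
       truth = list(scenario_id = scenario_id, params = as.list(params),
                    mutation = attr(g, "mutation"), seed = seed))
}
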