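## Per-locus and per-population microsatellite diversity statistics.

locus_alleles <- function(g, l, idx = seq_len(n_ind(g))) {
  v <- c(g$a1[idx, l], g$a2[idx, l])
  v[!is.na(v)]
}

#' Allele frequencies per locus
#'
#' Counts every non-missing allele copy once. With `stratify`, frequencies are
#' additionally tabulated within each population.
#'
#' @param g a [genotypes()] object.
#' @param stratify optional [population_map()].
#' @return an object of class `"allele_freqs"`: a list with one entry per
#'   locus, each holding `freq` (named numeric, sums to 1), `counts` (allele
#'   copy counts) and `n_genes`; with `stratify`, also `by_pop`, the same per
#'   population. Loci with no data are flagged with `n_genes = 0`.
#' @export
allele_frequencies <- function(g, stratify = NULL) {
  pops <- if (!is.null(stratify)) check_popmap(g, stratify)
  out <- lapply(seq_len(n_loci(g)), function(l) {
    v <- locus_alleles(g, l)
    e <- if (!length(v)) {
      list(freq = numeric(0), counts = integer(0), n_genes = 0L)
    } else {
      tab <- table(v)
      list(freq = as.numeric(tab) / sum(tab),
           counts = stats::setNames(as.integer(tab), names(tab)),
           n_genes = sum(tab))
    }
    if (length(e$freq)) names(e$freq) <- names(e$counts)
    if (!is.null(pops)) {
      e$by_pop <- lapply(levels(pops), function(p) {
        v <- locus_alleles(g, l, which(pops == p))
        if (!length(v)) return(list(freq = numeric(0), counts = integer(0),
                                    n_genes = 0L))
        tab <- table(v)
        list(freq = stats::setNames(as.numeric(tab) / sum(tab), names(tab)),
             counts = stats::setNames(as.integer(tab), names(tab)),
             n_genes = sum(tab))
      })
      names(e$by_pop) <- levels(pops)
    }
    e
  })
  names(out) <- g$loci$name
  class(out) <- "allele_freqs"
  out
}

#' @export
print.allele_freqs <- function(x, ...) {
  cat("Allele frequencies at", length(x), "loci\n")
  for (nm in names(x))
    cat(sprintf("  %s: %d alleles, %d gene copies\n", nm,
                length(x[[nm]]$freq), x[[nm]]$n_genes))
  invisible(x)
}

#' Gene diversity (unbiased expected heterozygosity)
#'
#' Nei's unbiased estimator \eqn{GD = n(1 - \sum p_i^2)/(n - 1)} with `n` the
#' number of gene copies; equals the probability that two gene copies drawn
#' without replacement differ.
#'
#' @param freqs an [allele_frequencies()] object.
#' @param unbiased if `FALSE` returns the plug-in \eqn{1 - \sum p_i^2}.
#' @return named numeric vector, one value per locus (`NA` where `n_genes < 2`).
#' @export
gene_diversity <- function(freqs, unbiased = TRUE) {
  vapply(freqs, function(e) {
    n <- e$n_genes
    if (n < 2L) return(NA_real_)
    h <- 1 - sum(e$freq^2)
    if (unbiased) n / (n - 1) * h else h
  }, numeric(1))
}

#' Polymorphic information content
#'
#' \eqn{PIC = 1 - \sum p_i^2 - \sum_{i<j} 2 p_i^2 p_j^2}; always at most the
#' plug-in expected heterozygosity.
#'
#' @param freqs an [allele_frequencies()] object.
#' @return named numeric vector per locus.
#' @export
pic <- function(freqs) {
  vapply(freqs, function(e) {
    p <- e$freq
    if (!length(p)) return(NA_real_)
    s2 <- sum(p^2)
    1 - s2 - (s2^2 - sum(p^4))
  }, numeric(1))
}

#' Rarefied allelic richness
#'
#' Expected number of distinct alleles in a subsample of `g` gene copies:
#' \eqn{AR(g) = \sum_i [1 - C(N - N_i, g) / C(N, g)]}.
#'
#' @param counts integer vector of allele copy counts at one locus, or an
#'   [allele_frequencies()] object (then a vector over loci is returned).
#' @param g rarefaction size in gene copies (`2 <= g <= N`).
#' @return allelic richness value(s) in `[1, A]`.
#' @export
allelic_richness <- function(counts, g) {
  one <- function(cnt) {
    N <- sum(cnt)
    if (g > N) stop("rarefaction size g exceeds the number of gene copies")
    sum(1 - exp(lchoose(N - cnt, g) - lchoose(N, g)))
  }
  if (inherits(counts, "allele_freqs"))
    vapply(counts, function(e) one(e$counts), numeric(1))
  else one(counts)
}

## ---------------------------------------------------------------------------
## Weir & Cockerham F_IS
## ---------------------------------------------------------------------------

# Variance components (a, b, c) per locus, Weir & Cockerham (1984), summed
# over alleles. Returns NULL when fewer than 2 individuals have data.
wc_components <- function(g, l, pops) {
  lev <- levels(pops)
  rows <- lapply(lev, function(p) {
    idx <- which(pops == p)
    keep <- idx[!is.na(g$a1[idx, l])]
    if (length(keep) < 1L) return(NULL)
    list(n = length(keep), a1 = g$a1[keep, l], a2 = g$a2[keep, l])
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  r <- length(rows)
  if (!r || sum(vapply(rows, `[[`, 0, "n")) < 2L) return(NULL)
  alleles <- sort(unique(unlist(lapply(rows, function(x) c(x$a1, x$a2)))))
  if (length(alleles) < 2L) return(NULL)
  ns <- vapply(rows, `[[`, 0, "n")
  nbar <- mean(ns)
  nc <- if (r > 1L) (r * nbar - sum(ns^2) / (r * nbar)) / (r - 1) else NA_real_
  a <- b <- cc <- 0
  for (al in alleles) {
    p_i <- vapply(rows, function(x) sum(x$a1 == al, x$a2 == al) / (2 * x$n),
                  numeric(1))
    h_i <- vapply(rows, function(x)
      sum((x$a1 == al) != (x$a2 == al)) / x$n, numeric(1))
    pbar <- sum(ns * p_i) / (r * nbar)
    hbar <- sum(ns * h_i) / (r * nbar)
    s2 <- if (r > 1L) sum(ns * (p_i - pbar)^2) / ((r - 1) * nbar) else 0
    if (r > 1L) {
      a <- a + (nbar / nc) *
        (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
    }
    b <- b + (nbar / (nbar - 1)) *
      (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
    cc <- cc + hbar / 2
  }
  c(a = if (r > 1L) a else NA_real_, b = b, c = cc)
}

#' Inbreeding coefficient F_IS (Weir & Cockerham)
#'
#' Variance-components estimator of the within-population inbreeding
#' coefficient, per locus and over all loci, with a permutation test obtained
#' by re-pairing the gene copies of each population at random (alleles
#' permuted among individuals within populations).
#'
#' @param g a [genotypes()] object.
#' @param pops a [population_map()]; a single-population map is allowed.
#' @param n_perm number of permutations (0 disables the test).
#' @param seed RNG seed for the permutation test.
#' @return an object of class `"fis_test"`: list with `per_locus` (named
#'   vector), `overall`, `p_per_locus`, `p_overall` (two-sided permutation
#'   p-values, `(k+1)/(n+1)` estimator).
#' @export
f_is <- function(g, pops, n_perm = 10000, seed = 1) {
  pops <- check_popmap(g, pops)
  comp <- lapply(seq_len(n_loci(g)), function(l) wc_components(g, l, pops))
  names(comp) <- g$loci$name
  fis_of <- function(cmp) {
    bc <- vapply(cmp, function(x) if (is.null(x)) c(NA, NA) else x[c("b", "c")],
                 numeric(2))
    b <- sum(bc[1, ], na.rm = TRUE); cc <- sum(bc[2, ], na.rm = TRUE)
    per <- apply(bc, 2, function(x)
      if (anyNA(x) || sum(x) == 0) NA_real_ else 1 - x[2] / sum(x))
    list(per = per, overall = if (b + cc > 0) 1 - cc / (b + cc) else NA_real_)
  }
  obs <- fis_of(comp)
  p_loc <- rep(NA_real_, n_loci(g)); p_all <- NA_real_
  if (n_perm > 0) {
    withr_seed(seed)
    hit_loc <- rep(0L, n_loci(g)); hit_all <- 0L
    for (b in seq_len(n_perm)) {
      gp <- permute_within_pops(g, pops)
      cmp <- lapply(seq_len(n_loci(g)), function(l) wc_components(gp, l, pops))
      perm <- fis_of(cmp)
      hit_loc <- hit_loc + as.integer(!is.na(perm$per) & !is.na(obs$per) &
                                        abs(perm$per) >= abs(obs$per))
      if (!is.na(perm$overall) && !is.na(obs$overall) &&
          abs(perm$overall) >= abs(obs$overall)) hit_all <- hit_all + 1L
    }
    p_loc <- (hit_loc + 1) / (n_perm + 1)
    p_loc[is.na(obs$per)] <- NA_real_
    p_all <- if (is.na(obs$overall)) NA_real_ else (hit_all + 1) / (n_perm + 1)
  }
  structure(list(per_locus = stats::setNames(obs$per, g$loci$name),
                 overall = obs$overall, p_per_locus = p_loc,
                 p_overall = p_all, n_perm = n_perm),
            class = "fis_test")
}

#' @export
print.fis_test <- function(x, ...) {
  cat(sprintf("Weir-Cockerham F_IS: overall %.4f (two-sided P = %s, %d permutations)\n",
              x$overall, format(x$p_overall, digits = 3), x$n_perm))
  invisible(x)
}

# Re-pair gene copies within each population (null of random mating).
permute_within_pops <- function(g, pops) {
  a1 <- g$a1; a2 <- g$a2
  for (p in levels(pops)) {
    idx <- which(pops == p)
    for (l in seq_len(ncol(a1))) {
      keep <- idx[!is.na(a1[idx, l])]
      if (length(keep) < 2L) next
      v <- sample(c(a1[keep, l], a2[keep, l]))
      a1[keep, l] <- v[seq_along(keep)]
      a2[keep, l] <- v[length(keep) + seq_along(keep)]
    }
  }
  g$a1 <- a1; g$a2 <- a2
  g
}

withr_seed <- function(seed) set.seed(as.integer(seed %% .Machine$integer.max))

#' Null-allele frequency estimators
#'
#' Chakraborty's \eqn{r = (He - Ho)/(He + Ho)} and Brookfield's first
#' estimator \eqn{r = (He - Ho)/(1 + He)}, with plug-in expected
#' heterozygosity. Negative values (heterozygote excess) are reported as
#' computed.
#'
#' @param g a [genotypes()] object.
#' @return data frame with per-locus `Ho`, `He`, `chakraborty`, `brookfield`.
#' @export
null_allele_frequency <- function(g) {
  freqs <- allele_frequencies(g)
  he <- gene_diversity(freqs, unbiased = FALSE)
  ho <- observed_heterozygosity(g)
  data.frame(locus = g$loci$name, Ho = ho, He = he,
             chakraborty = (he - ho) / (he + ho),
             brookfield = (he - ho) / (1 + he), row.names = NULL)
}

#' Observed heterozygosity per locus
#' @param g a [genotypes()] object.
#' @return named numeric vector of the fraction of heterozygous individuals
#'   among those with data, per locus.
#' @export
observed_heterozygosity <- function(g) {
  vapply(seq_len(n_loci(g)), function(l) {
    keep <- !is.na(g$a1[, l])
    if (!any(keep)) return(NA_real_)
    mean(g$a1[keep, l] != g$a2[keep, l])
  }, numeric(1)) -> ho
  stats::setNames(ho, g$loci$name)
}

## ---------------------------------------------------------------------------
## Exact Hardy-Weinberg test (Levene distribution)
## ---------------------------------------------------------------------------

# log-probability of a genotype count table under the Levene distribution.
# geno: named count vector over cells "i/j" (i <= j); n = individuals,
# cnt = allele copy counts.
levene_logprob <- function(diag_counts, het_counts, allele_counts) {
  n <- sum(diag_counts) + sum(het_counts)
  lgamma(n + 1) + sum(het_counts) * log(2) -
    sum(lgamma(c(diag_counts, het_counts) + 1)) +
    sum(lgamma(allele_counts + 1)) - lgamma(2 * n + 1)
}

# Enumerate all genotype tables with the given allele-count margins; calls
# fun(logp) for each. Aborts (returns FALSE) if more than `cap` tables or
# `node_cap` search nodes are visited.
enumerate_levene <- function(allele_counts, fun, cap = 2e5, node_cap = 5e5) {
  k <- length(allele_counts)
  cells <- list()
  for (i in seq_len(k)) for (j in i:k) cells[[length(cells) + 1L]] <- c(i, j)
  n_tab <- 0L
  n_node <- 0L
  counts <- integer(length(cells))
  rec <- function(ci, rem) {
    if (n_tab < 0L) return()
    n_node <<- n_node + 1L
    if (n_node > node_cap) { n_tab <<- -1L; return() }
    if (ci > length(cells)) {
      if (all(rem == 0L)) {
        n_tab <<- n_tab + 1L
        if (n_tab > cap) { n_tab <<- -1L; return() }
        dg <- counts[vapply(cells, function(cl) cl[1] == cl[2], logical(1))]
        ht <- counts[vapply(cells, function(cl) cl[1] != cl[2], logical(1))]
        fun(levene_logprob(dg, ht, allele_counts))
      }
      return()
    }
    cl <- cells[[ci]]
    if (cl[1] == cl[2]) {
      # entering row i: every earlier allele's margin must be exhausted
      if (cl[1] > 1L && any(rem[seq_len(cl[1] - 1L)] != 0L)) return()
      for (cnt in 0:(rem[cl[1]] %/% 2L)) {
        counts[ci] <<- cnt
        rem2 <- rem; rem2[cl[1]] <- rem2[cl[1]] - 2L * cnt
        rec(ci + 1L, rem2)
        if (n_tab < 0L) return()
      }
    } else {
      for (cnt in 0:min(rem[cl[1]], rem[cl[2]])) {
        counts[ci] <<- cnt
        rem2 <- rem
        rem2[cl[1]] <- rem2[cl[1]] - cnt
        rem2[cl[2]] <- rem2[cl[2]] - cnt
        rec(ci + 1L, rem2)
        if (n_tab < 0L) return()
      }
    }
  }
  rec(1L, as.integer(allele_counts))
  n_tab > 0L
}

hwe_one <- function(a1, a2, n_mc, seed, enum_cap = 2e5) {
  keep <- !is.na(a1)
  a1 <- a1[keep]; a2 <- a2[keep]
  n <- length(a1)
  if (n < 3L)
    return(list(p = NA_real_, method = "insufficient data", fis_sign = NA))
  alleles <- sort(unique(c(a1, a2)))
  k <- length(alleles)
  if (k < 2L)
    return(list(p = 1, method = "not testable (monomorphic)", fis_sign = NA))
  i1 <- match(a1, alleles); i2 <- match(a2, alleles)
  cnt <- tabulate(c(i1, i2), k)
  lgf <- lgamma(seq_len(2L * n + 1L))  # lgf[m + 1] = log(m!)
  const <- lgf[n + 1L] + sum(lgf[cnt + 1L]) - lgf[2L * n + 1L]
  logprob_from <- function(lo, hi) {
    gcnt <- tabulate((lo - 1L) * k + hi, k * k)
    const + sum(lo != hi) * log(2) - sum(lgf[gcnt + 1L])
  }
  lo <- pmin(i1, i2); hi <- pmax(i1, i2)
  lp_obs <- logprob_from(lo, hi)
  tol <- 1e-9
  # direction of deviation via the F_IS sign (Ho vs plug-in He)
  ho <- mean(a1 != a2)
  he <- 1 - sum((cnt / sum(cnt))^2)
  fis_sign <- sign(he - ho)  # positive = heterozygote deficit
  if (k <= 6L && enum_cap >= 1) {
    acc <- 0
    ok <- enumerate_levene(cnt, function(lp) {
      if (lp <= lp_obs + tol) acc <<- acc + exp(lp)
    }, cap = enum_cap)
    if (ok) return(list(p = min(acc, 1), method = "exact enumeration",
                        fis_sign = fis_sign))
  }
  # Monte-Carlo: shuffle the 2n gene copies and re-pair (samples the Levene
  # distribution exactly)
  withr_seed(seed)
  pool <- c(i1, i2)
  hits <- 0L
  for (b in seq_len(n_mc)) {
    v <- sample(pool)
    v1 <- v[1:n]; v2 <- v[(n + 1):(2 * n)]
    if (logprob_from(pmin(v1, v2), pmax(v1, v2)) <= lp_obs + tol)
      hits <- hits + 1L
  }
  list(p = (hits + 1) / (n_mc + 1), method = "monte carlo",
       fis_sign = fis_sign)
}

#' Exact test of Hardy-Weinberg equilibrium
#'
#' Conditional exact test on the genotype-count table given the allele
#' counts (the Levene distribution). Tables are fully enumerated when the
#' state space is small (at most `enum_cap` tables); otherwise the null is
#' sampled by Monte-Carlo re-pairing of the gene copies. The p-value is the
#' total probability of tables no more probable than the observed one.
#'
#' @param g a [genotypes()] object.
#' @param pops optional [population_map()]; when given, each population is
#'   tested separately in addition to the pooled sample.
#' @param n_mc Monte-Carlo sample size when enumeration is infeasible.
#' @param enum_cap maximum number of tables enumerated exactly.
#' @param seed RNG seed for the Monte-Carlo branch.
#' @return data frame with columns `locus`, `pop` (`"all"` for the pooled
#'   test), `p`, `method` and `direction` (`"deficit"`/`"excess"` of
#'   heterozygotes, from the sign of He - Ho).
#' @export
hwe_exact_test <- function(g, pops = NULL, n_mc = 1e5, enum_cap = 2e5,
                           seed = 1) {
  run <- function(idx, label) {
    do.call(rbind, lapply(seq_len(n_loci(g)), function(l) {
      r <- hwe_one(g$a1[idx, l], g$a2[idx, l], n_mc, seed + l, enum_cap)
      data.frame(locus = g$loci$name[l], pop = label, p = r$p,
                 method = r$method,
                 direction = if (is.na(r$fis_sign) || r$fis_sign == 0) NA_character_
                 else if (r$fis_sign > 0) "deficit" else "excess",
                 row.names = NULL)
    }))
  }
  out <- run(seq_len(n_ind(g)), "all")
  if (!is.null(pops)) {
    pops <- check_popmap(g, pops)
    for (p in levels(pops)) out <- rbind(out, run(which(pops == p), p))
  }
  out
}

#' Bonferroni significance calls
#'
#' @param pvals numeric vector of p-values from `m = length(pvals)`
#'   simultaneous tests (or supply `m` explicitly).
#' @param nominal nominal family-wise level.
#' @param m number of simultaneous tests.
#' @return logical vector: `TRUE` where `p < nominal / m`.
#' @export
bonferroni <- function(pvals, nominal = 0.05, m = length(pvals)) {
  if (!length(pvals)) stop("no p-values supplied")
  pvals < nominal / m
}

#' Genotypic linkage-disequilibrium test
#'
#' Log-likelihood-ratio (G) statistic on the two-locus genotype contingency
#' table for every pair of polymorphic loci, with the null distribution
#' obtained by permuting the genotypes of one locus among individuals within
#' populations.
#'
#' @param g a [genotypes()] object.
#' @param pops a [population_map()].
#' @param n_perm number of permutations.
#' @param seed RNG seed.
#' @return data frame with columns `locus1`, `locus2`, `G`, `p`; zero rows
#'   when fewer than two polymorphic loci are present.
#' @export
genotypic_ld_test <- function(g, pops, n_perm = 10000, seed = 1) {
  pops <- check_popmap(g, pops)
  geno_str <- function(a1, a2) ifelse(is.na(a1), NA,
                                      paste(pmin(a1, a2), pmax(a1, a2)))
  poly <- which(vapply(seq_len(n_loci(g)), function(l)
    length(unique(locus_alleles(g, l))) > 1L, logical(1)))
  out <- data.frame(locus1 = character(0), locus2 = character(0),
                    G = numeric(0), p = numeric(0))
  if (length(poly) < 2L) return(out)
  g_stat <- function(x, y) {
    keep <- !is.na(x) & !is.na(y)
    if (sum(keep) < 2L) return(NA_real_)
    tab <- table(x[keep], y[keep])
    e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    o <- tab[tab > 0]
    2 * sum(o * log(o / e[tab > 0]))
  }
  withr_seed(seed)
  for (i in seq_along(poly)[-length(poly)]) for (j in (i + 1):length(poly)) {
    l1 <- poly[i]; l2 <- poly[j]
    x <- geno_str(g$a1[, l1], g$a2[, l1])
    y <- geno_str(g$a1[, l2], g$a2[, l2])
    obs <- g_stat(x, y)
    hits <- 0L
    for (b in seq_len(n_perm)) {
      y2 <- y
      for (p in levels(pops)) {
        idx <- which(pops == p)
        y2[idx] <- y[idx][sample.int(length(idx))]
      }
      if (!is.na(obs) && g_stat(x, y2) >= obs - 1e-12) hits <- hits + 1L
    }
    out <- rbind(out, data.frame(locus1 = g$loci$name[l1],
                                 locus2 = g$loci$name[l2], G = obs,
                                 p = (hits + 1) / (n_perm + 1)))
  }
  out
}

#' Private alleles per population
#'
#' An allele is private to a population when it is observed in exactly one
#' population.
#'
#' @param g a [genotypes()] object.
#' @param pops a [population_map()] with at least two populations.
#' @return named integer vector: number of private alleles per population.
#' @export
private_alleles <- function(g, pops) {
  pops <- check_popmap(g, pops)
  if (nlevels(pops) < 2L) stop("need at least 2 populations")
  out <- stats::setNames(integer(nlevels(pops)), levels(pops))
  for (l in seq_len(n_loci(g))) {
    present <- lapply(levels(pops), function(p)
      unique(locus_alleles(g, l, which(pops == p))))
    all_alleles <- unique(unlist(present))
    for (al in all_alleles) {
      inpop <- vapply(present, function(v) al %in% v, logical(1))
      if (sum(inpop) == 1L) out[which(inpop)] <- out[which(inpop)] + 1L
    }
  }
  out
}

#' Per-locus diversity summary table
#'
#' The marker-characterization battery: number of alleles (A), PIC, gene
#' diversity (GD, unbiased, pooled and population-averaged), rarefied allelic
#' richness (AR), observed (Ho) and expected (He) heterozygosity, F_IS with
#' permutation significance, null-allele estimates, and the exact HWE test.
#'
#' @param g a [genotypes()] object.
#' @param pops a [population_map()].
#' @param rarefaction_g rarefaction size in gene copies; default is the
#'   smallest per-population non-missing gene count across loci.
#' @param n_perm permutations for the F_IS test.
#' @param n_mc Monte-Carlo sample size for HWE tests beyond enumeration.
#' @param seed RNG seed.
#' @return an object of class `"diversity_stats"`: list with `per_locus`
#'   (data frame mirroring a marker-characterization table), `mean` (column
#'   means), `fis` (the [f_is()] object), `hwe` (the [hwe_exact_test()]
#'   table), `rarefaction_g`.
#' @export
diversity_stats <- function(g, pops, rarefaction_g = NULL, n_perm = 2000,
                            n_mc = 1e5, seed = 1) {
  pops <- check_popmap(g, pops)
  freqs <- allele_frequencies(g, stratify = pops)
  if (is.null(rarefaction_g)) {
    ng <- unlist(lapply(freqs, function(e)
      vapply(e$by_pop, `[[`, 0L, "n_genes")))
    ng <- ng[ng > 0]
    rarefaction_g <- max(2L, min(ng))
  }
  A <- vapply(freqs, function(e) length(e$freq), numeric(1))
  gd_pool <- gene_diversity(freqs)
  gd_pop <- vapply(freqs, function(e) {
    v <- vapply(e$by_pop, function(b) {
      n <- b$n_genes
      if (n < 2) return(NA_real_)
      n / (n - 1) * (1 - sum(b$freq^2))
    }, numeric(1))
    mean(v, na.rm = TRUE)
  }, numeric(1))
  ar <- vapply(freqs, function(e) {
    if (e$n_genes < rarefaction_g) return(NA_real_)
    allelic_richness(e$counts, rarefaction_g)
  }, numeric(1))
  nul <- null_allele_frequency(g)
  fis <- f_is(g, pops, n_perm = n_perm, seed = seed)
  hwe <- hwe_exact_test(g, pops = NULL, n_mc = n_mc, seed = seed)
  per_locus <- data.frame(
    locus = g$loci$name, A = A, PIC = pic(freqs), GD = gd_pool,
    GD_pop_mean = gd_pop, AR = ar, Ho = nul$Ho, He = gd_pool,
    F_IS = fis$per_locus, NUL_chakraborty = nul$chakraborty,
    NUL_brookfield = nul$brookfield, hwe_p = hwe$p[hwe$pop == "all"],
    hwe_sig_bonferroni = bonferroni(hwe$p[hwe$pop == "all"]),
    row.names = NULL)
  structure(list(per_locus = per_locus,
                 mean = colMeans(per_locus[, c("A", "PIC", "GD", "AR", "Ho",
                                               "He", "F_IS")], na.rm = TRUE),
                 fis = fis, hwe = hwe, rarefaction_g = rarefaction_g),
            class = "diversity_stats")
}

#' @export
print.diversity_stats <- function(x, digits = 3, ...) {
  cat("Per-locus diversity statistics (rarefaction g =", x$rarefaction_g,
      "gene copies)\n")
  print(format(x$per_locus, digits = digits), row.names = FALSE)
  cat("\nMeans:\n")
  print(round(x$mean, digits))
  invisible(x)
}
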