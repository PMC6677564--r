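# shared test fixtures, all built in code

toy_panel <- function(n_loci = 1, amin = 0L, amax = 30L) {
  locus_panel(n_loci, motif_length = 1L, amin = amin, amax = amax)
}

# small genotype set from explicit allele pairs: x is a list of length-2
# vectors (one per individual), single locus
toy_genotypes <- function(calls, amin = 0L, amax = 30L) {
  a1 <- matrix(vapply(calls, `[`, 0L, 1L), ncol = 1)
  a2 <- matrix(vapply(calls, `[`, 0L, 2L), ncol = 1)
  genotypes(a1, a2, paste0("i", seq_along(calls)),
            toy_panel(1, amin, amax))
}

# random genotype set with optional missingness, for round-trip properties
random_genotypes <- function(seed, n_ind = 12, n_loci = 4, miss = 0.1) {
  set.seed(seed)
  panel <- locus_panel(n_loci, motif_length = 2L, amin = 5L, amax = 40L)
  a1 <- matrix(sample(10:30, n_ind * n_loci, TRUE), n_ind, n_loci)
  a2 <- matrix(sample(10:30, n_ind * n_loci, TRUE), n_ind, n_loci)
  gone <- matrix(runif(n_ind * n_loci) < miss, n_ind, n_loci)
  a1[gone] <- NA; a2[gone] <- NA
  g <- genotypes(a1, a2, paste0("ind", seq_len(n_ind)), panel)
  pops <- population_map(g$ind,
                         rep(c("p1", "p2"), each = ceiling(n_ind / 2),
                             length.out = n_ind))
  list(genotypes = g, pops = pops)
}

# two populations fixed for (possibly different) alleles at one locus
two_pop_fixture <- function(a_allele = 1L, b_allele = 2L, n = 4) {
  calls <- c(replicate(n, c(a_allele, a_allele), simplify = FALSE),
             replicate(n, c(b_allele, b_allele), simplify = FALSE))
  g <- toy_genotypes(calls)
  pops <- population_map(g$ind, rep(c("pA", "pB"), each = n))
  list(g = g, pops = pops)
}

random_alignment <- function(seed, n = 6, len = 60, mutate = 3) {
  set.seed(seed)
  base <- paste(sample(c("A", "C", "G", "T"), len, TRUE), collapse = "")
  seqs <- rep(base, n)
  for (k in seq_len(mutate)) {
    i <- sample(n, 1); pos <- sample(len, 1)
    old <- substr(seqs[i], pos, pos)
    substr(seqs[i], pos, pos) <- sample(setdiff(c("A", "C", "G", "T"), old), 1)
  }
  alignment_set(seqs, paste0("s", seq_len(n)))
}
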