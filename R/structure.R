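## AMOVA, pairwise F_ST and DAPC ordination.

# Per-locus AMOVA sums of squares on gene copies with the
# number-of-different-alleles (0/1) distance. With 0/1 distances the
# sum of squared pairwise distances collapses to allele-count sums:
#   SS = (n^2 - sum_a c_a^2) / (2 n)
ss_from_counts <- function(counts) {
  n <- sum(counts)
  if (n < 1) return(0)
  (n^2 - sum(counts^2)) / (2 * n)
}

amova_components_locus <- function(g, l, pops) {
  lev <- levels(pops)
  cnts <- lapply(lev, function(p) {
    v <- locus_alleles(g, l, which(pops == p))
    if (!length(v)) return(NULL)
    table(v)
  })
  keep <- !vapply(cnts, is.null, logical(1))
  cnts <- cnts[keep]
  P <- length(cnts)
  if (P < 2L) return(NULL)
  n_p <- vapply(cnts, sum, numeric(1))
  n <- sum(n_p)
  pooled <- table(unlist(lapply(cnts, function(tb)
    rep(as.integer(names(tb)), tb))))
  ss_t <- ss_from_counts(as.numeric(pooled))
  ss_w <- sum(vapply(cnts, function(tb) ss_from_counts(as.numeric(tb)),
                     numeric(1)))
  ss_a <- ss_t - ss_w
  df_a <- P - 1
  df_w <- n - P
  if (df_w <= 0) return(NULL)
  n_prime <- (n - sum(n_p^2) / n) / df_a
  sigma_w <- ss_w / df_w
  sigma_a <- (ss_a / df_a - sigma_w) / n_prime
  c(ss_t = ss_t, ss_a = ss_a, ss_w = ss_w, sigma_a = sigma_a,
    sigma_w = sigma_w)
}

amova_fst <- function(g, pops) {
  comp <- lapply(seq_len(n_loci(g)), function(l)
    amova_components_locus(g, l, pops))
  keep <- !vapply(comp, is.null, logical(1))
  comp <- comp[keep]
  if (!length(comp)) return(NULL)
  m <- do.call(rbind, comp)
  rownames(m) <- g$loci$name[keep]
  sa <- sum(m[, "sigma_a"]); sw <- sum(m[, "sigma_w"])
  list(per_locus = m, sigma_a = sa, sigma_w = sw,
       fst = if (sa + sw != 0) sa / (sa + sw) else NA_real_)
}

#' Analysis of molecular variance (two-level)
#'
#' Locus-by-locus AMOVA partitioning allele-level variation among and within
#' populations, using the number-of-different-alleles distance between gene
#' copies (an F_ST-like analysis). Variance components are summed over loci;
#' the permutation p-value is the fraction of whole-individual permutations
#' across populations with \eqn{F_{ST}} at least the observed (estimated as
#' `(k+1)/(n+1)`). Negative variance components are retained as computed.
#'
#' @param g a [genotypes()] object.
#' @param pops a [population_map()]; populations with a single individual are
#'   excluded with a warning. Missing genotypes are dropped per locus.
#' @param n_perm number of permutations (0 disables the test).
#' @param seed RNG seed.
#' @return an object of class `"amova"`: list with `components` (per-locus
#'   matrix of sums of squares and variance components), `sigma` (summed
#'   among/within components), `percent` (percent of variation per level),
#'   `fst`, `p`, `n_perm`.
#' @export
amova <- function(g, pops, n_perm = 1000, seed = 1) {
  pops <- check_popmap(g, pops)
  sizes <- table(pops)
  if (any(sizes < 2L)) {
    drop <- names(sizes)[sizes < 2L]
    warning("excluding population(s) with a single individual: ",
            paste(drop, collapse = ", "))
    keep <- !(pops %in% drop)
    g <- g[which(keep), ]
    pops <- factor(as.character(pops[keep]))
    names(pops) <- g$ind
  }
  if (nlevels(pops) < 2L) stop("need at least 2 populations of size >= 2")
  obs <- amova_fst(g, pops)
  if (is.null(obs)) stop("no locus with data in >= 2 populations")
  p <- NA_real_
  if (n_perm > 0) {
    withr_seed(seed)
    hits <- 0L
    for (b in seq_len(n_perm)) {
      perm <- pops[sample.int(length(pops))]
      names(perm) <- g$ind
      f <- amova_fst(g, perm)$fst
      if (!is.na(f) && f >= obs$fst - 1e-12) hits <- hits + 1L
    }
    p <- (hits + 1) / (n_perm + 1)
  }
  tot <- obs$sigma_a + obs$sigma_w
  structure(list(components = obs$per_locus,
                 sigma = c(among = obs$sigma_a, within = obs$sigma_w),
                 percent = c(among = 100 * obs$sigma_a / tot,
                             within = 100 * obs$sigma_w / tot),
                 fst = obs$fst, p = p, n_perm = n_perm),
            class = "amova")
}

#' @export
print.amova <- function(x, ...) {
  cat("AMOVA (two-level, number-of-different-alleles distance)\n")
  cat(sprintf("  among populations : %6.2f %%\n", x$percent["among"]))
  cat(sprintf("  within populations: %6.2f %%\n", x$percent["within"]))
  cat(sprintf("  F_ST over all loci: %.4f (P = %s, %d permutations)\n",
              x$fst, format(x$p, digits = 3), x$n_perm))
  invisible(x)
}

#' Pairwise F_ST matrix
#'
#' Every population pair is analysed as a two-population [amova()]; p-values
#' may be Bonferroni-adjusted across pairs.
#'
#' @param g a [genotypes()] object.
#' @param pops a [population_map()].
#' @param n_perm permutations per pair.
#' @param seed RNG seed.
#' @param bonferroni adjust p-values for the number of pairs.
#' @return an object of class `"pairwise_fst"`: list with `fst` (symmetric
#'   matrix, zero diagonal), `p` (permutation p per pair) and `n_perm`.
#' @export
pairwise_fst <- function(g, pops, n_perm = 1000, seed = 1,
                         bonferroni = FALSE) {
  pops <- check_popmap(g, pops)
  lev <- levels(pops)
  K <- length(lev)
  fst <- matrix(0, K, K, dimnames = list(lev, lev))
  pm <- matrix(NA_real_, K, K, dimnames = list(lev, lev))
  m <- K * (K - 1) / 2
  for (i in seq_len(K - 1)) for (j in (i + 1):K) {
    idx <- which(pops %in% lev[c(i, j)])
    sub <- g[idx, ]
    subpops <- factor(as.character(pops[idx]))
    names(subpops) <- sub$ind
    a <- amova(sub, subpops, n_perm = n_perm, seed = seed + i * K + j)
    fst[i, j] <- fst[j, i] <- a$fst
    pv <- if (bonferroni) min(1, a$p * m) else a$p
    pm[i, j] <- pm[j, i] <- pv
  }
  structure(list(fst = fst, p = pm, n_perm = n_perm),
            class = "pairwise_fst")
}

#' @export
print.pairwise_fst <- function(x, digits = 3, ...) {
  cat("Pairwise F_ST (lower triangle) / permutation P (upper)\n")
  m <- x$fst
  m[upper.tri(m)] <- x$p[upper.tri(x$p)]
  print(round(m, digits))
  invisible(x)
}

## ---------------------------------------------------------------------------
## DAPC
## ---------------------------------------------------------------------------

# Individuals as centred allele-dosage vectors: one column per allele per
# locus, value = (copies of that allele)/2; missing genotypes imputed at the
# column mean.
allele_dosage_matrix <- function(g, scale = FALSE) {
  cols <- list()
  for (l in seq_len(n_loci(g))) {
    alleles <- sort(unique(locus_alleles(g, l)))
    for (al in alleles) {
      v <- ((g$a1[, l] == al) + (g$a2[, l] == al)) / 2
      v[is.na(v)] <- mean(v, na.rm = TRUE)
      cols[[paste0(g$loci$name[l], ".", al)]] <- v
    }
  }
  X <- do.call(cbind, cols)
  rownames(X) <- g$ind
  scale(X, center = TRUE, scale = scale)
}

# BIC profile of k-means solutions on PC scores, spherical-Gaussian flavour:
# n log(WSS/n) + k d log(n), each cluster contributing d mean parameters.
kmeans_bic <- function(scores, k_max, seed) {
  withr_seed(seed)
  n <- nrow(scores); d <- ncol(scores)
  vapply(seq_len(k_max), function(k) {
    wss <- if (k == 1) sum(scale(scores, scale = FALSE)^2)
    else stats::kmeans(scores, k, nstart = 20, iter.max = 50)$tot.withinss
    n * log(wss / n) + k * d * log(n)
  }, numeric(1))
}

#' Discriminant analysis of principal components
#'
#' PCA of the centred allele-dosage matrix followed by linear discriminant
#' analysis on the retained principal components. Groups may be given (e.g. a
#' population map) or inferred without locational priors by k-means over the
#' PC scores, the number of clusters selected by BIC over `k = 1..k_max`.
#'
#' @param g a [genotypes()] object.
#' @param groups optional grouping (a [population_map()] or factor). When
#'   `NULL`, clusters are inferred.
#' @param n_pca number of principal components retained; default keeps the
#'   components explaining 90% of variance, capped at `n_ind/3`.
#' @param k_max maximum number of clusters scanned when inferring groups
#'   (default: number of populations in `groups`, else 8, plus 2).
#' @param scale scale allele-dosage columns to unit variance.
#' @param seed RNG seed for k-means.
#' @return an object of class `"dapc_result"`: list with `coords`
#'   (individual coordinates on the discriminant axes), `posterior`
#'   (assignment probabilities, rows sum to 1), `groups`, `n_pca`, `k`,
#'   `bic` (profile when clusters were inferred), `no_structure` flag, `lda`.
#' @export
dapc <- function(g, groups = NULL, n_pca = NULL, k_max = NULL, scale = FALSE,
                 seed = 1) {
  X <- allele_dosage_matrix(g, scale = scale)
  pc <- stats::prcomp(X, center = FALSE)
  pos <- which(pc$sdev > 1e-9)
  if (is.null(n_pca)) {
    cum <- cumsum(pc$sdev[pos]^2) / sum(pc$sdev[pos]^2)
    n_pca <- min(max(which(cum >= 0.9)[1], 2L), floor(n_ind(g) / 3))
  }
  n_pca <- min(n_pca, length(pos), n_ind(g) - 1L)
  scores <- pc$x[, seq_len(n_pca), drop = FALSE]
  bic <- NULL
  if (is.null(groups)) {
    if (is.null(k_max)) k_max <- 10L
    bic <- kmeans_bic(scores, k_max, seed)
    k <- which.min(bic)
    if (k == 1L) {
      return(structure(list(coords = NULL, posterior = NULL,
                            groups = factor(rep(1, n_ind(g))),
                            n_pca = n_pca, k = 1L, bic = bic,
                            no_structure = TRUE, lda = NULL),
                       class = "dapc_result"))
    }
    withr_seed(seed)
    groups <- factor(stats::kmeans(scores, k, nstart = 20,
                                   iter.max = 50)$cluster)
  } else {
    groups <- factor(as.character(if (inherits(groups, "popmap"))
      groups[g$ind] else groups))
    k <- nlevels(groups)
  }
  if (nlevels(groups) < 2L) stop("need at least 2 groups for the DA step")
  ld <- MASS::lda(scores, grouping = groups)
  pr <- stats::predict(ld, scores)
  structure(list(coords = pr$x, posterior = pr$posterior, groups = groups,
                 n_pca = n_pca, k = k, bic = bic, no_structure = FALSE,
                 lda = ld),
            class = "dapc_result")
}

#' @export
print.dapc_result <- function(x, ...) {
  if (x$no_structure) {
    cat("DAPC:", x$n_pca, "PCs retained; BIC selects k = 1 (no structure)\n")
    return(invisible(x))
  }
  cat("DAPC:", x$n_pca, "PCs retained,", nlevels(x$groups), "groups,",
      ncol(x$coords), "discriminant axis/axes\n")
  cat("group sizes:\n")
  print(table(x$groups))
  invisible(x)
}

#' @export
plot.dapc_result <- function(x, ...) {
  if (x$no_structure || is.null(x$coords)) {
    warning("no discriminant axes to plot")
    return(invisible(x))
  }
  cols <- as.integer(x$groups)
  if (ncol(x$coords) >= 2) {
    plot(x$coords[, 1], x$coords[, 2], col = cols, pch = 19,
         xlab = "LD1", ylab = "LD2", ...)
  } else {
    d <- x$coords[, 1]
    plot(d, jitter(rep(0, length(d))), col = cols, pch = 19,
         xlab = "LD1", ylab = "", yaxt = "n", ...)
  }
  invisible(x)
}
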