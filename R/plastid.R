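## Haplotype identification and diversity from concatenated plastid
## alignments.

align_matrix <- function(a) {
  do.call(rbind, strsplit(a$seq, ""))
}

# columns free of gaps/N (complete-deletion site filter)
clean_columns <- function(m) {
  !apply(m == "-" | m == "N", 2, any)
}

#' Identify haplotypes in an alignment
#'
#' Haplotypes are equivalence classes of sequences identical at all retained
#' sites. By default every column containing a gap or `N` in any sequence is
#' excluded before comparison (complete deletion); `exclude_gaps = FALSE`
#' retains all columns. Ids are assigned in decreasing frequency order, ties
#' broken by first occurrence after lexicographic sort of the core sequence.
#'
#' @param a an [alignment_set()].
#' @param exclude_gaps drop gap/N columns before comparing sequences.
#' @param prefix haplotype id prefix (e.g. `"CEh"`).
#' @return an object of class `"haplotype_table"`: list with `table` (data
#'   frame: `haplotype`, `count`, `frequency`), `assignment` (haplotype id per
#'   input sequence), `sequences` (representative full-length sequence per
#'   haplotype), `n_variable` and `n_informative` site counts (over retained
#'   columns), `variable_sites` (positions in the retained-column coordinate
#'   of the original alignment).
#' @export
identify_haplotypes <- function(a, exclude_gaps = TRUE, prefix = "H") {
  if (!length(a$seq)) stop("empty alignment")
  m <- align_matrix(a)
  keep <- if (exclude_gaps) clean_columns(m) else rep(TRUE, ncol(m))
  core <- apply(m[, keep, drop = FALSE], 1, paste, collapse = "")
  if (!sum(keep)) core <- rep("", nrow(m))
  uniq <- sort(unique(core))
  counts <- vapply(uniq, function(u) sum(core == u), integer(1))
  ord <- order(-counts, uniq)
  uniq <- uniq[ord]; counts <- counts[ord]
  ids <- paste0(prefix, seq_along(uniq))
  assignment <- ids[match(core, uniq)]
  names(assignment) <- a$ids
  reps <- vapply(uniq, function(u) a$seq[match(u, core)], character(1))
  mk <- m[, keep, drop = FALSE]
  nstates <- apply(mk, 2, function(col) length(unique(col)))
  variable <- which(nstates > 1)
  informative <- sum(vapply(variable, function(j) {
    tab <- table(mk[, j])
    sum(tab >= 2) >= 2
  }, logical(1)))
  structure(list(
    table = data.frame(haplotype = ids, count = counts,
                       frequency = counts / sum(counts), row.names = NULL),
    assignment = assignment, sequences = stats::setNames(unname(reps), ids),
    n_variable = length(variable), n_informative = informative,
    variable_sites = variable, n_sites_retained = sum(keep)),
    class = "haplotype_table")
}

#' @export
print.haplotype_table <- function(x, ...) {
  cat(nrow(x$table), "haplotype(s);", x$n_variable, "variable site(s),",
      x$n_informative, "parsimony-informative\n")
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Haplotype diversity with sampling standard deviation
#'
#' Nei's unbiased estimator \eqn{h = n(1 - \sum p_i^2)/(n - 1)} and its
#' sampling variance
#' \eqn{V(h) = \frac{2}{n(n-1)}\{2(n-2)[\sum p_i^3 - (\sum p_i^2)^2] +
#' \sum p_i^2 - (\sum p_i^2)^2\}}.
#'
#' @param counts integer haplotype counts (or a `haplotype_table`).
#' @return named numeric vector `c(h, sd)`.
#' @export
haplotype_diversity <- function(counts) {
  if (inherits(counts, "haplotype_table")) counts <- counts$table$count
  n <- sum(counts)
  if (n < 2) stop("need at least 2 sequences")
  p <- counts / n
  s2 <- sum(p^2); s3 <- sum(p^3)
  h <- n / (n - 1) * (1 - s2)
  v <- 2 / (n * (n - 1)) * (2 * (n - 2) * (s3 - s2^2) + s2 - s2^2)
  c(h = h, sd = sqrt(max(v, 0)))
}

#' Nucleotide diversity with sampling standard deviation
#'
#' Average proportion of differing sites over all sequence pairs, computed on
#' the columns retained after gap/N exclusion; the standard deviation uses
#' Nei's total-variance formula
#' \eqn{V(\pi) = \frac{n+1}{3(n-1)L}\pi + \frac{2(n^2+n+3)}{9n(n-1)}\pi^2}.
#'
#' @param a an [alignment_set()].
#' @param exclude_gaps drop gap/N columns before comparison.
#' @return named numeric vector `c(pi, sd, percent)` (`percent = 100 * pi`).
#' @export
nucleotide_diversity <- function(a, exclude_gaps = TRUE) {
  n <- length(a$seq)
  if (n < 2) stop("need at least 2 sequences")
  m <- align_matrix(a)
  keep <- if (exclude_gaps) clean_columns(m) else rep(TRUE, ncol(m))
  m <- m[, keep, drop = FALSE]
  L <- ncol(m)
  if (L < 1) stop("no sites left after exclusion")
  tot <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    tot <- tot + sum(m[i, ] != m[j, ])
  pi <- tot / choose(n, 2) / L
  v <- (n + 1) / (3 * (n - 1) * L) * pi +
    2 * (n^2 + n + 3) / (9 * n * (n - 1)) * pi^2
  c(pi = pi, sd = sqrt(max(v, 0)), percent = 100 * pi)
}

#' GC content of an alignment
#'
#' \eqn{(G + C)/(A + C + G + T)}; gaps and `N` are excluded from the
#' denominator.
#'
#' @param a an [alignment_set()] (or a character vector of sequences).
#' @return GC fraction in `[0, 1]`.
#' @export
gc_content <- function(a) {
  seqs <- if (inherits(a, "alignment_set")) a$seq else toupper(a)
  chars <- unlist(strsplit(seqs, ""))
  gc <- sum(chars %in% c("G", "C"))
  acgt <- sum(chars %in% c("A", "C", "G", "T"))
  if (!acgt) stop("no unambiguous bases")
  gc / acgt
}

#' Plastid diversity summary
#'
#' Convenience wrapper combining [identify_haplotypes()],
#' [haplotype_diversity()], [nucleotide_diversity()] and [gc_content()] for a
#' set of per-region alignments that are concatenated for haplotype-level
#' statistics.
#'
#' @param regions list of [alignment_set()] objects (one per plastid region).
#' @param prefix haplotype id prefix.
#' @return an object of class `"plastid_diversity"`: list with `haplotypes`,
#'   `h` (value and sd), `pi` (value, sd, percent), `gc` (per region),
#'   `alignment_length`.
#' @export
plastid_diversity <- function(regions, prefix = "H") {
  if (inherits(regions, "alignment_set")) regions <- list(regions)
  conc <- concatenate_alignments(regions)
  hap <- identify_haplotypes(conc, prefix = prefix)
  h <- if (length(conc$seq) >= 2) haplotype_diversity(hap)
       else c(h = NA_real_, sd = NA_real_)
  pi <- if (length(conc$seq) >= 2) nucleotide_diversity(conc)
        else c(pi = NA_real_, sd = NA_real_, percent = NA_real_)
  gc <- vapply(regions, gc_content, numeric(1))
  names(gc) <- vapply(regions, function(r) r$region[1], character(1))
  structure(list(haplotypes = hap, h = h, pi = pi, gc = gc,
                 alignment_length = nchar(conc$seq[1])),
            class = "plastid_diversity")
}

#' @export
print.plastid_diversity <- function(x, ...) {
  cat("Concatenated alignment of", x$alignment_length, "bp\n")
  print(x$haplotypes)
  cat(sprintf("h  = %.4f +/- %.4f\n", x$h["h"], x$h["sd"]))
  cat(sprintf("pi = %.6f +/- %.6f (%.4f %%)\n", x$pi["pi"], x$pi["sd"],
              x$pi["percent"]))
  cat("GC content per region:",
      paste(sprintf("%s %.3f", names(x$gc), x$gc), collapse = ", "), "\n")
  invisible(x)
}
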