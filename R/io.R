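#' Construct a diploid microsatellite genotype set
#'
#' The central data container of the package: diploid allele calls (in repeat
#' units) for a set of individuals at a panel of microsatellite loci. Alleles
#' are stored internally as integer repeat counts because the stepwise
#' mutation machinery operates on repeat numbers; fragment sizes in base pairs
#' are converted at ingest using each locus' motif length and size offset.
#'
#' @param a1,a2 integer matrices (individuals x loci) holding the two allele
#'   copies per call, in repeat units; `NA` marks a missing genotype (both
#'   copies must then be `NA`).
#' @param ind character vector of unique individual identifiers.
#' @param loci data frame describing the locus panel with columns `name`
#'   (unique), `motif_length` (bp per repeat unit, >= 1), `amin`, `amax`
#'   (allele range in repeat units, `amin < amax`) and optionally `offset`
#'   (bp offset used for fragment-size conversion).
#' @return an object of class `"genotypes"`.
#' @examples
#' g <- genotypes(a1 = matrix(10L, 2, 1), a2 = matrix(12L, 2, 1),
#'                ind = c("i1", "i2"),
#'                loci = data.frame(name = "L1", motif_length = 2,
#'                                  amin = 5, amax = 40))
#' n_ind(g)
#' @export
genotypes <- function(a1, a2, ind, loci) {
  a1 <- as.matrix(a1); a2 <- as.matrix(a2)
  storage.mode(a1) <- "integer"; storage.mode(a2) <- "integer"
  if (!all(dim(a1) == dim(a2))) stop("a1 and a2 must have identical dimensions")
  if (nrow(a1) < 1L || ncol(a1) < 1L)
    stop("need at least 1 individual and 1 locus")
  if (length(ind) != nrow(a1)) stop("length(ind) != nrow(a1)")
  if (anyDuplicated(ind)) stop("individual ids must be unique")
  loci <- as.data.frame(loci)
  if (is.null(loci$offset)) loci$offset <- 0L
  need <- c("name", "motif_length", "amin", "amax")
  if (!all(need %in% names(loci))) stop("loci must have columns: ",
                                        paste(need, collapse = ", "))
  if (nrow(loci) != ncol(a1)) stop("nrow(loci) != ncol(a1)")
  if (anyDuplicated(loci$name)) stop("locus names must be unique")
  if (any(loci$motif_length < 1)) stop("motif_length must be >= 1")
  if (any(loci$amin >= loci$amax)) stop("allele range must satisfy amin < amax")
  if (any(xor(is.na(a1), is.na(a2))))
    stop("half-missing calls are not allowed: both allele copies must be NA")
  for (l in seq_len(ncol(a1))) {
    v <- c(a1[, l], a2[, l])
    bad <- !is.na(v) & (v < loci$amin[l] | v > loci$amax[l])
    if (any(bad)) stop("allele outside declared range at locus ", loci$name[l])
  }
  dimnames(a1) <- dimnames(a2) <- list(ind, loci$name)
  structure(list(a1 = a1, a2 = a2, ind = as.character(ind), loci = loci),
            class = "genotypes")
}

#' @export
print.genotypes <- function(x, ...) {
  cat("Diploid microsatellite genotypes:", n_ind(x), "individuals x",
      n_loci(x), "loci\n")
  miss <- mean(is.na(x$a1))
  cat(sprintf("missing calls: %.1f%%\n", 100 * miss))
  invisible(x)
}

#' Number of individuals / loci in a genotype set
#' @param g a `genotypes` object.
#' @return an integer count.
#' @export
n_ind <- function(g) nrow(g$a1)

#' @rdname n_ind
#' @export
n_loci <- function(g) ncol(g$a1)

#' Subset a genotype set by individuals and/or loci
#' @param x a `genotypes` object.
#' @param i individual index (any standard row index).
#' @param j locus index.
#' @param ... unused.
#' @export
`[.genotypes` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(n_ind(x))
  if (missing(j)) j <- seq_len(n_loci(x))
  genotypes(x$a1[i, j, drop = FALSE], x$a2[i, j, drop = FALSE],
            x$ind[i], x$loci[j, , drop = FALSE])
}

#' Create a population map
#'
#' Assigns every individual to exactly one population (sampling site).
#'
#' @param ind character vector of individual identifiers.
#' @param pop vector of population labels, parallel to `ind`.
#' @param coords optional data frame of decimal-degree site coordinates with
#'   columns `pop`, `lon`, `lat`.
#' @return a named factor of class `"popmap"` (names = individuals).
#' @export
population_map <- function(ind, pop, coords = NULL) {
  if (length(ind) != length(pop)) stop("ind and pop must have equal length")
  if (anyDuplicated(ind)) stop("each individual must appear exactly once")
  out <- factor(pop)
  names(out) <- as.character(ind)
  attr(out, "coords") <- coords
  class(out) <- c("popmap", "factor")
  out
}

#' @export
print.popmap <- function(x, ...) {
  cat("Population map:", length(x), "individuals in", nlevels(x),
      "populations\n")
  print(table(unclass(x)))
  invisible(x)
}

check_popmap <- function(g, pops) {
  if (!all(g$ind %in% names(pops)))
    stop("population map is missing individuals: ",
         paste(setdiff(g$ind, names(pops)), collapse = ", "))
  p <- factor(as.character(pops[g$ind]))
  names(p) <- g$ind
  p
}

## ---------------------------------------------------------------------------
## GenePop and csv genotype formats
## ---------------------------------------------------------------------------

#' Read diploid microsatellite genotypes
#'
#' Reads a GenePop (`.gen`) file or the package's csv genotype table and
#' returns both the genotype matrix and the population map. GenePop allele
#' coding width (2 or 3 digits) is auto-detected; allele `0` is missing. When
#' `units = "bp"` fragment sizes are converted to repeat units with each
#' locus' motif length and an offset estimated as the minimum observed size
#' modulo the motif (unless `loci$offset` is supplied); off-lattice sizes are
#' rounded to the nearest repeat unit with a warning.
#'
#' @param path path to the input file.
#' @param dialect `"genepop"` or `"csv"`. The csv dialect has columns `ind`,
#'   `pop`, then one column per allele copy named `<locus>_1`, `<locus>_2`;
#'   missing calls are `NA`.
#' @param loci optional locus panel data frame (as in [genotypes()]); when
#'   absent a panel is inferred from the data (motif length 1, range padded
#'   around the observed alleles).
#' @param units `"repeat"` (default) if calls already are repeat counts, or
#'   `"bp"` for fragment sizes.
#' @return a list with elements `genotypes` (a [genotypes()] object), `pops`
#'   (a [population_map()]) and `report` (conversion notes).
#' @export
read_genotypes <- function(path, dialect = c("genepop", "csv"), loci = NULL,
                           units = c("repeat", "bp")) {
  dialect <- match.arg(dialect)
  units <- match.arg(units)
  if (!file.exists(path)) stop("file does not exist: ", path)
  raw <- switch(dialect,
                genepop = parse_genepop(path),
                csv = parse_genotype_csv(path))
  conv <- convert_alleles(raw$a1, raw$a2, raw$locus_names, loci, units)
  g <- genotypes(conv$a1, conv$a2, raw$ind, conv$loci)
  pops <- population_map(raw$ind, raw$pop)
  list(genotypes = g, pops = pops, report = conv$report)
}

parse_genepop <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*$", lines)]
  if (length(lines) < 3L) stop("malformed GenePop file: fewer than 3 lines")
  # line 1 = title; locus names until first 'pop'
  pop_lines <- grep("^\\s*pop\\s*$", lines, ignore.case = TRUE)
  if (!length(pop_lines)) stop("malformed GenePop file: no 'pop' line")
  first_pop <- pop_lines[1L]
  locus_names <- unlist(strsplit(paste(lines[2:(first_pop - 1L)],
                                       collapse = ","), "[,\\s]+"))
  locus_names <- locus_names[nzchar(locus_names)]
  ind <- character(); pop <- character()
  a1 <- list(); a2 <- list()
  pop_id <- 0L
  for (k in seq(first_pop, length(lines))) {
    line <- lines[k]
    if (grepl("^\\s*pop\\s*$", line, ignore.case = TRUE)) {
      pop_id <- pop_id + 1L
      next
    }
    bits <- strsplit(line, ",")[[1L]]
    if (length(bits) != 2L)
      stop("malformed GenePop file at line ", k, ": expected 'id , calls'")
    id <- trimws(bits[1L])
    calls <- unlist(strsplit(trimws(bits[2L]), "\\s+"))
    if (length(calls) != length(locus_names))
      stop("malformed GenePop file at line ", k, ": ", length(calls),
           " calls for ", length(locus_names), " loci")
    w <- nchar(calls[1L])
    if (!w %in% c(4L, 6L))
      stop("malformed GenePop file at line ", k,
           ": calls must be 4 or 6 digits wide")
    half <- w %/% 2L
    x1 <- as.integer(substr(calls, 1L, half))
    x2 <- as.integer(substr(calls, half + 1L, w))
    if (anyNA(x1) || anyNA(x2))
      stop("malformed GenePop file at line ", k, ": non-numeric allele call")
    x1[x1 == 0L] <- NA_integer_; x2[x2 == 0L] <- NA_integer_
    x2[is.na(x1)] <- NA_integer_; x1[is.na(x2)] <- NA_integer_
    ind <- c(ind, id); pop <- c(pop, paste0("pop", pop_id))
    a1[[length(a1) + 1L]] <- x1; a2[[length(a2) + 1L]] <- x2
  }
  list(ind = ind, pop = pop, locus_names = locus_names,
       a1 = do.call(rbind, a1), a2 = do.call(rbind, a2))
}

parse_genotype_csv <- function(path) {
  d <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!all(c("ind", "pop") %in% names(d)))
    stop("csv genotype table needs 'ind' and 'pop' columns")
  allele_cols <- setdiff(names(d), c("ind", "pop"))
  base <- sub("_[12]$", "", allele_cols)
  locus_names <- unique(base)
  c1 <- paste0(locus_names, "_1"); c2 <- paste0(locus_names, "_2")
  if (!all(c(c1, c2) %in% allele_cols))
    stop("csv dialect requires '<locus>_1' and '<locus>_2' columns per locus")
  a1 <- as.matrix(d[, c1, drop = FALSE]); a2 <- as.matrix(d[, c2, drop = FALSE])
  storage.mode(a1) <- "integer"; storage.mode(a2) <- "integer"
  miss <- is.na(a1) | is.na(a2)
  a1[miss] <- NA_integer_; a2[miss] <- NA_integer_
  list(ind = as.character(d$ind), pop = as.character(d$pop),
       locus_names = locus_names, a1 = a1, a2 = a2)
}

convert_alleles <- function(a1, a2, locus_names, loci, units) {
  L <- length(locus_names)
  report <- list(units = units, rounded = integer(0))
  if (is.null(loci)) {
    loci <- data.frame(name = locus_names, motif_length = 1L,
                       amin = NA_integer_, amax = NA_integer_, offset = 0L)
    infer_range <- TRUE
  } else {
    loci <- as.data.frame(loci)
    if (!setequal(loci$name, locus_names))
      stop("locus panel names do not match file loci")
    loci <- loci[match(locus_names, loci$name), , drop = FALSE]
    if (is.null(loci$offset)) loci$offset <- NA_integer_
    infer_range <- FALSE
  }
  for (l in seq_len(L)) {
    v1 <- a1[, l]; v2 <- a2[, l]
    if (units == "bp") {
      m <- loci$motif_length[l]
      off <- loci$offset[l]
      obs <- c(v1, v2); obs <- obs[!is.na(obs)]
      if (is.na(off)) off <- if (length(obs)) min(obs) %% m else 0L
      r1 <- (v1 - off) / m; r2 <- (v2 - off) / m
      offlat <- c(r1, r2) %% 1 != 0
      if (any(offlat, na.rm = TRUE)) {
        warning("locus ", locus_names[l],
                ": allele size not on the motif lattice; rounded")
        report$rounded <- c(report$rounded, sum(offlat, na.rm = TRUE))
      }
      v1 <- as.integer(round(r1)); v2 <- as.integer(round(r2))
      loci$offset[l] <- off
    }
    if (infer_range || is.na(loci$amin[l])) {
      obs <- c(v1, v2); obs <- obs[!is.na(obs)]
      loci$amin[l] <- if (length(obs)) min(obs) - 5L else 0L
      loci$amax[l] <- if (length(obs)) max(obs) + 5L else 1L
      if (loci$amax[l] - loci$amin[l] < 2L) loci$amax[l] <- loci$amin[l] + 2L
    }
    a1[, l] <- v1; a2[, l] <- v2
  }
  loci$offset[is.na(loci$offset)] <- 0L
  list(a1 = a1, a2 = a2, loci = loci, report = report)
}

#' Write genotypes to GenePop or csv
#'
#' @param g a `genotypes` object.
#' @param pops a [population_map()] covering the individuals of `g`.
#' @param path output file path.
#' @param dialect `"genepop"` or `"csv"`.
#' @param title GenePop title line.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(g, pops, path, dialect = c("genepop", "csv"),
                            title = "edgepop export") {
  dialect <- match.arg(dialect)
  pops <- check_popmap(g, pops)
  if (dialect == "csv") {
    d <- data.frame(ind = g$ind, pop = as.character(pops),
                    check.names = FALSE)
    for (l in seq_len(n_loci(g))) {
      d[[paste0(g$loci$name[l], "_1")]] <- g$a1[, l]
      d[[paste0(g$loci$name[l], "_2")]] <- g$a2[, l]
    }
    utils::write.csv(d, path, row.names = FALSE, na = "NA")
    return(invisible(path))
  }
  mx <- suppressWarnings(max(c(g$a1, g$a2), na.rm = TRUE))
  width <- if (is.finite(mx) && mx > 99) 3L else 2L
  fmt <- paste0("%0", width, "d")
  code <- function(x) {
    x[is.na(x)] <- 0L
    sprintf(fmt, x)
  }
  con <- file(path, "w"); on.exit(close(con))
  writeLines(title, con)
  writeLines(g$loci$name, con)
  for (p in levels(pops)) {
    writeLines("pop", con)
    idx <- which(pops == p)
    for (i in idx) {
      calls <- paste0(code(g$a1[i, ]), code(g$a2[i, ]))
      writeLines(paste0(g$ind[i], " , ", paste(calls, collapse = " ")), con)
    }
  }
  invisible(path)
}

## ---------------------------------------------------------------------------
## Aligned FASTA
## ---------------------------------------------------------------------------

#' Construct an aligned sequence set
#'
#' @param sequences character vector of equal-length aligned sequences over
#'   `A,C,G,T,-,N` (case-insensitive).
#' @param ids unique sequence identifiers.
#' @param region optional region label (bookkeeping for concatenation).
#' @return an object of class `"alignment_set"`.
#' @export
alignment_set <- function(sequences, ids, region = "region1") {
  sequences <- toupper(as.character(sequences))
  if (length(sequences) < 1L) stop("empty alignment")
  if (length(unique(nchar(sequences))) != 1L)
    stop("ragged alignment: sequences differ in length")
  if (length(ids) != length(sequences)) stop("ids and sequences differ in length")
  if (anyDuplicated(ids))
    stop("duplicate sequence ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  bad <- grepl("[^ACGTN-]", sequences)
  if (any(bad)) stop("unexpected characters in sequences: ",
                     paste(ids[bad], collapse = ", "))
  structure(list(seq = sequences, ids = as.character(ids),
                 region = as.character(region)),
            class = "alignment_set")
}

#' @export
print.alignment_set <- function(x, ...) {
  cat("Alignment:", length(x$seq), "sequences x", nchar(x$seq[1]), "bp",
      sprintf("(region%s: %s)\n", if (length(x$region) > 1) "s" else "",
              paste(x$region, collapse = "+")))
  invisible(x)
}

#' Read aligned FASTA files
#'
#' Each file is one aligned region; all files must contain the same sequence
#' ids. Parsing is done with \pkg{ape}.
#'
#' @param paths character vector of FASTA file paths.
#' @param regions optional region labels (default: file base names).
#' @return a list of [alignment_set()] objects, one per file, ids in the
#'   order of the first file.
#' @export
read_fasta_alignment <- function(paths, regions = NULL) {
  if (is.null(regions)) regions <- sub("\\.[^.]*$", "", basename(paths))
  out <- vector("list", length(paths))
  ref_ids <- NULL
  for (k in seq_along(paths)) {
    d <- ape::read.FASTA(paths[k])
    ids <- names(d)
    if (anyDuplicated(ids))
      stop("duplicate sequence ids in ", paths[k], ": ",
           paste(unique(ids[duplicated(ids)]), collapse = ", "))
    seqs <- toupper(vapply(as.character(d), paste, "", collapse = ""))
    if (length(unique(nchar(seqs))) != 1L)
      stop("ragged alignment in ", paths[k])
    if (is.null(ref_ids)) ref_ids <- ids
    else if (!setequal(ids, ref_ids))
      stop("sequence ids differ across regions; offenders: ",
           paste(union(setdiff(ids, ref_ids), setdiff(ref_ids, ids)),
                 collapse = ", "))
    out[[k]] <- alignment_set(unname(seqs[ref_ids]), ref_ids, regions[k])
  }
  names(out) <- regions
  out
}

#' Write an alignment to FASTA
#' @param a an `alignment_set`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta_alignment <- function(a, path) {
  con <- file(path, "w"); on.exit(close(con))
  for (i in seq_along(a$seq))
    writeLines(c(paste0(">", a$ids[i]), a$seq[i]), con)
  invisible(path)
}

#' Concatenate aligned regions
#'
#' Joins several per-region alignments (identical id sets) into a single
#' alignment treated as one sequence in all downstream analyses.
#'
#' @param regions a list of [alignment_set()] objects.
#' @return an [alignment_set()] whose length is the sum of region lengths.
#' @export
concatenate_alignments <- function(regions) {
  if (!length(regions)) stop("no regions to concatenate")
  ref <- regions[[1L]]
  seqs <- ref$seq
  labels <- ref$region
  if (length(regions) > 1L) for (k in 2:length(regions)) {
    r <- regions[[k]]
    if (!setequal(r$ids, ref$ids))
      stop("id set mismatch between regions: ",
           paste(union(setdiff(r$ids, ref$ids), setdiff(ref$ids, r$ids)),
                 collapse = ", "))
    seqs <- paste0(seqs, r$seq[match(ref$ids, r$ids)])
    labels <- c(labels, r$region)
  }
  alignment_set(seqs, ref$ids, labels)
}
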