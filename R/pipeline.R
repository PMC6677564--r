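## One-config orchestration of the full analysis with a run manifest.

# independent per-stage seed streams from one master seed (counter-based so
# toggling a stage does not shift the randomness of the others)
stage_seed <- function(seed, stage) {
  idx <- match(stage, c("stats", "structure", "plastid", "abc"))
  as.integer((as.numeric(seed) * 48271 + idx * 2654435) %% 2147483647)
}

write_tsv <- function(d, path) {
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full analysis pipeline
#'
#' Orchestrates diversity statistics, population structure, plastid
#' diversity and the ABC demographic analysis from a single configuration,
#' writing tab-separated outputs plus a JSON run manifest (inputs, seeds,
#' checksums, outputs, per-stage status).
#'
#' @param config a named list or the path to a YAML file with fields:
#'   `genotypes` (path), `dialect` (`"genepop"`/`"csv"`), `fasta` (character
#'   vector of aligned FASTA paths, optional), `out` (output directory),
#'   `seed` (mandatory), `stages` (subset of
#'   `c("stats", "structure", "plastid", "abc")`), `n_perm`,
#'   `rarefaction_g`, and `abc` (list: `n_per_scenario`, `k_direct`,
#'   `k_logistic`, `k_est`, `n_pods`).
#' @return the manifest, invisibly. Any stage failure is recorded in the
#'   manifest before the error is re-signalled.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config$seed)) stop("config$seed is mandatory")
  if (is.null(config$genotypes)) stop("config$genotypes is mandatory")
  stages <- config$stages %||% c("stats", "structure", "plastid", "abc")
  if (!length(config$fasta)) stages <- setdiff(stages, "plastid")
  out_dir <- config$out %||% "edgepop_out"
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  n_perm <- config$n_perm %||% 1000
  inputs <- c(config$genotypes, config$fasta)
  if (!all(file.exists(inputs)))
    stop("missing input file(s): ",
         paste(inputs[!file.exists(inputs)], collapse = ", "))
  manifest <- list(
    package = "edgepop",
    version = as.character(utils::packageVersion("edgepop")),
    seed = config$seed,
    inputs = as.list(tools::md5sum(inputs)),
    stages = list(), outputs = character(0))
  gin <- read_genotypes(config$genotypes,
                        dialect = config$dialect %||% "genepop")
  g <- gin$genotypes; pops <- gin$pops
  if (any(c("structure", "stats") %in% stages) && nlevels(pops) < 1L)
    stop("population map required for the stats/structure stages")
  err <- NULL
  run_stage <- function(name, fun) {
    res <- tryCatch({
      fun()
      manifest$stages[[name]] <<- "ok"
    }, error = function(e) {
      manifest$stages[[name]] <<- paste("failed:", conditionMessage(e))
      err <<- e
    })
    invisible(res)
  }
  add_out <- function(p) manifest$outputs <<- c(manifest$outputs, p)

  if ("stats" %in% stages) run_stage("stats", function() {
    ds <- diversity_stats(g, pops, rarefaction_g = config$rarefaction_g,
                          n_perm = n_perm, n_mc = config$n_mc %||% 1e5,
                          seed = stage_seed(config$seed, "stats"))
    add_out(write_tsv(ds$per_locus, file.path(out_dir, "per_locus_stats.tsv")))
    pa <- if (nlevels(pops) >= 2) private_alleles(g, pops) else NULL
    if (!is.null(pa))
      add_out(write_tsv(data.frame(pop = names(pa), private_alleles = pa),
                        file.path(out_dir, "private_alleles.tsv")))
  })
  if ("structure" %in% stages) run_stage("structure", function() {
    sd <- stage_seed(config$seed, "structure")
    am <- amova(g, pops, n_perm = n_perm, seed = sd)
    add_out(write_tsv(data.frame(level = c("among", "within"),
                                 sigma = am$sigma, percent = am$percent,
                                 fst = c(am$fst, NA), p = c(am$p, NA)),
                      file.path(out_dir, "amova.tsv")))
    pw <- pairwise_fst(g, pops, n_perm = max(100, n_perm %/% 10), seed = sd)
    add_out(write_tsv(as.data.frame(pw$fst),
                      file.path(out_dir, "pairwise_fst.tsv")))
    dp <- dapc(g, groups = NULL, seed = sd)
    if (!dp$no_structure)
      add_out(write_tsv(data.frame(ind = g$ind, group = dp$groups,
                                   dp$coords),
                        file.path(out_dir, "dapc_coords.tsv")))
  })
  if ("plastid" %in% stages) run_stage("plastid", function() {
    regions <- read_fasta_alignment(config$fasta)
    pd <- plastid_diversity(regions)
    add_out(write_tsv(pd$haplotypes$table,
                      file.path(out_dir, "haplotypes.tsv")))
    add_out(write_tsv(
      data.frame(stat = c("h", "h_sd", "pi", "pi_sd", "pi_percent",
                          paste0("gc_", names(pd$gc))),
                 value = c(pd$h, pd$pi, pd$gc)),
      file.path(out_dir, "plastid_diversity.tsv")))
  })
  if ("abc" %in% stages) run_stage("abc", function() {
    sd <- stage_seed(config$seed, "abc")
    cfg <- config$abc %||% list()
    nps <- cfg$n_per_scenario %||% 1000
    ss <- scenario_set(g$loci, n_ind(g))
    ref <- build_reference_table(ss, nps, seed = sd)
    n <- nrow(ref$stats)
    fit <- abc_fit(abc_summary_stats(g), ref,
                   k_direct = cfg$k_direct %||% max(50, n %/% 400),
                   k_logistic = cfg$k_logistic %||% max(200, n %/% 5),
                   k_est = cfg$k_est %||% max(100, n %/% 10))
    add_out(write_tsv(
      data.frame(scenario = names(fit$direct), direct = fit$direct,
                 logistic = fit$logistic$prob),
      file.path(out_dir, "abc_scenario_probs.tsv")))
    add_out(write_tsv(fit$posterior$summary,
                      file.path(out_dir, "abc_posterior.tsv")))
    if (!is.null(cfg$n_pods) && cfg$n_pods > 0) {
      pe <- predictive_error(ref, n_pods = cfg$n_pods, seed = sd + 1,
                             k_direct = min(fit$k[["direct"]], n))
      add_out(write_tsv(
        data.frame(scenario = names(pe$per_scenario),
                   error = pe$per_scenario, overall = pe$overall),
        file.path(out_dir, "abc_predictive_error.tsv")))
    }
  })
  manifest$output_md5 <- as.list(tools::md5sum(manifest$outputs))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  if (!is.null(err)) stop(err)
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
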