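## ABC model choice among the four demographic scenarios, local-linear
## posterior parameter estimation, predictive error and posterior model
## checking.

#' Build an ABC reference table
#'
#' Simulates `n_per_scenario` datasets per scenario from the joint prior and
#' records the demographic parameter draws together with the four summary
#' statistics. Statistics are later standardized by the table's median and
#' MAD; statistics with zero MAD are excluded from distances with a warning.
#'
#' @param ss a [scenario_set()].
#' @param n_per_scenario simulations per scenario.
#' @param seed RNG seed (the build is deterministic given the seed).
#' @param progress print a progress note every 10000 rows.
#' @return an object of class `"abc_ref"`: list with `stats` (matrix), `
#'   scenario` (integer vector), `params` (data frame, `NA` for parameters
#'   foreign to a row's scenario), `center`/`scale` (median/MAD), `ss`.
#' @export
build_reference_table <- function(ss, n_per_scenario, seed = 1,
                                  progress = FALSE) {
  stopifnot(n_per_scenario >= 1)
  withr_seed(seed)
  all_par <- unique(unlist(scenario_params))
  n_tot <- 4L * n_per_scenario
  stats_m <- matrix(NA_real_, n_tot, 4)
  colnames(stats_m) <- c("mean_A", "mean_GD", "mean_size_var", "mean_M")
  params <- matrix(NA_real_, n_tot, length(all_par),
                   dimnames = list(NULL, all_par))
  scen <- integer(n_tot)
  row <- 0L
  for (sid in ss$scenarios) {
    draws <- sample_prior(ss, sid, n_per_scenario)
    for (i in seq_len(n_per_scenario)) {
      row <- row + 1L
      scen[row] <- sid
      params[row, names(draws)] <- as.numeric(draws[i, ])
      stats_m[row, ] <- sim_stats(ss, sid, draws[i, , drop = FALSE])
      if (progress && row %% 10000L == 0L)
        message("reference table: ", row, "/", n_tot)
    }
  }
  center <- apply(stats_m, 2, stats::median)
  scale <- apply(stats_m, 2, stats::mad)
  # heavily saturated statistics can have zero MAD while still carrying
  # information in the tails; fall back to the standard deviation
  sds <- apply(stats_m, 2, stats::sd)
  scale[scale == 0] <- sds[scale == 0]
  structure(list(stats = stats_m, scenario = scen,
                 params = as.data.frame(params), center = center,
                 scale = scale, ss = ss, seed = seed),
            class = "abc_ref")
}

#' @export
print.abc_ref <- function(x, ...) {
  cat("ABC reference table:", nrow(x$stats), "rows (",
      paste(table(x$scenario), collapse = "/"), "per scenario )\n")
  invisible(x)
}

#' @rdname build_reference_table
#' @param object a [scenario_set()].
#' @param nsim total number of simulations (split equally over scenarios).
#' @param ... passed on to [build_reference_table()].
#' @export
simulate.scenario_set <- function(object, nsim = 4000, seed = 1, ...) {
  build_reference_table(object, n_per_scenario = nsim %/% 4L, seed = seed,
                        ...)
}

# standardized stats and usable columns
ref_normalize <- function(ref, warn = TRUE) {
  use <- ref$scale > 0
  if (!all(use) && warn)
    warning("statistic(s) with zero spread excluded from distances: ",
            paste(colnames(ref$stats)[!use], collapse = ", "))
  list(z = sweep(sweep(ref$stats[, use, drop = FALSE], 2, ref$center[use]),
                 2, ref$scale[use], "/"),
       use = use)
}

obs_normalize <- function(obs, ref, use) {
  (obs[colnames(ref$stats)][use] - ref$center[use]) / ref$scale[use]
}

ref_distances <- function(ref, obs, warn = TRUE) {
  nz <- ref_normalize(ref, warn)
  zo <- obs_normalize(obs, ref, nz$use)
  d2 <- rep(0, nrow(nz$z))
  for (j in seq_len(ncol(nz$z))) d2 <- d2 + (nz$z[, j] - zo[j])^2
  list(d = sqrt(d2), z = nz$z, zo = zo, use = nz$use)
}

logit_bounds <- function(par_name, priors) param_bounds(par_name, priors)

wquantile <- function(x, w, probs) {
  ord <- order(x)
  x <- x[ord]; w <- w[ord] / sum(w)
  cw <- cumsum(w)
  vapply(probs, function(p) x[which(cw >= p)[1]], numeric(1))
}

wmode <- function(x, w) {
  if (length(unique(x)) == 1L) return(x[1])
  d <- stats::density(x, weights = w / sum(w), bw = stats::bw.nrd0(x))
  d$x[which.max(d$y)]
}

# multinomial-logistic scenario probabilities at the observed point, with
# delta-method 95% CIs from the fit's asymptotic covariance
logistic_probs <- function(z, scen, zo, weights = NULL) {
  df <- data.frame(scenario = factor(scen), z)
  sep_flag <- FALSE
  fit <- withCallingHandlers(
    nnet::multinom(scenario ~ ., data = df, weights = weights, trace = FALSE,
                   maxit = 200),
    warning = function(w) {
      sep_flag <<- TRUE
      invokeRestart("muffleWarning")
    })
  co <- stats::coef(fit)
  if (is.null(dim(co))) co <- matrix(co, nrow = 1)
  if (any(abs(co) > 25)) {  # quasi-separation: regularize with weight decay
    sep_flag <- TRUE
    fit <- suppressWarnings(
      nnet::multinom(scenario ~ ., data = df, weights = weights,
                     trace = FALSE, maxit = 200, decay = 0.01))
    co <- stats::coef(fit)
    if (is.null(dim(co))) co <- matrix(co, nrow = 1)
  }
  lev <- fit$lev
  x <- c(1, as.numeric(zo))
  eta <- c(0, as.numeric(co %*% x))
  p <- exp(eta - max(eta)); p <- p / sum(p)
  names(p) <- lev
  ci <- matrix(NA_real_, length(lev), 2,
               dimnames = list(lev, c("lo", "hi")))
  V <- tryCatch(stats::vcov(fit), error = function(e) NULL)
  if (!is.null(V)) {
    K <- length(lev); np <- length(x)
    for (k in seq_len(K)) {
      # d p_k / d beta_{j, l} = p_k ((k == j) - p_j) x_l for j = 2..K
      gr <- numeric((K - 1) * np)
      for (j in 2:K) {
        gr[((j - 2) * np + 1):((j - 1) * np)] <-
          p[k] * ((k == j) - p[j]) * x
      }
      v <- drop(t(gr) %*% V %*% gr)
      half <- 1.96 * sqrt(max(v, 0))
      ci[k, ] <- c(max(0, p[k] - half), min(1, p[k] + half))
    }
  }
  list(prob = p, ci = ci, separation = sep_flag)
}

#' Fit the ABC demographic model
#'
#' The central estimator: given observed summary statistics (or a genotype
#' set) and a reference table, performs scenario choice by both the direct
#' rejection estimate (`k_direct` closest simulations) and weighted
#' multinomial logistic regression (`k_logistic` closest), then estimates the
#' posterior of the best scenario's parameters from the `k_est` closest rows
#' of that scenario by Beaumont local-linear regression adjustment:
#' parameters are logit-transformed to their prior bounds, regressed on the
#' standardized statistics with Epanechnikov kernel weights, adjusted to the
#' observed point and back-transformed.
#'
#' @param obs observed summary statistics (named vector as from
#'   [abc_summary_stats()]) or a [genotypes()] object.
#' @param ref an [build_reference_table()] object.
#' @param k_direct rows for the direct estimate.
#' @param k_logistic rows for the logistic estimate.
#' @param k_est rows for parameter estimation.
#' @return an object of class `"abc_fit"` with components `direct`
#'   (per-scenario probabilities), `logistic` (probabilities, 95% CIs,
#'   separation flag), `best_scenario`, `posterior` (per parameter: weighted
#'   adjusted sample, `mode`, `q050`, `q950`), `obs`, `k`.
#' @export
abc_fit <- function(obs, ref, k_direct = 500, k_logistic = 40000,
                    k_est = 20000) {
  if (inherits(obs, "genotypes")) obs <- abc_summary_stats(obs)
  n <- nrow(ref$stats)
  k_direct <- min(k_direct, n)
  k_logistic <- min(k_logistic, n)
  dd <- ref_distances(ref, obs)
  ord <- order(dd$d)
  # direct rejection estimate
  top <- ord[seq_len(k_direct)]
  direct <- table(factor(ref$scenario[top], levels = sort(unique(ref$scenario))))
  direct <- as.numeric(direct) / k_direct
  names(direct) <- paste0("scenario", sort(unique(ref$scenario)))
  # logistic regression estimate on the k_logistic closest rows
  topL <- ord[seq_len(k_logistic)]
  dmax <- max(dd$d[topL])
  wts <- if (dmax > 0) 1 - (dd$d[topL] / dmax)^2 else rep(1, k_logistic)
  wts[wts <= 0] <- min(wts[wts > 0], 1e-6)
  if (length(unique(ref$scenario[topL])) < 2L) {
    lg <- list(prob = stats::setNames(
      as.numeric(sort(unique(ref$scenario)) == ref$scenario[topL][1]),
      names(direct)), ci = NULL, separation = TRUE)
  } else {
    lg <- logistic_probs(dd$z[topL, , drop = FALSE], ref$scenario[topL],
                         dd$zo, weights = wts)
    names(lg$prob) <- paste0("scenario", names(lg$prob))
    if (!is.null(lg$ci)) rownames(lg$ci) <- paste0("scenario",
                                                   rownames(lg$ci))
  }
  best <- as.integer(sub("scenario", "", names(lg$prob)[which.max(lg$prob)]))
  post <- abc_estimate(obs, ref, scenario_id = best, k_est = k_est,
                       distances = dd)
  structure(list(obs = obs, direct = direct, logistic = lg,
                 best_scenario = best, posterior = post,
                 k = c(direct = k_direct, logistic = k_logistic,
                       est = post$k_est),
                 ref_rows = n),
            class = "abc_fit")
}

#' Local-linear posterior parameter estimation
#'
#' @param obs observed summary statistics.
#' @param ref reference table.
#' @param scenario_id scenario whose parameters to estimate.
#' @param k_est number of accepted rows.
#' @param distances internal precomputed distances.
#' @return list with `samples` (adjusted draws), `weights`, `summary` (data
#'   frame: `parameter`, `mode`, `q050`, `q950`), `adjusted` flag.
#' @export
abc_estimate <- function(obs, ref, scenario_id, k_est = 20000,
                         distances = NULL) {
  if (inherits(obs, "genotypes")) obs <- abc_summary_stats(obs)
  dd <- if (is.null(distances)) ref_distances(ref, obs) else distances
  rows <- which(ref$scenario == scenario_id)
  k_est <- min(k_est, length(rows))
  acc <- rows[order(dd$d[rows])[seq_len(k_est)]]
  dmax <- max(dd$d[acc])
  w <- if (dmax > 0) 1 - (dd$d[acc] / dmax)^2 else rep(1, k_est)
  w[w <= 0] <- min(w[w > 0], 1e-6)
  pars <- scenario_params[[as.character(scenario_id)]]
  X <- sweep(dd$z[acc, , drop = FALSE], 2, dd$zo)  # stats centred at obs
  eps <- 1e-6
  samples <- list()
  adjusted <- TRUE
  summ <- data.frame(parameter = pars, mode = NA_real_, q050 = NA_real_,
                     q950 = NA_real_)
  for (i in seq_along(pars)) {
    b <- logit_bounds(pars[i], ref$ss$priors)
    th <- ref$params[acc, pars[i]]
    u <- pmin(pmax((th - b[1]) / (b[2] - b[1]), eps), 1 - eps)
    z <- stats::qlogis(u)
    fit <- tryCatch(stats::lm.wfit(cbind(1, X), z, w),
                    error = function(e) NULL)
    if (is.null(fit)) {
      zadj <- z
      adjusted <- FALSE
    } else {
      beta <- fit$coefficients[-1]
      beta[is.na(beta)] <- 0
      zadj <- z - drop(X %*% beta)
    }
    thadj <- b[1] + (b[2] - b[1]) * stats::plogis(zadj)
    samples[[pars[i]]] <- thadj
    summ$mode[i] <- wmode(thadj, w)
    q <- wquantile(thadj, w, c(0.05, 0.95))
    summ$q050[i] <- q[1]; summ$q950[i] <- q[2]
  }
  list(scenario = scenario_id, samples = as.data.frame(samples), weights = w,
       summary = summ, adjusted = adjusted, k_est = k_est)
}

#' @export
print.abc_fit <- function(x, digits = 3, ...) {
  cat("ABC scenario choice (", x$ref_rows, "reference simulations )\n")
  tab <- rbind(direct = x$direct, logistic = x$logistic$prob)
  print(round(tab, digits))
  if (isTRUE(x$logistic$separation))
    cat("note: logistic fit regularized (quasi-separation)\n")
  cat("best scenario:", x$best_scenario, "\n")
  cat("\nPosterior parameter estimates (mode, 90% credible interval):\n")
  print(transform(x$posterior$summary, mode = signif(mode, digits),
                  q050 = signif(q050, digits), q950 = signif(q950, digits)),
        row.names = FALSE)
  invisible(x)
}

#' @export
summary.abc_fit <- function(object, ...) {
  out <- list(direct = object$direct, logistic = object$logistic$prob,
              logistic_ci = object$logistic$ci,
              best_scenario = object$best_scenario,
              posterior = object$posterior$summary)
  class(out) <- "summary.abc_fit"
  out
}

#' @export
print.summary.abc_fit <- function(x, ...) {
  cat("Scenario posterior probabilities\n")
  print(round(rbind(direct = x$direct, logistic = x$logistic), 4))
  if (!is.null(x$logistic_ci)) {
    cat("95% CIs (logistic):\n"); print(round(x$logistic_ci, 4))
  }
  cat("best scenario:", x$best_scenario, "\n")
  print(x$posterior, row.names = FALSE)
  invisible(x)
}

#' @export
coef.abc_fit <- function(object, ...) {
  stats::setNames(object$posterior$summary$mode,
                  object$posterior$summary$parameter)
}

#' @export
plot.abc_fit <- function(x, ...) {
  post <- x$posterior
  pars <- names(post$samples)
  op <- graphics::par(mfrow = c(1, length(pars)))
  on.exit(graphics::par(op))
  for (p in pars) {
    d <- stats::density(post$samples[[p]],
                        weights = post$weights / sum(post$weights))
    plot(d, main = p, xlab = p, ...)
  }
  invisible(x)
}

#' Posterior predictive simulation from a fitted ABC model
#'
#' Draws parameter vectors from the (weighted) adjusted posterior sample and
#' simulates summary statistics under the best scenario.
#'
#' @param object an [abc_fit()] object.
#' @param nsim number of posterior predictive datasets.
#' @param seed RNG seed.
#' @param ref the reference table used for the fit (supplies the scenario
#'   set).
#' @param ... unused.
#' @return data frame of simulated summary statistics (`nsim` rows).
#' @export
simulate.abc_fit <- function(object, nsim = 100, seed = 1, ref, ...) {
  withr_seed(seed)
  post <- object$posterior
  idx <- sample.int(nrow(post$samples), nsim, replace = TRUE,
                    prob = post$weights / sum(post$weights))
  out <- matrix(NA_real_, nsim, 4)
  colnames(out) <- names(object$obs)
  for (r in seq_len(nsim)) {
    pars <- post$samples[idx[r], , drop = FALSE]
    out[r, ] <- sim_stats(ref$ss, object$best_scenario, pars)
  }
  as.data.frame(out)
}

#' Predictive error of the scenario choice
#'
#' Simulates pseudo-observed datasets (pods) and reports the fraction
#' misclassified against the reference table. Pod parameters are drawn from
#' the priors by default; with `method = "posterior"` each scenario's pods
#' are drawn from its own local posterior around `obs` (requires `obs`),
#' measuring confidence in the choice for data like the observed. With
#' `pod_scenarios` restricted to the chosen scenario this is the
#' type-I-style confidence-in-choice error: the fraction of pods from the
#' selected model that would not be re-selected.
#'
#' @param ref a reference table.
#' @param n_pods pods per scenario.
#' @param seed RNG seed.
#' @param method `"prior"` or `"posterior"`.
#' @param obs observed summary statistics (needed for
#'   `method = "posterior"`).
#' @param pod_scenarios scenarios pods are generated from (default: all).
#' @param classifier `"direct"` (majority of the `k_direct` nearest rows) or
#'   `"logistic"` (multinomial regression on the `k_logistic` nearest).
#' @param k_direct rows for each pod's direct estimate.
#' @param k_logistic rows for each pod's logistic estimate.
#' @param k_est rows for the per-scenario posterior when
#'   `method = "posterior"`.
#' @return list with `overall` misclassification rate, `per_scenario` rates
#'   and the `confusion` matrix (true scenario x chosen scenario).
#' @export
predictive_error <- function(ref, n_pods = 100, seed = 1,
                             method = c("prior", "posterior"), obs = NULL,
                             pod_scenarios = NULL,
                             classifier = c("direct", "logistic"),
                             k_direct = 500, k_logistic = 1000,
                             k_est = 2000) {
  method <- match.arg(method)
  classifier <- match.arg(classifier)
  withr_seed(seed)
  ss <- ref$ss
  k_direct <- min(k_direct, nrow(ref$stats))
  k_logistic <- min(k_logistic, nrow(ref$stats))
  scen <- sort(unique(ref$scenario))
  if (is.null(pod_scenarios)) pod_scenarios <- scen
  confusion <- matrix(0L, length(pod_scenarios), length(scen),
                      dimnames = list(true = pod_scenarios, chosen = scen))
  post <- NULL
  if (method == "posterior") {
    if (is.null(obs)) stop("method = 'posterior' requires obs")
    post <- lapply(pod_scenarios, function(sid)
      abc_estimate(obs, ref, sid, k_est = k_est))
    names(post) <- as.character(pod_scenarios)
  }
  nz <- ref_normalize(ref, warn = FALSE)
  for (sid in pod_scenarios) {
    for (b in seq_len(n_pods)) {
      pars <- if (method == "prior") sample_prior(ss, sid, 1)
      else {
        ps <- post[[as.character(sid)]]
        ps$samples[sample.int(nrow(ps$samples), 1,
                              prob = ps$weights / sum(ps$weights)), ,
                   drop = FALSE]
      }
      s <- sim_stats(ss, sid, pars)
      zo <- obs_normalize(s, ref, nz$use)
      d2 <- rep(0, nrow(nz$z))
      for (j in seq_len(ncol(nz$z))) d2 <- d2 + (nz$z[, j] - zo[j])^2
      chosen <- if (classifier == "direct") {
        top <- order(d2)[seq_len(k_direct)]
        votes <- table(factor(ref$scenario[top], levels = scen))
        scen[which.max(votes)]
      } else {
        top <- order(d2)[seq_len(k_logistic)]
        if (length(unique(ref$scenario[top])) < 2L) ref$scenario[top][1]
        else {
          dmax <- sqrt(max(d2[top]))
          wts <- if (dmax > 0) 1 - (sqrt(d2[top]) / dmax)^2
                 else rep(1, length(top))
          wts[wts <= 0] <- min(wts[wts > 0], 1e-6)
          lg <- logistic_probs(nz$z[top, , drop = FALSE],
                               ref$scenario[top], zo, weights = wts)
          as.integer(names(lg$prob)[which.max(lg$prob)])
        }
      }
      confusion[as.character(sid), as.character(chosen)] <-
        confusion[as.character(sid), as.character(chosen)] + 1L
    }
  }
  per <- 1 - diag(confusion[, match(pod_scenarios, scen), drop = FALSE]) /
    rowSums(confusion)
  list(overall = 1 - sum(confusion[cbind(seq_along(pod_scenarios),
                                         match(pod_scenarios, scen))]) /
         sum(confusion),
       per_scenario = stats::setNames(per, paste0("scenario", pod_scenarios)),
       confusion = confusion, method = method, classifier = classifier,
       n_pods = n_pods)
}

#' Posterior model checking
#'
#' Simulates datasets from the fitted posterior and reports, per summary
#' statistic, the tail probability `P(simulated <= observed)`; statistics
#' with tail probability below 0.025 or above 0.975 are flagged as poorly
#' fitted.
#'
#' @param fit an [abc_fit()] object.
#' @param ref the reference table used for the fit.
#' @param n_ppc number of posterior predictive datasets.
#' @param seed RNG seed.
#' @return data frame with `statistic`, `observed`, `tail_prob`, `flagged`.
#' @export
posterior_model_check <- function(fit, ref, n_ppc = 200, seed = 1) {
  if (n_ppc < 2) warning("n_ppc < 2: tail probabilities are degenerate")
  sims <- simulate(fit, nsim = n_ppc, seed = seed, ref = ref)
  tails <- vapply(seq_along(fit$obs), function(j)
    mean(sims[, j] <= fit$obs[j]), numeric(1))
  data.frame(statistic = names(fit$obs), observed = as.numeric(fit$obs),
             tail_prob = tails, flagged = tails < 0.025 | tails > 0.975,
             row.names = NULL)
}
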