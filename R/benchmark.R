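# Baseline learners and the simulation benchmark.

#' Enumerate all signals graphs on a set of labels
#'
#' All 2^(S(S-1)) binary unit-diagonal matrices; only feasible for small S
#' (capped at S <= 5).
#'
#' @param labels character vector of signal labels.
#' @return list of signals graphs.
#' @export
enumerate_graphs <- function(labels) {
  S <- length(labels)
  if (S > 5L) .stop_input("exhaustive enumeration is capped at S <= 5")
  off <- .offdiag(S)
  n <- length(off)
  lapply(seq_len(2^n) - 1L, function(code) {
    g <- diag(S)
    dimnames(g) <- list(labels, labels)
    if (n > 0L) g[off] <- as.numeric(bitwAnd(bitwShiftR(code, seq_len(n) - 1L), 1L))
    g
  })
}

#' Baseline: a single EM run from the data-driven prior
#'
#' The plain-EM ablation of MC EMiNEM: effects are pre-filtered, the
#' attachment prior is initialized from the data, and a single EM run from
#' the identity graph returns its local maximum.  No MCMC, no prior
#' re-estimation.
#'
#' @param r log-odds matrix.
#' @param edge_prior scalar edge prior in (0, 1).
#' @param max_iter EM iteration cap.
#' @return the estimated signals graph.
#' @export
fit_em_only <- function(r, edge_prior = 0.5, max_iter = 100L) {
  r <- log_odds(r)
  rf <- filter_effects(r)$logodds
  g0 <- identity_graph(colnames(r))
  if (nrow(rf) == 0L) return(g0)
  run_em(g0, rf, init_prior(rf), edge_prior, max_iter = max_iter)$graph
}

#' Baseline: best of N randomly sampled local maxima
#'
#' Draws \code{n_draws} uniformly random unit-diagonal graphs, maps each to
#' its EM local maximum, and returns the best-scoring one under the
#' marginal log posterior with the data-driven prior.  Budget-matched to an
#' MCMC run of \code{n_draws} steps (one EM call per draw).  With
#' \code{map = FALSE} the raw random graphs are scored without the EM
#' mapping (a much weaker sampler, kept for reference).
#'
#' @param r log-odds matrix.
#' @param n_draws number of random graphs.
#' @param edge_prior scalar edge prior in (0, 1).
#' @param map map each draw to an EM local maximum before scoring.
#' @param max_iter EM iteration cap.
#' @return the estimated signals graph.  Uses the current RNG state.
#' @export
fit_random_sampling <- function(r, n_draws = 500L, edge_prior = 0.5,
                                map = TRUE, max_iter = 100L) {
  r <- log_odds(r)
  rf <- filter_effects(r)$logodds
  labs <- colnames(r)
  S <- length(labs)
  if (nrow(rf) == 0L) return(identity_graph(labs))
  nu <- init_prior(rf)
  ep <- .edge_prior_matrix(edge_prior, S)
  best_g <- NULL
  best_s <- -Inf
  for (i in seq_len(n_draws)) {
    g <- matrix(stats::rbinom(S * S, 1L, 0.5), S, S,
                dimnames = list(labs, labs))
    diag(g) <- 1
    if (map) {
      fit <- run_em(g, rf, nu, ep, max_iter = max_iter)
      g <- fit$graph; s <- fit$score
    } else {
      s <- log_posterior(g, rf, nu, ep)
    }
    if (s > best_s) { best_s <- s; best_g <- g }
  }
  best_g
}

#' Baseline: exhaustive maximum a posteriori graph
#'
#' Scores every unit-diagonal graph (S <= 4) under the marginal log
#' posterior with the data-driven prior and returns the maximizer.
#'
#' @param r log-odds matrix with at most 4 signals.
#' @param edge_prior scalar edge prior in (0, 1).
#' @return the MAP signals graph.
#' @export
fit_exhaustive <- function(r, edge_prior = 0.5) {
  r <- log_odds(r)
  if (ncol(r) > 4L) .stop_input("exhaustive search requires S <= 4")
  rf <- filter_effects(r)$logodds
  labs <- colnames(r)
  if (nrow(rf) == 0L) return(identity_graph(labs))
  nu <- init_prior(rf)
  gs <- enumerate_graphs(labs)
  sc <- vapply(gs, log_posterior, numeric(1), r = rf, nu = nu,
               ep = edge_prior)
  gs[[which.max(sc)]]
}

#' Benchmark chain settings
#'
#' Desk-scale defaults for simulation benchmarks: short Empirical Bayes
#' rounds (500-step chains, 3 rounds) instead of the tens of thousands of
#' steps used on full-size screens.  Pass a different
#' \code{\link{mc_eminem_config}} to restore longer runs.
#'
#' @return an \code{\link{mc_eminem_config}} list.
#' @export
benchmark_config <- function() {
  mc_eminem_config(n_steps = 500L, burn_in = 250L, thin = 5L,
                   max_rounds = 3L)
}

#' Default benchmark scenario grids
#'
#' Two grids mirroring the simulation study design: \code{"noise"} varies
#' the type-II error at a fixed graph size (11 signals,
#' beta in {0.01, 0.05, 0.1, 0.2}, alpha = 0.05) and \code{"size"} varies
#' the number of signals (5, 8, 11, 14) at beta = 0.1.  Both use 1000
#' effect genes with 20% on the null node and as many true edges as
#' signal nodes.
#'
#' @param which \code{"noise"} or \code{"size"}.
#' @param n_effects number of effect genes.
#' @return list of \code{\link{sim_scenario}} objects.
#' @export
benchmark_scenarios <- function(which = c("noise", "size"),
                                n_effects = 1000L) {
  which <- match.arg(which)
  if (which == "noise") {
    lapply(c(0.01, 0.05, 0.1, 0.2), function(b)
      sim_scenario(11L, n_effects, beta = b))
  } else {
    lapply(c(5L, 8L, 11L, 14L), function(S)
      sim_scenario(S, n_effects, beta = 0.1))
  }
}

#' Run the simulation benchmark
#'
#' For every scenario and replicate, samples a ground-truth NEM, generates
#' a noisy log-odds matrix under the alpha/beta model, fits it with each
#' requested method and records edge-wise sensitivity, specificity and
#' runtime.  Replicates are paired across methods (every method sees the
#' same data) and fully seeded.
#'
#' @param scenarios list of \code{\link{sim_scenario}} objects.
#' @param methods subset of \code{c("mc_eminem", "em_only",
#'   "random_sampling", "exhaustive")}; exhaustive requires S <= 4.
#' @param n_replicates replicates per scenario.
#' @param seed base seed; replicate i of scenario j uses a seed derived
#'   deterministically from it.
#' @param config chain settings for \code{mc_eminem} (also sets the
#'   random-sampling draw budget to its \code{n_steps}).
#' @param outdir optional directory: writes \code{benchmark_results.tsv},
#'   \code{benchmark_summary.tsv} and \code{benchmark_sensitivity.pdf}.
#' @return data frame with one row per scenario x method x replicate and
#'   columns \code{n_signals, n_effects, alpha, beta, scenario, method,
#'   replicate, sensitivity, specificity, runtime_s}; the per-scenario
#'   aggregation of \code{\link{summarize_benchmark}} is attached as
#'   attribute \code{"summary"}.
#' @export
run_benchmark <- function(scenarios, methods = c("mc_eminem", "em_only",
                                                 "random_sampling"),
                          n_replicates = 10L, seed = 1L,
                          config = benchmark_config(), outdir = NULL) {
  methods <- match.arg(methods, c("mc_eminem", "em_only", "random_sampling",
                                  "exhaustive"), several.ok = TRUE)
  if (inherits(scenarios, "sim_scenario")) scenarios <- list(scenarios)
  rows <- list()
  for (j in seq_along(scenarios)) {
    sc <- scenarios[[j]]
    if ("exhaustive" %in% methods && sc$n_signals > 4L)
      .stop_input("exhaustive method requested for S > 4")
    sc_id <- sprintf("S%d_a%g_b%g", sc$n_signals, sc$alpha, sc$beta)
    for (i in seq_len(n_replicates)) {
      rep_seed <- seed + 1000L * (j - 1L) + (i - 1L)
      set.seed(rep_seed)
      truth <- sample_nem(sc)
      r <- generate_logodds(truth)
      for (m in methods) {
        t0 <- proc.time()[["elapsed"]]
        est <- switch(m,
          mc_eminem = run_mc_eminem(r, config = config,
                                    seed = rep_seed)$final_graph,
          em_only = fit_em_only(r, edge_prior = config$edge_prior,
                                max_iter = config$max_iter),
          random_sampling = {
            set.seed(rep_seed)
            fit_random_sampling(r, n_draws = config$n_steps,
                                edge_prior = config$edge_prior,
                                max_iter = config$max_iter)
          },
          exhaustive = fit_exhaustive(r, edge_prior = config$edge_prior))
        dt <- proc.time()[["elapsed"]] - t0
        ev <- evaluate_edges(est, truth$graph)
        rows[[length(rows) + 1L]] <- data.frame(
          n_signals = sc$n_signals, n_effects = sc$n_effects,
          alpha = sc$alpha, beta = sc$beta, scenario = sc_id,
          method = m, replicate = i,
          sensitivity = ev[["sensitivity"]],
          specificity = ev[["specificity"]], runtime_s = dt)
      }
    }
  }
  res <- do.call(rbind, rows)
  summ <- summarize_benchmark(res)
  attr(res, "summary") <- summ
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(res, file.path(outdir, "benchmark_results.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(summ, file.path(outdir, "benchmark_summary.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    grDevices::pdf(file.path(outdir, "benchmark_sensitivity.pdf"),
                   width = 8, height = 4)
    plot_benchmark(res)
    grDevices::dev.off()
  }
  res
}

#' Aggregate benchmark results
#'
#' @param results data frame from \code{\link{run_benchmark}}.
#' @return data frame with per scenario x method means and standard errors
#'   of sensitivity and specificity.
#' @export
summarize_benchmark <- function(results) {
  se <- function(x) { x <- x[!is.na(x)]; stats::sd(x) / sqrt(length(x)) }
  sp <- split(results, list(results$scenario, results$method), drop = TRUE)
  out <- do.call(rbind, lapply(sp, function(d) data.frame(
    scenario = d$scenario[1], method = d$method[1],
    n_signals = d$n_signals[1], alpha = d$alpha[1], beta = d$beta[1],
    mean_sensitivity = mean(d$sensitivity, na.rm = TRUE),
    se_sensitivity = se(d$sensitivity),
    mean_specificity = mean(d$specificity, na.rm = TRUE),
    se_specificity = se(d$specificity))))
  rownames(out) <- NULL
  out[order(out$scenario, out$method), ]
}

#' Plot benchmark sensitivities
#'
#' One panel per scenario, methods on the x-axis, per-replicate
#' sensitivities as points with the mean as a bar.  Base-graphics; draw to
#' the active device.
#'
#' @param results data frame from \code{\link{run_benchmark}}.
#' @return invisibly, the summary data frame.
#' @export
plot_benchmark <- function(results) {
  scen <- unique(results$scenario)
  methods <- unique(results$method)
  op <- graphics::par(mfrow = c(1, length(scen)), mar = c(7, 4, 3, 1))
  on.exit(graphics::par(op))
  for (s in scen) {
    d <- results[results$scenario == s, ]
    x <- match(d$method, methods)
    graphics::plot(jitter(x, 0.3), d$sensitivity, xlim = c(0.5,
                   length(methods) + 0.5), ylim = c(0, 1), xaxt = "n",
                   xlab = "", ylab = "edge sensitivity", main = s,
                   pch = 19, col = grDevices::grey(0.4, 0.6))
    graphics::axis(1, at = seq_along(methods), labels = methods, las = 2)
    mns <- tapply(d$sensitivity, d$method, mean, na.rm = TRUE)[methods]
    graphics::segments(seq_along(methods) - 0.25, mns,
                       seq_along(methods) + 0.25, mns, lwd = 2,
                       col = "red3")
  }
  invisible(summarize_benchmark(results))
}
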