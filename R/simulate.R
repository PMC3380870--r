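# Synthetic NEM generator, alpha/beta log-odds noise model, baseline
# learners and benchmark metrics.

#' Define a simulation scenario
#'
#' @param n_signals number of signal nodes S.
#' @param n_effects number of effect genes E.
#' @param n_edges number of off-diagonal edges of the true signals graph;
#'   must be feasible for an acyclic orientation, i.e. at most
#'   \code{S(S-1)/2}.  Defaults to \code{n_signals} (a sparse hierarchy).
#' @param alpha type-I error of the implied optimal test, in (0, 1).
#' @param beta type-II error, in (0, 1); \code{alpha + beta < 1}.
#' @param null_fraction fraction of effects attached to the null node.
#' @return a named list of class \code{"sim_scenario"}.
#' @export
sim_scenario <- function(n_signals, n_effects, n_edges = n_signals,
                         alpha = 0.05, beta = 0.1, null_fraction = 0.2) {
  if (n_signals < 1L || n_effects < 1L)
    .stop_input("need n_signals >= 1 and n_effects >= 1")
  if (n_edges < 0L || n_edges > n_signals * (n_signals - 1L) / 2L)
    .stop_input("'n_edges' infeasible: an acyclic orientation on S nodes ",
                "supports at most S(S-1)/2 edges")
  if (alpha <= 0 || beta <= 0 || alpha + beta >= 1)
    .stop_input("need 0 < alpha, beta and alpha + beta < 1")
  if (null_fraction < 0 || null_fraction >= 1)
    .stop_input("'null_fraction' must be in [0, 1)")
  structure(list(n_signals = as.integer(n_signals),
                 n_effects = as.integer(n_effects),
                 n_edges = as.integer(n_edges),
                 alpha = alpha, beta = beta,
                 null_fraction = null_fraction),
            class = "sim_scenario")
}

# Kahn's algorithm on the off-diagonal adjacency
.is_acyclic <- function(g) {
  a <- g
  diag(a) <- 0
  indeg <- colSums(a)
  active <- rep(TRUE, nrow(a))
  repeat {
    src <- which(active & indeg == 0)
    if (length(src) == 0L) break
    active[src] <- FALSE
    if (length(src) == 1L) indeg <- indeg - a[src, ]
    else indeg <- indeg - colSums(a[src, , drop = FALSE])
  }
  !any(active)
}

#' Sample a random ground-truth NEM
#'
#' Draws the true signals graph uniformly among acyclic edge sets of the
#' requested size (rejection sampling over uniform draws of off-diagonal
#' positions), adds the unit diagonal, and attaches each effect uniformly
#' at random to a signal, except for a \code{null_fraction} share assigned
#' to the null node.
#'
#' @param scenario a \code{\link{sim_scenario}}.
#' @return list of class \code{"nem_truth"} with \code{graph} (signals
#'   graph), \code{attachment} (effects attachment) and \code{prior_star}
#'   (the deterministic true attachment prior, unit rows).  Uses the
#'   current RNG state.
#' @export
sample_nem <- function(scenario) {
  S <- scenario$n_signals
  E <- scenario$n_effects
  labs <- sprintf("S%02d", seq_len(S))
  elabs <- sprintf("e%04d", seq_len(E))
  off <- .offdiag(S)
  g <- NULL
  for (try in seq_len(10000L)) {
    cand <- matrix(0, S, S)
    if (scenario$n_edges > 0L)
      cand[off[sample.int(length(off), scenario$n_edges)]] <- 1
    if (.is_acyclic(cand)) { g <- cand; break }
  }
  if (is.null(g))
    .stop_input("could not sample an acyclic graph with ",
                scenario$n_edges, " edges")
  diag(g) <- 1
  dimnames(g) <- list(labs, labs)
  n_null <- round(scenario$null_fraction * E)
  tgt <- sample.int(S, E, replace = TRUE)
  if (n_null > 0L) tgt[sample.int(E, n_null)] <- NA_integer_
  att <- effects_attachment(tgt, signal_labels = labs,
                            effect_labels = elabs)
  ps <- matrix(0, E, S + 1L)
  ps[cbind(seq_len(E), ifelse(is.na(tgt), S + 1L, tgt))] <- 1
  prior_star <- attachment_prior(ps, signal_labels = labs,
                                 effect_labels = elabs)
  structure(list(graph = g, attachment = att, prior_star = prior_star,
                 scenario = scenario),
            class = "nem_truth")
}

#' Generate a noisy log-odds matrix from a ground truth
#'
#' Two-valued noise model of an optimal binary test with type-I error
#' \code{alpha} and type-II error \code{beta}: where the model predicts an
#' effect (\code{F[k, e] = 1}) the entry is \code{log((1-beta)/alpha)} with
#' probability \code{1 - beta} and \code{log(beta/(1-alpha))} otherwise;
#' where no effect is predicted the positive value occurs with probability
#' \code{alpha}.
#'
#' @param truth a \code{"nem_truth"} object.
#' @param alpha,beta error rates; default to the truth's scenario.
#' @return an E x S log-odds matrix.  Uses the current RNG state.
#' @export
generate_logodds <- function(truth, alpha = truth$scenario$alpha,
                             beta = truth$scenario$beta) {
  f <- predict_effects(truth$graph, truth$attachment)  # S x E
  p_pos <- t(ifelse(f == 1, 1 - beta, alpha))          # E x S
  pos <- log((1 - beta) / alpha)
  neg <- log(beta / (1 - alpha))
  vals <- ifelse(matrix(stats::runif(length(p_pos)), nrow(p_pos)) < p_pos,
                 pos, neg)
  log_odds(vals, effect_labels = colnames(f), signal_labels = rownames(f))
}

#' Edge-wise sensitivity and specificity of an estimated signals graph
#'
#' Counts are taken over the off-diagonal positions only (the diagonal is
#' fixed at 1 by convention).
#'
#' @param estimated,truth signals graphs with identical labels.
#' @return named numeric vector \code{c(sensitivity, specificity)};
#'   sensitivity is \code{NA} if the truth has no edge, specificity
#'   \code{NA} if it is complete.
#' @export
evaluate_edges <- function(estimated, truth) {
  if (!identical(dim(estimated), dim(truth)))
    .stop_input("graphs must have identical dimensions")
  if (!is.null(rownames(estimated)) && !is.null(rownames(truth)) &&
      !identical(rownames(estimated), rownames(truth)))
    .stop_input("graphs must have identical labels")
  off <- .offdiag(nrow(truth))
  e <- estimated[off]; t_ <- truth[off]
  tp <- sum(e == 1 & t_ == 1); fn <- sum(e == 0 & t_ == 1)
  tn <- sum(e == 0 & t_ == 0); fp <- sum(e == 1 & t_ == 0)
  c(sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_)
}

#' Normalized L1 distance between an attachment prior and the truth
#'
#' Mean over effects of the L1 distance between the prior row and the true
#' unit-vector row, divided by 2 (the maximum gene-wise L1 distance between
#' two stochastic vectors), so the result lies in [0, 1].
#'
#' @param nu attachment prior (E x (S+1)).
#' @param truth a \code{"nem_truth"} (its \code{prior_star} is used) or an
#'   E x (S+1) deterministic prior.
#' @return scalar in [0, 1].
#' @export
prior_l1 <- function(nu, truth) {
  star <- if (inherits(truth, "nem_truth")) truth$prior_star else truth
  if (!identical(dim(nu), dim(star)))
    .stop_input("prior dimensions do not match the truth")
  mean(rowSums(abs(nu - star))) / 2
}

#' Posterior quantile of the true signals graph
#'
#' Scores \code{n_random} uniformly random unit-diagonal binary graphs with
#' \code{\link{log_posterior}} and returns the fraction scoring strictly
#' below the true graph -- the position of the truth within the empirical
#' marginal posterior distribution.
#'
#' @param truth_graph the true signals graph.
#' @inheritParams log_posterior
#' @param n_random number of random graphs (>= 1).
#' @return quantile in [0, 1].  Uses the current RNG state.
#' @export
posterior_quantile <- function(truth_graph, r, nu, ep = 0.5,
                               n_random = 1000L) {
  if (n_random < 1L) .stop_input("'n_random' must be >= 1")
  S <- nrow(truth_graph)
  ref <- log_posterior(truth_graph, r, nu, ep)
  labs <- rownames(truth_graph)
  below <- 0L
  for (i in seq_len(n_random)) {
    g <- matrix(stats::rbinom(S * S, 1L, 0.5), S, S,
                dimnames = list(labs, labs))
    diag(g) <- 1
    if (log_posterior(g, r, nu, ep) < ref) below <- below + 1L
  }
  below / n_random
}
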