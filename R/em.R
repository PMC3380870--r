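# EMiNEM: closed-form EM for the NEM structure posterior.

#' One EM update of the signals graph
#'
#' E-step: compute the attachment posterior \code{omega} under the current
#' graph.  M-step: the expected complete log posterior is linear in the
#' entries of the graph, so it decomposes edge-wise and is maximized in
#' closed form; the updated graph sets the off-diagonal edge (k, s) to 1
#' exactly if
#' \deqn{\sum_e \omega_{es} R_{ek} + \mathrm{logit}\, p_{ks} > 0,}
#' where \eqn{p_{ks}} is the edge prior.  Ties (the sum exactly 0) leave
#' the edge absent, so exact ties yield the sparser graph.  The diagonal
#' stays 1.
#'
#' @inheritParams log_posterior
#' @return the updated signals graph.
#' @export
em_update <- function(g, r, nu, ep = 0.5) {
  .check_model_inputs(g, r, nu)
  ep <- .edge_prior_matrix(ep, nrow(g))
  .core_em_update(g, r, log(nu), log(ep) - log1p(-ep))
}

#' Run EM to a local maximum of the structure posterior
#'
#' Iterates \code{\link{em_update}} from \code{g0} until the graph stops
#' changing (graphs are binary, so convergence is detected by exact
#' identity) or \code{max_iter} is reached.  The sequence of marginal log
#' posteriors is monotonically non-decreasing; the fixed point is a local
#' maximum of \code{\link{log_posterior}}.  Should the discrete update ever
#' revisit an earlier graph without fixing (a cycle), the best-scoring
#' graph seen is returned and flagged.
#'
#' @param g0 starting signals graph.
#' @inheritParams log_posterior
#' @param max_iter maximum number of EM updates (default 100; convergence
#'   typically takes a handful of iterations).
#' @param keep_trajectory record the log posterior of every visited graph.
#'   Disabling this skips the per-iteration score evaluations (the score of
#'   the returned graph is always computed); the mode-hopping sampler runs
#'   with trajectories off.
#' @return object of class \code{"nem_em"}: a list with \code{graph} (the
#'   fixed point), \code{score} (its log posterior), \code{n_iterations},
#'   \code{trajectory} (log posterior of \code{g0} and of every graph
#'   visited, in order; length 1 when \code{keep_trajectory = FALSE}),
#'   \code{converged} and \code{cycled} flags.
#' @export
run_em <- function(g0, r, nu, ep = 0.5, max_iter = 100L,
                   keep_trajectory = TRUE) {
  if (max_iter < 1L) .stop_input("'max_iter' must be >= 1")
  .check_model_inputs(g0, r, nu)
  ep <- .edge_prior_matrix(ep, nrow(g0))
  lnu <- log(nu)
  logit_ep <- log(ep) - log1p(-ep)
  lep <- log(ep); lq <- log1p(-ep)
  off <- .offdiag(nrow(g0))
  g <- g0
  visited <- list(g)
  keys <- .graph_key(g)
  converged <- FALSE
  cycled <- FALSE
  n_iter <- 0L
  for (it in seq_len(max_iter)) {
    gn <- .core_em_update(g, r, lnu, logit_ep)
    n_iter <- it
    if (identical(as.integer(gn), as.integer(g))) {
      converged <- TRUE
      break
    }
    key <- .graph_key(gn)
    visited <- c(visited, list(gn))
    if (key %in% keys) { cycled <- TRUE; break }  # revisit without fixing
    keys <- c(keys, key)
    g <- gn
  }
  if (converged && !keep_trajectory) {
    # fixed point reached: by EM monotonicity it is the best scorer
    best_g <- g
    best_score <- .core_logpost(g, r, lnu, lep, lq, off)
    trajectory <- best_score
  } else {
    trajectory <- vapply(visited, .core_logpost, numeric(1),
                         r = r, lnu = lnu, lep = lep, lq = lq, off = off)
    # at convergence the last visited graph is the fixed point and, by EM
    # monotonicity, also a maximizer; prefer it on exact score ties
    best <- if (converged) length(trajectory) else which.max(trajectory)
    best_g <- visited[[best]]
    best_score <- trajectory[best]
    if (!keep_trajectory) trajectory <- best_score
  }
  structure(list(graph = best_g, score = best_score,
                 n_iterations = n_iter,
                 trajectory = trajectory,
                 converged = converged, cycled = cycled),
            class = "nem_em")
}

#' @export
print.nem_em <- function(x, ...) {
  cat("EM fit:", nrow(x$graph), "signals,",
      sum(x$graph) - nrow(x$graph), "edges, score", format(x$score),
      "after", x$n_iterations, "iteration(s)",
      if (x$cycled) "(cycle detected)" else "", "\n")
  invisible(x)
}
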