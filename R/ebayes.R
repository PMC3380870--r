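# Empirical Bayes outer loop: data-driven prior initialization, alternating
# MCMC sampling of the signals graph with re-estimation of the attachment
# prior from the sampled graphs.

#' Data-driven initialization of the attachment prior
#'
#' Initializes the prior of each effect's attachment as its attachment
#' posterior under the edge-free (identity) signals graph with a uniform
#' base prior, i.e. the row-normalization of
#' \code{(exp(R[e,1]), ..., exp(R[e,S]), 1)}.  Effects with strongly
#' negative log-odds rows are thereby absorbed by the null node.  Computed
#' in log space.
#'
#' @param r log-odds matrix (E x S).
#' @return an E x (S+1) row-stochastic attachment prior.
#' @export
init_prior <- function(r) {
  r <- as.matrix(r)
  lw <- cbind(r, 0)
  nu <- exp(lw - .lse_rows(lw))
  attachment_prior(nu,
                   signal_labels = colnames(r) %||%
                     paste0("S", seq_len(ncol(r))),
                   effect_labels = rownames(r))
}

#' Re-estimate the attachment prior from a chain trace
#'
#' Replaces the prior by the average, over the sampled signals graphs, of
#' the attachment posterior under the old prior -- an approximation of the
#' attachment posterior given the data with the graph integrated out.
#' Rows remain stochastic by construction.
#'
#' @param trace a \code{"nem_chain"} object with at least one sample.
#' @param r log-odds matrix.
#' @param nu_old the prior used to run the chain.
#' @return the updated E x (S+1) attachment prior.
#' @export
update_prior <- function(trace, r, nu_old) {
  graphs <- if (inherits(trace, "nem_chain")) trace$graphs else trace
  if (length(graphs) == 0L) .stop_input("empty trace")
  # identical graphs recur heavily in a converged trace: average over the
  # distinct graphs with multiplicity weights
  keys <- vapply(graphs, .graph_key, "")
  tab <- table(keys)
  first <- graphs[match(names(tab), keys)]
  w <- as.numeric(tab) / length(graphs)
  nu_new <- 0
  for (i in seq_along(first))
    nu_new <- nu_new + w[i] * attachment_posterior(first[[i]], r, nu_old)
  attachment_prior(nu_new,
                   signal_labels = utils::head(colnames(nu_old), -1L),
                   effect_labels = rownames(nu_old))
}

#' Default configuration of the Empirical Bayes sampler
#'
#' @param n_steps,burn_in,thin,n_flips chain settings per round (see
#'   \code{\link{run_chain}}).
#' @param max_rounds maximum number of Empirical Bayes rounds.
#' @param tol convergence tolerance on the maximum absolute change of the
#'   attachment prior between rounds.
#' @param edge_prior scalar edge prior in (0, 1); values below 0.5 act as a
#'   sparsity prior penalizing every edge equally.
#' @param max_iter EM iteration cap per proposal.
#' @return a named list of settings.
#' @export
mc_eminem_config <- function(n_steps = 20000L, burn_in = 10000L, thin = 10L,
                             n_flips = 1L, max_rounds = 5L, tol = 1e-3,
                             edge_prior = 0.5, max_iter = 100L) {
  list(n_steps = as.integer(n_steps), burn_in = as.integer(burn_in),
       thin = as.integer(thin), n_flips = as.integer(n_flips),
       max_rounds = as.integer(max_rounds), tol = tol,
       edge_prior = edge_prior, max_iter = as.integer(max_iter))
}

# per-effect argmax of an attachment posterior with lexicographic tie-break
.argmax_attachment <- function(om) {
  labs <- colnames(om)
  S1 <- ncol(om)
  pick <- vapply(seq_len(nrow(om)), function(e) {
    w <- om[e, ]
    cand <- which(w == max(w))
    if (length(cand) > 1L) cand <- cand[order(labs[cand])][1L]
    cand
  }, integer(1))
  tgt <- ifelse(pick == S1, NA_integer_, pick)
  effects_attachment(tgt, signal_labels = labs[-S1],
                     effect_labels = rownames(om))
}

#' Fit a NEM by MC EMiNEM
#'
#' The full Empirical Bayes procedure: (1) initialize the attachment prior
#' in a data-driven fashion (\code{\link{init_prior}}) and the edge prior
#' uniform; (2) sample signals graphs by mode-hopping MCMC
#' (\code{\link{run_chain}}); (3) replace the attachment prior by the
#' average attachment posterior over the sampled graphs
#' (\code{\link{update_prior}}); (4) repeat 2-3 until the prior stops
#' changing (max-abs change below \code{tol}) or \code{max_rounds} is
#' reached.  Effects without any positive log-odds entry are filtered out
#' beforehand (\code{\link{filter_effects}}) and reported as attached to
#' the null node.
#'
#' @param r log-odds matrix (E x S) with finite entries.
#' @param config settings list from \code{\link{mc_eminem_config}}.
#' @param seed integer seed controlling all randomness of the fit.
#' @param g0 optional starting graph (default: identity graph).
#' @return object of class \code{"mc_eminem"}: list with
#'   \code{final_graph} (highest-scoring sampled local maximum of the last
#'   round), \code{final_score}, \code{final_prior}, \code{attachment}
#'   (per-effect argmax of the final attachment posterior, over all
#'   original effects; filtered effects are null), \code{posterior}
#'   (final attachment posterior on the retained effects), \code{rounds}
#'   (list of per-round \code{trace} and \code{prior}), \code{converged},
#'   \code{kept} (retained effect indices), \code{config} and \code{seed}.
#' @export
run_mc_eminem <- function(r, config = mc_eminem_config(), seed = 1L,
                          g0 = NULL) {
  r <- log_odds(r)
  slabs <- colnames(r)
  flt <- filter_effects(r)
  rf <- flt$logodds
  if (nrow(rf) == 0L) {
    att <- effects_attachment(rep(NA_integer_, nrow(r)),
                              signal_labels = slabs,
                              effect_labels = rownames(r))
    return(structure(list(final_graph = identity_graph(slabs),
                          final_score = NA_real_, final_prior = NULL,
                          attachment = att, posterior = NULL,
                          rounds = list(), converged = FALSE,
                          kept = flt$kept, config = config, seed = seed),
                     class = "mc_eminem"))
  }
  set.seed(seed)
  ep <- .edge_prior_matrix(config$edge_prior, ncol(rf), labels = slabs)
  nu <- init_prior(rf)
  g <- g0 %||% identity_graph(slabs)
  rounds <- vector("list", config$max_rounds)
  converged <- FALSE
  for (round in seq_len(config$max_rounds)) {
    trace <- run_chain(g, rf, nu, ep, n_steps = config$n_steps,
                       burn_in = config$burn_in, thin = config$thin,
                       n_flips = config$n_flips, seed = NULL,
                       max_iter = config$max_iter)
    nu_new <- update_prior(trace, rf, nu)
    delta <- max(abs(nu_new - nu))
    rounds[[round]] <- list(trace = trace, prior = nu_new, delta = delta)
    nu <- nu_new
    g <- trace$final_state$mapped$graph  # warm start of the next round
    if (delta < config$tol) { converged <- TRUE; break }
  }
  rounds <- rounds[!vapply(rounds, is.null, logical(1))]
  last <- rounds[[length(rounds)]]$trace
  best <- which.max(last$scores)
  final_graph <- last$graphs[[best]]
  om <- attachment_posterior(final_graph, rf, nu)
  att_f <- .argmax_attachment(om)
  tgt <- rep(NA_integer_, nrow(r))
  tgt[flt$kept] <- unclass(att_f)
  att <- effects_attachment(tgt, signal_labels = slabs,
                            effect_labels = rownames(r))
  structure(list(final_graph = final_graph,
                 final_score = last$scores[best],
                 final_prior = nu, attachment = att, posterior = om,
                 rounds = rounds, converged = converged,
                 kept = flt$kept, config = config, seed = seed),
            class = "mc_eminem")
}

#' @export
print.mc_eminem <- function(x, ...) {
  S <- nrow(x$final_graph)
  cat("MC EMiNEM fit:", S, "signals,",
      sum(x$final_graph) - S, "edges, score", format(x$final_score), "\n")
  cat(" ", length(x$kept), "of", length(x$attachment),
      "effects retained;", sum(is.na(unclass(x$attachment))),
      "attached to the null node\n")
  cat(" ", length(x$rounds), "Empirical Bayes round(s);",
      if (x$converged) "prior converged" else "round limit reached", "\n")
  invisible(x)
}
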