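# Mode-hopping Metropolis-Hastings over EM local maxima.
#
# The underlying Markov chain lives on the raw graph space: a proposal
# flips off-diagonal entries of the current raw graph.  Before the
# acceptance test, the proposal is mapped to the "nearest" local maximum by
# EM, and the Hastings ratio is evaluated on the mapped graphs.  Since the
# flip proposal is symmetric, the ratio reduces to the posterior ratio of
# the mapped graphs.  The recorded series of mapped graphs is approximately
# a sample from the posterior restricted to the set of EM local maxima.

#' Propose a new signals graph by flipping edges
#'
#' Flips \code{n_flips} off-diagonal entries of \code{g}, chosen uniformly
#' without replacement; the diagonal is untouched.  The proposal is
#' symmetric: the probability of proposing \code{g'} from \code{g} equals
#' that of proposing \code{g} from \code{g'}.
#'
#' @param g signals graph with S >= 2.
#' @param n_flips number of entries to flip (1 <= n_flips <= S(S-1)).
#' @return the proposed signals graph.  Uses the current R random number
#'   generator state.
#' @export
propose_graph <- function(g, n_flips = 1L) {
  S <- nrow(g)
  if (S < 2L) .stop_input("proposals require at least 2 signals")
  off <- .offdiag(S)
  if (n_flips < 1L || n_flips > length(off))
    .stop_input("'n_flips' must be between 1 and S(S-1)")
  idx <- off[sample.int(length(off), n_flips)]
  g[idx] <- 1 - g[idx]
  g
}

#' Initialize the state of a mode-hopping chain
#'
#' @param g0 raw starting graph.
#' @inheritParams log_posterior
#' @param max_iter passed to \code{\link{run_em}}.
#' @return list with \code{raw} (the underlying chain state) and
#'   \code{mapped} (its EM image, a \code{"nem_em"} fit).
#' @export
chain_state <- function(g0, r, nu, ep = 0.5, max_iter = 100L) {
  list(raw = g0, mapped = run_em(g0, r, nu, ep, max_iter = max_iter))
}

#' One mode-hopping Metropolis-Hastings step
#'
#' Draws a flip proposal from the raw graph, maps it to a local maximum by
#' EM, and accepts with probability
#' \code{min(1, exp(score(mapped proposal) - score(current mapped)))}.
#' On acceptance the raw state becomes the (un-mapped) proposal; on
#' rejection the state is unchanged.
#'
#' @param state a state as returned by \code{\link{chain_state}}.
#' @inheritParams log_posterior
#' @param n_flips entries flipped per proposal.
#' @param max_iter passed to \code{\link{run_em}}.
#' @return the new state, with an \code{accepted} flag.
#' @export
mode_hop_step <- function(state, r, nu, ep = 0.5, n_flips = 1L,
                          max_iter = 100L) {
  prop <- propose_graph(state$raw, n_flips)
  fit <- run_em(prop, r, nu, ep, max_iter = max_iter)
  log_alpha <- fit$score - state$mapped$score
  if (log_alpha >= 0 || log(stats::runif(1)) < log_alpha) {
    state$raw <- prop
    state$mapped <- fit
    state$accepted <- TRUE
  } else {
    state$accepted <- FALSE
  }
  state
}

#' Run a mode-hopping MCMC chain
#'
#' Runs \code{n_steps} mode-hopping steps from \code{g0} and records the
#' mapped local maximum every \code{thin} steps after \code{burn_in}.
#' With a fixed \code{seed} the trace is bit-reproducible.
#'
#' @param g0 raw starting graph (default: caller supplies, conventionally
#'   the identity graph).
#' @inheritParams log_posterior
#' @param n_steps total number of MCMC steps.
#' @param burn_in steps discarded before recording (0 <= burn_in < n_steps).
#' @param thin record every \code{thin}-th step after burn-in.
#' @param n_flips entries flipped per proposal.
#' @param seed integer seed, or NULL to use the current RNG state.
#' @param max_iter EM iteration cap per proposal.
#' @return object of class \code{"nem_chain"}: list with \code{graphs}
#'   (list of sampled mapped graphs), \code{scores}, \code{steps} (step
#'   index of each sample), \code{acceptance_count}, \code{length}
#'   (= \code{n_steps}), \code{final_state} (list with the final \code{raw}
#'   graph and its \code{mapped} image/score), and the settings.
#' @export
run_chain <- function(g0, r, nu, ep = 0.5, n_steps = 20000L,
                      burn_in = 10000L, thin = 10L, n_flips = 1L,
                      seed = NULL, max_iter = 100L) {
  if (burn_in < 0L || n_steps <= burn_in)
    .stop_input("need n_steps > burn_in >= 0")
  if (thin < 1L) .stop_input("'thin' must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  ep <- .edge_prior_matrix(ep, nrow(g0))
  # EM is deterministic, so the EM image of a raw graph can be memoized;
  # raw states recur constantly (rejections, revisited neighborhoods)
  cache <- new.env(parent = emptyenv())
  lnu <- log(nu)
  logit_ep <- log(ep) - log1p(-ep)
  lep <- log(ep); lq <- log1p(-ep)
  off <- .offdiag(nrow(g0))
  em_image <- function(graw) {
    key <- .graph_key(graw)
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
    val <- .core_run_em(graw, r, lnu, logit_ep, lep, lq, off,
                        max_iter = max_iter)
    assign(key, val, envir = cache)
    val
  }
  raw <- g0
  mapped <- em_image(raw)
  n_keep <- (n_steps - burn_in) %/% thin
  graphs <- vector("list", n_keep)
  scores <- numeric(n_keep)
  steps <- integer(n_keep)
  acc <- 0L
  k <- 0L
  for (t in seq_len(n_steps)) {
    prop <- propose_graph(raw, n_flips)
    cand <- em_image(prop)
    log_alpha <- cand$score - mapped$score
    if (log_alpha >= 0 || log(stats::runif(1)) < log_alpha) {
      raw <- prop
      mapped <- cand
      acc <- acc + 1L
    }
    if (t > burn_in && (t - burn_in) %% thin == 0L) {
      k <- k + 1L
      graphs[[k]] <- mapped$graph
      scores[k] <- mapped$score
      steps[k] <- t
    }
  }
  structure(list(graphs = graphs[seq_len(k)], scores = scores[seq_len(k)],
                 steps = steps[seq_len(k)], acceptance_count = acc,
                 length = n_steps,
                 final_state = list(raw = raw, mapped = mapped),
                 settings = list(n_steps = n_steps, burn_in = burn_in,
                                 thin = thin, n_flips = n_flips,
                                 seed = seed)),
            class = "nem_chain")
}

#' @export
print.nem_chain <- function(x, ...) {
  cat("mode-hopping chain:", x$length, "steps,",
      length(x$graphs), "samples, acceptance rate",
      format(x$acceptance_count / x$length, digits = 3), "\n")
  invisible(x)
}

#' Per-edge sampling frequencies of a chain trace
#'
#' @param trace a \code{"nem_chain"} object (or a list of signals graphs).
#' @return S x S matrix of the fraction of samples containing each edge.
#' @export
edge_frequencies <- function(trace) {
  graphs <- if (inherits(trace, "nem_chain")) trace$graphs else trace
  if (length(graphs) == 0L) .stop_input("empty trace")
  Reduce(`+`, graphs) / length(graphs)
}
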