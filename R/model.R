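# NEM prediction semantics, marginal log posterior, attachment posterior,
# effect pre-filtering, indistinguishable-node merging.

# log attachment weights: lw[e, t] = log nu[e, t] + sum_k Gamma[k, t] R[e, k]
# for signal targets t, and log nu[e, null] for the null column (the null
# node is always predicted inactive, so its data term is exp(0) = 1).
# lnu = log(nu) is passed precomputed because this sits in the sampler's
# innermost loop.
.core_logweights <- function(g, r, lnu) {
  S <- ncol(r)
  lw <- lnu
  lw[, seq_len(S)] <- lw[, seq_len(S), drop = FALSE] + r %*% g
  lw
}

.attachment_logweights <- function(g, r, nu) .core_logweights(g, r, log(nu))

# score with precomputed log(nu), log(ep) and log(1 - ep)
.core_logpost <- function(g, r, lnu, lep, lq, off) {
  sum(.lse_rows(.core_logweights(g, r, lnu))) +
    sum(g[off] * lep[off] + (1 - g[off]) * lq[off])
}

# one EM update with precomputed log(nu) and logit(ep)
.core_em_update <- function(g, r, lnu, logit_ep) {
  lw <- .core_logweights(g, r, lnu)
  om <- exp(lw - .lse_rows(lw))
  S <- nrow(g)
  m <- crossprod(r, om[, seq_len(S), drop = FALSE])
  gnew <- (m + logit_ep > 0) * 1
  diag(gnew) <- 1
  dimnames(gnew) <- dimnames(g)
  gnew
}

# EM to a fixed point, returning only the image and its score; cycles fall
# back to the best-scoring visited graph (mirrors run_em)
.core_run_em <- function(g0, r, lnu, logit_ep, lep, lq, off, max_iter) {
  g <- g0
  keys <- .graph_key(g)
  visited <- list(g)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    gn <- .core_em_update(g, r, lnu, logit_ep)
    if (identical(as.integer(gn), as.integer(g))) { converged <- TRUE; break }
    key <- .graph_key(gn)
    visited <- c(visited, list(gn))
    if (key %in% keys) break
    keys <- c(keys, key)
    g <- gn
  }
  if (converged) {
    list(graph = g, score = .core_logpost(g, r, lnu, lep, lq, off))
  } else {
    sc <- vapply(visited, .core_logpost, numeric(1), r = r, lnu = lnu,
                 lep = lep, lq = lq, off = off)
    best <- which.max(sc)
    list(graph = visited[[best]], score = sc[best])
  }
}

.check_model_inputs <- function(g, r, nu = NULL, ep = NULL) {
  check_signals_graph(g)
  if (ncol(r) != nrow(g))
    .stop_input("log-odds columns must match the signals graph dimension")
  if (!is.null(colnames(r)) && !is.null(rownames(g)) &&
      !identical(colnames(r), rownames(g)))
    .stop_input("log-odds signal labels do not match the signals graph labels")
  if (!is.null(nu)) {
    if (nrow(nu) != nrow(r) || ncol(nu) != ncol(r) + 1L)
      .stop_input("attachment prior must be E x (S+1)")
    if (any(rowSums(nu) <= 0))
      .stop_input("attachment prior has an all-zero row")
  }
  invisible(NULL)
}

#' Predicted perturbation effects of a NEM
#'
#' An effect attached to signal s is predicted to respond to the
#' perturbation of signal k exactly if there is a two-step path
#' k -> s -> e, i.e. if \code{g[k, s] == 1} (the diagonal of \code{g} is
#' fixed at 1, so every effect responds at least to the perturbation of its
#' own signal).  Effects attached to the null node are predicted always
#' inactive.
#'
#' @param g signals graph (see \code{\link{signals_graph}}).
#' @param a effects attachment (see \code{\link{effects_attachment}}).
#' @return binary S x E matrix F with \code{F[k, e] = 1} iff effect e is
#'   predicted to respond to the perturbation of signal k.
#' @export
predict_effects <- function(g, a) {
  check_signals_graph(g)
  labs <- attr(a, "signal_labels")
  if (length(labs) != nrow(g) ||
      (!is.null(rownames(g)) && !identical(labs, rownames(g))))
    .stop_input("attachment signal labels do not match the signals graph")
  th <- .attachment_matrix(a)
  f <- g %*% th
  f[f > 1] <- 1  # columns of th are unit vectors, so this is a no-op guard
  f
}

#' Marginal log posterior of a signals graph
#'
#' The log posterior of \code{g} with the effects attachment integrated out
#' under the sparse-attachment assumption (each effect attaches to exactly
#' one signal or to the null node, independently across effects with prior
#' \code{nu}), plus edge-wise independent priors on the off-diagonal
#' entries of \code{g}.  Up to an additive constant that is fixed for fixed
#' (R, nu, edge prior):
#' \deqn{\sum_e \log\Big(\sum_s \nu_{es} e^{\sum_k \Gamma_{ks} R_{ek}}
#'       + \nu_{e,\mathrm{null}}\Big)
#'       + \sum_{k \ne s} \log P(\Gamma_{ks})}
#' Only score differences between graphs are meaningful.
#'
#' @param g signals graph.
#' @param r log-odds matrix (E x S).
#' @param nu attachment prior (E x (S+1), row-stochastic).
#' @param ep edge prior: scalar in (0,1) or S x S matrix of per-edge
#'   probabilities; the diagonal is ignored (fixed to 1).
#' @return a finite scalar; computed in log space via log-sum-exp.
#' @export
log_posterior <- function(g, r, nu, ep = 0.5) {
  .check_model_inputs(g, r, nu)
  ep <- .edge_prior_matrix(ep, nrow(g))
  out <- .core_logpost(g, r, log(nu), log(ep), log1p(-ep),
                       .offdiag(nrow(g)))
  if (!is.finite(out)) stop("log posterior is not finite", call. = FALSE)
  out
}

#' Posterior distribution of the effect attachments
#'
#' The E-step responsibilities of the EM algorithm: given the signals graph,
#' the posterior probability that effect e is attached to signal s is
#' proportional to \code{nu[e, s] * exp(sum_k g[k, s] * r[e, k])}, and to
#' \code{nu[e, null]} for the null node.  Rows are normalized to 1;
#' everything is computed in log space.
#'
#' @inheritParams log_posterior
#' @return row-stochastic E x (S+1) matrix of attachment probabilities.
#' @export
attachment_posterior <- function(g, r, nu) {
  .check_model_inputs(g, r, nu)
  lw <- .attachment_logweights(g, r, nu)
  om <- exp(lw - .lse_rows(lw))
  dimnames(om) <- dimnames(nu)
  om
}

#' Pre-filter effects with no positive evidence
#'
#' An effect gene whose log-odds row has no strictly positive entry can
#' never increase the posterior by being attached to a signal; such genes
#' are removed before estimation (they would attach to the null node
#' anyway, and their contribution to the score is a graph-independent
#' constant).  A row whose maximum is exactly 0 is removed as well, since
#' attaching it gives exactly no increase.
#'
#' @param r log-odds matrix (E x S).
#' @return list with \code{logodds} (the reduced matrix, possibly with zero
#'   rows) and \code{kept} (integer indices of the retained rows in the
#'   original matrix, named by effect label).
#' @export
filter_effects <- function(r) {
  r <- as.matrix(r)
  keep <- which(apply(r, 1L, max) > 0)
  if (length(keep) == 0L)
    warning("all effects filtered out: no effect has positive evidence",
            call. = FALSE)
  names(keep) <- rownames(r)[keep]
  list(logodds = r[keep, , drop = FALSE], kept = keep)
}

#' Merge indistinguishable signal nodes
#'
#' A bi-directional edge between two signals means their attached effects
#' are interchangeable without changing the likelihood: the two nodes are
#' indistinguishable in terms of their intervention effects and are
#' combined into one node.  Mutual-edge pairs are grouped transitively;
#' the merged node's label concatenates the member labels, its log-odds
#' column is the row-wise mean of the member columns, and its adjacency
#' row/column is the element-wise OR of the members'.
#'
#' @param g fitted signals graph.
#' @param r log-odds matrix on the same signals.
#' @return list with \code{graph} (merged signals graph), \code{logodds}
#'   (merged log-odds matrix) and \code{groups} (list mapping each merged
#'   label to its member labels).
#' @export
merge_indistinguishable <- function(g, r) {
  .check_model_inputs(g, r)
  S <- nrow(g)
  labs <- rownames(g)
  # union-find over mutual off-diagonal edges
  parent <- seq_len(S)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(S)) for (j in seq_len(S)) {
    if (i < j && g[i, j] == 1 && g[j, i] == 1) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
    }
  }
  root <- vapply(seq_len(S), find, integer(1))
  groups <- split(seq_len(S), root)
  new_labs <- unname(vapply(groups, function(m)
    paste(labs[m], collapse = ""), ""))
  Sm <- length(groups)
  gm <- matrix(0, Sm, Sm, dimnames = list(new_labs, new_labs))
  for (a in seq_len(Sm)) for (b in seq_len(Sm)) {
    gm[a, b] <- as.numeric(any(g[groups[[a]], groups[[b]]] == 1))
  }
  diag(gm) <- 1
  rm_ <- vapply(groups, function(m)
    rowMeans(r[, m, drop = FALSE]), numeric(nrow(r)))
  rm_ <- matrix(rm_, nrow = nrow(r),
                dimnames = list(rownames(r), new_labs))
  list(graph = gm, logodds = rm_,
       groups = stats::setNames(lapply(groups, function(m) labs[m]),
                                new_labs))
}
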