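# Independent brute-force oracles and small random-instance generators.
# Everything here deliberately avoids the package's log-space code paths:
# sums are over explicit enumerations in plain arithmetic.

logaddexp <- function(a, b) {
  m <- pmax(a, b)
  ifelse(is.infinite(m) & m < 0, -Inf, m + log(exp(a - m) + exp(b - m)))
}

# random test instance: log-odds, random row-stochastic prior, scalar edge
# prior; uses the current RNG state
rand_instance <- function(S, E, ep_range = c(0.2, 0.8)) {
  labs <- paste0("S", seq_len(S))
  r <- log_odds(matrix(stats::rnorm(E * S, sd = 2), E, S),
                effect_labels = paste0("e", seq_len(E)),
                signal_labels = labs)
  nu <- matrix(stats::runif(E * (S + 1), min = 0.05), E, S + 1)
  nu <- nu / rowSums(nu)
  nu <- attachment_prior(nu, signal_labels = labs,
                         effect_labels = rownames(r))
  ep <- stats::runif(1, ep_range[1], ep_range[2])
  g <- matrix(stats::rbinom(S * S, 1, 0.5), S, S, dimnames = list(labs, labs))
  diag(g) <- 1
  list(g = g, r = r, nu = nu, ep = ep, labs = labs)
}

oracle_edge_term <- function(g, ep) {
  S <- nrow(g)
  epm <- if (length(ep) == 1) matrix(ep, S, S) else ep
  out <- 0
  for (k in seq_len(S)) for (s in seq_len(S)) if (k != s)
    out <- out + if (g[k, s] == 1) log(epm[k, s]) else log(1 - epm[k, s])
  out
}

# marginal log posterior by literal enumeration of all (S+1)^E sparse
# attachments; the data term F[k, e] = g[k, target(e)] is computed directly
# from the two-step-path definition
oracle_log_posterior <- function(g, r, nu, ep) {
  S <- ncol(r); E <- nrow(r)
  grid <- expand.grid(rep(list(seq_len(S + 1L)), E))
  total <- -Inf
  for (i in seq_len(nrow(grid))) {
    tgt <- as.integer(unlist(grid[i, ]))
    ll <- 0
    for (e in seq_len(E)) if (tgt[e] <= S)
      ll <- ll + sum(g[, tgt[e]] * r[e, ])
    lp <- sum(log(nu[cbind(seq_len(E), tgt)]))
    total <- logaddexp(total, ll + lp)
  }
  total + oracle_edge_term(g, ep)
}

# expected complete log posterior Q(gnew | gcur), responsibilities computed
# by direct (non-log) normalization
oracle_q <- function(gnew, gcur, r, nu, ep) {
  S <- ncol(r); E <- nrow(r)
  q <- 0
  for (e in seq_len(E)) {
    w <- numeric(S + 1L)
    for (t in seq_len(S)) w[t] <- nu[e, t] * exp(sum(gcur[, t] * r[e, ]))
    w[S + 1L] <- nu[e, S + 1L]
    w <- w / sum(w)
    for (t in seq_len(S + 1L)) {
      if (w[t] == 0) next
      data_term <- if (t <= S) sum(gnew[, t] * r[e, ]) else 0
      q <- q + w[t] * (data_term + log(nu[e, t]))
    }
  }
  q + oracle_edge_term(gnew, ep)
}

# argmax of Q over all unit-diagonal graphs (exhaustive)
oracle_q_argmax <- function(gcur, r, nu, ep) {
  gs <- enumerate_graphs(colnames(r))
  qs <- vapply(gs, oracle_q, numeric(1), gcur = gcur, r = r, nu = nu,
               ep = ep)
  gs[[which.max(qs)]]
}

# all EM local maxima of an instance together with the theoretical
# stationary distribution of the mode-hopping sampler restricted to them
oracle_local_maxima <- function(r, nu, ep) {
  gs <- enumerate_graphs(colnames(r))
  images <- lapply(gs, function(g) run_em(g, r, nu, ep,
                                          keep_trajectory = FALSE))
  keys <- vapply(images, function(f) paste(as.integer(f$graph),
                                           collapse = ""), "")
  fixed <- !duplicated(keys)
  maxima <- lapply(images[fixed], `[[`, "graph")
  scores <- vapply(images[fixed], `[[`, numeric(1), "score")
  names(scores) <- keys[fixed]
  p <- exp(scores - max(scores))
  list(maxima = maxima, scores = scores, prob = p / sum(p))
}

# a small ground truth plus near-noiseless data, fully seeded by caller
noiseless_instance <- function(S, E, n_edges = S - 1L, null_fraction = 0.2,
                               eps = 1e-3) {
  sc <- sim_scenario(S, E, n_edges = n_edges, alpha = eps, beta = eps,
                     null_fraction = null_fraction)
  truth <- sample_nem(sc)
  list(truth = truth, r = generate_logodds(truth))
}
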