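# Downstream grouping of fitted results and consensus across seeds.

#' Group attached effects by signal and direction of regulation
#'
#' Prepares the input of a gene-set enrichment analysis: every non-null
#' attached effect is assigned to the group (attachment signal, direction),
#' where the direction is the sign of the mean entry of the user-supplied
#' direction matrix over exactly those perturbations in which the model
#' predicts an effect (\code{F[k, e] = 1}).  With S' signal nodes this
#' yields up to 2 S' groups.  Effects with net sign zero are excluded from
#' both direction groups and listed separately; effects on the null node
#' have no predicted perturbation and are excluded as well.
#'
#' @param result an \code{"mc_eminem"} fit (or a list with
#'   \code{final_graph} and \code{attachment}).
#' @param direction_matrix signed numeric E x S matrix giving the direction
#'   of expression change of each effect under each perturbation (e.g. the
#'   sign of the fold change); rows must cover the effects of the fit.
#' @return data frame with columns \code{signal}, \code{direction}
#'   (\code{"up"} or \code{"down"}) and \code{effect}; excluded zero-sign
#'   effects are attached as attribute \code{"ties"}.
#' @export
group_effects <- function(result, direction_matrix) {
  g <- result$final_graph
  att <- result$attachment
  labs <- attr(att, "signal_labels")
  dm <- as.matrix(direction_matrix)
  if (is.null(rownames(dm)) || !all(names(att) %in% rownames(dm)))
    .stop_input("direction matrix must have rows for every effect")
  if (ncol(dm) != nrow(g))
    .stop_input("direction matrix must have one column per signal")
  tgt <- unclass(att)
  attached <- which(!is.na(tgt))
  signal <- character(0); direction <- character(0); effect <- character(0)
  ties <- character(0)
  for (e in attached) {
    s <- tgt[e]
    pred <- which(g[, s] == 1)  # perturbations with a predicted effect
    net <- mean(dm[names(att)[e], pred])
    if (net > 0) d <- "up" else if (net < 0) d <- "down" else {
      ties <- c(ties, names(att)[e]); next
    }
    signal <- c(signal, labs[s]); direction <- c(direction, d)
    effect <- c(effect, names(att)[e])
  }
  out <- data.frame(signal = signal, direction = direction, effect = effect)
  out <- out[order(out$signal, out$direction, out$effect), ]
  rownames(out) <- NULL
  if (length(ties))
    message(length(ties), " effect(s) with net sign zero excluded")
  attr(out, "ties") <- ties
  out
}

#' Consensus over independent fits
#'
#' Per-edge sampling frequency across a list of fits (e.g. the same data
#' analyzed under different seeds) and the modal graph containing the edges
#' present in more than half of the runs.
#'
#' @param results list of at least two \code{"mc_eminem"} fits or signals
#'   graphs with identical labels.
#' @return list with \code{frequency} (S x S matrix of edge frequencies;
#'   diagonal 1) and \code{modal} (signals graph of edges with frequency
#'   > 0.5).
#' @export
consensus_graph <- function(results) {
  graphs <- lapply(results, function(x)
    if (inherits(x, "mc_eminem")) x$final_graph else x)
  if (length(graphs) < 2L) .stop_input("need at least 2 results")
  labs <- rownames(graphs[[1]])
  ok <- vapply(graphs, function(g) identical(rownames(g), labs), logical(1))
  if (!all(ok)) .stop_input("all results must share the same labels")
  freq <- Reduce(`+`, graphs) / length(graphs)
  modal <- (freq > 0.5) * 1
  diag(modal) <- 1
  dimnames(modal) <- dimnames(freq)
  list(frequency = freq, modal = modal)
}
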