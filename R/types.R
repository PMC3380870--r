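#' Construct a signals graph
#'
#' A signals graph is a binary S x S adjacency matrix with unit diagonal;
#' \code{g[k, s] = 1} means the perturbation of signal k also perturbs
#' signal s.  Row and column names carry the signal labels.
#'
#' @param adjacency square numeric/integer matrix with entries in {0, 1};
#'   the diagonal is forced to 1.
#' @param labels optional character vector of signal labels; defaults to the
#'   dimnames of \code{adjacency} or \code{S1, S2, ...}.
#' @return a validated binary matrix with unit diagonal and matching
#'   row/column names.
#' @examples
#' g <- signals_graph(matrix(c(1, 0, 1, 1), 2, 2), labels = c("A", "B"))
#' @export
signals_graph <- function(adjacency, labels = NULL) {
  adjacency <- as.matrix(adjacency)
  S <- nrow(adjacency)
  if (S < 1L || ncol(adjacency) != S)
    .stop_input("'adjacency' must be a square matrix with S >= 1")
  if (is.null(labels))
    labels <- rownames(adjacency) %||% paste0("S", seq_len(S))
  if (length(labels) != S) .stop_input("'labels' must have length S")
  storage.mode(adjacency) <- "double"
  diag(adjacency) <- 1
  dimnames(adjacency) <- list(labels, labels)
  check_signals_graph(adjacency)
  adjacency
}

#' @rdname signals_graph
#' @param g object to validate.
#' @export
check_signals_graph <- function(g) {
  if (!is.matrix(g) || nrow(g) != ncol(g))
    .stop_input("signals graph must be a square matrix")
  if (!all(g %in% c(0, 1)))
    .stop_input("signals graph entries must be 0 or 1")
  if (!all(diag(g) == 1))
    .stop_input("signals graph must have unit diagonal")
  invisible(g)
}

#' Identity signals graph
#'
#' The edge-free graph (identity matrix), the conventional starting point
#' of the EM iteration and of the MCMC chain.
#'
#' @param labels character vector of signal labels.
#' @return an S x S identity matrix with the given labels.
#' @export
identity_graph <- function(labels) {
  S <- length(labels)
  signals_graph(diag(S), labels = labels)
}

#' Construct a log-odds matrix
#'
#' The E x S data matrix R of a NEM analysis: \code{R[e, k]} is the log
#' ratio of the evidence that effect gene e changed versus did not change
#' upon perturbation of signal k, as produced upstream by a moderated
#' t-test / FDR pipeline (not part of this package).
#'
#' @param values numeric E x S matrix with finite entries.
#' @param effect_labels,signal_labels optional dimnames; default to the
#'   dimnames of \code{values} or generated labels.
#' @return a validated numeric matrix with dimnames.
#' @export
log_odds <- function(values, effect_labels = NULL, signal_labels = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (!all(is.finite(values))) .stop_input("log-odds entries must be finite")
  effect_labels <- effect_labels %||% rownames(values) %||%
    paste0("e", seq_len(nrow(values)))
  signal_labels <- signal_labels %||% colnames(values) %||%
    paste0("S", seq_len(ncol(values)))
  if (length(effect_labels) != nrow(values) ||
      length(signal_labels) != ncol(values))
    .stop_input("label lengths must match the dimensions of 'values'")
  dimnames(values) <- list(effect_labels, signal_labels)
  values
}

# label of the reserved null attachment target (an extra column appended to
# attachment priors/posteriors, never a node of the signals graph)
#' Reserved label of the null attachment node
#'
#' Effects attached to the null node are predicted always inactive; the
#' null node implements automatic feature selection.  It is represented as
#' an extra column of attachment priors/posteriors, never as a node of the
#' signals graph.
#'
#' @return the character label used for the null column.
#' @export
null_label <- function() ".null"

#' Construct an attachment prior (or posterior)
#'
#' A row-stochastic E x (S+1) matrix over the attachment targets of each
#' effect: the S signals plus the null node (last column).
#'
#' @param values nonnegative E x (S+1) matrix; rows must sum to 1 within
#'   \code{tol}.
#' @param signal_labels labels of the S signal columns.
#' @param effect_labels optional effect labels.
#' @param tol tolerance on the row sums.
#' @return validated matrix with columns \code{c(signal_labels, null_label())}.
#' @export
attachment_prior <- function(values, signal_labels, effect_labels = NULL,
                             tol = 1e-9) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (ncol(values) != length(signal_labels) + 1L)
    .stop_input("attachment prior must have S+1 columns (signals + null)")
  if (any(values < 0)) .stop_input("attachment prior entries must be >= 0")
  rs <- rowSums(values)
  if (any(abs(rs - 1) > tol))
    .stop_input("attachment prior rows must sum to 1 (tolerance ", tol, ")")
  effect_labels <- effect_labels %||% rownames(values) %||%
    paste0("e", seq_len(nrow(values)))
  dimnames(values) <- list(effect_labels, c(signal_labels, null_label()))
  values
}

#' Uniform attachment prior
#'
#' @param effect_labels,signal_labels labels of the effects / signals.
#' @return an E x (S+1) matrix with every entry \code{1 / (S + 1)}.
#' @export
uniform_prior <- function(effect_labels, signal_labels) {
  E <- length(effect_labels); S <- length(signal_labels)
  attachment_prior(matrix(1 / (S + 1), E, S + 1L),
                   signal_labels = signal_labels,
                   effect_labels = effect_labels)
}

#' Construct an effects attachment
#'
#' The sparse effects graph: each effect is attached to exactly one signal
#' or to the null node.
#'
#' @param target integer vector of length E with values in \code{1..S}, or
#'   \code{NA} for the null node; alternatively a character vector of
#'   signal labels (with \code{null_label()} or \code{NA} for null).
#' @param signal_labels labels of the S signals.
#' @param effect_labels optional effect labels.
#' @return an integer vector (NA = null) with names = effect labels and
#'   attribute \code{signal_labels}, of class \code{"effects_attachment"}.
#' @export
effects_attachment <- function(target, signal_labels, effect_labels = NULL) {
  if (is.character(target)) {
    idx <- match(target, signal_labels)
    bad <- !is.na(target) & target != null_label() & is.na(idx)
    if (any(bad))
      .stop_input("unknown signal label(s): ",
                  paste(unique(target[bad]), collapse = ", "))
    target <- idx
  }
  target <- as.integer(target)
  if (any(!is.na(target) & (target < 1L | target > length(signal_labels))))
    .stop_input("attachment targets must be in 1..S or NA (null)")
  effect_labels <- effect_labels %||% names(target) %||%
    paste0("e", seq_along(target))
  names(target) <- effect_labels
  attr(target, "signal_labels") <- signal_labels
  class(target) <- "effects_attachment"
  target
}

#' @export
print.effects_attachment <- function(x, ...) {
  labs <- attr(x, "signal_labels")
  tgt <- ifelse(is.na(unclass(x)), null_label(), labs[unclass(x)])
  cat("effects attachment:", length(x), "effects,",
      sum(is.na(unclass(x))), "on the null node\n")
  print(utils::head(data.frame(effect = names(x), signal = tgt,
                               row.names = NULL), 10L))
  if (length(x) > 10L) cat("...\n")
  invisible(x)
}

# S x E binary attachment matrix (null effects are zero columns)
.attachment_matrix <- function(a) {
  labs <- attr(a, "signal_labels")
  S <- length(labs); E <- length(a)
  th <- matrix(0, S, E, dimnames = list(labs, names(a)))
  tgt <- unclass(a)
  ok <- !is.na(tgt)
  th[cbind(tgt[ok], which(ok))] <- 1
  th
}

# expand a scalar edge prior into an S x S matrix; validate openness
.edge_prior_matrix <- function(ep, S, labels = NULL) {
  if (length(ep) == 1L) ep <- matrix(as.numeric(ep), S, S)
  ep <- as.matrix(ep)
  if (nrow(ep) != S || ncol(ep) != S)
    .stop_input("edge prior must be scalar or an S x S matrix")
  off <- .offdiag(S)
  if (any(ep[off] <= 0 | ep[off] >= 1))
    .stop_input("edge prior probabilities must lie strictly in (0, 1)")
  if (!is.null(labels)) dimnames(ep) <- list(labels, labels)
  ep
}
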