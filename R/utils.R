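# internal numerical helpers

# row-wise log-sum-exp; x a numeric matrix, returns length-nrow(x) vector
# (ties.method = "first" keeps max.col off the RNG stream)
.lse_rows <- function(x) {
  m <- x[cbind(seq_len(nrow(x)), max.col(x, ties.method = "first"))]
  m + log(rowSums(exp(x - m)))
}

# indices of off-diagonal entries of an S x S matrix
.offdiag <- function(S) which(rep(seq_len(S), S) != rep(seq_len(S), each = S))

`%||%` <- function(a, b) if (is.null(a)) b else a

.stop_input <- function(...) stop(..., call. = FALSE)

# canonical string key of a binary graph, used to detect revisits / count
# duplicates in a trace
.graph_key <- function(g) paste(as.integer(g), collapse = "")
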