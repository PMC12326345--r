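# Brute-force oracle for the interaction model: enumerate every ordered
# sequence of n particles drawn from m components. Each sequence occurs with
# probability prod(V) and contributes the geometric mean of its members'
# strengths. The closed-form model aggregates these sequences by type, so
# the two routes must agree exactly.
oracle_interaction <- function(V, strengths, n) {
  m <- length(V)
  seqs <- as.matrix(expand.grid(rep(list(seq_len(m)), n)))
  contrib <- apply(seqs, 1L, function(idx) {
    p <- prod(V[idx])
    s <- if (any(strengths[idx] == 0)) 0 else exp(mean(log(strengths[idx])))
    p * s
  })
  sum(contrib)
}

# Random binary composition away from the degenerate endpoints.
random_binary_comp <- function() {
  v <- stats::runif(1, 0.05, 0.95)
  composition(c("A", "B"), c(v, 1 - v))
}
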