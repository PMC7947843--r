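# independent oracles shared across test files

# JC69 transition probability (closed form, independent of the engine)
jc_p <- function(t) {
  e <- exp(-4 * t / 3)
  function(i, j) if (i == j) 0.25 + 0.75 * e else 0.25 - 0.25 * e
}

# brute-force likelihood by enumeration over all internal-state assignments
# (JC69, no rate variation); tree as phylo, alignment as character matrix
enum_loglik_jc <- function(tree, seq) {
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  states <- c(A = 1, C = 2, G = 3, T = 4)
  elen <- numeric(nnode)
  elen[tree$edge[, 2]] <- tree$edge.length
  internals <- (ntip + 1):nnode
  P <- lapply(seq_len(nnode), function(v) {
    f <- jc_p(elen[v])
    outer(1:4, 1:4, Vectorize(f))
  })
  tot <- 0
  grid <- as.matrix(expand.grid(rep(list(1:4), length(internals))))
  for (s in seq_len(ncol(seq))) {
    tipstate <- states[seq[tree$tip.label, s]]
    lik <- 0
    for (g in seq_len(nrow(grid))) {
      assign_state <- c(tipstate, grid[g, ])
      term <- 0.25
      for (e in seq_len(nrow(tree$edge))) {
        p <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
        term <- term * P[[ch]][assign_state[p], assign_state[ch]]
      }
      lik <- lik + term
    }
    tot <- tot + log(lik)
  }
  tot
}

# cubic brute-force 3-segment SSE oracle: loop over all (l, r), computing
# each segment's SSE from first principles
sse_oracle <- function(h, min_len) {
  L <- length(h)
  seg_sse <- function(x) sum((x - mean(x))^2)
  best <- c(Inf, NA, NA)
  for (l in min_len:(L - 2 * min_len)) {
    for (r in (l + min_len):(L - min_len)) {
      tot <- seg_sse(h[seq_len(l)]) + seg_sse(h[(l + 1):r]) +
        seg_sse(h[(r + 1):L])
      if (tot < best[1] - 1e-9) best <- c(tot, l, r)
    }
  }
  best
}
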