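# Independent oracles: exhaustive state enumeration for small trees
# (matrix exponentials via Matrix::expm, not the package's eigenpath),
# an amino-acid-level pruning oracle, and numeric-integration segment
# means for the discrete gamma.

# Exhaustive-enumeration log-likelihood: sums the joint probability over
# every assignment of internal-node states.  Feasible for <= 2 internal
# nodes (use unrooted trees for 4 tips).
oracle_loglik <- function(tree, aln, model) {
  edge <- tree$edge
  ntip <- length(tree$tip.label)
  S <- nrow(model$Q)
  states <- aln$states[tree$tip.label, , drop = FALSE]
  stopifnot(all(states > 0))
  internals <- sort(unique(edge[, 1]))
  root <- internals[!internals %in% edge[, 2]]
  Ps <- lapply(seq_len(nrow(edge)), function(e)
    as.matrix(Matrix::expm(tree$edge.length[e] * model$Q)))
  grid <- as.matrix(do.call(expand.grid,
                            rep(list(seq_len(S)), length(internals))))
  gcol <- function(node, s)
    if (node <= ntip) rep(states[node, s], nrow(grid))
    else grid[, match(node, internals)]
  tot <- 0
  for (s in seq_len(ncol(states))) {
    v <- model$freqs[gcol(root, s)]
    for (e in seq_len(nrow(edge)))
      v <- v * Ps[[e]][cbind(gcol(edge[e, 1], s), gcol(edge[e, 2], s))]
    tot <- tot + log(sum(v))
  }
  tot
}

# 20-state amino-acid pruning with Matrix::expm transition matrices.
aa_oracle_loglik <- function(tree, aa_states, Raa, fa) {
  tr <- stats::reorder(tree, "postorder")
  ntip <- length(tr$tip.label)
  aa_states <- aa_states[tr$tip.label, , drop = FALSE]
  Ps <- lapply(tr$edge.length, function(t) as.matrix(Matrix::expm(t * Raa)))
  tot <- 0
  for (s in seq_len(ncol(aa_states))) {
    L <- vector("list", ntip + tr$Nnode)
    for (e in seq_len(nrow(tr$edge))) {
      par <- tr$edge[e, 1]; ch <- tr$edge[e, 2]
      v <- if (ch <= ntip) {
        x <- numeric(20); x[aa_states[ch, s]] <- 1; x
      } else L[[ch]]
      y <- as.vector(Ps[[e]] %*% v)
      L[[par]] <- if (is.null(L[[par]])) y else L[[par]] * y
    }
    tot <- tot + log(sum(fa * L[[tr$edge[nrow(tr$edge), 1]]]))
  }
  tot
}

# Discrete-gamma segment means by numeric integration of x * density.
dg_integration_oracle <- function(alpha, m, priors = rep(1 / m, m)) {
  qb <- c(0, stats::qgamma(cumsum(priors)[-m], alpha, rate = alpha), Inf)
  vapply(seq_len(m), function(k)
    stats::integrate(function(x) x * stats::dgamma(x, alpha, rate = alpha),
                     qb[k], qb[k + 1], rel.tol = 1e-10)$value / priors[k],
    0)
}

# generator invariants under the unit-time normalization
expect_valid_generator <- function(m, tol = 1e-10) {
  Q <- m$Q; f <- m$freqs
  expect_lt(max(abs(rowSums(Q))), tol)
  expect_lt(max(abs(f * Q - t(f * Q))), tol)  # diag(f) Q symmetric
  expect_lt(abs(-sum(f * diag(Q)) - 1), tol)
  expect_true(all(Q[row(Q) != col(Q)] >= 0))
}
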