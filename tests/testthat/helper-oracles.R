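# Independent brute-force oracles and small fixture builders. These are the
# reference computations the implementation is checked against; they share
# no code with the package internals they verify.

make_pa <- function(m) {
  storage.mode(m) <- "integer"
  class(m) <- c("pa_matrix", class(m))
  m
}

# Random rooted binary tree with n tips (labelled t1..tn) and exp(1) branch
# lengths, built by sequential random attachment.
random_binary_tree <- function(n, seed) {
  set.seed(seed)
  tree <- ape::rtree(n, rooted = TRUE)
  tree$tip.label <- paste0("t", seq_len(n))
  tree$edge.length <- stats::rexp(nrow(tree$edge))
  tree
}

# Exhaustive small-parsimony oracle: minimum number of 0/1 state changes
# over all assignments of states to internal nodes.
brute_fitch <- function(tree, states) {
  tree <- stats::reorder(tree, "postorder")
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  tip_state <- as.integer(states[tree$tip.label])
  combos <- expand.grid(rep(list(0:1), nnode))
  best <- Inf
  for (i in seq_len(nrow(combos))) {
    full <- c(tip_state, as.integer(combos[i, ]))
    cost <- sum(full[tree$edge[, 1]] != full[tree$edge[, 2]])
    best <- min(best, cost)
  }
  best
}

# Matrix-exponential pruning oracle: enumerates all internal-node state
# combinations and sums path probabilities, using an eigen-decomposed
# 2-state generator (no shared code with the package's closed form).
brute_mk_loglik <- function(tree, states, q01, q10, root_p1) {
  P <- function(t) {
    Q <- matrix(c(-q01, q01, q10, -q10), 2, 2, byrow = TRUE)
    e <- eigen(Q)
    Re(e$vectors %*% diag(exp(e$values * t)) %*% solve(e$vectors))
  }
  tree <- stats::reorder(tree, "postorder")
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  tip_state <- as.integer(states[tree$tip.label])
  root <- ntip + 1L
  combos <- expand.grid(rep(list(0:1), nnode))
  total <- 0
  Pmats <- lapply(tree$edge.length, P)
  for (i in seq_len(nrow(combos))) {
    full <- c(tip_state, as.integer(combos[i, ]))
    pr <- if (full[root] == 1) root_p1 else 1 - root_p1
    for (e in seq_len(nrow(tree$edge))) {
      pr <- pr * Pmats[[e]][full[tree$edge[e, 1]] + 1L,
                            full[tree$edge[e, 2]] + 1L]
    }
    total <- total + pr
  }
  log(total)
}

# Plain power-iteration PageRank with edge weights (damping d), normalised
# to sum to 1; dangling nodes redistribute uniformly.
brute_pagerank <- function(nodes, from, to, weight, d = 0.85,
                           iters = 5000, tol = 1e-14) {
  n <- length(nodes)
  W <- matrix(0, n, n, dimnames = list(nodes, nodes))
  for (i in seq_along(from)) W[from[i], to[i]] <- W[from[i], to[i]] + weight[i]
  out_w <- rowSums(W)
  pr <- rep(1 / n, n)
  for (it in seq_len(iters)) {
    new <- rep((1 - d) / n, n)
    for (i in seq_len(n)) {
      if (out_w[i] > 0) {
        new <- new + d * pr[i] * W[i, ] / out_w[i]
      } else {
        new <- new + d * pr[i] / n
      }
    }
    if (max(abs(new - pr)) < tol) { pr <- new; break }
    pr <- new
  }
  stats::setNames(pr / sum(pr), nodes)
}

# Small deterministic benchmark used by several integration tests.
tiny_benchmark <- function(seed = 5) {
  generate_benchmark(n_tips = 96, n_null_genes = 40, n_mutualistic = 3,
                     n_commensal = 1, n_competitive = 2, seed = seed)
}

tiny_config <- function(seed = 5, ...) {
  screen_config(n_trees = 60, n_d_permutations = 100, seed = seed,
                rare_min = 0.02, common_max = 0.98, ...)
}
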