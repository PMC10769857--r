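#' Fitch parsimony score of a binary character
#'
#' Minimum number of presence/absence state changes needed to explain the
#' tip pattern on the tree (unordered, unweighted small parsimony). Used to
#' require that a gene family has been gained/lost repeatedly before its
#' associations are interpreted.
#'
#' @param tree a rooted binary \code{phylo}.
#' @param states named 0/1 vector; names must cover all tip labels.
#' @return integer change count (0 for a constant character).
#' @export
fitch_parsimony <- function(tree, states) {
  ts <- tree_struct(tree)
  m <- match_tip_states(ts, states)
  as.integer(fitch_many(ts, matrix(m, ncol = 1L)))
}

match_tip_states <- function(ts, states) {
  if (is.null(names(states))) {
    if (length(states) != ts$ntip) stop("states length != number of tips")
    return(as.numeric(states))
  }
  missing <- setdiff(ts$tip_labels, names(states))
  if (length(missing)) {
    stop("missing tip state(s): ", paste(missing, collapse = ", "))
  }
  as.numeric(states[ts$tip_labels])
}

# Vectorised Fitch over the columns of a 0/1 tip matrix (tips in
# ts$tip_labels order). State sets are bit-coded: 1 = {0}, 2 = {1}, 3 = {0,1}.
fitch_many <- function(ts, M) {
  nb <- ncol(M)
  code <- matrix(0L, ts$ntip + ts$nnode, nb)
  code[seq_len(ts$ntip), ] <- M + 1L
  changes <- numeric(nb)
  for (nd in ts$internal_post) {
    a <- code[ts$child1[nd], ]
    b <- code[ts$child2[nd], ]
    inter <- bitwAnd(a, b)
    disjoint <- inter == 0L
    changes <- changes + disjoint
    code[nd, ] <- ifelse(disjoint, bitwOr(a, b), inter)
  }
  changes
}

#' Sum of sister-clade differences
#'
#' The raw ingredient of the Fritz-Purvis D statistic: internal-node values
#' are estimated tips-to-root as the unweighted mean of the two daughter
#' values and the absolute left-right daughter differences are summed over
#' all internal nodes.
#'
#' @param tree a rooted binary \code{phylo}.
#' @param tip_values named numeric vector over the tips (binary or
#'   continuous).
#' @return the observed sum of sister-clade differences.
#' @export
sister_clade_changes <- function(tree, tip_values) {
  ts <- tree_struct(tree)
  m <- match_tip_states(ts, tip_values)
  d_sums(ts, matrix(m, ncol = 1L))
}

# Vectorised sister-clade difference sums over columns of a tip matrix.
d_sums <- function(ts, M) {
  nb <- ncol(M)
  V <- matrix(0, ts$ntip + ts$nnode, nb)
  V[seq_len(ts$ntip), ] <- M
  d <- numeric(nb)
  for (nd in ts$internal_post) {
    a <- V[ts$child1[nd], ]
    b <- V[ts$child2[nd], ]
    d <- d + abs(a - b)
    V[nd, ] <- (a + b) / 2
  }
  d
}

# B Brownian simulations on the tree: returns tips x B matrix of continuous
# values. Zero-length branches get epsilon = 1e-8 * tree height so every
# tip still receives independent noise.
brownian_tips <- function(ts, B) {
  eps <- 1e-8 * max(ts$height, .Machine$double.eps)
  n_nodes <- ts$ntip + ts$nnode
  V <- matrix(0, n_nodes, B)
  edge <- ts$edge
  elen <- pmax(ts$edge_length, eps)
  # preorder = reverse postorder over edges
  for (i in rev(seq_len(nrow(edge)))) {
    p <- edge[i, 1L]; ch <- edge[i, 2L]
    V[ch, ] <- V[p, ] + stats::rnorm(B, 0, sqrt(elen[i]))
  }
  V[seq_len(ts$ntip), , drop = FALSE]
}

# Threshold continuous columns so the k largest values become 1. Ties at the
# cut rank are broken by a tiny seeded jitter applied before ranking.
threshold_topk <- function(W, k) {
  W <- W + stats::rnorm(length(W), 0, 1e-12)
  apply(W, 2L, function(col) {
    out <- numeric(length(col))
    out[order(col, decreasing = TRUE)[seq_len(k)]] <- 1
    out
  })
}

#' Fritz-Purvis D statistic for a binary trait
#'
#' Measures whether a presence/absence pattern is phylogenetically random
#' (D near 1) or clumped as under a thresholded Brownian process (D near 0).
#' The observed sum of sister-clade differences is scaled between the mean
#' of \code{B} tip-shuffling permutations and the mean of \code{B}
#' Brownian-threshold simulations (the simulated continuous values are
#' binarised so the number of 1s matches the observed count):
#' \deqn{D = (d_{obs} - \bar d_b) / (\bar d_r - \bar d_b)}
#'
#' @param tree a rooted binary \code{phylo}.
#' @param states named 0/1 vector over the tips.
#' @param B number of permutations and Brownian replicates (default 1000).
#' @param seed integer seed.
#' @return list with \code{d_obs}, \code{mean_d_r}, \code{mean_d_b},
#'   \code{D}, \code{parsimony}, \code{n_permutations}, and a
#'   \code{degenerate} flag (constant trait, or null means too close to
#'   scale against).
#' @export
d_statistic <- function(tree, states, B = 1000L, seed = 1L) {
  ts <- tree_struct(tree)
  m <- match_tip_states(ts, states)
  set.seed(seed)
  perm_idx <- replicate(B, sample.int(ts$ntip))
  btips <- brownian_tips(ts, B)
  res <- d_stat_engine(ts, m, perm_idx, btips)
  res$parsimony <- as.integer(fitch_many(ts, matrix(m, ncol = 1L)))
  res$n_permutations <- as.integer(B)
  res
}

# Core D computation from precomputed permutation indices and Brownian tip
# draws (shared across PAPs inside signal_screen for speed).
d_stat_engine <- function(ts, m, perm_idx, btips) {
  k <- sum(m == 1)
  if (k == 0L || k == ts$ntip) {
    return(list(d_obs = NA_real_, mean_d_r = NA_real_, mean_d_b = NA_real_,
                D = NA_real_, degenerate = TRUE))
  }
  d_obs <- d_sums(ts, matrix(m, ncol = 1L))
  perm_M <- matrix(m[perm_idx], nrow = ts$ntip)
  mean_d_r <- mean(d_sums(ts, perm_M))
  mean_d_b <- mean(d_sums(ts, threshold_topk(btips, k)))
  denom <- mean_d_r - mean_d_b
  if (!is.finite(denom) || abs(denom) < 1e-9 * max(1, abs(mean_d_r))) {
    return(list(d_obs = d_obs, mean_d_r = mean_d_r, mean_d_b = mean_d_b,
                D = NA_real_, degenerate = TRUE))
  }
  list(d_obs = d_obs, mean_d_r = mean_d_r, mean_d_b = mean_d_b,
       D = (d_obs - mean_d_b) / denom, degenerate = FALSE)
}

#' Phylogenetic-signal screen over a PAP set
#'
#' Computes the Fitch parsimony score for every PAP and the Fritz-Purvis D
#' statistic for the requested subset (by default all; inside the full
#' pipeline D is evaluated only for PAPs passing the F1 gate, which is where
#' it is needed). The pass flag is \code{D > d_min} (strict) and
#' \code{parsimony >= parsimony_min}; degenerate PAPs fail.
#'
#' Permutation indices and Brownian draws are generated once from the
#' config seed and shared across PAPs, so the screen cost is one tree sweep
#' per PAP per replicate block.
#'
#' @param tree a rooted binary \code{phylo} covering the PAP genome set.
#' @param paps a \code{pap_set}.
#' @param config a \code{\link{screen_config}}.
#' @param d_for pattern ids for which to compute D (default all).
#' @return data.frame: pattern_id, d_obs, mean_d_r, mean_d_b, D, parsimony,
#'   degenerate, pass.
#' @export
signal_screen <- function(tree, paps, config = screen_config(),
                          d_for = NULL) {
  ts <- tree_struct(tree)
  ids <- paps$pattern_ids
  if (is.null(d_for)) d_for <- ids
  M <- paps$patterns[ts$tip_labels, , drop = FALSE]
  pars <- as.integer(fitch_many(ts, M))
  B <- config$n_d_permutations
  set.seed(hash_seed(config$seed, "signal_screen"))
  perm_idx <- replicate(B, sample.int(ts$ntip))
  btips <- brownian_tips(ts, B)
  out <- data.frame(pattern_id = ids, d_obs = NA_real_, mean_d_r = NA_real_,
                    mean_d_b = NA_real_, D = NA_real_, parsimony = pars,
                    degenerate = FALSE, pass = FALSE,
                    stringsAsFactors = FALSE)
  for (i in seq_along(ids)) {
    if (!(ids[i] %in% d_for)) next
    res <- d_stat_engine(ts, M[, i], perm_idx, btips)
    out$d_obs[i] <- res$d_obs
    out$mean_d_r[i] <- res$mean_d_r
    out$mean_d_b[i] <- res$mean_d_b
    out$D[i] <- res$D
    out$degenerate[i] <- res$degenerate
    out$pass[i] <- !res$degenerate && is.finite(res$D) &&
      res$D > config$d_min && pars[i] >= config$parsimony_min
  }
  out
}
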