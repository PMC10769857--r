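# Synthetic benchmark generator: trees plus presence-absence matrices with
# planted, mechanistically coupled gain/loss dynamics, so every pipeline
# stage can be validated against known ground truth.

#' Define a coupled gene module
#'
#' A module is a small set of genes evolving as one joint continuous-time
#' Markov chain: gene i gains at rate \code{alpha[i]} and loses at rate
#' \code{beta[i]}, each multiplied by \code{gain_mult[i, j]} /
#' \code{loss_mult[i, j]} for every other gene j currently present on the
#' lineage. Coupling therefore acts on the evolving state, not directly on
#' tip correlations, so phylogenetic structure arises naturally.
#'
#' @param genes character ids.
#' @param alpha,beta base gain/loss rates per unit branch length.
#' @param gain_mult,loss_mult m x m multiplier matrices (diagonal ignored;
#'   entry [i, j] applies to gene i when gene j is present).
#' @param category declared relationship for the truth table
#'   (\code{"mutualism"}, \code{"commensalism"}, \code{"competition"}, or
#'   \code{"null"}).
#' @return an object of class \code{"module_spec"}.
#' @export
module_spec <- function(genes, alpha, beta, gain_mult, loss_mult,
                        category = "null") {
  m <- length(genes)
  stopifnot(m >= 1, length(alpha) == m, length(beta) == m,
            all(dim(gain_mult) == c(m, m)), all(dim(loss_mult) == c(m, m)),
            all(alpha >= 0), all(beta >= 0),
            all(gain_mult >= 0), all(loss_mult >= 0))
  out <- list(genes = genes, alpha = alpha, beta = beta,
              gain_mult = gain_mult, loss_mult = loss_mult,
              category = category)
  class(out) <- "module_spec"
  out
}

#' Stock two-gene module specifications
#'
#' Strong-coupling defaults used by \code{\link{generate_benchmark}}; rates
#' are per unit branch length on a height-1 tree and were chosen so each
#' member keeps an intermediate prevalence and the tip patterns of a pair
#' agree (mutualism/commensalism) or complement (competition) closely
#' enough to be learnable. Turnover is high (roughly 40-70 state changes on
#' a 256-tip tree): planted modules emulate gene families under repeated
#' horizontal transfer and loss, the regime in which a widespread, patchy
#' distribution (D above zero) is attainable at all; genes this dynamic are
#' the ones whose associations the screen is designed to detect.
#'
#' \itemize{
#' \item mutualism: symmetric; gain x27 and loss x(1/27) when the partner is
#'   present, i.e. alone each gene is short-lived, together both persist.
#' \item commensalism: the host evolves independently; the commensal can
#'   only exist with the host (gain 0, loss x50 when host absent) and
#'   equilibrates to ~85\% occupancy of host genomes, so the host also
#'   occurs alone, as the commensalism rule requires.
#' \item competition: gain 0 and loss x12 when the partner is present; the
#'   empty state is short-lived, so the pair is near mutually exclusive.
#' }
#'
#' @param genes length-2 character vector.
#' @param category one of \code{"mutualism"}, \code{"commensalism"},
#'   \code{"competition"}.
#' @return a \code{\link{module_spec}}.
#' @export
module_pair <- function(genes,
                        category = c("mutualism", "commensalism",
                                     "competition")) {
  category <- match.arg(category)
  stopifnot(length(genes) == 2L)
  switch(category,
    mutualism = module_spec(
      genes,
      alpha = c(2.5, 2.5), beta = c(180, 180),
      gain_mult = matrix(c(1, 72, 72, 1), 2, 2),
      loss_mult = matrix(c(1, 1 / 72, 1 / 72, 1), 2, 2),
      category = "mutualism"),
    commensalism = module_spec(
      genes,  # genes[1] = host, genes[2] = commensal
      alpha = c(0.9, 0.13), beta = c(1.35, 100),
      gain_mult = matrix(c(1, 100, 1, 1), 2, 2),   # [2,1]: commensal x100 when host present
      loss_mult = matrix(c(1, 0.02, 1, 1), 2, 2),  # [2,1]: commensal loss damped with host
      category = "commensalism"),
    competition = module_spec(
      genes,
      alpha = c(150, 150), beta = c(3.75, 3.75),
      gain_mult = matrix(c(1, 0, 0, 1), 2, 2),
      loss_mult = matrix(c(1, 12, 12, 1), 2, 2),
      category = "competition"))
}

# Per-gene flip rates of the joint chain in state s (0/1 vector).
module_rates <- function(spec, s) {
  present <- which(s == 1)
  m <- length(s)
  r <- numeric(m)
  for (i in seq_len(m)) {
    others <- setdiff(present, i)
    if (s[i] == 0) {
      r[i] <- spec$alpha[i] * prod(spec$gain_mult[i, others])
    } else {
      r[i] <- spec$beta[i] * prod(spec$loss_mult[i, others])
    }
  }
  r
}

# Approximate stationary distribution of the joint chain by power iteration
# on the uniformised transition matrix over all 2^m states.
module_stationary <- function(spec) {
  m <- length(spec$genes)
  if (m > 12L) stop("module too large (> 12 genes): 2^m state space")
  n_states <- 2L^m
  states <- as.matrix(expand.grid(rep(list(0:1), m)))[, seq_len(m),
                                                      drop = FALSE]
  Q <- matrix(0, n_states, n_states)
  for (si in seq_len(n_states)) {
    r <- module_rates(spec, states[si, ])
    for (i in seq_len(m)) {
      flip <- states[si, ]
      flip[i] <- 1 - flip[i]
      sj <- sum(flip * 2L^(seq_len(m) - 1L)) + 1L
      Q[si, sj] <- r[i]
    }
    Q[si, si] <- -sum(r)
  }
  lam <- max(-diag(Q)) * 1.05 + 1e-12
  P <- diag(n_states) + Q / lam
  pi0 <- rep(1 / n_states, n_states)
  for (it in seq_len(5000L)) {
    pi1 <- as.vector(pi0 %*% P)
    if (max(abs(pi1 - pi0)) < 1e-12) break
    pi0 <- pi1
  }
  list(states = states, pi = pi0 / sum(pi0))
}

#' Simulate a coupled module on a tree
#'
#' Gillespie simulation of the joint chain along every branch; the root
#' state is drawn from the module's approximate stationary distribution.
#' With all multipliers equal to 1 this reduces to independent two-state
#' Mk simulation per gene.
#'
#' @param tree a rooted binary \code{phylo}.
#' @param spec a \code{\link{module_spec}} (at most 12 genes).
#' @param seed integer seed.
#' @return tips x genes 0/1 matrix (rownames = tip labels).
#' @export
simulate_module <- function(tree, spec, seed = 1L) {
  set.seed(seed)
  simulate_module_raw(tree_struct(tree), spec, module_stationary(spec))
}

simulate_module_raw <- function(ts, spec, stat) {
  m <- length(spec$genes)
  root_state <- stat$states[sample.int(nrow(stat$states), 1L,
                                       prob = stat$pi), ]
  node_state <- matrix(NA_integer_, ts$ntip + ts$nnode, m)
  node_state[ts$root, ] <- root_state
  edge <- ts$edge
  for (i in rev(seq_len(nrow(edge)))) {  # preorder
    s <- node_state[edge[i, 1L], ]
    remaining <- ts$edge_length[i]
    repeat {
      r <- module_rates(spec, s)
      total <- sum(r)
      if (total <= 0) break
      wait <- stats::rexp(1L, total)
      if (wait > remaining) break
      remaining <- remaining - wait
      flip <- sample.int(m, 1L, prob = r)
      s[flip] <- 1L - s[flip]
    }
    node_state[edge[i, 2L], ] <- s
  }
  out <- node_state[seq_len(ts$ntip), , drop = FALSE]
  dimnames(out) <- list(ts$tip_labels, spec$genes)
  out
}

#' Generate a benchmark with planted relationship structure
#'
#' Simulates a Yule backbone tree, evolves every module's joint chain and a
#' block of independent null genes on it, enforces the screen's prevalence
#' window by rejection (a module or null gene is resampled up to 50 times,
#' then dropped with a message), shuffles the column order, and returns the
#' exact truth table.
#'
#' @param n_tips tips of the Yule tree (default 256).
#' @param n_null_genes independent null genes (default 400).
#' @param n_mutualistic,n_commensal,n_competitive numbers of planted strong
#'   two-gene modules (defaults 20, 10, 10).
#' @param modules optional list of extra \code{\link{module_spec}}s.
#' @param seed master seed.
#' @param rare_min,common_max prevalence window enforced on every simulated
#'   gene (defaults 0.05 / 0.95).
#' @return list with \code{matrix} (a \code{pa_matrix}), \code{tree}, and
#'   \code{truth} (list with \code{pairs}: data.frame gene_i, gene_j,
#'   category, expected_polarity; and \code{null_genes}).
#' @export
generate_benchmark <- function(n_tips = 256L, n_null_genes = 400L,
                               n_mutualistic = 20L, n_commensal = 10L,
                               n_competitive = 10L, modules = list(),
                               seed = 1L,
                               rare_min = 0.05, common_max = 0.95) {
  tree <- simulate_tree(n_tips, "yule", seed = hash_seed(seed, "tree"))
  ts <- tree_struct(tree)
  specs <- modules
  mk_pairs <- function(n, category, prefix) {
    lapply(seq_len(n), function(i) {
      module_pair(sprintf("%s%02d_%s", prefix, i, c("a", "b")), category)
    })
  }
  specs <- c(specs,
             mk_pairs(n_mutualistic, "mutualism", "mut"),
             mk_pairs(n_commensal, "commensalism", "com"),
             mk_pairs(n_competitive, "competition", "cmp"))
  cols <- list()
  pairs <- list()
  dropped <- 0L
  for (k in seq_along(specs)) {
    spec <- specs[[k]]
    stat <- module_stationary(spec)
    set.seed(hash_seed(seed, paste0("module:", k)))
    ok <- FALSE
    for (try in seq_len(50L)) {
      tips <- simulate_module_raw(ts, spec, stat)
      prev <- colMeans(tips)
      if (all(prev >= rare_min & prev <= common_max)) { ok <- TRUE; break }
    }
    if (!ok) { dropped <- dropped + 1L; next }
    cols[[length(cols) + 1L]] <- tips
    if (length(spec$genes) == 2L) {
      pairs[[length(pairs) + 1L]] <- data.frame(
        gene_i = spec$genes[1L], gene_j = spec$genes[2L],
        category = spec$category,
        expected_polarity = if (spec$category == "competition")
          "avoidance" else "co-occurrence",
        stringsAsFactors = FALSE)
    }
  }
  if (dropped) message(dropped, " module(s) dropped: prevalence window ",
                       "not met in 50 draws")
  null_ids <- character(0)
  if (n_null_genes > 0L) {
    nulls <- simulate_null_benchmark(tree, n_null_genes,
                                     seed = hash_seed(seed, "nulls"),
                                     prevalence_range = c(rare_min,
                                                          common_max))
    null_cols <- unclass(nulls$matrix)
    null_ids <- colnames(null_cols)
    cols[[length(cols) + 1L]] <- null_cols[ts$tip_labels, , drop = FALSE]
  }
  mat <- do.call(cbind, lapply(cols, function(x)
    x[ts$tip_labels, , drop = FALSE]))
  set.seed(hash_seed(seed, "shuffle"))
  mat <- mat[, sample.int(ncol(mat)), drop = FALSE]
  list(matrix = new_pa_matrix(mat),
       tree = tree,
       truth = list(pairs = if (length(pairs)) do.call(rbind, pairs)
                    else data.frame(gene_i = character(),
                                    gene_j = character(),
                                    category = character(),
                                    expected_polarity = character()),
                    null_genes = null_ids))
}
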