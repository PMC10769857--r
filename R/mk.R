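# Two-state all-rates-different (ARD) Mk machinery: pruning likelihood,
# maximum-likelihood rate fitting, tip simulation, and the null
# false-discovery calibration that re-runs the whole screen on
# phylogeny-constrained but gene-independent data.

# Closed-form transition probabilities of the 2-state CTMC with gain rate
# q01 (0 -> 1) and loss rate q10 (1 -> 0) over time t. Returns the four
# entries for a vector of times.
mk_transition <- function(q01, q10, t) {
  s <- q01 + q10
  if (s <= 0) {
    n <- length(t)
    return(list(p00 = rep(1, n), p01 = rep(0, n),
                p10 = rep(0, n), p11 = rep(1, n)))
  }
  e <- exp(-s * t)
  list(p00 = (q10 + q01 * e) / s, p01 = q01 * (1 - e) / s,
       p10 = q10 * (1 - e) / s, p11 = (q01 + q10 * e) / s)
}

#' Pruning log-likelihood of a binary trait under the ARD Mk model
#'
#' Felsenstein pruning over the rooted binary tree with gain rate
#' \code{q01}, loss rate \code{q10}, and root state weighted by
#' \code{(1 - root_p1, root_p1)}.
#'
#' @param tree a rooted binary \code{phylo}.
#' @param states named 0/1 vector over the tips.
#' @param q01 gain rate (absent to present, per unit branch length).
#' @param q10 loss rate.
#' @param root_p1 probability of presence at the root.
#' @return the log-likelihood (\code{-Inf} if the data are impossible, e.g.
#'   mixed tip states on a zero-length tree).
#' @export
mk_log_likelihood <- function(tree, states, q01, q10, root_p1) {
  stopifnot(q01 >= 0, q10 >= 0, q01 + q10 > 0,
            root_p1 >= 0, root_p1 <= 1)
  ts <- tree_struct(tree)
  m <- match_tip_states(ts, states)
  L0 <- L1 <- numeric(ts$ntip + ts$nnode)
  scale_log <- 0
  L0[seq_len(ts$ntip)] <- as.numeric(m == 0)
  L1[seq_len(ts$ntip)] <- as.numeric(m == 1)
  for (nd in ts$internal_post) {
    down <- function(ch, len) {
      p <- mk_transition(q01, q10, len)
      c(p$p00 * L0[ch] + p$p01 * L1[ch],
        p$p10 * L0[ch] + p$p11 * L1[ch])
    }
    a <- down(ts$child1[nd], ts$len1[nd])
    b <- down(ts$child2[nd], ts$len2[nd])
    l0 <- a[1L] * b[1L]
    l1 <- a[2L] * b[2L]
    mx <- max(l0, l1)
    if (mx == 0) return(-Inf)
    scale_log <- scale_log + log(mx)
    L0[nd] <- l0 / mx
    L1[nd] <- l1 / mx
  }
  lik <- (1 - root_p1) * L0[ts$root] + root_p1 * L1[ts$root]
  if (lik <= 0) return(-Inf)
  log(lik) + scale_log
}

#' Fit the ARD Mk model to a binary trait
#'
#' Maximises the pruning log-likelihood over (q01, q10) by bounded
#' multi-start optimisation on the log scale. The root probability follows
#' the fitted model's stationary distribution, \code{q01 / (q01 + q10)},
#' unless a fixed \code{root_p1} is supplied.
#'
#' @param tree a rooted binary \code{phylo}.
#' @param states named 0/1 vector over the tips; must not be constant.
#' @param root_p1 optional fixed root presence probability; \code{NULL}
#'   (default) uses the stationary distribution of the candidate rates.
#' @param n_starts number of optimisation starts (default 4).
#' @param bounds rate bounds per unit branch length (default
#'   \code{c(1e-8, 1e3)}).
#' @return list with \code{q01}, \code{q10}, \code{root_p1},
#'   \code{log_likelihood}, \code{converged}.
#' @export
fit_ard <- function(tree, states, root_p1 = NULL, n_starts = 4L,
                    bounds = c(1e-8, 1e3)) {
  ts <- tree_struct(tree)
  m <- match_tip_states(ts, states)
  if (length(unique(m)) < 2L) stop("trait is constant; rates inestimable")
  prev <- mean(m)
  # rate scale from the parsimony change count per unit of tree length,
  # split between gain and loss by the observed prevalence
  changes <- max(1, fitch_many(ts, matrix(m, ncol = 1L)))
  base <- changes / max(sum(ts$edge_length), 1e-6)
  starts <- list(2 * c(prev, 1 - prev), c(1, 1), c(0.2, 0.2), c(5, 5))
  nll <- function(par) {
    q01 <- exp(par[1L]); q10 <- exp(par[2L])
    rp <- if (is.null(root_p1)) q01 / (q01 + q10) else root_p1
    -mk_log_likelihood(tree, states, q01, q10, rp)
  }
  lb <- log(bounds[1L]); ub <- log(bounds[2L])
  best <- NULL
  converged <- FALSE
  for (i in seq_len(min(n_starts, length(starts)))) {
    p0 <- pmin(pmax(log(starts[[i]] * base), lb), ub)
    opt <- tryCatch(
      stats::optim(p0, nll, method = "L-BFGS-B", lower = lb, upper = ub,
                   control = list(factr = 1e7)),
      error = function(e) NULL)
    if (is.null(opt)) next
    if (is.null(best) || opt$value < best$value) best <- opt
    if (opt$convergence == 0L) converged <- TRUE
  }
  if (is.null(best)) stop("ARD optimisation failed from every start")
  q01 <- exp(best$par[1L]); q10 <- exp(best$par[2L])
  rp <- if (is.null(root_p1)) q01 / (q01 + q10) else root_p1
  list(q01 = q01, q10 = q10, root_p1 = rp,
       log_likelihood = -best$value, converged = converged)
}

#' Simulate a binary trait under the ARD Mk model
#'
#' Draws the root state Bernoulli(\code{root_p1}) and evolves it down every
#' branch by exact sampling from the 2-state transition matrix.
#'
#' @param tree a rooted binary \code{phylo}.
#' @param model list with \code{q01}, \code{q10}, \code{root_p1} (e.g. from
#'   \code{\link{fit_ard}}).
#' @param seed integer seed.
#' @return named 0/1 vector over the tips.
#' @export
simulate_mk <- function(tree, model, seed = 1L) {
  set.seed(seed)
  simulate_mk_raw(tree_struct(tree), model$q01, model$q10, model$root_p1)
}

# Uses the current RNG stream (callers seed it).
simulate_mk_raw <- function(ts, q01, q10, root_p1) {
  state <- integer(ts$ntip + ts$nnode)
  state[ts$root] <- stats::rbinom(1L, 1L, root_p1)
  edge <- ts$edge
  for (i in rev(seq_len(nrow(edge)))) {  # preorder
    p <- state[edge[i, 1L]]
    tp <- mk_transition(q01, q10, ts$edge_length[i])
    pr1 <- if (p == 1) tp$p11 else tp$p01
    state[edge[i, 2L]] <- stats::rbinom(1L, 1L, pr1)
  }
  stats::setNames(state[seq_len(ts$ntip)], ts$tip_labels)
}

#' Simulate an independent-gene null matrix on a tree
#'
#' Every gene evolves independently under its own ARD Mk model, with rates
#' sampled so that traits keep an intermediate prevalence and flip state
#' repeatedly across the tree (the regime in which the screen's false
#' discoveries must be counted). Rates are drawn by sampling a gain/loss
#' ratio log-uniformly in \code{ratio_range} and scaling both rates so the
#' expected number of transitions on the tree (stationary switching rate
#' times total branch length) is log-uniform in \code{events_range}. Genes whose
#' realised prevalence falls outside \code{prevalence_range} are resampled
#' (up to 50 draws, then dropped with a message).
#'
#' @param tree a rooted binary \code{phylo}.
#' @param n_genes number of independent genes to simulate.
#' @param seed integer seed.
#' @param prevalence_range admissible realised prevalence (default
#'   \code{c(0.05, 0.95)}).
#' @param events_range expected transition count range (default
#'   \code{c(8, 15)}: gene histories flip state repeatedly, keeping
#'   expected parsimony at or above the screen's 8-change threshold, while
#'   remaining phylogenetically structured the way independently evolving
#'   accessory genes are).
#' @param ratio_range gain/loss ratio range (default \code{c(1/3, 3)}).
#' @return list with \code{matrix} (a \code{pa_matrix}, genomes x genes) and
#'   \code{rates} (data.frame gene, q01, q10, root_p1).
#' @export
simulate_null_benchmark <- function(tree, n_genes, seed = 1L,
                                    prevalence_range = c(0.05, 0.95),
                                    events_range = c(8, 15),
                                    ratio_range = c(1 / 3, 3)) {
  ts <- tree_struct(tree)
  total_len <- sum(ts$edge_length)
  set.seed(seed)
  cols <- matrix(0L, ts$ntip, n_genes,
                 dimnames = list(ts$tip_labels,
                                 sprintf("null%04d", seq_len(n_genes))))
  rates <- data.frame(gene = colnames(cols), q01 = NA_real_, q10 = NA_real_,
                      root_p1 = NA_real_)
  keep <- rep(TRUE, n_genes)
  for (g in seq_len(n_genes)) {
    ok <- FALSE
    for (try in seq_len(50L)) {
      ratio <- exp(stats::runif(1L, log(ratio_range[1L]), log(ratio_range[2L])))
      events <- exp(stats::runif(1L, log(events_range[1L]),
                                 log(events_range[2L])))
      # stationary switching rate = 2 q01 q10 / (q01 + q10)
      q10 <- events * (1 + ratio) / (2 * ratio * total_len)
      q01 <- ratio * q10
      rp <- q01 / (q01 + q10)
      states <- simulate_mk_raw(ts, q01, q10, rp)
      prev <- mean(states)
      if (prev >= prevalence_range[1L] && prev <= prevalence_range[2L]) {
        cols[, g] <- states
        rates[g, c("q01", "q10", "root_p1")] <- c(q01, q10, rp)
        ok <- TRUE
        break
      }
    }
    if (!ok) keep[g] <- FALSE
  }
  if (!all(keep)) {
    message(sum(!keep), " null gene(s) dropped: prevalence constraint ",
            "not met in 50 draws")
  }
  list(matrix = new_pa_matrix(cols[, keep, drop = FALSE]),
       rates = rates[keep, , drop = FALSE])
}

#' Null false-discovery calibration of the full screen
#'
#' Fits an ARD Mk model to every PAP, then repeatedly simulates all PAPs
#' independently on the tree and re-runs the predictability screen and the
#' phylogenetic-signal filter on the simulated data. Because the genes are
#' simulated independently, any PAP passing both the dual-class F1 gate and
#' the D/parsimony gate is a false discovery; the per-replicate fraction is
#' the calibration. D statistics are computed only for F1-passing simulated
#' PAPs, where the gate needs them.
#'
#' @param tree a rooted binary \code{phylo}.
#' @param paps a \code{pap_set} (real or synthetic input whose rates are to
#'   be emulated).
#' @param config a \code{\link{screen_config}}.
#' @param n_sims number of replicates (default \code{config$n_null_sims}).
#' @param rates optional precomputed data.frame (pattern_id, q01, q10,
#'   root_p1) to skip the fitting step.
#' @return list with \code{per_sim} (data.frame: sim, n_paps, n_f1_pass,
#'   n_both_pass, fraction_f1, fraction_both), \code{mean_fraction_both},
#'   \code{range_fraction_both}, and the fitted \code{rates}.
#' @export
null_fdr_screen <- function(tree, paps, config = screen_config(),
                            n_sims = NULL, rates = NULL) {
  if (is.null(n_sims)) n_sims <- config$n_null_sims
  ts <- tree_struct(tree)
  ids <- paps$pattern_ids
  if (is.null(rates)) {
    fits <- lapply(ids, function(id) {
      states <- stats::setNames(paps$patterns[, id], paps$genome_ids)
      fit_ard(tree, states)
    })
    rates <- data.frame(pattern_id = ids,
                        q01 = vapply(fits, `[[`, numeric(1), "q01"),
                        q10 = vapply(fits, `[[`, numeric(1), "q10"),
                        root_p1 = vapply(fits, `[[`, numeric(1), "root_p1"))
  }
  per_sim <- vector("list", n_sims)
  for (s in seq_len(n_sims)) {
    set.seed(hash_seed(config$seed, paste0("nullsim:", s)))
    sim <- vapply(seq_len(nrow(rates)), function(i) {
      simulate_mk_raw(ts, rates$q01[i], rates$q10[i], rates$root_p1[i])
    }, numeric(ts$ntip))
    colnames(sim) <- rates$pattern_id
    rownames(sim) <- ts$tip_labels
    sim <- sim[, apply(sim, 2L, function(x) length(unique(x)) > 1L),
               drop = FALSE]
    colnames(sim) <- sprintf("sim%05d", seq_len(ncol(sim)))
    sim_paps <- collapse_patterns(new_pa_matrix(sim))
    cfg <- config
    cfg$seed <- hash_seed(config$seed, paste0("nullscreen:", s))
    scr <- run_predictability_screen(sim_paps, cfg, importance_floor = Inf)
    f1_pass <- scr$metrics$pattern_id[scr$metrics$predictable]
    sig <- signal_screen(tree, sim_paps, cfg, d_for = f1_pass)
    both <- sum(scr$metrics$predictable &
                  sig$pass[match(scr$metrics$pattern_id, sig$pattern_id)])
    # count over simulated genes (collapsed duplicates expand back)
    n_genes <- ncol(sim)
    expand <- lengths(sim_paps$members)
    f1_genes <- sum(expand[f1_pass])
    both_ids <- scr$metrics$pattern_id[scr$metrics$predictable &
      sig$pass[match(scr$metrics$pattern_id, sig$pattern_id)]]
    both_genes <- sum(expand[both_ids])
    per_sim[[s]] <- data.frame(sim = s, n_paps = n_genes,
                               n_f1_pass = f1_genes,
                               n_both_pass = both_genes,
                               fraction_f1 = f1_genes / n_genes,
                               fraction_both = both_genes / n_genes)
  }
  per_sim <- do.call(rbind, per_sim)
  list(per_sim = per_sim,
       mean_fraction_both = mean(per_sim$fraction_both),
       range_fraction_both = range(per_sim$fraction_both),
       rates = rates)
}
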