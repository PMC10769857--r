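#' Screening configuration
#'
#' Collects every tunable threshold of the pipeline in one validated list.
#' Defaults are the published operating point of the screen: accessory genes
#' are kept when their prevalence lies in the closed interval
#' \code{[rare_min, common_max]}, each PAP is predicted with a forest of
#' \code{n_trees} depth-\code{max_depth} trees trained on a
#' \code{train_frac} stratified split, a PAP counts as accurately predicted
#' when the F1 score of both the present and the absent class reaches
#' \code{f1_min} on the held-out test set, edges need a normalised Gini
#' importance of at least \code{gini_min}, and predicted (target) PAPs must
#' show a Fritz-Purvis D above \code{d_min} (strict) together with a Fitch
#' parsimony score of at least \code{parsimony_min} state changes.
#'
#' @param rare_min minimum prevalence retained (fraction, default 0.01).
#' @param common_max maximum prevalence retained (fraction, default 0.99).
#' @param train_frac fraction of genomes in the training split (default 0.75).
#' @param n_trees trees per Random Forest (default 1000).
#' @param max_depth maximum tree depth (default 16).
#' @param f1_min dual-class F1 gate (default 0.90).
#' @param gini_min minimum edge importance, inclusive (default 0.01).
#' @param d_min D-statistic gate, exclusive (default 0).
#' @param parsimony_min minimum Fitch parsimony score, inclusive (default 8).
#' @param commensal_host_cover minimum P(host present | commensal present)
#'   for a commensal call (default 0.99).
#' @param commensal_presence_ratio minimum P(host present | commensal absent)
#'   as a multiple of the host's overall prevalence (default 0.20).
#' @param n_null_sims replicates for the null false-discovery calibration
#'   (default 100).
#' @param n_d_permutations permutation/simulation replicates inside the
#'   D statistic (default 1000).
#' @param seed master seed; every stochastic step derives its own stream
#'   from it (default 1).
#' @return an object of class \code{"screen_config"} (a named list).
#' @export
#' @examples
#' cfg <- screen_config(n_trees = 200, seed = 42)
#' cfg$f1_min
screen_config <- function(rare_min = 0.01, common_max = 0.99,
                          train_frac = 0.75, n_trees = 1000, max_depth = 16,
                          f1_min = 0.90, gini_min = 0.01, d_min = 0,
                          parsimony_min = 8,
                          commensal_host_cover = 0.99,
                          commensal_presence_ratio = 0.20,
                          n_null_sims = 100, n_d_permutations = 1000,
                          seed = 1L) {
  cfg <- list(rare_min = rare_min, common_max = common_max,
              train_frac = train_frac, n_trees = as.integer(n_trees),
              max_depth = as.integer(max_depth), f1_min = f1_min,
              gini_min = gini_min, d_min = d_min,
              parsimony_min = as.integer(parsimony_min),
              commensal_host_cover = commensal_host_cover,
              commensal_presence_ratio = commensal_presence_ratio,
              n_null_sims = as.integer(n_null_sims),
              n_d_permutations = as.integer(n_d_permutations),
              seed = as.integer(seed))
  stopifnot(cfg$rare_min > 0, cfg$rare_min < cfg$common_max,
            cfg$common_max < 1,
            cfg$train_frac > 0, cfg$train_frac < 1,
            cfg$n_trees >= 1L, cfg$max_depth >= 1L,
            cfg$f1_min >= 0, cfg$f1_min <= 1,
            cfg$gini_min >= 0,
            cfg$parsimony_min >= 0L,
            cfg$n_null_sims >= 1L, cfg$n_d_permutations >= 1L)
  class(cfg) <- "screen_config"
  cfg
}

#' @export
print.screen_config <- function(x, ...) {
  cat("panforest screen configuration\n")
  cat(sprintf("  prevalence window   : [%.4g, %.4g]\n", x$rare_min, x$common_max))
  cat(sprintf("  forest              : %d trees, depth %d, train frac %.2f\n",
              x$n_trees, x$max_depth, x$train_frac))
  cat(sprintf("  gates               : dual-class F1 >= %.2f, Gini >= %.3g, D > %.3g, parsimony >= %d\n",
              x$f1_min, x$gini_min, x$d_min, x$parsimony_min))
  cat(sprintf("  commensal rule      : host cover >= %.2f, presence ratio >= %.2f\n",
              x$commensal_host_cover, x$commensal_presence_ratio))
  cat(sprintf("  null calibration    : %d simulations, %d D permutations, seed %d\n",
              x$n_null_sims, x$n_d_permutations, x$seed))
  invisible(x)
}

# Deterministic 31-bit seed stream: master seed + stable string hash.
# Polynomial rolling hash mod (2^31 - 1); keeps per-PAP results stable when
# other PAPs are added or removed.
hash_seed <- function(master_seed, key) {
  m <- 2147483647
  h <- as.numeric(master_seed) %% m
  for (code in utf8ToInt(as.character(key))) {
    h <- (h * 31 + code) %% m
  }
  as.integer(h)
}
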