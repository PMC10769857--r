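#' Stratified train/test split
#'
#' Splits genome rows into a training fraction and a held-out test set,
#' stratified by the target pattern so both splits carry the overall
#' present/absent proportions to within one genome. Per-class training
#' counts are assigned by largest remainder under the constraint
#' \code{|train| = round(train_frac * N)} (remainder ties go to the larger
#' class), and the genomes drawn from each class follow one label-independent
#' permutation, so complementing the target swaps the class roles without
#' changing the partition.
#'
#' @param target 0/1 vector over the modelled genome rows.
#' @param train_frac training fraction.
#' @param seed integer seed.
#' @return list with integer index vectors \code{train} and \code{test},
#'   or \code{NULL} if either class has fewer than 2 genomes (the PAP is
#'   skipped).
#' @export
stratified_split <- function(target, train_frac = 0.75, seed = 1L) {
  n <- length(target)
  idx1 <- which(target == 1)
  idx0 <- which(target != 1)
  if (length(idx1) < 2L || length(idx0) < 2L) return(NULL)
  n_train <- round(train_frac * n)
  ideal1 <- train_frac * length(idx1)
  ideal0 <- train_frac * length(idx0)
  n1 <- floor(ideal1); n0 <- floor(ideal0)
  leftover <- n_train - n1 - n0
  if (leftover > 0L) {
    f1 <- ideal1 - n1; f0 <- ideal0 - n0
    pick1 <- if (f1 > f0) TRUE
             else if (f0 > f1) FALSE
             else length(idx1) >= length(idx0)  # tie: larger class first
    if (leftover >= 2L) { n1 <- n1 + 1L; n0 <- n0 + 1L }
    else if (pick1) n1 <- n1 + 1L else n0 <- n0 + 1L
  }
  set.seed(seed)
  perm <- sample.int(n)
  p1 <- perm[perm %in% idx1]
  p0 <- perm[perm %in% idx0]
  train <- sort(c(p1[seq_len(n1)], p0[seq_len(n0)]))
  list(train = train, test = sort(setdiff(seq_len(n), train)))
}

# Confusion counts -> the dual-class metric block. "Present" (1) is the
# positive class; zero-denominator metrics come back NA and fail the gate.
class_metrics <- function(tp, fp, fn, tn) {
  total <- tp + fp + fn + tn
  safe <- function(num, den) if (den > 0) num / den else NA_real_
  f1 <- function(p, r) if (is.na(p) || is.na(r) || (p + r) == 0) NA_real_
                       else 2 * p * r / (p + r)
  pp <- safe(tp, tp + fp); rp <- safe(tp, tp + fn)
  pa <- safe(tn, tn + fn); ra <- safe(tn, tn + fp)
  list(accuracy = safe(tp + tn, total),
       precision_present = pp, recall_present = rp, f1_present = f1(pp, rp),
       precision_absent = pa, recall_absent = ra, f1_absent = f1(pa, ra),
       tp = tp, fp = fp, fn = fn, tn = tn)
}

# Fit one Random Forest for a target vector and score it on the held-out
# test set. X: 0/1 feature matrix (modelled genome rows x predictor PAPs,
# target column excluded). Aggregation averages per-tree class
# probabilities; an exact 0.5 tie predicts "absent".
rf_fit_target <- function(X, y, config, seed) {
  split <- stratified_split(y, config$train_frac, seed)
  if (is.null(split)) {
    return(list(skipped = TRUE, metrics = NULL, importances = NULL,
                predictable = FALSE))
  }
  yf <- factor(y, levels = c(0, 1))
  fit <- ranger::ranger(x = X[split$train, , drop = FALSE],
                        y = yf[split$train],
                        num.trees = config$n_trees,
                        max.depth = config$max_depth,
                        mtry = ceiling(sqrt(ncol(X))),
                        importance = "impurity",
                        probability = TRUE,
                        seed = seed, num.threads = 1L)
  # soft vote: leaf class fractions averaged over trees
  share_present <- predict(fit, data = X[split$test, , drop = FALSE],
                           num.threads = 1L)$predictions[, "1"]
  pred <- as.integer(share_present > 0.5)
  truth <- y[split$test]
  m <- class_metrics(tp = sum(pred == 1 & truth == 1),
                     fp = sum(pred == 1 & truth == 0),
                     fn = sum(pred == 0 & truth == 1),
                     tn = sum(pred == 0 & truth == 0))
  imp <- fit$variable.importance
  imp[imp < 0] <- 0
  s <- sum(imp)
  if (s > 0) imp <- imp / s
  predictable <- !is.na(m$f1_present) && !is.na(m$f1_absent) &&
    m$f1_present >= config$f1_min && m$f1_absent >= config$f1_min
  list(skipped = FALSE, metrics = m, importances = imp,
       predictable = predictable)
}

#' Fit and score the Random Forest for one PAP
#'
#' Trains a forest predicting the target PAP from all other PAPs (over the
#' deduplicated genome rows), evaluates accuracy, per-class precision,
#' recall and F1 on the held-out test set, and returns the normalised Gini
#' (mean decrease in impurity) importance of every predictor. The per-PAP
#' seed is derived from the master seed by a stable hash of the pattern id,
#' so results for one PAP do not change when others are added.
#'
#' @param paps a \code{pap_set}.
#' @param target a pattern id in \code{paps}.
#' @param config a \code{\link{screen_config}}.
#' @return list with \code{pattern_id}, \code{skipped}, \code{predictable},
#'   \code{metrics} (see \code{class_metrics} fields) and \code{importances}
#'   (named vector over predictor pattern ids, summing to 1).
#' @export
fit_and_score_pap <- function(paps, target, config = screen_config()) {
  stopifnot(target %in% paps$pattern_ids)
  Xall <- paps$patterns[paps$model_rows, , drop = FALSE]
  y <- Xall[, target]
  X <- Xall[, colnames(Xall) != target, drop = FALSE]
  res <- rf_fit_target(X, y, config, hash_seed(config$seed, target))
  res$pattern_id <- target
  res
}

#' Predictability screen over all PAPs
#'
#' One Random Forest per PAP, each with an independent stratified split.
#' PAPs whose minority class has fewer than 2 modelled genomes are reported
#' as analysed-but-unpredictable with \code{skipped = TRUE}, so denominators
#' stay explicit.
#'
#' @param paps a \code{pap_set}.
#' @param config a \code{\link{screen_config}}.
#' @param importance_floor store only importances at or above this value in
#'   the sparse table (default \code{config$gini_min / 10}; the edge builder
#'   only consumes importances at \code{gini_min} and above).
#' @return list with \code{metrics} (data.frame, one row per PAP) and
#'   \code{importances} (data.frame: target, source, gini).
#' @export
run_predictability_screen <- function(paps, config = screen_config(),
                                      importance_floor = NULL) {
  if (is.null(importance_floor)) importance_floor <- config$gini_min / 10
  ids <- paps$pattern_ids
  rows <- vector("list", length(ids))
  imps <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    r <- fit_and_score_pap(paps, ids[i], config)
    m <- r$metrics
    if (is.null(m)) {
      m <- class_metrics(0L, 0L, 0L, 0L)
    }
    rows[[i]] <- as.data.frame(c(list(pattern_id = ids[i],
                                      skipped = r$skipped,
                                      predictable = r$predictable),
                                 lapply(m, unname)),
                               stringsAsFactors = FALSE)
    if (!is.null(r$importances)) {
      keep <- r$importances >= importance_floor
      if (any(keep)) {
        imps[[i]] <- data.frame(target = ids[i],
                                source = names(r$importances)[keep],
                                gini = unname(r$importances[keep]),
                                stringsAsFactors = FALSE)
      }
    }
  }
  metrics <- do.call(rbind, rows)
  importances <- if (any(!vapply(imps, is.null, logical(1)))) {
    do.call(rbind, imps[!vapply(imps, is.null, logical(1))])
  } else {
    data.frame(target = character(), source = character(), gini = numeric())
  }
  rownames(metrics) <- NULL
  list(metrics = metrics, importances = importances)
}

#' Stability of the predictable set under re-splitting
#'
#' Repeats the whole predictability screen with fresh train/test splits and
#' tallies, per PAP, how often it passes the dual-class F1 gate.
#'
#' @param paps a \code{pap_set}.
#' @param config a \code{\link{screen_config}}.
#' @param n_repeats number of repeated screens (default 100).
#' @return data.frame: pattern_id, n_predictable, n_repeats, status
#'   (\code{"always"}, \code{"never"}, or \code{"sometimes"}).
#' @export
repeat_stability <- function(paps, config = screen_config(),
                             n_repeats = 100L) {
  n_repeats <- as.integer(n_repeats)
  counts <- stats::setNames(integer(length(paps$pattern_ids)),
                            paps$pattern_ids)
  for (r in seq_len(n_repeats)) {
    cfg <- config
    cfg$seed <- hash_seed(config$seed, paste0("repeat:", r))
    scr <- run_predictability_screen(paps, cfg, importance_floor = Inf)
    counts <- counts + as.integer(scr$metrics$predictable)
  }
  data.frame(pattern_id = names(counts),
             n_predictable = unname(counts),
             n_repeats = n_repeats,
             status = ifelse(counts == n_repeats, "always",
                             ifelse(counts == 0L, "never", "sometimes")),
             stringsAsFactors = FALSE)
}

#' Sensitivity of the screen to genome downsampling
#'
#' Subsamples genomes without replacement, re-filters, re-collapses, and
#' re-runs the Random-Forest screen and the phylogenetic-signal filter on
#' each subsample.
#'
#' @param paps a \code{pap_set} built from the full matrix.
#' @param tree the prepared phylogeny for the full genome set.
#' @param config a \code{\link{screen_config}}.
#' @param fractions genome fractions retained (default
#'   \code{c(0.5, 0.25, 0.1, 0.05)}).
#' @param repeats subsamples per fraction (default 10).
#' @return data.frame: fraction, repeat, n_genomes, n_paps_analysed,
#'   n_predictable, n_predictable_with_D_pass.
#' @export
downsample_screen <- function(paps, tree, config = screen_config(),
                              fractions = c(0.5, 0.25, 0.1, 0.05),
                              repeats = 10L) {
  stopifnot(all(fractions > 0), all(fractions <= 1))
  m_full <- expand_patterns(paps)
  genomes <- rownames(m_full)
  out <- list()
  for (f in fractions) {
    for (r in seq_len(repeats)) {
      seed <- hash_seed(config$seed, sprintf("downsample:%g:%d", f, r))
      set.seed(seed)
      keep_n <- max(2L, round(f * length(genomes)))
      keep <- if (f >= 1) genomes else sort(sample(genomes, keep_n))
      sub <- unclass(m_full)[keep, , drop = FALSE]
      class(sub) <- c("pa_matrix", class(sub))
      sub <- suppressWarnings(
        filter_by_frequency(sub, config$rare_min, config$common_max))
      if (ncol(sub) == 0L) {
        out[[length(out) + 1L]] <- data.frame(
          fraction = f, rep = r, n_genomes = length(keep),
          n_paps_analysed = 0L, n_predictable = 0L,
          n_predictable_with_D_pass = 0L)
        next
      }
      sub_paps <- collapse_patterns(sub)
      sub_tree <- if (f >= 1) tree else ape::keep.tip(tree, keep)
      cfg <- config
      if (f < 1) cfg$seed <- seed  # fraction 1 reproduces the full screen
      scr <- run_predictability_screen(sub_paps, cfg, importance_floor = Inf)
      passed <- scr$metrics$pattern_id[scr$metrics$predictable]
      sig <- signal_screen(sub_tree, sub_paps, cfg, d_for = passed)
      n_both <- sum(scr$metrics$predictable &
                      sig$pass[match(scr$metrics$pattern_id, sig$pattern_id)])
      out[[length(out) + 1L]] <- data.frame(
        fraction = f, rep = r, n_genomes = length(keep),
        n_paps_analysed = nrow(scr$metrics),
        n_predictable = sum(scr$metrics$predictable),
        n_predictable_with_D_pass = n_both)
    }
  }
  do.call(rbind, out)
}
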