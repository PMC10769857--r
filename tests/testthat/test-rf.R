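test_that("stratified splits carry class proportions and are deterministic", {
  y <- c(rep(1, 20), rep(0, 80))
  sp <- stratified_split(y, 0.75, seed = 3)
  expect_length(sp$train, 75)
  expect_length(sp$test, 25)
  expect_identical(sum(y[sp$train]), 15)
  expect_identical(sum(y[sp$test]), 5)
  expect_identical(sort(c(sp$train, sp$test)), seq_along(y))
  expect_identical(stratified_split(y, 0.75, seed = 3), sp)
  expect_false(identical(stratified_split(y, 0.75, seed = 4), sp))
  # degenerate: a single positive genome cannot be stratified
  expect_null(stratified_split(c(1, rep(0, 7)), 0.75, seed = 1))
})

test_that("a perfect predictor yields dual F1 of 1 and dominant importance", {
  set.seed(10)
  n <- 200
  y <- rbinom(n, 1, 0.5)
  X <- cbind(copy = y,
             matrix(rbinom(n * 8, 1, 0.5), n, 8,
                    dimnames = list(NULL, paste0("noise", 1:8))))
  rownames(X) <- paste0("G", seq_len(n))
  cfg <- screen_config(n_trees = 100, seed = 2)
  for (seed in c(1, 7, 23)) {  # predictable for every seed
    r <- panforest:::rf_fit_target(X, y, cfg, seed)
    expect_true(r$predictable)
    expect_equal(r$metrics$f1_present, 1)
    expect_equal(r$metrics$f1_absent, 1)
    expect_identical(names(which.max(r$importances)), "copy")
    expect_gt(max(r$importances), 0.5)
  }
  # a pattern's complement is an equally perfect predictor through the
  # PAP-level interface (identical columns would collapse into one PAP)
  m <- cbind(tgt = y, comp = 1L - y,
             matrix(rbinom(n * 8, 1, 0.5), n, 8,
                    dimnames = list(NULL, paste0("noise", 1:8))))
  rownames(m) <- paste0("G", seq_len(n))
  paps <- collapse_patterns(make_pa(m))
  r <- fit_and_score_pap(paps, "PAP:tgt", cfg)
  expect_true(r$predictable)
  expect_equal(r$metrics$f1_present, 1)
  expect_identical(names(which.max(r$importances)), "PAP:comp")
})

test_that("importances are non-negative and sum to one", {
  bench <- tiny_benchmark()
  paps <- collapse_patterns(
    suppressWarnings(filter_by_frequency(bench$matrix, 0.02, 0.98)))
  cfg <- tiny_config()
  r <- fit_and_score_pap(paps, paps$pattern_ids[1], cfg)
  expect_true(all(r$importances >= 0))
  expect_equal(sum(r$importances), 1, tolerance = 1e-9)
})

test_that("metrics recomputed from confusion counts match stored fields", {
  bench <- tiny_benchmark()
  paps <- collapse_patterns(
    suppressWarnings(filter_by_frequency(bench$matrix, 0.02, 0.98)))
  cfg <- tiny_config()
  scr <- run_predictability_screen(paps, cfg, importance_floor = Inf)
  m <- scr$metrics
  with_counts <- m[!m$skipped, ]
  expect_gt(nrow(with_counts), 0)
  prec <- with_counts$tp / (with_counts$tp + with_counts$fp)
  rec <- with_counts$tp / (with_counts$tp + with_counts$fn)
  f1 <- 2 * prec * rec / (prec + rec)
  comparable <- is.finite(f1) & !is.na(with_counts$f1_present)
  expect_equal(with_counts$f1_present[comparable], f1[comparable])
  acc <- (with_counts$tp + with_counts$tn) /
    (with_counts$tp + with_counts$fp + with_counts$fn + with_counts$tn)
  expect_equal(with_counts$accuracy, acc)
  # the predictable flag is exactly the dual-class F1 gate
  gate <- !is.na(with_counts$f1_present) & !is.na(with_counts$f1_absent) &
    with_counts$f1_present >= cfg$f1_min & with_counts$f1_absent >= cfg$f1_min
  expect_identical(with_counts$predictable, gate)
})

test_that("complementing the target swaps the present/absent metric blocks", {
  set.seed(31)
  n <- 200
  X <- matrix(rbinom(n * 12, 1, 0.4), n, 12,
              dimnames = list(paste0("G", 1:n), paste0("f", 1:12)))
  y <- rbinom(n, 1, 0.3)
  cfg <- screen_config(n_trees = 80, seed = 6)
  for (seed in c(101, 202)) {
    a <- panforest:::rf_fit_target(X, y, cfg, seed)
    b <- panforest:::rf_fit_target(X, 1 - y, cfg, seed)
    expect_equal(a$metrics$f1_present, b$metrics$f1_absent)
    expect_equal(a$metrics$f1_absent, b$metrics$f1_present)
    expect_equal(a$metrics$precision_present, b$metrics$precision_absent)
    expect_equal(a$metrics$recall_present, b$metrics$recall_absent)
    expect_equal(a$metrics$accuracy, b$metrics$accuracy)
    expect_identical(a$metrics$tp, b$metrics$tn)
    expect_identical(a$metrics$fp, b$metrics$fn)
  }
})

test_that("the screen is deterministic under a fixed master seed", {
  bench <- tiny_benchmark()
  paps <- collapse_patterns(
    suppressWarnings(filter_by_frequency(bench$matrix, 0.02, 0.98)))
  cfg <- tiny_config()
  a <- run_predictability_screen(paps, cfg)
  b <- run_predictability_screen(paps, cfg)
  expect_identical(a, b)
})

test_that("repeat stability tallies always/never/sometimes", {
  set.seed(9)
  n <- 120
  target <- rbinom(n, 1, 0.5)
  m <- cbind(tgt = target, comp = 1L - target,
             matrix(rbinom(n * 6, 1, 0.5), n, 6,
                    dimnames = list(NULL, paste0("ns", 1:6))))
  rownames(m) <- paste0("G", seq_len(n))
  paps <- collapse_patterns(make_pa(m))
  cfg <- screen_config(n_trees = 60, seed = 5,
                       rare_min = 0.02, common_max = 0.98)
  tab <- repeat_stability(paps, cfg, n_repeats = 5)
  expect_identical(tab$status[tab$pattern_id == "PAP:comp"], "always")
  expect_identical(tab$status[tab$pattern_id == "PAP:tgt"], "always")
  expect_identical(tab$n_repeats, rep(5L, nrow(tab)))
  noise_status <- tab$status[grepl("PAP:ns", tab$pattern_id)]
  expect_true(all(noise_status == "never"))
})

test_that("downsampling at fraction 1 reproduces the full screen", {
  bench <- generate_benchmark(n_tips = 64, n_null_genes = 20,
                              n_mutualistic = 2, n_commensal = 0,
                              n_competitive = 1, seed = 8)
  paps <- collapse_patterns(
    suppressWarnings(filter_by_frequency(bench$matrix, 0.02, 0.98)))
  tree <- prepare_tree(bench$tree, rownames(bench$matrix))
  cfg <- tiny_config(seed = 8)
  full <- run_predictability_screen(paps, cfg, importance_floor = Inf)
  down <- downsample_screen(paps, tree, cfg, fractions = 1, repeats = 1)
  expect_identical(down$n_paps_analysed, nrow(full$metrics))
  expect_identical(down$n_predictable, sum(full$metrics$predictable))
  # smaller fractions keep running on few genomes without error
  tiny <- downsample_screen(paps, tree, cfg, fractions = 0.2, repeats = 2)
  expect_identical(nrow(tiny), 2L)
  expect_true(all(tiny$n_genomes == round(0.2 * 64)))
})
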