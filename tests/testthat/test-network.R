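# Helper: hand-built inputs for the edge builder. Patterns are chosen so
# conditional frequencies are unambiguous.
edge_fixture <- function() {
  n <- 100
  A <- c(rep(1, 50), rep(0, 50))
  B <- c(rep(1, 45), rep(0, 5), rep(1, 5), rep(0, 45))  # tracks A
  C <- 1 - A                                            # avoids A
  D <- c(rep(1, 25), rep(0, 75))                        # subset of A
  m <- cbind(A = A, B = B, C = C, D = D)
  rownames(m) <- paste0("G", seq_len(n))
  paps <- collapse_patterns(make_pa(m))
  ids <- c("PAP:A", "PAP:B", "PAP:C", "PAP:D")
  predictions <- data.frame(pattern_id = ids, predictable = TRUE,
                            stringsAsFactors = FALSE)
  signals <- data.frame(pattern_id = ids, D = 0.5, parsimony = 12L,
                        pass = TRUE, stringsAsFactors = FALSE)
  list(paps = paps, predictions = predictions, signals = signals)
}

test_that("edges respect the inclusive Gini boundary and target gates", {
  fx <- edge_fixture()
  imp <- data.frame(target = c("PAP:A", "PAP:A"),
                    source = c("PAP:B", "PAP:C"),
                    gini = c(0.0099, 0.0100))
  e <- build_edges(imp, fx$predictions, fx$signals, fx$paps, screen_config())
  expect_identical(nrow(e), 1L)
  expect_identical(e$source, "PAP:C")   # 0.0100 kept, 0.0099 dropped

  # target failing the dual-class F1 gate loses all incoming edges
  pred2 <- fx$predictions
  pred2$predictable[pred2$pattern_id == "PAP:A"] <- FALSE
  e2 <- build_edges(imp, pred2, fx$signals, fx$paps, screen_config())
  expect_identical(nrow(e2), 0L)

  # target failing the D gate loses all incoming edges; sources are exempt
  sig2 <- fx$signals
  sig2$pass[sig2$pattern_id == "PAP:A"] <- FALSE
  e3 <- build_edges(imp, fx$predictions, sig2, fx$paps, screen_config())
  expect_identical(nrow(e3), 0L)
  imp_rev <- data.frame(target = "PAP:B", source = "PAP:A", gini = 0.5)
  e4 <- build_edges(imp_rev, fx$predictions, sig2, fx$paps, screen_config())
  expect_identical(nrow(e4), 1L)  # A only a source: its D does not matter
})

test_that("polarity follows the conditional-frequency comparison", {
  fx <- edge_fixture()
  imp <- data.frame(target = c("PAP:A", "PAP:A"),
                    source = c("PAP:B", "PAP:C"),
                    gini = c(0.3, 0.3))
  e <- build_edges(imp, fx$predictions, fx$signals, fx$paps, screen_config())
  expect_identical(e$polarity[e$source == "PAP:B"], "co-occurrence")
  expect_identical(e$polarity[e$source == "PAP:C"], "avoidance")
  expect_error(
    build_edges(data.frame(target = "PAP:Z", source = "PAP:A", gini = 0.2),
                fx$predictions, fx$signals, fx$paps, screen_config()),
    "PAP:Z")
})

test_that("the commensalism rule reproduces the worked 50%/10% threshold", {
  # host prevalence 50% (45/90); commensal = 40 genomes, all with the host;
  # P(host | commensal) = 1.0 >= 0.99 and
  # P(host | commensal absent) = (45-40)/(90-40) = 0.10 = 0.20 * 0.50,
  # i.e. exactly the worked boundary, which is inclusive
  n <- 90
  host <- c(rep(1, 45), rep(0, 45))
  comm <- c(rep(1, 40), rep(0, 50))
  m <- cbind(H = host, C = comm)
  rownames(m) <- paste0("G", seq_len(n))
  paps <- collapse_patterns(make_pa(m))
  edges <- data.frame(source = "PAP:H", target = "PAP:C", gini = 0.4,
                      polarity = "co-occurrence", category = "uncategorized",
                      host = NA_character_, commensal = NA_character_,
                      stringsAsFactors = FALSE)
  out <- categorize_relationships(edges, paps, screen_config())
  expect_identical(out$category, "commensalism")
  expect_identical(out$host, "PAP:H")
  expect_identical(out$commensal, "PAP:C")

  # just below the boundary: commensal in 41 genomes ->
  # P(host | commensal absent) = 4/49 = 0.082 < 0.10 -> NOT commensal
  comm2 <- c(rep(1, 41), rep(0, 49))
  m2 <- cbind(H = host, C = comm2)
  rownames(m2) <- paste0("G", seq_len(n))
  paps2 <- collapse_patterns(make_pa(m2))
  out2 <- categorize_relationships(edges, paps2, screen_config())
  expect_false(out2$category == "commensalism")
})

test_that("category precedence and polarity consistency hold", {
  # two 30%-prevalence patterns co-occurring in exactly the same genomes
  # except 4, with reciprocal edges -> mutualism
  n <- 100
  A <- c(rep(1, 30), rep(0, 70))
  B <- c(rep(1, 28), 0, 0, 1, 1, rep(0, 68))
  X <- 1 - A  # avoidance partner
  m <- cbind(A = A, B = B, X = X)
  rownames(m) <- paste0("G", seq_len(n))
  paps <- collapse_patterns(make_pa(m))
  edges <- data.frame(
    source = c("PAP:A", "PAP:B", "PAP:X"),
    target = c("PAP:B", "PAP:A", "PAP:A"),
    gini = c(0.2, 0.2, 0.15),
    polarity = c("co-occurrence", "co-occurrence", "avoidance"),
    category = "uncategorized",
    host = NA_character_, commensal = NA_character_,
    stringsAsFactors = FALSE)
  out <- categorize_relationships(edges, paps, screen_config())
  expect_identical(out$category[1:2], c("mutualism", "mutualism"))
  expect_identical(out$category[3], "competition")
  # invariants: categories align with polarity; mutualism is symmetric
  expect_true(all(out$polarity[out$category == "competition"] == "avoidance"))
  expect_true(all(out$polarity[out$category %in%
    c("mutualism", "commensalism")] == "co-occurrence"))

  # a mutually exclusive avoidance pair is competition
  expect_identical(out$category[out$source == "PAP:X"], "competition")
})

test_that("network summaries count components and rank nodes like power iteration", {
  e <- data.frame(source = c("A", "C"), target = c("B", "D"),
                  gini = c(0.5, 0.5),
                  polarity = "co-occurrence", category = "mutualism",
                  host = NA_character_, commensal = NA_character_,
                  stringsAsFactors = FALSE)
  s <- network_summary(e)
  expect_identical(s$components$all$n, 2L)
  expect_identical(s$components$all$sizes, c(2L, 2L))
  expect_identical(s$components$avoidance$n, 0L)
  expect_equal(sum(s$pagerank), 1, tolerance = 1e-9)

  # symmetric two-node graph: equal PageRank
  e2 <- data.frame(source = c("A", "B"), target = c("B", "A"),
                   gini = c(0.3, 0.3), polarity = "co-occurrence",
                   category = "mutualism", host = NA, commensal = NA,
                   stringsAsFactors = FALSE)
  s2 <- network_summary(e2)
  expect_equal(unname(s2$pagerank["A"]), unname(s2$pagerank["B"]))

  # chain A -> B -> C: downstream accumulates rank; matches brute force
  e3 <- data.frame(source = c("A", "B"), target = c("B", "C"),
                   gini = c(0.2, 0.2), polarity = "co-occurrence",
                   category = "uncategorized", host = NA, commensal = NA,
                   stringsAsFactors = FALSE)
  s3 <- network_summary(e3)
  pr <- s3$pagerank
  expect_true(pr[["C"]] > pr[["B"]] && pr[["B"]] > pr[["A"]])
  oracle <- brute_pagerank(names(pr), e3$source, e3$target, e3$gini)
  expect_equal(unname(pr[names(oracle)]), unname(oracle), tolerance = 1e-6)
})

test_that("exclusion lists remove incident edges and commute with summaries", {
  e <- data.frame(source = c("H", "H", "A"), target = c("B", "C", "B"),
                  gini = c(0.2, 0.2, 0.2), polarity = "co-occurrence",
                  category = "uncategorized", host = NA, commensal = NA,
                  stringsAsFactors = FALSE)
  expect_identical(suppressMessages(apply_exclusion_list(e, character(0))), e)
  out <- suppressMessages(apply_exclusion_list(e, "H"))
  expect_identical(nrow(out), 1L)
  expect_identical(out$source, "A")
  expect_warning(suppressMessages(apply_exclusion_list(e, "nope")), "nope")
  s_direct <- network_summary(out)
  s_after <- network_summary(suppressMessages(apply_exclusion_list(e, "H")))
  expect_equal(s_direct, s_after)
})

test_that("GraphML export carries node attributes", {
  fx <- edge_fixture()
  e <- data.frame(source = "PAP:B", target = "PAP:A", gini = 0.3,
                  polarity = "co-occurrence", category = "mutualism",
                  host = NA_character_, commensal = NA_character_,
                  stringsAsFactors = FALSE)
  f <- tempfile(fileext = ".graphml")
  write_network_graphml(e, fx$paps, fx$predictions, fx$signals, f)
  g <- igraph::read_graph(f, format = "graphml")
  expect_setequal(igraph::V(g)$name, c("PAP:B", "PAP:A"))
  expect_true("prevalence" %in% igraph::vertex_attr_names(g))
  expect_true("pagerank" %in% igraph::vertex_attr_names(g))
})
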