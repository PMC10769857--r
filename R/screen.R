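#' Screen a pangenome for predictable genes and their relationships
#'
#' The full pipeline in one call: frequency-filter the presence-absence
#' matrix, collapse identical patterns into PAPs, prepare the phylogeny,
#' predict every PAP from all others with a Random Forest, filter predicted
#' PAPs by the Fritz-Purvis D statistic and Fitch parsimony, build the
#' directed predictor-target network, classify edges into putative
#' mutualism / commensalism / competition, and summarise the graph.
#'
#' @param pa a \code{pa_matrix} (see \code{\link{read_presence_absence}}).
#' @param tree a phylogeny accepted by \code{\link{prepare_tree}}; tips must
#'   cover the genomes of \code{pa}.
#' @param config a \code{\link{screen_config}}.
#' @param exclude pattern ids to drop from the network (externally produced
#'   exclusion list; default none).
#' @return an object of class \code{"pangenome_screen"}: list with
#'   \code{paps}, \code{tree}, \code{metrics}, \code{importances},
#'   \code{signals}, \code{edges}, \code{summary}, \code{config}, and
#'   bookkeeping counts in \code{counts}.
#' @export
#' @examples
#' bench <- generate_benchmark(n_tips = 64, n_null_genes = 20,
#'                             n_mutualistic = 2, n_commensal = 0,
#'                             n_competitive = 1, seed = 7)
#' cfg <- screen_config(n_trees = 50, n_d_permutations = 100, seed = 7,
#'                      rare_min = 0.02, common_max = 0.98)
#' scr <- pangenome_screen(bench$matrix, bench$tree, cfg)
#' print(scr)
pangenome_screen <- function(pa, tree, config = screen_config(),
                             exclude = character(0)) {
  filtered <- suppressWarnings(
    filter_by_frequency(pa, config$rare_min, config$common_max))
  paps <- collapse_patterns(filtered)
  tree <- prepare_tree(tree, rownames(pa))
  scr <- run_predictability_screen(paps, config)
  f1_pass <- scr$metrics$pattern_id[scr$metrics$predictable]
  signals <- signal_screen(tree, paps, config, d_for = f1_pass)
  edges <- build_edges(scr$importances, scr$metrics, signals, paps, config)
  if (length(exclude)) edges <- apply_exclusion_list(edges, exclude)
  edges <- categorize_relationships(edges, paps, config)
  summ <- network_summary(edges)
  sig_pass <- signals$pattern_id[signals$pass]
  counts <- list(
    n_genomes = nrow(pa),
    n_genes_input = ncol(pa),
    n_genes_filtered = ncol(filtered),
    n_paps = length(paps$pattern_ids),
    n_model_rows = length(paps$model_rows),
    n_predictable = length(f1_pass),
    n_predictable_d_pass = sum(f1_pass %in% sig_pass),
    fraction_predictable_d_pass =
      sum(f1_pass %in% sig_pass) / max(1L, length(paps$pattern_ids)))
  out <- list(paps = paps, tree = tree,
              metrics = scr$metrics, importances = scr$importances,
              signals = signals, edges = edges, summary = summ,
              counts = counts, config = config)
  class(out) <- "pangenome_screen"
  out
}

#' @export
print.pangenome_screen <- function(x, ...) {
  cn <- x$counts
  cat("pangenome_screen\n")
  cat(sprintf("  genomes: %d | genes: %d in, %d after frequency filter\n",
              cn$n_genomes, cn$n_genes_input, cn$n_genes_filtered))
  cat(sprintf("  PAPs: %d (over %d distinct genome rows)\n",
              cn$n_paps, cn$n_model_rows))
  cat(sprintf("  predictable (dual-class F1 >= %.2f): %d\n",
              x$config$f1_min, cn$n_predictable))
  cat(sprintf("  ... with D > %g and parsimony >= %d: %d (%.1f%%)\n",
              x$config$d_min, x$config$parsimony_min,
              cn$n_predictable_d_pass,
              100 * cn$fraction_predictable_d_pass))
  cat(sprintf("  network: %d nodes, %d edges\n",
              x$summary$n_nodes, x$summary$n_edges))
  if (length(x$summary$category_counts)) {
    cc <- x$summary$category_counts
    cat("  categories:",
        paste(sprintf("%s %d", names(cc), as.integer(cc)), collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' @export
summary.pangenome_screen <- function(object, ...) {
  out <- list(counts = object$counts,
              network = object$summary,
              metrics = object$metrics,
              config = object$config)
  class(out) <- "summary.pangenome_screen"
  out
}

#' @export
print.summary.pangenome_screen <- function(x, ...) {
  cn <- x$counts
  cat("Pangenome predictability screen\n")
  cat(sprintf("  %d genomes, %d/%d genes retained, %d PAPs\n",
              cn$n_genomes, cn$n_genes_filtered, cn$n_genes_input,
              cn$n_paps))
  cat(sprintf("  predictable PAPs: %d; with phylogenetic-signal pass: %d (%.1f%%)\n",
              cn$n_predictable, cn$n_predictable_d_pass,
              100 * cn$fraction_predictable_d_pass))
  comp <- x$network$components
  if (length(comp)) {
    for (nm in names(comp)) {
      cc <- comp[[nm]]
      if (cc$n > 0L) {
        cat(sprintf("  components (%s): %d, sizes %d..%d\n", nm, cc$n,
                    min(cc$sizes), max(cc$sizes)))
      }
    }
  }
  if (length(x$network$pagerank)) {
    top <- sort(x$network$pagerank, decreasing = TRUE)
    top <- top[seq_len(min(5L, length(top)))]
    cat("  top PageRank nodes:\n")
    for (i in seq_along(top)) {
      cat(sprintf("    %s  %.4g\n", names(top)[i], top[i]))
    }
  }
  invisible(x)
}

#' Plot the relationship network
#'
#' Draws the directed predictor-target graph with node size proportional to
#' PageRank and edge colour by polarity.
#'
#' @param x a \code{"pangenome_screen"}.
#' @param ... passed to \code{\link[igraph]{plot.igraph}}.
#' @export
plot.pangenome_screen <- function(x, ...) {
  if (nrow(x$edges) == 0L) {
    graphics::plot.new()
    graphics::title("empty relationship network")
    return(invisible(x))
  }
  g <- igraph::graph_from_data_frame(
    x$edges[, c("source", "target", "gini", "polarity")], directed = TRUE)
  pr <- x$summary$pagerank[igraph::V(g)$name]
  igraph::plot.igraph(
    g,
    vertex.size = 3 + 40 * pr / max(pr),
    vertex.label.cex = 0.6,
    edge.arrow.size = 0.3,
    edge.color = ifelse(igraph::E(g)$polarity == "avoidance",
                        "firebrick", "grey40"),
    ...)
  invisible(x)
}
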