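#' Build the directed predictor-target edge set
#'
#' Keeps an edge source -> target when the normalised Gini importance of the
#' source in the target's forest is at least \code{gini_min} (inclusive),
#' the target passed the dual-class F1 gate, and the target passed the
#' D/parsimony gate. Sources are exempt from the signal gates (a predictor
#' may itself be phylogenetically clumped). Polarity compares the target's
#' frequency among genomes with and without the source over the full genome
#' list: higher when present is co-occurrence, lower is avoidance, and an
#' exact tie (or an undefined frequency) drops the edge with a message.
#'
#' @param importances data.frame (target, source, gini) from
#'   \code{\link{run_predictability_screen}}.
#' @param predictions the screen's metrics data.frame.
#' @param signals a \code{\link{signal_screen}} table.
#' @param paps the \code{pap_set}.
#' @param config a \code{\link{screen_config}}.
#' @return data.frame of class \code{"relationship_edges"}: source, target,
#'   gini, polarity, category (initialised \code{"uncategorized"}), host,
#'   commensal.
#' @export
build_edges <- function(importances, predictions, signals, paps,
                        config = screen_config()) {
  need <- unique(c(importances$target, importances$source))
  miss <- setdiff(need, predictions$pattern_id)
  if (length(miss)) stop("pattern(s) missing from predictions: ",
                         paste(miss, collapse = ", "))
  miss <- setdiff(importances$target, signals$pattern_id)
  if (length(miss)) stop("pattern(s) missing from signals: ",
                         paste(miss, collapse = ", "))
  cand <- importances[importances$gini >= config$gini_min, , drop = FALSE]
  ok_target <- predictions$pattern_id[predictions$predictable]
  sig_pass <- signals$pattern_id[signals$pass]
  cand <- cand[cand$target %in% ok_target & cand$target %in% sig_pass, ,
               drop = FALSE]
  if (nrow(cand) == 0L) return(empty_edges())
  pol <- character(nrow(cand))
  dropped <- 0L
  for (i in seq_len(nrow(cand))) {
    fq <- pap_conditional_frequencies(paps$patterns[, cand$target[i]],
                                      paps$patterns[, cand$source[i]])
    if (fq$undefined ||
        fq$p_target_given_source_present == fq$p_target_given_source_absent) {
      pol[i] <- NA_character_
      dropped <- dropped + 1L
    } else if (fq$p_target_given_source_present >
               fq$p_target_given_source_absent) {
      pol[i] <- "co-occurrence"
    } else {
      pol[i] <- "avoidance"
    }
  }
  if (dropped) message(dropped, " edge(s) dropped: tied or undefined polarity")
  out <- data.frame(source = cand$source, target = cand$target,
                    gini = cand$gini, polarity = pol,
                    category = "uncategorized",
                    host = NA_character_, commensal = NA_character_,
                    stringsAsFactors = FALSE)
  out <- out[!is.na(out$polarity), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("relationship_edges", class(out))
  out
}

empty_edges <- function() {
  out <- data.frame(source = character(), target = character(),
                    gini = numeric(), polarity = character(),
                    category = character(), host = character(),
                    commensal = character(), stringsAsFactors = FALSE)
  class(out) <- c("relationship_edges", class(out))
  out
}

#' Classify edges as mutualism, commensalism, or competition
#'
#' Mutually exclusive categories with precedence commensalism > mutualism >
#' competition, applied per unordered gene pair:
#' \itemize{
#' \item commensalism: a co-occurrence pair where a host H and commensal C
#'   can be oriented (the more prevalent gene is tried as host first) such
#'   that P(H present | C present) >= \code{commensal_host_cover} and
#'   P(H present | C absent) >= \code{commensal_presence_ratio} * P(H),
#'   both boundaries inclusive, over the full genome list;
#' \item mutualism: both directions exist as qualifying co-occurrence
#'   edges (each endpoint therefore passed the F1 and D gates as a target)
#'   and the pair is not commensal;
#' \item competition: any qualifying avoidance edge.
#' }
#'
#' @param edges a \code{"relationship_edges"} data.frame from
#'   \code{\link{build_edges}}.
#' @param paps the \code{pap_set} (full genome list).
#' @param config a \code{\link{screen_config}}.
#' @return the edge set with \code{category} (and, for commensal edges,
#'   \code{host}/\code{commensal} roles) filled in.
#' @export
categorize_relationships <- function(edges, paps, config = screen_config()) {
  if (nrow(edges) == 0L) return(edges)
  pair_key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")
  keys <- pair_key(edges$source, edges$target)
  co <- edges$polarity == "co-occurrence"
  co_keys <- unique(keys[co])
  directed <- paste(edges$source, edges$target, sep = "\r")
  reciprocal <- co & (paste(edges$target, edges$source, sep = "\r") %in%
                        directed[co])
  commensal_of <- list()
  for (k in co_keys) {
    ab <- strsplit(k, "\r", fixed = TRUE)[[1L]]
    ord <- order(-paps$prevalence[ab])  # try the more prevalent as host
    for (h in ab[ord]) {
      cme <- setdiff(ab, h)
      fq <- pap_conditional_frequencies(paps$patterns[, h],
                                        paps$patterns[, cme])
      if (fq$undefined) next
      if (fq$p_target_given_source_present >= config$commensal_host_cover &&
          fq$p_target_given_source_absent >=
            config$commensal_presence_ratio * fq$p_target) {
        commensal_of[[k]] <- c(host = h, commensal = cme)
        break
      }
    }
  }
  for (i in seq_len(nrow(edges))) {
    k <- keys[i]
    if (co[i] && !is.null(commensal_of[[k]])) {
      edges$category[i] <- "commensalism"
      edges$host[i] <- commensal_of[[k]][["host"]]
      edges$commensal[i] <- commensal_of[[k]][["commensal"]]
    } else if (co[i] && reciprocal[i]) {
      edges$category[i] <- "mutualism"
    } else if (edges$polarity[i] == "avoidance") {
      edges$category[i] <- "competition"
    }
  }
  edges
}

#' Remove edges touching excluded patterns
#'
#' Consumes an externally produced exclusion list (e.g. gene families whose
#' sequences were found to be artefactually split between families) and
#' drops every incident edge.
#'
#' @param edges a \code{"relationship_edges"} data.frame.
#' @param excluded_pattern_ids character vector (may be empty); unknown ids
#'   draw a warning and are ignored.
#' @return the filtered edge set.
#' @export
apply_exclusion_list <- function(edges, excluded_pattern_ids) {
  if (length(excluded_pattern_ids) == 0L) return(edges)
  known <- unique(c(edges$source, edges$target))
  unknown <- setdiff(excluded_pattern_ids, known)
  if (length(unknown)) {
    warning("exclusion list id(s) not in the network: ",
            paste(unknown, collapse = ", "))
  }
  keep <- !(edges$source %in% excluded_pattern_ids |
              edges$target %in% excluded_pattern_ids)
  message(sum(!keep), " edge(s) removed by the exclusion list")
  out <- edges[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Summarise the relationship network
#'
#' Connected components (on all edges, co-occurrence-only, and
#' avoidance-only undirected projections), PageRank on the directed graph
#' with arc weights equal to the Gini importance (damping 0.85), and counts
#' per category.
#'
#' @param edges a \code{"relationship_edges"} data.frame.
#' @param damping PageRank damping factor (default 0.85).
#' @return list with \code{n_nodes}, \code{n_edges}, \code{components}
#'   (per projection: count and size distribution), \code{pagerank}
#'   (named vector summing to 1), and \code{category_counts}.
#' @export
network_summary <- function(edges, damping = 0.85) {
  if (nrow(edges) == 0L) {
    return(list(n_nodes = 0L, n_edges = 0L,
                components = list(), pagerank = numeric(0),
                category_counts = table(character())))
  }
  g <- igraph::graph_from_data_frame(
    edges[, c("source", "target", "gini")], directed = TRUE)
  comp_of <- function(sub_edges) {
    if (nrow(sub_edges) == 0L) return(list(n = 0L, sizes = integer(0)))
    gu <- igraph::graph_from_data_frame(
      sub_edges[, c("source", "target")], directed = FALSE)
    cc <- igraph::components(gu)
    list(n = as.integer(cc$no), sizes = as.integer(sort(unname(cc$csize))))
  }
  pr <- igraph::page_rank(g, weights = igraph::E(g)$gini,
                          damping = damping)$vector
  list(n_nodes = igraph::vcount(g),
       n_edges = nrow(edges),
       components = list(
         all = comp_of(edges),
         co_occurrence = comp_of(edges[edges$polarity == "co-occurrence", ]),
         avoidance = comp_of(edges[edges$polarity == "avoidance", ])),
       pagerank = pr,
       category_counts = table(edges$category))
}

#' Write the network as GraphML
#'
#' Node attributes (prevalence, D, parsimony, predictable flag, PageRank)
#' are attached for external visualisation tools.
#'
#' @param edges a \code{"relationship_edges"} data.frame.
#' @param paps the \code{pap_set}.
#' @param predictions metrics table (or \code{NULL}).
#' @param signals signal table (or \code{NULL}).
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_network_graphml <- function(edges, paps, predictions = NULL,
                                  signals = NULL, path) {
  g <- igraph::graph_from_data_frame(
    edges[, c("source", "target", "gini", "polarity", "category")],
    directed = TRUE)
  ids <- igraph::V(g)$name
  igraph::V(g)$prevalence <- unname(paps$prevalence[ids])
  if (!is.null(signals)) {
    i <- match(ids, signals$pattern_id)
    igraph::V(g)$D <- signals$D[i]
    igraph::V(g)$parsimony <- signals$parsimony[i]
  }
  if (!is.null(predictions)) {
    i <- match(ids, predictions$pattern_id)
    igraph::V(g)$predictable <- predictions$predictable[i]
  }
  igraph::V(g)$pagerank <- unname(
    igraph::page_rank(g, weights = igraph::E(g)$gini, damping = 0.85)$vector)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
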