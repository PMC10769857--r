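# Physical linkage between associated gene families, measured in gene
# counts along (possibly circular) replicons.

#' Circular gene-count distance
#'
#' Distance between two ordinal gene positions on a replicon: on a circular
#' replicon the minimum of the clockwise and anticlockwise paths, on a
#' linear one the ordinal difference. Adjacent genes are at distance 1.
#'
#' @param pos_a,pos_b 0-based ordinal positions (vectorised).
#' @param n_genes number of genes on the replicon.
#' @param circular logical.
#' @return integer distance(s).
#' @export
circular_distance <- function(pos_a, pos_b, n_genes, circular = TRUE) {
  if (any(pos_a < 0 | pos_a >= n_genes | pos_b < 0 | pos_b >= n_genes)) {
    stop("positions out of range [0, n_genes)")
  }
  d <- abs(pos_a - pos_b)
  if (circular) d <- pmin(d, n_genes - d)
  as.integer(d)
}

#' Read a gene-order table
#'
#' TSV with columns genome, replicon, circular (0/1), gene, position
#' (0-based ordinal within the replicon).
#'
#' @param path file to read.
#' @return data.frame with those columns; positions validated to be a
#'   permutation of 0..n-1 within each replicon.
#' @export
read_gene_orders <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  need <- c("genome", "replicon", "circular", "gene", "position")
  if (!all(need %in% colnames(tab))) {
    stop("gene-order table must have columns: ", paste(need, collapse = ", "))
  }
  by_rep <- split(tab$position, paste(tab$genome, tab$replicon))
  bad <- names(by_rep)[!vapply(by_rep, function(p) {
    identical(sort(p), seq_along(p) - 1L) || identical(sort(p), as.numeric(seq_along(p) - 1L))
  }, logical(1))]
  if (length(bad)) {
    stop("positions are not a permutation of 0..n-1 on: ",
         paste(bad, collapse = ", "))
  }
  tab
}

#' Per-genome linkage profile of a gene pair
#'
#' For each genome where both families are present, the minimum gene-count
#' distance over all placement combinations on shared replicons
#' (multi-copy families take the closest pair of copies). Genomes where the
#' two families sit only on different replicons are tallied as
#' cross-element. Distances are binned as in close (<= 10) and distant
#' (>= 21) fractions.
#'
#' @param gene_a,gene_b gene-family ids.
#' @param orders a gene-order data.frame (see \code{\link{read_gene_orders}}).
#' @return list with \code{distances} (named per genome), \code{cross_element}
#'   count, \code{n_coresident}, \code{frac_within_10}, \code{frac_beyond_21}.
#' @export
pair_linkage_profile <- function(gene_a, gene_b, orders) {
  oa <- orders[orders$gene == gene_a, , drop = FALSE]
  ob <- orders[orders$gene == gene_b, , drop = FALSE]
  genomes <- intersect(unique(oa$genome), unique(ob$genome))
  dists <- stats::setNames(numeric(0), character(0))
  cross <- 0L
  for (g in genomes) {
    ga <- oa[oa$genome == g, , drop = FALSE]
    gb <- ob[ob$genome == g, , drop = FALSE]
    shared <- intersect(ga$replicon, gb$replicon)
    if (length(shared) == 0L) {
      cross <- cross + 1L
      next
    }
    best <- Inf
    for (rp in shared) {
      ra <- ga[ga$replicon == rp, , drop = FALSE]
      rb <- gb[gb$replicon == rp, , drop = FALSE]
      n_rep <- sum(orders$genome == g & orders$replicon == rp)
      circ <- as.logical(ra$circular[1L])
      for (pa in ra$position) {
        d <- circular_distance(rep(pa, nrow(rb)), rb$position, n_rep, circ)
        best <- min(best, d)
      }
    }
    dists[g] <- best
  }
  list(distances = dists,
       cross_element = cross,
       n_coresident = length(dists),
       frac_within_10 = if (length(dists)) mean(dists <= 10) else NA_real_,
       frac_beyond_21 = if (length(dists)) mean(dists >= 21) else NA_real_)
}
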