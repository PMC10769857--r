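#' Read a gene presence-absence matrix
#'
#' Ingests the output of pangenome pipelines in either the Rtab dialect
#' (tab-delimited; first column gene-family id, header row of genome ids,
#' cells 0/1) or the Roary/Panaroo \code{gene_presence_absence.csv} dialect
#' (quoted CSV; genome columns follow a fixed block of metadata columns and
#' hold gene names, so any non-empty cell means presence).
#'
#' @param path file to read.
#' @param dialect \code{"rtab"}, \code{"roary_csv"}, or \code{"auto"}
#'   (sniffed: a comma in the header line selects \code{roary_csv}).
#' @param meta_cols number of leading metadata columns in the
#'   \code{roary_csv} dialect (default 14, the Roary/Panaroo layout).
#' @return a \code{pa_matrix}: binary genomes x genes matrix with genome ids
#'   as rownames and gene-family ids as colnames.
#' @export
read_presence_absence <- function(path, dialect = c("auto", "rtab", "roary_csv"),
                                  meta_cols = 14L) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  if (dialect == "auto") {
    header <- readLines(path, n = 1L)
    dialect <- if (grepl(",", header)) "roary_csv" else "rtab"
  }
  if (dialect == "rtab") {
    tab <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                             stringsAsFactors = FALSE)
    gene_ids <- as.character(tab[[1L]])
    genome_ids <- colnames(tab)[-1L]
    vals <- as.matrix(tab[, -1L, drop = FALSE])
    bad <- which(!(vals %in% c(0, 1, "0", "1")), arr.ind = FALSE)
    if (length(bad)) {
      idx <- arrayInd(bad[1L], dim(vals))
      stop(sprintf("non-binary cell '%s' at gene '%s', genome '%s'",
                   vals[bad[1L]], gene_ids[idx[1L]], genome_ids[idx[2L]]))
    }
    storage.mode(vals) <- "numeric"
    m <- t(vals)  # genomes x genes
    colnames(m) <- gene_ids
    rownames(m) <- genome_ids
  } else {
    tab <- utils::read.csv(path, header = TRUE, check.names = FALSE,
                           stringsAsFactors = FALSE, colClasses = "character")
    if (ncol(tab) <= meta_cols) {
      stop("roary_csv input has no genome columns beyond the ", meta_cols,
           " metadata columns")
    }
    gene_ids <- as.character(tab[[1L]])
    cells <- as.matrix(tab[, -(seq_len(meta_cols)), drop = FALSE])
    genome_ids <- colnames(cells)
    m <- t((!is.na(cells)) & nzchar(trimws(cells))) * 1
    colnames(m) <- gene_ids
    rownames(m) <- genome_ids
  }
  new_pa_matrix(m)
}

new_pa_matrix <- function(m) {
  genome_ids <- rownames(m)
  gene_ids <- colnames(m)
  if (is.null(genome_ids) || is.null(gene_ids)) {
    stop("pa_matrix requires genome rownames and gene colnames")
  }
  if (anyDuplicated(genome_ids)) {
    stop("duplicate genome ids: ",
         paste(unique(genome_ids[duplicated(genome_ids)]), collapse = ", "))
  }
  if (anyDuplicated(gene_ids)) {
    stop("duplicate gene ids: ",
         paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "))
  }
  if (!all(m %in% c(0, 1))) stop("pa_matrix cells must be 0 or 1")
  storage.mode(m) <- "integer"
  class(m) <- c("pa_matrix", class(m))
  m
}

#' Write a presence-absence matrix in Rtab dialect
#'
#' @param m a \code{pa_matrix} (genomes x genes).
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_rtab <- function(m, path) {
  tab <- data.frame(Gene = colnames(m), t(unclass(m)), check.names = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Filter gene families by prevalence
#'
#' Removes genes present in more than \code{common_max} or less than
#' \code{rare_min} of genomes; the closed interval is retained. Comparison
#' is count-based (keep gene iff \code{rare_min * N <= count <= common_max
#' * N}) so no float-threshold drift can flip a boundary case.
#'
#' @param m a \code{pa_matrix}.
#' @param rare_min,common_max prevalence bounds (fractions), both inclusive.
#' @return the filtered \code{pa_matrix}; genome set unchanged.
#' @export
filter_by_frequency <- function(m, rare_min = 0.01, common_max = 0.99) {
  stopifnot(rare_min > 0, rare_min < common_max, common_max < 1)
  n <- nrow(m)
  counts <- colSums(m)
  keep <- counts >= rare_min * n & counts <= common_max * n
  if (!any(keep)) warning("no gene family survives the frequency filter")
  out <- unclass(m)[, keep, drop = FALSE]
  class(out) <- c("pa_matrix", class(out))
  out
}

#' Collapse identical presence-absence patterns
#'
#' Genes sharing an identical column vector are merged into one
#' presence-absence pattern (PAP); genomes with identical row vectors are
#' recorded as one modelling class. The full genome list is kept on the
#' object because prevalence, conditional frequencies and the category rules
#' are defined over all genomes, while Random-Forest models are trained on
#' the deduplicated rows.
#'
#' @param m a frequency-filtered \code{pa_matrix}.
#' @return a \code{pap_set}: list with
#'   \item{patterns}{genomes x PAP binary matrix (full genome list);}
#'   \item{pattern_ids}{\code{"PAP:"} + lexicographically smallest member gene id;}
#'   \item{members}{list of member gene ids per PAP;}
#'   \item{prevalence}{fraction of genomes carrying each PAP;}
#'   \item{genome_ids}{all genome ids;}
#'   \item{model_rows}{indices of one representative genome per distinct row;}
#'   \item{genome_class}{named map genome id -> representative genome id;}
#'   \item{gene_to_pattern}{named map gene id -> pattern id.}
#' @export
collapse_patterns <- function(m) {
  vals <- unclass(m)
  gene_ids <- colnames(vals)
  genome_ids <- rownames(vals)
  col_key <- apply(vals, 2L, paste0, collapse = "")
  groups <- split(gene_ids, col_key)
  # stable pattern id: smallest member gene id
  ids <- vapply(groups, function(g) paste0("PAP:", sort(g)[1L]), character(1))
  ord <- order(ids)
  groups <- groups[ord]
  ids <- unname(ids[ord])
  first_gene <- vapply(groups, function(g) sort(g)[1L], character(1))
  patterns <- vals[, first_gene, drop = FALSE]
  colnames(patterns) <- ids
  row_key <- apply(patterns, 1L, paste0, collapse = "")
  reps <- !duplicated(row_key)
  rep_of <- genome_ids[tapply(seq_along(row_key), row_key, min)[row_key]]
  names(rep_of) <- genome_ids
  gene_to_pattern <- stats::setNames(rep(ids, lengths(groups)), unlist(groups))
  out <- list(patterns = patterns,
              pattern_ids = ids,
              members = stats::setNames(lapply(groups, sort), ids),
              prevalence = colMeans(patterns),
              genome_ids = genome_ids,
              model_rows = which(reps),
              genome_class = rep_of,
              gene_to_pattern = gene_to_pattern)
  class(out) <- "pap_set"
  out
}

#' @export
print.pap_set <- function(x, ...) {
  cat(sprintf("pap_set: %d PAPs over %d genomes (%d distinct genome rows)\n",
              length(x$pattern_ids), length(x$genome_ids),
              length(x$model_rows)))
  cat(sprintf("  member genes: %d; multi-gene PAPs: %d\n",
              length(x$gene_to_pattern), sum(lengths(x$members) > 1L)))
  invisible(x)
}

#' Expand a PAP set back to a gene-level matrix
#'
#' Inverse of \code{\link{collapse_patterns}} on the gene axis: rebuilds the
#' filtered genomes x genes matrix from the patterns and the membership map.
#'
#' @param paps a \code{pap_set}.
#' @return a \code{pa_matrix}.
#' @export
expand_patterns <- function(paps) {
  gene_ids <- names(paps$gene_to_pattern)
  m <- paps$patterns[, paps$gene_to_pattern[gene_ids], drop = FALSE]
  colnames(m) <- gene_ids
  m <- m[, order(gene_ids), drop = FALSE]
  new_pa_matrix(m)
}

#' Conditional frequencies between two patterns
#'
#' The 2x2 contingency table over genomes plus the target frequencies used
#' for edge polarity (co-occurrence vs avoidance) and the commensalism rule.
#' Computed over the full genome list.
#'
#' @param target,source binary vectors over the same genomes (names, if
#'   present, must agree).
#' @return list with counts \code{n11} (both), \code{n10} (target only),
#'   \code{n01} (source only), \code{n00} (neither), and frequencies
#'   \code{p_target}, \code{p_target_given_source_present},
#'   \code{p_target_given_source_absent} (\code{NA} when the conditioning
#'   class is empty, flagged via \code{undefined}).
#' @export
pap_conditional_frequencies <- function(target, source) {
  if (length(target) != length(source)) {
    stop("patterns are over different genome lists")
  }
  if (!is.null(names(target)) && !is.null(names(source)) &&
      !identical(names(target), names(source))) {
    stop("patterns are over different genome lists")
  }
  t1 <- target == 1; s1 <- source == 1
  n11 <- sum(t1 & s1); n10 <- sum(t1 & !s1)
  n01 <- sum(!t1 & s1); n00 <- sum(!t1 & !s1)
  p_t <- mean(t1)
  p_ts1 <- if ((n11 + n01) > 0L) n11 / (n11 + n01) else NA_real_
  p_ts0 <- if ((n10 + n00) > 0L) n10 / (n10 + n00) else NA_real_
  list(n11 = n11, n10 = n10, n01 = n01, n00 = n00,
       p_target = p_t,
       p_target_given_source_present = p_ts1,
       p_target_given_source_absent = p_ts0,
       undefined = is.na(p_ts1) || is.na(p_ts0))
}

#' Write the collapse maps as TSV
#'
#' @param paps a \code{pap_set}.
#' @param gene_path,genome_path output files for the gene -> pattern and
#'   genome -> class maps.
#' @return invisibly, a list of the two paths.
#' @export
write_collapse_map <- function(paps, gene_path, genome_path) {
  utils::write.table(
    data.frame(gene = names(paps$gene_to_pattern),
               pattern = unname(paps$gene_to_pattern)),
    gene_path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(genome = names(paps$genome_class),
               class = unname(paps$genome_class)),
    genome_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(list(gene_path, genome_path))
}
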