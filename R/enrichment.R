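#' Gene set collections
#'
#' A named list of gene sets over a common universe, the substrate of
#' over-representation analysis. Every member set must be a subset of the
#' universe.
#'
#' @param sets named list of character vectors.
#' @param universe character vector of all gene ids.
#' @return A `gene_set_collection`.
#' @export
gene_set_collection <- function(sets, universe) {
  stopifnot(is.list(sets), !is.null(names(sets)), !anyDuplicated(names(sets)))
  universe <- unique(as.character(universe))
  for (nm in names(sets)) {
    sets[[nm]] <- unique(as.character(sets[[nm]]))
    out <- setdiff(sets[[nm]], universe)
    if (length(out)) stop("set '", nm, "' contains genes outside the universe")
  }
  structure(list(sets = sets, universe = universe), class = "gene_set_collection")
}

#' Read a two-column gene-set table
#'
#' TSV with header `set_name<TAB>gene_id`, one membership per row.
#'
#' @param path path to the TSV.
#' @param universe the gene universe.
#' @return A [gene_set_collection()].
#' @export
read_gene_sets <- function(path, universe) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = "character")
  gene_set_collection(split(df$gene_id, df$set_name), universe)
}

#' Hypergeometric over-representation analysis
#'
#' For each set, the upper-tail probability of drawing at least the
#' observed overlap: with N the universe size, K the set size, n the query
#' size and k the overlap, `p = P[X >= k]` for
#' X ~ Hypergeometric(N, K, n). Records are BH-adjusted and sorted by
#' p-value.
#'
#' @param query a gene-id vector, subset of the collection's universe.
#' @param collection a [gene_set_collection()].
#' @return A data frame (set_name, k, K, n, N, p_value, q_value) sorted by
#'   ascending p.
#' @export
ora_hypergeometric <- function(query, collection) {
  stopifnot(inherits(collection, "gene_set_collection"))
  query <- unique(query)
  out <- setdiff(query, collection$universe)
  if (length(out)) {
    stop("query genes outside the universe: ", paste(out, collapse = ", "))
  }
  N <- length(collection$universe)
  n <- length(query)
  rec <- do.call(rbind, lapply(names(collection$sets), function(nm) {
    set <- collection$sets[[nm]]
    K <- length(set)
    k <- length(intersect(query, set))
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(set_name = nm, k = k, K = K, n = n, N = N, p_value = p,
               stringsAsFactors = FALSE)
  }))
  rec$q_value <- bh_adjust(rec$p_value)
  rec <- rec[order(rec$p_value, rec$set_name), , drop = FALSE]
  rownames(rec) <- NULL
  rec
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment with monotonicity enforcement;
#' output order matches input order.
#'
#' @param p_values numeric vector of p-values in [0, 1].
#' @return Adjusted values in the same order.
#' @export
bh_adjust <- function(p_values) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE) || anyNA(p_values)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p_values, method = "BH")
}
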