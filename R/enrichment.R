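#' Over-representation analysis of a gene set against a pathway database
#'
#' Hypergeometric upper-tail test per pathway, the classical
#' over-representation analysis. The focal genes are removed from the
#' query first, so enrichment describes the coexpressed neighborhood
#' rather than the focal genes themselves. BH adjustment is applied across
#' all tested pathways; raw p-values are reported alongside.
#'
#' @param query Character vector of gene IDs (e.g. the gene-network
#'   members); must lie inside the universe.
#' @param focal Character vector of focal gene IDs removed from the query.
#' @param db A \code{pathway_db}.
#' @param universe Character vector: the background gene universe (all
#'   measured genes).
#' @return data.frame sorted by ascending p with columns
#'   \code{pathway_id}, \code{description}, \code{overlap},
#'   \code{query_size}, \code{pathway_size}, \code{universe_size},
#'   \code{p}, \code{q_bh}.
#' @export
enrich <- function(query, focal, db, universe) {
  stopifnot(inherits(db, "pathway_db"))
  query <- unique(query)
  if (!all(query %in% universe))
    stop("query genes must lie inside the universe")
  qset <- setdiff(query, focal)
  if (!length(qset)) {
    warning("query is empty after removing focal genes")
    return(data.frame(pathway_id = character(0),
                      description = character(0), overlap = integer(0),
                      query_size = integer(0), pathway_size = integer(0),
                      universe_size = integer(0), p = numeric(0),
                      q_bh = numeric(0)))
  }
  N <- length(unique(universe))
  nq <- length(qset)
  sets <- lapply(db$sets, intersect, y = universe)
  sets <- sets[lengths(sets) >= 1L]
  a <- vapply(sets, function(s) length(intersect(s, qset)), integer(1L))
  m <- lengths(sets)
  p <- stats::phyper(a - 1L, m, N - m, nq, lower.tail = FALSE)
  out <- data.frame(pathway_id = names(sets),
                    description = unname(db$description[names(sets)]),
                    overlap = a, query_size = nq, pathway_size = m,
                    universe_size = N, p = p, q_bh = bh_fdr(p),
                    stringsAsFactors = FALSE, row.names = NULL)
  out[order(out$p, out$pathway_id), , drop = FALSE]
}
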