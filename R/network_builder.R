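#' Construct a typed coexpression network
#'
#' @param nodes data.frame with columns \code{id}, \code{node_type}
#'   ("gene" or "pathway") and \code{is_focal}.
#' @param edges data.frame with columns \code{from}, \code{to},
#'   \code{edge_type} ("gene-gene" or "gene-pathway"), \code{weight},
#'   \code{tissue}, \code{support}, \code{significant}, \code{empirical_p}.
#' @return An object of class \code{coex_network}.
#' @export
coex_network <- function(nodes, edges) {
  stopifnot(all(c("id", "node_type", "is_focal") %in% names(nodes)),
            all(c("from", "to", "edge_type", "weight", "tissue",
                  "support", "significant", "empirical_p") %in%
                  names(edges)))
  if (anyDuplicated(nodes$id)) stop("duplicate node id")
  if (nrow(edges) && any(edges$from == edges$to))
    stop("self-edges are not allowed")
  if (nrow(edges) &&
      !all(c(edges$from, edges$to) %in% nodes$id))
    stop("edge endpoint missing from node table")
  # canonical ordering so equal networks compare identical regardless of
  # construction path (builders, GraphML re-import)
  nodes <- nodes[order(nodes$node_type, nodes$id), , drop = FALSE]
  edges <- edges[order(edges$from, edges$to, edges$tissue), ,
                 drop = FALSE]
  rownames(nodes) <- NULL
  rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges), class = "coex_network")
}

#' @export
print.coex_network <- function(x, ...) {
  cat("<coex_network> ", nrow(x$nodes), " nodes (",
      sum(x$nodes$node_type == "gene"), " genes, ",
      sum(x$nodes$node_type == "pathway"), " pathways), ",
      nrow(x$edges), " edges\n", sep = "")
  invisible(x)
}

empty_edges <- function() {
  data.frame(from = character(0), to = character(0),
             edge_type = character(0), weight = numeric(0),
             tissue = character(0), support = integer(0),
             significant = logical(0), empirical_p = numeric(0),
             stringsAsFactors = FALSE)
}

#' Top-k coexpressed partners of a focal gene
#'
#' Ranks the candidate genes of one focal gene by signed averaged
#' correlation (descending; optionally by absolute value), excluding the
#' focal gene itself, and returns the k best. Boundary ties are broken by
#' ascending gene ID so the ranking is deterministic.
#'
#' @param table A \code{coexpression_table} (stratum "all" rows are used).
#' @param focal Focal gene ID.
#' @param k Number of partners (>= 1). Fewer candidates than k: all are
#'   returned.
#' @param rank_by_abs Rank by |R| instead of signed R (default FALSE).
#' @return data.frame with columns \code{focal}, \code{gene}, \code{R},
#'   \code{support}, \code{rank}.
#' @export
top_k_partners <- function(table, focal, k = 20L, rank_by_abs = FALSE) {
  stopifnot(k >= 1L)
  cand <- table[table$focal == focal & table$stratum == "all" &
                  table$gene != focal, , drop = FALSE]
  if (!nrow(cand)) {
    warning("focal gene '", focal, "' has no candidates in the table")
    return(data.frame(focal = character(0), gene = character(0),
                      R = numeric(0), support = integer(0),
                      rank = integer(0)))
  }
  key <- if (rank_by_abs) abs(cand$R) else cand$R
  ord <- order(-key, cand$gene)
  cand <- cand[ord[seq_len(min(k, nrow(cand)))], , drop = FALSE]
  data.frame(focal = focal, gene = cand$gene, R = cand$R,
             support = cand$support, rank = seq_len(nrow(cand)),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Assemble the top-k gene coexpression network
#'
#' Union of the top-k partner lists over all focal genes. When one focal
#' gene appears in another's top-k the pair contributes a single
#' undirected focal-focal edge. Edge weight is the averaged correlation R;
#' support records the number of contributing datasets.
#'
#' @param table A \code{coexpression_table} covering the focal genes.
#' @param focal Character vector of focal gene IDs.
#' @param k Partners per focal gene (default 20).
#' @param rank_by_abs Rank by |R| (default FALSE).
#' @return A \code{coex_network} of gene nodes and "gene-gene" edges.
#' @export
build_gene_network <- function(table, focal, k = 20L, rank_by_abs = FALSE) {
  tops <- do.call(rbind, lapply(focal, function(x)
    suppressWarnings(top_k_partners(table, x, k, rank_by_abs))))
  if (is.null(tops) || !nrow(tops)) {
    nodes <- data.frame(id = sort(unique(focal)), node_type = "gene",
                        is_focal = TRUE, stringsAsFactors = FALSE)
    return(coex_network(nodes, empty_edges()))
  }
  # canonical endpoint order dedups A->B / B->A focal-focal pairs
  a <- pmin(tops$focal, tops$gene)
  b <- pmax(tops$focal, tops$gene)
  keep <- !duplicated(paste(a, b, sep = "\r"))
  edges <- data.frame(from = a[keep], to = b[keep],
                      edge_type = "gene-gene", weight = tops$R[keep],
                      tissue = "all",
                      support = as.integer(tops$support[keep]),
                      significant = NA, empirical_p = NA_real_,
                      stringsAsFactors = FALSE)
  edges <- edges[order(edges$from, edges$to), , drop = FALSE]
  ids <- sort(unique(c(focal, edges$from, edges$to)))
  nodes <- data.frame(id = ids, node_type = "gene",
                      is_focal = ids %in% focal,
                      stringsAsFactors = FALSE)
  coex_network(nodes, edges)
}

#' Assemble the tissue-specific gene-pathway network
#'
#' Per focal gene: keep only the significant pathway scores, rank them by
#' score (descending, across all tissues jointly; ties broken by pathway
#' ID then tissue), take the top \code{top}, then drop edges supported by
#' fewer than \code{min_support} datasets of the tissue. Each surviving
#' edge carries its tissue label and score as weight.
#'
#' @param scores A \code{pathway_scores} data.frame
#'   (see \code{\link{score_pathways}}).
#' @param top Pathway edges kept per focal gene before the support filter
#'   (default 10).
#' @param min_support Minimum number of contributing datasets per edge
#'   (default 5).
#' @return A \code{coex_network} with gene and pathway nodes and
#'   "gene-pathway" edges.
#' @export
build_pathway_network <- function(scores, top = 10L, min_support = 5L) {
  stopifnot(top >= 1L, min_support >= 1L)
  sig <- scores[!is.na(scores$score) & scores$significant, , drop = FALSE]
  kept <- if (nrow(sig)) {
    parts <- lapply(split(sig, sig$focal), function(s) {
      ord <- order(-s$score, s$pathway_id, s$tissue)
      s <- s[ord[seq_len(min(top, nrow(s)))], , drop = FALSE]
      s[s$n_datasets_used >= min_support, , drop = FALSE]
    })
    do.call(rbind, c(parts, list(make.row.names = FALSE)))
  } else sig
  focal_ids <- sort(unique(scores$focal))
  if (!nrow(kept)) {
    nodes <- data.frame(id = focal_ids,
                        node_type = rep("gene", length(focal_ids)),
                        is_focal = rep(TRUE, length(focal_ids)),
                        stringsAsFactors = FALSE)
    return(coex_network(nodes, empty_edges()))
  }
  edges <- data.frame(from = kept$focal, to = kept$pathway_id,
                      edge_type = "gene-pathway", weight = kept$score,
                      tissue = kept$tissue,
                      support = as.integer(kept$n_datasets_used),
                      significant = kept$significant,
                      empirical_p = kept$empirical_p,
                      stringsAsFactors = FALSE)
  edges <- edges[order(edges$from, edges$to, edges$tissue), , drop = FALSE]
  ids_g <- sort(unique(c(focal_ids, edges$from)))
  ids_p <- sort(unique(edges$to))
  nodes <- rbind(
    data.frame(id = ids_g, node_type = "gene", is_focal = ids_g %in%
                 unique(scores$focal), stringsAsFactors = FALSE),
    data.frame(id = ids_p, node_type = "pathway", is_focal = FALSE,
               stringsAsFactors = FALSE))
  coex_network(nodes, edges)
}

#' Convert a coexpression network to an igraph object
#'
#' @param network A \code{coex_network}.
#' @return An undirected \code{igraph} graph with typed node and edge
#'   attributes (logicals encoded as 0/1 integers for GraphML fidelity).
#' @export
as_igraph <- function(network) {
  nodes <- network$nodes
  nodes$is_focal <- as.integer(nodes$is_focal)
  edges <- network$edges
  # -1 encodes "not applicable" (gene-gene edges carry no significance)
  edges$significant <- ifelse(is.na(edges$significant), -1L,
                              as.integer(edges$significant))
  igraph::graph_from_data_frame(edges, directed = FALSE,
                                vertices = nodes)
}

#' Export a coexpression network
#'
#' GraphML carries the full typed attribute set and round-trips through
#' \code{\link{import_network}} exactly; SIF uses interaction types
#' "coexpr" / "pathway-coexpr" (isolated nodes get a single-field line);
#' TSV is the long edge table.
#'
#' @param network A \code{coex_network}.
#' @param path Output file path.
#' @param format One of "graphml", "sif", "tsv".
#' @return Invisibly, \code{path}.
#' @export
export_network <- function(network, path,
                           format = c("graphml", "sif", "tsv")) {
  format <- match.arg(format)
  if (format == "graphml") {
    igraph::write_graph(as_igraph(network), path, format = "graphml")
  } else if (format == "sif") {
    e <- network$edges
    lines <- if (nrow(e))
      paste(e$from,
            ifelse(e$edge_type == "gene-gene", "coexpr", "pathway-coexpr"),
            e$to, sep = "\t") else character(0)
    isolated <- setdiff(network$nodes$id, c(e$from, e$to))
    writeLines(c(lines, isolated), path)
  } else {
    utils::write.table(network$edges, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

#' Re-import a GraphML coexpression network
#'
#' @param path GraphML file written by \code{\link{export_network}}.
#' @return The reconstructed \code{coex_network}.
#' @export
import_network <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  vn <- igraph::vertex_attr(g)
  nodes <- data.frame(id = vn$name, node_type = vn$node_type,
                      is_focal = as.logical(vn$is_focal),
                      stringsAsFactors = FALSE)
  el <- igraph::as_edgelist(g)
  en <- igraph::edge_attr(g)
  to_na <- function(x) { x[is.nan(x)] <- NA; x }
  sig <- if (nrow(el)) {
    s <- en$significant
    s[s < 0] <- NA
    as.logical(s)
  }
  edges <- if (nrow(el))
    data.frame(from = el[, 1L], to = el[, 2L],
               edge_type = en$edge_type, weight = to_na(en$weight),
               tissue = en$tissue, support = as.integer(en$support),
               significant = sig,
               empirical_p = to_na(en$empirical_p),
               stringsAsFactors = FALSE)
  else empty_edges()
  coex_network(nodes, edges)
}
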