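# Run code with a locally seeded RNG, restoring the caller's RNG state.
with_local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Tissue-specific gene-level coexpression restricted to DE datasets
#'
#' For a focal gene x and a tissue, averages the per-dataset Pearson
#' weights r_k over only the datasets that (i) have that unanimous tissue
#' and (ii) flagged x as differentially expressed — the dataset restriction
#' used for transporter-to-pathway scoring, on the rationale that a
#' transporter's regulatory context is only informative where the
#' transporter itself responds.
#'
#' @param x Focal gene ID.
#' @param tissue Tissue label.
#' @param collection A \code{dataset_collection}.
#' @param de_results List of \code{de_result} for the collection (e.g. from
#'   \code{\link{de_scan}}).
#' @return List with \code{R} (named vector over the gene universe, NA
#'   where undefined), \code{support} (named integer vector),
#'   \code{n_datasets_used} and \code{dataset_ids}.
#' @export
tissue_gene_scores <- function(x, tissue, collection, de_results) {
  ids <- de_restricted_datasets(x, tissue, collection, de_results)
  if (!length(ids)) {
    universe <- collection$gene_universe
    return(list(R = stats::setNames(rep(NA_real_, length(universe)),
                                    universe),
                support = stats::setNames(integer(length(universe)),
                                          universe),
                n_datasets_used = 0L, dataset_ids = character(0)))
  }
  acc <- accumulate_correlations(collection, x, ids)
  R <- acc$rsum[1L, ] / ifelse(acc$support[1L, ] > 0L,
                               acc$support[1L, ], NA_real_)
  list(R = R, support = acc$support[1L, ],
       n_datasets_used = length(ids), dataset_ids = ids)
}

de_restricted_datasets <- function(x, tissue, collection, de_results) {
  tiss <- collection_tissues(collection)
  names(Filter(function(id) {
    r <- de_results[[id]]
    !is.null(r) && r$testable && identical(tiss[[id]], tissue) &&
      x %in% r$table$gene_id &&
      isTRUE(r$table$is_DE[match(x, r$table$gene_id)])
  }, stats::setNames(as.list(names(collection$datasets)),
                     names(collection$datasets))))
}

# Mean of defined gene-level weights over a member set; NA if none defined.
set_score <- function(gene_R, members) {
  v <- gene_R[members]
  v <- v[!is.na(v)]
  if (!length(v)) NA_real_ else mean(v)
}

#' Tissue-specific coexpression score between a focal gene and a pathway
#'
#' The pathway score is the mean, over the pathway's in-universe members,
#' of the tissue-specific gene-level coexpression weights computed on the
#' DE-restricted dataset subset (see \code{\link{tissue_gene_scores}}).
#' Members with no defined gene-level weight are excluded from the mean
#' (with a message); if no tissue-matched dataset flags x as DE the score
#' is undefined (\code{NA}).
#'
#' @param x Focal gene ID.
#' @param pathway Character vector of member gene IDs.
#' @param tissue Tissue label.
#' @param collection A \code{dataset_collection}.
#' @param de_results List of \code{de_result} for the collection.
#' @param gene_scores Optional precomputed \code{\link{tissue_gene_scores}}
#'   output for (x, tissue), to avoid recomputation in batch scoring.
#' @return A one-row data.frame with columns \code{focal},
#'   \code{pathway_size} (m, in-universe member count), \code{tissue},
#'   \code{score}, \code{n_members_used}, \code{n_datasets_used}.
#' @export
pathway_score <- function(x, pathway, tissue, collection, de_results,
                          gene_scores = NULL) {
  members <- intersect(unique(pathway), collection$gene_universe)
  if (!length(members)) stop("pathway has no members in the gene universe")
  if (is.null(gene_scores))
    gene_scores <- tissue_gene_scores(x, tissue, collection, de_results)
  v <- gene_scores$R[members]
  used <- sum(!is.na(v))
  if (gene_scores$n_datasets_used > 0L && used < length(members))
    message("pathway score for '", x, "' in '", tissue, "': ",
            length(members) - used,
            " member(s) with undefined weight excluded")
  data.frame(focal = x, pathway_size = length(members), tissue = tissue,
             score = set_score(gene_scores$R, members),
             n_members_used = used,
             n_datasets_used = gene_scores$n_datasets_used,
             stringsAsFactors = FALSE)
}

#' Permutation null for a pathway coexpression score
#'
#' Each of B replicates replaces the pathway by m genes drawn uniformly
#' without replacement from the gene universe minus the focal gene itself,
#' scored identically on the same DE-restricted dataset subset. A strict
#' comparison counts null scores exceeding the observed one; the empirical
#' p-value uses the (exceed + 1) / (B + 1) convention so it is never zero,
#' and the \code{significant} flag — the criterion the downstream network
#' uses — is TRUE exactly when no null replicate exceeds the observed
#' score (with B = 100 this is the "empirical p < 0.01" rule).
#'
#' @param x Focal gene ID.
#' @param observed Observed score row from \code{\link{pathway_score}}.
#' @param universe Character vector: the gene universe to sample from.
#' @param B Number of replicates (default 100).
#' @param seed Integer seed; results are reproducible from it.
#' @param collection,de_results As in \code{\link{pathway_score}}.
#' @param gene_scores Optional precomputed gene-level scores for
#'   (x, tissue).
#' @return The \code{observed} row with columns \code{null_exceed},
#'   \code{B}, \code{empirical_p} and \code{significant} appended.
#' @export
permutation_null <- function(x, observed, universe, B = 100L, seed,
                             collection, de_results, gene_scores = NULL) {
  stopifnot(B >= 1L, nrow(observed) == 1L)
  pool <- setdiff(universe, x)
  m <- observed$pathway_size
  if (m > length(pool))
    stop("pathway size exceeds the samplable universe")
  if (is.null(gene_scores))
    gene_scores <- tissue_gene_scores(x, observed$tissue, collection,
                                      de_results)
  null_scores <- with_local_seed(seed, {
    vapply(seq_len(B), function(b)
      set_score(gene_scores$R, sample(pool, m)), numeric(1L))
  })
  exceed <- sum(!is.na(null_scores) & !is.na(observed$score) &
                  null_scores > observed$score)
  out <- observed
  out$null_exceed <- as.integer(exceed)
  out$B <- as.integer(B)
  out$empirical_p <- (exceed + 1) / (B + 1)
  out$significant <- !is.na(observed$score) && exceed == 0L
  out
}

#' Score all focal-gene x pathway x tissue combinations
#'
#' Batch driver: for each focal gene and tissue the gene-level weights are
#' computed once on the DE-restricted datasets, then every pathway is
#' scored and permutation-tested against B random same-size gene sets.
#' Combinations with no usable dataset are reported with \code{NA} score
#' and \code{significant = FALSE}.
#'
#' @param focal Character vector of focal gene IDs.
#' @param db A \code{pathway_db}.
#' @param collection A \code{dataset_collection}.
#' @param de_results List of \code{de_result} (e.g. \code{\link{de_scan}}).
#' @param tissues Tissue labels to score; defaults to all non-"mixed"
#'   tissues in the collection.
#' @param B Permutation replicates (default 100).
#' @param seed Integer seed for the permutation null.
#' @return A \code{pathway_scores} data.frame with one row per
#'   (focal, pathway, tissue): columns \code{focal}, \code{pathway_id},
#'   \code{tissue}, \code{score}, \code{pathway_size},
#'   \code{n_members_used}, \code{n_datasets_used}, \code{null_exceed},
#'   \code{B}, \code{empirical_p}, \code{significant}.
#' @export
score_pathways <- function(focal, db, collection, de_results,
                           tissues = NULL, B = 100L, seed) {
  stopifnot(inherits(db, "pathway_db"))
  if (is.null(tissues)) {
    tiss <- collection_tissues(collection)
    tissues <- sort(unique(tiss[tiss != "mixed"]))
  }
  universe <- collection$gene_universe
  rows <- list()
  i <- 0L
  for (x in focal) {
    for (tt in tissues) {
      gs <- tissue_gene_scores(x, tt, collection, de_results)
      for (pid in names(db$sets)) {
        obs <- suppressMessages(
          pathway_score(x, db$sets[[pid]], tt, collection, de_results,
                        gene_scores = gs))
        i <- i + 1L
        row <- permutation_null(x, obs, universe, B = B,
                                seed = subscore_seed(seed, i),
                                collection, de_results, gene_scores = gs)
        row$pathway_id <- pid
        rows[[i]] <- row
      }
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(focal = character(0), pathway_size = integer(0),
                      tissue = character(0), score = numeric(0),
                      n_members_used = integer(0),
                      n_datasets_used = integer(0),
                      null_exceed = integer(0), B = integer(0),
                      empirical_p = numeric(0), significant = logical(0),
                      pathway_id = character(0))
  out <- out[, c("focal", "pathway_id", "tissue", "score", "pathway_size",
                 "n_members_used", "n_datasets_used", "null_exceed", "B",
                 "empirical_p", "significant")]
  rownames(out) <- NULL
  class(out) <- c("pathway_scores", "data.frame")
  out
}

# Per-combination substream: keeps each (focal, pathway, tissue) null
# reproducible regardless of how many combinations precede it.
subscore_seed <- function(seed, i) {
  as.integer((as.double(seed) + 48271 * i) %% 2147483647)
}
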