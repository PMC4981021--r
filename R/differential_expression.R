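#' One-way fixed-effects ANOVA for a single gene
#'
#' Standard one-way ANOVA across replicate groups: upper-tail p from the
#' F(df_between, df_within) distribution. Degenerate inputs follow fixed
#' conventions so per-dataset gene scans never abort: zero within-group
#' variance with unequal group means gives \code{F = Inf, p = 0}; zero
#' variance everywhere (0/0) gives \code{p = 1}, both flagged via
#' \code{degenerate}.
#'
#' @param values_by_group List of numeric vectors, one per replicate group;
#'   at least two groups of at least two samples each.
#' @return List with elements \code{F}, \code{p} and \code{degenerate}.
#' @export
anova_pvalue <- function(values_by_group) {
  stopifnot(is.list(values_by_group), length(values_by_group) >= 2L)
  sizes <- lengths(values_by_group)
  if (any(sizes < 2L))
    stop("every replicate group needs >= 2 samples")
  y <- unlist(values_by_group, use.names = FALSE)
  g <- rep(seq_along(values_by_group), sizes)
  out <- row_anova(matrix(y, nrow = 1L), g)
  list(F = out$F[1L], p = out$p[1L], degenerate = out$degenerate[1L])
}

# Vectorized one-way ANOVA over matrix rows (genes). Returns F, p,
# degenerate flag and an untestable flag (zero total variance).
row_anova <- function(values, groups) {
  groups <- as.factor(groups)
  n <- ncol(values)
  glev <- levels(groups)
  G <- length(glev)
  sizes <- as.vector(table(groups))
  ind <- stats::model.matrix(~ groups - 1)          # n x G indicator
  gsum <- values %*% ind                            # genes x G
  gmean <- sweep(gsum, 2L, sizes, "/")
  grand <- rowSums(values) / n
  ssb <- rowSums(sweep(gmean - grand, 2L, sizes, "*") * (gmean - grand))
  sst <- rowSums((values - grand)^2)
  ssw <- pmax(sst - ssb, 0)
  dfb <- G - 1L
  dfw <- n - G
  # relative floor: SS that are 0 up to rounding are treated as 0
  eps <- sst * 1e-12
  zero_w <- ssw <= eps
  zero_t <- sst <= n * 1e-24
  Fstat <- (ssb / dfb) / (ssw / dfw)
  p <- stats::pf(Fstat, dfb, dfw, lower.tail = FALSE)
  Fstat[zero_w & !zero_t] <- Inf
  p[zero_w & !zero_t] <- 0
  Fstat[zero_t] <- NaN
  p[zero_t] <- 1
  list(F = Fstat, p = p, degenerate = zero_w | zero_t, untestable = zero_t)
}

#' Benjamini-Hochberg adjusted q-values
#'
#' Step-up BH adjustment, order-aligned with the input. A thin validating
#' wrapper over \code{stats::p.adjust(method = "BH")}.
#'
#' @param pvalues Numeric vector of p-values in [0, 1].
#' @return Numeric vector of q-values, same order as the input.
#' @export
bh_fdr <- function(pvalues) {
  stopifnot(is.numeric(pvalues))
  if (any(!is.na(pvalues) & (pvalues < 0 | pvalues > 1)))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

#' Per-dataset differential-expression scan
#'
#' For each gene, a one-way ANOVA across the dataset's replicate groups,
#' followed by BH adjustment across all testable genes of the dataset (the
#' per-dataset gene family). A gene is flagged DE when its q-value (or raw
#' p-value, see \code{threshold_on}) falls below the threshold. Replicate
#' groups with fewer than two samples are dropped with a warning; a dataset
#' with fewer than two usable groups is untestable and returns an object
#' with \code{testable = FALSE}, which downstream tallies skip.
#'
#' Genes with zero total variance in the dataset are untestable there: they
#' are excluded from the BH family and reported with \code{NA} q.
#'
#' @param dataset An \code{expression_dataset}.
#' @param q_threshold Significance threshold (default 0.001, applied to
#'   BH q-values).
#' @param threshold_on \code{"q"} (default) or \code{"p"}: which value the
#'   threshold is compared against.
#' @return A \code{de_result}: list with \code{dataset_id}, \code{tissue},
#'   \code{testable}, and \code{table}, a data.frame with columns
#'   \code{gene_id}, \code{F}, \code{p}, \code{q}, \code{is_DE}.
#' @export
de_flags <- function(dataset, q_threshold = 0.001, threshold_on = c("q", "p")) {
  stopifnot(inherits(dataset, "expression_dataset"),
            q_threshold > 0, q_threshold <= 1)
  threshold_on <- match.arg(threshold_on)
  grp <- dataset$replicate_group
  sizes <- table(grp)
  keep_groups <- names(sizes)[sizes >= 2L]
  if (length(keep_groups) < length(sizes))
    warning("dataset '", dataset$dataset_id, "': dropping ",
            length(sizes) - length(keep_groups),
            " replicate group(s) with < 2 samples")
  if (length(keep_groups) < 2L) {
    return(structure(list(dataset_id = dataset$dataset_id,
                          tissue = dataset$tissue, testable = FALSE,
                          table = NULL),
                     class = "de_result"))
  }
  keep <- grp %in% keep_groups
  a <- row_anova(dataset$values[, keep, drop = FALSE], grp[keep])
  q <- rep(NA_real_, length(a$p))
  q[!a$untestable] <- bh_fdr(a$p[!a$untestable])
  crit <- if (threshold_on == "q") q else a$p
  is_de <- !is.na(crit) & !a$untestable & crit < q_threshold
  structure(list(dataset_id = dataset$dataset_id, tissue = dataset$tissue,
                 testable = TRUE,
                 table = data.frame(gene_id = rownames(dataset$values),
                                    F = a$F, p = a$p, q = q, is_DE = is_de,
                                    stringsAsFactors = FALSE)),
            class = "de_result")
}

#' @export
print.de_result <- function(x, ...) {
  cat("<de_result> ", x$dataset_id, " (", x$tissue, "): ",
      if (x$testable) paste0(sum(x$table$is_DE), " / ", nrow(x$table),
                             " genes DE")
      else "untestable", "\n", sep = "")
  invisible(x)
}

#' Run the DE scan over a whole collection
#'
#' @param collection A \code{dataset_collection}.
#' @param q_threshold,threshold_on Passed to \code{\link{de_flags}}.
#' @return Named list of \code{de_result}, one per dataset.
#' @export
de_scan <- function(collection, q_threshold = 0.001,
                    threshold_on = c("q", "p")) {
  threshold_on <- match.arg(threshold_on)
  lapply(collection$datasets, de_flags, q_threshold = q_threshold,
         threshold_on = threshold_on)
}

#' Cross-dataset DE-frequency table per tissue
#'
#' For each gene and tissue, the fraction of that tissue's testable
#' datasets in which the gene was flagged DE. Datasets not containing a
#' gene are excluded from that gene's denominator; tissues with zero
#' testable datasets are omitted with a warning.
#'
#' @param results List of \code{de_result} (one per dataset, e.g. from
#'   \code{\link{de_scan}}).
#' @param collection The \code{dataset_collection} the results came from.
#' @param tissues Tissue labels to tally; defaults to all non-"mixed"
#'   tissues present in the collection.
#' @return data.frame with columns \code{gene_id}, \code{tissue},
#'   \code{n_de}, \code{n_datasets}, \code{frequency}.
#' @export
de_frequency <- function(results, collection, tissues = NULL) {
  ids <- vapply(results, function(r) r$dataset_id, character(1L))
  if (!all(ids %in% names(collection$datasets)))
    stop("every de_result must correspond to a dataset in the collection")
  tiss <- collection_tissues(collection)[ids]
  if (is.null(tissues)) tissues <- sort(unique(tiss[tiss != "mixed"]))
  out <- list()
  for (tt in tissues) {
    sel <- which(tiss == tt & vapply(results, `[[`, logical(1L), "testable"))
    if (!length(sel)) {
      warning("tissue '", tt, "' has no testable datasets; omitted")
      next
    }
    rows <- do.call(rbind, lapply(sel, function(i) {
      tab <- results[[i]]$table
      tab[!is.na(tab$q), c("gene_id", "is_DE")]
    }))
    if (!nrow(rows)) next
    n_ds <- rowsum(rep(1L, nrow(rows)), rows$gene_id)
    n_de <- rowsum(as.integer(rows$is_DE), rows$gene_id)
    genes <- rownames(n_ds)
    out[[tt]] <- data.frame(gene_id = genes, tissue = tt,
                            n_de = as.integer(n_de[, 1L]),
                            n_datasets = as.integer(n_ds[, 1L]),
                            frequency = n_de[, 1L] / n_ds[, 1L],
                            stringsAsFactors = FALSE, row.names = NULL)
  }
  if (!length(out))
    return(data.frame(gene_id = character(0), tissue = character(0),
                      n_de = integer(0), n_datasets = integer(0),
                      frequency = numeric(0)))
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}
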