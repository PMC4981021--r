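#' Pearson correlation between two expression vectors
#'
#' Sample Pearson correlation, the per-dataset coexpression weight r_k.
#' If either vector has zero variance the correlation is undefined and
#' \code{NA} is returned; averaged tables simply exclude such datasets.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return Correlation in [-1, 1], or \code{NA} when undefined.
#' @export
pearson <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3L)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y)
}

#' Per-dataset correlations between focal genes and all genes
#'
#' One Pearson correlation per (focal gene, gene) pair over ALL samples of
#' the dataset, pooling replicate groups. Focal genes absent from the
#' dataset yield no rows; pairs involving a zero-variance gene are
#' \code{NA}.
#'
#' @param dataset An \code{expression_dataset}.
#' @param focal Character vector of focal gene IDs.
#' @return Numeric matrix (present focal genes x dataset genes) of
#'   correlation weights, \code{NA} where undefined.
#' @export
per_dataset_correlations <- function(dataset, focal) {
  stopifnot(inherits(dataset, "expression_dataset"))
  present <- intersect(focal, rownames(dataset$values))
  if (!length(present))
    return(matrix(numeric(0), nrow = 0L, ncol = nrow(dataset$values),
                  dimnames = list(NULL, rownames(dataset$values))))
  vals <- dataset$values
  sds <- sqrt(rowSums((vals - rowMeans(vals))^2) / (ncol(vals) - 1L))
  r <- suppressWarnings(stats::cor(t(vals[present, , drop = FALSE]),
                                   t(vals)))
  r[sds[present] == 0, ] <- NA_real_
  r[, sds == 0] <- NA_real_
  rownames(r) <- present
  r
}

# Sum of defined r_k and contributing-dataset counts over a subset of
# datasets, on the focal x universe grid.
accumulate_correlations <- function(collection, focal, dataset_ids) {
  universe <- collection$gene_universe
  rsum <- matrix(0, length(focal), length(universe),
                 dimnames = list(focal, universe))
  cnt <- matrix(0L, length(focal), length(universe),
                dimnames = list(focal, universe))
  for (id in dataset_ids) {
    r <- per_dataset_correlations(collection$datasets[[id]], focal)
    if (!nrow(r)) next
    ok <- !is.na(r)
    r[!ok] <- 0
    fi <- rownames(r)
    rsum[fi, colnames(r)] <- rsum[fi, colnames(r), drop = FALSE] + r
    cnt[fi, colnames(r)] <- cnt[fi, colnames(r), drop = FALSE] + ok
  }
  list(rsum = rsum, support = cnt)
}

#' Dataset-averaged (or tissue-stratified) coexpression table
#'
#' The meta-analytic coexpression weight R between a focal gene x and gene
#' i is the arithmetic mean of the per-dataset Pearson weights r_k over the
#' datasets in which the pair is defined. With \code{stratum = "all"} every
#' dataset of the collection contributes; with a tissue label, only the
#' datasets whose (unanimous) tissue matches. \code{support} counts the
#' contributing datasets per pair; pairs defined in zero datasets get no
#' row.
#'
#' @param collection A \code{dataset_collection}.
#' @param focal Character vector of focal gene IDs.
#' @param stratum \code{"all"} or a tissue label.
#' @return A \code{coexpression_table}: data.frame with columns
#'   \code{focal}, \code{gene}, \code{stratum}, \code{R}, \code{support}.
#' @export
average_coexpression <- function(collection, focal, stratum = "all") {
  stopifnot(inherits(collection, "dataset_collection"),
            length(collection) >= 1L, length(stratum) == 1L)
  ids <- names(collection$datasets)
  if (!identical(stratum, "all")) {
    ids <- ids[collection_tissues(collection)[ids] == stratum]
    if (!length(ids))
      stop("no dataset in the collection has tissue '", stratum, "'")
  }
  acc <- accumulate_correlations(collection, focal, ids)
  keep <- which(acc$support > 0L, arr.ind = TRUE)
  tab <- data.frame(
    focal = rownames(acc$support)[keep[, 1L]],
    gene = colnames(acc$support)[keep[, 2L]],
    stratum = stratum,
    R = acc$rsum[keep] / acc$support[keep],
    support = as.integer(acc$support[keep]),
    stringsAsFactors = FALSE)
  tab <- tab[order(tab$focal, tab$gene), , drop = FALSE]
  rownames(tab) <- NULL
  class(tab) <- c("coexpression_table", "data.frame")
  tab
}

#' Critical Pearson correlation for a given sample size
#'
#' The smallest |r| significant at two-sided level alpha under the exact
#' null distribution of the sample correlation of bivariate-normal data:
#' r* = t* / sqrt(t*^2 + n - 2), with t* the two-sided alpha critical
#' value of Student's t on n - 2 degrees of freedom. The threshold falls
#' steeply with sample size (about 0.63 at n = 10 but 0.20 at n = 100),
#' which is why a single fixed PCC cutoff is not comparable across
#' datasets of different size.
#'
#' @param n Sample size (>= 3).
#' @param alpha Two-sided significance level in (0, 1).
#' @return The critical correlation in (0, 1).
#' @export
critical_pcc <- function(n, alpha = 0.05) {
  if (n < 3L) stop("critical_pcc needs n >= 3")
  stopifnot(alpha > 0, alpha < 1)
  tstar <- stats::qt(1 - alpha / 2, df = n - 2)
  tstar / sqrt(tstar^2 + n - 2)
}
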