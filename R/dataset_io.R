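#' Construct an expression dataset
#'
#' An \code{expression_dataset} holds one normalized genes x samples
#' expression matrix (one GEO-series analog) together with per-sample
#' replicate-group labels and a dataset-level tissue label. Values are
#' assumed already normalized on a log scale (e.g. RMA output); the package
#' performs no normalization of its own.
#'
#' The dataset-level tissue is \code{"mixed"} unless every sample carries the
#' same tissue label, in which case it is that label. Tissue-stratified
#' statistics use only datasets with a single (non-\code{"mixed"}) tissue.
#'
#' @param dataset_id Character scalar identifying the dataset.
#' @param values Numeric matrix, genes in rows (rownames = gene IDs),
#'   samples in columns (colnames = sample IDs). All values must be finite.
#' @param replicate_group Character vector of per-sample replicate-group
#'   labels, one per column of \code{values}.
#' @param sample_tissue Character vector of per-sample tissue labels, one
#'   per column of \code{values}.
#' @return An object of class \code{expression_dataset}: a list with
#'   elements \code{dataset_id}, \code{values}, \code{replicate_group},
#'   \code{sample_tissue} and \code{tissue} (the derived dataset-level
#'   label).
#' @export
expression_dataset <- function(dataset_id, values, replicate_group,
                               sample_tissue) {
  stopifnot(is.character(dataset_id), length(dataset_id) == 1L)
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  genes <- rownames(values)
  samples <- colnames(values)
  if (is.null(genes) || is.null(samples))
    stop("'values' must have gene rownames and sample colnames")
  if (anyDuplicated(genes))
    stop("duplicate gene ID in dataset '", dataset_id, "': ",
         genes[duplicated(genes)][1L])
  if (anyDuplicated(samples))
    stop("duplicate sample ID in dataset '", dataset_id, "': ",
         samples[duplicated(samples)][1L])
  if (!all(is.finite(values)))
    stop("non-finite expression value in dataset '", dataset_id, "'")
  if (length(replicate_group) != ncol(values))
    stop("replicate_group must have one entry per sample")
  if (length(sample_tissue) != ncol(values))
    stop("sample_tissue must have one entry per sample")
  replicate_group <- as.character(replicate_group)
  sample_tissue <- as.character(sample_tissue)
  tissue <- if (length(unique(sample_tissue)) == 1L) sample_tissue[1L]
            else "mixed"
  structure(
    list(dataset_id = dataset_id, values = values,
         replicate_group = stats::setNames(replicate_group, samples),
         sample_tissue = stats::setNames(sample_tissue, samples),
         tissue = tissue),
    class = "expression_dataset")
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat("<expression_dataset> ", x$dataset_id, ": ",
      nrow(x$values), " genes x ", ncol(x$values), " samples, ",
      length(unique(x$replicate_group)), " replicate groups, tissue '",
      x$tissue, "'\n", sep = "")
  invisible(x)
}

#' Number of samples in a dataset
#' @param dataset An \code{expression_dataset}.
#' @return Integer sample count.
#' @export
n_samples <- function(dataset) ncol(dataset$values)

#' Read an expression dataset from TSV files
#'
#' The matrix file is tab-delimited with a header row: first column
#' \code{gene_id}, remaining columns sample IDs. The metadata file is
#' tab-delimited with columns \code{sample_id}, \code{replicate_group},
#' \code{tissue}. Every matrix sample must appear in the metadata.
#'
#' @param matrix_path Path to the expression matrix TSV.
#' @param metadata_path Path to the sample metadata TSV.
#' @param dataset_id Dataset identifier; defaults to the matrix file name
#'   without extension.
#' @return An \code{expression_dataset}.
#' @export
read_expression_dataset <- function(matrix_path, metadata_path,
                                    dataset_id = NULL) {
  if (is.null(dataset_id))
    dataset_id <- sub("\\.[^.]*$", "", basename(matrix_path))
  tab <- utils::read.delim(matrix_path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character")
  if (ncol(tab) < 2L)
    stop("matrix file '", matrix_path, "' needs a gene_id column and at ",
         "least one sample column")
  genes <- tab[[1L]]
  if (anyDuplicated(genes))
    stop("duplicate gene ID '", genes[duplicated(genes)][1L],
         "' in '", matrix_path, "'")
  vals <- as.matrix(tab[, -1L, drop = FALSE])
  num <- suppressWarnings(array(as.numeric(vals), dim = dim(vals)))
  if (anyNA(num)) {
    bad <- which(is.na(num), arr.ind = TRUE)[1L, ]
    stop("non-numeric cell in '", matrix_path, "' at gene row ",
         bad[["row"]], " (", genes[bad[["row"]]], "), sample column '",
         colnames(vals)[bad[["col"]]], "'")
  }
  dimnames(num) <- list(genes, colnames(vals))

  meta <- utils::read.delim(metadata_path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
  need <- c("sample_id", "replicate_group", "tissue")
  if (!all(need %in% names(meta)))
    stop("metadata '", metadata_path, "' must have columns ",
         paste(need, collapse = ", "))
  missing <- setdiff(colnames(num), meta$sample_id)
  if (length(missing))
    stop("sample '", missing[1L], "' of '", matrix_path,
         "' is missing from metadata '", metadata_path, "'")
  idx <- match(colnames(num), meta$sample_id)
  expression_dataset(dataset_id, num,
                     replicate_group = meta$replicate_group[idx],
                     sample_tissue = meta$tissue[idx])
}

#' Write an expression dataset to TSV files
#'
#' Inverse of \code{\link{read_expression_dataset}}: round-tripping
#' reproduces IDs, labels and values to full precision.
#'
#' @param dataset An \code{expression_dataset}.
#' @param matrix_path,metadata_path Output paths.
#' @return Invisibly, the dataset.
#' @export
write_expression_dataset <- function(dataset, matrix_path, metadata_path) {
  df <- data.frame(gene_id = rownames(dataset$values),
                   dataset$values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                     matrix_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  meta <- data.frame(sample_id = colnames(dataset$values),
                     replicate_group = unname(dataset$replicate_group),
                     tissue = unname(dataset$sample_tissue),
                     stringsAsFactors = FALSE)
  utils::write.table(meta, metadata_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(dataset)
}

#' Construct a dataset collection
#'
#' A \code{dataset_collection} is the ordered set of expression datasets the
#' meta-analysis iterates over; the gene universe is the union of gene IDs
#' across member datasets. Pairwise statistics later use only the datasets
#' in which both genes are measured.
#'
#' @param datasets A list of \code{expression_dataset} objects with unique
#'   \code{dataset_id}s.
#' @return An object of class \code{dataset_collection} with elements
#'   \code{datasets} (named list) and \code{gene_universe}.
#' @export
dataset_collection <- function(datasets) {
  stopifnot(is.list(datasets))
  ok <- vapply(datasets, inherits, logical(1L), "expression_dataset")
  if (length(datasets) && !all(ok))
    stop("all elements must be expression_dataset objects")
  ids <- vapply(datasets, function(d) d$dataset_id, character(1L))
  if (anyDuplicated(ids))
    stop("duplicate dataset_id: ", ids[duplicated(ids)][1L])
  names(datasets) <- ids
  universe <- sort(unique(unlist(lapply(datasets,
                                        function(d) rownames(d$values)))))
  structure(list(datasets = datasets,
                 gene_universe = if (is.null(universe)) character(0)
                                 else universe),
            class = "dataset_collection")
}

#' @export
print.dataset_collection <- function(x, ...) {
  cat("<dataset_collection> ", length(x$datasets), " datasets, ",
      length(x$gene_universe), " genes in universe\n", sep = "")
  invisible(x)
}

#' @export
length.dataset_collection <- function(x) length(x$datasets)

#' Filter a collection by minimum sample count
#'
#' Retains, in their original order, only the datasets with at least
#' \code{min_samples} samples. The default of 12 mirrors the usual
#' inclusion rule for multi-dataset coexpression corpora, where short series
#' give unstable correlation estimates.
#'
#' @param collection A \code{dataset_collection}.
#' @param min_samples Minimum number of samples (>= 2).
#' @return The filtered \code{dataset_collection} (possibly empty); the gene
#'   universe is recomputed over the retained datasets.
#' @export
filter_collection <- function(collection, min_samples = 12L) {
  stopifnot(inherits(collection, "dataset_collection"),
            min_samples >= 2L)
  keep <- vapply(collection$datasets, n_samples, integer(1L)) >= min_samples
  dataset_collection(collection$datasets[keep])
}

#' Read a collection from a directory of TSV pairs
#'
#' Expects files \code{<id>.matrix.tsv} + \code{<id>.metadata.tsv} per
#' dataset, as written by \code{\link{write_collection}}.
#'
#' @param dir Directory path.
#' @return A \code{dataset_collection}.
#' @export
read_collection <- function(dir) {
  mats <- sort(list.files(dir, pattern = "\\.matrix\\.tsv$",
                          full.names = TRUE))
  if (!length(mats)) stop("no *.matrix.tsv files found in '", dir, "'")
  datasets <- lapply(mats, function(m) {
    id <- sub("\\.matrix\\.tsv$", "", basename(m))
    read_expression_dataset(m, file.path(dir, paste0(id, ".metadata.tsv")),
                            dataset_id = id)
  })
  dataset_collection(datasets)
}

#' Write a collection to a directory of TSV pairs
#'
#' @param collection A \code{dataset_collection}.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the collection.
#' @export
write_collection <- function(collection, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (d in collection$datasets)
    write_expression_dataset(
      d, file.path(dir, paste0(d$dataset_id, ".matrix.tsv")),
      file.path(dir, paste0(d$dataset_id, ".metadata.tsv")))
  invisible(collection)
}

#' Construct a pathway database
#'
#' Named gene sets (a GO Biological Process stand-in) restricted to a gene
#' universe. Memberships are deduplicated; sets emptied by the restriction
#' are dropped with a warning.
#'
#' @param sets Named list of character vectors of member gene IDs.
#' @param universe Character vector of gene IDs to restrict to, or NULL for
#'   no restriction.
#' @param descriptions Optional named character vector of descriptions.
#' @return An object of class \code{pathway_db}: list with \code{sets}
#'   (named list, restricted and deduplicated), \code{description} and
#'   \code{m} (named integer in-universe sizes).
#' @export
pathway_db <- function(sets, universe = NULL, descriptions = NULL) {
  stopifnot(is.list(sets), !is.null(names(sets)))
  if (anyDuplicated(names(sets)))
    stop("duplicate pathway_id: ", names(sets)[duplicated(names(sets))][1L])
  sets <- lapply(sets, function(s) unique(as.character(s)))
  if (!is.null(universe))
    sets <- lapply(sets, intersect, y = universe)
  empty <- lengths(sets) == 0L
  if (any(empty)) {
    warning("dropping ", sum(empty),
            " pathway(s) with no members in the gene universe: ",
            paste(utils::head(names(sets)[empty], 5L), collapse = ", "))
    sets <- sets[!empty]
  }
  if (is.null(descriptions))
    descriptions <- stats::setNames(rep("", length(sets)), names(sets))
  structure(list(sets = sets,
                 description = descriptions[names(sets)],
                 m = stats::setNames(lengths(sets), names(sets))),
            class = "pathway_db")
}

#' @export
print.pathway_db <- function(x, ...) {
  cat("<pathway_db> ", length(x$sets), " gene sets, sizes ",
      if (length(x$sets)) paste0(min(x$m), "-", max(x$m)) else "-",
      "\n", sep = "")
  invisible(x)
}

#' Read gene sets from a GMT file
#'
#' Standard GMT: one set per line, tab-delimited, fields name, description,
#' then member gene IDs. Lines with fewer than three fields are a hard
#' error (reported with the line number).
#'
#' @param gmt_path Path to the GMT file.
#' @param universe Optional gene universe to restrict members to.
#' @return A \code{pathway_db}.
#' @export
read_gene_sets <- function(gmt_path, universe = NULL) {
  lines <- readLines(gmt_path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3L)
  if (length(short))
    stop("malformed GMT line ", short[1L], " in '", gmt_path,
         "': fewer than 3 tab-delimited fields")
  ids <- vapply(fields, `[[`, character(1L), 1L)
  desc <- stats::setNames(vapply(fields, `[[`, character(1L), 2L), ids)
  sets <- stats::setNames(lapply(fields, function(f) f[-(1:2)]), ids)
  pathway_db(sets, universe = universe, descriptions = desc)
}

#' Write gene sets to a GMT file
#'
#' @param db A \code{pathway_db}.
#' @param gmt_path Output path.
#' @return Invisibly, the db.
#' @export
write_gene_sets <- function(db, gmt_path) {
  lines <- vapply(names(db$sets), function(id) {
    paste(c(id, db$description[[id]], db$sets[[id]]), collapse = "\t")
  }, character(1L))
  writeLines(lines, gmt_path)
  invisible(db)
}

#' Tissue label of each dataset in a collection
#'
#' @param collection A \code{dataset_collection}.
#' @return Named character vector (dataset_id -> tissue; \code{"mixed"} for
#'   datasets whose samples span tissues).
#' @export
collection_tissues <- function(collection) {
  vapply(collection$datasets, function(d) d$tissue, character(1L))
}
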