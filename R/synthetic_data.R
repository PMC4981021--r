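#' Configuration for a synthetic dataset collection
#'
#' Describes a collection of independent expression datasets with known
#' planted structure, standing in for a corpus of normalized microarray
#' series. Each dataset is a genes x samples Gaussian matrix on a log-like
#' expression scale: background genes are i.i.d. noise around gene-specific
#' baselines, planted partner genes are generated from their focal gene's
#' standardized latent so that the population Pearson correlation equals the
#' requested rho within datasets matching the tissue restriction (and 0
#' elsewhere), and planted DE genes receive a between-replicate-group mean
#' shift delta in matching datasets.
#'
#' @param n_datasets Number of datasets.
#' @param samples_per_dataset Samples per dataset (default 12, the usual
#'   corpus inclusion minimum).
#' @param n_groups Replicate groups per dataset (consecutive blocks of
#'   samples, as equal as possible; each must have >= 2 samples).
#' @param n_genes Number of genes in the shared universe.
#' @param focal_genes Character vector of focal gene IDs (must be among the
#'   generated gene IDs \code{g0001 ...}); defaults to the first gene.
#' @param tissue_labels Per-dataset tissue labels, recycled to
#'   \code{n_datasets}. All samples of a dataset share its label.
#' @param planted_partners List of planting specs, each a list with fields
#'   \code{focal} (gene ID), \code{partners} (gene IDs), \code{rho}
#'   (population correlation, |rho| < 1) and \code{tissue} (a tissue label,
#'   or \code{"all"} to plant in every dataset).
#' @param planted_de List of DE specs, each a list with fields \code{gene},
#'   \code{delta} (mean shift, expression units) and \code{tissue} (label or
#'   \code{"all"}). The shift is added to even-numbered replicate groups.
#' @param noise_sd Residual standard deviation (expression units).
#' @param baseline_range Range of the uniform gene-specific baselines.
#' @param seed Integer seed; the collection is fully reproducible from it.
#' @return A \code{simulation_config} list.
#' @export
simulation_config <- function(n_datasets, samples_per_dataset = 12L,
                              n_groups = 2L, n_genes = 100L,
                              focal_genes = NULL, tissue_labels = "mixed",
                              planted_partners = list(),
                              planted_de = list(), noise_sd = 1,
                              baseline_range = c(4, 12), seed = 1L) {
  stopifnot(n_datasets >= 1L, samples_per_dataset >= 2L * n_groups,
            n_groups >= 1L, n_genes >= 2L, noise_sd > 0,
            length(seed) == 1L, is.finite(seed))
  gene_ids <- gene_id_vector(n_genes)
  if (is.null(focal_genes)) focal_genes <- gene_ids[1L]
  if (!all(focal_genes %in% gene_ids))
    stop("focal_genes must be among the generated gene IDs")
  tissue_labels <- rep_len(as.character(tissue_labels), n_datasets)
  for (pp in planted_partners) {
    stopifnot(all(c("focal", "partners", "rho") %in% names(pp)))
    if (abs(pp$rho) >= 1) stop("planted |rho| must be < 1")
    if (!pp$focal %in% focal_genes)
      stop("planted partner focal '", pp$focal, "' is not a focal gene")
    if (!all(pp$partners %in% gene_ids) || pp$focal %in% pp$partners)
      stop("planted partners must be non-focal genes of the universe")
  }
  for (pd in planted_de) {
    stopifnot(all(c("gene", "delta") %in% names(pd)))
    if (!all(pd$gene %in% gene_ids))
      stop("planted DE gene outside the gene universe")
  }
  structure(list(n_datasets = as.integer(n_datasets),
                 samples_per_dataset = as.integer(samples_per_dataset),
                 n_groups = as.integer(n_groups),
                 n_genes = as.integer(n_genes),
                 gene_ids = gene_ids, focal_genes = focal_genes,
                 tissue_labels = tissue_labels,
                 planted_partners = planted_partners,
                 planted_de = planted_de, noise_sd = noise_sd,
                 baseline_range = baseline_range,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

gene_id_vector <- function(n_genes) {
  sprintf(paste0("g%0", max(4L, nchar(n_genes)), "d"), seq_len(n_genes))
}

# Substream scheme: gene baselines use set.seed(seed); dataset k uses
# set.seed((seed + 92821 * k) mod (2^31 - 1)). Adding datasets therefore
# never perturbs earlier ones.
dataset_seed <- function(seed, k) {
  as.integer((as.double(seed) + 92821 * k) %% 2147483647)
}

#' Generate a synthetic dataset collection with planted structure
#'
#' See \code{\link{simulation_config}} for the generative model. The
#' planted correlation is enforced at the population level only; sample
#' correlations scatter around rho with the usual Fisher-z spread, so
#' recovery checks must use tolerance bands.
#'
#' @param config A \code{simulation_config}.
#' @return A \code{dataset_collection}. The planted ground truth is
#'   attached as \code{attr(, "ground_truth")}, a list of two data frames:
#'   \code{partners} (focal, partner, rho, tissue) and \code{de}
#'   (gene, delta, tissue).
#' @export
generate_collection <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  ng <- config$n_genes
  ns <- config$samples_per_dataset
  set.seed(config$seed)
  baseline <- stats::runif(ng, config$baseline_range[1L],
                           config$baseline_range[2L])
  grp <- rep(seq_len(config$n_groups), length.out = ns)
  grp <- sort(grp)  # consecutive blocks, sizes as equal as possible
  gidx <- stats::setNames(seq_len(ng), config$gene_ids)

  datasets <- vector("list", config$n_datasets)
  for (k in seq_len(config$n_datasets)) {
    set.seed(dataset_seed(config$seed, k))
    tissue <- config$tissue_labels[k]
    z <- matrix(stats::rnorm(ng * ns), nrow = ng, ncol = ns)
    # Deterministic DE shift matrix (latent units; expression-scale shift
    # is delta), assembled before partner construction: a partner is built
    # from its focal gene's standardized SHIFTED latent, so the population
    # correlation equals rho even when the focal gene also carries a
    # planted group shift.
    shift_pattern <- ifelse(grp %% 2L == 0L, 1, 0)
    shifts <- matrix(0, nrow = ng, ncol = ns)
    for (pd in config$planted_de) {
      if (!identical(pd$tissue %||% "all", "all") &&
          !identical(pd$tissue, tissue)) next
      shifts[gidx[pd$gene], ] <- shifts[gidx[pd$gene], , drop = FALSE] +
        (pd$delta / config$noise_sd) *
        matrix(shift_pattern, length(pd$gene), ns, byrow = TRUE)
    }
    lat <- z
    for (pp in config$planted_partners) {
      if (!identical(pp$tissue %||% "all", "all") &&
          !identical(pp$tissue, tissue)) next
      fi <- gidx[[pp$focal]]
      pidx <- gidx[pp$partners]
      mu <- mean(shifts[fi, ])
      s2 <- 1 + mean((shifts[fi, ] - mu)^2)    # population variance
      u <- (z[fi, ] + shifts[fi, ] - mu) / sqrt(s2)
      lat[pidx, ] <- pp$rho * matrix(u, length(pidx), ns, byrow = TRUE) +
        sqrt(1 - pp$rho^2) * z[pidx, , drop = FALSE]
    }
    vals <- baseline + config$noise_sd * (lat + shifts)
    id <- sprintf("DS%03d", k)
    dimnames(vals) <- list(config$gene_ids,
                           sprintf("%s_s%02d", id, seq_len(ns)))
    datasets[[k]] <- expression_dataset(
      id, vals, replicate_group = paste0("grp", grp),
      sample_tissue = rep(tissue, ns))
  }
  coll <- dataset_collection(datasets)
  attr(coll, "ground_truth") <- ground_truth_tables(config)
  coll
}

ground_truth_tables <- function(config) {
  partners <- do.call(rbind, lapply(config$planted_partners, function(pp) {
    data.frame(focal = pp$focal, partner = pp$partners, rho = pp$rho,
               tissue = pp$tissue %||% "all", stringsAsFactors = FALSE)
  }))
  de <- do.call(rbind, lapply(config$planted_de, function(pd) {
    data.frame(gene = pd$gene, delta = pd$delta,
               tissue = pd$tissue %||% "all", stringsAsFactors = FALSE)
  }))
  empty_p <- data.frame(focal = character(0), partner = character(0),
                        rho = numeric(0), tissue = character(0))
  empty_d <- data.frame(gene = character(0), delta = numeric(0),
                        tissue = character(0))
  list(partners = if (is.null(partners)) empty_p else partners,
       de = if (is.null(de)) empty_d else de)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Random pathway database over a gene universe
#'
#' Draws named gene sets uniformly from the universe — a null-structure
#' stand-in for a curated gene-set collection, used for permutation-null
#' calibration and simulated pipeline runs.
#'
#' @param universe Character vector of gene IDs.
#' @param n_pathways Number of sets.
#' @param size_range Integer range of set sizes (inclusive).
#' @param seed Integer seed.
#' @return A \code{pathway_db}.
#' @export
random_pathway_db <- function(universe, n_pathways = 20L,
                              size_range = c(5L, 20L), seed) {
  stopifnot(length(universe) >= max(size_range), n_pathways >= 1L)
  sets <- with_local_seed(seed, {
    sizes <- sample(size_range[1L]:size_range[2L], n_pathways,
                    replace = TRUE)
    lapply(sizes, function(m) sample(universe, m))
  })
  names(sets) <- sprintf("PW%03d", seq_len(n_pathways))
  pathway_db(sets, universe = universe)
}

#' Write a simulated collection plus its ground-truth manifest
#'
#' Writes the matrix/metadata TSV pair per dataset and two manifest TSVs
#' (\code{ground_truth_partners.tsv}, \code{ground_truth_de.tsv}).
#'
#' @param config A \code{simulation_config}.
#' @param dir Output directory.
#' @return Invisibly, the generated \code{dataset_collection}.
#' @export
simulate_to_dir <- function(config, dir) {
  coll <- generate_collection(config)
  write_collection(coll, dir)
  gt <- attr(coll, "ground_truth")
  utils::write.table(gt$partners,
                     file.path(dir, "ground_truth_partners.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(gt$de, file.path(dir, "ground_truth_de.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(coll)
}
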