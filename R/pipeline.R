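#' Assemble a pipeline configuration
#'
#' Defaults follow the usual corpus-mining conventions: datasets with
#' fewer than 12 samples are excluded, DE means BH q < 0.001, gene
#' networks keep the top 20 partners per focal gene, pathway networks keep
#' the top 10 significant pathways per focal gene with edges supported by
#' at least 5 datasets of the tissue, and the permutation null uses
#' B = 100 replicates.
#'
#' @param focal_genes Character vector of focal gene IDs.
#' @param input_dir Directory of matrix/metadata TSV pairs (see
#'   \code{\link{read_collection}}); mutually exclusive with
#'   \code{simulation}.
#' @param simulation A \code{\link{simulation_config}}, to generate the
#'   input collection instead of reading one.
#' @param gmt_path Path to a GMT gene-set file; if NULL and
#'   \code{simulation} is given, a seeded random pathway database with
#'   \code{n_random_pathways} sets is used.
#' @param min_samples,de_threshold,de_threshold_on Collection filter and
#'   DE-scan parameters; see \code{\link{filter_collection}} and
#'   \code{\link{de_flags}}.
#' @param top_k_genes,top_pathways,min_support,rank_by_abs Network
#'   assembly parameters; see \code{\link{build_gene_network}} and
#'   \code{\link{build_pathway_network}}.
#' @param B,alpha Permutation replicate count and nominal significance
#'   level conventions.
#' @param n_random_pathways Number of random gene sets when no GMT is
#'   supplied for a simulated run.
#' @param seed Integer seed for every stochastic stage (mandatory).
#' @return A \code{pipeline_config} list.
#' @export
pipeline_config <- function(focal_genes = NULL, input_dir = NULL,
                            simulation = NULL, gmt_path = NULL,
                            min_samples = 12L, de_threshold = 0.001,
                            de_threshold_on = "q", top_k_genes = 20L,
                            top_pathways = 10L, min_support = 5L,
                            B = 100L, alpha = 0.05, rank_by_abs = FALSE,
                            n_random_pathways = 20L, seed) {
  if (is.null(input_dir) == is.null(simulation))
    stop("exactly one of 'input_dir' or 'simulation' must be given")
  if (missing(seed)) stop("'seed' is mandatory")
  if (is.null(focal_genes) && !is.null(simulation))
    focal_genes <- simulation$focal_genes
  if (is.null(focal_genes)) stop("'focal_genes' is required")
  stopifnot(min_samples >= 2L, de_threshold > 0, de_threshold <= 1,
            top_k_genes >= 1L, top_pathways >= 1L, min_support >= 1L,
            B >= 1L, alpha > 0, alpha < 1)
  structure(list(focal_genes = focal_genes, input_dir = input_dir,
                 simulation = simulation, gmt_path = gmt_path,
                 min_samples = as.integer(min_samples),
                 de_threshold = de_threshold,
                 de_threshold_on = match.arg(de_threshold_on, c("q", "p")),
                 top_k_genes = as.integer(top_k_genes),
                 top_pathways = as.integer(top_pathways),
                 min_support = as.integer(min_support),
                 B = as.integer(B), alpha = alpha,
                 rank_by_abs = isTRUE(rank_by_abs),
                 n_random_pathways = as.integer(n_random_pathways),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Flat keys mirror the \code{\link{pipeline_config}} arguments; an
#' optional nested \code{simulation:} block mirrors
#' \code{\link{simulation_config}}.
#'
#' @param path YAML config file.
#' @return A \code{pipeline_config}.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$simulation))
    raw$simulation <- do.call(simulation_config, raw$simulation)
  do.call(pipeline_config, raw)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  nrow(df)
}

#' Run the full coexpression-mining pipeline
#'
#' Stages, in order: acquire the collection (simulate or read), filter by
#' minimum sample count, per-dataset DE scan plus tissue DE frequencies,
#' dataset-averaged and tissue-stratified coexpression, permutation-tested
#' pathway scores, network assembly (top-k gene network and tissue
#' pathway network, GraphML + TSV), and over-representation analysis of
#' the gene-network members. Every intermediate table is written as TSV
#' under \code{out_dir}; a JSON manifest records the config hash, seed,
#' per-stage row counts and runtime. Reruns with identical config and
#' seed reproduce identical outputs.
#'
#' @param config A \code{pipeline_config}.
#' @param out_dir Output directory (created if absent).
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  t0 <- Sys.time()
  stages <- list()
  current <- "setup"
  mark <- function(name, rows) {
    stages[[name]] <<- list(status = "complete", rows = rows,
                            seconds = round(as.numeric(
                              difftime(Sys.time(), t0, units = "secs")), 3L))
  }
  cfg_path <- file.path(out_dir, "run_config.yaml")
  writeLines(yaml::as.yaml(unclass_config(config)), cfg_path)

  tryCatch({
    current <- "acquire"
    coll <- if (!is.null(config$simulation))
      generate_collection(config$simulation)
    else read_collection(config$input_dir)
    mark("acquire", length(coll))

    current <- "filter"
    coll <- filter_collection(coll, config$min_samples)
    mark("filter", length(coll))

    current <- "deg"
    if (length(coll) == 0L)
      stop("no dataset passed the min_samples = ", config$min_samples,
           " filter; nothing to analyze")
    de <- de_scan(coll, q_threshold = config$de_threshold,
                  threshold_on = config$de_threshold_on)
    de_tab <- do.call(rbind, lapply(de, function(r) {
      if (!r$testable) return(NULL)
      cbind(dataset_id = r$dataset_id, r$table)
    }))
    write_tsv(de_tab, file.path(out_dir, "de_results.tsv"))
    freq <- suppressWarnings(de_frequency(de, coll))
    mark("deg", write_tsv(freq, file.path(out_dir, "de_frequency.tsv")))

    current <- "coexpress"
    tiss <- unique(collection_tissues(coll))
    tiss <- sort(tiss[tiss != "mixed"])
    coex <- do.call(rbind, c(
      list(average_coexpression(coll, config$focal_genes, "all")),
      lapply(tiss, function(tt)
        average_coexpression(coll, config$focal_genes, tt))))
    mark("coexpress",
         write_tsv(coex, file.path(out_dir, "coexpression.tsv")))

    current <- "pathway"
    db <- if (!is.null(config$gmt_path))
      read_gene_sets(config$gmt_path, universe = coll$gene_universe)
    else random_pathway_db(coll$gene_universe,
                           n_pathways = config$n_random_pathways,
                           seed = config$seed)
    scores <- score_pathways(config$focal_genes, db, coll, de,
                             B = config$B, seed = config$seed)
    mark("pathway",
         write_tsv(scores, file.path(out_dir, "pathway_scores.tsv")))

    current <- "network"
    gnet <- build_gene_network(coex, config$focal_genes,
                               k = config$top_k_genes,
                               rank_by_abs = config$rank_by_abs)
    pnet <- build_pathway_network(scores, top = config$top_pathways,
                                  min_support = config$min_support)
    export_network(gnet, file.path(out_dir, "gene_network.graphml"),
                   "graphml")
    export_network(gnet, file.path(out_dir, "gene_network.tsv"), "tsv")
    export_network(pnet, file.path(out_dir, "pathway_network.graphml"),
                   "graphml")
    export_network(pnet, file.path(out_dir, "pathway_network.tsv"), "tsv")
    mark("network", nrow(gnet$edges) + nrow(pnet$edges))

    current <- "enrich"
    members <- gnet$nodes$id[gnet$nodes$node_type == "gene"]
    enr <- suppressWarnings(
      enrich(members, config$focal_genes, db, coll$gene_universe))
    mark("enrich", write_tsv(enr, file.path(out_dir, "enrichment.tsv")))
  }, error = function(e) {
    writeLines(paste0("stage '", current, "' failed: ",
                      conditionMessage(e)),
               file.path(out_dir, "FAILED"))
    stop("pipeline stage '", current, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })

  manifest <- list(config_md5 = unname(tools::md5sum(cfg_path)),
                   seed = config$seed, stages = stages,
                   runtime_seconds = round(as.numeric(
                     difftime(Sys.time(), t0, units = "secs")), 3L))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

# yaml-serializable view of the config (drops NULLs, flattens the
# simulation sub-config).
unclass_config <- function(config) {
  x <- unclass(config)
  if (!is.null(x$simulation)) {
    s <- unclass(x$simulation)
    s$gene_ids <- NULL
    x$simulation <- s
  }
  x[!vapply(x, is.null, logical(1L))]
}
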