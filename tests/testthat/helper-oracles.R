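# Independent brute-force oracles: straight-from-the-formula loops, kept
# deliberately naive and separate from the package implementation.

brute_pearson <- function(x, y) {
  mx <- sum(x) / length(x)
  my <- sum(y) / length(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# BH step-up by definition: q_i = min over j with p_(j) >= p_(i) of
# m * p_(j) / j, capped at 1.
brute_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    cand <- Inf
    for (j in seq_len(m)) {
      pj <- p[ord[j]]
      if (pj >= p[i] - 1e-15) cand <- min(cand, m * pj / j)
    }
    q[i] <- min(cand, 1)
  }
  q
}

# One-way ANOVA through R's linear-model machinery (independent route).
oracle_anova <- function(values_by_group) {
  df <- data.frame(y = unlist(values_by_group),
                   g = factor(rep(seq_along(values_by_group),
                                  lengths(values_by_group))))
  a <- stats::anova(stats::lm(y ~ g, df))
  list(F = a$`F value`[1L], p = a$`Pr(>F)`[1L])
}

# Averaged coexpression weight by definition: loop datasets, average defined r_k.
brute_average_R <- function(collection, x, i, dataset_ids) {
  rs <- c()
  for (id in dataset_ids) {
    d <- collection$datasets[[id]]
    if (!all(c(x, i) %in% rownames(d$values))) next
    vx <- d$values[x, ]
    vi <- d$values[i, ]
    if (stats::sd(vx) == 0 || stats::sd(vi) == 0) next
    rs <- c(rs, brute_pearson(vx, vi))
  }
  if (!length(rs)) return(list(R = NA_real_, support = 0L))
  list(R = sum(rs) / length(rs), support = length(rs))
}

# Pathway score by definition on DE-restricted tissue datasets.
brute_pathway_score <- function(collection, x, members, tissue,
                                de_results) {
  ids <- c()
  for (id in names(collection$datasets)) {
    d <- collection$datasets[[id]]
    r <- de_results[[id]]
    if (!identical(d$tissue, tissue) || !r$testable) next
    row <- match(x, r$table$gene_id)
    if (!is.na(row) && r$table$is_DE[row]) ids <- c(ids, id)
  }
  if (!length(ids)) return(NA_real_)
  vals <- c()
  for (k in members) {
    rk <- brute_average_R(collection, x, k, ids)
    if (rk$support > 0L) vals <- c(vals, rk$R)
  }
  if (!length(vals)) return(NA_real_)
  sum(vals) / length(vals)
}

brute_hyper_upper <- function(a, m, N, q) {
  # P(X >= a) by direct summation of the hypergeometric pmf
  total <- 0
  for (x in a:min(m, q))
    total <- total + choose(m, x) * choose(N - m, q - x) / choose(N, q)
  total
}

# Small deterministic hand-built fixtures -------------------------------

make_dataset <- function(id = "D1", values, groups, tissues) {
  expression_dataset(id, values, replicate_group = groups,
                     sample_tissue = tissues)
}

# a 3-gene x 4-sample dataset with simple integer expression
toy_dataset <- function(id = "D1", tissue = "root") {
  v <- rbind(g1 = c(1, 2, 3, 4),
             g2 = c(2, 4, 6, 8),
             g3 = c(1, 3, 2, 4))
  colnames(v) <- paste0(id, "_s", 1:4)
  make_dataset(id, v, groups = c("a", "a", "b", "b"),
               tissues = rep(tissue, 4))
}

# seeded small synthetic collection shared by several structural tests
toy_collection <- function(seed = 11, n_datasets = 4, n_genes = 12,
                           samples = 12, tissues = c("root", "leaf")) {
  generate_collection(simulation_config(
    n_datasets = n_datasets, samples_per_dataset = samples,
    n_genes = n_genes, tissue_labels = tissues, seed = seed))
}

write_tmp_gmt <- function(lines) {
  f <- withr::local_tempfile(fileext = ".gmt",
                             .local_envir = parent.frame())
  writeLines(lines, f)
  f
}
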