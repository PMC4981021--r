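# Shared fixture: a small collection where the focal gene is DE
# everywhere (so the DE restriction keeps all tissue datasets) and has a
# planted leaf-only partner module.
pathway_fixture <- function(seed = 61) {
  sc <- simulation_config(
    n_datasets = 16, samples_per_dataset = 16, n_genes = 30,
    focal_genes = "g0001", tissue_labels = c("root", "leaf"),
    planted_partners = list(list(focal = "g0001",
                                 partners = c("g0005", "g0006", "g0007"),
                                 rho = 0.8, tissue = "leaf")),
    planted_de = list(list(gene = "g0001", delta = 6, tissue = "all")),
    seed = seed)
  coll <- generate_collection(sc)
  list(coll = coll, de = de_scan(coll))
}

test_that("pathway scores average member gene weights on DE-restricted datasets", {
  fx <- pathway_fixture()
  gs <- tissue_gene_scores("g0001", "leaf", fx$coll, fx$de)
  expect_gt(gs$n_datasets_used, 0)
  # single-member pathway equals that gene's weight
  one <- pathway_score("g0001", "g0005", "leaf", fx$coll, fx$de)
  expect_equal(one$score, unname(gs$R["g0005"]), tolerance = 1e-14)
  # two members average exactly
  two <- pathway_score("g0001", c("g0005", "g0006"), "leaf", fx$coll,
                       fx$de)
  expect_equal(two$score, mean(gs$R[c("g0005", "g0006")]),
               tolerance = 1e-14)
  # planted leaf module scores near rho in leaf and near 0 in root
  mod <- c("g0005", "g0006", "g0007")
  leaf <- pathway_score("g0001", mod, "leaf", fx$coll, fx$de)
  root <- pathway_score("g0001", mod, "root", fx$coll, fx$de)
  expect_equal(leaf$score, 0.8, tolerance = 0.15)
  expect_lt(abs(root$score), 0.3)
})

test_that("scores match a brute-force reimplementation exactly", {
  fx <- pathway_fixture(seed = 67)
  for (members in list("g0010", c("g0004", "g0012", "g0020"))) {
    for (tt in c("root", "leaf")) {
      got <- pathway_score("g0001", members, tt, fx$coll, fx$de)$score
      want <- brute_pathway_score(fx$coll, "g0001", members, tt, fx$de)
      expect_equal(got, want, tolerance = 1e-12)
    }
  }
})

test_that("the whole universe as a pathway equals the mean gene-level score", {
  fx <- pathway_fixture(seed = 71)
  gs <- tissue_gene_scores("g0001", "leaf", fx$coll, fx$de)
  all_genes <- fx$coll$gene_universe
  got <- pathway_score("g0001", all_genes, "leaf", fx$coll, fx$de,
                       gene_scores = gs)$score
  expect_equal(got, mean(gs$R, na.rm = TRUE), tolerance = 1e-14)
})

test_that("permutation null follows the exceed-count conventions", {
  fx <- pathway_fixture()
  mod <- c("g0005", "g0006", "g0007")
  obs <- pathway_score("g0001", mod, "leaf", fx$coll, fx$de)
  out <- permutation_null("g0001", obs, fx$coll$gene_universe, B = 100,
                          seed = 8, collection = fx$coll,
                          de_results = fx$de)
  # planted module should beat every random 3-gene set
  expect_equal(out$null_exceed, 0L)
  expect_equal(out$empirical_p, 1 / 101, tolerance = 1e-12)
  expect_true(out$significant)
  # determinism under the same seed
  out2 <- permutation_null("g0001", obs, fx$coll$gene_universe, B = 100,
                           seed = 8, collection = fx$coll,
                           de_results = fx$de)
  expect_identical(out2$null_exceed, out$null_exceed)

  # an observed score below every null: flip the sign trick via a
  # strongly negative observed score
  low <- obs
  low$score <- -1
  worst <- permutation_null("g0001", low, fx$coll$gene_universe, B = 100,
                            seed = 8, collection = fx$coll,
                            de_results = fx$de)
  expect_equal(worst$null_exceed, 100L)
  expect_equal(worst$empirical_p, 1)
  expect_false(worst$significant)
  expect_error(
    permutation_null("g0001", transform(obs, pathway_size = 1000L),
                     fx$coll$gene_universe, B = 10, seed = 1,
                     collection = fx$coll, de_results = fx$de),
    "universe")
})

test_that("batch scoring flags planted modules per tissue and is reproducible", {
  fx <- pathway_fixture()
  db <- pathway_db(list(planted = c("g0005", "g0006", "g0007"),
                        null1 = c("g0010", "g0011", "g0012"),
                        null2 = c("g0015", "g0020", "g0025")),
                   universe = fx$coll$gene_universe)
  s1 <- score_pathways("g0001", db, fx$coll, fx$de, B = 100, seed = 3)
  s2 <- score_pathways("g0001", db, fx$coll, fx$de, B = 100, seed = 3)
  expect_identical(s1, s2)
  leaf_planted <- s1[s1$pathway_id == "planted" & s1$tissue == "leaf", ]
  expect_true(leaf_planted$significant)
  expect_equal(nrow(s1), 3L * 2L)   # pathways x tissues
  expect_true(all(s1$empirical_p > 0 & s1$empirical_p <= 1))
  expect_true(all(s1$significant == (s1$null_exceed == 0 &
                                       !is.na(s1$score))))
})

test_that("combinations with no usable dataset are reported as missing", {
  # focal gene never DE -> restriction empties the dataset set
  sc <- simulation_config(n_datasets = 4, n_genes = 10,
                          tissue_labels = "root", seed = 83)
  coll <- generate_collection(sc)
  de <- de_scan(coll)
  s <- score_pathways("g0001",
                      pathway_db(list(P = c("g0002", "g0003")),
                                 universe = coll$gene_universe),
                      coll, de, B = 20, seed = 1)
  expect_true(is.na(s$score))
  expect_equal(s$n_datasets_used, 0L)
  expect_false(s$significant)
})
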