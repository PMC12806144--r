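test_that("the exact Wilcoxon p-value matches enumeration", {
  loadings <- stats::setNames(10:1 / 10, paste0("g", 1:10))
  ## the top 3 of 10 ranks: exactly 1 of the C(10,3) = 120 configurations
  res <- wilcoxon_enrichment(loadings, paste0("g", 1:3), "positive")
  expect_equal(res$p, 1 / 120)
  ## the same set at the opposite pole is maximally non-significant
  res_neg <- wilcoxon_enrichment(loadings, paste0("g", 1:3), "negative")
  expect_equal(res_neg$p, 1)
  ## whole-universe set is degenerate
  expect_equal(wilcoxon_enrichment(loadings, names(loadings),
                                   "positive")$p, 1)
  expect_error(wilcoxon_enrichment(loadings, c("zz1", "zz2"), "positive"),
               "resolves")
})

test_that("normal approximation tracks the exact test on small universes", {
  set.seed(14)
  for (rep in 1:20) {
    loadings <- stats::setNames(rnorm(25), paste0("g", 1:25))
    members <- sample(names(loadings), 8)
    p_exact <- wilcoxon_enrichment(loadings, members, "positive")$p
    x <- loadings[members]; y <- loadings[setdiff(names(loadings),
                                                  members)]
    p_norm <- suppressWarnings(
      stats::wilcox.test(x, y, alternative = "greater",
                         exact = FALSE, correct = TRUE)$p.value)
    expect_lt(abs(p_norm - p_exact) / p_exact, 0.10)
  }
})

test_that("enrichment tables are deterministic and track the statistic", {
  sim <- gen_cref(small_model(seed = 23))
  dec <- svd_modules(sim$low_rank, n_levels = 3)
  loadings <- module_at(dec, 1)$gene_vector
  gs <- gen_gene_sets(loadings, n_sets = 8, strength = 0.8,
                      set_size = 15, seed = 3)
  tab <- enrich_all(dec, gs$sets, levels = 1)
  tab2 <- enrich_all(dec, gs$sets, levels = 1)
  expect_identical(tab, tab2)
  ## planted sets beat null sets at their planted level and pole
  pos <- tab[tab$pole == "positive", ]
  expect_lt(max(pos$p[gs$enriched]), min(pos$p[!gs$enriched]))
  ## p decreases monotonically with the rank-sum statistic at fixed size
  ord <- order(pos$statistic, decreasing = TRUE)
  expect_equal(order(pos$p[ord]), seq_along(ord))
  ## optional BH column
  tab_bh <- enrich_all(dec, gs$sets, levels = 1, bh = TRUE)
  expect_true("p_bh" %in% names(tab_bh))
  expect_true(all(tab_bh$p_bh >= tab_bh$p))
})

test_that("top pole genes follow the polarized order at both poles", {
  sim <- gen_cref(small_model(seed = 29))
  dec <- svd_modules(sim$low_rank, n_levels = 3)
  mod <- module_at(dec, 2)
  g <- length(mod$gene_vector)
  full <- top_pole_genes(dec, 2, "positive", g)
  expect_equal(full$gene_id,
               names(mod$gene_vector)[mod$gene_order])
  one <- top_pole_genes(dec, 2, "positive", 1)
  expect_equal(one$gene_id, full$gene_id[1])
  neg <- top_pole_genes(dec, 2, "negative", 3)
  expect_equal(neg$gene_id, rev(utils::tail(full$gene_id, 3)))
  expect_true(all(diff(full$loading) <= 0))
  expect_error(top_pole_genes(dec, 2, "positive", g + 1), "exceeds")
  ## planted pole genes occupy the extreme ranks of the planted level
  ## (the recovered sign convention may map either planted block to the
  ## positive pole)
  u_planted <- sim$model$gene_factors[, 3]
  pos_block <- sprintf("gene_%05d", which(u_planted > 1e-9))
  neg_block <- sprintf("gene_%05d", which(u_planted < -1e-9))
  top_n <- top_pole_genes(dec, 2, "positive", length(pos_block))
  expect_true(setequal(top_n$gene_id, pos_block) ||
                setequal(top_n$gene_id, neg_block))
})

test_that("species-specific pole genes honor ortholog maps", {
  sim_a <- gen_cref(small_model(seed = 31))
  sim_b <- gen_cref(small_model(seed = 37))
  da <- svd_modules(sim_a$low_rank, 3)
  db <- svd_modules(sim_b$low_rank, 3)
  ## identical species: nothing is specific
  expect_equal(nrow(species_specific_top_genes(da, list(da), 1,
                                               "positive", 25)), 0L)
  expect_equal(nrow(species_specific_top_genes(da, list(db), 1,
                                               "positive", 0)), 0L)
  spec <- species_specific_top_genes(da, list(db), 1, "positive", 25)
  top_a <- top_pole_genes(da, 1, "positive", 25)$gene_id
  top_b <- top_pole_genes(db, 1, "positive", 25)$gene_id
  expect_setequal(spec$gene_id, setdiff(top_a, top_b))
  ## unmapped focal genes count as species-specific
  empty_map <- stats::setNames(character(0), character(0))
  spec2 <- species_specific_top_genes(da, list(db), 1, "positive", 25,
                                      ortholog_maps = list(empty_map))
  expect_equal(nrow(spec2), 25L)
  expect_equal(attr(spec2, "n_unmapped"), 25L)
})

test_that("GMT files round-trip", {
  sets <- list(alpha = c("g1", "g2", "g3"), beta = c("g9", "g4"))
  path <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(sets, path)
  back <- read_gmt(path)
  expect_equal(back$alpha, sets$alpha)
  expect_equal(back$beta, sets$beta)
})
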