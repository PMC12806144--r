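test_that("generated matrices are deterministic under the seed", {
  m1 <- gen_cref(planted_model(120, 60, seed = 9,
                               spectrum = planted_spectrum(120, 60, 3)))
  m2 <- gen_cref(planted_model(120, 60, seed = 9,
                               spectrum = planted_spectrum(120, 60, 3)))
  expect_identical(unclass(m1$cref), unclass(m2$cref))
  expect_identical(m1$outlier_mask, m2$outlier_mask)
  m3 <- gen_cref(planted_model(120, 60, seed = 10,
                               spectrum = planted_spectrum(120, 60, 3)))
  expect_false(identical(unclass(m1$cref), unclass(m3$cref)))
})

test_that("the planted low-rank part matches the requested spectrum exactly", {
  sim <- gen_cref(small_model())
  sv <- svd(sim$low_rank)$d
  spec <- sim$model$spectrum
  expect_equal(sum(sv > 1e-8 * sv[1]), 6L)   # rank s+1 = 6
  expect_lt(max(abs(sv[1:6] - spec) / spec), 1e-6)
  expect_gte(min(sim$low_rank), 0)
  ## factor columns exactly orthonormal
  G <- crossprod(sim$model$gene_factors)
  expect_lt(max(abs(G - diag(ncol(G)))), 1e-10)
})

test_that("the outlier mask has exactly ceiling(fraction * g * m) entries", {
  sim <- gen_cref(small_model(corruption = 0.02))
  expect_equal(sum(sim$outlier_mask), ceiling(0.02 * 300 * 120))
  expect_equal(sum(sim$outlier_mask), 720L)
  expect_true(all(sim$sparse[sim$outlier_mask] > 0))
  expect_true(all(sim$sparse[!sim$outlier_mask] == 0))
})

test_that("invalid planted models are rejected", {
  expect_error(planted_model(100, 50, spectrum = c(10, 12, 5)),
               "strictly decreasing")
  expect_error(planted_model(100, 50, spectrum = c(10, 5, 2),
                             corruption_fraction = 1),
               "corruption_fraction")
})

test_that("species pairs share motif factors except the rotated pair", {
  base <- planted_model(240, 80, seed = 3,
                        spectrum = planted_spectrum(240, 80, 4))
  id_sc <- saltation_scenario(base, rotated_pair = c(2, 3),
                              rotation_deg = 0, gap_fraction = 0.02)
  pair0 <- gen_species_pair(id_sc)
  expect_equal(pair0$a$model$motif_factors,
               pair0$b$model$motif_factors, tolerance = 1e-12)
  orth_sc <- saltation_scenario(base, rotated_pair = c(2, 3),
                                rotation_deg = 90, gap_fraction = 0.02)
  pair90 <- gen_species_pair(orth_sc)
  va <- pair90$a$model$motif_factors[, 3]      # level 2
  vb <- pair90$b$model$motif_factors[, 3]
  expect_lt(abs(sum(va * vb)), 1e-12)
  ## other levels untouched; gene factors freshly drawn
  expect_equal(pair90$a$model$motif_factors[, c(1, 2, 5)],
               pair90$b$model$motif_factors[, c(1, 2, 5)])
  expect_false(identical(pair90$a$model$gene_factors,
                         pair90$b$model$gene_factors))
})

test_that("non-adjacent or out-of-range rotation pairs are rejected", {
  base <- planted_model(240, 80, spectrum = planted_spectrum(240, 80, 4))
  expect_error(saltation_scenario(base, rotated_pair = c(2, 4)),
               "adjacent")
  expect_error(saltation_scenario(base, rotated_pair = c(4, 5)),
               "out of range")
  expect_error(saltation_scenario(base, rotated_pair = c(2, 3),
                                  rotation_deg = 120), "rotation_deg")
})

test_that("a noise-free planted rotation is recovered to numerical precision", {
  base <- planted_model(240, 80, seed = 21, noise_model = "none",
                        corruption_fraction = 0,
                        spectrum = planted_spectrum(240, 80, 4))
  sc <- saltation_scenario(base, rotated_pair = c(2, 3),
                           rotation_deg = 40, gap_fraction = 0.05)
  pair <- gen_species_pair(sc)
  ## work on the exact planted low-rank matrices (no count rounding)
  da <- svd_modules(pair$a$low_rank, n_levels = 4)
  db <- svd_modules(pair$b$low_rank, n_levels = 4)
  ang <- rotation_angle(module_at(da, 2)$motif_vector,
                        module_at(da, 3)$motif_vector,
                        module_at(db, 2)$motif_vector)
  expect_lt(abs(ang$angle_deg - 40), 1e-6)
  expect_lt(ang$out_of_plane, 1e-10)
  r <- compare_motif_eigenvectors(module_at(da, 2)$motif_vector,
                                  module_at(db, 2)$motif_vector)$r
  expect_lt(abs(r - cos(40 * pi / 180)), 1e-6)
})

test_that("promoter fixtures plant exact counts, including empty ones", {
  lib <- random_pwm_library(4, seed = 4)
  fx0 <- gen_promoter_fixture(c(0, 0, 0, 0), lib, seed = 2)
  s0 <- as.character(fx0$genome[[1]])
  expect_equal(unname(oracle_cref_row(lib, s0, "minFP")), rep(0L, 4))
  fx <- gen_promoter_fixture(c(3, 0, 0, 0), lib, seed = 3)
  expect_equal(unname(oracle_cref_row(lib, as.character(fx$genome[[1]]),
                                      "minFP")), c(3L, 0L, 0L, 0L))
  ## over-full windows are rejected up front
  expect_error(gen_promoter_fixture(c(200, 0, 0, 0), lib, seed = 1),
               "cannot fit")
  ## determinism
  fx2 <- gen_promoter_fixture(c(3, 0, 0, 0), lib, seed = 3)
  expect_identical(as.character(fx$genome), as.character(fx2$genome))
})

test_that("minus-strand plantings are counted by the double-strand scan", {
  lib <- pwm_library(list(tiny_pwm()))
  found_minus <- FALSE
  for (seed in 1:12) {
    fx <- gen_promoter_fixture(2, lib, seed = seed)
    if (any(fx$sites$strand == "-")) {
      found_minus <- TRUE
      expect_equal(unname(oracle_cref_row(lib,
                                          as.character(fx$genome[[1]]),
                                          "minFP")), 2L)
    }
  }
  expect_true(found_minus)
})

test_that("repeat libraries carry exactly the planted motif subset", {
  lib <- random_pwm_library(10, seed = 8)
  ids <- pwm_ids(lib)
  rl <- gen_repeat_library(lib, ids[c(2, 5, 9)], seed = 6)
  expect_equal(rl$expected, sort(ids[c(2, 5, 9)]))
  got <- rowSums(sapply(as.character(rl$fasta), function(s)
    oracle_cref_row(lib, s, "minFP")))
  expect_equal(sort(names(got)[got > 0]), rl$expected)
  rl0 <- gen_repeat_library(lib, character(0), seed = 6)
  expect_equal(rl0$expected, character(0))
  expect_equal(find_mpa(lib, rl0$fasta, "minFP"), character(0))
})

test_that("gene-set generation is seeded and strength-controlled", {
  loadings <- stats::setNames(sort(stats::rnorm(500), decreasing = TRUE),
                              sprintf("g%03d", 1:500))
  gs <- gen_gene_sets(loadings, n_sets = 6, strength = 1, set_size = 10,
                      seed = 5)
  gs2 <- gen_gene_sets(loadings, n_sets = 6, strength = 1, set_size = 10,
                       seed = 5)
  expect_identical(gs, gs2)
  expect_equal(gs$enriched, rep(c(TRUE, FALSE), each = 3))
  ## strength-1 sets concentrate near the top of the order
  mean_rank_enr <- mean(match(unlist(gs$sets[gs$enriched]),
                              names(loadings)))
  mean_rank_null <- mean(match(unlist(gs$sets[!gs$enriched]),
                               names(loadings)))
  expect_lt(mean_rank_enr, 60)
  expect_gt(mean_rank_null, 150)
})
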