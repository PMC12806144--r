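test_that("jaccard similarity satisfies its identities", {
  expect_equal(jaccard(c("a", "b", "c"), c("b", "c", "d")), 0.5)
  expect_equal(jaccard(letters[1:3], letters[1:3]), 1)
  expect_equal(jaccard(letters[1:3], letters[4:6]), 0)
  expect_equal(jaccard(letters[1:10], letters[6:15]), 5 / 15)
  set.seed(6)
  for (i in 1:10) {
    a <- sample(letters, sample(0:10, 1))
    b <- sample(letters, sample(0:10, 1))
    expect_equal(as.numeric(jaccard(a, b)), as.numeric(jaccard(b, a)))
    expect_equal(as.numeric(jaccard(a, a)),
                 if (length(a)) 1 else 1)
  }
  both_empty <- jaccard(character(0), character(0))
  expect_equal(as.numeric(both_empty), 1)
  expect_true(attr(both_empty, "both_empty"))
})

test_that("relative MPA changes follow the percentage formula", {
  expect_equal(mpa_relative_change(30, 20), 50)
  expect_equal(mpa_relative_change(15, 20), -25)
  expect_equal(mpa_relative_change(20, 20), 0)
  expect_error(mpa_relative_change(5, 0), "undefined")
})

test_that("find_mpa recovers the planted motif subset exactly", {
  lib <- random_pwm_library(12, seed = 15)
  ids <- pwm_ids(lib)
  planted <- ids[c(1, 4, 7, 8, 11)]
  rl <- gen_repeat_library(lib, planted, seed = 10)
  expect_equal(find_mpa(lib, rl$fasta, "minFP"), sort(planted))
  ## FASTA round trip
  fa <- withr::local_tempfile(fileext = ".fa")
  Biostrings::writeXStringSet(rl$fasta, fa)
  expect_equal(find_mpa(lib, fa, "minFP"), sort(planted))
  ## empty library and empty repeats
  expect_equal(find_mpa(pwm_library(list()), rl$fasta, "minFP"),
               character(0))
  ## the permissive threshold set contains the stringent one
  minfn <- find_mpa(lib, rl$fasta, "minFN")
  expect_true(all(find_mpa(lib, rl$fasta, "minFP") %in% minfn))
})

test_that("pole motifs follow the polarized motif order", {
  sim <- gen_cref(small_model(seed = 41))
  dec <- svd_modules(sim$low_rank, n_levels = 3)
  mod <- module_at(dec, 1)
  m <- length(mod$motif_vector)
  all_m <- pole_motifs(dec, 1, "positive", m)
  expect_setequal(all_m, names(mod$motif_vector))
  expect_equal(pole_motifs(dec, 1, "positive", 1),
               names(mod$motif_vector)[mod$motif_order[1]])
  expect_error(pole_motifs(dec, 1, "positive", m + 1), "exceeds")
  ## counts are invariant to relabeling of off-pole motifs
  pole <- pole_motifs(dec, 1, "positive", 10)
  mpa_set <- pole[c(1, 3, 5)]
  rep_tab <- mpa_report(dec, dec, mpa_set, levels = 1, n = 10)
  expect_equal(rep_tab$count_focal, 3L)
  expect_equal(rep_tab$relative_change_pct, 0)
})

test_that("promoter windows overlapping repeats are flagged with lengths", {
  promoters <- data.frame(
    gene_id = sprintf("g%02d", 1:10), chrom = "chr1",
    start = seq(0, 9000, by = 1000),
    end = seq(0, 9000, by = 1000) + 500)
  repeats <- data.frame(
    name = c("AluY_1", "AluSx_2", "SVA_3", "AluY_4"),
    chrom = "chr1",
    start = c(100, 2200, 5400, 500),
    end = c(400, 2300, 5600, 900))
  ## AluY_4 is adjacent to g1's window [0, 500): no overlap (half-open)
  tab <- flag_repeat_insertions(promoters, repeats)
  expect_equal(nrow(tab), 3L)
  expect_equal(tab$gene_id, c("g01", "g03", "g06"))
  expect_equal(tab$repeat_name, c("AluY_1", "AluSx_2", "SVA_3"))
  ## a repeat entirely inside a window overlaps by its own length
  expect_equal(tab$overlap, c(300L, 100L, 100L))
})

test_that("repeat intervals parse from BED and RepeatMasker tables", {
  bed <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t100\t400\tAluY_1", "chr2\t0\t50\tSVA_2"), bed)
  b <- read_bed(bed)
  expect_equal(b$name, c("AluY_1", "SVA_2"))
  expect_equal(b$start, c(100L, 0L))
  out <- withr::local_tempfile(fileext = ".out")
  writeLines(c(
    "   SW  perc perc perc  query     position in query",
    "score  div. del. ins.  sequence  begin  end",
    "",
    "  463  11.4  0.0  0.0  chr1      101    400  (1000)  +  AluY   SINE/Alu",
    "  300  10.0  0.0  0.0  chr2      1      50   (20)    +  SVA_A  Retroposon"),
    out)
  r <- read_repeatmasker_out(out)
  expect_equal(r$chrom, c("chr1", "chr2"))
  expect_equal(r$start, c(100L, 0L))      # 1-based begin -> 0-based
  expect_equal(r$end, c(400L, 50L))
  expect_equal(r$name, c("AluY", "SVA_A"))
})
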