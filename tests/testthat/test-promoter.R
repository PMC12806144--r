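tx_df <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r)
    data.frame(transcript_id = r[[1]], chrom = r[[2]],
               start = as.integer(r[[3]]), end = as.integer(r[[4]]),
               strand = r[[5]], stringsAsFactors = FALSE)))
}

test_that("the most 5'-upstream transcript defines the TSS", {
  plus <- tx_df(list("t1", "chr1", 100, 900, "+"),
                list("t2", "chr1", 200, 800, "+"))
  expect_equal(select_tss(plus)$tss, 100)
  minus <- tx_df(list("t1", "chr1", 100, 500, "-"),
                 list("t2", "chr1", 300, 700, "-"))
  sel <- select_tss(minus)
  expect_equal(sel$tss, 700)
  expect_equal(sel$strand, "-")
  single <- tx_df(list("t1", "chr1", 42, 90, "+"))
  expect_equal(select_tss(single)$tss, 42)
  ## ties broken by lexicographic transcript id
  tie <- tx_df(list("tB", "chr1", 10, 50, "+"),
               list("tA", "chr1", 10, 60, "+"))
  expect_equal(select_tss(tie)$transcript_id, "tA")
})

test_that("inconsistent or empty annotations raise errors", {
  mixed <- tx_df(list("t1", "chr1", 1, 10, "+"),
                 list("t2", "chr1", 1, 10, "-"))
  expect_error(select_tss(mixed), "share chrom and strand")
  expect_error(select_tss(mixed[0, ]), "no annotated transcripts")
})

test_that("promoter windows are 1501 bp, strand-aware, clipped at edges", {
  set.seed(4)
  contig <- paste(sample(c("A", "C", "G", "T"), 12000, TRUE),
                  collapse = "")
  genome <- Biostrings::DNAStringSet(c(chr1 = contig))
  plus <- extract_promoter(genome, "chr1", 10000, "+")
  expect_equal(plus$region$start, 9000)
  expect_equal(plus$region$end, 10501)
  expect_equal(length(plus$seq), 1501L)
  expect_false(plus$region$clipped)
  expect_equal(as.character(plus$seq), substr(contig, 9001, 10501))
  minus <- extract_promoter(genome, "chr1", 10000, "-")
  expect_equal(minus$region$start, 9500)
  expect_equal(minus$region$end, 11001)
  expect_equal(as.character(minus$seq),
               as.character(Biostrings::reverseComplement(
                 Biostrings::DNAString(substr(contig, 9501, 11001)))))
  clip <- extract_promoter(genome, "chr1", 300, "+")
  expect_true(clip$region$clipped)
  expect_equal(clip$region$start, 0)
  expect_equal(clip$region$end, 801)
  expect_error(extract_promoter(genome, "chr1", 20000, "+"),
               "outside contig")
})

test_that("build_cref reproduces planted counts on a multi-gene fixture", {
  lib <- random_pwm_library(5, seed = 41)
  set.seed(12)
  target <- matrix(rpois(4 * 5, 1), 4, 5,
                   dimnames = list(sprintf("g%02d", 1:4), NULL))
  fx <- gen_promoter_genome(target, lib, seed = 600)
  cm <- build_cref(fx$genome, fx$annotation, lib, profile = "minFP")
  expect_equal(bare_matrix(cm), bare_matrix(fx$expected))
  expect_equal(rownames(cm), rownames(target))
  ## determinism of the build
  cm2 <- build_cref(fx$genome, fx$annotation, lib, profile = "minFP")
  expect_identical(unclass(cm), unclass(cm2))
})

test_that("build_cref round-trips through GFF3 and FASTA files", {
  lib <- random_pwm_library(3, seed = 43)
  fx <- gen_promoter_fixture(c(2, 0, 1), lib, seed = 77, strand = "-")
  fa <- withr::local_tempfile(fileext = ".fa")
  gff <- withr::local_tempfile(fileext = ".gff3")
  Biostrings::writeXStringSet(fx$genome, fa)
  rtracklayer::export(fx$annotation, gff, format = "gff3")
  cm <- build_cref(fa, gff, lib, profile = "minFP")
  expect_identical(as.integer(unclass(cm)[1, ]), unname(fx$expected))
})

test_that("an empty PWM library yields a g x 0 matrix", {
  lib <- random_pwm_library(2, seed = 5)
  fx <- gen_promoter_fixture(c(0, 0), lib, seed = 9)
  cm <- build_cref(fx$genome, fx$annotation, pwm_library(list()),
                   profile = "minFP")
  expect_equal(dim(cm), c(1L, 0L))
})

test_that("reverse-complementing the genome and flipping strands leaves the CREF unchanged", {
  lib <- random_pwm_library(4, seed = 47)
  set.seed(8)
  target <- matrix(rpois(2 * 4, 1), 2, 4)
  fx <- gen_promoter_genome(target, lib, seed = 900)
  cm <- build_cref(fx$genome, fx$annotation, lib, profile = "minFP")
  genome_rc <- Biostrings::reverseComplement(fx$genome)
  names(genome_rc) <- names(fx$genome)
  anno <- fx$annotation
  widths <- stats::setNames(Biostrings::width(fx$genome),
                            names(fx$genome))
  w <- widths[as.character(GenomicRanges::seqnames(anno))]
  new_start <- w - GenomicRanges::end(anno) + 1L
  new_end <- w - GenomicRanges::start(anno) + 1L
  flipped <- GenomicRanges::GRanges(
    seqnames = GenomicRanges::seqnames(anno),
    ranges = IRanges::IRanges(start = new_start, end = new_end),
    strand = ifelse(as.character(GenomicRanges::strand(anno)) == "+",
                    "-", "+"))
  S4Vectors::mcols(flipped) <- S4Vectors::mcols(anno)
  cm_rc <- build_cref(genome_rc, flipped, lib, profile = "minFP")
  expect_equal(bare_matrix(cm), bare_matrix(cm_rc))
  expect_equal(rownames(cm), rownames(cm_rc))
})

test_that("CREI thresholds counts at presence and quantiles summarize multiplicity", {
  cm <- cref_matrix(matrix(c(0, 1, 7, 0, 0, 2), 3, 2,
                           dimnames = list(paste0("g", 1:3),
                                           paste0("m", 1:2))))
  ci <- build_crei(cm)
  expect_equal(unname(unclass(ci)[, 1]), c(0, 1, 1))
  expect_equal(sum(ci), sum(cm > 0))
  ## all-zero matrix stays all-zero
  z <- cref_matrix(matrix(0L, 2, 2,
                          dimnames = list(c("a", "b"), c("x", "y"))))
  expect_true(all(unclass(build_crei(z)) == 0))
  col <- c(0, 0, 0, 0, 10, 10, 10, 10, 10, 10)
  cm2 <- cref_matrix(matrix(c(col, rep(5, 10)), 10, 2,
                            dimnames = list(sprintf("g%02d", 1:10),
                                            c("mA", "mB"))))
  q <- motif_multiplicity_quantiles(cm2)
  expect_equal(unlist(q[q$motif_id == "mA", c("q10", "q50", "q90")],
                      use.names = FALSE), c(0, 10, 10))
  expect_equal(unlist(q[q$motif_id == "mB", c("q10", "q50", "q90")],
                      use.names = FALSE), c(5, 5, 5))
  ## median of a symmetric column equals the sample median
  sym <- cref_matrix(matrix(0:8, 9, 1, dimnames = list(paste0("g", 1:9),
                                                       "mC")))
  expect_equal(motif_multiplicity_quantiles(sym, probs = 0.5)$q50, 4)
})
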