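test_that("MSS is 1 on the consensus and 0 on the anti-consensus", {
  p <- tiny_pwm()
  cons <- pwm_consensus(p)
  sc <- score_pwm_window(p, cons)
  expect_equal(sc$mss, 1)
  expect_equal(sc$css, 1)
  anti <- paste(c("A", "C", "G", "T")[apply(p$prob, 1, which.min)],
                collapse = "")
  expect_equal(score_pwm_window(p, anti)$mss, 0)
})

test_that("uniform PWMs are degenerate and ambiguous bases are skipped", {
  u <- pwm("UNIF", matrix(0.25, 6, 4))
  sc <- score_pwm_window(u, "ACGTAC")
  expect_true(sc$degenerate)
  expect_equal(sc$mss, 0)
  p <- tiny_pwm()
  sc_n <- score_pwm_window(p, "ACGTNCGTA")
  expect_true(sc_n$skipped)
  ## a window with N inside a scanned sequence is not counted
  seq_n <- paste0(strrep("T", 20), "ACGTNCGTA", strrep("T", 20))
  expect_equal(scan_sequence(p, seq_n, c(mss = 0.9, css = 0.9)), 0L)
})

test_that("sequences shorter than the motif yield zero hits", {
  expect_equal(scan_sequence(tiny_pwm(), "ACGT", "minFN"), 0L)
})

test_that("planted sites are found on both strands, overlaps each counted", {
  p <- tiny_pwm()
  cons <- pwm_consensus(p)
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(cons)))
  bg <- strrep("G", 30)
  th <- c(mss = 0.95, css = 0.95)
  expect_equal(scan_sequence(p, paste0(bg, cons, bg), th), 1L)
  hits <- scan_sequence(p, paste0(bg, rc, bg), th, detail = TRUE)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$strand, "-")
  expect_equal(hits$offset, 30L)
  ## overlapping occurrences are each counted: a poly-A motif tiles a
  ## poly-A run at every offset
  pa <- pwm("POLYA", {
    m <- matrix(0.03, 6, 4); m[, 1] <- 0.91; m
  })
  expect_equal(scan_sequence(pa, paste0(bg, strrep("A", 8), bg), th), 3L)
})

test_that("scanner agrees with the brute-force oracle on random sequences", {
  lib <- random_pwm_library(4, seed = 17)
  set.seed(31)
  for (rep in 1:5) {
    s <- paste(sample(c("A", "C", "G", "T"), 400, TRUE), collapse = "")
    for (p in lib) {
      expect_equal(scan_sequence(p, s, "minFN"),
                   oracle_scan_count(p, s, 0.70, 0.75))
    }
  }
})

test_that("lowering the MSS threshold never decreases a count", {
  lib <- random_pwm_library(3, seed = 23)
  set.seed(7)
  s <- paste(sample(c("A", "C", "G", "T"), 600, TRUE), collapse = "")
  for (p in lib) {
    lo <- scan_sequence(p, s, c(mss = 0.35, css = 0.4))
    hi <- scan_sequence(p, s, c(mss = 0.55, css = 0.4))
    expect_gte(lo, hi)
  }
})

test_that("TRANSFAC round-trip and JASPAR parsing work", {
  lib <- random_pwm_library(3, seed = 2)
  tf <- withr::local_tempfile(fileext = ".transfac")
  write_transfac(lib, tf)
  lib2 <- read_transfac(tf)
  expect_equal(pwm_ids(lib2), pwm_ids(lib))
  for (i in seq_along(lib)) {
    expect_equal(nrow(lib2[[i]]$prob), nrow(lib[[i]]$prob))
    expect_equal(unname(lib2[[i]]$prob), unname(lib[[i]]$prob),
                 tolerance = 0.05)
    expect_equal(pwm_consensus(lib2[[i]]), pwm_consensus(lib[[i]]))
  }
  jf <- withr::local_tempfile(fileext = ".pfm")
  writeLines(c(">MA0001.1 TEST",
               "A  [ 10  0  0  8 ]",
               "C  [  0 12  0  1 ]",
               "G  [  1  0 12  2 ]",
               "T  [  1  0  0  1 ]"), jf)
  jl <- read_jaspar(jf)
  expect_equal(pwm_ids(jl), "MA0001.1")
  expect_equal(nrow(jl[[1]]$prob), 4L)
  expect_equal(unname(jl[[1]]$prob[1, ]), c(10, 0, 1, 1) / 12)
})

test_that("invalid PWMs are rejected", {
  expect_error(pwm("BAD", matrix(c(0.5, 0.5, 0.2, 0.1), 1, 4)),
               "length")
  bad <- matrix(0.25, 5, 4); bad[1, 1] <- 0.5
  expect_error(pwm("BAD", bad), "sum to 1")
})

test_that("per-motif threshold files override library defaults", {
  lib <- random_pwm_library(3, seed = 9)
  tab <- data.frame(motif_id = pwm_ids(lib)[2], profile = "minFN",
                    mss = 0.99, css = 0.99)
  lib2 <- apply_threshold_file(lib, tab)
  expect_equal(lib2[[2]]$thresholds$minFN, c(mss = 0.99, css = 0.99))
  expect_equal(lib2[[1]]$thresholds$minFN, c(mss = 0.70, css = 0.75))
  ## raising a motif's threshold can only lower its counts
  set.seed(1)
  s <- paste(sample(c("A", "C", "G", "T"), 500, TRUE), collapse = "")
  expect_lte(scan_sequence(lib2[[2]], s, "minFN"),
             scan_sequence(lib[[2]], s, "minFN"))
  tf <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(tab, tf, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  lib3 <- apply_threshold_file(lib, tf)
  expect_equal(lib3[[2]]$thresholds$minFN, c(mss = 0.99, css = 0.99))
  expect_warning(apply_threshold_file(
    lib, data.frame(motif_id = "NOPE", profile = "minFN",
                    mss = 0.5, css = 0.5)), "unknown")
})
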