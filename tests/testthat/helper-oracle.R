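## Independent brute-force PWM scanner used as the oracle for the
## package's vectorized scanner. Everything is recomputed per window from
## the probability matrix alone, following the score definition directly.

oracle_prepare <- function(prob, pseudocount = 0.01) {
  f <- (prob + pseudocount) / rowSums(prob + pseudocount)
  info <- rowSums(f * log(4 * f))
  L <- nrow(prob)
  core <- if (L >= 5) {
    tot <- sapply(1:(L - 4), function(s) sum(info[s:(s + 4)]))
    s0 <- which.max(tot)
    s0:(s0 + 4)
  } else seq_len(L)
  W <- info * f
  list(W = W, core = core, L = L,
       lo = sum(apply(W, 1, min)), hi = sum(apply(W, 1, max)),
       loC = sum(apply(W, 1, min)[core]), hiC = sum(apply(W, 1, max)[core]))
}

oracle_window_scores <- function(prep, codes_window) {
  if (anyNA(codes_window)) return(c(mss = NA_real_, css = NA_real_))
  cur <- sum(prep$W[cbind(seq_len(prep$L), codes_window)])
  curC <- sum(prep$W[cbind(prep$core, codes_window[prep$core])])
  c(mss = (cur - prep$lo) / (prep$hi - prep$lo),
    css = (curC - prep$loC) / (prep$hiC - prep$loC))
}

oracle_codes <- function(seq_string) {
  match(strsplit(toupper(seq_string), "")[[1]], c("A", "C", "G", "T"))
}

## Count hits of one pwm on both strands of a sequence string.
oracle_scan_count <- function(p, seq_string, mss_min, css_min) {
  prep <- oracle_prepare(p$prob)
  count_strand <- function(codes) {
    n <- length(codes)
    if (n < prep$L) return(0L)
    hits <- 0L
    for (s in 1:(n - prep$L + 1)) {
      sc <- oracle_window_scores(prep, codes[s:(s + prep$L - 1)])
      if (!anyNA(sc) && sc["mss"] >= mss_min && sc["css"] >= css_min)
        hits <- hits + 1L
    }
    hits
  }
  codes <- oracle_codes(seq_string)
  rc <- rev(5L - codes)
  count_strand(codes) + count_strand(rc)
}

## Oracle CREF row: counts for every pwm of a library on one promoter
## sequence at a named profile.
oracle_cref_row <- function(pwm_lib, seq_string, profile) {
  vapply(pwm_lib, function(p) {
    th <- p$thresholds[[profile]]
    oracle_scan_count(p, seq_string, th[["mss"]], th[["css"]])
  }, integer(1))
}
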