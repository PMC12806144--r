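## Position weight matrices and MATCH-style similarity scoring.
##
## A motif is scored on an L-mer with the information-weighted similarity
## used by TRANSFAC's MATCH tool: each position i carries an information
## weight I(i) = sum_b f(i,b) * ln(4 f(i,b)); the raw score of a window is
## sum_i I(i) f(i, b_i), and the matrix similarity score (MSS) rescales it
## between the per-position least- and most-probable bases so that the
## consensus scores 1 and the anti-consensus scores 0. The core similarity
## score (CSS) is the same quantity restricted to the 5 consecutive
## positions of highest information content.

DNA_BASES <- c("A", "C", "G", "T")

#' Construct a position weight matrix object
#'
#' @param id Motif identifier.
#' @param prob Numeric L x 4 matrix of per-position base probabilities with
#'   columns in order A, C, G, T; each row must sum to 1 (tolerance 1e-9)
#'   and L must be at least 4.
#' @param thresholds Named list of threshold profiles; each profile is a
#'   numeric vector `c(mss = , css = )` with both values in \[0, 1\]. The
#'   defaults provide a permissive `minFN` profile (mss 0.70, css 0.75) and
#'   a stringent `minFP` profile (mss 0.90, css 0.95).
#' @param pseudocount Added to every probability before computing the
#'   information weights, avoiding log(0) for zero-frequency bases.
#'
#' @return An object of class `pwm` carrying the probability matrix, the
#'   pseudocounted probabilities, per-position information weights, the
#'   5-position core block, and threshold profiles.
#' @export
pwm <- function(id, prob,
                thresholds = list(minFN = c(mss = 0.70, css = 0.75),
                                  minFP = c(mss = 0.90, css = 0.95)),
                pseudocount = 0.01) {
  prob <- as.matrix(prob)
  if (ncol(prob) != 4L)
    stop_cref("PWM probability matrix must have 4 columns (A,C,G,T)",
              "pwm_error")
  if (nrow(prob) < 4L)
    stop_cref("PWM must have length >= 4", "pwm_error")
  if (any(abs(rowSums(prob) - 1) > 1e-9))
    stop_cref("PWM probability rows must each sum to 1", "pwm_error")
  if (any(prob < 0))
    stop_cref("PWM probabilities must be non-negative", "pwm_error")
  colnames(prob) <- DNA_BASES

  f <- prob + pseudocount
  f <- f / rowSums(f)
  info <- rowSums(f * log(4 * f))
  L <- nrow(prob)

  ## core: the contiguous 5-position block of maximal total information
  if (L >= 5L) {
    starts <- seq_len(L - 4L)
    tot <- vapply(starts, function(s) sum(info[s:(s + 4L)]), numeric(1))
    s0 <- starts[which.max(tot)]
    core <- s0:(s0 + 4L)
  } else {
    core <- seq_len(L)
  }

  weights <- info * f                      # L x 4, I(i) * f(i, b)
  structure(list(id = as.character(id),
                 prob = prob,
                 f = f,
                 info = info,
                 core = core,
                 weights = weights,
                 w_min = apply(weights, 1L, min),
                 w_max = apply(weights, 1L, max),
                 thresholds = thresholds),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("<pwm> %s  length %d  core %d-%d  IC %.2f\n",
              x$id, nrow(x$prob), min(x$core), max(x$core), sum(x$info)))
  invisible(x)
}

#' Consensus sequence of a PWM (most probable base at each position)
#' @param x A `pwm` object.
#' @return A character scalar over A/C/G/T.
#' @export
pwm_consensus <- function(x) {
  stopifnot(inherits(x, "pwm"))
  paste(DNA_BASES[apply(x$prob, 1L, which.max)], collapse = "")
}

#' Bundle PWMs into a motif library
#'
#' @param pwms List of `pwm` objects with unique ids.
#' @return A `pwm_library` (a named list of `pwm` objects).
#' @export
pwm_library <- function(pwms) {
  stopifnot(is.list(pwms), all(vapply(pwms, inherits, logical(1), "pwm")))
  ids <- vapply(pwms, function(p) p$id, character(1))
  if (anyDuplicated(ids))
    stop_cref("duplicate motif ids in PWM library", "pwm_error")
  names(pwms) <- ids
  structure(pwms, class = "pwm_library")
}

#' @export
print.pwm_library <- function(x, ...) {
  cat(sprintf("<pwm_library> %d motifs\n", length(x)))
  invisible(x)
}

#' Motif ids of a PWM library
#' @param lib A `pwm_library`.
#' @export
pwm_ids <- function(lib) {
  stopifnot(inherits(lib, "pwm_library"))
  unname(vapply(lib, function(p) p$id, character(1)))
}

## Resolve a threshold profile (a profile name defined on the pwm, or a
## named numeric vector c(mss=, css=)) to the numeric pair.
resolve_thresholds <- function(p, profile) {
  if (is.numeric(profile)) {
    if (!all(c("mss", "css") %in% names(profile)))
      stop_cref("numeric threshold must be named c(mss=, css=)",
                "threshold_error")
    return(profile[c("mss", "css")])
  }
  th <- p$thresholds[[profile]]
  if (is.null(th))
    stop_cref(sprintf("threshold profile '%s' not defined for motif %s",
                      profile, p$id), "threshold_error")
  th[c("mss", "css")]
}

seq_to_codes <- function(sequence) {
  if (inherits(sequence, "DNAString") || inherits(sequence, "DNAStringSet"))
    sequence <- as.character(sequence)
  stopifnot(is.character(sequence), length(sequence) == 1L)
  chars <- strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
  match(chars, DNA_BASES)                       # non-ACGT -> NA
}

#' Score a PWM against a single window
#'
#' Computes the MATCH-style matrix similarity score (MSS) and core
#' similarity score (CSS), both in \[0, 1\]. The consensus window scores
#' MSS = 1 and the anti-consensus window scores MSS = 0. Windows containing
#' an ambiguous base (e.g. N) are skipped, not scored. A PWM whose
#' information weights are all zero (uniform probabilities) is degenerate:
#' the score is defined to be 0 and flagged.
#'
#' @param p A `pwm` object.
#' @param window A character string or `DNAString` of the same length as
#'   the PWM.
#' @return A list with elements `mss`, `css`, `skipped` (ambiguous base)
#'   and `degenerate` (uninformative PWM).
#' @export
score_pwm_window <- function(p, window) {
  stopifnot(inherits(p, "pwm"))
  codes <- seq_to_codes(window)
  L <- nrow(p$prob)
  if (length(codes) != L)
    stop_cref("window length must equal PWM length", "pwm_error")
  if (anyNA(codes))
    return(list(mss = NA_real_, css = NA_real_,
                skipped = TRUE, degenerate = FALSE))
  cur <- sum(p$weights[cbind(seq_len(L), codes)])
  lo <- sum(p$w_min); hi <- sum(p$w_max)
  core <- p$core
  curC <- sum(p$weights[cbind(core, codes[core])])
  loC <- sum(p$w_min[core]); hiC <- sum(p$w_max[core])
  if (hi - lo < 1e-12)
    return(list(mss = 0, css = 0, skipped = FALSE, degenerate = TRUE))
  css <- if (hiC - loC < 1e-12) 0 else (curC - loC) / (hiC - loC)
  list(mss = (cur - lo) / (hi - lo), css = css,
       skipped = FALSE, degenerate = FALSE)
}

## Vectorized single-strand scan: MSS and CSS for every window start.
## Windows containing an ambiguous base get NA scores.
scan_strand <- function(p, codes) {
  L <- nrow(p$prob)
  n <- length(codes)
  nw <- n - L + 1L
  if (nw < 1L) return(NULL)
  cur <- numeric(nw)
  curC <- numeric(nw)
  in_core <- seq_len(L) %in% p$core
  for (i in seq_len(L)) {
    wi <- p$weights[i, ]
    contrib <- wi[codes[i:(nw + i - 1L)]]
    cur <- cur + contrib
    if (in_core[i]) curC <- curC + contrib
  }
  lo <- sum(p$w_min); hi <- sum(p$w_max)
  loC <- sum(p$w_min[p$core]); hiC <- sum(p$w_max[p$core])
  degenerate <- (hi - lo) < 1e-12
  mss <- if (degenerate) rep(0, nw) else (cur - lo) / (hi - lo)
  css <- if ((hiC - loC) < 1e-12) rep(0, nw) else (curC - loC) / (hiC - loC)
  if (degenerate) {
    bad <- is.na(cur)
    mss[bad] <- NA_real_; css[bad] <- NA_real_
  }
  list(mss = mss, css = css)
}

#' Count PWM hits on a sequence (both strands)
#'
#' Scans every window of the forward sequence and of its reverse complement
#' and counts windows whose MSS and CSS both reach the thresholds of the
#' chosen profile. Overlapping hits are each counted; a palindromic site
#' counts once per strand. Windows containing ambiguous bases are skipped.
#'
#' @param p A `pwm` object.
#' @param sequence Character string or `DNAString`.
#' @param profile Threshold profile name (default `"minFN"`) or a named
#'   numeric vector `c(mss =, css =)`.
#' @param detail If `TRUE`, return a data.frame of individual hits
#'   (0-based forward-strand offset, strand, mss, css) instead of a count.
#' @return Integer hit count, or a data.frame when `detail = TRUE`.
#' @export
scan_sequence <- function(p, sequence, profile = "minFN", detail = FALSE) {
  stopifnot(inherits(p, "pwm"))
  th <- resolve_thresholds(p, profile)
  codes <- seq_to_codes(sequence)
  L <- nrow(p$prob)
  n <- length(codes)
  hits <- list()
  fwd <- scan_strand(p, codes)
  if (!is.null(fwd)) {
    ok <- !is.na(fwd$mss) & fwd$mss >= th[["mss"]] & fwd$css >= th[["css"]]
    idx <- which(ok)
    if (length(idx))
      hits[["+"]] <- data.frame(offset = idx - 1L, strand = "+",
                                mss = fwd$mss[idx], css = fwd$css[idx])
  }
  rc_codes <- rev(5L - codes)                  # reverse complement in codes
  rev_ <- scan_strand(p, rc_codes)
  if (!is.null(rev_)) {
    ok <- !is.na(rev_$mss) & rev_$mss >= th[["mss"]] & rev_$css >= th[["css"]]
    idx <- which(ok)
    if (length(idx))
      ## report the position of a minus-strand hit in forward coordinates
      hits[["-"]] <- data.frame(offset = n - (idx - 1L) - L, strand = "-",
                                mss = rev_$mss[idx], css = rev_$css[idx])
  }
  out <- if (length(hits)) do.call(rbind, hits) else
    data.frame(offset = integer(0), strand = character(0),
               mss = numeric(0), css = numeric(0))
  rownames(out) <- NULL
  if (detail) out[order(out$offset, out$strand), , drop = FALSE]
  else nrow(out)
}

#' Read a TRANSFAC-format matrix file
#'
#' Parses the plain-text TRANSFAC matrix format: records separated by
#' `//`, identified by `ID`/`AC`/`NA` lines, with a `P0` (or `PO`) header
#' row followed by per-position base-count rows. Counts are converted to
#' probabilities row-wise.
#'
#' @param path Path to the matrix file.
#' @inheritParams pwm
#' @return A `pwm_library`.
#' @export
read_transfac <- function(path, thresholds = NULL) {
  lines <- readLines(path)
  pwms <- list()
  id <- NULL; rows <- list()
  flush <- function() {
    if (!is.null(id) && length(rows)) {
      counts <- do.call(rbind, rows)
      prob <- counts / rowSums(counts)
      args <- list(id = id, prob = prob)
      if (!is.null(thresholds)) args$thresholds <- thresholds
      pwms[[length(pwms) + 1L]] <<- do.call(pwm, args)
    }
    id <<- NULL; rows <<- list()
  }
  for (ln in lines) {
    ln <- trimws(ln)
    if (ln == "//") { flush(); next }
    if (ln == "" || grepl("^XX", ln)) next
    tag <- sub("^([A-Z0-9]+)\\s.*$", "\\1", ln)
    if (tag %in% c("ID", "AC", "NA")) {
      val <- trimws(sub("^[A-Z0-9]+\\s+", "", ln))
      if (is.null(id) || tag == "ID") id <- val
    } else if (grepl("^P[O0]\\b", ln)) {
      next
    } else if (grepl("^[0-9]+\\s", ln)) {
      fields <- strsplit(ln, "\\s+")[[1]]
      rows[[length(rows) + 1L]] <- as.numeric(fields[2:5])
    }
  }
  flush()
  if (!length(pwms))
    stop_cref("no matrices found in TRANSFAC file", "pwm_error")
  pwm_library(pwms)
}

#' Read JASPAR PFM text
#'
#' Parses the JASPAR text format: a `>ID name` header followed by four rows
#' `A [ counts ]`, `C [...]`, `G [...]`, `T [...]` (brackets optional).
#'
#' @inheritParams read_transfac
#' @return A `pwm_library`.
#' @export
read_jaspar <- function(path, thresholds = NULL) {
  lines <- readLines(path)
  pwms <- list()
  i <- 1L
  while (i <= length(lines)) {
    ln <- trimws(lines[i])
    if (startsWith(ln, ">")) {
      id <- strsplit(sub("^>", "", ln), "\\s+")[[1]][1]
      mat <- matrix(NA_real_, nrow = 4L, ncol = 0L)
      rows <- list()
      for (j in 1:4) {
        row <- trimws(lines[i + j])
        row <- gsub("^[ACGT]\\s*", "", row)
        row <- gsub("[][]", " ", row)
        rows[[j]] <- as.numeric(strsplit(trimws(row), "\\s+")[[1]])
      }
      counts <- t(do.call(rbind, rows))       # L x 4
      prob <- counts / rowSums(counts)
      args <- list(id = id, prob = prob)
      if (!is.null(thresholds)) args$thresholds <- thresholds
      pwms[[length(pwms) + 1L]] <- do.call(pwm, args)
      i <- i + 5L
    } else i <- i + 1L
  }
  if (!length(pwms))
    stop_cref("no matrices found in JASPAR file", "pwm_error")
  pwm_library(pwms)
}

#' Write a PWM library in TRANSFAC matrix format
#'
#' @param lib A `pwm_library`.
#' @param path Output path.
#' @param scale Counts written are `round(prob * scale)`.
#' @export
write_transfac <- function(lib, path, scale = 100) {
  stopifnot(inherits(lib, "pwm_library"))
  con <- file(path, "w")
  on.exit(close(con))
  for (p in lib) {
    writeLines(c(sprintf("ID %s", p$id), "P0      A      C      G      T"),
               con)
    counts <- round(p$prob * scale)
    for (i in seq_len(nrow(counts))) {
      cons <- DNA_BASES[which.max(p$prob[i, ])]
      writeLines(sprintf("%02d %6d %6d %6d %6d %s", i,
                         counts[i, 1], counts[i, 2], counts[i, 3],
                         counts[i, 4], cons), con)
    }
    writeLines("//", con)
  }
  invisible(path)
}

#' Generate a library of sharp synthetic PWMs
#'
#' Produces random high-information motifs whose consensus windows score
#' MSS = 1 by construction: at each position one dominant base carries most
#' of the probability mass. Such motifs make hit-free background sequences
#' easy to sample, which the promoter and repeat fixtures rely on.
#'
#' @param n_motifs Number of motifs.
#' @param length_range Integer range of motif lengths (inclusive).
#' @param dominance Range of the per-position probability of the consensus
#'   base; the remainder is split equally among the other bases.
#' @param seed Integer seed; identical seeds give identical libraries.
#' @inheritParams pwm
#' @return A `pwm_library` with motif ids `SYN_M001`, `SYN_M002`, ...
#' @export
random_pwm_library <- function(n_motifs, length_range = c(10L, 14L),
                               dominance = c(0.85, 0.95), seed = 1L,
                               thresholds = list(
                                 minFN = c(mss = 0.70, css = 0.75),
                                 minFP = c(mss = 0.90, css = 0.95))) {
  with_seed(seed, {
    pwms <- lapply(seq_len(n_motifs), function(i) {
      L <- sample(seq(length_range[1], length_range[2]), 1L)
      cons <- sample(1:4, L, replace = TRUE)
      dom <- stats::runif(L, dominance[1], dominance[2])
      prob <- matrix((1 - dom) / 3, nrow = L, ncol = 4L)
      prob[cbind(seq_len(L), cons)] <- dom
      pwm(sprintf("SYN_M%03d", i), prob, thresholds = thresholds)
    })
    pwm_library(pwms)
  })
}

#' Apply per-motif threshold profiles from a TSV file
#'
#' The file has columns `motif_id`, `profile`, `mss`, `css`; each row
#' (re)defines one profile for one motif, overriding the library's
#' defaults. Motifs absent from the file keep their current profiles.
#'
#' @param lib A `pwm_library`.
#' @param path TSV path (or a data.frame with the same columns).
#' @return The library with updated per-motif thresholds.
#' @export
apply_threshold_file <- function(lib, path) {
  stopifnot(inherits(lib, "pwm_library"))
  tab <- if (is.data.frame(path)) path else
    utils::read.table(path, sep = "\t", header = TRUE,
                      stringsAsFactors = FALSE)
  need <- c("motif_id", "profile", "mss", "css")
  if (!all(need %in% names(tab)))
    stop_cref("thresholds file needs columns motif_id, profile, mss, css",
              "threshold_error")
  unknown <- setdiff(unique(tab$motif_id), pwm_ids(lib))
  if (length(unknown))
    warning(sprintf("thresholds for %d unknown motif(s) ignored",
                    length(unknown)))
  out <- lapply(lib, function(p) {
    rows <- tab[tab$motif_id == p$id, , drop = FALSE]
    for (i in seq_len(nrow(rows)))
      p$thresholds[[rows$profile[i]]] <- c(mss = rows$mss[i],
                                           css = rows$css[i])
    p
  })
  pwm_library(out)
}
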