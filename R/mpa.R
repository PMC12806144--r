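## Motifs present on repeat (Alu/SVA-like) consensus sequences, their
## counts at eigenvector poles, relative changes between species, motif-
## set Jaccard similarity, and overlap of promoter windows with repeat
## insertions.

#' Identify motifs present on repeat consensus sequences (MPA)
#'
#' Scans every motif of the library against every consensus sequence
#' (both strands) and returns the set of motifs with at least one hit at
#' the profile's thresholds.
#'
#' @param pwm_lib A `pwm_library`.
#' @param repeats `DNAStringSet` of consensus sequences, or FASTA path.
#' @param profile Threshold profile (default `"minFN"`, the permissive
#'   option used for motif discovery).
#' @return Sorted character vector of motif ids (empty for an empty
#'   library or empty repeat file).
#' @export
find_mpa <- function(pwm_lib, repeats, profile = "minFN") {
  stopifnot(inherits(pwm_lib, "pwm_library"))
  if (is.character(repeats) && length(repeats) == 1L)
    repeats <- Biostrings::readDNAStringSet(repeats)
  if (length(pwm_lib) == 0L || length(repeats) == 0L) return(character(0))
  seqs <- as.character(repeats)
  present <- vapply(pwm_lib, function(p) {
    for (s in seqs) if (scan_sequence(p, s, profile) > 0L) return(TRUE)
    FALSE
  }, logical(1))
  sort(unname(pwm_ids(pwm_lib)[present]))
}

#' Top pole motifs of a polarized motif-eigenvector
#'
#' @inheritParams top_pole_genes
#' @param n Pole size (default 100: motifs ranked outside the top 100
#'   are treated as off-pole).
#' @return Character vector of motif ids, most extreme first.
#' @export
pole_motifs <- function(decomposition, level,
                        pole = c("positive", "negative"), n = 100L) {
  pole <- match.arg(pole)
  mod <- module_at(decomposition, level)
  m <- length(mod$motif_vector)
  if (n > m) stop_cref("n exceeds the number of motifs", "mpa_error")
  ord <- mod$motif_order
  idx <- if (pole == "positive") utils::head(ord, n) else
    rev(utils::tail(ord, n))
  names(mod$motif_vector)[idx]
}

#' Relative change of an MPA count from a reference species to a focal
#' species, in percent
#'
#' @param count_focal,count_ref Non-negative integers; the reference
#'   count must be positive.
#' @return `100 * (count_focal - count_ref) / count_ref`.
#' @export
mpa_relative_change <- function(count_focal, count_ref) {
  if (any(count_ref <= 0))
    stop_cref("relative change undefined for reference count 0",
              "undefined_change_error")
  100 * (count_focal - count_ref) / count_ref
}

#' Jaccard similarity of two sets
#'
#' @param a,b Vectors treated as sets.
#' @return `|intersect| / |union|` in \[0, 1\]; two empty sets give 1
#'   with attribute `both_empty = TRUE`.
#' @export
jaccard <- function(a, b) {
  a <- unique(a); b <- unique(b)
  if (!length(a) && !length(b))
    return(structure(1, both_empty = TRUE))
  length(intersect(a, b)) / length(union(a, b))
}

#' Per-level MPA pole counts and cross-species relative changes
#'
#' Counts, at every level, how many pole motifs of each species belong to
#' the MPA set, and the relative change from the reference species to the
#' focal one.
#'
#' @param decomp_focal,decomp_ref `dual_decomposition` objects (focal vs
#'   reference species).
#' @param mpa_set Motif-id set from [find_mpa()].
#' @param levels Levels to report.
#' @param pole Which pole to count (positive by default; use `"both"`
#'   for the union of the two poles).
#' @param n Pole size.
#' @return Data.frame with `level`, `count_focal`, `count_ref`,
#'   `relative_change_pct` (NA when the reference count is 0).
#' @export
mpa_report <- function(decomp_focal, decomp_ref, mpa_set,
                       levels = seq_len(min(decomp_focal$n_levels,
                                            decomp_ref$n_levels)),
                       pole = "positive", n = 100L) {
  count_one <- function(decomp, k) {
    ids <- if (pole == "both")
      union(pole_motifs(decomp, k, "positive", n),
            pole_motifs(decomp, k, "negative", n))
    else pole_motifs(decomp, k, pole, n)
    length(intersect(ids, mpa_set))
  }
  rows <- lapply(levels, function(k) {
    cf <- count_one(decomp_focal, k)
    cr <- count_one(decomp_ref, k)
    data.frame(level = k, count_focal = cf, count_ref = cr,
               relative_change_pct = if (cr > 0)
                 mpa_relative_change(cf, cr) else NA_real_)
  })
  do.call(rbind, rows)
}

## Normalize repeat intervals (BED path, RepeatMasker .out path, or a
## data.frame with name/chrom/start/end) into 0-based half-open rows.
normalize_repeat_intervals <- function(repeats) {
  if (is.character(repeats) && length(repeats) == 1L) {
    first <- readLines(repeats, n = 1L)
    repeats <- if (grepl("^\\s*(SW|score)\\b", first) ||
                   grepl("perc", first))
      read_repeatmasker_out(repeats)
    else read_bed(repeats)
  }
  stopifnot(is.data.frame(repeats),
            all(c("name", "chrom", "start", "end") %in% names(repeats)))
  if (any(repeats$end < repeats$start))
    stop_cref("malformed repeat interval: end < start", "parse_error")
  repeats
}

#' Read a BED file of repeat intervals (0-based half-open)
#' @param path BED path (columns chrom, start, end, name, ...).
#' @return Data.frame with `name`, `chrom`, `start`, `end`.
#' @export
read_bed <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 3L) stop_cref("BED needs >= 3 columns", "parse_error")
  data.frame(name = if (ncol(df) >= 4L) as.character(df[[4]])
             else sprintf("repeat_%d", seq_len(nrow(df))),
             chrom = as.character(df[[1]]),
             start = as.integer(df[[2]]), end = as.integer(df[[3]]),
             stringsAsFactors = FALSE)
}

#' Read a RepeatMasker .out table (1-based inclusive, converted to
#' 0-based half-open)
#' @param path RepeatMasker output path.
#' @return Data.frame with `name`, `chrom`, `start`, `end`.
#' @export
read_repeatmasker_out <- function(path) {
  lines <- readLines(path)
  body <- lines[grepl("^\\s*[0-9]+\\s", lines)]
  if (!length(body)) stop_cref("no intervals in RepeatMasker file",
                               "parse_error")
  fields <- strsplit(trimws(body), "\\s+")
  data.frame(name = vapply(fields, `[`, character(1), 10L),
             chrom = vapply(fields, `[`, character(1), 5L),
             start = as.integer(vapply(fields, `[`, character(1), 6L)) - 1L,
             end = as.integer(vapply(fields, `[`, character(1), 7L)),
             stringsAsFactors = FALSE)
}

#' Flag promoter windows overlapping repeat insertions
#'
#' Intersects promoter windows with repeat intervals (both 0-based
#' half-open on the same assembly) and reports every (gene, repeat) pair
#' overlapping by at least 1 bp, with the overlap length. Adjacent
#' half-open intervals do not overlap.
#'
#' @param promoters Data.frame with `gene_id`, `chrom`, `start`, `end`
#'   (e.g. the `regions` attribute of [build_cref()]).
#' @param repeats Repeat intervals: BED path, RepeatMasker .out path, or
#'   a data.frame with `name`, `chrom`, `start`, `end` (0-based
#'   half-open).
#' @return Data.frame (`gene_id`, `repeat_name`, `overlap`) sorted by
#'   gene then repeat.
#' @export
flag_repeat_insertions <- function(promoters, repeats) {
  repeats <- normalize_repeat_intervals(repeats)
  stopifnot(all(c("gene_id", "chrom", "start", "end") %in%
                  names(promoters)))
  ## half-open -> 1-based inclusive for IRanges; empty intervals dropped
  gr_p <- GenomicRanges::GRanges(promoters$chrom,
                                 IRanges::IRanges(promoters$start + 1L,
                                                  promoters$end))
  gr_r <- GenomicRanges::GRanges(repeats$chrom,
                                 IRanges::IRanges(repeats$start + 1L,
                                                  repeats$end))
  hits <- GenomicRanges::findOverlaps(gr_p, gr_r, minoverlap = 1L)
  ov <- IRanges::width(IRanges::pintersect(
    IRanges::ranges(gr_p)[S4Vectors::queryHits(hits)],
    IRanges::ranges(gr_r)[S4Vectors::subjectHits(hits)]))
  out <- data.frame(gene_id = promoters$gene_id[S4Vectors::queryHits(hits)],
                    repeat_name = repeats$name[S4Vectors::subjectHits(hits)],
                    overlap = ov, stringsAsFactors = FALSE)
  out <- out[order(out$gene_id, out$repeat_name), , drop = FALSE]
  rownames(out) <- NULL
  out
}
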