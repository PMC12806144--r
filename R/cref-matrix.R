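## The CREF matrix: genes x motifs counts of cis-regulatory elements found
## in proximal promoter windows, the basic data container of the package.

#' Construct a CREF matrix
#'
#' @param counts Non-negative integer matrix, genes as rows and motifs as
#'   columns.
#' @param gene_ids,motif_ids Unique row/column labels; taken from
#'   `dimnames(counts)` when omitted.
#' @param species Species tag (free text).
#' @return A `cref_matrix`: the counts matrix with labels and a `species`
#'   attribute.
#' @export
cref_matrix <- function(counts, gene_ids = rownames(counts),
                        motif_ids = colnames(counts), species = "unknown") {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop_cref("CREF entries must be non-negative",
                                 "cref_error")
  if (any(counts != floor(counts)))
    stop_cref("CREF entries must be integers", "cref_error")
  if (is.null(gene_ids)) gene_ids <- sprintf("gene_%05d", seq_len(nrow(counts)))
  if (is.null(motif_ids) && ncol(counts) > 0)
    motif_ids <- sprintf("motif_%04d", seq_len(ncol(counts)))
  if (length(gene_ids) != nrow(counts) ||
      length(motif_ids %||% character(0)) != ncol(counts))
    stop_cref("label lengths do not match matrix dimensions", "cref_error")
  if (anyDuplicated(gene_ids) || anyDuplicated(motif_ids))
    stop_cref("gene and motif ids must be unique", "cref_error")
  dimnames(counts) <- list(gene_ids, motif_ids)
  structure(counts, species = species, class = c("cref_matrix", "matrix"))
}

#' @export
print.cref_matrix <- function(x, ...) {
  cat(sprintf("<cref_matrix> %s: %d genes x %d motifs, total count %s\n",
              attr(x, "species"), nrow(x), ncol(x),
              format(sum(x), big.mark = ",")))
  invisible(x)
}

#' Binary cis-regulatory element incidence (CREI) matrix
#'
#' Thresholds a CREF matrix at presence/absence: entry (i, j) is 1 when
#' motif j occurs at least once in gene i's promoter window.
#'
#' @param cref A `cref_matrix`.
#' @return A `cref_matrix` of 0/1 incidences with the same labels.
#' @export
build_crei <- function(cref) {
  stopifnot(inherits(cref, "cref_matrix"))
  m <- unclass(cref)
  storage.mode(m) <- "integer"
  cref_matrix((m > 0L) * 1L, rownames(cref), colnames(cref),
              species = attr(cref, "species"))
}

#' Per-motif quantiles of cis-element multiplicity
#'
#' Summarizes, for each motif, the distribution of its occurrence counts
#' across genes by empirical (type-1) quantiles rounded to integers
#' (half-up), mirroring the usual presentation of motif multiplicity.
#'
#' @param cref A `cref_matrix`.
#' @param probs Sorted quantile probabilities in (0, 1); the default
#'   `c(0.10, 0.50, 0.90)` gives the lower decile, median and upper decile.
#' @return A data.frame with one row per motif and one column per
#'   probability (`q10`, `q50`, ... by percent).
#' @export
motif_multiplicity_quantiles <- function(cref, probs = c(0.10, 0.50, 0.90)) {
  stopifnot(inherits(cref, "cref_matrix"))
  if (is.unsorted(probs)) stop_cref("probs must be sorted", "cref_error")
  q <- apply(unclass(cref), 2L, stats::quantile, probs = probs,
             type = 1, names = FALSE)
  q <- if (is.null(dim(q))) matrix(q, nrow = length(probs)) else q
  out <- as.data.frame(t(round_half_up(q)))
  names(out) <- sprintf("q%02d", round(probs * 100))
  data.frame(motif_id = colnames(cref) %||% character(0), out,
             row.names = NULL)
}

#' Write / read a CREF matrix as TSV
#'
#' The on-disk format is a tab-separated table whose first column
#' (`gene_id`) holds gene identifiers and whose remaining columns are motif
#' ids.
#'
#' @param cref A `cref_matrix`.
#' @param path File path.
#' @export
write_cref <- function(cref, path) {
  stopifnot(inherits(cref, "cref_matrix"))
  df <- data.frame(gene_id = rownames(cref), unclass(cref),
                   check.names = FALSE)
  write_tsv(df, path)
}

#' @rdname write_cref
#' @param species Species tag attached to the matrix read back.
#' @export
read_cref <- function(path, species = "unknown") {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  cref_matrix(m, gene_ids = df[[1]], motif_ids = colnames(m),
              species = species)
}
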