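## Rank-based gene-set enrichment along polarized gene-eigenvectors.
##
## A gene set is enriched at a pole of a gene-eigenvector when its member
## loadings rank significantly toward that pole, assessed by a one-sided
## Wilcoxon rank-sum (Mann-Whitney) test of member versus non-member
## loadings. Ranks are computed on the raw (sign-fixed) loadings; the
## pole only chooses the direction of the alternative hypothesis.

#' Read / write gene sets in GMT format
#'
#' One set per line: name, description, then member ids, tab-separated.
#'
#' @param path GMT file path.
#' @return A named list of character vectors (class `gene_set_collection`)
#'   with a `source` attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  sets <- lapply(lines, function(ln) {
    fields <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    unique(fields[-(1:2)])
  })
  names(sets) <- vapply(lines, function(ln)
    strsplit(ln, "\t", fixed = TRUE)[[1]][1], character(1),
    USE.NAMES = FALSE)
  structure(sets, source = basename(path), class = "gene_set_collection")
}

#' @rdname read_gmt
#' @param sets Named list of character vectors.
#' @param description Second GMT column (recycled).
#' @export
write_gmt <- function(sets, path, description = "synthetic") {
  lines <- vapply(seq_along(sets), function(i)
    paste(c(names(sets)[i], description, sets[[i]]), collapse = "\t"),
    character(1))
  writeLines(lines, path)
  invisible(path)
}

#' One-sided Wilcoxon rank-sum enrichment of a gene set at a pole
#'
#' Tests whether member loadings rank higher toward the chosen pole than
#' non-member loadings: alternative `"greater"` on the loadings for the
#' positive pole, `"less"` for the negative pole. The exact null
#' distribution is enumerated for small problems (<= 10 resolved members
#' in a universe of <= 30 without ties); otherwise the normal
#' approximation with tie correction and continuity correction is used.
#' Unresolved members (absent from the universe) are dropped and counted.
#'
#' @param loadings Named numeric vector: the gene-eigenvector over the
#'   gene universe.
#' @param members Character vector of member gene ids.
#' @param pole `"positive"` or `"negative"`.
#' @param set_name Label carried into the result.
#' @return A one-row data.frame: `set`, `pole`, `n_members`,
#'   `n_unresolved`, `statistic` (rank-sum W of members vs rest), `p`.
#' @export
wilcoxon_enrichment <- function(loadings, members,
                                pole = c("positive", "negative"),
                                set_name = "set") {
  pole <- match.arg(pole)
  if (is.null(names(loadings)))
    stop_cref("loadings must be named by gene id", "enrichment_error")
  members <- unique(as.character(members))
  resolved <- intersect(members, names(loadings))
  if (!length(resolved))
    stop_cref("no gene-set member resolves against the universe",
              "enrichment_error")
  x <- loadings[resolved]
  y <- loadings[setdiff(names(loadings), resolved)]
  if (!length(y)) {
    ## degenerate: the set is the whole universe
    return(data.frame(set = set_name, pole = pole,
                      n_members = length(resolved),
                      n_unresolved = length(members) - length(resolved),
                      statistic = NA_real_, p = 1))
  }
  alternative <- if (pole == "positive") "greater" else "less"
  ties <- anyDuplicated(c(x, y)) > 0L
  exact <- length(resolved) <= 10L && length(loadings) <= 30L && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = alternative,
                       exact = exact, correct = TRUE))
  data.frame(set = set_name, pole = pole, n_members = length(resolved),
             n_unresolved = length(members) - length(resolved),
             statistic = unname(wt$statistic), p = wt$p.value)
}

#' Enrichment of a gene-set collection across levels and poles
#'
#' Runs [wilcoxon_enrichment()] for every (set, level, pole) combination
#' on the decomposition's gene-eigenvectors. Raw p-values are always
#' reported; Benjamini-Hochberg adjusted values are optional and off by
#' default.
#'
#' @param decomposition A `dual_decomposition`.
#' @param collection Named list of gene sets (e.g. from [read_gmt()]).
#' @param levels Levels to test (baseline excluded by default).
#' @param poles Poles to test.
#' @param bh Add a `p_bh` column of Benjamini-Hochberg adjusted values.
#' @return Data.frame with one row per (set, level, pole), ordered by
#'   level, pole, set.
#' @export
enrich_all <- function(decomposition, collection,
                       levels = seq_len(decomposition$n_levels),
                       poles = c("positive", "negative"), bh = FALSE) {
  stopifnot(inherits(decomposition, "dual_decomposition"))
  if (any(levels < 0L) || any(levels > decomposition$n_levels))
    stop_cref("levels outside decomposition depth", "decomposition_error")
  rows <- list()
  for (k in levels) {
    loadings <- module_at(decomposition, k)$gene_vector
    for (pole in poles) {
      for (nm in names(collection)) {
        row <- wilcoxon_enrichment(loadings, collection[[nm]], pole, nm)
        row$level <- k
        rows[[length(rows) + 1L]] <- row
      }
    }
  }
  out <- do.call(rbind, rows)
  out <- out[, c("set", "level", "pole", "n_members", "n_unresolved",
                 "statistic", "p")]
  if (bh) out$p_bh <- stats::p.adjust(out$p, method = "BH")
  out
}

#' Top pole genes of a polarized gene-eigenvector
#'
#' @param decomposition A `dual_decomposition`.
#' @param level Level index.
#' @param pole `"positive"` (head of the descending order) or
#'   `"negative"` (tail, most extreme first).
#' @param n Number of genes, `n <= g`.
#' @return Data.frame with `rank` (1 = most extreme at the pole),
#'   `gene_id`, `loading`.
#' @export
top_pole_genes <- function(decomposition, level,
                           pole = c("positive", "negative"), n) {
  pole <- match.arg(pole)
  mod <- module_at(decomposition, level)
  g <- length(mod$gene_vector)
  if (n > g) stop_cref("n exceeds the number of genes", "enrichment_error")
  ord <- mod$gene_order
  idx <- if (pole == "positive") utils::head(ord, n) else
    rev(utils::tail(ord, n))
  data.frame(rank = seq_len(n),
             gene_id = names(mod$gene_vector)[idx],
             loading = unname(mod$gene_vector[idx]))
}

#' Pole genes specific to a focal species
#'
#' Returns the genes in the focal species' top-N pole whose orthologs are
#' absent from every other species' top-N at the same level and pole.
#' Focal genes without an ortholog mapping are treated as
#' species-specific and counted.
#'
#' @param focal A `dual_decomposition` (the focal species).
#' @param others List of `dual_decomposition` objects.
#' @param level,pole,n As in [top_pole_genes()].
#' @param ortholog_maps `NULL` for the identity mapping (synthetic data),
#'   or a list parallel to `others` of named character vectors mapping
#'   focal gene ids to that species' gene ids.
#' @return Data.frame of species-specific pole genes (`rank`, `gene_id`,
#'   `loading`) with an `n_unmapped` attribute.
#' @export
species_specific_top_genes <- function(focal, others, level,
                                       pole = c("positive", "negative"),
                                       n, ortholog_maps = NULL) {
  pole <- match.arg(pole)
  if (n == 0L) {
    out <- data.frame(rank = integer(0), gene_id = character(0),
                      loading = numeric(0))
    attr(out, "n_unmapped") <- 0L
    return(out)
  }
  top_f <- top_pole_genes(focal, level, pole, n)
  n_unmapped <- 0L
  specific <- rep(TRUE, nrow(top_f))
  for (i in seq_along(others)) {
    top_o <- top_pole_genes(others[[i]], level, pole,
                            min(n, length(others[[i]]$gene_ids)))$gene_id
    mapped <- if (is.null(ortholog_maps)) top_f$gene_id else {
      mm <- ortholog_maps[[i]][top_f$gene_id]
      n_unmapped <- n_unmapped + sum(is.na(mm) & specific)
      mm
    }
    specific <- specific & (is.na(mapped) | !(mapped %in% top_o))
  }
  out <- top_f[specific, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_unmapped") <- n_unmapped
  out
}
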