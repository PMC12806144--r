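## Dual eigen-modules: the singular triplets (rho_k, u_k, v_k) of the
## low-rank part of a CREF matrix, with a deterministic sign convention
## and "polarization" (loadings sorted in descending order; the extremes
## of the order are the positive and negative poles). Level 0 is the
## baseline triplet and is skipped by downstream comparisons.

#' Apply the sign convention and polarization to one eigen-module
#'
#' SVD signs are arbitrary, so a deterministic convention is applied
#' before sorting: the motif-eigenvector gets the sign that makes the sum
#' of cubed loadings (its skewness direction) positive, and the
#' gene-eigenvector is flipped together with it so the singular value
#' stays non-negative. If the skewness is exactly zero, the sign making
#' the largest-magnitude loading positive is chosen. Polarizing an
#' already-polarized module is a no-op.
#'
#' @param module An `eigen_module` (see [svd_modules()]).
#' @return The module with `gene_vector`/`motif_vector` sign-fixed,
#'   descending `gene_order`/`motif_order` permutations filled in, and
#'   `sign_fixed = TRUE`. Ties in loadings are broken by label.
#' @export
polarize <- function(module) {
  stopifnot(inherits(module, "eigen_module"))
  v <- module$motif_vector
  u <- module$gene_vector
  degenerate <- length(unique(v)) == 1L
  skew <- sum(v^3)
  flip <- if (abs(skew) > 1e-12) skew < 0 else v[which.max(abs(v))] < 0
  if (flip) { v <- -v; u <- -u }
  order_desc <- function(x) {
    labs <- names(x) %||% as.character(seq_along(x))
    order(-x, labs)
  }
  module$motif_vector <- v
  module$gene_vector <- u
  module$motif_order <- order_desc(v)
  module$gene_order <- order_desc(u)
  module$sign_fixed <- TRUE
  module$degenerate <- degenerate
  module
}

new_eigen_module <- function(level, d, u, v, gene_ids, motif_ids) {
  names(u) <- gene_ids
  names(v) <- motif_ids
  structure(list(level = level, singular_value = d,
                 gene_vector = u, motif_vector = v,
                 gene_order = NULL, motif_order = NULL,
                 sign_fixed = FALSE,
                 baseline = level == 0L),
            class = "eigen_module")
}

#' @export
print.eigen_module <- function(x, ...) {
  cat(sprintf("<eigen_module> level %d%s, rho = %.4g\n", x$level,
              if (x$baseline) " (baseline)" else "", x$singular_value))
  invisible(x)
}

#' Extract polarized dual eigen-modules from a low-rank matrix
#'
#' Computes the SVD of `C`, truncates it to levels 0..`n_levels` (level 0
#' is the baseline and flagged as such), and polarizes every module.
#'
#' @param C Numeric matrix (typically the low-rank part of an
#'   [rpca_ialm()] fit), with gene/motif dimnames if available.
#' @param n_levels Deepest level retained; `n_levels + 1` singular
#'   triplets are kept and must not exceed `min(g, m)`.
#' @return A `dual_decomposition`: list with `modules` (eigen-modules
#'   0..n_levels), `singular_values` (the full spectrum head),
#'   `gene_ids`, `motif_ids`.
#' @export
svd_modules <- function(C, n_levels = 10L) {
  C <- as.matrix(C)
  if (n_levels + 1L > min(dim(C)))
    stop_cref("n_levels + 1 exceeds min(g, m)", "decomposition_error")
  sv <- svd(C)
  gene_ids <- rownames(C) %||% sprintf("gene_%05d", seq_len(nrow(C)))
  motif_ids <- colnames(C) %||% sprintf("motif_%04d", seq_len(ncol(C)))
  modules <- lapply(0:n_levels, function(k) {
    polarize(new_eigen_module(k, sv$d[k + 1L], sv$u[, k + 1L],
                              sv$v[, k + 1L], gene_ids, motif_ids))
  })
  structure(list(modules = modules,
                 singular_values = sv$d[seq_len(n_levels + 1L)],
                 n_levels = n_levels,
                 gene_ids = gene_ids, motif_ids = motif_ids),
            class = "dual_decomposition")
}

#' @export
print.dual_decomposition <- function(x, ...) {
  cat(sprintf("<dual_decomposition> levels 0..%d over %d genes x %d motifs\n",
              x$n_levels, length(x$gene_ids), length(x$motif_ids)))
  cat("  singular values:",
      paste(signif(x$singular_values, 4), collapse = ", "), "\n")
  invisible(x)
}

#' Fetch one module of a decomposition by level
#' @param decomposition A `dual_decomposition`.
#' @param level Level index (0 = baseline).
#' @export
module_at <- function(decomposition, level) {
  stopifnot(inherits(decomposition, "dual_decomposition"))
  if (level < 0L || level > decomposition$n_levels)
    stop_cref("level outside decomposition depth", "decomposition_error")
  decomposition$modules[[level + 1L]]
}

#' Robustly decompose a CREF matrix into polarized dual eigen-modules
#'
#' Convenience wrapper: [rpca_ialm()] followed by [svd_modules()] on the
#' low-rank part.
#'
#' @inheritParams rpca_ialm
#' @inheritParams svd_modules
#' @return A `dual_decomposition` with the `rpca_fit` attached as
#'   `$rpca`.
#' @export
decompose_cref <- function(ctilde, n_levels = 10L, lambda = "auto",
                           tol = 1e-7, max_iter = 200L, max_rank = Inf) {
  fit <- rpca_ialm(ctilde, lambda = lambda, tol = tol,
                   max_iter = max_iter, max_rank = max_rank)
  dec <- svd_modules(fit$low_rank, n_levels = n_levels)
  dec$rpca <- fit
  dec
}

#' Serialize a decomposition to TSV files
#'
#' Writes `<prefix>_singular_values.tsv`, `<prefix>_gene_loadings.tsv`
#' (genes x levels), `<prefix>_motif_loadings.tsv` (motifs x levels) and
#' `<prefix>_convergence.json`.
#'
#' @param decomposition A `dual_decomposition`.
#' @param prefix Output path prefix.
#' @return Invisibly, the vector of written paths.
#' @export
write_decomposition <- function(decomposition, prefix) {
  d <- decomposition
  lv <- sprintf("level_%d", 0:d$n_levels)
  paths <- c(sv = paste0(prefix, "_singular_values.tsv"),
             gene = paste0(prefix, "_gene_loadings.tsv"),
             motif = paste0(prefix, "_motif_loadings.tsv"),
             conv = paste0(prefix, "_convergence.json"))
  write_tsv(data.frame(level = 0:d$n_levels,
                       singular_value = d$singular_values), paths["sv"])
  gmat <- vapply(d$modules, function(m) m$gene_vector,
                 numeric(length(d$gene_ids)))
  colnames(gmat) <- lv
  write_tsv(data.frame(gene_id = d$gene_ids, gmat), paths["gene"])
  mmat <- vapply(d$modules, function(m) m$motif_vector,
                 numeric(length(d$motif_ids)))
  colnames(mmat) <- lv
  write_tsv(data.frame(motif_id = d$motif_ids, mmat), paths["motif"])
  conv <- if (!is.null(d$rpca))
    list(iterations = d$rpca$iterations, residual = d$rpca$residual,
         converged = d$rpca$converged, lambda = d$rpca$lambda,
         rank = d$rpca$rank)
  else list(iterations = NA, residual = NA, converged = NA)
  jsonlite::write_json(conv, paths["conv"], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
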