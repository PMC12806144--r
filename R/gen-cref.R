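## Synthetic CREF count matrices with planted low-rank structure, sparse
## outliers and count noise, plus matched two-species pairs.

#' Generate a synthetic CREF matrix from a planted model
#'
#' The observed matrix is `round(max(0, L + S + noise))` where
#' `L = sum_k rho_k u_k v_k'` is the planted low-rank part, `S` carries
#' exactly `ceiling(corruption_fraction * g * m)` large positive outliers
#' at seeded positions, and the noise follows the model's noise_model
#' (Poisson noise has mean equal to the low-rank entry). Identical models
#' (same seed) yield bit-identical output.
#'
#' @param model A `planted_model`.
#' @return An object of class `cref_sim`: a list with `cref` (the
#'   `cref_matrix`), `low_rank` (ground-truth L), `sparse` (planted
#'   outlier matrix), `outlier_mask` (logical matrix) and `model`.
#' @export
gen_cref <- function(model) {
  stopifnot(inherits(model, "planted_model"))
  g <- model$n_genes; m <- model$n_motifs
  L <- model$gene_factors %*% (model$spectrum * t(model$motif_factors))
  with_seed(model$seed + 13L, {
    n_out <- ceiling(model$corruption_fraction * g * m)
    mask <- matrix(FALSE, g, m)
    S <- matrix(0, g, m)
    if (n_out > 0L) {
      pos <- sample.int(g * m, n_out)
      mask[pos] <- TRUE
      S[pos] <- stats::runif(n_out, 3, 8) * mean(L)
    }
    noise <- switch(model$noise_model,
      none = matrix(0, g, m),
      poisson = matrix(stats::rpois(g * m, lambda = pmax(L, 0)) - L, g, m),
      `rounded-gaussian` = matrix(stats::rnorm(g * m, 0,
                                               sqrt(pmax(L, 1))), g, m))
    counts <- round(pmax(L + S + noise, 0))
    gene_ids <- sprintf("gene_%05d", seq_len(g))
    motif_ids <- sprintf("motif_%04d", seq_len(m))
    dimnames(L) <- dimnames(S) <- dimnames(mask) <-
      list(gene_ids, motif_ids)
    structure(list(cref = cref_matrix(counts, gene_ids, motif_ids,
                                      species = model$species),
                   low_rank = L, sparse = S, outlier_mask = mask,
                   model = model),
              class = "cref_sim")
  })
}

#' @export
print.cref_sim <- function(x, ...) {
  cat(sprintf("<cref_sim> %d x %d, %d planted outliers\n",
              nrow(x$cref), ncol(x$cref), sum(x$outlier_mask)))
  invisible(x)
}

## Rotate two columns of a factor matrix within their 2-D span.
rotate_factor_pair <- function(V, k, theta_deg) {
  th <- theta_deg * pi / 180
  vk <- V[, k]; vk1 <- V[, k + 1L]
  V[, k] <- cos(th) * vk + sin(th) * vk1
  V[, k + 1L] <- -sin(th) * vk + cos(th) * vk1
  V
}

#' Generate a matched two-species pair of synthetic CREF matrices
#'
#' Species A realizes the scenario's base model. Species B shares A's
#' motif labels and motif factors except at the rotated level pair, whose
#' two motif-eigenvectors are rotated within their span by the scenario
#' angle; B's gene factors are freshly drawn (different gene space) and
#' its spectrum carries the same near-degenerate gap.
#'
#' @param scenario A `saltation_scenario`.
#' @return A list with `a` and `b` (both `cref_sim`) and the `scenario`.
#' @export
gen_species_pair <- function(scenario) {
  stopifnot(inherits(scenario, "saltation_scenario"))
  base <- scenario$base
  k <- scenario$rotated_pair[1]
  V_B <- rotate_factor_pair(base$motif_factors, k + 1L,
                            scenario$rotation_deg)
  s <- length(base$spectrum) - 1L
  U_B <- planted_factors(base$n_genes, s, scenario$seed + 101L)
  model_b <- planted_model(base$n_genes, base$n_motifs,
                           spectrum = base$spectrum,
                           corruption_fraction = base$corruption_fraction,
                           noise_model = base$noise_model,
                           mean_count = base$mean_count,
                           seed = scenario$seed + 211L,
                           gene_factors = U_B, motif_factors = V_B,
                           species = "species_B")
  list(a = gen_cref(base), b = gen_cref(model_b), scenario = scenario)
}
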