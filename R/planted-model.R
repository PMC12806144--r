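## Planted ground truth for synthetic CREF matrices.
##
## A planted model holds an exact low-rank matrix L = sum_k rho_k u_k v_k'
## whose level-0 triplet is a dense positive baseline (constant loadings)
## and whose higher levels are two-pole block loadings: each level owns a
## disjoint block of genes (and of motifs), half loaded positively and
## half negatively. The construction is exactly orthonormal, keeps L
## entrywise non-negative whenever rho_k <= rho_0 / s for k >= 1, and
## mirrors the qualitative structure the analysis assumes: a dominant
## baseline plus sparse polarized modules.

## Exactly orthonormal factor matrix: dense positive baseline column plus
## s disjoint two-pole block columns over a seeded permutation of rows.
## Pole magnitudes are jittered (then recentred and renormalized, which
## preserves exact orthonormality thanks to the disjoint supports) so
## that no two loadings tie and planted matrix entries do not fall on a
## lattice whose rounding errors would be coherent across a block.
planted_factors <- function(n, s, seed, jitter = 0.1) {
  b <- floor(n / s)
  p <- floor(b / 2)
  if (p < 1L)
    stop_cref("too few rows for the requested number of levels",
              "invalid_model_error")
  with_seed(seed, {
    perm <- sample.int(n)
    U <- matrix(0, n, s + 1L)
    U[, 1L] <- 1 / sqrt(n)
    for (k in seq_len(s)) {
      idx <- perm[((k - 1L) * b + 1L):(k * b)]
      x <- stats::runif(2L * p, 1 - jitter, 1 + jitter) *
        rep(c(1, -1), each = p)
      x <- x - mean(x)                       # orthogonal to the baseline
      x <- x / sqrt(sum(x^2))
      U[idx[seq_len(2L * p)], k + 1L] <- x
    }
    U
  })
}

#' Default planted singular spectrum
#'
#' Returns `rho_0 = mean_count * sqrt(g * m)` (so that the baseline alone
#' contributes `mean_count` to every entry) followed by geometrically
#' decaying higher levels `rho_k = rho_0 * f1 * 0.9^(k-1)` whose adjacent
#' relative gaps are all 0.10. `f1` is capped at `0.66 / n_levels`, which
#' keeps the planted matrix entrywise non-negative. Optionally one
#' adjacent pair is squeezed to a prescribed relative gap, emulating the
#' near-degenerate spectral gaps that enable eigenvector saltation.
#'
#' @param n_genes,n_motifs Matrix dimensions.
#' @param n_levels Number of non-baseline levels `s`.
#' @param mean_count Baseline expected count per entry.
#' @param gap_pair Optional level `k` (1-based, baseline excluded): the
#'   pair (k, k+1) gets relative gap `gap`.
#' @param gap Target relative gap `(rho_k - rho_{k+1}) / rho_k` for
#'   `gap_pair`.
#' @return Numeric vector `rho_0 > rho_1 > ... > rho_s`.
#' @export
planted_spectrum <- function(n_genes, n_motifs, n_levels = 6L,
                             mean_count = 20, gap_pair = NULL, gap = NULL) {
  rho0 <- mean_count * sqrt(n_genes * n_motifs)
  f1 <- min(0.11, 0.66 / n_levels)
  f <- f1 * 0.9^(seq_len(n_levels) - 1L)
  if (!is.null(gap_pair)) {
    stopifnot(!is.null(gap), gap > 0, gap_pair >= 1L,
              gap_pair + 1L <= n_levels)
    f[gap_pair + 1L] <- f[gap_pair] * (1 - gap)
    if (gap_pair + 2L <= n_levels && f[gap_pair + 1L] <= f[gap_pair + 2L])
      stop_cref("requested gap would break strict spectrum decrease",
                "invalid_model_error")
  }
  c(rho0, rho0 * f)
}

#' Construct a planted low-rank model
#'
#' @param n_genes,n_motifs Dimensions g and m.
#' @param spectrum Strictly decreasing positive singular values
#'   `rho_0 > ... > rho_s`; default [planted_spectrum()].
#' @param corruption_fraction Fraction of entries corrupted by large
#'   sparse outliers, in \[0, 1).
#' @param noise_model One of `"none"`, `"poisson"` (counts drawn as
#'   Poisson with mean equal to the low-rank entry) or
#'   `"rounded-gaussian"`.
#' @param mean_count Baseline expected count (used by the default
#'   spectrum).
#' @param seed Integer seed; the factors and every later draw from the
#'   model are reproducible from it.
#' @param gene_factors,motif_factors Optional explicit orthonormal factor
#'   matrices (g x (s+1), m x (s+1)); by default block-structured factors
#'   are built from the seed.
#' @param species Species tag attached to generated matrices.
#' @return An object of class `planted_model`.
#' @export
planted_model <- function(n_genes, n_motifs, spectrum = NULL,
                          corruption_fraction = 0.02,
                          noise_model = c("poisson", "none",
                                          "rounded-gaussian"),
                          mean_count = 20, seed = 1L,
                          gene_factors = NULL, motif_factors = NULL,
                          species = "synthetic") {
  noise_model <- match.arg(noise_model)
  if (is.null(spectrum))
    spectrum <- planted_spectrum(n_genes, n_motifs, mean_count = mean_count)
  if (any(diff(spectrum) >= 0) || any(spectrum <= 0))
    stop_cref("spectrum must be strictly decreasing and positive",
              "invalid_model_error")
  if (corruption_fraction < 0 || corruption_fraction >= 1)
    stop_cref("corruption_fraction must lie in [0, 1)",
              "invalid_model_error")
  s <- length(spectrum) - 1L
  if (s + 1L > min(n_genes, n_motifs))
    stop_cref("more levels than matrix rank allows", "invalid_model_error")
  if (is.null(gene_factors))
    gene_factors <- planted_factors(n_genes, s, seed)
  if (is.null(motif_factors))
    motif_factors <- planted_factors(n_motifs, s, seed + 7L)
  check_orthonormal <- function(M, what) {
    d <- crossprod(M) - diag(ncol(M))
    if (max(abs(d)) > 1e-10)
      stop_cref(sprintf("%s are not orthonormal", what),
                "invalid_model_error")
  }
  check_orthonormal(gene_factors, "gene factors")
  check_orthonormal(motif_factors, "motif factors")
  structure(list(n_genes = as.integer(n_genes),
                 n_motifs = as.integer(n_motifs),
                 spectrum = spectrum,
                 gene_factors = gene_factors,
                 motif_factors = motif_factors,
                 corruption_fraction = corruption_fraction,
                 noise_model = noise_model,
                 mean_count = mean_count,
                 seed = as.integer(seed),
                 species = species),
            class = "planted_model")
}

#' @export
print.planted_model <- function(x, ...) {
  cat(sprintf(paste0("<planted_model> %d genes x %d motifs, %d levels + ",
                     "baseline, %.1f%% corruption, %s noise, seed %d\n"),
              x$n_genes, x$n_motifs, length(x$spectrum) - 1L,
              100 * x$corruption_fraction, x$noise_model, x$seed))
  invisible(x)
}

#' Describe a two-species saltation scenario
#'
#' Species B shares species A's motif space but its motif factors at one
#' adjacent level pair (k, k+1) are rotated within their 2-D span by a
#' prescribed angle, while its gene factors are drawn fresh (species have
#' different gene spaces). The spectrum of both species carries the
#' prescribed near-degenerate relative gap at the rotated pair; all other
#' levels are conserved.
#'
#' @param base A `planted_model` for species A; its spectrum is adjusted
#'   so the rotated pair has relative gap `gap_fraction`.
#' @param rotated_pair Adjacent level pair `c(k, k + 1)` (baseline level 0
#'   cannot be rotated).
#' @param rotation_deg Rotation angle in degrees, in \[0, 90\].
#' @param gap_fraction Target relative gap `(rho_k - rho_{k+1}) / rho_k`
#'   at the rotated pair.
#' @param seed Integer seed controlling species B's gene factors and all
#'   count draws.
#' @return An object of class `saltation_scenario`.
#' @export
saltation_scenario <- function(base = planted_model(3000L, 400L),
                               rotated_pair = c(4L, 5L),
                               rotation_deg = 40,
                               gap_fraction = 0.02,
                               seed = base$seed) {
  s <- length(base$spectrum) - 1L
  if (length(rotated_pair) != 2L || rotated_pair[2] != rotated_pair[1] + 1L)
    stop_cref("rotated_pair must be an adjacent pair (k, k+1)",
              "invalid_model_error")
  k <- rotated_pair[1]
  if (k < 1L || k + 1L > s)
    stop_cref("rotated pair out of range", "invalid_model_error")
  if (rotation_deg < 0 || rotation_deg > 90)
    stop_cref("rotation_deg must lie in [0, 90]", "invalid_model_error")
  stopifnot(gap_fraction > 0)
  spec <- base$spectrum
  spec[k + 2L] <- spec[k + 1L] * (1 - gap_fraction)
  if (k + 3L <= length(spec) && spec[k + 2L] <= spec[k + 3L])
    stop_cref("gap_fraction breaks strict spectrum decrease",
              "invalid_model_error")
  base <- planted_model(base$n_genes, base$n_motifs, spectrum = spec,
                        corruption_fraction = base$corruption_fraction,
                        noise_model = base$noise_model,
                        mean_count = base$mean_count, seed = base$seed,
                        gene_factors = base$gene_factors,
                        motif_factors = base$motif_factors,
                        species = "species_A")
  structure(list(base = base,
                 rotated_pair = as.integer(rotated_pair),
                 rotation_deg = rotation_deg,
                 gap_fraction = gap_fraction,
                 conserved_levels = setdiff(seq_len(s), rotated_pair),
                 seed = as.integer(seed)),
            class = "saltation_scenario")
}
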