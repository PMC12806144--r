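## Cross-species comparison of motif-eigenvectors: Pearson correlations
## (after sign alignment), Deming errors-in-variables fits, rotation
## angles of one species' eigenvector within the other's 2-D eigen-plane,
## and the conserved / divergent / saltation classification.
##
## Only motif-eigenvectors are compared across species — they share the
## motif dimension, whereas gene spaces differ between species.

#' Pearson correlation of two motif-eigenvectors after sign alignment
#'
#' SVD signs are arbitrary per species, so `vB` is flipped first whenever
#' that makes the correlation positive; the flip is reported.
#'
#' @param vA,vB Numeric loadings of equal length; when both are named the
#'   motif label order must agree.
#' @return List with `r` (correlation after alignment) and `sign_flipped`.
#' @export
compare_motif_eigenvectors <- function(vA, vB) {
  if (length(vA) != length(vB))
    stop_cref("motif-eigenvectors have different lengths",
              "alignment_error")
  if (!is.null(names(vA)) && !is.null(names(vB)) &&
      !identical(names(vA), names(vB)))
    stop_cref("motif label order differs between species",
              "alignment_error")
  r <- stats::cor(vA, vB)
  flip <- !is.na(r) && r < 0
  list(r = if (flip) -r else r, sign_flipped = flip)
}

#' Deming regression with unit error-variance ratio
#'
#' Errors-in-variables straight-line fit treating both coordinates as
#' noisy with equal error variance (delta = 1):
#' `slope = (s_yy - s_xx + sqrt((s_yy - s_xx)^2 + 4 s_xy^2)) / (2 s_xy)`,
#' `intercept = mean(y) - slope * mean(x)`. With delta = 1 the fit is
#' symmetric: swapping x and y inverts the slope.
#'
#' @param x,y Numeric vectors, length >= 3.
#' @return List with `slope` and `intercept`.
#' @export
deming_fit <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L)
    stop_cref("deming_fit needs n >= 3 paired points", "deming_error")
  sxx <- stats::var(x); syy <- stats::var(y); sxy <- stats::cov(x, y)
  if (abs(sxy) < .Machine$double.eps)
    stop_cref("undefined Deming slope: covariance is zero",
              "undefined_slope_error")
  slope <- (syy - sxx + sqrt((syy - sxx)^2 + 4 * sxy^2)) / (2 * sxy)
  list(slope = slope, intercept = mean(y) - slope * mean(x))
}

#' Rotation angle of a probe eigenvector within a reference eigen-plane
#'
#' Projects species B's level-k motif-eigenvector onto the 2-D span of
#' species A's (v_k, v_{k+1}) pair and reports
#' `atan2(|<probe, v_{k+1}>|, |<probe, v_k>|)` in degrees (sign-free, so
#' the SVD sign ambiguity cannot flip the angle), together with the
#' out-of-plane fraction `1 - ||projection||^2`.
#'
#' @param v_k,v_k1 Reference pair (unit length, near-orthogonal).
#' @param probe Probe vector (unit length, same dimension).
#' @return List with `angle_deg` in \[0, 90\] and `out_of_plane`.
#' @export
rotation_angle <- function(v_k, v_k1, probe) {
  stopifnot(length(v_k) == length(v_k1), length(v_k) == length(probe))
  if (abs(sum(v_k * v_k1)) > 1e-6 ||
      abs(sum(v_k^2) - 1) > 1e-6 || abs(sum(v_k1^2) - 1) > 1e-6)
    stop_cref("reference pair must be orthonormal", "degeneracy_error")
  a <- abs(sum(probe * v_k))
  b <- abs(sum(probe * v_k1))
  list(angle_deg = atan2(b, a) * 180 / pi,
       out_of_plane = max(0, 1 - (a^2 + b^2) / sum(probe^2)))
}

#' Classify levels as conserved, divergent or saltation
#'
#' A level is `"conserved"` when its cross-species correlation reaches
#' `r_conserved`; otherwise it is `"saltation"` when its adjacent
#' spectral gap is near-degenerate (`d < d_small`) — a small gap plus a
#' large rotation is the saltation signature — and `"divergent"`
#' otherwise.
#'
#' @param levels Integer vector of levels.
#' @param r Per-level cross-species correlations.
#' @param d Per-level relative gaps (gap of the pair (k, k+1)).
#' @param r_conserved,d_small Classification thresholds in (0, 1).
#' @return Character vector of labels.
#' @export
classify_levels <- function(levels, r, d, r_conserved = 0.95,
                            d_small = 0.05) {
  stopifnot(r_conserved > 0, r_conserved < 1, d_small > 0, d_small < 1,
            length(r) == length(levels), length(d) == length(levels))
  ifelse(r >= r_conserved, "conserved",
         ifelse(d < d_small, "saltation", "divergent"))
}

#' Compare two decompositions level by level
#'
#' For each requested level k: the sign-aligned Pearson correlation and
#' Deming fit of the two motif-eigenvectors, the rotation angle of B's
#' v_k within A's (v_k, v_{k+1}) plane (for k below the deepest level),
#' both species' relative gaps, and the conserved / divergent / saltation
#' label based on A's gap.
#'
#' @param decomp_a,decomp_b `dual_decomposition` objects sharing motif
#'   labels (species A is the reference).
#' @param levels Levels to compare (baseline 0 excluded by default).
#' @inheritParams classify_levels
#' @return A `comparison_result` data.frame with one row per level:
#'   `level`, `r`, `sign_flipped`, `slope`, `intercept`, `angle_deg`,
#'   `out_of_plane`, `d_a`, `d_b`, `label`.
#' @export
compare_species <- function(decomp_a, decomp_b,
                            levels = seq_len(min(decomp_a$n_levels,
                                                 decomp_b$n_levels) - 1L),
                            r_conserved = 0.95, d_small = 0.05) {
  stopifnot(inherits(decomp_a, "dual_decomposition"),
            inherits(decomp_b, "dual_decomposition"))
  if (!identical(decomp_a$motif_ids, decomp_b$motif_ids))
    stop_cref("species decompositions have different motif labels",
              "alignment_error")
  if (any(levels < 1L) || any(levels > min(decomp_a$n_levels,
                                           decomp_b$n_levels)))
    stop_cref("levels outside decomposition depth", "decomposition_error")
  gaps_a <- relative_distances(decomp_a, gap_threshold = d_small)
  gaps_b <- relative_distances(decomp_b, gap_threshold = d_small)
  gap_of <- function(gaps, k) {
    ## level k is judged by its pair gap d_k; the deepest level falls
    ## back to the gap above it
    if (k %in% gaps$level) gaps$d[gaps$level == k]
    else gaps$d[gaps$level == k - 1L]
  }
  rows <- lapply(levels, function(k) {
    va <- module_at(decomp_a, k)$motif_vector
    vb <- module_at(decomp_b, k)$motif_vector
    cmp <- compare_motif_eigenvectors(va, vb)
    if (cmp$sign_flipped) vb <- -vb
    dm <- deming_fit(va, vb)
    ang <- if (k + 1L <= decomp_a$n_levels) {
      rotation_angle(va, module_at(decomp_a, k + 1L)$motif_vector,
                     module_at(decomp_b, k)$motif_vector)
    } else list(angle_deg = NA_real_, out_of_plane = NA_real_)
    data.frame(level = k, r = cmp$r, sign_flipped = cmp$sign_flipped,
               slope = dm$slope, intercept = dm$intercept,
               angle_deg = ang$angle_deg, out_of_plane = ang$out_of_plane,
               d_a = gap_of(gaps_a, k), d_b = gap_of(gaps_b, k))
  })
  out <- do.call(rbind, rows)
  out$label <- classify_levels(out$level, out$r, out$d_a,
                               r_conserved, d_small)
  class(out) <- c("comparison_result", "data.frame")
  out
}
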