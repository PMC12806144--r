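## Robust principal component analysis: split an observed matrix into a
## low-rank part plus sparse outliers by nuclear-norm + L1 minimization,
##     min ||C||_* + lambda ||S||_1  s.t.  Ctilde = C + S,
## solved with the inexact augmented Lagrange multipliers (IALM) scheme:
## alternating singular-value thresholding on C and entrywise soft
## thresholding on S with a growing penalty mu.

soft_threshold <- function(x, tau) sign(x) * pmax(abs(x) - tau, 0)

## Leading part of the SVD. For small problems (or large requested rank)
## the exact LAPACK SVD is used; otherwise a randomized range finder with
## oversampling and two power iterations, the standard workhorse for
## singular-value thresholding at scale.
svd_top <- function(M, k) {
  d <- min(dim(M))
  k <- min(k, d)
  if (k >= 0.5 * d || d <= 150L) {
    s <- svd(M)
    return(list(u = s$u[, seq_len(k), drop = FALSE],
                d = s$d[seq_len(k)],
                v = s$v[, seq_len(k), drop = FALSE]))
  }
  p <- min(d, k + 10L)
  Omega <- matrix(stats::rnorm(ncol(M) * p), ncol(M), p)
  Y <- M %*% Omega
  for (i in 1:2) {
    Y <- qr.Q(qr(Y))
    Y <- M %*% crossprod(M, Y)
  }
  Q <- qr.Q(qr(Y))
  B <- crossprod(Q, M)
  s <- svd(B)
  list(u = Q %*% s$u[, seq_len(k), drop = FALSE],
       d = s$d[seq_len(k)],
       v = s$v[, seq_len(k), drop = FALSE])
}

spectral_norm <- function(M) svd_top(M, 1L)$d[1]

#' Robust low-rank + sparse decomposition by inexact augmented Lagrange
#' multipliers
#'
#' Decomposes an observed counts matrix `Ctilde` into `C + S` where `C`
#' has small nuclear norm (the principal regulatory structure) and `S` is
#' sparse (outliers), iterating singular-value thresholding on `C` and
#' entrywise soft thresholding on `S` until
#' `||Ctilde - C - S||_F / ||Ctilde||_F <= tol`.
#'
#' Internals follow the published IALM defaults: initial multiplier
#' `Y = Ctilde / max(||Ctilde||_2, ||Ctilde||_inf / lambda)`,
#' `mu_0 = 1.25 / ||Ctilde||_2`, growth factor 1.5.
#'
#' @param ctilde Numeric matrix or `cref_matrix`.
#' @param lambda Sparsity penalty; `"auto"` (default) uses the standard
#'   `1 / sqrt(max(g, m))`.
#' @param tol Relative Frobenius tolerance for the exact-fit constraint.
#' @param max_iter Iteration cap; non-convergence returns the best iterate
#'   with `converged = FALSE` and a warning.
#' @param max_rank Optional cap on the rank retained by the thresholding
#'   step. Useful on large noisy matrices, where the exact-fit iterate
#'   would otherwise accumulate many near-zero singular values; the
#'   leading modules are unaffected.
#' @param sketch_seed Internal seed for the randomized range finder, so
#'   that the decomposition is a deterministic function of its inputs; the
#'   caller's RNG state is untouched.
#' @return A list of class `rpca_fit`: `low_rank` (C), `sparse` (S),
#'   `lambda`, `iterations`, `residual`, `converged`, `rank`.
#' @export
rpca_ialm <- function(ctilde, lambda = "auto", tol = 1e-7,
                      max_iter = 200L, max_rank = Inf,
                      sketch_seed = 987654L) {
  labels <- dimnames(ctilde)
  D <- unclass(as.matrix(ctilde))
  storage.mode(D) <- "double"
  if (!all(is.finite(D)))
    stop_cref("matrix must be finite", "rpca_error")
  g <- nrow(D); m <- ncol(D)
  if (identical(lambda, "auto")) lambda <- 1 / sqrt(max(g, m))
  if (!(is.numeric(lambda) && lambda > 0))
    stop_cref("lambda must be positive or 'auto'", "rpca_error")
  normF <- sqrt(sum(D^2))
  if (normF == 0)
    return(structure(list(low_rank = D, sparse = D, lambda = lambda,
                          iterations = 0L, residual = 0,
                          converged = TRUE, rank = 0L),
                     class = "rpca_fit"))
  with_seed(sketch_seed, {
  norm2 <- spectral_norm(D)
  Y <- D / max(norm2, max(abs(D)) / lambda)
  mu <- 1.25 / norm2
  mu_max <- mu * 1e7
  rho <- 1.5
  S <- matrix(0, g, m)
  C <- matrix(0, g, m)
  sv <- 10L
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    M <- D - S + Y / mu
    k <- as.integer(min(sv, min(g, m), max_rank))
    repeat {
      sv_fit <- svd_top(M, k)
      svp <- sum(sv_fit$d > 1 / mu)
      if (svp < k || k >= min(min(g, m), max_rank)) break
      k <- as.integer(min(2L * k, min(g, m), max_rank))
    }
    svp <- max(svp, 1L)
    dthr <- sv_fit$d[seq_len(svp)] - 1 / mu
    dthr[dthr < 0] <- 0
    C <- sv_fit$u[, seq_len(svp), drop = FALSE] %*%
      (dthr * t(sv_fit$v[, seq_len(svp), drop = FALSE]))
    ## predicted rank for the next iteration (Lin et al. heuristic)
    sv <- if (svp < k) svp + 1L else
      as.integer(min(svp + round(0.05 * min(g, m)), min(g, m)))
    S <- soft_threshold(D - C + Y / mu, lambda / mu)
    R <- D - C - S
    Y <- Y + mu * R
    mu <- min(mu * rho, mu_max)
    res <- sqrt(sum(R^2)) / normF
    if (res <= tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning(sprintf("rpca_ialm did not reach tol %.1e in %d iterations (residual %.2e)",
                    tol, max_iter, res))
  dimnames(C) <- labels; dimnames(S) <- labels
  structure(list(low_rank = C, sparse = S, lambda = lambda,
                 iterations = it, residual = res, converged = converged,
                 rank = sum(dthr > 0)),
            class = "rpca_fit")
  })
}

#' @export
print.rpca_fit <- function(x, ...) {
  cat(sprintf("<rpca_fit> rank %d, %d iterations, residual %.2e (%s), lambda %.4g\n",
              x$rank, x$iterations, x$residual,
              if (x$converged) "converged" else "NOT converged", x$lambda))
  invisible(x)
}
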