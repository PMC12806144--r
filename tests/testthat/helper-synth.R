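## Shared fixtures built in code.

## A tiny fixed PWM: strong non-periodic consensus AACGTGCAT.
tiny_pwm <- function(id = "TINY", dom = 0.91) {
  cons <- c(1L, 1L, 2L, 3L, 4L, 3L, 2L, 1L, 4L)
  prob <- matrix((1 - dom) / 3, nrow = length(cons), ncol = 4)
  prob[cbind(seq_along(cons), cons)] <- dom
  pwm(id, prob)
}

## Rename the motifs of a library (e.g. to match synthetic CREF columns).
relabel_pwm_library <- function(lib, ids) {
  stopifnot(length(ids) == length(lib))
  pwm_library(lapply(seq_along(lib), function(i) {
    p <- lib[[i]]
    p$id <- ids[i]
    p
  }))
}

## Small planted model used across decomposition tests.
small_model <- function(seed = 5, noise = "none", corruption = 0,
                        g = 300, m = 120, s = 5) {
  planted_model(g, m, spectrum = planted_spectrum(g, m, s, 20),
                corruption_fraction = corruption, noise_model = noise,
                seed = seed)
}

expect_no_diff <- function(a, b, tol = 0) {
  testthat::expect_true(max(abs(a - b)) <= tol)
}

## Strip class and non-dim attributes, keeping a bare numeric matrix.
bare_matrix <- function(x) {
  m <- unclass(as.matrix(x))
  matrix(as.numeric(m), nrow(m), ncol(m))
}
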