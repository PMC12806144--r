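#' @keywords internal
"_PACKAGE"

## Evaluate `code` with the RNG seeded to `seed`, restoring the caller's
## RNG state afterwards. All generators route their randomness through this
## so that a given seed is reproducible and no global state leaks.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  force(code)
}

## Round half away from zero (so 0.5 -> 1, 2.5 -> 3), unlike base round()
## which rounds half to even. Used for integer quantile summaries.
round_half_up <- function(x) {
  floor(x + 0.5)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## Write a data.frame as a plain TSV with a header and no quoting.
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

stop_cref <- function(msg, class) {
  stop(structure(class = c(class, "crefdual_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}
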