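# Internal helpers shared across modules.

# Evaluate expr under a fixed RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv()))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

# sin(x)/x with the removable singularity filled.
sincx <- function(x) ifelse(abs(x) < 1e-12, 1, sin(x) / x)

stopf <- function(...) stop(sprintf(...), call. = FALSE)

# Linear interpolation in log-log space; x must be positive and ascending.
interpLogLog <- function(x, y, xout) {
  if (any(xout < min(x) - 1e-9) || any(xout > max(x) + 1e-9))
    stopf("energy %g keV outside the tabulated range [%g, %g]",
          xout[which(xout < min(x) - 1e-9 | xout > max(x) + 1e-9)][1],
          min(x), max(x))
  exp(stats::approx(log(x), log(y), xout = log(pmax(xout, min(x))),
                    rule = 2)$y)
}
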