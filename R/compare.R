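# Rank-based inter-system comparison of metric curves: per frequency bin,
# a global Kruskal-Wallis test across the systems, followed (only when
# the global test is significant -- a hierarchical gate) by unadjusted
# pairwise Mann-Whitney tests. U is reported as min(U_a, U_b) and Z from
# the tie-corrected normal approximation, the convention under which
# complete separation at n = m = 11 prints U = 0.

#' Extract the curve values falling in a frequency range
#'
#' Grid points with range-inclusive endpoints (within numerical
#' tolerance).
#'
#' @param curve a \linkS4class{FrequencySeries}.
#' @param range length-2 ascending frequency range, mm^-1.
#' @return numeric vector of curve values.
#' @export
binCurve <- function(curve, range) {
  f <- frequencies(curve)
  sel <- f >= range[1] - 1e-9 & f <= range[2] + 1e-9
  if (!any(sel)) stopf("validation error: no grid points in [%g, %g]",
                       range[1], range[2])
  seriesValues(curve)[sel]
}

#' Kruskal-Wallis test across groups
#'
#' Tie-corrected H statistic with df = k - 1 and a chi-square upper-tail
#' p-value (delegated to \code{stats::kruskal.test}). Fully tied data
#' (all pooled values equal) degenerate to H = 0, p = 1.
#'
#' @param groups list of >= 2 numeric samples.
#' @return list(H, df, p).
#' @export
kruskalWallis <- function(groups) {
  if (length(groups) < 2) stopf("need at least 2 groups")
  if (any(vapply(groups, length, integer(1)) == 0))
    stopf("validation error: empty group")
  pooled <- unlist(groups, use.names = FALSE)
  if (length(unique(pooled)) == 1)
    return(list(H = 0, df = length(groups) - 1L, p = 1))
  g <- factor(rep(seq_along(groups), lengths(groups)))
  kt <- stats::kruskal.test(pooled, g)
  list(H = unname(kt$statistic), df = unname(kt$parameter),
       p = unname(kt$p.value))
}

#' Mann-Whitney U test with normal approximation
#'
#' Midrank-tied U statistic reported as \eqn{U = \min(U_a, U_b)}, the
#' standardized
#' \eqn{Z = (U - nm/2) / \sqrt{nm((N+1) - \sum(t^3 - t)/(N(N-1)))/12}}
#' with the tie-correction term, and the two-sided normal p-value. An
#' exact permutation p-value (enumeration of all splits of the pooled
#' sample) is available for n + m <= 12.
#'
#' @param a,b numeric samples.
#' @param exact use the exact permutation distribution of min-U
#'   (n + m <= 12 only).
#' @return list(U, Z, p).
#' @examples
#' mannWhitney(1:3, 4:6, exact = TRUE)$p  # 0.1 (2 of 20 splits)
#' @export
mannWhitney <- function(a, b, exact = FALSE) {
  if (!length(a) || !length(b)) stopf("validation error: empty sample")
  n <- length(a); m <- length(b); N <- n + m
  pooled <- c(a, b)
  rk <- rank(pooled)
  ua <- sum(rk[seq_len(n)]) - n * (n + 1) / 2
  u <- min(ua, n * m - ua)
  ties <- table(pooled)
  tieTerm <- sum(ties^3 - ties)
  varU <- n * m / 12 * ((N + 1) - tieTerm / (N * (N - 1)))
  if (varU <= 0) return(list(U = u, Z = 0, p = 1))
  z <- (u - n * m / 2) / sqrt(varU)
  if (exact) {
    if (N > 12) stopf("exact enumeration limited to n + m <= 12")
    splits <- utils::combn(N, n)
    uDist <- apply(splits, 2, function(ix) {
      uaP <- sum(rk[ix]) - n * (n + 1) / 2
      min(uaP, n * m - uaP)
    })
    p <- mean(uDist <= u + 1e-9)
  } else {
    p <- min(1, 2 * stats::pnorm(z))
  }
  list(U = u, Z = z, p = p)
}

#' Stratified rank-based comparison of three systems
#'
#' Splits each system's metric curve into the low- and high-frequency
#' bins of \code{spec}, runs a Kruskal-Wallis test per bin, and -- only
#' where the global test is significant at \code{alpha} (hierarchical
#' testing) -- supplements all pairwise Mann-Whitney comparisons, without
#' multiplicity adjustment.
#'
#' @param systems named list of \linkS4class{FrequencySeries}, one per
#'   system, on identical grids.
#' @param spec a \linkS4class{FreqBinSpec}.
#' @param alpha significance level of the hierarchical gate (0.05).
#' @return A \linkS4class{ComparisonReport}.
#' @export
pairwiseReport <- function(systems, spec = FreqBinSpec("eDQE"),
                           alpha = 0.05) {
  if (is.null(names(systems)) || any(!nzchar(names(systems))))
    names(systems) <- paste0("system", seq_along(systems))
  grids <- lapply(systems, frequencies)
  for (g in grids[-1])
    if (length(g) != length(grids[[1]]) || max(abs(g - grids[[1]])) > 1e-9)
      stopf("validation error: curves are on mismatched frequency grids")
  bins <- list(low = spec@lowRange, high = spec@highRange)
  kwRows <- list(); pwRows <- list()
  for (bn in names(bins)) {
    rng <- bins[[bn]]
    samples <- lapply(systems, binCurve, range = rng)
    kw <- kruskalWallis(samples)
    kwRows[[bn]] <- data.frame(
      bin = bn, lo = rng[1], hi = rng[2],
      n = sum(lengths(samples)), H = kw$H, df = kw$df, p = kw$p)
    if (is.finite(kw$p) && kw$p < alpha) {
      prs <- utils::combn(names(systems), 2)
      for (k in seq_len(ncol(prs))) {
        mw <- mannWhitney(samples[[prs[1, k]]], samples[[prs[2, k]]])
        pwRows[[length(pwRows) + 1]] <- data.frame(
          bin = bn, pair = paste(prs[1, k], "vs", prs[2, k]),
          U = mw$U, Z = mw$Z, p = mw$p)
      }
    }
  }
  new("ComparisonReport", metric = spec@metric,
      kruskal = do.call(rbind, kwRows),
      pairwise = if (length(pwRows)) do.call(rbind, pwRows)
                 else data.frame(bin = character(), pair = character(),
                                 U = numeric(), Z = numeric(), p = numeric()),
      alpha = alpha)
}
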