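# Mean-shift change-point detection by penalised optimal partitioning with
# PELT pruning. Cost of a segment is its within-segment sum of squared
# deviations from the segment mean; each change point adds a penalty beta.
# The pruned dynamic programme returns the exact minimiser of
#   sum_k cost(segment_k) + beta * (#changepoints)
# under a minimum-segment-length constraint (squared-error cost satisfies
# the subadditivity condition required for PELT pruning with K = 0).

seg_cost <- function(cs, cs2, i, j) {
  # cost of segment (i, j]: indices are 0-based prefix positions
  n <- j - i
  (cs2[j + 1] - cs2[i + 1]) - (cs[j + 1] - cs[i + 1])^2 / n
}

#' Default segmentation penalty
#'
#' `2 * sigma^2 * log(n)` with sigma estimated robustly from the median
#' absolute deviation of first differences (noise-only under a piecewise
#' constant signal).
#'
#' A variance floor (`min_var`) supports series that have been scaled to
#' make unit variance a sensible lower bound (as with mCH levels scaled by
#' 1000), preventing over-segmentation of near-constant stretches.
#'
#' @param x numeric series
#' @param min_var lower bound on the variance estimate (default 0)
#' @export
default_penalty <- function(x, min_var = 0) {
  n <- length(x)
  if (n < 2) return(1)
  sigma <- mad(diff(x)) / sqrt(2)
  if (!is.finite(sigma) || sigma == 0) sigma <- sd(x) / sqrt(2)
  if (!is.finite(sigma) || sigma == 0) sigma <- 1e-8
  max(2 * max(sigma^2, min_var) * log(n), .Machine$double.eps)
}

#' Exact penalised mean-shift segmentation (PELT)
#'
#' @param x numeric values (finite; remove no-data bins first)
#' @param penalty per-changepoint penalty beta; `NULL` uses
#'   [default_penalty()]
#' @param minseglen minimum points per segment (default 2)
#' @return object of class `Segmentation`: list with `changepoints`
#'   (last index of each segment except the final one), `segments`
#'   (data.table first/last/mean), `penalty`, `minseglen`
#' @export
pelt_segment <- function(x, penalty = NULL, minseglen = 2) {
  stopifnot(minseglen >= 1)
  n <- length(x)
  if (any(!is.finite(x))) stop("values must be finite")
  if (is.null(penalty)) penalty <- default_penalty(x)
  if (n < 2 * minseglen) {
    return(new_segmentation(integer(0), x, penalty, minseglen))
  }
  cs <- c(0, cumsum(x))
  cs2 <- c(0, cumsum(x^2))
  F <- rep(Inf, n + 1)         # F[t+1] = optimal cost of x[1..t]
  F[1] <- -penalty
  last <- integer(n + 1)       # traceback: previous changepoint
  cands <- 0L                  # candidate previous changepoints (0-based)
  for (t in seq(minseglen, n)) {
    valid <- cands[cands <= t - minseglen]
    costs <- F[valid + 1] + seg_cost(cs, cs2, valid, t) + penalty
    k <- which.min(costs)
    F[t + 1] <- costs[k]
    last[t + 1] <- valid[k]
    # prune: candidates that can never win again (K = 0)
    keep <- (F[valid + 1] + seg_cost(cs, cs2, valid, t)) <= F[t + 1]
    cands <- c(valid[keep], cands[cands > t - minseglen], t)
  }
  cps <- integer(0)
  t <- n
  while (t > 0) {
    prev <- last[t + 1]
    if (prev > 0) cps <- c(prev, cps)
    t <- prev
  }
  new_segmentation(cps, x, penalty, minseglen)
}

new_segmentation <- function(cps, x, penalty, minseglen) {
  if (!length(x))
    return(structure(list(changepoints = integer(0),
                          segments = data.table(first = integer(0),
                                                last = integer(0),
                                                mean = numeric(0)),
                          penalty = penalty, minseglen = minseglen),
                     class = "Segmentation"))
  bounds <- c(0, cps, length(x))
  first <- head(bounds, -1) + 1
  last <- tail(bounds, -1)
  seg_mean <- mapply(function(a, b) mean(x[a:b]), first, last)
  segs <- data.table(first = first, last = last, mean = seg_mean)
  structure(list(changepoints = as.integer(cps), segments = segs[],
                 penalty = penalty, minseglen = minseglen),
            class = "Segmentation")
}

#' Unpruned O(n^2) optimal-partitioning reference
#'
#' Same objective and constraint as [pelt_segment()] without pruning;
#' retained as an independent cross-check for the pruned implementation.
#'
#' @inheritParams pelt_segment
#' @export
opt_partition_reference <- function(x, penalty = NULL, minseglen = 2) {
  n <- length(x)
  if (is.null(penalty)) penalty <- default_penalty(x)
  if (n < 2 * minseglen)
    return(new_segmentation(integer(0), x, penalty, minseglen))
  cs <- c(0, cumsum(x)); cs2 <- c(0, cumsum(x^2))
  F <- rep(Inf, n + 1); F[1] <- -penalty
  last <- integer(n + 1)
  for (t in seq(minseglen, n)) {
    taus <- 0:(t - minseglen)
    taus <- taus[taus == 0 | taus >= minseglen]
    costs <- F[taus + 1] + seg_cost(cs, cs2, taus, t) + penalty
    k <- which.min(costs)
    F[t + 1] <- costs[k]
    last[t + 1] <- taus[k]
  }
  cps <- integer(0); t <- n
  while (t > 0) {
    prev <- last[t + 1]
    if (prev > 0) cps <- c(prev, cps)
    t <- prev
  }
  new_segmentation(cps, x, penalty, minseglen)
}
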