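#' Exact change-points-in-mean detection
#'
#' Segments a series into contiguous pieces with constant mean by minimizing
#' the penalized least-squares criterion
#' `sum over segments of SSE(segment) / sigma^2 + beta * (#change points)`,
#' over all segmentations whose every segment (first and last included) has
#' length at least `min_seg_len`. The optimum is found exactly by dynamic
#' programming (optimal partitioning), which at these series lengths (~10^2
#' years) is instantaneous. The noise scale `sigma` is estimated robustly
#' from first differences (`mad(diff(x))/sqrt(2)`), so the criterion — and
#' hence the penalty — is invariant to rescaling the series, and the
#' estimate is not inflated by the mean shifts themselves.
#'
#' Penalties: `"MBIC"` (default) uses `beta = 3 log n`, `"BIC"` uses
#' `beta = 2 log n`, `"manual"` uses `penalty_value`.
#'
#' @param values Numeric series (finite).
#' @param min_seg_len Minimum segment length, years (default 10).
#' @param penalty `"MBIC"`, `"BIC"` or `"manual"`.
#' @param penalty_value Numeric penalty when `penalty = "manual"`.
#' @param years Optional year labels (default `seq_along(values)`); change
#'   points are reported as the first year of each new segment.
#' @return Object of class `cpt_set`: list with `changepoints` (years),
#'   `segments` (data frame `start_year, end_year, mean`), `cost` (optimal
#'   penalized cost), `min_seg_len`, `penalty`, `penalty_value`, `sigma`.
#' @examples
#' x <- c(rep(0, 20), rep(10, 20))
#' detect_mean_shifts(x, min_seg_len = 10)$changepoints  # index 21
#' @export
detect_mean_shifts <- function(values, min_seg_len = 10L,
                               penalty = c("MBIC", "BIC", "manual"),
                               penalty_value = NULL,
                               years = seq_along(values)) {
  penalty <- match.arg(penalty)
  if (!is.numeric(values) || any(!is.finite(values)))
    stop("values must be finite numerics")
  if (min_seg_len < 1) stop("min_seg_len must be >= 1")
  n <- length(values)
  stopifnot(length(years) == n)

  sigma <- diff_mad_sigma(values)
  beta <- penalty_beta(penalty, penalty_value, n)
  x <- if (sigma > 0) values / sigma else values * 0

  cs <- c(0, cumsum(x))
  cs2 <- c(0, cumsum(x^2))
  segcost <- function(a, b) {  # cost of x[a..b], 1-based inclusive
    s <- cs[b + 1] - cs[a]
    (cs2[b + 1] - cs2[a]) - s * s / (b - a + 1)
  }

  L <- as.integer(min_seg_len)
  # F[t+1]: optimal penalized cost of x[1..t]; ncp tracked for tie-breaking
  INF <- Inf
  F <- rep(INF, n + 1)
  ncp <- rep(NA_integer_, n + 1)
  prev <- rep(NA_integer_, n + 1)
  F[1] <- 0; ncp[1] <- -1L  # so first segment adds no penalty
  for (t in seq_len(n)) {
    if (t < L) next
    cand_s <- c(0L, if (t - L >= L) seq.int(L, t - L) else integer(0))
    best_c <- INF; best_k <- NA_integer_; best_s <- NA_integer_
    for (s in cand_s) {
      if (!is.finite(F[s + 1])) next
      cc <- F[s + 1] + segcost(s + 1, t) + beta
      kk <- ncp[s + 1] + 1L
      if (cc < best_c - 1e-12 ||
          (cc < best_c + 1e-12 && (kk < best_k ||
                                   (kk == best_k && s < best_s)))) {
        best_c <- cc; best_k <- kk; best_s <- s
      }
    }
    F[t + 1] <- best_c; ncp[t + 1] <- best_k; prev[t + 1] <- best_s
  }
  if (!is.finite(F[n + 1])) {
    # series shorter than one minimum segment: single segment, no penalty
    return(new_cpt_set(integer(0), values, years, min_seg_len, penalty,
                       beta, sigma, cost = if (sigma > 0) segcost(1, n) else 0))
  }

  bounds <- integer(0)
  t <- n
  while (t > 0) {
    s <- prev[t + 1]
    if (s > 0) bounds <- c(s, bounds)
    t <- s
  }
  cost <- F[n + 1] - beta * (length(bounds) + 1)  # strip per-segment beta
  cost <- cost + beta * length(bounds)            # re-add per-changepoint
  new_cpt_set(bounds, values, years, min_seg_len, penalty, beta, sigma,
              cost = cost)
}

diff_mad_sigma <- function(values) {
  if (length(values) < 2) return(0)
  s <- stats::mad(diff(values)) / sqrt(2)
  # MAD is 0 for noiseless piecewise-constant series; fall back to the
  # non-robust difference estimator so exact steps remain detectable
  if (s == 0) s <- stats::sd(diff(values)) / sqrt(2)
  s
}

penalty_beta <- function(penalty, penalty_value, n) {
  switch(penalty,
         MBIC = 3 * log(n),
         BIC = 2 * log(n),
         manual = {
           if (is.null(penalty_value) || !is.numeric(penalty_value))
             stop("penalty_value required for manual penalty")
           penalty_value
         })
}

# bounds: last index of each non-final segment (0-based split positions in
# 1..n-1 space, here 1-based "last index of left part")
new_cpt_set <- function(bounds, values, years, min_seg_len, penalty, beta,
                        sigma, cost) {
  n <- length(values)
  starts <- c(1L, bounds + 1L)
  ends <- c(bounds, n)
  seg <- data.frame(
    start_year = years[starts], end_year = years[ends],
    mean = vapply(seq_along(starts),
                  function(k) mean(values[starts[k]:ends[k]]), numeric(1)),
    row.names = NULL)
  structure(list(changepoints = years[bounds + 1L], segments = seg,
                 cost = cost, min_seg_len = as.integer(min_seg_len),
                 penalty = penalty, penalty_value = beta, sigma = sigma),
            class = "cpt_set")
}

#' @export
print.cpt_set <- function(x, ...) {
  cat("<cpt_set>", length(x$changepoints), "change point(s)",
      sprintf("[min segment %d, penalty %s = %.3g]\n",
              x$min_seg_len, x$penalty, x$penalty_value))
  if (length(x$changepoints))
    cat("  at:", paste(x$changepoints, collapse = ", "), "\n")
  print.data.frame(x$segments, digits = 4)
  invisible(x)
}

#' Brute-force segmentation oracle
#'
#' Enumerates every segmentation respecting the minimum segment length and
#' returns the one minimizing the same penalized cost as
#' [detect_mean_shifts()]; ties are broken by fewer change points, then by
#' the lexicographically earliest change-point vector. Exponential in the
#' series length, hence capped at 40 points; intended as an independent
#' correctness oracle.
#'
#' @inheritParams detect_mean_shifts
#' @return A `cpt_set`.
#' @export
brute_force_segment <- function(values, min_seg_len = 10L,
                                penalty = c("MBIC", "BIC", "manual"),
                                penalty_value = NULL,
                                years = seq_along(values)) {
  penalty <- match.arg(penalty)
  n <- length(values)
  if (n > 40) stop("brute force capped at length 40")
  if (!is.numeric(values) || any(!is.finite(values)))
    stop("values must be finite numerics")
  sigma <- diff_mad_sigma(values)
  beta <- penalty_beta(penalty, penalty_value, n)
  x <- if (sigma > 0) values / sigma else values * 0
  L <- as.integer(min_seg_len)

  segs_cost <- function(bounds) {
    starts <- c(1L, bounds + 1L); ends <- c(bounds, n)
    tot <- 0
    for (k in seq_along(starts)) {
      v <- x[starts[k]:ends[k]]
      tot <- tot + sum(v^2) - sum(v)^2 / length(v)
    }
    tot + beta * length(bounds)
  }

  best <- list(cost = Inf, bounds = integer(0))
  consider <- function(bounds) {
    cc <- segs_cost(bounds)
    better <- cc < best$cost - 1e-12
    if (!better && cc < best$cost + 1e-12) {
      if (length(bounds) < length(best$bounds)) better <- TRUE
      else if (length(bounds) == length(best$bounds) && length(bounds) > 0 &&
               isTRUE(vec_less(bounds, best$bounds))) better <- TRUE
    }
    if (better) best <<- list(cost = cc, bounds = bounds)
  }
  recurse <- function(start, bounds) {
    # the segment starting at `start` may close the series...
    if (n - start + 1 >= L) consider(bounds)
    # ...or end at e, leaving room for at least one more full segment
    e <- start + L - 1L
    while (e <= n - L) {
      recurse(e + 1L, c(bounds, e))
      e <- e + 1L
    }
  }
  if (n >= L) recurse(1L, integer(0))
  if (!is.finite(best$cost))  # series shorter than one minimum segment
    best <- list(cost = segs_cost(integer(0)), bounds = integer(0))
  new_cpt_set(best$bounds, values, years, min_seg_len, penalty, beta, sigma,
              cost = best$cost)
}

vec_less <- function(a, b) {
  for (k in seq_along(a)) {
    if (a[k] < b[k]) return(TRUE)
    if (a[k] > b[k]) return(FALSE)
  }
  FALSE
}

#' Change points for a batch of novelty series
#'
#' Applies [detect_mean_shifts()] with common parameters to every series.
#'
#' @param novelty List of `novelty_series` (or data frames with
#'   `year, value`).
#' @param ... Passed to [detect_mean_shifts()].
#' @return List of `cpt_set`, same names as the input.
#' @export
changepoints_batch <- function(novelty, ...) {
  lapply(novelty, function(s) {
    detect_mean_shifts(s$value, years = s$year, ...)
  })
}
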