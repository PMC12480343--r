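#' Ecological network analysis indices
#'
#' Information-theoretic indices of a food-web flow network `T`, where
#' `T[i, j]` is the flow from compartment i to compartment j (t/km^2/year).
#' With `TST = sum(T)`, row (donor) sums `T_i.` and column (recipient) sums
#' `T_.j`:
#'
#' * total system throughput: `TST = sum_ij T_ij`
#' * ascendency: `A = sum_ij T_ij log_b( T_ij * TST / (T_i. * T_.j) )`
#' * development capacity: `C = - sum_ij T_ij log_b( T_ij / TST )`
#' * overhead: `R = - sum_ij T_ij log_b( T_ij^2 / (T_i. * T_.j) )`
#'
#' with the convention `0 log 0 = 0` (zero flows contribute nothing). The
#' identity `C = A + R` holds for every nonnegative matrix, and all three are
#' nonnegative, with `A = C` (and `R = 0`) exactly when every row and column
#' carries at most one positive flow. Ascendency equals TST times the mutual
#' information of the flow-normalized joint distribution of (donor,
#' recipient); capacity equals TST times its Shannon entropy. Units are
#' flow x bits for the default base 2.
#'
#' @param net Square nonnegative numeric matrix.
#' @param base Logarithm base (default 2, i.e. bits).
#' @return A single number.
#' @examples
#' two_cycle <- matrix(c(0, 1, 1, 0), 2, 2)
#' ascendency(two_cycle)   # 2
#' capacity(two_cycle)     # 2
#' overhead(two_cycle)     # 0
#' @name ena_indices
NULL

check_flow_matrix <- function(net) {
  if (!is.matrix(net) || nrow(net) != ncol(net))
    stop("flow network must be a square matrix")
  if (!is.numeric(net) || anyNA(net)) stop("flows must be numeric, no NA")
  if (any(net < 0)) stop("flows must be nonnegative")
  invisible(net)
}

#' @rdname ena_indices
#' @export
total_system_throughput <- function(net) {
  check_flow_matrix(net)
  sum(net)
}

require_positive_tst <- function(net) {
  tst <- sum(net)
  if (tst <= 0)
    stop("index undefined for an all-zero flow matrix (TST = 0)")
  tst
}

#' @rdname ena_indices
#' @export
ascendency <- function(net, base = 2) {
  check_flow_matrix(net)
  tst <- require_positive_tst(net)
  ri <- rowSums(net)
  cj <- colSums(net)
  pos <- which(net > 0, arr.ind = TRUE)
  t_ij <- net[pos]
  sum(t_ij * log(t_ij * tst / (ri[pos[, 1]] * cj[pos[, 2]]), base = base))
}

#' @rdname ena_indices
#' @export
capacity <- function(net, base = 2) {
  check_flow_matrix(net)
  tst <- require_positive_tst(net)
  t_ij <- net[net > 0]
  -sum(t_ij * log(t_ij / tst, base = base))
}

#' @rdname ena_indices
#' @export
overhead <- function(net, base = 2) {
  check_flow_matrix(net)
  require_positive_tst(net)
  ri <- rowSums(net)
  cj <- colSums(net)
  pos <- which(net > 0, arr.ind = TRUE)
  t_ij <- net[pos]
  -sum(t_ij * log(t_ij^2 / (ri[pos[, 1]] * cj[pos[, 2]]), base = base))
}

# ---------------------------------------------------------------------------

#' Smooth a yearly series by local regression
#'
#' Degree-2 local regression with tricube weights (loess), evaluated at the
#' observed years, as commonly used to smooth index trajectories before
#' trend classification. Exact (direct) surface computation is used so
#' constant and straight-line inputs are reproduced to rounding error.
#'
#' @param values Numeric series.
#' @param span Smoothing span, fraction of points in each local window
#'   (0 < span <= 1, default 0.75).
#' @param years Optional x coordinates (default equally spaced).
#' @return Numeric vector of fitted values, same length as `values`.
#' @export
smooth_series <- function(values, span = 0.75, years = seq_along(values)) {
  stopifnot(is.numeric(values), length(years) == length(values))
  if (!is.numeric(span) || span <= 0 || span > 1)
    stop("span must be in (0, 1]")
  n <- length(values)
  if (n < 3) {
    warning("fewer than 3 points: returning the series unchanged")
    return(values)
  }
  # a degree-2 tricube local fit is numerically stable from ~7 points per
  # window; narrower requests are widened to that floor
  span_eff <- max(span, min(1, 7 / n))
  fit <- stats::loess(values ~ years, span = span_eff, degree = 2,
                      family = "gaussian",
                      control = stats::loess.control(surface = "direct"))
  as.numeric(stats::predict(fit, data.frame(years = years)))
}

#' Yearly ENA index series from flow matrices
#'
#' Computes TST, ascendency, capacity and overhead per year from a list of
#' flow matrices (one per year, ensemble-averaged upstream when the input is
#' a Monte-Carlo ensemble), plus smoothed variants of each via
#' [smooth_series()].
#'
#' @param flows Either an `ensemble_run` (member-mean flows are used) or a
#'   list of square flow matrices, one per year.
#' @param years Integer years; defaults to `names(flows)` or the run's years.
#' @param scenario Optional [scenario_spec()] label carried in the result.
#' @param base Log base for the indices (default 2).
#' @param span Smoothing span (default 0.75).
#' @return An object of class `index_series`: a data frame with columns
#'   `year, tst, ascendency, capacity, overhead` and `*_smoothed` variants;
#'   attributes `scenario`, `base`, `span`.
#' @export
index_series <- function(flows, years = NULL, scenario = NULL, base = 2,
                         span = 0.75) {
  if (inherits(flows, "ensemble_run")) {
    if (is.null(scenario)) scenario <- flows$scenario
    if (is.null(years)) years <- flows$years
    flows <- ensemble_mean_flows(flows)
  }
  if (!is.list(flows) || length(flows) == 0)
    stop("flows must be a non-empty list of matrices (or an ensemble_run)")
  if (is.null(years)) {
    years <- suppressWarnings(as.integer(names(flows)))
    if (anyNA(years)) years <- seq_along(flows)
  }
  stopifnot(length(years) == length(flows))

  a <- vapply(flows, ascendency, numeric(1), base = base)
  c_ <- vapply(flows, capacity, numeric(1), base = base)
  r <- vapply(flows, overhead, numeric(1), base = base)
  tst <- vapply(flows, total_system_throughput, numeric(1))

  sm <- function(v) if (length(v) >= 3) smooth_series(v, span, years) else v
  out <- data.frame(
    year = as.integer(years), tst = tst,
    ascendency = a, capacity = c_, overhead = r,
    tst_smoothed = sm(tst), ascendency_smoothed = sm(a),
    capacity_smoothed = sm(c_), overhead_smoothed = sm(r),
    row.names = NULL)
  structure(out, class = c("index_series", "data.frame"),
            scenario = scenario, base = base, span = span)
}

#' @export
print.index_series <- function(x, ...) {
  sc <- attr(x, "scenario")
  cat("<index_series>", if (!is.null(sc)) format(sc) else "",
      sprintf("(%d years, log base %g)\n", nrow(x), attr(x, "base")))
  print.data.frame(utils::head(as.data.frame(x)[, 1:5], 6), digits = 4)
  if (nrow(x) > 6) cat("  ...", nrow(x) - 6, "more years\n")
  invisible(x)
}

#' @export
plot.index_series <- function(x, smoothed = TRUE, ...) {
  suff <- if (smoothed) "_smoothed" else ""
  cols <- paste0(c("ascendency", "capacity", "overhead"), suff)
  old <- graphics::par(mfrow = c(3, 1), mar = c(3, 4, 1, 1))
  on.exit(graphics::par(old))
  for (k in seq_along(cols)) {
    graphics::plot(x$year, x[[cols[k]]], type = "l",
                   xlab = "", ylab = c("A", "C", "R")[k], ...)
  }
  invisible(x)
}
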