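#' Euclidean distance between biomass vectors
#'
#' @param x,y Numeric vectors of equal length (per-group biomasses).
#' @return `sqrt(sum((x - y)^2))`.
#' @export
euclidean_distance <- function(x, y) {
  if (length(x) != length(y)) stop("vectors must have equal length")
  sqrt(sum((x - y)^2))
}

#' Hellinger distance between composition vectors
#'
#' Distance between two proportion vectors, `sqrt(sum((sqrt(p) - sqrt(q))^2))`,
#' bounded in `[0, sqrt(2)]`; the square-root transform downweights dominant
#' groups (here, primary producers). Inputs not summing to 1 are normalized
#' with a warning; negative entries are rejected.
#'
#' @param p,q Nonnegative vectors of equal length.
#' @return A number in `[0, sqrt(2)]`.
#' @examples
#' hellinger_distance(c(1, 0), c(0, 1))  # sqrt(2): disjoint support
#' @export
hellinger_distance <- function(p, q) {
  if (length(p) != length(q)) stop("vectors must have equal length")
  if (any(p < 0) || any(q < 0)) stop("compositions must be nonnegative")
  norm1 <- function(v, nm) {
    s <- sum(v)
    if (s <= 0) stop(nm, " has zero total; composition undefined")
    if (abs(s - 1) > 1e-9) {
      warning(nm, " does not sum to 1; normalizing")
      v <- v / s
    }
    v
  }
  p <- norm1(p, "p")
  q <- norm1(q, "q")
  sqrt(sum((sqrt(p) - sqrt(q))^2))
}

#' Cumulative per-species novelty of one state against a baseline pool
#'
#' For each group, the minimum absolute biomass difference between the target
#' state and any baseline state; the total is the sum over groups. This is
#' the "novelty in individual species" measure: a species contributes only
#' the part of its biomass that cannot be matched by any baseline year.
#'
#' @param target Numeric biomass vector.
#' @param baseline_states Matrix (states x groups) or list of vectors.
#' @return List with `total` (number) and `per_species` (vector).
#' @export
cumulative_species_novelty <- function(target, baseline_states) {
  if (is.list(baseline_states))
    baseline_states <- do.call(rbind, baseline_states)
  if (is.null(dim(baseline_states)))
    baseline_states <- matrix(baseline_states, nrow = 1)
  if (nrow(baseline_states) < 1) stop("at least one baseline state required")
  if (ncol(baseline_states) != length(target))
    stop("baseline states and target must have the same group count")
  d <- abs(sweep(baseline_states, 2, target))  # states x groups
  per <- apply(d, 2, min)
  names(per) <- names(target)
  list(total = sum(per), per_species = per)
}

#' The three supported novelty measures
#'
#' @return Character vector: `"biomass_euclidean"`, `"composition_hellinger"`,
#'   `"cumulative_species"`.
#' @export
novelty_measures <- function() {
  c("biomass_euclidean", "composition_hellinger", "cumulative_species")
}

#' Novelty time series of an ensemble run
#'
#' Novelty of each target year is its minimum dissimilarity to the baseline:
#' `novelty(t) = min D(state_t, state_b)` over every baseline state. The
#' baseline pool covers the full uncertainty range (all members x all
#' baseline years); per target year, the minimum is taken separately for
#' each target member and the member values are averaged, yielding one
#' series per (scenario, measure).
#'
#' Measures: `"biomass_euclidean"` (Euclidean on raw biomasses),
#' `"composition_hellinger"` (Hellinger on per-year biomass proportions),
#' `"cumulative_species"` (sum over groups of the per-group minimum absolute
#' difference to any baseline state; for this measure the minimum is taken
#' per group rather than per state).
#'
#' @param run An `ensemble_run` (or any list with `biomass`
#'   members x years x groups and `years`).
#' @param measure One of `novelty_measures()`.
#' @param baseline_window,target_window Inclusive year ranges
#'   `c(first, last)`; defaults from the run's config (2000-2018 baseline,
#'   2019-2090 targets). Must not overlap.
#' @param groups Optional character subset of groups to use (default all).
#' @return Object of class `novelty_series`: data frame `year, value` with
#'   attributes `measure`, `scenario`, `baseline_window`, `target_window`.
#' @export
novelty_series <- function(run, measure = novelty_measures(),
                           baseline_window = NULL, target_window = NULL,
                           groups = NULL) {
  measure <- match.arg(measure)
  if (is.null(baseline_window))
    baseline_window <- run$config$baseline_window
  if (is.null(target_window))
    target_window <- run$config$target_window
  if (length(baseline_window) != 2 || length(target_window) != 2)
    stop("windows must be c(first_year, last_year)")
  if (baseline_window[2] >= target_window[1] && target_window[2] >= baseline_window[1])
    if (max(baseline_window[1], target_window[1]) <= min(baseline_window[2], target_window[2]))
      stop("baseline and target windows must not overlap")

  years <- run$years
  b_idx <- which(years >= baseline_window[1] & years <= baseline_window[2])
  t_idx <- which(years >= target_window[1] & years <= target_window[2])
  if (length(b_idx) == 0) stop("empty baseline window")
  if (length(t_idx) == 0) stop("empty target window")

  B <- run$biomass
  if (!is.null(groups)) {
    keep <- match(groups, dimnames(B)[[3]])
    if (anyNA(keep)) stop("unknown group(s): ",
                          paste(groups[is.na(keep)], collapse = ", "))
    B <- B[, , keep, drop = FALSE]
  }
  n_m <- dim(B)[1]

  # flatten to state matrices: rows = member x year states
  flat <- function(idx) {
    m <- matrix(aperm(B[, idx, , drop = FALSE], c(1, 2, 3)),
                nrow = n_m * length(idx), ncol = dim(B)[3])
    m
  }
  base_m <- flat(b_idx)
  targ_m <- flat(t_idx)

  val_mt <- switch(measure,
    biomass_euclidean = {
      d <- cross_dist(targ_m, base_m)
      matrix(apply(d, 1, min), n_m, length(t_idx))
    },
    composition_hellinger = {
      d <- cross_dist(sqrt(to_composition(targ_m)),
                      sqrt(to_composition(base_m)))
      matrix(apply(d, 1, min), n_m, length(t_idx))
    },
    cumulative_species = {
      tot <- numeric(nrow(targ_m))
      for (g in seq_len(ncol(targ_m))) {
        dg <- abs(outer(targ_m[, g], base_m[, g], "-"))
        tot <- tot + apply(dg, 1, min)
      }
      matrix(tot, n_m, length(t_idx))
    })

  out <- data.frame(year = years[t_idx], value = colMeans(val_mt),
                    row.names = NULL)
  structure(out, class = c("novelty_series", "data.frame"),
            measure = measure, scenario = run$scenario,
            baseline_window = baseline_window, target_window = target_window)
}

# rows-of-X vs rows-of-Y Euclidean cross-distance matrix
cross_dist <- function(X, Y) {
  d2 <- matrix(rowSums(X^2), nrow(X), nrow(Y)) +
    matrix(rowSums(Y^2), nrow(X), nrow(Y), byrow = TRUE) -
    2 * tcrossprod(X, Y)
  sqrt(pmax(d2, 0))
}

to_composition <- function(m) {
  s <- rowSums(m)
  if (any(s <= 0)) stop("composition undefined for zero-total states")
  m / s
}

#' Novelty series for every (run, measure) pair
#'
#' @param runs List of `ensemble_run` objects (typically one per scenario).
#' @param measures Character vector of measures (default all three).
#' @param scenarios Optional list of [scenario_spec()] that must all be
#'   covered by `runs`; missing scenarios are an error.
#' @param ... Passed to [novelty_series()].
#' @return List of `novelty_series`, one per (run, measure), e.g. 16
#'   scenarios x 3 measures = 48 series.
#' @export
novelty_batch <- function(runs, measures = novelty_measures(),
                          scenarios = NULL, ...) {
  if (inherits(runs, "ensemble_run")) runs <- list(runs)
  measures <- match.arg(measures, novelty_measures(), several.ok = TRUE)
  have <- vapply(runs, function(r) format(r$scenario), character(1))
  if (!is.null(scenarios)) {
    want <- vapply(scenarios, format, character(1))
    miss <- setdiff(want, have)
    if (length(miss))
      stop("runs missing for scenario(s): ", paste(miss, collapse = ", "))
  }
  out <- list()
  for (r in runs)
    for (m in measures) {
      s <- novelty_series(r, m, ...)
      out[[paste(format(r$scenario), m, sep = ".")]] <- s
    }
  out
}

#' @export
print.novelty_series <- function(x, ...) {
  sc <- attr(x, "scenario")
  cat("<novelty_series>", attr(x, "measure"),
      if (!is.null(sc)) paste0("[", format(sc), "]") else "",
      sprintf("years %d-%d\n", min(x$year), max(x$year)))
  cat(sprintf("  value range %.4g .. %.4g (baseline %d-%d)\n",
              min(x$value), max(x$value),
              attr(x, "baseline_window")[1], attr(x, "baseline_window")[2]))
  invisible(x)
}

#' @export
plot.novelty_series <- function(x, ...) {
  graphics::plot(x$year, x$value, type = "l", xlab = "year",
                 ylab = paste("novelty:", attr(x, "measure")), ...)
  invisible(x)
}
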