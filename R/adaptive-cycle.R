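#' Trend signature of the network indices at one year
#'
#' The three smoothed indices act as the axes of the adaptive cycle:
#' ascendency for connectedness, capacity for potential, overhead for
#' resilience. The signature at a year is the sign of the least-squares
#' slope of each smoothed index over a centered window (truncated at the
#' series edges), with slopes smaller in magnitude than a flatness threshold
#' treated as zero, plus a high/low resilience level relative to the
#' window-wide median of smoothed overhead.
#'
#' @param indices An `index_series`.
#' @param year Year at which to evaluate (must be in the series).
#' @param window Trend window width in years (default 7).
#' @param epsilon Flatness threshold per index, slope units per year. The
#'   default (`NULL`) uses 1% of each smoothed index's interquartile range.
#' @return List of class `trend_signature`: `year`, the three slopes
#'   (`connectedness_slope`, `potential_slope`, `resilience_slope`), their
#'   thresholded signs (`*_sign` in -1/0/1), and `resilience_level`
#'   (`"high"`/`"low"`).
#' @export
trend_signature <- function(indices, year, window = 7L, epsilon = NULL) {
  tab <- signature_table(indices, window, epsilon)
  i <- match(year, tab$year)
  if (is.na(i)) stop("year ", year, " not in the index series")
  structure(as.list(tab[i, ]), class = "trend_signature")
}

# Signatures for all years at once (single pass; used by the classifier).
signature_table <- function(indices, window = 7L, epsilon = NULL) {
  stopifnot(inherits(indices, "index_series"))
  years <- indices$year
  n <- length(years)
  a <- indices$ascendency_smoothed
  c_ <- indices$capacity_smoothed
  r <- indices$overhead_smoothed
  if (is.null(epsilon)) {
    epsilon <- 0.01 * c(stats::IQR(a), stats::IQR(c_), stats::IQR(r))
  } else if (length(epsilon) == 1) epsilon <- rep(epsilon, 3)

  half <- max(1L, as.integer(window) %/% 2L)
  slope_at <- function(v, i) {
    j <- max(1L, i - half):min(n, i + half)
    if (length(j) < 2) return(0)
    xs <- years[j] - mean(years[j])
    sum(xs * (v[j] - mean(v[j]))) / sum(xs^2)
  }
  sa <- vapply(seq_len(n), function(i) slope_at(a, i), numeric(1))
  sc <- vapply(seq_len(n), function(i) slope_at(c_, i), numeric(1))
  sr <- vapply(seq_len(n), function(i) slope_at(r, i), numeric(1))
  thresh <- function(s, e) ifelse(abs(s) < e, 0, sign(s))
  data.frame(
    year = years,
    connectedness_slope = sa, potential_slope = sc, resilience_slope = sr,
    connectedness_sign = thresh(sa, epsilon[1]),
    potential_sign = thresh(sc, epsilon[2]),
    resilience_sign = thresh(sr, epsilon[3]),
    resilience_level = ifelse(r >= stats::median(r), "high", "low"),
    stringsAsFactors = FALSE)
}

#' @export
print.trend_signature <- function(x, ...) {
  cat(sprintf("<trend_signature> year %d: connectedness %+.3g, potential %+.3g, resilience %+.3g (%s)\n",
              x$year, x$connectedness_slope, x$potential_slope,
              x$resilience_slope, x$resilience_level))
  invisible(x)
}

# phase signature predicates on a signature_table row set
sig_reorg <- function(tab)
  tab$connectedness_sign < 0 & tab$potential_sign > 0 &
  tab$resilience_level == "high"
sig_collapse <- function(tab)
  tab$connectedness_sign < 0 & tab$potential_sign < 0 &
  tab$resilience_sign > 0
sig_growth <- function(tab)
  tab$connectedness_sign > 0 & tab$potential_sign > 0 &
  tab$resilience_sign < 0

#' Anchor reorganization onsets at novelty change points
#'
#' A detected change point in a novelty series marks a candidate
#' reorganization onset; it is anchored when the index trends at that year
#' show the reorganization signature — falling connectedness (ascendency),
#' rising potential (capacity), and high resilience (overhead at or above
#' its window median). With `slack > 0`, the signature may be satisfied at
#' the nearest year within that many years of the change point, and the
#' anchor is placed there.
#'
#' @param changepoints A `cpt_set` (or integer vector of years).
#' @param indices An `index_series` on the same year axis.
#' @param window,epsilon Passed to the trend computation.
#' @param slack Maximum |year shift| allowed when matching the signature
#'   (default 0: the signature must hold at the change point itself).
#' @return List with `anchors` (integer years) and `diagnostics` (data frame
#'   `changepoint, anchored, anchor_year, failed`: which condition failed
#'   for unanchored change points).
#' @export
anchor_reorganization <- function(changepoints, indices, window = 7L,
                                  epsilon = NULL, slack = 0L) {
  cps <- if (inherits(changepoints, "cpt_set")) changepoints$changepoints
         else as.integer(changepoints)
  tab <- signature_table(indices, window, epsilon)
  ok <- sig_reorg(tab)
  anchors <- integer(0)
  diag <- data.frame(changepoint = integer(0), anchored = logical(0),
                     anchor_year = integer(0), failed = character(0),
                     stringsAsFactors = FALSE)
  for (cp in cps) {
    i <- match(cp, tab$year)
    if (is.na(i)) {
      diag <- rbind(diag, data.frame(changepoint = cp, anchored = FALSE,
                                     anchor_year = NA_integer_,
                                     failed = "year outside index series"))
      next
    }
    offs <- seq(-slack, slack)
    offs <- offs[order(abs(offs), offs)]   # nearest first, earlier on ties
    cand <- i + offs
    cand <- cand[cand >= 1 & cand <= nrow(tab)]
    hit <- cand[ok[cand]][1]
    if (!is.na(hit)) {
      anchors <- c(anchors, tab$year[hit])
      diag <- rbind(diag, data.frame(changepoint = cp, anchored = TRUE,
                                     anchor_year = tab$year[hit],
                                     failed = ""))
    } else {
      fails <- c(
        if (!(tab$connectedness_sign[i] < 0)) "connectedness not falling",
        if (!(tab$potential_sign[i] > 0)) "potential not rising",
        if (!(tab$resilience_level[i] == "high")) "resilience not high")
      diag <- rbind(diag, data.frame(changepoint = cp, anchored = FALSE,
                                     anchor_year = NA_integer_,
                                     failed = paste(fails, collapse = "; ")))
    }
  }
  list(anchors = sort(unique(anchors)), diagnostics = diag)
}

#' Classify adaptive-cycle phases along an index series
#'
#' Each anchored reorganization starts at its anchor year and extends
#' forward while the reorganization signature holds (at least
#' `min_reorg_len` years, capped before the next anchor). A collapse phase
#' is carved immediately before each anchor, extending backwards while the
#' collapse signature (falling connectedness and potential, rising
#' resilience) holds. Remaining years are labeled growth (r/K merged) when
#' connectedness and potential rise and resilience falls, else
#' `unclassified`. Collapse runs that would directly follow a reorganization
#' without an intervening growth segment are demoted to `unclassified`,
#' preserving the cyclic order collapse -> reorganization -> growth. The
#' cycle count is the number of reorganization segments.
#'
#' @param indices An `index_series`.
#' @param anchors Integer years (e.g. from [anchor_reorganization()]).
#' @param min_reorg_len Minimum reorganization duration, years (default 3).
#' @param window,epsilon Trend parameters, as in [trend_signature()].
#' @return Object of class `phase_segmentation`: list with `segments`
#'   (data frame `start_year, end_year, phase`), `cycle_count`, `anchors`,
#'   `labels` (per-year phase vector), `years`, `scenario`.
#' @export
classify_phases <- function(indices, anchors, min_reorg_len = 3L,
                            window = 7L, epsilon = NULL) {
  stopifnot(inherits(indices, "index_series"))
  if (nrow(indices) == 0) stop("empty index series")
  tab <- signature_table(indices, window, epsilon)
  n <- nrow(tab)
  years <- tab$year
  anchors <- sort(unique(as.integer(anchors)))
  if (any(!anchors %in% years))
    stop("anchors must lie on the index-series year axis")

  is_re <- sig_reorg(tab)
  is_co <- sig_collapse(tab)
  is_gr <- sig_growth(tab)
  lab <- rep("unclassified", n)

  # Slopes within half a trend window of a phase boundary mix the two
  # phases, so signatures blink off there; extension tolerates failing runs
  # up to that blur radius when a signature year lies beyond them.
  grace <- max(1L, as.integer(window) %/% 2L)

  a_idx <- match(anchors, years)
  for (k in seq_along(a_idx)) {
    i <- a_idx[k]
    cap <- if (k < length(a_idx)) a_idx[k + 1] - 1L else n
    # extend forward while the signature holds, bridging short failing runs
    j <- i; p <- i + 1L; fail_run <- 0L
    while (p <= cap) {
      if (is_re[p]) { j <- p; fail_run <- 0L }
      else { fail_run <- fail_run + 1L; if (fail_run > grace) break }
      p <- p + 1L
    }
    j <- min(cap, max(j, i + min_reorg_len - 1L))
    lab[i:j] <- "reorganization"
    # carve collapse immediately before the anchor, bridging the blur zone
    last_hit <- NA_integer_; p <- i - 1L; fail_run <- 0L
    while (p >= 1 && lab[p] == "unclassified") {
      if (is_co[p]) { last_hit <- p; fail_run <- 0L }
      else { fail_run <- fail_run + 1L; if (fail_run > grace) break }
      p <- p - 1L
    }
    if (!is.na(last_hit)) lab[last_hit:(i - 1L)] <- "collapse"
  }
  lab[lab == "unclassified" & is_gr] <- "growth_rK"

  lab <- enforce_cycle_order(lab)

  r <- rle(lab)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  seg <- data.frame(start_year = years[starts], end_year = years[ends],
                    phase = r$values, stringsAsFactors = FALSE)
  structure(list(segments = seg,
                 cycle_count = sum(r$values == "reorganization"),
                 anchors = anchors, labels = lab, years = years,
                 scenario = attr(indices, "scenario")),
            class = "phase_segmentation")
}

# Demote collapse runs that directly follow a reorganization (in the
# sequence of classified phases) without an intervening growth segment.
enforce_cycle_order <- function(lab) {
  r <- rle(lab)
  ph <- r$values[r$values != "unclassified"]
  if (length(ph) < 2) return(lab)
  # walk classified runs; map back to run indices
  run_is_phase <- which(r$values != "unclassified")
  for (k in seq_along(run_is_phase)[-1]) {
    cur <- r$values[run_is_phase[k]]
    prv <- r$values[run_is_phase[k - 1]]
    if (cur == "collapse" && prv == "reorganization")
      r$values[run_is_phase[k]] <- "unclassified"
  }
  inverse.rle(r)
}

#' @export
print.phase_segmentation <- function(x, ...) {
  sc <- x$scenario
  cat("<phase_segmentation>", if (!is.null(sc)) format(sc) else "",
      sprintf("- %d cycle(s)\n", x$cycle_count))
  print.data.frame(x$segments)
  invisible(x)
}

#' @export
summary.phase_segmentation <- function(object, ...) {
  phase_durations(object)
}

#' Phase durations
#'
#' @param segmentation A `phase_segmentation`.
#' @return List with `segments` (data frame with a `duration` column, years)
#'   and `mean_by_phase` (named vector of mean durations per phase).
#' @export
phase_durations <- function(segmentation) {
  stopifnot(inherits(segmentation, "phase_segmentation"))
  seg <- segmentation$segments
  seg$duration <- seg$end_year - seg$start_year + 1L
  list(segments = seg,
       mean_by_phase = tapply(seg$duration, seg$phase, mean))
}

# ---------------------------------------------------------------------------

#' Synthesize index series from a planted phase schedule
#'
#' Inverts the classification rules: builds continuous ascendency, capacity
#' and overhead trajectories by integrating per-phase slopes (growth: A and
#' C rise, R falls; collapse: A and C fall sharply, R rises sharply;
#' reorganization: A falls slowly, C rises, R stays at its local high), plus
#' Gaussian noise. Used to validate phase recovery end to end with known
#' truth.
#'
#' The default smoothing span is deliberately narrower than the
#' visualization default of [index_series()]: trend classification needs a
#' local-regression bandwidth commensurate with the shortest phase (a few
#' years), whereas a span of 0.75 over a ~90-year series averages over half
#' the century and erases decade-scale phases.
#'
#' @param schedule Data frame `start_year, end_year, phase` with contiguous
#'   segments and phases in `growth_rK`, `collapse`, `reorganization`.
#' @param noise_sd Standard deviation of additive Gaussian noise, in units
#'   of the (order-1) index scale (default 0.02).
#' @param seed Integer seed (required).
#' @param span Smoothing span for the returned series (default 0.15).
#' @return An `index_series` covering the schedule's years.
#' @export
simulate_phase_indices <- function(schedule, noise_sd = 0.02, seed,
                                   span = 0.15) {
  if (missing(seed)) stop("seed is required")
  stopifnot(all(c("start_year", "end_year", "phase") %in% names(schedule)))
  if (any(schedule$start_year[-1] != utils::head(schedule$end_year, -1) + 1L))
    stop("schedule segments must be contiguous")
  years <- schedule$start_year[1]:schedule$end_year[nrow(schedule)]
  n <- length(years)

  # per-phase slopes per year (index units); integrated to a continuous path
  sl <- list(
    growth_rK =      c(a = 0.040, c = 0.040, r = -0.030),
    collapse =       c(a = -0.090, c = -0.090, r = 0.150),
    reorganization = c(a = -0.030, c = 0.080, r = 0.010))
  phase_at <- rep(schedule$phase, schedule$end_year - schedule$start_year + 1L)
  if (!all(phase_at %in% names(sl)))
    stop("unknown phase: ",
         paste(setdiff(unique(phase_at), names(sl)), collapse = ", "))
  rates <- do.call(rbind, sl[phase_at])
  a <- 0.5 + cumsum(rates[, "a"]) - rates[1, "a"]
  c_ <- 0.5 + cumsum(rates[, "c"]) - rates[1, "c"]
  r <- 0.7 + cumsum(rates[, "r"]) - rates[1, "r"]
  with_seed(seed, {
    a <- a + stats::rnorm(n, 0, noise_sd)
    c_ <- c_ + stats::rnorm(n, 0, noise_sd)
    r <- r + stats::rnorm(n, 0, noise_sd)
  })
  out <- data.frame(
    year = years, tst = a + c_, ascendency = a, capacity = c_, overhead = r,
    tst_smoothed = smooth_series(a + c_, span, years),
    ascendency_smoothed = smooth_series(a, span, years),
    capacity_smoothed = smooth_series(c_, span, years),
    overhead_smoothed = smooth_series(r, span, years), row.names = NULL)
  structure(out, class = c("index_series", "data.frame"),
            scenario = NULL, base = 2, span = span)
}
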