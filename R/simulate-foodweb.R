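#' Simulate an ensemble of food-web biomass trajectories
#'
#' Emulates the statistical structure of calibrated ecosystem-model ensemble
#' output under a forcing scenario. Each Monte-Carlo member perturbs the
#' baseline biomasses once (lognormal, spread `config$member_sdlog`,
#' mimicking resampled input parameters); on top of that, biomass follows a
#' deterministic scenario trend, planted multiplicative steps at known shift
#' years, and multiplicative AR(1) noise:
#'
#' `B[m, t, g] = B0[g] * pert[m, g] * trend[g](t) * steps[g](t) * exp(e[m, t, g])`
#'
#' where `e` is a per-member, per-group AR(1) process on the log scale. The
#' scenario trend is log-linear from the first projection year: the climate
#' label scales a per-group warming sensitivity, the nutrient label a
#' eutrophication sensitivity, and the fishing label a fishery-exposure
#' sensitivity (see [default_config()]).
#'
#' @param config A [default_config()]-style `foodweb_config`.
#' @param scenario A [scenario_spec()].
#' @param members Number of Monte-Carlo members (>= 1).
#' @param seed Integer seed; required, so runs are reproducible by
#'   construction (identical inputs give bit-identical output).
#' @return An object of class `ensemble_run`: list with `scenario`, `years`,
#'   `members`, `biomass` (members x years x groups array, t/km^2),
#'   `config`, and `ground_truth` (data frame of planted shifts:
#'   `scenario, shift_year, group, factor`).
#' @examples
#' run <- simulate_biomass(default_config(), scenario_spec("RCP85", "REF", "SQ"),
#'                         members = 2, seed = 1)
#' dim(run$biomass)  # 2 x 91 x 28
#' @export
simulate_biomass <- function(config, scenario, members = 20L, seed) {
  stopifnot(inherits(config, "foodweb_config"), inherits(scenario, "scenario_spec"))
  if (!is.numeric(members) || length(members) != 1L || members < 1)
    stop("members must be a positive integer")
  members <- as.integer(members)
  if (missing(seed) || is.null(seed))
    stop("seed is required: no hidden global randomness")

  years <- config$years
  groups <- config$group_names
  n_t <- length(years)
  n_g <- length(groups)

  trend <- scenario_trend_matrix(config, scenario)          # years x groups
  steps <- shift_step_matrix(config, scenario)              # years x groups

  biomass <- with_seed(seed, {
    pert <- matrix(exp(stats::rnorm(members * n_g, 0, config$member_sdlog)),
                   members, n_g)
    ar1 <- config$noise$ar1
    sd0 <- config$noise$sd
    eps <- array(0, c(members, n_t, n_g))
    if (sd0 > 0) {
      innov <- array(stats::rnorm(members * n_t * n_g, 0, sd0),
                     c(members, n_t, n_g))
      # stationary start, then AR(1) recursion over years
      eps[, 1, ] <- innov[, 1, ] / sqrt(1 - ar1^2)
      for (t in seq_len(n_t)[-1])
        eps[, t, ] <- ar1 * eps[, t - 1, ] + innov[, t, ]
    }
    b <- array(0, c(members, n_t, n_g),
               dimnames = list(member = NULL, year = years, group = groups))
    det_tg <- trend * steps                                  # years x groups
    base <- config$baseline_biomass
    for (m in seq_len(members))
      b[m, , ] <- (det_tg * rep(base, each = n_t)) *
        rep(pert[m, ], each = n_t) * exp(eps[m, , ])
    b
  })

  gt <- planted_shifts(config, scenario)
  structure(list(scenario = scenario, years = years, members = members,
                 biomass = biomass, config = config,
                 ground_truth = gt),
            class = "ensemble_run")
}

# Deterministic per-group log-linear trend, flat over the baseline window.
scenario_trend_matrix <- function(config, scenario) {
  years <- config$years
  t_proj <- pmax(0, years - config$baseline_window[2])
  s <- config$sensitivity
  r <- config$trend_rates
  rate <- r$climate[[scenario$climate]] * s$warming +
    r$nutrient[[scenario$nutrient]] * s$nutrient +
    fishing_rate(config, scenario)
  exp(outer(t_proj, rate))
}

fishing_rate <- function(config, scenario) {
  s <- config$sensitivity
  v <- config$trend_rates$fishing[[scenario$fishing]]
  if (scenario$fishing == "Gil") v * s$gillnet else v * s$fishery
}

# years x groups matrix of persistent multiplicative steps
shift_step_matrix <- function(config, scenario) {
  years <- config$years
  groups <- config$group_names
  m <- matrix(1, length(years), length(groups),
              dimnames = list(years, groups))
  sh <- planted_shifts(config, scenario)
  for (k in seq_len(nrow(sh)))
    m[years >= sh$shift_year[k], sh$group[k]] <-
      m[years >= sh$shift_year[k], sh$group[k]] * sh$factor[k]
  m
}

#' Planted ground-truth shifts for a scenario
#'
#' @param config A `foodweb_config`.
#' @param scenario A [scenario_spec()].
#' @return Data frame with columns `scenario, shift_year, group, factor`.
#' @export
planted_shifts <- function(config, scenario) {
  sh <- config$shift_schedule
  sel <- sh$climate == scenario$climate & sh$nutrient == scenario$nutrient
  out <- sh[sel, c("year", "group", "factor"), drop = FALSE]
  data.frame(scenario = rep(format(scenario), nrow(out)),
             shift_year = out$year, group = out$group, factor = out$factor,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' @export
print.ensemble_run <- function(x, ...) {
  cat("<ensemble_run>", format(x$scenario), "\n")
  cat("  members:", x$members, " years:", min(x$years), "-", max(x$years),
      " groups:", dim(x$biomass)[3], "\n")
  if (nrow(x$ground_truth))
    cat("  planted shifts:",
        paste(sprintf("%s@%d x%.2g", x$ground_truth$group,
                      x$ground_truth$shift_year, x$ground_truth$factor),
              collapse = ", "), "\n")
  invisible(x)
}

# ---------------------------------------------------------------------------

#' Build the flow matrix implied by a biomass vector
#'
#' Consumption accounting in the style of mass-balanced food-web models: the
#' flow from prey i to consumer j is the consumer's total consumption
#' (biomass times Q/B) times its diet fraction on i,
#' `T[i, j] = B[j] * QB[j] * DC[i, j]`. An extra boundary compartment
#' `"import"` supplies each primary producer with an inflow equal to its
#' outflow (grazing drawn from it), so every compartment with outflow has
#' inflow and the matrix is a complete transfer description.
#'
#' @param biomass Named or ordered numeric vector, one entry per group
#'   (t/km^2). Must be nonnegative.
#' @param config A `foodweb_config`.
#' @return Square nonnegative matrix ((n+1) x (n+1), t/km^2/year) with
#'   dimnames `c(groups, "import")`; `T[i, j]` is the flow from i to j.
#' @examples
#' cfg <- default_config()
#' Tm <- flows_from_biomass(cfg$baseline_biomass, cfg)
#' @export
flows_from_biomass <- function(biomass, config) {
  groups <- config$group_names
  n <- length(groups)
  if (length(biomass) != n)
    stop("biomass vector length must equal the group count (", n, ")")
  if (any(biomass < 0)) stop("biomass must be nonnegative")
  biomass <- as.numeric(biomass)

  cons <- biomass * config$consumption_rate      # total consumption per group
  Tint <- config$diet_matrix * rep(cons, each = n)

  Tm <- matrix(0, n + 1L, n + 1L,
               dimnames = list(c(groups, "import"), c(groups, "import")))
  Tm[seq_len(n), seq_len(n)] <- Tint
  outflow <- rowSums(Tint)
  inflow <- colSums(Tint)
  need_import <- outflow > 0 & inflow == 0
  Tm["import", seq_len(n)][need_import] <- outflow[need_import]
  Tm
}

#' Ensemble-mean flow matrices per year
#'
#' Averages biomass across members per year and converts it to a flow matrix.
#' Because flows are linear in biomass for a fixed diet and Q/B, the flow
#' matrix of the member-mean biomass equals the member-mean of the per-member
#' flow matrices.
#'
#' @param run An `ensemble_run`.
#' @return Named list (by year) of flow matrices.
#' @export
ensemble_mean_flows <- function(run) {
  stopifnot(inherits(run, "ensemble_run"))
  bm <- apply(run$biomass, c(2, 3), mean)       # years x groups
  out <- lapply(seq_along(run$years),
                function(i) flows_from_biomass(bm[i, ], run$config))
  names(out) <- run$years
  out
}

# Evaluate expr with a temporary RNG state; restores any prior state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}
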