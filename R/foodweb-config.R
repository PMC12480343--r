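#' Scenario specification
#'
#' A scenario is one cell of the crossed design: a climate forcing pathway,
#' a nutrient-load management option, and a fishing management option.
#'
#' @param climate One of `"RCP45"`, `"RCP85"`.
#' @param nutrient One of `"BSAP"` (nutrient-load reductions), `"REF"`
#'   (reference loads).
#' @param fishing One of `"SQ"` (status quo), `"Dec"` (effort -50%),
#'   `"Inc"` (effort +100%), `"Gil"` (no gillnet fishery).
#'
#' @return An object of class `scenario_spec`.
#' @seealso [scenario_grid()]
#' @export
scenario_spec <- function(climate, nutrient, fishing) {
  chk <- function(value, levels, field) {
    value <- as.character(value)
    if (length(value) != 1L || !value %in% levels)
      stop("unknown ", field, " label ", dQuote(value), "; must be one of ",
           paste(levels, collapse = ", "), call. = FALSE)
    value
  }
  climate <- chk(climate, climate_levels(), "climate")
  nutrient <- chk(nutrient, nutrient_levels(), "nutrient")
  fishing <- chk(fishing, fishing_levels(), "fishing")
  structure(list(climate = climate, nutrient = nutrient, fishing = fishing),
            class = "scenario_spec")
}

climate_levels <- function() c("RCP45", "RCP85")
nutrient_levels <- function() c("BSAP", "REF")
fishing_levels <- function() c("SQ", "Dec", "Inc", "Gil")

#' @export
format.scenario_spec <- function(x, ...) {
  paste(x$climate, x$nutrient, x$fishing, sep = "_")
}

#' @export
print.scenario_spec <- function(x, ...) {
  cat("<scenario>", format(x), "\n")
  invisible(x)
}

#' Full crossed scenario grid
#'
#' Enumerates the Cartesian product of the two climate pathways, two
#' nutrient-load options, and four fishing options: 16 scenarios in a
#' deterministic order (fishing varying fastest, then nutrient, then climate).
#'
#' @return A list of [scenario_spec()] objects, length 16.
#' @examples
#' length(scenario_grid())  # 16
#' @export
scenario_grid <- function() {
  out <- list()
  for (cl in climate_levels())
    for (nu in nutrient_levels())
      for (fi in fishing_levels())
        out[[length(out) + 1L]] <- scenario_spec(cl, nu, fi)
  out
}

#' Parse a scenario label such as "RCP85_REF_SQ"
#'
#' @param label Character of the form `climate_nutrient_fishing`.
#' @return A [scenario_spec()].
#' @export
parse_scenario <- function(label) {
  parts <- strsplit(label, "_", fixed = TRUE)[[1]]
  if (length(parts) != 3L)
    stop("scenario label must be 'climate_nutrient_fishing', got: ", label)
  scenario_spec(parts[1], parts[2], parts[3])
}

# ---------------------------------------------------------------------------

#' Default synthetic food-web configuration
#'
#' Builds a fixed, fully documented configuration for a Baltic-type coastal
#' food web: 28 biotic groups spanning primary producers, zooplankton,
#' benthos, fish, seals and birds; 7 fishing fleets; and 3 invasive groups
#' (round goby, Harris mud crab, fish-hook water flea). The diet matrix is
#' column-stochastic (each consumer's diet fractions sum to 1) and spans at
#' least three trophic levels (producers -> invertebrates -> fish -> top
#' predators).
#'
#' All parameters are deterministic defaults; no randomness is involved here.
#'
#' @return An object of class `foodweb_config`: a list with elements
#'   `group_names`, `fleet_names`, `invasive_names`, `producer` (logical per
#'   group), `diet_matrix` (prey x consumer), `consumption_rate` (Q/B, per
#'   year), `baseline_biomass` (t/km^2), `noise` (AR(1) coefficient `ar1` and
#'   innovation standard deviation `sd` on the log scale), `member_sdlog`
#'   (lognormal spread of the per-member parameter perturbation),
#'   `sensitivity` (per-group warming, nutrient, fishery and gillnet
#'   sensitivities), `trend_rates` (scenario-level forcing rates per year),
#'   `shift_schedule` (planted multiplicative steps), and `years`.
#' @examples
#' cfg <- default_config()
#' length(cfg$group_names)   # 28
#' length(cfg$fleet_names)   # 7
#' @export
default_config <- function() {
  groups <- c(
    # primary producers (5)
    "fucus", "filamentous_algae", "other_macrophytes", "phytoplankton",
    "benthic_microalgae",
    # zooplankton (3; fishhook water flea is invasive)
    "zooplankton_small", "zooplankton_large", "fishhook_waterflea",
    # benthos (7; Harris mud crab is invasive)
    "benthic_bivalves", "benthic_gastropods", "benthic_amphipods",
    "benthic_polychaetes", "harris_mud_crab", "mysids", "saduria",
    # fish (11; round goby is invasive)
    "herring", "sprat", "sander_juv", "sander_adult", "perch", "cyprinids",
    "flounder", "round_goby", "stickleback", "whitefish", "pike",
    # top predators (2)
    "seals", "birds")
  n <- length(groups)
  stopifnot(n == 28L)

  fleets <- c("trawl_pelagic", "trawl_demersal", "gillnet_coastal",
              "gillnet_offshore", "trapnet", "longline", "recreational")

  invasive <- c("round_goby", "harris_mud_crab", "fishhook_waterflea")

  producer <- groups %in% c("fucus", "filamentous_algae", "other_macrophytes",
                            "phytoplankton", "benthic_microalgae")

  # Q/B consumption rates (per year); 0 for producers.
  qb <- c(fucus = 0, filamentous_algae = 0, other_macrophytes = 0,
          phytoplankton = 0, benthic_microalgae = 0,
          zooplankton_small = 35, zooplankton_large = 25,
          fishhook_waterflea = 30,
          benthic_bivalves = 8, benthic_gastropods = 7, benthic_amphipods = 12,
          benthic_polychaetes = 10, harris_mud_crab = 9, mysids = 15,
          saduria = 6,
          herring = 5.5, sprat = 6.5, sander_juv = 6, sander_adult = 3.2,
          perch = 3.8, cyprinids = 4.5, flounder = 3.5, round_goby = 5,
          stickleback = 7, whitefish = 4, pike = 2.8,
          seals = 15, birds = 60)[groups]

  # baseline mean biomass (t/km^2), eutrophic early-2000s coastal state
  b0 <- c(fucus = 3, filamentous_algae = 12, other_macrophytes = 5,
          phytoplankton = 18, benthic_microalgae = 4,
          zooplankton_small = 6, zooplankton_large = 4,
          fishhook_waterflea = 0.3,
          benthic_bivalves = 30, benthic_gastropods = 4, benthic_amphipods = 3,
          benthic_polychaetes = 5, harris_mud_crab = 0.4, mysids = 1.5,
          saduria = 0.8,
          herring = 8, sprat = 5, sander_juv = 0.4, sander_adult = 1.2,
          perch = 2.5, cyprinids = 4, flounder = 1.5, round_goby = 0.6,
          stickleback = 2, whitefish = 0.5, pike = 0.6,
          seals = 0.08, birds = 0.02)[groups]

  diet <- build_default_diet(groups)

  # warming sensitivity in [-1, 1]: heat-opportunists positive (filamentous
  # algae, cyprinids, sander, perch, round goby), cold-adapted negative
  warm <- c(fucus = -0.3, filamentous_algae = 0.8, other_macrophytes = 0.1,
            phytoplankton = 0.3, benthic_microalgae = 0.1,
            zooplankton_small = 0.2, zooplankton_large = -0.3,
            fishhook_waterflea = 0.7,
            benthic_bivalves = -0.5, benthic_gastropods = 0, benthic_amphipods = -0.2,
            benthic_polychaetes = 0.1, harris_mud_crab = 0.7, mysids = -0.2,
            saduria = -0.6,
            herring = -0.3, sprat = 0.2, sander_juv = 0.7, sander_adult = 0.7,
            perch = 0.6, cyprinids = 0.6, flounder = -0.2, round_goby = 0.8,
            stickleback = 0.4, whitefish = -0.6, pike = 0.1,
            seals = 0, birds = 0)[groups]

  # nutrient sensitivity in [-1, 1]: positive = favored by high loads (REF),
  # negative = favored by load reductions / clear water (BSAP)
  nutr <- c(fucus = -0.9, filamentous_algae = 0.8, other_macrophytes = -0.5,
            phytoplankton = 0.7, benthic_microalgae = -0.3,
            zooplankton_small = 0.4, zooplankton_large = 0.1,
            fishhook_waterflea = 0.3,
            benthic_bivalves = 0.4, benthic_gastropods = -0.1, benthic_amphipods = -0.2,
            benthic_polychaetes = 0.3, harris_mud_crab = 0.2, mysids = 0,
            saduria = -0.3,
            herring = 0.1, sprat = 0.2, sander_juv = 0.3, sander_adult = 0.3,
            perch = -0.1, cyprinids = 0.5, flounder = 0, round_goby = 0.2,
            stickleback = 0.3, whitefish = -0.5, pike = -0.2,
            seals = 0, birds = 0)[groups]

  # exposure to the general fishery (all fleets) and to gillnets specifically
  fish_exp <- c(herring = 0.8, sprat = 0.8, sander_juv = 0.2, sander_adult = 0.9,
                perch = 0.7, cyprinids = 0.3, flounder = 0.5, whitefish = 0.6,
                pike = 0.4)
  fexp <- stats::setNames(numeric(length(groups)), groups)
  fexp[names(fish_exp)] <- fish_exp
  gil_exp <- c(sander_adult = 0.9, perch = 0.6, whitefish = 0.8, pike = 0.5)
  gexp <- stats::setNames(numeric(length(groups)), groups)
  gexp[names(gil_exp)] <- gil_exp

  cfg <- list(
    group_names = groups,
    fleet_names = fleets,
    invasive_names = invasive,
    producer = stats::setNames(producer, groups),
    diet_matrix = diet,
    consumption_rate = qb,
    baseline_biomass = b0,
    noise = list(ar1 = 0.5, sd = 0.05),
    member_sdlog = 0.1,
    sensitivity = list(warming = warm, nutrient = nutr,
                       fishery = gexp * 0 + fexp, gillnet = gexp),
    # per-year log-trend rates applied from the first projection year on
    trend_rates = list(climate = c(RCP45 = 0.004, RCP85 = 0.012),
                       nutrient = c(BSAP = -0.006, REF = 0.006),
                       fishing = c(SQ = 0, Dec = 0.004, Inc = -0.004,
                                   Gil = 0.006)),
    shift_schedule = default_shift_schedule(),
    years = 2000:2090,
    baseline_window = c(2000L, 2018L),
    target_window = c(2019L, 2090L)
  )
  class(cfg) <- "foodweb_config"
  validate_foodweb_config(cfg)
  cfg
}

# Diet matrix: DC[i, j] = fraction of consumer j's diet taken from prey i.
# Columns for producers are all zero; consumer columns sum to exactly 1.
build_default_diet <- function(groups) {
  n <- length(groups)
  dc <- matrix(0, n, n, dimnames = list(groups, groups))
  set_diet <- function(consumer, ...) {
    d <- c(...)
    dc[names(d), consumer] <<- d / sum(d)
  }
  set_diet("zooplankton_small", phytoplankton = 0.9, benthic_microalgae = 0.1)
  set_diet("zooplankton_large", phytoplankton = 0.7, zooplankton_small = 0.3)
  set_diet("fishhook_waterflea", zooplankton_small = 0.6, phytoplankton = 0.4)
  set_diet("benthic_bivalves", phytoplankton = 0.85, benthic_microalgae = 0.15)
  set_diet("benthic_gastropods", filamentous_algae = 0.5, benthic_microalgae = 0.3,
           fucus = 0.2)
  set_diet("benthic_amphipods", filamentous_algae = 0.4, fucus = 0.3,
           benthic_microalgae = 0.3)
  set_diet("benthic_polychaetes", benthic_microalgae = 0.5, phytoplankton = 0.5)
  set_diet("harris_mud_crab", benthic_bivalves = 0.4, benthic_gastropods = 0.3,
           benthic_amphipods = 0.3)
  set_diet("mysids", zooplankton_small = 0.5, zooplankton_large = 0.3,
           phytoplankton = 0.2)
  set_diet("saduria", benthic_amphipods = 0.5, benthic_polychaetes = 0.5)
  set_diet("herring", zooplankton_small = 0.45, zooplankton_large = 0.4,
           mysids = 0.15)
  set_diet("sprat", zooplankton_small = 0.55, zooplankton_large = 0.45)
  set_diet("sander_juv", zooplankton_large = 0.4, mysids = 0.3,
           benthic_amphipods = 0.3)
  set_diet("sander_adult", herring = 0.35, sprat = 0.2, stickleback = 0.2,
           round_goby = 0.15, cyprinids = 0.1)
  set_diet("perch", benthic_amphipods = 0.25, mysids = 0.15, stickleback = 0.25,
           round_goby = 0.2, cyprinids = 0.15)
  set_diet("cyprinids", benthic_bivalves = 0.3, benthic_gastropods = 0.2,
           benthic_amphipods = 0.2, zooplankton_large = 0.3)
  set_diet("flounder", benthic_bivalves = 0.6, benthic_polychaetes = 0.25,
           benthic_amphipods = 0.15)
  set_diet("round_goby", benthic_bivalves = 0.55, benthic_gastropods = 0.25,
           benthic_amphipods = 0.2)
  set_diet("stickleback", zooplankton_small = 0.5, zooplankton_large = 0.3,
           benthic_amphipods = 0.2)
  set_diet("whitefish", benthic_amphipods = 0.4, mysids = 0.3,
           zooplankton_large = 0.3)
  set_diet("pike", perch = 0.4, cyprinids = 0.35, stickleback = 0.25)
  set_diet("seals", herring = 0.5, sprat = 0.2, sander_adult = 0.1,
           whitefish = 0.1, perch = 0.1)
  set_diet("birds", herring = 0.3, sprat = 0.2, stickleback = 0.3,
           round_goby = 0.2)
  dc
}

# Planted multiplicative biomass steps, keyed by climate x nutrient (fishing
# has second-order effects and shares the schedule). Years lie in the
# projection window; factors persist from the shift year on.
default_shift_schedule <- function() {
  data.frame(
    climate = c("RCP45", "RCP45", "RCP45", "RCP85", "RCP85", "RCP85",
                "RCP85", "RCP85"),
    nutrient = c("BSAP", "BSAP", "REF", "BSAP", "BSAP", "BSAP",
                 "REF", "REF"),
    year = c(2037L, 2062L, 2055L, 2030L, 2048L, 2065L, 2035L, 2069L),
    group = c("fucus", "round_goby", "filamentous_algae", "fucus",
              "sander_adult", "harris_mud_crab", "filamentous_algae",
              "benthic_bivalves"),
    factor = c(2.5, 2.0, 1.8, 2.0, 2.0, 2.0, 2.5, 0.4),
    stringsAsFactors = FALSE
  )
}

validate_foodweb_config <- function(cfg) {
  n <- length(cfg$group_names)
  dc <- cfg$diet_matrix
  stopifnot(is.matrix(dc), nrow(dc) == n, ncol(dc) == n)
  cs <- colSums(dc)
  consumer <- !cfg$producer
  if (any(abs(cs[consumer] - 1) > 1e-9))
    stop("consumer diet columns must sum to 1")
  if (any(cs[!consumer] != 0))
    stop("producer diet columns must be all zero")
  if (any(dc < 0)) stop("diet fractions must be nonnegative")
  if (any(cfg$consumption_rate < 0) || any(cfg$baseline_biomass < 0))
    stop("rates and biomasses must be nonnegative")
  if (!all(cfg$invasive_names %in% cfg$group_names))
    stop("invasive_names must be a subset of group_names")
  sh <- cfg$shift_schedule
  if (nrow(sh) > 0) {
    tw <- cfg$target_window
    if (any(sh$year < tw[1] | sh$year > tw[2]))
      stop("shift years must lie in the projection window")
    if (!all(sh$group %in% cfg$group_names))
      stop("shift groups must be known group names")
  }
  invisible(cfg)
}

#' @export
print.foodweb_config <- function(x, ...) {
  cat("<foodweb_config>\n")
  cat("  groups:   ", length(x$group_names),
      sprintf("(%d producers, %d invasive)", sum(x$producer),
              length(x$invasive_names)), "\n")
  cat("  fleets:   ", length(x$fleet_names), "\n")
  cat("  years:    ", min(x$years), "-", max(x$years),
      sprintf("(baseline %d-%d)", x$baseline_window[1], x$baseline_window[2]),
      "\n")
  cat("  noise:     AR(1) coef", x$noise$ar1, ", innovation sd", x$noise$sd,
      "(log scale)\n")
  cat("  planted shifts:", nrow(x$shift_schedule), "\n")
  invisible(x)
}
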