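test_that("default configuration matches the modeled system's structure", {
  cfg <- default_config()
  expect_length(cfg$group_names, 28)
  expect_length(cfg$fleet_names, 7)
  expect_length(cfg$invasive_names, 3)
  expect_true(all(cfg$invasive_names %in% cfg$group_names))

  dc <- cfg$diet_matrix
  consumer <- !cfg$producer
  expect_true(all(abs(colSums(dc)[consumer] - 1) < 1e-9))
  expect_true(all(colSums(dc)[!consumer] == 0))
  expect_true(all(dc >= 0))

  # the web spans at least three trophic levels: a producer feeds a
  # consumer that itself feeds another consumer
  herb <- consumer & colSums(dc[cfg$producer, ]) > 0
  pred_of_herb <- colSums(dc[herb, , drop = FALSE]) > 0
  expect_true(any(pred_of_herb))
})

test_that("scenario grid is the full 2 x 2 x 4 cross, without duplicates", {
  g <- scenario_grid()
  expect_length(g, 16)
  labels <- vapply(g, format, character(1))
  expect_length(unique(labels), 16)
  expect_length(Filter(function(s) s$climate == "RCP45" && s$nutrient == "BSAP", g), 4)
  expect_error(scenario_spec("RCP6.0", "BSAP", "SQ"), "climate")
})

test_that("simulation is deterministic and rejects invalid inputs", {
  cfg <- default_config()
  sc <- scenario_spec("RCP85", "REF", "SQ")
  r1 <- simulate_biomass(cfg, sc, members = 2, seed = 42)
  r2 <- simulate_biomass(cfg, sc, members = 2, seed = 42)
  expect_identical(r1$biomass, r2$biomass)
  r3 <- simulate_biomass(cfg, sc, members = 2, seed = 43)
  expect_false(identical(r1$biomass, r3$biomass))

  expect_error(simulate_biomass(cfg, sc, members = 0, seed = 1), "members")
  expect_error(simulate_biomass(cfg, sc, members = 2), "seed")
  expect_true(all(r1$biomass >= 0))
})

test_that("degenerate parameters give constant biomass over years", {
  cfg <- flat_config()
  run <- simulate_biomass(cfg, scenario_spec("RCP85", "REF", "SQ"),
                          members = 3, seed = 5)
  for (m in 1:3) {
    rng <- apply(run$biomass[m, , ], 2, function(v) diff(range(v)))
    expect_true(all(rng == 0))
  }
})

test_that("a planted multiplicative step is recovered from the sample mean", {
  cfg <- flat_config()
  cfg$noise$sd <- 0.02
  cfg$shift_schedule <- data.frame(climate = "RCP45", nutrient = "BSAP",
                                   year = 2035L, group = "perch", factor = 3)
  run <- simulate_biomass(cfg, scenario_spec("RCP45", "BSAP", "SQ"),
                          members = 50, seed = 11)
  expect_equal(run$ground_truth$shift_year, 2035L)
  b <- run$biomass[, , "perch"]
  before <- run$years < 2035
  ratio <- rowMeans(b[, !before]) / rowMeans(b[, before])
  se <- stats::sd(ratio) / sqrt(length(ratio))
  expect_lt(abs(mean(ratio) - 3), 3 * se + 1e-9)
})

test_that("flow matrices follow the consumption rule", {
  cfg <- default_config()
  n <- length(cfg$group_names)
  b <- cfg$baseline_biomass

  Tm <- flows_from_biomass(b, cfg)
  expect_equal(dim(Tm), c(n + 1, n + 1))
  expect_true(all(Tm >= 0))

  # internal column sums equal B * Q/B for every consumer, checked against
  # an independent elementwise summation
  for (j in which(!cfg$producer)) {
    expected <- sum(b[j] * cfg$consumption_rate[j] * cfg$diet_matrix[, j])
    expect_equal(unname(sum(Tm[seq_len(n), j])), expected, tolerance = 1e-12)
    expect_equal(expected, unname(b[j] * cfg$consumption_rate[j]),
                 tolerance = 1e-12)
  }
  # every compartment with outflow has inflow (imports close producers)
  outflow <- rowSums(Tm)[seq_len(n)]
  inflow <- colSums(Tm)[seq_len(n)]
  expect_true(all(inflow[outflow > 0] > 0))

  expect_true(all(flows_from_biomass(rep(0, n), cfg) == 0))
  expect_error(flows_from_biomass(rep(-1, n), cfg), "nonnegative")
  expect_error(flows_from_biomass(b[-1], cfg), "length")
})

test_that("a single consumer's flow is biomass times Q/B times diet share", {
  cfg <- flat_config()
  b <- numeric(28)
  names(b) <- cfg$group_names
  # herring eats zooplankton etc.; isolate one consumer with unit diet prey
  cfg$diet_matrix[, "herring"] <- 0
  cfg$diet_matrix["zooplankton_small", "herring"] <- 1
  cfg$consumption_rate["herring"] <- 10
  b["herring"] <- 2
  Tm <- flows_from_biomass(b, cfg)
  expect_equal(unname(Tm["zooplankton_small", "herring"]), 20)
  expect_equal(sum(Tm[cfg$group_names, cfg$group_names]), 20)
})

test_that("mean flows equal flows of mean biomass (linearity)", {
  cfg <- flat_config()
  cfg$noise$sd <- 0.1
  run <- simulate_biomass(cfg, scenario_spec("RCP45", "REF", "SQ"),
                          members = 4, seed = 3)
  fl <- ensemble_mean_flows(run)
  y <- 10
  per_member <- lapply(1:4, function(m)
    flows_from_biomass(run$biomass[m, y, ], cfg))
  expect_equal(fl[[y]], Reduce(`+`, per_member) / 4, tolerance = 1e-12)
})
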