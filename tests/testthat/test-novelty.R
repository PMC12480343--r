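test_that("distance primitives match hand values and brute-force sums", {
  expect_equal(euclidean_distance(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(euclidean_distance(c(0, 0), c(3, 4)), 5)
  expect_error(euclidean_distance(1:3, 1:4), "length")
  set.seed(5)
  for (k in 1:20) {
    x <- stats::runif(5); y <- stats::runif(5)
    acc <- 0
    for (g in 1:5) acc <- acc + (x[g] - y[g])^2
    expect_equal(euclidean_distance(x, y), sqrt(acc), tolerance = 1e-12)
  }

  expect_equal(hellinger_distance(c(0.3, 0.7), c(0.3, 0.7)), 0)
  expect_equal(hellinger_distance(c(1, 0), c(0, 1)), sqrt(2), tolerance = 0)
  expect_equal(hellinger_distance(c(0.5, 0.5), c(1, 0)), sqrt(2 - sqrt(2)),
               tolerance = 1e-12)
  expect_warning(d <- hellinger_distance(c(2, 2), c(1, 0)), "normalizing")
  expect_equal(d, hellinger_distance(c(0.5, 0.5), c(1, 0)))
  expect_error(hellinger_distance(c(-0.1, 1.1), c(1, 0)), "nonnegative")
})

test_that("cumulative species novelty takes per-species minima over the baseline", {
  base <- rbind(c(1, 1), c(2, 3))
  out <- cumulative_species_novelty(c(4, 1), base)
  expect_equal(unname(out$per_species), c(2, 0))
  expect_equal(out$total, 2)

  expect_equal(cumulative_species_novelty(c(2, 3), base)$total, 0)
  # total is bounded by the L1 distance to any single baseline state
  for (b in 1:2)
    expect_lte(out$total, sum(abs(c(4, 1) - base[b, ])))
  expect_error(cumulative_species_novelty(c(1, 2), base[0, , drop = FALSE]),
               "baseline")
})

test_that("novelty series equal exhaustive minima on constructed states", {
  # one member, two baseline years with states (0,0) and (3,4), one target (6,8)
  b <- array(0, c(1, 3, 2))
  b[1, 1, ] <- c(0, 0); b[1, 2, ] <- c(3, 4); b[1, 3, ] <- c(6, 8)
  run <- make_run(b, 2000:2002, c(2000, 2001), c(2002, 2002))
  nv <- novelty_series(run, "biomass_euclidean")
  expect_equal(nv$value, 5)  # min(10, 5)

  # a target state replaying a baseline state has zero novelty
  br <- array(0, c(1, 3, 2))
  br[1, 1, ] <- c(1, 2); br[1, 2, ] <- c(3, 4); br[1, 3, ] <- c(3, 4)
  run_r <- make_run(br, 2000:2002, c(2000, 2001), c(2002, 2002))
  for (m in novelty_measures())
    expect_equal(novelty_series(run_r, m)$value, 0, tolerance = 1e-12)

  # member averaging: members with novelty 2 and 4 give 3
  b2 <- array(0, c(2, 2, 2))
  b2[, 1, ] <- rbind(c(1, 0), c(1, 0))
  b2[1, 2, ] <- c(3, 0)   # euclidean novelty 2
  b2[2, 2, ] <- c(5, 0)   # euclidean novelty 4
  run2 <- make_run(b2, 2000:2001, c(2000, 2000), c(2001, 2001))
  expect_equal(novelty_series(run2, "biomass_euclidean")$value, 3)

  expect_error(novelty_series(run, "mahalanobis"), "arg")
  expect_error(novelty_series(run, "biomass_euclidean",
                              baseline_window = c(2000, 2001),
                              target_window = c(2001, 2002)), "overlap")
})

test_that("novelty matches the double-loop oracle and is monotone in the baseline", {
  for (trial in 1:60) {
    set.seed(trial)
    n_m <- sample(1:3, 1)
    b <- array(stats::rlnorm(n_m * 10 * 4, 0, 0.5), c(n_m, 10, 4))
    run <- make_run(b, 2000:2009, c(2000, 2004), c(2005, 2009))
    for (m in novelty_measures()) {
      got <- novelty_series(run, m, c(2000, 2004), c(2005, 2009))
      want <- novelty_oracle(run, m, c(2000, 2004), c(2005, 2009))
      expect_equal(got$value, want$value, tolerance = 1e-12)
      # enlarging the baseline pool never increases novelty
      small <- novelty_series(run, m, c(2000, 2002), c(2005, 2009))
      expect_true(all(got$value <= small$value + 1e-12))
    }
  }
})

test_that("composition novelty is scale-free, biomass novelty scales linearly", {
  set.seed(77)
  b <- array(stats::rlnorm(2 * 8 * 5, 0, 0.3), c(2, 8, 5))
  run <- make_run(b, 2000:2007, c(2000, 2003), c(2004, 2007))
  k <- 3.7
  run_k <- make_run(b * k, 2000:2007, c(2000, 2003), c(2004, 2007))
  expect_equal(novelty_series(run_k, "composition_hellinger")$value,
               novelty_series(run, "composition_hellinger")$value,
               tolerance = 1e-12)
  expect_equal(novelty_series(run_k, "biomass_euclidean")$value,
               k * novelty_series(run, "biomass_euclidean")$value,
               tolerance = 1e-12)
  # Hellinger bounded by sqrt(2)
  expect_true(all(novelty_series(run, "composition_hellinger")$value <= sqrt(2)))
})

test_that("batched novelty yields one series per scenario-measure pair", {
  set.seed(12)
  runs <- lapply(list(scenario_spec("RCP45", "BSAP", "SQ"),
                      scenario_spec("RCP85", "REF", "SQ")), function(sc) {
    b <- array(stats::rlnorm(2 * 6 * 3), c(2, 6, 3))
    make_run(b, 2000:2005, c(2000, 2002), c(2003, 2005), scenario = sc)
  })
  out <- novelty_batch(runs)
  expect_length(out, 6)
  expect_length(unique(names(out)), 6)
  out1 <- novelty_batch(runs[[1]])
  expect_length(out1, 3)
  expect_error(
    novelty_batch(runs, scenarios = scenario_grid()),
    "missing")
})
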