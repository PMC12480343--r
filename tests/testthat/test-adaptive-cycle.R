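# Build an index_series with fully controlled smoothed columns.
manual_index_series <- function(years, a, c_, r) {
  out <- data.frame(year = years, tst = a + c_, ascendency = a,
                    capacity = c_, overhead = r,
                    tst_smoothed = a + c_, ascendency_smoothed = a,
                    capacity_smoothed = c_, overhead_smoothed = r)
  structure(out, class = c("index_series", "data.frame"),
            scenario = NULL, base = 2, span = NA)
}

test_that("trend signatures recover known slopes and flatness", {
  years <- 2000:2040
  idx <- manual_index_series(years,
                             a = 1 + 0.5 * seq_along(years),
                             c_ = rep(3, length(years)),
                             r = 10 - 0.2 * seq_along(years))
  sig <- trend_signature(idx, 2020, window = 7, epsilon = 1e-9)
  expect_equal(sig$connectedness_slope, 0.5, tolerance = 1e-6)
  expect_equal(sig$resilience_slope, -0.2, tolerance = 1e-6)
  expect_gt(sig$connectedness_sign, 0)
  # constant series with positive flatness threshold has zero sign
  expect_equal(sig$potential_sign, 0)
  expect_error(trend_signature(idx, 1990), "not in the index series")
})

test_that("change points anchor as reorganization only under the right signature", {
  years <- 2000:2040
  n <- length(years)
  # falling connectedness, rising potential, high overhead in 2nd half
  a <- c(seq(1, 2, length.out = 20), seq(2, 1, length.out = 21))
  c_ <- c(seq(2, 1, length.out = 20), seq(1, 2.2, length.out = 21))
  r <- c(rep(1, 20), rep(3, 21))
  idx <- manual_index_series(years, a, c_, r)
  anc <- anchor_reorganization(c(2030), idx, epsilon = 1e-9)
  expect_equal(anc$anchors, 2030)
  expect_true(anc$diagnostics$anchored)

  # all three rising: not anchored, with the failing condition reported
  idx_up <- manual_index_series(years, a = seq(1, 3, length.out = n),
                                c_ = seq(1, 3, length.out = n),
                                r = seq(1, 3, length.out = n))
  anc2 <- anchor_reorganization(c(2030), idx_up, epsilon = 1e-9)
  expect_length(anc2$anchors, 0)
  expect_match(anc2$diagnostics$failed, "connectedness")

  # no change points, no reorganization
  seg <- classify_phases(idx_up, integer(0), epsilon = 1e-9)
  expect_equal(seg$cycle_count, 0)
  expect_false("reorganization" %in% seg$segments$phase)
})

test_that("uniform growth gives a single full-cover growth segment", {
  years <- 2019:2090
  n <- length(years)
  idx <- manual_index_series(years, a = seq(1, 3, length.out = n),
                             c_ = seq(1, 3, length.out = n),
                             r = seq(3, 1, length.out = n))
  seg <- classify_phases(idx, integer(0), epsilon = 1e-9)
  expect_equal(nrow(seg$segments), 1)
  expect_equal(seg$segments$phase, "growth_rK")
  expect_equal(seg$segments$start_year, 2019)
  expect_equal(seg$segments$end_year, 2090)
  expect_equal(seg$cycle_count, 0)
})

test_that("planted phase schedules are recovered to boundary accuracy", {
  sch <- data.frame(
    start_year = c(2019, 2030, 2034, 2043),
    end_year = c(2029, 2033, 2042, 2060),
    phase = c("growth_rK", "collapse", "reorganization", "growth_rK"))
  idx <- simulate_phase_indices(sch, noise_sd = 0.005, seed = 99)
  anc <- anchor_reorganization(2034, idx, slack = 2)
  expect_length(anc$anchors, 1)
  expect_lte(abs(anc$anchors - 2034), 2)
  seg <- classify_phases(idx, anc$anchors)

  expect_equal(seg$cycle_count, 1)
  expect_equal(unique(seg$labels[seg$years %in% 2035:2041]), "reorganization")
  expect_true("collapse" %in% seg$labels[seg$years %in% 2029:2034])
  expect_equal(unique(seg$labels[seg$years %in% 2048:2056]), "growth_rK")
  truth <- planted_labels(sch, seg$years)
  expect_gte(mean(seg$labels == truth), 0.85)

  # segments tile the analysis window
  expect_equal(seg$segments$start_year[1], 2019)
  expect_equal(seg$segments$end_year[nrow(seg$segments)], 2060)
  expect_true(all(seg$segments$start_year[-1] ==
                    utils::head(seg$segments$end_year, -1) + 1))
})

test_that("classified phases never run reorganization directly into collapse", {
  for (s in 1:25) {
    rp <- random_phase_schedule(s)
    idx <- simulate_phase_indices(rp$schedule, seed = s * 17)
    onsets <- rp$schedule$start_year[rp$schedule$phase == "reorganization"]
    seg <- classify_phases(idx, anchor_reorganization(onsets, idx,
                                                      slack = 2)$anchors)
    ph <- seg$segments$phase[seg$segments$phase != "unclassified"]
    if (length(ph) > 1)
      for (k in seq_along(ph)[-1])
        expect_false(ph[k] == "collapse" && ph[k - 1] == "reorganization")
    # every reorganization segment starts at an anchor
    starts <- seg$segments$start_year[seg$segments$phase == "reorganization"]
    expect_true(all(starts %in% seg$anchors))
    expect_equal(seg$cycle_count,
                 sum(seg$segments$phase == "reorganization"))
  }
})

test_that("phase durations partition the window", {
  sch <- data.frame(start_year = c(2019, 2040), end_year = c(2039, 2109),
                    phase = c("growth_rK", "growth_rK"))
  idx <- simulate_phase_indices(sch, seed = 1)
  seg <- classify_phases(idx, integer(0))
  dur <- phase_durations(seg)
  expect_equal(sum(dur$segments$duration), 2109 - 2019 + 1)

  # single-segment fixture of known length
  one <- structure(list(segments = data.frame(start_year = 2000,
                                              end_year = 2090,
                                              phase = "growth_rK"),
                        cycle_count = 0, anchors = integer(0),
                        labels = rep("growth_rK", 91), years = 2000:2090,
                        scenario = NULL),
                   class = "phase_segmentation")
  d1 <- phase_durations(one)
  expect_equal(d1$segments$duration, 91)
  expect_equal(unname(d1$mean_by_phase["growth_rK"]), 91)
})
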