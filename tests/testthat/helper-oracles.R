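# Independent oracles and fixture builders used across the suite.

# Ascendency as TST x mutual information of the flow-normalized joint
# distribution; an independent route to the same quantity.
mi_ascendency <- function(net, base = 2) {
  tst <- sum(net)
  p <- net / tst
  pi_ <- rowSums(p)
  pj <- colSums(p)
  tot <- 0
  for (i in seq_len(nrow(p)))
    for (j in seq_len(ncol(p)))
      if (p[i, j] > 0)
        tot <- tot + p[i, j] * log(p[i, j] / (pi_[i] * pj[j]), base = base)
  tst * tot
}

random_flow_matrix <- function(n, sparsity = 0.4) {
  m <- matrix(stats::runif(n * n, 0, 5), n, n)
  m[matrix(stats::runif(n * n) < sparsity, n, n)] <- 0
  if (sum(m) == 0) m[1, min(2, n)] <- 1
  m
}

# Minimal ensemble_run wrapper around a raw biomass array.
make_run <- function(biomass, years, baseline_window, target_window,
                     scenario = scenario_spec("RCP45", "BSAP", "SQ")) {
  stopifnot(length(dim(biomass)) == 3, dim(biomass)[2] == length(years))
  structure(list(scenario = scenario, years = years,
                 members = dim(biomass)[1], biomass = biomass,
                 config = list(baseline_window = baseline_window,
                               target_window = target_window),
                 ground_truth = data.frame()),
            class = "ensemble_run")
}

# Exhaustive double-loop novelty oracle (tiny runs only).
novelty_oracle <- function(run, measure, baseline_window, target_window) {
  years <- run$years
  B <- run$biomass
  b_idx <- which(years >= baseline_window[1] & years <= baseline_window[2])
  t_idx <- which(years >= target_window[1] & years <= target_window[2])
  n_m <- dim(B)[1]
  base_states <- list()
  for (m in seq_len(n_m)) for (y in b_idx)
    base_states[[length(base_states) + 1]] <- B[m, y, ]
  hell <- function(x, y) {
    p <- x / sum(x); q <- y / sum(y)
    sqrt(sum((sqrt(p) - sqrt(q))^2))
  }
  out <- numeric(length(t_idx))
  for (k in seq_along(t_idx)) {
    per_member <- numeric(n_m)
    for (m in seq_len(n_m)) {
      x <- B[m, t_idx[k], ]
      per_member[m] <- switch(measure,
        biomass_euclidean = min(vapply(base_states,
          function(b) sqrt(sum((x - b)^2)), numeric(1))),
        composition_hellinger = min(vapply(base_states,
          function(b) hell(x, b), numeric(1))),
        cumulative_species = {
          tot <- 0
          for (g in seq_along(x))
            tot <- tot + min(vapply(base_states,
              function(b) abs(x[g] - b[g]), numeric(1)))
          tot
        })
    }
    out[k] <- mean(per_member)
  }
  data.frame(year = years[t_idx], value = out)
}

# Default config with all stochastic and forced variation switched off.
flat_config <- function() {
  cfg <- default_config()
  cfg$noise$sd <- 0
  cfg$trend_rates <- list(climate = c(RCP45 = 0, RCP85 = 0),
                          nutrient = c(BSAP = 0, REF = 0),
                          fishing = c(SQ = 0, Dec = 0, Inc = 0, Gil = 0))
  cfg$shift_schedule <- cfg$shift_schedule[0, ]
  cfg
}

# Random planted phase schedule starting 2019; returns list(schedule, n_cycles).
random_phase_schedule <- function(seed) {
  set.seed(seed)
  n_cyc <- sample(1:2, 1)
  segs <- list(); yr <- 2019L
  add <- function(ph, len) {
    e <- yr + len - 1L
    segs[[length(segs) + 1]] <<- data.frame(start_year = yr, end_year = e,
                                            phase = ph)
    yr <<- e + 1L
  }
  add("growth_rK", sample(15:25, 1))
  for (k in seq_len(n_cyc)) {
    add("collapse", sample(4:7, 1))
    add("reorganization", sample(8:14, 1))
    add("growth_rK", sample(15:25, 1))
  }
  list(schedule = do.call(rbind, segs), n_cycles = n_cyc)
}

planted_labels <- function(schedule, years) {
  truth <- rep(NA_character_, length(years))
  for (k in seq_len(nrow(schedule)))
    truth[years >= schedule$start_year[k] & years <= schedule$end_year[k]] <-
      schedule$phase[k]
  truth
}
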