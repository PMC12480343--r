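#' Default pipeline configuration
#'
#' @param scenarios `"all"` (the 16-cell grid) or a character vector of
#'   scenario labels such as `"RCP85_REF_SQ"`.
#' @param members Monte-Carlo ensemble size (default 20).
#' @param seed Top-level integer seed; all stage randomness derives from it.
#' @return A list of class `pipeline_config`.
#' @export
default_pipeline_config <- function(scenarios = "all", members = 20L,
                                    seed = 1L) {
  cfg <- list(
    foodweb = default_config(),
    scenarios = scenarios,
    members = as.integer(members),
    seed = as.integer(seed),
    baseline_window = c(2000L, 2018L),
    target_window = c(2019L, 2090L),
    log_base = 2,
    span = 0.75,
    min_seg_len = 10L,
    penalty = "MBIC",
    trend_window = 7L,
    epsilon = NULL,
    min_reorg_len = 3L,
    anchor_slack = 2L,
    write_flows = FALSE)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Validate a raw pipeline configuration
#'
#' Checks every field and reports all violations at once rather than
#' stopping at the first.
#'
#' @param raw A list (e.g. parsed from YAML) or a `pipeline_config`. Fields
#'   missing from `raw` take the defaults of [default_pipeline_config()].
#' @return A validated `pipeline_config`; errors with the full violation
#'   list otherwise.
#' @export
validate_config <- function(raw) {
  cfg <- default_pipeline_config()
  known <- names(cfg)
  if (!is.list(raw)) stop("config must be a list")
  unknown <- setdiff(names(raw), c(known, "foodweb"))
  for (f in intersect(names(raw), known)) cfg[[f]] <- raw[[f]]

  bad <- character(0)
  if (length(unknown))
    bad <- c(bad, paste0("unknown field(s): ", paste(unknown, collapse = ", ")))
  if (!identical(cfg$scenarios, "all")) {
    for (s in cfg$scenarios) {
      ok <- tryCatch({ parse_scenario(s); TRUE },
                     error = function(e) conditionMessage(e))
      if (!isTRUE(ok)) bad <- c(bad, paste0("scenarios: ", ok))
    }
  }
  if (!is.numeric(cfg$members) || length(cfg$members) != 1 || cfg$members < 1)
    bad <- c(bad, "members: must be a positive integer")
  if (is.null(cfg$seed) || !is.numeric(cfg$seed) || length(cfg$seed) != 1)
    bad <- c(bad, "seed: required (single integer)")
  for (w in c("baseline_window", "target_window")) {
    v <- cfg[[w]]
    if (!is.numeric(v) || length(v) != 2 || v[1] > v[2])
      bad <- c(bad, paste0(w, ": must be c(first_year, last_year)"))
  }
  if (is.numeric(cfg$baseline_window) && is.numeric(cfg$target_window) &&
      length(cfg$baseline_window) == 2 && length(cfg$target_window) == 2 &&
      max(cfg$baseline_window[1], cfg$target_window[1]) <=
      min(cfg$baseline_window[2], cfg$target_window[2]))
    bad <- c(bad, "windows: baseline and target windows overlap")
  if (!is.numeric(cfg$log_base) || cfg$log_base <= 0 || cfg$log_base == 1)
    bad <- c(bad, "log_base: must be positive and != 1")
  if (!is.numeric(cfg$span) || cfg$span <= 0 || cfg$span > 1)
    bad <- c(bad, "span: must be in (0, 1]")
  if (!is.numeric(cfg$min_seg_len) || cfg$min_seg_len < 1)
    bad <- c(bad, "min_seg_len: must be >= 1")
  if (!cfg$penalty %in% c("MBIC", "BIC", "manual"))
    bad <- c(bad, "penalty: must be MBIC, BIC or manual")
  if (!is.numeric(cfg$trend_window) || cfg$trend_window < 2)
    bad <- c(bad, "trend_window: must be >= 2")
  if (!is.numeric(cfg$min_reorg_len) || cfg$min_reorg_len < 1)
    bad <- c(bad, "min_reorg_len: must be >= 1")
  if (length(bad))
    stop("invalid pipeline config:\n  - ", paste(bad, collapse = "\n  - "))
  cfg$members <- as.integer(cfg$members)
  cfg$seed <- as.integer(cfg$seed)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' @param path Path to a YAML file.
#' @return A validated `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  validate_config(yaml::read_yaml(path))
}

#' Run the full analysis pipeline
#'
#' Executes the five stages for every requested scenario: (1) synthesize the
#' biomass ensemble, (2) compute ensemble-mean flow matrices and ENA index
#' series, (3) compute the three novelty series against the baseline window,
#' (4) detect change points in mean in each novelty series, (5) anchor
#' reorganization phases at the change points and classify the adaptive
#' cycle. Writes tidy CSVs (`biomass.csv`, `indices.csv`, `novelty.csv`,
#' `changepoints.csv`, `phases.csv`, `cycles.csv`, `ground_truth.csv`,
#' optionally `flows.csv`) plus a JSON run manifest. Deterministic for a
#' fixed seed: each scenario uses the derived seed `seed + 1000 * index`.
#'
#' @param config A `pipeline_config` (see [default_pipeline_config()],
#'   [validate_config()]).
#' @param out_dir Output directory (created if missing).
#' @param quiet Suppress per-stage progress messages.
#' @return The run manifest (list), invisibly; its `outputs` element lists
#'   the files written.
#' @export
run_pipeline <- function(config = default_pipeline_config(),
                         out_dir = tempfile("ecocycler_run_"),
                         quiet = FALSE) {
  config <- validate_config(unclass(config))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(...)

  scenarios <- if (identical(config$scenarios, "all")) scenario_grid()
               else lapply(config$scenarios, parse_scenario)
  fw <- config$foodweb
  fw$baseline_window <- config$baseline_window
  fw$target_window <- config$target_window

  manifest <- list(
    package = "ecocycler",
    version = as.character(utils::packageVersion("ecocycler")),
    seed = config$seed,
    members = config$members,
    n_scenarios = length(scenarios),
    parameters = config[c("baseline_window", "target_window", "log_base",
                          "span", "min_seg_len", "penalty", "trend_window",
                          "min_reorg_len", "anchor_slack")],
    stages = character(0), warnings = character(0), outputs = character(0))
  wcollect <- function(expr) {
    withCallingHandlers(expr, warning = function(w) {
      manifest$warnings <<- c(manifest$warnings, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  }

  biomass_rows <- list(); flow_rows <- list(); index_rows <- list()
  novelty_rows <- list(); cp_rows <- list(); phase_rows <- list()
  cycle_rows <- list(); gt_rows <- list()

  for (si in seq_along(scenarios)) {
    sc <- scenarios[[si]]
    label <- format(sc)
    seed_s <- config$seed + 1000L * si
    say("[", si, "/", length(scenarios), "] ", label)

    stage <- "generate"
    res <- tryCatch({
      run <- simulate_biomass(fw, sc, members = config$members, seed = seed_s)

      stage <- "ena"
      flows <- ensemble_mean_flows(run)
      idx <- index_series(flows, years = run$years, scenario = sc,
                          base = config$log_base, span = config$span)

      stage <- "novelty"
      novs <- wcollect(novelty_batch(run,
                                     baseline_window = config$baseline_window,
                                     target_window = config$target_window))

      stage <- "changepoint"
      cps <- changepoints_batch(novs, min_seg_len = config$min_seg_len,
                                penalty = config$penalty)

      stage <- "phases"
      cp_years <- sort(unique(unlist(lapply(cps, `[[`, "changepoints"))))
      anc <- anchor_reorganization(cp_years, idx,
                                   window = config$trend_window,
                                   epsilon = config$epsilon,
                                   slack = config$anchor_slack)
      seg <- classify_phases(idx, anc$anchors,
                             min_reorg_len = config$min_reorg_len,
                             window = config$trend_window,
                             epsilon = config$epsilon)
      list(run = run, flows = flows, idx = idx, novs = novs, cps = cps,
           anc = anc, seg = seg)
    }, error = function(e) {
      stop("pipeline stage '", stage, "' failed for scenario ", label, ": ",
           conditionMessage(e), call. = FALSE)
    })

    biomass_rows[[label]] <- biomass_wide(res$run)
    if (isTRUE(config$write_flows))
      flow_rows[[label]] <- flows_long(res$flows, label)
    ix <- as.data.frame(res$idx)
    index_rows[[label]] <- cbind(scenario = label, ix)
    novelty_rows[[label]] <- do.call(rbind, lapply(res$novs, function(s)
      data.frame(scenario = label, measure = attr(s, "measure"),
                 year = s$year, value = s$value)))
    cp_rows[[label]] <- do.call(rbind, lapply(names(res$cps), function(nm) {
      cp <- res$cps[[nm]]$changepoints
      if (!length(cp)) return(NULL)
      data.frame(scenario = label,
                 measure = attr(res$novs[[nm]], "measure"), year = cp)
    }))
    phase_rows[[label]] <- cbind(scenario = label, res$seg$segments)
    cycle_rows[[label]] <- data.frame(scenario = label,
                                      cycle_count = res$seg$cycle_count)
    gt_rows[[label]] <- res$run$ground_truth
    manifest$stages <- union(manifest$stages,
                             c("generate", "ena", "novelty", "changepoint",
                               "phases"))
  }

  wr <- function(rows, file) {
    df <- do.call(rbind, Filter(Negate(is.null), rows))
    if (is.null(df)) df <- data.frame()
    path <- file.path(out_dir, file)
    utils::write.csv(df, path, row.names = FALSE)
    manifest$outputs <<- c(manifest$outputs, path)
    path
  }
  wr(biomass_rows, "biomass.csv")
  if (isTRUE(config$write_flows)) wr(flow_rows, "flows.csv")
  wr(index_rows, "indices.csv")
  wr(novelty_rows, "novelty.csv")
  wr(cp_rows, "changepoints.csv")
  wr(phase_rows, "phases.csv")
  wr(cycle_rows, "cycles.csv")
  wr(gt_rows, "ground_truth.csv")

  manifest$config_hash <- config_hash(config)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  say("done: ", out_dir)
  invisible(manifest)
}

biomass_wide <- function(run) {
  b <- run$biomass
  n_m <- dim(b)[1]; n_t <- dim(b)[2]
  out <- data.frame(
    scenario = format(run$scenario),
    year = rep(run$years, each = n_m),
    member = rep(seq_len(n_m), times = n_t))
  g <- dimnames(b)[[3]]
  for (k in seq_along(g))
    out[[g[k]]] <- as.vector(b[, , k])
  out
}

flows_long <- function(flows, label) {
  do.call(rbind, lapply(names(flows), function(y) {
    Tm <- flows[[y]]
    pos <- which(Tm > 0, arr.ind = TRUE)
    if (!nrow(pos)) return(NULL)
    data.frame(scenario = label, year = as.integer(y),
               source = rownames(Tm)[pos[, 1]],
               target = colnames(Tm)[pos[, 2]],
               flow_t_km2_yr = Tm[pos])
  }))
}

# stable content hash of the serialized config (no external digest dep)
config_hash <- function(config) {
  raw <- serialize(unclass(config), NULL, version = 2)
  sprintf("%08x-%d", sum(as.integer(raw) * seq_along(raw)) %% 0xFFFFFFF,
          length(raw))
}
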