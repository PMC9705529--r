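#' Small synthetic node roster for demos and tests
#'
#' A balanced table with `n_per_system` nodes in each of the six system
#' labels (five named systems plus "Others"), for desk-scale runs where
#' the bundled 80-node roster is larger than needed.
#'
#' @param n_per_system Nodes per system (>= 2 so recruitment is defined).
#' @return A `node_table`.
#' @export
make_demo_nodes <- function(n_per_system = 2) {
  if (n_per_system < 2) stop("need >= 2 nodes per system")
  sys <- rep(all_system_labels(), each = n_per_system)
  tab <- data.frame(node_id = seq_along(sys) - 1L,
                    label = sprintf("%s_%d", sys,
                                    rep(seq_len(n_per_system),
                                        times = length(all_system_labels()))),
                    system = sys)
  validate_node_table(tab)
}

#' Pipeline run configuration
#'
#' Gathers every tunable of the end-to-end synthetic study in one
#' validated list. Defaults mirror the analysis conditions used
#' throughout the package: 300 ms / 50 % windows, alpha band, gamma = 1,
#' omega = 0.25, FDR alpha = 0.05. `run_config()` builds one in R;
#' `load_run_config()` reads the same fields from YAML.
#'
#' @param n_nodes,nodes_per_system Roster: either `n_nodes = 80` with the
#'   bundled table (or `node_table` path), or a demo roster of
#'   `nodes_per_system` per system.
#' @param node_table Optional path to a CSV node table.
#' @param n_trials,fs,trial_duration,band,noise_sd,coupling,n_modules,switch_prob
#'   Generator settings (see [sim_config()]).
#' @param effect Planted condition effect (see [make_condition_pair()]),
#'   e.g. `list(switch_mult = list(DMN = 0.5))`.
#' @param window_ms,overlap Window geometry.
#' @param gamma,omega,reps Community detection settings.
#' @param alpha FDR level.
#' @param seed Base seed for the whole run.
#' @return A validated `run_config` list.
#' @export
run_config <- function(n_nodes = 80, nodes_per_system = NULL,
                       node_table = NULL, n_trials = 20, fs = 500,
                       trial_duration = 2, band = c(8, 13),
                       noise_sd = 0.3, coupling = 1, n_modules = 2,
                       switch_prob = 0.4,
                       effect = list(switch_mult = list(DMN = 0.5)),
                       window_ms = 300, overlap = 0.5,
                       gamma = 1, omega = 0.25, reps = 50,
                       alpha = 0.05, seed = 1L) {
  cfg <- list(n_nodes = n_nodes, nodes_per_system = nodes_per_system,
              node_table = node_table, n_trials = n_trials, fs = fs,
              trial_duration = trial_duration, band = band,
              noise_sd = noise_sd, coupling = coupling,
              n_modules = n_modules, switch_prob = switch_prob,
              effect = effect, window_ms = window_ms, overlap = overlap,
              gamma = gamma, omega = omega, reps = reps, alpha = alpha,
              seed = seed)
  validate_run_config(cfg)
}

#' @rdname run_config
#' @param path YAML file with any subset of the fields above.
#' @export
load_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  base <- formals(run_config)
  known <- names(base)
  unknown <- setdiff(names(y), known)
  if (length(unknown))
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  cfg <- lapply(known, function(f)
    if (f %in% names(y)) y[[f]] else eval(base[[f]]))
  names(cfg) <- known
  if (!is.null(cfg$band)) cfg$band <- as.numeric(unlist(cfg$band))
  validate_run_config(cfg)
}

#' @rdname run_config
#' @param cfg A config list to validate.
#' @export
validate_run_config <- function(cfg) {
  fail <- function(...) stop("invalid run config: ", ...)
  if (cfg$gamma <= 0) fail("gamma must be > 0")
  if (cfg$omega < 0) fail("omega must be >= 0")
  if (cfg$reps < 1) fail("reps must be >= 1")
  if (cfg$alpha <= 0 || cfg$alpha >= 1) fail("alpha must be in (0, 1)")
  if (cfg$overlap < 0 || cfg$overlap >= 1) fail("overlap must be in [0, 1)")
  if (length(cfg$band) != 2 || cfg$band[1] >= cfg$band[2])
    fail("band must be c(low, high) with low < high")
  if (cfg$n_trials < 3) fail("n_trials must be >= 3 for paired statistics")
  p <- unlist(cfg$switch_prob)
  if (any(p < 0 | p > 1)) fail("switch_prob must lie in [0, 1]")
  structure(cfg, class = "run_config")
}

resolve_map <- function(cfg) {
  nodes <- if (!is.null(cfg$nodes_per_system))
    make_demo_nodes(cfg$nodes_per_system)
  else load_node_table(cfg$node_table)
  if (is.null(cfg$nodes_per_system) && nrow(nodes) != cfg$n_nodes)
    stop("node table has ", nrow(nodes), " nodes; config expects ",
         cfg$n_nodes)
  system_map(nodes)
}

#' Run the synthetic condition-contrast pipeline end to end
#'
#' Stages: (1) generate a matched condition pair with the configured
#' planted effect; (2) per trial, WPLI stacks, multilayer graphs,
#' repeated generalized Louvain, and system-level metric frames; (3)
#' paired condition statistics with FDR. Every stage is cached as a file
#' in `out_dir` and skipped when its artifact already exists, so deleting
#' a late artifact and rerunning regenerates it from cached upstream
#' stages. Deterministic for a fixed config seed. The resolved config and
#' package version are written next to the outputs.
#'
#' @param cfg A `run_config` (or path to a YAML config).
#' @param out_dir Artifact directory (created if needed).
#' @param quiet Suppress per-stage log lines.
#' @return The artifact directory, invisibly. Artifacts:
#'   `data_cond1/`, `data_cond2/` (ROI bundles), `metrics_cond1.csv`,
#'   `metrics_cond2.csv`, `stats_flexibility.csv`,
#'   `stats_integration.csv`, `resolved_config.json`.
#' @export
run_pipeline <- function(cfg, out_dir, quiet = FALSE) {
  if (is.character(cfg)) cfg <- load_run_config(cfg)
  stopifnot(inherits(cfg, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log <- function(...) if (!quiet) message("[dynmodnet] ", ...)
  map <- resolve_map(cfg)
  jsonlite::write_json(
    list(config = unclass(cfg),
         package_version = as.character(utils::packageVersion("dynmodnet"))),
    file.path(out_dir, "resolved_config.json"), auto_unbox = TRUE,
    digits = NA, null = "null")

  sc <- sim_config(n_nodes = map$n_nodes, fs = cfg$fs,
                   trial_duration = cfg$trial_duration,
                   n_trials = cfg$n_trials, band = cfg$band,
                   coupling = cfg$coupling, noise_sd = cfg$noise_sd,
                   n_modules = cfg$n_modules,
                   switch_prob = unlist(cfg$switch_prob),
                   window_ms = cfg$window_ms, overlap = cfg$overlap,
                   seed = cfg$seed)
  seeds <- child_seeds(cfg$seed, 3L)

  d1 <- file.path(out_dir, "data_cond1")
  d2 <- file.path(out_dir, "data_cond2")
  if (!file.exists(file.path(d1, "meta.json"))) {
    log("stage simulate: ", cfg$n_trials, " trials x 2 conditions")
    effect <- cfg$effect
    if (!is.null(effect$switch_mult))
      effect$switch_mult <- unlist(effect$switch_mult)
    pair <- make_condition_pair(sc, effect, map, seed = seeds[1])
    write_roi_ts(pair$cond1, d1)
    write_roi_ts(pair$cond2, d2)
  } else log("stage simulate: cached")

  mfile <- file.path(out_dir, c("metrics_cond1.csv", "metrics_cond2.csv"))
  spec <- window_spec(cfg$window_ms, cfg$overlap)
  for (k in 1:2) {
    if (file.exists(mfile[k])) { log("stage metrics cond", k, ": cached"); next }
    log("stage metrics cond", k, ": ", cfg$n_trials, " trials, R = ",
        cfg$reps)
    ts <- read_roi_ts(file.path(out_dir, paste0("data_cond", k)))
    mf <- trial_metrics(ts, map, spec = spec, band = NULL,
                        gamma = cfg$gamma, omega = cfg$omega,
                        reps = cfg$reps, seed = seeds[1 + k])
    write_metric_frame(mf, mfile[k])
  }

  sfile <- file.path(out_dir, c("stats_flexibility.csv",
                                "stats_integration.csv"))
  if (!all(file.exists(sfile))) {
    log("stage stats")
    mf1 <- read.csv(mfile[1]); mf2 <- read.csv(mfile[2])
    write.csv(compare_conditions(mf1, mf2, "flexibility",
                                 alpha = cfg$alpha),
              sfile[1], row.names = FALSE)
    ints <- compare_conditions(mf1, mf2, "integration", alpha = cfg$alpha)
    write.csv(ints, sfile[2], row.names = FALSE)
  } else log("stage stats: cached")
  invisible(out_dir)
}

#' Summarize a completed pipeline run
#'
#' Recomputes the reporting tables from the run's artifacts: per-system
#' flexibility means with significance stars, symmetric pairwise
#' integration / recruitment change matrices (recruitment on the
#' diagonal), and percent-change summaries.
#'
#' @param out_dir A directory produced by [run_pipeline()].
#' @return A `run_report` list with `flexibility` (data.frame),
#'   `integration` (data.frame), `change_matrix` (symmetric matrix of
#'   mean condition differences; integration off-diagonal, recruitment on
#'   the diagonal), and `percent_change` (per-system flexibility).
#' @export
report_run <- function(out_dir) {
  need <- c("metrics_cond1.csv", "metrics_cond2.csv",
            "stats_flexibility.csv", "stats_integration.csv")
  missing <- need[!file.exists(file.path(out_dir, need))]
  if (length(missing))
    stop("incomplete run, missing artifact(s): ",
         paste(missing, collapse = ", "))
  mf1 <- read.csv(file.path(out_dir, "metrics_cond1.csv"))
  mf2 <- read.csv(file.path(out_dir, "metrics_cond2.csv"))
  if (nrow(mf1) == 0L || nrow(mf2) == 0L) stop("empty metric frames")
  fl <- read.csv(file.path(out_dir, "stats_flexibility.csv"),
                 colClasses = c(stars = "character"))
  ints <- read.csv(file.path(out_dir, "stats_integration.csv"),
                   colClasses = c(stars = "character"))
  systems <- c("SMN", "DMN", "VN", "ATN")
  mean_of <- function(mf, metric, unit)
    mean(mf$value[mf$metric == metric & mf$unit == unit])
  M <- matrix(0, 4, 4, dimnames = list(systems, systems))
  for (i in 1:4) {
    M[i, i] <- mean_of(mf2, "recruitment", systems[i]) -
      mean_of(mf1, "recruitment", systems[i])
    if (i < 4) for (j in (i + 1):4) {
      u <- paste(systems[i], systems[j], sep = "-")
      M[i, j] <- M[j, i] <- mean_of(mf2, "integration", u) -
        mean_of(mf1, "integration", u)
    }
  }
  pre <- vapply(fl$unit, function(u) mean_of(mf1, "flexibility", u),
                numeric(1))
  post <- vapply(fl$unit, function(u) mean_of(mf2, "flexibility", u),
                 numeric(1))
  pc <- percent_change(pre, post)
  fl$mean_cond1 <- pre
  fl$mean_cond2 <- post
  structure(list(flexibility = fl, integration = ints,
                 change_matrix = M,
                 percent_change = data.frame(unit = fl$unit,
                                             signed = pc$signed,
                                             magnitude = pc$magnitude)),
            class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat("Per-system flexibility (cond1 vs cond2):\n")
  print(x$flexibility, digits = 4)
  cat("\nIntegration contrasts:\n")
  print(x$integration, digits = 4)
  cat("\nChange matrix (integration off-diagonal, recruitment diagonal):\n")
  print(round(x$change_matrix, 4))
  cat("\nPercent change in flexibility:\n")
  print(x$percent_change, digits = 4)
  invisible(x)
}
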