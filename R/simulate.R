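#' Simulation configuration
#'
#' Defines the study conditions emulated by the synthetic generator:
#' 80-node ROI recordings, 2-s trials at 500 Hz, alpha-band (8-13 Hz)
#' oscillations whose pairwise phase-lagged coupling follows a planted,
#' time-varying module schedule laid out on the same 300 ms / 50 %-overlap
#' window grid used by the analysis.
#'
#' @param n_nodes Number of ROIs (nodes).
#' @param fs Sampling rate in Hz.
#' @param trial_duration Trial length in seconds; `fs * trial_duration`
#'   must be an integer.
#' @param n_trials Trials per condition.
#' @param band Carrier band in Hz, `c(low, high)`.
#' @param lag_range Per-node phase-lag magnitudes are drawn uniformly from
#'   `[lag_range[1], lag_range[2]]` radians with alternating sign by node
#'   index. Must be bounded away from 0 and pi: WPLI is blind to zero-lag
#'   coupling by design, so a zero lag would plant an invisible effect.
#' @param coupling Coupling strength in `[0, 1]`: amplitude of the shared
#'   module carrier in each node's signal.
#' @param noise_sd SD of the independent white noise added per node.
#' @param n_modules Number of planted modules.
#' @param switch_prob Per-window module resampling probability; scalar or a
#'   vector named by system label.
#' @param window_ms,overlap Analysis window geometry the schedule is laid
#'   out on (see [window_spec()]).
#' @param seed Integer seed; all randomness derives from it through one
#'   child seed per trial (see [child_seeds()]).
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_nodes = 80, fs = 500, trial_duration = 2,
                       n_trials = 20, band = c(8, 13),
                       lag_range = c(pi / 8, 3 * pi / 8),
                       coupling = 1, noise_sd = 0.3,
                       n_modules = 2, switch_prob = 0.4,
                       window_ms = 300, overlap = 0.5, seed = 1L) {
  n_samples <- fs * trial_duration
  if (abs(n_samples - round(n_samples)) > 1e-9)
    stop("fs * trial_duration must be an integer number of samples")
  if (coupling < 0 || coupling > 1) stop("coupling must be in [0, 1]")
  if (fs <= 2 * band[2]) stop("fs must exceed twice the band's upper edge")
  if (lag_range[1] <= 0 || lag_range[2] >= pi)
    stop("zero-lag coupling is invisible to WPLI: lag_range must lie strictly inside (0, pi)")
  if (lag_range[1] > lag_range[2]) stop("lag_range must be increasing")
  structure(list(n_nodes = as.integer(n_nodes), fs = fs,
                 trial_duration = trial_duration,
                 n_samples = as.integer(round(n_samples)),
                 n_trials = as.integer(n_trials), band = band,
                 lag_range = lag_range, coupling = coupling,
                 noise_sd = noise_sd, n_modules = as.integer(n_modules),
                 switch_prob = switch_prob,
                 window_ms = window_ms, overlap = overlap,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Derive child seeds from one base seed
#'
#' The documented seed-splitting scheme: the base seed seeds R's RNG once
#' and `n` independent child seeds are drawn from it, so every trial (or
#' repetition) has its own reproducible stream.
#'
#' @param seed Integer base seed.
#' @param n Number of child seeds.
#' @return Integer vector of length `n`.
#' @export
child_seeds <- function(seed, n) {
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  sample.int(2147483646L, n)
}

#' Plant a module schedule
#'
#' Draws a ground-truth node-by-window module assignment. Window 1 is a
#' balanced random partition into `n_modules`; at each later window every
#' node independently resamples its module uniformly (over all modules,
#' including the current one) with its system's switch probability. A
#' node's planted flexibility is then the fraction S/T of windows at which
#' its label changed.
#'
#' @param n_nodes Number of nodes.
#' @param n_windows Number of time windows (layers).
#' @param n_modules Number of planted modules; must not exceed `n_nodes`.
#' @param switch_prob Scalar in `[0, 1]`, or a vector named by system label
#'   (requires `map`); unnamed systems default to 0.
#' @param map Optional [system_map()] used to resolve per-system
#'   probabilities.
#' @param seed Integer seed.
#' @param comodule Optional `list(systems = c(A, B), prob = q)`: at every
#'   window each node of systems A or B is additionally pulled into a
#'   designated shared module with probability `q`, raising planted
#'   cross-system allegiance between A and B.
#' @return A `module_schedule`: list with `assignment` (n_nodes x n_windows
#'   integer matrix), `n_windows`, `n_modules`, `switch_prob` (per-node).
#' @export
make_schedule <- function(n_nodes, n_windows, n_modules, switch_prob,
                          map = NULL, seed = 1L, comodule = NULL) {
  if (n_modules < 1L) stop("n_modules must be >= 1")
  if (n_modules > n_nodes) stop("n_modules may not exceed n_nodes")
  p <- resolve_switch_prob(switch_prob, n_nodes, map)
  if (any(p < 0 | p > 1)) stop("switch probabilities must lie in [0, 1]")
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  g <- matrix(0L, n_nodes, n_windows)
  g[, 1L] <- sample(rep_len(seq_len(n_modules), n_nodes))
  if (n_windows > 1L) {
    for (w in 2:n_windows) {
      g[, w] <- g[, w - 1L]
      hit <- runif(n_nodes) < p
      if (any(hit))
        g[hit, w] <- sample.int(n_modules, sum(hit), replace = TRUE)
    }
  }
  if (!is.null(comodule)) {
    ids <- unlist(lapply(comodule$systems, system_members, map = map))
    idx <- ids + 1L
    for (w in seq_len(n_windows)) {
      hit <- runif(length(idx)) < comodule$prob
      g[idx[hit], w] <- 1L
    }
  }
  structure(list(assignment = g, n_windows = as.integer(n_windows),
                 n_modules = as.integer(n_modules), switch_prob = p),
            class = "module_schedule")
}

resolve_switch_prob <- function(switch_prob, n_nodes, map) {
  if (is.null(names(switch_prob))) {
    if (length(switch_prob) == 1L) return(rep(switch_prob, n_nodes))
    if (length(switch_prob) == n_nodes) return(as.numeric(switch_prob))
    stop("unnamed switch_prob must be scalar or one value per node")
  }
  if (is.null(map))
    stop("per-system switch_prob requires a system_map")
  unknown <- setdiff(names(switch_prob), all_system_labels())
  if (length(unknown))
    stop("unknown system label in switch_prob: ",
         paste(unknown, collapse = ", "))
  p <- rep(0, n_nodes)
  for (s in names(switch_prob))
    p[system_members(map, s) + 1L] <- switch_prob[[s]]
  p
}

#' Planted flexibility of a schedule
#'
#' Applies F = S/T directly to the ground-truth assignment: per node, the
#' count S of consecutive-window label changes over the total number of
#' windows T.
#'
#' @param schedule A `module_schedule`.
#' @return Numeric vector of per-node planted flexibility.
#' @export
planted_flexibility <- function(schedule) {
  g <- schedule$assignment
  T <- ncol(g)
  if (T < 2L) stop("flexibility undefined for T < 2")
  rowSums(g[, -1L, drop = FALSE] != g[, -T, drop = FALSE]) / T
}

#' Planted allegiance of a schedule
#'
#' Fraction of windows in which two nodes share a planted module.
#'
#' @param schedule A `module_schedule`.
#' @return Symmetric n_nodes x n_nodes matrix with unit diagonal.
#' @export
planted_allegiance <- function(schedule) {
  g <- schedule$assignment
  n <- nrow(g)
  P <- matrix(0, n, n)
  for (w in seq_len(ncol(g)))
    P <- P + outer(g[, w], g[, w], "==")
  P / ncol(g)
}

#' Synthesize ROI time series from a planted schedule
#'
#' Within each run of windows sharing an assignment, the nodes of one
#' planted module receive a common band-limited carrier (unit-variance
#' filtered white noise), each at its own fixed nonzero phase lag from the
#' module reference, scaled by `coupling`; independent white noise at
#' `noise_sd` is added per node. Carriers of different modules are
#' independent. At schedule transitions the old and new signals are
#' cross-faded with a raised-cosine window of 20 ms or less, so switches do
#' not inject broadband clicks into the carrier band.
#'
#' @param config A [sim_config()].
#' @param schedule A `module_schedule`, or a list of `n_trials` schedules
#'   (one per trial). Its window count must match the window grid implied
#'   by the config.
#' @param map Optional [system_map()] carried into provenance.
#' @param condition Condition tag stored on the result.
#' @param lags Optional explicit per-node phase lags in radians (all
#'   nonzero mod pi); by default lags are drawn per trial from
#'   `lag_range` with alternating sign.
#' @return A `roi_ts`: list with `data` (node x sample x trial array),
#'   `fs`, `labels`, `condition`, `schedules`, and `provenance`.
#' @export
synthesize <- function(config, schedule, map = NULL,
                       condition = "synthetic", lags = NULL) {
  stopifnot(inherits(config, "sim_config"))
  schedules <- if (inherits(schedule, "module_schedule"))
    rep(list(schedule), config$n_trials) else schedule
  if (length(schedules) != config$n_trials)
    stop("need one schedule, or one per trial")
  spec <- window_spec(config$window_ms, config$overlap)
  win <- make_windows(config$n_samples, config$fs, spec)
  W <- nrow(win)
  for (s in schedules)
    if (s$n_windows != W)
      stop("schedule has ", s$n_windows, " windows but the config's ",
           "window grid implies ", W)
  if (!is.null(lags)) {
    if (length(lags) != config$n_nodes)
      stop("lags must have one value per node")
    if (any(abs(sin(lags)) < 1e-12))
      stop("zero-lag coupling is invisible to WPLI: lags must be nonzero mod pi")
  }
  n <- config$n_nodes
  ns <- config$n_samples
  dat <- array(0, dim = c(n, ns, config$n_trials))
  seeds <- child_seeds(config$seed, config$n_trials)
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  for (tr in seq_len(config$n_trials)) {
    set.seed(seeds[tr])
    dat[, , tr] <- synth_trial(config, schedules[[tr]], win, lags)
  }
  structure(list(data = dat, fs = config$fs,
                 labels = sprintf("node%03d", seq_len(n) - 1L),
                 condition = condition, schedules = schedules,
                 provenance = list(seed = config$seed,
                                   config = unclass(config))),
            class = "roi_ts")
}

# One trial; RNG assumed seeded by caller. Each planted module has one
# persistent band-limited carrier for the whole trial (carriers of
# different modules are independent); a node receives the carrier of its
# current module at its fixed per-node phase lag. Schedule window w
# governs the samples for which window w is the dominant cover: segment
# boundaries sit at the midpoints of the window overlaps, so layer w's
# WPLI is driven mostly by assignment column w. When a node switches
# modules it cross-fades from its old to its new carrier with a
# raised-cosine ramp of 20 ms or less; non-switching nodes stay fully
# coherent with their module throughout.
synth_trial <- function(config, schedule, win, lags) {
  n <- config$n_nodes
  ns <- config$n_samples
  g <- schedule$assignment
  W <- ncol(g)
  if (is.null(lags)) {
    mag <- runif(n, config$lag_range[1], config$lag_range[2])
    lags <- mag * ifelse(seq_len(n) %% 2L == 0L, -1, 1)
  }
  rot <- exp(-1i * lags)
  wl <- win[1, "end"] - win[1, "start"]
  step <- if (W > 1L) win[2, "start"] - win[1, "start"] else wl
  cb <- c(0L, if (W > 1L) win[2:W, "start"] + (wl - step) %/% 2L, ns)
  f <- max(1L, round(0.01 * config$fs))        # half fade width (<=10 ms)
  sb <- module_subbands(schedule$n_modules, config$band)
  Z <- vapply(seq_len(schedule$n_modules), function(m)
    analytic_signal(band_limited_noise(ns, config$fs, sb[m, ])),
    complex(ns))
  x <- matrix(0, n, ns)
  for (i in seq_len(n)) {
    brk <- c(TRUE, g[i, -1L] != g[i, -W])
    run_id <- cumsum(brk)
    for (r in unique(run_id)) {
      wins <- which(run_id == r)
      a <- cb[wins[1L]] + 1L                   # 1-based core start
      b <- cb[wins[length(wins)] + 1L]         # 1-based core end
      idx <- max(1L, a - f):min(ns, b + f)
      env <- rep(1, length(idx))
      if (a > 1L) {                            # fade in over [a-f, a+f-1]
        ramp <- which(idx <= a + f - 1L)
        tt <- idx[ramp] - (a - f) + 1L         # 1..2f
        env[ramp] <- (1 - cos(pi * (tt - 0.5) / (2 * f))) / 2
      }
      if (b < ns) {                            # fade out over [b-f+1, b+f]
        ramp <- which(idx >= b - f + 1L)
        tt <- idx[ramp] - b + f                # 1..2f, complements fade-in
        env[ramp] <- env[ramp] * (1 + cos(pi * (tt - 0.5) / (2 * f))) / 2
      }
      x[i, idx] <- x[i, idx] +
        config$coupling * Re(rot[i] * Z[idx, g[i, wins[1L]]]) * env
    }
  }
  if (config$noise_sd > 0)
    x <- x + matrix(rnorm(n * ns, sd = config$noise_sd), n, ns)
  x
}

# unit-variance band-limited Gaussian noise, synthesized in the frequency
# domain (complex Gaussian coefficients on the in-band bins, hermitian
# symmetry), numerically stable for arbitrarily narrow bands
band_limited_noise <- function(n_samples, fs, band) {
  n <- n_samples
  freqs <- (seq_len(n) - 1L) * fs / n
  half <- 2:(floor(n / 2) + 1L)                # positive-frequency bins
  sel <- half[freqs[half] >= band[1] & freqs[half] <= band[2]]
  if (!length(sel)) sel <- half[which.min(abs(freqs[half] - mean(band)))]
  X <- complex(real = rep(0, n), imaginary = rep(0, n))
  X[sel] <- complex(real = rnorm(length(sel)),
                    imaginary = rnorm(length(sel)))
  X[n + 2L - sel] <- Conj(X[sel])              # hermitian symmetry
  y <- Re(fft(X, inverse = TRUE)) / n
  y / sd(y)
}

# per-module carrier sub-bands: evenly spaced centre frequencies inside
# the configured band (random jitter, random module order) so rhythms of
# different modules beat against each other within a window
module_subbands <- function(n_modules, band) {
  hw <- 0.5
  margin <- min(hw + 0.25, diff(band) / 4)
  centres <- if (n_modules == 1L) mean(band) else
    seq(band[1] + margin, band[2] - margin, length.out = n_modules)
  centres <- centres + runif(n_modules, -0.15, 0.15)
  centres <- sample(centres)
  cbind(low = pmax(band[1], centres - hw),
        high = pmin(band[2], centres + hw))
}

#' Generate a matched condition pair with a planted effect
#'
#' Emulates a baseline-versus-stimulation contrast: both conditions share
#' the generator settings, but condition 2's per-system switch
#' probabilities are multiplied by `effect$switch_mult` (e.g. `c(DMN =
#' 0.5)` halves DMN module switching, lowering its planted flexibility) and
#' an optional `effect$comodule` raises cross-system co-module probability.
#' Each trial in each condition draws its own schedule, so planted metrics
#' carry trial-to-trial sampling variability.
#'
#' @param config A [sim_config()]; `switch_prob` may be scalar or named by
#'   system.
#' @param effect `list(switch_mult = <named numeric>, comodule =
#'   list(systems = c(A, B), prob = q))`; either element may be omitted.
#' @param map A [system_map()].
#' @param seed Base seed for the pair (defaults to the config seed).
#' @return List with `cond1` and `cond2` (`roi_ts` objects, schedules
#'   attached).
#' @export
make_condition_pair <- function(config, effect, map, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"), inherits(map, "system_map"))
  base_p <- config$switch_prob
  if (is.null(names(base_p)))
    base_p <- structure(rep(base_p[1], 6), names = all_system_labels())
  p2 <- base_p
  if (!is.null(effect$switch_mult)) {
    for (s in names(effect$switch_mult))
      p2[[s]] <- p2[[s]] * effect$switch_mult[[s]]
  }
  if (any(unlist(p2) < 0 | unlist(p2) > 1))
    stop("effect drives a switch probability outside [0, 1]")
  spec <- window_spec(config$window_ms, config$overlap)
  W <- nrow(make_windows(config$n_samples, config$fs, spec))
  seeds <- child_seeds(seed, 2L * config$n_trials + 2L)
  sch1 <- lapply(seq_len(config$n_trials), function(i)
    make_schedule(config$n_nodes, W, config$n_modules, base_p, map,
                  seed = seeds[i]))
  sch2 <- lapply(seq_len(config$n_trials), function(i)
    make_schedule(config$n_nodes, W, config$n_modules, p2, map,
                  seed = seeds[config$n_trials + i],
                  comodule = effect$comodule))
  cfg1 <- config; cfg1$seed <- seeds[2L * config$n_trials + 1L]
  cfg2 <- config; cfg2$seed <- seeds[2L * config$n_trials + 2L]
  list(cond1 = synthesize(cfg1, sch1, map, condition = "cond1"),
       cond2 = synthesize(cfg2, sch2, map, condition = "cond2"))
}

#' @export
print.roi_ts <- function(x, ...) {
  d <- dim(x$data)
  cat("roi_ts:", d[1], "nodes x", d[2], "samples x", d[3], "trials @",
      x$fs, "Hz, condition:", x$condition, "\n")
  invisible(x)
}

#' Write / read an ROI time-series bundle
#'
#' On-disk form: `data.bin` (little-endian doubles, node fastest) plus
#' `meta.json` (dimensions, fs, labels, condition, provenance).
#'
#' @param x A `roi_ts`.
#' @param dir Bundle directory (created if missing).
#' @return `write_roi_ts` the directory, invisibly; `read_roi_ts` a
#'   `roi_ts` (schedules are not persisted).
#' @export
write_roi_ts <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  con <- file(file.path(dir, "data.bin"), "wb")
  writeBin(as.vector(x$data), con, size = 8, endian = "little")
  close(con)
  meta <- list(dim = dim(x$data), fs = x$fs, labels = x$labels,
               condition = x$condition, provenance = x$provenance)
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_roi_ts
#' @export
read_roi_ts <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  d <- as.integer(meta$dim)
  con <- file(file.path(dir, "data.bin"), "rb")
  v <- readBin(con, "double", n = prod(d), size = 8, endian = "little")
  close(con)
  structure(list(data = array(v, dim = d), fs = meta$fs,
                 labels = meta$labels, condition = meta$condition,
                 schedules = NULL, provenance = meta$provenance),
            class = "roi_ts")
}
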