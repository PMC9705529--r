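test_that("schedules honor switch probabilities at the extremes", {
  map <- tiny_map()
  # no switching: planted flexibility identically zero
  sch0 <- make_schedule(12, 12, 3, 0, map, seed = 1)
  expect_equal(planted_flexibility(sch0), rep(0, 12))
  # switch_prob 1 with 2 modules, uniform resampling: label changes with
  # probability 1/2 per node-window (binomial oracle, 3 SE band)
  n <- 100; W <- 101
  sch1 <- make_schedule(n, W, 2, 1, seed = 2)
  rate <- mean(sch1$assignment[, -1] != sch1$assignment[, -W])
  se <- sqrt(0.25 / (n * (W - 1)))
  expect_lt(abs(rate - 0.5), 3 * se)
})

test_that("a single forced switch over 12 windows gives planted flexibility 1/12", {
  g <- matrix(1L, 1, 12)
  g[1, 7:12] <- 2L
  sch <- structure(list(assignment = g, n_windows = 12L, n_modules = 2L,
                        switch_prob = 0), class = "module_schedule")
  expect_equal(planted_flexibility(sch), 1 / 12)
})

test_that("schedule construction validates its arguments", {
  expect_error(make_schedule(3, 12, 5, 0.2), "may not exceed")
  expect_error(make_schedule(12, 12, 2, 1.2), "\\[0, 1\\]")
  expect_error(make_schedule(12, 12, 2, c(DMN = 0.5)), "system_map")
})

test_that("planted allegiance matches direct pair counting", {
  g <- rbind(c(1L, 1L, 2L), c(1L, 2L, 2L), c(2L, 2L, 2L))
  sch <- structure(list(assignment = g, n_windows = 3L, n_modules = 2L,
                        switch_prob = 0), class = "module_schedule")
  P <- planted_allegiance(sch)
  brute <- matrix(0, 3, 3)
  for (w in 1:3) for (i in 1:3) for (j in 1:3)
    brute[i, j] <- brute[i, j] + (g[i, w] == g[j, w]) / 3
  expect_equal(P, brute)
})

test_that("synthesis is deterministic under a fixed seed", {
  map <- tiny_map()
  cfg <- sim_config(n_nodes = 12, n_trials = 3, seed = 7)
  sch <- make_schedule(12, 12, 2, 0.4, map, seed = 5)
  a <- synthesize(cfg, sch, map)
  b <- synthesize(cfg, sch, map)
  expect_identical(a$data, b$data)
  cfg2 <- cfg; cfg2$seed <- 8L
  expect_false(identical(a$data, synthesize(cfg2, sch, map)$data))
})

test_that("synthesized carriers are band-limited to the carrier band", {
  map <- tiny_map()
  cfg <- sim_config(n_nodes = 12, n_trials = 2, seed = 3, noise_sd = 0)
  sch <- make_schedule(12, 12, 2, 0.4, map, seed = 4)
  ts <- synthesize(cfg, sch, map)
  for (tr in 1:2) for (i in c(1, 6, 12)) {
    x <- ts$data[i, , tr]
    spec <- Mod(fft(x))^2
    freqs <- (seq_along(x) - 1) * cfg$fs / length(x)
    inband <- freqs >= cfg$band[1] - 2 & freqs <= cfg$band[2] + 2
    inband <- inband | rev(inband)           # negative-frequency mirror
    expect_gt(sum(spec[inband]) / sum(spec), 0.9)
  }
})

test_that("zero-lag coupling is rejected up front", {
  map <- tiny_map()
  expect_error(sim_config(lag_range = c(0, pi / 4)), "zero-lag")
  cfg <- sim_config(n_nodes = 12, n_trials = 1, seed = 1)
  sch <- make_schedule(12, 12, 2, 0, map, seed = 1)
  expect_error(synthesize(cfg, sch, map, lags = rep(0, 12)), "zero-lag")
  expect_error(synthesize(cfg, sch, map, lags = rep(pi, 12)), "zero-lag")
})

test_that("condition pairs plant the requested flexibility ratio", {
  map <- tiny_map()
  cfg <- sim_config(n_nodes = 12, n_trials = 60, seed = 21,
                    noise_sd = 0.3, switch_prob = 0.4, n_modules = 2)
  pair <- make_condition_pair(cfg, list(switch_mult = c(DMN = 0.5)), map)
  dmn <- system_members(map, "DMN") + 1
  pl <- function(ts) sapply(ts$schedules, function(s)
    mean(planted_flexibility(s)[dmn]))
  m1 <- mean(pl(pair$cond1)); m2 <- mean(pl(pair$cond2))
  # expected per-node change rate q = p * (K-1)/K, planted F = q*(T-1)/T
  expect_equal(m1, 0.4 * 0.5 * 11 / 12, tolerance = 0.15)
  expect_equal(m2 / m1, 0.5, tolerance = 0.25)
  # other systems unaffected in expectation
  smn <- system_members(map, "SMN") + 1
  s1 <- mean(sapply(pair$cond1$schedules, function(s) mean(planted_flexibility(s)[smn])))
  s2 <- mean(sapply(pair$cond2$schedules, function(s) mean(planted_flexibility(s)[smn])))
  expect_equal(s2 / s1, 1, tolerance = 0.25)
})

test_that("null effects plant no systematic difference", {
  map <- tiny_map()
  cfg <- sim_config(n_nodes = 12, n_trials = 80, seed = 31)
  pair <- make_condition_pair(cfg, list(), map)
  d <- sapply(seq_len(80), function(i)
    mean(planted_flexibility(pair$cond1$schedules[[i]])) -
      mean(planted_flexibility(pair$cond2$schedules[[i]])))
  expect_lt(abs(mean(d)), 3 * sd(d) / sqrt(length(d)))
})

test_that("co-module effects raise planted cross-system allegiance", {
  map <- tiny_map()
  cfg <- sim_config(n_nodes = 12, n_trials = 40, seed = 41)
  eff <- list(comodule = list(systems = c("SMN", "VN"), prob = 0.6))
  pair <- make_condition_pair(cfg, eff, map)
  smn <- system_members(map, "SMN") + 1
  vn <- system_members(map, "VN") + 1
  cross <- function(ts) mean(sapply(ts$schedules, function(s)
    mean(planted_allegiance(s)[smn, vn])))
  expect_gt(cross(pair$cond2), cross(pair$cond1) + 0.1)
})

test_that("effects that push probabilities outside [0, 1] are rejected", {
  map <- tiny_map()
  cfg <- sim_config(n_nodes = 12, n_trials = 3, switch_prob = 0.8)
  expect_error(make_condition_pair(cfg, list(switch_mult = c(DMN = 2)), map),
               "outside \\[0, 1\\]")
})

test_that("ROI time-series bundles round-trip through disk", {
  map <- tiny_map()
  cfg <- sim_config(n_nodes = 12, n_trials = 2, seed = 5)
  sch <- make_schedule(12, 12, 2, 0.4, map, seed = 6)
  ts <- synthesize(cfg, sch, map, condition = "demo")
  dir <- file.path(tempfile(), "bundle")
  write_roi_ts(ts, dir)
  back <- read_roi_ts(dir)
  expect_identical(back$data, ts$data)
  expect_identical(back$condition, "demo")
  expect_identical(back$labels, ts$labels)
  expect_equal(back$fs, ts$fs)
})
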