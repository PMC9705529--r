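test_that("flexibility follows F = S/T exactly", {
  expect_equal(flexibility(matrix(c(1, 1, 2, 2), 1)), 1 / 4)
  expect_equal(flexibility(matrix(3, 1, 8)), 0)
  expect_equal(flexibility(matrix(rep(1:2, 6), 1)), 11 / 12)
  expect_error(flexibility(matrix(1, 2, 1)), "T < 2")
})

test_that("flexibility is invariant under module relabeling", {
  set.seed(3)
  labs <- matrix(sample(1:4, 60, replace = TRUE), 5, 12)
  base <- flexibility(labs)
  for (k in 1:10) {
    perm <- sample(1:4)
    expect_equal(flexibility(matrix(perm[labs], 5, 12)), base)
  }
})

test_that("allegiance counts shared-module observations over reps and layers", {
  # all nodes always together
  one <- array(1L, dim = c(4, 3, 2))
  expect_equal(allegiance(structure(list(labels = one),
                                    class = "partition_ensemble")),
               matrix(1, 4, 4))
  # fixed disjoint modules: block structure of ones and zeros
  labs <- array(rep(c(1L, 1L, 2L, 2L), 6), dim = c(4, 3, 2))
  P <- allegiance(structure(list(labels = labs),
                            class = "partition_ensemble"))
  expect_equal(P, rbind(c(1, 1, 0, 0), c(1, 1, 0, 0),
                        c(0, 0, 1, 1), c(0, 0, 1, 1)))
  # hand ensemble, R = 2, T = 2, 3 nodes: brute-force pair counting
  labs <- array(0L, dim = c(3, 2, 2))
  labs[, , 1] <- rbind(c(1L, 1L), c(1L, 2L), c(2L, 2L))
  labs[, , 2] <- rbind(c(1L, 2L), c(1L, 2L), c(1L, 1L))
  ens <- structure(list(labels = labs), class = "partition_ensemble")
  brute <- matrix(0, 3, 3)
  for (r in 1:2) for (l in 1:2)
    brute <- brute + outer(labs[, l, r], labs[, l, r], "==") / 4
  expect_equal(allegiance(ens), brute)
  # per-layer variant pools over repetitions only
  byl <- allegiance(ens, by_layer = TRUE)
  expect_equal(byl[1, , ],
               (outer(labs[, 1, 1], labs[, 1, 1], "==") +
                  outer(labs[, 1, 2], labs[, 1, 2], "==")) / 2)
})

test_that("recruitment and integration have the prescribed limiting values", {
  map <- tiny_map()
  n <- map$n_nodes
  ones <- matrix(1, n, n)
  expect_equal(unname(recruitment(ones, map)), rep(1, 5))
  expect_equal(integration(ones, map), 1)
  expect_equal(integration(ones, map, "SMN", "DMN"), 1)
  # allegiance exactly block-diagonal by system: recruitment 1, integration 0
  blocks <- outer(map$system, map$system, "==") * 1
  expect_equal(unname(recruitment(blocks, map)), rep(1, 5))
  expect_equal(integration(blocks, map), 0)
  expect_equal(integration(blocks, map, "VN", "ATN"), 0)
})

test_that("recruitment and pairwise integration match brute-force averages", {
  set.seed(4)
  map <- tiny_map()
  n <- map$n_nodes
  P <- matrix(runif(n * n), n); P <- (P + t(P)) / 2; diag(P) <- 1
  smn <- system_members(map, "SMN") + 1
  vn <- system_members(map, "VN") + 1
  expect_equal(integration(P, map, "SMN", "VN"), mean(P[smn, vn]))
  brute_rec <- mean(sapply(seq_along(smn), function(k)
    mean(P[smn[k], smn[-k]])))
  expect_equal(recruitment(P, map, "SMN"), brute_rec)
  # within-system co-occurrence (i != j) equals recruitment for 2-node systems
  expect_equal(recruitment(P, map, "SMN"),
               mean(P[smn, smn][upper.tri(diag(2))]))
  expect_error(integration(P, map, "SMN", "SMN"), "disjoint")
  expect_error(integration(P, map, "SMN"), "both systems")
  one_node <- validate_node_table(
    data.frame(node_id = 0:1, label = c("a", "b"),
               system = c("SMN", "DMN")))
  expect_error(recruitment(P[1:2, 1:2], system_map(one_node), "SMN"),
               "singleton")
})

test_that("overall integration is the mean of the six pairwise values", {
  set.seed(5)
  map <- tiny_map()
  n <- map$n_nodes
  P <- matrix(runif(n * n), n); P <- (P + t(P)) / 2; diag(P) <- 1
  four <- c("SMN", "DMN", "VN", "ATN")
  pairs <- combn(four, 2)
  vals <- sapply(seq_len(6), function(k)
    integration(P, map, pairs[1, k], pairs[2, k]))
  expect_equal(integration(P, map), mean(vals))
  M <- integration_matrix(P, map)
  expect_equal(M, t(M))
  expect_equal(diag(M), sapply(four, function(s) recruitment(P, map, s)))
  expect_equal(M["SMN", "VN"], integration(P, map, "SMN", "VN"))
})

test_that("node-to-system density averages stack weights over layers and targets", {
  map <- tiny_map()
  n <- map$n_nodes
  uni <- array(0.37, dim = c(2, n, n))
  for (l in 1:2) diag(uni[l, , ]) <- 0
  expect_equal(node_to_system_density(uni, map, 0, "DMN"), 0.37)
  expect_equal(node_to_system_density(array(0, dim = c(2, n, n)), map, 0, "VN"), 0)
  set.seed(6)
  st <- random_stack(2, n)
  vn <- system_members(map, "VN")
  node <- 0
  brute <- mean(sapply(1:2, function(w)
    mean(sapply(vn, function(j) st[w, node + 1, j + 1]))))
  expect_equal(node_to_system_density(st, map, node, "VN"), brute)
  one_sys <- validate_node_table(
    data.frame(node_id = 0:1, label = c("a", "b"),
               system = c("SMN", "SMN")))
  expect_error(
    node_to_system_density(st[, 1:2, 1:2], system_map(one_sys), 0, "DMN"),
    "no target nodes")
})

test_that("percent change computes signed and magnitude forms", {
  pc <- percent_change(0.4, 0.2)
  expect_equal(pc$signed, -50)
  expect_equal(pc$magnitude, 50)
  expect_equal(percent_change(0.3, 0.3)$signed, 0)
  v <- percent_change(c(1, 2, 4), c(2, 1, 5))
  expect_equal(v$signed, c(100, -50, 25))
  expect_equal(v$magnitude, c(100, 50, 25))
  expect_error(percent_change(c(1, 0), c(1, 1)), "zero baseline")
})

test_that("trial_metrics produces a tidy, finite metric frame", {
  map <- tiny_map()
  cfg <- sim_config(n_nodes = 12, n_trials = 3, seed = 17)
  sch <- lapply(child_seeds(2, 3), function(s)
    make_schedule(12, 12, 2, 0.4, map, seed = s))
  ts <- synthesize(cfg, sch, map)
  mf <- trial_metrics(ts, map, reps = 10, seed = 9)
  expect_s3_class(mf, "metric_frame")
  expect_setequal(unique(mf$metric),
                  c("flexibility", "recruitment", "integration"))
  expect_equal(sort(unique(mf$trial)), 1:3)
  expect_true(all(is.finite(mf$value)))
  fl <- mf$value[mf$metric == "flexibility"]
  expect_true(all(fl >= 0 & fl <= 11 / 12))
  ri <- mf$value[mf$metric != "flexibility"]
  expect_true(all(ri >= 0 & ri <= 1))
  # overall integration row equals the mean of the six pairwise rows
  for (tr in 1:3) {
    rows <- mf[mf$trial == tr & mf$metric == "integration", ]
    expect_equal(rows$value[rows$unit == "overall"],
                 mean(rows$value[rows$unit != "overall"]))
  }
  expect_equal(metric_values(mf, "flexibility", "DMN"),
               mf$value[mf$metric == "flexibility" & mf$unit == "DMN"])
  expect_error(metric_values(mf, "flexibility", "nope"), "no rows")
})
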