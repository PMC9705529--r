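#' Node flexibility
#'
#' F = S/T: the number of times a node changes its functional module
#' between consecutive time windows (S), over the total number of windows
#' (T). The maximum attainable value is therefore (T-1)/T. For an
#' ensemble the per-node values are averaged over repetitions.
#'
#' @param x A node x layer label matrix, a `partition`, or a
#'   `partition_ensemble`.
#' @return Numeric vector of per-node flexibility.
#' @export
flexibility <- function(x) UseMethod("flexibility")

#' @export
flexibility.matrix <- function(x) {
  T <- ncol(x)
  if (T < 2L) stop("flexibility undefined for T < 2")
  rowSums(x[, -1L, drop = FALSE] != x[, -T, drop = FALSE]) / T
}

#' @export
flexibility.partition <- function(x) flexibility(x$labels)

#' @export
flexibility.partition_ensemble <- function(x) {
  R <- dim(x$labels)[3]
  rowMeans(vapply(seq_len(R), function(r) flexibility(x$labels[, , r]),
                  numeric(dim(x$labels)[1])))
}

#' Module allegiance matrix
#'
#' `P[i, j]` is the probability that nodes i and j are assigned to the
#' same functional module, pooled over all (repetition, layer)
#' observations of the ensemble; `by_layer = TRUE` instead keeps one
#' matrix per layer (pooling over repetitions only).
#'
#' @param ensemble A `partition_ensemble` (or node x layer matrix, treated
#'   as an ensemble of one).
#' @param by_layer If `TRUE`, return an `n_layers x n x n` array.
#' @return Symmetric matrix in `[0, 1]` with unit diagonal (or per-layer
#'   array).
#' @export
allegiance <- function(ensemble, by_layer = FALSE) {
  labs <- if (inherits(ensemble, "partition_ensemble")) ensemble$labels
          else array(ensemble, dim = c(dim(ensemble), 1L))
  n <- dim(labs)[1]; L <- dim(labs)[2]; R <- dim(labs)[3]
  if (by_layer) {
    out <- array(0, dim = c(L, n, n))
    for (l in seq_len(L)) {
      P <- matrix(0, n, n)
      for (r in seq_len(R))
        P <- P + outer(labs[, l, r], labs[, l, r], "==")
      out[l, , ] <- P / R
    }
    return(out)
  }
  P <- matrix(0, n, n)
  for (r in seq_len(R))
    for (l in seq_len(L))
      P <- P + outer(labs[, l, r], labs[, l, r], "==")
  P / (R * L)
}

#' Recruitment of a large-scale system
#'
#' The probability that a node co-occurs in functional modules with nodes
#' of its own system: per node, the mean allegiance to the other nodes of
#' its system; per system, the mean over its nodes.
#'
#' @param P Allegiance matrix.
#' @param map A [system_map()].
#' @param system A named system label, or `NULL` for all five named
#'   systems (systems with fewer than two nodes are an error when
#'   requested explicitly).
#' @param nodewise If `TRUE`, return the per-node values instead of the
#'   system mean.
#' @return Scalar (or named vector over systems; or per-node vector).
#' @export
recruitment <- function(P, map, system = NULL, nodewise = FALSE) {
  stopifnot(inherits(map, "system_map"))
  if (is.null(system)) {
    vals <- vapply(map$named_systems,
                   function(s) recruitment(P, map, s), numeric(1))
    return(vals)
  }
  ids <- system_members(map, system) + 1L
  if (length(ids) < 2L)
    stop("recruitment undefined for singleton system: ", system)
  node_vals <- vapply(seq_along(ids), function(k)
    mean(P[ids[k], ids[-k]]), numeric(1))
  if (nodewise) structure(node_vals, names = ids - 1L)
  else mean(node_vals)
}

#' Integration between (or across) large-scale systems
#'
#' Pairwise form: the mean allegiance between nodes of system A and nodes
#' of system B (A and B disjoint). Overall form (`sysA = sysB = NULL`):
#' the mean of the pairwise values over all six unordered pairs among
#' SMN, DMN, VN, ATN - the four systems most relevant to a
#' somatosensory-plus-visual task.
#'
#' @param P Allegiance matrix.
#' @param map A [system_map()].
#' @param sysA,sysB System labels, or both `NULL` for overall integration.
#' @return Scalar.
#' @export
integration <- function(P, map, sysA = NULL, sysB = NULL) {
  stopifnot(inherits(map, "system_map"))
  if (is.null(sysA) && is.null(sysB)) {
    four <- c("SMN", "DMN", "VN", "ATN")
    pairs <- utils::combn(four, 2)
    vals <- vapply(seq_len(ncol(pairs)), function(k)
      integration(P, map, pairs[1, k], pairs[2, k]), numeric(1))
    return(mean(vals))
  }
  if (is.null(sysA) || is.null(sysB))
    stop("give both systems, or neither for overall integration")
  a <- system_members(map, sysA) + 1L
  b <- system_members(map, sysB) + 1L
  if (length(a) == 0L || length(b) == 0L)
    stop("empty system in integration: ", sysA, " / ", sysB)
  if (sysA == sysB || length(intersect(a, b)))
    stop("integration requires disjoint systems (see recruitment for within-system co-occurrence)")
  mean(P[a, b])
}

#' Pairwise integration / recruitment matrix
#'
#' The reporting form: a symmetric system x system matrix whose
#' off-diagonal entries are pairwise integration and whose diagonal
#' carries each system's recruitment.
#'
#' @param P Allegiance matrix.
#' @param map A [system_map()].
#' @param systems Which systems to tabulate (default SMN, DMN, VN, ATN).
#' @return Symmetric named matrix.
#' @export
integration_matrix <- function(P, map, systems = c("SMN", "DMN", "VN", "ATN")) {
  k <- length(systems)
  M <- matrix(0, k, k, dimnames = list(systems, systems))
  for (i in seq_len(k)) {
    M[i, i] <- recruitment(P, map, systems[i])
    if (i < k) for (j in (i + 1L):k) {
      M[i, j] <- M[j, i] <- integration(P, map, systems[i], systems[j])
    }
  }
  M
}

#' Mean connectivity density from one node to a system
#'
#' Average WPLI weight, over all layers of the stack, between `node` and
#' every node of `system` (excluding the node itself if it belongs to the
#' system).
#'
#' @param stack A `conn_stack`.
#' @param map A [system_map()].
#' @param node 0-based node id.
#' @param system Target system label.
#' @return Scalar mean weight.
#' @export
node_to_system_density <- function(stack, map, node, system) {
  stopifnot(inherits(map, "system_map"))
  ids <- system_members(map, system)
  ids <- setdiff(ids, node) + 1L
  if (length(ids) == 0L)
    stop("no target nodes left in system ", system, " after excluding node ", node)
  mean(stack[, node + 1L, ids])
}

#' Percent change between two condition values
#'
#' `signed = 100 * (post - pre) / pre`; `magnitude = |signed|`.
#' Vectorized; a zero baseline is an error.
#'
#' @param pre,post Numeric vectors (baseline and comparison values).
#' @return List with `signed` and `magnitude`.
#' @export
percent_change <- function(pre, post) {
  if (any(pre == 0)) stop("zero baseline in percent change")
  signed <- 100 * (post - pre) / pre
  list(signed = signed, magnitude = abs(signed))
}

#' Per-trial dynamic modular network metrics
#'
#' The workhorse: for every trial of an ROI time-series set, builds the
#' WPLI connectivity stack, couples it into a multilayer graph, runs
#' repeated generalized Louvain, and tabulates system-level flexibility,
#' recruitment, pairwise and overall integration (all averaged over the
#' detection repetitions).
#'
#' @param x A `roi_ts`.
#' @param map A [system_map()] whose roster matches the data.
#' @param spec A [window_spec()].
#' @param band Band in Hz for the WPLI estimator (`NULL` if the data are
#'   already narrow-band).
#' @param gamma,omega Multilayer modularity parameters.
#' @param reps Community-detection repetitions per trial.
#' @param seed Base seed; each trial gets a child seed.
#' @param debias Use the debiased squared WPLI.
#' @return A tidy `metric_frame` data.frame: `trial`, `unit`, `metric`,
#'   `value`. Units are system labels, system pairs (`"A-B"`), or
#'   `"overall"`.
#' @export
trial_metrics <- function(x, map, spec = window_spec(), band = NULL,
                          gamma = 1, omega = 0.25, reps = 50,
                          seed = 1L, debias = FALSE) {
  stopifnot(inherits(x, "roi_ts"), inherits(map, "system_map"))
  if (dim(x$data)[1] != map$n_nodes)
    stop("system map has ", map$n_nodes, " nodes but data have ",
         dim(x$data)[1])
  n_trials <- dim(x$data)[3]
  seeds <- child_seeds(seed, n_trials)
  four <- c("SMN", "DMN", "VN", "ATN")
  pairs <- utils::combn(four, 2)
  rows <- vector("list", n_trials)
  for (tr in seq_len(n_trials)) {
    stack <- connectivity_stack(x$data[, , tr], x$fs, spec, band = band,
                                debias = debias)
    graph <- multilayer_graph(stack, gamma = gamma, omega = omega)
    ens <- gl_ensemble(graph, R = reps, base_seed = seeds[tr])
    fl <- flexibility(ens)
    P <- allegiance(ens)
    rec <- recruitment(P, map)
    pint <- vapply(seq_len(ncol(pairs)), function(k)
      integration(P, map, pairs[1, k], pairs[2, k]), numeric(1))
    sys_fl <- vapply(map$named_systems, function(s)
      mean(fl[system_members(map, s) + 1L]), numeric(1))
    rows[[tr]] <- data.frame(
      trial = tr,
      unit = c(map$named_systems, names(rec),
               paste(pairs[1, ], pairs[2, ], sep = "-"), "overall"),
      metric = c(rep("flexibility", length(sys_fl)),
                 rep("recruitment", length(rec)),
                 rep("integration", length(pint)), "integration"),
      value = c(sys_fl, rec, pint, mean(pint)))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("metric_frame", "data.frame")
  out
}

#' Extract one metric's per-trial values from a metric frame
#'
#' @param mf A `metric_frame`.
#' @param metric Metric name.
#' @param unit Unit (system, pair, or `"overall"`).
#' @return Numeric vector ordered by trial.
#' @export
metric_values <- function(mf, metric, unit) {
  sel <- mf$metric == metric & mf$unit == unit
  if (!any(sel)) stop("no rows for metric ", metric, ", unit ", unit)
  v <- mf$value[sel][order(mf$trial[sel])]
  v
}

#' Write a metric frame as tidy CSV
#'
#' @param mf A `metric_frame`.
#' @param path Output CSV path (`trial,unit,metric,value`).
#' @export
write_metric_frame <- function(mf, path) {
  write.csv(as.data.frame(mf)[, c("trial", "unit", "metric", "value")],
            path, row.names = FALSE)
  invisible(path)
}
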