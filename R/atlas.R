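#' Node tables and large-scale system maps
#'
#' A node table assigns every ROI (node) of the parcellation to exactly one
#' large-scale functional system: SMN (somatomotor), DMN (default mode),
#' VN (visual), ATN (attention), TPN (task positive), or "Others" for nodes
#' outside the five named systems. "Others" nodes take part in connectivity
#' and community detection but are excluded from system-level metric
#' summaries.
#'
#' The bundled default is an 80-node table of AAL cortical region names with
#' a literature-typical system assignment. It is a synthetic stand-in (see
#' the file name) for study-specific assignments and is fully replaceable:
#' point `path` at any CSV with header `node_id,label,system`.
#'
#' @param path Path to a CSV node table (`node_id,label,system`, UTF-8,
#'   0-based contiguous `node_id`). `NULL` (default) loads the bundled
#'   80-node table.
#' @return A `node_table`: a data.frame with columns `node_id` (0-based
#'   integer), `label`, `system`, validated against the invariants above.
#' @examples
#' nodes <- load_node_table()
#' nrow(nodes)   # 80
#' table(nodes$system)
#' @export
load_node_table <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "aal80_systems_synthetic.csv",
                        package = "dynmodnet", mustWork = TRUE)
  }
  if (!file.exists(path)) stop("node table file not found: ", path)
  tab <- read.csv(path, stringsAsFactors = FALSE)
  validate_node_table(tab)
}

#' @rdname load_node_table
#' @param tab A data.frame to validate as a node table.
#' @export
validate_node_table <- function(tab) {
  req <- c("node_id", "label", "system")
  if (!all(req %in% names(tab)))
    stop("node table must have columns: ", paste(req, collapse = ", "))
  tab$node_id <- as.integer(tab$node_id)
  n <- nrow(tab)
  if (n < 1L) stop("node table is empty")
  if (anyDuplicated(tab$node_id))
    stop("duplicate node_id in node table")
  if (!identical(sort(tab$node_id), seq_len(n) - 1L))
    stop("non-contiguous node ids: node_id must be 0..N-1")
  bad <- !(tab$system %in% all_system_labels())
  if (any(bad))
    stop("unknown system label in row(s) ",
         paste(which(bad), collapse = ", "), ": ",
         paste(unique(tab$system[bad]), collapse = ", "))
  tab <- tab[order(tab$node_id), , drop = FALSE]
  rownames(tab) <- NULL
  class(tab) <- c("node_table", "data.frame")
  tab
}

#' Known system labels
#'
#' @return Character vector of the five named large-scale systems
#'   (`named_systems()`) or of all six labels including `"Others"`
#'   (`all_system_labels()`).
#' @export
named_systems <- function() c("SMN", "DMN", "VN", "ATN", "TPN")

#' @rdname named_systems
#' @export
all_system_labels <- function() c(named_systems(), "Others")

#' Build a system map from a node table
#'
#' A `system_map` is the lookup used by all metric functions: for each
#' system label, the 0-based ids of its member nodes.
#'
#' @param nodes A `node_table` (see [load_node_table()]).
#' @return A `system_map` list with elements `members` (named list of
#'   integer node-id vectors), `system` (per-node label, in node order),
#'   `named_systems`, and `n_nodes`.
#' @export
system_map <- function(nodes = load_node_table()) {
  nodes <- validate_node_table(as.data.frame(nodes))
  members <- lapply(all_system_labels(),
                    function(s) nodes$node_id[nodes$system == s])
  names(members) <- all_system_labels()
  structure(list(members = members,
                 system = nodes$system,
                 named_systems = named_systems(),
                 n_nodes = nrow(nodes)),
            class = "system_map")
}

#' Members of one system
#'
#' @param map A `system_map`.
#' @param system One of the six system labels.
#' @return Integer vector of 0-based node ids (possibly empty).
#' @export
system_members <- function(map, system) {
  stopifnot(inherits(map, "system_map"))
  if (!(system %in% names(map$members)))
    stop("unknown system label: ", system)
  map$members[[system]]
}

#' @export
print.system_map <- function(x, ...) {
  cat("system_map:", x$n_nodes, "nodes\n")
  sizes <- vapply(x$members, length, integer(1))
  print(sizes)
  invisible(x)
}

#' Write a node table back to CSV
#'
#' Round-trips bit-exactly with [load_node_table()].
#'
#' @param nodes A `node_table`.
#' @param path Output CSV path.
#' @export
write_node_table <- function(nodes, path) {
  write.csv(as.data.frame(nodes)[, c("node_id", "label", "system")],
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
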