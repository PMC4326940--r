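#' Traced-cell data model
#'
#' A `cell_trace` is a rooted tree of 3-D points in physical micrometres,
#' following SWC semantics: every node has a unique id, a parent id (`-1`
#' for the root, the soma), coordinates and an optional radius. It is the
#' common currency between the synthetic generator, the automated tracer and
#' the morphometric layer.
#'
#' @param nodes A data frame with columns `node_id`, `parent_id`, `x`, `y`,
#'   `z` (micrometres) and optionally `radius` and `type`.
#' @param cell_id Label for the cell.
#' @param comments Character vector of metadata lines (without the leading
#'   `#`), preserved on SWC round-trips.
#' @param validate Run the structural validator (default `TRUE`).
#' @return An object of class `cell_trace`.
#' @export
cell_trace <- function(nodes, cell_id = "cell", comments = character(),
                       validate = TRUE) {
  nodes <- tibble::as_tibble(nodes)
  if (!"radius" %in% names(nodes)) nodes$radius <- NA_real_
  if (!"type" %in% names(nodes)) nodes$type <- NA_integer_
  nodes$node_id <- as.integer(nodes$node_id)
  nodes$parent_id <- as.integer(nodes$parent_id)
  tr <- structure(
    list(nodes = nodes[, c("node_id", "parent_id", "x", "y", "z",
                           "radius", "type")],
         cell_id = cell_id, comments = comments),
    class = "cell_trace")
  if (validate) validate_trace(tr)
  tr
}

#' Validate a cell trace
#'
#' Checks the structural invariants of the traced-tree model: unique node
#' ids, exactly one root (parent id `-1`), every parent id present, finite
#' coordinates, and an acyclic, connected parent graph.
#'
#' @param trace A `cell_trace`.
#' @return The trace, invisibly; stops with an informative error otherwise.
#' @export
validate_trace <- function(trace) {
  stopifnot(inherits(trace, "cell_trace"))
  nd <- trace$nodes
  if (nrow(nd) == 0) stop("trace has no nodes", call. = FALSE)
  if (anyDuplicated(nd$node_id))
    stop("duplicate node id: ",
         nd$node_id[duplicated(nd$node_id)][1], call. = FALSE)
  if (!all(is.finite(nd$x) & is.finite(nd$y) & is.finite(nd$z)))
    stop("non-finite coordinates in trace", call. = FALSE)
  roots <- nd$node_id[nd$parent_id == -1L]
  if (length(roots) == 0) stop("trace has no root node", call. = FALSE)
  if (length(roots) > 1)
    stop("multiple roots: nodes ", paste(roots, collapse = ", "),
         call. = FALSE)
  nonroot <- nd[nd$parent_id != -1L, ]
  missing <- setdiff(nonroot$parent_id, nd$node_id)
  if (length(missing))
    stop("dangling parent id ", missing[1], " (node ",
         nonroot$node_id[match(missing[1], nonroot$parent_id)], ")",
         call. = FALSE)
  # acyclicity + connectivity: walk each node to the root
  parent <- stats::setNames(nd$parent_id, nd$node_id)
  depth <- stats::setNames(rep(NA_integer_, nrow(nd)), nd$node_id)
  depth[as.character(roots)] <- 0L
  for (id in nd$node_id) {
    chain <- character()
    cur <- as.character(id)
    while (is.na(depth[cur])) {
      if (cur %in% chain)
        stop("cycle detected at node ", cur, call. = FALSE)
      chain <- c(chain, cur)
      cur <- as.character(parent[cur])
    }
    d <- depth[cur]
    for (k in rev(seq_along(chain))) {
      d <- d + 1L
      depth[chain[k]] <- d
    }
  }
  invisible(trace)
}

#' @export
print.cell_trace <- function(x, ...) {
  cat("<cell_trace> ", x$cell_id, ": ", nrow(x$nodes), " nodes, root ",
      trace_root(x), "\n", sep = "")
  invisible(x)
}

# id of the root node
trace_root <- function(trace) {
  trace$nodes$node_id[trace$nodes$parent_id == -1L]
}

#' Edge table of a trace
#'
#' One row per parent-child edge with its Euclidean length in micrometres.
#'
#' @param trace A `cell_trace`.
#' @return A tibble with columns `node_id`, `parent_id`, `length`.
#' @export
trace_edges <- function(trace) {
  nd <- trace$nodes
  ch <- nd[nd$parent_id != -1L, ]
  if (nrow(ch) == 0)
    return(tibble::tibble(node_id = integer(), parent_id = integer(),
                          length = double()))
  pi <- match(ch$parent_id, nd$node_id)
  tibble::tibble(
    node_id = ch$node_id, parent_id = ch$parent_id,
    length = sqrt((ch$x - nd$x[pi])^2 + (ch$y - nd$y[pi])^2 +
                  (ch$z - nd$z[pi])^2))
}

# children lookup: named list parent id -> integer vector of child ids
trace_children <- function(trace) {
  ch <- trace$nodes[trace$nodes$parent_id != -1L, ]
  split(ch$node_id, factor(ch$parent_id, levels = trace$nodes$node_id))
}

#' Read an SWC reconstruction
#'
#' Parses the standard SWC dialect (`id type x y z radius parent`, `#`
#' comment lines). Comment lines are preserved as metadata on the returned
#' trace. Structural problems (multiple roots, cycles, dangling parent ids)
#' raise a format error naming the offending node.
#'
#' @param path Path to an SWC file.
#' @param cell_id Optional label; defaults to the file name.
#' @return A `cell_trace`.
#' @export
read_swc <- function(path, cell_id = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  comments <- sub("^#\\s?", "", lines[startsWith(trimws(lines), "#")])
  body <- trimws(lines[!startsWith(trimws(lines), "#")])
  body <- body[nzchar(body)]
  if (length(body) == 0) stop("SWC file has no nodes: ", path, call. = FALSE)
  fields <- strsplit(body, "\\s+")
  if (any(lengths(fields) != 7))
    stop("malformed SWC line: '", body[which(lengths(fields) != 7)[1]], "'",
         call. = FALSE)
  m <- matrix(as.numeric(unlist(fields)), ncol = 7, byrow = TRUE)
  if (anyNA(m)) stop("non-numeric field in SWC file", call. = FALSE)
  nodes <- tibble::tibble(
    node_id = as.integer(m[, 1]), type = as.integer(m[, 2]),
    x = m[, 3], y = m[, 4], z = m[, 5], radius = m[, 6],
    parent_id = as.integer(m[, 7]))
  cell_trace(nodes,
             cell_id = cell_id %||% sub("\\.swc$", "", basename(path)),
             comments = comments)
}

#' Write an SWC reconstruction
#'
#' Coordinates are written at 1e-6 um precision so write/read round-trips
#' are lossless at that tolerance.
#'
#' @param trace A `cell_trace`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_swc <- function(trace, path) {
  validate_trace(trace)
  nd <- trace$nodes
  type <- ifelse(is.na(nd$type), ifelse(nd$parent_id == -1L, 1L, 3L),
                 nd$type)
  radius <- ifelse(is.na(nd$radius), 1, nd$radius)
  lines <- c(
    paste0("# ", trace$comments),
    sprintf("%d %d %.6f %.6f %.6f %.6f %d",
            nd$node_id, type, nd$x, nd$y, nd$z, radius, nd$parent_id))
  writeLines(lines, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
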