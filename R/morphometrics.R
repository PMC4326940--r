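#' Decompose a trace into branches
#'
#' A branch is a maximal path between consecutive topological nodes of the
#' tree: the soma (root), bifurcation points (nodes with two or more
#' children) and terminal tips. Branches whose path length does not exceed
#' `min_length` are flagged as filtered: they are dropped from branch
#' counts and from the branch-length distribution, but their length still
#' contributes to the cell's total branch length. Every edge of the trace
#' belongs to exactly one branch.
#'
#' @param trace A `cell_trace`.
#' @param min_length Minimum counted branch length in um (default 0.5).
#' @return A tibble with one row per branch: `branch_id`, `start_node`
#'   (topological node the branch leaves), `end_node`, `n_edges`, `length`
#'   (um), `kept` (logical, `length > min_length`), and a list-column
#'   `path` of node ids from start to end.
#' @export
decompose_branches <- function(trace, min_length = 0.5) {
  validate_trace(trace)
  nd <- trace$nodes
  root <- trace_root(trace)
  if (nrow(nd) == 1)
    return(tibble::tibble(branch_id = integer(), start_node = integer(),
                          end_node = integer(), n_edges = integer(),
                          length = double(), kept = logical(),
                          path = list()))
  kids <- trace_children(trace)
  outdeg <- lengths(kids)
  names(outdeg) <- nd$node_id
  is_topo <- outdeg >= 2 | outdeg == 0 | nd$node_id == root
  ed <- trace_edges(trace)
  elen <- stats::setNames(ed$length, ed$node_id)

  rows <- list()
  bid <- 0L
  # walk from each topological node down each child chain
  for (tn in nd$node_id[is_topo]) {
    for (child in kids[[as.character(tn)]]) {
      path <- c(tn, child)
      len <- elen[[as.character(child)]]
      cur <- child
      while (!is_topo[match(cur, nd$node_id)]) {
        nxt <- kids[[as.character(cur)]]
        path <- c(path, nxt)
        len <- len + elen[[as.character(nxt)]]
        cur <- nxt
      }
      bid <- bid + 1L
      rows[[bid]] <- list(branch_id = bid, start_node = tn,
                          end_node = cur, n_edges = length(path) - 1L,
                          length = len, path = list(as.integer(path)))
    }
  }
  out <- dplyr::bind_rows(lapply(rows, tibble::as_tibble))
  out$kept <- out$length > min_length
  out[, c("branch_id", "start_node", "end_node", "n_edges", "length",
          "kept", "path")]
}

#' Count bifurcations of a trace
#'
#' A non-soma node with `k >= 2` children contributes `k - 1` bifurcations;
#' the soma is excluded because primary processes emanate from it rather
#' than arising by splitting.
#'
#' @param trace A `cell_trace`.
#' @return Integer bifurcation count.
#' @export
count_bifurcations <- function(trace) {
  validate_trace(trace)
  root <- trace_root(trace)
  ch <- trace$nodes[trace$nodes$parent_id != -1L, ]
  deg <- table(ch$parent_id)
  deg <- deg[names(deg) != as.character(root)]
  sum(pmax(as.integer(deg) - 1L, 0L))
}

#' Total branch length of a trace
#'
#' Sum over all parent-child edges of the Euclidean distance between the
#' endpoints, in micrometres. No minimum-length filter is applied here:
#' filtered fine branches still count toward the total.
#'
#' @param trace A `cell_trace`.
#' @return Length in um.
#' @export
total_branch_length <- function(trace) {
  sum(trace_edges(trace)$length)
}

#' Tree area of a trace
#'
#' The planar area enclosed by the polygon through the outermost points of
#' the cell's processes: the convex hull of all node coordinates projected
#' onto the xy-plane, in um^2.
#'
#' @param trace A `cell_trace`.
#' @return Area in um^2.
#' @export
tree_area <- function(trace) {
  validate_trace(trace)
  pts <- unique(cbind(trace$nodes$x, trace$nodes$y))
  if (nrow(pts) < 3)
    stop("degenerate geometry: fewer than 3 distinct projected points",
         call. = FALSE)
  h <- grDevices::chull(pts[, 1], pts[, 2])
  if (length(h) < 3)
    stop("degenerate geometry: projected points are collinear",
         call. = FALSE)
  a <- polygon_area(pts[h, 1], pts[h, 2])
  if (a <= 0)
    stop("degenerate geometry: projected points are collinear",
         call. = FALSE)
  a
}

# shoelace formula, absolute area
polygon_area <- function(x, y) {
  n <- length(x)
  j <- c(n, seq_len(n - 1))
  abs(sum(x[j] * y - x * y[j])) / 2
}

#' Cell depth
#'
#' Extent of the trace along the optical axis: `max(z) - min(z)` in um.
#'
#' @param trace A `cell_trace`.
#' @return Depth in um.
#' @export
cell_depth <- function(trace) {
  diff(range(trace$nodes$z))
}

#' Coverage volume
#'
#' Micrometres of process contained in a (10 um)^3 cube of tissue: the
#' total branch length divided by the cell volume (tree area x depth) and
#' multiplied by 1000.
#'
#' @param total_length Total branch length L, um.
#' @param area Tree area A, um^2.
#' @param depth Cell depth Z, um.
#' @return Coverage volume, um of process per (10 um)^3.
#' @export
coverage_volume <- function(total_length, area, depth) {
  v <- area * depth
  if (!isTRUE(v > 0))
    stop("coverage volume undefined: cell volume is zero", call. = FALSE)
  total_length / v * 1000
}

#' Per-cell morphometric record
#'
#' Computes the full morphometric panel for one traced cell: number of
#' bifurcations, number of branches (after the minimum-length filter),
#' total branch length L, tree area A (convex hull of the xy projection),
#' depth Z, volume V = A * Z and coverage volume CV = L / V x 1000, plus
#' the per-branch length distribution.
#'
#' @param trace A `cell_trace`, or a `scene_truth` / list of traces (one
#'   row per cell is returned).
#' @param min_branch_length Minimum counted branch length, um.
#' @return A tibble with one row per cell: `cell_id`, `n_bifurcations`,
#'   `n_branches`, `total_branch_length`, `tree_area`, `depth`, `volume`,
#'   `coverage_volume`, `normalized` (FALSE) and a list-column
#'   `branch_lengths` of counted branch lengths.
#' @export
morphometrics <- function(trace, min_branch_length = 0.5) {
  if (inherits(trace, "scene_truth")) trace <- trace$traces
  if (!inherits(trace, "cell_trace")) {
    return(dplyr::bind_rows(lapply(trace, morphometrics,
                                   min_branch_length = min_branch_length)))
  }
  br <- decompose_branches(trace, min_length = min_branch_length)
  L <- total_branch_length(trace)
  A <- tree_area(trace)
  Z <- cell_depth(trace)
  tibble::tibble(
    cell_id = trace$cell_id,
    n_bifurcations = count_bifurcations(trace),
    n_branches = sum(br$kept),
    total_branch_length = L,
    tree_area = A,
    depth = Z,
    volume = A * Z,
    coverage_volume = coverage_volume(L, A, Z),
    normalized = FALSE,
    branch_lengths = list(br$length[br$kept]))
}

#' Branch-length distribution histogram
#'
#' Pools the counted branch lengths of a group of cells into left-closed
#' bins `[k w, (k + 1) w)`.
#'
#' @param records A morphometrics tibble (with the `branch_lengths`
#'   list-column) or a numeric vector of branch lengths.
#' @param bin_width Bin width w in um.
#' @return A tibble with `bin_left`, `bin_right`, `count`.
#' @export
branch_length_histogram <- function(records, bin_width = 1) {
  if (bin_width <= 0) stop("bin_width must be positive", call. = FALSE)
  lens <- if (is.numeric(records)) records
          else unlist(records$branch_lengths)
  if (length(lens) == 0)
    return(tibble::tibble(bin_left = double(), bin_right = double(),
                          count = integer()))
  k <- floor(lens / bin_width)
  tab <- table(k)
  tibble::tibble(bin_left = as.numeric(names(tab)) * bin_width,
                 bin_right = (as.numeric(names(tab)) + 1) * bin_width,
                 count = as.integer(tab))
}

#' Normalize a morphometric record to a reference slice thickness
#'
#' Scales the extensive quantities — bifurcation count, branch count, total
#' branch length and the per-branch lengths used for histograms — by
#' `target_thickness / depth`, so cells imaged through different tissue
#' thicknesses are comparable. Tree area and coverage volume are left
#' unchanged (coverage volume is already volume-normalized).
#'
#' @param records A morphometrics tibble.
#' @param target_thickness Reference thickness in um (default 20).
#' @return The records with scaled extensive columns and
#'   `normalized = TRUE`.
#' @export
normalize_to_thickness <- function(records, target_thickness = 20) {
  if (any(records$depth <= 0))
    stop("cannot normalize a record with zero depth", call. = FALSE)
  f <- target_thickness / records$depth
  records$n_bifurcations <- records$n_bifurcations * f
  records$n_branches <- records$n_branches * f
  records$total_branch_length <- records$total_branch_length * f
  records$branch_lengths <- purrr::map2(records$branch_lengths, f, `*`)
  records$normalized <- TRUE
  records
}
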