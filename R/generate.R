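#' Generation parameters for a synthetic microglial cell
#'
#' Bundles the stochastic growth law for one traced cell. Cortical microglia
#' show roughly three orders of process hierarchy: 7-9 primary processes
#' leaving the soma, medium processes branching off them, and very fine
#' terminal processes of a few micrometres. The growth model is a discrete
#' random tree: each ~`segment_length_mean` um segment either bifurcates
#' (probability `bifurcation_prob`, entering the next branch order), extends
#' at the same order (`extend_prob`), or terminates; independently, segment
#' endpoints can spawn short terminal fine processes (1-4 um) with
#' probability `fine_process_rate`. The aged phenotype is reached by
#' lowering `fine_process_rate` and `bifurcation_prob`; the three plaque
#' layers by progressively more amoeboid presets.
#'
#' @param condition One of `"young"`, `"aged"`, `"plaque_L1"`,
#'   `"plaque_L2"`, `"plaque_L3"`. Sets the per-condition defaults below;
#'   any argument given explicitly overrides its default.
#' @param n_primary Integer (or integer vector to sample from) count of
#'   soma-emanating primary processes. Default `7:9` for ramified
#'   conditions.
#' @param bifurcation_prob Probability per segment of splitting in two.
#'   May be a vector indexed by branch order (last value recycled), so
#'   phenotypes can branch differently at primary, medium and fine order.
#' @param extend_prob Probability per segment of continuing at the same
#'   branch order; per-order vectors as for `bifurcation_prob`.
#' @param segment_length_mean,segment_length_sd Segment length distribution
#'   (um, normal truncated at 0.6 um).
#' @param max_order Branch-order cap (primary process = order 1).
#' @param fine_process_rate Probability per segment endpoint of spawning a
#'   terminal fine process of length 1-4 um.
#' @param tortuosity Per-step angular jitter (radians) of the growth
#'   direction.
#' @param soma_radius Soma radius in um (rendered and used as root radius).
#' @param process_radius Tube radius per branch order, um.
#' @param fine_radius Tube radius of fine processes, um.
#' @param z_flatten Factor (0-1] compressing growth in z, so cells stay
#'   within a 20-40 um slice.
#' @param slab_z Slab thickness in um: growth reflects off the slab faces,
#'   emulating cells contained in (and truncated by) a tissue section.
#' @param reach_radius,reach_taper Territorial confinement: beyond
#'   `reach_radius` um (in-plane distance from the soma) the continuation
#'   probabilities decay with scale `reach_taper` um, emulating the
#'   bounded, tiled territories of microglia.
#' @param step_length Polyline discretisation step, um.
#' @param min_separation If set (um), cells are resampled until no two
#'   tree-distant branches pass within this Euclidean distance of each
#'   other — guaranteeing well-separated branches for tracer validation.
#'   `NULL` (default) disables the check.
#' @param seed Integer seed; identical parameters and seed give identical
#'   cells.
#' @return A `gen_params` list.
#' @export
gen_params <- function(condition = c("young", "aged", "plaque_L1",
                                     "plaque_L2", "plaque_L3"),
                       n_primary = NULL, bifurcation_prob = NULL,
                       extend_prob = NULL, segment_length_mean = NULL,
                       segment_length_sd = NULL, max_order = NULL,
                       fine_process_rate = NULL, tortuosity = NULL,
                       soma_radius = NULL, process_radius = NULL,
                       fine_radius = NULL, z_flatten = NULL,
                       slab_z = NULL, reach_radius = NULL,
                       reach_taper = NULL, step_length = NULL,
                       min_separation = NULL, seed = 1L) {
  condition <- match.arg(condition)
  def <- switch(condition,
    young = list(n_primary = 7:9, bifurcation_prob = 0.50,
                 extend_prob = 0.35, segment_length_mean = 5,
                 segment_length_sd = 1.5, max_order = 3,
                 fine_process_rate = 0.7, tortuosity = 0.15),
    # aged cells lose fine processes and higher-order branching but keep
    # persistent primary processes, so the territory (hull) survives while
    # the arbor inside it empties out
    aged = list(n_primary = 5:7, bifurcation_prob = c(0.05, 0.02, 0),
                extend_prob = c(0.95, 0.35, 0.35),
                segment_length_mean = 3.3,
                segment_length_sd = 1.2, max_order = 3,
                fine_process_rate = 0.03, tortuosity = 0.22,
                z_flatten = 0.45),
    plaque_L1 = list(n_primary = 4:6, bifurcation_prob = 0.05,
                     extend_prob = 0.20, segment_length_mean = 2.5,
                     segment_length_sd = 0.8, max_order = 2,
                     fine_process_rate = 0.05, tortuosity = 0.25),
    plaque_L2 = list(n_primary = 5:7, bifurcation_prob = 0.20,
                     extend_prob = 0.30, segment_length_mean = 4,
                     segment_length_sd = 1.2, max_order = 3,
                     fine_process_rate = 0.15, tortuosity = 0.20),
    plaque_L3 = list(n_primary = 7:9, bifurcation_prob = 0.35,
                     extend_prob = 0.35, segment_length_mean = 4.5,
                     segment_length_sd = 1.5, max_order = 3,
                     fine_process_rate = 0.30, tortuosity = 0.18))
  p <- list(
    condition = condition,
    n_primary = n_primary %||% def$n_primary,
    bifurcation_prob = bifurcation_prob %||% def$bifurcation_prob,
    extend_prob = extend_prob %||% def$extend_prob,
    segment_length_mean = segment_length_mean %||% def$segment_length_mean,
    segment_length_sd = segment_length_sd %||% def$segment_length_sd,
    max_order = max_order %||% def$max_order,
    fine_process_rate = fine_process_rate %||% def$fine_process_rate,
    tortuosity = tortuosity %||% def$tortuosity,
    soma_radius = soma_radius %||% 3.0,
    process_radius = process_radius %||% c(0.6, 0.4, 0.3),
    fine_radius = fine_radius %||% 0.25,
    z_flatten = z_flatten %||% def$z_flatten %||% 0.25,
    slab_z = slab_z %||% 16,
    reach_radius = reach_radius %||% 22,
    reach_taper = reach_taper %||% 6,
    step_length = step_length %||% 1.0,
    min_separation = min_separation,
    seed = as.integer(seed))
  for (nm in c("bifurcation_prob", "extend_prob", "fine_process_rate")) {
    if (any(p[[nm]] < 0) || any(p[[nm]] > 1))
      stop(nm, " must lie in [0, 1]", call. = FALSE)
  }
  ords <- seq_len(p$max_order %||% 3)
  pb <- p$bifurcation_prob[pmin(ords, length(p$bifurcation_prob))]
  pe <- p$extend_prob[pmin(ords, length(p$extend_prob))]
  if (any(pb + pe > 1))
    stop("bifurcation_prob + extend_prob must not exceed 1 at any order",
         call. = FALSE)
  for (nm in c("segment_length_mean", "segment_length_sd", "soma_radius",
               "fine_radius", "step_length"))
    if (any(p[[nm]] <= 0) && nm != "segment_length_sd")
      stop(nm, " must be positive", call. = FALSE)
  if (p$segment_length_sd < 0)
    stop("segment_length_sd must be non-negative", call. = FALSE)
  if (any(p$n_primary < 1)) stop("n_primary must be >= 1", call. = FALSE)
  if (p$max_order < 1) stop("max_order must be >= 1", call. = FALSE)
  structure(p, class = "gen_params")
}

#' Generation parameters for tracer validation cells
#'
#' A ramified-cell geometry designed so the rendered tubes satisfy the
#' assumptions under which automated tracing can be checked against ground
#' truth exactly: no terminal fine processes, low tortuosity, tube radii
#' at or above the axial voxel size (no pinch-off between z-planes), first
#' bifurcations outside the soma-collapse ball, and rejection-resampling
#' until all tree-distant branches stay at least `min_separation` apart
#' (well-separated branches). Used by the raster round-trip tests; not a
#' realistic phenotype.
#'
#' @param seed Integer seed.
#' @return A `gen_params` object.
#' @export
roundtrip_params <- function(seed = 1L) {
  gen_params("young", n_primary = 7:9, bifurcation_prob = 0.35,
             extend_prob = 0.35, segment_length_mean = 7,
             segment_length_sd = 1, fine_process_rate = 0,
             tortuosity = 0.08, soma_radius = 4,
             process_radius = c(0.7, 0.6, 0.5), z_flatten = 0.5,
             min_separation = 2.5, seed = seed)
}

# run expr with a private, restorable RNG state
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# unit vector with gaussian jitter, z compressed by zf
jitter_dir <- function(d, sd, zf) {
  d <- d + stats::rnorm(3, 0, sd) * c(1, 1, zf)
  d / sqrt(sum(d^2))
}

# a direction roughly perpendicular to d, for fine-process take-off
perp_dir <- function(d, zf) {
  v <- stats::rnorm(3) * c(1, 1, zf)
  v <- v - sum(v * d) * d
  n <- sqrt(sum(v^2))
  if (n < 1e-9) v <- c(-d[2], d[1], 0) else v <- v / n
  (0.7 * v + 0.71 * d) / sqrt(sum((0.7 * v + 0.71 * d)^2))
}

#' Generate one synthetic microglial cell trace
#'
#' Grows a rooted random tree according to the law in [gen_params()]: the
#' soma sits at the origin, `n_primary` primary processes leave it at
#' roughly even azimuths, and each process grows segment by segment,
#' bifurcating, extending or terminating, with optional terminal fine
#' processes. The trace is a polyline tree in micrometres with per-order
#' tube radii, directly consumable by [morphometrics()] and
#' [render_stack()].
#'
#' @param params A `gen_params` object.
#' @param cell_id Label for the cell.
#' @return A `cell_trace`.
#' @export
generate_cell_trace <- function(params, cell_id = "cell") {
  stopifnot(inherits(params, "gen_params"))
  with_seed(params$seed, {
    if (is.null(params$min_separation)) {
      generate_cell_trace_impl(params, cell_id)
    } else {
      tr <- NULL
      for (try in 1:50) {
        tr <- generate_cell_trace_impl(params, cell_id)
        if (branches_separated(tr, params$min_separation,
                               params$soma_radius + 2)) break
        tr <- NULL
      }
      if (is.null(tr))
        stop("could not generate a cell with min_separation = ",
             params$min_separation, " in 50 attempts", call. = FALSE)
      tr
    }
  })
}

# TRUE when no two tree-distant points of the trace come closer than `sep`
# (pairs where both points sit in the soma neighbourhood are exempt: they
# are handled by soma collapse in the tracer)
branches_separated <- function(trace, sep, soma_excl) {
  nd <- trace$nodes
  n <- nrow(nd)
  pos <- cbind(nd$x, nd$y, nd$z)
  d2 <- as.matrix(stats::dist(pos))^2
  close_ <- d2 < sep^2
  ed <- trace_edges(trace)
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  g <- igraph::add_edges(g, rbind(match(ed$parent_id, nd$node_id),
                                  match(ed$node_id, nd$node_id)),
                         weight = ed$length)
  td <- igraph::distances(g)
  near_soma <- sqrt(rowSums(pos^2)) < soma_excl
  bad <- close_ & td > 3 * sep &
    !(outer(near_soma, near_soma, `&`))
  !any(bad)
}

generate_cell_trace_impl <- function(params, cell_id) {
  p <- params
  max_nodes <- 20000L
  nodes <- new.env(parent = emptyenv())
  nodes$id <- 0L
  nodes$rows <- vector("list", 512)
  add_node <- function(parent, pos, radius) {
    nodes$id <- nodes$id + 1L
    nodes$rows[[nodes$id]] <- c(nodes$id, parent, pos, radius)
    nodes$id
  }
  root <- add_node(-1L, c(0, 0, 0), p$soma_radius)
  order_radius <- function(ord)
    p$process_radius[min(ord, length(p$process_radius))]

  zhalf <- p$slab_z / 2
  reflect_z <- function(pos, d) {
    if (pos[3] > zhalf) {
      pos[3] <- 2 * zhalf - pos[3]
      d[3] <- -abs(d[3])
    } else if (pos[3] < -zhalf) {
      pos[3] <- -2 * zhalf - pos[3]
      d[3] <- abs(d[3])
    }
    list(pos = pos, d = d)
  }

  grow_fine <- function(parent, pos, dir) {
    len <- stats::runif(1, 1, 4)
    d <- perp_dir(dir, p$z_flatten)
    nsteps <- max(1L, round(len / p$step_length))
    cur <- parent
    for (s in seq_len(nsteps)) {
      pos <- pos + d * (len / nsteps)
      rz <- reflect_z(pos, d); pos <- rz$pos; d <- rz$d
      d <- jitter_dir(d, p$tortuosity, p$z_flatten)
      cur <- add_node(cur, pos, p$fine_radius)
    }
  }

  # iterative DFS over growing tips to keep determinism independent of depth
  stack_ <- list()
  nprim <- if (length(p$n_primary) > 1) sample(p$n_primary, 1) else p$n_primary
  az0 <- stats::runif(1, 0, 2 * pi)
  # stratified elevations: primaries jointly sample the slab depth, so no
  # cell degenerates to a planar arbor
  els <- p$z_flatten * (seq(-0.6, 0.6, length.out = nprim)[sample(nprim)] +
                          stats::rnorm(nprim, 0, 0.08))
  for (k in seq_len(nprim)) {
    az <- az0 + 2 * pi * (k - 1) / nprim + stats::rnorm(1, 0, 0.15)
    el <- els[k]
    d <- c(cos(az) * cos(el), sin(az) * cos(el), sin(el))
    start <- d * p$soma_radius * 0.8
    id <- add_node(root, start, order_radius(1))
    stack_[[length(stack_) + 1L]] <-
      list(node = id, pos = start, dir = d, order = 1L)
  }

  while (length(stack_) > 0 && nodes$id < max_nodes) {
    tip <- stack_[[length(stack_)]]
    stack_[[length(stack_)]] <- NULL
    seg <- max(0.6, stats::rnorm(1, p$segment_length_mean,
                                 p$segment_length_sd))
    nsteps <- max(1L, round(seg / p$step_length))
    pos <- tip$pos; d <- tip$dir; cur <- tip$node
    for (s in seq_len(nsteps)) {
      pos <- pos + d * (seg / nsteps)
      rz <- reflect_z(pos, d); pos <- rz$pos; d <- rz$d
      d <- jitter_dir(d, p$tortuosity, p$z_flatten)
      cur <- add_node(cur, pos, order_radius(tip$order))
    }
    if (stats::runif(1) < p$fine_process_rate)
      grow_fine(cur, pos, d)
    u <- stats::runif(1)
    p_bif <- p$bifurcation_prob[min(tip$order, length(p$bifurcation_prob))]
    p_ext <- p$extend_prob[min(tip$order, length(p$extend_prob))]
    # territorial confinement: continuation decays beyond reach_radius
    r_xy <- sqrt(pos[1]^2 + pos[2]^2)
    f <- exp(-max(0, r_xy - p$reach_radius) / p$reach_taper)
    p_bif <- p_bif * f
    p_ext <- p_ext * f
    can_bifurcate <- tip$order < p$max_order
    if (can_bifurcate && u < p_bif) {
      ang <- stats::runif(1, 0.4, 0.8)       # half-angle between daughters
      axis <- perp_dir(d, 1)
      for (sgn in c(-1, 1)) {
        dd <- d * cos(ang) + sgn * axis * sin(ang)
        dd <- dd / sqrt(sum(dd^2))
        stack_[[length(stack_) + 1L]] <-
          list(node = cur, pos = pos, dir = dd, order = tip$order + 1L)
      }
    } else if (u < p_bif * can_bifurcate + p_ext) {
      stack_[[length(stack_) + 1L]] <-
        list(node = cur, pos = pos, dir = d, order = tip$order)
    } # else: terminate
  }

  m <- do.call(rbind, nodes$rows[seq_len(nodes$id)])
  cell_trace(tibble::tibble(
    node_id = as.integer(m[, 1]), parent_id = as.integer(m[, 2]),
    x = m[, 3], y = m[, 4], z = m[, 5], radius = m[, 6]),
    cell_id = cell_id)
}

#' Generate a synthetic multi-cell field
#'
#' Places cells by a uniform spatial point process inside a field of
#' `field_size` micrometres and grows each with [generate_cell_trace()].
#' When a plaque is present, cell phenotype follows three concentric layers
#' around the plaque center: amoeboid cells (`plaque_L1`) within the inner
#' radius, cells with reduced complexity (`plaque_L2`) in the middle
#' annulus, and mildly de-ramified cells (`plaque_L3`) beyond. A second
#' (CD39-like) channel intensity is drawn per cell: high for L1/L2, a
#' normal/low mixture for L3, and the reference distribution for young and
#' aged fields.
#'
#' Each cell has its own RNG stream derived from the master seed and the
#' cell index, so adding a cell never perturbs existing cells.
#'
#' @param condition Field condition for non-plaque fields (`"young"` or
#'   `"aged"`); ignored inside plaque layers.
#' @param n_cells Fixed number of cells (`"fixed-n"` mode). If `NULL`, the
#'   count is `density` x field area / (100 um)^2, rounded.
#' @param density Cells per 100 x 100 um^2; must be positive. The default
#'   is calibrated so that young fields are near-contiguously covered by
#'   processes (grid means of a few um per 25 um^2 square, vacant area of
#'   a few percent).
#' @param field_size Numeric length 3, field extent (X, Y, Z) in um. The
#'   default leaves a border around the central 160 um grid window.
#' @param min_soma_distance Minimum distance between somata, um (placement
#'   by dart throwing; relaxed automatically if the field cannot hold the
#'   requested count).
#' @param plaque `NULL`, or a list with `center` (x, y in um; defaults to
#'   the field center) and `layer_radii` (defaults `c(40, 70, 140)` um).
#' @param params Named list of `gen_params` overrides per condition label,
#'   e.g. `list(young = gen_params("young", fine_process_rate = 0))`.
#' @param mfi_law Per-condition law for the channel-2 mean intensity; see
#'   Details in the package vignette. Override rarely.
#' @param margin Minimum soma distance from the x/y field borders, um.
#' @param seed Master integer seed.
#' @return A `scene_truth` object: `traces` (named list of `cell_trace` in
#'   field coordinates), `cells` (tibble with cell id, condition, layer,
#'   soma position and `mfi_ch2`), `plaque_center`, `field_size`,
#'   `condition`, `seed`.
#' @export
generate_field <- function(condition = c("young", "aged"), n_cells = NULL,
                           density = 12, field_size = c(200, 200, 20),
                           plaque = NULL, params = list(), mfi_law = NULL,
                           margin = 25, min_soma_distance = 20,
                           seed = 1L) {
  condition <- match.arg(condition)
  if (density <= 0) stop("density must be positive", call. = FALSE)
  stopifnot(length(field_size) == 3, all(field_size > 0))
  if (!is.null(plaque)) {
    plaque$center <- plaque$center %||% field_size[1:2] / 2
    plaque$layer_radii <- plaque$layer_radii %||% c(40, 70, 140)
    if (any(plaque$center < 0) || any(plaque$center > field_size[1:2]))
      stop("plaque center lies outside the field", call. = FALSE)
  }
  n <- n_cells %||% round(density * prod(field_size[1:2]) / 1e4)
  if (n < 1)
    stop("field too small for one cell at this density", call. = FALSE)
  if (any(field_size[1:2] <= 2 * margin))
    stop("field too small for one cell (margin exceeds field)",
         call. = FALSE)

  mfi_law <- mfi_law %||% default_mfi_law
  seed <- as.integer(seed)

  placements <- with_seed(seed, {
    xs <- numeric(n); ys <- numeric(n); zs <- numeric(n)
    sep <- min_soma_distance
    placed <- 0L
    tries <- 0L
    while (placed < n) {
      x <- stats::runif(1, margin, field_size[1] - margin)
      y <- stats::runif(1, margin, field_size[2] - margin)
      tries <- tries + 1L
      if (placed == 0L ||
          min((xs[seq_len(placed)] - x)^2 +
              (ys[seq_len(placed)] - y)^2) >= sep^2) {
        placed <- placed + 1L
        xs[placed] <- x; ys[placed] <- y
        # z drawn on acceptance so earlier cells are unaffected by later ones
        zs[placed] <- stats::runif(1, field_size[3] * 0.4,
                                   field_size[3] * 0.6)
        tries <- 0L
      } else if (tries > 200L) {
        sep <- sep * 0.8  # field too crowded for the requested spacing
        tries <- 0L
      }
    }
    tibble::tibble(x = xs, y = ys, z = zs)
  })

  cond_of <- function(x, y) {
    if (is.null(plaque)) return(condition)
    r <- sqrt(sum((c(x, y) - plaque$center)^2))
    if (r <= plaque$layer_radii[1]) "plaque_L1"
    else if (r <= plaque$layer_radii[2]) "plaque_L2"
    else "plaque_L3"
  }
  layer_of <- function(cond) switch(cond, plaque_L1 = 1L, plaque_L2 = 2L,
                                    plaque_L3 = 3L, NA_integer_)

  traces <- vector("list", n)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    ci <- cond_of(placements$x[i], placements$y[i])
    seed_i <- (seed %% 1000003L) * 1009L + 97L * i  # per-cell stream
    pp <- params[[ci]] %||% gen_params(ci)
    pp$seed <- seed_i
    id <- sprintf("cell_%03d", i)
    tr <- generate_cell_trace(pp, cell_id = id)
    tr$nodes$x <- tr$nodes$x + placements$x[i]
    tr$nodes$y <- tr$nodes$y + placements$y[i]
    tr$nodes$z <- tr$nodes$z + placements$z[i]
    # keep the trace inside the field (clamp the rare overshooting tip)
    tr$nodes$x <- pmin(pmax(tr$nodes$x, 0), field_size[1])
    tr$nodes$y <- pmin(pmax(tr$nodes$y, 0), field_size[2])
    tr$nodes$z <- pmin(pmax(tr$nodes$z, 0.25), field_size[3] - 0.25)
    mfi <- with_seed(seed_i + 7L, mfi_law(ci))
    traces[[i]] <- tr
    rows[[i]] <- tibble::tibble(
      cell_id = id, condition = ci, layer = layer_of(ci),
      soma_x = placements$x[i], soma_y = placements$y[i],
      soma_z = placements$z[i], mfi_ch2 = mfi)
  }
  names(traces) <- vapply(rows, function(r) r$cell_id, "")
  structure(list(
    traces = traces, cells = dplyr::bind_rows(rows),
    plaque_center = if (is.null(plaque)) NULL else plaque$center,
    layer_radii = if (is.null(plaque)) NULL else plaque$layer_radii,
    condition = if (is.null(plaque)) condition else "plaque",
    field_size = field_size, seed = seed),
    class = "scene_truth")
}

# CD39-like channel-2 mean intensity per condition (arbitrary units):
# reference distribution N(100, 15); plaque layers 1-2 high; layer 3 an
# even normal/low mixture.
default_mfi_law <- function(condition) {
  v <- switch(condition,
    young = stats::rnorm(1, 100, 15),
    aged = stats::rnorm(1, 100, 15),
    plaque_L1 = stats::rnorm(1, 190, 20),
    plaque_L2 = stats::rnorm(1, 170, 20),
    plaque_L3 = if (stats::runif(1) < 0.5) stats::rnorm(1, 100, 15)
                else stats::rnorm(1, 55, 10))
  max(v, 1)
}

#' @export
print.scene_truth <- function(x, ...) {
  cat("<scene_truth> ", nrow(x$cells), " cells, condition ", x$condition,
      ", field ", paste(x$field_size, collapse = " x "), " um\n", sep = "")
  invisible(x)
}
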