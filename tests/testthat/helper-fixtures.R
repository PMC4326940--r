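# Shared fixtures and independent oracles, built in code.

# straight polyline trace along x
make_path_trace <- function(n = 11, step = 1, y = 0, z = 0, radius = 0.5) {
  cell_trace(data.frame(
    node_id = seq_len(n), parent_id = c(-1L, seq_len(n - 1)),
    x = (seq_len(n) - 1) * step, y = y, z = z, radius = radius),
    cell_id = "path")
}

# Y trace: stem of length l0 along +x, daughters l1/l2 at +-45 degrees
make_y_trace <- function(l0 = 20, l1 = 20, l2 = 20, radius = 0.5,
                         step = 1, origin = c(0, 30, 10)) {
  n0 <- round(l0 / step); n1 <- round(l1 / step); n2 <- round(l2 / step)
  stem <- data.frame(node_id = 1:(n0 + 1), parent_id = c(-1L, 1:n0),
                     x = origin[1] + seq(0, l0, length.out = n0 + 1),
                     y = origin[2], z = origin[3])
  s <- sqrt(0.5)
  d1 <- data.frame(node_id = (n0 + 2):(n0 + 1 + n1),
                   parent_id = c(n0 + 1L, (n0 + 2):(n0 + n1)),
                   x = origin[1] + l0 + seq_len(n1) * step * s,
                   y = origin[2] + seq_len(n1) * step * s, z = origin[3])
  d2 <- data.frame(node_id = (n0 + n1 + 2):(n0 + n1 + 1 + n2),
                   parent_id = c(n0 + 1L, (n0 + n1 + 2):(n0 + n1 + n2)),
                   x = origin[1] + l0 + seq_len(n2) * step * s,
                   y = origin[2] - seq_len(n2) * step * s, z = origin[3])
  nd <- rbind(stem, d1, d2)
  nd$radius <- radius
  cell_trace(nd, cell_id = "Y")
}

# N-ray star skeleton mask centred in a square field
make_star_skeleton <- function(n_rays = 12, ray_length = 155,
                               pixel_size = 0.5, field_px = 641) {
  m <- matrix(FALSE, field_px, field_px)
  ctr <- field_px / 2 * pixel_size
  for (k in seq_len(n_rays) - 1) {
    a <- 2 * pi * k / n_rays
    t <- seq(0, ray_length, by = pixel_size / 2)
    i <- pmin(pmax(round((ctr + t * cos(a)) / pixel_size + 0.5), 1),
              field_px)
    j <- pmin(pmax(round((ctr + t * sin(a)) / pixel_size + 0.5), 1),
              field_px)
    m[cbind(i, j)] <- TRUE
  }
  list(skel = skeleton_mask(m, pixel_size), center = c(ctr, ctr))
}

# independent bifurcation oracle: explicit O(n^2) child counting
bf_bifurcations <- function(trace) {
  nd <- trace$nodes
  root <- nd$node_id[nd$parent_id == -1]
  total <- 0L
  for (id in nd$node_id) {
    if (id == root) next
    k <- 0L
    for (p in nd$parent_id) if (p == id) k <- k + 1L
    if (k >= 2) total <- total + (k - 1L)
  }
  total
}

# brute-force convex hull area: an edge (i, j) lies on the hull iff all
# other points fall on one side; orders hull edges and applies the
# shoelace formula. O(n^3).
bf_hull_area <- function(x, y) {
  pts <- unique(cbind(x, y))
  n <- nrow(pts)
  stopifnot(n >= 3)
  edges <- list()
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    cross <- (pts[j, 1] - pts[i, 1]) * (pts[, 2] - pts[i, 2]) -
             (pts[j, 2] - pts[i, 2]) * (pts[, 1] - pts[i, 1])
    cross <- cross[-c(i, j)]
    if (all(cross >= -1e-12) || all(cross <= 1e-12))
      edges[[length(edges) + 1]] <- c(i, j)
  }
  em <- do.call(rbind, edges)
  # walk edges into a cycle
  verts <- em[1, ]
  em <- em[-1, , drop = FALSE]
  while (nrow(em) > 0) {
    cur <- verts[length(verts)]
    hit <- which(em[, 1] == cur | em[, 2] == cur)[1]
    if (is.na(hit)) break
    nxt <- setdiff(em[hit, ], cur)
    em <- em[-hit, , drop = FALSE]
    if (nxt == verts[1]) break
    verts <- c(verts, nxt)
  }
  px <- pts[verts, 1]; py <- pts[verts, 2]
  k <- length(px)
  jj <- c(k, seq_len(k - 1))
  abs(sum(px[jj] * py - px * py[jj])) / 2
}

# analytic count of intersections between a circle and a set of segments
bf_circle_crossings <- function(segs, center, r) {
  total <- 0L
  for (k in seq_len(nrow(segs))) {
    p1 <- segs[k, 1:2] - center; p2 <- segs[k, 3:4] - center
    d <- p2 - p1
    a <- sum(d^2); b <- 2 * sum(p1 * d); cc <- sum(p1^2) - r^2
    disc <- b^2 - 4 * a * cc
    if (disc <= 0) next
    for (s in c(-1, 1)) {
      t <- (-b + s * sqrt(disc)) / (2 * a)
      if (t >= 0 && t <= 1) total <- total + 1L
    }
  }
  total
}

# radial segments around `ctr` with enforced angular separation, so each
# circle crossing is an isolated pixel component (the premise under which
# component counting and analytic intersection counting agree)
make_radial_segments <- function(n, ctr, r_in = c(5, 55),
                                 span = c(50, 100)) {
  base <- sample(seq_len(n)) # shuffled even spacing
  segs <- NULL
  for (k in seq_len(n)) {
    a <- 2 * pi * base[k] / n + runif(1, -0.05, 0.05)
    # keep endpoints >= 1.5 um away from the sampled radii (multiples of
    # 5 um): an endpoint sitting inside a one-pixel annulus is a genuine
    # half-crossing that analytic counting resolves by a knife edge
    r0 <- sample(seq(r_in[1], r_in[2], by = 5), 1) + runif(1, 1.5, 3.5)
    r1 <- r0 + sample(seq(span[1], span[2], by = 5), 1)
    jit <- runif(1, -0.04, 0.04)
    segs <- rbind(segs, c(ctr + r0 * c(cos(a), sin(a)),
                          ctr + r1 * c(cos(a + jit), sin(a + jit))))
  }
  segs
}

# rasterize segments (um coordinates) onto a skeleton mask
rasterize_segments <- function(segs, pixel_size, field_px) {
  m <- matrix(FALSE, field_px, field_px)
  for (k in seq_len(nrow(segs))) {
    len <- sqrt(sum((segs[k, 3:4] - segs[k, 1:2])^2))
    t <- seq(0, 1, length.out = max(2, ceiling(len / (pixel_size / 2))))
    xs <- segs[k, 1] + t * (segs[k, 3] - segs[k, 1])
    ys <- segs[k, 2] + t * (segs[k, 4] - segs[k, 2])
    i <- pmin(pmax(round(xs / pixel_size + 0.5), 1), field_px)
    j <- pmin(pmax(round(ys / pixel_size + 0.5), 1), field_px)
    m[cbind(i, j)] <- TRUE
  }
  skeleton_mask(m, pixel_size)
}

# per-cell morphometrics for a group of generated cells
gen_morpho_group <- function(condition, n, seed0, ...) {
  dplyr::bind_rows(lapply(seq_len(n), function(i) {
    p <- gen_params(condition, seed = seed0 + i, ...)
    morphometrics(generate_cell_trace(p, cell_id = sprintf("%s_%02d",
                                                           condition, i)))
  }))
}
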