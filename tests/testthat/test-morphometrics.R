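test_that("branch decomposition partitions the tree as expected", {
  # straight 3-node path of 10 um -> one branch of 10 um
  tr <- make_path_trace(n = 3, step = 5)
  br <- decompose_branches(tr)
  expect_equal(nrow(br), 1)
  expect_equal(br$length, 10)
  expect_equal(br$n_edges, 2)

  # Y: 5 um stem splitting into ~3 and ~4 um daughters -> 3 branches
  y <- make_y_trace(5, 3, 4)
  br <- decompose_branches(y)
  expect_equal(nrow(br), 3)
  expect_equal(sum(br$length), total_branch_length(y))
  expect_true(all(br$kept))

  # sub-threshold daughter is dropped from counts, kept in the total
  nd <- data.frame(node_id = 1:4, parent_id = c(-1L, 1L, 2L, 2L),
                   x = c(0, 5, 8, 5.2), y = c(0, 0, 0.6, 0.2),
                   z = c(0, 0.3, 0.8, 0.4))
  tr <- cell_trace(nd)
  br <- decompose_branches(tr, min_length = 0.5)
  expect_equal(nrow(br), 3)
  expect_equal(sum(br$kept), 2)
  m <- morphometrics(tr)
  expect_equal(m$n_branches, 2)
  expect_equal(m$total_branch_length, sum(br$length))
  expect_gt(m$total_branch_length, sum(br$length[br$kept]))

  # single-node trace -> zero branches, no error
  single <- cell_trace(data.frame(node_id = 1, parent_id = -1L,
                                  x = 0, y = 0, z = 0))
  expect_equal(nrow(decompose_branches(single)), 0)

  # every edge belongs to exactly one branch, on generated cells
  for (s in 1:5) {
    g <- generate_cell_trace(gen_params("young", seed = 400 + s))
    br <- decompose_branches(g)
    edge_count <- sum(br$n_edges)
    expect_equal(edge_count, nrow(g$nodes) - 1)
    expect_equal(sum(br$length), total_branch_length(g), tolerance = 1e-9)
  }
})

test_that("bifurcation counting matches a brute-force oracle", {
  expect_equal(count_bifurcations(make_path_trace(10)), 0)
  # full binary tree with 8 tips on one primary process -> 7
  nodes <- data.frame(node_id = 1L, parent_id = -1L, x = 0, y = 0, z = 0)
  nodes <- rbind(nodes, data.frame(node_id = 2L, parent_id = 1L,
                                   x = 1, y = 0, z = 0))
  nid <- 2L
  level <- list(2L)
  for (depth in 1:3) {
    nxt <- integer()
    for (p in level[[1]]) for (k in 1:2) {
      nid <- nid + 1L
      nodes <- rbind(nodes, data.frame(node_id = nid, parent_id = p,
                                       x = depth + stats::runif(1),
                                       y = stats::runif(1), z = 0))
      nxt <- c(nxt, nid)
    }
    level[[1]] <- nxt
  }
  tr <- cell_trace(nodes)
  expect_equal(count_bifurcations(tr), 7)
  expect_equal(bf_bifurcations(tr), 7)

  set.seed(42)
  for (s in 1:25) {
    g <- generate_cell_trace(gen_params(
      sample(c("young", "aged", "plaque_L2"), 1), seed = 800 + s))
    expect_equal(count_bifurcations(g), bf_bifurcations(g))
  }
})

test_that("total branch length is the Euclidean edge sum", {
  tr <- cell_trace(data.frame(node_id = 1:2, parent_id = c(-1L, 1L),
                              x = c(0, 3), y = c(0, 4), z = 0))
  expect_equal(total_branch_length(tr), 5)
  y <- make_y_trace(5, 3, 4)
  expect_equal(total_branch_length(y), 5 + 3 + 4, tolerance = 1e-9)
})

test_that("tree area equals the brute-force hull oracle", {
  sq <- cell_trace(data.frame(node_id = 1:5, parent_id = c(-1L, 1:4),
                              x = c(0, 10, 10, 0, 0),
                              y = c(0, 0, 10, 10, 5), z = 0))
  expect_equal(tree_area(sq), 100)

  line <- make_path_trace(5)
  expect_error(tree_area(line), "degenerate")
  expect_error(tree_area(cell_trace(data.frame(
    node_id = 1:2, parent_id = c(-1L, 1L), x = 0:1, y = 0, z = 0))),
    "degenerate")

  set.seed(7)
  for (k in 1:200) {
    n <- sample(5:15, 1)
    nd <- data.frame(node_id = seq_len(n), parent_id = c(-1L, seq_len(n - 1)),
                     x = stats::runif(n, 0, 50),
                     y = stats::runif(n, 0, 50), z = stats::runif(n, 0, 10))
    tr <- cell_trace(nd)
    expect_equal(tree_area(tr), bf_hull_area(nd$x, nd$y),
                 tolerance = 1e-9)
  }
})

test_that("coverage volume follows the definitional formula", {
  expect_equal(coverage_volume(100, 200, 5), 100)
  expect_error(coverage_volume(10, 0, 5), "zero")
  # independent-path recomputation on random generated cells
  for (s in 1:10) {
    g <- generate_cell_trace(gen_params("young", seed = 900 + s))
    m <- morphometrics(g)
    cv2 <- total_branch_length(g) /
      (bf_hull_area(g$nodes$x, g$nodes$y) * diff(range(g$nodes$z))) * 1000
    expect_equal(m$coverage_volume, cv2, tolerance = 1e-9)
    expect_equal(m$volume, m$tree_area * m$depth, tolerance = 1e-12)
  }
})

test_that("coverage volume scales as s^-2 under uniform spatial scaling", {
  g <- generate_cell_trace(gen_params("young", seed = 77))
  m0 <- morphometrics(g)
  for (s in c(0.5, 2, 4)) {
    gs <- g
    gs$nodes$x <- gs$nodes$x * s
    gs$nodes$y <- gs$nodes$y * s
    gs$nodes$z <- gs$nodes$z * s
    ms <- morphometrics(gs)
    expect_equal(ms$coverage_volume, m0$coverage_volume / s^2,
                 tolerance = 1e-12)
  }
})

test_that("branch-length histograms bin and conserve counts", {
  h <- branch_length_histogram(c(2.5, 2.5, 7.0), bin_width = 1)
  expect_equal(h$count[h$bin_left == 2], 2)
  expect_equal(h$count[h$bin_left == 7], 1)
  expect_equal(nrow(h), 2)
  expect_equal(nrow(branch_length_histogram(numeric(0))), 0)
  expect_error(branch_length_histogram(1:3, bin_width = 0), "positive")

  recs <- gen_morpho_group("young", 5, 600)
  h <- branch_length_histogram(recs, bin_width = 1)
  expect_equal(sum(h$count), sum(recs$n_branches))
})

test_that("thickness normalization scales extensive quantities only", {
  rec <- tibble::tibble(cell_id = "c", n_bifurcations = 10, n_branches = 20,
                        total_branch_length = 100, tree_area = 500,
                        depth = 40, volume = 20000, coverage_volume = 5,
                        normalized = FALSE, branch_lengths = list(rep(5, 20)))
  nr <- normalize_to_thickness(rec, 20)
  expect_equal(nr$total_branch_length, 50)
  expect_equal(nr$n_bifurcations, 5)
  expect_equal(nr$tree_area, 500)
  expect_true(nr$normalized)
  rec20 <- rec; rec20$depth <- 20
  expect_equal(normalize_to_thickness(rec20)$total_branch_length, 100)
  expect_error(normalize_to_thickness(dplyr::mutate(rec, depth = 0)),
               "zero depth")
  # coverage volume invariant under normalization
  recs <- gen_morpho_group("young", 20, 700)
  expect_equal(normalize_to_thickness(recs)$coverage_volume,
               recs$coverage_volume)
})

test_that("rigid motions preserve the morphometric panel", {
  g <- generate_cell_trace(gen_params("young", seed = 55))
  m0 <- morphometrics(g)
  th <- 0.7
  rot <- g
  x <- g$nodes$x; y <- g$nodes$y
  rot$nodes$x <- cos(th) * x - sin(th) * y + 12
  rot$nodes$y <- sin(th) * x + cos(th) * y - 5
  rot$nodes$z <- g$nodes$z + 3
  m1 <- morphometrics(rot)
  expect_equal(m1$total_branch_length, m0$total_branch_length,
               tolerance = 1e-9)
  expect_equal(m1$n_bifurcations, m0$n_bifurcations)
  expect_equal(m1$n_branches, m0$n_branches)
  expect_equal(m1$depth, m0$depth, tolerance = 1e-9)
  expect_equal(m1$tree_area, m0$tree_area, tolerance = 1e-6)
  # general 3-D rotation preserves total length
  a <- 0.5
  r3 <- g
  y2 <- g$nodes$y; z2 <- g$nodes$z
  r3$nodes$y <- cos(a) * y2 - sin(a) * z2
  r3$nodes$z <- sin(a) * y2 + cos(a) * z2
  expect_equal(total_branch_length(r3), m0$total_branch_length,
               tolerance = 1e-9)
})
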