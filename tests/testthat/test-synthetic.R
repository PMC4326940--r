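test_that("cell generation is deterministic in seed and parameters", {
  p <- gen_params("young", seed = 11)
  a <- generate_cell_trace(p)
  b <- generate_cell_trace(p)
  expect_identical(a$nodes, b$nodes)
  d <- generate_cell_trace(gen_params("young", seed = 12))
  expect_false(identical(a$nodes, d$nodes))
})

test_that("root out-degree equals the drawn primary-process count", {
  for (s in 1:10) {
    tr <- generate_cell_trace(gen_params("young", seed = s))
    root <- tr$nodes$node_id[tr$nodes$parent_id == -1]
    outdeg <- sum(tr$nodes$parent_id == root)
    expect_true(outdeg %in% 7:9)
  }
  tr <- generate_cell_trace(gen_params("young", n_primary = 5L, seed = 1))
  root <- tr$nodes$node_id[tr$nodes$parent_id == -1]
  expect_equal(sum(tr$nodes$parent_id == root), 5)
})

test_that("invalid generation parameters are rejected", {
  expect_error(gen_params("young", bifurcation_prob = 1.2), "\\[0, 1\\]")
  expect_error(gen_params("young", fine_process_rate = -0.1), "\\[0, 1\\]")
  expect_error(gen_params("young", segment_length_mean = 0), "positive")
  expect_error(gen_params("young", n_primary = 0), ">= 1")
  expect_error(gen_params("young", bifurcation_prob = 0.7,
                          extend_prob = 0.5), "exceed 1")
})

test_that("branch growth is monotone in fine-process rate and branching", {
  mean_L <- function(fine, bif, n = 200) {
    mean(vapply(seq_len(n), function(i) {
      p <- gen_params("young", fine_process_rate = fine,
                      bifurcation_prob = bif, seed = 5000 + i)
      total_branch_length(generate_cell_trace(p))
    }, 0))
  }
  expect_gt(mean_L(0.8, 0.4), mean_L(0.2, 0.4))
  expect_gt(mean_L(0.4, 0.5), mean_L(0.4, 0.25))
})

test_that("generated traces satisfy the structural invariants", {
  for (cond in c("young", "aged", "plaque_L1", "plaque_L2", "plaque_L3")) {
    tr <- generate_cell_trace(gen_params(cond, seed = 3))
    expect_silent(validate_trace(tr))
  }
})

test_that("field generation respects counts, bounds and plaque layers", {
  expect_error(generate_field("young", density = 0), "density")
  expect_error(generate_field("young", n_cells = 1,
                              field_size = c(30, 30, 10)),
               "too small")

  sc <- generate_field("young", n_cells = 50, seed = 2)
  expect_equal(nrow(sc$cells), 50)
  expect_length(sc$traces, 50)
  for (tr in sc$traces) {
    expect_true(all(tr$nodes$x >= 0 & tr$nodes$x <= sc$field_size[1]))
    expect_true(all(tr$nodes$y >= 0 & tr$nodes$y <= sc$field_size[2]))
    expect_true(all(tr$nodes$z >= 0 & tr$nodes$z <= sc$field_size[3]))
  }
  expect_false(anyDuplicated(sc$cells$cell_id) > 0)
  expect_true(all(sc$cells$mfi_ch2 >= 0))

  pf <- generate_field(n_cells = 30, field_size = c(300, 300, 20),
                       plaque = list(), seed = 4)
  d <- sqrt((pf$cells$soma_x - pf$plaque_center[1])^2 +
            (pf$cells$soma_y - pf$plaque_center[2])^2)
  expect_true(all(pf$cells$condition[d <= 40] == "plaque_L1"))
  expect_true(all(pf$cells$condition[d > 40 & d <= 70] == "plaque_L2"))
  expect_true(all(pf$cells$condition[d > 70] == "plaque_L3"))
  expect_equal(pf$cells$layer, c(1L, 2L, 3L)[match(
    pf$cells$condition, c("plaque_L1", "plaque_L2", "plaque_L3"))])
})

test_that("per-cell random streams: adding cells never perturbs earlier ones", {
  a <- generate_field("young", n_cells = 6, seed = 9)
  b <- generate_field("young", n_cells = 9, seed = 9)
  for (i in 1:6)
    expect_identical(a$traces[[i]]$nodes, b$traces[[i]]$nodes)
  expect_identical(a$cells$mfi_ch2, b$cells$mfi_ch2[1:6])
})

test_that("rendering is deterministic and confined to the trace tubes", {
  tr <- make_path_trace(n = 21, step = 1, y = 10, z = 5)
  r1 <- render_stack(tr, psf_sigma = 0, noise = NULL, channels = 1)
  r2 <- render_stack(tr, psf_sigma = 0, noise = NULL, channels = 1)
  expect_identical(r1$stacks$ch1$data, r2$stacks$ch1$data)
  # zero blur, zero noise: nonzero voxels exactly the truth tube
  expect_identical(r1$stacks$ch1$data > 0, r1$truth > 0)
  # containment: every truth voxel centre lies within the tube radius of
  # the (straight, axis-aligned) centreline
  dims <- dim(r1$truth)
  idx <- which(r1$truth > 0)
  co <- arrayInd(idx, dims)
  pos <- sweep(co - 0.5, 2, r1$stacks$ch1$voxel_size, `*`)
  ctr_y <- stats::median(pos[, 2]); ctr_z <- stats::median(pos[, 3])
  perp <- sqrt((pos[, 2] - ctr_y)^2 + (pos[, 3] - ctr_z)^2)
  expect_true(all(perp <= max(tr$nodes$radius) + 1e-9))

  sc <- generate_field("young", n_cells = 3, field_size = c(100, 100, 16),
                       seed = 5)
  ra <- render_stack(sc, voxel_size = c(0.5, 0.5, 0.5), seed = 7)
  rb <- render_stack(sc, voxel_size = c(0.5, 0.5, 0.5), seed = 7)
  expect_identical(ra$stacks$ch1$data, rb$stacks$ch1$data)
  expect_identical(ra$stacks$ch2$data, rb$stacks$ch2$data)
})

test_that("channel-2 intensity scales with the planted per-cell MFI", {
  tr <- make_path_trace(n = 31, step = 1, y = 10, z = 5)
  mean_ch2 <- function(mfi) {
    sc <- render_stack(tr, psf_sigma = 0, noise = NULL, channels = 1)
    scene <- structure(list(
      traces = stats::setNames(list(tr), tr$cell_id),
      cells = tibble::tibble(cell_id = tr$cell_id, condition = NA,
                             layer = NA, soma_x = NA, soma_y = NA,
                             soma_z = NA, mfi_ch2 = mfi),
      plaque_center = NULL, condition = "single",
      field_size = c(32, 22, 12), seed = 0L), class = "scene_truth")
    r <- render_stack(scene, psf_sigma = 0, noise = NULL, channels = 2)
    mean(r$stacks$ch2$data[r$truth > 0])
  }
  m1 <- mean_ch2(100)
  m2 <- mean_ch2(173)
  expect_equal(m2 / m1, 1.73, tolerance = 0.01)
})

test_that("rendering rejects impossible geometries", {
  sc <- generate_field("young", n_cells = 2, field_size = c(80, 80, 16),
                       margin = 20, seed = 1)
  expect_error(render_stack(sc, voxel_size = c(100, 0.5, 0.5)),
               "voxel size exceeds")
  expect_error(render_stack(sc, voxel_size = c(-1, 0.5, 0.5)), "positive")
})

test_that("a scene writes to disk and reads back consistently", {
  dir <- withr::local_tempdir()
  sc <- generate_field("young", n_cells = 2, field_size = c(80, 80, 14),
                       margin = 20, seed = 6)
  man <- write_scene(sc, dir, voxel_size = c(1, 1, 1), psf_sigma = 0,
                     noise = NULL)
  expect_true(file.exists(file.path(dir, "ch1.tif")))
  expect_true(file.exists(file.path(dir, "cells.csv")))
  expect_true(file.exists(file.path(dir, "manifest.json")))
  expect_length(list.files(dir, pattern = "\\.swc$"), 2)
  st <- read_stack(file.path(dir, "ch1.tif"), man$voxel_size,
                   scale = man$intensity_scale$ch1)
  rnd <- render_stack(sc, voxel_size = c(1, 1, 1), psf_sigma = 0,
                      noise = NULL)
  expect_equal(max(abs(st$data - rnd$stacks$ch1$data)) /
                 max(rnd$stacks$ch1$data) < 1e-3, TRUE)
  tr <- read_swc(file.path(dir, paste0(sc$cells$cell_id[1], ".swc")))
  expect_equal(tr$nodes$x, sc$traces[[1]]$nodes$x, tolerance = 1e-5)
})
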