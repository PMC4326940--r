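test_that("maximum z-projection equals the per-pixel loop oracle", {
  one <- image_stack(array(runif(100), c(10, 10, 1)), c(1, 1, 1))
  expect_equal(max_projection(one), one$data[, , 1],
               ignore_attr = TRUE)

  a <- array(0, c(6, 6, 2)); a[1, 1, 1] <- 5; a[4, 4, 2] <- 7
  pr <- max_projection(image_stack(a, c(1, 1, 1)))
  expect_equal(pr[1, 1], 5); expect_equal(pr[4, 4], 7)

  set.seed(3)
  arr <- array(runif(8 * 7 * 5), c(8, 7, 5))
  pr <- max_projection(image_stack(arr, c(1, 1, 1)))
  oracle <- matrix(0, 8, 7)
  for (i in 1:8) for (j in 1:7) oracle[i, j] <- max(arr[i, j, ])
  expect_equal(pr, oracle, ignore_attr = TRUE)
})

test_that("thresholding separates bimodal images and logs its threshold", {
  img <- matrix(10, 20, 20); img[5:10, 5:10] <- 200
  bw <- threshold_binarize(img, "otsu")
  expect_equal(bw, img == 200, ignore_attr = TRUE)
  expect_true(attr(bw, "threshold") > 10 && attr(bw, "threshold") <= 200)
  expect_error(threshold_binarize(img, 201), "outside intensity range")
  bw2 <- threshold_binarize(img, 100)
  expect_equal(attr(bw2, "threshold"), 100)
})

test_that("Otsu foreground covers the synthetic truth mask", {
  sc <- generate_field("young", n_cells = 4, field_size = c(120, 120, 16),
                       margin = 30, seed = 12)
  rnd <- render_stack(sc, voxel_size = c(0.5, 0.5, 0.5), psf_sigma = 0.25,
                      channels = 1, seed = 12)
  pr <- max_projection(rnd$stacks$ch1)
  truth2d <- max_projection(rnd$truth) > 0
  bw <- threshold_binarize(pr, "otsu")
  expect_gt(sum(bw & truth2d) / sum(truth2d), 0.95)
})

test_that("2-D skeletonization thins to one-pixel width", {
  m <- matrix(FALSE, 40, 60)
  m[18:22, 10:50] <- TRUE              # 5-px-wide bar, 41 px long
  sk <- skeletonize_mask(m, pixel_size = 1)
  # a symmetric ribbon collapses to a single-pixel line; thinning retracts
  # the flat end caps by up to half the ribbon width at each end
  expect_lte(sum(sk$pixels), 41 + 2)
  expect_gte(sum(sk$pixels), 41 - 5)
  # all rows collapse to (about) one pixel per column
  expect_true(all(colSums(sk$pixels[, 12:48]) <= 1 + 1e-9))

  empty <- skeletonize_mask(matrix(FALSE, 10, 10), pixel_size = 1)
  expect_equal(sum(empty$pixels), 0)

  set.seed(9)
  for (k in 1:20) {
    mm <- matrix(runif(900) < 0.3, 30, 30)
    sk <- skeletonize_mask(mm, pixel_size = 1)
    expect_lte(sum(sk$pixels), sum(mm))
  }
})

test_that("skeleton length weighs axial and diagonal steps correctly", {
  m <- matrix(FALSE, 15, 15); m[8, 3:13] <- TRUE
  expect_equal(skeleton_length(skeleton_mask(m, 0.5)), 10 * 0.5)
  d <- matrix(FALSE, 15, 15); d[cbind(3:13, 3:13)] <- TRUE
  expect_equal(skeleton_length(skeleton_mask(d, 0.5)),
               10 * sqrt(2) * 0.5, tolerance = 1e-12)
  iso <- matrix(FALSE, 5, 5); iso[3, 3] <- TRUE
  expect_equal(skeleton_length(skeleton_mask(iso, 0.5)), 0.5)

  # conservation over a partition of the image
  set.seed(21)
  mm <- matrix(runif(3600) < 0.2, 60, 60)
  sk <- skeleton_mask(mm, 0.5)
  total <- skeleton_length(sk)
  qsum <- 0
  for (qi in 0:1) for (qj in 0:1) {
    reg <- matrix(FALSE, 60, 60)
    reg[qi * 30 + 1:30, qj * 30 + 1:30] <- TRUE
    qsum <- qsum + skeleton_length(sk, region = reg)
  }
  expect_equal(qsum, total, tolerance = 1e-9)
})

test_that("grid analysis measures per-square lengths with conservation", {
  # horizontal line spanning the whole window through one row:
  # every square holds exactly 5 um, sum 160 um
  px <- 0.5; n_px <- 340                      # 170 um field, 160 um window
  m <- matrix(FALSE, n_px, n_px); m[, 170] <- TRUE
  gr <- grid_analysis(skeleton_mask(m, px))
  row_idx <- which(rowSums(gr$lengths) > 0)
  expect_equal(unname(gr$lengths[, which(colSums(gr$lengths) > 0)]),
               rep(5, 32), tolerance = 1e-9)
  expect_equal(gr$total_length, 160, tolerance = 1e-9)

  empty <- grid_analysis(skeleton_mask(matrix(FALSE, 400, 400), 0.5))
  expect_true(all(empty$lengths == 0))
  expect_equal(empty$vacant_percent, 100)
  expect_equal(empty$mean_length, 0)

  expect_error(grid_analysis(skeleton_mask(matrix(FALSE, 50, 50), 0.5)),
               "smaller than")

  # vacancy threshold: paper definition, < 1 um of process
  m2 <- matrix(FALSE, 340, 340)
  m2[171:173, 170] <- TRUE                    # one 1.0 um stub
  gr2 <- grid_analysis(skeleton_mask(m2, px))
  expect_equal(sum(gr2$lengths >= 1), 1)
  expect_equal(gr2$vacant_percent, 100 * 1023 / 1024)
})

test_that("grid lengths sum to the window skeleton length on random fields", {
  set.seed(5)
  for (k in 1:10) {
    mm <- matrix(runif(400 * 400) < runif(1, 0.02, 0.2), 400, 400)
    sk <- skeleton_mask(mm, 0.5)
    gr <- grid_analysis(sk)
    reg <- matrix(FALSE, 400, 400)
    o <- round(gr$window_origin / 0.5)
    reg[(o[1] + 1):(o[1] + 320), (o[2] + 1):(o[2] + 320)] <- TRUE
    expect_equal(gr$total_length, skeleton_length(sk, region = reg),
                 tolerance = 1e-6)
    expect_equal(sum(gr$lengths), gr$total_length, tolerance = 1e-9)
    expect_equal(sum(gr$histogram$count), length(gr$lengths))
  }
})

test_that("a 12-ray star yields 12 crossings at every radius, decaying 1/r", {
  star <- make_star_skeleton(12)
  sp <- sholl_profile(star$skel, star$center)
  expect_equal(sp$profile$radius, seq(40, 140, by = 5))
  expect_true(all(sp$profile$raw == 12))
  expect_equal(sp$profile$normalized[1], 12 / (2 * pi * 0.040),
               tolerance = 0.02)
  # exact 1/r decay of the normalized profile
  expect_equal(sp$profile$normalized * sp$profile$radius,
               rep(sp$profile$normalized[1] * 40,
                   nrow(sp$profile)), tolerance = 1e-9)
})

test_that("sholl handles empty fields, clipping and bad parameters", {
  sk <- skeleton_mask(matrix(FALSE, 100, 100), 1)
  sp <- sholl_profile(sk, c(50, 50))
  expect_true(all(sp$profile$raw == 0))
  expect_error(sholl_profile(sk, c(50, 50), r_min = 100, r_max = 50),
               "r_min")
  expect_error(sholl_profile(sk, c(50, 50), step = 0), "step")
  expect_error(sholl_profile(sk, c(500, 50)), "outside")
  # clipped circles: in-field arc fraction below 1 near the border
  star <- make_star_skeleton(6, field_px = 401)    # 200 um field
  sp2 <- sholl_profile(star$skel, star$center)
  expect_true(any(sp2$profile$arc_fraction < 1))
  sp3 <- sholl_profile(star$skel, star$center, clip = "full")
  expect_true(all(sp3$profile$normalized <= sp2$profile$normalized + 1e-9))
})

test_that("sholl raw counts match the analytic segment-circle oracle", {
  set.seed(17)
  ctr <- c(160, 160)
  segs <- make_radial_segments(14, ctr)
  sk <- rasterize_segments(segs, pixel_size = 0.5, field_px = 641)
  sp <- sholl_profile(sk, ctr)
  for (i in seq_len(nrow(sp$profile))) {
    expect_lte(abs(sp$profile$raw[i] -
                   bf_circle_crossings(segs, ctr, sp$profile$radius[i])), 1)
  }
})

test_that("density heat maps reflect local foreground density", {
  full <- density_heatmap(matrix(TRUE, 30, 30), 5, pixel_size = 1)
  expect_equal(range(full), c(1, 1), tolerance = 1e-9)
  empty <- density_heatmap(matrix(FALSE, 30, 30), 5, pixel_size = 1)
  expect_equal(range(empty), c(0, 0))
  set.seed(2)
  m <- matrix(runif(900) < 0.2, 30, 30)
  hm <- density_heatmap(m, 4, pixel_size = 1)
  expect_equal(sum(hm), sum(m), tolerance = 1e-6)  # mass conservation
  expect_true(all(hm >= 0 & hm <= 1))
})

test_that("the field pipeline orders conditions by coverage", {
  vac <- function(cond, fine, seed) {
    sc <- generate_field(cond, n_cells = 30, seed = seed,
                         params = stats::setNames(
                           list(gen_params(cond, fine_process_rate = fine,
                                           seed = 1)), cond))
    rnd <- render_stack(sc, voxel_size = c(0.5, 0.5, 0.5), psf_sigma = 0.3,
                        channels = 1, seed = seed)
    sk <- skeletonize_mask(threshold_binarize(max_projection(rnd$stacks$ch1)))
    grid_analysis(sk)$vacant_percent
  }
  # lowering fine-process production never decreases vacant area
  v_hi <- vac("young", 0.7, 31)
  v_lo <- vac("young", 0.1, 31)
  expect_gte(v_lo, v_hi)
})
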