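test_that("segmentation labels blobs and applies the area filter", {
  img <- matrix(5, 60, 60)
  img[10:20, 10:20] <- 200      # 121 px blob
  img[40:42, 40:42] <- 200      # 9 px blob
  seg <- segment_cells(img, threshold = 100, min_area = 20,
                       pixel_size = 1)
  expect_equal(nrow(seg$cells), 1)
  expect_equal(seg$cells$mask_area, 121)
  seg2 <- segment_cells(img, threshold = 100, min_area = 5,
                        pixel_size = 1)
  expect_equal(nrow(seg2$cells), 2)
  # nothing survives the area filter: empty result, not an error
  seg3 <- segment_cells(img, threshold = 100, min_area = 1e5,
                        pixel_size = 1)
  expect_equal(nrow(seg3$cells), 0)
})

test_that("per-cell MFI is the masked mean of channel 2", {
  img <- matrix(0, 30, 30); img[5:10, 5:10] <- 100
  seg <- segment_cells(img, threshold = 50, min_area = 1, pixel_size = 1)
  ch2 <- matrix(3.5, 30, 30)
  rec <- cell_mfi(seg, ch2)
  expect_equal(rec$mfi, 3.5)
  expect_equal(rec$mask_area, 36)
  expect_error(cell_mfi(seg, matrix(1, 10, 10)), "geometries differ")
  empty <- segment_cells(img, threshold = 50, min_area = 1e5,
                         pixel_size = 1)
  expect_equal(nrow(cell_mfi(empty, ch2)), 0)
})

test_that("synthetic fields segment one-to-one and preserve MFI order", {
  ok <- 0; total <- 0
  for (s in 1:3) {
    sc <- generate_field("young", n_cells = 8, field_size = c(300, 300, 20),
                         min_soma_distance = 70, margin = 35, seed = s)
    rnd <- render_stack(sc, voxel_size = c(0.5, 0.5, 0.5),
                        psf_sigma = 0.3, seed = s)
    seg <- segment_cells(rnd$stacks$ch1, min_area = 30)
    d2 <- outer(seg$cells$centroid_x, sc$cells$soma_x, "-")^2 +
          outer(seg$cells$centroid_y, sc$cells$soma_y, "-")^2
    ok <- ok + sum(sqrt(apply(d2, 1, min)) < 10)
    total <- total + nrow(sc$cells)
  }
  expect_gte(ok / total, 0.9)

  # zero noise: per-cell MFI rank order equals the planted order
  sc <- generate_field("young", n_cells = 8, field_size = c(300, 300, 20),
                       min_soma_distance = 70, margin = 35, seed = 9)
  rnd <- render_stack(sc, voxel_size = c(0.5, 0.5, 0.5), psf_sigma = 0.2,
                      noise = NULL, seed = 9)
  seg <- segment_cells(rnd$stacks$ch1, min_area = 30)
  mfi <- cell_mfi(seg, rnd$stacks$ch2)
  d2 <- outer(seg$cells$centroid_x, sc$cells$soma_x, "-")^2 +
        outer(seg$cells$centroid_y, sc$cells$soma_y, "-")^2
  planted <- sc$cells$mfi_ch2[apply(d2, 1, which.min)]
  expect_equal(order(mfi$mfi), order(planted))
})

test_that("reference-quantile classification behaves at its fixed points", {
  set.seed(31)
  ref <- rnorm(1000, 100, 15)
  rec <- tibble::tibble(cell_id = seq_along(ref), mfi = ref)
  cl <- classify_reference(rec, ref)
  expect_equal(cl$summary$percent[cl$summary$cd39_class == "low"], 5,
               tolerance = 2, ignore_attr = TRUE)
  expect_equal(cl$summary$percent[cl$summary$cd39_class == "high"], 5,
               tolerance = 2, ignore_attr = TRUE)
  expect_equal(sum(cl$summary$percent), 100)

  flat <- classify_reference(tibble::tibble(mfi = rep(7, 50)), rep(7, 50))
  expect_equal(flat$summary$percent[flat$summary$cd39_class == "pos"], 100)

  expect_error(classify_reference(rec, numeric(0)), "empty reference")
  expect_error(classify_reference(rec, ref, lower_q = 0.9, upper_q = 0.1),
               "lower_q")
})

test_that("classification is invariant to common affine rescaling", {
  set.seed(12)
  ref <- rnorm(400, 100, 15)
  test <- tibble::tibble(mfi = c(rnorm(80, 100, 15), rnorm(10, 175, 15),
                                 rnorm(10, 25, 15)))
  a <- classify_reference(test, ref)
  scaled <- test; scaled$mfi <- test$mfi * 3.7 + 12
  b <- classify_reference(scaled, ref * 3.7 + 12)
  expect_identical(a$cells$cd39_class, b$cells$cd39_class)
})

test_that("a planted low/pos/high mixture is recovered", {
  set.seed(101)
  ref <- rnorm(1000, 100, 15)
  n <- 500
  mfis <- c(rnorm(0.8 * n, 100, 15),
            rnorm(0.1 * n, 100 + 5 * 15, 15),
            rnorm(0.1 * n, 100 - 5 * 15, 15))
  cl <- classify_reference(tibble::tibble(mfi = mfis), ref,
                           lower_q = 0.01, upper_q = 0.99)
  pct <- cl$summary$percent
  names(pct) <- as.character(cl$summary$cd39_class)
  expect_lte(abs(pct[["high"]] - 10), 3)
  expect_lte(abs(pct[["low"]] - 10), 3)
  g <- glance(cl)
  expect_equal(g$pct_low + g$pct_pos + g$pct_high, 100)
})
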