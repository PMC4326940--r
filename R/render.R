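#' Image stack container
#'
#' A 3-D fluorescence z-stack with per-axis voxel sizes in micrometres.
#' Voxel `[i, j, k]` (1-based) has its center at `((i - 0.5) dx,
#' (j - 0.5) dy, (k - 0.5) dz)`, so physical coordinates are unambiguous on
#' anisotropic stacks.
#'
#' @param data Non-negative 3-D numeric array (x, y, z).
#' @param voxel_size Numeric length 3, micrometres per voxel along x, y, z.
#' @param channel Channel label.
#' @return An `image_stack`.
#' @export
image_stack <- function(data, voxel_size, channel = "ch1") {
  if (length(dim(data)) == 2) dim(data) <- c(dim(data), 1L)
  stopifnot(length(dim(data)) == 3, length(voxel_size) == 3)
  if (any(voxel_size <= 0)) stop("voxel sizes must be positive", call. = FALSE)
  if (any(dim(data) < 1)) stop("stack dimensions must be >= 1", call. = FALSE)
  if (min(data) < 0) stop("stack intensities must be non-negative",
                          call. = FALSE)
  structure(list(data = data, voxel_size = as.numeric(voxel_size),
                 channel = channel),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  cat("<image_stack> ", x$channel, ": ",
      paste(dim(x$data), collapse = " x "), " voxels @ ",
      paste(signif(x$voxel_size, 3), collapse = " x "), " um\n", sep = "")
  invisible(x)
}

#' Render a synthetic scene into noisy multi-channel z-stacks
#'
#' Rasterizes every trace edge as a capsule (tube) of its node radii into a
#' voxel grid, blurs with a separable Gaussian approximation of the PSF and
#' adds noise. Channel 1 carries the structural (GFP/IbaI-like) signal at a
#' fixed tube intensity; channel 2 scales each cell's tube intensity with
#' its planted `mfi_ch2`, emulating a CD39-like stain. A ground-truth
#' voxel-to-cell-id map (from the unblurred tubes) is returned alongside.
#'
#' @param scene A `scene_truth` from [generate_field()], or a single
#'   `cell_trace` (treated as a one-cell scene; bounds from the trace).
#' @param voxel_size Micrometres per voxel (dx, dy, dz). Default
#'   `c(0.25, 0.25, 0.5)`.
#' @param psf_sigma Gaussian PSF sigma in um (scalar, isotropic in xy and z;
#'   or length 3). `0` disables blurring.
#' @param noise `list(model = "gaussian", sd = ...)` with `sd` as a
#'   fraction of the channel-1 tube intensity, or
#'   `list(model = "poisson", gain = ...)`, or `NULL` for noise-free.
#' @param channels Which channels to render (subset of `1:2`).
#' @param tube_value Channel-1 tube intensity (arbitrary units).
#' @param seed Seed for the noise draw.
#' @return A list with `stacks` (named list of `image_stack`), `truth`
#'   (integer array of cell indices, 0 = background), and `cells` (the
#'   scene's cell table, or a minimal one for a bare trace).
#' @export
render_stack <- function(scene, voxel_size = c(0.25, 0.25, 0.5),
                         psf_sigma = 0.3,
                         noise = list(model = "gaussian", sd = 0.05),
                         channels = 1:2, tube_value = 200, seed = 1L) {
  if (inherits(scene, "cell_trace")) {
    pad <- max(scene$nodes$radius, 1, na.rm = TRUE) + 2
    shift <- c(min(scene$nodes$x), min(scene$nodes$y), min(scene$nodes$z)) -
      pad
    tr <- scene
    tr$nodes$x <- tr$nodes$x - shift[1]
    tr$nodes$y <- tr$nodes$y - shift[2]
    tr$nodes$z <- tr$nodes$z - shift[3]
    fs <- c(max(tr$nodes$x), max(tr$nodes$y), max(tr$nodes$z)) + pad
    scene <- structure(list(
      traces = stats::setNames(list(tr), tr$cell_id),
      cells = tibble::tibble(cell_id = tr$cell_id, condition = NA_character_,
                             layer = NA_integer_, soma_x = NA_real_,
                             soma_y = NA_real_, soma_z = NA_real_,
                             mfi_ch2 = 100),
      plaque_center = NULL, condition = "single", field_size = fs,
      seed = 0L), class = "scene_truth")
  }
  stopifnot(inherits(scene, "scene_truth"))
  if (any(voxel_size <= 0)) stop("voxel sizes must be positive",
                                 call. = FALSE)
  if (any(voxel_size > scene$field_size))
    stop("voxel size exceeds the field extent", call. = FALSE)
  if (length(psf_sigma) == 1) psf_sigma <- rep(psf_sigma, 3)
  dims <- as.integer(ceiling(scene$field_size / voxel_size))

  edge_matrix <- function(value_per_cell) {
    out <- vector("list", length(scene$traces))
    for (i in seq_along(scene$traces)) {
      tr <- scene$traces[[i]]
      nd <- tr$nodes
      ch <- nd[nd$parent_id != -1L, ]
      pi <- match(ch$parent_id, nd$node_id)
      r_child <- ifelse(is.na(ch$radius), 0.4, ch$radius)
      r_par <- ifelse(is.na(nd$radius[pi]), 0.4, nd$radius[pi])
      out[[i]] <- cbind(nd$x[pi], nd$y[pi], nd$z[pi], r_par,
                        ch$x, ch$y, ch$z, r_child,
                        value_per_cell[i], i)
    }
    do.call(rbind, out)
  }

  mfi <- scene$cells$mfi_ch2
  stacks <- list()
  truth <- NULL
  for (chn in channels) {
    val <- if (chn == 1) rep(tube_value, length(scene$traces)) else mfi
    ras <- rasterize_tubes_cpp(dims, edge_matrix(val), voxel_size)
    if (chn == 1) truth <- ras$labels
    img <- ras$intensity
    if (any(psf_sigma > 0))
      img <- gaussian_blur3d_cpp(img, dims, psf_sigma / voxel_size)
    if (!is.null(noise)) {
      img <- with_seed(seed + chn, {
        if (identical(noise$model, "gaussian")) {
          pmax(img + stats::rnorm(length(img), 0,
                                  noise$sd * tube_value), 0)
        } else if (identical(noise$model, "poisson")) {
          stats::rpois(length(img), img * noise$gain) / noise$gain
        } else stop("unknown noise model: ", noise$model, call. = FALSE)
      })
    }
    dim(img) <- dims
    stacks[[paste0("ch", chn)]] <-
      image_stack(img, voxel_size, paste0("ch", chn))
  }
  if (is.null(truth)) {
    ras <- rasterize_tubes_cpp(dims, edge_matrix(rep(tube_value,
                                                     length(scene$traces))),
                               voxel_size)
    truth <- ras$labels
  }
  list(stacks = stacks, truth = truth, cells = scene$cells,
       voxel_size = as.numeric(voxel_size))
}

#' Write / read a z-stack as multi-page TIFF
#'
#' Intensities are stored as 16-bit pages scaled by a factor recorded in
#' the returned object; [read_stack()] restores the original scale given
#' that factor.
#'
#' @param stack An `image_stack`.
#' @param path Output TIFF path.
#' @return For `write_stack`, the scale factor used, invisibly.
#' @export
write_stack <- function(stack, path) {
  mx <- max(stack$data, 1e-12)
  pages <- lapply(seq_len(dim(stack$data)[3]),
                  function(k) t(stack$data[, , k]) / mx)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(mx)
}

#' @rdname write_stack
#' @param voxel_size Voxel sizes (um) of the stored stack.
#' @param scale Intensity scale factor returned by [write_stack()].
#' @param channel Channel label.
#' @export
read_stack <- function(path, voxel_size, scale = 1, channel = "ch1") {
  pages <- tiff::readTIFF(path, all = TRUE)
  arr <- array(0, c(ncol(pages[[1]]), nrow(pages[[1]]), length(pages)))
  for (k in seq_along(pages)) arr[, , k] <- t(pages[[k]])
  image_stack(arr * scale, voxel_size, channel)
}

#' Write a full synthetic scene to disk
#'
#' Emits one multi-page TIFF per channel, one SWC file per cell, a CSV
#' truth table and a JSON manifest (field size, voxel size, seed, intensity
#' scales), so a rendered scene can be consumed like acquired data.
#'
#' @param scene A `scene_truth`.
#' @param dir Output directory (created if needed).
#' @param ... Passed to [render_stack()].
#' @return The manifest, invisibly.
#' @export
write_scene <- function(scene, dir, ...) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rnd <- render_stack(scene, ...)
  scales <- list()
  for (nm in names(rnd$stacks))
    scales[[nm]] <- write_stack(rnd$stacks[[nm]],
                                file.path(dir, paste0(nm, ".tif")))
  for (tr in scene$traces)
    write_swc(tr, file.path(dir, paste0(tr$cell_id, ".swc")))
  utils::write.csv(scene$cells, file.path(dir, "cells.csv"),
                   row.names = FALSE)
  manifest <- list(field_size = scene$field_size,
                   voxel_size = rnd$voxel_size,
                   condition = scene$condition,
                   plaque_center = scene$plaque_center,
                   seed = scene$seed, intensity_scale = scales)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
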