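#' Maximum z-projection
#'
#' Collapses a z-stack to 2-D by the per-pixel maximum across planes.
#'
#' @param stack An `image_stack` or a 3-D array.
#' @return A 2-D matrix with attribute `pixel_size` (um per pixel in-plane)
#'   when available from the stack.
#' @export
max_projection <- function(stack) {
  arr <- if (inherits(stack, "image_stack")) stack$data else stack
  if (length(dim(arr)) == 2) arr <- array(arr, c(dim(arr), 1))
  out <- arr[, , 1]
  nz <- dim(arr)[3]
  if (nz > 1) for (k in 2:nz) out <- pmax(out, arr[, , k])
  if (inherits(stack, "image_stack")) {
    if (abs(stack$voxel_size[1] - stack$voxel_size[2]) > 1e-9)
      warning("in-plane voxel sizes differ; using dx as pixel_size")
    attr(out, "pixel_size") <- stack$voxel_size[1]
  }
  out
}

#' Binarize an image by a global threshold
#'
#' Foreground = pixels at or above the threshold, chosen by Otsu's method
#' on a 256-level histogram or given as a fixed value. The applied
#' threshold is stored on the result so it is always reported with the
#' analysis.
#'
#' @param image 2-D numeric matrix.
#' @param method `"otsu"` or a fixed numeric threshold.
#' @return Logical matrix with attributes `threshold` and (if present on
#'   the input) `pixel_size`.
#' @export
threshold_binarize <- function(image, method = "otsu") {
  if (length(image) == 0) stop("empty image", call. = FALSE)
  rng <- range(image)
  if (is.numeric(method)) {
    if (method < rng[1] || method > rng[2])
      stop("fixed threshold ", method, " outside intensity range [",
           rng[1], ", ", rng[2], "]", call. = FALSE)
    thr <- method
  } else if (identical(method, "otsu")) {
    if (rng[2] == rng[1]) {
      thr <- rng[1]
    } else {
      norm <- (image - rng[1]) / (rng[2] - rng[1])
      thr <- EBImage::otsu(EBImage::Image(norm), range = c(0, 1),
                           levels = 256) * (rng[2] - rng[1]) + rng[1]
    }
  } else stop("unknown threshold method: ", method, call. = FALSE)
  out <- image >= thr
  attr(out, "threshold") <- thr
  attr(out, "pixel_size") <- attr(image, "pixel_size")
  out
}

#' Skeletonize a binary field mask
#'
#' Topology-preserving 2-D thinning (Zhang-Suen) of the thresholded
#' projection to a one-pixel-wide skeleton.
#'
#' @param mask Logical matrix.
#' @param pixel_size um per pixel (isotropic in-plane); taken from the mask
#'   attribute when omitted.
#' @return A `skeleton_mask`: list with `pixels` (logical matrix) and
#'   `pixel_size`.
#' @export
skeletonize_mask <- function(mask, pixel_size = attr(mask, "pixel_size")) {
  if (is.null(pixel_size)) stop("pixel_size required", call. = FALSE)
  if (pixel_size <= 0) stop("pixel_size must be positive", call. = FALSE)
  px <- thin2d_cpp(matrix(as.logical(mask), nrow(mask), ncol(mask)))
  structure(list(pixels = px, pixel_size = as.numeric(pixel_size)),
            class = "skeleton_mask")
}

#' Construct a skeleton mask directly
#'
#' For pre-skeletonized input (or programmatically drawn skeletons).
#'
#' @param pixels Logical matrix, one-pixel-wide skeleton.
#' @param pixel_size um per pixel.
#' @return A `skeleton_mask`.
#' @export
skeleton_mask <- function(pixels, pixel_size) {
  if (pixel_size <= 0) stop("pixel_size must be positive", call. = FALSE)
  structure(list(pixels = matrix(as.logical(pixels), nrow(pixels),
                                 ncol(pixels)),
                 pixel_size = as.numeric(pixel_size)),
            class = "skeleton_mask")
}

#' @export
print.skeleton_mask <- function(x, ...) {
  cat("<skeleton_mask> ", nrow(x$pixels), " x ", ncol(x$pixels),
      " px @ ", x$pixel_size, " um, ", sum(x$pixels),
      " skeleton pixels\n", sep = "")
  invisible(x)
}

# per-pixel length contributions: each 8-connected neighbour pair
# contributes half its step length (pixel_size axial, sqrt(2) pixel_size
# diagonal) to both pixels; isolated pixels contribute one pixel_size.
skeleton_length_field <- function(skel) {
  m <- skel$pixels
  p <- skel$pixel_size
  nr <- nrow(m); nc <- ncol(m)
  contrib <- matrix(0, nr, nc)
  pair_add <- function(a_idx, b_idx, w) {
    contrib[a_idx] <<- contrib[a_idx] + w / 2
    contrib[b_idx] <<- contrib[b_idx] + w / 2
  }
  if (nr > 1) { # vertical neighbours
    hit <- m[-nr, , drop = FALSE] & m[-1, , drop = FALSE]
    ij <- which(hit, arr.ind = TRUE)
    if (nrow(ij)) pair_add(cbind(ij[, 1], ij[, 2]),
                           cbind(ij[, 1] + 1, ij[, 2]), p)
  }
  if (nc > 1) { # horizontal
    hit <- m[, -nc, drop = FALSE] & m[, -1, drop = FALSE]
    ij <- which(hit, arr.ind = TRUE)
    if (nrow(ij)) pair_add(cbind(ij[, 1], ij[, 2]),
                           cbind(ij[, 1], ij[, 2] + 1), p)
  }
  if (nr > 1 && nc > 1) { # diagonals
    hit <- m[-nr, -nc, drop = FALSE] & m[-1, -1, drop = FALSE]
    ij <- which(hit, arr.ind = TRUE)
    if (nrow(ij)) pair_add(cbind(ij[, 1], ij[, 2]),
                           cbind(ij[, 1] + 1, ij[, 2] + 1), sqrt(2) * p)
    hit <- m[-1, -nc, drop = FALSE] & m[-nr, -1, drop = FALSE]
    ij <- which(hit, arr.ind = TRUE)
    if (nrow(ij)) pair_add(cbind(ij[, 1] + 1, ij[, 2]),
                           cbind(ij[, 1], ij[, 2] + 1), sqrt(2) * p)
  }
  # isolated pixels
  iso <- m & contrib == 0
  contrib[iso] <- p
  contrib
}

#' Skeleton path length
#'
#' Total process length represented by a skeleton, in um: each unordered
#' pair of 8-connected skeleton pixels contributes one step (`pixel_size`
#' for axial steps, `sqrt(2) * pixel_size` for diagonal steps) and isolated
#' pixels contribute one `pixel_size`. With a `region`, pairs straddling
#' the region boundary contribute half their step, so lengths over a
#' partition of the image sum exactly to the whole-image length.
#'
#' @param skel A `skeleton_mask`.
#' @param region Optional logical matrix selecting pixels.
#' @return Length in um.
#' @export
skeleton_length <- function(skel, region = NULL) {
  stopifnot(inherits(skel, "skeleton_mask"))
  contrib <- skeleton_length_field(skel)
  if (is.null(region)) sum(contrib) else sum(contrib[region])
}

#' Grid analysis of spatial coverage
#'
#' Overlays an `n x n` grid of squares of `square_area` um^2 (default 32 x
#' 32 squares of 25 um^2, i.e. 5 um side) on the central window of a
#' skeletonized projection and measures the process length in each square.
#' Neighbour steps crossing a square boundary are split half-half between
#' the two squares, so the per-square lengths sum exactly to the window's
#' skeleton length. Squares containing less than `vacant_below` um of
#' process count as vacant.
#'
#' @param skel A `skeleton_mask`.
#' @param n Grid dimension (squares per side).
#' @param square_area Square area in um^2.
#' @param vacant_below Vacancy threshold in um (default 1).
#' @param hist_bin Histogram bin width in um (default 1).
#' @return A `grid_result`: `lengths` (n x n matrix, um), `square_side`,
#'   `mean_length`, `vacant_percent`, `histogram` (tibble), `total_length`,
#'   `window_origin` (um), `pixel_size`.
#' @export
grid_analysis <- function(skel, n = 32, square_area = 25,
                          vacant_below = 1, hist_bin = 1) {
  stopifnot(inherits(skel, "skeleton_mask"))
  side <- sqrt(square_area)
  p <- skel$pixel_size
  img_um <- dim(skel$pixels) * p
  win <- n * side
  if (any(img_um < win - 1e-9))
    stop("field (", paste(signif(img_um, 4), collapse = " x "),
         " um) smaller than the ", n, " x ", n, " grid window (", win,
         " um)", call. = FALSE)
  origin <- (img_um - win) / 2
  contrib <- skeleton_length_field(skel)
  ij <- which(contrib > 0, arr.ind = TRUE)
  lengths <- matrix(0, n, n)
  if (nrow(ij)) {
    cx <- (ij[, 1] - 0.5) * p - origin[1]
    cy <- (ij[, 2] - 0.5) * p - origin[2]
    inside <- cx >= 0 & cx < win & cy >= 0 & cy < win
    gi <- pmin(floor(cx[inside] / side), n - 1) + 1
    gj <- pmin(floor(cy[inside] / side), n - 1) + 1
    vals <- contrib[ij][inside]
    if (length(vals)) {
      acc <- rowsum(vals, group = gi + (gj - 1) * n)
      lengths[as.integer(rownames(acc))] <- acc[, 1]
    }
  }
  lv <- as.vector(lengths)
  hist <- branch_length_histogram(lv, bin_width = hist_bin)
  structure(list(
    lengths = lengths, square_side = side,
    mean_length = mean(lv),
    vacant_percent = 100 * mean(lv < vacant_below),
    histogram = hist, total_length = sum(lv),
    window_origin = origin, pixel_size = p),
    class = "grid_result")
}

#' @export
print.grid_result <- function(x, ...) {
  cat("<grid_result> ", nrow(x$lengths), " x ", ncol(x$lengths),
      " squares of ", x$square_side, " um; mean ",
      signif(x$mean_length, 4), " um/square; vacant ",
      signif(x$vacant_percent, 4), "%\n", sep = "")
  invisible(x)
}

#' Modified Sholl profile of a skeletonized field
#'
#' Counts intersections between skeletonized processes and concentric
#' circles around a center (an amyloid-plaque center, or an arbitrary cell
#' in control fields). On a discrete skeleton an intersection is one
#' 8-connected component of skeleton pixels inside a thin annulus of each
#' circle; the annulus half-width is 0.75 pixels, the smallest band a
#' digital 8-connected curve cannot step across (a diagonal step changes
#' the radial distance by at most `sqrt(2)/2` pixels). Counts are
#' normalized to the circle perimeter and
#' reported per millimetre of arc; when a circle is clipped by the image
#' border only the in-field arc fraction is used (set `clip = "full"` to
#' normalize by the full perimeter).
#'
#' @param skel A `skeleton_mask`.
#' @param center (x, y) in um; must lie in the field.
#' @param r_min,r_max,step Radii in um (defaults 40, 140, 5).
#' @param clip `"arc"` (default) or `"full"`.
#' @return A `sholl_profile` with `profile` tibble (`radius`, `raw`,
#'   `arc_fraction`, `normalized` in intersections per mm) and the call
#'   geometry.
#' @export
sholl_profile <- function(skel, center, r_min = 40, r_max = 140, step = 5,
                          clip = c("arc", "full")) {
  stopifnot(inherits(skel, "skeleton_mask"))
  clip <- match.arg(clip)
  if (r_min >= r_max) stop("r_min must be below r_max", call. = FALSE)
  if (step <= 0) stop("step must be positive", call. = FALSE)
  p <- skel$pixel_size
  img_um <- dim(skel$pixels) * p
  if (any(center < 0) || any(center > img_um))
    stop("center lies outside the field", call. = FALSE)
  radii <- seq(r_min, r_max, by = step)
  idx <- which(skel$pixels, arr.ind = TRUE)
  if (nrow(idx)) {
    px <- (idx[, 1] - 0.5) * p
    py <- (idx[, 2] - 0.5) * p
    dist <- sqrt((px - center[1])^2 + (py - center[2])^2)
  } else dist <- numeric()

  ang <- seq(0, 2 * pi, length.out = 721)[-721]
  rows <- lapply(radii, function(r) {
    in_ann <- dist >= r - 0.75 * p & dist < r + 0.75 * p
    raw <- if (!any(in_ann)) 0L else
      n_pixel_components(idx[in_ann, , drop = FALSE])
    fx <- center[1] + r * cos(ang)
    fy <- center[2] + r * sin(ang)
    frac <- mean(fx >= 0 & fx <= img_um[1] & fy >= 0 & fy <= img_um[2])
    use_frac <- if (clip == "arc") frac else 1
    arc_mm <- 2 * pi * r * use_frac / 1000
    tibble::tibble(radius = r, raw = raw, arc_fraction = frac,
                   normalized = if (arc_mm > 0) raw / arc_mm else NA_real_)
  })
  structure(list(profile = dplyr::bind_rows(rows), center = center,
                 pixel_size = p, clip = clip),
            class = "sholl_profile")
}

# number of 8-connected components among a set of pixel coordinates
n_pixel_components <- function(coords) {
  n <- nrow(coords)
  if (n <= 1) return(n)
  key <- paste(coords[, 1], coords[, 2])
  lookup <- stats::setNames(seq_len(n), key)
  from <- integer(); to <- integer()
  for (o in list(c(1, 0), c(0, 1), c(1, 1), c(1, -1))) {
    nkey <- paste(coords[, 1] + o[1], coords[, 2] + o[2])
    j <- lookup[nkey]
    hit <- !is.na(j)
    from <- c(from, which(hit)); to <- c(to, unname(j[hit]))
  }
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (length(from)) g <- igraph::add_edges(g, rbind(from, to))
  igraph::components(g)$no
}

#' @export
print.sholl_profile <- function(x, ...) {
  cat("<sholl_profile> center (", paste(signif(x$center, 4),
                                        collapse = ", "),
      ") um, radii ", min(x$profile$radius), "-", max(x$profile$radius),
      " um; mean ", signif(mean(x$profile$normalized, na.rm = TRUE), 4),
      " crossings/mm\n", sep = "")
  invisible(x)
}

#' Process-density heat map
#'
#' Local foreground density of a mask or skeleton by disk-kernel
#' convolution; values in [0, 1]. A visualization aid for spotting regions
#' vacant of microglial processes.
#'
#' @param mask Logical matrix or `skeleton_mask`.
#' @param kernel_radius Disk radius in um.
#' @param pixel_size um per pixel (taken from a `skeleton_mask`
#'   automatically).
#' @return Numeric matrix in [0, 1].
#' @export
density_heatmap <- function(mask, kernel_radius = 10,
                            pixel_size = attr(mask, "pixel_size")) {
  if (inherits(mask, "skeleton_mask")) {
    pixel_size <- mask$pixel_size
    mask <- mask$pixels
  }
  if (is.null(pixel_size)) stop("pixel_size required", call. = FALSE)
  rp <- max(1, round(kernel_radius / pixel_size))
  size <- 2 * rp + 1
  br <- EBImage::makeBrush(size, shape = "disc")
  br <- br / sum(br)
  out <- EBImage::filter2(EBImage::Image(mask * 1), br,
                          boundary = "circular")
  m <- pmin(pmax(EBImage::imageData(out), 0), 1)
  matrix(m, nrow(mask), ncol(mask))
}
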