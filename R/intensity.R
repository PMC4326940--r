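#' Segment IbaI-positive cells in the structural channel
#'
#' Thresholds the maximum z-projection of channel 1, labels connected
#' foreground components and discards components below `min_area`. To keep
#' thin diagonal processes attached to their cell, labelling runs on a
#' one-pixel dilation of the mask and labels are then restricted to the
#' original foreground.
#'
#' @param stack Channel-1 `image_stack`, or an already-projected matrix
#'   (then give `pixel_size`).
#' @param threshold `"otsu"` or a fixed numeric threshold.
#' @param min_area Minimum cell area in um^2.
#' @param pixel_size um per pixel when `stack` is a matrix.
#' @return A `cell_segmentation`: `labels` (integer matrix, 0 background),
#'   `cells` (tibble: `cell_id`, `n_px`, `mask_area` um^2, `centroid_x`,
#'   `centroid_y` um), `threshold`, `pixel_size`. An empty foreground
#'   yields zero cells, not an error.
#' @export
segment_cells <- function(stack, threshold = "otsu", min_area = 30,
                          pixel_size = NULL) {
  proj <- if (inherits(stack, "image_stack")) max_projection(stack)
          else stack
  pixel_size <- pixel_size %||% attr(proj, "pixel_size")
  if (is.null(pixel_size)) stop("pixel_size required", call. = FALSE)
  mask <- threshold_binarize(proj, threshold)
  thr <- attr(mask, "threshold")
  empty <- structure(list(
    labels = matrix(0L, nrow(proj), ncol(proj)),
    cells = tibble::tibble(cell_id = integer(), n_px = integer(),
                           mask_area = double(), centroid_x = double(),
                           centroid_y = double()),
    threshold = thr, pixel_size = pixel_size),
    class = "cell_segmentation")
  if (!any(mask)) return(empty)

  kern <- EBImage::makeBrush(3, shape = "box")
  fat <- EBImage::dilate(EBImage::Image(mask * 1), kern)
  lab <- EBImage::bwlabel(fat)
  lab <- EBImage::imageData(lab) * mask          # restrict to foreground
  lab <- matrix(as.integer(lab), nrow(proj), ncol(proj))

  px_area <- pixel_size^2
  ids <- sort(unique(lab[lab > 0]))
  counts <- tabulate(lab, nbins = max(ids))
  keep <- ids[counts[ids] * px_area >= min_area]
  if (length(keep) == 0) return(empty)
  relab <- integer(max(ids))
  relab[keep] <- seq_along(keep)
  lab[lab > 0] <- relab[lab[lab > 0]]

  ij <- which(lab > 0, arr.ind = TRUE)
  l <- lab[ij]
  cells <- tibble::tibble(
    cell_id = seq_along(keep),
    n_px = tabulate(l, nbins = length(keep)),
    centroid_x = as.vector(rowsum((ij[, 1] - 0.5) * pixel_size, l)) /
      tabulate(l, nbins = length(keep)),
    centroid_y = as.vector(rowsum((ij[, 2] - 0.5) * pixel_size, l)) /
      tabulate(l, nbins = length(keep)))
  cells$mask_area <- cells$n_px * px_area
  structure(list(labels = lab,
                 cells = cells[, c("cell_id", "n_px", "mask_area",
                                   "centroid_x", "centroid_y")],
                 threshold = thr, pixel_size = pixel_size),
            class = "cell_segmentation")
}

#' @export
print.cell_segmentation <- function(x, ...) {
  cat("<cell_segmentation> ", nrow(x$cells), " cells (threshold ",
      signif(x$threshold, 4), ")\n", sep = "")
  invisible(x)
}

#' Per-cell mean fluorescence intensity in a second channel
#'
#' Mean of the channel-2 maximum z-projection over each segmented cell's
#' channel-1 mask — the per-cell CD39-like MFI.
#'
#' @param seg A `cell_segmentation` from [segment_cells()].
#' @param stack2 Channel-2 `image_stack` or projected matrix with the same
#'   in-plane geometry as the segmentation.
#' @return A tibble: `cell_id`, `mask_area` (um^2), `mfi`.
#' @export
cell_mfi <- function(seg, stack2) {
  stopifnot(inherits(seg, "cell_segmentation"))
  proj2 <- if (inherits(stack2, "image_stack")) max_projection(stack2)
           else stack2
  if (!all(dim(proj2) == dim(seg$labels)))
    stop("channel geometries differ: segmentation is ",
         paste(dim(seg$labels), collapse = " x "), ", channel 2 is ",
         paste(dim(proj2), collapse = " x "), call. = FALSE)
  if (nrow(seg$cells) == 0)
    return(tibble::tibble(cell_id = integer(), mask_area = double(),
                          mfi = double()))
  l <- seg$labels[seg$labels > 0]
  v <- proj2[seg$labels > 0]
  sums <- rowsum(v, l)
  ids <- as.integer(rownames(sums))
  tibble::tibble(cell_id = ids,
                 mask_area = seg$cells$mask_area[match(ids,
                                                       seg$cells$cell_id)],
                 mfi = unname(sums[, 1]) / tabulate(l)[ids])
}

#' Classify cells by MFI against a reference distribution
#'
#' Lower and upper MFI thresholds are set as quantiles of a reference
#' group's MFI distribution (by default the 5th and 95th percentiles,
#' standing in for thresholds drawn on a young wild-type group); cells
#' below the lower threshold are `low`, above the upper `high`, and `pos`
#' in between.
#'
#' @param records Tibble with an `mfi` column (e.g. from [cell_mfi()]).
#' @param reference_mfis Numeric vector of reference-group MFIs.
#' @param lower_q,upper_q Reference quantiles defining the thresholds.
#' @return A `cd39_classification`: `cells` (records plus `cd39_class`),
#'   `summary` (tibble of class counts and percentages summing to 100),
#'   `thresholds` (named numeric).
#' @export
classify_reference <- function(records, reference_mfis,
                               lower_q = 0.05, upper_q = 0.95) {
  if (length(reference_mfis) == 0)
    stop("empty reference distribution", call. = FALSE)
  if (!(lower_q > 0 && lower_q < upper_q && upper_q < 1))
    stop("require 0 < lower_q < upper_q < 1", call. = FALSE)
  thr <- stats::quantile(reference_mfis, c(lower_q, upper_q), names = FALSE)
  cls <- dplyr::case_when(records$mfi < thr[1] ~ "low",
                          records$mfi > thr[2] ~ "high",
                          TRUE ~ "pos")
  records$cd39_class <- factor(cls, levels = c("low", "pos", "high"))
  counts <- as.integer(table(records$cd39_class))
  smry <- tibble::tibble(
    cd39_class = factor(c("low", "pos", "high"),
                        levels = c("low", "pos", "high")),
    n = counts,
    percent = 100 * counts / nrow(records))
  structure(list(cells = records, summary = smry,
                 thresholds = c(lower = thr[1], upper = thr[2]),
                 quantiles = c(lower_q = lower_q, upper_q = upper_q)),
            class = "cd39_classification")
}

#' @export
print.cd39_classification <- function(x, ...) {
  cat("<cd39_classification> thresholds [",
      paste(signif(x$thresholds, 4), collapse = ", "), "]\n", sep = "")
  print(x$summary)
  invisible(x)
}
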