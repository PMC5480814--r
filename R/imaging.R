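# Nucleolar morphometry from fluorescence images.  Operator chain:
# maximum-intensity projection -> rolling-ball background subtraction
# (morphological white top-hat with a disc of the stated radius) ->
# Gaussian smoothing -> binary mask at a fraction of the maximum
# processed intensity -> connected-component labeling -> per-region
# areas.  The threshold is relative to the processed maximum, so the
# segmentation is invariant to rescaling the intensities.

#' Read a TIFF image or stack
#'
#' @param path TIFF file; multi-page files are returned as a 3-D array
#'   with planes in the third dimension.
#' @return numeric matrix or array.
#' @export
read_image_stack <- function(path) {
  planes <- tiff::readTIFF(path, all = TRUE)
  if (length(planes) == 1) return(planes[[1]])
  simplify2array(planes)
}

#' Maximum-intensity projection of a stack
#'
#' @param stack matrix (returned unchanged) or 3-D array.
#' @return matrix of per-pixel maxima across planes.
#' @export
max_project <- function(stack) {
  if (is.matrix(stack)) return(stack)
  stopifnot(length(dim(stack)) == 3)
  apply(stack, c(1, 2), max)
}

#' Segment and measure nucleolar regions
#'
#' Applies the morphometry operator chain to a fluorescence image or
#' stack and measures each resulting distinct spot as one nucleolar
#' region.  An all-zero image yields an empty table (the mask is empty
#' when the processed maximum is 0), not an error.
#'
#' @param stack numeric matrix, 3-D array, or TIFF path.
#' @param rolling_ball_radius radius (pixels) of the background
#'   structuring element.
#' @param blur_sigma Gaussian smoothing standard deviation (pixels).
#' @param threshold_fraction mask threshold as a fraction of the
#'   maximum processed intensity.
#' @param min_area drop regions smaller than this many pixels
#'   (default 0: keep all).
#' @param pixel_area_um2 optional area of one pixel in square microns;
#'   adds a calibrated `area_um2` column.
#' @return a `region_table` list: `regions` (data frame with `region`,
#'   `area_px`, centroid columns), `n_regions`, `mean_area_px`.
#' @export
quantify_nucleoli <- function(stack, rolling_ball_radius = 5,
                              blur_sigma = 2, threshold_fraction = 0.25,
                              min_area = 0, pixel_area_um2 = NULL) {
  stopifnot(rolling_ball_radius > 0, blur_sigma > 0,
            threshold_fraction > 0)
  if (is.character(stack)) stack <- read_image_stack(stack)
  img <- max_project(stack)
  stopifnot(length(img) > 0, all(is.finite(img)))

  empty <- data.frame(region = integer(), area_px = numeric(),
                      centroid_x = numeric(), centroid_y = numeric())
  empty_table <- structure(list(regions = empty, n_regions = 0L,
                                mean_area_px = NA_real_),
                           class = "region_table")
  if (max(img) <= 0) return(empty_table)

  # fluorescence units are arbitrary: work on the 8-bit-equivalent
  # relative scale the ball-radius convention assumes.  This also
  # makes the segmentation invariant to intensity rescaling.
  img <- img / max(img) * 255
  proc <- img - rolling_ball_background(img, rolling_ball_radius)
  proc <- EBImage::imageData(EBImage::gblur(EBImage::Image(proc),
                                            sigma = blur_sigma))

  mx <- max(proc)
  if (mx <= 0) return(empty_table)
  mask <- proc >= threshold_fraction * mx
  labels <- label_components8(mask)
  n <- max(labels)
  if (n == 0) {
    return(structure(list(regions = empty, n_regions = 0L,
                          mean_area_px = NA_real_),
                     class = "region_table"))
  }
  area <- tabulate(labels[labels > 0], nbins = n)
  cx <- vapply(seq_len(n), function(k) mean(row(labels)[labels == k]),
               numeric(1))
  cy <- vapply(seq_len(n), function(k) mean(col(labels)[labels == k]),
               numeric(1))
  regions <- data.frame(region = seq_len(n), area_px = area,
                        centroid_x = cx, centroid_y = cy)
  regions <- regions[regions$area_px >= min_area, , drop = FALSE]
  regions$region <- seq_len(nrow(regions))
  if (!is.null(pixel_area_um2)) {
    regions$area_um2 <- regions$area_px * pixel_area_um2
  }
  rownames(regions) <- NULL
  structure(list(regions = regions, n_regions = nrow(regions),
                 mean_area_px = if (nrow(regions)) mean(regions$area_px)
                 else NA_real_),
            class = "region_table")
}

# offsets and heights of a spherical (ball) structuring function:
# height sqrt(r^2 - dx^2 - dy^2) over the disc of radius r
ball_element <- function(radius) {
  r <- as.integer(ceiling(radius))
  g <- expand.grid(dx = -r:r, dy = -r:r)
  g <- g[g$dx^2 + g$dy^2 <= radius^2, , drop = FALSE]
  list(offsets = as.matrix(g[, c("dx", "dy")]),
       height = sqrt(radius^2 - g$dx^2 - g$dy^2))
}

# grayscale erosion/dilation with a structuring function, computed as
# a running min/max over shifted copies; pixels outside the image are
# ignored (equivalent to +/-Inf padding)
gray_morph <- function(img, offsets, height, fun, init) {
  nr <- nrow(img); nc <- ncol(img)
  out <- matrix(init, nr, nc)
  sgn <- if (identical(fun, pmin)) -1 else 1
  for (k in seq_len(nrow(offsets))) {
    dx <- offsets[k, 1]; dy <- offsets[k, 2]
    xs <- max(1, 1 - dx):min(nr, nr - dx)
    ys <- max(1, 1 - dy):min(nc, nc - dy)
    out[xs, ys] <- fun(out[xs, ys], img[xs + dx, ys + dy] + sgn * height[k])
  }
  out
}

#' Rolling-ball background of a grayscale image
#'
#' Rolls a ball of the given radius beneath the intensity landscape
#' (intensity and pixel units commensurate); at each position the
#' ball's apex gives the background estimate, i.e.
#' `erode(img, ball) + radius` with a spherical structuring function.
#' Subtracting it from the image gives the background-corrected
#' signal.  Intensities should be on the 8-bit gray-level scale the
#' radius convention assumes (see [quantify_nucleoli()], which
#' normalizes before calling this).
#'
#' @param img numeric matrix.
#' @param radius ball radius in pixels / gray levels.
#' @return background matrix of the same dimensions.
#' @export
rolling_ball_background <- function(img, radius) {
  ball <- ball_element(radius)
  gray_morph(img, ball$offsets, ball$height, pmin, Inf) + radius
}

# 8-connected component labeling: 4-connected pass (EBImage::bwlabel)
# followed by union-find merging of labels that touch diagonally,
# matching the ImageJ particle-analysis convention.
label_components8 <- function(mask) {
  lab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(mask * 1)))
  n <- max(lab)
  if (n <= 1) return(lab)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  nr <- nrow(lab); nc <- ncol(lab)
  for (shift in list(c(1, 1), c(1, -1))) {
    a <- lab[seq_len(nr - 1), , drop = FALSE]
    b <- lab[-1, , drop = FALSE]
    if (shift[2] == 1) {
      a <- a[, seq_len(nc - 1), drop = FALSE]; b <- b[, -1, drop = FALSE]
    } else {
      a <- a[, -1, drop = FALSE]; b <- b[, seq_len(nc - 1), drop = FALSE]
    }
    touch <- a > 0 & b > 0 & a != b
    if (any(touch)) {
      for (pair in unique(cbind(a[touch], b[touch]))[, , drop = FALSE] |>
             asplit(1)) {
        ra <- find(pair[1]); rb <- find(pair[2])
        if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
      }
    }
  }
  roots <- vapply(seq_len(n), find, numeric(1))
  relab <- match(roots, sort(unique(roots)))
  out <- lab
  out[lab > 0] <- relab[lab[lab > 0]]
  out
}

#' @export
print.region_table <- function(x, ...) {
  cat(sprintf("region table: %d nucleolar regions, mean area %.1f px\n",
              x$n_regions, x$mean_area_px))
  invisible(x)
}

#' Area distributions and a two-group comparison of nucleolar regions
#'
#' Pools region areas per group, computes a fixed-bin histogram
#' density for each, and compares the group mean areas with a
#' two-sided t test (two groups only).  Identical degenerate groups
#' report p = 1.
#'
#' @param tables list of `region_table` objects.
#' @param groups group label per table.
#' @param n_bins histogram bins over the pooled area range.
#' @return list with `density` (data frame: `group`, `mid`,
#'   `density`), `means` (named vector), `test` (a `test_result`, or
#'   `NULL` unless exactly 2 groups).
#' @export
area_distribution <- function(tables, groups, n_bins = 30) {
  stopifnot(length(tables) == length(groups))
  areas <- lapply(tables, function(tb) tb$regions$area_px)
  by_group <- lapply(unique(groups), function(g) {
    unlist(areas[groups == g], use.names = FALSE)
  })
  names(by_group) <- unique(groups)
  if (any(lengths(by_group) == 0)) stop("empty group: no regions")
  pooled <- unlist(by_group, use.names = FALSE)
  breaks <- seq(min(pooled), max(pooled), length.out = n_bins + 1)
  if (min(pooled) == max(pooled)) breaks <- min(pooled) + c(-0.5, 0.5)
  dens <- do.call(rbind, lapply(names(by_group), function(g) {
    h <- graphics::hist(by_group[[g]], breaks = breaks, plot = FALSE)
    data.frame(group = g, mid = h$mids, density = h$density)
  }))
  means <- vapply(by_group, mean, numeric(1))
  test <- NULL
  if (length(by_group) == 2) {
    a <- by_group[[1]]; b <- by_group[[2]]
    if (sd(c(a, b)) == 0) {
      test <- structure(list(statistic = 0, p_value = 1,
                             n = length(a) + length(b),
                             method = "two-sample t",
                             mean_delta = mean(a) - mean(b),
                             degenerate = TRUE),
                        class = "test_result")
    } else {
      ht <- t.test(a, b)
      test <- structure(list(statistic = unname(ht$statistic),
                             p_value = ht$p.value,
                             n = length(a) + length(b),
                             method = "two-sample t",
                             mean_delta = mean(a) - mean(b),
                             degenerate = FALSE),
                        class = "test_result")
    }
  }
  list(density = dens, means = means, test = test)
}
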