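#' One tip-to-base intensity trace
#'
#' @param intensities ADU values ordered tip to base, all in \[0, 65535\].
#' @param arc_positions arc distance from the tip in micrometres per sample,
#'   strictly increasing from 0.
#' @param pixel_size micrometres per pixel.
#' @param filopodium_id,channel identifiers.
#' @return an object of class \code{profile_record}.
#' @export
profile_record <- function(intensities, arc_positions, pixel_size,
                           filopodium_id = NA, channel = NA) {
  if (length(intensities) != length(arc_positions)) {
    stopf("intensities and arc_positions lengths differ")
  }
  if (length(intensities) < 2) stopf("a profile needs >= 2 samples")
  if (arc_positions[1] != 0 || is.unsorted(arc_positions, strictly = TRUE)) {
    stopf("arc_positions must increase strictly from 0")
  }
  if (any(intensities < 0 | intensities > 65535)) {
    stopf("intensities must lie in [0, 65535]")
  }
  structure(list(filopodium_id = filopodium_id, channel = channel,
                 intensities = as.numeric(intensities),
                 arc_positions = as.numeric(arc_positions),
                 pixel_size = pixel_size),
            class = "profile_record")
}

#' @export
print.profile_record <- function(x, ...) {
  cat(sprintf("Profile %s / %s: %d samples over %.2f um\n",
              x$filopodium_id, x$channel, length(x$intensities),
              max(x$arc_positions)))
  invisible(x)
}

#' Normalize an image to the brightest cellular structure
#'
#' Linear rescale of a 16-bit image so that the brightest pixel inside the
#' cell mask maps to 65535 and the background floor (the modal value outside
#' the mask) maps to 0, rounding and clipping to \[0, 65535\]. This reproduces
#' an automatic brightness/contrast adjustment that uses the brightest
#' cellular structure as the upper anchor, and makes fixed ADU thresholds
#' (such as the tip-positivity threshold of 5000) comparable across images.
#'
#' @param image numeric matrix in \[0, 65535\].
#' @param cell_mask logical matrix of the same shape, TRUE inside the cell.
#' @return integer matrix in \[0, 65535\].
#' @export
normalize_image <- function(image, cell_mask) {
  if (!all(dim(image) == dim(cell_mask))) {
    stopf("mask shape differs from image shape")
  }
  if (!any(cell_mask)) stopf("cell mask is empty")
  if (min(image) == max(image)) {
    stopf("undefined scale: the image is constant (%g)", image[1])
  }
  m <- max(image[cell_mask])
  outside <- image[!cell_mask]
  b <- if (length(outside)) {
    # modal background: most frequent rounded intensity outside the mask
    tab <- table(round(outside))
    as.numeric(names(tab)[which.max(tab)])
  } else {
    0
  }
  if (m <= b) stopf("undefined scale: in-mask maximum (%g) <= background (%g)", m, b)
  out <- clip16((image - b) * 65535 / (m - b))
  storage.mode(out) <- "integer"
  out
}

#' Extract a tip-to-base line intensity profile
#'
#' Samples the image along a tip-first polyline at approximately one-pixel
#' arc spacing using bilinear interpolation. Sample 0 sits exactly on the tip
#' vertex. With \code{width > 1}, each sample averages \code{width} bilinear
#' reads taken at one-pixel offsets perpendicular to the local segment
#' direction.
#'
#' @param image numeric matrix (16-bit scale).
#' @param polyline n x 2 matrix (columns x, y), 0-based pixel centres, tip
#'   first, total arc length >= 2 px.
#' @param pixel_size micrometres per pixel.
#' @param width odd integer line width in pixels.
#' @param filopodium_id,channel identifiers carried into the record.
#' @return a \code{\link{profile_record}}.
#' @export
extract_profile <- function(image, polyline, pixel_size, width = 1,
                            filopodium_id = NA, channel = NA) {
  polyline <- as.matrix(polyline)
  if (nrow(polyline) < 2) stopf("polyline needs >= 2 vertices")
  if (width < 1 || width %% 2 == 0) stopf("'width' must be an odd integer >= 1")
  seg <- diff(polyline)
  seg_len <- sqrt(rowSums(seg^2))
  if (any(seg_len == 0)) stopf("polyline has consecutive duplicate vertices")
  cum <- c(0, cumsum(seg_len))
  total <- cum[length(cum)]
  if (total < 2) stopf("polyline arc length is %.2f px; need >= 2 px", total)
  if (any(polyline[, 1] < 0) || any(polyline[, 2] < 0) ||
      any(polyline[, 1] > ncol(image) - 1) || any(polyline[, 2] > nrow(image) - 1)) {
    stopf("polyline extends outside the image")
  }
  n <- floor(total) + 1
  s <- seq(0, total, length.out = n)
  # locate each arc position on its segment
  idx <- pmin(findInterval(s, cum, rightmost.closed = TRUE), nrow(polyline) - 1)
  frac <- (s - cum[idx]) / seg_len[idx]
  pts_x <- polyline[idx, 1] + frac * seg[idx, 1]
  pts_y <- polyline[idx, 2] + frac * seg[idx, 2]
  if (width == 1) {
    vals <- bilinear(image, pts_x, pts_y)
  } else {
    ux <- seg[idx, 1] / seg_len[idx]
    uy <- seg[idx, 2] / seg_len[idx]
    offsets <- seq(-(width - 1) / 2, (width - 1) / 2)
    acc <- 0
    for (o in offsets) {
      acc <- acc + bilinear(image, pts_x - o * uy, pts_y + o * ux)
    }
    vals <- acc / width
  }
  profile_record(clip16(vals), s * pixel_size, pixel_size,
                 filopodium_id = filopodium_id, channel = channel)
}

#' Find local maxima by prominence (ImageJ Find-Maxima semantics)
#'
#' A local maximum is counted when it is impossible to reach a strictly
#' higher pixel from it without first descending by at least
#' \code{prominence} (the "noise tolerance"): starting from each candidate
#' maximum, the region of 8-connected pixels with value greater than
#' \code{value - prominence} is flooded; candidates whose region contains a
#' higher pixel, or an equal-valued candidate already accepted, are merged
#' away.
#'
#' @param image numeric matrix.
#' @param prominence minimum drop (ADU) separating two distinct maxima (> 0).
#' @return data.frame with 0-based \code{x}, \code{y} and \code{value} per
#'   accepted maximum.
#' @export
find_maxima <- function(image, prominence) {
  check_number(prominence, "prominence", lower = 0, strict = TRUE)
  h <- nrow(image)
  w <- ncol(image)
  # candidate maxima: pixels not smaller than any 8-neighbour
  is_max <- matrix(TRUE, h, w)
  shifts <- expand.grid(dy = -1:1, dx = -1:1)
  shifts <- shifts[!(shifts$dy == 0 & shifts$dx == 0), ]
  padded <- matrix(-Inf, h + 2, w + 2)
  padded[2:(h + 1), 2:(w + 1)] <- image
  for (k in seq_len(nrow(shifts))) {
    nb <- padded[2:(h + 1) + shifts$dy[k], 2:(w + 1) + shifts$dx[k]]
    is_max <- is_max & (image >= nb)
  }
  cand <- which(is_max)
  if (!length(cand)) {
    return(data.frame(x = integer(0), y = integer(0), value = numeric(0)))
  }
  cand <- cand[order(image[cand], decreasing = TRUE)]
  accepted <- integer(0)
  accepted_mark <- logical(h * w)  # pixels flooded by an accepted maximum
  visited <- logical(h * w)        # pixels flooded by any processed candidate
  nb_off <- (shifts$dx * h + shifts$dy)
  queue <- integer(h * w)
  for (c0 in cand) {
    # a candidate inside the flood of an equal-or-higher candidate merges away
    if (visited[c0]) next
    v <- image[c0]
    floor_v <- v - prominence
    seen <- logical(h * w)
    queue[1] <- c0
    qh <- 1L
    qt <- 1L
    seen[c0] <- TRUE
    keep <- TRUE
    while (qh <= qt) {
      p <- queue[qh]
      qh <- qh + 1L
      if (image[p] > v || accepted_mark[p]) {
        keep <- FALSE
        break
      }
      py <- (p - 1L) %% h + 1L
      px <- (p - 1L) %/% h + 1L
      for (k in seq_along(nb_off)) {
        ny <- py + shifts$dy[k]
        nx <- px + shifts$dx[k]
        if (ny < 1 || ny > h || nx < 1 || nx > w) next
        q <- p + nb_off[k]
        if (!seen[q] && image[q] > floor_v) {
          seen[q] <- TRUE
          qt <- qt + 1L
          queue[qt] <- q
        }
      }
    }
    visited <- visited | seen
    if (keep) {
      accepted <- c(accepted, c0)
      accepted_mark <- accepted_mark | seen
    }
  }
  data.frame(x = (accepted - 1) %/% h, y = (accepted - 1) %% h,
             value = image[accepted])
}

#' Build a cell mask from an F-actin image
#'
#' Threshold (Otsu by default), fill holes, and keep the largest connected
#' component(s).
#'
#' @param factin_image numeric matrix in \[0, 65535\].
#' @param threshold ADU threshold; \code{NULL} uses Otsu's method.
#' @param keep number of largest components to keep.
#' @return logical matrix, TRUE inside the cell.
#' @export
factin_cell_mask <- function(factin_image, threshold = NULL, keep = 1) {
  img01 <- factin_image / 65535
  if (is.null(threshold)) {
    threshold <- EBImage::otsu(EBImage::Image(img01), range = c(0, 1)) * 65535
  }
  bw <- EBImage::Image(factin_image > threshold)
  bw <- EBImage::fillHull(bw)
  lab <- EBImage::bwlabel(bw)
  labs <- as.integer(lab)
  sizes <- tabulate(labs[labs > 0])
  if (!length(sizes)) return(matrix(FALSE, nrow(factin_image), ncol(factin_image)))
  keep_ids <- order(sizes, decreasing = TRUE)[seq_len(min(keep, length(sizes)))]
  matrix(as.integer(lab) %in% keep_ids, nrow(factin_image), ncol(factin_image))
}

#' Estimate and subtract a smooth image background
#'
#' Grayscale morphological opening with a disc structuring element of the
#' given radius (the classical approximation of rolling-ball background
#' estimation); the opened image is subtracted and the result floored at 0.
#'
#' @param image numeric matrix.
#' @param radius disc radius in pixels.
#' @return background-subtracted matrix.
#' @export
subtract_background <- function(image, radius = 50) {
  check_number(radius, "radius", lower = 1)
  brush <- EBImage::makeBrush(2 * floor(radius) + 1, shape = "disc")
  bg <- EBImage::opening(EBImage::Image(image / 65535), brush)
  pmax(image - as.matrix(bg) * 65535, 0)
}

#' Count filopodial MYO10 spots outside the cell body
#'
#' Detects MYO10 maxima with \code{\link{find_maxima}} (after optional
#' background subtraction) and counts only those falling outside the
#' F-actin-derived cell mask, excluding intracellular MYO10 accumulations
#' from the filopodium count.
#'
#' @param myo10_image,factin_image numeric matrices of the same shape.
#' @param prominence Find-Maxima noise tolerance in ADU (> 0).
#' @param mask_threshold ADU threshold for the F-actin mask; \code{NULL} =
#'   Otsu.
#' @param background_radius rolling-ball-style radius in px, or \code{NULL}
#'   to skip background subtraction.
#' @return integer spot count, with the accepted maxima as attribute
#'   \code{"spots"}.
#' @export
count_myo10_spots <- function(myo10_image, factin_image, prominence,
                              mask_threshold = NULL, background_radius = NULL) {
  if (!all(dim(myo10_image) == dim(factin_image))) {
    stopf("images must have the same shape")
  }
  mask <- factin_cell_mask(factin_image, threshold = mask_threshold)
  if (!any(mask)) stopf("empty cell mask: no cell detected in the F-actin image")
  img <- myo10_image
  if (!is.null(background_radius)) {
    img <- subtract_background(img, background_radius)
  }
  mx <- find_maxima(img, prominence)
  outside <- !mask[cbind(mx$y + 1, mx$x + 1)]
  # drop background "maxima" of flat zero regions
  outside <- outside & mx$value > 0
  n <- sum(outside)
  attr(n, "spots") <- mx[outside, , drop = FALSE]
  n
}
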