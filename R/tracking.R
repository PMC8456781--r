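#' Detect fluorescent spots with a Laplacian-of-Gaussian filter
#'
#' The image is convolved with a scale-normalized inverted LoG kernel at
#' \eqn{\sigma = diameter / (2\sqrt{2})}, the scale at which the response of a
#' blob of the given diameter peaks. Local maxima of the response above
#' \code{quality_threshold} become detections; with \code{subpixel = TRUE}
#' each position is refined by a one-dimensional quadratic fit per axis
#' (offset clamped to half a pixel).
#'
#' The quality is the filter response in arbitrary units that scale with spot
#' intensity; the threshold is therefore a free parameter to calibrate per
#' dataset.
#'
#' @param image numeric matrix (one frame), 16-bit scale.
#' @param pixel_size micrometres per pixel.
#' @param diameter estimated spot diameter in micrometres (default 0.8).
#' @param quality_threshold minimum LoG response.
#' @param subpixel enable quadratic subpixel localization.
#' @return data.frame with \code{x_um}, \code{y_um}, \code{x_px}, \code{y_px}
#'   (0-based) and \code{quality}.
#' @export
detect_spots <- function(image, pixel_size, diameter = 0.8,
                         quality_threshold = 20, subpixel = TRUE) {
  check_number(pixel_size, "pixel_size", lower = 0, strict = TRUE)
  sigma_px <- diameter / (2 * sqrt(2)) / pixel_size
  if (diameter < pixel_size) {
    stopf("spot diameter (%.3g um) is below one pixel (%.3g um)",
          diameter, pixel_size)
  }
  r <- max(2, ceiling(4 * sigma_px))
  ax <- -r:r
  g2 <- outer(ax^2, ax^2, `+`)
  # inverted, scale-normalized LoG: positive response on bright blobs
  kern <- -(g2 - 2 * sigma_px^2) / sigma_px^2 * exp(-g2 / (2 * sigma_px^2))
  kern <- kern - mean(kern)  # zero-sum: flat background gives zero response
  resp <- as.matrix(EBImage::filter2(EBImage::Image(image), kern,
                                     boundary = "replicate"))
  h <- nrow(resp)
  w <- ncol(resp)
  padded <- matrix(-Inf, h + 2, w + 2)
  padded[2:(h + 1), 2:(w + 1)] <- resp
  is_max <- matrix(TRUE, h, w)
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0 && dx == 0) next
    nb <- padded[2:(h + 1) + dy, 2:(w + 1) + dx]
    # strict on earlier neighbours breaks plateau ties deterministically
    is_max <- is_max & if (dy < 0 || (dy == 0 && dx < 0)) resp > nb else resp >= nb
  }
  idx <- which(is_max & resp > quality_threshold)
  if (!length(idx)) {
    return(data.frame(x_um = numeric(0), y_um = numeric(0),
                      x_px = numeric(0), y_px = numeric(0),
                      quality = numeric(0)))
  }
  py <- (idx - 1) %% h + 1
  px <- (idx - 1) %/% h + 1
  x_px <- px - 1
  y_px <- py - 1
  if (subpixel) {
    ok_x <- px > 1 & px < w
    ok_y <- py > 1 & py < h
    dx <- rep(0, length(idx))
    dy <- rep(0, length(idx))
    den_x <- resp[cbind(py, pmax(px - 1, 1))] - 2 * resp[cbind(py, px)] +
      resp[cbind(py, pmin(px + 1, w))]
    den_y <- resp[cbind(pmax(py - 1, 1), px)] - 2 * resp[cbind(py, px)] +
      resp[cbind(pmin(py + 1, h), px)]
    num_x <- resp[cbind(py, pmax(px - 1, 1))] - resp[cbind(py, pmin(px + 1, w))]
    num_y <- resp[cbind(pmax(py - 1, 1), px)] - resp[cbind(pmin(py + 1, h), px)]
    dx[ok_x & den_x < 0] <- (0.5 * num_x / den_x)[ok_x & den_x < 0]
    dy[ok_y & den_y < 0] <- (0.5 * num_y / den_y)[ok_y & den_y < 0]
    x_px <- x_px + pmin(pmax(dx, -0.5), 0.5)
    y_px <- y_px + pmin(pmax(dy, -0.5), 0.5)
  }
  data.frame(x_um = x_px * pixel_size, y_um = y_px * pixel_size,
             x_px = x_px, y_px = y_px, quality = resp[idx])
}

#' Detect spots in every frame of a stack
#'
#' @param stack 3D array (y, x, frame) or list of matrices.
#' @param ... passed to \code{\link{detect_spots}}.
#' @inheritParams detect_spots
#' @return data.frame of detections with a \code{frame} column.
#' @export
detect_spots_stack <- function(stack, pixel_size, ...) {
  frames <- if (is.list(stack)) stack else
    lapply(seq_len(dim(stack)[3]), function(i) stack[, , i])
  out <- lapply(seq_along(frames), function(i) {
    d <- detect_spots(frames[[i]], pixel_size, ...)
    if (nrow(d)) d$frame <- i
    d
  })
  out <- out[vapply(out, nrow, integer(1)) > 0]
  if (!length(out)) {
    return(data.frame(x_um = numeric(0), y_um = numeric(0),
                      x_px = numeric(0), y_px = numeric(0),
                      quality = numeric(0), frame = integer(0)))
  }
  do.call(rbind, out)
}

# Minimum-total-distance one-to-one assignment between two point sets,
# restricted to pairs closer than `gate`. Maximum cardinality takes priority
# over total distance (the usual frame-to-frame LAP). Solved as a
# maximum-weight bipartite matching with weights C - d, C large.
assign_points <- function(ax, ay, bx, by, gate) {
  na <- length(ax)
  nb <- length(bx)
  if (na == 0 || nb == 0) return(rep(NA_integer_, na))
  d <- sqrt(outer(ax, bx, `-`)^2 + outer(ay, by, `-`)^2)
  edges <- which(d <= gate, arr.ind = TRUE)
  if (!nrow(edges)) return(rep(NA_integer_, na))
  big <- (min(na, nb) + 1) * gate
  g <- igraph::graph_from_data_frame(
    data.frame(from = paste0("a", edges[, 1]),
               to = paste0("b", edges[, 2]),
               weight = big - d[edges]),
    directed = FALSE,
    vertices = data.frame(name = c(paste0("a", seq_len(na)),
                                   paste0("b", seq_len(nb))),
                          type = rep(c(FALSE, TRUE), c(na, nb)))
  )
  m <- igraph::max_bipartite_match(g, weights = igraph::E(g)$weight)
  match_a <- m$matching[paste0("a", seq_len(na))]
  out <- rep(NA_integer_, na)
  hit <- !is.na(match_a)
  out[hit] <- as.integer(sub("^b", "", match_a[hit]))
  out
}

#' Link per-frame detections into tracks
#'
#' For each consecutive frame pair, detections are joined by the
#' minimum-total-distance one-to-one assignment restricted to displacements
#' of at most \code{max_link_distance}; unmatched detections start or end
#' tracks. No gap closing: a missed frame terminates the track. Tracks
#' touching the first or last frame of the movie are flagged censored.
#'
#' @param detections data.frame with columns \code{frame}, \code{x_um},
#'   \code{y_um} (e.g. from \code{\link{detect_spots_stack}}).
#' @param max_link_distance micrometres (default 1).
#' @param n_frames movie length; defaults to \code{max(frame)}.
#' @return data.frame with columns \code{track_id}, \code{frame},
#'   \code{x_um}, \code{y_um}.
#' @export
link_tracks <- function(detections, max_link_distance = 1,
                        n_frames = if (nrow(detections)) max(detections$frame) else 0) {
  if (!all(c("frame", "x_um", "y_um") %in% names(detections))) {
    stopf("detections need columns frame, x_um, y_um")
  }
  if (!nrow(detections)) {
    return(data.frame(track_id = integer(0), frame = integer(0),
                      x_um = numeric(0), y_um = numeric(0)))
  }
  detections <- detections[order(detections$frame), ]
  detections$track_id <- NA_integer_
  next_id <- 1L
  frames <- sort(unique(detections$frame))
  rows_in <- split(seq_len(nrow(detections)), detections$frame)
  # seed tracks in the first populated frame
  first <- as.character(frames[1])
  detections$track_id[rows_in[[first]]] <- seq_along(rows_in[[first]])
  next_id <- length(rows_in[[first]]) + 1L
  for (i in seq_along(frames)[-1]) {
    prev_rows <- if (frames[i - 1] == frames[i] - 1) {
      rows_in[[as.character(frames[i - 1])]]
    } else {
      integer(0)  # a frame gap terminates all tracks
    }
    cur_rows <- rows_in[[as.character(frames[i])]]
    link <- assign_points(detections$x_um[prev_rows], detections$y_um[prev_rows],
                          detections$x_um[cur_rows], detections$y_um[cur_rows],
                          max_link_distance)
    if (length(prev_rows)) {
      hit <- !is.na(link)
      detections$track_id[cur_rows[link[hit]]] <-
        detections$track_id[prev_rows[hit]]
    }
    new <- which(is.na(detections$track_id[cur_rows]))
    if (length(new)) {
      detections$track_id[cur_rows[new]] <- next_id + seq_along(new) - 1L
      next_id <- next_id + length(new)
    }
  }
  out <- detections[, c("track_id", "frame", "x_um", "y_um")]
  attr(out, "n_frames") <- n_frames
  rownames(out) <- NULL
  out
}

#' Track lifetimes from linked detections
#'
#' Lifetime of a track spanning k consecutive frames is \code{(k - 1) *
#' frame_interval}. Tracks touching the first or last movie frame are
#' censored (their true lifetime is only bounded from below) and excluded
#' from summaries by default.
#'
#' @param tracks a \code{\link{link_tracks}} result.
#' @param frame_interval seconds between frames (default 5).
#' @param n_frames movie length in frames; defaults to the attribute stored
#'   by \code{link_tracks}.
#' @return data.frame with \code{track_id}, \code{n_frames_track},
#'   \code{lifetime_s}, \code{censored}.
#' @export
lifetimes <- function(tracks, frame_interval = 5,
                      n_frames = attr(tracks, "n_frames")) {
  if (frame_interval <= 0) stopf("'frame_interval' must be > 0")
  if (is.null(n_frames)) n_frames <- if (nrow(tracks)) max(tracks$frame) else 0
  sp <- split(tracks$frame, tracks$track_id)
  data.frame(
    track_id = as.integer(names(sp)),
    n_frames_track = vapply(sp, length, integer(1)),
    lifetime_s = (vapply(sp, length, integer(1)) - 1) * frame_interval,
    censored = vapply(sp, function(f) min(f) == 1 || max(f) == n_frames,
                      logical(1)),
    row.names = NULL
  )
}

#' Mean lifetime of uncensored tracks
#'
#' @param lt a \code{\link{lifetimes}} result.
#' @param include_censored include censored tracks (default FALSE).
#' @return mean lifetime in seconds.
#' @export
mean_lifetime <- function(lt, include_censored = FALSE) {
  keep <- if (include_censored) rep(TRUE, nrow(lt)) else !lt$censored
  if (!any(keep)) stopf("no uncensored tracks")
  mean(lt$lifetime_s[keep])
}
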