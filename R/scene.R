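#' Describe how one channel stains a synthetic cell
#'
#' A channel law sets the spatial intensity model used when rendering a
#' synthetic scene. Four modes cover the localization patterns seen for
#' filopodial proteins:
#' \describe{
#'   \item{\code{tip_exponential}}{intensity decays exponentially with arc
#'     distance from the filopodium tip, \code{amplitude * exp(-d / decay_length)};
#'     models tip-enriched proteins such as MYO10 or active \eqn{\beta}1 integrin.}
#'   \item{\code{uniform}}{constant \code{amplitude} along the whole filopodium;
#'     models uniformly distributed (e.g. inactive) integrin.}
#'   \item{\code{shaft_uniform}}{constant \code{amplitude} along the shaft but
#'     zero within the tip-most 15\% of the arc length; models tip-excluded
#'     staining.}
#'   \item{\code{body_only}}{no filopodial signal at all; only the cell body.}
#' }
#' The cell body disk is rendered at \code{amplitude * body_fraction} for every
#' mode. Each filopodium independently carries the filopodial signal with
#' probability \code{tip_positive_fraction}; negatives receive no filopodial
#' signal for this channel (the cell body is unaffected).
#'
#' @param name channel label, e.g. \code{"MYO10"} or \code{"active-b1"}.
#' @param spatial_mode one of \code{"tip_exponential"}, \code{"uniform"},
#'   \code{"shaft_uniform"}, \code{"body_only"}.
#' @param amplitude peak intensity in ADU on the 0-65535 scale.
#' @param decay_length exponential decay length in micrometres
#'   (\code{tip_exponential} only).
#' @param tip_positive_fraction probability in \[0, 1\] that a filopodium
#'   carries the filopodial signal in this channel.
#' @param body_fraction cell-body intensity as a fraction of \code{amplitude}.
#' @return an object of class \code{channel_law}.
#' @export
#' @examples
#' channel_law("MYO10", "tip_exponential", amplitude = 30000, decay_length = 0.5)
channel_law <- function(name,
                        spatial_mode = c("tip_exponential", "uniform",
                                         "shaft_uniform", "body_only"),
                        amplitude,
                        decay_length = 1,
                        tip_positive_fraction = 1,
                        body_fraction = if (spatial_mode[1] == "tip_exponential") 0.2 else 0.5) {
  spatial_mode <- match.arg(spatial_mode)
  check_number(amplitude, "amplitude", lower = 0)
  check_number(decay_length, "decay_length", lower = 0, strict = TRUE)
  check_number(tip_positive_fraction, "tip_positive_fraction", 0, 1)
  check_number(body_fraction, "body_fraction", lower = 0)
  structure(
    list(name = as.character(name), spatial_mode = spatial_mode,
         amplitude = amplitude, decay_length = decay_length,
         tip_positive_fraction = tip_positive_fraction,
         body_fraction = body_fraction),
    class = "channel_law"
  )
}

#' Default four-channel staining panel
#'
#' MYO10 (tip-enriched, always positive), F-actin (whole filopodium plus a
#' bright cell body), active \eqn{\beta}1 integrin (tip-enriched in a subset of
#' filopodia) and inactive \eqn{\beta}1 integrin (uniform along the shaft).
#'
#' @param active_fraction fraction of filopodia positive for active
#'   \eqn{\beta}1 integrin at their tip.
#' @return list of \code{channel_law} objects.
#' @export
default_channel_laws <- function(active_fraction = 0.5) {
  list(
    channel_law("MYO10", "tip_exponential", amplitude = 40000,
                decay_length = 0.75),
    channel_law("F-actin", "uniform", amplitude = 30000, body_fraction = 1),
    channel_law("active-b1", "tip_exponential", amplitude = 30000,
                decay_length = 1, tip_positive_fraction = active_fraction),
    channel_law("inactive-b1", "shaft_uniform", amplitude = 15000)
  )
}

#' Configuration for a synthetic filopodia scene
#'
#' Defaults mimic structured-illumination imaging of a U2-OS-like cell:
#' 0.08 um pixels, a cell body of radius 8 um, and 30 filopodia of 2-8 um
#' radiating from it.
#'
#' @param image_size integer (height, width) in pixels.
#' @param pixel_size pixel size in micrometres.
#' @param n_filopodia number of filopodia to render.
#' @param filopodium_length_range (min, max) filopodium length in micrometres.
#' @param cell_radius cell-body radius in micrometres.
#' @param channel_models list of \code{\link{channel_law}} objects.
#' @param noise list with \code{poisson_scale} (photons per ADU conversion used
#'   for shot noise; 0 disables) and \code{read_sd} (Gaussian read noise SD in
#'   ADU; 0 disables).
#' @param seed integer seed making the scene fully reproducible.
#' @return an object of class \code{scene_config}.
#' @export
scene_config <- function(image_size = c(512L, 512L),
                         pixel_size = 0.08,
                         n_filopodia = 30,
                         filopodium_length_range = c(2, 8),
                         cell_radius = 8,
                         channel_models = default_channel_laws(),
                         noise = list(poisson_scale = 4, read_sd = 60),
                         seed = 1L) {
  check_number(pixel_size, "pixel_size", lower = 0, strict = TRUE)
  check_number(n_filopodia, "n_filopodia", lower = 0)
  check_number(cell_radius, "cell_radius", lower = 0, strict = TRUE)
  if (length(image_size) != 2 || any(image_size < 8)) {
    stopf("'image_size' must be (height, width) with both >= 8")
  }
  if (length(filopodium_length_range) != 2 ||
      any(filopodium_length_range <= 0) ||
      filopodium_length_range[1] > filopodium_length_range[2]) {
    stopf("'filopodium_length_range' must be 0 < min <= max")
  }
  if (!all(vapply(channel_models, inherits, logical(1), "channel_law"))) {
    stopf("'channel_models' must be a list of channel_law objects")
  }
  if (is.null(noise)) noise <- list(poisson_scale = 0, read_sd = 0)
  # the longest filopodium plus the cell body must fit inside the image
  reach_px <- (cell_radius + filopodium_length_range[2]) / pixel_size
  if (reach_px + 2 > min(image_size) / 2) {
    stopf("image too small: cell radius + max filopodium length needs %.0f px, have %.0f",
          reach_px + 2, min(image_size) / 2)
  }
  structure(
    list(image_size = as.integer(image_size), pixel_size = pixel_size,
         n_filopodia = as.integer(n_filopodia),
         filopodium_length_range = filopodium_length_range,
         cell_radius = cell_radius, channel_models = channel_models,
         noise = noise, bit_depth = 16L, seed = as.integer(seed)),
    class = "scene_config"
  )
}

# Noise-free intensity of one channel at arc distance d_um from the tip of a
# filopodium of length len_um. Exposed internally so the renderer and any
# closed-form check share one definition.
law_intensity <- function(law, d_um, len_um) {
  switch(law$spatial_mode,
    tip_exponential = law$amplitude * exp(-d_um / law$decay_length),
    uniform = rep(law$amplitude, length(d_um)),
    shaft_uniform = ifelse(d_um >= 0.15 * len_um, law$amplitude, 0),
    body_only = rep(0, length(d_um))
  )
}

# Render one straight filopodium into img (modified in place via return).
# Anti-aliasing: a pixel at perpendicular distance t from the segment axis
# receives a tent weight max(0, 1 - t); only pixels whose projection falls
# within the segment get signal. Overlaps combine with pmax.
render_segment <- function(img, tip, base, law, len_um, pixel_size) {
  h <- nrow(img)
  w <- ncol(img)
  lo_x <- max(0, floor(min(tip[1], base[1])) - 2)
  hi_x <- min(w - 1, ceiling(max(tip[1], base[1])) + 2)
  lo_y <- max(0, floor(min(tip[2], base[2])) - 2)
  hi_y <- min(h - 1, ceiling(max(tip[2], base[2])) + 2)
  xs <- lo_x:hi_x
  ys <- lo_y:hi_y
  px <- matrix(rep(xs, each = length(ys)), nrow = length(ys))
  py <- matrix(rep(ys, times = length(xs)), nrow = length(ys))
  v <- base - tip
  seg_len <- sqrt(sum(v^2))
  u <- v / seg_len
  relx <- px - tip[1]
  rely <- py - tip[2]
  s <- relx * u[1] + rely * u[2]          # arc position along axis, px
  t <- abs(relx * u[2] - rely * u[1])     # perpendicular distance, px
  wgt <- pmax(0, 1 - t)
  inside <- s >= 0 & s <= seg_len
  val <- matrix(0, nrow(px), ncol(px))
  val[inside] <- law_intensity(law, s[inside] * pixel_size, len_um) * wgt[inside]
  sub <- img[ys + 1, xs + 1, drop = FALSE]
  img[ys + 1, xs + 1] <- pmax(sub, val)
  img
}

#' Render a synthetic multichannel filopodia scene
#'
#' Draws a circular cell body with \code{n_filopodia} straight filopodia
#' radiating from its edge, renders each channel according to its
#' \code{\link{channel_law}}, and applies shot plus read noise. Filopodia
#' polylines are stored tip-first in 0-based pixel-centre coordinates; the
#' per-filopodium, per-channel ground-truth positivity flags are kept so
#' downstream estimates can be checked against truth.
#'
#' The noise-free render rule for a pixel with centre p is:
#' cell body contributes \code{amplitude * body_fraction} inside the disk
#' (edge anti-aliased over one pixel); a filopodium contributes
#' \code{law(d) * max(0, 1 - t)} where d is the arc distance (um) from the tip
#' of the projection of p onto the segment and t the perpendicular distance
#' (px), provided the projection falls on the segment; contributions combine
#' by maximum. Noise: \code{rpois(I/poisson_scale) * poisson_scale +
#' rnorm(0, read_sd)}, then rounded and clipped to \[0, 65535\].
#'
#' @param config a \code{\link{scene_config}}.
#' @return an object of class \code{synthetic_scene}: list with
#'   \code{config}, \code{polylines} (list of n x 2 matrices, columns x, y,
#'   tip-first), \code{ground_truth_positive} (filopodia x channels logical
#'   matrix), \code{lengths_um}, \code{images} (named list of 16-bit integer
#'   matrices), \code{cell_center_px}, \code{cell_radius_px}.
#' @export
#' @examples
#' sc <- make_scene(scene_config(n_filopodia = 5, seed = 7))
#' length(sc$polylines)
make_scene <- function(config) {
  if (!inherits(config, "scene_config")) {
    stopf("'config' must be a scene_config")
  }
  h <- config$image_size[1]
  w <- config$image_size[2]
  px_sz <- config$pixel_size
  center <- c((w - 1) / 2, (h - 1) / 2)
  r_px <- config$cell_radius / px_sz
  n <- config$n_filopodia
  laws <- config$channel_models
  ch_names <- vapply(laws, `[[`, character(1), "name")

  with_seed(config$seed, {
    # geometry: stratified angles keep filopodia from overlapping
    if (n > 0) {
      angles <- 2 * pi * ((seq_len(n) - 1) + runif(n, 0.25, 0.75)) / n
      lengths_um <- runif(n, config$filopodium_length_range[1],
                          config$filopodium_length_range[2])
    } else {
      angles <- numeric(0)
      lengths_um <- numeric(0)
    }
    polylines <- vector("list", n)
    for (i in seq_len(n)) {
      u <- c(cos(angles[i]), sin(angles[i]))
      base <- center + r_px * u
      tip <- center + (r_px + lengths_um[i] / px_sz) * u
      polylines[[i]] <- rbind(tip, base)
      dimnames(polylines[[i]]) <- list(c("tip", "base"), c("x", "y"))
    }
    positive <- matrix(TRUE, nrow = n, ncol = length(laws),
                       dimnames = list(NULL, ch_names))
    for (j in seq_along(laws)) {
      if (n > 0 && laws[[j]]$tip_positive_fraction < 1) {
        positive[, j] <- runif(n) < laws[[j]]$tip_positive_fraction
      }
    }

    # body mask coverage, anti-aliased over one pixel at the rim
    xg <- matrix(rep(0:(w - 1), each = h), nrow = h)
    yg <- matrix(rep(0:(h - 1), times = w), nrow = h)
    dist_c <- sqrt((xg - center[1])^2 + (yg - center[2])^2)
    body_cov <- pmin(pmax(r_px - dist_c + 0.5, 0), 1)

    images <- vector("list", length(laws))
    names(images) <- ch_names
    for (j in seq_along(laws)) {
      law <- laws[[j]]
      img <- law$amplitude * law$body_fraction * body_cov
      for (i in seq_len(n)) {
        if (!positive[i, j]) next
        img <- render_segment(img, polylines[[i]][1, ], polylines[[i]][2, ],
                              law, lengths_um[i], px_sz)
      }
      if (config$noise$poisson_scale > 0) {
        img[] <- rpois(length(img), img / config$noise$poisson_scale) *
          config$noise$poisson_scale
      }
      if (config$noise$read_sd > 0) {
        img[] <- img + rnorm(length(img), 0, config$noise$read_sd)
      }
      img <- clip16(img)
      storage.mode(img) <- "integer"
      images[[j]] <- img
    }

    structure(
      list(config = config, polylines = polylines,
           ground_truth_positive = positive, lengths_um = lengths_um,
           images = images, cell_center_px = center, cell_radius_px = r_px),
      class = "synthetic_scene"
    )
  })
}

#' @export
print.synthetic_scene <- function(x, ...) {
  cat(sprintf("Synthetic filopodia scene: %d x %d px (%.3f um/px), %d filopodia, %d channels\n",
              x$config$image_size[1], x$config$image_size[2],
              x$config$pixel_size, length(x$polylines), length(x$images)))
  cat(sprintf("  channels: %s\n", paste(names(x$images), collapse = ", ")))
  invisible(x)
}
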