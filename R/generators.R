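#' Simulate immunogold particle distances from a filopodium tip
#'
#' Draws particle-to-tip distances either uniformly along the filopodium or
#' from an exponential law concentrated at the tip (truncated at the
#' filopodium length), emulating gold-labelled receptor positions measured on
#' electron micrographs.
#'
#' @param n number of particles (>= 0).
#' @param mode \code{"tip_exponential"} or \code{"uniform"}.
#' @param scale exponential scale in nanometres (tip_exponential only).
#' @param filo_length filopodium length in nanometres.
#' @param label group label carried into downstream comparisons.
#' @param seed integer seed.
#' @return a \code{gold_particles} object: list with \code{label} and
#'   \code{distances} (nm from the tip, all in \[0, filo_length\]).
#' @export
#' @examples
#' g <- make_gold_particles(100, "tip_exponential", scale = 200,
#'                          filo_length = 2000, seed = 1)
#' range(g$distances)
make_gold_particles <- function(n, mode = c("tip_exponential", "uniform"),
                                scale = 200, filo_length = 2000,
                                label = mode[1], seed = NULL) {
  mode <- match.arg(mode)
  if (!is.numeric(n) || length(n) != 1 || n < 0 || n != round(n)) {
    stopf("'n' must be a non-negative integer")
  }
  check_number(filo_length, "filo_length", lower = 0, strict = TRUE)
  check_number(scale, "scale", lower = 0, strict = TRUE)
  d <- with_seed(seed, {
    if (n == 0) {
      numeric(0)
    } else if (mode == "uniform") {
      runif(n, 0, filo_length)
    } else {
      # inverse-CDF sampling of an exponential truncated at filo_length
      u <- runif(n)
      -scale * log(1 - u * (1 - exp(-filo_length / scale)))
    }
  })
  gold_particles(label, d)
}

#' Construct an immunogold particle set from measured distances
#'
#' @param label group label (e.g. \code{"active"} / \code{"inactive"}).
#' @param distances particle-to-tip distances in nanometres, all >= 0.
#' @return a \code{gold_particles} object.
#' @export
gold_particles <- function(label, distances) {
  distances <- as.numeric(distances)
  if (any(distances < 0 | is.na(distances))) {
    stopf("gold particle distances must be non-negative and non-missing")
  }
  structure(list(label = as.character(label), distances = distances),
            class = "gold_particles")
}

#' Simulate a ligand-depletion binding titration
#'
#' Generates a geometric dilution series of ligand concentrations and the
#' corresponding binding signal under the single-site ligand-depletion
#' (quadratic) model: \code{signal = F_free + (F_bound - F_free) * AL / A0}
#' where AL is given by \code{\link{complex_concentration}}. Gaussian noise of
#' standard deviation \code{noise_sd} is added to the signal.
#'
#' @param A0 fixed fluorescent-partner concentration, molar (default 20 nM,
#'   the labelled-protein concentration used in the thermophoresis assays).
#' @param top_L0 highest ligand concentration, molar.
#' @param n_points number of titration points (>= 4).
#' @param dilution_factor factor (> 1) between consecutive points.
#' @param Kd ground-truth dissociation constant, molar.
#' @param F_free,F_bound signal of the free and fully bound fluorescent
#'   partner (must differ).
#' @param noise_sd Gaussian signal noise SD (same units as the signal).
#' @param seed integer seed.
#' @return a \code{titration} object: data.frame with columns
#'   \code{L0_molar} and \code{signal}, with attributes \code{A0} and
#'   \code{truth} (the generating parameters).
#' @export
#' @examples
#' t <- make_titration(Kd = 4.7e-6, F_free = 800, F_bound = 900,
#'                     noise_sd = 0, seed = 1)
#' head(t)
make_titration <- function(A0 = 2e-8, top_L0 = 2e-4, n_points = 16,
                           dilution_factor = 2, Kd, F_free, F_bound,
                           noise_sd = 0, seed = NULL) {
  check_number(A0, "A0", lower = 0, strict = TRUE)
  check_number(top_L0, "top_L0", lower = 0, strict = TRUE)
  check_number(Kd, "Kd", lower = 0, strict = TRUE)
  check_number(noise_sd, "noise_sd", lower = 0)
  if (n_points < 4) stopf("'n_points' must be >= 4")
  if (dilution_factor <= 1) stopf("'dilution_factor' must be > 1")
  if (F_free == F_bound) {
    stopf("degenerate amplitude: F_free must differ from F_bound")
  }
  L0 <- top_L0 / dilution_factor^(0:(n_points - 1))
  al <- complex_concentration(A0, L0, Kd)
  signal <- F_free + (F_bound - F_free) * al / A0
  if (noise_sd > 0) {
    signal <- with_seed(seed, signal + rnorm(n_points, 0, noise_sd))
  }
  titration(L0, signal, A0,
            truth = list(Kd = Kd, F_free = F_free, F_bound = F_bound,
                         noise_sd = noise_sd))
}

#' Construct a titration from measured points
#'
#' @param L0 ligand concentrations, molar (length >= 4).
#' @param signal binding signal per point (raw ratio or normalized
#'   fluorescence; the depletion model is affine in the bound fraction so
#'   either works).
#' @param A0 fixed fluorescent-partner concentration, molar.
#' @param truth optional list of generating parameters (synthetic data only).
#' @return a \code{titration} object.
#' @export
titration <- function(L0, signal, A0, truth = NULL) {
  if (length(L0) != length(signal)) stopf("L0 and signal lengths differ")
  if (length(L0) < 4) stopf("a titration needs >= 4 points")
  if (any(L0 < 0)) stopf("ligand concentrations must be >= 0")
  check_number(A0, "A0", lower = 0, strict = TRUE)
  structure(data.frame(L0_molar = as.numeric(L0), signal = as.numeric(signal)),
            A0 = A0, truth = truth,
            class = c("titration", "data.frame"))
}

#' Simulate a gated flow-cytometry population
#'
#' Per-cell stain intensities are drawn from stain-specific log-normal
#' distributions, the standard shape of flow-cytometric fluorescence after
#' gating.
#'
#' @param n_cells number of cells.
#' @param stain_params named list; each element \code{c(meanlog, sdlog)} for
#'   one stain (natural-log parameters of the log-normal).
#' @param condition condition label attached to every row.
#' @param seed integer seed.
#' @return data.frame with columns \code{cell_id}, \code{stain},
#'   \code{intensity}, \code{condition}.
#' @export
#' @examples
#' fp <- make_flow_population(100, list(F = c(6, 0.4), F_PB1 = c(7, 0.3)),
#'                            seed = 2)
make_flow_population <- function(n_cells, stain_params, condition = "ctrl",
                                 seed = NULL) {
  if (!is.list(stain_params) || is.null(names(stain_params)) ||
      any(names(stain_params) == "")) {
    stopf("'stain_params' must be a named list of c(meanlog, sdlog)")
  }
  if (n_cells < 1) stopf("'n_cells' must be >= 1")
  with_seed(seed, {
    out <- lapply(names(stain_params), function(st) {
      p <- stain_params[[st]]
      if (length(p) != 2 || p[2] < 0) stopf("bad parameters for stain '%s'", st)
      data.frame(cell_id = seq_len(n_cells), stain = st,
                 intensity = rlnorm(n_cells, p[1], p[2]),
                 condition = condition)
    })
    do.call(rbind, out)
  })
}

# Expected observed frame count for an exponential lifetime discretized to
# frames: E[ceiling(T / interval)] with T ~ Exp(mean_lifetime), by direct
# summation of the survival function.
expected_frames_discretized <- function(mean_lifetime, interval, kmax = 10000) {
  k <- 0:(kmax - 1)
  sum(exp(-k * interval / mean_lifetime))
}

#' Simulate a time-lapse of transient fluorescent spots
#'
#' Spots appear at a uniformly chosen frame, live for an exponential lifetime
#' (rounded up to at least one frame), and perform a bounded random walk.
#' Tracks running into the first or last movie frame are truncated there and
#' marked censored in the ground truth.
#'
#' @param n_spots number of spots.
#' @param mean_lifetime mean lifetime in seconds.
#' @param interval frame interval in seconds (> 0).
#' @param n_frames movie length in frames.
#' @param arena (width, height) of the field in micrometres.
#' @param max_step maximum per-frame displacement in micrometres.
#' @param seed integer seed.
#' @return a \code{timelapse} object: list with \code{spots} (data.frame:
#'   frame, x_um, y_um, spot_id), \code{ground_truth} (data.frame: spot_id,
#'   lifetime_s, observed_frames, start_frame, censored), \code{interval},
#'   \code{n_frames}, \code{arena}.
#' @export
make_timelapse <- function(n_spots, mean_lifetime, interval = 5,
                           n_frames = 60, arena = c(20, 20), max_step = 0.2,
                           seed = NULL) {
  if (interval <= 0) stopf("'interval' must be > 0")
  check_number(mean_lifetime, "mean_lifetime", lower = 0, strict = TRUE)
  if (n_spots < 0) stopf("'n_spots' must be >= 0")
  with_seed(seed, {
    rows <- vector("list", n_spots)
    gt <- vector("list", n_spots)
    for (i in seq_len(n_spots)) {
      life_s <- rexp(1, 1 / mean_lifetime)
      want_frames <- max(1, ceiling(life_s / interval))
      start <- sample.int(n_frames, 1)
      end <- min(n_frames, start + want_frames - 1)
      frames <- start:end
      censored <- (start + want_frames - 1 > n_frames) || start == 1 ||
        end == n_frames
      x <- numeric(length(frames))
      y <- numeric(length(frames))
      x[1] <- runif(1, 0, arena[1])
      y[1] <- runif(1, 0, arena[2])
      for (k in seq_along(frames)[-1]) {
        ang <- runif(1, 0, 2 * pi)
        step <- runif(1, 0, max_step)
        x[k] <- pmin(pmax(x[k - 1] + step * cos(ang), 0), arena[1])
        y[k] <- pmin(pmax(y[k - 1] + step * sin(ang), 0), arena[2])
      }
      rows[[i]] <- data.frame(frame = frames, x_um = x, y_um = y, spot_id = i)
      gt[[i]] <- data.frame(spot_id = i, lifetime_s = life_s,
                            observed_frames = length(frames),
                            start_frame = start, censored = censored)
    }
    spots <- if (n_spots > 0) do.call(rbind, rows) else
      data.frame(frame = integer(0), x_um = numeric(0), y_um = numeric(0),
                 spot_id = integer(0))
    truth <- if (n_spots > 0) do.call(rbind, gt) else
      data.frame(spot_id = integer(0), lifetime_s = numeric(0),
                 observed_frames = integer(0), start_frame = integer(0),
                 censored = logical(0))
    spots <- spots[order(spots$frame, spots$spot_id), ]
    rownames(spots) <- NULL
    structure(list(spots = spots, ground_truth = truth, interval = interval,
                   n_frames = n_frames, arena = arena),
              class = "timelapse")
  })
}

#' Render a time-lapse of spots to a 16-bit image stack
#'
#' Each spot becomes an isotropic Gaussian of the given amplitude and width;
#' frames can carry Poisson + read noise like \code{\link{make_scene}}.
#'
#' @param tl a \code{\link{make_timelapse}} result.
#' @param pixel_size micrometres per pixel.
#' @param amplitude peak spot intensity in ADU.
#' @param spot_sigma_um Gaussian sigma in micrometres.
#' @param noise list(poisson_scale, read_sd) or NULL for noise-free.
#' @param seed integer seed for the noise.
#' @return 3D array (y, x, frame) of 16-bit intensities.
#' @export
render_timelapse <- function(tl, pixel_size = 0.1, amplitude = 20000,
                             spot_sigma_um = 0.17, noise = NULL, seed = NULL) {
  if (!inherits(tl, "timelapse")) stopf("'tl' must be a timelapse")
  w <- ceiling(tl$arena[1] / pixel_size) + 1
  h <- ceiling(tl$arena[2] / pixel_size) + 1
  sig_px <- spot_sigma_um / pixel_size
  stack <- array(0, dim = c(h, w, tl$n_frames))
  xg <- matrix(rep(0:(w - 1), each = h), nrow = h)
  yg <- matrix(rep(0:(h - 1), times = w), nrow = h)
  for (fr in seq_len(tl$n_frames)) {
    sp <- tl$spots[tl$spots$frame == fr, , drop = FALSE]
    img <- matrix(0, h, w)
    for (i in seq_len(nrow(sp))) {
      cx <- sp$x_um[i] / pixel_size
      cy <- sp$y_um[i] / pixel_size
      img <- img + amplitude * exp(-((xg - cx)^2 + (yg - cy)^2) / (2 * sig_px^2))
    }
    stack[, , fr] <- img
  }
  if (!is.null(noise)) {
    stack <- with_seed(seed, {
      if (noise$poisson_scale > 0) {
        stack[] <- rpois(length(stack), stack / noise$poisson_scale) *
          noise$poisson_scale
      }
      if (noise$read_sd > 0) {
        stack[] <- stack + rnorm(length(stack), 0, noise$read_sd)
      }
      stack
    })
  }
  stack[] <- clip16(stack)
  attr(stack, "pixel_size") <- pixel_size
  attr(stack, "frame_interval") <- tl$interval
  stack
}
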