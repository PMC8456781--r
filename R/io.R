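#' Read a 16-bit TIFF image stack with calibration
#'
#' Reads a (multipage) TIFF as a list of 16-bit integer matrices. Spatial
#' calibration is taken from a YAML sidecar written by
#' \code{\link{write_image}} (same path with extension \code{.yaml}) or from
#' the arguments; a missing calibration is an error. Inputs that are not
#' 16-bit are rescaled to the 0-65535 range with a warning (8-bit values are
#' multiplied by 257).
#'
#' @param path TIFF file path.
#' @param pixel_size micrometres per pixel; overrides the sidecar.
#' @param frame_interval seconds between frames (time-lapse only).
#' @param channel_names optional labels, one per page.
#' @return an \code{image_stack}: list with \code{pixels} (list of integer
#'   matrices, one per page), \code{channel_names}, \code{pixel_size},
#'   \code{frame_interval}.
#' @export
read_image <- function(path, pixel_size = NULL, frame_interval = NULL,
                       channel_names = NULL) {
  if (!file.exists(path)) stopf("image file not found: %s", path)
  pages <- tiff::readTIFF(path, all = TRUE, info = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  bits <- attr(pages[[1]], "bits.per.sample")
  if (!is.null(bits) && bits != 16) {
    warning(sprintf("%d-bit TIFF rescaled to 16-bit (0-65535)", bits),
            call. = FALSE)
  }
  # readTIFF returns [0,1]; scaling back by 65535 maps 8-bit v/255 to v*257
  pixels <- lapply(pages, function(p) {
    if (length(dim(p)) == 3) p <- p[, , 1]
    # drop the TIFF tag attributes readTIFF attaches
    matrix(as.integer(clip16(p * 65535)), nrow(p), ncol(p))
  })
  side <- sidecar_path(path)
  meta <- if (file.exists(side)) yaml::read_yaml(side) else list()
  pixel_size <- pixel_size %||% meta$pixel_size
  frame_interval <- frame_interval %||% meta$frame_interval
  channel_names <- channel_names %||% meta$channel_names %||%
    paste0("ch", seq_along(pixels))
  if (is.null(pixel_size)) {
    stopf("no calibration for %s: supply 'pixel_size' or a %s sidecar",
          path, basename(side))
  }
  check_number(pixel_size, "pixel_size", lower = 0, strict = TRUE)
  names(pixels) <- channel_names
  structure(list(pixels = pixels, channel_names = channel_names,
                 pixel_size = pixel_size, frame_interval = frame_interval),
            class = "image_stack")
}

#' Write a 16-bit TIFF image stack with a calibration sidecar
#'
#' @param stack an \code{image_stack}, a single matrix, or a list of matrices
#'   with values in \[0, 65535\].
#' @param path output TIFF path; calibration is written to the \code{.yaml}
#'   sidecar next to it.
#' @param pixel_size,frame_interval,channel_names calibration when
#'   \code{stack} is not an \code{image_stack}.
#' @return \code{path}, invisibly.
#' @export
write_image <- function(stack, path, pixel_size = NULL, frame_interval = NULL,
                        channel_names = NULL) {
  if (inherits(stack, "image_stack")) {
    pixels <- stack$pixels
    pixel_size <- pixel_size %||% stack$pixel_size
    frame_interval <- frame_interval %||% stack$frame_interval
    channel_names <- channel_names %||% stack$channel_names
  } else if (is.matrix(stack)) {
    pixels <- list(stack)
  } else {
    pixels <- stack
  }
  if (is.null(pixel_size)) stopf("'pixel_size' is required to write an image")
  if (any(vapply(pixels, function(p) any(p < 0 | p > 65535), logical(1)))) {
    stopf("pixel values must lie in [0, 65535]")
  }
  pages <- lapply(pixels, function(p) matrix(p / 65535, nrow(p), ncol(p)))
  tiff::writeTIFF(pages, path, bits.per.sample = 16)
  meta <- list(pixel_size = pixel_size,
               channel_names = channel_names %||% paste0("ch", seq_along(pixels)))
  if (!is.null(frame_interval)) meta$frame_interval <- frame_interval
  yaml::write_yaml(meta, sidecar_path(path))
  invisible(path)
}

sidecar_path <- function(path) sub("\\.tiff?$", ".yaml", path, ignore.case = TRUE)

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read tip-first polyline annotations from CSV
#'
#' Expected columns: \code{filopodium_id}, \code{vertex_index} (0-based,
#' 0 = tip, consecutive), \code{x_px}, \code{y_px} (0-based pixel centres).
#'
#' @param path CSV path.
#' @return named list of n x 2 matrices (columns x, y), tip first.
#' @export
read_polylines <- function(path) {
  if (!file.exists(path)) stopf("polyline file not found: %s", path)
  df <- read.csv(path)
  need <- c("filopodium_id", "vertex_index", "x_px", "y_px")
  if (!all(need %in% names(df))) {
    stopf("polyline CSV must have columns: %s", paste(need, collapse = ", "))
  }
  key <- paste(df$filopodium_id, df$vertex_index)
  if (anyDuplicated(key)) {
    stopf("duplicated (filopodium_id, vertex_index) at row %d",
          which(duplicated(key))[1])
  }
  out <- lapply(split(df, df$filopodium_id), function(g) {
    if (is.unsorted(g$vertex_index, strictly = TRUE)) {
      bad <- which(diff(g$vertex_index) <= 0)[1] + 1
      stopf("out-of-order vertex_index for filopodium '%s' at file row %d",
            g$filopodium_id[1], as.integer(rownames(g)[bad]) + 1L)
    }
    if (!all(g$vertex_index == seq_len(nrow(g)) - 1)) {
      stopf("vertex indices of filopodium '%s' are not consecutive from 0",
            g$filopodium_id[1])
    }
    if (nrow(g) < 2) stopf("filopodium '%s' has < 2 vertices", g$filopodium_id[1])
    m <- cbind(x = g$x_px, y = g$y_px)
    if (any(rowSums(abs(diff(m))) == 0)) {
      stopf("filopodium '%s' has consecutive duplicate vertices",
            g$filopodium_id[1])
    }
    m
  })
  out
}

#' @rdname read_polylines
#' @param polylines named list of n x 2 matrices (columns x, y), tip first.
#' @export
write_polylines <- function(polylines, path) {
  ids <- names(polylines) %||% seq_along(polylines)
  rows <- lapply(seq_along(polylines), function(i) {
    m <- polylines[[i]]
    data.frame(filopodium_id = ids[i], vertex_index = seq_len(nrow(m)) - 1L,
               x_px = m[, 1], y_px = m[, 2])
  })
  write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Read and write tip-to-base intensity profiles as long CSV
#'
#' Columns: \code{filopodium_id}, \code{channel}, \code{sample_index}
#' (0 = tip), \code{distance_um}, \code{intensity}; one extra column
#' \code{pixel_size} keeps the round trip lossless.
#'
#' @param records list of \code{\link{profile_record}} objects.
#' @param path CSV path.
#' @return \code{write_profiles}: the path, invisibly; \code{read_profiles}:
#'   a list of \code{profile_record} objects.
#' @export
write_profiles <- function(records, path) {
  rows <- lapply(records, function(r) {
    data.frame(filopodium_id = r$filopodium_id, channel = r$channel,
               sample_index = seq_along(r$intensities) - 1L,
               distance_um = r$arc_positions, intensity = r$intensities,
               pixel_size = r$pixel_size)
  })
  write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_profiles
#' @export
read_profiles <- function(path) {
  if (!file.exists(path)) stopf("profile file not found: %s", path)
  df <- read.csv(path)
  need <- c("filopodium_id", "channel", "sample_index", "distance_um",
            "intensity")
  if (!all(need %in% names(df))) {
    stopf("profile CSV must have columns: %s", paste(need, collapse = ", "))
  }
  keys <- unique(df[, c("filopodium_id", "channel")])
  lapply(seq_len(nrow(keys)), function(i) {
    g <- df[df$filopodium_id == keys$filopodium_id[i] &
              df$channel == keys$channel[i], ]
    g <- g[order(g$sample_index), ]
    profile_record(g$intensity, g$distance_um,
                   pixel_size = if (!is.null(g$pixel_size)) g$pixel_size[1] else NA,
                   filopodium_id = keys$filopodium_id[i],
                   channel = keys$channel[i])
  })
}

#' Read and write titration, flow, Ct and spot tables
#'
#' Plain-CSV dialects for the remaining pipeline tables. Titration CSV:
#' \code{L0_molar}, \code{signal}, \code{A0_molar} (constant column). Flow
#' CSV: \code{cell_id}, \code{stain}, \code{intensity}, \code{condition}.
#' Ct CSV: \code{gene}, \code{sample}, \code{ct}. Spots CSV: \code{frame},
#' \code{x_um}, \code{y_um} and optional \code{spot_id}.
#'
#' @param x object to write (titration / data.frame).
#' @param path CSV path.
#' @return readers return the object; writers return the path invisibly.
#' @name table_io
NULL

#' @rdname table_io
#' @export
write_titration <- function(x, path) {
  df <- data.frame(L0_molar = x$L0_molar, signal = x$signal,
                   A0_molar = attr(x, "A0"))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname table_io
#' @export
read_titration <- function(path) {
  if (!file.exists(path)) stopf("titration file not found: %s", path)
  df <- read.csv(path)
  need <- c("L0_molar", "signal", "A0_molar")
  if (!all(need %in% names(df))) {
    stopf("titration CSV must have columns: %s", paste(need, collapse = ", "))
  }
  titration(df$L0_molar, df$signal, df$A0_molar[1])
}

#' @rdname table_io
#' @export
write_flow <- function(x, path) {
  write.csv(x, path, row.names = FALSE)
  invisible(path)
}

#' @rdname table_io
#' @export
read_flow <- function(path) {
  if (!file.exists(path)) stopf("flow file not found: %s", path)
  df <- read.csv(path)
  need <- c("cell_id", "stain", "intensity")
  if (!all(need %in% names(df))) {
    stopf("flow CSV must have columns: %s", paste(need, collapse = ", "))
  }
  if (any(df$intensity < 0)) stopf("flow intensities must be >= 0")
  df
}

#' @rdname table_io
#' @export
write_ct <- function(x, path) {
  write.csv(x, path, row.names = FALSE)
  invisible(path)
}

#' @rdname table_io
#' @export
read_ct <- function(path) {
  if (!file.exists(path)) stopf("Ct file not found: %s", path)
  df <- read.csv(path)
  need <- c("gene", "sample", "ct")
  if (!all(need %in% names(df))) {
    stopf("Ct CSV must have columns: %s", paste(need, collapse = ", "))
  }
  if (any(df$ct <= 0)) stopf("Ct values must be > 0")
  df
}

#' @rdname table_io
#' @export
write_spots <- function(x, path) {
  write.csv(x, path, row.names = FALSE)
  invisible(path)
}

#' @rdname table_io
#' @export
read_spots <- function(path) {
  if (!file.exists(path)) stopf("spots file not found: %s", path)
  df <- read.csv(path)
  need <- c("frame", "x_um", "y_um")
  if (!all(need %in% names(df))) {
    stopf("spots CSV must have columns: %s", paste(need, collapse = ", "))
  }
  df
}
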