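#' Reduce a tip-to-base profile to 40 median bins
#'
#' To make filopodia of different lengths comparable, each profile is reduced
#' to a fixed number of bins: sample i of n (0-based) is assigned to bin
#' \code{floor(i * n_bins / n)} and each bin takes the median of its samples.
#' Profiles with fewer samples than bins are first nearest-neighbour
#' upsampled to \code{n_bins} samples and flagged.
#'
#' @param record a \code{\link{profile_record}} (tip-first).
#' @param n_bins number of bins (default 40, bin 1 = tip).
#' @return a \code{binned_profile}: list with \code{bin_values} (length
#'   \code{n_bins}), \code{length_um} (last arc position), \code{upsampled},
#'   \code{filopodium_id}, \code{channel}.
#' @export
#' @examples
#' r <- profile_record(1:40, 0:39 * 0.08, 0.08)
#' identical(bin_profile(r)$bin_values, as.numeric(1:40))
bin_profile <- function(record, n_bins = 40) {
  if (!inherits(record, "profile_record")) stopf("'record' must be a profile_record")
  if (n_bins < 1) stopf("'n_bins' must be >= 1")
  x <- record$intensities
  n <- length(x)
  upsampled <- n < n_bins
  if (upsampled) {
    # nearest-neighbour upsampling to one sample per bin
    src <- floor((seq_len(n_bins) - 0.5) * n / n_bins) + 1
    x <- x[pmin(src, n)]
    n <- n_bins
  }
  bin <- floor((seq_len(n) - 1) * n_bins / n) + 1
  vals <- as.numeric(tapply(x, factor(bin, levels = seq_len(n_bins)), median))
  structure(
    list(filopodium_id = record$filopodium_id, channel = record$channel,
         bin_values = vals, length_um = max(record$arc_positions),
         upsampled = upsampled),
    class = "binned_profile"
  )
}

#' Average binned profiles into a localization map
#'
#' Each group's map row is the per-bin arithmetic mean across its binned
#' profiles, the heatmap that shows where a protein sits along the average
#' filopodium.
#'
#' @param profiles list of \code{\link{bin_profile}} results.
#' @param group_by \code{"channel"}, or a character vector of group labels,
#'   one per profile.
#' @return a \code{filopodia_map}: data.frame with columns \code{group},
#'   \code{bin}, \code{mean}, \code{n}.
#' @export
build_map <- function(profiles, group_by = "channel") {
  if (!length(profiles)) stopf("no profiles to map")
  groups <- if (identical(group_by, "channel")) {
    vapply(profiles, function(p) as.character(p$channel), character(1))
  } else {
    if (length(group_by) != length(profiles)) {
      stopf("'group_by' must be \"channel\" or one label per profile")
    }
    as.character(group_by)
  }
  if (anyNA(groups)) stopf("empty group label for profile %d", which(is.na(groups))[1])
  n_bins <- length(profiles[[1]]$bin_values)
  out <- lapply(unique(groups), function(g) {
    rows <- profiles[groups == g]
    if (!length(rows)) stopf("group '%s' has no profiles", g)
    m <- do.call(rbind, lapply(rows, `[[`, "bin_values"))
    data.frame(group = g, bin = seq_len(n_bins), mean = colMeans(m),
               n = nrow(m))
  })
  structure(do.call(rbind, out), class = c("filopodia_map", "data.frame"))
}

#' Map as a bins-by-group matrix (heatmap-ready)
#'
#' @param map a \code{\link{build_map}} result.
#' @return numeric matrix, one row per group, one column per bin.
#' @export
map_matrix <- function(map) {
  gs <- unique(map$group)
  m <- t(vapply(gs, function(g) map$mean[map$group == g], numeric(max(map$bin))))
  rownames(m) <- gs
  colnames(m) <- paste0("bin", seq_len(ncol(m)))
  m
}

#' Tip/shaft enrichment ratio of a binned profile
#'
#' Mean intensity over the tip bins (1-6) divided by the mean over the shaft
#' bins (7-40). Values above 1 indicate tip enrichment.
#'
#' @param profile a \code{\link{bin_profile}} result.
#' @param tip_bins,shaft_bins bin index vectors.
#' @return the enrichment ratio (dimensionless).
#' @export
#' @examples
#' r <- profile_record(rep(100, 40), 0:39 * 0.08, 0.08)
#' enrichment_ratio(bin_profile(r))  # 1
enrichment_ratio <- function(profile, tip_bins = 1:6, shaft_bins = 7:40) {
  if (!inherits(profile, "binned_profile")) {
    stopf("'profile' must be a binned_profile")
  }
  v <- profile$bin_values
  if (max(c(tip_bins, shaft_bins)) > length(v)) stopf("bin index out of range")
  shaft <- mean(v[shaft_bins])
  if (shaft == 0) {
    stopf("undefined enrichment ratio: shaft mean is 0 (filopodium %s)",
          profile$filopodium_id)
  }
  mean(v[tip_bins]) / shaft
}

#' Classify a filopodium as tip-positive
#'
#' A filopodium is positive for a protein at its tip when the average
#' intensity over the tip bins reaches the threshold (default 5000 on the
#' normalized 0-65535 scale); the boundary value itself counts as positive.
#'
#' @param profile a \code{\link{bin_profile}} result.
#' @param threshold ADU threshold in \[0, 65535\].
#' @param tip_bins bins defining the tip.
#' @return logical.
#' @export
classify_tip_positive <- function(profile, threshold = 5000, tip_bins = 1:6) {
  if (!inherits(profile, "binned_profile")) {
    stopf("'profile' must be a binned_profile")
  }
  check_number(threshold, "threshold", 0, 65535)
  mean(profile$bin_values[tip_bins]) >= threshold
}

#' Percentage of tip-positive filopodia
#'
#' @param profiles list of \code{\link{bin_profile}} results.
#' @param ... passed to \code{\link{classify_tip_positive}}.
#' @return percentage in \[0, 100\].
#' @export
percent_positive <- function(profiles, ...) {
  if (!length(profiles)) stopf("no profiles given")
  100 * mean(vapply(profiles, classify_tip_positive, logical(1), ...))
}

#' Filopodium length from a profile
#'
#' The arc length of the traced tip-to-base line, in micrometres.
#'
#' @param record a \code{\link{profile_record}}.
#' @return length in micrometres.
#' @export
filopodium_length <- function(record) {
  if (!inherits(record, "profile_record")) stopf("'record' must be a profile_record")
  max(record$arc_positions)
}

#' Arc length of a polyline in micrometres
#'
#' @param polyline n x 2 matrix in pixel coordinates.
#' @param pixel_size micrometres per pixel.
#' @return length in micrometres.
#' @export
polyline_length <- function(polyline, pixel_size) {
  polyline <- as.matrix(polyline)
  if (nrow(polyline) < 2) stopf("polyline needs >= 2 vertices")
  sum(sqrt(rowSums(diff(polyline)^2))) * pixel_size
}
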