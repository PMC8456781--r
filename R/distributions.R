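#' Probability-density curve of particle-to-tip distances
#'
#' Gaussian kernel density of the distances, returned on an explicit grid so
#' the area under the curve is (numerically) one: particle positions along
#' filopodia are compared as probability densities, never rescaled by
#' filopodium length.
#'
#' @param set a \code{\link{gold_particles}} object or numeric vector of
#'   distances (nm).
#' @param bandwidth kernel bandwidth in nm, or \code{"auto"} for Silverman's
#'   rule of thumb.
#' @param n_grid number of grid points.
#' @return data.frame with columns \code{grid_nm} and \code{density}
#'   (1/nm); attribute \code{bandwidth} records the bandwidth used.
#' @export
#' @examples
#' g <- make_gold_particles(200, "uniform", filo_length = 2000, seed = 3)
#' d <- density_curve(g)
density_curve <- function(set, bandwidth = "auto", n_grid = 512) {
  x <- if (inherits(set, "gold_particles")) set$distances else as.numeric(set)
  if (length(x) < 2) stopf("density needs >= 2 distances")
  if (identical(bandwidth, "auto")) {
    if (sd(x) == 0) {
      stopf("zero-variance distances: supply an explicit 'bandwidth' in nm")
    }
    bw <- stats::bw.nrd0(x)
  } else {
    check_number(bandwidth, "bandwidth", lower = 0, strict = TRUE)
    bw <- bandwidth
  }
  d <- density(x, bw = bw, n = n_grid, from = min(x) - 4 * bw,
               to = max(x) + 4 * bw)
  out <- data.frame(grid_nm = d$x, density = d$y)
  attr(out, "bandwidth") <- bw
  out
}

# Two-sample Kolmogorov-Smirnov statistic: sup |ECDF_x - ECDF_y|.
ks_statistic <- function(x, y) {
  pts <- sort(c(x, y))
  max(abs(ecdf(x)(pts) - ecdf(y)(pts)))
}

#' Bootstrap two-sample Kolmogorov-Smirnov test
#'
#' Compares two distance distributions with the KS statistic
#' \eqn{D = \sup_t |F_x(t) - F_y(t)|}; significance comes from a bootstrap
#' null in which both samples are redrawn with replacement, at their original
#' sizes, from the pooled data. The p-value uses the add-one correction
#' \eqn{p = (1 + \#\{D^* \ge D\}) / (n_{boot} + 1)}, so ties in the data are
#' handled without any asymptotic approximation.
#'
#' @param x,y numeric vectors (or \code{\link{gold_particles}}), each n >= 2.
#' @param n_boot number of bootstrap resamples (default 1000).
#' @param seed integer seed.
#' @return list with \code{D}, \code{p}, \code{n_boot}, \code{n_x},
#'   \code{n_y}; class \code{bootstrap_ks}.
#' @export
#' @examples
#' a <- make_gold_particles(50, "tip_exponential", seed = 1)
#' b <- make_gold_particles(50, "uniform", seed = 2)
#' bootstrap_ks(a, b, n_boot = 200, seed = 3)
bootstrap_ks <- function(x, y, n_boot = 1000, seed = NULL) {
  if (inherits(x, "gold_particles")) x <- x$distances
  if (inherits(y, "gold_particles")) y <- y$distances
  if (length(x) < 2 || length(y) < 2) stopf("both samples need n >= 2")
  if (n_boot < 1) stopf("'n_boot' must be >= 1")
  d_obs <- ks_statistic(x, y)
  pooled <- c(x, y)
  nx <- length(x)
  ny <- length(y)
  exceed <- with_seed(seed, {
    sum(vapply(seq_len(n_boot), function(i) {
      xs <- sample(pooled, nx, replace = TRUE)
      ys <- sample(pooled, ny, replace = TRUE)
      ks_statistic(xs, ys) >= d_obs
    }, logical(1)))
  })
  structure(list(D = d_obs, p = (1 + exceed) / (n_boot + 1),
                 n_boot = n_boot, n_x = nx, n_y = ny),
            class = "bootstrap_ks")
}

#' @export
print.bootstrap_ks <- function(x, ...) {
  cat(sprintf("Bootstrap KS test: D = %.4f, p = %.4g (%d resamples, n = %d vs %d)\n",
              x$D, x$p, x$n_boot, x$n_x, x$n_y))
  invisible(x)
}
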