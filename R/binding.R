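#' Bound-complex concentration under ligand depletion
#'
#' Single-site equilibrium between a fluorescent partner A (total
#' concentration \code{A0}) and a ligand L (total \code{L0}) with dissociation
#' constant \code{Kd}. Because A is not in vast excess the free-ligand
#' approximation does not hold and the complex concentration is the root of
#' \deqn{AL^2 - (A0 + L0 + Kd) AL + A0 L0 = 0,}
#' i.e. \deqn{AL = \frac{1}{2}\left((A0+L0+Kd) - \sqrt{(A0+L0+Kd)^2 - 4 A0 L0}\right).}
#' Computed in the cancellation-free form \code{2 A0 L0 / (S + sqrt(S^2 - 4 A0 L0))}.
#'
#' @param A0 total fluorescent-partner concentration, molar (> 0).
#' @param L0 total ligand concentration(s), molar (>= 0); vectorized.
#' @param Kd dissociation constant, molar (> 0).
#' @return complex concentration(s) AL in molar, with 0 <= AL <= min(A0, L0).
#' @export
#' @examples
#' complex_concentration(2e-8, 1e-5, 1e-5)
complex_concentration <- function(A0, L0, Kd) {
  check_number(A0, "A0", lower = 0, strict = TRUE)
  check_number(Kd, "Kd", lower = 0, strict = TRUE)
  if (any(L0 < 0) || any(is.na(L0))) stopf("'L0' must be >= 0")
  s <- A0 + L0 + Kd
  disc <- s^2 - 4 * A0 * L0
  2 * A0 * L0 / (s + sqrt(pmax(disc, 0)))
}

#' Normalized thermophoresis fluorescence
#'
#' Ratio of the fluorescence after IR-laser activation (\code{F1}) to the
#' fluorescence before (\code{F0}).
#'
#' @param F1 fluorescence after IR-laser activation (>= 0).
#' @param F0 fluorescence before activation (> 0).
#' @return \code{F1 / F0}, vectorized.
#' @export
#' @examples
#' delta_fnorm(840, 800)
delta_fnorm <- function(F1, F0) {
  if (any(F0 <= 0)) stopf("'F0' must be > 0")
  F1 / F0
}

# Model signal at ligand concentrations L0.
binding_signal <- function(L0, A0, Kd, F_free, F_bound) {
  F_free + (F_bound - F_free) * complex_concentration(A0, L0, Kd) / A0
}

#' Fit the ligand-depletion binding model to a titration
#'
#' Least-squares fit of
#' \code{signal = F_free + (F_bound - F_free) * AL(A0, L0, Kd) / A0}
#' over the three parameters (Kd, F_free, F_bound), with AL the quadratic
#' ligand-depletion root (\code{\link{complex_concentration}}). Kd is fitted
#' on a log scale and bounded to \[1e-12, 1\] M. With \code{init = "auto"} a
#' log-spaced grid of Kd seeds is scored (amplitudes solved by linear least
#' squares at each seed) and the best seed starts a Levenberg-Marquardt
#' refinement. Replicate experiments are pooled by concatenating their points
#' into one titration before fitting.
#'
#' @param titration a \code{\link{titration}} (or data.frame with columns
#'   \code{L0_molar} and \code{signal}).
#' @param A0 fluorescent-partner concentration, molar; defaults to the
#'   titration's \code{A0} attribute.
#' @param init \code{"auto"} or a numeric Kd starting guess in molar.
#' @return an object of class \code{kd_fit} with components \code{kd}
#'   (molar), \code{f_free}, \code{f_bound}, \code{sse}, \code{converged},
#'   \code{n}, plus the data; supports \code{print}, \code{summary},
#'   \code{coef}, \code{predict}, \code{fitted}, \code{residuals},
#'   \code{plot}.
#' @export
#' @examples
#' t <- make_titration(Kd = 4.7e-6, F_free = 800, F_bound = 900, noise_sd = 0)
#' fit <- fit_kd(t)
#' coef(fit)["kd_molar"] * 1e6  # Kd in micromolar
fit_kd <- function(titration, A0 = attr(titration, "A0"), init = "auto") {
  if (is.null(A0)) stopf("'A0' must be supplied (molar)")
  check_number(A0, "A0", lower = 0, strict = TRUE)
  L0 <- titration$L0_molar
  y <- titration$signal
  if (length(L0) < 4) stopf("need >= 4 titration points")
  if (length(unique(L0)) < 4) stopf("need >= 4 distinct ligand concentrations")

  # linear LS for the amplitudes given Kd; returns c(F_free, F_bound, sse)
  amps_for <- function(kd) {
    frac <- complex_concentration(A0, L0, kd) / A0
    fit <- lm.fit(cbind(1 - frac, frac), y)
    c(unname(fit$coefficients), sum(fit$residuals^2))
  }

  if (identical(init, "auto")) {
    span <- log10(range(L0[L0 > 0]))
    if (diff(span) < 2) {
      stopf("auto init needs ligand concentrations spanning >= 2 orders of magnitude")
    }
    grid <- 10^seq(-12, 0, length.out = 49)
    scores <- vapply(grid, function(k) amps_for(k)[3], numeric(1))
    kd0 <- grid[which.min(scores)]
  } else {
    check_number(init, "init", lower = 0, strict = TRUE)
    kd0 <- init
  }
  a0 <- amps_for(kd0)

  # no-binding guard: amplitude must exceed 3x the residual noise at the best seed
  noise_est <- sqrt(a0[3] / max(1, length(y) - 3))
  if (abs(a0[2] - a0[1]) < 3 * noise_est) {
    stopf("no detectable binding: signal amplitude (%.3g) below 3x noise (%.3g)",
          abs(a0[2] - a0[1]), noise_est)
  }

  df <- data.frame(L0 = L0, y = y)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ binding_signal(L0, A0, 10^lkd, ff, fb),
      data = df,
      start = list(lkd = log10(kd0), ff = a0[1], fb = a0[2]),
      lower = c(-12, -Inf, -Inf),
      upper = c(0, Inf, Inf),
      control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-14,
                                           ptol = 1e-14)
    ),
    error = function(e) NULL
  )
  if (is.null(fit)) {
    kd <- kd0; ff <- a0[1]; fb <- a0[2]; sse <- a0[3]; converged <- FALSE
  } else {
    p <- coef(fit)
    kd <- 10^p[["lkd"]]; ff <- p[["ff"]]; fb <- p[["fb"]]
    sse <- sum(residuals(fit)^2)
    converged <- fit$convInfo$isConv
  }
  yhat <- binding_signal(L0, A0, kd, ff, fb)
  structure(
    list(kd = kd, f_free = ff, f_bound = fb, sse = sse,
         converged = isTRUE(converged), n = length(y), A0 = A0,
         data = df, fitted_values = yhat, residual_values = y - yhat),
    class = "kd_fit"
  )
}

#' @export
print.kd_fit <- function(x, ...) {
  cat("Ligand-depletion binding fit\n")
  cat(sprintf("  Kd      = %.4g M (%.3g uM)\n", x$kd, x$kd * 1e6))
  cat(sprintf("  F_free  = %.6g\n  F_bound = %.6g\n", x$f_free, x$f_bound))
  cat(sprintf("  n = %d points, SSE = %.4g, converged: %s\n",
              x$n, x$sse, x$converged))
  invisible(x)
}

#' @export
coef.kd_fit <- function(object, ...) {
  c(kd_molar = object$kd, f_free = object$f_free, f_bound = object$f_bound)
}

#' @export
fitted.kd_fit <- function(object, ...) object$fitted_values

#' @export
residuals.kd_fit <- function(object, ...) object$residual_values

#' @export
predict.kd_fit <- function(object, newdata = NULL, ...) {
  L0 <- if (is.null(newdata)) object$data$L0 else {
    if (is.data.frame(newdata)) {
      if (!is.null(newdata$L0_molar)) newdata$L0_molar else newdata$L0
    } else {
      newdata
    }
  }
  binding_signal(L0, object$A0, object$kd, object$f_free, object$f_bound)
}

#' @export
summary.kd_fit <- function(object, ...) {
  rse <- sqrt(object$sse / max(1, object$n - 3))
  structure(list(fit = object, residual_se = rse), class = "summary.kd_fit")
}

#' @export
print.summary.kd_fit <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  residual SE = %.4g\n", x$residual_se))
  invisible(x)
}

#' @param x a \code{kd_fit}.
#' @param ... passed to \code{plot}.
#' @rdname fit_kd
#' @export
plot.kd_fit <- function(x, ...) {
  L0 <- x$data$L0
  pos <- L0[L0 > 0]
  grid <- 10^seq(log10(min(pos)) - 0.5, log10(max(pos)) + 0.5, length.out = 200)
  plot(L0, x$data$y, log = "x", xlab = "[L0] (M)", ylab = "signal",
       main = sprintf("Kd = %.3g uM", x$kd * 1e6), ...)
  lines(grid, predict(x, grid))
  invisible(x)
}

#' Percentile-bootstrap confidence interval for a fitted Kd
#'
#' Case resampling: titration points are resampled with replacement and the
#' model refitted; the interval is the percentile range of the bootstrap Kd
#' distribution.
#'
#' @param fit a \code{\link{fit_kd}} result.
#' @param n_boot number of bootstrap refits.
#' @param conf confidence level.
#' @param seed integer seed.
#' @return named numeric: \code{lower}, \code{upper} (molar).
#' @export
bootstrap_kd_ci <- function(fit, n_boot = 200, conf = 0.95, seed = NULL) {
  if (!inherits(fit, "kd_fit")) stopf("'fit' must be a kd_fit")
  if (n_boot < 1) stopf("'n_boot' must be >= 1")
  kds <- with_seed(seed, {
    vapply(seq_len(n_boot), function(i) {
      idx <- sample.int(fit$n, fit$n, replace = TRUE)
      tt <- titration(fit$data$L0[idx], fit$data$y[idx], fit$A0)
      res <- tryCatch(fit_kd(tt, init = fit$kd)$kd, error = function(e) NA_real_)
      res
    }, numeric(1))
  })
  qs <- quantile(kds, c((1 - conf) / 2, 1 - (1 - conf) / 2), na.rm = TRUE)
  c(lower = unname(qs[1]), upper = unname(qs[2]))
}
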