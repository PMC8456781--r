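# Independent brute-force oracles used to check the package implementations.
# These deliberately re-derive each quantity from its definition, sharing no
# code with the functions under test.

# Noise-free per-pixel render of a scene's channel, looping over every pixel:
# body disk (anti-aliased rim) combined by max with each filopodium's
# tent-weighted law intensity at the projection of the pixel onto the segment.
oracle_render_channel <- function(scene, law) {
  h <- scene$config$image_size[1]
  w <- scene$config$image_size[2]
  px_sz <- scene$config$pixel_size
  ctr <- scene$cell_center_px
  r <- scene$cell_radius_px
  img <- matrix(0, h, w)
  for (row in seq_len(h)) {
    for (col in seq_len(w)) {
      x <- col - 1
      y <- row - 1
      v <- law$amplitude * law$body_fraction *
        min(max(r - sqrt((x - ctr[1])^2 + (y - ctr[2])^2) + 0.5, 0), 1)
      for (i in seq_along(scene$polylines)) {
        tip <- scene$polylines[[i]][1, ]
        base <- scene$polylines[[i]][2, ]
        seg <- base - tip
        len <- sqrt(sum(seg^2))
        u <- seg / len
        s <- (x - tip[1]) * u[1] + (y - tip[2]) * u[2]
        t <- abs((x - tip[1]) * u[2] - (y - tip[2]) * u[1])
        if (s < 0 || s > len) next
        lawv <- switch(law$spatial_mode,
          tip_exponential = law$amplitude * exp(-(s * px_sz) / law$decay_length),
          uniform = law$amplitude,
          shaft_uniform = if (s * px_sz >= 0.15 * len * px_sz) law$amplitude else 0,
          body_only = 0)
        v <- max(v, lawv * max(0, 1 - t))
      }
      img[row, col] <- min(max(round(v), 0), 65535)
    }
  }
  img
}

# Find-maxima oracle: a local maximum of value v counts unless a strictly
# higher pixel can be reached through pixels of value > v - prominence;
# equal-valued maxima connected within tolerance count once.
oracle_find_maxima_count <- function(img, prominence) {
  h <- nrow(img)
  w <- ncol(img)
  neighbours <- function(p) {
    py <- (p - 1) %% h + 1
    px <- (p - 1) %/% h + 1
    out <- integer(0)
    for (dy in -1:1) for (dx in -1:1) {
      if (dy == 0 && dx == 0) next
      ny <- py + dy
      nx <- px + dx
      if (ny >= 1 && ny <= h && nx >= 1 && nx <= w) {
        out <- c(out, (nx - 1) * h + ny)
      }
    }
    out
  }
  is_local_max <- function(p) all(img[p] >= img[neighbours(p)])
  region_of <- function(p) {
    floor_v <- img[p] - prominence
    seen <- logical(h * w)
    seen[p] <- TRUE
    stack <- p
    while (length(stack)) {
      q <- stack[length(stack)]
      stack <- stack[-length(stack)]
      for (nb in neighbours(q)) {
        if (!seen[nb] && img[nb] > floor_v) {
          seen[nb] <- TRUE
          stack <- c(stack, nb)
        }
      }
    }
    which(seen)
  }
  cands <- Filter(is_local_max, seq_len(h * w))
  kept <- list()
  for (p in cands) {
    reg <- region_of(p)
    if (any(img[reg] > img[p])) next
    kept[[length(kept) + 1]] <- list(p = p, region = reg)
  }
  if (!length(kept)) return(0L)
  # merge equal-valued maxima lying in each other's tolerance region
  k <- length(kept)
  parent <- seq_len(k)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (i != j && kept[[j]]$p %in% kept[[i]]$region) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[rj] <- ri
    }
  }
  length(unique(vapply(seq_len(k), find, integer(1))))
}

# Exhaustive min-distance assignment with a distance gate: maximizes the
# number of links, then minimizes total distance, by enumerating every
# partial injective mapping of A points to B points.
oracle_assign <- function(ax, ay, bx, by, gate) {
  na <- length(ax)
  nb <- length(bx)
  best <- list(links = -1, dist = Inf, map = rep(NA_integer_, na))
  recurse <- function(i, used, map, dist) {
    if (i > na) {
      links <- sum(!is.na(map))
      if (links > best$links ||
          (links == best$links && dist < best$dist)) {
        best <<- list(links = links, dist = dist, map = map)
      }
      return(invisible())
    }
    recurse(i + 1, used, map, dist)  # leave a_i unmatched
    for (j in seq_len(nb)) {
      if (used[j]) next
      d <- sqrt((ax[i] - bx[j])^2 + (ay[i] - by[j])^2)
      if (d > gate) next
      used[j] <- TRUE
      map[i] <- j
      recurse(i + 1, used, map, dist + d)
      used[j] <- FALSE
      map[i] <- NA_integer_
    }
  }
  recurse(1, logical(nb), rep(NA_integer_, na), 0)
  best$map
}

# Direct 40-bin median binning from the definition: sample i of n (0-based)
# goes to bin floor(i * n_bins / n).
oracle_bin <- function(x, n_bins = 40) {
  n <- length(x)
  vapply(seq_len(n_bins) - 1, function(b) {
    ix <- which(floor((seq_len(n) - 1) * n_bins / n) == b)
    median(x[ix])
  }, numeric(1))
}

# Gaussian spot test image: spots is a data.frame with x, y (0-based pixel
# centres), amplitude; sigma in pixels.
gaussian_spot_image <- function(h, w, spots, sigma = 2) {
  xg <- matrix(rep(0:(w - 1), each = h), nrow = h)
  yg <- matrix(rep(0:(h - 1), times = w), nrow = h)
  img <- matrix(0, h, w)
  for (i in seq_len(nrow(spots))) {
    img <- img + spots$amplitude[i] *
      exp(-((xg - spots$x[i])^2 + (yg - spots$y[i])^2) / (2 * sigma^2))
  }
  img
}

# Bisection root of the binding quadratic AL^2 - (A0+L0+Kd) AL + A0 L0 = 0
# on [0, min(A0, L0)].
oracle_complex_root <- function(A0, L0, Kd) {
  f <- function(al) al^2 - (A0 + L0 + Kd) * al + A0 * L0
  lo <- 0
  hi <- min(A0, L0)
  if (f(hi) > 0) return(hi)
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# Trapezoidal integral, independent of the package's internals.
trapz_test <- function(x, y) {
  sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
}
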