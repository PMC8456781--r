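# Internal helpers shared across modules.

# Run `code` with the RNG seeded to `seed`, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(code)
}

# Clip to the unsigned 16-bit range and round to integer ADU.
clip16 <- function(x) {
  pmin(pmax(round(x), 0), 65535)
}

# Bilinear interpolation of a matrix at 0-based pixel-centre coordinates.
# img[row, col] holds the pixel at x = col - 1, y = row - 1. Points are
# clamped to the image border.
bilinear <- function(img, x, y) {
  h <- nrow(img)
  w <- ncol(img)
  x <- pmin(pmax(x, 0), w - 1)
  y <- pmin(pmax(y, 0), h - 1)
  x0 <- pmin(floor(x), w - 2)
  y0 <- pmin(floor(y), h - 2)
  fx <- x - x0
  fy <- y - y0
  i00 <- img[cbind(y0 + 1, x0 + 1)]
  i01 <- img[cbind(y0 + 1, x0 + 2)]
  i10 <- img[cbind(y0 + 2, x0 + 1)]
  i11 <- img[cbind(y0 + 2, x0 + 2)]
  (1 - fy) * ((1 - fx) * i00 + fx * i01) + fy * ((1 - fx) * i10 + fx * i11)
}

# Trapezoidal integral of y over x.
trapz <- function(x, y) {
  sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
}

# 32-bit FNV-1a hash of a character string; used to derive per-stage seeds
# and config fingerprints without extra dependencies.
fnv1a32 <- function(s) {
  bytes <- as.integer(charToRaw(s))
  h <- 2166136261
  for (b in bytes) {
    # xor on the low byte only (b < 256); h stays a double below 2^32
    h <- h - h %% 256 + bitwXor(h %% 256, b)
    # 32-bit multiply by the FNV prime 16777619 in 16-bit halves so every
    # intermediate stays well under 2^53
    lo <- h %% 65536
    hi <- h %/% 65536
    h <- (lo * 16777619 + ((hi * 16777619) %% 65536) * 65536) %% 4294967296
  }
  h
}

# Derive a per-stage seed below 2^31 from a global seed and a stage label.
derive_seed <- function(global_seed, stage) {
  as.integer((global_seed %% 65536) * 32749 + fnv1a32(stage) %% 32749) %% 2147483647L
}

stopf <- function(fmt, ...) {
  stop(sprintf(fmt, ...), call. = FALSE)
}

check_number <- function(x, name, lower = -Inf, upper = Inf, strict = FALSE) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x)) {
    stopf("'%s' must be a single number", name)
  }
  ok <- if (strict) x > lower && x < upper else x >= lower && x <= upper
  if (!ok) stopf("'%s' = %g is out of range", name, x)
  invisible(x)
}
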