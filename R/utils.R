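# Internal helpers shared across modules.
#
# Image convention used throughout the package: a grayscale image is a numeric
# matrix with rows indexing y (top-down) and columns indexing x (left-right).
# Pixel coordinates are 0-based with pixel centers at integer positions, so
# pixel (x, y) lives at image[y + 1, x + 1]. Rectangles are half-open:
# [x0, x1) x [y0, y1).

#' Evaluate code with a temporary RNG seed
#'
#' Sets the RNG to a known state, runs `expr`, and restores the caller's
#' RNG state afterwards so library code never perturbs user-level randomness.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed %% 2147483647L))
  expr
}

# Deterministic fan-out of one global seed into per-object streams.
# Documented scheme: stream k of seed s is (s + 7919 * k) mod (2^31 - 1).
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) + 7919 * as.numeric(k)) %% 2147483647)
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)

check_positive <- function(x, field) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x <= 0)) {
    stopf("field '%s' must be positive and finite", field)
  }
  invisible(x)
}

check_nonnegative <- function(x, field) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0)) {
    stopf("field '%s' must be nonnegative and finite", field)
  }
  invisible(x)
}

# Clip the segment (x0,y0)-(x1,y1) to the rectangle [xmin,xmax] x [ymin,ymax]
# (Liang-Barsky). Returns NULL when the segment lies fully outside.
clip_segment <- function(x0, y0, x1, y1, xmin, xmax, ymin, ymax) {
  dx <- x1 - x0
  dy <- y1 - y0
  p <- c(-dx, dx, -dy, dy)
  q <- c(x0 - xmin, xmax - x0, y0 - ymin, ymax - y0)
  t0 <- 0
  t1 <- 1
  for (i in 1:4) {
    if (p[i] == 0) {
      if (q[i] < 0) return(NULL)
    } else {
      r <- q[i] / p[i]
      if (p[i] < 0) {
        if (r > t1) return(NULL)
        if (r > t0) t0 <- r
      } else {
        if (r < t0) return(NULL)
        if (r < t1) t1 <- r
      }
    }
  }
  c(x0 + t0 * dx, y0 + t0 * dy, x0 + t1 * dx, y0 + t1 * dy)
}

# Bilinear sampling of a matrix image at 0-based (x, y) positions.
# Out-of-bounds positions return `fill`.
bilinear_sample <- function(img, x, y, fill = 0) {
  h <- nrow(img)
  w <- ncol(img)
  x0 <- floor(x)
  y0 <- floor(y)
  fx <- x - x0
  fy <- y - y0
  inside <- x0 >= 0 & y0 >= 0 & x0 <= w - 1 & y0 <= h - 1
  # clamp the upper neighbor at the border so edge pixels sample themselves
  x1 <- pmin(x0 + 1, w - 1)
  y1 <- pmin(y0 + 1, h - 1)
  out <- rep(fill, length(x))
  if (any(inside)) {
    i <- which(inside)
    v00 <- img[cbind(y0[i] + 1, x0[i] + 1)]
    v01 <- img[cbind(y0[i] + 1, x1[i] + 1)]
    v10 <- img[cbind(y1[i] + 1, x0[i] + 1)]
    v11 <- img[cbind(y1[i] + 1, x1[i] + 1)]
    out[i] <- (1 - fy[i]) * ((1 - fx[i]) * v00 + fx[i] * v01) +
      fy[i] * ((1 - fx[i]) * v10 + fx[i] * v11)
  }
  out
}

# 0-based pixel-center coordinate grids for an h x w image, as long vectors
# in column-major matrix order.
pixel_grid <- function(h, w) {
  list(
    x = rep(0:(w - 1), each = h),
    y = rep(0:(h - 1), times = w)
  )
}
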