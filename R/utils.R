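#' @keywords internal
"_PACKAGE"

`%||%` <- function(x, y) if (is.null(x)) y else x

# Run code under a fixed seed without disturbing the caller's RNG state.
with_seed_if <- function(seed, code) {
  if (is.null(seed)) force(code) else withr::with_seed(as.integer(seed), code)
}

# Bilinear sampling of a matrix at continuous pixel coordinates.
# Coordinates are 0-based pixel-centered: x = column - 1, y = row - 1,
# y increasing downward. Points outside the grid return `outside`.
# If `mask` is supplied, only in-mask neighbors contribute and the
# weights are renormalized; a point with no in-mask neighbor returns
# `outside`.
sample_bilinear <- function(mat, x, y, mask = NULL, outside = 0) {
  ny <- nrow(mat); nx <- ncol(mat)
  x0 <- floor(x); y0 <- floor(y)
  fx <- x - x0; fy <- y - y0
  val <- numeric(length(x))
  wsum <- numeric(length(x))
  for (k in 1:4) {
    dx <- c(0L, 1L, 0L, 1L)[k]
    dy <- c(0L, 0L, 1L, 1L)[k]
    xi <- x0 + dx; yi <- y0 + dy
    w <- (if (dx == 0) 1 - fx else fx) * (if (dy == 0) 1 - fy else fy)
    ok <- xi >= 0 & xi < nx & yi >= 0 & yi < ny & w > 0
    if (!is.null(mask)) {
      ok[ok] <- mask[cbind(yi[ok] + 1L, xi[ok] + 1L)]
    }
    idx <- which(ok)
    if (length(idx)) {
      val[idx] <- val[idx] + w[idx] * mat[cbind(yi[idx] + 1L, xi[idx] + 1L)]
      wsum[idx] <- wsum[idx] + w[idx]
    }
  }
  out <- ifelse(wsum > 0, val / wsum, outside)
  as.numeric(out)
}

# Polygon for an ellipse in pixel coordinates, semi-axes in pixels,
# major axis along `u` (unit vector), `n` vertices.
ellipse_polygon <- function(center, semi_major, semi_minor, u, n = 64L) {
  v <- c(-u[2], u[1])
  th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  x <- center[1] + semi_major * cos(th) * u[1] + semi_minor * sin(th) * v[1]
  y <- center[2] + semi_major * cos(th) * u[2] + semi_minor * sin(th) * v[2]
  cbind(x = x, y = y)
}

# Trapezoidal area under y(x); thin wrapper so all AUCs share one rule.
trapezoid_auc <- function(x, y) pracma::trapz(x, y)

stop_if_not_scalar_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    stop(sprintf("`%s` must be a single positive number", name), call. = FALSE)
}
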