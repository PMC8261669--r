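#' Convert a 3-channel image between color spaces
#'
#' Represents an RGB composite (channels in `[0,1]`) in one of the color
#' spaces used by the stepwise background removal: HSV, YCbCr (ITU-R BT.601,
#' studio swing, as in common image toolboxes) or CIE Lab (sRGB companding,
#' D65 white point). All transforms are exactly invertible on in-gamut
#' values via [from_color_space()].
#'
#' @param img3 `rows x cols x 3` array with values in `[0,1]` (RGB order).
#' @param space one of `"HSV"`, `"YCbCr"`, `"Lab"`.
#' @return `rows x cols x 3` array in the requested space. HSV channels are
#'   all in `[0,1]` (hue as a fraction of the circle); YCbCr channels are in
#'   `[0,1]` with the neutral chroma midpoint at `128/255`; Lab channels are
#'   on the usual L in `[0,100]`, a/b roughly `[-110,110]` scales.
#' @examples
#' gray <- array(0.5, dim = c(2, 2, 3))
#' to_color_space(gray, "HSV")[, , 2]  # saturation 0
#' @export
to_color_space <- function(img3, space = c("HSV", "YCbCr", "Lab")) {
  space <- match.arg(space)
  d <- dim(img3)
  stopifnot(length(d) == 3L, d[3] == 3L)
  if (min(img3) < 0 || max(img3) > 1)
    stop("channel values must lie in [0,1]")
  m <- matrix(img3, ncol = 3L)  # pixels x RGB
  out <- switch(space,
    HSV = t(grDevices::rgb2hsv(t(m), maxColorValue = 1)),
    YCbCr = .rgb_to_ycbcr(m),
    Lab = .rgb_to_lab(m)
  )
  array(out, dim = d, dimnames = list(NULL, NULL, colnames(out)))
}

#' Invert a color-space transform back to RGB
#'
#' @param img3 `rows x cols x 3` array produced by [to_color_space()].
#' @param space the space `img3` is in.
#' @return RGB array with channels in `[0,1]`.
#' @export
from_color_space <- function(img3, space = c("HSV", "YCbCr", "Lab")) {
  space <- match.arg(space)
  d <- dim(img3)
  stopifnot(length(d) == 3L, d[3] == 3L)
  m <- matrix(img3, ncol = 3L)
  out <- switch(space,
    HSV = .hsv_to_rgb(m),
    YCbCr = .ycbcr_to_rgb(m),
    Lab = .lab_to_rgb(m)
  )
  array(out, dim = d, dimnames = list(NULL, NULL, c("r", "g", "b")))
}

# ---- YCbCr (BT.601 studio swing, channels scaled to [0,1]) ----

.ycbcr_fwd <- rbind(c(65.481, 128.553, 24.966),
                    c(-37.797, -74.203, 112),
                    c(112, -93.786, -18.214))

.rgb_to_ycbcr <- function(m) {
  out <- m %*% t(.ycbcr_fwd) / 255
  out <- sweep(out, 2, c(16, 128, 128) / 255, `+`)
  colnames(out) <- c("y", "cb", "cr")
  out
}

.ycbcr_to_rgb <- function(m) {
  m <- sweep(m, 2, c(16, 128, 128) / 255, `-`) * 255
  out <- m %*% t(solve(.ycbcr_fwd))
  colnames(out) <- c("r", "g", "b")
  out
}

# ---- HSV (inverse of grDevices::rgb2hsv; h, s, v all in [0,1]) ----

.hsv_to_rgb <- function(m) {
  h <- m[, 1] * 6; s <- m[, 2]; v <- m[, 3]
  i <- floor(h) %% 6
  f <- h - floor(h)
  p <- v * (1 - s); q <- v * (1 - s * f); tt <- v * (1 - s * (1 - f))
  r <- g <- b <- v
  r[i == 1] <- q[i == 1]; r[i == 2] <- p[i == 2]; r[i == 3] <- p[i == 3]
  r[i == 4] <- tt[i == 4]
  g[i == 0] <- tt[i == 0]; g[i == 3] <- q[i == 3]; g[i == 4] <- p[i == 4]
  g[i == 5] <- p[i == 5]
  b[i == 0] <- p[i == 0]; b[i == 1] <- p[i == 1]; b[i == 2] <- tt[i == 2]
  b[i == 5] <- q[i == 5]
  cbind(r = r, g = g, b = b)
}

# ---- CIE Lab (sRGB companding, D65 white), closed form both ways ----

.srgb_to_xyz_m <- rbind(c(0.4124564, 0.3575761, 0.1804375),
                        c(0.2126729, 0.7151522, 0.0721750),
                        c(0.0193339, 0.1191920, 0.9503041))
# white point taken as the matrix image of RGB white, so neutral inputs map
# to a = b = 0 exactly
.d65 <- rowSums(.srgb_to_xyz_m)

.srgb_decompand <- function(u) ifelse(u <= 0.04045, u / 12.92,
                                      ((u + 0.055) / 1.055)^2.4)
.srgb_compand <- function(u) ifelse(u <= 0.0031308, 12.92 * u,
                                    1.055 * u^(1 / 2.4) - 0.055)

.lab_f <- function(t) ifelse(t > (6 / 29)^3, t^(1 / 3),
                             t / (3 * (6 / 29)^2) + 4 / 29)
.lab_finv <- function(t) ifelse(t > 6 / 29, t^3, 3 * (6 / 29)^2 * (t - 4 / 29))

.rgb_to_lab <- function(m) {
  xyz <- .srgb_decompand(m) %*% t(.srgb_to_xyz_m)
  fxyz <- .lab_f(sweep(xyz, 2, .d65, `/`))
  out <- cbind(l = 116 * fxyz[, 2] - 16,
               a = 500 * (fxyz[, 1] - fxyz[, 2]),
               b = 200 * (fxyz[, 2] - fxyz[, 3]))
  out
}

.lab_to_rgb <- function(m) {
  fy <- (m[, 1] + 16) / 116
  fx <- fy + m[, 2] / 500
  fz <- fy - m[, 3] / 200
  xyz <- sweep(.lab_finv(cbind(fx, fy, fz)), 2, .d65, `*`)
  out <- .srgb_compand(xyz %*% t(solve(.srgb_to_xyz_m)))
  colnames(out) <- c("r", "g", "b")
  out
}
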