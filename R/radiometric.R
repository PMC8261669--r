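#' Convert raw digital numbers to radiance
#'
#' Inverts the sensor part of the forward model of [render_raw_capture()]
#' (flat vignette): `radiance = dn / (gain * exposure * 65535)`, in model
#' radiance units. Dividing out gain and exposure makes captures taken at
#' different camera settings comparable; the remaining per-band illumination
#' scale is what panel-based calibration removes.
#'
#' @param dn_band numeric matrix of digital numbers in `[0, 65535]`.
#' @param gain,exposure positive per-band sensor settings.
#' @return Radiance matrix (non-negative).
#' @export
dn_to_radiance <- function(dn_band, gain, exposure) {
  if (gain <= 0 || exposure <= 0) stop("gain and exposure must be positive")
  dn_band / (gain * exposure * 65535)
}

#' Summarize the calibration reflectance panel
#'
#' Converts each band's panel capture to radiance and averages over a central
#' crop (the central 50 percent box, standing in for the interactive panel
#' crop), pairing it with the panel's known reflectance.
#'
#' @param capture a `raw_capture`.
#' @return Object of class `panel_reading`: list with per-band `radiance`
#'   (positive scalars) and `known_reflectance`.
#' @export
panel_reading <- function(capture) {
  stopifnot(inherits(capture, "raw_capture"))
  rad <- numeric(5L)
  for (b in seq_len(5L)) {
    p <- capture$panel_dn[[b]]
    nr <- nrow(p); nc <- ncol(p)
    ri <- seq.int(floor(nr / 4) + 1, ceiling(3 * nr / 4))
    ci <- seq.int(floor(nc / 4) + 1, ceiling(3 * nc / 4))
    rad[b] <- mean(dn_to_radiance(p[ri, ci, drop = FALSE],
                                  capture$gains[b], capture$exposures[b]))
  }
  if (any(rad <= 0)) stop("unusable panel capture: zero panel radiance")
  structure(list(radiance = rad, known_reflectance = capture$panel_reflectance),
            class = "panel_reading")
}

#' Unified-factor reflectance calibration
#'
#' The panel-based calibration: for each band a single scale factor
#' `factor_b = known_reflectance_b / panel_radiance_b` converts radiance to
#' reflectance, assuming illumination constant over the mission. Values are
#' clipped to `[0,1]` and the number of clipped pixels recorded.
#'
#' @param capture a `raw_capture`.
#' @param panel optionally a precomputed [panel_reading()]; defaults to the
#'   capture's own panel.
#' @return A `reflectance_stack`: `rows x cols x 5` array in `[0,1]` with
#'   attributes `method = "unified_factor"` and `n_clipped`.
#' @export
unified_factor_reflectance <- function(capture, panel = panel_reading(capture)) {
  stopifnot(inherits(capture, "raw_capture"), inherits(panel, "panel_reading"))
  d1 <- dim(capture$dn_bands[[1]])
  out <- array(0, dim = c(d1[1], d1[2], 5L),
               dimnames = list(NULL, NULL, FLOOD_BANDS))
  n_clipped <- 0L
  for (b in seq_len(5L)) {
    rad <- dn_to_radiance(capture$dn_bands[[b]], capture$gains[b],
                          capture$exposures[b])
    refl <- rad * (panel$known_reflectance[b] / panel$radiance[b])
    n_clipped <- n_clipped + sum(refl < 0 | refl > 1)
    out[, , b] <- pmin(pmax(refl, 0), 1)
  }
  structure(out, method = "unified_factor", n_clipped = n_clipped,
            class = c("reflectance_stack", "array"))
}

#' Max-min reflectance rescaling
#'
#' Rescales each band's digital numbers linearly from `[0, 65535]` to
#' `[0, 1]`. No panel is involved, so the result is robust to exposure
#' auto-compensation between images but is not an absolute reflectance.
#'
#' @param capture a `raw_capture`.
#' @return A `reflectance_stack` with `method = "max_min"`.
#' @export
maxmin_reflectance <- function(capture) {
  stopifnot(inherits(capture, "raw_capture"))
  d1 <- dim(capture$dn_bands[[1]])
  out <- array(0, dim = c(d1[1], d1[2], 5L),
               dimnames = list(NULL, NULL, FLOOD_BANDS))
  for (b in seq_len(5L)) out[, , b] <- capture$dn_bands[[b]] / 65535
  structure(out, method = "max_min", n_clipped = 0L,
            class = c("reflectance_stack", "array"))
}

#' @export
print.reflectance_stack <- function(x, ...) {
  cat(sprintf("Reflectance stack %d x %d x 5 (%s), %d pixel(s) clipped\n",
              dim(x)[1], dim(x)[2], attr(x, "method"), attr(x, "n_clipped")))
  invisible(x)
}
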