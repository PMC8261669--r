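#' Render a scene to a raw 16-bit digital-number capture
#'
#' Applies the documented forward sensor model per band b:
#' `DN = round(clip(reflectance * illumination_b * gain_b * exposure_b * 65535,
#' 0, 65535))` (a flat vignette), and renders the calibration reflectance
#' panel with the same model (the panel sees the nominal illumination of the
#' mission start, so a per-plot illumination drop -- the optional sudden
#' light change -- is not reflected in the panel capture). Panel-based
#' calibration of the output recovers the input reflectance to within the
#' DN quantization step.
#'
#' @param scene a `plot_scene`.
#' @param config the [sim_config()] in force (gains, exposures, illumination,
#'   panel reflectance).
#' @return An object of class `raw_capture`: list with `dn_bands` (five
#'   integer-valued matrices), `panel_dn` (five small panel rasters),
#'   `gains`, `exposures`, `panel_reflectance`, the thermal raster (thermal
#'   cameras report degC directly) and plot metadata.
#' @export
render_raw_capture <- function(scene, config) {
  stopifnot(inherits(scene, "plot_scene"))
  if (any(config$band_gains <= 0) || any(config$band_exposures <= 0))
    stop("band gains and exposures must be positive")
  illum_factor <- if (is.null(scene$illum_factor)) 1 else scene$illum_factor
  dn_bands <- vector("list", 5L); names(dn_bands) <- FLOOD_BANDS
  panel_dn <- vector("list", 5L); names(panel_dn) <- FLOOD_BANDS
  for (b in seq_len(5L)) {
    scale_b <- config$illumination[b] * config$band_gains[b] *
      config$band_exposures[b] * 65535
    dn_bands[[b]] <- round(pmin(pmax(
      scene$reflectance[, , b] * scale_b * illum_factor, 0), 65535))
    panel_dn[[b]] <- matrix(round(pmin(pmax(
      config$panel_reflectance[b] * scale_b, 0), 65535)), 16L, 16L)
  }
  structure(list(
    plot_id = scene$plot_id, fis = scene$fis, height_m = scene$height_m,
    dn_bands = dn_bands, panel_dn = panel_dn,
    gains = config$band_gains, exposures = config$band_exposures,
    panel_reflectance = config$panel_reflectance,
    thermal = scene$thermal,
    gsd_mm_ms = scene$gsd_mm_ms, gsd_mm_thermal = scene$gsd_mm_thermal
  ), class = "raw_capture")
}

#' @export
print.raw_capture <- function(x, ...) {
  cat(sprintf("Raw capture %s (FIS %d, %g m): 5 DN bands %d x %d, panel %d x %d\n",
              x$plot_id, x$fis, x$height_m,
              nrow(x$dn_bands[[1]]), ncol(x$dn_bands[[1]]),
              nrow(x$panel_dn[[1]]), ncol(x$panel_dn[[1]])))
  invisible(x)
}
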