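#' Multispectral band order used throughout the package
#'
#' Band order of the five-band multispectral stacks: blue, green, red,
#' red edge, near infrared (NIR), matching a typical five-band agricultural
#' multispectral camera.
#'
#' @export
FLOOD_BANDS <- c("blue", "green", "red", "rededge", "nir")

#' Simulation configuration for synthetic soybean flooding-injury fields
#'
#' Builds the parameter set that drives [generate_field()]. The defaults
#' describe a field of 724 single-row soybean breeding plots scored with a
#' five-level flooding injury score (FIS, 1 = no apparent injury,
#' 5 = most plants severely injured or dead), imaged at 20 m above ground
#' with a five-band multispectral camera (13.2 mm/pixel) and a thermal
#' camera (23.4 mm/pixel). Higher flights (50/80 m) are realised by
#' [degrade_to_height()] as resolution loss plus thermal atmospheric
#' attenuation.
#'
#' Each plot scene is composed of three ground classes:
#' \describe{
#'   \item{canopy}{an elongated noisy super-ellipse along the row axis whose
#'     area fraction, NDVI and temperature depend on FIS (cooler, greener and
#'     larger at low FIS);}
#'   \item{soil}{sunlit bare soil, hot (52.3 degC) and low-NDVI;}
#'   \item{shadow}{shaded soil/plant residue, dark in all bands and a few
#'     degrees cooler (48.5 degC) than sunlit soil, assigned blockwise so
#'     that contiguous pure-soil patches remain.}
#' }
#' The default FIS-conditional means are calibrated so that, under the default
#' class mixture `fis_probs`, the field-wide mean canopy temperature is
#' 39.0 degC, the mean canopy NDVI is 0.51, sunlit soil is 52.3 degC and the
#' pooled non-canopy background averages 49.4 degC at 20 m.
#'
#' @param n_plots number of plots in the field (default 724).
#' @param fis_probs length-5 probability vector of FIS class proportions.
#' @param plot_px_20m integer (rows, cols) of the multispectral plot ROI at
#'   20 m; rows run along the planted row (the "length" axis).
#' @param gsd_mm_ms,gsd_mm_thermal named numeric vectors mapping flight height
#'   ("20","50","80") to ground sampling distance in mm/pixel for the
#'   multispectral and thermal sensors.
#' @param canopy_temp_mean_c length-5 vector, mean canopy temperature (degC)
#'   at 20 m for FIS 1..5.
#' @param soil_temp_mean_c,shadow_temp_mean_c sunlit-soil and shaded-background
#'   temperatures (degC) at 20 m.
#' @param shadow_frac fraction of the non-canopy background assigned to the
#'   shadow class (blockwise).
#' @param canopy_ndvi_mean length-5 vector, mean canopy NDVI for FIS 1..5.
#' @param soil_ndvi_mean NDVI of sunlit soil.
#' @param canopy_refl_sum reflectance sum NIR + red used to place the canopy
#'   NIR/red bands on the configured NDVI (see Details).
#' @param canopy_area_frac length-5 vector, fraction of the ROI covered by
#'   canopy for FIS 1..5.
#' @param canopy_porosity fraction of the canopy envelope occupied by small
#'   sunlit gaps between plants/leaves. The gaps are resolvable at the 20 m
#'   ground sampling distance (so K-means rejects them from the thermal
#'   canopy cluster and color segmentation removes them) but blend into
#'   canopy pixels at 50/80 m -- the mechanism by which apparent canopy
#'   temperature rises and NDVI falls with flight height.
#' @param noise_sd_refl per-pixel Gaussian reflectance noise SD (all bands).
#' @param noise_sd_thermal per-pixel thermal noise SD (degC).
#' @param plot_sd_temp,plot_sd_ndvi,plot_sd_area between-plot random-effect
#'   SDs for canopy temperature (degC), canopy NDVI and canopy area fraction.
#' @param band_gains,band_exposures per-band positive sensor gain and exposure
#'   scalars of the raw digital-number (DN) forward model.
#' @param illumination per-band illumination scale of the forward model; this
#'   is what panel-based calibration must divide out.
#' @param panel_reflectance per-band known reflectance of the calibration
#'   reflectance panel, in (0,1).
#' @param attenuation_tau named vector mapping height to thermal atmospheric
#'   transmissivity in (0,1]; the observed temperature is
#'   `tau * T + (1 - tau) * ambient`.
#' @param thermal_blur_px named vector mapping degraded heights ("50","80")
#'   to the Gaussian point-spread-function SD, in output pixels, applied to
#'   the thermal raster after downsampling: single raw thermal frames at
#'   altitude carry optical/motion blur that mixes canopy edges beyond pure
#'   footprint averaging, increasingly so at 80 m. Tuned jointly with
#'   `attenuation_tau` to reproduce the observed height trends (apparent
#'   canopy warming, soil cooling); set to 0 to disable.
#' @param ambient_temp_c ambient air temperature (degC), default 33.4.
#' @param exposure_drop optional list `list(frac=, factor=)` applying a global
#'   exposure drop to a random fraction of plots (emulating a sudden light
#'   change during a mission); `NULL` (default) disables it.
#' @param seed integer seed controlling all randomness of the generator.
#'
#' @details
#' Per-pixel canopy NIR and red reflectance are solved from the target NDVI
#' `n` and band sum `s = canopy_refl_sum`: `NIR = s(1+n)/2`, `red = s(1-n)/2`,
#' so that the NDVI of the noise-free scene equals the configured mean
#' exactly. The remaining bands are fixed class spectra chosen so the
#' stepwise color-space segmentation can separate the classes.
#'
#' @return An object of class `sim_config` (a validated list).
#' @seealso [generate_field()], [degrade_to_height()], [render_raw_capture()]
#' @export
sim_config <- function(n_plots = 724L,
                       fis_probs = c(0.18, 0.27, 0.27, 0.18, 0.10),
                       plot_px_20m = c(80L, 40L),
                       gsd_mm_ms = c(`20` = 13.2, `50` = 34.7, `80` = 55.6),
                       gsd_mm_thermal = c(`20` = 23.4, `50` = 68.0, `80` = 108.8),
                       canopy_temp_mean_c = c(37.25, 38.25, 39.25, 40.25, 41.25),
                       soil_temp_mean_c = 52.3,
                       shadow_temp_mean_c = 48.5,
                       shadow_frac = 0.7632,
                       canopy_ndvi_mean = c(0.615, 0.555, 0.495, 0.435, 0.375),
                       soil_ndvi_mean = 0.10,
                       canopy_refl_sum = 0.45,
                       canopy_area_frac = c(0.60, 0.52, 0.44, 0.36, 0.25),
                       canopy_porosity = 0.15,
                       noise_sd_refl = 0.012,
                       noise_sd_thermal = 0.5,
                       plot_sd_temp = 0.30,
                       plot_sd_ndvi = 0.02,
                       plot_sd_area = 0.02,
                       band_gains = rep(0.8, 5),
                       band_exposures = rep(0.6, 5),
                       illumination = c(1.05, 1.10, 1.00, 0.95, 0.90),
                       panel_reflectance = rep(0.49, 5),
                       attenuation_tau = c(`20` = 1.0, `50` = 0.9259, `80` = 0.7989),
                       thermal_blur_px = c(`50` = 0.25, `80` = 0.9),
                       ambient_temp_c = 33.4,
                       exposure_drop = NULL,
                       seed = 1L) {
  cfg <- list(
    n_plots = as.integer(n_plots), fis_probs = fis_probs,
    plot_px_20m = as.integer(plot_px_20m),
    gsd_mm_ms = gsd_mm_ms, gsd_mm_thermal = gsd_mm_thermal,
    canopy_temp_mean_c = canopy_temp_mean_c,
    soil_temp_mean_c = soil_temp_mean_c,
    shadow_temp_mean_c = shadow_temp_mean_c,
    shadow_frac = shadow_frac,
    canopy_ndvi_mean = canopy_ndvi_mean,
    soil_ndvi_mean = soil_ndvi_mean,
    canopy_refl_sum = canopy_refl_sum,
    canopy_area_frac = canopy_area_frac,
    canopy_porosity = canopy_porosity,
    noise_sd_refl = noise_sd_refl, noise_sd_thermal = noise_sd_thermal,
    plot_sd_temp = plot_sd_temp, plot_sd_ndvi = plot_sd_ndvi,
    plot_sd_area = plot_sd_area,
    band_gains = band_gains, band_exposures = band_exposures,
    illumination = illumination,
    panel_reflectance = panel_reflectance,
    attenuation_tau = attenuation_tau,
    thermal_blur_px = thermal_blur_px,
    ambient_temp_c = ambient_temp_c,
    exposure_drop = exposure_drop,
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$n_plots < 5L)
    stop("n_plots must be at least 5 (one per FIS level)")
  if (length(cfg$fis_probs) != 5L || any(cfg$fis_probs < 0))
    stop("fis_probs must be 5 non-negative proportions")
  if (abs(sum(cfg$fis_probs) - 1) > 1e-12)
    stop("fis_probs must sum to 1")
  if (length(cfg$plot_px_20m) != 2L || any(cfg$plot_px_20m < 8L))
    stop("plot_px_20m must give at least 8x8 pixels")
  for (nm in c("canopy_temp_mean_c", "canopy_ndvi_mean", "canopy_area_frac"))
    if (length(cfg[[nm]]) != 5L || any(!is.finite(cfg[[nm]])))
      stop(nm, " must be a finite length-5 vector (FIS 1..5)")
  if (any(cfg$canopy_temp_mean_c >= cfg$soil_temp_mean_c))
    stop("canopy must be cooler than sunlit soil for every FIS")
  if (any(cfg$canopy_ndvi_mean <= cfg$soil_ndvi_mean))
    stop("canopy NDVI must exceed soil NDVI for every FIS")
  if (any(cfg$canopy_area_frac < 0) || any(cfg$canopy_area_frac > 0.95))
    stop("canopy_area_frac must be in [0, 0.95]")
  if (cfg$canopy_porosity < 0 || cfg$canopy_porosity >= 0.5)
    stop("canopy_porosity must lie in [0, 0.5)")
  for (nm in c("gsd_mm_ms", "gsd_mm_thermal")) {
    g <- cfg[[nm]]
    if (!all(c("20", "50", "80") %in% names(g)))
      stop(nm, " must be named with heights 20, 50, 80")
    if (any(diff(g[c("20", "50", "80")]) <= 0))
      stop(nm, " must be strictly increasing with height")
  }
  if (any(cfg$band_gains <= 0) || any(cfg$band_exposures <= 0))
    stop("band gains and exposures must be positive")
  if (any(cfg$panel_reflectance <= 0) || any(cfg$panel_reflectance >= 1))
    stop("panel_reflectance must lie in (0,1)")
  tau <- cfg$attenuation_tau
  if (any(tau <= 0) || any(tau > 1))
    stop("attenuation_tau must lie in (0,1]")
  if (cfg$shadow_frac < 0 || cfg$shadow_frac > 1)
    stop("shadow_frac must lie in [0,1]")
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic flooding-injury field configuration\n")
  cat(sprintf("  plots: %d   FIS proportions: %s\n", x$n_plots,
              paste(format(x$fis_probs), collapse = " ")))
  cat(sprintf("  plot ROI at 20 m: %d x %d px (multispectral, %.1f mm/px)\n",
              x$plot_px_20m[1], x$plot_px_20m[2], x$gsd_mm_ms[["20"]]))
  cat(sprintf("  canopy temp (FIS 1..5): %s degC; soil %.1f, shadow %.1f degC\n",
              paste(format(x$canopy_temp_mean_c), collapse = " "),
              x$soil_temp_mean_c, x$shadow_temp_mean_c))
  cat(sprintf("  canopy NDVI (FIS 1..5): %s; soil %.2f\n",
              paste(format(x$canopy_ndvi_mean), collapse = " "),
              x$soil_ndvi_mean))
  cat(sprintf("  seed: %d\n", x$seed))
  invisible(x)
}

# Fixed class spectra (reflectance) of the non-canopy classes and the
# non-NIR/red canopy bands; order blue, green, red, rededge, nir.
# Canopy red/NIR come from the configured NDVI (see sim_config Details).
.class_spectra <- list(
  canopy = c(blue = 0.05, green = 0.13, red = NA, rededge = 0.33, nir = NA),
  soil   = c(blue = 0.15, green = 0.22, red = NA, rededge = 0.24, nir = NA),
  shadow = c(blue = 0.02, green = 0.035, red = 0.022, rededge = 0.035,
             nir = 0.042)
)

# soil red/NIR from soil NDVI with band sum 0.55
.soil_refl_sum <- 0.55
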