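#' Per-pixel NDVI and its masked mean
#'
#' NDVI = (NIR - R) / (NIR + R) on reflectance values. Pixels with
#' NIR + R = 0 are undefined (NA) and excluded from the mean.
#'
#' @param stack a `reflectance_stack` (or 5-band array with named bands).
#' @param mask optional `canopy_mask` (or logical matrix) restricting the
#'   mean; `NULL` averages over all defined pixels.
#' @return List with `ndvi` (matrix, NA where undefined) and `mean` (the
#'   masked mean; NA with an `invalid` flag when the mask is empty).
#' @export
compute_ndvi <- function(stack, mask = NULL) {
  stopifnot(length(dim(stack)) == 3L)
  nir <- unclass(stack)[, , "nir"]
  red <- unclass(stack)[, , "red"]
  s <- nir + red
  ndvi <- ifelse(s == 0, NA_real_, (nir - red) / s)
  m <- if (is.null(mask)) matrix(TRUE, nrow(ndvi), ncol(ndvi)) else
    if (inherits(mask, "canopy_mask")) mask$mask else mask
  vals <- ndvi[m]
  invalid <- !any(m)
  list(ndvi = ndvi,
       mean = if (invalid) NA_real_ else mean(vals, na.rm = TRUE),
       invalid = invalid)
}

#' Canopy geometry from a mask
#'
#' Area is the count of canopy pixels; length is the number of image rows
#' containing at least one canopy pixel (rows run along the planted row);
#' width is the number of occupied image columns.
#'
#' @param mask `canopy_mask` or logical matrix.
#' @return Named numeric vector `c(area_px, width_px, length_px)`; all zero
#'   for an empty mask.
#' @export
canopy_geometry <- function(mask) {
  m <- if (inherits(mask, "canopy_mask")) mask$mask else mask
  stopifnot(is.logical(m) || all(m %in% c(0, 1)))
  m <- m > 0
  c(area_px = sum(m),
    width_px = sum(colSums(m) > 0),
    length_px = sum(rowSums(m) > 0))
}

#' Mean canopy temperature
#'
#' Arithmetic mean of the thermal raster over the canopy mask pixels.
#'
#' @param thermal numeric matrix (degC), on the thermal grid.
#' @param mask `canopy_mask` (from [kmeans_thermal_mask()]) or logical matrix
#'   aligned with `thermal`.
#' @return Mean temperature in degC (NA for an empty mask).
#' @export
canopy_temperature <- function(thermal, mask) {
  m <- if (inherits(mask, "canopy_mask")) mask$mask else mask
  stopifnot(identical(dim(thermal), dim(m)))
  if (!any(m)) return(NA_real_)
  mean(thermal[m])
}

#' Assemble the five plot-level features for one plot
#'
#' Combines the masked NDVI mean, canopy geometry (multispectral grid) and
#' canopy temperature (thermal grid) into one feature record. The two sensor
#' grids differ in resolution and are never resampled onto each other.
#'
#' @param stack calibrated `reflectance_stack` of the plot.
#' @param thermal thermal raster (degC).
#' @param ms_mask `canopy_mask` on the multispectral grid.
#' @param thermal_mask `canopy_mask` on the thermal grid.
#' @param plot_id,fis,height_m plot metadata carried into the record.
#' @return One-row data frame with columns plot_id, fis, height_m,
#'   canopy_temp_c, ndvi_mean, area_px, width_px, length_px, valid.
#' @export
extract_features <- function(stack, thermal, ms_mask, thermal_mask,
                             plot_id = NA_character_, fis = NA_integer_,
                             height_m = NA_real_) {
  geom <- canopy_geometry(ms_mask)
  nd <- compute_ndvi(stack, ms_mask)
  tc <- canopy_temperature(thermal, thermal_mask)
  valid_ms <- if (inherits(ms_mask, "canopy_mask")) ms_mask$valid else
    any(ms_mask)
  valid_th <- if (inherits(thermal_mask, "canopy_mask")) thermal_mask$valid else
    any(if (is.list(thermal_mask)) thermal_mask$mask else thermal_mask)
  data.frame(plot_id = plot_id, fis = fis, height_m = height_m,
             canopy_temp_c = tc, ndvi_mean = nd$mean,
             area_px = unname(geom["area_px"]),
             width_px = unname(geom["width_px"]),
             length_px = unname(geom["length_px"]),
             valid = valid_ms && valid_th && !nd$invalid && !is.na(tc),
             stringsAsFactors = FALSE)
}

#' Run the imaging pipeline over a field and extract the feature table
#'
#' For every plot: render the raw capture, calibrate (unified-factor via the
#' panel, or max-min), segment the multispectral stack with the stepwise
#' procedure and the thermal raster with K-means, and extract the five
#' features. This is the per-height feature table the group comparisons and
#' the FNN classifier consume.
#'
#' @param field a `plot_field` (at any single height).
#' @param method calibration method, `"unified_factor"` or `"max_min"`.
#' @param thr a [threshold_set()].
#' @param seed seed for the per-plot K-means initialisations.
#' @return Data frame, one row per plot (see [extract_features()]).
#' @export
pipeline_features <- function(field, method = c("unified_factor", "max_min"),
                              thr = threshold_set(), seed = 1L) {
  stopifnot(inherits(field, "plot_field"))
  method <- match.arg(method)
  rows <- vector("list", length(field$scenes))
  for (i in seq_along(field$scenes)) {
    sc <- field$scenes[[i]]
    cap <- render_raw_capture(sc, field$config)
    stack <- if (method == "unified_factor") unified_factor_reflectance(cap)
             else maxmin_reflectance(cap)
    ms_mask <- suppressWarnings(remove_background_multispectral(stack, thr))
    th_mask <- kmeans_thermal_mask(cap$thermal, seed = seed + i)
    rows[[i]] <- extract_features(stack, cap$thermal, ms_mask, th_mask,
                                  plot_id = sc$plot_id, fis = sc$fis,
                                  height_m = sc$height_m)
  }
  do.call(rbind, rows)
}
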