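# Thermal rasters are stored in 32-bit float TIFF as degC / .thermal_scale
# (TIFF writing here maps [0,1]); the scale is echoed in simconfig.yaml.
.thermal_scale <- 100

#' Write a field's raw captures to disk
#'
#' Renders every scene with [render_raw_capture()] and writes the on-disk
#' layout: one single-band 16-bit TIFF per DN band (`<plot>_<band>.tif`),
#' one 32-bit float TIFF for thermal (`<plot>_thermal.tif`, degC divided by
#' 100), one panel TIFF per band (`panel_<band>.tif`, shared by the
#' mission), a `manifest.csv` (plot_id, fis, height_m, GSDs, file paths) and
#' a `simconfig.yaml` echo of all generator parameters.
#'
#' @param field a `plot_field`.
#' @param dir output directory (created if needed).
#' @return Invisibly, the manifest data frame.
#' @export
write_captures <- function(field, dir) {
  stopifnot(inherits(field, "plot_field"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- field$config
  man <- field$manifest
  paths <- matrix("", nrow(man), 6L,
                  dimnames = list(NULL, c(FLOOD_BANDS, "thermal")))
  for (i in seq_along(field$scenes)) {
    cap <- render_raw_capture(field$scenes[[i]], cfg)
    for (b in seq_len(5L)) {
      f <- sprintf("%s_%s.tif", cap$plot_id, FLOOD_BANDS[b])
      tiff::writeTIFF(cap$dn_bands[[b]] / 65535, file.path(dir, f),
                      bits.per.sample = 16L)
      paths[i, b] <- f
      if (i == 1L)
        tiff::writeTIFF(cap$panel_dn[[b]] / 65535,
                        file.path(dir, sprintf("panel_%s.tif", FLOOD_BANDS[b])),
                        bits.per.sample = 16L)
    }
    f <- sprintf("%s_thermal.tif", cap$plot_id)
    tiff::writeTIFF(cap$thermal / .thermal_scale, file.path(dir, f),
                    bits.per.sample = 32L)
    paths[i, 6L] <- f
  }
  man <- cbind(man, as.data.frame(paths, stringsAsFactors = FALSE))
  utils::write.csv(man, file.path(dir, "manifest.csv"), row.names = FALSE)
  echo <- unclass(cfg)
  echo$thermal_scale <- .thermal_scale
  echo <- lapply(echo, function(v) if (is.null(v)) "null" else v)
  yaml::write_yaml(echo, file.path(dir, "simconfig.yaml"))
  invisible(man)
}

#' Read raw captures back from disk
#'
#' Reads the layout written by [write_captures()] and reconstructs the
#' `raw_capture` objects (DN bands, shared panel, thermal in degC) together
#' with the manifest.
#'
#' @param dir directory containing `manifest.csv`.
#' @return List with `captures` (list of `raw_capture`), `manifest` and the
#'   `config` echo (plain list).
#' @export
read_captures <- function(dir) {
  man <- utils::read.csv(file.path(dir, "manifest.csv"),
                         stringsAsFactors = FALSE)
  cfg <- yaml::read_yaml(file.path(dir, "simconfig.yaml"))
  tscale <- cfg$thermal_scale
  panel_dn <- lapply(FLOOD_BANDS, function(b)
    round(tiff::readTIFF(file.path(dir, sprintf("panel_%s.tif", b))) * 65535))
  names(panel_dn) <- FLOOD_BANDS
  caps <- vector("list", nrow(man))
  for (i in seq_len(nrow(man))) {
    dn <- lapply(FLOOD_BANDS, function(b)
      round(tiff::readTIFF(file.path(dir, man[[b]][i])) * 65535))
    names(dn) <- FLOOD_BANDS
    caps[[i]] <- structure(list(
      plot_id = man$plot_id[i], fis = man$fis[i], height_m = man$height_m[i],
      dn_bands = dn, panel_dn = panel_dn,
      gains = unlist(cfg$band_gains), exposures = unlist(cfg$band_exposures),
      panel_reflectance = unlist(cfg$panel_reflectance),
      thermal = tiff::readTIFF(file.path(dir, man$thermal[i])) * tscale,
      gsd_mm_ms = man$gsd_mm_ms[i], gsd_mm_thermal = man$gsd_mm_thermal[i]
    ), class = "raw_capture")
  }
  list(captures = caps, manifest = man, config = cfg)
}
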