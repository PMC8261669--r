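#' Generate a synthetic field of soybean plots at 20 m
#'
#' Draws `n_plots` flooding injury scores from `fis_probs` and renders one
#' ground-truth scene per plot at the 20 m flight height: a five-band
#' reflectance stack in `[0,1]` (band order blue/green/red/rededge/NIR), a
#' thermal raster in degC on the (coarser) thermal grid, a boolean canopy
#' truth mask and a ground-class map (canopy/soil/shadow) on both grids.
#' The canopy is a connected, elongated super-ellipse along the row axis
#' (image rows) with a noisy boundary; its area fraction, NDVI and
#' temperature depend on FIS as configured. Identical configurations
#' (including the seed) give bit-identical fields.
#'
#' @param config a [sim_config()] object.
#' @return An object of class `plot_field`: a list with `scenes` (list of
#'   `plot_scene` objects), `manifest` (data frame with plot_id, fis,
#'   height_m, gsd columns) and `config`.
#' @examples
#' fld <- generate_field(sim_config(n_plots = 10, seed = 42))
#' table(fld$manifest$fis)
#' @export
generate_field <- function(config) {
  validate_sim_config(config)
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(config$seed)

  n <- config$n_plots
  fis <- sample.int(5L, n, replace = TRUE, prob = config$fis_probs)
  drop_ids <- integer(0)
  if (!is.null(config$exposure_drop))
    drop_ids <- sample.int(n, max(1L, round(config$exposure_drop$frac * n)))
  scenes <- vector("list", n)
  for (i in seq_len(n)) {
    illum_factor <- if (i %in% drop_ids) config$exposure_drop$factor else 1
    scenes[[i]] <- .make_plot_scene(sprintf("plot%04d", i), fis[i], config,
                                    illum_factor = illum_factor)
  }
  manifest <- data.frame(
    plot_id = vapply(scenes, `[[`, "", "plot_id"),
    fis = fis,
    height_m = 20,
    gsd_mm_ms = config$gsd_mm_ms[["20"]],
    gsd_mm_thermal = config$gsd_mm_thermal[["20"]],
    band_order = paste(FLOOD_BANDS, collapse = "|"),
    stringsAsFactors = FALSE
  )
  structure(list(scenes = scenes, manifest = manifest, config = config),
            class = "plot_field")
}

#' @export
print.plot_field <- function(x, ...) {
  h <- unique(x$manifest$height_m)
  cat(sprintf("Synthetic soybean field: %d plots at %s m\n",
              nrow(x$manifest), paste(h, collapse = "/")))
  cat("FIS histogram:\n")
  print(table(FIS = x$manifest$fis))
  invisible(x)
}

# Low-frequency random field: coarse iid normal grid, bilinearly upsampled.
# Used for the noisy canopy boundary.
.smooth_noise <- function(rows, cols, coarse = c(8L, 4L), sd = 1) {
  g <- matrix(stats::rnorm(coarse[1] * coarse[2], sd = sd), coarse[1], coarse[2])
  ry <- seq(1, coarse[1], length.out = rows)
  rx <- seq(1, coarse[2], length.out = cols)
  y0 <- pmin(floor(ry), coarse[1] - 1L); fy <- ry - y0
  x0 <- pmin(floor(rx), coarse[2] - 1L); fx <- rx - x0
  a <- g[cbind(rep(y0, cols), rep(x0, each = rows))]
  b <- g[cbind(rep(y0 + 1, cols), rep(x0, each = rows))]
  cc <- g[cbind(rep(y0, cols), rep(x0 + 1, each = rows))]
  d <- g[cbind(rep(y0 + 1, cols), rep(x0 + 1, each = rows))]
  fym <- rep(fy, cols); fxm <- rep(fx, each = rows)
  m <- a * (1 - fym) * (1 - fxm) + b * fym * (1 - fxm) +
    cc * (1 - fym) * fxm + d * fym * fxm
  matrix(m, rows, cols)
}

# Super-ellipse canopy mask with target area fraction, elongated along rows.
.canopy_mask <- function(rows, cols, area_frac, boundary_amp = 0.15) {
  if (area_frac <= 0) return(matrix(FALSE, rows, cols))
  p <- 4
  shape_const <- 4 * gamma(1 + 1 / p)^2 / gamma(1 + 2 / p)  # area = const*a*b
  aspect <- 2 * rows / cols  # semi-axis ratio a/b keeps the blob row-elongated
  target <- area_frac * rows * cols
  b <- sqrt(target / (shape_const * aspect))
  a <- aspect * b
  cy <- (rows + 1) / 2 + stats::runif(1, -2, 2)
  cx <- (cols + 1) / 2 + stats::runif(1, -1.5, 1.5)
  dy <- abs((seq_len(rows) - cy) / a)
  dx <- abs((seq_len(cols) - cx) / b)
  f <- outer(dy^p, rep(1, cols)) + outer(rep(1, rows), dx^p)
  eps <- .smooth_noise(rows, cols, sd = boundary_amp)
  f + eps <= 1
}

# Per-pixel red/NIR pair realising a target NDVI at a given band sum.
.ndvi_pair <- function(ndvi, band_sum) {
  c(red = band_sum * (1 - ndvi) / 2, nir = band_sum * (1 + ndvi) / 2)
}

.make_plot_scene <- function(plot_id, fis, cfg, illum_factor = 1) {
  rows <- cfg$plot_px_20m[1]; cols <- cfg$plot_px_20m[2]
  area_frac <- cfg$canopy_area_frac[fis] +
    if (cfg$plot_sd_area > 0) stats::rnorm(1, sd = cfg$plot_sd_area) else 0
  area_frac <- min(max(area_frac, 0), 0.95)
  # canopy envelope is inflated so that net area after punching sunlit gaps
  # (porosity) matches the configured fraction
  # Gaps come at two scales: fine leaf-scale gaps (~2 px wavelength, blended
  # away already at the 50 m GSD) and coarse between-plant bare patches
  # (~8 px, still resolved at 50 m but blended at 80 m). Half the porosity
  # budget goes to each.
  por <- cfg$canopy_porosity
  blob <- .canopy_mask(rows, cols, min(area_frac / (1 - por), 0.95))
  gaps <- matrix(FALSE, rows, cols)
  if (por > 0 && any(blob)) {
    fine <- .smooth_noise(rows, cols, coarse = c(40L, 20L), sd = 1)
    coarse <- .smooth_noise(rows, cols, coarse = c(10L, 5L), sd = 1)
    gaps <- blob & ((fine > stats::quantile(fine, 1 - por / 2)) |
                      (coarse > stats::quantile(coarse, 1 - por / 2)))
  }
  mask <- blob & !gaps
  # the canopy contract is a connected blob: fragments split off by gaps
  # below the 1%-area noise rule are not canopy
  if (any(mask)) {
    mask <- area_noise_filter(mask, 0.01)
    attributes(mask) <- list(dim = dim(mask))
  }
  degenerate <- !any(mask)

  # blockwise shadow assignment over the background keeps contiguous sunlit
  # soil patches (needed for pure-soil sampling)
  cell <- 8L
  ncy <- ceiling(rows / cell); ncx <- ceiling(cols / cell)
  shadow_cells <- matrix(stats::runif(ncy * ncx) < cfg$shadow_frac, ncy, ncx)
  cell_of <- shadow_cells[cbind(rep((seq_len(rows) - 1L) %/% cell + 1L, cols),
                                rep((seq_len(cols) - 1L) %/% cell + 1L,
                                    each = rows))]
  class_map <- matrix(2L, rows, cols)        # 1 canopy, 2 soil, 3 shadow
  class_map[matrix(cell_of, rows, cols)] <- 3L
  class_map[gaps] <- 2L   # sunlit gaps between plants show bare soil
  class_map[mask] <- 1L

  ndvi_c <- cfg$canopy_ndvi_mean[fis] +
    if (cfg$plot_sd_ndvi > 0) stats::rnorm(1, sd = cfg$plot_sd_ndvi) else 0
  can_rn <- .ndvi_pair(ndvi_c, cfg$canopy_refl_sum)
  soil_rn <- .ndvi_pair(cfg$soil_ndvi_mean, .soil_refl_sum)
  spectra <- rbind(
    canopy = replace(.class_spectra$canopy, c("red", "nir"), can_rn),
    soil   = replace(.class_spectra$soil, c("red", "nir"), soil_rn),
    shadow = .class_spectra$shadow
  )
  refl <- array(0, dim = c(rows, cols, 5L),
                dimnames = list(NULL, NULL, FLOOD_BANDS))
  for (b in seq_len(5L)) {
    base <- spectra[class_map, b]
    if (cfg$noise_sd_refl > 0)
      base <- base + stats::rnorm(length(base), sd = cfg$noise_sd_refl)
    refl[, , b] <- pmin(pmax(matrix(base, rows, cols), 0), 1)
  }

  # thermal raster on its own (coarser) grid, classes carried over by
  # nearest-neighbour sampling of the multispectral class map
  trows <- max(2L, round(rows * cfg$gsd_mm_ms[["20"]] / cfg$gsd_mm_thermal[["20"]]))
  tcols <- max(2L, round(cols * cfg$gsd_mm_ms[["20"]] / cfg$gsd_mm_thermal[["20"]]))
  iy <- pmin(rows, pmax(1L, ceiling((seq_len(trows) - 0.5) * rows / trows)))
  ix <- pmin(cols, pmax(1L, ceiling((seq_len(tcols) - 0.5) * cols / tcols)))
  thermal_class <- class_map[iy, ix, drop = FALSE]
  temp_c <- cfg$canopy_temp_mean_c[fis] +
    if (cfg$plot_sd_temp > 0) stats::rnorm(1, sd = cfg$plot_sd_temp) else 0
  class_temps <- c(temp_c, cfg$soil_temp_mean_c, cfg$shadow_temp_mean_c)
  thermal <- matrix(class_temps[thermal_class], trows, tcols)
  if (cfg$noise_sd_thermal > 0)
    thermal <- thermal + matrix(stats::rnorm(trows * tcols,
                                             sd = cfg$noise_sd_thermal),
                                trows, tcols)

  structure(list(
    plot_id = plot_id, fis = fis, height_m = 20,
    reflectance = refl, thermal = thermal,
    truth_mask = mask, class_map = class_map,
    thermal_class = thermal_class,
    gsd_mm_ms = cfg$gsd_mm_ms[["20"]],
    gsd_mm_thermal = cfg$gsd_mm_thermal[["20"]],
    row_direction = "rows",
    illum_factor = illum_factor,
    degenerate = degenerate
  ), class = "plot_scene")
}

#' @export
print.plot_scene <- function(x, ...) {
  cat(sprintf("Plot scene %s: FIS %d at %g m\n", x$plot_id, x$fis, x$height_m))
  cat(sprintf("  multispectral %d x %d px (%.1f mm/px), thermal %d x %d px (%.1f mm/px)\n",
              nrow(x$truth_mask), ncol(x$truth_mask), x$gsd_mm_ms,
              nrow(x$thermal), ncol(x$thermal), x$gsd_mm_thermal))
  cat(sprintf("  canopy fraction %.3f%s\n", mean(x$truth_mask),
              if (x$degenerate) " [degenerate: empty canopy]" else ""))
  invisible(x)
}
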