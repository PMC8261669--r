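#' Exact area-average resampling of a raster
#'
#' Downsamples a matrix by a (possibly non-integer) scale ratio, each output
#' pixel being the exact area-weighted average of the input cells its
#' footprint covers. This is the mixed-pixel model of coarser ground sampling
#' distance: output cell `i` covers input interval `[(i-1)*ratio, i*ratio)`
#' on each axis, and fractional overlaps are weighted accordingly.
#'
#' @param mat numeric matrix.
#' @param ratio scale ratio `>= 1` (output dimensions are `floor(dim / ratio)`,
#'   at least 1).
#' @return The resampled matrix.
#' @examples
#' resample_area(matrix(1:16, 4, 4), 2)  # 2x2 block means
#' @export
resample_area <- function(mat, ratio) {
  stopifnot(is.matrix(mat), ratio >= 1)
  if (ratio == 1) return(mat)
  wr <- .area_op(nrow(mat), ratio)
  wc <- .area_op(ncol(mat), ratio)
  wr %*% mat %*% t(wc)
}

# 1-D area-average operator: n_out x n_in matrix of normalized overlap weights
.area_op <- function(n_in, ratio) {
  n_out <- max(1L, floor(n_in / ratio))
  w <- matrix(0, n_out, n_in)
  for (i in seq_len(n_out)) {
    a <- (i - 1) * ratio; b <- i * ratio
    k <- seq.int(floor(a) + 1, min(ceiling(b), n_in))
    ov <- pmax(0, pmin(b, k) - pmax(a, k - 1))
    w[i, k] <- ov / sum(ov)
  }
  w
}

# Separable Gaussian blur (sensor point-spread function), edge-renormalized
.gauss_blur <- function(mat, sd_px) {
  half <- max(1L, ceiling(3 * sd_px))
  k <- exp(-(seq(-half, half))^2 / (2 * sd_px^2))
  k <- k / sum(k)
  conv1 <- function(m) {  # along rows of each column
    n <- nrow(m)
    out <- matrix(0, n, ncol(m))
    for (o in seq(-half, half)) {
      w <- k[o + half + 1]
      src <- pmin(pmax(seq_len(n) + o, 1L), n)
      out <- out + w * m[src, , drop = FALSE]
    }
    out
  }
  t(conv1(t(conv1(mat))))
}

#' Degrade a 20 m scene to a higher flight height
#'
#' Emulates flying at 50 or 80 m: all rasters are area-average downsampled by
#' the ratio of ground sampling distances (so canopy edges blur into mixed
#' pixels), the thermal raster is additionally attenuated through the longer
#' atmospheric path as `T_obs = tau * T + (1 - tau) * ambient`, the truth
#' mask is downsampled by majority vote, and the class map by plurality.
#'
#' @param scene a `plot_scene` at 20 m (from [generate_field()]).
#' @param height_m target height, one of 20 (identity), 50 or 80.
#' @param config the [sim_config()] that produced the scene.
#' @return A `plot_scene` at the requested height.
#' @export
degrade_to_height <- function(scene, height_m, config) {
  stopifnot(inherits(scene, "plot_scene"))
  if (height_m == 20) return(scene)
  h <- as.character(height_m)
  if (!h %in% names(config$gsd_mm_ms))
    stop("unknown flight height: ", height_m)
  if (scene$height_m != 20)
    stop("degrade_to_height expects a 20 m scene")

  r_ms <- config$gsd_mm_ms[[h]] / config$gsd_mm_ms[["20"]]
  r_th <- config$gsd_mm_thermal[[h]] / config$gsd_mm_thermal[["20"]]
  tau <- config$attenuation_tau[[h]]

  out <- scene
  d <- dim(scene$reflectance)
  nr <- max(1L, floor(d[1] / r_ms)); nc <- max(1L, floor(d[2] / r_ms))
  refl <- array(0, dim = c(nr, nc, d[3]), dimnames = dimnames(scene$reflectance))
  wr <- .area_op(d[1], r_ms); wc <- .area_op(d[2], r_ms)
  for (b in seq_len(d[3])) refl[, , b] <- wr %*% scene$reflectance[, , b] %*% t(wc)
  out$reflectance <- refl

  thermal <- resample_area(scene$thermal, r_th)
  blur <- config$thermal_blur_px
  blur <- if (length(blur) > 1) blur[[h]] else blur
  if (!is.null(blur) && blur > 0) thermal <- .gauss_blur(thermal, blur)
  out$thermal <- tau * thermal + (1 - tau) * config$ambient_temp_c

  out$truth_mask <- (wr %*% (scene$truth_mask * 1) %*% t(wc)) >= 0.5
  cls_fracs <- lapply(1:3, function(k) wr %*% ((scene$class_map == k) * 1) %*% t(wc))
  out$class_map <- matrix(max.col(cbind(as.vector(cls_fracs[[1]]),
                                        as.vector(cls_fracs[[2]]),
                                        as.vector(cls_fracs[[3]])),
                                  ties.method = "first"), nr, nc)
  twr <- .area_op(nrow(scene$thermal), r_th)
  twc <- .area_op(ncol(scene$thermal), r_th)
  tfr <- lapply(1:3, function(k) twr %*% ((scene$thermal_class == k) * 1) %*% t(twc))
  out$thermal_class <- matrix(max.col(cbind(as.vector(tfr[[1]]),
                                            as.vector(tfr[[2]]),
                                            as.vector(tfr[[3]])),
                                      ties.method = "first"),
                              nrow(thermal), ncol(thermal))
  out$height_m <- height_m
  out$gsd_mm_ms <- config$gsd_mm_ms[[h]]
  out$gsd_mm_thermal <- config$gsd_mm_thermal[[h]]
  out$degenerate <- !any(out$truth_mask)
  out
}

#' Degrade every scene of a field to a height
#'
#' @param field a `plot_field` at 20 m.
#' @param height_m target flight height (20, 50 or 80).
#' @return A `plot_field` at the requested height.
#' @export
degrade_field <- function(field, height_m) {
  stopifnot(inherits(field, "plot_field"))
  if (height_m == 20) return(field)
  field$scenes <- lapply(field$scenes, degrade_to_height, height_m = height_m,
                         config = field$config)
  field$manifest$height_m <- height_m
  field$manifest$gsd_mm_ms <- field$config$gsd_mm_ms[[as.character(height_m)]]
  field$manifest$gsd_mm_thermal <-
    field$config$gsd_mm_thermal[[as.character(height_m)]]
  field
}
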