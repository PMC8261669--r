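#' Threshold set for stepwise multispectral background removal
#'
#' Fixed numeric keep-boxes for the four-step background removal of
#' [remove_background_multispectral()]. The interactive freehand regions of
#' the original workflow are replaced by axis-aligned boxes (lo/hi per
#' channel) frozen once against the default synthetic class spectra, for
#' reproducibility:
#' \describe{
#'   \item{step1}{YCbCr box on the (red, NIR, red edge) composite; drops the
#'     bulk of sunlit soil (its blue-difference chroma falls below the box).}
#'   \item{step2}{YCbCr box on the true-color (red, green, blue) composite;
#'     drops remaining bright soil by its luma.}
#'   \item{step3}{HSV box on the true-color composite; drops dark pixels
#'     (shadow, fallen leaves) by their low value channel.}
#'   \item{min_area_frac}{connected components smaller than this fraction of
#'     the image are removed as noise (default 0.01, i.e. the 1 percent
#'     rule; strictly-smaller components are removed).}
#' }
#'
#' @param step1,step2 lists `list(lo=, hi=)` of length-3 bounds on (Y, Cb, Cr).
#' @param step3 list `list(lo=, hi=)` of length-3 bounds on (H, S, V).
#' @param min_area_frac minimum component area as a fraction of the image.
#' @return Object of class `threshold_set`.
#' @export
threshold_set <- function(step1 = list(lo = c(0.03, 0.500, 0.30),
                                       hi = c(0.60, 0.620, 0.52)),
                          step2 = list(lo = c(0.03, 0.40, 0.40),
                                       hi = c(0.21, 0.52, 0.54)),
                          step3 = list(lo = c(0, 0, 0.075),
                                       hi = c(1, 1, 1)),
                          min_area_frac = 0.01) {
  thr <- list(step1 = step1, step2 = step2, step3 = step3,
              min_area_frac = min_area_frac)
  for (s in c("step1", "step2", "step3")) {
    b <- thr[[s]]
    if (length(b$lo) != 3L || length(b$hi) != 3L || any(b$lo > b$hi))
      stop(s, " bounds must be length-3 with lo <= hi")
  }
  if (min_area_frac <= 0 || min_area_frac >= 1)
    stop("min_area_frac must lie in (0,1)")
  class(thr) <- "threshold_set"
  thr
}

.in_box <- function(img3, lo, hi) {
  (img3[, , 1] >= lo[1] & img3[, , 1] <= hi[1] &
     img3[, , 2] >= lo[2] & img3[, , 2] <= hi[2] &
     img3[, , 3] >= lo[3] & img3[, , 3] <= hi[3])
}

#' Stepwise background removal on a multispectral stack
#'
#' Applies the four steps of the background-removal procedure in order:
#' (1) a YCbCr keep-box on the (red, NIR, red edge) composite removes most
#' sunlit soil; (2) a YCbCr keep-box on the true-color composite removes
#' remaining soil near the canopy; (3) an HSV keep-box removes dark pixels
#' (shadows, fallen leaves); (4) connected components smaller than
#' `min_area_frac` of the image (8-connectivity, strict `<`) are removed as
#' noise. Each step's mask is a subset of the previous step's.
#'
#' @param stack a `reflectance_stack` (5 bands, `[0,1]`).
#' @param thr a [threshold_set()].
#' @return Object of class `canopy_mask`: list with the boolean `mask`,
#'   `source = "multispectral"`, a per-step `log` of removed pixel counts,
#'   `n_regions_removed`, `area_px` and a `valid` flag (FALSE when the mask
#'   empties out, e.g. a dead plot of pure soil).
#' @export
remove_background_multispectral <- function(stack, thr = threshold_set()) {
  stopifnot(length(dim(stack)) == 3L, dim(stack)[3] == 5L)
  composite1 <- unclass(stack)[, , c("red", "nir", "rededge")]
  rgb <- unclass(stack)[, , c("red", "green", "blue")]

  mask <- .in_box(to_color_space(composite1, "YCbCr"),
                  thr$step1$lo, thr$step1$hi)
  removed <- sum(!mask)
  steps <- c("ycbcr_composite", "ycbcr_rgb", "hsv_dark", "area_filter")
  log <- data.frame(step = steps, removed_px = c(removed, 0L, 0L, 0L))
  n_regions <- 0L

  if (any(mask)) {
    keep2 <- .in_box(to_color_space(rgb, "YCbCr"), thr$step2$lo, thr$step2$hi)
    log$removed_px[2] <- sum(mask & !keep2)
    mask <- mask & keep2
  }
  if (any(mask)) {
    keep3 <- .in_box(to_color_space(rgb, "HSV"), thr$step3$lo, thr$step3$hi)
    log$removed_px[3] <- sum(mask & !keep3)
    mask <- mask & keep3
  }
  if (any(mask)) {
    filtered <- area_noise_filter(mask, thr$min_area_frac)
    log$removed_px[4] <- sum(mask & !filtered)
    n_regions <- attr(filtered, "n_regions_removed")
    mask <- matrix(as.vector(filtered), nrow(mask), ncol(mask))
  }
  valid <- any(mask)
  if (!valid)
    warning("background removal produced an empty canopy mask (dead plot?)")
  structure(list(mask = mask, source = "multispectral", log = log,
                 n_regions_removed = n_regions, area_px = sum(mask),
                 valid = valid),
            class = "canopy_mask")
}

#' Label connected components of a binary mask (8-connectivity)
#'
#' Components are labelled with `EBImage::bwlabel()` (4-connectivity) and
#' labels touching diagonally are then merged by union-find, yielding the
#' 8-connected components used by the area noise filter.
#'
#' @param mask logical matrix.
#' @return Integer matrix of component labels (0 = background).
#' @export
label_components <- function(mask) {
  stopifnot(is.logical(mask) || all(mask %in% c(0, 1)))
  lab <- EBImage::bwlabel(mask * 1L)
  lab <- matrix(as.integer(lab), nrow(mask), ncol(mask))
  nlab <- max(lab)
  if (nlab < 2L) return(lab)
  nr <- nrow(lab); nc <- ncol(lab)
  pairs <- rbind(
    cbind(as.vector(lab[-nr, -nc]), as.vector(lab[-1, -1])),   # down-right
    cbind(as.vector(lab[-nr, -1]), as.vector(lab[-1, -nc]))    # down-left
  )
  pairs <- pairs[pairs[, 1] > 0L & pairs[, 2] > 0L &
                   pairs[, 1] != pairs[, 2], , drop = FALSE]
  parent <- seq_len(nlab)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  for (k in seq_len(nrow(pairs))) {
    a <- find(pairs[k, 1]); b <- find(pairs[k, 2])
    if (a != b) parent[max(a, b)] <- min(a, b)
  }
  root <- vapply(seq_len(nlab), find, 1L)
  dense <- match(root, sort(unique(root)))
  out <- lab
  out[lab > 0L] <- dense[lab[lab > 0L]]
  out
}

#' Remove small connected components from a mask
#'
#' Implements the 1-percent area rule: 8-connected components whose pixel
#' count is strictly less than `min_fraction` times the total image pixel
#' count are treated as noise and removed; larger components are untouched.
#'
#' @param mask logical matrix.
#' @param min_fraction minimum retained component area as a fraction of the
#'   image, in (0,1).
#' @return Logical matrix with attribute `n_regions_removed`.
#' @export
area_noise_filter <- function(mask, min_fraction = 0.01) {
  stopifnot(min_fraction > 0, min_fraction < 1)
  mask <- mask > 0
  if (!any(mask)) return(structure(mask, n_regions_removed = 0L))
  lab <- label_components(mask)
  sizes <- tabulate(lab[lab > 0L])
  cutoff <- min_fraction * length(mask)
  small <- which(sizes < cutoff)
  out <- mask
  if (length(small)) out[lab %in% small] <- FALSE
  structure(out, n_regions_removed = length(small))
}

#' K-means canopy mask on a thermal raster
#'
#' One-dimensional K-means with k = 2 on the temperature values (k-means++
#' initialisation under the given seed, then the standard iteration), taking
#' the cluster with the lower mean as canopy: plants transpire and stay
#' cooler than soil. The result does not depend on cluster label order.
#'
#' @param thermal numeric matrix of temperatures (degC); needs at least two
#'   distinct values.
#' @param seed integer seed for the initialisation.
#' @return Object of class `canopy_mask` with `source = "thermal"` and the
#'   two cluster means in `cluster_means`.
#' @export
kmeans_thermal_mask <- function(thermal, seed = 1L) {
  stopifnot(is.matrix(thermal), all(is.finite(thermal)))
  x <- as.vector(thermal)
  if (length(unique(x)) < 2L)
    stop("constant thermal raster: no canopy/background separation")
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  # k-means++ seeding for k = 2
  c1 <- x[sample.int(length(x), 1L)]
  d2 <- (x - c1)^2
  c2 <- x[sample.int(length(x), 1L, prob = d2 / sum(d2))]
  km <- stats::kmeans(x, centers = matrix(c(c1, c2), 2, 1), iter.max = 300L)
  lower <- which.min(km$centers)
  mask <- matrix(km$cluster == lower, nrow(thermal), ncol(thermal))
  structure(list(mask = mask, source = "thermal",
                 cluster_means = sort(as.vector(km$centers)),
                 area_px = sum(mask), n_regions_removed = 0L, valid = TRUE),
            class = "canopy_mask")
}

#' @export
print.canopy_mask <- function(x, ...) {
  cat(sprintf("Canopy mask (%s): %d of %d px canopy%s\n", x$source,
              x$area_px, length(x$mask),
              if (!x$valid) " [invalid: empty]" else ""))
  if (!is.null(x$cluster_means))
    cat(sprintf("  cluster means: %.2f / %.2f degC\n",
                x$cluster_means[1], x$cluster_means[2]))
  invisible(x)
}
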