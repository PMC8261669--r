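#' Run the full flooding-injury scoring pipeline on a synthetic field
#'
#' End-to-end convenience: generate the field at 20 m, degrade to the
#' requested height, render and calibrate every plot, segment, extract the
#' five features, and fit the FNN classifier on the valid records.
#'
#' @param config a [sim_config()]; its `seed` drives scene generation.
#' @param height_m flight height (20, 50 or 80).
#' @param method calibration method (see [pipeline_features()]).
#' @param thr segmentation [threshold_set()].
#' @param fnn an [fnn_config()].
#' @param seed seed for K-means initialisation, the 90/10 split and the
#'   network initialisation (defaults to the config seed).
#' @return List with `field`, `features` (data frame) and `model`
#'   (a [fis_fnn()] fit).
#' @export
run_flood_pipeline <- function(config = sim_config(), height_m = 20,
                               method = "unified_factor",
                               thr = threshold_set(), fnn = fnn_config(),
                               seed = config$seed) {
  field <- generate_field(config)
  field <- degrade_field(field, height_m)
  features <- pipeline_features(field, method = method, thr = thr, seed = seed)
  model <- fis_fnn(fis ~ canopy_temp_c + ndvi_mean + area_px + width_px +
                     length_px,
                   data = features, config = fnn, seed = seed)
  list(field = field, features = features, model = model)
}

#' Sample pure-soil regions from a field
#'
#' Scans the ground-truth thermal class maps for axis-aligned windows
#' containing only sunlit-soil pixels and returns the mean observed
#' temperature of each, emulating the selection of bare-soil reference
#' locations on the thermal imagery.
#'
#' @param field a `plot_field`.
#' @param n number of regions to collect.
#' @param size window side length in thermal pixels.
#' @return Numeric vector of `n` region mean temperatures (degC). Errors if
#'   the field does not contain enough pure-soil windows.
#' @export
sample_soil_regions <- function(field, n = 10L, size = 4L) {
  stopifnot(inherits(field, "plot_field"))
  out <- numeric(0)
  for (sc in field$scenes) {
    cls <- sc$thermal_class
    soil <- (cls == 2L) * 1
    nr <- nrow(soil); nc <- ncol(soil)
    if (nr < size || nc < size) next
    # windows with every pixel soil, via summed-area counts
    cs <- apply(apply(soil, 2, cumsum), 1, cumsum)  # nc x nr transposed sums
    full <- size * size
    for (i in seq_len(nr - size + 1L)) {
      for (j in seq_len(nc - size + 1L)) {
        tot <- cs[j + size - 1L, i + size - 1L] -
          (if (i > 1L) cs[j + size - 1L, i - 1L] else 0) -
          (if (j > 1L) cs[j - 1L, i + size - 1L] else 0) +
          (if (i > 1L && j > 1L) cs[j - 1L, i - 1L] else 0)
        if (tot == full) {
          out <- c(out, mean(sc$thermal[i:(i + size - 1L),
                                        j:(j + size - 1L)]))
          break
        }
      }
      if (length(out) && length(out) >= n) break
    }
    if (length(out) >= n) break
  }
  if (length(out) < n)
    stop("found only ", length(out), " pure-soil windows of size ", size)
  out[seq_len(n)]
}
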