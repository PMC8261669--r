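# Shared fixtures, built in code and memoised for the test run.

.fixtures <- new.env(parent = emptyenv())

small_config <- function(n = 40L, seed = 7L, ...) {
  sim_config(n_plots = n, seed = seed, ...)
}

# all randomness off: exact class means, deterministic shapes given seed
noisefree_config <- function(n = 10L, seed = 3L, ...) {
  sim_config(n_plots = n, seed = seed, noise_sd_refl = 0,
             noise_sd_thermal = 0, plot_sd_temp = 0, plot_sd_ndvi = 0,
             plot_sd_area = 0, ...)
}

get_field <- function(key, maker) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- maker()
  .fixtures[[key]]
}

small_field <- function() get_field("small", function()
  generate_field(small_config()))

noisefree_field <- function() get_field("noisefree", function()
  generate_field(noisefree_config()))

as_stack <- function(scene) {
  structure(scene$reflectance, method = "truth", n_clipped = 0L,
            class = c("reflectance_stack", "array"))
}

# independent 8-connectivity component labelling oracle (BFS flood fill)
label_components_oracle <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  cur <- 0L
  offs <- expand.grid(dr = -1:1, dc = -1:1)
  offs <- offs[!(offs$dr == 0 & offs$dc == 0), ]
  for (j in seq_len(nc)) for (i in seq_len(nr)) {
    if (!mask[i, j] || lab[i, j] != 0L) next
    cur <- cur + 1L
    queue <- matrix(c(i, j), 1)
    lab[i, j] <- cur
    while (nrow(queue)) {
      p <- queue[1, , drop = FALSE]; queue <- queue[-1, , drop = FALSE]
      for (k in seq_len(nrow(offs))) {
        ii <- p[1] + offs$dr[k]; jj <- p[2] + offs$dc[k]
        if (ii >= 1 && ii <= nr && jj >= 1 && jj <= nc &&
            mask[ii, jj] && lab[ii, jj] == 0L) {
          lab[ii, jj] <- cur
          queue <- rbind(queue, c(ii, jj))
        }
      }
    }
  }
  lab
}
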