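#' One-way ANOVA with Tukey HSD letters
#'
#' Compares a feature across groups (flight heights, or FIS levels) by
#' one-way ANOVA at the given significance level, followed by Tukey honest
#' significant difference tests on all pairs and a compact letter display:
#' groups sharing a letter are not significantly different at `alpha`.
#' ANOVA and Tukey tests are delegated to [stats::aov()] and
#' [stats::TukeyHSD()]; the letters come from the standard insert-absorb
#' algorithm over the non-significant pairs, with groups ordered by
#' descending mean.
#'
#' @param values numeric vector of observations.
#' @param groups group labels (coerced to factor), at least two groups with
#'   at least two observations each.
#' @param alpha significance level (default 0.05).
#' @return Object of class `group_comparison`: per-group summary table
#'   (n, mean, sd, letter), `F`, `p`, and the matrix of pairwise Tukey
#'   adjusted p-values.
#' @examples
#' g <- rep(c("20m", "50m", "80m"), each = 10)
#' x <- rnorm(30, mean = rep(c(39, 40.3, 41.1), each = 10), sd = 0.4)
#' group_compare(x, g)
#' @export
group_compare <- function(values, groups, alpha = 0.05) {
  g <- factor(groups)
  stopifnot(length(values) == length(g))
  if (nlevels(g) < 2L) stop("need at least two groups")
  n_by <- tapply(values, g, length)
  if (any(n_by < 2L)) stop("every group needs at least two observations")

  k <- nlevels(g)
  means <- tapply(values, g, mean)
  sds <- tapply(values, g, sd)

  if (stats::var(values) == 0) {
    # all observations identical: no variation to partition
    Fst <- 0; p <- 1
    pmat <- matrix(1, k, k, dimnames = list(levels(g), levels(g)))
    diag(pmat) <- NA_real_
  } else {
    fit <- stats::aov(values ~ g)
    tab <- summary(fit)[[1]]
    Fst <- tab[["F value"]][1]
    p <- tab[["Pr(>F)"]][1]
    tk <- stats::TukeyHSD(fit, conf.level = 1 - alpha)$g
    pmat <- matrix(NA_real_, k, k, dimnames = list(levels(g), levels(g)))
    prs <- strsplit(rownames(tk), "-", fixed = TRUE)
    for (i in seq_along(prs)) {
      a <- prs[[i]][1]; b <- prs[[i]][2]
      pmat[a, b] <- pmat[b, a] <- tk[i, "p adj"]
    }
  }
  letters_ <- .cld_letters(pmat, means, alpha)
  tab <- data.frame(group = levels(g), n = as.integer(n_by),
                    mean = as.numeric(means), sd = as.numeric(sds),
                    letter = letters_[levels(g)],
                    stringsAsFactors = FALSE, row.names = NULL)
  structure(list(table = tab, F = Fst, p = p, tukey_p = pmat, alpha = alpha),
            class = "group_comparison")
}

# Compact letter display, insert-absorb: start from the group with the
# largest mean; a group joins an existing letter column only if it is
# non-significant against every member. Ties broken by mean then label.
.cld_letters <- function(pmat, means, alpha) {
  groups <- names(means)[order(-unlist(means), names(means))]
  cols <- list()  # each element: character vector of member groups
  for (gname in groups) {
    placed <- FALSE
    for (j in seq_along(cols)) {
      if (all(pmat[gname, cols[[j]]] >= alpha, na.rm = TRUE)) {
        cols[[j]] <- c(cols[[j]], gname)
        placed <- TRUE
      }
    }
    if (!placed) cols[[length(cols) + 1L]] <- gname
  }
  # absorb columns fully contained in another
  keep <- rep(TRUE, length(cols))
  for (j in seq_along(cols)) for (j2 in seq_along(cols))
    if (j != j2 && keep[j] && keep[j2] && all(cols[[j]] %in% cols[[j2]]))
      keep[j] <- FALSE
  cols <- cols[keep]
  out <- stats::setNames(rep("", length(means)), names(means))
  for (j in seq_along(cols))
    for (gname in cols[[j]])
      out[gname] <- paste0(out[gname], letters[j])
  # letters in display order follow descending group mean
  out
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F = %.4g, p = %.4g (alpha = %g)\n",
              x$F, x$p, x$alpha))
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Group-comparison report over a feature table
#'
#' Convenience wrapper producing the standard comparison layout: each
#' feature across flight heights, and each feature across FIS levels within
#' each height.
#'
#' @param features feature table from [pipeline_features()] (possibly several
#'   heights bound together); invalid rows are dropped.
#' @param feats feature columns to compare.
#' @param alpha significance level.
#' @return Data frame with one row per group per comparison: comparison id,
#'   feature, group, n, mean, sd, letter, F and p.
#' @export
stats_report <- function(features,
                         feats = c("canopy_temp_c", "ndvi_mean", "area_px"),
                         alpha = 0.05) {
  features <- features[features$valid, , drop = FALSE]
  out <- list()
  add <- function(id, feat, cmp) {
    cbind(comparison = id, feature = feat, cmp$table,
          F = cmp$F, p = cmp$p, row.names = NULL)
  }
  for (f in feats) {
    if (length(unique(features$height_m)) > 1L)
      out[[length(out) + 1L]] <-
        add("height", f, group_compare(features[[f]], features$height_m, alpha))
    for (h in sort(unique(features$height_m)))
      out[[length(out) + 1L]] <-
        add(sprintf("fis_at_%gm", h), f,
            group_compare(features[[f]][features$height_m == h],
                          features$fis[features$height_m == h], alpha))
  }
  do.call(rbind, out)
}
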