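#' Per-class scalp topography of one feature family
#'
#' For each electrode, the mean of that electrode's `family` feature over
#' all epochs of the given class, pooled across every subject and session
#' in the cohort (epoch-weighted; set `subject_weighted = TRUE` to average
#' per-subject means instead).
#'
#' @param fm a `feature_matrix` (possibly many subjects).
#' @param family feature family, e.g. `"DE_gamma"` or `"EMD_Dt"`.
#' @param class emotion label to average over.
#' @param subject_weighted average subject means instead of pooled epochs.
#' @return a `topography_map`: named electrode values, the family and class,
#'   and the layout.
#' @export
class_topography <- function(fm, family, class, subject_weighted = FALSE) {
  info <- feature_info(colnames(fm$X))
  cols <- which(info$family == family)
  if (length(cols) == 0) stop("unknown feature family: ", family)
  keep <- fm$meta$emotion == class
  if (!any(keep)) stop("class not present in cohort: ", class)
  sub <- fm$X[keep, cols, drop = FALSE]
  if (subject_weighted) {
    by_subj <- rowsum(sub, fm$meta$subject_id[keep]) /
      as.vector(table(fm$meta$subject_id[keep]))
    vals <- colMeans(by_subj)
  } else {
    vals <- colMeans(sub)
  }
  names(vals) <- info$electrode[cols]
  vals <- vals[fm$layout$name]
  structure(list(values = vals, family = family, class = class,
                 layout = fm$layout),
            class = "topography_map")
}

#' @export
print.topography_map <- function(x, ...) {
  cat(sprintf("<topography_map> %s / %s over %d electrodes (range %.3f .. %.3f)\n",
              x$family, x$class, length(x$values), min(x$values),
              max(x$values)))
  invisible(x)
}

#' Per-class distribution summary of one feature
#'
#' Five-number summary (min, Q1, median, Q3, max) plus Tukey outlier fences
#' (Q1 - 1.5 IQR, Q3 + 1.5 IQR) of a single feature, per emotion class —
#' the numbers behind a per-feature boxplot.
#'
#' @param fm a `feature_matrix`.
#' @param feature feature name, e.g. `"T7_DE_gamma"`.
#' @return data.frame with one row per class present in the cohort.
#' @export
feature_distribution <- function(fm, feature) {
  j <- match(feature, colnames(fm$X))
  if (is.na(j)) stop("unknown feature: ", feature)
  classes <- intersect(emotion_levels(), unique(fm$meta$emotion))
  out <- lapply(classes, function(cl) {
    x <- fm$X[fm$meta$emotion == cl, j]
    q <- stats::quantile(x, c(0, 0.25, 0.5, 0.75, 1), names = FALSE)
    iqr <- q[4] - q[2]
    data.frame(class = cl, min = q[1], q1 = q[2], median = q[3], q3 = q[4],
               max = q[5], fence_low = q[2] - 1.5 * iqr,
               fence_high = q[4] + 1.5 * iqr, n = length(x))
  })
  do.call(rbind, out)
}

#' Interpolate a topography onto a head-disc grid
#'
#' Inverse-distance-weighted (power 2) interpolation of the electrode
#' values onto a `resolution` x `resolution` grid over `[-1, 1]^2`, masked
#' (NA) outside the unit head circle. IDW never overshoots: every grid
#' value lies within the range of the electrode values.
#'
#' @param map a `topography_map` from [class_topography()].
#' @param resolution grid size per axis.
#' @param power IDW exponent.
#' @return list with `x`, `y` (grid axes) and `grid` (resolution x
#'   resolution matrix, NA outside the head circle).
#' @export
interpolate_scalp <- function(map, resolution = 40, power = 2) {
  lay <- map$layout
  if (nrow(lay) < 3) stop("need at least 3 electrodes")
  if (nrow(unique(lay[, c("x", "y")])) < nrow(lay)) {
    stop("degenerate electrode positions (duplicates)")
  }
  gx <- seq(-1, 1, length.out = resolution)
  gy <- seq(-1, 1, length.out = resolution)
  grid <- matrix(NA_real_, resolution, resolution)
  vals <- as.numeric(map$values)
  for (i in seq_len(resolution)) {
    for (j in seq_len(resolution)) {
      if (gx[i]^2 + gy[j]^2 > 1) next
      d2 <- (lay$x - gx[i])^2 + (lay$y - gy[j])^2
      hit <- which(d2 < 1e-12)
      if (length(hit) > 0) {
        grid[i, j] <- vals[hit[1]]
      } else {
        w <- d2^(-power / 2)
        grid[i, j] <- sum(w * vals) / sum(w)
      }
    }
  }
  list(x = gx, y = gy, grid = grid)
}

#' Write a topography map to CSV
#' @param map a `topography_map`.
#' @param path output file.
#' @export
write_topography_csv <- function(map, path) {
  utils::write.csv(data.frame(electrode = names(map$values),
                              value = as.numeric(map$values),
                              family = map$family, class = map$class),
                   path, row.names = FALSE)
  invisible(path)
}
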