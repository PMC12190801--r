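# Independent point-in-convex-hull oracle: p is in conv(S) iff the directions
# from p to the points of S do not fit in an open half-plane (largest angular
# gap <= pi), or p coincides with a point of S. Independent of chull() and of
# any polygon rasterization.
in_hull_oracle <- function(px, py, sx, sy) {
  dx <- sx - px; dy <- sy - py
  on <- dx == 0 & dy == 0
  if (any(on)) return(TRUE)
  ang <- sort(atan2(dy, dx))
  gaps <- c(diff(ang), 2 * pi - (ang[length(ang)] - ang[1]))
  max(gaps) <= pi + 1e-9
}

hull_fill_oracle <- function(slice) {
  out <- matrix(FALSE, nrow(slice), ncol(slice))
  if (!any(slice)) return(out)
  pts <- which(slice, arr.ind = TRUE)
  for (i in seq_len(nrow(out))) {
    for (j in seq_len(ncol(out))) {
      out[i, j] <- in_hull_oracle(i, j, pts[, 1], pts[, 2])
    }
  }
  out
}

# Brute-force Youden search: every observed value as cut-point, both
# directions, direct counting; ties toward higher sensitivity then lower
# cut-point (mirrors the documented tie-break so equality is well defined).
youden_oracle <- function(v, y) {
  best <- NULL
  for (cut in sort(unique(v))) {
    for (dir in c("abnormal-above", "abnormal-below")) {
      pos <- if (dir == "abnormal-above") v >= cut else v <= cut
      sens <- sum(pos & y == 1) / sum(y == 1)
      spec <- sum(!pos & y == 0) / sum(y == 0)
      j <- sens + spec - 1
      if (is.null(best) || j > best$youden + 1e-12 ||
          (abs(j - best$youden) <= 1e-12 &&
           (sens > best$sensitivity + 1e-12 ||
            (abs(sens - best$sensitivity) <= 1e-12 && cut < best$cutpoint)))) {
        best <- list(cutpoint = cut, direction = dir, youden = j,
                     sensitivity = sens, specificity = spec)
      }
    }
  }
  best
}
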