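#' Sex-specific optimal cut-points by the Youden index
#'
#' For each sex stratum, exhaustively evaluates the Youden index
#' J = sensitivity + specificity - 1 over every observed metric value as a
#' candidate cut-point and over both orientations of abnormality
#' (`abnormal-above`: positive when value >= cut-point; `abnormal-below`:
#' positive when value <= cut-point), and returns the maximizer. Ties are
#' broken toward the candidate with higher sensitivity, then the lower
#' cut-point, and a tie flag is set whenever more than one
#' (cut-point, direction) pair attains the maximum.
#'
#' @param data A data frame.
#' @param value Column with the metric (unquoted).
#' @param outcome Column with the binary outcome (unquoted; logical or 0/1).
#' @param sex Optional stratifying column (unquoted); when omitted a single
#'   stratum `"all"` is used.
#' @return A tibble with one row per stratum: `sex`, `cutpoint`, `direction`,
#'   `youden`, `sensitivity`, `specificity`, `n`, `n_pos`, `tied`.
#' @export
#' @examples
#' d <- data.frame(v = c(1, 2, 3, 4), y = c(0, 0, 1, 1))
#' youden_thresholds(d, v, y)
youden_thresholds <- function(data, value, outcome, sex = NULL) {
  v_all <- eval_tidy(enquo(value), data)
  y_all <- as.integer(as.logical(eval_tidy(enquo(outcome), data)))
  sex_quo <- enquo(sex)
  g_all <- if (rlang::quo_is_null(sex_quo)) rep("all", length(v_all))
           else as.character(eval_tidy(sex_quo, data))
  keep <- !is.na(v_all) & !is.na(y_all) & !is.na(g_all)
  v_all <- v_all[keep]; y_all <- y_all[keep]; g_all <- g_all[keep]

  purrr::map_dfr(unique(g_all), function(g) {
    v <- v_all[g_all == g]; y <- y_all[g_all == g]
    n_pos <- sum(y == 1L); n_neg <- sum(y == 0L)
    if (n_pos == 0L || n_neg == 0L) {
      abort(sprintf("Stratum '%s' has a single outcome class; no cut-point is defined.", g))
    }
    u <- sort(unique(v))
    idx <- factor(match(v, u), levels = seq_along(u))
    pos_at <- vapply(split(y, idx), sum, numeric(1))
    cnt_at <- vapply(split(y, idx), length, numeric(1))
    cum_pos <- cumsum(pos_at)           # positives with value <= u_i
    cum_all <- cumsum(cnt_at)
    cum_neg <- cum_all - cum_pos
    # abnormal-above: positive when v >= c
    sens_ab <- (n_pos - c(0, utils::head(cum_pos, -1))) / n_pos
    spec_ab <- c(0, utils::head(cum_neg, -1)) / n_neg
    # abnormal-below: positive when v <= c
    sens_be <- cum_pos / n_pos
    spec_be <- (n_neg - cum_neg) / n_neg
    cand <- tibble(
      cutpoint = c(u, u),
      direction = rep(c("abnormal-above", "abnormal-below"), each = length(u)),
      sensitivity = unname(c(sens_ab, sens_be)),
      specificity = unname(c(spec_ab, spec_be))
    )
    cand$youden <- cand$sensitivity + cand$specificity - 1
    jmax <- max(cand$youden)
    at_max <- cand[cand$youden >= jmax - 1e-12, ]
    best <- at_max[order(-at_max$sensitivity, at_max$cutpoint), ][1, ]
    tibble(
      sex = g, cutpoint = best$cutpoint, direction = best$direction,
      youden = best$youden, sensitivity = best$sensitivity,
      specificity = best$specificity, n = length(v), n_pos = n_pos,
      tied = nrow(at_max) > 1L
    )
  })
}

#' Classify metric values as abnormal given a threshold row
#'
#' @param values Numeric metric values.
#' @param threshold One row of a [youden_thresholds()] result.
#' @return Logical vector, `TRUE` when abnormal.
#' @export
apply_threshold <- function(values, threshold) {
  if (threshold$direction == "abnormal-above") values >= threshold$cutpoint
  else values <= threshold$cutpoint
}
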