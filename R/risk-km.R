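#' Stratified Kaplan-Meier curves with pairwise hazard ratios
#'
#' Product-limit survival estimates per group (e.g. threshold-defined
#' normal/abnormal classes) together with unadjusted pairwise hazard ratios
#' from single-covariate Cox fits. Curves start at 1 and are monotone
#' non-increasing; with no censoring the estimate equals one minus the
#' empirical CDF of event times.
#'
#' @param data Cohort data frame.
#' @param group Grouping column name (coerced to factor).
#' @param time,event Column names of follow-up time and event type.
#' @param event_of_interest Values of `event` counted as events.
#' @return An object of class `bc_km`: the `survfit` object, the group
#'   factor, and a tibble of pairwise hazard ratios. Use [tidy()] and
#'   [autoplot()].
#' @export
km_stratified <- function(data, group, time = "time", event = "event",
                          event_of_interest = c("death", "mi")) {
  g <- factor(data[[group]])
  if (nlevels(g) < 2L) abort("At least two groups are required.")
  t <- data[[time]]
  status <- as.integer(as.character(data[[event]]) %in% event_of_interest)
  for (lv in levels(g)) {
    if (sum(g == lv) == 0L) abort(sprintf("Group '%s' is empty.", lv))
    if (sum(status[g == lv]) == 0L) {
      abort(sprintf("Group '%s' has no events.", lv))
    }
  }
  df <- data.frame(.time = t, .status = status, .group = g)
  sf <- survival::survfit(survival::Surv(.time, .status) ~ .group, data = df)

  pairs <- utils::combn(levels(g), 2, simplify = FALSE)
  hr <- purrr::map_dfr(pairs, function(p) {
    sub <- df[df$.group %in% p, ]
    sub$.x <- as.integer(sub$.group == p[2])
    cf <- survival::coxph(survival::Surv(.time, .status) ~ .x, data = sub,
                          ties = "efron")
    est <- coef(cf)[[1]]; se <- sqrt(vcov(cf)[1, 1])
    tibble(reference = p[1], comparison = p[2],
           hr = exp(est), conf.low = exp(est - 1.96 * se),
           conf.high = exp(est + 1.96 * se),
           p.value = 2 * stats::pnorm(-abs(est / se)))
  })
  structure(list(survfit = sf, group = g, hr = hr,
                 event_of_interest = event_of_interest),
            class = "bc_km")
}

#' @describeIn km_stratified Tabulated step functions: one row per event time
#'   and group with `n.risk`, `n.event`, the survival `estimate` and its CI.
#' @param x A `bc_km` object.
#' @param ... Unused.
#' @method tidy bc_km
#' @export
tidy.bc_km <- function(x, ...) {
  sf <- x$survfit
  strata <- rep(names(sf$strata), sf$strata)
  tibble(
    group = sub("^\\.group=", "", strata),
    time = sf$time, n.risk = sf$n.risk, n.event = sf$n.event,
    n.censor = sf$n.censor, estimate = sf$surv,
    conf.low = sf$lower, conf.high = sf$upper
  )
}

#' @describeIn km_stratified Group sizes, event counts and pairwise HRs.
#' @method glance bc_km
#' @export
glance.bc_km <- function(x, ...) {
  tibble(
    n_groups = nlevels(x$group),
    n = length(x$group),
    n_events = sum(x$survfit$n.event),
    max_pairwise_hr = max(x$hr$hr)
  )
}

#' @describeIn km_stratified Kaplan-Meier plot (step curves per group).
#' @param object A `bc_km` object.
#' @method autoplot bc_km
#' @export
autoplot.bc_km <- function(object, ...) {
  td <- tidy(object)
  # prepend the (0, 1) anchor per group so curves start at 1
  anchor <- dplyr::distinct(td, .data$group)
  anchor$time <- 0; anchor$estimate <- 1
  curves <- dplyr::bind_rows(anchor, td[, c("group", "time", "estimate")])
  ggplot2::ggplot(curves,
                  ggplot2::aes(x = .data$time, y = .data$estimate,
                               colour = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Years", y = "Survival probability", colour = NULL) +
    ggplot2::theme_minimal()
}
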