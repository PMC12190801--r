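# shared covariate preparation: optional natural-log transform, then
# standardization to cohort SD 1 so hazard ratios are per SD increase;
# SDs are computed after the transform
prepare_covariates <- function(data, covariates, log_covariates, standardize) {
  out <- list()
  scaling <- list()
  for (cv in covariates) {
    if (!cv %in% names(data)) abort(sprintf("Covariate '%s' not found.", cv))
    x <- data[[cv]]
    if (is.factor(x) || is.character(x)) {
      out[[cv]] <- factor(x)
      next
    }
    logged <- cv %in% log_covariates
    if (logged) {
      if (any(x <= 0, na.rm = TRUE)) {
        abort(sprintf("Covariate '%s' must be positive for log transform.", cv))
      }
      x <- log(x)
    }
    binary <- all(x %in% c(0, 1, NA))
    ctr <- 0; scl <- 1
    if (standardize && !binary) {
      ctr <- mean(x, na.rm = TRUE); scl <- sd(x, na.rm = TRUE)
      if (!is.finite(scl) || scl == 0) {
        abort(sprintf("Covariate '%s' has zero variance.", cv))
      }
      x <- (x - ctr) / scl
    }
    if (!all(is.finite(x[!is.na(x)]))) {
      abort(sprintf("Covariate '%s' is not finite after transformation.", cv))
    }
    out[[cv]] <- x
    scaling[[cv]] <- tibble(term = cv, log_transformed = logged,
                            center = ctr, scale = scl, binary = binary)
  }
  list(frame = as_tibble(out), scaling = dplyr::bind_rows(scaling))
}

#' Fit a per-SD Cox proportional-hazards model
#'
#' Continuous covariates are standardized to cohort SD 1 before fitting, so
#' hazard ratios are per standard-deviation increase; covariates listed in
#' `log_covariates` are natural-log transformed first (SDs are taken after
#' the transform). Factor covariates (e.g. the CAC category with 0 as
#' reference) enter as categories. Ties are handled with the Efron
#' approximation. Non-convergence and infinite-coefficient warnings from the
#' partial-likelihood maximization are collected and re-raised, never
#' swallowed.
#'
#' @param data Cohort data frame.
#' @param covariates Character vector of covariate column names.
#' @param time,event Column names of follow-up time and event type.
#' @param event_of_interest Values of `event` counted as events; everything
#'   else is censored. The default treats death and MI as a composite.
#' @param log_covariates Covariates to log-transform before standardization.
#' @param standardize Standardize continuous covariates (default `TRUE`).
#' @return An object of class `bc_cox` with the `coxph` fit, log-likelihoods,
#'   event counts, and the scaling table. Use [tidy()] / [glance()].
#' @export
fit_cox <- function(data, covariates, time = "time", event = "event",
                    event_of_interest = c("death", "mi"),
                    log_covariates = character(), standardize = TRUE) {
  t <- data[[time]]
  status <- as.integer(as.character(data[[event]]) %in% event_of_interest)
  if (sum(status) < 10L) {
    abort(sprintf("Only %d events; at least 10 are required.", sum(status)))
  }
  prep <- prepare_covariates(data, covariates, log_covariates, standardize)
  df <- tibble(.time = t, .status = status)
  for (cv in names(prep$frame)) df[[cv]] <- prep$frame[[cv]]
  rhs <- if (length(covariates)) paste(sprintf("`%s`", covariates), collapse = " + ") else "1"
  fml <- stats::as.formula(paste("survival::Surv(.time, .status) ~", rhs))
  warns <- character(0)
  fit <- withCallingHandlers(
    survival::coxph(fml, data = df, ties = "efron", x = TRUE),
    warning = function(w) {
      warns <<- c(warns, conditionMessage(w))
      invokeRestart("muffleWarning")
    }
  )
  if (length(warns)) {
    warning("coxph reported: ", paste(unique(warns), collapse = "; "), call. = FALSE)
  }
  structure(
    list(fit = fit, n = nrow(df), nevent = sum(status),
         loglik = fit$loglik, covariates = covariates,
         event_of_interest = event_of_interest, scaling = prep$scaling,
         warnings = warns),
    class = "bc_cox"
  )
}

#' @export
print.bc_cox <- function(x, ...) {
  cat(sprintf("<bc_cox> %d subjects, %d events (%s); per-SD hazard ratios:\n",
              x$n, x$nevent, paste(x$event_of_interest, collapse = "+")))
  print(tidy(x, exponentiate = TRUE), n = Inf)
  invisible(x)
}

#' @describeIn fit_cox Tidy the coefficients (broom-style). With
#'   `exponentiate = TRUE` estimates and CI bounds are hazard ratios.
#' @param x A `bc_cox` object.
#' @param exponentiate Report hazard ratios instead of log-hazards.
#' @param conf.level Confidence level.
#' @param ... Unused.
#' @method tidy bc_cox
#' @export
tidy.bc_cox <- function(x, exponentiate = FALSE, conf.level = 0.95, ...) {
  co <- coef(x$fit)
  se <- sqrt(diag(vcov(x$fit)))
  zq <- stats::qnorm(1 - (1 - conf.level) / 2)
  out <- tibble(
    term = names(co), estimate = unname(co), std.error = unname(se),
    statistic = unname(co / se),
    p.value = 2 * stats::pnorm(-abs(unname(co / se))),
    conf.low = unname(co - zq * se), conf.high = unname(co + zq * se)
  )
  if (exponentiate) {
    out$estimate <- exp(out$estimate)
    out$conf.low <- exp(out$conf.low)
    out$conf.high <- exp(out$conf.high)
  }
  out
}

#' @describeIn fit_cox One-row model summary: n, events, log-likelihoods and
#'   the LR chi-square against the null model.
#' @method glance bc_cox
#' @export
glance.bc_cox <- function(x, ...) {
  df <- sum(!is.na(coef(x$fit)))
  lr <- 2 * (x$loglik[2] - x$loglik[1])
  tibble(
    n = x$n, nevent = x$nevent,
    loglik = x$loglik[2], null_loglik = x$loglik[1],
    lr_chisq = lr, df = df,
    p.value = if (df > 0) pchisq(lr, df, lower.tail = FALSE) else NA_real_
  )
}

#' @describeIn fit_cox Forest plot of per-SD hazard ratios.
#' @param object A `bc_cox` object.
#' @method autoplot bc_cox
#' @export
autoplot.bc_cox <- function(object, ...) {
  td <- tidy(object, exponentiate = TRUE)
  ggplot2::ggplot(td, ggplot2::aes(x = .data$estimate, y = .data$term)) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$conf.low, xmax = .data$conf.high), height = 0.2
    ) +
    ggplot2::geom_vline(xintercept = 1, linetype = 2) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Hazard ratio per SD (95% CI)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Likelihood-ratio chi-square increment between nested Cox models
#'
#' chi^2 = 2 (LL_extended - LL_base) with degrees of freedom equal to the
#' difference in fitted parameters. The significance flag uses a
#' multiplicity-adjusted alpha of 0.001 by default.
#'
#' @param base,extended `bc_cox` fits on the same subjects and events; the
#'   base covariates must be a subset of the extended ones.
#' @param alpha Significance gate for the `significant` flag.
#' @return A tibble: `chisq`, `df`, `p.value`, `significant`.
#' @export
lr_chi2_increment <- function(base, extended, alpha = 0.001) {
  stopifnot(inherits(base, "bc_cox"), inherits(extended, "bc_cox"))
  if (base$n != extended$n || base$nevent != extended$nevent) {
    abort("Models were fitted on different subjects or events; the LR test is undefined.")
  }
  if (!all(base$covariates %in% extended$covariates)) {
    abort("Models are not nested: base covariates are not a subset of the extended model.")
  }
  df <- sum(!is.na(coef(extended$fit))) - sum(!is.na(coef(base$fit)))
  chisq <- 2 * (extended$loglik[2] - base$loglik[2])
  if (chisq < -1e-6) {
    abort("Extended model has lower log-likelihood than the base; models are not nested.")
  }
  chisq <- max(chisq, 0)
  p <- if (df > 0) pchisq(chisq, df, lower.tail = FALSE) else NA_real_
  tibble(chisq = chisq, df = df, p.value = p,
         significant = !is.na(p) & p < alpha)
}

#' Proportional-hazards diagnostics from scaled Schoenfeld residuals
#'
#' Per-covariate and global tests of the proportional-hazards assumption
#' (correlation of scaled Schoenfeld residuals with event time), via
#' [survival::cox.zph()]. A model with no covariates emits no tests.
#'
#' @param fit A `bc_cox` object.
#' @param transform Time transform passed to `cox.zph` (default `"km"`).
#' @return A tibble: `term`, `chisq`, `df`, `p.value`; the last row is
#'   `GLOBAL`. Zero rows for a null model.
#' @export
schoenfeld_check <- function(fit, transform = "km") {
  stopifnot(inherits(fit, "bc_cox"))
  if (sum(!is.na(coef(fit$fit))) == 0L) {
    return(tibble(term = character(), chisq = numeric(), df = numeric(),
                  p.value = numeric()))
  }
  zp <- survival::cox.zph(fit$fit, transform = transform)
  tb <- zp$table
  tibble(term = rownames(tb), chisq = tb[, "chisq"], df = tb[, "df"],
         p.value = tb[, "p"])
}

#' Competing-risk model for myocardial infarction
#'
#' Models MI with death as the competing event. The default is the Fine-Gray
#' subdistribution-hazard regression ([cmprsk::crr()]); `method =
#' "cause-specific"` instead fits a cause-specific Cox model censoring the
#' competing deaths. Continuous covariates are standardized per SD exactly as
#' in [fit_cox()].
#'
#' @param data Cohort data frame.
#' @param covariates Covariate column names.
#' @param time,event Column names; `event` must distinguish the MI, death and
#'   censored states.
#' @param mi_code,death_code Values of `event` marking MI and death.
#' @param method `"fine-gray"` (default) or `"cause-specific"`.
#' @param log_covariates,standardize As in [fit_cox()].
#' @return An object of class `bc_crr`; use [tidy()] / [glance()].
#' @export
competing_risk_mi <- function(data, covariates, time = "time", event = "event",
                              mi_code = "mi", death_code = "death",
                              method = c("fine-gray", "cause-specific"),
                              log_covariates = character(), standardize = TRUE) {
  method <- match.arg(method)
  ev <- as.character(data[[event]])
  n_mi <- sum(ev == mi_code)
  if (n_mi == 0L) abort("No MI events in the cohort.")
  if (method == "cause-specific") {
    fit <- fit_cox(data, covariates, time = time, event = event,
                   event_of_interest = mi_code,
                   log_covariates = log_covariates, standardize = standardize)
    return(structure(list(fit = fit, method = method, n = fit$n,
                          n_mi = fit$nevent,
                          n_competing = sum(ev == death_code)),
                     class = "bc_crr"))
  }
  prep <- prepare_covariates(data, covariates, log_covariates, standardize)
  mm <- stats::model.matrix(~., data = prep$frame)[, -1, drop = FALSE]
  fstatus <- integer(nrow(data))
  fstatus[ev == mi_code] <- 1L
  fstatus[ev == death_code] <- 2L
  fit <- cmprsk::crr(ftime = data[[time]], fstatus = fstatus, cov1 = mm,
                     failcode = 1, cencode = 0)
  if (!fit$converged) warning("Fine-Gray fit did not converge.", call. = FALSE)
  structure(
    list(fit = fit, method = method, scaling = prep$scaling,
         n = nrow(data), n_mi = n_mi, n_competing = sum(ev == death_code)),
    class = "bc_crr"
  )
}

#' @describeIn competing_risk_mi Tidy the subdistribution (or cause-specific)
#'   log-hazard coefficients.
#' @param x A `bc_crr` object.
#' @param exponentiate Report (sub)hazard ratios.
#' @param conf.level Confidence level.
#' @param ... Unused.
#' @method tidy bc_crr
#' @export
tidy.bc_crr <- function(x, exponentiate = FALSE, conf.level = 0.95, ...) {
  if (x$method == "cause-specific") {
    return(tidy(x$fit, exponentiate = exponentiate, conf.level = conf.level))
  }
  co <- x$fit$coef
  se <- sqrt(diag(x$fit$var))
  zq <- stats::qnorm(1 - (1 - conf.level) / 2)
  out <- tibble(
    term = names(co), estimate = unname(co), std.error = unname(se),
    statistic = unname(co / se),
    p.value = 2 * stats::pnorm(-abs(unname(co / se))),
    conf.low = unname(co - zq * se), conf.high = unname(co + zq * se)
  )
  if (exponentiate) {
    out$estimate <- exp(out$estimate)
    out$conf.low <- exp(out$conf.low)
    out$conf.high <- exp(out$conf.high)
  }
  out
}

#' @describeIn competing_risk_mi One-row summary with event counts.
#' @method glance bc_crr
#' @export
glance.bc_crr <- function(x, ...) {
  tibble(n = x$n, n_mi = x$n_mi, n_competing = x$n_competing,
         method = x$method)
}

#' @export
print.bc_crr <- function(x, ...) {
  cat(sprintf("<bc_crr> %s model: %d subjects, %d MI events, %d competing deaths\n",
              x$method, x$n, x$n_mi, x$n_competing))
  print(tidy(x, exponentiate = TRUE), n = Inf)
  invisible(x)
}
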