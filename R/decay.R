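#' Fit an RNA decay time series
#'
#' Two estimators of a first-order degradation rate from a decay series
#' (e.g. sRNA copy numbers after transcription shut-off by inducer washout,
#' or mRNA abundance after a rifampicin chase):
#'
#' * `model = "loglinear"`: ordinary least squares of `ln(value)` against
#'   time; the degradation rate is minus the slope and the lifetime its
#'   reciprocal.
#' * `model = "one_phase"`: nonlinear least squares of
#'   `value(t) = plateau + span * exp(-rate * t)`, the standard model for
#'   relative RT-qPCR abundances that decay to a nonzero baseline.
#'
#' @param data Tibble or data frame with columns `time_s` and `value`
#'   (copies per cell or relative abundance; must be positive for the
#'   log-linear model).
#' @param model `"loglinear"` (default) or `"one_phase"`.
#' @param normalize If `TRUE`, values are divided by the fitted/first value
#'   at `t = 0` before fitting. Affects the intercept only, never the rate.
#' @return An object of class `decay_fit` with fields `rate` (s^-1),
#'   `lifetime_s` (`1/rate`; `Inf`, flagged, when the series does not
#'   decay), `intercept`/`plateau`/`span`, `r2`, and `model`.
#' @examples
#' tt <- c(0, 120, 240, 360, 480, 600, 900, 1200)
#' fit_decay(tibble::tibble(time_s = tt, value = 100 * exp(-0.0016 * tt)))
#' @export
fit_decay <- function(data, model = c("loglinear", "one_phase"),
                      normalize = FALSE) {
  model <- match.arg(model)
  stopifnot(all(c("time_s", "value") %in% names(data)))
  tt <- as.numeric(data$time_s)
  vv <- as.numeric(data$value)
  if (is.unsorted(tt, strictly = TRUE)) stop("`time_s` must be strictly increasing", call. = FALSE)
  if (normalize) vv <- vv / vv[1]

  if (model == "loglinear") {
    if (length(tt) < 3L) stop("log-linear fit needs at least 3 points", call. = FALSE)
    if (any(vv <= 0)) stop("log-linear fit needs positive values", call. = FALSE)
    ols <- stats::lm(log(vv) ~ tt)
    slope <- unname(stats::coef(ols)[2L])
    rate <- -slope
    lv <- log(vv)
    ss_tot <- sum((lv - mean(lv))^2)
    r2 <- if (ss_tot > 0) 1 - sum(stats::residuals(ols)^2) / ss_tot else NA_real_
    res <- list(
      rate = rate,
      lifetime_s = if (rate > 0) 1 / rate else Inf,
      decaying = rate > 0,
      intercept = unname(stats::coef(ols)[1L]),
      r2 = r2,
      model = "loglinear",
      fit = ols
    )
  } else {
    if (length(tt) < 4L) stop("one-phase fit needs at least 4 points", call. = FALSE)
    plateau0 <- min(vv)
    span0 <- max(vv) - min(vv)
    if (span0 <= 0) {
      # flat series: the decay rate is indeterminate
      return(structure(list(
        rate = NA_real_, lifetime_s = NA_real_, decaying = FALSE,
        plateau = plateau0, span = 0, r2 = NA_real_,
        model = "one_phase", fit = NULL
      ), class = "decay_fit"))
    }
    # rate initializer from the log ratio of first to last point above plateau
    top <- vv[1] - plateau0 + span0 * 1e-3
    bot <- max(vv[length(vv)] - plateau0, span0 * 1e-3)
    rate0 <- max(log(top / bot) / (tt[length(tt)] - tt[1]), 1e-6)
    nls_fit <- tryCatch(
      minpack.lm::nlsLM(
        vv ~ plateau + span * exp(-rate * tt),
        start = list(plateau = plateau0, span = span0, rate = rate0),
        lower = c(0, 0, 0),
        control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-12)
      ),
      error = function(e) {
        stop("one-phase fit did not converge (start: plateau=", signif(plateau0, 3),
             ", span=", signif(span0, 3), ", rate=", signif(rate0, 3), "): ",
             conditionMessage(e), call. = FALSE)
      }
    )
    cf <- stats::coef(nls_fit)
    rate <- unname(cf["rate"])
    ss_res <- sum(stats::residuals(nls_fit)^2)
    ss_tot <- sum((vv - mean(vv))^2)
    res <- list(
      rate = rate,
      lifetime_s = if (rate > 0) 1 / rate else Inf,
      decaying = rate > 0,
      plateau = unname(cf["plateau"]), span = unname(cf["span"]),
      r2 = 1 - ss_res / ss_tot,
      model = "one_phase",
      fit = nls_fit
    )
  }
  structure(res, class = "decay_fit")
}

#' @export
print.decay_fit <- function(x, ...) {
  cat("<decay_fit:", x$model, ">\n")
  if (isTRUE(x$decaying)) {
    cat(sprintf("  rate %.4g s^-1, lifetime %.3g min (R^2 %.4f)\n",
                x$rate, x$lifetime_s / 60, x$r2))
  } else {
    cat("  no decay detected (rate <= 0 or indeterminate)\n")
  }
  invisible(x)
}

#' @rdname tidy.srna_fit
#' @export
tidy.decay_fit <- function(x, ...) {
  tibble::tibble(
    term = c("rate", "lifetime_min",
             if (x$model == "loglinear") "intercept" else c("plateau", "span")),
    estimate = c(x$rate, x$lifetime_s / 60,
                 if (x$model == "loglinear") x$intercept else c(x$plateau, x$span))
  )
}

#' @rdname glance.srna_fit
#' @export
glance.decay_fit <- function(x, ...) {
  tibble::tibble(rate = x$rate, lifetime_min = x$lifetime_s / 60,
                 r2 = x$r2, model = x$model, decaying = x$decaying)
}

#' Lifetime in minutes from a first-order degradation rate
#'
#' @param rate Degradation rate in s^-1; must be positive.
#' @param digits If not `NULL`, round to this many significant figures for
#'   reporting (reporting only; computations always use full precision).
#' @return Lifetime `1/rate` in minutes.
#' @examples
#' lifetime_from_rate(0.0016) # 10.4 min
#' @export
lifetime_from_rate <- function(rate, digits = NULL) {
  stopifnot(is.numeric(rate))
  if (any(rate <= 0)) stop("`rate` must be positive", call. = FALSE)
  out <- 1 / rate / 60
  if (!is.null(digits)) out <- signif(out, digits)
  out
}

#' Fold change by the delta-delta-Ct method
#'
#' Relative RT-qPCR quantification: `fold = 2^-ddCt` with
#' `ddCt = (Ct_target,treated - Ct_ref,treated) -
#' (Ct_target,control - Ct_ref,control)`.
#'
#' @param ct_target_treated,ct_ref_treated,ct_target_control,ct_ref_control
#'   Ct values (finite numerics; vectors recycle as usual).
#' @return Fold change of the target relative to the control condition.
#' @examples
#' ddct_fold_change(21, 15, 20, 15) # ddCt = 1 -> 0.5
#' @export
ddct_fold_change <- function(ct_target_treated, ct_ref_treated,
                             ct_target_control, ct_ref_control) {
  args <- list(ct_target_treated, ct_ref_treated, ct_target_control, ct_ref_control)
  if (!all(vapply(args, function(a) is.numeric(a) && all(is.finite(a)), logical(1)))) {
    stop("all Ct values must be finite numerics", call. = FALSE)
  }
  ddct <- (ct_target_treated - ct_ref_treated) -
    (ct_target_control - ct_ref_control)
  2^(-ddct)
}
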