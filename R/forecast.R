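#' Linear trend fit and four-fraction-ahead prediction of a DP_sum series
#'
#' Fits an ordinary least-squares line through all observed per-fraction
#' DP_sum values (fraction index as regressor) and extrapolates the next four
#' fractions.  Predictions require at least five observed fractions; with
#' fewer the fit is refused and the returned object carries a reason code.
#' Predicted values are not clamped to physical ranges (a V95 prediction may
#' leave [0, 100]); an annotation marks out-of-range predictions instead, so
#' downstream accuracy evaluation stays unbiased.
#'
#' @param series numeric DP_sum values observed at `fractions`.
#' @param fractions fraction indices (default `1..k`).
#' @param min_obs minimum observations before predictions are issued.
#' @param horizon number of fractions predicted ahead.
#' @param range optional length-2 physical range used only to annotate
#'   predictions (e.g. `c(0, 100)` for V95).
#' @return a `trend_series` object: observed data, OLS coefficients
#'   (intercept, slope per fraction), and a tibble of predictions
#'   `pdp_sum` for the next `horizon` fractions (`NULL` when refused, with
#'   `reason`).
#' @export
fit_predict <- function(series, fractions = seq_along(series), min_obs = 5L,
                        horizon = 4L, range = NULL) {
  series <- as.numeric(series)
  k <- length(series)
  stopifnot(length(fractions) == k)
  obj <- structure(list(observed = tibble::tibble(fraction = fractions,
                                                  dp_sum = series),
                        coefficients = NULL, predictions = NULL, reason = NULL),
                   class = "trend_series")
  if (k < min_obs) {
    obj$reason <- "insufficient_fractions"
    return(obj)
  }
  fit <- stats::lm.fit(cbind(intercept = 1, fraction = fractions), series)
  coefs <- stats::setNames(unname(fit$coefficients), c("intercept", "slope"))
  fpred <- fractions[k] + seq_len(horizon)
  pdp <- unname(coefs[["intercept"]] + coefs[["slope"]] * fpred)
  obj$coefficients <- coefs
  obj$predictions <- tibble::tibble(
    fraction = fpred, pdp_sum = pdp,
    out_of_range = if (is.null(range)) FALSE else pdp < range[1] | pdp > range[2])
  obj
}

#' Predicted value of a fitted trend at arbitrary fractions
#' @param object a `trend_series` with coefficients.
#' @param fraction fraction indices.
#' @param ... ignored.
#' @export
predict.trend_series <- function(object, fraction, ...) {
  if (is.null(object$coefficients))
    stop("trend was not fitted (", object$reason %||% "no fit", ")", call. = FALSE)
  object$coefficients[["intercept"]] + object$coefficients[["slope"]] * fraction
}

#' @export
generics::tidy

#' @export
generics::glance

#' @export
tidy.trend_series <- function(x, ...) {
  if (is.null(x$coefficients))
    return(tibble::tibble(term = character(), estimate = numeric()))
  tibble::tibble(term = names(x$coefficients),
                 estimate = unname(x$coefficients))
}

#' @export
glance.trend_series <- function(x, ...) {
  obs <- x$observed
  fitted <- if (is.null(x$coefficients)) rep(NA_real_, nrow(obs))
            else predict(x, obs$fraction)
  tibble::tibble(n_obs = nrow(obs),
                 sigma = if (is.null(x$coefficients)) NA_real_
                         else sqrt(sum((obs$dp_sum - fitted)^2) / max(nrow(obs) - 2, 1)),
                 refused = !is.null(x$reason),
                 reason = x$reason %||% NA_character_)
}

#' @export
print.trend_series <- function(x, ...) {
  cat("<trend_series>", nrow(x$observed), "observed fractions")
  if (is.null(x$coefficients)) {
    cat(" — no predictions (", x$reason, ")\n", sep = "")
  } else {
    cat(sprintf(": slope %+.4g per fraction; predictions at fractions %s\n",
                x$coefficients[["slope"]],
                paste(x$predictions$fraction, collapse = ", ")))
  }
  invisible(x)
}

#' First predicted crossing of an endpoint level
#'
#' Scans the four predicted fractions of a fitted trend for the first strict
#' violation of the given endpoint level.
#'
#' @param trend a `trend_series` with predictions.
#' @param spec one endpoint row.
#' @param level `"adaptation"` or `"warning"`.
#' @return predicted crossing fraction, or `NA` if no predicted violation.
#' @export
predicted_crossing <- function(trend, spec, level = c("adaptation", "warning")) {
  level <- match.arg(level)
  if (is.null(trend$predictions)) return(NA_integer_)
  thr <- spec[[level]]
  viol <- if (spec$direction == "lower_bound") trend$predictions$pdp_sum < thr
          else trend$predictions$pdp_sum > thr
  if (!any(viol)) NA_integer_ else trend$predictions$fraction[which(viol)[1]]
}

#' Prediction accuracy at the threshold-crossing fraction
#'
#' For every flagged series with crossing fraction `Fx`, the trend is refit on
#' the fractions observed up to the anchor `Fx - i` (for lookaheads
#' `i = 4, 3, 2, 1`) and extrapolated to `Fx`; the difference
#' `pDP_sum[Fx - i] - DP_sum[Fx]` is averaged over the `n` series and reported
#' with its two-sided 95% confidence half-width from the Student t
#' distribution on `n - 1` degrees of freedom.  Series with `Fx < 5` are
#' excluded (the model needs five treated fractions), and anchors earlier than
#' five observed fractions yield no prediction for that lookahead.
#'
#' @param flagged_series list; each element a list with `observed` (DP_sum
#'   values for fractions `1..k`, `k >= Fx`) and `fx` (crossing fraction).
#' @param min_obs minimum observed fractions at the anchor.
#' @return tibble of class `prediction_accuracy`: one row per lookahead with
#'   `n`, `mean_diff`, `sd_diff`, `ci95_half`.
#' @export
eval_accuracy <- function(flagged_series, min_obs = 5L) {
  keep <- Filter(function(s) s$fx >= min_obs, flagged_series)
  rows <- lapply(4:1, function(i) {
    diffs <- vapply(keep, function(s) {
      anchor <- s$fx - i
      if (anchor < min_obs) return(NA_real_)
      tr <- fit_predict(s$observed[seq_len(anchor)], min_obs = min_obs)
      predict(tr, s$fx) - s$observed[s$fx]
    }, 0)
    diffs <- diffs[!is.na(diffs)]
    n <- length(diffs)
    tibble::tibble(
      lookahead = i, n = n,
      mean_diff = if (n) mean(diffs) else NA_real_,
      sd_diff = if (n > 1) stats::sd(diffs) else NA_real_,
      ci95_half = if (n > 1) stats::qt(0.975, n - 1) * stats::sd(diffs) / sqrt(n)
                  else NA_real_)
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("prediction_accuracy", class(out))
  out
}

#' Plot a DP trend with its four-fraction-ahead prediction
#' @param object a `trend_series`.
#' @param ... ignored.
#' @export
autoplot.trend_series <- function(object, ...) {
  p <- ggplot2::ggplot(object$observed,
                       ggplot2::aes(x = .data$fraction, y = .data$dp_sum)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "Fraction", y = "DP_sum") + ggplot2::theme_minimal()
  if (!is.null(object$predictions))
    p <- p + ggplot2::geom_line(data = object$predictions,
                                ggplot2::aes(y = .data$pdp_sum),
                                linetype = "dashed", colour = "firebrick") +
      ggplot2::geom_point(data = object$predictions,
                          ggplot2::aes(y = .data$pdp_sum),
                          shape = 1, colour = "firebrick")
  p
}
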