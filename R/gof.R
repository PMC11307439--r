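# Goodness-of-fit battery and calibration for continuous predictions,
# with errors e = observed - predicted.

#' Goodness-of-fit report
#'
#' Computes the thirteen-measure battery for continuous predictions:
#' \describe{
#'   \item{rmse}{`sqrt(mean(e^2))`}
#'   \item{rrmse}{`100 * rmse / mean(obs)` (percent)}
#'   \item{sdr}{`sd(e) / sd(obs)` (standard deviation ratio)}
#'   \item{cv}{`100 * sd(e) / mean(obs)` (percent)}
#'   \item{pc}{Pearson correlation of observed and predicted}
#'   \item{pi}{performance index, `rrmse / (1 + pc)`}
#'   \item{me}{mean error, `mean(e)`}
#'   \item{rae}{relative approximation error, `sum(e^2) / sum(obs^2)`}
#'   \item{mrae}{`sqrt(rae / n)` (see the methods vignette for this
#'     definitional choice)}
#'   \item{mape}{`100 * mean(|e| / obs)` (percent)}
#'   \item{mad}{mean absolute deviation, `mean(|e|)`}
#'   \item{aic}{least-squares form `n * log(sse / n) + 2p`}
#'   \item{caic}{small-sample corrected, `aic + 2p(p+1)/(n-p-1)`}
#' }
#' Ratio measures are reported NA (with a reason attribute) when an
#' observed value is zero.
#'
#' @param observed,predicted Numeric response vectors of equal length
#'   (n >= 2); `observed` must have positive mean for the ratio
#'   measures.
#' @param n_params Effective parameter count `p` for AIC/CAIC (terms
#'   including the constant).
#' @return A `gof_report` list with the thirteen measures.
#' @export
gof <- function(observed, predicted, n_params) {
  stopifnot(is.numeric(observed), is.numeric(predicted),
            length(observed) == length(predicted))
  n <- length(observed)
  if (n < 2L) stop("gof() needs at least two observations", call. = FALSE)
  if (anyNA(observed) || anyNA(predicted)) {
    stop("gof() does not accept missing values", call. = FALSE)
  }
  stopifnot(is.numeric(n_params), length(n_params) == 1L, n_params >= 1)
  e <- observed - predicted
  sse <- sum(e^2)
  mo <- mean(observed)
  if (mo <= 0) stop("observed mean must be positive for the ratio measures",
                    call. = FALSE)
  any_zero <- any(observed == 0)
  rmse <- sqrt(sse / n)
  sd_e <- stats::sd(e)
  pc <- if (stats::sd(predicted) > 0 && stats::sd(observed) > 0) {
    stats::cor(observed, predicted)
  } else NA_real_
  rrmse <- 100 * rmse / mo
  rae <- sse / sum(observed^2)
  p <- n_params
  out <- list(
    rmse = rmse,
    rrmse = rrmse,
    sdr = sd_e / stats::sd(observed),
    cv = 100 * sd_e / mo,
    pc = pc,
    pi = if (is.na(pc)) NA_real_ else rrmse / (1 + pc),
    me = mean(e),
    rae = rae,
    mrae = sqrt(rae / n),
    mape = if (any_zero) NA_real_ else 100 * mean(abs(e) / observed),
    mad = mean(abs(e)),
    aic = n * log(sse / n) + 2 * p,
    caic = n * log(sse / n) + 2 * p + 2 * p * (p + 1) / (n - p - 1)
  )
  if (any_zero) attr(out, "absent") <- c(mape = "zero observed value")
  structure(out, class = "gof_report")
}

#' @export
print.gof_report <- function(x, ...) {
  lbl <- c(rmse = "Root mean square error (RMSE)",
           rrmse = "Relative RMSE (RRMSE, %)",
           sdr = "Standard deviation ratio (SDR)",
           cv = "Coefficient of variation (CV, %)",
           pc = "Pearson correlation (PC)",
           pi = "Performance index (PI)",
           me = "Mean error (ME)",
           rae = "Relative approximation error (RAE)",
           mrae = "Mean relative approximation error (MRAE)",
           mape = "Mean absolute percentage error (MAPE, %)",
           mad = "Mean absolute deviation (MAD)",
           aic = "Akaike information criterion (AIC)",
           caic = "Corrected AIC (CAIC)")
  for (nm in names(lbl)) {
    cat(sprintf("%-44s %10.4g\n", lbl[[nm]], x[[nm]]))
  }
  invisible(x)
}

#' Calibration of continuous predictions
#'
#' Least-squares fit of `observed = a + b * predicted`.  Reports the
#' intercept (`citl_intercept`), slope, and R-squared of that
#' regression, and the calibration-in-the-large mean difference
#' `mean(observed) - mean(predicted)`.  Perfect predictions give slope
#' 1, zero offsets, R-squared 1.
#'
#' @param observed,predicted Numeric vectors, n >= 3; `predicted` must
#'   not be constant.
#' @return A `calibration_report` list: `citl_mean_diff`,
#'   `citl_intercept`, `slope`, `rsq`.
#' @export
calibration <- function(observed, predicted) {
  stopifnot(is.numeric(observed), is.numeric(predicted),
            length(observed) == length(predicted))
  if (length(observed) < 3L) stop("calibration() needs n >= 3", call. = FALSE)
  if (anyNA(observed) || anyNA(predicted)) {
    stop("calibration() does not accept missing values", call. = FALSE)
  }
  if (stats::sd(predicted) == 0) {
    stop("calibration slope undefined for constant predictions",
         call. = FALSE)
  }
  fit <- stats::lm.fit(cbind(1, predicted), observed)
  res <- fit$residuals
  sst <- sum((observed - mean(observed))^2)
  structure(list(
    citl_mean_diff = mean(observed) - mean(predicted),
    citl_intercept = unname(fit$coefficients[1L]),
    slope = unname(fit$coefficients[2L]),
    rsq = if (sst > 0) 1 - sum(res^2) / sst else 1
  ), class = "calibration_report")
}

#' @export
print.calibration_report <- function(x, ...) {
  cat(sprintf(paste0("Calibration: slope %.3f, intercept %.2f, ",
                     "mean difference %.2f, R^2 %.3f\n"),
              x$slope, x$citl_intercept, x$citl_mean_diff, x$rsq))
  invisible(x)
}
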