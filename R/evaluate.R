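#' Split observations into calibration and validation sets
#'
#' Per-cultivar random partition, deterministic in the seed. In "full"
#' mode, `round(fraction * n)` observations (round-half-to-even) go to
#' calibration; in "scarce" mode exactly `count` observations (default
#' 10) are used for calibration and the rest for validation. Cultivars
#' with too few observations to leave at least one validation point are
#' excluded with a warning.
#'
#' @param observations Data frame with a `cultivar` column.
#' @param mode "full" or "scarce".
#' @param fraction Calibration fraction for "full" mode (default 0.75).
#' @param count Calibration count for "scarce" mode (default 10).
#' @param seed Integer seed.
#' @param chronological If `TRUE`, take the earliest seasons for
#'   calibration instead of a random draw.
#' @return List with data frames `calibration` and `validation`;
#'   excluded cultivars are recorded in the `excluded` attribute.
#' @export
split_observations <- function(observations, mode = c("full", "scarce"),
                               fraction = 0.75, count = 10, seed = 1L,
                               chronological = FALSE) {
  mode <- match.arg(mode)
  set.seed(seed)
  cal <- val <- list()
  excluded <- character(0)
  for (cv in sort(unique(as.character(observations$cultivar)))) {
    rows <- observations[observations$cultivar == cv, , drop = FALSE]
    n <- nrow(rows)
    ncal <- if (mode == "full") round(fraction * n) else count
    if (ncal < 1 || ncal >= n) {
      excluded <- c(excluded, cv)
      next
    }
    idx <- if (chronological) order(rows$season)[seq_len(ncal)] else
      sample.int(n, ncal)
    cal[[cv]] <- rows[idx, , drop = FALSE]
    val[[cv]] <- rows[-idx, , drop = FALSE]
  }
  if (length(excluded))
    warning("cultivar(s) excluded from the split (too few observations): ",
            paste(excluded, collapse = ", "))
  bindrows <- function(lst)
    if (length(lst)) do.call(rbind, c(lst, list(make.row.names = FALSE)))
    else observations[0, , drop = FALSE]
  out <- list(calibration = bindrows(cal), validation = bindrows(val))
  attr(out, "excluded") <- excluded
  out
}

#' Bloom-prediction performance metrics
#'
#' Root Mean Square Error, Ratio of Performance to Interquartile
#' distance (interquartile range of the observations divided by the
#' RMSE; quartiles by linear interpolation between order statistics),
#' mean bias (predicted minus observed) and the proportion of absolute
#' residuals exceeding 7 days. Predictions that are `NA` (failures to
#' bloom) are excluded from the metrics and counted separately.
#'
#' @param predicted Numeric vector of predicted bloom DOY.
#' @param observed Numeric vector of observed bloom DOY, same length.
#' @return List of class `metric_report`: `rmse`, `rpiq` (NA with
#'   `rpiq_infinite = TRUE` when rmse is 0), `mean_bias`, `n`,
#'   `prop_large_error`, `n_no_bloom`.
#' @export
compute_metrics <- function(predicted, observed) {
  if (length(predicted) != length(observed))
    stop("predicted and observed must have the same length")
  keep <- !is.na(predicted)
  n_no_bloom <- sum(!keep)
  predicted <- predicted[keep]
  observed <- observed[keep]
  n <- length(predicted)
  if (n == 0) stop("no bloom predictions to evaluate")
  res <- predicted - observed
  rmse <- sqrt(mean(res^2))
  iqr <- if (n >= 2)
    diff(stats::quantile(observed, c(0.25, 0.75), names = FALSE, type = 7))
  else NA_real_
  rpiq_inf <- rmse == 0
  structure(list(rmse = rmse,
                 rpiq = if (rpiq_inf || is.na(iqr)) NA_real_ else iqr / rmse,
                 rpiq_infinite = rpiq_inf,
                 mean_bias = mean(res),
                 n = n,
                 prop_large_error = mean(abs(res) > 7),
                 n_no_bloom = n_no_bloom),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf(
    "n = %d: RMSE %.2f days, RPIQ %s, bias %+.2f days, |res|>7d: %.0f%%%s\n",
    x$n, x$rmse,
    if (x$rpiq_infinite) "Inf (zero error)" else sprintf("%.2f", x$rpiq),
    x$mean_bias, 100 * x$prop_large_error,
    if (x$n_no_bloom) sprintf(", %d no-bloom excluded", x$n_no_bloom) else ""))
  invisible(x)
}

#' Evaluate a fitted model on an observation set
#'
#' Convenience wrapper: predicts every observation's bloom date and
#' computes the metric report.
#'
#' @inheritParams predict_bloom
#' @return A `metric_report`; predictions are attached as the
#'   `predictions` attribute.
#' @export
evaluate_model <- function(model, observations, seasons) {
  pred <- predict_bloom(model, observations, seasons)
  rep <- compute_metrics(pred$predicted_doy, pred$bloom_doy)
  attr(rep, "predictions") <- pred
  rep
}
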