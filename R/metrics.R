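#' Per-sample prediction errors (REP and PRESS)
#'
#' `rep = predicted - actual` per sample, and `press = rep^2`. The plain
#' difference is the convention used in published QPAR test-set tables (on
#' the 100 + delta% activity scale the difference and the percentage ratio
#' nearly coincide); `relative = TRUE` opts into the ratio variant
#' `100 * (predicted - actual) / actual`. `press` is always the squared
#' plain difference, so `sum(press)` feeds RMSEP and q2 unchanged.
#'
#' @param actual,predicted equal-length numeric vectors.
#' @param relative use the percentage-ratio REP variant (default `FALSE`).
#' @return data.frame with columns `actual`, `predicted`, `rep`, `press`.
#' @examples
#' repPress(85.32, 121.30) # rep 35.98, press 1294.56
#' @export
repPress <- function(actual, predicted, relative = FALSE) {
  if (length(actual) != length(predicted))
    stop("actual and predicted must have equal length")
  diff <- predicted - actual
  rep <- if (relative) 100 * diff / actual else diff
  data.frame(actual = actual, predicted = predicted, rep = rep,
             press = diff^2)
}

#' Root mean squared error
#'
#' `sqrt(mean((predicted - actual)^2))` — RMSET on training fits, RMSEP on
#' test-set predictions.
#'
#' @param actual,predicted equal-length, non-empty numeric vectors.
#' @return scalar RMSE.
#' @export
rmse <- function(actual, predicted) {
  if (!length(actual)) stop("empty input")
  if (length(actual) != length(predicted))
    stop("actual and predicted must have equal length")
  sqrt(mean((predicted - actual)^2))
}

#' Squared Pearson correlation of predictions and observations
#'
#' The R2 convention of QPAR validation tables: the squared correlation
#' coefficient of the regression between predicted and experimental
#' activities (R2t on the training fit, R2p on the test set).
#'
#' @param actual,predicted numeric vectors, both with nonzero variance.
#' @return scalar in \[0, 1\].
#' @export
r2Corr <- function(actual, predicted) {
  if (var(actual) == 0 || var(predicted) == 0)
    stop("degenerate input: zero variance")
  cor(actual, predicted)^2
}

#' Cross-validated determination coefficient q2
#'
#' `q2 = 1 - sum((predicted - actual)^2) / sum((actual - mean(actual))^2)`.
#' Unlike [r2Corr()] this penalizes bias and scale errors, so it can be
#' much lower than the squared correlation on the same predictions (and can
#' go negative for predictions worse than the mean).
#'
#' @param actual,predicted numeric vectors; `actual` with nonzero variance.
#' @return scalar `<= 1`.
#' @export
q2 <- function(actual, predicted) {
  if (var(actual) == 0) stop("degenerate input: actual has zero variance")
  1 - sum((predicted - actual)^2) / sum((actual - mean(actual))^2)
}

#' Assemble the full validation report for a fitted model
#'
#' Training metrics (R2t, RMSET), test metrics (R2p, RMSEP, q2) and the
#' per-sample test table (actual, predicted, REP, PRESS), plus the model
#' size. RMSECV is whatever leave-one-out value the caller obtained during
#' component selection (`NA` if not supplied).
#'
#' @param model a fitted [PLSModel-class].
#' @param XTrain,yTrain training data the model was fitted on (full-grid
#'   matrix; the model extracts its variable subset).
#' @param XTest,yTest held-out test data.
#' @param rmsecv leave-one-out RMSE at the chosen component count.
#' @return A [ValidationReport-class].
#' @export
validationReport <- function(model, XTrain, yTrain, XTest, yTest,
                             rmsecv = NA_real_) {
  fitTrain <- predict(model, XTrain)
  predTest <- predict(model, XTest)
  ps <- repPress(yTest, predTest)
  new("ValidationReport",
      r2Train = r2Corr(yTrain, fitTrain),
      rmset = rmse(yTrain, fitTrain),
      rmsecv = rmsecv,
      nComponents = model@nComponents,
      nVariables = length(model@coef),
      r2Test = r2Corr(yTest, predTest),
      rmsep = rmse(yTest, predTest),
      q2 = q2(yTest, predTest),
      perSample = ps)
}

#' Batch-wise summary of an activity series
#'
#' Mean, sample standard deviation (n - 1), minimum and maximum of the
#' activities per batch — the summary block of a panel activity table.
#'
#' @param activity numeric activity vector.
#' @param batch batch label per sample.
#' @return data.frame with one row per batch: `batch`, `n`, `mean`, `sd`,
#'   `min`, `max`.
#' @export
batchSummary <- function(activity, batch) {
  if (length(activity) != length(batch))
    stop("activity and batch must have equal length")
  ub <- unique(batch)
  out <- data.frame(
    batch = ub,
    n = vapply(ub, function(b) sum(batch == b), 0L),
    mean = vapply(ub, function(b) mean(activity[batch == b]), 0),
    sd = vapply(ub, function(b) {
      v <- activity[batch == b]
      if (length(v) >= 2) sd(v) else NA_real_
    }, 0),
    min = vapply(ub, function(b) min(activity[batch == b]), 0),
    max = vapply(ub, function(b) max(activity[batch == b]), 0))
  rownames(out) <- NULL
  out
}

#' Write a validation report to JSON and CSV
#'
#' JSON carries the scalar metrics; the CSV mirrors the per-sample test
#' table layout (number, actual, predicted, REP, PRESS).
#'
#' @param report a [ValidationReport-class].
#' @param jsonFile,csvFile output paths (either may be `NULL` to skip).
#' @return Invisibly, the paths written.
#' @export
writeReport <- function(report, jsonFile = NULL, csvFile = NULL) {
  if (!is.null(jsonFile))
    jsonlite::write_json(list(
      r2_train = report@r2Train, rmset = report@rmset,
      rmsecv = report@rmsecv, n_components = report@nComponents,
      n_variables = report@nVariables, r2_test = report@r2Test,
      rmsep = report@rmsep, q2 = report@q2),
      jsonFile, auto_unbox = TRUE, digits = NA, na = "null")
  if (!is.null(csvFile)) {
    ps <- report@perSample
    write.csv(cbind(number = seq_len(nrow(ps)), ps), csvFile,
              row.names = FALSE)
  }
  invisible(c(json = jsonFile, csv = csvFile))
}
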