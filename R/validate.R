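#' Pearson product-moment correlation with validity checks
#'
#' Thin wrapper around [stats::cor()] that rejects degenerate input: the
#' correlation between reference and predicted MET values is undefined when
#' either vector has zero variance.
#'
#' @param observed,predicted Equal-length numeric vectors, length >= 2.
#' @return Correlation coefficient in `[-1, 1]`.
#' @export
pearson_r <- function(observed, predicted) {
  if (length(observed) < 2L || length(observed) != length(predicted))
    stop("need equal-length vectors with at least 2 elements")
  if (stats::sd(observed) == 0 || stats::sd(predicted) == 0)
    stop("correlation undefined: zero variance in observed or predicted values")
  stats::cor(observed, predicted)
}

#' Leave-one-out cross-validation of MET models
#'
#' For each of the `N` records the model is refit on the remaining `N - 1`
#' records and the held-out MET is predicted; `RMSE_cv` over all `N`
#' held-out predictions and the Pearson correlation between reference and
#' predicted values summarize out-of-sample accuracy. Any fold whose fit
#' fails aborts the validation with the fold index; folds are never
#' silently skipped.
#'
#' For piecewise models each fold by default re-runs the full LS/GA search
#' with a fold-derived deterministic seed (`seed + fold`), so change points
#' are re-estimated per fold. `refit_changepoints = FALSE` instead reuses
#' the full-data change points and refits only the (analytic) slopes per
#' fold; this is much faster but optimistic, since the held-out point
#' influenced the change-point locations.
#'
#' @param cohort A [walk_cohort()] with `N >= 3`.
#' @param model `"polynomial"`, `"piecewise"` or `"linear"`.
#' @param order Polynomial order (for `model = "polynomial"`).
#' @param n_segments Segment count (for `model = "piecewise"`).
#' @param config [ga_config()] used by piecewise folds.
#' @param seed Base seed for stochastic fold fits.
#' @param refit_changepoints Re-estimate change points in every fold
#'   (default) or reuse the full-data ones.
#' @return A list of class `loo_report`: `predictions` (per-record held-out
#'   MET), `rmse_cv`, `pearson_r`, `n`, and a `spec` echo including the
#'   change-point handling mode.
#' @examples
#' co <- walk_cohort(velocity = c(1, 2, 3), met = c(1.5, 2.0, 2.5))
#' loo_cv(co, "polynomial", order = 1)$rmse_cv  # 0: folds predict exactly
#' @export
loo_cv <- function(cohort, model = c("polynomial", "piecewise", "linear"),
                   order = 3, n_segments = 4, config = ga_config(),
                   seed = 20180209, refit_changepoints = TRUE) {
  stopifnot(inherits(cohort, "walk_cohort"))
  model <- match.arg(model)
  n <- nrow(cohort)
  if (n < 3L) stop("LOO cross-validation needs at least 3 records")
  full_cps <- NULL
  if (model == "piecewise" && !refit_changepoints) {
    full_cps <- fit_met_piecewise(cohort, n_segments, config,
                                  seed = seed)$model$change_points
  }
  preds <- numeric(n)
  for (l in seq_len(n)) {
    train <- cohort[-l, , drop = FALSE]
    attr(train, "label") <- cohort_label(cohort)
    class(train) <- c("walk_cohort", "data.frame")
    fold_fit <- tryCatch({
      switch(model,
        polynomial = fit_met_polynomial(train, order)$model,
        linear = met_linear(),
        piecewise = if (refit_changepoints) {
          fit_met_piecewise(train, n_segments, config,
                            seed = seed + l)$model
        } else {
          inner <- slopes_given_change_points(train, full_cps)
          met_piecewise(inner$slopes, full_cps,
                        population = cohort_label(cohort))
        })
    }, error = function(e) {
      stop(sprintf("LOO fold %d failed: %s", l, conditionMessage(e)))
    })
    preds[l] <- predict(fold_fit, cohort$velocity[l])
  }
  structure(
    list(predictions = preds,
         rmse_cv = rmse(cohort$met, preds),
         pearson_r = pearson_r(cohort$met, preds),
         n = n,
         spec = list(model = model,
                     order = if (model == "polynomial") order else NULL,
                     n_segments = if (model == "piecewise") n_segments else NULL,
                     refit_changepoints =
                       if (model == "piecewise") refit_changepoints else NULL,
                     seed = seed)),
    class = "loo_report")
}

#' @export
print.loo_report <- function(x, ...) {
  cat(sprintf("Leave-one-out CV (%s model, N = %d folds)\n",
              x$spec$model, x$n))
  cat(sprintf("  RMSE_cv = %.4f MET, Pearson R = %.4f\n",
              x$rmse_cv, x$pearson_r))
  invisible(x)
}

#' Reference-vs-predicted table for a validation report
#'
#' Pairs each record's reference MET with its held-out prediction, the
#' format behind reference-vs-predicted scatter diagnostics.
#'
#' @param report A `loo_report`.
#' @param cohort The cohort the report was computed on.
#' @return A data frame with columns `velocity`, `reference`, `predicted`.
#' @export
cv_table <- function(report, cohort) {
  stopifnot(inherits(report, "loo_report"), inherits(cohort, "walk_cohort"),
            nrow(cohort) == report$n)
  data.frame(velocity = cohort$velocity, reference = cohort$met,
             predicted = report$predictions)
}
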