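# Metrics, null baselines, ensembles, Y-scrambling, and residual
# diagnostics.

#' Root mean squared error
#'
#' @param observed,predicted Numeric vectors of equal length >= 1.
#' @return `sqrt(mean((observed - predicted)^2))`.
#' @export
rmse <- function(observed, predicted) {
  assert_that(length(observed) == length(predicted),
              "observed and predicted must have equal length")
  assert_that(length(observed) >= 1, "need at least one value")
  sqrt(mean((observed - predicted)^2))
}

#' Pearson correlation of observed and predicted values
#'
#' @param observed,predicted Numeric vectors (n >= 3, non-constant).
#' @return Pearson's r.
#' @export
pearson_r <- function(observed, predicted) {
  assert_that(length(observed) == length(predicted) && length(observed) >= 3,
              "need >= 3 paired values")
  if (stats::sd(observed) == 0 || stats::sd(predicted) == 0) {
    stop("correlation undefined for constant input", call. = FALSE)
  }
  stats::cor(observed, predicted)
}

#' Squared correlation / coefficient of determination
#'
#' The default convention is the square of Pearson's r between observed
#' and predicted values (the convention used when judging Y-scrambling
#' collapse); `method = "cod"` gives the coefficient of determination
#' `1 - SSE/SST` instead.
#'
#' @inheritParams pearson_r
#' @param method `"pearson"` (default) or `"cod"`.
#' @return R-squared under the chosen convention.
#' @export
r_squared <- function(observed, predicted, method = c("pearson", "cod")) {
  method <- match.arg(method)
  if (method == "pearson") {
    pearson_r(observed, predicted)^2
  } else {
    assert_that(length(observed) == length(predicted),
                "observed and predicted must have equal length")
    1 - sum((observed - predicted)^2) /
      sum((observed - mean(observed))^2)
  }
}

#' Mean-predictor (null model) RMSE
#'
#' Test-split RMSE of the constant model that predicts the
#' training-split mean label for every test compound — the baseline any
#' learned model must beat.
#'
#' @param dataset A split [bioactivity_dataset()] (single target).
#' @return Numeric RMSE.
#' @export
mean_predictor_rmse <- function(dataset) {
  split <- split_of(dataset)
  r <- dataset$records
  s <- split[r$compound_id]
  train_y <- r$pIC50[s == "train"]
  test_y <- r$pIC50[s == "test"]
  assert_that(length(train_y) >= 1 && length(test_y) >= 1,
              "train or test split is empty")
  rmse(test_y, rep(mean(train_y), length(test_y)))
}

#' Average two prediction sets into an ensemble
#'
#' Per-compound arithmetic mean of two prediction vectors. By convexity
#' of the Euclidean norm the ensemble RMSE never exceeds the mean of the
#' component RMSEs.
#'
#' @param preds_a,preds_b Named numeric vectors of predictions covering
#'   the same compounds.
#' @param observed Named numeric vector of observed values for those
#'   compounds.
#' @return An object of class `ensemble_result`: component RMSEs,
#'   ensemble RMSE, percent change vs. each component, and the averaged
#'   predictions.
#' @export
ensemble_average <- function(preds_a, preds_b, observed) {
  ids <- names(observed)
  assert_that(!is.null(ids) && !is.null(names(preds_a)) &&
                !is.null(names(preds_b)),
              "predictions and observations must be named by compound id")
  miss_a <- setdiff(ids, names(preds_a))
  miss_b <- setdiff(ids, names(preds_b))
  if (length(miss_a) || length(miss_b)) {
    stop("prediction coverage mismatch; missing ids: ",
         paste(unique(c(miss_a, miss_b)), collapse = ", "), call. = FALSE)
  }
  a <- preds_a[ids]
  b <- preds_b[ids]
  ens <- (a + b) / 2
  rmse_a <- rmse(observed, a)
  rmse_b <- rmse(observed, b)
  rmse_e <- rmse(observed, ens)
  structure(list(
    component_rmses = c(a = rmse_a, b = rmse_b),
    ensemble_rmse = rmse_e,
    relative_improvement_vs_each = c(
      a = 100 * (rmse_a - rmse_e) / rmse_a,
      b = 100 * (rmse_b - rmse_e) / rmse_b
    ),
    predictions = ens
  ), class = "ensemble_result")
}

#' Y-scramble a dataset
#'
#' Permutes the activity labels uniformly at random within the union of
#' the training and validation compounds (per target); test labels and
#' all structures are untouched. A model trained on the scrambled data
#' should collapse to chance performance (test R-squared near zero).
#'
#' @param dataset A split [bioactivity_dataset()].
#' @param seed Integer seed (ignored when `permutation` is given).
#' @param permutation Optional named list (by target) of permutation
#'   index vectors over that target's train+validation rows; supplying
#'   the inverse (`lapply(p, order)`) of a previous scramble's recorded
#'   permutations restores the original dataset.
#' @return The dataset with scrambled train/validation labels; the
#'   permutations used are recorded in `attr(, "permutations")`.
#' @export
y_scramble <- function(dataset, seed = 1L, permutation = NULL) {
  split <- split_of(dataset)
  r <- dataset$records
  perms <- list()
  with_seed(seed, {
    for (t in unique(r$target_id)) {
      sel <- which(r$target_id == t &
                     split[r$compound_id] %in% c("train", "validation"))
      p <- permutation[[t]] %||% sample(length(sel))
      assert_that(length(p) == length(sel) &&
                    setequal(p, seq_along(sel)),
                  paste0("invalid permutation for target '", t, "'"))
      r$pIC50[sel] <- r$pIC50[sel][p]
      perms[[t]] <- p
    }
  })
  dataset$records <- r
  attr(dataset, "permutations") <- perms
  dataset
}

#' Residual diagnostics for a run
#'
#' Summarizes the test-split residuals of a `run_result`: mean and SD,
#' normal Q-Q pairs (theoretical vs. sample quantiles of the
#' standardized residuals), and a heteroscedasticity statistic — the
#' slope of `|residual|` regressed on the predicted value, with its
#' p-value; the heteroscedastic flag is raised at p < 0.01.
#'
#' @param run A `run_result` with at least 20 test predictions.
#' @return An object of class `residual_diagnostics`.
#' @export
residual_diagnostics <- function(run) {
  te <- run$predictions[run$predictions$split == "test", , drop = FALSE]
  if (nrow(te) < 20) {
    stop("need at least 20 test predictions for diagnostics, got ",
         nrow(te), call. = FALSE)
  }
  res <- te$observed - te$predicted
  m <- mean(res)
  s <- stats::sd(res)
  std <- if (s > 0) (res - m) / s else res * 0
  qq <- data.frame(theoretical = stats::qnorm(stats::ppoints(length(std))),
                   sample = sort(std))
  if (stats::sd(te$predicted) > 0 && s > 0) {
    fit <- stats::lm(abs(res) ~ te$predicted)
    sm <- summary(fit)$coefficients
    slope <- sm[2, 1]
    p <- sm[2, 4]
  } else {
    slope <- 0
    p <- 1
  }
  structure(list(mean = m, sd = s, qq = qq,
                 het_slope = slope, het_p = p,
                 heteroscedastic = is.finite(p) && p < 0.01),
            class = "residual_diagnostics")
}

#' @export
print.residual_diagnostics <- function(x, ...) {
  cat("Residuals: mean", signif(x$mean, 4), ", sd", signif(x$sd, 4),
      "| heteroscedasticity slope", signif(x$het_slope, 4),
      "(p =", signif(x$het_p, 3), ")",
      if (x$heteroscedastic) "[FLAGGED]" else "", "\n")
  invisible(x)
}
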