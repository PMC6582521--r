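# Balanced fixed-effect full-factorial comparison of runs via
# treatment-coded ordinary least squares, with Type-II ANOVA and
# adjusted R-squared.

prepare_factors <- function(table, factors, ref_levels) {
  for (f in factors) {
    assert_that(f %in% names(table), paste("missing factor column:", f))
    lv <- unique(as.character(table[[f]]))
    if (length(lv) < 2) {
      stop("factor '", f, "' needs at least 2 levels, found ", length(lv),
           call. = FALSE)
    }
    ref <- ref_levels[[f]] %||% sort(lv)[1]
    assert_that(ref %in% lv,
                paste0("reference level '", ref, "' absent from factor '",
                       f, "'"))
    table[[f]] <- stats::relevel(factor(table[[f]], levels = sort(lv)), ref)
  }
  table
}

empty_cells <- function(table, factors) {
  tb <- table(table[factors])
  idx <- which(tb == 0, arr.ind = TRUE)
  if (length(idx) == 0) return(character(0))
  apply(idx, 1, function(r) {
    paste(mapply(function(f, i) paste0(f, "=", dimnames(tb)[[f]][i]),
                 factors, r), collapse = ", ")
  })
}

fit_ols <- function(table, formula, factors, response) {
  fit <- stats::lm(formula, data = table)
  if (anyNA(stats::coef(fit))) {
    cells <- empty_cells(table, factors)
    stop("design is rank deficient; inestimable cell(s): ",
         paste(utils::head(cells, 10), collapse = "; "), call. = FALSE)
  }
  # a noiseless planted design fits exactly; summary() warns and the
  # ANOVA decomposition is degenerate, but the coefficients are the point
  sm <- suppressWarnings(summary(fit))
  fstat <- sm$fstatistic
  anova_tab <- tryCatch(as.data.frame(car::Anova(fit, type = 2)),
                        error = function(e) NULL)
  coefs <- stats::coef(fit)
  structure(list(
    intercept = unname(coefs["(Intercept)"]),
    coefficients = coefs[-1],
    adjusted_r2 = sm$adj.r.squared,
    r2 = sm$r.squared,
    overall_p = if (is.null(fstat)) NA_real_ else
      unname(stats::pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE)),
    anova = anova_tab,
    residuals = stats::residuals(fit),
    fitted = stats::fitted(fit),
    model = fit
  ), class = "factorial_fit")
}

#' Main-effects factorial model of run performance
#'
#' Ordinary least squares with treatment (dummy) coding:
#' `response ~ dataset + model + batch + augmentation` (or any supplied
#' factor set). The intercept is the mean response of the reference-level
#' combination; each coefficient is a level's offset from it. Per-factor
#' p-values come from a Type-II ANOVA, which coincides with the
#' sequential decomposition on balanced designs.
#'
#' @param table Data frame with one row per run: factor columns plus a
#'   numeric response (by default the run's test RMSE in pIC50 units).
#' @param factors Character vector of factor column names.
#' @param response Name of the response column.
#' @param ref_levels Named list of reference levels per factor (default:
#'   alphabetically first level).
#' @return An object of class `factorial_fit`: intercept, coefficients,
#'   `adjusted_r2`, overall F p-value, Type-II `anova` table, residuals
#'   and fitted values (`fitted + residuals` reproduces the response
#'   row-wise).
#' @export
fit_main_effects <- function(table,
                             factors = c("dataset", "model", "batch",
                                         "augmentation"),
                             response = "response",
                             ref_levels = list()) {
  assert_that(response %in% names(table),
              paste("missing response column:", response))
  table <- prepare_factors(table, factors, ref_levels)
  f <- stats::as.formula(paste(response, "~",
                               paste(factors, collapse = " + ")))
  fit_ols(table, f, factors, response)
}

#' Two-factor factorial model with interaction
#'
#' `response ~ dataset + model + dataset:model` with treatment coding —
#' the comparison of model families across datasets where the relative
#' ordering of families may differ per dataset.
#'
#' @inheritParams fit_main_effects
#' @param factors Exactly two factor column names.
#' @return A `factorial_fit`.
#' @export
fit_interaction <- function(table, factors = c("dataset", "model"),
                            response = "response", ref_levels = list()) {
  assert_that(length(factors) == 2, "interaction fit takes exactly 2 factors")
  assert_that(response %in% names(table),
              paste("missing response column:", response))
  table <- prepare_factors(table, factors, ref_levels)
  f <- stats::as.formula(paste(response, "~", factors[1], "*", factors[2]))
  fit_ols(table, f, factors, response)
}

#' @export
print.factorial_fit <- function(x, ...) {
  cat("Treatment-coded OLS fit: intercept", signif(x$intercept, 5),
      "| adjusted R^2", signif(x$adjusted_r2, 4),
      "| overall p", format.pval(x$overall_p), "\n")
  cat(length(x$coefficients), "non-reference coefficients\n")
  if (!is.null(x$anova)) {
    cat("Type-II ANOVA factors:",
        paste(rownames(x$anova)[rownames(x$anova) != "Residuals"],
              collapse = ", "), "\n")
  }
  invisible(x)
}

#' Keep the best ConvNet run per dataset and replicate
#'
#' For each (dataset, replicate) cell, retains the run with the lowest
#' test RMSE; ties go to the architecture listed first in
#' `architecture_order` (or first appearance).
#'
#' @param runs Data frame with columns `dataset`, `replicate`, `model`
#'   and `rmse_test`.
#' @param architecture_order Optional character vector fixing the
#'   tie-break order of `model` values.
#' @return The selected rows, one per (dataset, replicate).
#' @export
select_best_per_cell <- function(runs, architecture_order = NULL) {
  required <- c("dataset", "replicate", "model", "rmse_test")
  missing <- setdiff(required, names(runs))
  assert_that(length(missing) == 0,
              paste("runs are missing column(s):",
                    paste(missing, collapse = ", ")))
  ord <- architecture_order %||% unique(runs$model)
  runs$.arch_rank <- match(runs$model, ord)
  key <- interaction(runs$dataset, runs$replicate, drop = TRUE)
  picked <- lapply(split(runs, key), function(d) {
    d[order(d$rmse_test, d$.arch_rank), , drop = FALSE][1, , drop = FALSE]
  })
  out <- do.call(rbind, picked)
  out$.arch_rank <- NULL
  row.names(out) <- NULL
  out[order(out$dataset, out$replicate), , drop = FALSE]
}

#' Check replicate balance of a factorial table
#'
#' @param table Data frame of runs.
#' @param factors Factor columns defining the design cells.
#' @return A list with `balanced` (logical), `counts` (data frame of
#'   per-cell replicate counts) and `offending` (cells whose count
#'   differs from the modal count, or all cells when the table is
#'   empty).
#' @export
check_balance <- function(table, factors = c("dataset", "model", "batch",
                                             "augmentation")) {
  factors <- intersect(factors, names(table))
  if (nrow(table) == 0 || length(factors) == 0) {
    return(list(balanced = FALSE,
                counts = data.frame(), offending = data.frame()))
  }
  tb <- as.data.frame(table(table[factors]), stringsAsFactors = FALSE)
  names(tb)[ncol(tb)] <- "n"
  ok <- length(unique(tb$n)) == 1 && all(tb$n > 0)
  list(balanced = ok, counts = tb,
       offending = tb[tb$n != max(tb$n), , drop = FALSE])
}
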