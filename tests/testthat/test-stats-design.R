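# Treatment-coded factorial fits: exact recovery, marginal-mean
# equivalence on balanced designs, interactions, and balance checks.

planted_table <- function(noise_sd = 0, replicates = 2, seed = 1) {
  generate_run_table(
    levels = list(dataset = c("A2780", "CCRF", "DU145", "HCT15"),
                  model = c("alexnet", "densenet", "resnet", "vgg"),
                  batch = c("4", "16", "32"),
                  augmentation = c("0", "1")),
    effects = list(dataset = c(CCRF = 0.12, DU145 = -0.08, HCT15 = 0.25),
                   model = c(densenet = -0.05, resnet = -0.11, vgg = -0.09),
                   batch = c("16" = 0.03, "32" = 0.06),
                   augmentation = c("1" = -0.04)),
    mu0 = 0.85, noise_sd = noise_sd, replicates = replicates, seed = seed)
}

refs <- list(dataset = "A2780", model = "alexnet", batch = "4",
             augmentation = "0")

test_that("noiseless balanced designs are recovered exactly", {
  rt <- planted_table()
  fit <- fit_main_effects(rt$table, ref_levels = refs)
  expect_equal(fit$intercept, 0.85, tolerance = 1e-10)
  for (f in names(rt$truth$effects)) {
    e <- rt$truth$effects[[f]]
    for (lv in names(e)) {
      expect_equal(unname(fit$coefficients[paste0(f, lv)]), unname(e[lv]),
                   tolerance = 1e-8)
    }
  }
  # fitted + residual reproduces the response row-wise
  expect_equal(unname(fit$fitted + fit$residuals), rt$table$response,
               tolerance = 1e-10)
})

test_that("on balanced designs OLS effects equal marginal mean differences", {
  rt <- planted_table(noise_sd = 0.2, replicates = 3, seed = 5)
  fit <- fit_main_effects(rt$table, ref_levels = refs)
  tab <- rt$table
  for (f in c("dataset", "model", "batch", "augmentation")) {
    marg <- tapply(tab$response, tab[[f]], mean)
    for (lv in setdiff(names(marg), refs[[f]])) {
      expect_equal(unname(fit$coefficients[paste0(f, lv)]),
                   unname(marg[lv] - marg[refs[[f]]]), tolerance = 1e-10)
    }
  }
  # intercept-related identities of the OLS fit
  expect_equal(sum(fit$residuals), 0, tolerance = 1e-8)
  expect_lte(fit$adjusted_r2, fit$r2)
})

test_that("row order does not affect the fit", {
  rt <- planted_table(noise_sd = 0.1, seed = 3)
  fit1 <- fit_main_effects(rt$table, ref_levels = refs)
  set.seed(4)
  fit2 <- fit_main_effects(rt$table[sample(nrow(rt$table)), ],
                           ref_levels = refs)
  expect_equal(fit1$coefficients, fit2$coefficients, tolerance = 1e-12)
  expect_equal(fit1$adjusted_r2, fit2$adjusted_r2, tolerance = 1e-12)
})

test_that("type-II and sequential ANOVA agree on balanced designs", {
  rt <- planted_table(noise_sd = 0.15, replicates = 3, seed = 9)
  fit <- fit_main_effects(rt$table, ref_levels = refs)
  seq_tab <- stats::anova(fit$model)
  for (f in c("dataset", "model", "batch", "augmentation")) {
    expect_equal(fit$anova[f, "Pr(>F)"], seq_tab[f, "Pr(>F)"],
                 tolerance = 1e-10)
  }
})

test_that("interaction fits recover planted cell offsets", {
  base <- generate_run_table(
    levels = list(dataset = c("A", "B", "C"),
                  model = c("conv", "rf", "dnn", "ens")),
    effects = list(dataset = c(B = 0.1, C = -0.2),
                   model = c(rf = 0.05, dnn = 0.07, ens = -0.03)),
    mu0 = 0.8, noise_sd = 0, replicates = 2,
    interactions = data.frame(dataset = "B", model = "rf", effect = 0.5,
                              stringsAsFactors = FALSE),
    seed = 2)
  fit <- fit_interaction(base$table,
                         ref_levels = list(dataset = "A", model = "conv"))
  expect_equal(unname(fit$coefficients["datasetB:modelrf"]), 0.5,
               tolerance = 1e-8)

  # additive table: all interaction coefficients are zero
  add <- generate_run_table(
    levels = list(dataset = c("A", "B"), model = c("conv", "rf")),
    effects = list(dataset = c(B = 0.1), model = c(rf = 0.05)),
    mu0 = 0.8, noise_sd = 0, replicates = 2, seed = 3)
  fita <- fit_interaction(add$table,
                          ref_levels = list(dataset = "A", model = "conv"))
  inter <- fita$coefficients[grepl(":", names(fita$coefficients))]
  expect_true(all(abs(inter) < 1e-8))

  # a single model level cannot be fitted
  solo <- add$table[add$table$model == "rf", ]
  expect_error(fit_interaction(solo), "at least 2 levels")
})

test_that("empty design cells raise a rank-deficiency error naming them", {
  rt <- generate_run_table(
    levels = list(dataset = c("A", "B"), model = c("m1", "m2")),
    mu0 = 1, noise_sd = 0.1, replicates = 2, seed = 6)
  broken <- rt$table[!(rt$table$dataset == "B" & rt$table$model == "m2"), ]
  expect_error(fit_interaction(broken, ref_levels = list(dataset = "A",
                                                         model = "m1")),
               "dataset=B.*model=m2|rank deficient")
})

test_that("select_best_per_cell keeps the lowest-RMSE run with stable ties", {
  runs <- expand.grid(dataset = c("D1", "D2"), replicate = 1:3,
                      model = c("alexnet", "vgg"),
                      stringsAsFactors = FALSE)
  set.seed(11)
  runs$rmse_test <- round(runif(nrow(runs), 0.5, 1.0), 3)
  best <- select_best_per_cell(runs)
  expect_equal(nrow(best), 6)  # one per (dataset, replicate)
  for (i in seq_len(nrow(best))) {
    cell <- runs[runs$dataset == best$dataset[i] &
                   runs$replicate == best$replicate[i], ]
    expect_equal(best$rmse_test[i], min(cell$rmse_test))
  }
  # exact tie: the architecture listed first wins
  tie <- data.frame(dataset = "D", replicate = 1,
                    model = c("vgg", "alexnet"), rmse_test = c(0.7, 0.7),
                    stringsAsFactors = FALSE)
  expect_equal(select_best_per_cell(tie)$model, "vgg")
  expect_equal(select_best_per_cell(tie,
                                    architecture_order = c("alexnet",
                                                           "vgg"))$model,
               "alexnet")
})

test_that("check_balance reports unbalanced and empty tables", {
  rt <- planted_table(replicates = 2)
  expect_true(check_balance(rt$table)$balanced)
  rep1 <- check_balance(rt$table[-1, ])
  expect_false(rep1$balanced)
  expect_equal(nrow(rep1$offending), 1)
  empty <- check_balance(rt$table[0, ])
  expect_false(empty$balanced)
})
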