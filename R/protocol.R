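#' Fit the full five-model prognostication pipeline
#'
#' The core model-development protocol, repeated over independent runs:
#'
#' 1. split the cohort 60/20/20 into training (A), testing (B) and
#'    internal-validation (C) partitions, stratified by the five-year
#'    outcome;
#' 2. fine-tune the pretrained parameter vector and train the tree
#'    learners on A; select hyperparameters and the ensemble simplex
#'    weights on B (ICI criterion by default);
#' 3. refit the learners and re-fine-tune on A+B;
#' 4. evaluate the pretrained model, the fine-tuned model, the random
#'    survival forest, the boosted Cox model and the stacked ensemble on
#'    the held-out C (ICI and IPCW AUROC, invalid fractions for the
#'    parametric models);
#' 5. reoptimize the ensemble weights on C;
#' 6. refit everything on the full cohort.
#'
#' Medians and IQRs across runs form the internal-validation report.
#' The final bundle pools runs: fine-tuned parameters and ensemble
#' weights by averaging, hyperparameters by majority vote, with the
#' learners refitted once on the full cohort under the voted values.
#' A failing run is recorded and skipped rather than aborting the
#' experiment.
#'
#' @param cohort the development cohort.
#' @param params0 pretrained initialization ([param_vector()]).
#' @param runs number of independent runs (default 10).
#' @param fractions A/B/C split fractions.
#' @param grids named list with `rsf` and `xgb` hyper grids
#'   ([default_grid()]).
#' @param ft_cfg a [finetune_config()].
#' @param criterion `"ici"` or `"auroc"` for hyperparameter/weight
#'   selection.
#' @param scenario assumption scenario for the parametric models.
#' @param resolution simplex grid step for the ensemble weights.
#' @param rebalance `"none"`, `"oversample"` or `"weights"`; rebalancing
#'   hooks are off by default.
#' @param seed master seed; per-run seeds are derived from it and logged.
#' @param horizon years.
#' @return an object of class `stacksurv` with `print`, `summary`,
#'   `coef` and `predict` methods.
#' @export
stacksurv <- function(cohort, params0 = standin_params(), runs = 10,
                      fractions = c(0.6, 0.2, 0.2),
                      grids = default_grid(), ft_cfg = finetune_config(),
                      criterion = c("ici", "auroc"),
                      scenario = assumption_scenario("default"),
                      resolution = 0.05,
                      rebalance = c("none", "oversample", "weights"),
                      seed = 1, horizon = 5) {
  criterion <- match.arg(criterion)
  rebalance <- match.arg(rebalance)
  if (is.character(scenario)) scenario <- assumption_scenario(scenario)
  stopifnot(inherits(cohort, "cohort"), runs >= 1)
  set.seed(seed)
  run_seeds <- sample.int(.Machine$integer.max %/% 2, runs)

  models <- c("predict", "f_predict", "rsf", "xgb", "ensemble")
  run_rows <- list(); run_detail <- list(); failures <- integer(0)

  for (r in seq_len(runs)) {
    res <- tryCatch(
      .one_run(cohort, params0, fractions, grids, ft_cfg, criterion,
               scenario, resolution, rebalance, run_seeds[r], horizon),
      error = function(e) e)
    if (inherits(res, "error")) {
      warning("run ", r, " failed: ", conditionMessage(res))
      failures <- c(failures, r)
      next
    }
    run_rows[[length(run_rows) + 1]] <- cbind(run = r, res$metrics)
    run_detail[[length(run_detail) + 1]] <- res
  }
  if (!length(run_detail)) stop("every run failed")

  per_run <- do.call(rbind, run_rows)
  report <- do.call(rbind, lapply(models, function(mod) {
    sub <- per_run[per_run$model == mod, ]
    data.frame(
      model = mod,
      ici_median = median(sub$ici), ici_q25 = quantile(sub$ici, .25, names = FALSE),
      ici_q75 = quantile(sub$ici, .75, names = FALSE),
      auroc_median = median(sub$auroc),
      auroc_q25 = quantile(sub$auroc, .25, names = FALSE),
      auroc_q75 = quantile(sub$auroc, .75, names = FALSE),
      invalid_fraction = mean(sub$invalid_fraction),
      stringsAsFactors = FALSE)
  }))

  # final bundle: averaged fine-tuned parameters and weights, voted hypers,
  # learners refitted on the full cohort
  ft_final <- average_param_vectors(lapply(run_detail, `[[`, "params_full"))
  hyper_rsf <- majority_vote(lapply(run_detail, `[[`, "hyper_rsf"))
  hyper_xgb <- majority_vote(lapply(run_detail, `[[`, "hyper_xgb"))
  w_final <- average_weights(lapply(run_detail, `[[`, "weights_C"))
  wts <- .rebalance_weights(cohort, rebalance, horizon)
  rsf_final <- fit_learner("rsf", cohort, hyper_rsf, weights = wts,
                           seed = seed, horizon = horizon)
  xgb_final <- fit_learner("xgb", cohort, hyper_xgb, weights = wts,
                           seed = seed, horizon = horizon)

  structure(list(
    report = report, per_run = per_run, runs = runs, failed_runs = failures,
    final = list(params0 = params0, params_finetuned = ft_final,
                 rsf = rsf_final, xgb = xgb_final, weights = w_final,
                 hyper = list(rsf = hyper_rsf, xgb = hyper_xgb)),
    criterion = criterion, scenario = scenario, horizon = horizon,
    seed = seed, run_seeds = run_seeds, fractions = fractions,
    n = nrow(cohort)),
    class = "stacksurv")
}

.rebalance_weights <- function(cohort, rebalance, horizon) {
  if (rebalance == "weights") case_weights(cohort, "inverse_prevalence", horizon)
  else NULL
}

.one_run <- function(cohort, params0, fractions, grids, ft_cfg, criterion,
                     scenario, resolution, rebalance, run_seed, horizon) {
  co <- cohort
  if (rebalance == "oversample") {
    co <- oversample_events(co, 0.5, seed = run_seed, horizon = horizon)
  }
  parts <- stratified_split(co, fractions, seed = run_seed, horizon = horizon)
  A <- parts[[1]]; B <- parts[[2]]; C <- parts[[3]]
  AB <- as_cohort(rbind(as.data.frame(A), as.data.frame(B)), provenance = "A+B")

  # stage 1-2: fit on A, select on B
  ft_A <- finetune(params0, A, ft_cfg, scenario, horizon)
  hyper_rsf <- select_hyperparameters("rsf", grids$rsf, A, B, criterion,
                                      seed = run_seed, horizon = horizon)
  hyper_xgb <- select_hyperparameters("xgb", grids$xgb, A, B, criterion,
                                      seed = run_seed, horizon = horizon)
  wA <- .rebalance_weights(A, rebalance, horizon)
  rsf_A <- fit_learner("rsf", A, hyper_rsf, weights = wA, seed = run_seed,
                       horizon = horizon)
  xgb_A <- fit_learner("xgb", A, hyper_xgb, weights = wA, seed = run_seed,
                       horizon = horizon)
  preds_B <- cbind(
    f_predict = batch_predict(B, ft_A, scenario)$p_bc_death_5y,
    rsf = predict_5y_surv(rsf_A, B),
    xgb = predict_5y_surv(xgb_A, B))
  w_B <- fit_stack_weights(preds_B, B, criterion, resolution, horizon)

  # stage 3: refit on A+B
  ft_AB <- finetune(params0, AB, ft_cfg, scenario, horizon)
  wAB <- .rebalance_weights(AB, rebalance, horizon)
  rsf_AB <- fit_learner("rsf", AB, hyper_rsf, weights = wAB, seed = run_seed,
                        horizon = horizon)
  xgb_AB <- fit_learner("xgb", AB, hyper_xgb, weights = wAB, seed = run_seed,
                        horizon = horizon)

  # stage 4: internal validation on C
  pred_C <- list(
    predict = batch_predict(C, params0, scenario)$p_bc_death_5y,
    f_predict = batch_predict(C, ft_AB, scenario)$p_bc_death_5y,
    rsf = predict_5y_surv(rsf_AB, C),
    xgb = predict_5y_surv(xgb_AB, C))
  comp_C <- cbind(f_predict = pred_C$f_predict, rsf = pred_C$rsf,
                  xgb = pred_C$xgb)
  pred_C$ensemble <- ensemble_predict(comp_C, w_B)
  metrics <- do.call(rbind, lapply(names(pred_C), function(mod) {
    p <- pred_C[[mod]]
    data.frame(model = mod,
               ici = suppressWarnings(as.numeric(ici(p, C, horizon))),
               auroc = as.numeric(ipcw_auroc(p, C, horizon)),
               invalid_fraction = mean(is.na(p)),
               stringsAsFactors = FALSE)
  }))

  # stage 5: reoptimize weights on C; stage 6: refit on the full cohort
  w_C <- fit_stack_weights(comp_C, C, criterion, resolution, horizon)
  ft_full <- finetune(params0, co, ft_cfg, scenario, horizon)

  list(metrics = metrics, params_AB = ft_AB, params_full = ft_full,
       hyper_rsf = hyper_rsf, hyper_xgb = hyper_xgb,
       weights_B = w_B, weights_C = w_C, seed = run_seed)
}

#' @export
print.stacksurv <- function(x, ...) {
  cat("<stacksurv> five-model 5-year prognostication fit\n")
  cat("  n =", x$n, "; runs =", x$runs,
      if (length(x$failed_runs)) paste0("(", length(x$failed_runs), " failed)"),
      "; criterion =", x$criterion, "\n")
  print(summary(x))
  invisible(x)
}

#' @export
summary.stacksurv <- function(object, ...) {
  r <- object$report
  out <- data.frame(
    model = r$model,
    ICI = sprintf("%.3f (%.3f-%.3f)", r$ici_median, r$ici_q25, r$ici_q75),
    AUROC = sprintf("%.3f (%.3f-%.3f)", r$auroc_median, r$auroc_q25, r$auroc_q75),
    invalid = sprintf("%.1f%%", 100 * r$invalid_fraction))
  out
}

#' @export
coef.stacksurv <- function(object, ...) {
  list(params_finetuned = object$final$params_finetuned,
       weights = object$final$weights,
       hyper = object$final$hyper)
}

#' Predict five-year breast-cancer-death probabilities from a fitted bundle
#'
#' @param object a fitted [stacksurv()] object.
#' @param newdata a cohort.
#' @param model which model's predictions to return; the ensemble (the
#'   default) predicts for every record, falling back to the tree
#'   learners when the parametric component is invalid.
#' @param ... unused.
#' @return data frame `id`, `p_bc_death_5y` plus per-component columns.
#' @export
predict.stacksurv <- function(object, newdata,
                              model = c("ensemble", "predict", "f_predict",
                                        "rsf", "xgb"), ...) {
  model <- match.arg(model)
  comp <- .bundle_predictions(object, newdata)
  p <- switch(model,
    ensemble = ensemble_predict(comp[, c("f_predict", "rsf", "xgb")],
                                object$final$weights),
    predict = comp[, "predict"],
    f_predict = comp[, "f_predict"],
    rsf = comp[, "rsf"],
    xgb = comp[, "xgb"])
  data.frame(id = newdata$id, p_bc_death_5y = p, comp,
             stringsAsFactors = FALSE)
}

.bundle_predictions <- function(object, newdata, scenario = object$scenario) {
  cbind(
    predict = batch_predict(newdata, object$final$params0, scenario)$p_bc_death_5y,
    f_predict = batch_predict(newdata, object$final$params_finetuned,
                              scenario)$p_bc_death_5y,
    rsf = predict_5y_surv(object$final$rsf, newdata),
    xgb = predict_5y_surv(object$final$xgb, newdata))
}

#' External validation of a fitted bundle
#'
#' Evaluates all five models on an external cohort: ICI and IPCW AUROC
#' with bootstrap percentile confidence intervals, the invalid-prediction
#' fraction of the parametric components, and the mean predicted
#' five-year survival against the Kaplan-Meier estimate (to expose
#' systematic survival over- or under-estimation under cohort shift).
#'
#' @param object a fitted [stacksurv()].
#' @param cohort external cohort.
#' @param B bootstrap resamples.
#' @param seed integer seed.
#' @return data frame of class `stacksurv_validation`.
#' @export
external_validation <- function(object, cohort, B = 200, seed = 1) {
  stopifnot(inherits(object, "stacksurv"))
  comp <- .bundle_predictions(object, cohort)
  preds <- cbind(comp,
                 ensemble = ensemble_predict(comp[, c("f_predict", "rsf", "xgb")],
                                             object$final$weights))
  h <- object$horizon
  # cause-specific reference on the predictions' scale: breast-cancer-death-
  # free survival, other-cause deaths treated as censoring
  km_surv <- km_estimator(
    data.frame(time = pmin(cohort$time_years, h),
               event = ifelse(cohort$event == "bc_death" &
                                cohort$time_years <= h, "bc_death", "censored")),
    h)
  out <- lapply(colnames(preds), function(mod) {
    p <- preds[, mod]
    ic <- bootstrap_ci(function(pr, s) ici(pr, s, h), p, cohort, B = B,
                       seed = seed)
    au <- bootstrap_ci(function(pr, s) ipcw_auroc(pr, s, h), p, cohort, B = B,
                       seed = seed)
    data.frame(model = mod,
               ici = as.numeric(ic), ici_lo = attr(ic, "ci")[1],
               ici_hi = attr(ic, "ci")[2],
               auroc = as.numeric(au), auroc_lo = attr(au, "ci")[1],
               auroc_hi = attr(au, "ci")[2],
               invalid_fraction = mean(is.na(p)),
               mean_pred_surv = mean(1 - p, na.rm = TRUE),
               km_surv = km_surv,
               stringsAsFactors = FALSE)
  })
  structure(do.call(rbind, out), class = c("stacksurv_validation", "data.frame"))
}

#' High-risk subgroup stratification
#'
#' The adverse clinicopathological profile associated with degraded model
#' transportability: node-positive disease, tumor size >= 2 cm and grade
#' 3.  Records missing any defining variable are excluded and counted.
#'
#' @param cohort a cohort.
#' @return list with cohorts `high` and `rest` and the count `n_excluded`.
#' @export
stratify_high_risk <- function(cohort) {
  stopifnot(inherits(cohort, "cohort"))
  complete <- !is.na(cohort$nodes) & !is.na(cohort$size_mm) & !is.na(cohort$grade)
  high <- complete & cohort$nodes >= 1 & cohort$size_mm >= 20 & cohort$grade == 3
  rest <- complete & !high
  list(high = as_cohort(as.data.frame(cohort[high, , drop = FALSE]),
                        provenance = "high_risk"),
       rest = as_cohort(as.data.frame(cohort[rest, , drop = FALSE]),
                        provenance = "rest"),
       n_excluded = sum(!complete))
}

#' Sensitivity of predictions to dataset-level input assumptions
#'
#' Re-evaluates the fitted bundle under alternative assumption scenarios
#' and reports per-model metric tables plus the per-record prediction
#' spread (max minus min across scenarios).  The tree learners do not
#' consume the assumed inputs, so their spread is structurally zero; the
#' parametric models respond to the fills.
#'
#' @param object a fitted [stacksurv()].
#' @param cohort evaluation cohort.
#' @param scenarios character vector of scenario names.
#' @return list with elements `metrics` (per scenario x model) and
#'   `spread` (per model: mean and max per-record spread).
#' @export
run_sensitivity <- function(object, cohort,
                            scenarios = c("default", "optimistic", "pessimistic")) {
  stopifnot(inherits(object, "stacksurv"))
  h <- object$horizon
  pred_by_scen <- lapply(scenarios, function(sc) {
    comp <- .bundle_predictions(object, cohort, assumption_scenario(sc))
    cbind(comp, ensemble = ensemble_predict(
      comp[, c("f_predict", "rsf", "xgb")], object$final$weights))
  })
  names(pred_by_scen) <- scenarios
  metrics <- do.call(rbind, lapply(scenarios, function(sc) {
    preds <- pred_by_scen[[sc]]
    do.call(rbind, lapply(colnames(preds), function(mod) {
      p <- preds[, mod]
      data.frame(scenario = sc, model = mod,
                 ici = suppressWarnings(as.numeric(ici(p, cohort, h))),
                 auroc = as.numeric(ipcw_auroc(p, cohort, h)),
                 stringsAsFactors = FALSE)
    }))
  }))
  mods <- colnames(pred_by_scen[[1]])
  spread <- do.call(rbind, lapply(mods, function(mod) {
    pm <- sapply(pred_by_scen, function(x) x[, mod])
    sp <- apply(pm, 1, function(z) if (all(is.na(z))) NA_real_
                else max(z, na.rm = TRUE) - min(z, na.rm = TRUE))
    data.frame(model = mod, mean_spread = mean(sp, na.rm = TRUE),
               max_spread = max(sp, na.rm = TRUE), stringsAsFactors = FALSE)
  }))
  list(metrics = metrics, spread = spread)
}
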