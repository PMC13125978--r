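#' Default hyperparameter grids for the tree-based survival learners
#'
#' Desk-scale grids: random survival forest over number of trees and
#' minimal node size; gradient-boosted Cox model over tree depth,
#' learning rate and boosting rounds.
#'
#' @param kind `"rsf"` or `"xgb"`; `NULL` returns both.
#' @return a named list of candidate-value vectors (or a list of two such
#'   lists).
#' @export
default_grid <- function(kind = NULL) {
  grids <- list(
    rsf = list(num_trees = c(250, 500, 1000), min_node_size = c(5, 15, 50)),
    xgb = list(max_depth = c(2, 3, 4), eta = c(0.01, 0.05, 0.1),
               nrounds = c(100, 300)))
  if (is.null(kind)) grids else grids[[match.arg(kind, names(grids))]]
}

# Feature matrix shared by both learners.  xgboost keeps NAs (native
# default-direction routing).  ranger has no native missing-value
# support, so a documented sentinel adapter is applied: missing cells are
# encoded as -1, strictly below the observed range of every feature, so
# splits can route missing values as their own group.
.learner_features <- c("age", "nodes", "size_mm", "grade", "er_positive",
                       "pr_positive", "laterality", "radiotherapy",
                       "chemotherapy", "trastuzumab")

.learner_matrix <- function(cohort, sentinel = FALSE) {
  X <- cbind(
    age = cohort$age, nodes = cohort$nodes, size_mm = cohort$size_mm,
    grade = cohort$grade,
    er_positive = as.numeric(cohort$er_positive),
    pr_positive = as.numeric(cohort$pr_positive),
    laterality = as.numeric(cohort$laterality),
    radiotherapy = as.numeric(cohort$radiotherapy),
    chemotherapy = as.numeric(cohort$chemotherapy),
    trastuzumab = as.numeric(cohort$trastuzumab))
  if (sentinel) X[is.na(X)] <- -1
  X
}

#' Fit a de-novo tree-based survival learner
#'
#' Fits a random survival forest (`ranger`) or a gradient-boosted Cox
#' model (`xgboost`, objective `survival:cox`) for breast-cancer death;
#' other-cause deaths are treated as censoring at their time
#' (cause-specific modeling).  Both fitted learners produce a five-year
#' breast-cancer-death probability for any record, including records with
#' missing covariates: the boosted model routes missing values along
#' learned default directions, the forest via the sentinel encoding.  For
#' the boosted model the baseline cumulative hazard at the horizon is
#' estimated on the training data by the Breslow estimator.
#'
#' @param kind `"rsf"` or `"xgb"`.
#' @param train training cohort with at least one event.
#' @param hyper named list of hyperparameter values (see
#'   [default_grid()]); absent entries take the first grid value.
#' @param weights optional per-record case weights.
#' @param seed integer seed.
#' @param horizon years (used for the stored baseline hazard).
#' @return an object of class `stacksurv_learner`.
#' @export
fit_learner <- function(kind = c("rsf", "xgb"), train, hyper = list(),
                        weights = NULL, seed = 1, horizon = 5) {
  kind <- match.arg(kind)
  stopifnot(inherits(train, "cohort"))
  status <- as.character(train$event) == "bc_death"
  if (!any(status)) stop("training cohort has no breast-cancer-death events")
  grid <- default_grid(kind)
  for (nm in names(grid)) if (is.null(hyper[[nm]])) hyper[[nm]] <- grid[[nm]][1]
  time <- train$time_years

  if (kind == "rsf") {
    X <- .learner_matrix(train, sentinel = TRUE)
    df <- data.frame(X, time = time, status = as.numeric(status))
    set.seed(seed)
    model <- ranger::ranger(
      survival::Surv(time, status) ~ ., data = df,
      num.trees = hyper$num_trees, min.node.size = hyper$min_node_size,
      case.weights = weights, seed = seed, num.threads = 1)
    obj <- list(kind = "rsf", model = model, hyper = hyper, seed = seed,
                horizon = horizon, n = nrow(train), n_events = sum(status))
  } else {
    X <- .learner_matrix(train, sentinel = FALSE)
    y <- ifelse(status, time, -time)
    dtrain <- xgboost::xgb.DMatrix(X, label = y,
                                   weight = weights %||% rep(1, nrow(X)))
    params <- list(objective = "survival:cox", eta = hyper$eta,
                   max_depth = hyper$max_depth, nthread = 1,
                   seed = seed)
    model <- xgboost::xgb.train(params = params, data = dtrain,
                                nrounds = hyper$nrounds, verbose = 0)
    f <- predict(model, dtrain, outputmargin = TRUE)
    h0 <- .breslow_cumhaz(time, status, f, horizon)
    obj <- list(kind = "xgb", model = model, hyper = hyper, seed = seed,
                horizon = horizon, h0_horizon = h0,
                n = nrow(train), n_events = sum(status))
  }
  structure(obj, class = "stacksurv_learner")
}

# Breslow baseline cumulative hazard at `horizon` given margins f.
.breslow_cumhaz <- function(time, status, f, horizon) {
  ef <- exp(f - max(f))            # rescale for overflow safety
  scale <- exp(max(f))
  dt <- sort(unique(time[status & time <= horizon]))
  h0 <- 0
  for (s in dt) {
    at_risk <- time >= s
    h0 <- h0 + sum(status & time == s) / (sum(ef[at_risk]) * scale)
  }
  h0
}

#' @export
print.stacksurv_learner <- function(x, ...) {
  cat("<stacksurv_learner> ", x$kind, "; n = ", x$n, " (", x$n_events,
      " events); hyper: ",
      paste(names(x$hyper), unlist(x$hyper), sep = "=", collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Five-year breast-cancer-death probability from a fitted learner
#'
#' Evaluates the learner's survival function at the horizon.  Valid for
#' every record, regardless of missing covariates.
#'
#' @param model a fitted [fit_learner()] object.
#' @param cohort records to predict.
#' @return numeric vector of death probabilities by the horizon.
#' @export
predict_5y_surv <- function(model, cohort) {
  stopifnot(inherits(model, "stacksurv_learner"))
  if (model$kind == "rsf") {
    X <- .learner_matrix(cohort, sentinel = TRUE)
    pr <- predict(model$model, data = as.data.frame(X), num.threads = 1)
    idx <- which(pr$unique.death.times <= model$horizon)
    if (!length(idx)) return(rep(0, nrow(cohort)))
    S <- pr$survival
    if (is.null(dim(S))) S <- matrix(S, nrow = nrow(X))
    s5 <- S[, max(idx)]
    pmin(pmax(1 - s5, 0), 1)
  } else {
    X <- .learner_matrix(cohort, sentinel = FALSE)
    f <- predict(model$model, xgboost::xgb.DMatrix(X), outputmargin = TRUE)
    pmin(pmax(1 - exp(-model$h0_horizon * exp(f)), 0), 1)
  }
}

#' @export
predict.stacksurv_learner <- function(object, newdata, ...) {
  predict_5y_surv(object, newdata)
}

#' Exhaustive hyperparameter selection on a held-out partition
#'
#' Fits every grid candidate on `train`, evaluates five-year ICI (or
#' IPCW AUROC) of its predictions on `test`, and returns the candidate
#' minimizing ICI (or maximizing AUROC).  Ties are broken by the first
#' occurrence in grid order; candidates on which evaluation fails are
#' skipped.
#'
#' @param kind `"rsf"` or `"xgb"`.
#' @param grid named list of candidate-value vectors.
#' @param train,test cohorts.
#' @param criterion `"ici"` or `"auroc"`.
#' @param seed integer seed used for every fit.
#' @param horizon years.
#' @return named list: the selected hyperparameter values.
#' @export
select_hyperparameters <- function(kind, grid = default_grid(kind), train, test,
                                   criterion = c("ici", "auroc"), seed = 1,
                                   horizon = 5) {
  criterion <- match.arg(criterion)
  if (!length(grid) || !all(lengths(grid) > 0)) stop("hyperparameter grid is empty")
  cand <- expand.grid(grid, KEEP.OUT.ATTRS = FALSE)
  score <- rep(NA_real_, nrow(cand))
  for (i in seq_len(nrow(cand))) {
    hy <- as.list(cand[i, , drop = FALSE])
    score[i] <- tryCatch({
      m <- fit_learner(kind, train, hy, seed = seed, horizon = horizon)
      p <- predict_5y_surv(m, test)
      if (criterion == "ici") {
        suppressWarnings(as.numeric(ici(p, test, horizon)))
      } else {
        -as.numeric(ipcw_auroc(p, test, horizon))
      }
    }, error = function(e) NA_real_)
  }
  if (all(is.na(score))) stop("no grid candidate could be evaluated")
  as.list(cand[which.min(score), , drop = FALSE])
}

#' Majority vote over per-run hyperparameter choices
#'
#' Per hyperparameter, the modal value across runs; ties are broken
#' toward the smaller (numerically, or first in sort order) value, i.e.
#' the simpler model.
#'
#' @param choices non-empty list of named hyperparameter lists.
#' @return named list of voted values.
#' @export
majority_vote <- function(choices) {
  stopifnot(length(choices) >= 1)
  nms <- names(choices[[1]])
  out <- lapply(nms, function(nm) {
    vals <- sapply(choices, function(ch) ch[[nm]])
    tab <- table(vals)
    winners <- names(tab)[tab == max(tab)]
    w <- sort(winners)[1]
    if (is.numeric(vals)) as.numeric(sort(as.numeric(winners))[1]) else w
  })
  setNames(out, nms)
}
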