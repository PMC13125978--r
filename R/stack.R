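#' Simplex weights for the stacked ensemble
#'
#' @param w nonnegative weights summing to 1.
#' @param components component names, in order.
#' @return an object of class `stack_weights`.
#' @export
stack_weights <- function(w, components = c("f_predict", "rsf", "xgb")) {
  if (length(w) != length(components)) stop("one weight per component")
  if (any(w < 0) || abs(sum(w) - 1) > 1e-9) {
    stop("weights must be nonnegative and sum to 1")
  }
  structure(setNames(as.numeric(w), components), class = "stack_weights")
}

#' @export
print.stack_weights <- function(x, ...) {
  cat("<stack_weights> ",
      paste(names(x), sprintf("%.3f", x), sep = "=", collapse = "  "), "\n")
  invisible(x)
}

# All simplex grid points at the given resolution, rows in lexicographic
# order over the components; resolution must divide 1.
.simplex_grid <- function(k, resolution) {
  steps <- round(1 / resolution)
  if (abs(steps * resolution - 1) > 1e-9) stop("resolution must divide 1")
  rec <- function(k, total) {
    if (k == 1) return(matrix(total, ncol = 1))
    out <- NULL
    for (i in 0:total) {
      sub <- rec(k - 1, total - i)
      out <- rbind(out, cbind(i, sub))
    }
    out
  }
  rec(k, steps) * resolution
}

#' Combine per-component predictions with simplex weights
#'
#' Weighted sum over the components valid (non-`NA`) for each record,
#' with the weights renormalized to sum to 1 over that subset, so the
#' ensemble still predicts when the parametric component is invalid.
#'
#' @param preds numeric matrix (records x components) or vector of one
#'   record's per-component predictions; `NA` marks an invalid component.
#' @param weights a [stack_weights()] aligned with the columns.
#' @return per-record combined probabilities.
#' @export
ensemble_predict <- function(preds, weights) {
  if (is.null(dim(preds))) preds <- matrix(preds, nrow = 1)
  if (ncol(preds) != length(weights)) stop("prediction/weight dimension mismatch")
  wm <- matrix(rep(as.numeric(weights), each = nrow(preds)), nrow = nrow(preds))
  wm[is.na(preds)] <- 0
  denom <- rowSums(wm)
  if (any(denom == 0)) stop("record(s) with no valid component prediction")
  rowSums(preds * wm, na.rm = TRUE) / denom
}

#' Fit ensemble weights by exhaustive simplex-grid search
#'
#' Evaluates the combined prediction at every simplex grid point at the
#' configured resolution and returns the weights minimizing the
#' five-year ICI (or maximizing the IPCW AUROC).  Ties go to the first
#' point in lexicographic grid order, which makes the search exhaustively
#' testable against enumeration.
#'
#' @param component_preds numeric matrix (records x components), `NA` for
#'   invalid entries; column names name the components.
#' @param samples a cohort or data frame aligned with the rows.
#' @param criterion `"ici"` or `"auroc"`.
#' @param resolution simplex grid step (default 0.05).
#' @param horizon years.
#' @return a [stack_weights()] with attribute `objective`.
#' @export
fit_stack_weights <- function(component_preds, samples,
                              criterion = c("ici", "auroc"),
                              resolution = 0.05, horizon = 5) {
  criterion <- match.arg(criterion)
  if (is.null(dim(component_preds)) || ncol(component_preds) < 2) {
    stop("need at least two components")
  }
  if (nrow(component_preds) == 0) stop("empty predictions")
  if (!any(rowSums(!is.na(component_preds)) == ncol(component_preds))) {
    stop("need at least one record where all components are valid")
  }
  comps <- colnames(component_preds) %||%
    paste0("component", seq_len(ncol(component_preds)))
  grid <- .simplex_grid(ncol(component_preds), resolution)
  best <- NULL; best_val <- Inf
  for (i in seq_len(nrow(grid))) {
    w <- stack_weights(grid[i, ], comps)
    val <- tryCatch({
      comb <- ensemble_predict(component_preds, w)
      if (criterion == "ici") {
        suppressWarnings(as.numeric(ici(comb, samples, horizon)))
      } else {
        -as.numeric(ipcw_auroc(comb, samples, horizon))
      }
    }, error = function(e) NA_real_)
    if (is.finite(val) && val < best_val - 1e-15) {
      best_val <- val; best <- w
    }
  }
  if (is.null(best)) stop("no grid point could be evaluated")
  attr(best, "objective") <- if (criterion == "ici") best_val else -best_val
  best
}

#' Average ensemble weights across runs
#'
#' Element-wise mean followed by renormalization onto the simplex.
#'
#' @param weight_list list of [stack_weights()] sharing component order.
#' @return a `stack_weights`.
#' @export
average_weights <- function(weight_list) {
  stopifnot(length(weight_list) >= 1)
  comps <- names(weight_list[[1]])
  for (w in weight_list) {
    if (!identical(names(w), comps)) stop("component order mismatch")
  }
  m <- Reduce(`+`, lapply(weight_list, as.numeric)) / length(weight_list)
  stack_weights(m / sum(m), comps)
}
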