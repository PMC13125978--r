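#' Net benefit of model-guided intervention at one risk threshold
#'
#' Records with predicted five-year mortality risk greater than or equal
#' to `p_t` form the high-risk set.  The cumulative event probability at
#' the horizon within that set is estimated by Kaplan-Meier, from which
#' true positives `TP = n_high * F` and false positives
#' `FP = n_high * (1 - F)` are derived, and
#' `NB = TP/n - (FP/n) * p_t / (1 - p_t)`, where the weighting term
#' `p_t / (1 - p_t)` reflects the relative cost of a false positive
#' against the benefit of a true positive implied by the chosen
#' threshold (the standard decision-curve weighting).  An empty
#' high-risk set yields 0.  Records with invalid (`NA`) predictions are
#' excluded and counted.
#'
#' @param pred predicted event probabilities.
#' @param samples a cohort or data frame aligned with `pred`.
#' @param p_t threshold probability in (0, 1).
#' @param horizon years.
#' @return net benefit (numeric scalar) with attributes `n_high`,
#'   `n_used`, `n_excluded`.
#' @export
net_benefit <- function(pred, samples, p_t, horizon = 5) {
  if (p_t <= 0 || p_t >= 1) stop("threshold must lie strictly in (0, 1)")
  s <- .as_samples(samples)
  keep <- !is.na(pred)
  p <- pred[keep]; time <- s$time[keep]; code <- s$code[keep]
  n <- length(p)
  high <- p >= p_t
  if (!any(high)) {
    return(structure(0, n_high = 0L, n_used = n, n_excluded = sum(!keep),
                     class = c("metric_result", "numeric")))
  }
  t5 <- pmin(time[high], horizon)
  d5 <- code[high] == "bc_death" & time[high] <= horizon
  f_high <- 1 - km_estimator(
    data.frame(time = t5, event = ifelse(d5, "bc_death", "censored")), horizon)
  n_high <- sum(high)
  tp <- n_high * f_high
  fp <- n_high * (1 - f_high)
  nb <- tp / n - (fp / n) * p_t / (1 - p_t)
  structure(nb, n_high = n_high, n_used = n, n_excluded = sum(!keep),
            class = c("metric_result", "numeric"))
}

#' Decision curve over a threshold grid
#'
#' Net benefit of the model, of treating everyone, and of treating no
#' one, across thresholds (default 1% to 10% five-year mortality risk).
#'
#' @inheritParams net_benefit
#' @param thresholds strictly increasing grid inside (0, 1).
#' @return data frame of class `decision_curve` with columns `threshold`,
#'   `nb_model`, `nb_all`, `nb_none`, `n_high`.
#' @export
decision_curve <- function(pred, samples, thresholds = seq(0.01, 0.10, by = 0.005),
                           horizon = 5) {
  if (any(thresholds <= 0) || any(thresholds >= 1) ||
      is.unsorted(thresholds, strictly = TRUE)) {
    stop("thresholds must be strictly increasing inside (0, 1)")
  }
  # treat-all evaluated on the same records as the model (valid predictions)
  all_pred <- ifelse(is.na(pred), NA_real_, 1)
  rows <- lapply(thresholds, function(pt) {
    nbm <- net_benefit(pred, samples, pt, horizon)
    nba <- net_benefit(all_pred, samples, pt, horizon)
    data.frame(threshold = pt, nb_model = as.numeric(nbm),
               nb_all = as.numeric(nba), nb_none = 0,
               n_high = attr(nbm, "n_high"))
  })
  structure(do.call(rbind, rows), class = c("decision_curve", "data.frame"))
}
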