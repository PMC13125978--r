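#' Monte-Carlo Shapley attribution for one prediction
#'
#' Model-agnostic Shapley values estimated by Monte-Carlo sampling of
#' feature coalitions: for each feature, the average over `m` draws of
#' the prediction with that feature taken from the instance (and a random
#' coalition of the other features also from the instance, the rest from
#' a random background record) minus the prediction with the feature
#' taken from the background record as well.  The attributions sum to the
#' instance prediction minus the background mean prediction up to
#' Monte-Carlo error (the efficiency property), shrinking as `1/sqrt(m)`.
#' Missing feature values are a legitimate feature state here — the
#' models tolerate missingness — so coalitions may carry `NA`s.
#'
#' @param predict_fn function taking a data frame of patient records and
#'   returning one probability per row.
#' @param instance one-row data frame (or cohort row) to explain.
#' @param background background cohort (reference population).
#' @param m Monte-Carlo samples per feature.
#' @param seed integer seed.
#' @param features feature columns to attribute over.
#' @return named numeric vector of attributions with attributes
#'   `baseline` (background mean prediction), `prediction` and `se`
#'   (per-feature Monte-Carlo standard errors).
#' @export
mc_shap <- function(predict_fn, instance, background, m = 200, seed = 1,
                    features = .learner_features) {
  stopifnot(m >= 1, nrow(background) >= 1)
  instance <- as.data.frame(instance)[1, , drop = FALSE]
  bg <- as.data.frame(background)
  set.seed(seed)
  k <- length(features)
  baseline <- mean(predict_fn(bg))
  phi <- se <- setNames(numeric(k), features)
  for (j in seq_len(k)) {
    fj <- features[j]
    zi <- sample.int(nrow(bg), m, replace = TRUE)
    with_j <- without_j <- bg[zi, , drop = FALSE]
    for (r in seq_len(m)) {
      # random feature order; the coalition = features preceding j
      perm <- sample(features)
      pos <- which(perm == fj)
      coal <- if (pos > 1) perm[seq_len(pos - 1)] else character(0)
      if (length(coal)) {
        with_j[r, coal] <- instance[, coal]
        without_j[r, coal] <- instance[, coal]
      }
      with_j[r, fj] <- instance[, fj]
    }
    diffs <- predict_fn(with_j) - predict_fn(without_j)
    phi[j] <- mean(diffs)
    se[j] <- sd(diffs) / sqrt(m)
  }
  structure(phi, baseline = baseline,
            prediction = unname(predict_fn(instance)), se = se)
}

#' Cohort-level Shapley summary ranking
#'
#' Runs [mc_shap()] for every record of `cohort` and ranks features by
#' mean absolute attribution; also reports the mean signed attribution
#' and the rank, sufficient to reconstruct a beeswarm-style summary.
#'
#' @inheritParams mc_shap
#' @param cohort records to explain.
#' @return data frame (`feature`, `mean_abs`, `mean_signed`, `rank`)
#'   ordered by decreasing `mean_abs`, with attribute `values` holding
#'   the full record x feature attribution matrix.
#' @export
shap_summary <- function(predict_fn, cohort, background, m = 200, seed = 1,
                         features = .learner_features) {
  stopifnot(nrow(cohort) >= 1)
  vals <- matrix(NA_real_, nrow(cohort), length(features),
                 dimnames = list(cohort$id, features))
  for (i in seq_len(nrow(cohort))) {
    vals[i, ] <- mc_shap(predict_fn, cohort[i, , drop = FALSE], background,
                         m = m, seed = seed + i, features = features)
  }
  out <- data.frame(feature = features,
                    mean_abs = colMeans(abs(vals)),
                    mean_signed = colMeans(vals),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$mean_abs), ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  attr(out, "values") <- vals
  out
}
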