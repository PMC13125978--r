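#' @importFrom survival Surv coxph survfit basehaz coxph.control
NULL

# Normalize an outcome argument: accepts a cohort (time_years/event) or a
# data frame with columns time and event/status.  Returns
# list(time, code) with code in {censored, bc_death, other_death}.
.as_samples <- function(samples) {
  if (inherits(samples, "cohort") ||
      all(c("time_years", "event") %in% names(samples))) {
    time <- samples$time_years
    code <- as.character(samples$event)
  } else if (all(c("time", "event") %in% names(samples))) {
    time <- samples$time
    code <- as.character(samples$event)
  } else stop("samples must carry time and event columns")
  if (any(time <= 0)) stop("follow-up times must be positive")
  if (!all(code %in% .event_levels)) stop("unknown event codes in samples")
  list(time = time, code = code)
}

#' Kaplan-Meier survival estimate at a time point
#'
#' Product-limit estimate of breast-cancer-death-free survival.  With
#' `flip = TRUE` the censoring indicator is flipped so the same machinery
#' estimates the censoring distribution G (deaths of any cause then count
#' as censorings of the censoring time).  `left = TRUE` evaluates the left
#' limit S(t-), needed for inverse-probability-of-censoring case weights.
#'
#' @param samples a cohort or data frame with time and event columns.
#' @param t evaluation time(s) in years, `t >= 0`.
#' @param flip estimate the censoring distribution instead.
#' @param left evaluate the left-continuous version.
#' @return survival probabilities at `t`.
#' @export
km_estimator <- function(samples, t, flip = FALSE, left = FALSE) {
  if (any(t < 0)) stop("evaluation time must be nonnegative")
  s <- .as_samples(samples)
  status <- if (flip) s$code == "censored" else s$code != "censored"
  fit <- survfit(Surv(s$time, status) ~ 1)
  .eval_km(fit, t, left = left)
}

.eval_km <- function(fit, t, left = FALSE) {
  times <- fit$time[fit$n.event > 0]
  surv <- fit$surv[fit$n.event > 0]
  vapply(t, function(tt) {
    idx <- if (left) which(times < tt) else which(times <= tt)
    if (!length(idx)) 1 else surv[max(idx)]
  }, numeric(1))
}

# Restricted cubic spline basis (k knots -> k-1 columns incl. linear term)
.rcs_basis <- function(x, knots) {
  k <- length(knots)
  out <- matrix(x, ncol = 1)
  if (k >= 3) {
    norm2 <- (knots[k] - knots[1])^2
    pos3 <- function(u) pmax(u, 0)^3
    for (j in 1:(k - 2)) {
      col <- (pos3(x - knots[j]) -
                pos3(x - knots[k - 1]) * (knots[k] - knots[j]) /
                  (knots[k] - knots[k - 1]) +
                pos3(x - knots[k]) * (knots[k - 1] - knots[j]) /
                  (knots[k] - knots[k - 1])) / norm2
      out <- cbind(out, col)
    }
  }
  colnames(out) <- paste0("rcs", seq_len(ncol(out)))
  out
}

.cloglog <- function(p) log(-log(1 - pmin(pmax(p, 1e-10), 1 - 1e-10)))

#' Integrated calibration index for five-year predictions
#'
#' The ICI is the mean absolute difference between predicted event
#' probabilities and smoothed observed probabilities.  The smoothed
#' observed probability is obtained from a flexible hazard-based
#' calibration model: a cause-specific proportional-hazards regression of
#' the breast-cancer-death outcome on a restricted-cubic-spline basis
#' (4 knots) of the complementary log-log of the predicted probability;
#' each record's smoothed observed probability is its predicted cumulative
#' incidence at the horizon under that calibration model.  Records with
#' invalid (`NA`) predictions are excluded and counted.  Near-constant
#' predictions degrade the smoother; in that case a Kaplan-Meier
#' single-bin estimate is used with a warning.
#'
#' @param pred predicted probabilities of breast-cancer death by the
#'   horizon (`NA` = invalid prediction).
#' @param samples a cohort or data frame with time and event columns,
#'   aligned with `pred`.
#' @param horizon years.
#' @return the ICI as a numeric scalar with attributes `n_used` and
#'   `n_excluded`.
#' @export
ici <- function(pred, samples, horizon = 5) {
  s <- .as_samples(samples)
  keep <- !is.na(pred)
  n_excl <- sum(!keep)
  p <- pred[keep]; time <- s$time[keep]; code <- s$code[keep]
  n <- length(p)
  if (n < 2) stop("too few valid predictions for calibration")
  if (n < 50) warning("fewer than 50 valid predictions; ICI is unstable")
  # cause-specific outcome at horizon: bc death; other death censors
  t5 <- pmin(time, horizon)
  d5 <- code == "bc_death" & time <= horizon

  x <- .cloglog(p)
  knots <- unique(quantile(x, c(.05, .35, .65, .95), names = FALSE))
  smoothed <- NULL
  if (length(knots) >= 3 && diff(range(x)) > 1e-6) {
    X <- .rcs_basis(x, knots)
    fit <- tryCatch(
      coxph(Surv(t5, d5) ~ X, control = coxph.control(iter.max = 50)),
      error = function(e) NULL, warning = function(w) NULL)
    if (!is.null(fit) && all(is.finite(coef(fit)))) {
      lp <- drop(X %*% coef(fit)) - sum(coef(fit) * colMeans(X))
      bh <- basehaz(fit, centered = TRUE)
      idx <- which(bh$time <= horizon)
      H0 <- if (length(idx)) bh$hazard[max(idx)] else 0
      smoothed <- 1 - exp(-H0 * exp(lp))
    }
  }
  if (is.null(smoothed)) {
    warning("degenerate calibration smoother; using single-bin Kaplan-Meier")
    f_km <- 1 - km_estimator(data.frame(time = t5,
                                        event = ifelse(d5, "bc_death", "censored")),
                             horizon)
    smoothed <- rep(f_km, n)
  }
  structure(mean(abs(p - smoothed)), n_used = n, n_excluded = n_excl,
            class = c("metric_result", "numeric"))
}

#' @export
print.metric_result <- function(x, ...) {
  cat(sprintf("%.5f", unclass(x)))
  ci <- attr(x, "ci")
  if (!is.null(ci)) cat(sprintf("  (95%% CI %.5f-%.5f)", ci[1], ci[2]))
  cat("  [n_used =", attr(x, "n_used"))
  if (!is.null(attr(x, "n_excluded"))) cat(", n_excluded =", attr(x, "n_excluded"))
  cat("]\n")
  invisible(x)
}

#' IPCW time-dependent AUROC at a horizon
#'
#' Cumulative-case / dynamic-control area under the ROC curve with
#' inverse-probability-of-censoring weighting: cases are records with a
#' breast-cancer death by the horizon, weighted `1/G(T_i-)`; controls are
#' records event-free at the horizon, weighted `1/G(horizon)`, where `G`
#' is the Kaplan-Meier estimate of the censoring distribution (evaluated
#' left-continuously for cases).  Records dying of other causes before
#' the horizon are neither cases nor controls.  Prediction ties receive
#' half credit.  Reduces exactly to the Mann-Whitney AUROC when censoring
#' is absent.
#'
#' @inheritParams ici
#' @return AUROC as a numeric scalar with attributes `n_used`,
#'   `n_excluded`.
#' @export
ipcw_auroc <- function(pred, samples, horizon = 5) {
  s <- .as_samples(samples)
  keep <- !is.na(pred)
  n_excl <- sum(!keep)
  p <- pred[keep]; time <- s$time[keep]; code <- s$code[keep]
  case <- code == "bc_death" & time <= horizon
  ctrl <- time > horizon
  if (!any(case) || !any(ctrl)) {
    stop("IPCW AUROC undefined: need at least one case and one control at horizon")
  }
  cens_fit <- survfit(Surv(time, code == "censored") ~ 1)
  G_case <- .eval_km(cens_fit, time[case], left = TRUE)
  G_h <- .eval_km(cens_fit, horizon, left = FALSE)
  w_case <- 1 / pmax(G_case, 1e-10)
  w_ctrl <- rep(1 / pmax(G_h, 1e-10), sum(ctrl))

  pc <- p[case]; pt <- p[ctrl]
  ord <- order(pt)
  pt_s <- pt[ord]; wt_s <- w_ctrl[ord]
  cw <- cumsum(wt_s)
  # for each case: total control weight strictly below + half of ties
  n_strict <- findInterval(pc, pt_s, left.open = TRUE)  # controls with pred <  case pred
  n_upto <- findInterval(pc, pt_s)                      # controls with pred <= case pred
  w_below <- ifelse(n_strict > 0, cw[pmax(n_strict, 1)], 0)
  w_upto <- ifelse(n_upto > 0, cw[pmax(n_upto, 1)], 0)
  w_tie <- w_upto - w_below
  num <- sum(w_case * (w_below + 0.5 * w_tie))
  den <- sum(w_case) * sum(wt_s)
  structure(num / den, n_used = sum(case) + sum(ctrl), n_excluded = n_excl,
            class = c("metric_result", "numeric"))
}

#' Quartile calibration table
#'
#' Trims records with predicted probabilities outside the configured
#' percentile band (default 10th-90th), forms quartiles of predicted
#' probability, and reports per quartile the mean and SD of the predicted
#' probabilities and the Kaplan-Meier observed event probability at the
#' horizon with its Greenwood standard error.  Predictions pooled across
#' several runs can be concatenated before binning.
#'
#' @inheritParams ici
#' @param trim lower/upper percentile bounds of the kept band.
#' @return data frame with one row per quartile.
#' @export
calibration_quartiles <- function(pred, samples, horizon = 5,
                                  trim = c(0.10, 0.90)) {
  s <- .as_samples(samples)
  keep <- !is.na(pred)
  p <- pred[keep]; time <- s$time[keep]; code <- s$code[keep]
  if (length(p) < 4) stop("need at least 4 valid predictions")
  qb <- quantile(p, trim, names = FALSE)
  inb <- p >= qb[1] & p <= qb[2]
  p <- p[inb]; time <- time[inb]; code <- code[inb]
  br <- unique(quantile(p, c(0, .25, .5, .75, 1), names = FALSE))
  bin <- cut(p, br, include.lowest = TRUE, labels = FALSE)
  out <- lapply(sort(unique(bin)), function(b) {
    sel <- bin == b
    t5 <- pmin(time[sel], horizon)
    d5 <- code[sel] == "bc_death" & time[sel] <= horizon
    fit <- survfit(Surv(t5, d5) ~ 1)
    obs <- 1 - .eval_km(fit, horizon)
    idx <- which(fit$time <= horizon & fit$n.event > 0)
    se <- if (length(idx)) fit$std.err[max(idx)] * fit$surv[max(idx)] else 0
    data.frame(quartile = b, n = sum(sel),
               mean_pred = mean(p[sel]), sd_pred = sd(p[sel]),
               obs_event = obs, se_obs = se)
  })
  do.call(rbind, out)
}

#' Bootstrap percentile confidence interval for a metric
#'
#' Resamples records with replacement, recomputes the metric on each
#' resample, and reports the empirical 2.5th and 97.5th percentiles.  The
#' point estimate is computed on the original sample.  Resamples on which
#' the metric fails are skipped and counted, with a warning when more
#' than 1% are skipped.
#'
#' @param metric_fn function `(pred, samples) -> numeric`.
#' @param pred predicted probabilities.
#' @param samples a cohort or data frame aligned with `pred`.
#' @param B number of bootstrap resamples (>= 2).
#' @param seed integer seed.
#' @param level confidence level.
#' @return the point estimate with attributes `ci`, `n_used`, `n_skipped`.
#' @export
bootstrap_ci <- function(metric_fn, pred, samples, B = 2000, seed = 1,
                         level = 0.95) {
  if (B < 2) stop("B must be >= 2")
  s <- .as_samples(samples)
  df <- data.frame(time = s$time, event = s$code, stringsAsFactors = FALSE)
  point <- metric_fn(pred, df)
  n <- length(pred)
  set.seed(seed)
  vals <- rep(NA_real_, B)
  for (b in seq_len(B)) {
    idx <- sample.int(n, n, replace = TRUE)
    vals[b] <- tryCatch(
      suppressWarnings(as.numeric(metric_fn(pred[idx], df[idx, , drop = FALSE]))),
      error = function(e) NA_real_)
  }
  n_skip <- sum(is.na(vals))
  if (n_skip > 0.01 * B) {
    warning(n_skip, " of ", B, " bootstrap resamples failed and were skipped")
  }
  alpha <- (1 - level) / 2
  ci <- quantile(vals, c(alpha, 1 - alpha), na.rm = TRUE, names = FALSE)
  structure(as.numeric(point), ci = ci, n_used = n, n_skipped = n_skip,
            n_excluded = attr(point, "n_excluded"),
            class = c("metric_result", "numeric"))
}
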