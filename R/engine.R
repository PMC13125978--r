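#' Assumption scenarios for dataset-level absent inputs
#'
#' Some inputs of the pretrained prognostic tool (HER2, Ki-67, mode of
#' detection, smoking, year of diagnosis, micrometastases, chemotherapy
#' generation, bisphosphonates, heart-dose category, endocrine therapy)
#' are typically absent at the dataset level in adjuvant endocrine-therapy
#' trial data, and are filled by standard-of-care assumptions.  Three
#' scenarios are shipped: `default` (standard of care: HER2 inferred from
#' trastuzumab use, endocrine therapy implied by trial eligibility,
#' symptomatic detection, second-generation chemotherapy), `optimistic`
#' (every ambiguous fill set to its risk-lowering value) and `pessimistic`
#' (risk-raising values).  Scenarios differ only in fill values; they
#' never touch record-level-missing mandatory inputs.
#'
#' @param name `"default"`, `"optimistic"` or `"pessimistic"`.
#' @return an object of class `assumption_scenario`: a named list of fill
#'   constants plus the HER2 inference rule.
#' @export
assumption_scenario <- function(name = c("default", "optimistic", "pessimistic")) {
  name <- match.arg(name)
  fills <- switch(name,
    default = list(her2_base = FALSE, ki67 = FALSE,
                   mode_of_detection = "symptomatic", smoking = FALSE,
                   year_of_diagnosis = 2003, micrometastases = FALSE,
                   chemo_generation = 2, bisphosphonates = FALSE,
                   heart_dose_category = 1, hormone_therapy = TRUE),
    optimistic = list(her2_base = FALSE, ki67 = FALSE,
                      mode_of_detection = "screen", smoking = FALSE,
                      year_of_diagnosis = 2003, micrometastases = FALSE,
                      chemo_generation = 3, bisphosphonates = TRUE,
                      heart_dose_category = 0, hormone_therapy = TRUE),
    pessimistic = list(her2_base = TRUE, ki67 = TRUE,
                       mode_of_detection = "symptomatic", smoking = TRUE,
                       year_of_diagnosis = 2003, micrometastases = TRUE,
                       chemo_generation = 1, bisphosphonates = FALSE,
                       heart_dose_category = 3, hormone_therapy = TRUE))
  structure(list(name = name, fills = fills), class = "assumption_scenario")
}

#' Fill dataset-level absent inputs under an assumption scenario
#'
#' Adds (or completes) the extended input columns of a cohort using the
#' scenario's fill values.  HER2 is inferred positive whenever trastuzumab
#' was given, regardless of scenario; otherwise the scenario's base value
#' applies.  Cells already observed are never overwritten, and mandatory
#' record-level inputs (age, size, nodes, grade, ER) are never filled.
#'
#' @param cohort a cohort (or any data frame of patient records).
#' @param scenario an [assumption_scenario()] or a scenario name.
#' @return the cohort with complete extended columns.
#' @export
apply_assumptions <- function(cohort, scenario = assumption_scenario("default")) {
  if (is.character(scenario)) scenario <- assumption_scenario(scenario)
  df <- cohort
  f <- scenario$fills
  fill_col <- function(df, col, value) {
    if (!col %in% names(df)) df[[col]] <- value
    else df[[col]][is.na(df[[col]])] <- value
    df
  }
  # HER2: trastuzumab use implies positivity; scenario base elsewhere
  her2_fill <- ifelse(!is.na(df$trastuzumab) & df$trastuzumab,
                      TRUE, f$her2_base)
  if (!"her2" %in% names(df)) df$her2 <- her2_fill
  else df$her2[is.na(df$her2)] <- her2_fill[is.na(df$her2)]
  for (col in c("ki67", "mode_of_detection", "smoking", "year_of_diagnosis",
                "micrometastases", "chemo_generation", "bisphosphonates",
                "heart_dose_category", "hormone_therapy")) {
    df <- fill_col(df, col, f[[col]])
  }
  df
}

#' Fractional-polynomial baseline cumulative hazard
#'
#' `H0(t) = exp(c0 + sum_k c_k b_k(t))` where each basis term `b_k(t)` is
#' `t^p` for an exponent `p` in {-2, -1, -0.5, 0.5, 1, 2, 3} or `ln t`
#' (encoded as exponent 0).  `H0(0)` is defined as 0.
#'
#' @param t time in years, `t >= 0` (vectorized).
#' @param coeffs numeric vector: intercept followed by one coefficient per
#'   basis exponent.
#' @param basis vector of fractional-polynomial exponents.
#' @return cumulative hazard values.
#' @export
baseline_cumhaz <- function(t, coeffs, basis = c(0, 0.5)) {
  if (any(t < 0)) stop("baseline cumulative hazard requires t >= 0")
  if (length(coeffs) != length(basis) + 1) {
    stop("need one intercept plus one coefficient per basis exponent")
  }
  out <- numeric(length(t))
  pos <- t > 0
  if (any(pos)) {
    tp <- t[pos]
    lp <- rep(coeffs[1], length(tp))
    for (k in seq_along(basis)) {
      bk <- if (basis[k] == 0) log(tp) else tp^basis[k]
      lp <- lp + coeffs[k + 1] * bk
    }
    out[pos] <- exp(lp)
  }
  out
}

# Build the engine design: covariate matrices keyed to parameter names,
# validity flags and per-record missing-mandatory reasons.  The design
# depends only on the covariates and the mandatory-input list, not on the
# coefficient values, so it can be reused across objective evaluations
# during fine-tuning.
engine_design <- function(cohort, params = standin_params(),
                          scenario = assumption_scenario("default")) {
  df <- apply_assumptions(cohort, scenario)
  n <- nrow(df)
  mandatory <- attr(params, "mandatory")
  miss <- sapply(mandatory, function(v) is.na(df[[v]]))
  if (n == 1) miss <- matrix(miss, nrow = 1, dimnames = list(NULL, mandatory))
  valid <- rowSums(miss) == 0
  reasons <- apply(miss, 1, function(m) mandatory[m], simplify = FALSE)

  # reference patient: age 65, size 15 mm, node-negative, grade 1, ER+/PR+,
  # untreated, HER2-/Ki67-, symptomatic detection, non-smoker
  age <- df$age
  or0 <- function(x) ifelse(is.na(x), 0, x)       # non-mandatory -> reference
  tl <- function(x) or0(as.numeric(x))            # logical -> 0/1
  Xbc <- cbind(
    bc_size = log(df$size_mm / 15),
    bc_nodes = log(df$nodes + 1),
    bc_age1 = (age / 65)^-2 - 1,
    bc_age2 = log(age / 65),
    bc_grade2 = as.numeric(df$grade == 2),
    bc_grade3 = as.numeric(df$grade == 3),
    bc_er_neg = as.numeric(!df$er_positive),
    bc_pr_neg = tl(!df$pr_positive),
    bc_her2_pos = tl(df$her2),
    bc_ki67_pos = tl(df$ki67),
    bc_chemo = tl(df$chemotherapy),
    bc_hormone = tl(df$hormone_therapy),
    bc_trastuzumab = tl(df$trastuzumab),
    bc_bisphosphonates = tl(df$bisphosphonates),
    bc_radio = tl(df$radiotherapy),
    bc_screen = as.numeric(or0(df$mode_of_detection == "screen"))
  )
  Xoth <- cbind(
    oth_age1 = (age / 65)^-2 - 1,
    oth_age2 = log(age / 65),
    oth_smoking = tl(df$smoking),
    oth_heart_dose = tl(df$radiotherapy) * or0(as.numeric(df$heart_dose_category))
  )
  list(X_bc = Xbc, X_oth = Xoth, valid = valid, reasons = reasons, n = n)
}

#' Cause-specific prognostic indices
#'
#' Linear predictors of the competing-risks engine: the breast-cancer
#' index combines log tumor size, log(nodes + 1), two fractional-polynomial
#' age terms, grade and receptor indicators, HER2/Ki-67 and the treatment
#' effects; the other-cause index is driven by age, smoking and cardiac
#' radiation exposure.  Covariates are centered at the reference patient
#' (age 65, 15 mm, node-negative, grade 1, ER+/PR+, untreated), at which
#' both indices are 0.
#'
#' @param input a cohort (or one-row record) with extended inputs filled,
#'   e.g. by [apply_assumptions()].
#' @param params a [param_vector()].
#' @return a two-column matrix `(pi_bc, pi_oth)`; rows with missing
#'   mandatory inputs are `NA` and flagged in `attr(, "valid")`.
#' @export
prognostic_index <- function(input, params = standin_params()) {
  d <- engine_design(input, params, scenario = assumption_scenario("default"))
  .pi_from_design(d, params)
}

.pi_from_design <- function(d, params) {
  v <- as.numeric(params); names(v) <- names(params)
  pi_bc <- drop(d$X_bc %*% v[colnames(d$X_bc)])
  pi_oth <- drop(d$X_oth %*% v[colnames(d$X_oth)])
  pi_bc[!d$valid] <- NA_real_
  pi_oth[!d$valid] <- NA_real_
  out <- cbind(pi_bc = pi_bc, pi_oth = pi_oth)
  attr(out, "valid") <- d$valid
  out
}

# Annual-grid competing-risks computation shared by all prediction paths.
# Returns a list of n x horizon matrices.  Per year j the cause-specific
# cumulative-hazard increment is H0_c(j) exp(pi_c) - H0_c(j-1) exp(pi_c);
# all-cause survival is exp(-sum_c H_c); the annual death mass
# S(j-1) (1 - exp(-dH)) is apportioned to causes proportionally to their
# hazard increments, which makes F_bc + F_oth + S_all telescope to 1.
.curves_from_design <- function(d, params, horizon = 5) {
  v <- as.numeric(params); names(v) <- names(params)
  basis <- attr(params, "basis")
  yrs <- 0:horizon
  H0b <- baseline_cumhaz(yrs, v[c("bc_base_const", "bc_base_logt", "bc_base_sqrt")],
                         basis$bc)
  H0o <- baseline_cumhaz(yrs, v[c("oth_base_const", "oth_base_logt", "oth_base_sqrt")],
                         basis$oth)
  pis <- .pi_from_design(d, params)
  eb <- exp(pis[, "pi_bc"]); eo <- exp(pis[, "pi_oth"])
  n <- d$n
  Hb <- outer(eb, H0b[-1]); Ho <- outer(eo, H0o[-1])
  dHb <- outer(eb, diff(H0b)); dHo <- outer(eo, diff(H0o))
  S <- exp(-(Hb + Ho))
  Sprev <- cbind(1, S[, -horizon, drop = FALSE])
  dH <- dHb + dHo
  mass <- Sprev * (1 - exp(-dH))
  frac_b <- ifelse(dH > 0, dHb / dH, 0)
  Fb <- mass * frac_b
  Fo <- mass * (1 - frac_b)
  if (horizon > 1) {
    for (j in 2:horizon) {
      Fb[, j] <- Fb[, j - 1] + Fb[, j]
      Fo[, j] <- Fo[, j - 1] + Fo[, j]
    }
  }
  list(H_bc = Hb, H_oth = Ho, S_all = S, F_bc = Fb, F_oth = Fo,
       valid = d$valid, reasons = d$reasons)
}

#' Annual competing-risks survival curve for one record
#'
#' @param record a one-row cohort (or data frame with the cohort fields).
#' @param params a [param_vector()].
#' @param scenario an [assumption_scenario()] or name.
#' @param horizon years.
#' @return data frame with `year`, cumulative hazards `H_bc`/`H_oth`,
#'   all-cause survival `S_all` and cumulative incidences `F_bc`/`F_oth`;
#'   `F_bc + F_oth + S_all = 1` on every row.
#' @export
survival_curve <- function(record, params = standin_params(),
                           scenario = assumption_scenario("default"),
                           horizon = 5) {
  d <- engine_design(record, params, scenario)
  if (!all(d$valid)) stop("survival_curve needs complete mandatory inputs")
  cv <- .curves_from_design(d, params, horizon)
  data.frame(year = seq_len(horizon),
             H_bc = cv$H_bc[1, ], H_oth = cv$H_oth[1, ],
             S_all = cv$S_all[1, ], F_bc = cv$F_bc[1, ], F_oth = cv$F_oth[1, ])
}

#' Five-year breast-cancer-death prediction for one record
#'
#' Returns an explicit invalid result (with the list of missing mandatory
#' inputs) rather than an error or a silent guess when the record lacks
#' mandatory inputs after dataset-level assumptions are applied.
#'
#' @inheritParams survival_curve
#' @return a list of class `prediction_result`: `status`
#'   (`"valid"`/`"invalid"`), `p_bc_death_5y`, `p_surv_5y`,
#'   `invalid_reason`.
#' @export
predict_5y <- function(record, params = standin_params(),
                       scenario = assumption_scenario("default")) {
  d <- engine_design(record, params, scenario)
  if (!d$valid[1]) {
    return(structure(list(status = "invalid", p_bc_death_5y = NA_real_,
                          p_surv_5y = NA_real_,
                          invalid_reason = d$reasons[[1]]),
                     class = "prediction_result"))
  }
  cv <- .curves_from_design(d, params, horizon = 5)
  p <- unname(cv$F_bc[1, 5])
  structure(list(status = "valid", p_bc_death_5y = p, p_surv_5y = 1 - p,
                 invalid_reason = character(0)),
            class = "prediction_result")
}

#' @export
print.prediction_result <- function(x, ...) {
  if (x$status == "valid") {
    cat(sprintf("<prediction> 5y bc-death probability %.4f (survival %.4f)\n",
                x$p_bc_death_5y, x$p_surv_5y))
  } else {
    cat("<prediction> INVALID; missing mandatory input(s): ",
        paste(x$invalid_reason, collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Batch five-year predictions over a cohort
#'
#' @param cohort a cohort.
#' @inheritParams survival_curve
#' @return data frame (`id`, `status`, `p_bc_death_5y`, `reasons`) with
#'   attribute `invalid_fraction`.
#' @export
batch_predict <- function(cohort, params = standin_params(),
                          scenario = assumption_scenario("default")) {
  d <- engine_design(cohort, params, scenario)
  p <- rep(NA_real_, d$n)
  if (any(d$valid)) {
    cv <- .curves_from_design(d, params, horizon = 5)
    p[d$valid] <- unname(cv$F_bc[d$valid, 5])
  }
  out <- data.frame(
    id = cohort$id,
    status = ifelse(d$valid, "valid", "invalid"),
    p_bc_death_5y = p,
    reasons = vapply(d$reasons, paste, "", collapse = ";"),
    stringsAsFactors = FALSE)
  attr(out, "invalid_fraction") <- mean(!d$valid)
  out
}
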