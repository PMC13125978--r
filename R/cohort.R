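#' @importFrom stats median quantile rbinom rnorm runif rlnorm sd setNames
#'   coef optim plogis qlogis predict aggregate complete.cases
#' @importFrom utils read.csv write.csv head modifyList
NULL

# Canonical column set of a cohort data frame. `extended` PREDICT inputs
# (her2, ki67, ...) travel as additional columns when present.
.cohort_core_cols <- c(
  "id", "age", "nodes", "laterality", "er_positive", "pr_positive",
  "size_mm", "grade", "radiotherapy", "chemotherapy", "trastuzumab",
  "time_years", "event"
)

.event_levels <- c("censored", "bc_death", "other_death")
.laterality_levels <- c("left", "right", "bilateral")

.extended_cols <- c(
  "her2", "ki67", "mode_of_detection", "smoking", "year_of_diagnosis",
  "micrometastases", "chemo_generation", "bisphosphonates",
  "heart_dose_category", "hormone_therapy"
)

#' Construct a patient cohort
#'
#' A cohort is a data frame with one row per patient carrying the
#' clinicopathological covariates used for five-year survival
#' prognostication (age, positive nodes, laterality, ER/PR status, tumor
#' size in mm, grade, radiotherapy, chemotherapy, trastuzumab), follow-up
#' time in years and an event code (`censored`, `bc_death`,
#' `other_death`).  Missing covariate cells are explicit `NA`s; follow-up
#' must be strictly positive (patients not followed beyond enrollment are
#' excluded at construction).
#'
#' @param df data frame with at least `id`, `time_years` and `event`
#'   columns; covariate columns are coerced to their declared types and
#'   filled with `NA` when absent.
#' @param provenance character label recording where the rows came from.
#' @param bounds plausibility bounds, a list with elements `age`, `nodes`,
#'   `size_mm`, each `c(lo, hi)`.
#' @return an object of class `cohort` (a data frame).
#' @export
as_cohort <- function(df, provenance = "unspecified",
                      bounds = list(age = c(18, 105), nodes = c(0, 60),
                                    size_mm = c(0.1, 300))) {
  stopifnot(is.data.frame(df))
  req <- c("id", "time_years", "event")
  miss <- setdiff(req, names(df))
  if (length(miss)) {
    stop("cohort is missing mandatory columns: ", paste(miss, collapse = ", "))
  }
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  df$id <- as.character(df$id)
  if (anyDuplicated(df$id)) stop("cohort ids must be unique")

  ev <- as.character(df$event)
  bad <- !is.na(ev) & !(ev %in% .event_levels)
  if (any(bad)) {
    stop("unknown event code(s): ", paste(unique(ev[bad]), collapse = ", "),
         " (expected ", paste(.event_levels, collapse = "/"), ")")
  }
  if (anyNA(ev)) stop("event indicator may not be missing")
  df$event <- factor(ev, levels = .event_levels)

  df$time_years <- as.numeric(df$time_years)
  if (anyNA(df$time_years)) stop("follow-up time may not be missing")
  n_drop <- sum(df$time_years <= 0)
  if (n_drop > 0) {
    message("as_cohort: excluded ", n_drop,
            " record(s) with follow-up time <= 0")
    df <- df[df$time_years > 0, , drop = FALSE]
  }

  num_cols <- c("age", "nodes", "size_mm", "grade")
  lgl_cols <- c("er_positive", "pr_positive", "radiotherapy",
                "chemotherapy", "trastuzumab")
  for (cl in num_cols) df[[cl]] <- if (cl %in% names(df)) as.numeric(df[[cl]]) else NA_real_
  for (cl in lgl_cols) df[[cl]] <- if (cl %in% names(df)) as.logical(df[[cl]]) else NA
  lat <- if ("laterality" %in% names(df)) as.character(df$laterality) else NA_character_
  badlat <- !is.na(lat) & !(lat %in% .laterality_levels)
  if (any(badlat)) stop("unknown laterality value(s): ",
                        paste(unique(lat[badlat]), collapse = ", "))
  df$laterality <- factor(lat, levels = .laterality_levels)

  .check_bounds(df$age, bounds$age, "age")
  .check_bounds(df$nodes, bounds$nodes, "nodes")
  .check_bounds(df$size_mm, bounds$size_mm, "size_mm")
  if (any(!is.na(df$grade) & !(df$grade %in% 1:3))) {
    stop("grade must be 1, 2 or 3")
  }
  if (any(!is.na(df$nodes) & df$nodes != round(df$nodes))) {
    stop("nodes must be an integer count")
  }

  keep <- c(.cohort_core_cols, intersect(.extended_cols, names(df)))
  df <- df[, keep, drop = FALSE]
  rownames(df) <- NULL
  structure(df,
            provenance = provenance,
            schema_version = "1.0",
            n_excluded_nonpositive_time = n_drop,
            class = c("cohort", "data.frame"))
}

.check_bounds <- function(x, b, what) {
  if (is.null(b)) return(invisible())
  out <- !is.na(x) & (x < b[1] | x > b[2])
  if (any(out)) {
    stop(sum(out), " record(s) have ", what, " outside plausibility bounds [",
         b[1], ", ", b[2], "]")
  }
}

#' Read a cohort from CSV
#'
#' Reads a one-row-per-patient CSV with a header.  Empty cells and the
#' string `"NA"` are treated as missing.  A column-mapping schema can
#' rename arbitrary source columns onto the canonical fields and declare
#' the tumor-size unit (`"mm"`, the internal unit, or `"cm"`, converted on
#' load).  Rows with non-positive follow-up are dropped and counted, and a
#' message is emitted for every exclusion batch.
#'
#' @param path CSV file path.
#' @param schema optional list with elements `columns` (named character
#'   vector mapping canonical name -> source column name), `size_unit`
#'   (`"mm"` or `"cm"`) and `event_codes` (named character vector mapping
#'   source codes onto `censored`/`bc_death`/`other_death`).
#' @param provenance label stored on the cohort.
#' @return a [as_cohort()] cohort.
#' @export
read_cohort <- function(path, schema = NULL, provenance = basename(path)) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- tryCatch(
    read.csv(path, stringsAsFactors = FALSE, na.strings = c("", "NA")),
    error = function(e) stop("malformed CSV '", path, "': ", conditionMessage(e))
  )
  if (!is.null(schema$columns)) {
    for (canon in names(schema$columns)) {
      src <- schema$columns[[canon]]
      if (!src %in% names(df)) stop("schema maps '", canon,
                                    "' to absent column '", src, "'")
      names(df)[names(df) == src] <- canon
    }
  }
  if (identical(schema$size_unit, "cm") && "size_mm" %in% names(df)) {
    df$size_mm <- as.numeric(df$size_mm) * 10
  }
  if (!is.null(schema$event_codes) && "event" %in% names(df)) {
    ev <- as.character(df$event)
    known <- ev %in% names(schema$event_codes)
    if (any(!known & !is.na(ev))) {
      stop("unknown event code(s) under schema: ",
           paste(unique(ev[!known & !is.na(ev)]), collapse = ", "))
    }
    df$event <- unname(schema$event_codes[ev])
  }
  as_cohort(df, provenance = provenance)
}

#' Write a cohort to CSV
#'
#' @param cohort a cohort.
#' @param path output path; missing values are written as empty cells.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(inherits(cohort, "cohort"))
  df <- as.data.frame(cohort)
  write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Binary event indicator at a horizon
#'
#' Breast-cancer death observed at or before `horizon` counts as an
#' event; everything else (censoring, other-cause death, later events)
#' counts as a non-event.  This is the indicator used for outcome
#' stratification and for the discrimination metrics.
#'
#' @param cohort a cohort.
#' @param horizon years.
#' @return logical vector.
#' @export
event_at_horizon <- function(cohort, horizon = 5) {
  cohort$event == "bc_death" & cohort$time_years <= horizon
}

#' Outcome-stratified random split
#'
#' Splits a cohort into `length(fractions)` partitions stratified by the
#' binary event indicator at the horizon.  Within each stratum the first
#' k-1 partitions receive `floor(fraction * stratum size)` records and the
#' last partition the remainder, so partition sizes can deviate slightly
#' from the exact proportions (on 7563 records with 187 events an 80/20
#' split yields 6049 and 1514).  Reproducible under `seed`.
#'
#' @param cohort a cohort.
#' @param fractions numeric vector in (0,1] summing to 1.
#' @param seed integer seed.
#' @param horizon stratification horizon in years.
#' @return list of cohorts.
#' @export
stratified_split <- function(cohort, fractions, seed = 1, horizon = 5) {
  stopifnot(inherits(cohort, "cohort"))
  if (any(fractions <= 0) || any(fractions > 1) ||
      abs(sum(fractions) - 1) > 1e-12) {
    stop("fractions must lie in (0,1] and sum to 1")
  }
  k <- length(fractions)
  ev <- event_at_horizon(cohort, horizon)
  idx_parts <- vector("list", k)
  set.seed(seed)
  for (stratum in list(which(ev), which(!ev))) {
    m <- length(stratum)
    if (m == 0) next
    perm <- stratum[sample.int(m)]
    sizes <- floor(fractions[-k] * m)
    sizes <- c(sizes, m - sum(sizes))
    stops <- cumsum(sizes)
    starts <- c(1, head(stops, -1) + 1)
    for (j in seq_len(k)) {
      if (sizes[j] > 0) {
        idx_parts[[j]] <- c(idx_parts[[j]], perm[starts[j]:stops[j]])
      }
    }
  }
  lapply(seq_len(k), function(j) {
    sub <- cohort[sort(idx_parts[[j]]), , drop = FALSE]
    as_cohort(as.data.frame(sub),
              provenance = paste0(attr(cohort, "provenance"), "/part", j))
  })
}

#' Cohort summary table
#'
#' Medians with IQRs for continuous variables, counts with percentages for
#' categorical variables (percentages computed excluding missing values),
#' the five-year breast-cancer-death count, and median follow-up.
#'
#' @param object a cohort.
#' @param horizon event horizon in years.
#' @param ... unused.
#' @return a data frame with columns `variable`, `statistic`, `value`.
#' @export
summary.cohort <- function(object, horizon = 5, ...) {
  if (nrow(object) == 0) stop("cannot summarize an empty cohort")
  rows <- list()
  add <- function(variable, statistic, value) {
    rows[[length(rows) + 1]] <<- data.frame(
      variable = variable, statistic = statistic, value = value,
      stringsAsFactors = FALSE)
  }
  cont <- function(x, nm) {
    q <- quantile(x, c(.25, .5, .75), na.rm = TRUE, names = FALSE)
    add(nm, "median", q[2]); add(nm, "q25", q[1]); add(nm, "q75", q[3])
    add(nm, "n_missing", sum(is.na(x)))
  }
  pct <- function(x, nm, level) {
    obs <- !is.na(x)
    add(nm, paste0("n_", level), sum(x[obs] == level))
    add(nm, paste0("pct_", level), 100 * mean(x[obs] == level))
    add(nm, "n_missing", sum(!obs))
  }
  cont(object$age, "age")
  cont(object$size_mm, "size_mm")
  nodal <- cut(object$nodes, c(-Inf, 0, 3, 9, Inf),
               labels = c("N0", "N1", "N2", "N3"))
  for (lv in levels(nodal)) pct(as.character(nodal), "nodal_stage", lv)
  for (lv in 1:3) pct(object$grade, "grade", lv)
  for (lv in .laterality_levels) pct(as.character(object$laterality),
                                     "laterality", lv)
  for (v in c("er_positive", "pr_positive", "radiotherapy",
              "chemotherapy", "trastuzumab")) {
    pct(as.character(object[[v]]), v, "TRUE")
  }
  ev <- event_at_horizon(object, horizon)
  add("event_5y", "n", sum(ev)); add("event_5y", "pct", 100 * mean(ev))
  cont(object$time_years, "follow_up_years")
  out <- do.call(rbind, rows)
  class(out) <- c("cohort_summary", "data.frame")
  out
}

#' @export
print.cohort <- function(x, ...) {
  cat("<cohort> ", nrow(x), " records  (provenance: ",
      attr(x, "provenance"), ")\n", sep = "")
  cat("  5y bc-death events: ", sum(event_at_horizon(x)),
      sprintf(" (%.1f%%)", 100 * mean(event_at_horizon(x))),
      "; median follow-up: ",
      sprintf("%.2f", median(x$time_years)), " y\n", sep = "")
  invisible(x)
}

#' Random oversampling of event records
#'
#' Dataset-level outcome rebalancing: event records (five-year
#' breast-cancer death) are resampled with replacement, optionally with
#' smoothed Gaussian perturbation of continuous covariates, until the
#' event fraction reaches `target_event_fraction`.  Original records are
#' retained.  Rebalancing is an optional utility kept switched off in the
#' default modeling pipeline.
#'
#' @param cohort a cohort.
#' @param target_event_fraction desired event fraction in (0,1).
#' @param perturb_sd relative SD of the multiplicative perturbation
#'   applied to `age` and `size_mm` of duplicated rows (0 = exact copies).
#' @param seed integer seed.
#' @param horizon event horizon in years.
#' @return an enlarged cohort.
#' @export
oversample_events <- function(cohort, target_event_fraction,
                              perturb_sd = 0, seed = 1, horizon = 5) {
  stopifnot(inherits(cohort, "cohort"))
  ev <- event_at_horizon(cohort, horizon)
  n <- nrow(cohort); ne <- sum(ev)
  if (ne == 0) stop("cannot oversample a cohort with no events")
  if (target_event_fraction <= ne / n) {
    if (target_event_fraction < ne / n) {
      warning("target event fraction below current fraction; cohort unchanged")
    }
    return(cohort)
  }
  # solve (ne + k) / (n + k) >= target
  k <- ceiling((target_event_fraction * n - ne) / (1 - target_event_fraction))
  set.seed(seed)
  pick <- sample(which(ev), k, replace = TRUE)
  dup <- as.data.frame(cohort[pick, , drop = FALSE])
  if (perturb_sd > 0) {
    dup$age <- dup$age * exp(rnorm(k, 0, perturb_sd))
    dup$size_mm <- dup$size_mm * exp(rnorm(k, 0, perturb_sd))
  }
  dup$id <- sprintf("%s_os%04d", dup$id, seq_len(k))
  out <- rbind(as.data.frame(cohort), dup)
  as_cohort(out, provenance = paste0(attr(cohort, "provenance"), "+oversampled"))
}

#' Per-record case weights
#'
#' Algorithm-level outcome rebalancing.  `none` gives unit weights;
#' `inverse_prevalence` weights five-year event records by
#' `n / (2 n_event)` and non-events by `n / (2 n_nonevent)`, so weights
#' sum to `n`.
#'
#' @param cohort a cohort.
#' @param scheme `"none"` or `"inverse_prevalence"`.
#' @param horizon event horizon in years.
#' @return numeric weight vector of length `nrow(cohort)`.
#' @export
case_weights <- function(cohort, scheme = c("none", "inverse_prevalence"),
                         horizon = 5) {
  scheme <- match.arg(scheme)
  n <- nrow(cohort)
  if (scheme == "none") return(rep(1, n))
  ev <- event_at_horizon(cohort, horizon)
  ne <- sum(ev)
  if (ne == 0 || ne == n) stop("inverse_prevalence weights need both classes")
  ifelse(ev, n / (2 * ne), n / (2 * (n - ne)))
}
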