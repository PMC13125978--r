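test_that("CSV round trip preserves a well-formed cohort", {
  co <- toy_cohort(10)
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(co, path)
  back <- read_cohort(path, provenance = "toy")
  expect_equal(nrow(back), 10)
  expect_equal(back$id, co$id)
  expect_equal(back$size_mm, co$size_mm)
  expect_equal(as.character(back$event), as.character(co$event))
  # summary is unchanged by the round trip
  expect_equal(summary(back)$value, summary(co)$value)
})

test_that("records without positive follow-up are excluded at load", {
  df <- toy_cohort_df(10)
  df$time_years[4] <- 0
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(df, path, row.names = FALSE, na = "")
  expect_message(co <- read_cohort(path), "excluded 1")
  expect_equal(nrow(co), 9)
  expect_equal(attr(co, "n_excluded_nonpositive_time"), 1)
})

test_that("unknown event codes and schema mapping are handled", {
  df <- toy_cohort_df(6)
  df$event[2] <- "dead"
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(df, path, row.names = FALSE, na = "")
  expect_error(read_cohort(path), "dead")
  # a schema can map foreign codes and cm-sized tumors
  df2 <- toy_cohort_df(6)
  df2$event <- c("alive", "dcd", "alive", "alive", "other", "alive")
  df2$size_cm <- df2$size_mm / 10
  df2$size_mm <- NULL
  path2 <- withr::local_tempfile(fileext = ".csv")
  write.csv(df2, path2, row.names = FALSE, na = "")
  co <- read_cohort(path2, schema = list(
    columns = c(size_mm = "size_cm"), size_unit = "cm",
    event_codes = c(alive = "censored", dcd = "bc_death",
                    other = "other_death")))
  expect_equal(co$size_mm, toy_cohort_df(6)$size_mm)
  expect_equal(as.character(co$event)[2], "bc_death")
})

test_that("stratified split follows the per-stratum floor rule", {
  # toy enumeration: n=10 with 2 events at 60/20/20
  df <- toy_cohort_df(10)
  df$time_years <- rep(4, 10)
  df$event <- c("bc_death", "bc_death", rep("censored", 8))
  co <- as_cohort(df, "toy")
  parts <- stratified_split(co, c(0.6, 0.2, 0.2), seed = 7)
  # brute-force floor rule: events (2): floor(1.2)=1, floor(0.4)=0, rest 1;
  # non-events (8): floor(4.8)=4, floor(1.6)=1, rest 3
  expect_equal(sapply(parts, nrow), c(5, 1, 4))
  ev_counts <- sapply(parts, function(p) sum(event_at_horizon(p)))
  expect_equal(ev_counts, c(1, 0, 1))
})

test_that("split partitions are disjoint, exhaustive and seed-reproducible", {
  co <- generate_cohort(generator_config("ma27_like", n = 500), seed = 2)
  p1 <- stratified_split(co, c(0.6, 0.2, 0.2), seed = 3)
  p2 <- stratified_split(co, c(0.6, 0.2, 0.2), seed = 3)
  ids <- unlist(lapply(p1, function(x) x$id))
  expect_setequal(ids, co$id)
  expect_equal(length(ids), length(unique(ids)))
  expect_identical(lapply(p1, `[[`, "id"), lapply(p2, `[[`, "id"))
  # single-fraction split returns the whole cohort
  whole <- stratified_split(co, 1, seed = 1)
  expect_setequal(whole[[1]]$id, co$id)
  expect_error(stratified_split(co, c(0.5, 0.4)), "sum to 1")
})

test_that("summary computes percentages excluding missing values", {
  df <- toy_cohort_df(4)
  df$pr_positive <- c(TRUE, TRUE, FALSE, NA)
  df$age <- c(60, 64, 70, 64)
  co <- as_cohort(df, "toy")
  s <- summary(co)
  pr <- s$value[s$variable == "pr_positive" & s$statistic == "pct_TRUE"]
  expect_equal(pr, 100 * 2 / 3, tolerance = 1e-12)
  expect_equal(s$value[s$variable == "age" & s$statistic == "median"][1], 64)
  expect_error(summary(as_cohort(toy_cohort_df(3)[0, ], "empty")), "empty")
})

test_that("oversampling reaches the target event fraction without touching labels", {
  df <- toy_cohort_df(100)
  df$time_years <- rep(4, 100)
  df$event <- c(rep("bc_death", 2), rep("censored", 98))
  co <- as_cohort(df, "toy")
  out <- oversample_events(co, 0.5, perturb_sd = 0, seed = 1)
  ev <- event_at_horizon(out)
  expect_gte(mean(ev), 0.5 - 1 / nrow(out))
  expect_equal(nrow(out), 196)
  expect_equal(sum(ev), 98)
  # duplicated rows are exact copies under zero perturbation
  dup <- out[grepl("_os", out$id), ]
  expect_true(all(dup$size_mm %in% co$size_mm[event_at_horizon(co)]))
  # no-op cases
  expect_identical(nrow(oversample_events(co, 0.02, seed = 1)), nrow(co))
  expect_warning(oversample_events(co, 0.001, seed = 1), "below current")
  df$event <- "censored"
  expect_error(oversample_events(as_cohort(df, "x"), 0.5), "no events")
})

test_that("inverse-prevalence case weights follow the formula and sum to n", {
  df <- toy_cohort_df(100)
  df$time_years <- rep(4, 100)
  df$event <- c(rep("bc_death", 10), rep("censored", 90))
  co <- as_cohort(df, "toy")
  expect_equal(case_weights(co, "none"), rep(1, 100))
  w <- case_weights(co, "inverse_prevalence")
  expect_equal(unique(w[event_at_horizon(co)]), 100 / 20)
  expect_equal(unique(w[!event_at_horizon(co)]), 100 / 180)
  expect_equal(sum(w), 100)
})
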