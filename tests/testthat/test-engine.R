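test_that("parameter vectors are validated and round-trip through JSON", {
  p <- standin_params()
  expect_s3_class(p, "param_vector")
  expect_length(p, 26)
  expect_error(param_vector(as.numeric(p)[1:25], attr(p, "groups")), "26")
  path <- withr::local_tempfile(fileext = ".json")
  write_params(p, path, provenance = list(note = "test"))
  back <- read_params(path)
  expect_equal(as.numeric(back), as.numeric(p))
  expect_identical(names(back), names(p))
  expect_identical(attr(back, "mandatory"), attr(p, "mandatory"))
})

test_that("averaging parameter vectors is element-wise", {
  p <- standin_params()
  mk <- function(v) param_vector(setNames(v, names(p)), attr(p, "groups"))
  v1 <- mk(rep(1, 26)); v2 <- mk(rep(3, 26))
  expect_equal(as.numeric(average_param_vectors(list(v1, v2))), rep(2, 26))
  expect_equal(as.numeric(average_param_vectors(list(v1, mk(-rep(1, 26))))),
               rep(0, 26))
  expect_equal(as.numeric(average_param_vectors(rep(list(p), 10))),
               as.numeric(p))
  expect_error(average_param_vectors(list(v1, structure(v2, names = rev(names(p))))))
})

test_that("assumption fills follow the HER2/trastuzumab rule and never touch mandatory inputs", {
  df <- toy_cohort_df(4)
  df$trastuzumab <- c(TRUE, FALSE, TRUE, FALSE)
  df$grade[2] <- NA  # record-level missing mandatory input
  co <- as_cohort(df, "toy")
  filled <- apply_assumptions(co, "default")
  expect_equal(filled$her2, c(TRUE, FALSE, TRUE, FALSE))
  expect_true(all(filled$hormone_therapy))
  expect_true(is.na(filled$grade[2]))
  # records with no dataset-level gaps are unchanged
  pre <- apply_assumptions(co, "default")
  again <- apply_assumptions(pre, "optimistic")
  expect_equal(again$ki67, pre$ki67)
  # scenarios share the missingness pattern and differ only in fill values
  opt <- apply_assumptions(co, "optimistic")
  pes <- apply_assumptions(co, "pessimistic")
  expect_identical(is.na(opt$grade), is.na(pes$grade))
  expect_false(identical(opt$heart_dose_category, pes$heart_dose_category))
})

test_that("prognostic index is zero at reference and linear in coefficients", {
  ref <- data.frame(id = "r", age = 65, nodes = 0, laterality = "left",
                    er_positive = TRUE, pr_positive = TRUE, size_mm = 15,
                    grade = 1, radiotherapy = FALSE, chemotherapy = FALSE,
                    trastuzumab = FALSE, time_years = 5, event = "censored",
                    her2 = FALSE, ki67 = FALSE, mode_of_detection = "symptomatic",
                    smoking = FALSE, bisphosphonates = FALSE,
                    heart_dose_category = 0, micrometastases = FALSE,
                    chemo_generation = 2, year_of_diagnosis = 2003,
                    hormone_therapy = FALSE,
                    stringsAsFactors = FALSE)
  co <- as_cohort(ref, "ref")
  pis <- prognostic_index(co, standin_params())
  expect_equal(unname(pis[1, ]), c(0, 0), tolerance = 1e-12)
  # doubling one coefficient doubles its additive contribution
  p <- standin_params()
  rec <- co; rec$nodes <- 4
  base <- prognostic_index(rec, p)[1, "pi_bc"]
  p2 <- p; p2["bc_nodes"] <- 2 * p2["bc_nodes"]
  contrib <- p["bc_nodes"] * log(5)
  expect_equal(prognostic_index(rec, p2)[1, "pi_bc"], base + contrib,
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("baseline cumulative hazard obeys the fractional-polynomial algebra", {
  # single ln-t term with unit coefficient and zero intercept -> H0(t) = t
  t <- c(0.5, 1, 2, 5)
  expect_equal(baseline_cumhaz(t, c(0, 1), basis = 0), t, tolerance = 1e-12)
  # intercept shift scales multiplicatively
  h1 <- baseline_cumhaz(t, c(-2, 0.8, 0.3))
  h2 <- baseline_cumhaz(t, c(-2 + 0.7, 0.8, 0.3))
  expect_equal(h2, h1 * exp(0.7), tolerance = 1e-12)
  # nondecreasing on the annual grid for the shipped stand-in coefficients
  p <- standin_params()
  hb <- baseline_cumhaz(0:5, p[c("bc_base_const", "bc_base_logt", "bc_base_sqrt")])
  ho <- baseline_cumhaz(0:5, p[c("oth_base_const", "oth_base_logt", "oth_base_sqrt")])
  expect_true(all(diff(hb) > 0) && all(diff(ho) > 0))
  expect_equal(hb[1], 0)
  expect_error(baseline_cumhaz(-1, c(0, 1)), "t >= 0")
})

test_that("missing mandatory inputs yield an explicit invalid prediction", {
  df <- toy_cohort_df(3)
  df$grade[1] <- NA
  df$size_mm[2] <- NA
  df$nodes[2] <- NA
  co <- as_cohort(df, "toy")
  r1 <- predict_5y(co[1, ])
  expect_equal(r1$status, "invalid")
  expect_equal(r1$invalid_reason, "grade")
  r2 <- predict_5y(co[2, ])
  expect_setequal(r2$invalid_reason, c("size_mm", "nodes"))
  r3 <- predict_5y(co[3, ])
  expect_equal(r3$status, "valid")
  expect_equal(r3$p_surv_5y, 1 - r3$p_bc_death_5y)
  bp <- batch_predict(co)
  expect_equal(attr(bp, "invalid_fraction"), 2 / 3)
  expect_equal(bp$status, c("invalid", "invalid", "valid"))
  # cohort where every record lacks size -> invalid fraction 1
  df2 <- toy_cohort_df(4); df2$size_mm <- NA
  expect_equal(attr(batch_predict(as_cohort(df2, "x")), "invalid_fraction"), 1)
})

test_that("the annual grid matches a literal year-by-year evaluation", {
  co <- toy_cohort(6)[3, ]
  p <- standin_params()
  got <- survival_curve(co, p)
  # independent spreadsheet-style computation of the same quantities
  filled <- apply_assumptions(co, "default")
  pi_bc <- p["bc_size"] * log(filled$size_mm / 15) +
    p["bc_nodes"] * log(filled$nodes + 1) +
    p["bc_age1"] * ((filled$age / 65)^-2 - 1) +
    p["bc_age2"] * log(filled$age / 65) +
    p["bc_grade2"] * (filled$grade == 2) + p["bc_grade3"] * (filled$grade == 3) +
    p["bc_er_neg"] * (!filled$er_positive) +
    p["bc_pr_neg"] * (!filled$pr_positive) +
    p["bc_her2_pos"] * filled$her2 + p["bc_ki67_pos"] * filled$ki67 +
    p["bc_chemo"] * filled$chemotherapy + p["bc_hormone"] * filled$hormone_therapy +
    p["bc_trastuzumab"] * filled$trastuzumab +
    p["bc_bisphosphonates"] * filled$bisphosphonates +
    p["bc_radio"] * filled$radiotherapy +
    p["bc_screen"] * (filled$mode_of_detection == "screen")
  pi_oth <- p["oth_age1"] * ((filled$age / 65)^-2 - 1) +
    p["oth_age2"] * log(filled$age / 65) + p["oth_smoking"] * filled$smoking +
    p["oth_heart_dose"] * filled$radiotherapy * filled$heart_dose_category
  S_prev <- 1; Fb <- 0; Hb_prev <- 0; Ho_prev <- 0
  for (j in 1:5) {
    Hb <- exp(p["bc_base_const"] + p["bc_base_logt"] * log(j) +
                p["bc_base_sqrt"] * sqrt(j)) * exp(pi_bc)
    Ho <- exp(p["oth_base_const"] + p["oth_base_logt"] * log(j) +
                p["oth_base_sqrt"] * sqrt(j)) * exp(pi_oth)
    dHb <- Hb - Hb_prev; dHo <- Ho - Ho_prev; dH <- dHb + dHo
    Fb <- Fb + S_prev * (1 - exp(-dH)) * dHb / dH
    S_prev <- exp(-(Hb + Ho)); Hb_prev <- Hb; Ho_prev <- Ho
  }
  expect_equal(got$F_bc[5], unname(Fb), tolerance = 1e-12)
  expect_equal(predict_5y(co, p)$p_bc_death_5y, unname(Fb), tolerance = 1e-12)
})

test_that("competing-risks identities hold on every record", {
  co <- generate_cohort(generator_config("ma27_like", n = 200), seed = 5)
  d <- stacksurv:::engine_design(co)
  cv <- stacksurv:::.curves_from_design(d, standin_params())
  ok <- d$valid
  total <- cv$F_bc[ok, ] + cv$F_oth[ok, ] + cv$S_all[ok, ]
  expect_lt(max(abs(total - 1)), 1e-9)
  expect_true(all(diff(t(cv$F_bc[ok, ])) >= -1e-12))
  expect_true(all(diff(t(cv$S_all[ok, ])) <= 1e-12))
  # single-risk limit: zero other-cause hazard
  p0 <- standin_params()
  v <- setNames(as.numeric(p0), names(p0))
  v["oth_base_const"] <- -60
  p1 <- param_vector(v, attr(p0, "groups"))
  cv1 <- stacksurv:::.curves_from_design(d, p1)
  expect_equal(cv1$F_bc[ok, 5], 1 - exp(-cv1$H_bc[ok, 5]), tolerance = 1e-9)
})

test_that("risk is monotone in nodes and size under the stand-in parameters", {
  base <- toy_cohort_df(1)
  base$grade <- 2; base$er_positive <- TRUE
  risk <- function(nodes, size) {
    df <- base; df$nodes <- nodes; df$size_mm <- size
    predict_5y(as_cohort(df, "g"))$p_bc_death_5y
  }
  rn <- sapply(c(0, 1, 2, 5, 10, 20), risk, size = 20)
  rs <- sapply(c(5, 10, 15, 25, 40, 80), function(s) risk(2, s))
  expect_true(all(diff(rn) > 0))
  expect_true(all(diff(rs) > 0))
})

test_that("optimistic and pessimistic scenarios bracket the default", {
  co <- generate_cohort(generator_config("ma27_like", n = 300), seed = 6)
  p <- standin_params()
  pd <- batch_predict(co, p, "default")$p_bc_death_5y
  po <- batch_predict(co, p, "optimistic")$p_bc_death_5y
  pp <- batch_predict(co, p, "pessimistic")$p_bc_death_5y
  ok <- !is.na(pd)
  expect_true(all(po[ok] <= pd[ok] + 1e-12))
  expect_true(all(pp[ok] >= pd[ok] - 1e-12))
})
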