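# Fixture builders shared across the suite.  Everything is generated in
# code; no stored data.

# Minimal hand-written cohort data frame (n rows, deterministic values).
toy_cohort_df <- function(n = 10) {
  set.seed(99)
  data.frame(
    id = sprintf("P%03d", seq_len(n)),
    age = seq(50, 78, length.out = n),
    nodes = rep(c(0, 0, 1, 3, 0), length.out = n),
    laterality = rep(c("left", "right"), length.out = n),
    er_positive = TRUE,
    pr_positive = rep(c(TRUE, TRUE, FALSE), length.out = n),
    size_mm = seq(8, 42, length.out = n),
    grade = rep(c(1, 2, 3), length.out = n),
    radiotherapy = rep(c(TRUE, FALSE), length.out = n),
    chemotherapy = rep(c(FALSE, TRUE, FALSE), length.out = n),
    trastuzumab = FALSE,
    time_years = seq(0.8, 6.2, length.out = n),
    event = rep(c("censored", "bc_death", "censored", "censored",
                  "other_death"), length.out = n),
    stringsAsFactors = FALSE)
}

toy_cohort <- function(n = 10) as_cohort(toy_cohort_df(n), provenance = "toy")

# Uncensored samples with known binary outcome (time > horizon for
# non-events), for metric oracle checks.
uncensored_samples <- function(y, horizon = 5, seed = 1) {
  set.seed(seed)
  data.frame(
    time = ifelse(y == 1, runif(length(y), 0.1, horizon - 0.1), horizon + 5),
    event = ifelse(y == 1, "bc_death", "censored"),
    stringsAsFactors = FALSE)
}

# Small engine-consistent synthetic world: covariates from the ma27-like
# generator, event times from the prognostic engine under `params`.
engine_world <- function(n, params = standin_params(), seed = 1,
                         missingness = FALSE) {
  cfg <- generator_config("ma27_like", n = n)
  cfg$event_model <- list(kind = "params", params = params)
  if (!missingness) cfg$missingness <- list()
  generate_cohort(cfg, seed = seed)
}

# Brute-force pair-counting AUROC (independent oracle).
brute_auroc <- function(pred, y) {
  pos <- pred[y == 1]; neg <- pred[y == 0]
  mean(outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b)))
}
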