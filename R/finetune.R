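#' Fine-tuning configuration
#'
#' Controls the parameter-based transfer-learning step: re-estimating the
#' 26-parameter vector of the prognostic engine on a new cohort by local
#' optimization of the five-year ICI, initialized at the pretrained
#' values.  Nelder-Mead is the default optimizer because the ICI
#' objective is derivative-free and non-smooth through the calibration
#' smoother.
#'
#' @param optimizer `"nelder_mead"` or `"powell"` (coordinate search).
#' @param max_iter maximum objective evaluations.
#' @param tol convergence tolerance on the objective.
#' @param bounds optional 2-row matrix (lower/upper) of per-parameter
#'   boxes; violations are clamped after optimization.
#' @param runs_to_average number of independent runs whose fine-tuned
#'   vectors the experiment protocol averages.
#' @return a list of class `finetune_config`.
#' @export
finetune_config <- function(optimizer = c("nelder_mead", "powell"),
                            max_iter = 2000, tol = 1e-5, bounds = NULL,
                            runs_to_average = 10) {
  optimizer <- match.arg(optimizer)
  stopifnot(max_iter >= 1, tol > 0)
  structure(list(optimizer = optimizer, max_iter = max_iter, tol = tol,
                 bounds = bounds, runs_to_average = runs_to_average),
            class = "finetune_config")
}

#' ICI objective for a parameter vector on a cohort
#'
#' Evaluates the five-year ICI of the engine's predictions under `params`
#' over the records with valid predictions (records invalid because of
#' missing mandatory inputs are excluded; validity depends only on
#' missingness, not on the parameter values).
#'
#' @param params a [param_vector()].
#' @param cohort a cohort.
#' @param scenario an [assumption_scenario()] or name.
#' @param horizon years.
#' @return the ICI (numeric scalar).
#' @export
ici_objective <- function(params, cohort, scenario = assumption_scenario("default"),
                          horizon = 5) {
  pred <- batch_predict(cohort, params, scenario)
  if (all(is.na(pred$p_bc_death_5y))) {
    stop("all predictions invalid; cannot evaluate the calibration objective")
  }
  as.numeric(ici(pred$p_bc_death_5y, cohort, horizon))
}

#' Fine-tune the pretrained parameter vector on a cohort
#'
#' Parameter-based transfer learning: all 26 parameters are re-estimated
#' by local optimization of the five-year ICI, starting from the
#' pretrained values.  Covariates are not re-standardized, so fine-tuned
#' vectors from independent runs stay on a common scale and can be
#' averaged.  The fitted vector is guaranteed not to be worse than the
#' initialization (up to `tol`); if the optimizer fails, the
#' initialization is returned with a warning and a `failed` attribute.
#'
#' @param params0 initialization, a [param_vector()] of length 26.
#' @param cohort fitting cohort.
#' @param cfg a [finetune_config()].
#' @param scenario an [assumption_scenario()] or name.
#' @param horizon years.
#' @return the fine-tuned `param_vector`, with attributes `objective_init`,
#'   `objective_final` and `evals`.
#' @export
finetune <- function(params0, cohort, cfg = finetune_config(),
                     scenario = assumption_scenario("default"), horizon = 5) {
  stopifnot(inherits(params0, "param_vector"))
  if (is.character(scenario)) scenario <- assumption_scenario(scenario)
  d <- engine_design(cohort, params0, scenario)
  if (!any(d$valid)) stop("all records invalid under the mandatory-input set")
  sub <- cohort[d$valid, , drop = FALSE]
  t5 <- sub$time_years; code <- as.character(sub$event)
  samples <- data.frame(time = t5, event = code, stringsAsFactors = FALSE)
  dv <- engine_design(as_cohort(as.data.frame(sub), provenance = "finetune"),
                      params0, scenario)

  make_pv <- function(v) {
    param_vector(setNames(v, names(params0)), groups = attr(params0, "groups"),
                 basis = attr(params0, "basis"),
                 mandatory = attr(params0, "mandatory"))
  }
  n_eval <- 0L
  obj <- function(v) {
    n_eval <<- n_eval + 1L
    pv <- make_pv(v)
    p <- .curves_from_design(dv, pv, horizon = horizon)$F_bc[, horizon]
    val <- tryCatch(suppressWarnings(as.numeric(ici(p, samples, horizon))),
                    error = function(e) NA_real_)
    if (!is.finite(val)) 1 else val
  }
  f0 <- obj(as.numeric(params0))
  res <- tryCatch({
    if (cfg$optimizer == "nelder_mead") {
      optim(as.numeric(params0), obj, method = "Nelder-Mead",
            control = list(maxit = cfg$max_iter, reltol = cfg$tol))
    } else {
      .powell_search(as.numeric(params0), obj, max_iter = cfg$max_iter,
                     tol = cfg$tol)
    }
  }, error = function(e) NULL)

  if (is.null(res) || !is.finite(res$value) || res$value > f0 + cfg$tol) {
    warning("fine-tuning did not improve the objective; returning initialization")
    out <- params0
    attr(out, "failed") <- TRUE
    attr(out, "objective_init") <- f0
    attr(out, "objective_final") <- f0
    attr(out, "evals") <- n_eval
    return(out)
  }
  v <- res$par
  if (!is.null(cfg$bounds)) v <- pmin(pmax(v, cfg$bounds[1, ]), cfg$bounds[2, ])
  out <- make_pv(v)
  attr(out, "objective_init") <- f0
  attr(out, "objective_final") <- res$value
  attr(out, "evals") <- n_eval
  out
}

# Simple coordinate-descent line search ("powell" option): cycles through
# parameters, golden-section step halving on each coordinate.
.powell_search <- function(par, fn, max_iter = 2000, tol = 1e-5) {
  f <- fn(par)
  step <- rep(0.25, length(par))
  evals <- 1
  repeat {
    improved <- FALSE
    for (j in seq_along(par)) {
      for (s in c(step[j], -step[j])) {
        if (evals >= max_iter) return(list(par = par, value = f))
        cand <- par; cand[j] <- cand[j] + s
        fc <- fn(cand); evals <- evals + 1
        if (fc < f - 1e-12) { par <- cand; f <- fc; improved <- TRUE; break }
      }
    }
    if (!improved) {
      step <- step / 2
      if (all(step < tol)) break
    }
    if (evals >= max_iter) break
  }
  list(par = par, value = f)
}
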