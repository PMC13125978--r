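#' Pretrained-model parameter vectors
#'
#' The competing-risks prognostic engine is driven by a vector of exactly
#' 26 named parameters, grouped into baseline-hazard coefficients for the
#' breast-cancer and other-cause hazards, cause-specific covariate
#' coefficients, and treatment effects.  `param_vector()` validates and
#' tags a numeric vector; [standin_params()] returns the stand-in
#' coefficient set shipped with the package.
#'
#' @param values named numeric vector of length 26.
#' @param groups named character vector assigning each parameter to one of
#'   `baseline_bc`, `baseline_oth`, `covariate_bc`, `covariate_oth`,
#'   `treatment_effect`.
#' @param basis list with elements `bc` and `oth`: fractional-polynomial
#'   exponents of the baseline cumulative-hazard bases (0 encodes `ln t`);
#'   each baseline has one coefficient per exponent plus an intercept.
#' @param mandatory character vector of record-level inputs whose absence
#'   makes a prediction invalid.
#' @return an object of class `param_vector`.
#' @export
param_vector <- function(values, groups, basis = list(bc = c(0, 0.5), oth = c(0, 0.5)),
                         mandatory = c("age", "size_mm", "nodes", "grade",
                                       "er_positive")) {
  if (length(values) != 26) stop("a parameter vector has exactly 26 entries, got ",
                                 length(values))
  if (is.null(names(values)) || anyDuplicated(names(values))) {
    stop("parameter names must be present and unique")
  }
  allowed <- c("baseline_bc", "baseline_oth", "covariate_bc",
               "covariate_oth", "treatment_effect")
  if (!setequal(names(groups), names(values)) || !all(groups %in% allowed)) {
    stop("every parameter must be assigned to exactly one recognized group")
  }
  ok_p <- c(-2, -1, -0.5, 0, 0.5, 1, 2, 3)
  if (!all(unlist(basis) %in% ok_p)) {
    stop("fractional-polynomial exponents must lie in {-2,-1,-0.5,0,0.5,1,2,3}")
  }
  structure(as.numeric(setNames(values, names(values))),
            names = names(values),
            groups = groups[names(values)],
            basis = basis, mandatory = mandatory,
            class = "param_vector")
}

#' @export
print.param_vector <- function(x, ...) {
  cat("<param_vector> 26 parameters\n")
  g <- attr(x, "groups")
  for (grp in unique(g)) {
    cat("  ", grp, ": ", paste(names(x)[g == grp], collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

# Stand-in coefficient values.  The published tool's coefficients are not
# reproduced here; these are documented plausible magnitudes with the
# clinically correct signs (risk increases with size, nodes, grade,
# receptor negativity; adjuvant therapies reduce the breast-cancer hazard;
# other-cause mortality rises steeply with age).  All shipped defaults and
# tests are defined against this set.
.standin_values <- c(
  bc_base_const  = -6.20, bc_base_logt  = 1.00, bc_base_sqrt  = 0.50,
  oth_base_const = -6.60, oth_base_logt = 1.10, oth_base_sqrt = 0.30,
  bc_size = 0.75, bc_nodes = 0.70, bc_age1 = 0.20, bc_age2 = 1.20,
  bc_grade2 = 0.45, bc_grade3 = 0.95, bc_er_neg = 0.35, bc_pr_neg = 0.25,
  bc_her2_pos = 0.30, bc_ki67_pos = 0.20,
  oth_age1 = 0.30, oth_age2 = 5.80, oth_smoking = 0.45,
  bc_chemo = -0.35, bc_hormone = -0.30, bc_trastuzumab = -0.30,
  bc_bisphosphonates = -0.10, bc_radio = -0.10, bc_screen = -0.25,
  oth_heart_dose = 0.05
)

.standin_groups <- c(
  bc_base_const = "baseline_bc", bc_base_logt = "baseline_bc",
  bc_base_sqrt = "baseline_bc",
  oth_base_const = "baseline_oth", oth_base_logt = "baseline_oth",
  oth_base_sqrt = "baseline_oth",
  bc_size = "covariate_bc", bc_nodes = "covariate_bc",
  bc_age1 = "covariate_bc", bc_age2 = "covariate_bc",
  bc_grade2 = "covariate_bc", bc_grade3 = "covariate_bc",
  bc_er_neg = "covariate_bc", bc_pr_neg = "covariate_bc",
  bc_her2_pos = "covariate_bc", bc_ki67_pos = "covariate_bc",
  oth_age1 = "covariate_oth", oth_age2 = "covariate_oth",
  oth_smoking = "covariate_oth",
  bc_chemo = "treatment_effect", bc_hormone = "treatment_effect",
  bc_trastuzumab = "treatment_effect",
  bc_bisphosphonates = "treatment_effect", bc_radio = "treatment_effect",
  bc_screen = "treatment_effect", oth_heart_dose = "treatment_effect"
)

#' Shipped stand-in parameter set
#'
#' @return a [param_vector()] with the stand-in coefficients used by all
#'   shipped defaults, examples and tests.
#' @export
standin_params <- function() {
  param_vector(.standin_values, .standin_groups)
}

#' Read / write parameter files
#'
#' Parameter files are JSON with fields `names`, `values`, `groups`,
#' `basis` (`bc` and `oth` exponent lists), `mandatory`, and an optional
#' free-form `provenance` block, so externally published coefficient sets
#' can be loaded into the engine.
#'
#' @param path JSON file path.
#' @return a `param_vector` (for `read_params`) or `path` invisibly.
#' @export
read_params <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  pv <- param_vector(setNames(as.numeric(j$values), j$names),
                     groups = setNames(as.character(j$groups), j$names),
                     basis = lapply(j$basis, as.numeric),
                     mandatory = as.character(j$mandatory))
  attr(pv, "provenance") <- j$provenance
  pv
}

#' @rdname read_params
#' @param params a `param_vector`.
#' @param provenance optional list written alongside the values (e.g.
#'   initialization hash, fitting cohort, final objective).
#' @export
write_params <- function(params, path, provenance = NULL) {
  stopifnot(inherits(params, "param_vector"))
  j <- list(names = names(params),
            values = as.numeric(params),
            groups = unname(attr(params, "groups")),
            basis = attr(params, "basis"),
            mandatory = attr(params, "mandatory"))
  if (!is.null(provenance)) j$provenance <- provenance
  jsonlite::write_json(j, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Element-wise average of parameter vectors
#'
#' Used to pool the fine-tuned coefficient vectors across independent
#' experiment runs into the final model bundle.
#'
#' @param vectors list of `param_vector`s sharing names and order.
#' @return a `param_vector`.
#' @export
average_param_vectors <- function(vectors) {
  stopifnot(length(vectors) >= 1)
  nm <- names(vectors[[1]])
  for (v in vectors) {
    if (!identical(names(v), nm)) stop("parameter vectors have mismatched names")
  }
  mean_vals <- Reduce(`+`, lapply(vectors, as.numeric)) / length(vectors)
  param_vector(setNames(mean_vals, nm),
               groups = attr(vectors[[1]], "groups"),
               basis = attr(vectors[[1]], "basis"),
               mandatory = attr(vectors[[1]], "mandatory"))
}
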