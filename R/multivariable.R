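#' Logistic sex-estimation model standard
#'
#' A bone-wise binary logistic model: Z = sum(coef_j * x_j) + intercept,
#' p(male) = 1 / (1 + exp(-Z)). Coefficients are per-millimetre weights.
#'
#' @param model_id integer identifier.
#' @param bone bone name (registry spelling).
#' @param variables ordered character vector of measurement codes.
#' @param coefficients numeric vector, one per variable.
#' @param intercept numeric intercept.
#' @param bone_label optional display label (e.g. a variant tag such as
#'   "SCAPULA (glenoid cavity)").
#' @param reported optional provenance metadata (published accuracies).
#' @param caution optional free-text caution surfaced in casework reports.
#' @param separation logical; TRUE when the fit showed complete separation.
#' @return object of class `logistic_model`.
#' @export
logistic_model <- function(model_id, bone, variables, coefficients,
                           intercept, bone_label = bone, reported = NULL,
                           caution = NULL, separation = FALSE) {
  if (length(variables) != length(coefficients))
    stopf("model %s: %d variables but %d coefficients", model_id,
          length(variables), length(coefficients))
  registry_entry(variables)
  structure(list(model_id = model_id, bone = bone,
                 bone_label = bone_label,
                 variables = as.character(variables),
                 coefficients = as.numeric(coefficients),
                 intercept = as.numeric(intercept),
                 reported = reported, caution = caution,
                 separation = isTRUE(separation)),
            class = "logistic_model")
}

#' @export
print.logistic_model <- function(x, ...) {
  cat(sprintf("<logistic_model %s> %s: Z = %s %+g\n", x$model_id,
              x$bone_label,
              paste(sprintf("%g*%s", x$coefficients, x$variables),
                    collapse = " + "),
              x$intercept))
  invisible(x)
}

#' Linear score of a logistic model
#'
#' Multiplies each measurement (mm) by its coefficient, sums, and adds the
#' intercept. All model variables must be present: no imputation is ever
#' performed, mirroring the complete-case rule under which the models were
#' fitted.
#'
#' @param model a `logistic_model`.
#' @param values named numeric vector (or one-row data.frame) of
#'   measurements in mm, names = codes.
#' @return the linear score Z.
#' @export
linear_score <- function(model, values) {
  if (is.data.frame(values)) values <- unlist(values[1, , drop = TRUE])
  x <- values[model$variables]
  missing <- model$variables[is.na(x)]
  if (length(missing))
    stopf("model %s not applicable: missing measurement(s) %s",
          model$model_id, paste(missing, collapse = ", "))
  sum(model$coefficients * as.numeric(x)) + model$intercept
}

#' Male probability and sex call from a linear score
#'
#' p(male) = 1 / (1 + exp(-Z)); p(female) = 1 - p(male). Scores above 0
#' (p > 0.5) call male, below 0 female; exactly 0.5 is indeterminate.
#'
#' @param z numeric vector of linear scores.
#' @return data.frame with columns `z`, `p_male`, `p_female`, `call`.
#' @export
male_probability <- function(z) {
  p <- stats::plogis(z)
  call <- ifelse(p > 0.5, "male", ifelse(p < 0.5, "female",
                                         "indeterminate"))
  data.frame(z = z, p_male = p, p_female = 1 - p,
             call = factor(call,
                           levels = c("male", "female", "indeterminate")))
}

#' Solve a model's decision boundary for one variable
#'
#' Given fixed values for all other variables of a model, returns the value
#' of `free_code` at which Z = 0 (p = 0.5). Useful for casework reporting
#' of how far a measurement sits from the boundary.
#'
#' @param model a `logistic_model`.
#' @param free_code the variable to solve for.
#' @param fixed named numeric vector of the remaining variables (may be
#'   empty for single-variable models).
#' @return boundary value in mm.
#' @export
decision_boundary <- function(model, free_code, fixed = numeric()) {
  if (!free_code %in% model$variables)
    stopf("%s is not a variable of model %s", free_code, model$model_id)
  k <- match(free_code, model$variables)
  if (model$coefficients[k] == 0)
    stopf("coefficient of %s is zero; boundary undefined", free_code)
  others <- setdiff(model$variables, free_code)
  x <- fixed[others]
  if (anyNA(x) && length(others))
    stopf("fixed values missing for: %s",
          paste(others[is.na(x)], collapse = ", "))
  rest <- if (length(others))
    sum(model$coefficients[match(others, model$variables)] *
          as.numeric(x)) else 0
  -(rest + model$intercept) / model$coefficients[k]
}

#' Fit a bone-wise logistic regression model
#'
#' Maximum-likelihood binary logistic fit of sex (male = 1) on the listed
#' measurements, using only individuals with every measurement of the bone
#' present (complete cases). Unpenalised `stats::glm` fit with
#' epsilon 1e-8 and a fixed iteration cap; deterministic for fixed input.
#' Complete separation is detected and flagged, never silently accepted.
#'
#' @param train an `osteo_dataset` (training subset) with known sexes.
#' @param bone bone name; used to label the model.
#' @param variables measurement codes to include (default: every registry
#'   code of the bone observed in the data).
#' @param model_id identifier for the resulting standard.
#' @param min_per_sex minimum complete cases per sex (default 10).
#' @return a [logistic_model()] with `n_m`/`n_f` complete-case counts
#'   attached; `separation` is TRUE when fitted probabilities reached 0/1.
#' @export
fit_bone_model <- function(train, bone, variables = NULL,
                           model_id = NA_integer_, min_per_sex = 10) {
  if (is.null(variables)) {
    variables <- intersect(bone_codes(bone),
                           unique(train$observations$code))
  }
  if (!length(variables)) stopf("no variables to fit for %s", bone)
  wide <- resolved_values(train, variables)
  keep <- stats::complete.cases(wide[variables]) & wide$sex %in% c("M", "F")
  wide <- wide[keep, , drop = FALSE]
  n_m <- sum(wide$sex == "M"); n_f <- sum(wide$sex == "F")
  if (n_m < min_per_sex || n_f < min_per_sex)
    stopf("insufficient complete cases for %s (%d M / %d F, need %d per sex)",
          bone, n_m, n_f, min_per_sex)
  df <- wide[variables]
  df$.male <- as.integer(wide$sex == "M")
  fit <- suppressWarnings(stats::glm(
    stats::reformulate(variables, ".male"), data = df,
    family = stats::binomial(),
    control = stats::glm.control(epsilon = 1e-8, maxit = 100),
    start = rep(0, length(variables) + 1L)))
  pr <- stats::fitted(fit)
  sep <- any(pr > 1 - 1e-8) || any(pr < 1e-8)
  co <- stats::coef(fit)
  m <- logistic_model(model_id, bone, variables, co[variables],
                      co[["(Intercept)"]], separation = sep)
  m$n_m <- n_m; m$n_f <- n_f
  m
}

#' Evaluate a logistic model on a dataset
#'
#' Applies the model to every complete case with known sex and computes
#' per-sex accuracies and class discrimination bias (same conventions as
#' [classification_metrics()]).
#'
#' @param dataset an `osteo_dataset` with known sexes.
#' @param model a `logistic_model`.
#' @param averaging `"balanced"` or `"pooled"`.
#' @return a `classification_metrics` object.
#' @export
evaluate_model <- function(dataset, model,
                           averaging = c("balanced", "pooled")) {
  averaging <- match.arg(averaging)
  wide <- resolved_values(dataset, model$variables)
  keep <- stats::complete.cases(wide[model$variables]) &
    wide$sex %in% c("M", "F")
  if (!any(keep)) stopf("no complete cases for model %s", model$model_id)
  wide <- wide[keep, , drop = FALSE]
  z <- as.matrix(wide[model$variables]) %*% model$coefficients +
    model$intercept
  classification_metrics(wide$sex, male_probability(as.numeric(z))$call,
                         averaging)
}
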