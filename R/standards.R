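#' Load a standards bundle
#'
#' A standards bundle packages univariate sectioning points and bone-wise
#' logistic models, together with the provenance metadata (training means,
#' sample sizes, published accuracies) needed to apply and report them.
#' With `path = NULL` the packaged Italian postcranial standards are
#' loaded: 118 sectioning points (the three female-larger, non-significant
#' pelvic/sacral measurements are excluded) and 43 logistic models covering
#' 32 bones.
#'
#' All invariants are verified at load: every code exists in the registry,
#' every sectioning point equals the midpoint of its stored sex means (to
#' `sp_tolerance`, which defaults to half the printed 0.1 mm precision so
#' that published tables with half-way rounding validate; bundles emitted
#' by [develop_standards()] carry full-precision values and pass an exact
#' check), and every model has one coefficient per variable, all drawn from
#' the model's bone.
#'
#' @param path JSON file, or `NULL` for the packaged standards.
#' @param sp_tolerance maximum |sp - (mean_m + mean_f)/2| accepted, in mm.
#' @return object of class `standards_bundle` with elements `name`,
#'   `version`, `source`, `sectioning_points` (named list of
#'   `sectioning_point`), `models` (named list of `logistic_model`) and
#'   `excluded_codes`.
#' @export
load_bundle <- function(path = NULL, sp_tolerance = 0.05) {
  packaged <- is.null(path)
  if (packaged && !is.null(.osteosex_cache$bundle))
    return(.osteosex_cache$bundle)
  if (packaged)
    path <- system.file("extdata", "italian_postcranial_standards.json",
                        package = "osteosex", mustWork = TRUE)
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  for (field in c("name", "sectioning_points", "models"))
    if (is.null(raw[[field]]))
      stopf("bundle %s: missing field '%s'", path, field)

  sps <- lapply(raw$sectioning_points, function(r) {
    for (f in c("code", "mean_m_mm", "mean_f_mm", "sp_mm"))
      if (is.null(r[[f]])) stopf("sectioning point missing field %s", f)
    registry_entry(r$code)
    mm <- as.numeric(r$mean_m_mm); mf <- as.numeric(r$mean_f_mm)
    sp <- as.numeric(r$sp_mm)
    if (abs(sp - (mm + mf) / 2) > sp_tolerance + 1e-12)
      stopf("sectioning point for %s (%.4f) is not the midpoint of its means (%.4f)",
            r$code, sp, (mm + mf) / 2)
    if (mm <= mf)
      stopf("sectioning point for %s: male mean not larger than female mean",
            r$code)
    structure(list(code = r$code, mean_m_mm = mm, mean_f_mm = mf,
                   sp_mm = sp,
                   n_m = r$n_m_train %||% r$n_m %||% NA_integer_,
                   n_f = r$n_f_train %||% r$n_f %||% NA_integer_,
                   reported = r$reported, bone = r$bone %||% NA_character_,
                   label = r$label %||% NA_character_),
              class = "sectioning_point")
  })
  names(sps) <- vapply(sps, `[[`, "", "code")
  if (anyDuplicated(names(sps))) stopf("duplicate sectioning point codes")

  models <- lapply(raw$models, function(r) {
    for (f in c("model_id", "bone", "variables", "coefficients",
                "intercept"))
      if (is.null(r[[f]])) stopf("model missing field %s", f)
    logistic_model(
      model_id = r$model_id, bone = r$bone,
      bone_label = r$bone_label %||% r$bone,
      variables = unlist(r$variables),
      coefficients = as.numeric(unlist(r$coefficients)),
      intercept = as.numeric(r$intercept),
      reported = r$reported, caution = r$caution)
  })
  names(models) <- vapply(models, function(m) as.character(m$model_id), "")

  bundle <- structure(
    list(name = raw$name, version = raw$version %||% NA_character_,
         source = raw$source %||% NA_character_,
         sectioning_points = sps, models = models,
         excluded_codes = raw$excluded_codes %||% list()),
    class = "standards_bundle")
  if (packaged) .osteosex_cache$bundle <- bundle
  bundle
}

#' @export
print.standards_bundle <- function(x, ...) {
  cat(sprintf("<standards_bundle '%s' v%s> %d sectioning points, %d logistic models\n",
              x$name, x$version, length(x$sectioning_points),
              length(x$models)))
  invisible(x)
}

#' Serialise a standards bundle to JSON
#'
#' Numeric values are written as decimal strings at full precision so that
#' a written bundle reloads bit-identically and repeated serialisations of
#' the same bundle are byte-identical.
#'
#' @param bundle a `standards_bundle`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_bundle <- function(bundle, path) {
  stopifnot(inherits(bundle, "standards_bundle"))
  num <- function(x) format(x, digits = 17, scientific = FALSE, trim = TRUE)
  sps <- lapply(unname(bundle$sectioning_points), function(s) {
    list(code = s$code, bone = s$bone, label = s$label,
         mean_m_mm = as.numeric(num(s$mean_m_mm)),
         mean_f_mm = as.numeric(num(s$mean_f_mm)),
         sp_mm = as.numeric(num(s$sp_mm)),
         n_m_train = s$n_m, n_f_train = s$n_f, reported = s$reported)
  })
  models <- lapply(unname(bundle$models), function(m) {
    list(model_id = m$model_id, bone = m$bone, bone_label = m$bone_label,
         variables = m$variables, coefficients = num(m$coefficients),
         intercept = num(m$intercept), reported = m$reported,
         caution = m$caution)
  })
  out <- list(name = bundle$name, version = bundle$version,
              source = bundle$source, unit = "mm",
              sectioning_points = sps, excluded_codes =
                bundle$excluded_codes, models = models)
  writeLines(jsonlite::toJSON(out, auto_unbox = TRUE, digits = NA,
                              null = "null", pretty = FALSE), path)
  invisible(path)
}
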