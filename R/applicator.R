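#' Estimate sex for one individual
#'
#' Applies every applicable standard in a bundle to one individual's
#' side-resolved measurements. A sectioning point is applicable when its
#' measurement is present; a logistic model when every one of its variables
#' is present (no imputation). Inapplicable standards are listed with the
#' missing codes. Each applied model reports p(male) alongside its
#' published test accuracy as a reliability cue. Per the source standards,
#' no default aggregation across bones is performed; an accuracy-weighted
#' majority vote across applied models is available behind `vote = TRUE`
#' as an extension.
#'
#' @param dataset an `osteo_dataset`.
#' @param individual_id the individual to report on.
#' @param bundle a `standards_bundle` (default: packaged Italian
#'   standards).
#' @param vote logical; add the optional aggregate vote.
#' @return object of class `sex_estimate_report`: `individual_id`,
#'   `univariate_calls` (data.frame code/value/sp/call), `model_results`
#'   (data.frame model_id/bone/z/p_male/call/reported test accuracy /
#'   caution), `inapplicable` (data.frame standard/reason), `summary`
#'   (call counts), optionally `vote`.
#' @export
estimate_individual <- function(dataset, individual_id,
                                bundle = load_bundle(), vote = FALSE) {
  stopifnot(inherits(dataset, "osteo_dataset"),
            inherits(bundle, "standards_bundle"))
  if (!individual_id %in% dataset$individuals$individual_id)
    stopf("unknown individual: %s", individual_id)
  codes <- unique(unlist(c(
    lapply(bundle$sectioning_points, `[[`, "code"),
    lapply(bundle$models, `[[`, "variables"))))
  wide <- resolved_values(dataset, codes)
  row <- wide[wide$individual_id == individual_id, , drop = FALSE]
  values <- unlist(row[1, codes, drop = TRUE])

  uni <- do.call(rbind, lapply(unname(bundle$sectioning_points),
                               function(s) {
    v <- values[[s$code]]
    if (is.na(v)) return(NULL)
    data.frame(code = s$code, value_mm = v, sp_mm = s$sp_mm,
               call = as.character(classify_univariate(v, s)),
               stringsAsFactors = FALSE)
  }))
  uni_missing <- vapply(unname(bundle$sectioning_points),
                        function(s) is.na(values[[s$code]]), TRUE)

  res <- list(); inapp <- list()
  for (m in unname(bundle$models)) {
    x <- values[m$variables]
    if (anyNA(x)) {
      inapp[[length(inapp) + 1L]] <- data.frame(
        standard = sprintf("model %s (%s)", m$model_id, m$bone_label),
        reason = sprintf("missing %s",
                         paste(m$variables[is.na(x)], collapse = ", ")),
        stringsAsFactors = FALSE)
      next
    }
    z <- sum(m$coefficients * as.numeric(x)) + m$intercept
    p <- male_probability(z)
    res[[length(res) + 1L]] <- data.frame(
      model_id = m$model_id, bone = m$bone_label, z = z,
      p_male = p$p_male, call = as.character(p$call),
      reported_test_acc_pct =
        (m$reported$test$acc_t_pct %||% NA_real_),
      caution = m$caution %||% NA_character_,
      stringsAsFactors = FALSE)
  }
  for (s in unname(bundle$sectioning_points)[uni_missing]) {
    inapp[[length(inapp) + 1L]] <- data.frame(
      standard = sprintf("sectioning point %s", s$code),
      reason = "measurement absent", stringsAsFactors = FALSE)
  }
  model_results <- if (length(res)) do.call(rbind, res) else
    data.frame(model_id = integer(), bone = character(), z = numeric(),
               p_male = numeric(), call = character(),
               reported_test_acc_pct = numeric(), caution = character(),
               stringsAsFactors = FALSE)
  inapplicable <- if (length(inapp)) do.call(rbind, inapp) else
    data.frame(standard = character(), reason = character(),
               stringsAsFactors = FALSE)
  calls <- c(if (!is.null(uni)) uni$call, model_results$call)
  summary <- list(
    n_univariate_applied = if (is.null(uni)) 0L else nrow(uni),
    n_models_applied = nrow(model_results),
    n_inapplicable = nrow(inapplicable),
    calls = c(male = sum(calls == "male"),
              female = sum(calls == "female"),
              indeterminate = sum(calls == "indeterminate")))
  out <- list(individual_id = individual_id,
              univariate_calls = uni %||% data.frame(
                code = character(), value_mm = numeric(),
                sp_mm = numeric(), call = character(),
                stringsAsFactors = FALSE),
              model_results = model_results,
              inapplicable = inapplicable, summary = summary)
  if (vote) out$vote <- accuracy_weighted_vote(model_results)
  structure(out, class = "sex_estimate_report")
}

# optional extension: accuracy-weighted majority vote over applied models
accuracy_weighted_vote <- function(model_results) {
  if (!nrow(model_results)) return(list(call = "none", weight_male = NA))
  w <- model_results$reported_test_acc_pct
  w[is.na(w)] <- 50
  wm <- sum(w[model_results$call == "male"])
  wf <- sum(w[model_results$call == "female"])
  list(call = if (wm > wf) "male" else if (wf > wm) "female"
              else "indeterminate",
       weight_male = wm / (wm + wf))
}

#' @export
print.sex_estimate_report <- function(x, ...) {
  cat(sprintf("<sex_estimate_report %s> %d SP calls, %d models applied, %d standards inapplicable\n",
              x$individual_id, x$summary$n_univariate_applied,
              x$summary$n_models_applied, x$summary$n_inapplicable))
  cat(sprintf("  calls: %d male / %d female / %d indeterminate\n",
              x$summary$calls[["male"]], x$summary$calls[["female"]],
              x$summary$calls[["indeterminate"]]))
  invisible(x)
}

#' Serialise a report to JSON
#'
#' @param report a `sex_estimate_report`.
#' @param path optional output file; when `NULL` the JSON string is
#'   returned.
#' @return JSON string or `path` invisibly.
#' @export
report_to_json <- function(report, path = NULL) {
  stopifnot(inherits(report, "sex_estimate_report"))
  j <- jsonlite::toJSON(unclass(report), auto_unbox = TRUE, digits = NA,
                        null = "null")
  if (is.null(path)) return(j)
  writeLines(j, path)
  invisible(path)
}

#' Estimate sex for every individual in a dataset
#'
#' Maps [estimate_individual()] over the dataset in its stored order and
#' tabulates a cohort summary of calls per standard.
#'
#' @inheritParams estimate_individual
#' @return list with `reports` (named list of `sex_estimate_report`) and
#'   `cohort_summary` (data.frame standard/n_applied/n_male/n_female/
#'   n_indeterminate).
#' @export
estimate_batch <- function(dataset, bundle = load_bundle(), vote = FALSE) {
  ids <- dataset$individuals$individual_id
  reports <- lapply(ids, estimate_individual, dataset = dataset,
                    bundle = bundle, vote = vote)
  names(reports) <- ids
  tab <- list()
  add <- function(standard, call) {
    row <- tab[[standard]] %||% c(male = 0L, female = 0L,
                                  indeterminate = 0L)
    row[[call]] <- row[[call]] + 1L
    tab[[standard]] <<- row
  }
  for (r in reports) {
    if (nrow(r$univariate_calls))
      for (i in seq_len(nrow(r$univariate_calls)))
        add(paste0("SP ", r$univariate_calls$code[i]),
            r$univariate_calls$call[i])
    if (nrow(r$model_results))
      for (i in seq_len(nrow(r$model_results)))
        add(sprintf("model %s", r$model_results$model_id[i]),
            r$model_results$call[i])
  }
  cohort <- data.frame(
    standard = names(tab),
    n_applied = vapply(tab, sum, 0L),
    n_male = vapply(tab, `[[`, 0L, "male"),
    n_female = vapply(tab, `[[`, 0L, "female"),
    n_indeterminate = vapply(tab, `[[`, 0L, "indeterminate"),
    stringsAsFactors = FALSE)
  rownames(cohort) <- NULL
  list(reports = reports, cohort_summary = cohort)
}
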