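# fixture builders shared across test files; everything is generated in
# code, nothing is read from disk

# dataset from a wide data.frame (individual_id, sex, V* columns)
toy_dataset <- function(wide) {
  codes <- setdiff(names(wide), c("individual_id", "sex", "age_years"))
  reg <- osteo_registry()
  obs <- do.call(rbind, lapply(codes, function(code) {
    keep <- !is.na(wide[[code]])
    if (!any(keep)) return(NULL)
    bilateral <- reg$bilateral[match(code, reg$code)]
    data.frame(individual_id = wide$individual_id[keep], code = code,
               side = if (bilateral) "left" else "midline",
               value_mm = wide[[code]][keep], stringsAsFactors = FALSE)
  }))
  osteo_dataset(
    data.frame(individual_id = wide$individual_id, sex = wide$sex,
               age_years = wide$age_years %||% NA_real_,
               stringsAsFactors = FALSE),
    obs)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# two-sex single-measurement dataset with prescribed values
two_sex_dataset <- function(values_m, values_f, code = "V1") {
  df <- data.frame(
    individual_id = c(sprintf("m%03d", seq_along(values_m)),
                      sprintf("f%03d", seq_along(values_f))),
    sex = rep(c("M", "F"), c(length(values_m), length(values_f))),
    stringsAsFactors = FALSE)
  df[[code]] <- c(values_m, values_f)
  toy_dataset(df)
}

# independent spreadsheet-style reliability oracle: TEM via mean
# within-pair variance (var of two values = d^2/2), s^2 via stats::var
oracle_reliability <- function(a, b) {
  within <- apply(cbind(a, b), 1, stats::var)   # d_i^2 / 2
  tem <- sqrt(mean(within))
  all <- c(a, b)
  list(tem = tem, rtem = 100 * tem / mean(all),
       r = 1 - tem^2 / stats::var(all))
}

# exhaustive enumeration oracle for classification metrics
oracle_metrics <- function(truth, call, averaging) {
  correct_m <- 0; correct_f <- 0; n_m <- 0; n_f <- 0
  for (i in seq_along(truth)) {
    if (truth[i] == "M") {
      n_m <- n_m + 1
      if (!is.na(call[i]) && call[i] == "male") correct_m <- correct_m + 1
    } else if (truth[i] == "F") {
      n_f <- n_f + 1
      if (!is.na(call[i]) && call[i] == "female")
        correct_f <- correct_f + 1
    }
  }
  am <- 100 * correct_m / n_m; af <- 100 * correct_f / n_f
  at <- if (averaging == "balanced") (am + af) / 2 else
    100 * (correct_m + correct_f) / (n_m + n_f)
  list(acc_m = am, acc_f = af, acc_t = at, bias = am - af)
}
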