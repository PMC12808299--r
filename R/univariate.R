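#' Screen a measurement for sexual dimorphism
#'
#' Tests for a male-female difference in one measurement. Normality is
#' assessed per sex with the Shapiro-Wilk test at alpha = 0.05; when both
#' sexes are compatible with normality an independent (pooled-variance)
#' Student's t-test is used, otherwise a Mann-Whitney U test. The direction
#' of dimorphism is taken from the sign of mean(M) - mean(F).
#'
#' @param dataset an `osteo_dataset` with known sexes.
#' @param code measurement code to screen.
#' @param alpha significance level (default 0.05).
#' @return list of class `dimorphism_screen`: `code`, `n_m`, `n_f`,
#'   `normal_m`, `normal_f`, `test_used` (`"student_t"` or
#'   `"mann_whitney"`), `p_value`, `significant`, `direction`
#'   (`"male_larger"` / `"female_larger"`), `mean_m`, `mean_f`, and
#'   `testable` (FALSE when a sex has fewer than 3 values).
#' @export
screen_dimorphism <- function(dataset, code, alpha = 0.05) {
  wide <- resolved_values(dataset, code)
  vm <- wide[[code]][wide$sex == "M"]; vm <- vm[!is.na(vm)]
  vf <- wide[[code]][wide$sex == "F"]; vf <- vf[!is.na(vf)]
  out <- list(code = code, n_m = length(vm), n_f = length(vf),
              mean_m = mean(vm), mean_f = mean(vf))
  if (length(vm) < 3 || length(vf) < 3) {
    out$testable <- FALSE
    out$significant <- FALSE
    return(structure(out, class = "dimorphism_screen"))
  }
  # shapiro.test accepts 3..5000 values; larger samples are truncated to
  # the first 5000 (ample power at that size)
  sw <- function(v) {
    if (length(v) > 5000) v <- v[seq_len(5000)]
    if (stats::sd(v) == 0) return(FALSE)
    stats::shapiro.test(v)$p.value >= alpha
  }
  out$normal_m <- sw(vm); out$normal_f <- sw(vf)
  if (out$normal_m && out$normal_f) {
    out$test_used <- "student_t"
    out$p_value <- stats::t.test(vm, vf, var.equal = TRUE)$p.value
  } else {
    out$test_used <- "mann_whitney"
    out$p_value <- stats::wilcox.test(vm, vf, exact = FALSE)$p.value
  }
  out$testable <- TRUE
  out$significant <- out$p_value < alpha
  out$direction <- if (out$mean_m >= out$mean_f) "male_larger"
                   else "female_larger"
  structure(out, class = "dimorphism_screen")
}

#' Derive a univariate sectioning point
#'
#' The sectioning point is the midpoint of the male and female training
#' means: SP = (mean_M + mean_F) / 2. Only measurements that screen as
#' significantly dimorphic with males larger are eligible; female-larger
#' measurements (pubis, ischiopubic ramus, sacral breadth in the reference
#' collection) are excluded from single-variable standards.
#'
#' @param train an `osteo_dataset` (training subset) with known sexes.
#' @param code measurement code.
#' @param screen optional precomputed [screen_dimorphism()] result; when
#'   supplied and not significant/male-larger the derivation refuses.
#' @return list of class `sectioning_point`: `code`, `mean_m_mm`,
#'   `mean_f_mm`, `sp_mm` (full precision), `n_m`, `n_f`.
#' @export
derive_sectioning_point <- function(train, code, screen = NULL) {
  if (!is.null(screen)) {
    if (!isTRUE(screen$significant))
      stopf("refusing to derive a sectioning point for %s: not significantly dimorphic",
            code)
    if (!identical(screen$direction, "male_larger"))
      stopf("refusing to derive a sectioning point for %s: females larger",
            code)
  }
  wide <- resolved_values(train, code)
  vm <- wide[[code]][wide$sex == "M"]; vm <- vm[!is.na(vm)]
  vf <- wide[[code]][wide$sex == "F"]; vf <- vf[!is.na(vf)]
  if (!length(vm) || !length(vf))
    stopf("need values for both sexes to derive a sectioning point for %s",
          code)
  mm <- mean(vm); mf <- mean(vf)
  structure(list(code = code, mean_m_mm = mm, mean_f_mm = mf,
                 sp_mm = (mm + mf) / 2, n_m = length(vm),
                 n_f = length(vf), degenerate = mm <= mf),
            class = "sectioning_point")
}

#' Classify a measurement value against a sectioning point
#'
#' Values above the sectioning point are classified male, below female, and
#' exactly equal indeterminate. Missing values give no call (`NA`).
#'
#' @param value_mm numeric vector of measurement values in mm.
#' @param standard a `sectioning_point` (or any list with `sp_mm`), or a
#'   single numeric sectioning point.
#' @return factor with levels `male`, `female`, `indeterminate`.
#' @export
classify_univariate <- function(value_mm, standard) {
  sp <- if (is.numeric(standard)) standard[[1L]] else standard$sp_mm
  out <- ifelse(is.na(value_mm), NA_character_,
         ifelse(value_mm > sp, "male",
         ifelse(value_mm < sp, "female", "indeterminate")))
  factor(out, levels = c("male", "female", "indeterminate"))
}

#' Per-sex classification metrics
#'
#' Computes the percentage of correct classifications per sex, the overall
#' rate, and the class discrimination bias (%M - %F). Indeterminate and
#' missing calls count as incorrect. With `averaging = "balanced"` the
#' overall rate is the mean of the two sex-specific rates; `"pooled"`
#' divides total correct by total classified individuals.
#'
#' @param truth character/factor of true sexes (`"M"`/`"F"`).
#' @param call factor of calls from [classify_univariate()] or a logistic
#'   model (`male`/`female`/`indeterminate`, `NA` = no call).
#' @param averaging `"balanced"` (default) or `"pooled"`.
#' @return list of class `classification_metrics`: `acc_m_pct`,
#'   `acc_f_pct`, `acc_t_pct`, `cd_bias_pct`, `n_m`, `n_f`,
#'   `n_indeterminate`, `bias_acceptable` (|bias| within 5 points),
#'   `averaging`.
#' @export
classification_metrics <- function(truth, call,
                                   averaging = c("balanced", "pooled")) {
  averaging <- match.arg(averaging)
  keep <- truth %in% c("M", "F")
  truth <- truth[keep]; call <- call[keep]
  n_m <- sum(truth == "M"); n_f <- sum(truth == "F")
  ok_m <- sum(truth == "M" & !is.na(call) & call == "male")
  ok_f <- sum(truth == "F" & !is.na(call) & call == "female")
  acc_m <- if (n_m) 100 * ok_m / n_m else NA_real_
  acc_f <- if (n_f) 100 * ok_f / n_f else NA_real_
  acc_t <- if (averaging == "balanced") mean(c(acc_m, acc_f))
           else if (n_m + n_f) 100 * (ok_m + ok_f) / (n_m + n_f)
           else NA_real_
  bias <- acc_m - acc_f
  structure(list(acc_m_pct = acc_m, acc_f_pct = acc_f, acc_t_pct = acc_t,
                 cd_bias_pct = bias, n_m = n_m, n_f = n_f,
                 n_indeterminate =
                   sum(!is.na(call) & call == "indeterminate"),
                 bias_acceptable = is.finite(bias) && abs(bias) <= 5,
                 averaging = averaging),
            class = "classification_metrics")
}

#' @export
print.classification_metrics <- function(x, ...) {
  cat(sprintf(
    "%%T %.1f  %%M %.1f (n=%d)  %%F %.1f (n=%d)  CD bias %+.1f [%s]\n",
    x$acc_t_pct, x$acc_m_pct, x$n_m, x$acc_f_pct, x$n_f, x$cd_bias_pct,
    x$averaging))
  invisible(x)
}

#' Evaluate a sectioning point on a dataset
#'
#' @param dataset an `osteo_dataset` with known sexes.
#' @param standard a `sectioning_point` standard.
#' @param averaging `"balanced"` or `"pooled"`; see
#'   [classification_metrics()].
#' @return a `classification_metrics` object (individuals lacking the
#'   measurement are excluded).
#' @export
evaluate_univariate <- function(dataset, standard,
                                averaging = c("balanced", "pooled")) {
  averaging <- match.arg(averaging)
  wide <- resolved_values(dataset, standard$code)
  v <- wide[[standard$code]]
  keep <- !is.na(v) & wide$sex %in% c("M", "F")
  classification_metrics(wide$sex[keep],
                         classify_univariate(v[keep], standard),
                         averaging)
}
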