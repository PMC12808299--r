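#' Repeat-measurement pair set
#'
#' Holds the two determinations of one measurement for a set of individuals
#' (or individual sides), aligned pairwise, for technical error of
#' measurement analysis.
#'
#' @param session1,session2 numeric vectors of equal length, in mm; element
#'   i of each is the same individual/side measured twice.
#' @param code measurement code the pairs belong to (optional, for
#'   reporting).
#' @return an object of class `repeat_pairs`.
#' @export
repeat_pairs <- function(session1, session2, code = NA_character_) {
  if (length(session1) != length(session2))
    stopf("sessions must be aligned pairwise (lengths %d and %d)",
          length(session1), length(session2))
  if (!length(session1)) stopf("empty repeat pair set")
  assert_positive_finite(session1, "session1")
  assert_positive_finite(session2, "session2")
  structure(list(session1 = as.numeric(session1),
                 session2 = as.numeric(session2),
                 code = code, n = length(session1)),
            class = "repeat_pairs")
}

#' Technical error of measurement
#'
#' TEM = sqrt( sum(d_i^2) / (2N) ) where d_i is the difference between the
#' two determinations for pair i. Absolute measurement-error magnitude in
#' the unit of the measurements (mm).
#'
#' @param pairs a [repeat_pairs()] object.
#' @return TEM in mm.
#' @export
tem <- function(pairs) {
  stopifnot(inherits(pairs, "repeat_pairs"))
  d <- pairs$session1 - pairs$session2
  sqrt(sum(d^2) / (2 * pairs$n))
}

#' Relative technical error of measurement
#'
#' rTEM = 100 * TEM / grand mean of all 2N values; a scale-free precision
#' index in percent.
#'
#' @inheritParams tem
#' @return rTEM in percent.
#' @export
rtem <- function(pairs) {
  stopifnot(inherits(pairs, "repeat_pairs"))
  gm <- mean(c(pairs$session1, pairs$session2))
  if (!is.finite(gm) || gm <= 0) stopf("grand mean must be positive")
  100 * tem(pairs) / gm
}

#' Reliability coefficient
#'
#' R = 1 - TEM^2 / s^2, where s^2 is the sample variance (denominator
#' 2N - 1) of all 2N raw values. R is the fraction of total variance not
#' attributable to measurement error; 1 is perfectly reliable. R can be
#' negative in degenerate designs with no between-subject variance; it is
#' reported as computed, never clamped.
#'
#' @inheritParams tem
#' @return R (at most 1).
#' @export
reliability_coefficient <- function(pairs) {
  stopifnot(inherits(pairs, "repeat_pairs"))
  if (pairs$n < 2) stopf("R needs at least 2 pairs")
  t2 <- tem(pairs)^2
  s2 <- stats::var(c(pairs$session1, pairs$session2))
  if (s2 == 0) {
    if (t2 == 0) return(1)               # all values identical
    stopf("zero total variance with non-zero TEM")
  }
  1 - t2 / s2
}

#' Multi-session technical error of measurement
#'
#' Generalisation of [tem()] to K >= 2 determinations per individual:
#' TEM = sqrt( sum_i sum_k (x_ik - xbar_i)^2 / (N (K - 1)) ). With K = 2
#' this reduces to the two-session formula. Provided as an extension; the
#' packaged standards were developed with exactly two determinations.
#'
#' @param x numeric matrix, one row per individual, one column per session.
#' @return TEM in mm.
#' @export
tem_multi <- function(x) {
  x <- as.matrix(x)
  if (ncol(x) < 2) stopf("need at least 2 sessions")
  assert_positive_finite(as.numeric(x), "measurements")
  dev <- x - rowMeans(x)
  sqrt(sum(dev^2) / (nrow(x) * (ncol(x) - 1)))
}

#' Assess reliability against acceptability thresholds
#'
#' Flags rTEM at the study thresholds (< 1.5% intra-observer, < 2.0%
#' inter-observer) and the broader < 5% literature bound, and R at the
#' > 0.95 standard. Assessment is advisory: no measurement is excluded
#' automatically.
#'
#' @param rtem_pct relative TEM in percent.
#' @param r_coef reliability coefficient, or `NA` if not computed.
#' @param context `"intra"` or `"inter"` observer comparison.
#' @return list with the threshold used and logical flags `flag_rtem`
#'   (rTEM at or above the context threshold), `flag_rtem_5pct` and
#'   `flag_r` (R at or below 0.95).
#' @export
assess_reliability <- function(rtem_pct, r_coef = NA_real_,
                               context = c("intra", "inter")) {
  context <- match.arg(context)
  thr <- if (context == "intra") 1.5 else 2.0
  list(context = context, rtem_threshold_pct = thr,
       flag_rtem = rtem_pct >= thr,
       flag_rtem_5pct = rtem_pct >= 5,
       flag_r = !is.na(r_coef) & r_coef <= 0.95)
}

#' Reliability summary table for repeat-measurement data
#'
#' Computes n, TEM, rTEM and R per measurement code from a long table of
#' repeat determinations and attaches the acceptability flags.
#'
#' @param repeats data.frame with columns `individual_id`, `code`,
#'   `session` (1 or 2), `value_mm`, and optionally `side`. Each
#'   (individual, side) is one pair.
#' @param context `"intra"` or `"inter"`.
#' @return data.frame with one row per code: `code`, `n`, `tem_mm`,
#'   `rtem_pct`, `r_coef`, `flag_rtem`, `flag_r`.
#' @export
reliability_summary <- function(repeats, context = c("intra", "inter")) {
  context <- match.arg(context)
  need <- c("individual_id", "code", "session", "value_mm")
  if (!all(need %in% names(repeats)))
    stopf("repeats needs columns %s", paste(need, collapse = ", "))
  if (is.null(repeats$side)) repeats$side <- "unsided"
  out <- lapply(split(repeats, repeats$code), function(sub) {
    key <- paste(sub$individual_id, sub$side)
    s1 <- sub[sub$session == 1, ]; s2 <- sub[sub$session == 2, ]
    common <- intersect(paste(s1$individual_id, s1$side),
                        paste(s2$individual_id, s2$side))
    if (!length(common)) return(NULL)
    v1 <- s1$value_mm[match(common, paste(s1$individual_id, s1$side))]
    v2 <- s2$value_mm[match(common, paste(s2$individual_id, s2$side))]
    p <- repeat_pairs(v1, v2, code = sub$code[[1L]])
    r <- if (p$n >= 2) reliability_coefficient(p) else NA_real_
    rt <- rtem(p)
    fl <- assess_reliability(rt, r, context)
    data.frame(code = p$code, n = p$n, tem_mm = tem(p), rtem_pct = rt,
               r_coef = r, flag_rtem = fl$flag_rtem, flag_r = fl$flag_r,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out <- out[order(match(out$code, osteo_registry()$code)), , drop = FALSE]
  rownames(out) <- NULL
  out
}
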