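#' Osteometric dataset
#'
#' Container for individuals and their postcranial measurement observations.
#' Observations are stored long (one row per individual, code, side); use
#' [resolved_values()] for the side-resolved wide view used by all analyses.
#'
#' @param individuals data.frame with columns `individual_id` (character,
#'   unique), `sex` (`"M"`, `"F"` or `"unknown"`) and optionally `age_years`.
#' @param observations data.frame with columns `individual_id`, `code`,
#'   `side` (`"left"`, `"right"`, `"midline"` or `"unsided"` for
#'   pre-resolved imports) and `value_mm` (positive, finite).
#' @param registry measurement registry; defaults to the packaged 121-entry
#'   registry.
#'
#' @details Midline sides are only valid for unpaired elements (vertebrae,
#' sternum, sacrum) and left/right only for paired ones. Values must be
#' strictly positive and finite; pathology- or callus-affected measurements
#' are an upstream data-entry exclusion, not enforced here. At most one
#' observation per (individual, code, side) is allowed and sides are never
#' averaged.
#'
#' @return An object of class `osteo_dataset`.
#' @export
osteo_dataset <- function(individuals,
                          observations = NULL,
                          registry = osteo_registry()) {
  individuals <- as.data.frame(individuals, stringsAsFactors = FALSE)
  if (!all(c("individual_id", "sex") %in% names(individuals)))
    stopf("individuals needs columns individual_id and sex")
  individuals$individual_id <- as.character(individuals$individual_id)
  if (anyDuplicated(individuals$individual_id))
    stopf("duplicated individual_id in individuals table")
  bad_sex <- !individuals$sex %in% c("M", "F", "unknown")
  if (any(bad_sex))
    stopf("sex must be 'M', 'F' or 'unknown' (rows %s)",
          paste(utils::head(which(bad_sex), 10L), collapse = ", "))
  if (is.null(individuals$age_years))
    individuals$age_years <- rep(NA_real_, nrow(individuals))

  if (is.null(observations)) {
    observations <- data.frame(individual_id = character(),
                               code = character(), side = character(),
                               value_mm = numeric(),
                               stringsAsFactors = FALSE)
  }
  observations <- as.data.frame(observations, stringsAsFactors = FALSE)
  need <- c("individual_id", "code", "side", "value_mm")
  if (!all(need %in% names(observations)))
    stopf("observations needs columns %s", paste(need, collapse = ", "))
  observations <- observations[need]
  observations$individual_id <- as.character(observations$individual_id)

  if (nrow(observations)) {
    unknown_id <- !observations$individual_id %in% individuals$individual_id
    if (any(unknown_id))
      stopf("observations reference unknown individuals: %s",
            paste(unique(observations$individual_id[unknown_id]),
                  collapse = ", "))
    entry <- registry_entry(observations$code)  # errors on unknown codes
    bad_side <- !observations$side %in%
      c("left", "right", "midline", "unsided")
    if (any(bad_side))
      stopf("invalid side values: %s",
            paste(unique(observations$side[bad_side]), collapse = ", "))
    mid_on_paired <- observations$side == "midline" & entry$bilateral
    if (any(mid_on_paired))
      stopf("side 'midline' used for paired elements (rows %s)",
            paste(utils::head(which(mid_on_paired), 10L), collapse = ", "))
    lr_on_midline <- observations$side %in% c("left", "right") &
      !entry$bilateral
    if (any(lr_on_midline))
      stopf("left/right side used for midline elements (rows %s)",
            paste(utils::head(which(lr_on_midline), 10L), collapse = ", "))
    assert_positive_finite(observations$value_mm, "value_mm")
    key <- paste(observations$individual_id, observations$code,
                 observations$side)
    if (anyDuplicated(key))
      stopf("duplicate (individual, code, side) observations: %s",
            paste(utils::head(unique(key[duplicated(key)]), 5L),
                  collapse = "; "))
  }

  structure(list(individuals = individuals, observations = observations,
                 registry = registry),
            class = "osteo_dataset")
}

#' @export
print.osteo_dataset <- function(x, ...) {
  sc <- sex_counts(x)
  cat(sprintf(
    "<osteo_dataset> %d individuals (%d M / %d F / %d unknown), %d observations on %d measurements\n",
    nrow(x$individuals), sc[["M"]], sc[["F"]], sc[["unknown"]],
    nrow(x$observations), length(unique(x$observations$code))))
  invisible(x)
}

#' Count individuals per sex
#'
#' @param x an `osteo_dataset`.
#' @return named integer vector with entries `M`, `F` and `unknown`.
#' @export
sex_counts <- function(x) {
  stopifnot(inherits(x, "osteo_dataset"))
  out <- table(factor(x$individuals$sex, levels = c("M", "F", "unknown")))
  stats::setNames(as.integer(out), names(out))
}

#' Resolve laterality for one measurement of one individual
#'
#' Returns the left-side value when present, otherwise the right-side value,
#' otherwise the midline/unsided value; sides are never averaged. This is
#' the left-preferred laterality rule under which the packaged standards
#' were developed.
#'
#' @param x an `osteo_dataset`.
#' @param individual_id individual identifier.
#' @param code measurement code.
#' @return the value in mm, or `NA_real_` when the element is absent.
#' @export
resolve_side <- function(x, individual_id, code) {
  stopifnot(inherits(x, "osteo_dataset"))
  registry_entry(code)
  obs <- x$observations
  obs <- obs[obs$individual_id == individual_id & obs$code == code, ,
             drop = FALSE]
  for (s in c("left", "right", "midline", "unsided")) {
    hit <- obs$value_mm[obs$side == s]
    if (length(hit)) return(hit[[1L]])
  }
  NA_real_
}

#' Side-resolved wide view of a dataset
#'
#' @param x an `osteo_dataset`.
#' @param codes measurement codes to include; defaults to every code with at
#'   least one observation, in registry order.
#' @return data.frame with `individual_id`, `sex`, `age_years` and one
#'   numeric column per code (NA = element absent).
#' @export
resolved_values <- function(x, codes = NULL) {
  stopifnot(inherits(x, "osteo_dataset"))
  if (is.null(codes)) {
    codes <- intersect(x$registry$code, unique(x$observations$code))
  } else {
    registry_entry(codes)
  }
  out <- x$individuals[c("individual_id", "sex", "age_years")]
  obs <- x$observations
  # order encodes side preference: left < right < midline < unsided
  pref <- match(obs$side, c("left", "right", "midline", "unsided"))
  obs <- obs[order(obs$individual_id, obs$code, pref), , drop = FALSE]
  obs <- obs[!duplicated(paste(obs$individual_id, obs$code)), , drop = FALSE]
  for (code in codes) {
    sub <- obs[obs$code == code, , drop = FALSE]
    out[[code]] <- sub$value_mm[match(out$individual_id, sub$individual_id)]
  }
  rownames(out) <- NULL
  out
}

#' Read an osteometric dataset from CSV
#'
#' Two layouts are supported. `wide`: columns `individual_id`, `sex`,
#' optionally `age_years`, then one column per measurement code holding
#' side-resolved values (stored with side `"unsided"` for paired elements).
#' `long`: columns `individual_id`, `sex`, `age_years` (optional), `code`,
#' `side`, `value_mm`, fully preserving laterality.
#'
#' Missing values are empty cells. Non-numeric or non-positive measurement
#' values are rejected with row-level diagnostics, as are duplicate
#' (individual, code, side) entries.
#'
#' @param path CSV file path (UTF-8, comma separator, dot decimal).
#' @param layout `"wide"` or `"long"`.
#' @param registry measurement registry.
#' @return an [osteo_dataset()].
#' @export
read_osteo_csv <- function(path, layout = c("wide", "long"),
                           registry = osteo_registry()) {
  layout <- match.arg(layout)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character", check.names = FALSE)
  if (!all(c("individual_id", "sex") %in% names(raw)))
    stopf("malformed header in %s: need individual_id and sex", path)
  parse_num <- function(txt, where) {
    txt <- trimws(txt)
    miss <- is.na(txt) | txt == ""
    val <- suppressWarnings(as.numeric(txt))
    bad <- !miss & (is.na(val) | val <= 0 | !is.finite(val))
    if (any(bad))
      stopf("non-numeric or non-positive values in %s: %s", path,
            paste(utils::head(where[bad], 10L), collapse = "; "))
    val
  }
  age <- if ("age_years" %in% names(raw))
    suppressWarnings(as.numeric(raw$age_years)) else NA_real_

  if (layout == "wide") {
    codes <- intersect(registry$code, names(raw))
    if (!length(codes))
      stopf("no measurement columns (V1..V121) found in %s", path)
    individuals <- data.frame(individual_id = raw$individual_id,
                              sex = raw$sex, age_years = age,
                              stringsAsFactors = FALSE)
    obs <- NULL
    for (code in codes) {
      val <- parse_num(raw[[code]],
                       sprintf("row %d column %s", seq_len(nrow(raw)), code))
      keep <- !is.na(val)
      if (!any(keep)) next
      bilateral <- registry$bilateral[match(code, registry$code)]
      obs <- rbind(obs, data.frame(
        individual_id = raw$individual_id[keep], code = code,
        side = if (bilateral) "unsided" else "midline",
        value_mm = val[keep], stringsAsFactors = FALSE))
    }
  } else {
    need <- c("code", "side", "value_mm")
    if (!all(need %in% names(raw)))
      stopf("malformed header in %s: long layout needs %s", path,
            paste(need, collapse = ", "))
    val <- parse_num(raw$value_mm, sprintf("row %d", seq_len(nrow(raw))))
    keep <- !is.na(val)
    first <- !duplicated(raw$individual_id)
    individuals <- data.frame(individual_id = raw$individual_id[first],
                              sex = raw$sex[first],
                              age_years = age[first],
                              stringsAsFactors = FALSE)
    obs <- data.frame(individual_id = raw$individual_id[keep],
                      code = raw$code[keep], side = raw$side[keep],
                      value_mm = val[keep], stringsAsFactors = FALSE)
  }
  osteo_dataset(individuals, obs, registry)
}

#' Write an osteometric dataset to CSV
#'
#' The long layout is lossless (all sides preserved); the wide layout writes
#' the side-resolved view. `read_osteo_csv(write_osteo_csv(x))` restores the
#' dataset exactly for the long layout, and the resolved view exactly for
#' the wide layout.
#'
#' @param x an `osteo_dataset`.
#' @param path output file path.
#' @param layout `"wide"` or `"long"`.
#' @return `path`, invisibly.
#' @export
write_osteo_csv <- function(x, path, layout = c("wide", "long")) {
  layout <- match.arg(layout)
  stopifnot(inherits(x, "osteo_dataset"))
  if (layout == "wide") {
    out <- resolved_values(x)
  } else {
    out <- merge(x$individuals, x$observations, by = "individual_id",
                 all.x = TRUE, sort = FALSE)
    out <- out[order(match(out$individual_id, x$individuals$individual_id),
                     match(out$code, x$registry$code), out$side), ]
    out <- out[c("individual_id", "sex", "age_years", "code", "side",
                 "value_mm")]
  }
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}
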