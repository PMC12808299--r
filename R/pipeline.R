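#' Stratified train/test split
#'
#' Randomly partitions individuals of each sex at the given fraction,
#' reproducibly from a seed. The per-sex training count is
#' `round(fraction * n_sex)`; with 200 per sex and the default 0.75 this
#' yields 150 training and 50 test individuals per sex.
#'
#' @param dataset an `osteo_dataset` with known sexes (individuals of
#'   unknown sex are refused).
#' @param train_fraction fraction in (0, 1); default 0.75.
#' @param seed integer seed.
#' @return list with `train` and `test` (`osteo_dataset`s); disjoint and
#'   exhaustive.
#' @export
stratified_split <- function(dataset, train_fraction = 0.75, seed = 1L) {
  stopifnot(inherits(dataset, "osteo_dataset"),
            train_fraction > 0, train_fraction < 1)
  sexes <- dataset$individuals$sex
  if (any(sexes == "unknown"))
    stopf("stratified_split needs known sexes for all individuals")
  if (any(table(factor(sexes, levels = c("M", "F"))) < 2))
    stopf("need at least 2 individuals per sex to split")
  train_ids <- with_seed(seed, {
    unlist(lapply(c("M", "F"), function(s) {
      ids <- dataset$individuals$individual_id[sexes == s]
      sample(ids, round(train_fraction * length(ids)))
    }))
  })
  subset_ids <- function(ids) {
    osteo_dataset(
      dataset$individuals[dataset$individuals$individual_id %in% ids, ],
      dataset$observations[
        dataset$observations$individual_id %in% ids, ],
      dataset$registry)
  }
  list(train = subset_ids(train_ids),
       test = subset_ids(setdiff(dataset$individuals$individual_id,
                                 train_ids)))
}

#' Develop osteometric sex-estimation standards from a dataset
#'
#' Runs the full standards-development workflow: stratified 75/25 split;
#' per-measurement dimorphism screening on the training subset (excluding
#' non-significant and female-larger measurements); sectioning-point
#' derivation from the training means; evaluation of every sectioning
#' point on both subsets; bone-wise complete-case logistic fits (one model
#' per bone over its screened variables, skipping metacarpals and
#' metatarsals, which carry a single length measurement each); and model
#' evaluation on both subsets.
#'
#' Stage seeds are derived from the master seed by fixed offsets (split =
#' seed, fitting is deterministic), so reruns with identical input and
#' seed emit byte-identical bundles.
#'
#' No multiple-testing correction is applied across screens by default
#' (matching the reference protocol); `p_adjust = "holm"` is available as
#' an extension.
#'
#' @param dataset an `osteo_dataset` with known sexes.
#' @param train_fraction passed to [stratified_split()].
#' @param seed master seed.
#' @param min_per_sex minimum complete cases per sex for a bone model.
#' @param model_specs optional named list `bone = c(codes)` overriding the
#'   default one-model-per-bone variable sets.
#' @param p_adjust `"none"` (default) or `"holm"`.
#' @param averaging accuracy averaging mode for the report.
#' @param name bundle name.
#' @return list with `bundle` (a `standards_bundle` that validates under
#'   [load_bundle()] round-trip), `report` (data.frames `screen`,
#'   `sectioning_points`, `models`) and `provenance` (seed, counts).
#' @export
develop_standards <- function(dataset, train_fraction = 0.75, seed = 1L,
                              min_per_sex = 10, model_specs = NULL,
                              p_adjust = c("none", "holm"),
                              averaging = c("balanced", "pooled"),
                              name = "developed-standards") {
  p_adjust <- match.arg(p_adjust)
  averaging <- match.arg(averaging)
  split <- stratified_split(dataset, train_fraction, seed)
  train <- split$train; test <- split$test
  codes <- intersect(dataset$registry$code,
                     unique(train$observations$code))

  screens <- lapply(codes, function(code) screen_dimorphism(train, code))
  names(screens) <- codes
  pvals <- vapply(screens, function(s) s$p_value %||% NA_real_, 0)
  if (p_adjust == "holm") {
    adj <- stats::p.adjust(pvals, "holm")
    for (i in seq_along(screens)) {
      screens[[i]]$p_value_adjusted <- adj[[i]]
      screens[[i]]$significant <- isTRUE(adj[[i]] < 0.05)
    }
  }
  screen_tab <- do.call(rbind, lapply(screens, function(s) data.frame(
    code = s$code, n_m = s$n_m, n_f = s$n_f,
    testable = s$testable, test_used = s$test_used %||% NA_character_,
    p_value = s$p_value %||% NA_real_,
    significant = s$significant,
    direction = s$direction %||% NA_character_,
    stringsAsFactors = FALSE)))
  rownames(screen_tab) <- NULL

  eligible <- vapply(screens, function(s)
    isTRUE(s$testable) && isTRUE(s$significant) &&
      identical(s$direction, "male_larger"), TRUE)

  sps <- list(); sp_rows <- list()
  for (code in codes[eligible]) {
    sp <- derive_sectioning_point(train, code, screens[[code]])
    reg <- registry_entry(code)
    sp$bone <- reg$bone; sp$label <- reg$label
    ev_tr <- evaluate_univariate(train, sp, averaging)
    ev_te <- evaluate_univariate(test, sp, averaging)
    sp$reported <- list(
      train = list(acc_t_pct = ev_tr$acc_t_pct,
                   cd_bias_pct = ev_tr$cd_bias_pct),
      test = list(n_m = ev_te$n_m, n_f = ev_te$n_f,
                  acc_t_pct = ev_te$acc_t_pct,
                  cd_bias_pct = ev_te$cd_bias_pct))
    sps[[code]] <- sp
    sp_rows[[code]] <- data.frame(
      code = code, mean_m_mm = sp$mean_m_mm, mean_f_mm = sp$mean_f_mm,
      sp_mm = sp$sp_mm, n_m = sp$n_m, n_f = sp$n_f,
      train_acc_t_pct = ev_tr$acc_t_pct,
      train_cd_bias_pct = ev_tr$cd_bias_pct,
      test_acc_t_pct = ev_te$acc_t_pct,
      test_cd_bias_pct = ev_te$cd_bias_pct, stringsAsFactors = FALSE)
  }

  if (is.null(model_specs)) {
    reg <- registry_entry(codes[eligible])
    no_models <- c(sprintf("MC%d", 1:5), sprintf("MT%d", 1:5))
    model_specs <- split(reg$code, reg$bone)
    model_specs <- model_specs[!names(model_specs) %in% no_models]
  }
  models <- list(); model_rows <- list(); mid <- 0L
  for (bone in names(model_specs)) {
    mid <- mid + 1L
    fit <- tryCatch(
      fit_bone_model(train, bone, model_specs[[bone]], model_id = mid,
                     min_per_sex = min_per_sex),
      error = function(e) e)
    if (inherits(fit, "error")) {
      model_rows[[bone]] <- data.frame(
        model_id = mid, bone = bone, n_train = NA_integer_,
        skipped = conditionMessage(fit), stringsAsFactors = FALSE)
      next
    }
    ev_tr <- evaluate_model(train, fit, averaging)
    ev_te <- evaluate_model(test, fit, averaging)
    fit$reported <- list(
      train = list(n = ev_tr$n_m + ev_tr$n_f, acc_t_pct = ev_tr$acc_t_pct,
                   acc_m_pct = ev_tr$acc_m_pct, acc_f_pct = ev_tr$acc_f_pct,
                   cd_bias_pct = ev_tr$cd_bias_pct),
      test = list(n = ev_te$n_m + ev_te$n_f, acc_t_pct = ev_te$acc_t_pct,
                  acc_m_pct = ev_te$acc_m_pct, acc_f_pct = ev_te$acc_f_pct,
                  cd_bias_pct = ev_te$cd_bias_pct))
    models[[as.character(mid)]] <- fit
    model_rows[[bone]] <- data.frame(
      model_id = mid, bone = bone, n_train = ev_tr$n_m + ev_tr$n_f,
      separation = fit$separation,
      train_acc_t_pct = ev_tr$acc_t_pct,
      test_acc_t_pct = ev_te$acc_t_pct,
      test_cd_bias_pct = ev_te$cd_bias_pct, stringsAsFactors = FALSE)
  }

  bundle <- structure(
    list(name = name, version = "1.0",
         source = sprintf("developed from %d individuals, seed %d",
                          nrow(dataset$individuals), seed),
         sectioning_points = sps, models = models,
         excluded_codes = lapply(codes[!eligible], function(code) {
           s <- screens[[code]]
           list(code = code,
                reason = if (!isTRUE(s$testable)) "untestable"
                         else if (identical(s$direction, "female_larger"))
                           "female larger" else "not significant")
         })),
    class = "standards_bundle")

  list(bundle = bundle,
       report = list(
         screen = screen_tab,
         sectioning_points = do.call(rbind, unname(sp_rows)),
         models = do.call(rbind,
                          lapply(unname(model_rows), function(d) {
                            d[setdiff(c("model_id", "bone", "n_train",
                                        "separation", "train_acc_t_pct",
                                        "test_acc_t_pct",
                                        "test_cd_bias_pct", "skipped"),
                                      names(d))] <- NA
                            d
                          }))),
       provenance = list(seed = seed, train_fraction = train_fraction,
                         averaging = averaging, p_adjust = p_adjust,
                         n_train = nrow(train$individuals),
                         n_test = nrow(test$individuals)))
}
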