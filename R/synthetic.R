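# synthetic osteometric data with the statistical structure the method
# assumes: within-sex multivariate normal measurements, equicorrelated
# within a bone, anchored to the packaged per-sex training means

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Packaged per-sex training means
#'
#' Male and female training means for all 121 measurements, as transcribed
#' into the packaged standards bundle (the three female-larger measurements
#' carry their means too, although they have no sectioning point).
#'
#' @return data.frame with columns `code`, `mean_m_mm`, `mean_f_mm`.
#' @export
packaged_means <- function() {
  b <- load_bundle()
  sp <- data.frame(
    code = vapply(b$sectioning_points, `[[`, "", "code"),
    mean_m_mm = vapply(b$sectioning_points, `[[`, 0, "mean_m_mm"),
    mean_f_mm = vapply(b$sectioning_points, `[[`, 0, "mean_f_mm"),
    stringsAsFactors = FALSE)
  ex <- do.call(rbind, lapply(b$excluded_codes, function(r)
    data.frame(code = r$code, mean_m_mm = as.numeric(r$mean_m_mm),
               mean_f_mm = as.numeric(r$mean_f_mm),
               stringsAsFactors = FALSE)))
  out <- rbind(sp, ex)
  out <- out[order(match(out$code, osteo_registry()$code)), ]
  rownames(out) <- NULL
  out
}

#' Simulation configuration
#'
#' Defines the generative model for synthetic osteometric datasets: per
#' sex and per bone, measurements are multivariate normal with the
#' configured means, standard deviation `cv * mean`, and equicorrelation
#' `within_bone_rho` among measurements of the same bone; draws are
#' truncated at zero by redraw. Bone-level loss emulates taphonomic
#' absence of whole elements; measurement-level missingness is MCAR.
#'
#' Default means are the packaged per-sex training means; the reference
#' study does not publish per-measurement standard deviations, so the
#' default coefficient of variation (0.05) is a modelling assumption
#' typical of adult osteometric dimensions, not a published value.
#'
#' @param n_male,n_female individuals per sex.
#' @param codes measurement codes to simulate (default: all 121).
#' @param mean_overrides named list `code = c(mean_m, mean_f)` overriding
#'   the packaged means.
#' @param cv coefficient of variation per measurement (> 0).
#' @param within_bone_rho equicorrelation of measurements sharing a bone;
#'   must exceed -1/(k-1) for the largest simulated bone block of size k.
#' @param missing_rate per-observation MCAR missingness probability.
#' @param bone_loss_rate probability an individual's entire bone is absent.
#' @param repeat_error_sd_pct observer-error SD, percent of the true value,
#'   used by [generate_repeats()].
#' @param seed integer seed; all generation is reproducible from it.
#' @return list of class `simulation_config`.
#' @export
simulation_config <- function(n_male = 150, n_female = 150, codes = NULL,
                              mean_overrides = NULL, cv = 0.05,
                              within_bone_rho = 0.6, missing_rate = 0,
                              bone_loss_rate = 0,
                              repeat_error_sd_pct = 1, seed = 1L) {
  stopifnot(n_male >= 0, n_female >= 0, cv > 0,
            missing_rate >= 0, missing_rate <= 1,
            bone_loss_rate >= 0, bone_loss_rate <= 1,
            within_bone_rho < 1, repeat_error_sd_pct >= 0)
  means <- packaged_means()
  if (is.null(codes)) codes <- means$code else registry_entry(codes)
  mtab <- means[match(codes, means$code), ]
  if (!is.null(mean_overrides)) {
    for (code in names(mean_overrides)) {
      if (!code %in% codes)
        stopf("mean override for unknown/unsimulated code %s", code)
      mtab[mtab$code == code, c("mean_m_mm", "mean_f_mm")] <-
        as.list(mean_overrides[[code]])
    }
  }
  reg <- registry_entry(codes)
  kmax <- max(table(reg$bone))
  if (kmax > 1 && within_bone_rho <= -1 / (kmax - 1))
    stopf("within_bone_rho %.3f is not positive definite for bone blocks of size %d",
          within_bone_rho, kmax)
  structure(list(n_male = n_male, n_female = n_female, codes = codes,
                 means = mtab, cv = cv, within_bone_rho = within_bone_rho,
                 missing_rate = missing_rate,
                 bone_loss_rate = bone_loss_rate,
                 repeat_error_sd_pct = repeat_error_sd_pct,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

# equicorrelated multivariate normal, truncated at zero by redraw
rmvn_block <- function(n, mu, sd, rho) {
  k <- length(mu)
  if (k == 1L) {
    x <- matrix(stats::rnorm(n, mu, sd), ncol = 1)
  } else {
    R <- matrix(rho, k, k); diag(R) <- 1
    L <- chol(R * tcrossprod(sd))
    x <- matrix(stats::rnorm(n * k), n, k) %*% L +
      matrix(mu, n, k, byrow = TRUE)
  }
  for (iter in 1:100) {
    bad <- which(rowSums(x <= 0) > 0)
    if (!length(bad)) break
    x[bad, ] <- Recall(length(bad), mu, sd, rho)
  }
  x
}

#' Generate a synthetic osteometric dataset
#'
#' @param config a [simulation_config()].
#' @return an [osteo_dataset()] with individuals `M0001..`, `F0001..`;
#'   bilateral observations are emitted as left-side (the generator
#'   emulates a left-preferred collection protocol).
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  with_seed(config$seed, {
    reg <- registry_entry(config$codes)
    ids <- c(sprintf("M%04d", seq_len(config$n_male)),
             sprintf("F%04d", seq_len(config$n_female)))
    sexes <- rep(c("M", "F"), c(config$n_male, config$n_female))
    individuals <- data.frame(individual_id = ids, sex = sexes,
                              age_years = NA_real_,
                              stringsAsFactors = FALSE)
    obs <- list()
    for (bone in unique(reg$bone)) {
      codes <- config$codes[reg$bone == bone]
      bilateral <- reg$bilateral[match(codes[1], reg$code)]
      for (sex in c("M", "F")) {
        n <- if (sex == "M") config$n_male else config$n_female
        if (!n) next
        mu <- config$means[[if (sex == "M") "mean_m_mm" else "mean_f_mm"]][
          match(codes, config$means$code)]
        x <- rmvn_block(n, mu, config$cv * mu, config$within_bone_rho)
        keep_bone <- stats::runif(n) >= config$bone_loss_rate
        who <- ids[sexes == sex]
        for (j in seq_along(codes)) {
          keep <- keep_bone & stats::runif(n) >= config$missing_rate
          if (!any(keep)) next
          obs[[length(obs) + 1L]] <- data.frame(
            individual_id = who[keep], code = codes[j],
            side = if (bilateral) "left" else "midline",
            value_mm = x[keep, j], stringsAsFactors = FALSE)
        }
      }
    }
    obs <- if (length(obs)) do.call(rbind, obs) else NULL
    osteo_dataset(individuals, obs)
  })
}

#' Generate two-session repeat measurements for reliability analysis
#'
#' Emulates an intra- or inter-observer repeat protocol: a random subset of
#' individuals is re-measured, each observation receiving independent
#' Gaussian error with SD `repeat_error_sd_pct`% of the true value in both
#' sessions.
#'
#' @param dataset an `osteo_dataset` (typically from [generate_dataset()]).
#' @param config a [simulation_config()] (supplies error SD and seed).
#' @param n_individuals how many individuals to subsample (default: all).
#' @return long data.frame `individual_id`, `side`, `code`, `session`,
#'   `value_mm` suitable for [reliability_summary()].
#' @export
generate_repeats <- function(dataset, config, n_individuals = NULL) {
  stopifnot(inherits(dataset, "osteo_dataset"),
            inherits(config, "simulation_config"))
  if (!nrow(dataset$observations)) stopf("dataset has no observations")
  with_seed(config$seed + 1L, {
    ids <- dataset$individuals$individual_id
    if (!is.null(n_individuals) && n_individuals < length(ids))
      ids <- sort(sample(ids, n_individuals))
    obs <- dataset$observations
    obs <- obs[obs$individual_id %in% ids, , drop = FALSE]
    sd <- config$repeat_error_sd_pct / 100 * obs$value_mm
    out <- rbind(
      data.frame(obs[c("individual_id", "side", "code")], session = 1L,
                 value_mm = obs$value_mm + stats::rnorm(nrow(obs), 0, sd)),
      data.frame(obs[c("individual_id", "side", "code")], session = 2L,
                 value_mm = obs$value_mm + stats::rnorm(nrow(obs), 0, sd)))
    out$value_mm <- pmax(out$value_mm, 0.001)
    rownames(out) <- NULL
    out
  })
}

#' Generate labelled data from a logistic model
#'
#' Draws covariates from an equicorrelated normal centred midway between
#' the packaged male and female means (SD = `cv` times the centre) and
#' assigns sex labels Bernoulli(p_male(Z)) under the supplied model.
#' Intended for parameter-recovery testing of [fit_bone_model()].
#'
#' @param model a `logistic_model`.
#' @param n number of individuals.
#' @param seed integer seed.
#' @param cv coefficient of variation of the covariate distribution.
#' @param rho equicorrelation among the covariates.
#' @return an [osteo_dataset()] with sexes assigned by the model.
#' @export
generate_from_model <- function(model, n, seed = 1L, cv = 0.08,
                                rho = 0.3) {
  stopifnot(inherits(model, "logistic_model"))
  means <- packaged_means()
  mu <- rowMeans(means[match(model$variables, means$code),
                       c("mean_m_mm", "mean_f_mm")])
  with_seed(seed, {
    x <- rmvn_block(n, mu, cv * mu, rho)
    colnames(x) <- model$variables
    z <- as.numeric(x %*% model$coefficients + model$intercept)
    male <- stats::rbinom(n, 1, stats::plogis(z)) == 1
    ids <- sprintf("S%05d", seq_len(n))
    individuals <- data.frame(individual_id = ids,
                              sex = ifelse(male, "M", "F"),
                              age_years = NA_real_,
                              stringsAsFactors = FALSE)
    reg <- registry_entry(model$variables)
    obs <- do.call(rbind, lapply(seq_along(model$variables), function(j)
      data.frame(individual_id = ids, code = model$variables[j],
                 side = if (reg$bilateral[j]) "left" else "midline",
                 value_mm = x[, j], stringsAsFactors = FALSE)))
    osteo_dataset(individuals, obs)
  })
}
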