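test_that("linear score multiplies, sums and adds the intercept", {
  b <- load_bundle()
  m18 <- b$models[["18"]]    # 4th rib width
  expect_equal(linear_score(m18, c(V52 = 17.2)), 1.588 * 17.2 - 24.067)
  expect_equal(linear_score(m18, c(V52 = 17.2)), 3.2466)

  m3 <- b$models[["3"]]      # glenoid cavity
  expect_equal(linear_score(m3, c(V6 = 38.4, V7 = 28.8)),
               0.968 * 38.4 + 0.432 * 28.8 - 45.931)
  expect_equal(linear_score(m3, c(V6 = 38.4, V7 = 28.8)), 3.6818,
               tolerance = 1e-10)

  # all-zero inputs leave only the intercept
  expect_equal(linear_score(m3, c(V6 = 0, V7 = 0)), m3$intercept)

  # no imputation: missing variables must be named in the error
  expect_error(linear_score(m3, c(V6 = 38.4)), "V7")
  expect_error(linear_score(m3, c(V6 = 38.4, V7 = NA)),
               "not applicable")
})

test_that("male probability follows the logistic rule with 0.5 cutoff", {
  p0 <- male_probability(0)
  expect_equal(p0$p_male, 0.5)
  expect_equal(as.character(p0$call), "indeterminate")

  p <- male_probability(3.2466)
  expect_equal(p$p_male, 1 / (1 + exp(-3.2466)))
  expect_equal(round(p$p_male, 4), 0.9626)
  expect_equal(as.character(p$call), "male")
  expect_equal(p$p_male + p$p_female, 1)

  # antisymmetry and monotonicity
  z <- seq(-6, 6, by = 0.5)
  expect_equal(male_probability(-z)$p_male, 1 - male_probability(z)$p_male)
  expect_true(all(diff(male_probability(z)$p_male) > 0))
})

test_that("decision boundary solves Z = 0 for one variable", {
  b <- load_bundle()
  m18 <- b$models[["18"]]
  expect_equal(decision_boundary(m18, "V52"), 24.067 / 1.588)
  # feeding the boundary back gives p = 0.5 (to numerical precision)
  z <- linear_score(m18, c(V52 = decision_boundary(m18, "V52")))
  expect_equal(male_probability(z)$p_male, 0.5, tolerance = 1e-12)

  # radius model 9: solve head diameter at fixed max length 226.1
  m9 <- b$models[["9"]]
  fixed <- c(V19 = 226.1)
  bd <- decision_boundary(m9, "V22", fixed)
  k <- match(c("V19", "V22"), m9$variables)
  expect_equal(bd, -(m9$coefficients[k[1]] * 226.1 + m9$intercept) /
                 m9$coefficients[k[2]])
  expect_equal(linear_score(m9, c(fixed, V22 = bd)), 0, tolerance = 1e-9)

  expect_error(decision_boundary(m9, "V6"), "not a variable")
  mz <- logistic_model(99, "RADIUS", c("V19", "V22"), c(0.5, 0), -10)
  expect_error(decision_boundary(mz, "V22"), "zero")
})

test_that("bone-model fitting recovers a known generating model", {
  b <- load_bundle()
  m3 <- b$models[["3"]]
  ds <- generate_from_model(m3, n = 6000, seed = 31, cv = 0.08, rho = 0.3)
  fit <- fit_bone_model(ds, "SCAPULA", m3$variables)
  # sign pattern always recovered; magnitudes close at this n
  expect_equal(sign(fit$coefficients), sign(m3$coefficients))
  expect_equal(fit$coefficients, m3$coefficients, tolerance = 0.25)
  expect_false(fit$separation)
  # determinism: refit on identical data gives identical coefficients
  fit2 <- fit_bone_model(ds, "SCAPULA", m3$variables)
  expect_identical(fit$coefficients, fit2$coefficients)
  expect_identical(fit$intercept, fit2$intercept)
})

test_that("complete separation is flagged, insufficient cases refused", {
  ds <- two_sex_dataset(seq(160, 174, by = 1), seq(130, 144, by = 1))
  fit <- fit_bone_model(ds, "CLAVICLE", "V1")
  expect_true(fit$separation)
  expect_error(fit_bone_model(two_sex_dataset(rnorm(5, 150, 4),
                                              rnorm(5, 140, 4)),
                              "CLAVICLE", "V1"),
               "insufficient complete cases")
})

test_that("model evaluation matches enumeration and uses complete cases", {
  # hand-built model: male iff V1 > 146.5
  m <- logistic_model(1, "CLAVICLE", "V1", 1, -146.5)
  wide <- data.frame(individual_id = sprintf("i%d", 1:6),
                     sex = rep(c("M", "F"), each = 3),
                     stringsAsFactors = FALSE)
  wide$V1 <- c(150, 151, 140, 140, 150, 139)  # one error per sex
  ds <- toy_dataset(wide)
  got <- evaluate_model(ds, m)
  expect_equal(got$acc_m_pct, 100 * 2 / 3)
  expect_equal(got$acc_f_pct, 100 * 2 / 3)
  expect_equal(got$cd_bias_pct, 0)

  # missing variable rows are dropped (complete-case rule)
  wide$V1[1] <- NA
  got2 <- evaluate_model(toy_dataset(wide), m)
  expect_equal(c(got2$n_m, got2$n_f), c(2L, 3L))

  wide$V1 <- NA_real_
  expect_error(evaluate_model(toy_dataset(wide[0, ]), m))
})

test_that("classification is invariant under consistent rescaling", {
  b <- load_bundle()
  m3 <- b$models[["3"]]
  vals <- c(V6 = 36.1, V7 = 27.0)
  z1 <- linear_score(m3, vals)
  scaled <- logistic_model(3, m3$bone, m3$variables,
                           m3$coefficients * 10, m3$intercept)
  z2 <- linear_score(scaled, vals / 10)
  expect_equal(z1, z2)
})
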