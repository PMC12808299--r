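test_that("sectioning point is the midpoint of the training sex means", {
  # clavicle-like means 154.0 / 139.0 -> SP 146.5
  ds <- two_sex_dataset(c(150, 154, 158), c(135, 139, 143))
  sp <- derive_sectioning_point(ds, "V1")
  expect_equal(sp$mean_m_mm, 154.0)
  expect_equal(sp$mean_f_mm, 139.0)
  expect_equal(sp$sp_mm, 146.5)
  expect_equal(c(sp$n_m, sp$n_f), c(3L, 3L))

  # glenoid-like means 38.4 / 33.2 -> SP 35.8
  ds2 <- two_sex_dataset(c(38.0, 38.8), c(32.8, 33.6), code = "V6")
  expect_equal(derive_sectioning_point(ds2, "V6")$sp_mm, 35.8)

  # equal means: degenerate, flagged
  ds3 <- two_sex_dataset(c(10, 12), c(11, 11))
  sp3 <- derive_sectioning_point(ds3, "V1")
  expect_equal(sp3$sp_mm, 11)
  expect_true(sp3$degenerate)
})

test_that("sectioning point derivation is exchangeable and unit-equivariant", {
  set.seed(1)
  vm <- runif(20, 150, 160); vf <- runif(20, 135, 145)
  sp1 <- derive_sectioning_point(two_sex_dataset(vm, vf), "V1")
  sp2 <- derive_sectioning_point(
    two_sex_dataset(rev(vm), sample(vf)), "V1")
  expect_equal(sp1$sp_mm, sp2$sp_mm)
  sp10 <- derive_sectioning_point(two_sex_dataset(10 * vm, 10 * vf), "V1")
  expect_equal(sp10$sp_mm, 10 * sp1$sp_mm)
})

test_that("three-way classification rule: above male, below female, equal indeterminate", {
  sp <- list(sp_mm = 146.5)
  expect_equal(as.character(classify_univariate(150.0, sp)), "male")
  expect_equal(as.character(classify_univariate(139.0, sp)), "female")
  expect_equal(as.character(classify_univariate(146.5, sp)),
               "indeterminate")
  expect_true(is.na(classify_univariate(NA_real_, sp)))
  expect_equal(as.character(classify_univariate(c(147, 146, 146.5), sp)),
               c("male", "female", "indeterminate"))
})

test_that("classification metrics match enumeration on toy sets", {
  # 4M/4F, one male misclassified
  truth <- rep(c("M", "F"), each = 4)
  call <- factor(c("male", "male", "male", "female",
                   rep("female", 4)),
                 levels = c("male", "female", "indeterminate"))
  m <- classification_metrics(truth, call, "balanced")
  expect_equal(m$acc_m_pct, 75)
  expect_equal(m$acc_f_pct, 100)
  expect_equal(m$acc_t_pct, 87.5)
  expect_equal(m$cd_bias_pct, -25)
  expect_false(m$bias_acceptable)

  # perfect separation
  ds <- two_sex_dataset(rep(150, 10), rep(140, 10))
  perfect <- evaluate_univariate(ds, list(code = "V1", sp_mm = 146.5))
  expect_equal(perfect$acc_t_pct, 100)
  expect_equal(perfect$cd_bias_pct, 0)

  # published convention check: %M - %F
  m2 <- classification_metrics(
    rep(c("M", "F"), c(32, 32)),
    factor(c(rep("male", 28), rep("female", 4),
             rep("female", 29), rep("male", 3)),
           levels = c("male", "female", "indeterminate")))
  expect_equal(m2$cd_bias_pct, m2$acc_m_pct - m2$acc_f_pct)

  # random toys against the enumeration oracle
  set.seed(99)
  for (rep in 1:25) {
    n <- sample(4:10, 1)
    truth <- sample(c("M", "F"), n, replace = TRUE)
    if (length(unique(truth)) < 2) next
    call <- factor(sample(c("male", "female", "indeterminate"), n,
                          replace = TRUE),
                   levels = c("male", "female", "indeterminate"))
    for (avg in c("balanced", "pooled")) {
      got <- classification_metrics(truth, call, avg)
      want <- oracle_metrics(truth, call, avg)
      expect_equal(got$acc_m_pct, want$acc_m)
      expect_equal(got$acc_f_pct, want$acc_f)
      expect_equal(got$acc_t_pct, want$acc_t)
      expect_equal(got$cd_bias_pct, want$bias)
    }
  }
})

test_that("balanced and pooled overall rates agree iff the design is balanced", {
  truth <- rep(c("M", "F"), c(4, 4))
  call <- factor(c("male", "male", "male", "female", rep("female", 4)),
                 levels = c("male", "female", "indeterminate"))
  expect_equal(classification_metrics(truth, call, "balanced")$acc_t_pct,
               classification_metrics(truth, call, "pooled")$acc_t_pct)
  truth2 <- rep(c("M", "F"), c(6, 2))
  call2 <- factor(c(rep("male", 3), rep("female", 3), "female", "male"),
                  levels = c("male", "female", "indeterminate"))
  b <- classification_metrics(truth2, call2, "balanced")$acc_t_pct
  p <- classification_metrics(truth2, call2, "pooled")$acc_t_pct
  expect_equal(b, mean(c(50, 50)))
  expect_equal(p, 100 * 4 / 8)
  # indeterminate counts as incorrect
  call3 <- factor(rep("indeterminate", 8),
                  levels = c("male", "female", "indeterminate"))
  expect_equal(classification_metrics(truth, call3)$acc_t_pct, 0)
})

test_that("dimorphism screen picks the right test and direction", {
  set.seed(21)
  # well-separated normal samples: Student's t, significant, male larger
  ds <- two_sex_dataset(rnorm(150, 154, 5), rnorm(150, 139, 5))
  s <- screen_dimorphism(ds, "V1")
  expect_true(s$testable)
  expect_equal(s$test_used, "student_t")
  expect_true(s$significant)
  expect_equal(s$direction, "male_larger")

  # female-larger variable (pubis-like): flagged, SP derivation refuses
  ds2 <- two_sex_dataset(rnorm(100, 70.9, 3), rnorm(100, 74.5, 3),
                         code = "V76")
  s2 <- screen_dimorphism(ds2, "V76")
  expect_equal(s2$direction, "female_larger")
  expect_error(derive_sectioning_point(ds2, "V76", s2), "females larger")

  # heavily skewed data routes to Mann-Whitney
  ds3 <- two_sex_dataset(exp(rnorm(120, 3.2, 0.6)),
                         exp(rnorm(120, 2.6, 0.6)))
  s3 <- screen_dimorphism(ds3, "V1")
  expect_equal(s3$test_used, "mann_whitney")
  expect_true(s3$significant)

  # insufficient sample: untestable
  s4 <- screen_dimorphism(two_sex_dataset(c(10, 11), c(9, 10)), "V1")
  expect_false(s4$testable)
  expect_error(derive_sectioning_point(two_sex_dataset(c(10, 11), c(9, 10)),
                                       "V1", s4), "not significantly")
})

test_that("screen type-I error sits near the nominal 5 % level", {
  set.seed(2024)
  hits <- 0L; reps <- 400L
  for (i in seq_len(reps)) {
    ds <- two_sex_dataset(rnorm(30, 100, 5), rnorm(30, 100, 5))
    if (isTRUE(screen_dimorphism(ds, "V1")$significant)) hits <- hits + 1L
  }
  rate <- hits / reps
  # binomial SD at p=0.05, n=400 is 0.011; accept +/- 4 SD
  expect_gt(rate, 0.006)
  expect_lt(rate, 0.094)
})

test_that("univariate evaluation skips missing measurements", {
  wide <- data.frame(individual_id = sprintf("i%d", 1:6),
                     sex = rep(c("M", "F"), each = 3),
                     stringsAsFactors = FALSE)
  wide$V1 <- c(150, 151, NA, 140, NA, NA)
  ds <- toy_dataset(wide)
  m <- evaluate_univariate(ds, list(code = "V1", sp_mm = 146.5))
  expect_equal(c(m$n_m, m$n_f), c(2L, 1L))
  expect_equal(m$acc_t_pct, 100)
})
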