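test_that("registry is complete: 121 unique codes over 46 bones, all mm", {
  reg <- osteo_registry()
  expect_setequal(reg$code, sprintf("V%d", 1:121))
  expect_false(anyDuplicated(reg$code) > 0)
  expect_equal(length(unique(reg$bone)), 46L)
  expect_true(all(reg$unit == "mm"))
  # every code maps to exactly one bone
  expect_equal(nrow(unique(reg[c("code", "bone")])), 121L)
  # midline elements are the unpaired ones
  midline <- unique(reg$bone[!reg$bilateral])
  expect_setequal(midline, c("STERNUM", "ATLAS", "C2", "C7", "T1", "T12",
                             "L1", "L5", "SACRUM"))
  expect_error(registry_entry("V999"), "unknown measurement")
})

test_that("laterality resolution prefers left, falls back right, never averages", {
  ds <- osteo_dataset(
    data.frame(individual_id = c("a", "b", "c"), sex = "M"),
    data.frame(
      individual_id = c("a", "a", "b", "c"),
      code = "V1",
      side = c("left", "right", "right", "left"),
      value_mm = c(154.0, 151.0, 151.0, 140.0)))
  expect_equal(resolve_side(ds, "a", "V1"), 154.0)
  expect_equal(resolve_side(ds, "b", "V1"), 151.0)
  expect_true(is.na(resolve_side(ds, "a", "V2")))
  expect_error(resolve_side(ds, "a", "V999"), "unknown")

  # independent of observation insertion order
  ds2 <- osteo_dataset(
    ds$individuals,
    ds$observations[c(4, 3, 2, 1), ])
  expect_equal(resolve_side(ds2, "a", "V1"), 154.0)
  wide <- resolved_values(ds, "V1")
  expect_equal(wide$V1[wide$individual_id == "a"], 154.0)
})

test_that("dataset invariants are enforced", {
  ind <- data.frame(individual_id = "a", sex = "M")
  # positivity
  expect_error(osteo_dataset(ind, data.frame(
    individual_id = "a", code = "V1", side = "left", value_mm = -3)),
    "positive")
  # duplicate (individual, code, side)
  expect_error(osteo_dataset(ind, data.frame(
    individual_id = c("a", "a"), code = "V1", side = "left",
    value_mm = c(1, 2))), "duplicate")
  # midline side only for unpaired elements (V1 clavicle is paired)
  expect_error(osteo_dataset(ind, data.frame(
    individual_id = "a", code = "V1", side = "midline", value_mm = 150)),
    "midline")
  # left/right invalid for vertebrae (V53 atlas)
  expect_error(osteo_dataset(ind, data.frame(
    individual_id = "a", code = "V53", side = "left", value_mm = 47)),
    "midline elements")
  expect_error(osteo_dataset(data.frame(individual_id = "a", sex = "X")),
               "sex")
})

test_that("wide CSV round-trips the resolved view exactly", {
  wide <- data.frame(individual_id = c("i1", "i2"), sex = c("M", "F"),
                     stringsAsFactors = FALSE)
  wide$V1 <- c(154.0, 139.0); wide$V52 <- c(17.2, 13.4)
  ds <- toy_dataset(wide)
  path <- withr::local_tempfile(fileext = ".csv")
  write_osteo_csv(ds, path, "wide")
  back <- read_osteo_csv(path, "wide")
  expect_equal(nrow(back$individuals), 2L)
  expect_equal(resolved_values(back)[c("individual_id", "sex", "V1", "V52")],
               resolved_values(ds)[c("individual_id", "sex", "V1", "V52")])
})

test_that("long CSV round-trip is lossless including both sides", {
  ds <- osteo_dataset(
    data.frame(individual_id = c("a", "b"), sex = c("M", "F"),
               age_years = c(60, NA)),
    data.frame(individual_id = c("a", "a", "b"), code = "V1",
               side = c("left", "right", "right"),
               value_mm = c(154.0, 151.5, 139.0)))
  path <- withr::local_tempfile(fileext = ".csv")
  write_osteo_csv(ds, path, "long")
  back <- read_osteo_csv(path, "long")
  o1 <- ds$observations[order(ds$observations$individual_id,
                              ds$observations$side), ]
  o2 <- back$observations[order(back$observations$individual_id,
                                back$observations$side), ]
  rownames(o1) <- rownames(o2) <- NULL
  expect_equal(o1, o2)
  expect_equal(back$individuals$age_years, c(60, NA))
})

test_that("malformed CSV input is rejected with diagnostics", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("individual_id,sex,V1", "a,M,-3.0"), path)
  expect_error(read_osteo_csv(path, "wide"), "non-positive")
  writeLines(c("individual_id,sex,V1", "a,M,abc"), path)
  expect_error(read_osteo_csv(path, "wide"), "non-numeric")
  writeLines(c("id,sex,V1", "a,M,150"), path)
  expect_error(read_osteo_csv(path, "wide"), "header")
})

test_that("empty dataset writes a header-only file and reads back empty", {
  ds <- osteo_dataset(data.frame(individual_id = character(),
                                 sex = character()))
  path <- withr::local_tempfile(fileext = ".csv")
  write_osteo_csv(ds, path, "long")
  expect_equal(length(readLines(path)), 1L)
})

test_that("synthetic dataset round-trips exactly through wide CSV", {
  cfg <- simulation_config(n_male = 20, n_female = 20,
                           codes = c("V1", "V6", "V7", "V53"), seed = 11)
  ds <- generate_dataset(cfg)
  path <- withr::local_tempfile(fileext = ".csv")
  write_osteo_csv(ds, path, "wide")
  back <- read_osteo_csv(path, "wide")
  a <- resolved_values(ds); b <- resolved_values(back)
  expect_equal(a[names(b)], b)
})
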