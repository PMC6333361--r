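test_that("a model round-trips through the CSV directory format", {
  m <- toy_fleet()
  dir <- withr::local_tempdir()
  write_model(m, dir)
  m2 <- read_model(dir)
  expect_equal(m2$groups, m$groups)
  expect_equal(m2$diet, m$diet)
  expect_equal(m2$import, m$import)
  expect_equal(m2$landings, m$landings)
  expect_equal(m2$discards, m$discards)
  expect_equal(m2$detritus_fate, m$detritus_fate)
  expect_equal(m2$discard_fate, m$discard_fate)
})

test_that("a 2-group toy reads back with 2 groups and no fleets", {
  dir <- withr::local_tempdir()
  write_model(toy_two_group(), dir)
  m <- read_model(dir)
  expect_s3_class(m, "fw_model")
  expect_equal(nrow(m$groups), 2)
  expect_equal(ncol(m$landings), 0)
})

test_that("result tables round-trip through write/read", {
  dir <- withr::local_tempdir()
  b <- suppressWarnings(balance(toy_two_group(detritus = TRUE)))
  for (x in list(tidy(b), detritus_budget(b),
                 system_statistics(b))) {
    f <- tempfile(tmpdir = dir, fileext = ".csv")
    write_results(x, f)
    y <- read_results(f)
    num <- vapply(x, is.numeric, logical(1))
    expect_equal(as.data.frame(y[num]), as.data.frame(x[num]),
                 tolerance = 1e-12)
    # the written numeric text is a fixed point: rewriting what was read
    # reproduces the file byte for byte
    f2 <- tempfile(tmpdir = dir, fileext = ".csv")
    write_results(y, f2)
    f3 <- tempfile(tmpdir = dir, fileext = ".csv")
    write_results(read_results(f2), f3)
    expect_identical(readLines(f2), readLines(f3))
  }
})

test_that("matrices round-trip through write_results with row labels", {
  m <- matrix(c(0.25, -1, 3, 0), 2, 2,
              dimnames = list(c("a", "b"), c("x", "y")))
  f <- withr::local_tempfile(fileext = ".csv")
  write_results(m, f)
  y <- read_results(f)
  expect_equal(y$row, c("a", "b"))
  expect_equal(unname(as.matrix(y[, c("x", "y")])), unname(m))
})

test_that("diet columns that do not sum to one are rejected with the column named", {
  groups <- toy_two_group()$groups
  expect_error(
    fw_model(groups, data.frame(prey = "PP", ZOO = 0.8)),
    "ZOO")
})

test_that("validation reports rather than raises, and is idempotent", {
  m <- toy_three_group()
  rep1 <- validate_model(m)
  expect_equal(nrow(rep1[rep1$severity == "error", ]), 0)
  expect_identical(rep1, validate_model(m))
})

test_that("under-determined and over-determined groups are flagged", {
  groups <- toy_two_group()$groups
  groups$B[1] <- NA  # PP now has neither B nor EE
  m <- fw_model(groups, data.frame(prey = "PP", ZOO = 1), check = FALSE)
  rep <- validate_model(m)
  expect_true(any(rep$severity == "error" &
                    grepl("under-determined", rep$message)))

  groups2 <- toy_two_group()$groups
  groups2$EE[1] <- 0.1  # both B and EE given
  m2 <- fw_model(groups2, data.frame(prey = "PP", ZOO = 1), check = FALSE)
  rep2 <- validate_model(m2)
  expect_true(any(rep2$severity == "warning" &
                    grepl("over-determined", rep2$message)))
})

test_that("implausible production/consumption ratios draw a warning", {
  groups <- toy_two_group()$groups
  groups$QB[2] <- NA
  groups$PQ <- c(NA, 0.9)
  m <- fw_model(groups, data.frame(prey = "PP", ZOO = 1), check = FALSE)
  rep <- validate_model(m)
  expect_true(any(rep$severity == "warning" & grepl("P/Q", rep$message)))
})

test_that("unresolvable group names in the diet are an error", {
  groups <- toy_two_group()$groups
  expect_error(
    fw_model(groups, data.frame(prey = "NOPE", ZOO = 1)),
    "NOPE")
})
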