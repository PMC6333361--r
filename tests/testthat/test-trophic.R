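test_that("producers and detritus sit at TL 1, simple consumers stack above", {
  b <- balance(toy_two_group(detritus = TRUE))
  tl <- trophic_levels(b)
  expect_equal(tl$TL[tl$group == "PP"], 1)
  expect_equal(tl$TL[tl$group == "DET"], 1)
  expect_equal(tl$TL[tl$group == "ZOO"], 2)
})

test_that("a 50/50 diet on TL 1 and TL 2 prey gives TL 2.5 and OI 0.25", {
  b <- balance(toy_tl_chain())
  oi <- omnivory(b)
  expect_equal(oi$TL[oi$group == "C2"], 2.5)
  # variance of prey TLs about 1.5: 0.5*(1-1.5)^2 + 0.5*(2-1.5)^2
  expect_equal(oi$OI[oi$group == "C2"], 0.25)
  expect_equal(oi$OI[oi$group == "H"], 0)  # single prey, zero variance
})

test_that("the TL linear solve matches fixed-point iteration on random webs", {
  for (s in c(2, 9, 21)) {
    bw <- balanced_default_web(seed = s)
    tl <- trophic_levels(bw)
    ref <- fixed_point_tl(bw)
    expect_lt(max(abs(tl$TL - ref[tl$group])), 1e-10)
  }
})

test_that("OI is invariant under splitting a prey into two of equal TL", {
  # replace C2's 50% share of P with 25% + 25% of two identical producers
  groups <- tibble::tibble(
    group = c("P", "Pb", "H", "C2"),
    type = c("producer", "producer", "consumer", "consumer"),
    domain = "pelagic",
    B = c(10, 10, 1, 0.2), PB = c(10, 10, 2, 1), QB = c(NA, NA, 8, 5),
    EE = c(NA, NA, NA, 0))
  diet <- data.frame(prey = c("P", "Pb", "H"),
                     H = c(1, 0, 0), C2 = c(0.25, 0.25, 0.5))
  b <- balance(fw_model(groups, diet, check = FALSE))
  oi <- omnivory(b)
  expect_equal(oi$OI[oi$group == "C2"], 0.25)
})

test_that("SOI is a weighted mean lying between min and max consumer OI", {
  bw <- balanced_default_web(seed = 17)
  oi <- omnivory(bw)
  soi <- system_omnivory(bw, oi)
  cons <- oi$OI[oi$type == "consumer"]
  expect_gte(soi, min(cons))
  expect_lte(soi, max(cons))
})

test_that("system totals add up on the 2-group toy", {
  b <- balance(toy_two_group())
  st <- system_statistics(b)
  expect_equal(st$total_consumption, 10)
  expect_equal(st$total_production, 102)  # 100 + 2
})

test_that("TST decomposes exactly into its four flow classes", {
  bw <- balanced_default_web(seed = 23)
  st <- system_statistics(bw)
  expect_equal(st$TST,
               st$total_consumption + st$total_export +
                 st$total_respiration + st$total_flow_to_detritus,
               tolerance = 1e-9)
})

test_that("an all-producer web reports infinite PP/R", {
  groups <- tibble::tibble(
    group = c("P1", "P2"), type = "producer", domain = "pelagic",
    B = c(10, 5), PB = c(10, 20), EE = c(0, 0))
  m <- fw_model(groups, diet = matrix(0, 2, 0,
                                      dimnames = list(c("P1", "P2"), NULL)),
                check = FALSE)
  b <- balance(m)
  st <- system_statistics(b)
  expect_equal(st$total_consumption, 0)
  expect_true(is.infinite(st$PP_R))
})

test_that("a fully imported diet falls back to TL 2 with a warning", {
  groups <- tibble::tibble(
    group = c("PP", "MIG"), type = c("producer", "consumer"),
    domain = "pelagic", B = c(10, 1), PB = c(10, 2), QB = c(NA, 10),
    EE = c(0, 0))
  diet <- data.frame(prey = c("PP", "import"), MIG = c(0, 1))
  b <- suppressWarnings(balance(fw_model(groups, diet, check = FALSE)))
  expect_warning(tl <- trophic_levels(b), "import")
  expect_equal(tl$TL[tl$group == "MIG"], 2)
})

test_that("the two import conventions agree when no diet is imported", {
  b <- balance(toy_three_group())
  expect_equal(trophic_levels(b, "renormalise")$TL,
               trophic_levels(b, "tl1")$TL)
})

test_that("import conventions differ visibly for a heavy importer", {
  groups <- tibble::tibble(
    group = c("P", "H", "TOP"),
    type = c("producer", "consumer", "consumer"),
    domain = "pelagic",
    B = c(100, 5, 0.1), PB = c(10, 2, 0.5), QB = c(NA, 8, 3),
    EE = c(NA, NA, 0))
  diet <- data.frame(prey = c("P", "H", "import"),
                     H = c(1, 0, 0), TOP = c(0, 0.3, 0.7))
  b <- balance(fw_model(groups, diet, check = FALSE))
  tl_r <- trophic_levels(b, "renormalise")
  tl_1 <- trophic_levels(b, "tl1")
  expect_equal(tl_r$TL[tl_r$group == "TOP"], 3)       # import at mean prey TL
  expect_equal(tl_1$TL[tl_1$group == "TOP"], 1 + 0.3 * 2 + 0.7 * 1)
})
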