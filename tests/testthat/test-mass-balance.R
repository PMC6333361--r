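test_that("a single missing EE is recovered by hand-checkable arithmetic", {
  # producer production 10*10 = 100; consumed 1*10*1 = 10 -> EE = 0.1
  b <- balance(toy_two_group())
  g <- tidy(b)
  expect_equal(g$EE[g$group == "PP"], 0.1)
  expect_lt(max(abs(b$diagnostics$residual)), 1e-8)
})

test_that("mixed unknowns (B and EE) solve the 2-unknown linear system", {
  # carnivore eats 0.5*3*1 = 1.5 of herbivore; herbivore production B*1*0.5
  # must equal it -> B = 3; herbivore then consumes 3*5 = 15 of the
  # producer's 500 -> EE = 0.03
  b <- balance(toy_three_group())
  g <- tidy(b)
  expect_equal(g$B[g$group == "HRB"], 3.0)
  expect_equal(g$EE[g$group == "PP"], 0.03)
})

test_that("flows reproduce consumption: column sums plus import equal Q", {
  b <- balance(toy_two_group())
  expect_equal(unname(b$flows["PP", "ZOO"]), 10)

  bw <- balanced_default_web(seed = 7)
  fl <- compute_flows(bw)
  q_from_flows <- colSums(fl$flows) + fl$import
  g <- tidy(bw)
  expect_equal(unname(q_from_flows),
               g$Q[match(names(q_from_flows), g$group)],
               tolerance = 1e-12)
})

test_that("import consumption is split out from in-system consumption", {
  groups <- tibble::tibble(
    group = c("PP", "ZOO"), type = c("producer", "consumer"),
    domain = "pelagic", B = c(10, 1), PB = c(10, 2), QB = c(NA, 10),
    EE = c(NA, 0))
  diet <- data.frame(prey = c("PP", "import"), ZOO = c(0.3, 0.7))
  b <- balance(fw_model(groups, diet, check = FALSE))
  expect_equal(unname(b$flows["PP", "ZOO"]), 3)
  expect_equal(unname(b$import_flow["ZOO"]), 7)
})

test_that("the detritus budget itemizes unassimilated, dead and uneaten flows", {
  # ZOO: U = 0.2*10 = 2, M0*B = 2 (EE = 0); PP unconsumed = 90 -> inflow 94
  b <- balance(toy_two_group(detritus = TRUE))
  det <- detritus_budget(b)
  expect_equal(det$inflow, 94)
  expect_equal(det$outflow, 0)   # no detritivores
  expect_equal(det$export, 94)
})

test_that("conservation holds per consumer: Q = P + R + U", {
  bw <- balanced_default_web(seed = 3)
  g <- tidy(bw)
  cons <- g[g$type == "consumer", ]
  expect_equal(cons$Q, cons$P + cons$R + cons$U, tolerance = 1e-12)
})

test_that("a fully determined consistent model is a fixed point of the solver", {
  bw <- balanced_default_web(seed = 11)
  m <- bw$model  # all B and EE known and consistent
  b2 <- suppressWarnings(balance(m))
  expect_equal(tidy(b2)$B, tidy(bw)$B, tolerance = 1e-12)
  expect_equal(tidy(b2)$EE, tidy(bw)$EE, tolerance = 1e-12)
  expect_lt(max(abs(b2$diagnostics$residual)), 1e-8)
})

test_that("hiding each group's B or EE in turn recovers the truth", {
  m <- suppressMessages(generate_web(web_config(seed = 5)))
  truth <- attr(m, "truth")
  hide <- setNames(rep(c("B", "EE"), length.out = nrow(truth)), truth$group)
  pm <- perturb_for_recovery(m, hide)
  b <- suppressWarnings(balance(pm))
  g <- tidy(b)
  i <- match(truth$group, g$group)
  rel_b <- abs(g$B[i] - truth$B) / truth$B
  rel_e <- abs(g$EE[i] - truth$EE) / truth$EE
  expect_lt(max(rel_b, rel_e), 1e-9)
})

test_that("uniform biomass rescaling leaves EE and TL unchanged", {
  m <- suppressMessages(generate_web(web_config(seed = 13)))
  b1 <- suppressWarnings(balance(m))
  k <- 3.7
  m2 <- m
  m2$groups$B <- m2$groups$B * k
  m2$groups$BA <- m2$groups$BA * k
  m2$groups$NM <- m2$groups$NM * k
  m2$landings <- m2$landings * k
  m2$discards <- m2$discards * k
  b2 <- suppressWarnings(balance(m2))
  expect_equal(tidy(b2)$EE, tidy(b1)$EE, tolerance = 1e-10)
  expect_equal(trophic_levels(b2)$TL, trophic_levels(b1)$TL,
               tolerance = 1e-10)
})

test_that("negative respiration is flagged, not fatal", {
  groups <- tibble::tibble(
    group = c("PP", "ZOO"), type = c("producer", "consumer"),
    domain = "pelagic", B = c(10, 1), PB = c(10, 9), QB = c(NA, 10),
    EE = c(NA, 0))  # P/Q = 0.9 with GS 0.2 -> R = 8 - 9 < 0
  m <- fw_model(groups, data.frame(prey = "PP", ZOO = 1), check = FALSE)
  expect_warning(b <- balance(m), "negative respiration")
  expect_true(any(b$diagnostics$flag_negative_respiration))
})

test_that("solved non-positive biomass is an error", {
  groups <- tibble::tibble(
    group = c("PP", "HRB", "CRN"),
    type = c("producer", "consumer", "consumer"),
    domain = "pelagic",
    B = c(100, NA, 0.5), PB = c(5, 1, 0.8), QB = c(NA, 5, 3),
    EE = c(NA, 0.5, 0),
    # emigration far exceeding what predation sustains drives B below zero
    NM = c(0, -5, 0))
  diet <- data.frame(prey = c("PP", "HRB"), HRB = c(1, 0), CRN = c(0, 1))
  m <- fw_model(groups, diet, check = FALSE)
  expect_error(suppressWarnings(balance(m)), "non-positive")
})
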