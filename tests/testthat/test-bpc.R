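test_that("exploitation arithmetic: E = F/Z and CumE sums contributions", {
  # Y = 0.2, B = 1, PB = 1 -> F = 0.2, E = 0.2
  b <- suppressWarnings(balance(toy_fleet()))
  ex <- exploitation(b)
  expect_equal(ex$groups$E[ex$groups$group == "G"], 0.2)
  expect_equal(ex$groups$E[ex$groups$group == "P"], 0)  # unfished

  # one fleet catching two groups with contributions 0.2 and 0.3 -> CumE 0.5
  groups <- tibble::tibble(
    group = c("P", "A", "B"),
    type = c("producer", "consumer", "consumer"),
    domain = "demersal",
    B = c(50, 1, 2), PB = c(10, 1, 1.5), QB = c(NA, 4, 5),
    EE = c(NA, 0, 0))
  diet <- data.frame(prey = "P", A = 1, B = 1)
  landings <- data.frame(group = c("A", "B"), FLT = c(0.2, 0.9))
  bb <- suppressWarnings(balance(fw_model(groups, diet, landings = landings,
                                          check = FALSE)))
  ex2 <- exploitation(bb)
  expect_equal(sort(ex2$contributions$E), c(0.2, 0.3))
  expect_equal(ex2$fleets$CumE, 0.5)
})

test_that("summing per-fleet contributions over fleets recovers total E", {
  bw <- balanced_default_web(seed = 12)
  ex <- exploitation(bw)
  by_group <- tapply(ex$contributions$E, ex$contributions$group, sum)
  tot <- setNames(ex$groups$E, ex$groups$group)
  expect_equal(as.numeric(by_group),
               unname(tot[names(by_group)]), tolerance = 1e-12)
})

test_that("discard ratios come in both definitions", {
  b <- suppressWarnings(balance(toy_fleet()))
  dr <- discard_ratio(b)
  expect_equal(dr$ratio_catch, dr$discards / (dr$landings + dr$discards))
})

test_that("single-domain webs have zero cross-domain flux", {
  cfg <- web_config(domains = "pelagic", n_producers = 2, n_consumers = 8,
                    n_detritus = 1, seed = 31)
  b <- suppressMessages(suppressWarnings(balance(generate_web(cfg))))
  fx <- cross_domain_flux(b)
  expect_equal(fx$consumer_flux, rep(0, nrow(fx)))
  expect_equal(fx$source_flux, rep(0, nrow(fx)))
})

test_that("cross-domain flux sums only the out-of-domain flows", {
  # pelagic consumer eating 3 of benthic prey and 5 of pelagic prey
  groups <- tibble::tibble(
    group = c("BP", "PP", "C"),
    type = c("producer", "producer", "consumer"),
    domain = c("benthic", "pelagic", "pelagic"),
    B = c(10, 10, 1), PB = c(10, 10, 2), QB = c(NA, NA, 8),
    EE = c(NA, NA, 0))
  diet <- data.frame(prey = c("BP", "PP"), C = c(3 / 8, 5 / 8))
  b <- balance(fw_model(groups, diet, check = FALSE))
  fx <- cross_domain_flux(b)
  expect_equal(fx$consumer_flux[fx$group == "C"], 3)
  expect_equal(fx$source_flux[fx$group == "BP"], 3)
  expect_equal(fx$source_flux[fx$group == "PP"], 0)  # same domain as C
})

test_that("cross-domain consumption, same-domain consumption and import partition Q", {
  bw <- balanced_default_web(seed = 16)
  fx <- cross_domain_flux(bw)
  g <- tidy(bw)
  Tm <- bw$flows
  dom <- setNames(g$domain, g$group)
  for (cc in colnames(Tm)) {
    same <- sum(Tm[dom[rownames(Tm)] == dom[cc], cc])
    tot <- fx$consumer_flux[fx$group == cc] + same + bw$import_flow[cc]
    expect_equal(unname(tot), g$Q[g$group == cc], tolerance = 1e-9)
  }
})

test_that("excluding counterpart groups removes their flows, unknown codes error", {
  bw <- balanced_default_web(seed = 16)
  fx_all <- cross_domain_flux(bw)
  drop <- bw$groups$group[bw$groups$type == "producer"]
  fx_ex <- cross_domain_flux(bw, exclude = drop)
  expect_true(all(fx_ex$consumer_flux <= fx_all$consumer_flux + 1e-12))
  expect_error(cross_domain_flux(bw, exclude = "NOT_A_GROUP"), "NOT_A_GROUP")
})

test_that("merging all domains into one zeroes every cross-domain quantity", {
  m <- suppressMessages(generate_web(web_config(seed = 25)))
  m$groups$domain <- "pelagic"
  m$detritus_fate <- m$detritus_fate  # fate unchanged; domains relabelled
  b <- suppressWarnings(balance(m))
  fx <- cross_domain_flux(b)
  expect_equal(max(abs(fx$consumer_flux)), 0)
  expect_equal(max(abs(fx$source_flux)), 0)
  ci <- cross_domain_impact(mti(b))
  expect_equal(max(abs(as.matrix(ci[, -(1:2)]))), 0)
})

test_that("cross-domain impact selects the hand-picked entries of M", {
  # three domains in a chain; closed-form 2x2 block extended by a zero row
  b <- balance(toy_tl_chain())   # P benthic, H demersal, C2 pelagic
  im <- mti(b)
  ci <- cross_domain_impact(im)
  M <- im$M
  for (gg in c("P", "H", "C2")) {
    others <- setdiff(c("P", "H", "C2"), gg)
    expect_equal(ci$impact_out_pos[ci$group == gg],
                 sum(pmax(M[gg, others], 0)))
    expect_equal(ci$impact_in_neg[ci$group == gg],
                 sum(pmin(M[others, gg], 0)))
  }
  expect_true(all(ci$impact_out_pos >= 0))
  expect_true(all(ci$impact_out_neg <= 0))
})

test_that("an all-zero impact matrix yields all-zero cross-domain fields", {
  b <- balance(toy_tl_chain())
  im <- mti(b)
  im$M[] <- 0
  ci <- cross_domain_impact(im)
  expect_equal(max(abs(as.matrix(ci[, -(1:2)]))), 0)
})
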