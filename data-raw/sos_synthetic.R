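# Builds inst/extdata/sos_synthetic: a SYNTHETIC parameterization on the
# published structure of the Strait of Sicily food-web model (72 functional
# groups with their codes/domains, 18 fleet segments, 3 detritus pools, a 70%
# diet import for bluefin tuna, an immigration term for swordfish, and B
# estimated instead of EE for BO, EUP and MB). All numeric values are drawn
# by the package's balanced-web generator: the published supplementary
# parameter and diet tables are NOT redistributed here.
#
# Run from the package root:  Rscript data-raw/sos_synthetic.R

devtools::load_all(".", quiet = TRUE)

g <- function(code, long, dom, type, layer) {
  tibble::tibble(group = code, long_name = long, domain = dom, type = type,
                 layer = as.integer(layer))
}
p <- "pelagic"; d <- "demersal"; b <- "benthic"

structure_tbl <- dplyr::bind_rows(
  g("SB",   "Seabirds",                               p, "consumer", 4),
  g("MM",   "Marine mammals",                         p, "consumer", 4),
  g("TUR",  "Sea turtles",                            p, "consumer", 4),
  g("XIP",  "Sword fish",                             p, "consumer", 4),
  g("THU",  "Bluefin tuna",                           p, "consumer", 4),
  g("LPL",  "Large pelagic fish",                     p, "consumer", 4),
  g("MPL",  "Medium pelagic fish",                    p, "consumer", 3),
  g("SPL",  "Other small pelagic fish",               p, "consumer", 2),
  g("HAK0", "European hake <6 cm",                    d, "consumer", 2),
  g("HAK1", "European hake 6-12 cm",                  d, "consumer", 3),
  g("HAK2", "European hake 12.1-22 cm",               d, "consumer", 3),
  g("HAK3", "European hake 22.1-41 cm",               d, "consumer", 4),
  g("HAK4", "European hake >41 cm",                   d, "consumer", 4),
  g("MUL0", "Red mullet <8 cm",                       d, "consumer", 2),
  g("MUL1", "Red mullet 8-12 cm",                     d, "consumer", 2),
  g("MUL2", "Red mullet 12.1-17 cm",                  d, "consumer", 3),
  g("MUL3", "Red mullet >17 cm",                      d, "consumer", 3),
  g("TRA",  "Horse mackerel",                         d, "consumer", 3),
  g("PAG",  "Pandora",                                d, "consumer", 3),
  g("DFS",  "Demersal fish (slope)",                  d, "consumer", 3),
  g("DFH",  "Demersal fish crustacean feeders (shelf)", d, "consumer", 3),
  g("DSM",  "Demersal fish mixed food (shelf)",       d, "consumer", 3),
  g("DSP",  "Demersal fish piscivorous (shelf)",      d, "consumer", 4),
  g("DSR",  "Demersal fish rocky (shelf)",            d, "consumer", 3),
  g("MSC",  "Mesopelagic fish crustacean feeders (slope)", d, "consumer", 3),
  g("MSG",  "Mesopelagic fish jelly feeders (slope)", d, "consumer", 3),
  g("MSP",  "Mesopelagic fish piscivorous (slope)",   d, "consumer", 4),
  g("RSH",  "Rays and skates (shelf)",                d, "consumer", 3),
  g("RSS",  "Rays and skates (slope)",                d, "consumer", 3),
  g("SSH",  "Sharks (shelf)",                         d, "consumer", 4),
  g("SSS",  "Sharks (slope)",                         d, "consumer", 4),
  g("ENG",  "European anchovy",                       p, "consumer", 2),
  g("SAR",  "European pilchard",                      p, "consumer", 2),
  g("EPI",  "Epipelagic fish",                        p, "consumer", 2),
  g("CEBH", "Cephalopods benthic (shelf)",            d, "consumer", 3),
  g("CEBS", "Cephalopods benthic (slope)",            d, "consumer", 3),
  g("CEPH", "Cephalopods pelagic (shelf)",            d, "consumer", 3),
  g("CEPS", "Cephalopods pelagic (slope)",            d, "consumer", 3),
  g("DNS",  "Decapods natant (slope)",                d, "consumer", 2),
  g("DNH",  "Decapods natant (shelf)",                d, "consumer", 2),
  g("DRS",  "Decapods reptant (slope)",               d, "consumer", 2),
  g("DRH",  "Decapods reptant (shelf)",               d, "consumer", 2),
  g("ARF",  "Giant red shrimp",                       d, "consumer", 2),
  g("PWL",  "Deep water rose shrimp",                 d, "consumer", 2),
  g("SUP",  "Suprabenthos",                           b, "consumer", 2),
  g("O",    "Macrobenthos omnivore",                  b, "consumer", 2),
  g("FF",   "Macrobenthos filter-feeder",             b, "consumer", 1),
  g("DF",   "Macrobenthos deposit-feeder",            b, "consumer", 1),
  g("C",    "Macrobenthos carnivore",                 b, "consumer", 2),
  g("PAR",  "Macrobenthos parasite",                  b, "consumer", 2),
  g("SCA",  "Macrobenthos scavenger",                 b, "consumer", 2),
  g("H",    "Macrobenthos herbivore",                 b, "consumer", 1),
  g("GRA",  "Macrobenthos grazer",                    b, "consumer", 1),
  g("SF",   "Macrobenthos suspension-feeder",         b, "consumer", 1),
  g("PF",   "Macrobenthos particulate-feeder",        b, "consumer", 1),
  g("BO",   "Meiobenthos",                            b, "consumer", 1),
  g("EUP",  "Euphausiacea",                           p, "consumer", 2),
  g("ZG",   "Gelatinous zooplankton",                 p, "consumer", 2),
  g("ZL",   "Large zooplankton",                      p, "consumer", 2),
  g("ZM",   "Mesozooplankton",                        p, "consumer", 1),
  g("ZS",   "Microzooplankton",                       p, "consumer", 1),
  g("PB",   "Pelagic bacteria",                       p, "consumer", 1),
  g("BB",   "Sediment bacteria",                      b, "consumer", 1),
  g("PS",   "Pico-phytoplankton",                     p, "producer", 0),
  g("DFL",  "Dinoflagellates",                        p, "producer", 0),
  g("PL",   "Diatom",                                 p, "producer", 0),
  g("MB",   "Microphytobenthos",                      b, "producer", 0),
  g("SG",   "Seagrass",                               b, "producer", 0),
  g("MA",   "Macroalgae",                             b, "producer", 0),
  g("DC",   "Detritus carrion",                       b, "detritus", 0),
  g("SPOM", "Suspended particulate organic matter",   d, "detritus", 0),
  g("BD",   "Benthic detritus",                       b, "detritus", 0)
)
stopifnot(nrow(structure_tbl) == 72, anyDuplicated(structure_tbl$group) == 0)

fleet_names <- c("1.GNS", "1.LLD", "1.LTL", "1.LH", "1.MIS", "1.PS",
                 "2.FPO", "2.GNS", "2.LLD", "2.MIS", "2.OTB_D", "2.OTB_DWS",
                 "2.OTB_MDD", "2.OTM", "2.PTM", "2.PS", "3.OTM",
                 "3.OTB_MDDW")
stopifnot(length(fleet_names) == 18)

cfg <- web_config(seed = 42L)
model <- generate_web(cfg, structure = structure_tbl,
                      fleet_names = fleet_names)
truth <- attr(model, "truth")

# bluefin tuna: 70% of consumption outside the model area (diet import)
sc <- sum(model$diet[, "THU"])
model$diet[, "THU"] <- model$diet[, "THU"] * 0.3 / sc
model$import["THU"] <- 0.7

# swordfish: immigration (negative net migration) balancing part of its catch,
# kept feasible against the synthetic production scale
i_xip <- match("XIP", model$groups$group)
removal_xip <- sum(model$diet["XIP", ] *
                     model$groups$B[match(colnames(model$diet),
                                          model$groups$group)] *
                     model$groups$QB[match(colnames(model$diet),
                                           model$groups$group)], na.rm = TRUE) +
  sum(model$landings["XIP", ] + model$discards["XIP", ])
model$groups$NM[i_xip] <- -min(0.025, 0.5 * removal_xip)

# unassimilated food and other mortality settle to benthic detritus for
# benthic/demersal groups and stay suspended for pelagic groups; discards
# sink as carrion (the fw_model default already routes them to DC)
living <- model$groups$group[model$groups$type != "detritus"]
dom <- model$groups$domain[match(living, model$groups$group)]
fate <- matrix(0, length(living), 3,
               dimnames = list(living, c("DC", "SPOM", "BD")))
fate[cbind(living, ifelse(dom == "pelagic", "SPOM", "BD"))] <- 1
model$detritus_fate <- fate

# B is the estimated parameter (EE given) for meiobenthos, euphausiids and
# microphytobenthos; everywhere else the solver estimates EE
model$groups$B <- truth$B[match(model$groups$group, truth$group)]
model$groups$EE <- NA_real_
for (code in c("BO", "EUP", "MB")) {
  i <- match(code, model$groups$group)
  model$groups$EE[i] <- truth$EE[match(code, truth$group)]
  model$groups$B[i] <- NA_real_
}

# sanity: solves, EE in (0, 1], impact propagation convergent
bal <- balance(model)
stopifnot(all(abs(bal$diagnostics$residual) < 1e-8))
ee <- tidy(bal)$EE[tidy(bal)$type != "detritus"]
stopifnot(all(ee > 0 & ee <= 1))
rho <- max(Mod(eigen(net_impact_matrix(bal), only.values = TRUE)$values))
cat(sprintf("fixture spectral radius: %.3f\n", rho))
stopifnot(rho < 1)

out <- file.path("inst", "extdata", "sos_synthetic")
write_model(model, out)
writeLines(c(
  "# sos_synthetic",
  "",
  "A SYNTHETIC parameterization on the published structure of the Strait of",
  "Sicily food-web model: 72 functional-group codes, long names and domain",
  "labels, 18 fleet segments, 3 detritus pools, a 70% diet import for",
  "bluefin tuna (THU), an immigration term for swordfish (XIP), and biomass",
  "estimated instead of ecotrophic efficiency for BO, EUP and MB.",
  "",
  "All numeric parameters (biomasses, rates, diet fractions, catches) are",
  "synthetic values from trophicweb's balanced-web generator",
  "(data-raw/sos_synthetic.R, seed 42). They are NOT the published values;",
  "use this model as a realistic-sized test bed only."
), file.path(out, "README.md"))
cat("written to", out, "\n")
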