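# hand-built miniature webs used across the suite; expected values for these
# are derived by hand (ledgers of flows, 2x2 inversions) in the tests

# producer eaten entirely by one consumer; consumer unexploited (EE = 0)
toy_two_group <- function(detritus = FALSE) {
  groups <- tibble::tibble(
    group = c("PP", "ZOO", if (detritus) "DET"),
    type = c("producer", "consumer", if (detritus) "detritus"),
    domain = "pelagic",
    B = c(10, 1, if (detritus) 1),
    PB = c(10, 2, if (detritus) NA),
    QB = c(NA, 10, if (detritus) NA),
    EE = c(NA, 0, if (detritus) NA))
  fw_model(groups, data.frame(prey = "PP", ZOO = 1), check = FALSE)
}

# two unknowns of different kinds: herbivore B and producer EE
toy_three_group <- function() {
  groups <- tibble::tibble(
    group = c("PP", "HRB", "CRN"),
    type = c("producer", "consumer", "consumer"),
    domain = c("pelagic", "pelagic", "demersal"),
    B = c(100, NA, 0.5),
    PB = c(5, 1, 0.8),
    QB = c(NA, 5, 3),
    EE = c(NA, 0.5, 0))
  diet <- data.frame(prey = c("PP", "HRB"), HRB = c(1, 0), CRN = c(0, 1))
  fw_model(groups, diet, check = FALSE)
}

# three trophic levels for TL/OI arithmetic: C2's in-system diet is 50%
# producer, 50% herbivore; both consumers feed half outside the system, which
# keeps the impact series convergent and, under the renormalised import
# convention, leaves the textbook TL/OI values intact
toy_tl_chain <- function() {
  groups <- tibble::tibble(
    group = c("P", "H", "C2"),
    type = c("producer", "consumer", "consumer"),
    domain = c("benthic", "demersal", "pelagic"),
    B = c(10, 1, 0.2),
    PB = c(10, 2, 1),
    QB = c(NA, 8, 5),
    EE = c(NA, NA, 0))
  diet <- data.frame(prey = c("P", "H", "import"),
                     H = c(0.5, 0, 0.5), C2 = c(0.25, 0.25, 0.5))
  fw_model(groups, diet, check = FALSE)
}

# one fished group: predation removes 0.3, the fleet 0.2 (40% of removal)
toy_fleet <- function() {
  groups <- tibble::tibble(
    group = c("P", "G", "X"),
    type = c("producer", "consumer", "consumer"),
    domain = "demersal",
    B = c(50, 1, 0.1),
    PB = c(10, 1, 1),
    QB = c(NA, 4, 3),
    EE = c(NA, NA, 0))
  diet <- data.frame(prey = c("P", "G"), G = c(1, 0), X = c(0, 1))
  landings <- data.frame(group = "G", FLT = 0.2)
  fw_model(groups, diet, landings = landings, check = FALSE)
}

# one fleet on a predator, one on its prey; the apex is partly cannibalistic
# so every removal denominator stays diluted and the impact series converges
toy_fleet2 <- function() {
  groups <- tibble::tibble(
    group = c("P", "G", "X"),
    type = c("producer", "consumer", "consumer"),
    domain = "demersal",
    B = c(50, 1, 0.5),
    PB = c(10, 1, 0.6),
    QB = c(NA, 4, 3),
    EE = c(NA, NA, NA))
  diet <- data.frame(prey = c("P", "G", "X", "import"),
                     G = c(0.25, 0, 0, 0.75),
                     X = c(0, 0.35, 0.30, 0.35))
  landings <- data.frame(group = c("G", "X"),
                         FLTG = c(0.3, 0), FLTX = c(0, 0.05))
  fw_model(groups, diet, landings = landings, check = FALSE)
}

balanced_default_web <- function(seed = 1, ...) {
  m <- suppressMessages(generate_web(web_config(seed = seed, ...)))
  suppressMessages(suppressWarnings(balance(m)))
}

# independent series oracle: the truncated Neumann sum S_n = q + ... + q^n,
# accumulated by doubling (S_2n = S_n + q^n S_n), so webs with spectral
# radius just under one still converge in ~60 steps
neumann_mti <- function(q, tol = 1e-13, max_doublings = 200) {
  S <- q
  P <- q
  for (k in seq_len(max_doublings)) {
    add <- P %*% S
    S <- S + add
    P <- P %*% P
    if (max(abs(add)) < tol) return(S)
  }
  stop("series did not converge")
}

# independent fixed-point oracle for fractional trophic levels
fixed_point_tl <- function(balanced, tol = 1e-13, max_n = 100000) {
  DC <- balanced$model$diet
  imp <- balanced$model$import[colnames(DC)]
  ok <- (1 - imp) > 1e-12
  DCr <- DC
  DCr[, ok] <- sweep(DC[, ok, drop = FALSE], 2, (1 - imp)[ok], "/")
  DCr[, !ok] <- 0
  g <- balanced$groups
  tl <- setNames(rep(1, nrow(g)), g$group)
  for (n in seq_len(max_n)) {
    new <- tl
    for (cc in colnames(DCr)) new[cc] <- 1 + sum(DCr[, cc] * tl)
    if (max(abs(new - tl)) < tol) return(new)
    tl <- new
  }
  stop("TL iteration did not converge")
}
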