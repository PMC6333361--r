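# balanced-by-construction synthetic food webs with domains, detritus, fleets

#' Configuration for the synthetic web generator
#'
#' Collects the knobs of [generate_web()] with defaults emulating a small
#' three-domain shelf ecosystem: layered consumers on top of benthic and
#' pelagic producers, two detritus pools, three fleets with landings and
#' discards, a biomass pyramid with vertex up, and diets drawn with fixed
#' connectance and Dirichlet weights.
#'
#' @param domains Domain labels (default benthic/demersal/pelagic).
#' @param n_producers,n_consumers Integer counts per domain (recycled if
#'   scalar). At least one producer overall is required.
#' @param n_layers Number of consumer layers (intended trophic strata).
#' @param n_detritus Number of detritus pools (>= 1); pool 1 is benthic, pool
#'   2 (if present) a suspended, non-benthic pool.
#' @param n_fleets Number of fishing fleets (>= 0).
#' @param connectance Probability that an eligible lower-layer prey enters a
#'   consumer's diet, in (0, 1].
#' @param ee_range Target range (lo, hi) in (0, 1) for the ecotrophic
#'   efficiencies implied by predation; consumer biomasses are shrunk so no
#'   prey exceeds `hi`.
#' @param import_prob,import_range Probability that a consumer feeds partly
#'   outside the system, and the range of that import fraction. The defaults
#'   give most consumers a sizeable import: the share leakage this creates
#'   keeps the direct-impact matrix comfortably inside the convergent regime
#'   (spectral radius < 1) required for Mixed Trophic Impact analysis.
#' @param diet_evenness Dirichlet shape for diet weights; larger values give
#'   more even diets (and weaker pairwise impacts).
#' @param fleet_coverage Probability that a fleet catches any given consumer;
#'   broad coverage splits removal shares across fleets.
#' @param gs Unassimilated fraction of consumption for all consumers.
#' @param pb_producer,pb_consumer,pq_range Plausible rate ranges:
#'   producer P/B in `[10, 200]` yr\eqn{^{-1}}; consumer P/B in `[0.2, 5]`
#'   decreasing with layer; P/Q in `[0.1, 0.35]`.
#' @param b_producer Producer biomass range (t km\eqn{^{-2}}).
#' @param pyramid_ratio Ratio of successive layer biomass totals (< 1 gives a
#'   pyramid with vertex up).
#' @param seed Integer seed driving the single pseudo-random stream.
#' @return A list of class `web_config`.
#' @export
web_config <- function(domains = c("benthic", "demersal", "pelagic"),
                       n_producers = c(2, 0, 2),
                       n_consumers = c(8, 8, 8),
                       n_layers = 3,
                       n_detritus = 2,
                       n_fleets = 3,
                       connectance = 0.6,
                       ee_range = c(0.2, 0.9),
                       import_prob = 1,
                       import_range = c(0.35, 0.6),
                       diet_evenness = 3,
                       fleet_coverage = 1,
                       gs = 0.2,
                       pb_producer = c(10, 200),
                       pb_consumer = c(0.2, 5),
                       pq_range = c(0.1, 0.35),
                       b_producer = c(20, 60),
                       pyramid_ratio = 0.25,
                       seed = 1L) {
  n_producers <- rep_len(as.integer(n_producers), length(domains))
  n_consumers <- rep_len(as.integer(n_consumers), length(domains))
  if (sum(n_producers) < 1) abort("need at least one producer")
  if (n_detritus < 1) abort("need at least one detritus pool")
  if (connectance <= 0 || connectance > 1) {
    abort("connectance must lie in (0, 1]")
  }
  if (!(ee_range[1] > 0 && ee_range[1] < ee_range[2] && ee_range[2] < 1)) {
    abort("ee_range must satisfy 0 < lo < hi < 1")
  }
  structure(list(
    domains = domains, n_producers = n_producers, n_consumers = n_consumers,
    n_layers = as.integer(n_layers), n_detritus = as.integer(n_detritus),
    n_fleets = as.integer(n_fleets), connectance = connectance,
    ee_range = ee_range, import_prob = import_prob,
    import_range = import_range, diet_evenness = diet_evenness,
    fleet_coverage = fleet_coverage, gs = gs, pb_producer = pb_producer,
    pb_consumer = pb_consumer, pq_range = pq_range, b_producer = b_producer,
    pyramid_ratio = pyramid_ratio, seed = as.integer(seed)),
    class = "web_config")
}

# build the generic group/layer skeleton implied by a config
config_structure <- function(config) {
  rows <- list()
  for (d in seq_along(config$domains)) {
    np <- config$n_producers[d]
    if (np > 0) {
      rows[[length(rows) + 1L]] <- tibble::tibble(
        group = sprintf("P%s%d", toupper(substr(config$domains[d], 1, 1)),
                        seq_len(np)),
        type = "producer", domain = config$domains[d], layer = 0L)
    }
    m <- config$n_consumers[d]
    if (m > 0) {
      # decreasing layer occupancy: weights halve per layer; the apex layer
      # keeps a single group per domain (few catch-only removal columns)
      w <- 2^(config$n_layers - seq_len(config$n_layers))
      cnt <- pmax(1L, floor(m * w / sum(w)))
      if (config$n_layers > 1 && m > config$n_layers) {
        cnt[config$n_layers] <- 1L
      }
      while (sum(cnt) > m) {
        i_hi <- which.max(cnt[-config$n_layers])
        cnt[i_hi] <- cnt[i_hi] - 1L
      }
      while (sum(cnt) < m) cnt[1L] <- cnt[1L] + 1L
      lay <- rep(seq_len(config$n_layers), cnt)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        group = sprintf("C%s%d", toupper(substr(config$domains[d], 1, 1)),
                        seq_len(m)),
        type = "consumer", domain = config$domains[d], layer = lay)
    }
  }
  pick <- function(want) {
    if (want %in% config$domains) want else config$domains[1]
  }
  det_dom <- c(pick("benthic"), pick("demersal"),
               rep(pick("benthic"), max(0, config$n_detritus - 2)))
  rows[[length(rows) + 1L]] <- tibble::tibble(
    group = sprintf("DET%d", seq_len(config$n_detritus)),
    type = "detritus", domain = det_dom[seq_len(config$n_detritus)],
    layer = 0L)
  out <- dplyr::bind_rows(rows)
  out$long_name <- out$group
  out
}

#' Generate a balanced-by-construction synthetic food web
#'
#' Builds a domain-labelled, layered food web whose true biomasses and
#' ecotrophic efficiencies are known by construction, then emits it as an
#' unbalanced [fw_model] with every living group's EE blanked — the balance
#' solver must recover them. Construction: (1) groups are layered by intended
#' trophic position; (2) each consumer samples prey from lower layers (and
#' the detritus pools) with the configured connectance and Dirichlet diet
#' weights, optionally with an import fraction; every non-top group is
#' guaranteed at least one predator; (3) P/B and Q/B are drawn from plausible
#' ranges decreasing with layer; (4) producer biomass sets the pyramid base
#' and each consumer layer's biomass is scaled so that no prey's implied EE
#' exceeds the target upper bound; (5) fleet catches take at most half of
#' each target's unconsumed production, so final EE stays below 1 (every
#' top-layer consumer is targeted when fleets exist); (6) the resulting
#' direct-impact matrix is checked for spectral radius < 1, regenerating with
#' an incremented sub-seed if needed (logged via a message).
#'
#' The generated model is deterministic given the seed and carries the truth
#' table as `attr(model, "truth")` (tibble `group`, `B`, `EE`).
#'
#' @param config A [web_config()].
#' @param structure Optional custom group skeleton: a data frame with columns
#'   `group`, `long_name`, `type`, `domain`, `layer` (producers and detritus
#'   at layer 0, consumers at 1..n_layers) that replaces the generic skeleton
#'   implied by the config counts.
#' @param fleet_names Optional character vector of fleet names (its length
#'   overrides `n_fleets`).
#' @return An [fw_model] with a `truth` attribute.
#' @seealso [perturb_for_recovery()]
#' @export
#' @examples
#' m <- generate_web(web_config(seed = 42))
#' b <- balance(m)
#' range(tidy(b)$EE[tidy(b)$type != "detritus"])  # inside (0, 1]
generate_web <- function(config = web_config(), structure = NULL,
                         fleet_names = NULL) {
  stopifnot(inherits(config, "web_config"))
  for (attempt in 0:24) {
    sub_seed <- config$seed + attempt * 1000L
    model <- withr::with_seed(sub_seed,
                              synthesize_web(config, structure, fleet_names))
    bal <- suppressWarnings(balance(model_with_truth(model)))
    rho <- max(Mod(eigen(net_impact_matrix(bal),
                         only.values = TRUE)$values))
    if (rho < 1 - 1e-9) {
      if (attempt > 0) {
        inform(sprintf(
          "generate_web: spectral radius >= 1; regenerated with sub-seed %d",
          sub_seed))
      }
      return(model)
    }
  }
  abort("generate_web: could not reach spectral radius < 1 in 25 attempts")
}

# apply the stored truth so a generated model can be balanced directly
model_with_truth <- function(model) {
  truth <- attr(model, "truth")
  m <- model
  idx <- match(truth$group, m$groups$group)
  m$groups$B[idx] <- truth$B
  m$groups$EE[idx] <- NA
  m
}

synthesize_web <- function(config, structure = NULL, fleet_names = NULL) {
  str_tbl <- structure %||% config_structure(config)
  str_tbl <- tibble::as_tibble(str_tbl)
  if (is.null(str_tbl$long_name)) str_tbl$long_name <- str_tbl$group
  n_layers_eff <- max(str_tbl$layer)
  codes <- str_tbl$group
  n <- nrow(str_tbl)
  is_cons <- str_tbl$type == "consumer"
  is_det <- str_tbl$type == "detritus"
  living <- codes[!is_det]
  layers <- str_tbl$layer

  # rates
  PB <- rep(NA_real_, n)
  PB[str_tbl$type == "producer"] <-
    runif(sum(str_tbl$type == "producer"),
          config$pb_producer[1], config$pb_producer[2])
  QB <- rep(NA_real_, n)
  for (l in seq_len(n_layers_eff)) {
    idx <- which(is_cons & layers == l)
    if (length(idx) == 0) next
    hi <- max(config$pb_consumer[1] * 2,
              config$pb_consumer[2] * 0.45^(l - 1))
    lo <- max(config$pb_consumer[1], hi * 0.3)
    PB[idx] <- runif(length(idx), lo, hi)
    QB[idx] <- PB[idx] / runif(length(idx), config$pq_range[1],
                               config$pq_range[2])
  }

  # diets; upper-layer consumers are partly cannibalistic, which keeps every
  # apex group's removal denominators positive even in unfished webs and, as
  # the self-loop is excluded from pairwise impacts, damps impact propagation
  DC <- matrix(0, n, sum(is_cons), dimnames = list(codes, codes[is_cons]))
  imp <- setNames(rep(0, sum(is_cons)), codes[is_cons])
  for (jj in seq_len(sum(is_cons))) {
    j <- which(is_cons)[jj]
    cand <- which(layers < layers[j] | is_det)
    cand <- setdiff(cand, j)
    if (length(cand) == 0) {
      abort(sprintf("infeasible config: no prey available for layer %d",
                    layers[j]))
    }
    take <- cand[runif(length(cand)) < config$connectance]
    if (length(take) == 0) take <- sample(cand, 1L)
    w <- rgamma(length(take), shape = config$diet_evenness)
    w[is_det[take]] <- w[is_det[take]] * 0.5   # detritivory stays moderate
    w <- w / sum(w)
    im <- 0
    if (runif(1) < config$import_prob) {
      im <- runif(1, config$import_range[1], config$import_range[2])
    }
    pq_j <- PB[j] / QB[j]
    canni <- 0
    if (layers[j] == n_layers_eff ||
        (layers[j] >= 2 && runif(1) < 0.3)) {
      # self-diet share scaled by P/Q so cannibalism alone implies a
      # self-EE of 0.2-0.4, far below the overall EE ceiling
      canni <- min(runif(1, 0.2, 0.4) * pq_j, 0.5 * (1 - im))
    }
    DC[take, jj] <- w * (1 - im - canni)
    DC[j, jj] <- canni
    imp[jj] <- im
  }
  # every non-top living group needs predators; at least two where the web
  # allows it, so no single consumer dominates any prey's removal
  top_layer <- n_layers_eff
  for (i in which(!is_det & layers < top_layer)) {
    higher <- which(is_cons & layers > layers[i])
    need <- min(2L, length(higher))
    have <- which(DC[i, ] > 0)
    short <- need - length(have)
    if (short <= 0) next
    pool <- setdiff(match(codes[higher], colnames(DC)), have)
    for (jj in sample(pool, min(short, length(pool)))) {
      share <- 0.1 * (1 - imp[jj])
      DC[, jj] <- DC[, jj] * (1 - imp[jj] - share) / sum(DC[, jj])
      DC[i, jj] <- DC[i, jj] + share
    }
  }

  # biomasses, layer by layer, capping implied EE at ee_range[2]
  B <- rep(NA_real_, n)
  B[str_tbl$type == "producer"] <-
    runif(sum(str_tbl$type == "producer"),
          config$b_producer[1], config$b_producer[2])
  B[is_det] <- 1
  prev_total <- sum(B[str_tbl$type == "producer"])
  demand <- setNames(rep(0, n), codes)     # accumulated predation per group
  for (l in seq_len(n_layers_eff)) {
    idx <- which(is_cons & layers == l)
    if (length(idx) == 0) next
    # each layer sits below the previous layer's realized total, so the
    # pyramid (vertex up) survives any EE-cap shrinking applied earlier
    tot_l <- prev_total * config$pyramid_ratio
    w <- rgamma(length(idx), shape = 2)
    B[idx] <- tot_l * w / sum(w)
    new_dem <- setNames(rep(0, n), codes)
    for (j in idx) new_dem <- new_dem + B[j] * QB[j] * DC[, codes[j]]
    live_prey <- which(!is_det & new_dem > 0)
    if (length(live_prey) > 0) {
      cap <- config$ee_range[2] * B[live_prey] * PB[live_prey] -
        demand[live_prey]
      if (any(cap <= 0)) {
        abort(sprintf(
          "infeasible config: no predation capacity left at layer %d", l))
      }
      s <- min(1, 0.9 * min(cap / new_dem[live_prey]))
      if (s < 1) {
        B[idx] <- B[idx] * s
        new_dem <- new_dem * s
      }
    }
    demand <- demand + new_dem
    prev_total <- sum(B[idx])
  }

  # recompute demand cleanly from final biomasses
  demand <- setNames(rep(0, n), codes)
  for (jj in seq_len(ncol(DC))) {
    j <- which(codes == colnames(DC)[jj])
    demand <- demand + B[j] * QB[j] * DC[, jj]
  }
  P <- ifelse(is_det, 0, B * PB)
  ee_pred <- ifelse(is_det, NA, ifelse(P > 0, demand[codes] / P, 0))

  # fleets: catch at most half of the unconsumed production
  fleets <- fleet_names %||%
    (if (config$n_fleets > 0) sprintf("FLT%d", seq_len(config$n_fleets))
     else character(0))
  landings <- matrix(0, n, length(fleets), dimnames = list(codes, fleets))
  discards <- matrix(0, n, length(fleets), dimnames = list(codes, fleets))
  if (length(fleets) > 0) {
    cons_idx <- which(is_cons)
    targeted <- matrix(runif(length(cons_idx) * length(fleets)) <
                         config$fleet_coverage,
                       length(cons_idx), length(fleets))
    # top-layer consumers must be fished so their EE stays positive, and by
    # several fleets where possible so no fleet is a sole remover
    need <- max(1L, min(2L, length(fleets)))
    for (t in which(layers[cons_idx] == top_layer)) {
      short <- need - sum(targeted[t, ])
      if (short > 0) {
        targeted[t, sample(which(!targeted[t, ]), short)] <- TRUE
      }
    }
    for (t in seq_along(cons_idx)) {
      fs <- which(targeted[t, ])
      if (length(fs) == 0) next
      i <- cons_idx[t]
      # light exploitation, well under the 0.5 * slack cap that keeps EE < 1;
      # for predated groups the catch also stays a minor share of total
      # removal so no fleet dominates any group's mortality
      tot_catch <- runif(1, 0.05, 0.3) * 0.5 * (1 - ee_pred[i]) * P[i]
      if (demand[i] > 0) tot_catch <- min(tot_catch, 0.2 * demand[i])
      w <- rgamma(length(fs), shape = 8); w <- w / sum(w)
      dr <- runif(1, 0.1, 0.5)
      landings[i, fs] <- tot_catch * w * (1 - dr)
      discards[i, fs] <- tot_catch * w * dr
    }
  }

  Y <- row_sums(landings) + row_sums(discards)
  EE_true <- ifelse(is_det, NA, ifelse(P > 0, (demand[codes] + Y) / P, 0))

  groups <- tibble::tibble(
    group = codes, long_name = str_tbl$long_name, type = str_tbl$type,
    domain = str_tbl$domain,
    B = B, PB = PB, QB = QB, PQ = NA_real_,
    EE = NA_real_,
    GS = ifelse(is_cons, config$gs, 0),
    BA = 0, NM = 0)

  model <- fw_model(groups, rbind(DC, import = imp),
                    landings = landings, discards = discards, check = FALSE)
  attr(model, "truth") <- tibble::tibble(
    group = codes[!is_det], B = B[!is_det], EE = EE_true[!is_det])
  attr(model, "layers") <- setNames(layers, codes)
  model
}

#' Hide parameters of a generated web for recovery testing
#'
#' Takes a model with a known truth table (from [generate_web()]) and emits a
#' model definition where, for each selected group, exactly one of `B`/`EE`
#' is blanked and the other fixed at its true value; unselected living groups
#' keep their full (consistent) parameterization. The truth table travels
#' along in `attr(, "truth")` for the test harness.
#'
#' @param model An [fw_model] carrying a `truth` attribute.
#' @param hide Named character vector: names are living group codes, values
#'   `"B"` or `"EE"` saying which parameter to hide for that group. A group
#'   may appear only once.
#' @return An [fw_model] with a `truth` attribute.
#' @export
perturb_for_recovery <- function(model, hide) {
  stopifnot(inherits(model, "fw_model"))
  truth <- attr(model, "truth")
  if (is.null(truth)) abort("`model` must carry a truth attribute")
  if (is.null(names(hide)) || !all(hide %in% c("B", "EE"))) {
    abort("`hide` must be a named vector of \"B\"/\"EE\" choices")
  }
  if (anyDuplicated(names(hide))) {
    abort("cannot hide both B and EE for one group")
  }
  bad <- setdiff(names(hide), truth$group)
  if (length(bad) > 0) {
    abort(paste("unknown or non-living group(s) in `hide`:",
                paste(bad, collapse = ", ")))
  }
  m <- model
  idx <- match(truth$group, m$groups$group)
  m$groups$B[idx] <- truth$B
  m$groups$EE[idx] <- truth$EE
  for (gname in names(hide)) {
    i <- match(gname, m$groups$group)
    if (hide[[gname]] == "B") m$groups$B[i] <- NA else m$groups$EE[i] <- NA
  }
  attr(m, "truth") <- truth
  m
}
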