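# fisheries exploitation and benthic-pelagic coupling decompositions

#' Exploitation rates and cumulative fleet exploitation
#'
#' Direct fishing pressure per group and per fleet. For group \eqn{i}:
#' fishing mortality \eqn{F_i = \sum_f Y_{if} / B_i} (catch = landings +
#' discards), total mortality \eqn{Z_i = PB_i} (the steady-state identity),
#' and exploitation rate \eqn{E_i = F_i / Z_i}. Each fleet's cumulative
#' exploitation rate sums its per-group contributions:
#' \eqn{CumE_f = \sum_i (Y_{if} / B_i) / Z_i}.
#'
#' @param balanced An `fw_balanced` object with fleets.
#' @return An object of class `fw_exploitation`: list with
#'   \describe{
#'     \item{groups}{tibble `group`, `domain`, `catch`, `F`, `Z`, `E` over
#'       living groups.}
#'     \item{fleets}{tibble `fleet`, `CumE`.}
#'     \item{contributions}{long tibble `group`, `fleet`, `E` of per-fleet
#'       exploitation contributions (zero rows omitted).}
#'   }
#' @export
exploitation <- function(balanced) {
  stopifnot(inherits(balanced, "fw_balanced"))
  g <- balanced$groups
  model <- balanced$model
  living <- g$type != "detritus"
  catch <- (model$landings + model$discards)[g$group[living], , drop = FALSE]
  B <- g$B[living]
  Z <- g$PB[living]
  Ftot <- row_sums(catch) / B
  E <- Ftot / Z
  groups <- tibble::tibble(
    group = g$group[living], domain = g$domain[living],
    catch = unname(row_sums(catch)), F = unname(Ftot), Z = unname(Z),
    E = unname(E))
  contrib_m <- sweep(catch, 1, B * Z, "/")
  fleets <- tibble::tibble(
    fleet = colnames(catch),
    CumE = unname(col_sums(contrib_m)))
  contributions <- tibble::as_tibble(
    as.data.frame.table(contrib_m, stringsAsFactors = FALSE))
  names(contributions) <- c("group", "fleet", "E")
  contributions <- dplyr::filter(contributions, .data$E > 0)
  structure(list(groups = groups, fleets = fleets,
                 contributions = contributions),
            class = "fw_exploitation")
}

#' @export
print.fw_exploitation <- function(x, ...) {
  cat(sprintf("<fw_exploitation> %d groups, %d fleets\n",
              nrow(x$groups), nrow(x$fleets)))
  top <- dplyr::slice_max(x$groups, .data$E, n = 5)
  cat("  most exploited:",
      paste(sprintf("%s (E=%.2f)", top$group, top$E), collapse = ", "), "\n")
  invisible(x)
}

#' @describeIn exploitation Per-group exploitation tibble.
#' @param x An `fw_exploitation` object.
#' @param ... Unused.
#' @method tidy fw_exploitation
#' @export
tidy.fw_exploitation <- function(x, ...) x$groups

#' Per-fleet discard ratios
#'
#' Descriptive discard intensity per fleet under the two common definitions:
#' discards over total catch and discards over landings.
#'
#' @param balanced An `fw_balanced` object.
#' @return Tibble `fleet`, `landings`, `discards`,
#'   `ratio_catch` (= D / (L + D)), `ratio_landings` (= D / L).
#' @export
discard_ratio <- function(balanced) {
  stopifnot(inherits(balanced, "fw_balanced"))
  L <- col_sums(balanced$model$landings)
  D <- col_sums(balanced$model$discards)
  tibble::tibble(
    fleet = colnames(balanced$model$landings),
    landings = unname(L), discards = unname(D),
    ratio_catch = unname(ifelse(L + D > 0, D / (L + D), NA_real_)),
    ratio_landings = unname(ifelse(L > 0, D / L, NA_real_)))
}

#' Cross-domain consumption fluxes
#'
#' Quantifies benthic–pelagic coupling by direct trophic flow: for each group
#' `g` in domain `D`, the consumer flux is the consumption by `g` of prey
#' outside `D`, and the source flux is the predation on `g` by consumers
#' outside `D` (t km\eqn{^{-2}} yr\eqn{^{-1}}). Counterpart groups listed in
#' `exclude` (typically lower-trophic-level compartments whose huge fluxes
#' would swamp the comparison) are left out of both sums.
#'
#' @param balanced An `fw_balanced` object with domain labels.
#' @param exclude Character vector of group codes excluded from the
#'   counterpart sets (default none). Unknown codes are an error.
#' @return Tibble `group`, `domain`, `type`, `consumer_flux`, `source_flux`.
#' @export
cross_domain_flux <- function(balanced, exclude = NULL) {
  stopifnot(inherits(balanced, "fw_balanced"))
  g <- balanced$groups
  exclude <- exclude %||% character(0)
  bad <- setdiff(exclude, g$group)
  if (length(bad) > 0) {
    abort(paste("unknown group(s) in `exclude`:", paste(bad, collapse = ", ")))
  }
  Tm <- balanced$flows
  dom <- setNames(g$domain, g$group)
  consumer_flux <- setNames(rep(0, nrow(g)), g$group)
  source_flux <- setNames(rep(0, nrow(g)), g$group)
  for (cc in colnames(Tm)) {
    other <- rownames(Tm)[dom[rownames(Tm)] != dom[cc] &
                            !rownames(Tm) %in% exclude]
    consumer_flux[cc] <- sum(Tm[other, cc])
  }
  for (p in rownames(Tm)) {
    other <- colnames(Tm)[dom[colnames(Tm)] != dom[p] &
                            !colnames(Tm) %in% exclude]
    source_flux[p] <- sum(Tm[p, other])
  }
  tibble::tibble(group = g$group, domain = g$domain, type = g$type,
                 consumer_flux = unname(consumer_flux[g$group]),
                 source_flux = unname(source_flux[g$group]))
}

#' Cross-domain impact decomposition
#'
#' Splits each living group's total (direct + indirect) impacts by target
#' domain membership: the positive and negative parts of its summed impact on
#' living groups of the *other* domains, and of the impact it receives from
#' them. Fleets and detritus pools are excluded from the domain sums.
#'
#' @param impact An `fw_mti` object computed on a balanced model with
#'   domain-labelled groups.
#' @return Tibble `group`, `domain`, `impact_out_pos`, `impact_out_neg`,
#'   `impact_in_pos`, `impact_in_neg` (positives \eqn{\ge 0}, negatives
#'   \eqn{\le 0}).
#' @export
cross_domain_impact <- function(impact) {
  stopifnot(inherits(impact, "fw_mti"))
  comps <- impact$components
  liv <- comps$component[comps$kind == "group"]
  dom <- setNames(comps$domain, comps$component)
  M <- impact$M[liv, liv, drop = FALSE]
  out <- purrr::map_dfr(liv, function(gg) {
    other <- liv[dom[liv] != dom[gg] & liv != gg]
    mo <- M[gg, other]
    mi <- M[other, gg]
    tibble::tibble(
      group = gg, domain = unname(dom[gg]),
      impact_out_pos = sum(pmax(mo, 0)),
      impact_out_neg = sum(pmin(mo, 0)),
      impact_in_pos = sum(pmax(mi, 0)),
      impact_in_neg = sum(pmin(mi, 0)))
  })
  out
}
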