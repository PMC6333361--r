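# fractional trophic levels, omnivory, system-level flow statistics

# diet renormalised over in-system prey (or with import as a TL-1 prey)
effective_diet <- function(balanced,
                           import_convention = c("renormalise", "tl1")) {
  import_convention <- match.arg(import_convention)
  DC <- balanced$model$diet
  imp <- balanced$model$import[colnames(DC)]
  if (import_convention == "renormalise") {
    denom <- 1 - imp
    DC2 <- DC
    ok <- denom > 1e-12
    DC2[, ok] <- sweep(DC[, ok, drop = FALSE], 2, denom[ok], "/")
    DC2[, !ok] <- 0
    list(DC = DC2, import = setNames(rep(0, length(imp)), names(imp)),
         all_import = !ok)
  } else {
    list(DC = DC, import = imp, all_import = imp >= 1 - 1e-12)
  }
}

#' Fractional trophic levels
#'
#' Producers and detritus sit at trophic level 1; each consumer sits one level
#' above the diet-weighted mean of its prey:
#' \eqn{TL_j = 1 + \sum_i DC'_{ij} TL_i}, solved as a single linear system.
#'
#' `DC'` is the diet with the import fraction handled according to
#' `import_convention`:
#' \describe{
#'   \item{`"renormalise"` (default)}{imports are excluded and the in-system
#'     diet renormalised to 1, i.e. the imported food is assumed to have the
#'     consumer's mean in-system prey TL. This keeps a large import fraction
#'     (e.g. a migratory predator feeding mostly outside the system) from
#'     dragging its TL toward 2.}
#'   \item{`"tl1"`}{the import is treated as an extra prey of TL 1.}
#' }
#' A consumer whose diet is 100\% import has no in-system prey; it is assigned
#' TL 2 with a warning.
#'
#' @param balanced An `fw_balanced` object.
#' @param import_convention See Details.
#' @return Tibble with columns `group`, `domain`, `type`, `TL`.
#' @export
#' @examples
#' b <- balance(toy <- fw_model(
#'   tibble::tibble(group = c("PP", "ZOO"), type = c("producer", "consumer"),
#'                  domain = "pelagic", B = c(10, 1), PB = c(10, 2),
#'                  QB = c(NA, 10), EE = c(NA, 0)),
#'   data.frame(prey = "PP", ZOO = 1), check = FALSE))
#' trophic_levels(b)
trophic_levels <- function(balanced,
                           import_convention = c("renormalise", "tl1")) {
  stopifnot(inherits(balanced, "fw_balanced"))
  ed <- effective_diet(balanced, import_convention)
  g <- balanced$groups
  codes <- g$group
  n <- length(codes)
  is_cons <- g$type == "consumer"

  if (any(ed$all_import)) {
    warn(paste("consumer(s) with fully imported diet assigned TL 2:",
               paste(names(ed$all_import)[ed$all_import], collapse = ", ")))
  }

  # (I - W) TL = rhs ; W holds prey weights for consumer rows only
  W <- matrix(0, n, n, dimnames = list(codes, codes))
  cons_codes <- colnames(ed$DC)
  for (cc in cons_codes) {
    W[cc, ] <- ed$DC[codes, cc]
  }
  rhs <- rep(1, n)
  # import under "tl1" contributes import * TL(1) to the prey-weighted mean
  rhs[match(cons_codes, codes)] <- 1 + ed$import[cons_codes] * 1
  rhs[!is_cons] <- 1
  W[!is_cons, ] <- 0
  # fully-imported consumers: TL = 2 by convention
  full <- names(ed$all_import)[ed$all_import]
  if (length(full) > 0) {
    W[full, ] <- 0
    rhs[match(full, codes)] <- 2
  }
  TL <- drop(solve(diag(n) - W, rhs))
  tibble::tibble(group = codes, domain = g$domain, type = g$type,
                 TL = unname(TL))
}

#' Omnivory indices
#'
#' A consumer's omnivory index is the diet-weighted variance of its prey
#' trophic levels about their mean (\eqn{TL_j - 1}):
#' \eqn{OI_j = \sum_i DC'_{ij} (TL_i - (TL_j - 1))^2}. Producers and detritus
#' have OI 0 (and single-prey consumers too).
#'
#' @inheritParams trophic_levels
#' @param tl Optional result of [trophic_levels()] (recomputed if missing;
#'   pass it to guarantee a consistent import convention).
#' @return Tibble with columns `group`, `domain`, `type`, `TL`, `OI`.
#' @seealso [system_omnivory()]
#' @export
omnivory <- function(balanced, tl = NULL,
                     import_convention = c("renormalise", "tl1")) {
  stopifnot(inherits(balanced, "fw_balanced"))
  import_convention <- match.arg(import_convention)
  if (is.null(tl)) {
    tl <- suppressWarnings(trophic_levels(balanced, import_convention))
  }
  ed <- effective_diet(balanced, import_convention)
  TL <- setNames(tl$TL, tl$group)
  oi <- setNames(rep(0, nrow(tl)), tl$group)
  for (cc in colnames(ed$DC)) {
    w <- ed$DC[, cc]
    mean_prey <- TL[cc] - 1
    v <- sum(w * (TL[names(w)] - mean_prey)^2)
    # under "tl1" the import behaves as a TL-1 prey
    v <- v + ed$import[cc] * (1 - mean_prey)^2
    oi[cc] <- v
  }
  out <- tl
  out$OI <- unname(oi[out$group])
  out
}

#' System omnivory index
#'
#' The system omnivory index (SOI) is the mean consumer omnivory index
#' weighted by the logarithm of each consumer's food intake:
#' \eqn{SOI = \sum_j OI_j \log Q_j / \sum_j \log Q_j} (natural log).
#' Consumers with \eqn{Q_j \le 1} t km\eqn{^{-2}} yr\eqn{^{-1}} would get
#' non-positive weights; they are weighted by \eqn{\log(1 + Q_j)} instead.
#'
#' @inheritParams omnivory
#' @param oi Optional result of [omnivory()].
#' @return A single number.
#' @export
system_omnivory <- function(balanced, oi = NULL,
                            import_convention = c("renormalise", "tl1")) {
  stopifnot(inherits(balanced, "fw_balanced"))
  if (is.null(oi)) {
    oi <- suppressWarnings(omnivory(balanced,
                                    import_convention = import_convention))
  }
  g <- balanced$groups
  cons <- g$group[g$type == "consumer"]
  q <- setNames(g$Q, g$group)[cons]
  w <- ifelse(q > 1, log(q), log1p(q))
  ok <- w > 0
  if (!any(ok)) return(NA_real_)
  sum(oi$OI[match(cons, oi$group)][ok] * w[ok]) / sum(w[ok])
}

#' System-level flow statistics
#'
#' Totals over the balanced web (t km\eqn{^{-2}} yr\eqn{^{-1}} unless
#' dimensionless): total production \eqn{\sum B \cdot PB} over living groups,
#' total consumption \eqn{\sum Q}, total respiration, total flow into
#' detritus, total export (landings + detritus export + net migration +
#' biomass accumulation), total system throughput
#' \eqn{TST = consumption + exports + respiration + flows\ into\ detritus},
#' net primary production PP, PP/R, PP/B (B summed over living groups) and
#' the system omnivory index. A web with no respiration reports `PP/R = Inf`.
#'
#' @inheritParams omnivory
#' @return One-row tibble.
#' @export
system_statistics <- function(balanced,
                              import_convention = c("renormalise", "tl1")) {
  stopifnot(inherits(balanced, "fw_balanced"))
  g <- balanced$groups
  living <- g$type != "detritus"
  total_production <- sum(g$P[living])
  total_consumption <- sum(g$Q[living])
  total_respiration <- sum(g$R[living])
  det <- balanced$detritus
  total_flow_to_detritus <- sum(det$inflow)
  total_export <- sum(balanced$model$landings) + sum(det$export) +
    sum(g$NM[living]) + sum(g$BA[living])
  tst <- total_consumption + total_export + total_respiration +
    total_flow_to_detritus
  pp <- sum(g$P[g$type == "producer"])
  soi <- system_omnivory(balanced, import_convention = import_convention)
  tibble::tibble(
    total_production = total_production,
    total_consumption = total_consumption,
    total_respiration = total_respiration,
    total_flow_to_detritus = total_flow_to_detritus,
    total_export = total_export,
    TST = tst,
    PP = pp,
    PP_R = if (total_respiration > 0) pp / total_respiration else Inf,
    PP_B = pp / sum(g$B[living]),
    SOI = soi
  )
}
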