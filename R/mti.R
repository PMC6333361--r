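# Mixed Trophic Impact: direct net-impact matrix, Leontief-style inversion,
# cumulative impact vectors, fleet sub-views

#' Direct net-impact matrix
#'
#' Builds the square matrix of direct pairwise net impacts over all model
#' components — living groups, detritus pools and fishing fleets — defined as
#' \eqn{q_{ij} = d_{ji} - f_{ij}}:
#' \describe{
#'   \item{\eqn{d_{ji}}}{the fraction component `i` contributes to the intake
#'     of `j`: the diet fraction for a consumer `j`, the catch composition
#'     \eqn{Y_{if} / \sum Y_{\cdot f}} for a fleet `j`, and the inflow
#'     composition (including fleet discards) for a detritus pool `j`.}
#'   \item{\eqn{f_{ij}}}{the fraction of the total removal of `j` — all
#'     predation plus all catches — attributable to consumer or fleet `i`.
#'     Other (non-predation, non-catch) mortality is not part of the
#'     denominator, so fleet impacts are commensurate with predation.}
#' }
#' Fleets are never removed by anything (no negative impacts on fleets) and
#' detritus never removes anything. Landings leave the system; discards feed
#' the detritus pools, giving fleets a positive direct impact on detritus in
#' proportion to their discard contribution. A component with zero total
#' removal receives no negative impacts. The diagonal is set to 0.
#'
#' @param balanced An `fw_balanced` object.
#' @return A square numeric matrix with component codes as dimnames and a
#'   `components` attribute (tibble with `component`, `kind`, `domain`).
#' @seealso [mti()]
#' @export
net_impact_matrix <- function(balanced) {
  stopifnot(inherits(balanced, "fw_balanced"))
  g <- balanced$groups
  model <- balanced$model
  fleets <- colnames(model$landings)
  comp <- c(g$group, fleets)
  kind <- c(ifelse(g$type == "detritus", "detritus", "group"),
            rep("fleet", length(fleets)))
  nc <- length(comp)

  catch <- model$landings + model$discards     # group x fleet
  Tm <- balanced$flows                          # prey x consumer

  # d[j, i]: contribution of i to the intake of j
  d <- matrix(0, nc, nc, dimnames = list(comp, comp))
  for (cc in colnames(Tm)) d[cc, rownames(model$diet)] <- model$diet[, cc]
  det <- balanced$detritus
  if (nrow(det) > 0) {
    living <- g$group[g$type != "detritus"]
    loss <- setNames(
      g$U[match(living, g$group)] +
        g$M0[match(living, g$group)] * g$B[match(living, g$group)], living)
    disc_tot <- col_sums(model$discards)
    for (p in det$pool) {
      if (det$inflow[det$pool == p] <= 0) next
      contrib <- loss * model$detritus_fate[living, p]
      d[p, living] <- contrib / det$inflow[det$pool == p]
      if (length(fleets) > 0) {
        d[p, fleets] <- disc_tot * model$discard_fate[, p] /
          det$inflow[det$pool == p]
      }
    }
  }
  for (f in fleets) {
    tot <- sum(catch[, f])
    if (tot > 0) d[f, rownames(catch)] <- catch[, f] / tot
  }

  # f[i, j]: share of the total removal of j attributable to i; for living
  # groups the denominator is all predation plus all catches. For a detritus
  # pool the denominator is its total inflow: consumption of a pool that
  # mostly exports removes little of what the pool receives, so detritivory
  # on such a pool exerts a proportionally weak negative impact.
  removal <- row_sums(Tm) + row_sums(catch)    # per group (incl. detritus)
  if (nrow(det) > 0) {
    removal[det$pool] <- pmax(det$inflow, removal[det$pool])
  }
  fmat <- matrix(0, nc, nc, dimnames = list(comp, comp))
  for (j in g$group) {
    if (removal[j] <= 0) next
    fmat[colnames(Tm), j] <- Tm[j, ] / removal[j]
    if (length(fleets) > 0) fmat[fleets, j] <- catch[j, ] / removal[j]
  }

  q <- t(d) - fmat
  diag(q) <- 0
  attr(q, "components") <- tibble::tibble(
    component = comp, kind = kind,
    domain = c(g$domain, rep(NA_character_, length(fleets))))
  q
}

#' Mixed Trophic Impact analysis
#'
#' Propagates the direct net impacts through all indirect pathways with the
#' Leontief-style inversion \eqn{M = (I - q)^{-1} - I}, so that `M[i, j]` is
#' the total (direct plus indirect) impact of component `i` on component `j`
#' for a small sustained increase in `i`. Requires the spectral radius of `q`
#' to be below 1 (otherwise the impact series does not converge and an error
#' is raised).
#'
#' The overall cumulative impact exerted by `i` is the signed row sum
#' \eqn{\epsilon_i = \sum_{j \ne i} M_{ij}}; the cumulative impact suffered is
#' the column sum. The root-sum-of-squares variant used in some keystoneness
#' work is also reported (`epsilon_rss`), but the signed sum is the default
#' ranking.
#'
#' @param x Either a direct-impact matrix from [net_impact_matrix()] or an
#'   `fw_balanced` object (the matrix is then built internally).
#' @return An object of class `fw_mti`: list with `components` (tibble), `q`,
#'   `M` (matrices) and `impacts` (tibble with `component`, `kind`, `domain`,
#'   `epsilon`, `suffered`, `epsilon_rss`).
#' @export
#' @examples
#' q <- matrix(c(0, -1, 1, 0), 2, 2, dimnames = list(c("P", "C"), c("P", "C")))
#' mti(q)$M  # closed form: [[-0.5, 0.5], [-0.5, -0.5]]
mti <- function(x) {
  if (inherits(x, "fw_balanced")) {
    q <- net_impact_matrix(x)
  } else {
    q <- x
    if (!is.matrix(q) || nrow(q) != ncol(q)) {
      abort("`x` must be an fw_balanced object or a square matrix")
    }
    if (is.null(rownames(q))) {
      dimnames(q) <- list(paste0("c", seq_len(nrow(q))),
                          paste0("c", seq_len(nrow(q))))
    }
  }
  comps <- attr(q, "components") %||% tibble::tibble(
    component = rownames(q), kind = "group", domain = NA_character_)
  rho <- max(Mod(eigen(q, only.values = TRUE)$values))
  if (!is.finite(rho) || rho >= 1 + 1e-8) {
    abort(sprintf(
      "non-convergent impact propagation: spectral radius %.3f >= 1", rho))
  }
  if (rho >= 1 - 1e-12) {
    # a unit eigenvalue (e.g. an isolated predator-prey pair) leaves I - q
    # invertible even though the impact series itself does not converge
    warn(sprintf(
      "impact propagation marginally non-convergent (spectral radius %.6f); returning the matrix inverse",
      rho))
  }
  n <- nrow(q)
  M <- tryCatch(solve(diag(n) - q),
                error = function(e) abort("I - q is singular")) - diag(n)
  dimnames(M) <- dimnames(q)
  eps <- rowSums(M) - diag(M)
  suf <- colSums(M) - diag(M)
  off <- M; diag(off) <- 0
  eps_rss <- sqrt(rowSums(off^2))
  impacts <- comps
  impacts$epsilon <- unname(eps)
  impacts$suffered <- unname(suf)
  impacts$epsilon_rss <- unname(eps_rss)
  structure(list(components = comps, q = q, M = M, impacts = impacts,
                 spectral_radius = rho),
            class = "fw_mti")
}

#' @export
print.fw_mti <- function(x, ...) {
  cat(sprintf("<fw_mti> %d components (%d groups, %d detritus, %d fleets)\n",
              nrow(x$components), sum(x$components$kind == "group"),
              sum(x$components$kind == "detritus"),
              sum(x$components$kind == "fleet")))
  cat(sprintf("  spectral radius of q: %.3f\n", x$spectral_radius))
  top <- dplyr::slice_max(x$impacts, .data$epsilon, n = 3)
  cat("  top epsilon:",
      paste(sprintf("%s (%.2f)", top$component, top$epsilon),
            collapse = ", "), "\n")
  invisible(x)
}

#' @describeIn mti Long tibble of total impacts `(impactor, impacted,
#'   direct, total)`.
#' @param ... Unused.
#' @method tidy fw_mti
#' @export
tidy.fw_mti <- function(x, ...) {
  out <- tibble::as_tibble(as.data.frame.table(x$M, stringsAsFactors = FALSE))
  names(out) <- c("impactor", "impacted", "total")
  qd <- as.data.frame.table(x$q, stringsAsFactors = FALSE)
  out$direct <- qd$Freq
  out[, c("impactor", "impacted", "direct", "total")]
}

#' @describeIn mti One-row summary (components, spectral radius, impact
#'   extremes).
#' @method glance fw_mti
#' @export
glance.fw_mti <- function(x, ...) {
  tibble::tibble(
    n_components = nrow(x$components),
    n_fleets = sum(x$components$kind == "fleet"),
    spectral_radius = x$spectral_radius,
    max_epsilon = max(x$impacts$epsilon),
    min_epsilon = min(x$impacts$epsilon)
  )
}

#' Fleet-centred views of the impact matrix
#'
#' Extracts the fleet-on-group and fleet-on-fleet sub-matrices of the total
#' impact matrix, preserving component order, and attaches sign summaries:
#' fleet-on-fleet negatives are competitive conflicts, positives indirect
#' benefits.
#'
#' @param impact An `fw_mti` object.
#' @return List with `fleet_on_group` and `fleet_on_fleet` matrices (possibly
#'   0-row) and `summary`, a tibble per fleet with counts of benefited and
#'   impacted groups/fleets.
#' @export
fleet_views <- function(impact) {
  stopifnot(inherits(impact, "fw_mti"))
  comps <- impact$components
  fl <- comps$component[comps$kind == "fleet"]
  gr <- comps$component[comps$kind != "fleet"]
  fog <- impact$M[fl, gr, drop = FALSE]
  fof <- impact$M[fl, fl, drop = FALSE]
  if (length(fl) == 0) {
    return(list(fleet_on_group = fog, fleet_on_fleet = fof,
                summary = tibble::tibble(fleet = character(),
                                         groups_pos = integer(),
                                         groups_neg = integer(),
                                         fleets_pos = integer(),
                                         fleets_neg = integer())))
  }
  off_diag <- fof; diag(off_diag) <- NA
  summary <- tibble::tibble(
    fleet = fl,
    groups_pos = apply(fog > 0, 1, sum),
    groups_neg = apply(fog < 0, 1, sum),
    fleets_pos = apply(off_diag > 0, 1, function(z) sum(z, na.rm = TRUE)),
    fleets_neg = apply(off_diag < 0, 1, function(z) sum(z, na.rm = TRUE))
  )
  list(fleet_on_group = fog, fleet_on_fleet = fof, summary = summary)
}
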