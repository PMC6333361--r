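#' Solve the mass-balance master equations
#'
#' For every living group \eqn{i} the steady-state master equation
#' \deqn{B_i \, PB_i \, EE_i = \sum_j B_j \, QB_j \, DC_{ij} + Y_i + NM_i + BA_i}
#' must hold, where the sum runs over in-system consumers, \eqn{Y_i} is total
#' catch (landings plus discards), \eqn{NM} net migration and \eqn{BA} biomass
#' accumulation. Each living group contributes one equation and (normally) one
#' unknown — its missing `B` or `EE` — giving a linear system that is solved
#' directly. Rank-deficient or rectangular systems (over-determined groups)
#' fall back to a minimum-norm least-squares solution via the generalized
#' inverse, with a rank warning in the diagnostics.
#'
#' After solving, all flows are derived: the consumption matrix
#' \eqn{T_{ij} = B_j QB_j DC_{ij}}, import consumption, respiration
#' \eqn{R_j = (1-GS_j) Q_j - P_j}, unassimilated flow \eqn{U_j = GS_j Q_j},
#' predation mortality \eqn{M2}, other mortality \eqn{M0 = PB (1 - EE)},
#' per-fleet fishing mortality, and the detritus budgets.
#'
#' `EE` outside \eqn{[0, 1]}, negative respiration, and non-small residuals
#' are diagnostics (flags), not errors, so inputs can be iterated as in manual
#' balancing practice; a solved `B <= 0` or a singular exactly-determined
#' system aborts.
#'
#' @param model An [fw_model].
#' @param tol Absolute residual tolerance (t km\eqn{^{-2}} yr\eqn{^{-1}}) for
#'   the per-group balance check; default `1e-8`.
#' @return An object of class `fw_balanced`: list with
#'   \describe{
#'     \item{groups}{tibble with solved `B`, `EE` and derived `P`, `Q`, `R`,
#'       `U`, `M0`, `M2`, `F`, `catch` per group.}
#'     \item{flows}{prey x consumer consumption matrix `T` (all groups as
#'       rows, consumers as columns).}
#'     \item{import_flow}{named vector of import consumption per consumer.}
#'     \item{detritus}{per-pool budget tibble (see [detritus_budget()]).}
#'     \item{diagnostics}{per-living-group tibble with `EE`, `residual` and
#'       flags.}
#'     \item{model}{the input model with solved values filled in.}
#'   }
#' @seealso [trophic_levels()], [mti()], [exploitation()]
#' @export
#' @examples
#' m <- fw_model(
#'   tibble::tibble(
#'     group = c("PP", "ZOO"), type = c("producer", "consumer"),
#'     domain = "pelagic", B = c(10, 1), PB = c(10, 2), QB = c(NA, 10),
#'     EE = c(NA, 0)),
#'   data.frame(prey = "PP", ZOO = 1), check = FALSE)
#' b <- balance(m)
#' tidy(b)$EE  # producer EE = 0.1
balance <- function(model, tol = 1e-8) {
  stopifnot(inherits(model, "fw_model"))
  g <- model$groups
  codes <- g$group
  n <- nrow(g)
  living <- which(g$type != "detritus")
  consumers <- which(g$type == "consumer")

  # derive QB from PQ where needed; producers/detritus have QB 0
  QB <- g$QB
  use_pq <- is.na(QB) & !is.na(g$PQ) & g$type == "consumer"
  QB[use_pq] <- g$PB[use_pq] / g$PQ[use_pq]
  QB[g$type != "consumer"] <- 0
  if (anyNA(QB)) {
    abort(sprintf("consumer(s) without QB or PQ: %s",
                  paste(g$group[is.na(QB)], collapse = ", ")))
  }

  Y <- row_sums(model$landings) + row_sums(model$discards)

  B <- g$B
  EE <- g$EE
  unknown_B <- living[is.na(B[living])]
  unknown_EE <- setdiff(living[is.na(EE[living])], unknown_B)
  unknowns <- c(unknown_B, unknown_EE)
  kind <- c(rep("B", length(unknown_B)), rep("EE", length(unknown_EE)))
  k <- length(unknowns)

  # equations: for each living i,
  #   B_i PB_i EE_i - sum_j B_j QB_j DC[i,j] = Y_i + NM_i + BA_i
  # unknown terms stay on the left in A; known terms move to the right in b
  DC <- model$diet
  A <- matrix(0, length(living), k)
  b <- Y[living] + g$NM[living] + g$BA[living]
  col_of <- setNames(seq_len(k), codes[unknowns])
  for (r in seq_along(living)) {
    i <- living[r]
    ci <- codes[i]
    if (i %in% unknown_B) {
      A[r, col_of[ci]] <- A[r, col_of[ci]] + g$PB[i] * EE[i]
    } else if (i %in% unknown_EE) {
      A[r, col_of[ci]] <- A[r, col_of[ci]] + B[i] * g$PB[i]
    } else {
      b[r] <- b[r] - B[i] * g$PB[i] * EE[i]
    }
    for (j in consumers) {
      dc <- DC[ci, codes[j]]
      if (dc == 0) next
      if (j %in% unknown_B) {
        A[r, col_of[codes[j]]] <- A[r, col_of[codes[j]]] - QB[j] * dc
      } else {
        b[r] <- b[r] + B[j] * QB[j] * dc
      }
    }
  }

  rank_warning <- FALSE
  x <- numeric(0)
  if (k > 0) {
    if (k == length(living)) {
      sol <- tryCatch(solve(A, b), error = function(e) NULL)
      if (is.null(sol)) {
        sol <- MASS::ginv(A) %*% b
        rank_warning <- TRUE
        dep <- codes[unknowns]
        warn(paste("balance system is singular; minimum-norm solution",
                   "returned for:", paste(dep, collapse = ", ")))
      }
      x <- drop(sol)
    } else {
      qrA <- qr(A)
      if (qrA$rank < k) {
        x <- drop(MASS::ginv(A) %*% b)
        rank_warning <- TRUE
        warn("rank-deficient balance system; minimum-norm solution returned")
      } else {
        x <- qr.coef(qrA, b)
      }
    }
    B[unknowns[kind == "B"]] <- x[kind == "B"]
    EE[unknowns[kind == "EE"]] <- x[kind == "EE"]
  }

  bad_B <- living[!is.na(B[living]) & B[living] <= 0]
  if (length(bad_B) > 0) {
    abort(sprintf("solved biomass is non-positive for: %s",
                  paste(codes[bad_B], collapse = ", ")))
  }

  # detritus keeps its given B (inert for the balance itself)
  P <- ifelse(g$type == "detritus", 0, B * g$PB)
  Q <- B * QB
  T_mat <- matrix(0, n, length(consumers),
                  dimnames = list(codes, codes[consumers]))
  for (jj in seq_along(consumers)) {
    j <- consumers[jj]
    T_mat[, jj] <- B[j] * QB[j] * DC[, codes[j]]
  }
  import_flow <- setNames(Q[consumers] * model$import[codes[consumers]],
                          codes[consumers])
  U <- ifelse(g$type == "consumer", g$GS * Q, 0)
  R <- ifelse(g$type == "consumer", (1 - g$GS) * Q - P, 0)
  M2_flow <- row_sums(T_mat)
  M2 <- ifelse(g$type == "detritus" | is.na(B) | B == 0, NA, M2_flow / B)
  M0 <- ifelse(g$type == "detritus", NA, g$PB * (1 - EE))
  Ftot <- ifelse(g$type == "detritus" | is.na(B) | B == 0, NA, Y / B)

  residual <- rep(NA_real_, n)
  residual[living] <- P[living] * EE[living] -
    (M2_flow[living] + Y[living] + g$NM[living] + g$BA[living])

  groups_out <- g
  groups_out$B <- B
  groups_out$QB <- QB
  groups_out$EE <- EE
  groups_out$P <- P
  groups_out$Q <- Q
  groups_out$R <- R
  groups_out$U <- U
  groups_out$M0 <- M0
  groups_out$M2 <- M2
  groups_out$F <- Ftot
  groups_out$catch <- Y

  diagnostics <- tibble::tibble(
    group = codes[living],
    solved = codes[living] %in% codes[unknowns],
    B = B[living], EE = EE[living],
    residual = residual[living],
    flag_ee = EE[living] < 0 | EE[living] > 1,
    flag_residual = abs(residual[living]) > tol,
    flag_negative_respiration = g$type[living] == "consumer" & R[living] < 0,
    rank_warning = rank_warning
  )
  if (any(diagnostics$flag_residual)) {
    # over-determined/inconsistent inputs are reported, not fatal
    warn(sprintf("balance residual exceeds %.1e for: %s", tol,
                 paste(diagnostics$group[diagnostics$flag_residual],
                       collapse = ", ")))
  }
  if (any(diagnostics$flag_negative_respiration)) {
    warn(paste("negative respiration for:",
               paste(diagnostics$group[diagnostics$flag_negative_respiration],
                     collapse = ", ")))
  }

  model_out <- model
  model_out$groups$B <- B
  model_out$groups$EE <- EE
  model_out$groups$QB <- QB

  bal <- structure(
    list(groups = groups_out, flows = T_mat, import_flow = import_flow,
         detritus = NULL, diagnostics = diagnostics, model = model_out,
         tol = tol),
    class = "fw_balanced"
  )
  bal$detritus <- detritus_budget(bal)
  bal
}

#' @export
print.fw_balanced <- function(x, ...) {
  g <- x$groups
  living <- g$type != "detritus"
  cat(sprintf("<fw_balanced> %d groups, %d fleets\n", nrow(g),
              ncol(x$model$landings)))
  cat(sprintf("  EE range (living): [%.3f, %.3f]; max |residual| = %.2e\n",
              min(g$EE[living]), max(g$EE[living]),
              max(abs(x$diagnostics$residual), na.rm = TRUE)))
  if (any(x$diagnostics$flag_ee)) {
    cat("  flagged EE outside [0, 1]:",
        paste(x$diagnostics$group[x$diagnostics$flag_ee], collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' @describeIn balance Per-group tibble of solved parameters and derived
#'   rates.
#' @param x An `fw_balanced` object.
#' @param ... Unused.
#' @method tidy fw_balanced
#' @export
tidy.fw_balanced <- function(x, ...) {
  x$groups
}

#' @describeIn balance One-row tibble of system statistics (same as
#'   [system_statistics()]).
#' @method glance fw_balanced
#' @export
glance.fw_balanced <- function(x, ...) {
  system_statistics(x)
}

#' Consumption flows of a balanced model
#'
#' Returns the prey-by-consumer consumption matrix
#' \eqn{T_{ij} = B_j QB_j DC_{ij}} (t km\eqn{^{-2}} yr\eqn{^{-1}}); import
#' consumption \eqn{B_j QB_j IMP_j} is recorded separately so that in-system
#' column sums plus import reproduce each consumer's total consumption
#' \eqn{Q_j}.
#'
#' @param balanced An `fw_balanced` object.
#' @param long If `TRUE`, return a long tibble `(prey, consumer, flow)` of the
#'   non-zero in-system flows plus `"import"` rows; otherwise (default) a list
#'   with the matrix and the import vector.
#' @return See `long`.
#' @export
compute_flows <- function(balanced, long = FALSE) {
  stopifnot(inherits(balanced, "fw_balanced"))
  if (!long) {
    return(list(flows = balanced$flows, import = balanced$import_flow))
  }
  m <- balanced$flows
  out <- tibble::as_tibble(as.data.frame.table(m, stringsAsFactors = FALSE))
  names(out) <- c("prey", "consumer", "flow")
  imp <- tibble::tibble(prey = "import",
                        consumer = names(balanced$import_flow),
                        flow = unname(balanced$import_flow))
  out <- dplyr::bind_rows(out, imp)
  dplyr::filter(out, .data$flow > 0)
}

#' Detritus budgets of a balanced model
#'
#' For each detritus pool \eqn{d}: inflow is the fate-routed sum of
#' unassimilated consumption and other-mortality losses over living groups
#' plus fleet discards routed to \eqn{d}; outflow is the consumption of the
#' pool by detritivores; export is inflow minus outflow (negative exports are
#' flagged imbalances); the pool's pseudo-EE is outflow/inflow.
#'
#' @param balanced An `fw_balanced` object.
#' @return Tibble with columns `pool`, `inflow`, `outflow`, `export`, `EE`,
#'   `flag_imbalance`.
#' @export
detritus_budget <- function(balanced) {
  stopifnot(inherits(balanced, "fw_balanced"))
  g <- balanced$groups
  model <- balanced$model
  det <- g$group[g$type == "detritus"]
  if (length(det) == 0) {
    return(tibble::tibble(pool = character(), inflow = double(),
                          outflow = double(), export = double(),
                          EE = double(), flag_imbalance = logical()))
  }
  living <- g$group[g$type != "detritus"]
  loss <- setNames(g$U[match(living, g$group)] +
                     g$M0[match(living, g$group)] * g$B[match(living, g$group)],
                   living)
  inflow_bio <- drop(loss %*% model$detritus_fate[living, , drop = FALSE])
  disc_tot <- col_sums(model$discards)
  inflow_disc <- if (length(disc_tot) > 0) {
    drop(disc_tot %*% model$discard_fate)
  } else {
    setNames(rep(0, length(det)), det)
  }
  inflow <- inflow_bio + inflow_disc[det]
  outflow <- row_sums(balanced$flows)[det]
  export <- inflow - outflow
  tibble::tibble(
    pool = det,
    inflow = unname(inflow[det]),
    outflow = unname(outflow),
    export = unname(export[det]),
    EE = ifelse(inflow[det] > 0, outflow / inflow[det], NA_real_),
    flag_imbalance = unname(export[det]) < 0
  )
}
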