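# end-to-end pipeline: balance -> indices -> MTI -> BPC -> CSV outputs

#' Run the full analysis pipeline
#'
#' Chains the analysis stages on a model definition — balance, trophic
#' indices, Mixed Trophic Impact, exploitation and benthic–pelagic coupling —
#' and writes every result table as CSV into `out_dir`. Stage failures are
#' re-raised with the stage name prefixed; progress and settings are logged
#' to standard error. Two runs with identical inputs and settings produce
#' byte-identical outputs.
#'
#' Files written: `balanced_groups.csv`, `flows.csv`, `detritus_budget.csv`,
#' `diagnostics.csv`, `trophic_indices.csv`, `system_stats.csv`,
#' `mti_matrix.csv`, `epsilon.csv`, `exploitation.csv`, `cum_e.csv`,
#' `bpc_flux.csv`, `bpc_impact.csv`.
#'
#' @param input A model directory (see [read_model()]) or an [fw_model].
#' @param out_dir Output directory, created if needed.
#' @param import_convention Import handling for trophic levels, see
#'   [trophic_levels()].
#' @param epsilon Cumulative-impact definition reported in `epsilon.csv`
#'   first: signed row `"sum"` (default) or root-sum-of-squares `"rss"` (both
#'   columns are always written).
#' @param exclude Group codes excluded from cross-domain flux counterparts.
#' @param tol Balance residual tolerance.
#' @param quiet Suppress log messages.
#' @return Invisibly, a list with the balanced model, result objects and the
#'   vector of written file paths.
#' @export
run_pipeline <- function(input, out_dir,
                         import_convention = c("renormalise", "tl1"),
                         epsilon = c("sum", "rss"),
                         exclude = NULL, tol = 1e-8, quiet = FALSE) {
  import_convention <- match.arg(import_convention)
  epsilon <- match.arg(epsilon)
  log <- function(...) if (!quiet) message("[trophicweb] ", sprintf(...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("%s: %s", name, conditionMessage(e)))
    })
  }

  log("pipeline start (package %s, tol = %g, import = %s, epsilon = %s)",
      as.character(utils::packageVersion("trophicweb")), tol,
      import_convention, epsilon)
  model <- if (inherits(input, "fw_model")) input else
    stage("read", read_model(input))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  bal <- stage("balance", balance(model, tol = tol))
  log("balance: %d groups, max |residual| = %.2e", nrow(bal$groups),
      max(abs(bal$diagnostics$residual), na.rm = TRUE))
  tl <- stage("indices", suppressWarnings(
    trophic_levels(bal, import_convention)))
  oi <- stage("indices", suppressWarnings(
    omnivory(bal, tl, import_convention)))
  stats <- stage("indices", system_statistics(bal, import_convention))
  imp <- stage("mti", mti(bal))
  expl <- stage("bpc", exploitation(bal))
  flux <- stage("bpc", cross_domain_flux(bal, exclude = exclude))
  cdi <- stage("bpc", cross_domain_impact(imp))

  eps_tbl <- imp$impacts
  if (epsilon == "rss") {
    eps_tbl <- eps_tbl[, c("component", "kind", "domain", "epsilon_rss",
                           "epsilon", "suffered")]
  }

  files <- c(
    balanced_groups = write_results(bal$groups,
                                    file.path(out_dir, "balanced_groups.csv")),
    flows = write_results(compute_flows(bal, long = TRUE),
                          file.path(out_dir, "flows.csv")),
    detritus_budget = write_results(bal$detritus,
                                    file.path(out_dir, "detritus_budget.csv")),
    diagnostics = write_results(bal$diagnostics,
                                file.path(out_dir, "diagnostics.csv")),
    trophic_indices = write_results(oi,
                                    file.path(out_dir, "trophic_indices.csv")),
    system_stats = write_results(stats,
                                 file.path(out_dir, "system_stats.csv")),
    mti_matrix = write_results(imp$M, file.path(out_dir, "mti_matrix.csv")),
    epsilon = write_results(eps_tbl, file.path(out_dir, "epsilon.csv")),
    exploitation = write_results(expl$groups,
                                 file.path(out_dir, "exploitation.csv")),
    cum_e = write_results(expl$fleets, file.path(out_dir, "cum_e.csv")),
    bpc_flux = write_results(flux, file.path(out_dir, "bpc_flux.csv")),
    bpc_impact = write_results(cdi, file.path(out_dir, "bpc_impact.csv"))
  )
  log("wrote %d files to %s", length(files), out_dir)
  invisible(list(balanced = bal, trophic = oi, statistics = stats,
                 mti = imp, exploitation = expl, bpc_flux = flux,
                 bpc_impact = cdi, files = files))
}

#' Read a pipeline run configuration
#'
#' Reads a YAML run configuration with fields `input`, `out_dir` and any of
#' the optional settings of [run_pipeline()] (`import_convention`, `epsilon`,
#' `exclude`, `tol`, `quiet`), validates them against the documented
#' enumerations, and returns the argument list.
#'
#' @param path YAML file path.
#' @return Named list of arguments for [run_pipeline()].
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$input) || is.null(cfg$out_dir)) {
    abort("run config needs `input` and `out_dir`")
  }
  allowed <- c("input", "out_dir", "import_convention", "epsilon", "exclude",
               "tol", "quiet")
  extra <- setdiff(names(cfg), allowed)
  if (length(extra) > 0) {
    abort(paste("unknown config field(s):", paste(extra, collapse = ", ")))
  }
  if (!is.null(cfg$import_convention) &&
      !cfg$import_convention %in% c("renormalise", "tl1")) {
    abort("import_convention must be \"renormalise\" or \"tl1\"")
  }
  if (!is.null(cfg$epsilon) && !cfg$epsilon %in% c("sum", "rss")) {
    abort("epsilon must be \"sum\" or \"rss\"")
  }
  cfg
}

#' Path to the synthetic Strait-of-Sicily-structured example model
#'
#' Returns the directory of the shipped example model. Its *structure* mirrors
#' the published Strait of Sicily Ecopath parameterization — the 72
#' functional-group codes, long names and benthic/demersal/pelagic domain
#' labels, 3 detritus pools, the 18 fleet segments, a 70% diet import for
#' bluefin tuna and an immigration term for swordfish — but all numeric
#' parameters (biomasses, rates, diets, catches) are synthetic values from the
#' package's balanced-web generator: the published supplementary parameter and
#' diet tables are not redistributed here. Use it as a realistic-sized test
#' bed, not as the published model.
#'
#' @return Directory path usable with [read_model()].
#' @export
#' @examples
#' m <- read_model(sos_synthetic_model())
#' m
sos_synthetic_model <- function() {
  system.file("extdata", "sos_synthetic", package = "trophicweb",
              mustWork = TRUE)
}

#' Lower-trophic-level group codes of the example model
#'
#' The conventional exclusion set for cross-domain flux comparisons on the
#' example model: macrobenthos feeding classes, suprabenthos, meiobenthos,
#' zooplankton, euphausiids, gelatinous plankton, bacteria, phytoplankton,
#' seagrass/macroalgae and the detritus pools. Excluding these leaves the
#' fish, cephalopod and large decapod groups whose cross-domain flows are
#' comparable in magnitude.
#'
#' @return Character vector of group codes.
#' @export
sos_lower_trophic_groups <- function() {
  c("SUP", "O", "FF", "DF", "C", "PAR", "SCA", "H", "GRA", "SF", "PF",
    "BO", "EUP", "ZG", "ZL", "ZM", "ZS", "PB", "BB", "PS", "DFL", "PL",
    "MB", "SG", "MA", "DC", "SPOM", "BD")
}
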