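#' Construct a food-web model definition
#'
#' Bundles the tables that define an (as yet unbalanced) mass-balance food-web
#' model: the functional-group table, the diet-composition matrix with its
#' import row, the fleet landings/discards, and the fate fractions that route
#' non-harvest losses and discards to the detritus pools.
#'
#' @param groups A data frame with one row per functional group, in model
#'   order, with columns:
#'   \describe{
#'     \item{group}{short unique code (e.g. `"THU"`, `"HAK4"`).}
#'     \item{long_name}{free-text name (optional).}
#'     \item{type}{one of `"consumer"`, `"producer"`, `"detritus"`.}
#'     \item{domain}{one of `"benthic"`, `"demersal"`, `"pelagic"`.}
#'     \item{B}{biomass density (t km\eqn{^{-2}}), or `NA` if to be solved.}
#'     \item{PB}{production/biomass ratio (yr\eqn{^{-1}}).}
#'     \item{QB}{consumption/biomass ratio (yr\eqn{^{-1}}, consumers), or `NA`
#'       if `PQ` is given.}
#'     \item{PQ}{production/consumption ratio, an alternative to `QB`.}
#'     \item{EE}{ecotrophic efficiency in \eqn{[0, 1]}, or `NA` if to be
#'       solved.}
#'     \item{GS}{unassimilated fraction of consumption; defaults to 0.2 for
#'       consumers.}
#'     \item{BA}{biomass accumulation (t km\eqn{^{-2}} yr\eqn{^{-1}});
#'       default 0.}
#'     \item{NM}{net migration, emigration minus immigration (t km\eqn{^{-2}}
#'       yr\eqn{^{-1}}, may be negative); default 0.}
#'   }
#'   Missing optional columns are filled with their defaults.
#' @param diet Diet composition: a prey-by-consumer data frame (first column =
#'   prey code) or numeric matrix. Entry `[i, j]` is the fraction of prey `i`
#'   in the diet of consumer `j`. An optional row named `"import"` gives the
#'   fraction of each consumer's diet taken outside the system. Every consumer
#'   column must sum to 1 (including import) within `1e-6`.
#' @param landings,discards Group-by-fleet catch tables (t km\eqn{^{-2}}
#'   yr\eqn{^{-1}}): data frames (first column = group code) or matrices.
#'   `NULL` means an unfished model.
#' @param detritus_fate Living-group-by-detritus-pool fractions routing
#'   unassimilated food and other (non-predation, non-catch) mortality; rows
#'   must sum to 1. `NULL` uses the domain default: benthic and demersal
#'   groups route to a benthic-domain detritus pool, pelagic groups to a
#'   non-benthic pool (falling back to the first pool).
#' @param discard_fate Fleet-by-detritus-pool fractions routing discards; rows
#'   sum to 1. `NULL` routes all discards to the carrion pool (code `"DC"` or
#'   long name containing "carrion") if present, else to the first pool.
#' @param check If `TRUE` (default), run [validate_model()] and abort on
#'   blocking errors.
#'
#' @return An object of class `fw_model`: a list with elements `groups`
#'   (tibble), `diet` (prey x consumer matrix), `import` (named vector),
#'   `landings`, `discards` (group x fleet matrices), `detritus_fate`
#'   (living-group x pool matrix) and `discard_fate` (fleet x pool matrix).
#' @seealso [read_model()], [balance()], [generate_web()]
#' @export
#' @examples
#' groups <- tibble::tibble(
#'   group = c("PP", "ZOO"),
#'   type = c("producer", "consumer"),
#'   domain = c("pelagic", "pelagic"),
#'   B = c(10, 1), PB = c(10, 2), QB = c(NA, 10), EE = c(NA, 0)
#' )
#' diet <- data.frame(prey = "PP", ZOO = 1)
#' m <- fw_model(groups, diet)
#' m
fw_model <- function(groups, diet, landings = NULL, discards = NULL,
                     detritus_fate = NULL, discard_fate = NULL,
                     check = TRUE) {
  groups <- tibble::as_tibble(as.data.frame(groups))
  if (!"group" %in% names(groups)) {
    abort("`groups` must have a `group` column of unique codes")
  }
  groups$group <- as.character(groups$group)
  for (col in c("long_name", "type", "domain")) {
    if (!col %in% names(groups)) groups[[col]] <- NA_character_
    groups[[col]] <- as.character(groups[[col]])
  }
  groups$long_name[is.na(groups$long_name)] <-
    groups$group[is.na(groups$long_name)]
  for (col in c("B", "PB", "QB", "PQ", "EE", "GS", "BA", "NM")) {
    if (!col %in% names(groups)) groups[[col]] <- NA_real_
    groups[[col]] <- as.numeric(groups[[col]])
  }
  groups$GS[is.na(groups$GS) & groups$type == "consumer"] <- 0.2
  groups$GS[groups$type != "consumer"] <- 0
  groups$BA[is.na(groups$BA)] <- 0
  groups$NM[is.na(groups$NM)] <- 0
  groups <- groups[, c("group", "long_name", "type", "domain",
                       "B", "PB", "QB", "PQ", "EE", "GS", "BA", "NM")]

  codes <- groups$group
  consumers <- codes[groups$type == "consumer"]
  detritus <- codes[groups$type == "detritus"]
  living <- codes[groups$type != "detritus"]
  fleets <- union(colnames(landings %||% matrix(0, 0, 0)),
                  colnames(discards %||% matrix(0, 0, 0)))
  fleets <- setdiff(fleets, "group")

  if (is.data.frame(diet)) diet <- df_to_matrix(diet)
  imp <- setNames(rep(0, length(consumers)), consumers)
  if ("import" %in% rownames(diet)) {
    imp_row <- setNames(as.numeric(diet["import", ]), colnames(diet))
    diet <- diet[rownames(diet) != "import", , drop = FALSE]
    keep <- intersect(names(imp_row), consumers)
    imp[keep] <- imp_row[keep]
  }
  diet <- conform_matrix(diet, codes, consumers, "diet")

  to_catch <- function(x, what) {
    if (is.data.frame(x)) x <- df_to_matrix(x)
    conform_matrix(x, codes, fleets, what)
  }
  landings <- to_catch(landings, "landings")
  discards <- to_catch(discards, "discards")

  if (is.data.frame(detritus_fate)) detritus_fate <- df_to_matrix(detritus_fate)
  if (is.null(detritus_fate)) {
    detritus_fate <- default_detritus_fate(groups, living, detritus)
  } else {
    detritus_fate <- conform_matrix(detritus_fate, living, detritus,
                                    "detritus_fate")
  }
  if (is.data.frame(discard_fate)) discard_fate <- df_to_matrix(discard_fate)
  if (is.null(discard_fate)) {
    discard_fate <- default_discard_fate(groups, fleets, detritus)
  } else {
    discard_fate <- conform_matrix(discard_fate, fleets, detritus,
                                   "discard_fate")
  }

  model <- structure(
    list(groups = groups, diet = diet, import = imp,
         landings = landings, discards = discards,
         detritus_fate = detritus_fate, discard_fate = discard_fate),
    class = "fw_model"
  )
  if (check) {
    rep <- validate_model(model)
    errs <- rep[rep$severity == "error", , drop = FALSE]
    if (nrow(errs) > 0) {
      abort(paste0("invalid model definition:\n",
                   paste0("- ", errs$message, collapse = "\n")))
    }
  }
  model
}

# benthic/demersal losses settle to a benthic-domain pool; pelagic losses stay
# suspended if a non-benthic pool exists
default_detritus_fate <- function(groups, living, detritus) {
  fate <- matrix(0, length(living), length(detritus),
                 dimnames = list(living, detritus))
  if (length(detritus) == 0) return(fate)
  det_dom <- groups$domain[match(detritus, groups$group)]
  benthic_pool <- detritus[match("benthic", det_dom)]
  if (is.na(benthic_pool)) benthic_pool <- detritus[1L]
  susp_pool <- detritus[det_dom != "benthic"][1L]
  if (is.na(susp_pool)) susp_pool <- detritus[1L]
  dom <- groups$domain[match(living, groups$group)]
  pool <- ifelse(dom == "pelagic", susp_pool, benthic_pool)
  pool[is.na(pool)] <- detritus[1L]
  fate[cbind(living, pool)] <- 1
  fate
}

default_discard_fate <- function(groups, fleets, detritus) {
  fate <- matrix(0, length(fleets), length(detritus),
                 dimnames = list(fleets, detritus))
  if (length(detritus) == 0 || length(fleets) == 0) return(fate)
  carrion <- detritus[toupper(detritus) == "DC" |
                        grepl("carrion", groups$long_name[
                          match(detritus, groups$group)], ignore.case = TRUE)]
  pool <- if (length(carrion) > 0) carrion[1L] else detritus[1L]
  fate[, pool] <- 0; fate[, pool] <- 1
  fate
}

#' @export
print.fw_model <- function(x, ...) {
  g <- x$groups
  cat(sprintf(
    "<fw_model> %d groups (%d consumers, %d producers, %d detritus), %d fleets\n",
    nrow(g), sum(g$type == "consumer"), sum(g$type == "producer"),
    sum(g$type == "detritus"), ncol(x$landings)))
  n_unk <- sum(is.na(g$B[g$type != "detritus"])) +
    sum(is.na(g$EE[g$type != "detritus"]))
  cat(sprintf("  unknowns to solve: %d; domains: %s\n", n_unk,
              paste(sort(unique(g$domain)), collapse = ", ")))
  invisible(x)
}

#' Validate a model definition
#'
#' Checks the structural and numeric invariants of a model definition and
#' returns a report instead of raising conditions: blocking problems are rows
#' with `severity == "error"`, implausible-but-legal inputs are `"warning"`s.
#' The function is pure — the same input always yields the same report.
#'
#' Checks include: unique group codes and valid type/domain labels; exactly
#' one of B/EE missing per living group (both missing is an error, both
#' present an over-determination warning); consumers have QB or PQ; producers
#' and detritus have none; `GS` in \eqn{[0, 1)}; positive `PB` for living
#' groups and positive `B` when given; diet columns (plus import) summing to 1
#' within `1e-6` with non-negative entries; non-negative catches; fate rows
#' summing to 1; and PQ within the plausible 0.1–0.35 band (warning outside).
#'
#' @param model An [fw_model].
#' @return A tibble with columns `severity`, `scope`, `item`, `message`.
#' @export
validate_model <- function(model) {
  g <- model$groups
  out <- list()
  note <- function(severity, scope, item, message) {
    out[[length(out) + 1L]] <<- tibble::tibble(
      severity = severity, scope = scope, item = item, message = message)
  }

  if (anyDuplicated(g$group)) {
    note("error", "groups", g$group[duplicated(g$group)][1],
         sprintf("duplicated group code: %s",
                 paste(unique(g$group[duplicated(g$group)]), collapse = ", ")))
  }
  bad_type <- !g$type %in% GROUP_TYPES
  if (any(bad_type)) {
    note("error", "groups", g$group[bad_type][1],
         sprintf("invalid type for %s (must be consumer/producer/detritus)",
                 paste(g$group[bad_type], collapse = ", ")))
  }
  bad_dom <- !g$domain %in% DOMAINS
  if (any(bad_dom)) {
    note("error", "groups", g$group[bad_dom][1],
         sprintf("invalid domain for %s (must be benthic/demersal/pelagic)",
                 paste(g$group[bad_dom], collapse = ", ")))
  }

  for (i in seq_len(nrow(g))) {
    gi <- g[i, ]
    code <- gi$group
    living <- gi$type != "detritus"
    if (living) {
      if (is.na(gi$B) && is.na(gi$EE)) {
        note("error", "groups", code,
             sprintf("under-determined group %s: both B and EE missing", code))
      }
      if (!is.na(gi$B) && !is.na(gi$EE)) {
        note("warning", "groups", code,
             sprintf("group %s is over-determined (both B and EE given); its balance residual will be reported", code))
      }
      if (is.na(gi$PB) || gi$PB <= 0) {
        note("error", "groups", code,
             sprintf("group %s: PB must be given and > 0", code))
      }
    }
    if (!is.na(gi$B) && gi$B <= 0) {
      note("error", "groups", code, sprintf("group %s: B must be > 0", code))
    }
    if (!is.na(gi$EE) && (gi$EE < 0 || gi$EE > 1)) {
      note("warning", "groups", code,
           sprintf("group %s: EE = %.3f outside [0, 1]", code, gi$EE))
    }
    if (gi$type == "consumer") {
      if (is.na(gi$QB) && is.na(gi$PQ)) {
        note("error", "groups", code,
             sprintf("consumer %s needs QB or PQ", code))
      }
      pq <- if (!is.na(gi$PQ)) gi$PQ else if (!is.na(gi$QB) && gi$QB > 0)
        gi$PB / gi$QB else NA_real_
      if (!is.na(pq) && (pq < 0.1 || pq > 0.35)) {
        note("warning", "groups", code,
             sprintf("consumer %s: P/Q = %.3f outside plausible range 0.1-0.35",
                     code, pq))
      }
      if (is.na(gi$GS) || gi$GS < 0 || gi$GS >= 1) {
        note("error", "groups", code,
             sprintf("consumer %s: GS must lie in [0, 1)", code))
      }
    } else {
      if (!is.na(gi$QB) && gi$QB != 0) {
        note("warning", "groups", code,
             sprintf("%s %s has QB; it will be ignored", gi$type, code))
      }
    }
  }

  # diet columns
  if (any(model$diet < 0)) {
    bad <- colnames(model$diet)[apply(model$diet < 0, 2, any)]
    note("error", "diet", bad[1],
         sprintf("negative diet fraction in column(s): %s",
                 paste(bad, collapse = ", ")))
  }
  csum <- col_sums(model$diet) + model$import[colnames(model$diet)]
  bad <- abs(csum - 1) > 1e-6
  if (any(bad)) {
    for (cc in colnames(model$diet)[bad]) {
      note("error", "diet", cc,
           sprintf("diet column %s sums to %.6f (must be 1 including import)",
                   cc, csum[cc]))
    }
  }
  if (any(model$landings < 0) || any(model$discards < 0)) {
    note("error", "fleets", NA_character_, "negative landings or discards")
  }
  if (ncol(model$detritus_fate) > 0) {
    rs <- row_sums(model$detritus_fate)
    bad <- abs(rs - 1) > 1e-6
    if (any(bad)) {
      note("error", "detritus_fate", rownames(model$detritus_fate)[bad][1],
           sprintf("detritus_fate rows not summing to 1: %s",
                   paste(rownames(model$detritus_fate)[bad], collapse = ", ")))
    }
    if (ncol(model$landings) > 0) {
      rs <- row_sums(model$discard_fate)
      bad <- abs(rs - 1) > 1e-6
      if (any(bad)) {
        note("error", "discard_fate", rownames(model$discard_fate)[bad][1],
             sprintf("discard_fate rows not summing to 1: %s",
                     paste(rownames(model$discard_fate)[bad], collapse = ", ")))
      }
    }
  }

  if (length(out) == 0) {
    tibble::tibble(severity = character(), scope = character(),
                   item = character(), message = character())
  } else {
    dplyr::bind_rows(out)
  }
}

#' Read a model definition from a directory of CSV tables
#'
#' Reads the documented CSV set: `groups.csv` (one row per group, first column
#' `group`), `diet.csv` (first column `prey`, one column per consumer, optional
#' `import` row), and optionally `fleets_landings.csv`, `fleets_discards.csv`
#' (first column `group`, one column per fleet), `detritus_fate.csv` (first
#' column `group`, one column per detritus pool) and `discard_fate.csv` (first
#' column `fleet`). Files are UTF-8, `.` decimal separator; empty cells are
#' missing values, not zeros. Group order is file order and is preserved in
#' every derived matrix.
#'
#' @param path Directory containing the tables.
#' @return An [fw_model]; validation errors abort with the offending
#'   row/column named.
#' @seealso [write_model()]
#' @export
read_model <- function(path) {
  need <- file.path(path, c("groups.csv", "diet.csv"))
  missing <- need[!file.exists(need)]
  if (length(missing) > 0) {
    abort(paste("missing model table(s):", paste(missing, collapse = ", ")))
  }
  rd <- function(f) {
    p <- file.path(path, f)
    if (!file.exists(p)) return(NULL)
    readr::read_csv(p, show_col_types = FALSE, progress = FALSE)
  }
  groups <- rd("groups.csv")
  if (!"group" %in% names(groups)) abort("groups.csv: missing column `group`")
  fw_model(
    groups = groups,
    diet = rd("diet.csv"),
    landings = rd("fleets_landings.csv"),
    discards = rd("fleets_discards.csv"),
    detritus_fate = rd("detritus_fate.csv"),
    discard_fate = rd("discard_fate.csv")
  )
}

#' Write a model definition to a directory of CSV tables
#'
#' Inverse of [read_model()]: writes the same CSV dialect (UTF-8, `.` decimal
#' separator, empty cells for missing values). `read_model(write_model(m))`
#' returns a model identical to `m`.
#'
#' @param model An [fw_model].
#' @param path Output directory (created if needed).
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(model$groups, file.path(path, "groups.csv"), na = "")
  diet <- matrix_to_df(rbind(model$diet, import = model$import), "prey")
  readr::write_csv(diet, file.path(path, "diet.csv"), na = "")
  if (ncol(model$landings) > 0) {
    readr::write_csv(matrix_to_df(model$landings, "group"),
                     file.path(path, "fleets_landings.csv"), na = "")
    readr::write_csv(matrix_to_df(model$discards, "group"),
                     file.path(path, "fleets_discards.csv"), na = "")
    readr::write_csv(matrix_to_df(model$discard_fate, "fleet"),
                     file.path(path, "discard_fate.csv"), na = "")
  }
  if (ncol(model$detritus_fate) > 0) {
    readr::write_csv(matrix_to_df(model$detritus_fate, "group"),
                     file.path(path, "detritus_fate.csv"), na = "")
  }
  invisible(path)
}

#' Write and read result tables
#'
#' Result tables (tibbles or labelled matrices) are written as CSV with a
#' deterministic column order and full double precision, so that
#' `read_results(write_results(x, f))` reproduces `x` exactly.
#'
#' @param x A data frame, or a numeric matrix with dimnames (written with its
#'   row labels in a first `row` column).
#' @param path Output file path.
#' @return For `write_results`, `path` invisibly; for `read_results`, a
#'   tibble.
#' @export
write_results <- function(x, path) {
  if (is.matrix(x)) x <- matrix_to_df(x, "row")
  readr::write_csv(tibble::as_tibble(x), path, na = "")
  invisible(path)
}

#' @rdname write_results
#' @export
read_results <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  # every column this package writes is numeric, character or logical flag;
  # an all-NA column can only have been numeric
  for (j in seq_along(out)) {
    if (is.logical(out[[j]]) && all(is.na(out[[j]]))) {
      out[[j]] <- as.numeric(out[[j]])
    }
  }
  out
}
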