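# Country-year panel and scenario table I/O.
#
# Internal representation: plain data.frames with canonical column names and
# all proportions on the [0,1] scale. Percentages in input files (any value
# > 1 and all <= 100 within a proportion column) are auto-detected and
# rescaled with a warning, since both conventions occur in the source
# databases.

panel_columns <- c("country_id", "region_id", "year",
                   "stunting_moderate", "stunting_severe", "pou",
                   "gdp_pc", "gini", "pop_u5")

scenario_columns <- c("country_id", "region_id", "scenario_id",
                      "kcal_pc_day", "gdp_pc_proj", "gini_baseline",
                      "cv_baseline", "mder", "pop_u5_proj")

default_panel_schema <- c(country_id = "country", region_id = "region",
                          year = "year",
                          stunting_moderate = "stunting_moderate",
                          stunting_severe = "stunting_severe",
                          pou = "pou", gdp_pc = "gdp_pc", gini = "gini",
                          pop_u5 = "pop_u5")

# proportion-scale columns subject to percent auto-detection
panel_prop_cols <- c("stunting_moderate", "stunting_severe", "pou", "gini")

apply_schema <- function(tab, schema, required, what) {
  missing_cols <- setdiff(unname(schema[required]), names(tab))
  if (length(missing_cols)) {
    stop(what, " is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  out <- tab[, unname(schema[required]), drop = FALSE]
  names(out) <- required
  out
}

# A column is taken to be percent-scaled only when the bulk of its values
# (not just an occasional out-of-bounds entry) exceed 1: a lone value of,
# say, 1.2 in an otherwise [0,1] column is a data error to be excluded,
# not a unit convention.
rescale_percent_cols <- function(tab, cols) {
  for (cl in cols) {
    v <- tab[[cl]]
    v_ok <- v[!is.na(v)]
    if (length(v_ok) && mean(v_ok > 1) > 0.5 && all(v_ok <= 100)) {
      warning("column '", cl, "' looks like percentages; dividing by 100",
              call. = FALSE)
      tab[[cl]] <- v / 100
    }
  }
  tab
}

#' Read a country-year stunting panel
#'
#' Reads a CSV of country-year observations of stunting prevalence,
#' undernourishment, per capita GDP, Gini coefficient and under-5
#' population, validates each record, and drops (with a logged reason)
#' records violating the domain invariants: proportions in [0,1],
#' moderate + severe stunting <= 1, positive GDP, year in [1900, 2100],
#' non-negative population, and no missing fields.
#'
#' @param path CSV file with a header row.
#' @param schema named character vector mapping canonical names
#'   (\code{country_id}, \code{region_id}, \code{year},
#'   \code{stunting_moderate}, \code{stunting_severe}, \code{pou},
#'   \code{gdp_pc}, \code{gini}, \code{pop_u5}) to the file's column names;
#'   defaults cover the \code{country}/\code{region} shorthand.
#' @return a data.frame with the canonical columns, proportions on [0,1].
#'   Excluded rows are recorded in \code{attr(, "exclusions")}, a data.frame
#'   of row numbers and reasons.
#' @export
read_panel <- function(path, schema = NULL) {
  if (!file.exists(path)) stop("panel file not found: ", path, call. = FALSE)
  schema <- resolve_schema(schema, default_panel_schema)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  tab <- apply_schema(raw, schema, panel_columns, "panel")
  tab$year <- as.integer(tab$year)
  for (cl in setdiff(panel_columns, c("country_id", "region_id", "year"))) {
    tab[[cl]] <- as.double(tab[[cl]])
  }
  tab <- rescale_percent_cols(tab, panel_prop_cols)
  validate_panel(tab)
}

resolve_schema <- function(schema, default) {
  if (is.null(schema)) return(default)
  out <- default
  out[names(schema)] <- schema
  out
}

validate_panel <- function(tab) {
  reason <- rep(NA_character_, nrow(tab))
  flag <- function(bad, why) ifelse(bad & is.na(reason), why, reason)
  num_cols <- setdiff(panel_columns, c("country_id", "region_id"))
  incomplete <- Reduce(`|`, lapply(tab[num_cols], function(v) !is.finite(v)))
  reason <- flag(incomplete, "missing or non-numeric field")
  in01 <- function(v) !is.na(v) & v >= 0 & v <= 1
  for (cl in c("stunting_moderate", "stunting_severe", "pou", "gini")) {
    reason <- flag(!is.na(tab[[cl]]) & !in01(tab[[cl]]),
                   paste0(cl, " outside [0,1]"))
  }
  reason <- flag(in01(tab$stunting_moderate) & in01(tab$stunting_severe) &
                   tab$stunting_moderate + tab$stunting_severe > 1,
                 "moderate + severe stunting > 1")
  reason <- flag(!is.na(tab$gdp_pc) & tab$gdp_pc <= 0, "gdp_pc must be > 0")
  reason <- flag(!is.na(tab$year) & (tab$year < 1900 | tab$year > 2100),
                 "year outside [1900, 2100]")
  reason <- flag(!is.na(tab$pop_u5) & tab$pop_u5 < 0, "negative pop_u5")
  keep <- is.na(reason)
  exclusions <- data.frame(row = which(!keep), reason = reason[!keep],
                           stringsAsFactors = FALSE)
  if (nrow(exclusions)) {
    message(nrow(exclusions), " record(s) excluded: ",
            paste(sprintf("row %d (%s)", exclusions$row, exclusions$reason),
                  collapse = "; "))
  }
  out <- tab[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "exclusions") <- exclusions
  out
}

#' Write a panel to CSV
#'
#' Inverse of [read_panel()]: numeric fields are written with 17 significant
#' digits so that write-then-read round-trips are lossless.
#'
#' @param panel a panel data.frame (canonical columns).
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_panel <- function(panel, path) {
  out <- panel[, panel_columns, drop = FALSE]
  names(out) <- unname(default_panel_schema[panel_columns])
  for (cl in names(out)) {
    if (is.double(out[[cl]])) out[[cl]] <- sprintf("%.17g", out[[cl]])
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a scenario input table
#'
#' Scenario rows carry, per country and scenario, the projected per capita
#' calorie availability (kcal/person/day), projected per capita GDP,
#' baseline Gini, baseline intake-distribution coefficient of variation,
#' baseline minimum dietary energy requirement (MDER, kcal/person/day) and
#' projected under-5 population.
#'
#' @param path CSV file.
#' @param schema optional named character vector overriding canonical ->
#'   file column names (canonical names: \code{country_id},
#'   \code{region_id}, \code{scenario_id}, \code{kcal_pc_day},
#'   \code{gdp_pc_proj}, \code{gini_baseline}, \code{cv_baseline},
#'   \code{mder}, \code{pop_u5_proj}).
#' @return a data.frame with the canonical scenario columns.
#' @export
read_scenarios <- function(path, schema = NULL) {
  if (!file.exists(path)) stop("scenario file not found: ", path, call. = FALSE)
  schema <- resolve_schema(schema, stats::setNames(scenario_columns,
                                                   scenario_columns))
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  tab <- apply_schema(raw, schema, scenario_columns, "scenario table")
  tab <- rescale_percent_cols(tab, c("gini_baseline", "cv_baseline"))
  bad <- !(tab$kcal_pc_day > 0) | !(tab$mder > 0) |
    !(tab$cv_baseline > 0 & tab$cv_baseline < 1)
  if (any(bad)) {
    stop("invalid scenario row(s): ", paste(which(bad), collapse = ", "),
         " (need kcal_pc_day > 0, mder > 0, cv_baseline in (0,1))",
         call. = FALSE)
  }
  tab
}

#' Split a panel into training and holdout sets
#'
#' Reserves a random fraction of the records for model validation. The
#' holdout size is \code{round(holdout_fraction * n)} (half-up), so a
#' 186-record panel at fraction 0.2 yields 37 holdout and 149 training
#' records. The split is deterministic for a fixed seed.
#'
#' @param panel a panel data.frame.
#' @param holdout_fraction fraction in (0,1) reserved for validation.
#' @param seed integer RNG seed.
#' @return a list with \code{train}, \code{holdout} (data.frames) and
#'   \code{holdout_idx} (row indices into \code{panel}).
#' @export
split_panel <- function(panel, holdout_fraction = 0.2, seed = 1L) {
  n <- nrow(panel)
  if (n < 1L) stop("panel is empty", call. = FALSE)
  if (!(holdout_fraction > 0 && holdout_fraction < 1)) {
    stop("holdout_fraction must be in (0, 1)", call. = FALSE)
  }
  n_hold <- round_half_up(holdout_fraction * n)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  idx <- sort(sample.int(n, n_hold))
  list(train = panel[setdiff(seq_len(n), idx), , drop = FALSE],
       holdout = panel[idx, , drop = FALSE],
       holdout_idx = idx)
}

# Save/restore the global RNG state so that seeded package internals do not
# perturb a user's random stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
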