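# Synthetic country-year panels and scenario inputs with known ground
# truth, so fitting and projection are testable end-to-end without any
# external download.

#' Synthetic-data configuration
#'
#' Defaults emulate the structure of the global calibration panel: 186
#' country-year records over 1988-2008, per capita GDP between $81 and
#' $5,513, Gini between 0.17 and 0.74, undernourishment between 5% and
#' 70%, and the published central parameters as generating truth. The
#' ground-truth development anchors place the worst baseline at the
#' configured range corner (minimum GDP, maximum Gini), so the score is a
#' fixed function of the covariates rather than of the realized draw.
#'
#' @param n_records number of country-year records.
#' @param n_countries,n_regions numbers of distinct countries and regions
#'   (countries recur across years, as in the real panel).
#' @param true_params generating [stunting_params()].
#' @param residual_sd per-level Gaussian noise SD on the proportion scale,
#'   named \code{c(moderate=, severe=)}.
#' @param gdp_range,gini_range,pou_range covariate ranges (uniform draws).
#' @param scenario_effects named multiplicative calorie shifts per
#'   scenario; the first entry is the reference. Defaults put the two
#'   climate scenarios 11-12% below the no-climate-change reference.
#' @param gdp_pou_cor Gaussian-copula correlation between GDP and PoU
#'   draws (default 0, i.e. independent; negative values mimic the
#'   poorer-countries-hungrier structure of real panels).
#' @param cv_baseline,mder baseline intake-distribution CV and minimum
#'   dietary energy requirement used when constructing scenarios.
#' @param gdp_growth multiplicative GDP growth to the projection horizon;
#'   a scalar or a vector recycled over regions.
#' @param seed integer RNG seed.
#' @return a list of class \code{synth_config}.
#' @export
synth_config <- function(n_records = 186L, n_countries = 62L, n_regions = 10L,
                         true_params = default_params(),
                         residual_sd = c(moderate = 0.02, severe = 0.02),
                         gdp_range = c(81, 5513),
                         gini_range = c(0.17, 0.74),
                         pou_range = c(0.05, 0.70),
                         scenario_effects = c(noCC = 1.00, NCAR = 0.88,
                                              CSIRO = 0.89),
                         gdp_pou_cor = 0,
                         cv_baseline = 0.25, mder = 1800,
                         gdp_growth = 5, seed = 1L) {
  stopifnot(n_records >= n_countries, n_countries >= n_regions,
            inherits(true_params, "stunting_params"),
            all(residual_sd >= 0),
            gdp_range[1] > 0, diff(gdp_range) > 0,
            gini_range[1] >= 0, gini_range[2] < 1, diff(gini_range) > 0,
            pou_range[1] > 0, pou_range[2] <= 1, diff(pou_range) > 0,
            gdp_pou_cor >= -1, gdp_pou_cor <= 1,
            all(scenario_effects > 0), cv_baseline > 0, cv_baseline < 1,
            mder > 0, all(gdp_growth > 0))
  if (is.null(names(residual_sd))) {
    residual_sd <- stats::setNames(rep_len(residual_sd, 2), stunting_levels)
  }
  structure(list(n_records = as.integer(n_records),
                 n_countries = as.integer(n_countries),
                 n_regions = as.integer(n_regions),
                 true_params = true_params, residual_sd = residual_sd,
                 gdp_range = gdp_range, gini_range = gini_range,
                 pou_range = pou_range, scenario_effects = scenario_effects,
                 gdp_pou_cor = gdp_pou_cor,
                 cv_baseline = cv_baseline, mder = mder,
                 gdp_growth = gdp_growth, seed = as.integer(seed)),
            class = "synth_config")
}

truth_anchors <- function(config) {
  dev_anchors(gdp_saturation = 10000, gini_saturation = 0.38,
              adjusted_income_worst =
                config$gdp_range[1] * (1 - config$gini_range[2]))
}

synth_country_ids <- function(config) {
  sprintf("C%03d", seq_len(config$n_countries))
}

synth_region_of <- function(config) {
  # round-robin country -> region map
  stats::setNames(sprintf("R%02d",
                          rep_len(seq_len(config$n_regions),
                                  config$n_countries)),
                  synth_country_ids(config))
}

#' Generate a synthetic country-year panel
#'
#' Draws covariates (PoU, GDP, Gini) independently and uniformly over the
#' configured ranges, computes the development score with the
#' ground-truth anchors, and sets per-level stunting to the bilinear
#' surface plus Gaussian noise. Two safeguards keep all records valid
#' proportions without distorting the error distribution: covariates are
#' redrawn while the noiseless surface sits within 3 residual SDs of a
#' proportion bound (selection on covariates only, which leaves the OLS
#' errors untruncated), and the rare noise draws that still cross a bound
#' are resampled.
#'
#' @param config a [synth_config()].
#' @return list with \code{panel} (a panel data.frame, see
#'   [read_panel()]) and \code{truth}: the generating \code{params},
#'   \code{anchors}, per-record development scores \code{w}, and
#'   \code{residual_sd}.
#' @export
generate_panel <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(derive_seed(config$seed, "panel"))

  anchors <- truth_anchors(config)
  region_of <- synth_region_of(config)
  country <- rep_len(synth_country_ids(config), config$n_records)
  n <- config$n_records
  sd2 <- config$residual_sd[["moderate"]]
  sd3 <- config$residual_sd[["severe"]]
  margin2 <- 3 * sd2
  margin3 <- 3 * sd3

  surface <- function(x, w) {
    p <- predict_stunting(config$true_params, x, w)
    c(p$moderate, p$severe)
  }

  rec <- matrix(NA_real_, n, 6,
                dimnames = list(NULL, c("pou", "gdp_pc", "gini", "w",
                                        "y2", "y3")))
  for (i in seq_len(n)) {
    ok <- FALSE
    rho <- config$gdp_pou_cor
    for (try in seq_len(1000L)) {
      # Gaussian copula between PoU and GDP (independent when rho = 0);
      # marginals stay uniform over the configured ranges
      z1 <- stats::rnorm(1)
      z2 <- rho * z1 + sqrt(1 - rho^2) * stats::rnorm(1)
      x <- config$pou_range[1] + stats::pnorm(z1) * diff(config$pou_range)
      gdp <- config$gdp_range[1] + stats::pnorm(z2) * diff(config$gdp_range)
      gini <- stats::runif(1, config$gini_range[1], config$gini_range[2])
      w <- development_score(gdp, gini, anchors)
      ys <- surface(x, w)
      if (ys[1] >= margin2 && ys[1] <= 1 - margin2 &&
          ys[2] >= margin3 && ys[2] <= 1 - margin3 &&
          ys[1] + ys[2] <= 1 - margin2 - margin3) {
        ok <- TRUE
        break
      }
    }
    if (!ok) {
      stop("could not draw covariates with a feasible stunting surface; ",
           "the configured ranges and parameters are incompatible",
           call. = FALSE)
    }
    y2 <- y3 <- NA_real_
    for (try in seq_len(100L)) {
      y2 <- ys[1] + if (sd2 > 0) stats::rnorm(1, 0, sd2) else 0
      y3 <- ys[2] + if (sd3 > 0) stats::rnorm(1, 0, sd3) else 0
      if (y2 >= 0 && y3 >= 0 && y2 + y3 <= 1) break
      if (try == 100L) {
        stop("noise resampling failed; residual_sd too large for the ",
             "configured surface", call. = FALSE)
      }
    }
    rec[i, ] <- c(x, gdp, gini, w, y2, y3)
  }

  panel <- data.frame(
    country_id = country,
    region_id = unname(region_of[country]),
    year = sample(1988:2008, n, replace = TRUE),
    stunting_moderate = rec[, "y2"],
    stunting_severe = rec[, "y3"],
    pou = rec[, "pou"],
    gdp_pc = rec[, "gdp_pc"],
    gini = rec[, "gini"],
    pop_u5 = round(exp(stats::runif(n, log(1e5), log(3e7)))),
    stringsAsFactors = FALSE
  )
  list(panel = panel,
       truth = list(params = config$true_params, anchors = anchors,
                    w = rec[, "w"], residual_sd = config$residual_sd))
}

#' Generate synthetic scenario inputs
#'
#' One row per country and scenario. Baseline calorie availability is
#' back-solved (via [solve_des()]) so that the baseline PoU matches a
#' target drawn from the configured range; each scenario's calories are
#' the baseline times its configured multiplicative effect, while the
#' Gini, intake CV and MDER stay at baseline. Projected GDP is baseline
#' GDP times the per-region growth factor.
#'
#' @param config a [synth_config()].
#' @param baseline_pou optional named vector of baseline PoU targets per
#'   country; drawn uniformly from \code{config$pou_range} when NULL.
#' @return a scenario data.frame (see [read_scenarios()]) with an
#'   attached \code{attr(, "baseline")} data.frame of per-country
#'   baseline DES, PoU and GDP.
#' @export
generate_scenarios <- function(config, baseline_pou = NULL) {
  stopifnot(inherits(config, "synth_config"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(derive_seed(config$seed, "scenarios"))

  ids <- synth_country_ids(config)
  region_of <- synth_region_of(config)
  growth <- stats::setNames(
    rep_len(config$gdp_growth, config$n_regions),
    sprintf("R%02d", seq_len(config$n_regions)))

  if (is.null(baseline_pou)) {
    baseline_pou <- stats::setNames(
      stats::runif(length(ids), config$pou_range[1], config$pou_range[2]),
      ids)
  }
  gdp_base <- stats::runif(length(ids), config$gdp_range[1],
                           config$gdp_range[2])
  gini <- stats::runif(length(ids), config$gini_range[1],
                       config$gini_range[2])
  pop <- round(exp(stats::runif(length(ids), log(1e5), log(3e7))))
  des_base <- vapply(baseline_pou[ids], solve_des, numeric(1),
                     cv = config$cv_baseline, mder = config$mder)

  out <- do.call(rbind, lapply(names(config$scenario_effects), function(s) {
    data.frame(
      country_id = ids,
      region_id = unname(region_of[ids]),
      scenario_id = s,
      kcal_pc_day = des_base * config$scenario_effects[[s]],
      gdp_pc_proj = gdp_base * unname(growth[region_of[ids]]),
      gini_baseline = gini,
      cv_baseline = config$cv_baseline,
      mder = config$mder,
      pop_u5_proj = pop,
      stringsAsFactors = FALSE
    )
  }))
  rownames(out) <- NULL
  attr(out, "baseline") <- data.frame(country_id = ids, des = des_base,
                                      pou = unname(baseline_pou[ids]),
                                      gdp_pc = gdp_base,
                                      stringsAsFactors = FALSE)
  out
}
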