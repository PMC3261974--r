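# Monte Carlo propagation of parameter uncertainty through the bilinear
# model, with accept/reject bookkeeping on the (0,1) proportion scale,
# population-weighted regional aggregation, and scenario comparisons.

#' Draw one batch of parameter sets
#'
#' alpha, gamma and theta are drawn from normal distributions centred on
#' their point estimates with their standard errors; beta is drawn
#' uniformly over its plausible (1st-10th percentile) range. Degenerate
#' inputs (zero SEs, collapsed beta range) reproduce the point estimates
#' exactly.
#'
#' @param params a [stunting_params()] object.
#' @param level \code{"moderate"} / \code{"severe"} (or 2 / 3).
#' @param n number of draws.
#' @return an \code{n x 4} matrix with columns alpha, beta, gamma, theta.
#'   Uses (and advances) the current RNG stream; seed it with
#'   \code{set.seed} for reproducibility.
#' @export
sample_params <- function(params, level, n = 1L) {
  stopifnot(inherits(params, "stunting_params"), n >= 1L)
  lv <- params$levels[[match_level(level)]]
  draw_norm <- function(p) {
    if (p[["se"]] == 0) rep(p[["estimate"]], n)
    else stats::rnorm(n, p[["estimate"]], p[["se"]])
  }
  b <- lv$beta
  beta <- if (b$low == b$high) rep(b$low, n) else stats::runif(n, b$low, b$high)
  cbind(alpha = draw_norm(lv$alpha), beta = beta,
        gamma = draw_norm(lv$gamma), theta = draw_norm(lv$theta))
}

#' Monte Carlo stunting simulation for one country
#'
#' For each stunting level independently: draw a parameter set, evaluate
#' the bilinear model at the country's (x, w), accept the estimate iff it
#' lies strictly inside (0, 1), and repeat until \code{n_target} estimates
#' are accepted (the first \code{n_target} in draw order). Rejections are
#' counted separately below 0 and above 1, since one-sided rejection
#' biases the accepted mean (upward when only low estimates are
#' rejected).
#'
#' @param params a [stunting_params()] object.
#' @param x proportion undernourished in [0, 1].
#' @param w development score in [0, 1].
#' @param n_target number of accepted samples per level (default 100000).
#' @param seed master seed; a sub-seed is derived per level so levels are
#'   independent.
#' @param accept_floor minimal tolerated acceptance rate; if a probe batch
#'   falls below it the model is being evaluated far outside its fitted
#'   range and the run aborts with a diagnostic.
#' @return a list per level (\code{moderate}, \code{severe}), each with
#'   \code{samples} (length \code{n_target}), \code{n_rejected_low},
#'   \code{n_rejected_high}.
#' @export
simulate_country <- function(params, x, w, n_target = 100000, seed = 1L,
                             accept_floor = 0.01) {
  stopifnot(x >= 0, x <= 1, w >= 0, w <= 1, n_target >= 1)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  out <- lapply(stunting_levels, function(level) {
    set.seed(derive_seed(seed, "level", level))
    accepted <- numeric(0)
    rej_low <- 0L
    rej_high <- 0L
    probe_checked <- FALSE
    rate <- 1
    while (length(accepted) < n_target) {
      need <- n_target - length(accepted)
      m <- min(max(ceiling(need / max(rate, accept_floor)), 1000L), 2000000L)
      th <- sample_params(params, level, m)
      y <- th[, "alpha"] + th[, "beta"] * x + th[, "gamma"] * w +
        th[, "theta"] * x * w
      ok <- y > 0 & y < 1
      if (!probe_checked) {
        rate <- mean(ok)
        probe_checked <- TRUE
        if (rate < accept_floor) {
          stop(sprintf(paste0("acceptance rate %.2f%% for %s stunting at ",
                              "(x = %.3f, w = %.3f) is below the %.0f%% ",
                              "floor; the model is being evaluated outside ",
                              "its fitted range"),
                       100 * rate, level, x, w, 100 * accept_floor),
               call. = FALSE)
        }
      }
      # keep draw order: truncate the batch at the draw that completes
      # the target so rejection counts refer to the same draw sequence
      cum <- cumsum(ok)
      if (cum[m] >= need) {
        cut <- which(cum == need)[1]
        y <- y[seq_len(cut)]
        ok <- ok[seq_len(cut)]
      }
      accepted <- c(accepted, y[ok])
      rej_low <- rej_low + sum(y <= 0)
      rej_high <- rej_high + sum(y >= 1)
    }
    list(samples = accepted, n_rejected_low = rej_low,
         n_rejected_high = rej_high)
  })
  names(out) <- stunting_levels
  out
}

#' Population-weighted regional aggregation
#'
#' Combines per-country Monte Carlo samples into regional samples,
#' draw-by-draw: the t-th regional sample is the population-weighted mean
#' of the countries' t-th samples. Consequently the regional mean equals
#' the weighted mean of country means exactly.
#'
#' @param country_samples named list of equal-length numeric vectors, one
#'   per country.
#' @param weights named numeric vector of positive population weights,
#'   matching \code{names(country_samples)}.
#' @return regional sample vector of the common length.
#' @export
aggregate_region <- function(country_samples, weights) {
  stopifnot(length(country_samples) >= 1L)
  lens <- lengths(country_samples)
  if (length(unique(lens)) != 1L) {
    stop("countries have mismatched sample counts: ",
         paste(lens, collapse = ", "), call. = FALSE)
  }
  weights <- weights[names(country_samples)]
  if (anyNA(weights) || any(weights <= 0)) {
    stop("every country needs a positive weight", call. = FALSE)
  }
  num <- Reduce(`+`, Map(`*`, country_samples, as.list(weights)))
  num / sum(weights)
}

#' Summarize a Monte Carlo sample
#'
#' @param samples numeric vector (at least 2 values).
#' @param probs percentile points to report.
#' @param bins number of fixed-width histogram bins over
#'   \code{[0, max(samples)]}.
#' @return list with \code{mean}, \code{sd} (n-1 denominator),
#'   \code{quantiles}, and \code{histogram} (\code{breaks}, \code{counts}).
#' @export
summarize_samples <- function(samples, probs = c(0.025, 0.25, 0.5, 0.75,
                                                 0.975), bins = 50L) {
  stopifnot(length(samples) >= 2L)
  breaks <- seq(0, max(samples), length.out = bins + 1L)
  if (breaks[1] == breaks[bins + 1L]) breaks <- c(0, max(samples[1], 1e-12))
  counts <- tabulate(pmin(findInterval(samples, breaks,
                                       rightmost.closed = TRUE),
                          length(breaks) - 1L),
                     nbins = length(breaks) - 1L)
  list(mean = mean(samples), sd = stats::sd(samples),
       quantiles = stats::quantile(samples, probs = probs, names = TRUE),
       histogram = list(breaks = breaks, counts = counts))
}

#' Relative increase under climate change
#'
#' The headline comparison statistic: the mean of the two climate-scenario
#' values relative to the no-climate-change value,
#' \code{100 * ((a + b) / 2 / noCC - 1)} percent. The unrounded value is
#' returned; the nearest integer (used in reporting) is attached as
#' \code{attr(, "rounded")}.
#'
#' @param mean_nocc no-climate-change mean (> 0).
#' @param mean_a,mean_b means under the two climate scenarios.
#' @return percent relative increase (unrounded), or \code{NA} with a
#'   warning when \code{mean_nocc} is zero.
#' @export
relative_increase <- function(mean_nocc, mean_a, mean_b) {
  if (is.na(mean_nocc) || mean_nocc == 0) {
    warning("relative increase undefined: reference mean is zero",
            call. = FALSE)
    return(NA_real_)
  }
  value <- 100 * ((mean_a + mean_b) / 2 / mean_nocc - 1)
  structure(value, rounded = round_half_up(value))
}

#' Project stunting under climate scenarios
#'
#' The full projection pipeline: for every scenario row, compute the
#' projected PoU (scenario calories with baseline CV and MDER) and the
#' development score (projected GDP with baseline Gini), run the
#' per-country Monte Carlo simulation, aggregate to regions with
#' population weights, and summarize. When the scenarios include a
#' reference (\code{reference_id}) plus at least two others, relative
#' increases in regional mean stunting and in regional PoU are reported.
#'
#' Countries whose projected PoU exceeds \code{pou_fit_max} (the maximum
#' undernourishment in the data used to fit the published model, 76%) are
#' flagged with a warning: estimates there extrapolate beyond the fitted
#' range.
#'
#' @param params a [stunting_params()] object (e.g. from
#'   [stunting_fit()]\code{$params} or [default_params()]).
#' @param scenarios scenario data.frame, see [read_scenarios()].
#' @param anchors [dev_anchors()] for the development score.
#' @param n_draws accepted Monte Carlo samples per country x scenario x
#'   level (default 100000).
#' @param seed master seed; per-country sub-seeds are derived from
#'   (seed, country, scenario) so countries are independent and the run
#'   is reproducible.
#' @param reference_id scenario id of the no-climate-change reference.
#' @param pou_fit_max fitted-range ceiling for PoU warnings.
#' @return object of class \code{stunting_projection}: \code{country}
#'   (country x scenario inputs, PoU, w, per-level means and rejection
#'   counts), \code{regional} (region x scenario x level mean/sd,
#'   rejection proportions), \code{regional_pou} (population-weighted
#'   PoU), \code{increases} (relative increases vs the reference, stunting
#'   and PoU), \code{histograms} (per region x scenario x level), and the
#'   call settings.
#' @export
project_stunting <- function(params, scenarios, anchors, n_draws = 100000,
                             seed = 1L, reference_id = "noCC",
                             pou_fit_max = 0.76) {
  stopifnot(inherits(params, "stunting_params"), inherits(anchors, "dev_anchors"))
  sc <- scenarios
  sc$pou <- project_pou(sc)
  sc$w <- development_score(sc$gdp_pc_proj, sc$gini_baseline, anchors)
  over <- sc$pou > pou_fit_max
  if (any(over)) {
    warning("projected PoU exceeds the fitted range (", 100 * pou_fit_max,
            "%) for: ",
            paste(unique(sprintf("%s/%s (%.0f%%)", sc$country_id[over],
                                 sc$scenario_id[over], 100 * sc$pou[over])),
                  collapse = ", "),
            "; interpret those stunting estimates cautiously", call. = FALSE)
  }

  sims <- vector("list", nrow(sc))
  for (i in seq_len(nrow(sc))) {
    sims[[i]] <- simulate_country(
      params, x = sc$pou[i], w = sc$w[i], n_target = n_draws,
      seed = derive_seed(seed, sc$country_id[i], sc$scenario_id[i]))
  }

  country <- do.call(rbind, lapply(seq_len(nrow(sc)), function(i) {
    do.call(rbind, lapply(stunting_levels, function(lv) {
      s <- sims[[i]][[lv]]
      data.frame(country_id = sc$country_id[i], region_id = sc$region_id[i],
                 scenario_id = sc$scenario_id[i], level = lv,
                 pou = sc$pou[i], w = sc$w[i],
                 mean = mean(s$samples), sd = stats::sd(s$samples),
                 n_rejected_low = s$n_rejected_low,
                 n_rejected_high = s$n_rejected_high,
                 pop = sc$pop_u5_proj[i], stringsAsFactors = FALSE)
    }))
  }))

  cells <- unique(country[, c("region_id", "scenario_id", "level")])
  regional <- do.call(rbind, lapply(seq_len(nrow(cells)), function(j) {
    cell <- cells[j, ]
    rows <- which(sc$region_id == cell$region_id &
                    sc$scenario_id == cell$scenario_id)
    samples <- stats::setNames(lapply(rows, function(i)
      sims[[i]][[cell$level]]$samples), sc$country_id[rows])
    weights <- stats::setNames(sc$pop_u5_proj[rows], sc$country_id[rows])
    agg <- aggregate_region(samples, weights)
    sm <- summarize_samples(agg)
    rej <- country[country$region_id == cell$region_id &
                     country$scenario_id == cell$scenario_id &
                     country$level == cell$level, ]
    n_draws_tot <- length(rows) * n_draws
    data.frame(cell, mean = sm$mean, sd = sm$sd,
               prop_rejected_low = sum(rej$n_rejected_low) /
                 (n_draws_tot + sum(rej$n_rejected_low) +
                    sum(rej$n_rejected_high)),
               prop_rejected_high = sum(rej$n_rejected_high) /
                 (n_draws_tot + sum(rej$n_rejected_low) +
                    sum(rej$n_rejected_high)),
               stringsAsFactors = FALSE)
  }))
  rownames(regional) <- NULL

  histograms <- lapply(seq_len(nrow(cells)), function(j) {
    cell <- cells[j, ]
    rows <- which(sc$region_id == cell$region_id &
                    sc$scenario_id == cell$scenario_id)
    samples <- stats::setNames(lapply(rows, function(i)
      sims[[i]][[cell$level]]$samples), sc$country_id[rows])
    agg <- aggregate_region(samples,
                            stats::setNames(sc$pop_u5_proj[rows],
                                            sc$country_id[rows]))
    c(cell, summarize_samples(agg)["histogram"])
  })

  rp_cells <- unique(sc[, c("region_id", "scenario_id")])
  regional_pou <- do.call(rbind, lapply(seq_len(nrow(rp_cells)), function(j) {
    cell <- rp_cells[j, ]
    rows <- sc$region_id == cell$region_id & sc$scenario_id == cell$scenario_id
    data.frame(cell, pou = stats::weighted.mean(sc$pou[rows],
                                                sc$pop_u5_proj[rows]),
               stringsAsFactors = FALSE)
  }))
  rownames(regional_pou) <- NULL

  increases <- compute_increases(regional, regional_pou, reference_id)

  # levels are simulated independently, so no/mild stunting is closed on
  # the summary means; a negative value is a diagnostic, not an error
  nomild <- do.call(rbind, lapply(seq_len(nrow(rp_cells)), function(j) {
    cell <- rp_cells[j, ]
    sel <- regional$region_id == cell$region_id &
      regional$scenario_id == cell$scenario_id
    data.frame(cell,
               mean = 1 - sum(regional$mean[sel]),
               stringsAsFactors = FALSE)
  }))
  rownames(nomild) <- NULL
  if (any(nomild$mean < 0)) {
    message("implied no/mild stunting is negative for ",
            sum(nomild$mean < 0), " regional cell(s); the independently ",
            "fitted levels overlap there")
  }

  structure(list(country = country, regional = regional,
                 regional_pou = regional_pou, nomild = nomild,
                 increases = increases,
                 histograms = histograms, n_draws = n_draws, seed = seed,
                 reference_id = reference_id),
            class = "stunting_projection")
}

compute_increases <- function(regional, regional_pou, reference_id) {
  scenario_ids <- unique(regional$scenario_id)
  climate_ids <- setdiff(scenario_ids, reference_id)
  if (!(reference_id %in% scenario_ids) || length(climate_ids) != 2L) {
    return(NULL)
  }
  pick <- function(df, region, scen, level = NULL, col) {
    sel <- df$region_id == region & df$scenario_id == scen
    if (!is.null(level)) sel <- sel & df$level == level
    df[[col]][sel]
  }
  stunt <- do.call(rbind, lapply(unique(regional$region_id), function(rg) {
    do.call(rbind, lapply(stunting_levels, function(lv) {
      ri <- relative_increase(pick(regional, rg, reference_id, lv, "mean"),
                              pick(regional, rg, climate_ids[1], lv, "mean"),
                              pick(regional, rg, climate_ids[2], lv, "mean"))
      data.frame(region_id = rg, level = lv, quantity = "stunting",
                 increase_pct = as.numeric(ri),
                 increase_pct_rounded = attr(ri, "rounded"),
                 stringsAsFactors = FALSE)
    }))
  }))
  pou <- do.call(rbind, lapply(unique(regional_pou$region_id), function(rg) {
    ri <- relative_increase(pick(regional_pou, rg, reference_id, NULL, "pou"),
                            pick(regional_pou, rg, climate_ids[1], NULL, "pou"),
                            pick(regional_pou, rg, climate_ids[2], NULL, "pou"))
    data.frame(region_id = rg, level = NA_character_, quantity = "pou",
               increase_pct = as.numeric(ri),
               increase_pct_rounded = attr(ri, "rounded"),
               stringsAsFactors = FALSE)
  }))
  rbind(stunt, pou)
}

#' @export
print.stunting_projection <- function(x, ...) {
  cat("Stunting projection (", x$n_draws, " accepted draws per country/",
      "scenario/level, seed ", x$seed, ")\n\n", sep = "")
  tab <- x$regional
  tab$mean <- sprintf("%.1f", 100 * tab$mean)
  tab$sd <- sprintf("%.1f", 100 * tab$sd)
  tab$prop_rejected_low <- sprintf("%.2f%%", 100 * tab$prop_rejected_low)
  tab$prop_rejected_high <- sprintf("%.2f%%", 100 * tab$prop_rejected_high)
  names(tab)[names(tab) == "mean"] <- "mean %"
  names(tab)[names(tab) == "sd"] <- "sd %"
  cat("Regional stunting (percent of children):\n")
  print(tab, row.names = FALSE)
  if (!is.null(x$increases)) {
    cat("\nRelative increases vs '", x$reference_id, "' (percent):\n",
        sep = "")
    inc <- x$increases
    inc$increase_pct <- sprintf("%.1f", inc$increase_pct)
    print(inc, row.names = FALSE)
  }
  invisible(x)
}

#' Sensitivity of projections to the saturation assumption
#'
#' Re-runs a projection with the development-score saturation point
#' replaced by the best observed adjusted income in the calibration panel
#' (see [calibrate_anchors_nosat()]) and reports, per regional cell, the
#' difference in projected mean stunting. This is a comparison report,
#' not a test: the expectation is that the difference is negligible.
#'
#' @param params,scenarios,n_draws,seed as in [project_stunting()].
#' @param panel calibration panel used for both anchor sets.
#' @return data.frame of regional cells with mean stunting under both
#'   anchor choices and their difference (proportion scale).
#' @export
saturation_sensitivity <- function(params, scenarios, panel,
                                   n_draws = 10000, seed = 1L) {
  with_sat <- project_stunting(params, scenarios, calibrate_anchors(panel),
                               n_draws = n_draws, seed = seed)
  without <- project_stunting(params, scenarios,
                              calibrate_anchors_nosat(panel),
                              n_draws = n_draws, seed = seed)
  a <- with_sat$regional[, c("region_id", "scenario_id", "level", "mean")]
  b <- without$regional[, c("region_id", "scenario_id", "level", "mean")]
  names(b)[4] <- "mean_nosat"
  out <- merge(a, b)
  out$difference <- out$mean_nosat - out$mean
  out
}
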