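# The development score: a 0-1 index of the nonfood (socioeconomic) causes
# of stunting, driven by per capita GDP and the Gini coefficient.

#' Inequality-adjusted income
#'
#' The score's underlying welfare measure: per capita GDP discounted by
#' income inequality, \code{gdp_pc * (1 - gini)}. Strictly increasing in
#' GDP and strictly decreasing in the Gini coefficient.
#'
#' @param gdp_pc per capita GDP (2000 US$), > 0. Vectorized.
#' @param gini Gini coefficient in [0, 1). Vectorized.
#' @return inequality-adjusted income (same units as \code{gdp_pc}).
#' @export
adjusted_income <- function(gdp_pc, gini) {
  if (any(!is.finite(gdp_pc)) || any(gdp_pc <= 0)) {
    stop("gdp_pc must be finite and > 0", call. = FALSE)
  }
  if (any(!is.finite(gini)) || any(gini < 0) || any(gini >= 1)) {
    stop("gini must lie in [0, 1); gini = 1 is a degenerate distribution",
         call. = FALSE)
  }
  gdp_pc * (1 - gini)
}

#' Calibrate development-score anchors from a baseline panel
#'
#' The score equals 1 when nonfood causes are at their baseline global
#' maximum, i.e. at the minimum inequality-adjusted income observed in the
#' calibration panel; it equals 0 at the saturation point beyond which
#' socioeconomic conditions no longer contribute to stunting (by default
#' $10,000 per capita GDP with a Gini of 0.38).
#'
#' @param panel a panel data.frame with \code{gdp_pc} and \code{gini}
#'   columns (see [read_panel()]).
#' @param gdp_saturation,gini_saturation the saturation point.
#' @return an object of class \code{dev_anchors} with fields
#'   \code{gdp_saturation}, \code{gini_saturation} and
#'   \code{adjusted_income_worst}.
#' @export
calibrate_anchors <- function(panel, gdp_saturation = 10000,
                              gini_saturation = 0.38) {
  if (is.null(panel) || nrow(panel) == 0L) {
    stop("cannot calibrate anchors from an empty panel", call. = FALSE)
  }
  worst <- min(adjusted_income(panel$gdp_pc, panel$gini))
  dev_anchors(gdp_saturation, gini_saturation, worst)
}

#' @rdname calibrate_anchors
#' @param adjusted_income_worst the panel minimum of [adjusted_income()],
#'   where the score equals 1.
#' @export
dev_anchors <- function(gdp_saturation = 10000, gini_saturation = 0.38,
                        adjusted_income_worst) {
  a_opt <- gdp_saturation * (1 - gini_saturation)
  stopifnot(gdp_saturation > 0, gini_saturation >= 0, gini_saturation < 1,
            adjusted_income_worst > 0)
  if (!(adjusted_income_worst < a_opt)) {
    stop("adjusted_income_worst must lie below the saturation income ",
         format(a_opt), call. = FALSE)
  }
  structure(list(gdp_saturation = gdp_saturation,
                 gini_saturation = gini_saturation,
                 adjusted_income_worst = adjusted_income_worst),
            class = "dev_anchors")
}

#' @export
print.dev_anchors <- function(x, ...) {
  cat("Development-score anchors\n",
      "  saturation (w = 0): GDP ", format(x$gdp_saturation),
      " at Gini ", format(x$gini_saturation), "\n",
      "  worst baseline (w = 1): adjusted income ",
      format(x$adjusted_income_worst), "\n", sep = "")
  invisible(x)
}

#' Development score
#'
#' Maps per capita GDP and the Gini coefficient to the nonfood-cause score
#' w in [0, 1]: 0 when socioeconomic conditions are at or beyond the
#' saturation point (all remaining stunting is food-attributable), 1 at the
#' baseline global worst. Between the anchors the score interpolates
#' linearly in log inequality-adjusted income, the standard income-health
#' scale:
#' \deqn{w = \mathrm{clamp}\left(\frac{\ln a_{opt} - \ln a}
#'   {\ln a_{opt} - \ln a_{worst}}, 0, 1\right)}
#' with \eqn{a = gdp (1 - gini)} and \eqn{a_{opt}} the saturation income.
#'
#' @inheritParams adjusted_income
#' @param anchors a [dev_anchors()] object.
#' @return scores in [0, 1]; non-increasing in \code{gdp_pc},
#'   non-decreasing in \code{gini}.
#' @export
development_score <- function(gdp_pc, gini, anchors) {
  stopifnot(inherits(anchors, "dev_anchors"))
  a <- adjusted_income(gdp_pc, gini)
  a_opt <- anchors$gdp_saturation * (1 - anchors$gini_saturation)
  clamp01((log(a_opt) - log(a)) /
            (log(a_opt) - log(anchors$adjusted_income_worst)))
}

#' Anchors with the saturation assumption disabled
#'
#' Sensitivity variant: instead of pinning w = 0 at the $10,000 / 0.38
#' saturation point, pins it at the best (maximum) inequality-adjusted
#' income observed in the panel. Useful for checking how much the
#' saturation assumption moves projections; see
#' [saturation_sensitivity()].
#'
#' @inheritParams calibrate_anchors
#' @export
calibrate_anchors_nosat <- function(panel) {
  if (is.null(panel) || nrow(panel) == 0L) {
    stop("cannot calibrate anchors from an empty panel", call. = FALSE)
  }
  a <- adjusted_income(panel$gdp_pc, panel$gini)
  best <- max(a)
  dev_anchors(gdp_saturation = best * (1 + 1e-9), gini_saturation = 0,
              adjusted_income_worst = min(a))
}
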