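# FAO-style prevalence of undernourishment (PoU): the proportion of a
# population whose habitual dietary energy intake falls below the minimum
# dietary energy requirement (MDER), under a lognormal model of the
# within-population intake distribution.

#' Lognormal intake distribution
#'
#' The unique lognormal with mean equal to the per capita dietary energy
#' supply (DES) and a given coefficient of variation:
#' \eqn{\sigma = \sqrt{\ln(cv^2 + 1)}}, \eqn{\mu = \ln(des) - \sigma^2/2},
#' so that \eqn{e^{\mu + \sigma^2/2} = des}.
#'
#' @param des mean per capita dietary energy supply (kcal/person/day), > 0.
#' @param cv coefficient of variation of habitual intake, > 0.
#' @return an object of class \code{intake_distribution} with fields
#'   \code{des}, \code{cv}, \code{mu}, \code{sigma}.
#' @export
intake_distribution <- function(des, cv) {
  if (!is.finite(des) || des <= 0) stop("des must be > 0", call. = FALSE)
  if (!is.finite(cv) || cv <= 0) stop("cv must be > 0", call. = FALSE)
  sigma <- sqrt(log(cv^2 + 1))
  structure(list(des = des, cv = cv, mu = log(des) - sigma^2 / 2,
                 sigma = sigma),
            class = "intake_distribution")
}

#' @export
print.intake_distribution <- function(x, ...) {
  cat("Lognormal intake distribution: DES", format(x$des),
      "kcal/day, CV", format(x$cv),
      sprintf("(mu = %.4f, sigma = %.4f)\n", x$mu, x$sigma))
  invisible(x)
}

#' Prevalence of undernourishment
#'
#' PoU = F(mder), the lognormal intake CDF evaluated at the minimum dietary
#' energy requirement. Strictly decreasing in \code{des} and strictly
#' increasing in \code{mder}; always in (0, 1).
#'
#' @inheritParams intake_distribution
#' @param mder minimum dietary energy requirement (kcal/person/day), > 0.
#' @return the proportion undernourished.
#' @export
estimate_pou <- function(des, cv, mder) {
  if (any(!is.finite(mder)) || any(mder <= 0)) {
    stop("mder must be > 0", call. = FALSE)
  }
  if (length(des) > 1L || length(cv) > 1L || length(mder) > 1L) {
    n <- max(length(des), length(cv), length(mder))
    return(mapply(estimate_pou, rep_len(des, n), rep_len(cv, n),
                  rep_len(mder, n)))
  }
  d <- intake_distribution(des, cv)
  stats::plnorm(mder, meanlog = d$mu, sdlog = d$sigma)
}

#' Scenario PoU
#'
#' Computes PoU for scenario rows (see [read_scenarios()]): the projected
#' calorie availability is scenario-specific, while the intake-distribution
#' CV and the MDER are always held at their baseline values (no projections
#' for either exist).
#'
#' @param scenario a scenario data.frame with columns \code{kcal_pc_day},
#'   \code{cv_baseline}, \code{mder}.
#' @return a numeric vector of PoU values, one per row.
#' @export
project_pou <- function(scenario) {
  estimate_pou(scenario$kcal_pc_day, scenario$cv_baseline, scenario$mder)
}

#' Back-solve calorie availability from a target PoU
#'
#' Finds the DES at which [estimate_pou()] equals \code{pou}, by root
#' finding over \code{des}. Used by the synthetic-scenario generator to
#' construct baselines with a prescribed undernourishment level.
#'
#' @param pou target proportion undernourished, in (0, 1).
#' @inheritParams estimate_pou
#' @return the dietary energy supply (kcal/person/day).
#' @export
solve_des <- function(pou, cv, mder) {
  stopifnot(pou > 0, pou < 1)
  f <- function(des) estimate_pou(des, cv, mder) - pou
  lower <- mder * 1e-3
  upper <- mder * 1e3
  if (f(lower) < 0 || f(upper) > 0) {
    stop("failed to bracket the root: target PoU ", pou,
         " unattainable for mder ", mder, call. = FALSE)
  }
  stats::uniroot(f, c(lower, upper), tol = 1e-10)$root
}
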