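#' Model parameter container
#'
#' Bundles, for each stunting level (moderate, severe), the physiological
#' coefficient \code{beta} (a central estimate with a plausible low/high
#' range taken from low percentiles of the stunting/undernourishment ratio
#' distribution) and the nonfood regression parameters \code{alpha} (the
#' intercept), \code{gamma} (development-score coefficient) and \code{theta}
#' (undernourishment x development-score interaction), each as a point
#' estimate with a standard error.
#'
#' @param moderate,severe per-level parameter lists, each with components
#'   \code{beta} (a \code{beta_estimate}, see [estimate_beta()], or a list
#'   with \code{low}, \code{central}, \code{high}), and \code{alpha},
#'   \code{gamma}, \code{theta}, each a numeric vector
#'   \code{c(estimate, se)}.
#' @param diagnostics optional list of fit diagnostics (sample size,
#'   residual standard deviation, design condition number per level).
#' @return an object of class \code{stunting_params}.
#' @seealso [default_params()] for the published central estimates.
#' @export
stunting_params <- function(moderate, severe, diagnostics = NULL) {
  levels <- list(moderate = moderate, severe = severe)
  for (nm in names(levels)) {
    lv <- levels[[nm]]
    stopifnot(all(c("beta", "alpha", "gamma", "theta") %in% names(lv)))
    b <- lv$beta
    if (!(is.list(b) && all(c("low", "central", "high") %in% names(b)))) {
      stop("beta for level '", nm, "' must have low/central/high components",
           call. = FALSE)
    }
    if (!(b$low > 0 && b$low <= b$central && b$central <= b$high)) {
      stop("beta for level '", nm, "' must satisfy 0 < low <= central <= high",
           call. = FALSE)
    }
    for (p in c("alpha", "gamma", "theta")) {
      est <- lv[[p]]
      if (length(est) == 1L) est <- c(est, 0)
      if (is.na(est[2]) || est[2] < 0) {
        stop("standard error for ", p, " (level '", nm, "') must be >= 0",
             call. = FALSE)
      }
      levels[[nm]][[p]] <- stats::setNames(as.numeric(est), c("estimate", "se"))
    }
  }
  structure(list(levels = levels, diagnostics = diagnostics),
            class = "stunting_params")
}

#' Published central parameter estimates
#'
#' The default parameter set: for moderate stunting beta = 0.35
#' (range 0.20-0.44), alpha = 0.025 +/- 0.013, gamma = 0.26 +/- 0.028,
#' theta = -0.43 +/- 0.041; for severe stunting beta = 0.18 (0.11-0.28),
#' alpha = -0.052 +/- 0.021, gamma = 0.34 +/- 0.044, theta = -0.18 +/- 0.064.
#'
#' @return a [stunting_params()] object.
#' @export
default_params <- function() {
  stunting_params(
    moderate = list(
      beta  = list(low = 0.20, central = 0.35, high = 0.44),
      alpha = c(0.025, 0.013),
      gamma = c(0.26, 0.028),
      theta = c(-0.43, 0.041)
    ),
    severe = list(
      beta  = list(low = 0.11, central = 0.18, high = 0.28),
      alpha = c(-0.052, 0.021),
      gamma = c(0.34, 0.044),
      theta = c(-0.18, 0.064)
    )
  )
}

#' @export
print.stunting_params <- function(x, digits = 3, ...) {
  cat("Stunting model parameters\n")
  tab <- as.data.frame(x)
  print(format(tab, digits = digits), row.names = FALSE)
  invisible(x)
}

#' @export
as.data.frame.stunting_params <- function(x, ...) {
  rows <- lapply(names(x$levels), function(nm) {
    lv <- x$levels[[nm]]
    data.frame(
      level = nm,
      beta = lv$beta$central, beta_low = lv$beta$low, beta_high = lv$beta$high,
      alpha = lv$alpha[["estimate"]], alpha_se = lv$alpha[["se"]],
      gamma = lv$gamma[["estimate"]], gamma_se = lv$gamma[["se"]],
      theta = lv$theta[["estimate"]], theta_se = lv$theta[["se"]],
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' Read / write a parameter file
#'
#' Parameters are serialized as JSON so fitted models can be passed between
#' the fitting and projection steps (and between CLI invocations).
#'
#' @param params a [stunting_params()] object.
#' @param path file path.
#' @return \code{write_params} returns \code{path} invisibly;
#'   \code{read_params} returns a \code{stunting_params} object.
#' @export
write_params <- function(params, path) {
  stopifnot(inherits(params, "stunting_params"))
  out <- lapply(params$levels, function(l) {
    list(beta = unclass(l$beta)[c("low", "central", "high")],
         alpha = as.list(l$alpha), gamma = as.list(l$gamma),
         theta = as.list(l$theta))
  })
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_params
#' @export
read_params <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  lv <- lapply(raw, function(l) {
    list(beta = as.list(l$beta[c("low", "central", "high")]),
         alpha = unlist(l$alpha[c("estimate", "se")]),
         gamma = unlist(l$gamma[c("estimate", "se")]),
         theta = unlist(l$theta[c("estimate", "se")]))
  })
  stunting_params(moderate = lv$moderate, severe = lv$severe)
}
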