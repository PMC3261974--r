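# The core stunting model.
#
# Bilinear model, per stunting level k in {moderate, severe}:
#
#   y_k = alpha_k + beta_k * x + gamma_k * w + theta_k * x * w
#   y_nomild = 1 - y_moderate - y_severe
#
# where x is the proportion undernourished (food causes) and w the
# development score (nonfood causes). Fitting is stepwise and
# theory-driven: beta_k, the assumed physiological link between
# undernourishment and stunting, is estimated first as a low percentile of
# the observed y_k / x ratio distribution (the minimum in principle; the
# 5th percentile in practice to guard against data errors, with the 1st
# and 10th as a plausible range). The food-attributable share
# r_k = beta_k * x is subtracted, and the nonfood residual
# s_k = y_k - r_k is regressed on (1, w, x*w) by ordinary least squares.

#' Stunting/undernourishment ratio distribution
#'
#' Returns the ratios y_k / x across the panel, sorted ascending. Records
#' with zero undernourishment are excluded (ratio undefined) and counted
#' in \code{attr(, "n_excluded")}.
#'
#' @param panel a panel data.frame (see [read_panel()]).
#' @param level \code{"moderate"}, \code{"severe"}, or the numeric codes
#'   2 / 3.
#' @return ascending numeric vector of ratios.
#' @export
ratio_distribution <- function(panel, level) {
  level <- match_level(level)
  if (is.null(panel) || nrow(panel) == 0L) stop("panel is empty", call. = FALSE)
  y <- panel[[paste0("stunting_", level)]]
  x <- panel$pou
  keep <- x > 0
  if (!any(keep)) {
    stop("all records have zero undernourishment; ratios undefined",
         call. = FALSE)
  }
  out <- sort(y[keep] / x[keep])
  attr(out, "n_excluded") <- sum(!keep)
  out
}

#' Estimate the physiological coefficient beta
#'
#' The central estimate is a low percentile of the ratio distribution
#' (default the 5th), bracketed by the 1st and 10th percentiles as the
#' plausible range. Percentiles use linear interpolation between closest
#' order statistics with the exclusive-endpoint plotting convention
#' (\code{stats::quantile} type 6). Percentiles (0, 0, 0) degenerate to
#' the sample minimum.
#'
#' @param ratios ascending ratio vector from [ratio_distribution()]
#'   (at least 2 values).
#' @param percentiles numeric \code{c(low, central, high)} percent points,
#'   default \code{c(1, 5, 10)}.
#' @param level optional level label carried through for printing.
#' @return an object of class \code{beta_estimate}: list with \code{low},
#'   \code{central}, \code{high}, \code{n_ratios}, \code{level}.
#' @export
estimate_beta <- function(ratios, percentiles = c(1, 5, 10), level = NULL) {
  if (length(ratios) < 2L) {
    stop("need at least 2 ratios to estimate beta", call. = FALSE)
  }
  p <- percentiles / 100
  if (!(all(p >= 0) && all(p < 1) && p[1] <= p[2] && p[2] <= p[3])) {
    stop("percentiles must satisfy 0 <= low <= central <= high < 100",
         call. = FALSE)
  }
  q <- unname(stats::quantile(ratios, probs = p, type = 6, names = FALSE))
  out <- list(low = q[1], central = q[2], high = q[3],
              n_ratios = length(ratios), level = level,
              percentiles = percentiles)
  if (!(out$low > 0 && out$low <= out$central && out$central <= out$high)) {
    stop("beta percentiles are not positive and ordered; check the ratio ",
         "distribution (smallest ratio = ", format(min(ratios)), ")",
         call. = FALSE)
  }
  structure(out, class = "beta_estimate")
}

#' @export
print.beta_estimate <- function(x, digits = 3, ...) {
  cat(sprintf("beta%s = %s (plausible range %s-%s), from %d ratios\n",
              if (is.null(x$level)) "" else paste0(" [", x$level, "]"),
              format(x$central, digits = digits),
              format(x$low, digits = digits),
              format(x$high, digits = digits), x$n_ratios))
  invisible(x)
}

#' Food-attributable stunting
#'
#' The share of stunting attributable to food causes: \code{beta * x}.
#' With the published central beta of 0.35 for moderate stunting, each 1%
#' of the population undernourished implies 0.35% of children moderately
#' stunted.
#'
#' @param beta the physiological coefficient (> 0); a scalar or a
#'   \code{beta_estimate} (its central value is used).
#' @param x proportion undernourished in [0, 1]. Vectorized.
#' @return the food-attributable proportion stunted.
#' @export
attribute_food <- function(beta, x) {
  if (is.list(beta)) beta <- beta$central
  stopifnot(beta > 0, all(x >= 0 & x <= 1))
  beta * x
}

#' Nonfood stunting residual
#'
#' The remainder after food attribution: \code{y - r}. May be negative
#' when \code{beta * x} exceeds observed stunting; negatives are retained
#' (truncation would bias the downstream regression).
#'
#' @param y observed proportion stunted in [0, 1].
#' @param r food-attributable proportion from [attribute_food()].
#' @return \code{y - r}.
#' @export
residual_nonfood <- function(y, r) {
  stopifnot(all(y >= 0 & y <= 1), all(r >= 0 & r <= 1))
  y - r
}

#' Fit the nonfood regression
#'
#' For each level, ordinary least squares of the nonfood residual s on
#' \code{(1, w, x*w)}, beta having been fixed beforehand (stepwise fit).
#' Negative residuals are kept. The two levels are fitted independently;
#' no joint sum-to-one constraint is imposed at this stage.
#'
#' @param train training panel data.frame.
#' @param beta named list of \code{beta_estimate}s
#'   (\code{moderate}, \code{severe}).
#' @param anchors [dev_anchors()] used to compute the development score;
#'   if \code{NULL}, calibrated from \code{train}.
#' @return a [stunting_params()] object; \code{$diagnostics} records, per
#'   level, the sample size, residual standard deviation and the design
#'   matrix condition number (x*w is correlated with w by construction;
#'   the condition number quantifies it).
#' @export
fit_nonfood <- function(train, beta, anchors = NULL) {
  if (nrow(train) <= 3L) {
    stop("need more than 3 training records", call. = FALSE)
  }
  if (is.null(anchors)) anchors <- calibrate_anchors(train)
  w <- development_score(train$gdp_pc, train$gini, anchors)
  x <- train$pou
  X <- cbind(`(Intercept)` = 1, w = w, xw = x * w)
  if (qr(X)$rank < 3L) {
    stop("nonfood design is rank deficient (is the development score ",
         "constant across the panel?)", call. = FALSE)
  }
  fit_level <- function(level) {
    y <- train[[paste0("stunting_", level)]]
    r <- attribute_food(beta[[level]], x)
    s <- y - r
    fit <- stats::lm.fit(X, s)
    est <- fit$coefficients
    dof <- length(s) - 3L
    sigma2 <- sum(fit$residuals^2) / dof
    se <- sqrt(diag(chol2inv(qr.R(qr(X)))) * sigma2)
    list(params = list(beta = beta[[level]],
                       alpha = c(est[[1]], se[[1]]),
                       gamma = c(est[[2]], se[[2]]),
                       theta = c(est[[3]], se[[3]])),
         diag = list(n = length(s), residual_sd = sqrt(sigma2),
                     kappa = kappa(X, exact = TRUE)))
  }
  fm <- fit_level("moderate")
  fs <- fit_level("severe")
  stunting_params(moderate = fm$params, severe = fs$params,
                  diagnostics = list(moderate = fm$diag, severe = fs$diag,
                                     anchors = anchors))
}

#' Predict stunting proportions
#'
#' Evaluates the bilinear model at given undernourishment x and
#' development score w, per level, and closes the composition with
#' \code{y_nomild = 1 - y_moderate - y_severe}. No clamping is applied at
#' this layer; out-of-range handling belongs to the Monte Carlo engine.
#'
#' @param params a [stunting_params()] object.
#' @param x proportion undernourished in [0, 1]. Vectorized.
#' @param w development score in [0, 1]. Vectorized.
#' @param beta \code{"central"} (default), \code{"low"} or \code{"high"}:
#'   which beta point to use.
#' @return a data.frame with columns \code{nomild}, \code{moderate},
#'   \code{severe}; rows sum to 1 exactly.
#' @export
predict_stunting <- function(params, x, w, beta = c("central", "low", "high")) {
  stopifnot(inherits(params, "stunting_params"),
            all(x >= 0 & x <= 1), all(w >= 0 & w <= 1))
  beta <- match.arg(beta)
  eval_level <- function(level) {
    lv <- params$levels[[level]]
    lv$alpha[["estimate"]] + lv$beta[[beta]] * x +
      lv$gamma[["estimate"]] * w + lv$theta[["estimate"]] * x * w
  }
  y2 <- eval_level("moderate")
  y3 <- eval_level("severe")
  data.frame(nomild = 1 - y2 - y3, moderate = y2, severe = y3)
}

#' Fit the full stunting model
#'
#' End-to-end fit: estimates beta for both levels on the full panel (the
#' percentile estimator is a rough approximation, so all records are
#' used), reserves a random holdout fraction for validation, calibrates
#' the development-score anchors, and fits the nonfood regression on the
#' training records.
#'
#' @param panel a panel data.frame (see [read_panel()]).
#' @param holdout_fraction fraction reserved for validation (default 0.2).
#' @param seed RNG seed for the split.
#' @param percentiles beta percentile policy, see [estimate_beta()].
#' @param anchors optional [dev_anchors()]; calibrated from the full panel
#'   when \code{NULL}.
#' @param gdp_saturation,gini_saturation saturation point used when
#'   calibrating anchors.
#' @return an object of class \code{stunting_fit} with components
#'   \code{params} ([stunting_params()]), \code{anchors}, \code{train},
#'   \code{holdout}, \code{beta}, and \code{call}. Methods:
#'   \code{print}, \code{summary}, \code{coef}, \code{predict},
#'   \code{residuals}, \code{plot}, \code{simulate}.
#' @examples
#' panel <- generate_panel(synth_config(seed = 7))$panel
#' fit <- stunting_fit(panel, seed = 7)
#' summary(fit)
#' predict(fit, x = 0.2, w = 0.5)
#' @export
stunting_fit <- function(panel, holdout_fraction = 0.2, seed = 1L,
                         percentiles = c(1, 5, 10), anchors = NULL,
                         gdp_saturation = 10000, gini_saturation = 0.38) {
  beta <- list(
    moderate = estimate_beta(ratio_distribution(panel, "moderate"),
                             percentiles, level = "moderate"),
    severe = estimate_beta(ratio_distribution(panel, "severe"),
                           percentiles, level = "severe")
  )
  if (is.null(anchors)) {
    anchors <- calibrate_anchors(panel, gdp_saturation, gini_saturation)
  }
  split <- split_panel(panel, holdout_fraction, seed)
  params <- fit_nonfood(split$train, beta, anchors)
  structure(list(params = params, anchors = anchors, beta = beta,
                 train = split$train, holdout = split$holdout,
                 seed = seed, call = match.call()),
            class = "stunting_fit")
}

#' @export
print.stunting_fit <- function(x, ...) {
  cat("Bilinear stunting model fit\n")
  cat("  records:", nrow(x$train), "training /", nrow(x$holdout),
      "holdout\n\n")
  print(x$params, ...)
  invisible(x)
}

#' @export
coef.stunting_fit <- function(object, ...) {
  tab <- as.data.frame(object$params)
  m <- as.matrix(tab[, c("alpha", "beta", "gamma", "theta")])
  rownames(m) <- tab$level
  m
}

#' @export
residuals.stunting_fit <- function(object, level = "moderate", ...) {
  level <- match_level(level)
  pred <- predict(object, newdata = object$train)
  object$train[[paste0("stunting_", level)]] - pred[[level]]
}

#' @rdname stunting_fit
#' @param object a \code{stunting_fit}.
#' @param newdata panel-like data.frame with \code{pou}, \code{gdp_pc} and
#'   \code{gini} columns (the development score is computed with the fit's
#'   anchors); alternatively supply \code{x} and \code{w} directly.
#' @param x,w direct model inputs, used when \code{newdata} is NULL.
#' @param ... unused.
#' @export
predict.stunting_fit <- function(object, newdata = NULL, x = NULL, w = NULL,
                                 ...) {
  if (!is.null(newdata)) {
    x <- newdata$pou
    w <- development_score(newdata$gdp_pc, newdata$gini, object$anchors)
  }
  if (is.null(x) || is.null(w)) {
    stop("supply either newdata or both x and w", call. = FALSE)
  }
  predict_stunting(object$params, x, w)
}

#' @export
summary.stunting_fit <- function(object, ...) {
  val <- validate_model(object)
  structure(list(params = object$params, anchors = object$anchors,
                 n_train = nrow(object$train),
                 n_holdout = nrow(object$holdout),
                 validation = val),
            class = "summary.stunting_fit")
}

#' @export
print.summary.stunting_fit <- function(x, digits = 3, ...) {
  cat("Bilinear stunting model\n")
  cat(sprintf("  %d training records, %d holdout records\n\n",
              x$n_train, x$n_holdout))
  print(x$params, digits = digits)
  dg <- x$params$diagnostics
  if (!is.null(dg)) {
    cat(sprintf("\n  residual SD: moderate %.4f, severe %.4f\n",
                dg$moderate$residual_sd, dg$severe$residual_sd))
    cat(sprintf("  design condition number: %.1f\n", dg$moderate$kappa))
  }
  cat("\nHoldout validation (Pearson r, observed vs predicted):\n")
  print(round(x$validation$correlations, digits), ...)
  invisible(x)
}

#' Validate the model on holdout records
#'
#' Predicts each holdout record from its undernourishment and development
#' score and reports the Pearson correlation of observed vs predicted
#' proportions, per level (no/mild, moderate, severe), plus the scatter
#' table behind the correlations.
#'
#' @param fit a [stunting_fit()] object.
#' @param holdout optional panel data.frame; defaults to the fit's own
#'   reserved holdout.
#' @return list with \code{correlations} (named numeric, NA with a flag
#'   when a level has zero variance) and \code{scatter} (data.frame of
#'   level, observed, predicted).
#' @export
validate_model <- function(fit, holdout = NULL) {
  holdout <- holdout %||% fit$holdout
  if (nrow(holdout) < 3L) stop("need at least 3 holdout records", call. = FALSE)
  pred <- predict(fit, newdata = holdout)
  obs <- data.frame(
    nomild = 1 - holdout$stunting_moderate - holdout$stunting_severe,
    moderate = holdout$stunting_moderate,
    severe = holdout$stunting_severe
  )
  cors <- vapply(names(obs), function(lv) {
    if (stats::sd(obs[[lv]]) == 0 || stats::sd(pred[[lv]]) == 0) {
      return(NA_real_)
    }
    stats::cor(obs[[lv]], pred[[lv]])
  }, numeric(1))
  if (anyNA(cors)) {
    warning("correlation undefined for level(s) with zero variance: ",
            paste(names(cors)[is.na(cors)], collapse = ", "), call. = FALSE)
  }
  scatter <- do.call(rbind, lapply(names(obs), function(lv) {
    data.frame(level = lv, observed = obs[[lv]], predicted = pred[[lv]])
  }))
  list(correlations = cors, scatter = scatter)
}

#' @export
plot.stunting_fit <- function(x, ...) {
  val <- validate_model(x)
  op <- graphics::par(mfrow = c(1, 3))
  on.exit(graphics::par(op))
  for (lv in unique(val$scatter$level)) {
    d <- val$scatter[val$scatter$level == lv, ]
    lim <- range(d$observed, d$predicted)
    graphics::plot(d$observed, d$predicted, xlim = lim, ylim = lim,
                   xlab = "observed proportion", ylab = "predicted",
                   main = sprintf("%s (r = %.2f)", lv,
                                  val$correlations[[lv]]), ...)
    graphics::abline(0, 1, lty = 2)
  }
  invisible(x)
}

#' @rdname simulate_country
#' @param object a [stunting_fit()] object.
#' @param nsim number of accepted draws per level.
#' @param seed master RNG seed.
#' @param ... unused.
#' @export
simulate.stunting_fit <- function(object, nsim = 1000, seed = 1L,
                                  x, w, ...) {
  simulate_country(object$params, x = x, w = w, n_target = nsim, seed = seed)
}
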