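# Internal helpers shared across modules.

# Round half away from zero (so 37.2 -> 37, 18.5 -> 19). base::round()
# rounds half to even, which does not reproduce conventional holdout sizes.
round_half_up <- function(x) floor(x + 0.5)

clamp01 <- function(x) pmin(pmax(x, 0), 1)

# Deterministic 31-bit seed derived from a master seed plus arbitrary string
# labels (country, scenario, level ...), so that per-country Monte Carlo
# streams are independent and reproducible from a single master seed.
derive_seed <- function(master, ...) {
  stopifnot(is.numeric(master), length(master) == 1L, is.finite(master))
  labels <- paste(vapply(list(...), as.character, character(1)), collapse = "\r")
  h <- as.double(master) %% 2147483629
  for (code in utf8ToInt(labels)) {
    h <- (h * 31 + code) %% 2147483629
  }
  as.integer(h) + 1L
}

stunting_levels <- c("moderate", "severe")

# Accept either a level name or the conventional numeric code (2 = moderate,
# 3 = severe) used throughout the model's equations.
match_level <- function(level) {
  if (is.numeric(level)) {
    if (!level %in% c(2, 3)) {
      stop("numeric stunting level must be 2 (moderate) or 3 (severe)", call. = FALSE)
    }
    return(stunting_levels[level - 1])
  }
  match.arg(level, stunting_levels)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
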