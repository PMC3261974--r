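# Shared fixtures, built in code.

# A tiny hand-constructed panel with easy arithmetic.
toy_panel <- function() {
  data.frame(
    country_id = c("AAA", "BBB", "CCC"),
    region_id = c("R1", "R1", "R2"),
    year = c(2000L, 2001L, 2002L),
    stunting_moderate = c(0.20, 0.10, 0.30),
    stunting_severe = c(0.10, 0.05, 0.15),
    pou = c(0.40, 0.50, 0.25),
    gdp_pc = c(1000, 2500, 400),
    gini = c(0.40, 0.30, 0.55),
    pop_u5 = c(1e6, 2e6, 5e5),
    stringsAsFactors = FALSE
  )
}

write_toy_csv <- function(panel = toy_panel(), path = tempfile(fileext = ".csv")) {
  out <- panel
  names(out)[names(out) == "country_id"] <- "country"
  names(out)[names(out) == "region_id"] <- "region"
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  path
}

# Degenerate parameter set: zero SEs and collapsed beta ranges, so every
# Monte Carlo draw equals the central surface.
degenerate_params <- function(base = default_params()) {
  lv <- lapply(base$levels, function(l) {
    list(beta = list(low = l$beta$central, central = l$beta$central,
                     high = l$beta$central),
         alpha = c(l$alpha[["estimate"]], 0),
         gamma = c(l$gamma[["estimate"]], 0),
         theta = c(l$theta[["estimate"]], 0))
  })
  stunting_params(moderate = lv$moderate, severe = lv$severe)
}

# Ground-truth anchors matching the generator's range-corner convention.
truth_anchors_for_tests <- function(cfg) {
  dev_anchors(10000, 0.38, cfg$gdp_range[1] * (1 - cfg$gini_range[2]))
}

# Independent brute-force OLS via explicit normal equations.
normal_equations_fit <- function(X, y) {
  solve(t(X) %*% X, t(X) %*% y)[, 1]
}
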