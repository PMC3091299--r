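# small simulated studies shared across test files; built once per test run
small_config <- function(...) {
  args <- list(...)
  defaults <- list(n_individuals = 60, n_probes = 60, probes_per_gene = 3,
                   snps_per_cis_window = 10, fraction_probes_with_meqtl = 0.3,
                   effect_fixed = 1, seed = 42)
  defaults[names(args)] <- args
  do.call(sim_config, defaults)
}

# closed-form OLS oracle used to check fit_additive (sum-of-products form)
ols_oracle <- function(g, y) {
  n <- length(g)
  gc <- g - mean(g); yc <- y - mean(y)
  slope <- sum(gc * yc) / sum(gc^2)
  resid <- yc - slope * gc
  se <- sqrt(sum(resid^2) / (n - 2) / sum(gc^2))
  stat <- slope / se
  list(slope = slope, se = se, stat = stat,
       p = 2 * pt(-abs(stat), n - 2),
       r2 = cor(g, y)^2)
}
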