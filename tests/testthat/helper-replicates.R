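# Monte-Carlo replicate drivers shared by the validation suite.

SPEC_FULL_GXE <- gxe_spec(free = c("alpha_g", "gamma_g", "lambda_g",
                                   "alpha_e", "gamma_e"))
SPEC_MODEL1 <- gxe_spec(free = c("alpha_g", "alpha_e"))

# One heritability-recovery replicate under the homogeneous polygenic preset.
replicate_polygenic <- function(seed) {
  sc <- scenario_presets(seed = seed)[["polygenic"]]
  d <- simulate_dataset(sc)
  dat <- gxe_data(d$ped, d$pheno, trait = "trait")
  fit <- fit_ml(dat, SPEC_MODEL1, starts = 2, seed = seed)
  c(h2 = fit$h2, se = fit$h2_se)
}

# One GxE-recovery replicate under the variance-heterogeneity preset:
# full-model estimates plus the slope-test p-value.
replicate_variance_het <- function(seed) {
  sc <- scenario_presets(seed = seed)[["variance-het"]]
  d <- simulate_dataset(sc)
  dat <- gxe_data(d$ped, d$pheno, trait = "trait")
  ff <- fit_ml(dat, SPEC_FULL_GXE, starts = 2, seed = seed)
  f0 <- constrained_fit(dat, SPEC_FULL_GXE, c(gamma_g = 0), starts = 1,
                        seed = seed,
                        extra_starts = list(ff$estimates[SPEC_FULL_GXE$free]))
  p_gamma <- lrt_p(max(0, 2 * (ff$loglik - f0$loglik)), chi2_null(1))
  c(ff$estimates[SPEC_FULL_GXE$free], p_gamma = p_gamma)
}

# One global-null replicate: slope-test statistic and decay-test statistic
# (0 exactly when the decay estimate sits on its boundary).
replicate_null <- function(seed, n_families) {
  sc <- scenario_presets(seed = seed)[["polygenic"]]
  sc$n_families <- n_families
  d <- simulate_dataset(sc)
  dat <- gxe_data(d$ped, d$pheno, trait = "trait")
  ff <- fit_ml(dat, SPEC_FULL_GXE, starts = 2, seed = seed)
  f0 <- constrained_fit(dat, SPEC_FULL_GXE, c(gamma_g = 0), starts = 1,
                        seed = seed,
                        extra_starts = list(ff$estimates[SPEC_FULL_GXE$free]))
  gamma_stat <- max(0, 2 * (ff$loglik - f0$loglik))
  if (ff$estimates[["lambda_g"]] <= 1e-6) {
    lambda_stat <- 0
  } else {
    fl <- constrained_fit(dat, SPEC_FULL_GXE, c(lambda_g = 0), starts = 1,
                          seed = seed,
                          extra_starts = list(ff$estimates[SPEC_FULL_GXE$free]))
    lambda_stat <- max(0, 2 * (ff$loglik - fl$loglik))
  }
  c(gamma_stat = gamma_stat, lambda_stat = lambda_stat)
}

# Twelve-trait synthetic panel mixing the presets.
panel_traits_12 <- function(seed) {
  presets <- scenario_presets(seed = seed)
  pick <- rep(c("polygenic", "variance-het", "null", "corr-decay"), 3)
  traits <- lapply(pick, function(nm) {
    list(params = presets[[nm]]$params, spec = presets[[nm]]$spec)
  })
  names(traits) <- sprintf("t%02d_%s", seq_along(pick), gsub("-", "", pick))
  traits
}
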