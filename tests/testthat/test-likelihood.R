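# Tiny helper: wrap a pedigree + vectors into gxe_data via a data frame.
make_data <- function(ped, y, z, include_zses_mean = TRUE) {
  pheno <- data.frame(id = ped$id, trait = y, zses = z,
                      stringsAsFactors = FALSE)
  gxe_data(ped, pheno, trait = "trait", include_zses_mean = include_zses_mean)
}

test_that("single-observation likelihood equals the normal density", {
  ped <- pedigree("solo", sex = "F")
  dat <- make_data(ped, y = 0, z = 0, include_zses_mean = FALSE)
  spec <- gxe_spec(genetic = FALSE, free = "alpha_e")
  # sig2_p = 1, beta = 0, y = 0: -log(2*pi)/2
  params <- gxe_params(alpha_e = 0, beta = c("(Intercept)" = 0))
  ll <- gxe_loglik(params, spec, dat)
  expect_equal(ll, -0.5 * log(2 * pi))
  expect_equal(round(ll, 5), -0.91894)
  # doubling sig2_e changes the loglik by -log(2)/2
  params2 <- gxe_params(alpha_e = log(2), beta = c("(Intercept)" = 0))
  expect_equal(gxe_loglik(params2, spec, dat) - ll, -0.5 * log(2))
})

test_that("blocked likelihood equals a dense MVN oracle", {
  set.seed(20)
  for (rep in 1:10) {
    ped <- random_pedigree(max_n = 12)
    n <- nrow(ped)
    z <- rnorm(n)
    y <- rnorm(n)
    dat <- make_data(ped, y, z)
    spec <- gxe_spec(household = TRUE,
                     free = c("alpha_g", "gamma_g", "lambda_g",
                              "alpha_e", "gamma_e",
                              "alpha_c", "gamma_c", "lambda_c"))
    params <- random_params(household = TRUE)
    beta <- c(0.2, -0.1)
    params$beta <- beta
    # dense evaluation over all individuals at once (block structure is a
    # zero pattern of the dense matrix)
    kin <- compute_kinship(ped)
    hh <- household_matrix(ped)
    ids <- unlist(lapply(dat$blocks, `[[`, "ids"))
    ii <- match(ids, ped$id)
    omega <- elementwise_covariance(params, spec, kin[ii, ii], hh[ii, ii],
                                    z[ii])
    X <- do.call(rbind, lapply(dat$blocks, `[[`, "X"))
    oracle <- dense_mvn_loglik(y[ii], drop(X %*% beta), omega)
    expect_equal(gxe_loglik(params, spec, dat), oracle, tolerance = 1e-8)
  }
})

test_that("profiled mean coefficients maximize the likelihood over beta", {
  set.seed(21)
  ped <- random_pedigree(max_n = 10)
  dat <- make_data(ped, rnorm(nrow(ped)), rnorm(nrow(ped)))
  spec <- gxe_spec(free = c("alpha_g", "alpha_e"))
  params <- gxe_params(alpha_g = log(0.4), alpha_e = log(0.6))
  core <- gxevc:::loglik_core(params, spec, dat)
  for (k in 1:5) {
    jitter <- core$beta + rnorm(length(core$beta), 0, 0.1)
    pj <- params
    pj$beta <- jitter
    expect_lte(gxe_loglik(pj, spec, dat), core$loglik + 1e-10)
  }
})

test_that("ML fit recovers polygenic truth and flags degenerate input", {
  sc <- sim_scenario(n_families = 30, seed = 31,
                     params = gxe_params(alpha_g = log(0.45),
                                         alpha_e = log(0.55)))
  d <- simulate_dataset(sc)
  dat <- gxe_data(d$ped, d$pheno, trait = "trait")
  fit <- fit_ml(dat, gxe_spec(free = c("alpha_g", "alpha_e")),
                starts = 3, seed = 1)
  expect_s3_class(fit, "gxe_fit")
  expect_true(fit$convergence %in% c("converged", "boundary"))
  expect_lt(abs(fit$h2 - 0.45), 0.15)
  expect_true(is.finite(fit$loglik))
  expect_true(all(is.finite(fit$se[!fit$boundary])))

  tiny <- pedigree(id = c("a", "b", "k"), father = c(NA, NA, "a"),
                   mother = c(NA, NA, "b"), sex = c("M", "F", "F"))
  tiny_dat <- make_data(tiny, y = c(0.1, -0.2, 0.3), z = c(0, 0.5, 1))
  expect_error(
    suppressWarnings(fit_ml(tiny_dat, gxe_spec(free = c("alpha_g",
                                                        "alpha_e")))),
    "not enough individuals")
})

test_that("nested fits respect the likelihood ordering", {
  sc <- scenario_presets(seed = 32)[["polygenic"]]
  sc$n_families <- 25L
  d <- simulate_dataset(sc)
  dat <- gxe_data(d$ped, d$pheno, trait = "trait")
  spec_full <- gxe_spec(free = c("alpha_g", "gamma_g", "lambda_g",
                                 "alpha_e", "gamma_e"))
  fit1 <- fit_ml(dat, gxe_spec(free = c("alpha_g", "alpha_e")),
                 starts = 3, seed = 1)
  warm <- spec_full$fixed
  warm[names(fit1$estimates)] <- fit1$estimates
  fit_full <- fit_ml(dat, spec_full, starts = 3, seed = 1,
                     extra_starts = list(warm))
  # nesting: the larger model can only do better
  expect_gte(fit_full$loglik, fit1$loglik - 1e-8)
  # constraining all GxE functions to zero reproduces the polygenic fit
  fit_red <- constrained_fit(dat, spec_full,
                             c(gamma_g = 0, lambda_g = 0, gamma_e = 0),
                             starts = 3, seed = 1,
                             extra_starts = list(fit1$estimates[
                               c("alpha_g", "alpha_e")]))
  expect_equal(fit_red$loglik, fit1$loglik, tolerance = 1e-6)
  # constraining every free parameter: direct evaluation, no optimization
  all_fixed <- constrained_fit(dat, gxe_spec(free = c("alpha_g", "alpha_e")),
                               c(alpha_g = log(0.45), alpha_e = log(0.55)))
  params <- gxe_params(alpha_g = log(0.45), alpha_e = log(0.55))
  expect_equal(all_fixed$loglik,
               gxe_loglik(params, gxe_spec(free = c("alpha_g", "alpha_e")),
                          dat))
  expect_error(constrained_fit(dat, spec_full, c(alpha_q = 0)), "not free")
})

test_that("trait location/scale transforms act on intercept and alphas", {
  sc <- sim_scenario(n_families = 20, seed = 33)
  d <- simulate_dataset(sc)
  dat0 <- gxe_data(d$ped, d$pheno, trait = "trait")
  spec <- gxe_spec(free = c("alpha_g", "alpha_e"))
  fit0 <- fit_ml(dat0, spec, starts = 2, seed = 1)

  d$pheno$shifted <- d$pheno$trait + 5
  fit_shift <- fit_ml(gxe_data(d$ped, d$pheno, trait = "shifted"),
                      spec, starts = 2, seed = 1)
  expect_equal(fit_shift$beta[["(Intercept)"]],
               fit0$beta[["(Intercept)"]] + 5, tolerance = 1e-4)
  expect_equal(fit_shift$estimates[spec$free], fit0$estimates[spec$free],
               tolerance = 1e-4)

  d$pheno$scaled <- d$pheno$trait * 3
  fit_scale <- fit_ml(gxe_data(d$ped, d$pheno, trait = "scaled"),
                      spec, starts = 2, seed = 1)
  expect_equal(unname(fit_scale$estimates[c("alpha_g", "alpha_e")]),
               unname(fit0$estimates[c("alpha_g", "alpha_e")]) + 2 * log(3),
               tolerance = 1e-3)
})

test_that("estimator bias shrinks with the number of families", {
  truth <- c(alpha_g = log(0.45), gamma_g = -0.5)
  spec <- gxe_spec(free = c("alpha_g", "gamma_g", "lambda_g",
                            "alpha_e", "gamma_e"))
  bias_at <- function(n_fam, seeds) {
    est <- sapply(seeds, function(s) {
      sc <- scenario_presets(seed = s)[["variance-het"]]
      sc$n_families <- n_fam
      d <- simulate_dataset(sc)
      dat <- gxe_data(d$ped, d$pheno, trait = "trait")
      fit_ml(dat, spec, starts = 2, seed = s)$estimates[names(truth)]
    })
    rowMeans(est) - truth
  }
  b_small <- bias_at(8L, 101:108)
  b_large <- bias_at(40L, 101:108)
  expect_lt(sum(abs(b_large)), sum(abs(b_small)) + 0.1)
})
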