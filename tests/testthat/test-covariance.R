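test_that("variance and decay correlation functions match closed forms", {
  expect_equal(variance_fn(0, 0, 3), 1)
  expect_equal(variance_fn(log(2), 0, 5), 2)
  expect_equal(variance_fn(0, -0.5, 1), exp(-0.5))
  expect_gt(variance_fn(-10, -3, -3), 0)

  expect_equal(decay_corr_fn(0, -2, 3), 1)
  expect_equal(decay_corr_fn(log(2), 0, 1), 0.5)
  expect_equal(decay_corr_fn(5, 1.3, 1.3), 1)
  expect_equal(decay_corr_fn(0.7, 1, 2), decay_corr_fn(0.7, 2, 1))
  expect_error(decay_corr_fn(-0.1, 0, 1), "lambda")
})

test_that("parameter and spec constructors enforce their invariants", {
  expect_error(gxe_params(lambda_g = -1), "lambda")
  expect_error(gxe_params(alpha_g = Inf), "finite")
  expect_error(gxe_spec(free = "alpha_q"), "unknown")
  expect_error(gxe_spec(genetic = FALSE, free = c("alpha_g", "alpha_e")),
               "genetic")
  expect_error(gxe_spec(household = FALSE,
                        free = c("alpha_e", "lambda_c")), "household")
  expect_error(gxe_spec(free = "alpha_g"), "alpha_e")
})

test_that("assembled covariance matches the element-wise definition", {
  set.seed(10)
  for (rep in 1:10) {
    ped <- random_pedigree(max_n = 8)
    kin <- compute_kinship(ped)
    hh <- household_matrix(ped)
    z <- rnorm(nrow(ped))
    spec <- gxe_spec(household = TRUE,
                     free = c("alpha_g", "gamma_g", "lambda_g",
                              "alpha_e", "gamma_e",
                              "alpha_c", "gamma_c", "lambda_c"))
    params <- random_params(household = TRUE)
    omega <- build_covariance(params, spec, kin, hh, z)
    expect_equal(omega, elementwise_covariance(params, spec, kin, hh, z),
                 tolerance = 1e-12, ignore_attr = TRUE)
    expect_equal(omega, t(omega))
    expect_silent(chol(omega))  # PD whenever sig2e > 0
  }
})

test_that("hand-computed two-individual covariances are reproduced", {
  # parent-offspring entries of a trio, unit variances, no heterogeneity
  ped <- pedigree(id = c("p", "q", "o"), father = c(NA, NA, "p"),
                  mother = c(NA, NA, "q"), sex = c("M", "F", "F"))
  kin <- compute_kinship(ped)[c("p", "o"), c("p", "o")]
  spec <- gxe_spec(free = c("alpha_g", "alpha_e"))
  omega <- build_covariance(gxe_params(), spec, kin, z = c(0, 0))
  expect_equal(omega, matrix(c(2, 0.5, 0.5, 2), 2), ignore_attr = TRUE)

  # heterogeneous genetic variance and correlation decay, z = (0, 1):
  # off-diagonal 0.5 * sqrt(1 * e^-0.5) * e^-ln2 ~ 0.19470
  spec2 <- gxe_spec(free = c("alpha_g", "gamma_g", "lambda_g",
                             "alpha_e", "gamma_e"))
  p2 <- gxe_params(alpha_g = 0, gamma_g = -0.5, lambda_g = log(2))
  omega2 <- build_covariance(p2, spec2, kin, z = c(0, 1))
  expect_equal(omega2[1, 2], 0.5 * sqrt(exp(-0.5)) * 0.5)
  expect_equal(round(omega2[1, 2], 5), 0.19470)
  expect_equal(diag(omega2), c(2, exp(-0.5) + 1), ignore_attr = TRUE)
})

test_that("homogeneous reduction is bit-identical to the polygenic form", {
  set.seed(11)
  ped <- random_pedigree(max_n = 10)
  kin <- compute_kinship(ped)
  hh <- household_matrix(ped)
  z <- rnorm(nrow(ped))
  spec <- gxe_spec(household = TRUE,
                   free = c("alpha_g", "alpha_c", "alpha_e"))
  params <- gxe_params(alpha_g = log(0.4), alpha_c = log(0.1),
                       alpha_e = log(0.5))
  # identical component variances on both sides (exp(log(v)) need not be
  # bit-identical to v, so feed the same floats through both paths)
  vg <- exp(log(0.4))
  vc <- exp(log(0.1))
  ve <- exp(log(0.5))
  expect_identical(build_covariance(params, spec, kin, hh, z),
                   polygenic_covariance(vg, ve, vc, kin, hh))
  spec1 <- gxe_spec(free = c("alpha_g", "alpha_e"))
  expect_identical(build_covariance(params, spec1, kin, hh, z),
                   polygenic_covariance(vg, ve, 0, kin))
})

test_that("decay correlation matrices are positive semidefinite", {
  set.seed(12)
  for (rep in 1:10) {
    z <- rnorm(sample(3:12, 1))
    lambda <- rexp(1)
    R <- exp(-lambda * abs(outer(z, z, "-")))
    ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
    expect_gt(min(ev), -1e-8)
  }
})

test_that("heritability ratios normalize over active components", {
  spec <- gxe_spec(free = c("alpha_g", "alpha_e"))
  expect_equal(heritability_at(gxe_params(), spec, 0)$h2, 0.5)
  spec0 <- gxe_spec(genetic = FALSE, free = "alpha_e")
  expect_equal(heritability_at(gxe_params(), spec0, 0)$h2, 0)
  # homogeneous three-component split 0.45/0.11/0.44
  spec2 <- gxe_spec(household = TRUE,
                    free = c("alpha_g", "alpha_c", "alpha_e"))
  p <- gxe_params(alpha_g = log(0.45), alpha_c = log(0.11),
                  alpha_e = log(0.44))
  h <- heritability_at(p, spec2, 0)
  expect_equal(h$h2, 0.45)
  expect_equal(h$c2, 0.11)
  # h2 + c2 <= 1 along the environment axis
  hgrid <- heritability_at(p, spec2, seq(-3, 3, 0.5))
  expect_true(all(hgrid$h2 + hgrid$c2 <= 1))
  expect_true(all(hgrid$h2 >= 0 & hgrid$h2 <= 1))
})

test_that("function grids expose monotone curves and a coherent surface", {
  spec <- gxe_spec(free = c("alpha_g", "gamma_g", "lambda_g",
                            "alpha_e", "gamma_e"))
  params <- gxe_params(alpha_g = log(0.45), gamma_g = -0.5,
                       lambda_g = 0.3, alpha_e = log(0.55), gamma_e = 0.4)
  grid <- seq(-3, 3, 0.25)
  fg <- function_grid(params, spec, grid)
  curves <- fg$curves
  vg <- curves$value[curves$component == "sig2_g"]
  ve <- curves$value[curves$component == "sig2_e"]
  vp <- curves$value[curves$component == "sig2_p"]
  expect_true(all(diff(vg) < 0))  # gamma_g < 0: strictly decreasing
  expect_true(all(diff(ve) > 0))  # gamma_e > 0: strictly increasing
  expect_equal(vp, vg + ve)
  # opposite slopes can make total variance non-monotone (dip and rise)
  expect_true(any(diff(vp) < 0) && any(diff(vp) > 0))
  # surface: symmetric, diagonal equals the genetic variance curve
  surf <- fg$surface
  diag_rows <- surf[surf$z_i == surf$z_j, ]
  expect_equal(diag_rows$cov[order(diag_rows$z_i)], vg)
  swapped <- surf[order(surf$z_j, surf$z_i), ]
  expect_equal(surf$cov[order(surf$z_i, surf$z_j)], swapped$cov)
})
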