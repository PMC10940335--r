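# GxE variance and correlation functions and phenotypic covariance assembly.
#
# Additive genetic and residual environmental variances (and, when a
# household component is modelled, the household variance) are exponential
# functions of the standardized environment z:
#   sigma_g^2(z) = exp(alpha_g + gamma_g * z)
#   sigma_e^2(z) = exp(alpha_e + gamma_e * z)
#   sigma_c^2(z) = exp(alpha_c + gamma_c * z)
# and the genetic / household correlations between two individuals decay
# exponentially in their environmental distance:
#   rho_g(zi, zj) = exp(-lambda_g * |zi - zj|)
#   rho_c(zi, zj) = exp(-lambda_c * |zi - zj|)
# No GxE means gamma_g = 0 (homogeneous genetic variance) and lambda_g = 0
# (genetic correlation 1 across environments).

GXE_PAR_NAMES <- c("alpha_g", "gamma_g", "lambda_g",
                   "alpha_e", "gamma_e",
                   "alpha_c", "gamma_c", "lambda_c")

#' GxE variance-function parameters
#'
#' Bundles the variance-function parameters (log-variance intercepts
#' `alpha_*`, log-variance slopes per environment unit `gamma_*`,
#' correlation decay rates `lambda_* >= 0`) and optional mean-model
#' coefficients `beta`.
#'
#' @param alpha_g,gamma_g,lambda_g genetic variance/correlation parameters.
#' @param alpha_e,gamma_e residual environmental variance parameters.
#' @param alpha_c,gamma_c,lambda_c household variance/correlation
#'   parameters (ignored unless the model spec declares a household
#'   component).
#' @param beta optional named numeric of mean-model coefficients.
#' @return An object of class `gxe_params`.
#' @export
gxe_params <- function(alpha_g = 0, gamma_g = 0, lambda_g = 0,
                       alpha_e = 0, gamma_e = 0,
                       alpha_c = 0, gamma_c = 0, lambda_c = 0,
                       beta = NULL) {
  p <- c(alpha_g = alpha_g, gamma_g = gamma_g, lambda_g = lambda_g,
         alpha_e = alpha_e, gamma_e = gamma_e,
         alpha_c = alpha_c, gamma_c = gamma_c, lambda_c = lambda_c)
  if (any(!is.finite(p))) stop("non-finite parameter", call. = FALSE)
  if (lambda_g < 0 || lambda_c < 0) {
    stop("decay rates lambda must be >= 0", call. = FALSE)
  }
  structure(list(par = p, beta = beta), class = "gxe_params")
}

#' @export
print.gxe_params <- function(x, ...) {
  cat("GxE variance-function parameters:\n")
  print(round(x$par, 5))
  if (!is.null(x$beta)) {
    cat("mean model:\n")
    print(round(x$beta, 5))
  }
  invisible(x)
}

#' Model specification: components and free parameters
#'
#' Declares which variance components are present (residual always;
#' genetic and household optional) and which variance-function parameters
#' are free in a fit.  Parameters not free are held fixed (slopes and decay
#' rates at 0 unless overridden), which is how every null model in the
#' testing hierarchy is expressed.
#'
#' @param genetic include the additive genetic component?
#' @param household include the household component?
#' @param free character vector of free parameter names (subset of
#'   `alpha_g, gamma_g, lambda_g, alpha_e, gamma_e, alpha_c, gamma_c,
#'   lambda_c`).
#' @param fixed named numeric of fixed values for non-free parameters
#'   (defaults 0).
#' @return An object of class `gxe_spec`.
#' @examples
#' model1 <- gxe_spec(free = c("alpha_g", "alpha_e"))        # polygenic
#' full <- gxe_spec(free = c("alpha_g", "gamma_g", "lambda_g",
#'                           "alpha_e", "gamma_e"))          # GxE, no household
#' @export
gxe_spec <- function(genetic = TRUE, household = FALSE,
                     free = c("alpha_g", "alpha_e"),
                     fixed = NULL) {
  bad <- setdiff(free, GXE_PAR_NAMES)
  if (length(bad)) {
    stop("unknown parameter(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  genetic_pars <- c("alpha_g", "gamma_g", "lambda_g")
  household_pars <- c("alpha_c", "gamma_c", "lambda_c")
  if (!genetic && length(intersect(free, genetic_pars))) {
    stop("genetic parameters cannot be free when the component is absent",
         call. = FALSE)
  }
  if (!household && length(intersect(free, household_pars))) {
    stop("household parameters cannot be free when the component is absent",
         call. = FALSE)
  }
  if (!"alpha_e" %in% free) {
    # residual variance is always present and nearly always estimated;
    # fixing it is allowed through `fixed`
    if (is.null(fixed) || !"alpha_e" %in% names(fixed)) {
      stop("alpha_e must be free or given a fixed value", call. = FALSE)
    }
  }
  fx <- stats::setNames(rep(0, length(GXE_PAR_NAMES)), GXE_PAR_NAMES)
  if (!is.null(fixed)) {
    bad <- setdiff(names(fixed), GXE_PAR_NAMES)
    if (length(bad)) {
      stop("unknown fixed parameter(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    fx[names(fixed)] <- fixed
  }
  structure(list(genetic = genetic, household = household,
                 free = free, fixed = fx),
            class = "gxe_spec")
}

#' Exponential variance function of the environment
#'
#' @param alpha log-variance at z = 0.
#' @param gamma log-variance slope per environment unit.
#' @param z environment value(s).
#' @return `exp(alpha + gamma * z)`, strictly positive.
#' @export
variance_fn <- function(alpha, gamma, z) exp(alpha + gamma * z)

#' Exponential-decay correlation function of environmental distance
#'
#' @param lambda decay rate, `>= 0`.
#' @param zi,zj environment values.
#' @return `exp(-lambda * |zi - zj|)`, in (0, 1]; 1 iff `lambda = 0` or
#'   `zi = zj`.
#' @export
decay_corr_fn <- function(lambda, zi, zj) {
  if (any(lambda < 0)) stop("lambda must be >= 0", call. = FALSE)
  exp(-lambda * abs(zi - zj))
}

#' Polygenic (environment-homogeneous) covariance matrix
#'
#' The model 1 / model 2 covariance:
#' `sig2g * K + sig2c * H + sig2e * I`, with `K` the additive relationship
#' matrix and `H` the household indicator matrix.
#'
#' @param sig2g,sig2c,sig2e component variances (`sig2c = 0` drops the
#'   household term).
#' @param kin additive relationship matrix block.
#' @param hh household indicator block (may be `NULL` when `sig2c = 0`).
#' @return Covariance matrix.
#' @export
polygenic_covariance <- function(sig2g, sig2e, sig2c = 0, kin, hh = NULL) {
  omega <- sig2g * kin
  if (sig2c != 0) omega <- omega + sig2c * hh
  diag(omega) <- diag(omega) + sig2e
  omega
}

#' Assemble the phenotypic covariance matrix under the GxE model
#'
#' `Omega[i, j] = K[i, j] * sqrt(sig2g(zi) sig2g(zj)) * rho_g(zi, zj)
#'             + H[i, j] * sqrt(sig2c(zi) sig2c(zj)) * rho_c(zi, zj)
#'             + [i == j] * sig2e(zi)`.
#' Each individual's own environment enters the cross terms through the
#' geometric mean of the two variance-function values.  When all slopes
#' and decay rates are zero this reduces exactly (bit for bit) to
#' [polygenic_covariance()].
#'
#' @param params a [gxe_params] object.
#' @param spec a [gxe_spec] object.
#' @param kin additive relationship block.
#' @param hh household indicator block (required if `spec$household`).
#' @param z environment values for the block's individuals.
#' @param dz optional precomputed `abs(outer(z, z, "-"))`.
#' @return Symmetric covariance matrix, positive definite whenever
#'   `sig2e > 0`.
#' @export
build_covariance <- function(params, spec, kin, hh = NULL, z, dz = NULL) {
  p <- params$par
  if (any(!is.finite(p))) stop("non-finite parameter", call. = FALSE)
  n <- length(z)
  het_g <- spec$genetic && (p["gamma_g"] != 0 || p["lambda_g"] != 0)
  het_c <- spec$household && (p["gamma_c"] != 0 || p["lambda_c"] != 0)
  if ((het_g || het_c) && is.null(dz)) dz <- abs(outer(z, z, "-"))

  if (!spec$genetic) {
    omega <- matrix(0, n, n)
  } else if (!het_g) {
    omega <- exp(p[["alpha_g"]]) * kin
  } else {
    sdg <- exp(0.5 * (p[["alpha_g"]] + p[["gamma_g"]] * z))
    omega <- kin * tcrossprod(sdg) * exp(-p[["lambda_g"]] * dz)
  }
  if (spec$household) {
    if (is.null(hh)) stop("household matrix required", call. = FALSE)
    if (!het_c) {
      omega <- omega + exp(p[["alpha_c"]]) * hh
    } else {
      sdc <- exp(0.5 * (p[["alpha_c"]] + p[["gamma_c"]] * z))
      omega <- omega + hh * tcrossprod(sdc) * exp(-p[["lambda_c"]] * dz)
    }
  }
  sig2e <- if (p["gamma_e"] == 0) rep(exp(p[["alpha_e"]]), n) else
    exp(p[["alpha_e"]] + p[["gamma_e"]] * z)
  diag(omega) <- diag(omega) + sig2e
  omega
}

#' Heritability and household share of variance at an environment value
#'
#' `h2(z) = sig2g(z) / sig2p(z)` and `c2(z) = sig2c(z) / sig2p(z)` with
#' `sig2p(z)` the sum of the active component variances at z.
#'
#' @param params a [gxe_params].
#' @param spec a [gxe_spec].
#' @param z environment value(s).
#' @return Data frame with columns `z`, `h2`, `c2` (`c2 = 0` when no
#'   household component).
#' @export
heritability_at <- function(params, spec, z = 0) {
  p <- params$par
  sig2g <- if (spec$genetic) variance_fn(p[["alpha_g"]], p[["gamma_g"]], z)
           else rep(0, length(z))
  sig2c <- if (spec$household) variance_fn(p[["alpha_c"]], p[["gamma_c"]], z)
           else rep(0, length(z))
  sig2e <- variance_fn(p[["alpha_e"]], p[["gamma_e"]], z)
  sig2p <- sig2g + sig2c + sig2e
  data.frame(z = z, h2 = sig2g / sig2p, c2 = sig2c / sig2p)
}

#' Evaluate variance and correlation functions on an environment grid
#'
#' Produces figure-ready long tables: the component variance curves
#' (`sig2_g`, `sig2_e`, `sig2_c`, and their sum `sig2_p`) over the grid,
#' and the additive genetic covariance surface
#' `sqrt(sig2_g(zi) sig2_g(zj)) * rho_g(zi, zj)` over grid pairs, whose
#' diagonal equals the genetic variance curve.
#'
#' @param params a [gxe_params].
#' @param spec a [gxe_spec].
#' @param z_grid numeric grid of environment values.
#' @return List with `curves` (columns `component`, `z`, `value`) and
#'   `surface` (columns `z_i`, `z_j`, `cov`).
#' @export
function_grid <- function(params, spec, z_grid = seq(-3, 3, by = 0.1)) {
  if (any(!is.finite(z_grid))) stop("grid must be finite", call. = FALSE)
  p <- params$par
  comps <- list()
  sig2p <- rep(0, length(z_grid))
  if (spec$genetic) {
    v <- variance_fn(p[["alpha_g"]], p[["gamma_g"]], z_grid)
    comps$sig2_g <- v
    sig2p <- sig2p + v
  }
  if (spec$household) {
    v <- variance_fn(p[["alpha_c"]], p[["gamma_c"]], z_grid)
    comps$sig2_c <- v
    sig2p <- sig2p + v
  }
  v <- variance_fn(p[["alpha_e"]], p[["gamma_e"]], z_grid)
  comps$sig2_e <- v
  sig2p <- sig2p + v
  comps$sig2_p <- sig2p
  curves <- do.call(rbind, lapply(names(comps), function(nm) {
    data.frame(component = nm, z = z_grid, value = comps[[nm]])
  }))
  surface <- NULL
  if (spec$genetic) {
    sdg <- sqrt(variance_fn(p[["alpha_g"]], p[["gamma_g"]], z_grid))
    cov <- tcrossprod(sdg) *
      exp(-p[["lambda_g"]] * abs(outer(z_grid, z_grid, "-")))
    surface <- data.frame(z_i = rep(z_grid, times = length(z_grid)),
                          z_j = rep(z_grid, each = length(z_grid)),
                          cov = as.vector(cov))
  }
  list(curves = curves, surface = surface)
}
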