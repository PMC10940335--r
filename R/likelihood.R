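# Family-blocked multivariate-normal likelihood and ML estimation.
#
# The log-likelihood is a sum over family blocks b of
#   log MVN(y_b; X_b beta, Omega_b(theta)),
# with Omega_b assembled by build_covariance().  The mean coefficients beta
# enter linearly, so for fitting they are profiled out by generalized least
# squares at each variance-parameter value; the profile curvature gives the
# correct asymptotic covariance for the variance parameters.

# Internal bounds for the optimizer.  alpha is a log variance: the lower
# bound corresponds to a component variance of exp(-30) ~ 1e-13, an
# effective zero that lets boundary ("component absent") solutions be
# reached smoothly.  lambda has a hard boundary at 0 because lambda = 0
# (correlation 1 across environments) is itself a null hypothesis.
PAR_LOWER <- c(alpha_g = -30, gamma_g = -15, lambda_g = 0,
               alpha_e = -30, gamma_e = -15,
               alpha_c = -30, gamma_c = -15, lambda_c = 0)
PAR_UPPER <- c(alpha_g = 30, gamma_g = 15, lambda_g = 50,
               alpha_e = 30, gamma_e = 15,
               alpha_c = 30, gamma_c = 15, lambda_c = 50)
BOUNDARY_TOL <- 1e-6

#' Assemble per-block fitting data from a pedigree and phenotype table
#'
#' Joins a phenotype table to the pedigree, computes the additive
#' relationship and household matrices from the full pedigree (individuals
#' without a trait value still connect their relatives), then restricts to
#' complete cases of trait, environment and covariates within each family
#' block.
#'
#' @param ped a [pedigree].
#' @param pheno data frame with an id column, the trait, the environment
#'   index, and any covariates.
#' @param trait name of the trait column.
#' @param zses name of the environment-index column.
#' @param covariates character vector of covariate column names for the
#'   mean model.
#' @param id name of the id column in `pheno`.
#' @param include_zses_mean include the environment index as a mean-model
#'   covariate (default `TRUE`), so variance-function estimates are not
#'   confounded by a mean trend in the environment.
#' @return An object of class `gxe_data`: a list of family blocks, each
#'   holding `ids`, `y`, `X`, `z`, `kin`, `hh`, `dz`, plus totals `n`,
#'   `n_blocks` and the design column names.
#' @export
gxe_data <- function(ped, pheno, trait, zses = "zses",
                     covariates = character(), id = "id",
                     include_zses_mean = TRUE) {
  stopifnot(inherits(ped, "pedigree"))
  for (col in c(id, trait, zses, covariates)) {
    if (!col %in% names(pheno)) {
      stop("phenotype table lacks column '", col, "'", call. = FALSE)
    }
  }
  if (!all(pheno[[id]] %in% ped$id)) {
    stop("phenotype ids not in the pedigree: ",
         paste(utils::head(setdiff(pheno[[id]], ped$id), 3), collapse = ", "),
         call. = FALSE)
  }
  blocks <- family_blocks(ped)
  rows <- match(ped$id, pheno[[id]])
  y <- pheno[[trait]][rows]
  z <- pheno[[zses]][rows]
  covs <- if (length(covariates)) {
    as.matrix(pheno[rows, covariates, drop = FALSE])
  } else {
    matrix(numeric(0), nrow(ped), 0)
  }
  keep <- !is.na(y) & !is.na(z)
  if (ncol(covs)) keep <- keep & stats::complete.cases(covs)
  names(keep) <- ped$id

  xnames <- c("(Intercept)", covariates, if (include_zses_mean) "zses")
  block_data <- list()
  for (ids in blocks) {
    ids_kept <- ids[keep[ids]]
    if (!length(ids_kept)) next
    # relationship structure is computed on the block's full sub-pedigree
    # (kinship and households never link across blocks), so individuals
    # without a trait value still connect their relatives
    jj <- match(ids, ped$id)
    sub <- ped[jj, , drop = FALSE]
    class(sub) <- c("pedigree", "data.frame")
    kin_b <- compute_kinship(sub)
    hh_b <- household_matrix(sub)
    sel <- match(ids_kept, ids)
    ii <- match(ids_kept, ped$id)
    zb <- z[ii]
    Xb <- cbind(1, covs[ii, , drop = FALSE],
                if (include_zses_mean) zb)
    colnames(Xb) <- xnames
    block_data[[length(block_data) + 1L]] <- list(
      ids = ids_kept, y = y[ii], X = Xb, z = zb,
      kin = kin_b[sel, sel, drop = FALSE],
      hh = hh_b[sel, sel, drop = FALSE],
      dz = abs(outer(zb, zb, "-")))
  }
  if (!length(block_data)) stop("no usable individuals", call. = FALSE)
  structure(list(blocks = block_data,
                 n = sum(vapply(block_data, function(b) length(b$y), 1L)),
                 n_blocks = length(block_data),
                 xnames = xnames, trait = trait),
            class = "gxe_data")
}

#' @export
print.gxe_data <- function(x, ...) {
  cat("gxe_data: trait '", x$trait, "', ", x$n, " individuals in ",
      x$n_blocks, " family blocks\n", sep = "")
  invisible(x)
}

# Core evaluation.  Returns either the exact log-likelihood at a given beta
# or the profile log-likelihood (beta maximized out by GLS), together with
# the GLS beta and its covariance.
loglik_core <- function(params, spec, data, beta = NULL) {
  p <- ncol(data$blocks[[1L]]$X)
  XtWX <- matrix(0, p, p)
  XtWy <- numeric(p)
  ytWy <- 0
  logdet <- 0
  for (b in data$blocks) {
    omega <- build_covariance(params, spec, kin = b$kin, hh = b$hh,
                              z = b$z, dz = b$dz)
    R <- tryCatch(chol(omega), error = function(e) NULL)
    if (is.null(R)) {
      stop("covariance not positive definite in block containing '",
           b$ids[1L], "'", call. = FALSE)
    }
    u <- backsolve(R, b$y, transpose = TRUE)
    V <- backsolve(R, b$X, transpose = TRUE)
    XtWX <- XtWX + crossprod(V)
    XtWy <- XtWy + crossprod(V, u)[, 1L]
    ytWy <- ytWy + sum(u^2)
    logdet <- logdet + 2 * sum(log(diag(R)))
  }
  if (is.null(beta)) {
    beta <- solve(XtWX, XtWy)
    quad <- ytWy - sum(XtWy * beta)
  } else {
    quad <- ytWy - 2 * sum(XtWy * beta) + drop(crossprod(beta, XtWX %*% beta))
  }
  ll <- -0.5 * (data$n * log(2 * pi) + logdet + quad)
  list(loglik = ll, beta = stats::setNames(as.numeric(beta), data$xnames),
       beta_vcov = solve(XtWX))
}

#' Log-likelihood of the GxE variance-components model
#'
#' Sum over family blocks of the multivariate-normal log density with mean
#' `X beta` and covariance from [build_covariance()].  If `params$beta` is
#' `NULL` the mean coefficients are profiled out (maximized by generalized
#' least squares), which is the value the optimizer maximizes.
#'
#' @param params a [gxe_params] (its `beta`, if non-`NULL`, is used as the
#'   fixed mean-model coefficient vector).
#' @param spec a [gxe_spec].
#' @param data a [gxe_data].
#' @return Log-likelihood in nats.
#' @export
gxe_loglik <- function(params, spec, data) {
  loglik_core(params, spec, data, beta = params$beta)$loglik
}

full_par <- function(free_values, spec) {
  p <- spec$fixed
  p[names(free_values)] <- free_values
  p
}

# Component summands of the block covariance (used by the gradient).
cov_parts <- function(p, spec, b) {
  n <- length(b$z)
  G <- NULL
  if (spec$genetic) {
    G <- if (p[["gamma_g"]] == 0 && p[["lambda_g"]] == 0) {
      exp(p[["alpha_g"]]) * b$kin
    } else {
      sdg <- exp(0.5 * (p[["alpha_g"]] + p[["gamma_g"]] * b$z))
      b$kin * tcrossprod(sdg) * exp(-p[["lambda_g"]] * b$dz)
    }
  }
  C <- NULL
  if (spec$household) {
    C <- if (p[["gamma_c"]] == 0 && p[["lambda_c"]] == 0) {
      exp(p[["alpha_c"]]) * b$hh
    } else {
      sdc <- exp(0.5 * (p[["alpha_c"]] + p[["gamma_c"]] * b$z))
      b$hh * tcrossprod(sdc) * exp(-p[["lambda_c"]] * b$dz)
    }
  }
  se <- if (p[["gamma_e"]] == 0) rep(exp(p[["alpha_e"]]), n) else
    exp(p[["alpha_e"]] + p[["gamma_e"]] * b$z)
  omega <- if (is.null(G)) matrix(0, n, n) else G
  if (!is.null(C)) omega <- omega + C
  diag(omega) <- diag(omega) + se
  list(G = G, C = C, se = se, omega = omega)
}

# Profile log-likelihood (beta maximized out) and, optionally, its analytic
# gradient with respect to the variance-function parameters.  By the
# envelope theorem the gradient at the profiled beta is the ordinary MVN
# score  dl/dtheta = -1/2 * sum(A * dOmega),  A = Omega^-1 - a a',
# a = Omega^-1 (y - X beta-hat), evaluated block by block; each dOmega is
# an elementwise transform of the component summand.
profile_eval <- function(pfull, spec, data, grad = FALSE) {
  nb <- length(data$blocks)
  p <- ncol(data$blocks[[1L]]$X)
  XtWX <- matrix(0, p, p)
  XtWy <- numeric(p)
  ytWy <- 0
  logdet <- 0
  chols <- if (grad) vector("list", nb)
  parts <- if (grad) vector("list", nb)
  for (k in seq_len(nb)) {
    b <- data$blocks[[k]]
    pr <- cov_parts(pfull, spec, b)
    R <- chol(pr$omega)
    u <- backsolve(R, b$y, transpose = TRUE)
    V <- backsolve(R, b$X, transpose = TRUE)
    XtWX <- XtWX + crossprod(V)
    XtWy <- XtWy + crossprod(V, u)[, 1L]
    ytWy <- ytWy + sum(u * u)
    logdet <- logdet + 2 * sum(log(diag(R)))
    if (grad) {
      chols[[k]] <- R
      parts[[k]] <- pr
    }
  }
  beta <- solve(XtWX, XtWy)
  quad <- ytWy - sum(XtWy * beta)
  ll <- -0.5 * (data$n * log(2 * pi) + logdet + quad)
  out <- list(loglik = ll, beta = beta)
  if (grad) {
    free <- spec$free
    g <- stats::setNames(numeric(length(free)), free)
    for (k in seq_len(nb)) {
      b <- data$blocks[[k]]
      R <- chols[[k]]
      pr <- parts[[k]]
      r <- b$y - drop(b$X %*% beta)
      a <- backsolve(R, backsolve(R, r, transpose = TRUE))
      A <- chol2inv(R) - tcrossprod(a)
      dA <- diag(A)
      if ("alpha_g" %in% free) g[["alpha_g"]] <- g[["alpha_g"]] -
        0.5 * sum(A * pr$G)
      if ("gamma_g" %in% free) g[["gamma_g"]] <- g[["gamma_g"]] -
        0.5 * sum(A * pr$G * (0.5 * outer(b$z, b$z, "+")))
      if ("lambda_g" %in% free) g[["lambda_g"]] <- g[["lambda_g"]] +
        0.5 * sum(A * pr$G * b$dz)
      if ("alpha_c" %in% free) g[["alpha_c"]] <- g[["alpha_c"]] -
        0.5 * sum(A * pr$C)
      if ("gamma_c" %in% free) g[["gamma_c"]] <- g[["gamma_c"]] -
        0.5 * sum(A * pr$C * (0.5 * outer(b$z, b$z, "+")))
      if ("lambda_c" %in% free) g[["lambda_c"]] <- g[["lambda_c"]] +
        0.5 * sum(A * pr$C * b$dz)
      if ("alpha_e" %in% free) g[["alpha_e"]] <- g[["alpha_e"]] -
        0.5 * sum(dA * pr$se)
      if ("gamma_e" %in% free) g[["gamma_e"]] <- g[["gamma_e"]] -
        0.5 * sum(dA * pr$se * b$z)
    }
    out$grad <- g
  }
  out
}

# Safe negative profile log-likelihood and gradient for the optimizer.
# fn caches the gradient computed alongside the function value so the
# subsequent gr call at the same point is free.
make_objective <- function(spec, data) {
  cache <- new.env(parent = emptyenv())
  cache$theta <- NULL
  fn <- function(theta) {
    pfull <- full_par(stats::setNames(theta, spec$free), spec)
    ev <- tryCatch(profile_eval(pfull, spec, data, grad = TRUE),
                   error = function(e) NULL)
    if (is.null(ev) || !is.finite(ev$loglik)) {
      cache$theta <- theta
      cache$grad <- rep(0, length(theta))
      return(1e10)
    }
    cache$theta <- theta
    cache$grad <- -ev$grad
    -ev$loglik
  }
  gr <- function(theta) {
    if (!is.null(cache$theta) && identical(cache$theta, theta)) {
      return(cache$grad)
    }
    fn(theta)
    cache$grad
  }
  list(fn = fn, gr = gr)
}

# Method-of-moments style automatic start: split the OLS residual variance
# across active components.
auto_start <- function(spec, data) {
  yy <- unlist(lapply(data$blocks, `[[`, "y"))
  XX <- do.call(rbind, lapply(data$blocks, `[[`, "X"))
  res <- stats::lm.fit(XX, yy)$residuals
  v <- max(stats::var(res), 1e-6)
  share_g <- if (spec$genetic) 0.4 else 0
  share_c <- if (spec$household) 0.15 else 0
  start <- c(alpha_g = log(max(share_g, 1e-4) * v),
             gamma_g = 0, lambda_g = 0,
             alpha_e = log((1 - share_g - share_c) * v), gamma_e = 0,
             alpha_c = log(max(share_c, 1e-4) * v), gamma_c = 0,
             lambda_c = 0)
  start[spec$free]
}

#' Maximum-likelihood fit of a GxE variance-components model
#'
#' Maximizes the profile log-likelihood over the free variance-function
#' parameters by bounded quasi-Newton (`L-BFGS-B`), with decay rates
#' bounded below at 0 so the no-decay null (`lambda = 0`) is attainable
#' exactly.  Multiple starts (a moment-based start plus seeded jitter)
#' guard against local optima; the best converged optimum is returned.
#' Standard errors come from the inverse negative Hessian of the profile
#' log-likelihood at interior estimates; parameters on a bound are flagged
#' and get no SE.
#'
#' @param data a [gxe_data].
#' @param spec a [gxe_spec].
#' @param start `"auto"` or a named numeric vector over `spec$free`.
#' @param starts number of optimizer starts (default 5).
#' @param seed integer seed for the start jitter.
#' @param extra_starts optional list of additional named start vectors
#'   (used for warm starts from nested fits).
#' @param control passed to [stats::optim()] (defaults `maxit = 1000`).
#' @return An object of class `gxe_fit`: estimates (full parameter vector),
#'   `beta` and `beta_se`, per-free-parameter `se`, `loglik`, `convergence`
#'   (`"converged"`, `"max-iter"` or `"boundary"`), logical `boundary` per
#'   free parameter, `n`, `n_blocks`, the spec, and `h2`/`c2` at z = 0 with
#'   delta-method SEs.
#' @export
fit_ml <- function(data, spec, start = "auto", starts = 5L, seed = 1L,
                   extra_starts = NULL, control = list()) {
  stopifnot(inherits(data, "gxe_data"), inherits(spec, "gxe_spec"))
  free <- spec$free
  if (data$n_blocks < 2L && length(free) > 1L) {
    warning("fewer than 2 family blocks; variance parameters may be ",
            "poorly identified")
  }
  if (data$n <= length(free) + ncol(data$blocks[[1L]]$X)) {
    stop("not enough individuals to identify the model", call. = FALSE)
  }
  obj <- make_objective(spec, data)
  base_start <- if (identical(start, "auto")) auto_start(spec, data) else {
    if (!all(free %in% names(start))) {
      stop("start must name every free parameter", call. = FALSE)
    }
    start[free]
  }
  start_list <- list(base_start)
  if (starts > 1L) {
    rng <- local_rng(seed)
    for (k in seq_len(starts - 1L)) {
      jit <- base_start
      is_lambda <- grepl("^lambda", free)
      jit[!is_lambda] <- jit[!is_lambda] + rng$rnorm(sum(!is_lambda), 0, 0.4)
      jit[is_lambda] <- abs(jit[is_lambda] + rng$rnorm(sum(is_lambda), 0, 0.2))
      start_list[[length(start_list) + 1L]] <- jit
    }
  }
  for (s in extra_starts) start_list[[length(start_list) + 1L]] <- s[free]

  lower <- PAR_LOWER[free]
  upper <- PAR_UPPER[free]
  ctrl <- utils::modifyList(list(maxit = 1000L), control)
  best <- NULL
  diagnostics <- character(0)
  for (s in start_list) {
    s <- pmin(pmax(s, lower), upper)
    opt <- tryCatch(
      stats::optim(s, obj$fn, gr = obj$gr, method = "L-BFGS-B",
                   lower = lower, upper = upper, control = ctrl),
      error = function(e) e)
    if (inherits(opt, "error")) {
      diagnostics <- c(diagnostics, conditionMessage(opt))
      next
    }
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  if (is.null(best)) {
    stop("all optimizer starts failed:\n",
         paste(unique(diagnostics), collapse = "\n"), call. = FALSE)
  }
  theta <- stats::setNames(best$par, free)
  at_bound <- theta <= lower + BOUNDARY_TOL | theta >= upper - BOUNDARY_TOL
  convergence <- if (any(at_bound)) "boundary"
                 else if (best$convergence == 0L) "converged" else "max-iter"

  pfull <- full_par(theta, spec)
  params <- structure(list(par = pfull, beta = NULL), class = "gxe_params")
  core <- loglik_core(params, spec, data)
  params$beta <- core$beta

  se <- stats::setNames(rep(NA_real_, length(free)), free)
  vcov_free <- matrix(NA_real_, length(free), length(free),
                      dimnames = list(free, free))
  interior <- which(!at_bound)
  if (length(interior)) {
    H <- tryCatch(stats::optimHess(theta, obj$fn, gr = obj$gr),
                  error = function(e) NULL)
    if (!is.null(H)) {
      Hi <- H[interior, interior, drop = FALSE]
      Vi <- tryCatch(solve(Hi), error = function(e) NULL)
      if (!is.null(Vi) && all(diag(Vi) > 0)) {
        se[interior] <- sqrt(diag(Vi))
        vcov_free[interior, interior] <- Vi
      }
    }
  }
  h2 <- heritability_se(pfull, spec, free, vcov_free)

  structure(list(estimates = pfull, params = params,
                 beta = core$beta,
                 beta_se = sqrt(diag(core$beta_vcov)),
                 se = se, vcov = vcov_free,
                 loglik = -best$value,
                 convergence = convergence, boundary = at_bound,
                 n = data$n, n_blocks = data$n_blocks,
                 spec = spec, h2 = h2$h2, h2_se = h2$h2_se,
                 c2 = h2$c2, c2_se = h2$c2_se),
            class = "gxe_fit")
}

# Delta-method SEs for h2(0) and c2(0) from the free-parameter covariance.
heritability_se <- function(pfull, spec, free, vcov_free) {
  h_of <- function(theta) {
    p <- pfull
    p[free] <- theta
    params <- structure(list(par = p, beta = NULL), class = "gxe_params")
    unlist(heritability_at(params, spec, 0)[, c("h2", "c2")])
  }
  est <- h_of(pfull[free])
  h2_se <- c2_se <- NA_real_
  if (!any(is.na(vcov_free))) {
    eps <- 1e-5
    J <- vapply(seq_along(free), function(j) {
      th <- pfull[free]
      th[j] <- th[j] + eps
      (h_of(th) - est) / eps
    }, numeric(2))
    V <- J %*% vcov_free %*% t(J)
    if (all(diag(V) >= 0)) {
      h2_se <- sqrt(V[1L, 1L])
      c2_se <- sqrt(V[2L, 2L])
    }
  }
  list(h2 = unname(est[1L]), c2 = unname(est[2L]),
       h2_se = h2_se, c2_se = c2_se)
}

#' @export
print.gxe_fit <- function(x, ...) {
  cat("GxE variance-components fit (", x$convergence, ")\n", sep = "")
  cat("  n =", x$n, "in", x$n_blocks, "blocks; loglik =",
      format(x$loglik, digits = 8), "\n")
  est <- x$estimates[x$spec$free]
  tab <- data.frame(estimate = est, se = x$se[x$spec$free],
                    boundary = x$boundary)
  print(round(tab[, 1:2], 4))
  cat("  h2(0) =", round(x$h2, 3),
      if (!is.na(x$h2_se)) paste0("(", round(x$h2_se, 3), ")"), "\n")
  if (x$spec$household) {
    cat("  c2(0) =", round(x$c2, 3),
        if (!is.na(x$c2_se)) paste0("(", round(x$c2_se, 3), ")"), "\n")
  }
  invisible(x)
}

#' Fit with named parameters constrained to fixed values
#'
#' Used to build every null model in the testing hierarchy: the listed
#' parameters are removed from the free set and fixed at the given values,
#' and the remaining free parameters are re-estimated.  If every free
#' parameter is constrained the log-likelihood is evaluated directly with
#' no optimization.
#'
#' @param data a [gxe_data].
#' @param spec a [gxe_spec] describing the *unconstrained* model.
#' @param constraints named numeric, e.g. `c(gamma_g = 0)`.
#' @param ... passed to [fit_ml()].
#' @return A `gxe_fit`.
#' @export
constrained_fit <- function(data, spec, constraints, ...) {
  bad <- setdiff(names(constraints), spec$free)
  if (length(bad)) {
    stop("constraint names not free in the spec: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  free_left <- setdiff(spec$free, names(constraints))
  fixed <- spec$fixed
  fixed[names(constraints)] <- constraints
  if (!length(free_left)) {
    params <- structure(list(par = fixed, beta = NULL), class = "gxe_params")
    spec0 <- spec
    spec0$free <- character(0)
    spec0$fixed <- fixed
    core <- loglik_core(params, spec, data)
    params$beta <- core$beta
    h2 <- heritability_at(params, spec, 0)
    return(structure(list(estimates = fixed, params = params,
                          beta = core$beta,
                          beta_se = sqrt(diag(core$beta_vcov)),
                          se = numeric(0), vcov = NULL,
                          loglik = core$loglik,
                          convergence = "converged",
                          boundary = logical(0),
                          n = data$n, n_blocks = data$n_blocks,
                          spec = spec0,
                          h2 = h2$h2, h2_se = NA_real_,
                          c2 = h2$c2, c2_se = NA_real_),
                     class = "gxe_fit"))
  }
  spec2 <- spec
  spec2$free <- free_left
  spec2$fixed <- fixed
  fit_ml(data, spec2, ...)
}

# Small deterministic RNG wrapper that does not disturb the global stream.
local_rng <- function(seed) {
  env <- new.env()
  env$state <- {
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
    set.seed(seed)
    s <- get(".Random.seed", .GlobalEnv)
    if (is.null(old)) rm(".Random.seed", envir = .GlobalEnv)
    else assign(".Random.seed", old, .GlobalEnv)
    s
  }
  env$rnorm <- function(n, mean = 0, sd = 1) {
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
    assign(".Random.seed", env$state, .GlobalEnv)
    x <- stats::rnorm(n, mean, sd)
    env$state <- get(".Random.seed", .GlobalEnv)
    if (is.null(old)) rm(".Random.seed", envir = .GlobalEnv)
    else assign(".Random.seed", old, .GlobalEnv)
    x
  }
  env
}
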