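# Likelihood-ratio tests with boundary-aware null distributions, and the
# three-stage gatekeeping procedure:
#   stage 1 - is the trait heritable, and is there a household component?
#   stage 2 - is the full GxE model superior to the homogeneous model?
#   stage 3 - which GxE functions drive it (gamma_g, lambda_g, gamma_e,
#             and, under model 2, gamma_c, lambda_c)?
#
# A variance or decay rate tested at the boundary of its space has the
# half-mixture null 1/2 * chi2_0 + 1/2 * chi2_1: the p-value is
# 1/2 * P(chi2_1 >= stat), exactly 0.5 when the estimate sits on the
# boundary (statistic 0).

NEG_LRT_TOL <- 1e-6

#' Null-distribution specifications for likelihood-ratio tests
#'
#' @param df degrees of freedom.
#' @return A distribution spec for [lrt_p()].
#' @export
chi2_null <- function(df) {
  stopifnot(df >= 1)
  structure(list(type = "chi2", df = df), class = "lrt_null")
}

#' @rdname chi2_null
#' @export
halfmix_null <- function() {
  structure(list(type = "halfmix"), class = "lrt_null")
}

#' @rdname chi2_null
#' @param weights mixture weights summing to 1.
#' @param dfs degrees of freedom per component (0 = point mass at 0).
#' @export
mixture_null <- function(weights, dfs) {
  stopifnot(length(weights) == length(dfs),
            abs(sum(weights) - 1) < 1e-8, all(weights >= 0))
  structure(list(type = "mixture", weights = weights, dfs = dfs),
            class = "lrt_null")
}

#' Likelihood-ratio test p-value
#'
#' @param stat LRT statistic, `2 * (loglik_alt - loglik_null)`, `>= 0`.
#' @param null a distribution spec from [chi2_null()], [halfmix_null()] or
#'   [mixture_null()].
#' @return Upper-tail p-value.
#' @examples
#' lrt_p(0, halfmix_null())      # 0.5 at a boundary estimate
#' lrt_p(3.841459, chi2_null(1)) # ~0.05
#' @export
lrt_p <- function(stat, null) {
  stopifnot(stat >= 0, inherits(null, "lrt_null"))
  tail1 <- function(df) {
    if (df == 0) as.numeric(stat <= 0) else
      stats::pchisq(stat, df, lower.tail = FALSE)
  }
  switch(null$type,
    chi2 = tail1(null$df),
    halfmix = 0.5 * stats::pchisq(stat, 1, lower.tail = FALSE),
    mixture = sum(null$weights * vapply(null$dfs, tail1, numeric(1))),
    stop("unknown null distribution spec", call. = FALSE))
}

#' Multiple-testing adjustment
#'
#' Bonferroni by default: `min(1, m * p)` with `m` the size of the test
#' family (e.g. the trait panel), matching the capped `1.00000` convention
#' of multi-trait screens.
#'
#' @param p numeric vector of raw p-values in `[0, 1]`.
#' @param m family size; defaults to `length(p)`.
#' @param method `"bonferroni"`, `"holm"`, `"BH"` or `"none"` (`holm`/`BH`
#'   use [stats::p.adjust()] over the vector and ignore `m`).
#' @return Adjusted p-values, never below the raw ones, capped at 1.
#' @export
adjust_pvalues <- function(p, m = length(p), method = "bonferroni") {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE), m >= 1)
  switch(method,
    bonferroni = pmin(1, m * p),
    none = p,
    holm = ,
    BH = stats::p.adjust(p, method = method),
    stop("unknown adjustment method '", method, "'", call. = FALSE))
}

# Build a TestResult row.  Negative statistics (optimizer noise) are
# clipped to 0; clips beyond NEG_LRT_TOL get a warning.
make_test <- function(name, ll_alt, ll_null, null, stage,
                      m = 1L, method = "bonferroni") {
  stat <- 2 * (ll_alt - ll_null)
  clipped <- FALSE
  if (stat < 0) {
    if (stat < -NEG_LRT_TOL) {
      warning("negative LRT statistic (", format(stat), ") for '", name,
              "' clipped to 0; consider tightening optimizer tolerance")
    }
    stat <- 0
    clipped <- TRUE
  }
  p <- lrt_p(stat, null)
  data.frame(name = name, stat = stat, df = if (null$type == "chi2") null$df
             else NA_real_,
             null = null$type, p_raw = p,
             p_adjusted = adjust_pvalues(p, m = m, method = method),
             stage = stage, clipped = clipped,
             stringsAsFactors = FALSE)
}

#' Stage 1: heritability and household-component tests
#'
#' Tests `sig2_g = 0` and (when household structure is present)
#' `sig2_c = 0`, each by a boundary LRT with the half-mixture null.  The
#' working model is model 1 (genetic + residual) when the household
#' component is non-significant at `alpha`, else model 2 (genetic +
#' household + residual); heritability is re-estimated under the chosen
#' model.
#'
#' @param data a [gxe_data].
#' @param alpha gatekeeping significance level (default 0.05).
#' @param household `NULL` (auto-detect shared households in the data),
#'   `TRUE` or `FALSE`.
#' @param starts,seed passed to [fit_ml()].
#' @return List with `model` (1 or 2), `fit` (the chosen homogeneous fit),
#'   `fit_null` (no-genetic fit under the chosen model), `tests` (data
#'   frame), and `heritable` (logical gate at `alpha`).
#' @export
test_heritability <- function(data, alpha = 0.05, household = NULL,
                              starts = 3L, seed = 1L) {
  if (is.null(household)) {
    household <- any(vapply(data$blocks, function(b) {
      h <- b$hh
      diag(h) <- 0
      any(h > 0)
    }, logical(1)))
  }
  spec1 <- gxe_spec(genetic = TRUE, household = FALSE,
                    free = c("alpha_g", "alpha_e"))
  spec_e <- gxe_spec(genetic = FALSE, household = FALSE, free = "alpha_e")
  fit_e <- fit_ml(data, spec_e, starts = starts, seed = seed + 1L)
  # warm start exactly nested at the no-genetic optimum (genetic variance
  # at its effective zero) so the heritability LRT is never negative
  fit1 <- fit_ml(data, spec1, starts = starts, seed = seed,
                 extra_starts = list(c(alpha_g = PAR_LOWER[["alpha_g"]],
                                       alpha_e = fit_e$estimates[["alpha_e"]])))
  tests <- NULL
  model <- 1L
  fit <- fit1
  fit_null <- fit_e
  if (household) {
    spec2 <- gxe_spec(genetic = TRUE, household = TRUE,
                      free = c("alpha_g", "alpha_c", "alpha_e"))
    # one warm start exactly nested at the model-1 optimum (household
    # variance at its effective zero), one with a small household share
    ab <- fit1$estimates[c("alpha_g", "alpha_e")]
    fit2 <- fit_ml(data, spec2, starts = starts, seed = seed + 2L,
                   extra_starts = list(c(ab, alpha_c = PAR_LOWER[["alpha_c"]]),
                                       c(ab, alpha_c = -4)))
    hh_test <- make_test("household_variance", fit2$loglik, fit1$loglik,
                         halfmix_null(), stage = 1L)
    if (hh_test$p_raw < alpha) {
      model <- 2L
      fit <- fit2
      spec_ce <- gxe_spec(genetic = FALSE, household = TRUE,
                          free = c("alpha_c", "alpha_e"))
      fit_null <- fit_ml(data, spec_ce, starts = starts, seed = seed + 3L,
                         extra_starts = list(
                           fit2$estimates[c("alpha_c", "alpha_e")]))
      if (fit_null$loglik > fit$loglik) {
        # re-polish the nesting fit from the null optimum's corner
        fit <- fit_ml(data, spec2, starts = 1L, seed = seed + 4L,
                      extra_starts = list(
                        c(alpha_g = PAR_LOWER[["alpha_g"]],
                          fit_null$estimates[c("alpha_c", "alpha_e")])))
      }
    }
    tests <- hh_test
  }
  h_test <- make_test("heritability", fit$loglik, fit_null$loglik,
                      halfmix_null(), stage = 1L)
  tests <- rbind(h_test, tests)
  list(model = model, fit = fit, fit_null = fit_null, tests = tests,
       heritable = h_test$p_raw < alpha)
}

# Full-GxE spec for a given base model.
full_gxe_spec <- function(model) {
  if (model == 2L) {
    gxe_spec(genetic = TRUE, household = TRUE,
             free = c("alpha_g", "gamma_g", "lambda_g",
                      "alpha_e", "gamma_e",
                      "alpha_c", "gamma_c", "lambda_c"))
  } else {
    gxe_spec(genetic = TRUE, household = FALSE,
             free = c("alpha_g", "gamma_g", "lambda_g",
                      "alpha_e", "gamma_e"))
  }
}

#' Stage 2: joint test of the GxE model against the homogeneous model
#'
#' Fits the full GxE model (free `gamma_g`, `lambda_g`, `gamma_e`, plus
#' `gamma_c`, `lambda_c` under model 2) and compares it to the homogeneous
#' base fit by an LRT with a chi-square null on the number of freed
#' parameters (3 under model 1, 5 under model 2).  Because the decay rates
#' sit on a boundary under the null, this reference distribution is
#' conservative.  The base fit is used as a warm start, which guarantees a
#' non-negative statistic.
#'
#' @param data a [gxe_data].
#' @param stage1 result of [test_heritability()] (supplies the base model
#'   and fit).
#' @param starts,seed passed to [fit_ml()].
#' @return List with `test` (one-row data frame, raw p only; panel-level
#'   adjustment is applied by the caller), `fit_full`, `fit_base`, `df`.
#' @export
test_gxe_joint <- function(data, stage1, starts = 3L, seed = 1L) {
  model <- stage1$model
  fit_base <- stage1$fit
  spec_full <- full_gxe_spec(model)
  warm <- spec_full$fixed
  warm[names(fit_base$estimates)] <- fit_base$estimates
  fit_full <- fit_ml(data, spec_full, starts = starts, seed = seed,
                     extra_starts = list(warm))
  df <- if (model == 2L) 5L else 3L
  test <- make_test("gxe_joint", fit_full$loglik, fit_base$loglik,
                    chi2_null(df), stage = 2L)
  list(test = test, fit_full = fit_full, fit_base = fit_base, df = df)
}

COMPONENT_TESTS <- data.frame(
  par = c("gamma_g", "gamma_e", "gamma_c", "lambda_g", "lambda_c"),
  label = c("Homogeneous additive genetic variance",
            "Homogeneous residual environmental variance",
            "Homogeneous household variance",
            "Genetic correlation equals 1",
            "Household correlation equals 1"),
  stringsAsFactors = FALSE)

#' Stage 3: single-parameter tests of the GxE functions
#'
#' For each GxE function parameter free in the full model, refits with that
#' parameter constrained to 0 (warm-started from the full fit) and tests by
#' LRT: slope (`gamma`) tests against chi2(1), decay (`lambda`) tests
#' against the boundary half-mixture.  A decay rate already estimated at
#' the boundary needs no refit: its statistic is exactly 0 and its
#' half-mixture p-value exactly 0.5.
#'
#' @param data a [gxe_data].
#' @param stage2 result of [test_gxe_joint()].
#' @param m adjustment multiplier for the reported p-values (default 1:
#'   per-test reporting).
#' @param method adjustment method.
#' @param starts,seed passed to [fit_ml()].
#' @return Data frame with one row per component test (`par`, `label`,
#'   `stat`, `p_raw`, `p_adjusted`, `estimate`).
#' @export
test_gxe_components <- function(data, stage2, m = 1L, method = "bonferroni",
                                starts = 2L, seed = 1L) {
  fit_full <- stage2$fit_full
  spec <- fit_full$spec
  pars <- intersect(COMPONENT_TESTS$par, spec$free)
  out <- NULL
  for (par in pars) {
    is_lambda <- grepl("^lambda", par)
    null <- if (is_lambda) halfmix_null() else chi2_null(1)
    if (is_lambda && fit_full$estimates[par] <= BOUNDARY_TOL) {
      # constrained model attains the same maximum
      row <- make_test(par, fit_full$loglik, fit_full$loglik, null,
                       stage = 3L, m = m, method = method)
    } else {
      fit0 <- constrained_fit(data, spec,
                              stats::setNames(0, par),
                              starts = starts, seed = seed,
                              extra_starts = list(fit_full$estimates[spec$free]))
      row <- make_test(par, fit_full$loglik, fit0$loglik, null,
                       stage = 3L, m = m, method = method)
    }
    row$label <- COMPONENT_TESTS$label[COMPONENT_TESTS$par == par]
    row$estimate <- unname(fit_full$estimates[par])
    out <- rbind(out, row)
  }
  out
}
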