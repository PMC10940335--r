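# Trait preprocessing: zSES construction, exclusions, covariate
# residualization, rank-based inverse normalization, mediation screen.

standardize <- function(x) {
  mu <- mean(x, na.rm = TRUE)
  sdev <- stats::sd(x, na.rm = TRUE)
  if (!is.finite(sdev) || sdev == 0) {
    stop("cannot standardize a zero-variance vector", call. = FALSE)
  }
  (x - mu) / sdev
}

#' Standardized socioeconomic index (zSES)
#'
#' The composite SES environment index: the standardized sum of the
#' standardized occupational index (e.g. Duncan SEI) and education years,
#' `z = standardize(standardize(sei) + standardize(edu))`.  Sample mean and
#' SD (denominator n - 1) are taken over non-missing entries; an entry is
#' missing in the output when either input is missing.  The result is
#' invariant to affine rescaling of either input.
#'
#' @param sei numeric vector of socioeconomic-index scores.
#' @param education numeric vector of education years, same length.
#' @return Numeric vector with sample mean 0 and SD 1 over non-missing
#'   entries.
#' @export
zses_score <- function(sei, education) {
  if (length(sei) != length(education)) {
    stop("sei and education must have the same length", call. = FALSE)
  }
  if (sum(!is.na(sei)) < 2L || sum(!is.na(education)) < 2L) {
    stop("need at least 2 non-missing values in each input", call. = FALSE)
  }
  standardize(standardize(sei) + standardize(education))
}

#' Remove individuals flagged for exclusion
#'
#' Drops rows with any exclusion flag set (disease status or medication use
#' that alters the trait metabolism).  A missing flag means not excluded.
#' A pure filter: retained rows are unaltered.
#'
#' @param table data frame of per-individual phenotypes.
#' @param flag_cols character vector of 0/1 flag column names.
#' @return The filtered data frame, with attribute `n_excluded`.
#' @export
apply_exclusions <- function(table, flag_cols) {
  missing_cols <- setdiff(flag_cols, names(table))
  if (length(missing_cols)) {
    stop("exclusion flag column(s) not found: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (length(flag_cols) == 0L) {
    attr(table, "n_excluded") <- 0L
    return(table)
  }
  flags <- as.matrix(table[flag_cols])
  flags[is.na(flags)] <- 0
  drop <- rowSums(flags != 0) > 0
  out <- table[!drop, , drop = FALSE]
  attr(out, "n_excluded") <- sum(drop)
  message(sum(drop), " individual(s) excluded; ", nrow(out), " remain")
  out
}

#' Residualize a trait on covariates by ordinary least squares
#'
#' Fits `trait ~ intercept + covariates` on complete cases and returns the
#' residuals (missing where any input is missing) together with the
#' proportion of trait variance accounted for by the covariates.
#'
#' @param trait numeric vector.
#' @param covariates numeric matrix or data frame of covariate columns
#'   (may have zero columns).
#' @return A list with `residuals` (same length as `trait`), `r_squared`,
#'   `coefficients`, and `n` (complete cases used).
#' @export
residualize <- function(trait, covariates = NULL) {
  n <- length(trait)
  if (is.null(covariates) || NCOL(covariates) == 0L ||
      (is.data.frame(covariates) && ncol(covariates) == 0L)) {
    X <- matrix(numeric(0), n, 0)
  } else {
    X <- as.matrix(covariates)
    if (nrow(X) != n) stop("trait and covariates lengths differ", call. = FALSE)
  }
  ok <- !is.na(trait) & (ncol(X) == 0L | stats::complete.cases(X))
  if (sum(ok) < ncol(X) + 2L) {
    stop("too few complete cases to residualize", call. = FALSE)
  }
  Xf <- cbind(`(Intercept)` = 1, X[ok, , drop = FALSE])
  qrX <- qr(Xf)
  if (qrX$rank < ncol(Xf)) {
    bad <- colnames(Xf)[qrX$pivot[seq.int(qrX$rank + 1L, ncol(Xf))]]
    stop("rank-deficient design; collinear column(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  fit <- stats::lm.fit(Xf, trait[ok])
  res <- rep(NA_real_, n)
  res[ok] <- fit$residuals
  tss <- sum((trait[ok] - mean(trait[ok]))^2)
  r2 <- if (tss > 0) 1 - sum(fit$residuals^2) / tss else 0
  list(residuals = res, r_squared = r2,
       coefficients = fit$coefficients, n = sum(ok))
}

#' Rank-based inverse normal transformation
#'
#' Maps values to standard-normal quantiles through their ranks using the
#' Blom offset: `qnorm((r - c) / (n + 1 - 2c))` with `c = 3/8` by default,
#' average ranks under ties.  Strictly rank-preserving on distinct values;
#' any monotone transform of the input yields an identical output.
#'
#' @param x numeric vector (missing entries stay missing).
#' @param offset rank offset constant, default `3/8` (Blom).
#' @return Numeric vector of normal scores.
#' @export
inverse_normalize <- function(x, offset = 3 / 8) {
  ok <- !is.na(x)
  n <- sum(ok)
  if (n < 2L) stop("need at least 2 non-missing values", call. = FALSE)
  if (length(unique(x[ok])) == 1L) {
    stop("all values identical; inverse normalization undefined", call. = FALSE)
  }
  r <- rank(x[ok], ties.method = "average")
  out <- rep(NA_real_, length(x))
  out[ok] <- stats::qnorm((r - offset) / (n + 1 - 2 * offset))
  out
}

#' Mediation screen: does a covariate predict the SES index?
#'
#' Simple linear regression with the SES index as the dependent variable
#' and one candidate mediator (a diet or alcohol covariate) as predictor;
#' a significant slope flags the covariate as a potential mediator of the
#' SES effect.  The slope p-value is two-sided and adjusted for the number
#' of screens performed.
#'
#' @param zses numeric vector, the SES index.
#' @param covariate numeric vector, same length.
#' @param m number of screens in the family (for the adjustment).
#' @param method adjustment method, see [adjust_pvalues()].
#' @return List with `slope`, `se`, `p_raw`, `p_adjusted`, `n`.
#' @export
mediation_screen <- function(zses, covariate, m = 1L, method = "bonferroni") {
  ok <- !is.na(zses) & !is.na(covariate)
  if (sum(ok) < 3L) stop("too few complete pairs", call. = FALSE)
  if (stats::sd(covariate[ok]) == 0) {
    stop("zero-variance covariate", call. = FALSE)
  }
  fit <- stats::lm(zses[ok] ~ covariate[ok])
  sm <- summary(fit)$coefficients
  p <- sm[2L, 4L]
  list(slope = unname(sm[2L, 1L]), se = unname(sm[2L, 2L]),
       p_raw = unname(p),
       p_adjusted = adjust_pvalues(p, m = m, method = method),
       n = sum(ok))
}

#' Classify metabolic syndrome status from component traits
#'
#' Applies the component thresholds: triglycerides > 150 mg/dL; HDL
#' cholesterol < 40 mg/dL (men) / < 50 mg/dL (women); blood pressure >=
#' 135/85 mmHg (either systolic or diastolic bound); fasting glucose >
#' 100 mg/dL.  Status is positive when at least `threshold` of the four
#' component flags are set.  A missing component leaves its flag missing;
#' status is missing only when the observed flags cannot decide it either
#' way.  Some published criteria print the blood-pressure bound with the
#' inequality reversed; the elevated-pressure direction used here is the
#' clinically standard one and `bp_high` can flip it.
#'
#' @param tg,hdl,sbp,dbp,glucose numeric vectors (mg/dL, mmHg).
#' @param sex character vector, `"M"`/`"F"`.
#' @param threshold number of flags required for a positive call, default 3.
#' @param bp_high if `TRUE` (default) blood pressure >= 135/85 flags; if
#'   `FALSE` the direction is reversed.
#' @return Data frame of the four logical flags, `n_flags`, and logical
#'   `ms_status`.
#' @export
ms_classify <- function(tg, hdl, sbp, dbp, glucose, sex, threshold = 3L,
                        bp_high = TRUE) {
  if (!all(sex %in% c("M", "F") | is.na(sex))) {
    stop("unknown sex code; expected \"M\"/\"F\"", call. = FALSE)
  }
  hdl_cut <- ifelse(sex == "M", 40, 50)
  flag_tg <- tg > 150
  flag_hdl <- hdl < hdl_cut
  bp <- (sbp >= 135) | (dbp >= 85)
  flag_bp <- if (bp_high) bp else !bp
  flag_fg <- glucose > 100
  flags <- cbind(tg = flag_tg, hdl = flag_hdl, bp = flag_bp, fg = flag_fg)
  n_set <- rowSums(flags, na.rm = TRUE)
  n_miss <- rowSums(is.na(flags))
  status <- rep(NA, length(tg))
  status[n_set >= threshold] <- TRUE                 # decided positive
  status[n_set + n_miss < threshold] <- FALSE        # cannot reach threshold
  data.frame(flag_tg, flag_hdl, flag_bp, flag_fg,
             n_flags = n_set, ms_status = status)
}
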