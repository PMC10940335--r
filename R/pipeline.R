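# Panel orchestration: preprocess -> stage 1 / 2 / 3 across a trait panel,
# table- and figure-ready exports, manifest.

#' Validate a run configuration
#'
#' A configuration is a nested list (typically read from a YAML file):
#' \preformatted{
#' pedigree: ped.csv
#' phenotypes: pheno.csv
#' zses: zses            # or sei + education column names
#' exclusion_flags: [excl_flag]
#' traits:
#'   trait01: {covariates: [age, sex]}
#'   trait02: {covariates: []}
#' options: {alpha: 0.05, adjust: bonferroni, starts: 3, seed: 1}
#' }
#'
#' @param config nested list.
#' @return The config with defaults filled in; errors on an invalid one.
#' @export
validate_config <- function(config) {
  if (is.null(config$traits) || !length(config$traits)) {
    stop("config must declare a non-empty trait list", call. = FALSE)
  }
  opts <- config$options %||% list()
  opts$alpha <- opts$alpha %||% 0.05
  if (opts$alpha <= 0 || opts$alpha >= 1) {
    stop("alpha must be in (0, 1)", call. = FALSE)
  }
  opts$adjust <- opts$adjust %||% "bonferroni"
  opts$starts <- opts$starts %||% 3L
  opts$seed <- opts$seed %||% 1L
  opts$z_grid <- opts$z_grid %||% list(from = -3, to = 3, by = 0.1)
  config$options <- opts
  config$exclusion_flags <- config$exclusion_flags %||% character(0)
  config$zses <- config$zses %||% "zses"
  config
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a run configuration from a YAML file
#' @param path YAML file path.
#' @return Validated config list.
#' @export
read_run_config <- function(path) {
  validate_config(yaml::read_yaml(path))
}

# Per-trait preprocessing: exclusions, complete cases, residualization on
# covariates, inverse normalization.
preprocess_trait <- function(pheno, trait, covariates, flag_cols) {
  tab <- suppressMessages(apply_exclusions(pheno, flag_cols))
  if (!nrow(tab)) {
    stop("all individuals excluded; nothing to analyze", call. = FALSE)
  }
  covs <- if (length(covariates)) tab[, covariates, drop = FALSE] else NULL
  covs <- if (!is.null(covs)) {
    as.data.frame(lapply(covs, function(x) {
      if (is.character(x)) as.numeric(factor(x)) else as.numeric(x)
    }))
  }
  res <- residualize(tab[[trait]], covs)
  tab$trait_norm <- inverse_normalize(res$residuals)
  list(table = tab, r_squared = res$r_squared,
       n = sum(!is.na(tab$trait_norm)),
       n_excluded = attr(tab, "n_excluded") %||% 0L)
}

#' Run the three-stage GxE analysis over a trait panel
#'
#' For each trait: exclusions, covariate residualization, inverse
#' normalization, stage-1 heritability/household testing, stage-2 joint
#' GxE test (adjusted across the panel), and stage-3 component tests for
#' the stage-2 survivors.  A failing trait is quarantined (its error
#' recorded) and the rest of the panel proceeds.
#'
#' @param ped a [pedigree].
#' @param pheno phenotype data frame (id column joining the pedigree).
#' @param traits named list, one entry per trait, each a list with a
#'   `covariates` character vector (possibly empty).
#' @param zses name of the environment-index column.
#' @param exclusion_flags character vector of 0/1 exclusion columns.
#' @param alpha gatekeeping level.
#' @param adjust adjustment method for the stage-2 panel.
#' @param starts optimizer starts per fit.
#' @param seed integer seed controlling every stochastic step.
#' @return An object of class `gxe_panel`: per-trait results, the stage-2
#'   adjusted p-values, stage-3 tables, and a run manifest.
#' @export
run_panel <- function(ped, pheno, traits, zses = "zses",
                      exclusion_flags = character(0),
                      alpha = 0.05, adjust = "bonferroni",
                      starts = 3L, seed = 1L) {
  stopifnot(length(traits) >= 1L, alpha > 0, alpha < 1)
  trait_names <- names(traits)
  results <- stats::setNames(vector("list", length(traits)), trait_names)
  for (k in seq_along(traits)) {
    nm <- trait_names[k]
    results[[nm]] <- tryCatch({
      prep <- preprocess_trait(pheno, nm, traits[[nm]]$covariates %||%
                                 character(0), exclusion_flags)
      dat <- gxe_data(ped, prep$table, trait = "trait_norm", zses = zses)
      s1 <- test_heritability(dat, alpha = alpha, starts = starts,
                              seed = seed + 101L * k)
      out <- list(trait = nm, data = dat, prep = prep, stage1 = s1,
                  stage2 = NULL, stage3 = NULL, error = NULL)
      if (s1$heritable) {
        out$stage2 <- test_gxe_joint(dat, s1, starts = starts,
                                     seed = seed + 101L * k + 1L)
      }
      out
    }, error = function(e) {
      list(trait = nm, error = conditionMessage(e))
    })
  }
  # stage-2 panel adjustment over all traits (panel size = full panel)
  m_panel <- length(traits)
  for (nm in trait_names) {
    r <- results[[nm]]
    if (!is.null(r$error) || is.null(r$stage2)) next
    r$stage2$test$p_adjusted <- adjust_pvalues(r$stage2$test$p_raw,
                                               m = m_panel, method = adjust)
    results[[nm]] <- r
  }
  # stage 3 only for stage-2 survivors (gatekeeping)
  for (k in seq_along(traits)) {
    nm <- trait_names[k]
    r <- results[[nm]]
    if (!is.null(r$error) || is.null(r$stage2)) next
    if (r$stage2$test$p_adjusted < alpha) {
      r$stage3 <- tryCatch(
        test_gxe_components(r$data, r$stage2, starts = max(2L, starts - 1L),
                            seed = seed + 101L * k + 2L),
        error = function(e) NULL)
      results[[nm]] <- r
    }
  }
  manifest <- list(
    seed = seed, alpha = alpha, adjust = adjust, starts = starts,
    n_traits = length(traits),
    traits = lapply(results, function(r) {
      if (!is.null(r$error)) return(list(error = r$error))
      list(n = r$data$n, n_blocks = r$data$n_blocks,
           model = r$stage1$model,
           heritable = r$stage1$heritable,
           stage2_p_adjusted = if (!is.null(r$stage2))
             r$stage2$test$p_adjusted else NA,
           stage3_run = !is.null(r$stage3))
    }))
  structure(list(results = results, manifest = manifest, alpha = alpha),
            class = "gxe_panel")
}

#' Run a panel from a configuration file
#'
#' Thin wrapper: reads the config, the pedigree and phenotype files,
#' derives the environment index from `sei`/`education` columns when no
#' `zses` column is present, and calls [run_panel()].
#'
#' @param config a config list (see [validate_config()]) or a YAML path.
#' @return A `gxe_panel`.
#' @export
run_panel_config <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  config <- validate_config(config)
  ped <- read_pedigree(config$pedigree)
  pheno <- utils::read.csv(config$phenotypes, stringsAsFactors = FALSE)
  if (!config$zses %in% names(pheno)) {
    if (all(c("sei", "education") %in% names(pheno))) {
      pheno[[config$zses]] <- zses_score(pheno$sei, pheno$education)
    } else {
      stop("phenotype file has neither a '", config$zses,
           "' column nor sei/education columns", call. = FALSE)
    }
  }
  opts <- config$options
  run_panel(ped, pheno, traits = config$traits, zses = config$zses,
            exclusion_flags = config$exclusion_flags,
            alpha = opts$alpha, adjust = opts$adjust,
            starts = opts$starts, seed = opts$seed)
}

fmt_p <- function(p) {
  ifelse(is.na(p), "-----",
         ifelse(p >= 1e-4, formatC(p, format = "f", digits = 5),
                formatC(p, format = "e", digits = 3)))
}

NA_MARK <- "-----"

# "estimate (se)" with a marker when the SE is unavailable (boundary fit)
fmt_est <- function(est, se) {
  if (is.na(est)) return(NA_MARK)
  sprintf("%.2f (%s)", est,
          if (is.na(se)) "---" else sprintf("%.2f", se))
}

#' Export panel results as three CSV tables
#'
#' Table 2 analogue: per trait, N, heritability (SE) and p, household
#' share (SE) and p (missing marker under model 1), and the covariate
#' variance share.  Table 3 analogue: per trait, the panel-adjusted joint
#' GxE p-value.  Table 4 analogue: stage-2 survivors, five component-test
#' p-values with missing markers for tests not in the trait's model.
#'
#' @param panel a `gxe_panel`.
#' @param outdir output directory (created if needed).
#' @return Invisibly, the three file paths.
#' @export
export_tables <- function(panel, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  res <- panel$results
  t2 <- do.call(rbind, lapply(res, function(r) {
    if (!is.null(r$error)) {
      return(data.frame(trait = r$trait, n = NA, h2 = NA_MARK, h2_p = NA_MARK,
                        c2 = NA_MARK, c2_p = NA_MARK, covariate_r2 = NA_MARK))
    }
    s1 <- r$stage1
    fit <- s1$fit
    htest <- s1$tests[s1$tests$name == "heritability", ]
    hh <- s1$tests[s1$tests$name == "household_variance", ]
    data.frame(
      trait = r$trait, n = r$data$n,
      h2 = fmt_est(fit$h2, fit$h2_se),
      h2_p = fmt_p(htest$p_raw),
      c2 = if (s1$model == 2L) fmt_est(fit$c2, fit$c2_se) else NA_MARK,
      c2_p = if (nrow(hh)) fmt_p(hh$p_raw) else NA_MARK,
      covariate_r2 = sprintf("%.2f", r$prep$r_squared))
  }))
  t3 <- do.call(rbind, lapply(res, function(r) {
    p <- if (!is.null(r$error)) NA
         else if (is.null(r$stage2)) NA else r$stage2$test$p_adjusted
    data.frame(trait = r$trait, p_adjusted = fmt_p(p))
  }))
  t4 <- do.call(rbind, lapply(res, function(r) {
    if (!is.null(r$error) || is.null(r$stage3)) return(NULL)
    s3 <- r$stage3
    getp <- function(par) {
      i <- match(par, s3$name)
      if (is.na(i)) NA else s3$p_adjusted[i]
    }
    data.frame(trait = r$trait,
               homog_genetic_variance = fmt_p(getp("gamma_g")),
               homog_residual_variance = fmt_p(getp("gamma_e")),
               homog_household_variance = fmt_p(getp("gamma_c")),
               genetic_correlation_eq_1 = fmt_p(getp("lambda_g")),
               household_correlation_eq_1 = fmt_p(getp("lambda_c")))
  }))
  if (is.null(t4)) {
    t4 <- data.frame(trait = character(0),
                     homog_genetic_variance = character(0),
                     homog_residual_variance = character(0),
                     homog_household_variance = character(0),
                     genetic_correlation_eq_1 = character(0),
                     household_correlation_eq_1 = character(0))
  }
  paths <- file.path(outdir, c("heritability.csv", "gxe_joint.csv",
                               "gxe_components.csv"))
  utils::write.csv(t2, paths[1L], row.names = FALSE, quote = FALSE)
  utils::write.csv(t3, paths[2L], row.names = FALSE, quote = FALSE)
  utils::write.csv(t4, paths[3L], row.names = FALSE, quote = FALSE)
  invisible(paths)
}

#' Export variance-function grids and genetic covariance surfaces
#'
#' For each trait with a fitted GxE model: the component variance curves
#' over the environment grid (`component,z,value`; the total is the sum of
#' the active components) and the additive genetic covariance surface
#' (`z_i,z_j,cov`).
#'
#' @param panel a `gxe_panel`.
#' @param outdir output directory.
#' @param z_from,z_to,z_by grid limits and step (standardized environment
#'   units).
#' @return Invisibly, the written file paths.
#' @export
export_function_grids <- function(panel, outdir, z_from = -3, z_to = 3,
                                  z_by = 0.1) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  grid <- seq(z_from, z_to, by = z_by)
  paths <- character(0)
  for (r in panel$results) {
    if (!is.null(r$error) || is.null(r$stage2)) next
    fit <- r$stage2$fit_full
    fg <- function_grid(fit$params, fit$spec, grid)
    p1 <- file.path(outdir, paste0(r$trait, "_curves.csv"))
    utils::write.csv(fg$curves, p1, row.names = FALSE, quote = FALSE)
    paths <- c(paths, p1)
    if (!is.null(fg$surface)) {
      p2 <- file.path(outdir, paste0(r$trait, "_surface.csv"))
      utils::write.csv(fg$surface, p2, row.names = FALSE, quote = FALSE)
      paths <- c(paths, p2)
    }
  }
  invisible(paths)
}

#' Write the run manifest
#'
#' @param panel a `gxe_panel`.
#' @param path output YAML path.
#' @return Invisibly, the path.
#' @export
write_manifest <- function(panel, path) {
  yaml::write_yaml(panel$manifest, path)
  invisible(path)
}

#' @export
print.gxe_panel <- function(x, ...) {
  res <- x$results
  cat("GxE panel:", length(res), "traits\n")
  for (r in res) {
    if (!is.null(r$error)) {
      cat("  ", r$trait, ": ERROR (", r$error, ")\n", sep = "")
    } else {
      cat(sprintf("  %s: n=%d model=%d h2=%.2f%s\n", r$trait, r$data$n,
                  r$stage1$model, r$stage1$fit$h2,
                  if (!is.null(r$stage2))
                    sprintf(" gxe_p_adj=%s", fmt_p(r$stage2$test$p_adjusted))
                  else " (not heritable)"))
    }
  }
  invisible(x)
}
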