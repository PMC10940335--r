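# Synthetic pedigree / phenotype generator.
#
# Emulates the structure of an extended-family study of Mexican American
# households: ~42 three-generation families recruited around a founder
# couple, offspring who marry in spouses and have children, nuclear-family
# household assignment, a household-clustered standardized SES index, and
# traits drawn from the GxE variance-components model itself (so every
# pipeline stage can be validated by parameter recovery).

#' Simulation scenario
#'
#' @param n_families number of extended families.
#' @param mean_sibship mean sibship size; sibships are `1 + Poisson(mean - 1)`.
#' @param marry_prob probability that a second-generation offspring marries
#'   (bringing in a founder spouse) and reproduces.
#' @param generations pedigree depth (2 or 3; default 3).
#' @param tau SD of the household-level SES component; individual-level SD
#'   is 1, and the final index is standardized, so `tau` controls
#'   within-household SES clustering (`tau = 0`: none).
#' @param params true [gxe_params] for trait generation.
#' @param spec [gxe_spec] declaring the active components of the truth.
#' @param beta_age,beta_sex mean-model effects of age (per year) and sex
#'   (female contrast); default 0, i.e. traits emulate already-residualized
#'   normalized values.
#' @param prop_female probability an individual is female.
#' @param exclusion_rate probability an individual carries an exclusion
#'   flag (disease/medication), default 0.
#' @param seed integer seed; fully determines the output.
#' @return An object of class `sim_scenario`.
#' @export
sim_scenario <- function(n_families = 42L, mean_sibship = 4.5,
                         marry_prob = 0.9,
                         generations = 3L, tau = 1,
                         params = gxe_params(alpha_g = log(0.45),
                                             alpha_e = log(0.55)),
                         spec = gxe_spec(free = c("alpha_g", "alpha_e")),
                         beta_age = 0, beta_sex = 0,
                         prop_female = 0.57, exclusion_rate = 0,
                         seed = 1L) {
  stopifnot(n_families >= 1L, mean_sibship >= 1, generations %in% 2:3,
            tau >= 0, marry_prob >= 0, marry_prob <= 1)
  structure(list(n_families = as.integer(n_families),
                 mean_sibship = mean_sibship, marry_prob = marry_prob,
                 generations = as.integer(generations), tau = tau,
                 params = params, spec = spec,
                 beta_age = beta_age, beta_sex = beta_sex,
                 prop_female = prop_female,
                 exclusion_rate = exclusion_rate,
                 seed = as.integer(seed)),
            class = "sim_scenario")
}

draw_sex <- function(n, prop_female) {
  ifelse(stats::runif(n) < prop_female, "F", "M")
}

# Internal: generate one family's records starting at id counter `base`.
sim_family <- function(fam, scenario) {
  pid <- function(k) sprintf("F%02d-I%03d", fam, k)
  hid <- function(k) sprintf("F%02d-H%02d", fam, k)
  k <- 0L
  nxt <- function() {
    k <<- k + 1L
    pid(k)
  }
  rec <- list()
  add <- function(id, father, mother, sex, household) {
    rec[[length(rec) + 1L]] <<- data.frame(
      id = id, father = father, mother = mother, sex = sex,
      household = household, stringsAsFactors = FALSE)
  }
  h <- 0L
  nxt_h <- function() {
    h <<- h + 1L
    hid(h)
  }
  home0 <- nxt_h()
  dad <- nxt()
  mom <- nxt()
  add(dad, NA, NA, "M", home0)
  add(mom, NA, NA, "F", home0)
  nsib <- 1L + stats::rpois(1L, scenario$mean_sibship - 1)
  for (s in seq_len(nsib)) {
    child <- nxt()
    sex <- draw_sex(1L, scenario$prop_female)
    marries <- scenario$generations >= 3L &&
      stats::runif(1L) < scenario$marry_prob
    if (!marries) {
      add(child, dad, mom, sex, home0)  # stays in the parental household
    } else {
      home <- nxt_h()
      add(child, dad, mom, sex, home)
      spouse <- nxt()
      add(spouse, NA, NA, if (sex == "M") "F" else "M", home)
      ngc <- 1L + stats::rpois(1L, scenario$mean_sibship - 1)
      f <- if (sex == "M") child else spouse
      m <- if (sex == "M") spouse else child
      for (g in seq_len(ngc)) {
        add(nxt(), f, m, draw_sex(1L, scenario$prop_female), home)
      }
    }
  }
  do.call(rbind, rec)
}

#' Simulate an extended-family pedigree
#'
#' Per family: a founder couple, a Poisson-distributed sibship of
#' offspring, spouses married in as new founders, and grandchildren.
#' Households follow nuclear families: the founder couple keeps unmarried
#' offspring; each married offspring founds a household with spouse and
#' children.  Deterministic given `scenario$seed`.
#'
#' @param scenario a [sim_scenario].
#' @return A [pedigree].
#' @export
simulate_pedigree <- function(scenario) {
  set.seed(scenario$seed)
  simulate_pedigree_impl(scenario)
}

simulate_pedigree_impl <- function(scenario) {
  recs <- do.call(rbind, lapply(seq_len(scenario$n_families), sim_family,
                                scenario = scenario))
  pedigree(id = recs$id, father = recs$father, mother = recs$mother,
           sex = recs$sex, household = recs$household)
}

#' Simulate a household-clustered standardized SES index
#'
#' `z_i = standardize(u_{household(i)} + v_i)` with `u ~ N(0, tau^2)` per
#' household and `v ~ N(0, 1)` per individual; the output has sample mean
#' 0 and SD 1.  Individuals without a household id get only the individual
#' term.
#'
#' @param ped a [pedigree].
#' @param scenario a [sim_scenario] (uses `tau`); the caller controls the
#'   RNG state.
#' @return List with `zses` (standardized) and `raw` (pre-standardization
#'   latent value, useful for emitting consistent SEI/education columns).
#' @export
simulate_zses <- function(ped, scenario) {
  hh <- ped$household
  u <- stats::setNames(stats::rnorm(length(unique(hh[!is.na(hh)])),
                                    0, scenario$tau),
                       unique(hh[!is.na(hh)]))
  raw <- stats::rnorm(nrow(ped), 0, 1)
  has_h <- !is.na(hh)
  raw[has_h] <- raw[has_h] + u[hh[has_h]]
  list(zses = standardize(raw), raw = raw)
}

#' Simulate a trait under the GxE variance-components model
#'
#' Per family block: `y_b = X_b beta + L_b eps` with `L_b` the Cholesky
#' factor of the block covariance from [build_covariance()] at the true
#' parameters and `eps` iid standard normal.
#'
#' @param ped a [pedigree].
#' @param z standardized environment vector (pedigree order).
#' @param X mean-model design matrix (pedigree order), or `NULL` for a
#'   zero mean.
#' @param scenario a [sim_scenario] (truth `params`, `spec`); caller
#'   controls the RNG state.
#' @return Numeric trait vector in pedigree order.
#' @export
simulate_trait <- function(ped, z, X = NULL, scenario) {
  blocks <- family_blocks(ped)
  y <- numeric(nrow(ped))
  names(y) <- ped$id
  for (ids in blocks) {
    ii <- match(ids, ped$id)
    sub <- ped[ii, , drop = FALSE]
    class(sub) <- c("pedigree", "data.frame")
    omega <- build_covariance(scenario$params, scenario$spec,
                              kin = compute_kinship(sub),
                              hh = household_matrix(sub), z = z[ii])
    L <- tryCatch(chol(omega), error = function(e) {
      stop("covariance not positive definite in block containing '",
           ids[1L], "' at the given parameters", call. = FALSE)
    })
    y[ii] <- crossprod(L, stats::rnorm(length(ii)))
  }
  mu <- if (is.null(X)) 0 else drop(X %*% attr(X, "beta"))
  unname(y) + mu
}

#' Simulate a complete dataset (pedigree + phenotype table)
#'
#' Runs the pedigree, SES, covariate and trait generators under one seed.
#' The phenotype table carries `sei` and `education` columns constructed
#' so that [zses_score()] reproduces the simulated `zses` exactly (both
#' are affine in the latent SES value), plus `age` (uniform 18-94), `sex`,
#' an exclusion flag column, and one column per requested trait.
#'
#' @param scenario a [sim_scenario].
#' @param traits named list of `list(params =, spec =)` truths, one per
#'   trait column; defaults to a single column `trait` drawn under the
#'   scenario's own truth.
#' @return List with `ped` (a [pedigree]) and `pheno` (data frame).
#' @export
simulate_dataset <- function(scenario, traits = NULL) {
  set.seed(scenario$seed)
  ped <- simulate_pedigree_impl(scenario)
  zs <- simulate_zses(ped, scenario)
  n <- nrow(ped)
  age <- round(stats::runif(n, 18, 94))
  excl <- as.integer(stats::runif(n) < scenario$exclusion_rate)
  pheno <- data.frame(
    id = ped$id,
    sex = ped$sex,
    age = age,
    sei = 40 + 12 * zs$raw,
    education = 12 + 3 * zs$raw,
    zses = zs$zses,
    excl_flag = excl,
    stringsAsFactors = FALSE)
  if (is.null(traits)) {
    traits <- list(trait = list(params = scenario$params,
                                spec = scenario$spec))
  }
  for (nm in names(traits)) {
    sc <- scenario
    sc$params <- traits[[nm]]$params
    sc$spec <- traits[[nm]]$spec
    X <- cbind(age = age, sexF = as.numeric(ped$sex == "F"))
    attr(X, "beta") <- c(scenario$beta_age, scenario$beta_sex)
    pheno[[nm]] <- simulate_trait(ped, zs$zses, X, sc)
  }
  list(ped = ped, pheno = pheno)
}

#' Named preset scenarios
#'
#' Stable presets covering the study conditions the generator emulates:
#' \describe{
#'   \item{null}{no genetic variance (residual only, unit variance).}
#'   \item{polygenic}{homogeneous h2 = 0.45 (genetic 0.45 / residual 0.55
#'     on the unit-variance scale).}
#'   \item{variance-het}{genetic variance decreasing in the environment
#'     (`gamma_g = -0.5`) with correlation decay `lambda_g = 0.3`.}
#'   \item{corr-decay}{homogeneous variances with genetic correlation
#'     decay `lambda_g = 0.5`.}
#'   \item{household-het}{household component (c2 = 0.11 at z = 0, h2 =
#'     0.31) whose variance decreases in the environment
#'     (`gamma_c = -0.5`).}
#' }
#'
#' @param seed seed applied to every preset.
#' @return Named list of [sim_scenario] objects.
#' @export
scenario_presets <- function(seed = 1L) {
  base <- function(params, spec) {
    sim_scenario(params = params, spec = spec, seed = seed)
  }
  spec_g <- gxe_spec(free = c("alpha_g", "alpha_e"))
  spec_gxe <- gxe_spec(free = c("alpha_g", "gamma_g", "lambda_g",
                                "alpha_e", "gamma_e"))
  spec_hh <- gxe_spec(household = TRUE,
                      free = c("alpha_g", "alpha_e",
                               "alpha_c", "gamma_c", "lambda_c"))
  list(
    "null" = base(gxe_params(alpha_e = 0),
                  gxe_spec(genetic = FALSE, free = "alpha_e")),
    "polygenic" = base(gxe_params(alpha_g = log(0.45), alpha_e = log(0.55)),
                       spec_g),
    "variance-het" = base(gxe_params(alpha_g = log(0.45), gamma_g = -0.5,
                                     lambda_g = 0.3,
                                     alpha_e = log(0.55)),
                          spec_gxe),
    "corr-decay" = base(gxe_params(alpha_g = log(0.45), lambda_g = 0.5,
                                   alpha_e = log(0.55)),
                        spec_gxe),
    "household-het" = base(gxe_params(alpha_g = log(0.31),
                                      alpha_c = log(0.11), gamma_c = -0.5,
                                      alpha_e = log(0.58)),
                           spec_hh))
}

#' Write a simulated dataset to pedigree and phenotype files
#'
#' Emits the same comma-delimited dialects [read_pedigree()] and the
#' pipeline read.  Byte-identical across repeated runs with the same
#' scenario.
#'
#' @param dataset result of [simulate_dataset()].
#' @param ped_path,pheno_path output CSV paths.
#' @return Invisibly, the two paths.
#' @export
write_dataset <- function(dataset, ped_path, pheno_path) {
  ped_out <- as.data.frame(dataset$ped)
  ped_out$father[is.na(ped_out$father)] <- "NA"
  ped_out$mother[is.na(ped_out$mother)] <- "NA"
  utils::write.csv(ped_out, ped_path, row.names = FALSE, quote = FALSE)
  ph <- dataset$pheno
  num <- vapply(ph, is.numeric, logical(1))
  ph[num] <- lapply(ph[num], function(x) formatC(x, digits = 10,
                                                 format = "g"))
  utils::write.csv(ph, pheno_path, row.names = FALSE, quote = FALSE)
  invisible(c(ped_path, pheno_path))
}
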