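# Independent oracles and small fixtures used across the suite.

# Dense multivariate-normal log density, coded independently of the
# package's blocked Cholesky path (determinant + solve).
dense_mvn_loglik <- function(y, mu, omega) {
  r <- y - mu
  ld <- as.numeric(determinant(omega, logarithm = TRUE)$modulus)
  -0.5 * (length(y) * log(2 * pi) + ld + drop(crossprod(r, solve(omega, r))))
}

# Element-wise GxE covariance, written directly from the definition
# (independent of build_covariance's vectorized assembly).
elementwise_covariance <- function(params, spec, kin, hh, z) {
  p <- params$par
  n <- length(z)
  omega <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (spec$genetic) {
        vg_i <- exp(p[["alpha_g"]] + p[["gamma_g"]] * z[i])
        vg_j <- exp(p[["alpha_g"]] + p[["gamma_g"]] * z[j])
        rho <- exp(-p[["lambda_g"]] * abs(z[i] - z[j]))
        omega[i, j] <- omega[i, j] + kin[i, j] * sqrt(vg_i * vg_j) * rho
      }
      if (spec$household) {
        vc_i <- exp(p[["alpha_c"]] + p[["gamma_c"]] * z[i])
        vc_j <- exp(p[["alpha_c"]] + p[["gamma_c"]] * z[j])
        rho <- exp(-p[["lambda_c"]] * abs(z[i] - z[j]))
        omega[i, j] <- omega[i, j] + hh[i, j] * sqrt(vc_i * vc_j) * rho
      }
      if (i == j) {
        omega[i, j] <- omega[i, j] + exp(p[["alpha_e"]] + p[["gamma_e"]] * z[i])
      }
    }
  }
  omega
}

# Gene-dropping Monte-Carlo kinship: founders carry unique allele labels,
# children inherit one random allele from each parent; phi is the IBD
# probability of two randomly drawn alleles, estimated across replicates
# (vectorized over replicates).
gene_drop_kinship <- function(ped, reps = 1e5) {
  n <- nrow(ped)
  idx <- seq_len(n)
  names(idx) <- ped$id
  fidx <- unname(idx[ped$father])
  midx <- unname(idx[ped$mother])
  ord <- gxevc:::pedigree_order(ped)
  A1 <- vector("list", n)
  A2 <- vector("list", n)
  for (i in ord) {
    if (is.na(fidx[i])) {
      A1[[i]] <- rep.int(2L * i - 1L, reps)
      A2[[i]] <- rep.int(2L * i, reps)
    } else {
      pick <- stats::runif(reps) < 0.5
      A1[[i]] <- ifelse(pick, A1[[fidx[i]]], A2[[fidx[i]]])
      pick <- stats::runif(reps) < 0.5
      A2[[i]] <- ifelse(pick, A1[[midx[i]]], A2[[midx[i]]])
    }
  }
  two_phi <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  se <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  for (i in seq_len(n)) {
    for (j in i:n) {
      share <- ((A1[[i]] == A1[[j]]) + (A1[[i]] == A2[[j]]) +
                (A2[[i]] == A1[[j]]) + (A2[[i]] == A2[[j]])) / 4
      two_phi[i, j] <- two_phi[j, i] <- 2 * mean(share)
      se[i, j] <- se[j, i] <- 2 * stats::sd(share) / sqrt(reps)
    }
  }
  list(two_phi = two_phi, se = se)
}

# Random multi-generation pedigree of at most `max_n` individuals, with
# random household labels; used for property tests.
random_pedigree <- function(max_n = 12, households = TRUE) {
  n_founders <- sample(2:4, 1)
  id <- paste0("f", seq_len(n_founders))
  father <- mother <- rep(NA_character_, n_founders)
  sex <- rep(c("M", "F"), length.out = n_founders)
  while (length(id) < max_n) {
    males <- id[sex == "M"]
    females <- id[sex == "F"]
    if (!length(males) || !length(females)) break
    f <- sample(males, 1)
    m <- sample(females, 1)
    # avoid mating an individual with its own descendant (keep acyclic)
    anc <- function(x) {
      out <- character(0)
      stack <- x
      while (length(stack)) {
        cur <- stack[1]
        stack <- stack[-1]
        i <- match(cur, id)
        for (p in c(father[i], mother[i])) {
          if (!is.na(p)) {
            out <- c(out, p)
            stack <- c(stack, p)
          }
        }
      }
      out
    }
    if (f %in% anc(m) || m %in% anc(f)) next
    kid <- paste0("k", length(id) + 1)
    id <- c(id, kid)
    father <- c(father, f)
    mother <- c(mother, m)
    sex <- c(sex, sample(c("M", "F"), 1))
    if (stats::runif(1) < 0.3 && length(id) < max_n) {
      # marry in a founder now and then
      new <- paste0("s", length(id) + 1)
      id <- c(id, new)
      father <- c(father, NA)
      mother <- c(mother, NA)
      sex <- c(sex, sample(c("M", "F"), 1))
    }
  }
  hh <- if (households) paste0("h", sample(1:3, length(id), replace = TRUE))
        else NA
  pedigree(id = id, father = father, mother = mother, sex = sex,
           household = hh)
}

# Random valid GxE parameters for property tests.
random_params <- function(household = FALSE) {
  gxe_params(alpha_g = stats::runif(1, -1.5, 0.5),
             gamma_g = stats::runif(1, -0.8, 0.8),
             lambda_g = stats::rexp(1, 4),
             alpha_e = stats::runif(1, -1.5, 0.5),
             gamma_e = stats::runif(1, -0.8, 0.8),
             alpha_c = if (household) stats::runif(1, -2.5, -0.5) else 0,
             gamma_c = if (household) stats::runif(1, -0.8, 0.8) else 0,
             lambda_c = if (household) stats::rexp(1, 4) else 0)
}

# Small three-generation fixture: grandparents, two married children,
# one grandchild each; first cousins c1 x c2.
cousin_pedigree <- function() {
  pedigree(
    id = c("gf", "gm", "a", "b", "sa", "sb", "c1", "c2"),
    father = c(NA, NA, "gf", "gf", NA, NA, "a", "sb"),
    mother = c(NA, NA, "gm", "gm", NA, NA, "sa", "b"),
    sex = c("M", "F", "M", "F", "F", "M", "F", "M"),
    household = c("h1", "h1", "h2", "h3", "h2", "h3", "h2", "h3"))
}
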