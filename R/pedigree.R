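# Pedigree ingestion, kinship and household structure.

MISSING_TOKENS <- c("", "0", "NA")

#' Construct and validate a pedigree
#'
#' A pedigree holds one record per individual with optional parent links,
#' sex, and an optional household assignment.  Founders have both parents
#' missing; non-founders have both parents named and present in the
#' pedigree; the parent-offspring graph must be acyclic.
#'
#' @param id character vector of unique individual identifiers.
#' @param father,mother character vectors of parent identifiers; `NA` for
#'   founders.  An individual must have either zero or two named parents.
#' @param sex character vector, `"M"` or `"F"`.
#' @param household optional character vector of household identifiers
#'   (`NA` = household unknown).
#' @return An object of class `pedigree`: a data frame with columns
#'   `id`, `father`, `mother`, `sex`, `household`.
#' @examples
#' ped <- pedigree(id = c("p1", "p2", "k1"),
#'                 father = c(NA, NA, "p1"),
#'                 mother = c(NA, NA, "p2"),
#'                 sex = c("M", "F", "F"),
#'                 household = c("h1", "h1", "h1"))
#' n_founders(ped)
#' @export
pedigree <- function(id, father = NA, mother = NA, sex = "F", household = NA) {
  n <- length(id)
  df <- data.frame(
    id = as.character(id),
    father = rep_len(as.character(father), n),
    mother = rep_len(as.character(mother), n),
    sex = rep_len(as.character(sex), n),
    household = rep_len(as.character(household), n),
    stringsAsFactors = FALSE
  )
  df$father[df$father %in% MISSING_TOKENS] <- NA_character_
  df$mother[df$mother %in% MISSING_TOKENS] <- NA_character_
  df$household[df$household %in% MISSING_TOKENS] <- NA_character_
  validate_pedigree(df)
  class(df) <- c("pedigree", "data.frame")
  df
}

validate_pedigree <- function(df) {
  if (anyDuplicated(df$id)) {
    dup <- df$id[duplicated(df$id)][1L]
    stop("duplicate individual id: '", dup, "'", call. = FALSE)
  }
  one_parent <- xor(is.na(df$father), is.na(df$mother))
  if (any(one_parent)) {
    stop("individual '", df$id[one_parent][1L],
         "' has exactly one named parent; pedigrees require zero or two",
         call. = FALSE)
  }
  for (col in c("father", "mother")) {
    known <- !is.na(df[[col]])
    missing_parent <- known & !(df[[col]] %in% df$id)
    if (any(missing_parent)) {
      i <- which(missing_parent)[1L]
      stop(col, " '", df[[col]][i], "' of individual '", df$id[i],
           "' is not in the pedigree", call. = FALSE)
    }
  }
  bad_sex <- !(df$sex %in% c("M", "F"))
  if (any(bad_sex)) {
    stop("unknown sex code '", df$sex[bad_sex][1L], "' for individual '",
         df$id[bad_sex][1L], "' (expected \"M\" or \"F\")", call. = FALSE)
  }
  # acyclicity via Kahn's algorithm; also yields the evaluation order
  if (is.null(pedigree_order(df))) {
    stop("pedigree contains a cycle (an individual is its own ancestor)",
         call. = FALSE)
  }
  invisible(df)
}

# Topological order with parents before offspring, or NULL if cyclic.
pedigree_order <- function(df) {
  n <- nrow(df)
  idx <- seq_len(n)
  names(idx) <- df$id
  fidx <- unname(idx[df$father])
  midx <- unname(idx[df$mother])
  indeg <- integer(n)
  children <- vector("list", n)
  for (i in idx) {
    for (p in c(fidx[i], midx[i])) {
      if (!is.na(p)) {
        indeg[i] <- indeg[i] + 1L
        children[[p]] <- c(children[[p]], i)
      }
    }
  }
  queue <- which(indeg == 0L)
  ord <- integer(0)
  while (length(queue)) {
    i <- queue[1L]
    queue <- queue[-1L]
    ord <- c(ord, i)
    for (ch in children[[i]]) {
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) queue <- c(queue, ch)
    }
  }
  if (length(ord) < n) NULL else ord
}

#' Read a pedigree from a delimited text file
#'
#' Accepts comma- or tab-delimited files with a header row.  Missing-parent
#' and missing-household tokens `""`, `"0"` and `"NA"` are normalized to
#' missing.  Sex may be coded `"M"`/`"F"` or `1`/`2` (1 = male).
#'
#' @param path path to the pedigree file.
#' @param dialect named list mapping the canonical column names `id`,
#'   `father`, `mother`, `sex`, `household` to the column names used in the
#'   file.  Columns absent from the list keep their canonical name;
#'   `household` is optional in the file.
#' @param sex_codes named character vector mapping file codes to `"M"`/`"F"`.
#' @return A [pedigree] object.
#' @export
read_pedigree <- function(path,
                          dialect = list(),
                          sex_codes = c("M" = "M", "F" = "F",
                                        "1" = "M", "2" = "F")) {
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          colClasses = "character",
                          na.strings = "NA", stringsAsFactors = FALSE)
  cols <- list(id = "id", father = "father", mother = "mother",
               sex = "sex", household = "household")
  cols[names(dialect)] <- dialect
  for (need in c("id", "father", "mother", "sex")) {
    if (!cols[[need]] %in% names(df)) {
      stop("pedigree file lacks required column '", cols[[need]], "'",
           call. = FALSE)
    }
  }
  hh <- if (cols$household %in% names(df)) df[[cols$household]] else NA
  sex_raw <- df[[cols$sex]]
  sex <- unname(sex_codes[sex_raw])
  sex[is.na(sex)] <- sex_raw[is.na(sex)]  # let the validator report it
  pedigree(id = df[[cols$id]], father = df[[cols$father]],
           mother = df[[cols$mother]], sex = sex, household = hh)
}

#' Number of founders in a pedigree
#' @param ped a [pedigree].
#' @return Integer count of individuals with both parents missing.
#' @export
n_founders <- function(ped) sum(is.na(ped$father) & is.na(ped$mother))

#' Additive relationship (2 * kinship) matrix
#'
#' Computes kinship coefficients by the standard recursion over individuals
#' sorted so parents precede offspring: for founders `phi_ii = 1/2`, for a
#' non-founder with parents (f, m) `phi_ii = (1 + phi_fm) / 2` (so inbreeding
#' inflates the diagonal) and `phi_ij = (phi_jf + phi_jm) / 2` for any j
#' processed before i.  The returned matrix holds the additive relationship
#' `2 * phi`, the coefficient that scales the additive genetic covariance
#' between relatives under the polygenic model.
#'
#' @param ped a [pedigree].
#' @return A symmetric numeric matrix with dimnames equal to the individual
#'   ids; diagonal `1 + F` (inbreeding coefficient F), entries in `[0, 2]`.
#' @examples
#' ped <- pedigree(id = c("f", "m", "c"), father = c(NA, NA, "f"),
#'                 mother = c(NA, NA, "m"), sex = c("M", "F", "F"))
#' compute_kinship(ped)["f", "c"]  # parent-offspring: 0.5
#' @export
compute_kinship <- function(ped) {
  n <- nrow(ped)
  idx <- seq_len(n)
  names(idx) <- ped$id
  fidx <- unname(idx[ped$father])
  midx <- unname(idx[ped$mother])
  ord <- pedigree_order(ped)
  phi <- matrix(0, n, n)
  done <- integer(0)
  for (i in ord) {
    f <- fidx[i]
    m <- midx[i]
    if (is.na(f)) {
      phi[i, i] <- 0.5
    } else {
      if (length(done)) {
        row <- 0.5 * (phi[f, done] + phi[m, done])
        phi[i, done] <- row
        phi[done, i] <- row
      }
      phi[i, i] <- 0.5 * (1 + phi[f, m])
    }
    done <- c(done, i)
  }
  phi <- 2 * phi
  dimnames(phi) <- list(ped$id, ped$id)
  phi
}

#' Household sharing indicator matrix
#'
#' `H[i, j] = 1` when i and j share a household id.  Individuals with a
#' missing household id get an all-zero row and column, including the
#' diagonal, so they contribute no household variance.
#'
#' @param ped a [pedigree].
#' @return A symmetric 0/1 matrix with id dimnames.
#' @export
household_matrix <- function(ped) {
  n <- nrow(ped)
  hh <- ped$household
  H <- matrix(0, n, n)
  for (members in split(seq_len(n)[!is.na(hh)], hh[!is.na(hh)])) {
    H[members, members] <- 1
  }
  dimnames(H) <- list(ped$id, ped$id)
  H
}

#' Family blocks: connected components of pedigree and household links
#'
#' The phenotypic covariance matrix is block diagonal over the connected
#' components of the union of the parent-offspring graph and the shared-
#' household graph (household effects correlate individuals across nuclear
#' families), so the likelihood factorizes over these blocks.
#'
#' @param ped a [pedigree].
#' @return A list of disjoint character vectors of ids, jointly covering
#'   every individual.
#' @export
family_blocks <- function(ped) {
  n <- nrow(ped)
  idx <- seq_len(n)
  names(idx) <- ped$id
  parent <- idx  # union-find
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  union <- function(i, j) {
    ri <- find(i)
    rj <- find(j)
    if (ri != rj) parent[rj] <<- ri
    invisible(NULL)
  }
  fidx <- unname(idx[ped$father])
  midx <- unname(idx[ped$mother])
  for (i in idx) {
    if (!is.na(fidx[i])) union(i, fidx[i])
    if (!is.na(midx[i])) union(i, midx[i])
  }
  hh <- ped$household
  for (members in split(seq_len(n)[!is.na(hh)], hh[!is.na(hh)])) {
    if (length(members) > 1L) {
      for (m in members[-1L]) union(members[1L], m)
    }
  }
  roots <- vapply(idx, find, integer(1))
  unname(lapply(split(ped$id, roots), as.character))
}

#' Export nonzero kinship entries in long format
#'
#' @param kin matrix from [compute_kinship()].
#' @param path output CSV path (`id1,id2,k2`), upper triangle including the
#'   diagonal, nonzero entries only.
#' @return The data frame written, invisibly.
#' @export
write_kinship <- function(kin, path) {
  keep <- which(upper.tri(kin, diag = TRUE) & kin != 0, arr.ind = TRUE)
  out <- data.frame(id1 = rownames(kin)[keep[, 1L]],
                    id2 = colnames(kin)[keep[, 2L]],
                    k2 = kin[keep])
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(out)
}
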