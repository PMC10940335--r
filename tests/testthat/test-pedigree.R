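test_that("pedigree files are read, normalized and validated", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,father,mother,sex,household",
               "p1,0,NA,M,h1",
               "p2,,,F,h1",
               "k1,p1,p2,2,h1"), path)
  ped <- read_pedigree(path)
  expect_s3_class(ped, "pedigree")
  expect_equal(n_founders(ped), 2L)
  expect_identical(ped$sex, c("M", "F", "F"))
  expect_true(is.na(ped$father[2]))

  # tab-delimited dialect with renamed columns
  path2 <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("iid\tpa\tma\tsx", "x\t0\t0\t1", "y\t0\t0\t2", "z\tx\ty\t1"),
             path2)
  ped2 <- read_pedigree(path2, dialect = list(id = "iid", father = "pa",
                                              mother = "ma", sex = "sx"))
  expect_equal(nrow(ped2), 3L)
  expect_true(all(is.na(ped2$household)))
})

test_that("pedigree validation rejects malformed structures", {
  expect_error(pedigree(id = c("a", "a"), sex = "M"), "duplicate")
  expect_error(pedigree(id = c("a", "b"), father = c(NA, "ghost"),
                        mother = c(NA, "a"), sex = c("F", "M")),
               "not in the pedigree")
  expect_error(pedigree(id = c("a", "b"), father = c("b", NA),
                        mother = c(NA, NA), sex = "M"),
               "one named parent")
  # two-individual cycle: each is the other's parent
  expect_error(pedigree(id = c("a", "b", "c"),
                        father = c("b", "a", NA),
                        mother = c("c", "c", NA),
                        sex = c("M", "M", "F")),
               "cycle")
  expect_error(pedigree(id = "a", sex = "X"), "sex")
})

test_that("kinship recursion reproduces the classical coefficients", {
  ped <- pedigree(
    id = c("f", "m", "m2", "s1", "s2", "h1"),
    father = c(NA, NA, NA, "f", "f", "f"),
    mother = c(NA, NA, NA, "m", "m", "m2"),
    sex = c("M", "F", "F", "M", "F", "M"))
  K <- compute_kinship(ped)
  expect_equal(K["f", "s1"], 0.5)    # parent-offspring
  expect_equal(K["s1", "s2"], 0.5)   # full sibs
  expect_equal(K["s1", "h1"], 0.25)  # half sibs
  expect_equal(K["m", "m2"], 0)      # unrelated founders
  expect_equal(unname(diag(K)), rep(1, 6))

  expect_equal(compute_kinship(cousin_pedigree())["c1", "c2"], 0.125)
})

test_that("kinship handles inbreeding loops on the diagonal", {
  # full-sib mating: offspring has F = 1/4, diagonal 1.25
  ped <- pedigree(id = c("f", "m", "s1", "s2", "i"),
                  father = c(NA, NA, "f", "f", "s1"),
                  mother = c(NA, NA, "m", "m", "s2"),
                  sex = c("M", "F", "M", "F", "F"))
  K <- compute_kinship(ped)
  expect_equal(K["i", "i"], 1.25)
})

test_that("kinship agrees with the gene-dropping Monte-Carlo oracle", {
  set.seed(42)
  K <- compute_kinship(cousin_pedigree())
  gd <- gene_drop_kinship(cousin_pedigree(), reps = 2e4)
  expect_lt(abs(K["c1", "c2"] - gd$two_phi["c1", "c2"]),
            3 * gd$se["c1", "c2"])
  # rate-based band: with hundreds of simultaneous pair comparisons a
  # fixed 3-SE band is exceeded by chance ~0.3% of the time
  n_pairs <- 0L
  n_beyond <- 0L
  worst_z <- 0
  for (rep in 1:5) {
    ped <- random_pedigree(max_n = 12)
    K <- compute_kinship(ped)
    gd <- gene_drop_kinship(ped, reps = 2e4)
    off <- which(upper.tri(K) & gd$se > 0, arr.ind = TRUE)
    z <- abs(K[off] - gd$two_phi[off]) / gd$se[off]
    n_pairs <- n_pairs + length(z)
    n_beyond <- n_beyond + sum(z > 3)
    worst_z <- max(worst_z, z)
  }
  expect_lte(n_beyond / n_pairs, 0.01)
  expect_lt(worst_z, 5)
})

test_that("kinship is invariant to input row order and PSD by block", {
  set.seed(7)
  for (rep in 1:5) {
    ped <- random_pedigree(max_n = 10)
    K <- compute_kinship(ped)
    # shuffle rows (keeping validity: validation is order-free)
    perm <- sample(nrow(ped))
    ped2 <- pedigree(id = ped$id[perm], father = ped$father[perm],
                     mother = ped$mother[perm], sex = ped$sex[perm],
                     household = ped$household[perm])
    K2 <- compute_kinship(ped2)
    expect_equal(K2[rownames(K), colnames(K)], K)
    for (ids in family_blocks(ped)) {
      ev <- eigen(K[ids, ids, drop = FALSE], symmetric = TRUE,
                  only.values = TRUE)$values
      expect_gt(min(ev), -1e-8)
    }
  }
})

test_that("household matrix follows the stated conventions", {
  ped <- pedigree(id = c("a", "b", "c", "d"),
                  sex = "F", household = c("h1", "h1", "h2", NA))
  H <- household_matrix(ped)
  expect_equal(H["a", "b"], 1)
  expect_equal(H["a", "c"], 0)
  expect_equal(unname(diag(H)), c(1, 1, 1, 0))  # missing household: zero row
  expect_equal(sum(H["d", ]), 0)
  expect_equal(H, t(H))
})

test_that("family blocks merge pedigree and household connectivity", {
  trio <- function(tag, hh) {
    data.frame(id = paste0(tag, 1:3),
               father = c(NA, NA, paste0(tag, 1)),
               mother = c(NA, NA, paste0(tag, 2)),
               sex = c("M", "F", "F"), household = hh)
  }
  two <- rbind(trio("a", "h1"), trio("b", "h2"))
  ped <- pedigree(two$id, two$father, two$mother, two$sex, two$household)
  expect_length(family_blocks(ped), 2L)

  shared <- rbind(trio("a", "h1"), trio("b", "h1"))  # shared household
  ped2 <- pedigree(shared$id, shared$father, shared$mother, shared$sex,
                   shared$household)
  blocks <- family_blocks(ped2)
  expect_length(blocks, 1L)
  expect_setequal(blocks[[1]], ped2$id)

  single <- pedigree("solo", sex = "F")
  expect_equal(family_blocks(single), list("solo"))
})

test_that("kinship export round-trips nonzero entries", {
  path <- withr::local_tempfile(fileext = ".csv")
  K <- compute_kinship(cousin_pedigree())
  out <- write_kinship(K, path)
  back <- read.csv(path)
  expect_equal(nrow(back), sum(upper.tri(K, diag = TRUE) & K != 0))
  i <- which(back$id1 == "c1" & back$id2 == "c2" |
             back$id1 == "c2" & back$id2 == "c1")
  expect_equal(back$k2[i], 0.125)
})
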