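test_that("trio pedigree: sorting, founder creation and depths", {
  ped <- trio_ped()
  expect_s3_class(ped, "pedigree")
  expect_equal(attr(ped, "founder_count"), 2L)
  expect_equal(ped$generation[match("X", ped$id)], 1L)

  # implied founder auto-created from a CSV
  tf <- tempfile(fileext = ".csv")
  writeLines(c("id,sire,dam", "X,P,0"), tf)
  ped2 <- read_pedigree(tf)
  expect_true("P" %in% ped2$id)
  expect_equal(attr(ped2, "founder_count"), 1L)
  expect_equal(nrow(ped2), 2L)

  # sorted output regardless of input order
  sh <- as_pedigree(data.frame(id = c("X", "S", "D"),
                               sire = c("S", NA, NA), dam = c("D", NA, NA)))
  expect_true(match("X", sh$id) > max(match(c("S", "D"), sh$id)))
})

test_that("invalid pedigrees are rejected with informative errors", {
  expect_error(as_pedigree(data.frame(id = c("X", "Y"), sire = c("Y", "X"),
                                      dam = c("0", "0"))),
               "cycle.*X.*Y|cycle.*Y.*X")
  expect_error(as_pedigree(data.frame(id = c("A", "A"), sire = c("0", "0"),
                                      dam = c("0", "0"))),
               "duplicate")
  expect_error(as_pedigree(data.frame(id = "X", sire = "P", dam = "P")),
               "identical")
  expect_error(as_pedigree(data.frame(id = "X", sire = "X", dam = "0")),
               "own parent")
})

test_that("A carries the textbook relationships and invariants", {
  A <- build_A(trio_ped())
  expect_equal(A["X", "S"], 0.5)
  expect_equal(A["X", "D"], 0.5)
  expect_equal(A["X", "X"], 1)

  ped <- as_pedigree(data.frame(
    id = c("s1", "d1", "d2", "a", "b", "c"),
    sire = c(NA, NA, NA, "s1", "s1", "s1"),
    dam = c(NA, NA, NA, "d1", "d1", "d2")))
  A <- build_A(ped)
  expect_equal(A["a", "b"], 0.5)    # full sibs
  expect_equal(A["a", "c"], 0.25)   # paternal half sibs
  expect_true(all(A[upper.tri(A)] %in% c(0, 0.25, 0.5)))  # 2-gen, non-inbred
  expect_equal(unname(diag(A)), rep(1, 6))
  expect_equal(A, t(A))
  expect_true(min(eigen(A, symmetric = TRUE, only.values = TRUE)$values) > -1e-10)

  # offspring of two full sibs: F = 0.25
  ped3 <- as_pedigree(data.frame(
    id = c("s", "d", "a", "b", "x"),
    sire = c(NA, NA, "s", "s", "a"),
    dam = c(NA, NA, "d", "d", "b")))
  expect_equal(build_A(ped3)["x", "x"], 1.25)
  expect_equal(unname(inbreeding(ped3)[match("x", ped3$id)]), 0.25)
})

test_that("sparse A-inverse follows the Henderson rules and inverts A", {
  # founders only -> identity
  f <- as_pedigree(data.frame(id = c("a", "b", "c"), sire = NA, dam = NA))
  expect_equal(as.matrix(build_A_inverse(f)), diag(3),
               ignore_attr = TRUE)

  # single-offspring trio pattern
  Ai <- as.matrix(build_A_inverse(trio_ped()))
  expect_equal(unname(sort(diag(Ai))), c(1.5, 1.5, 2))
  expect_equal(Ai["X", "S"], -1)
  expect_equal(Ai["S", "D"], 0.5)

  # random deep pedigree (with inbreeding): A^-1 A = I to 1e-8
  ped <- random_pedigree(200, seed = 3)
  A <- build_A(ped)
  Ai <- build_A_inverse(ped)
  expect_lt(max(abs(as.matrix(Ai %*% A) - diag(nrow(ped)))), 1e-8)
})

test_that("family structure groups by shared parent pairs only", {
  fam <- family_structure(trio_ped())
  expect_equal(fam$n_families, 1L)
  expect_equal(fam$family_sizes, 1L)

  # shared dam, different sires -> two families
  ped <- as_pedigree(data.frame(
    id = c("s1", "s2", "d", "x", "y"),
    sire = c(NA, NA, NA, "s1", "s2"),
    dam = c(NA, NA, NA, "d", "d")))
  expect_equal(family_structure(ped)$n_families, 2L)

  # invariant to record order of the input
  df <- data.frame(id = c("s1", "d1", "d2", "a", "b", "c"),
                   sire = c(NA, NA, NA, "s1", "s1", "s1"),
                   dam = c(NA, NA, NA, "d1", "d1", "d2"))
  f1 <- family_structure(as_pedigree(df))
  f2 <- family_structure(as_pedigree(df[sample(nrow(df)), ]))
  expect_equal(f1$n_families, f2$n_families)
  expect_equal(sort(f1$family_sizes), sort(f2$family_sizes))
  ids <- sort(df$id)
  expect_equal(f1$family[ids], f2$family[ids])
})
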