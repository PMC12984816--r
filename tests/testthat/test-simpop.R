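test_that("design generator reconciles sire, dam and family counts", {
  ped <- sim_design(design_spec(), seed = 4)
  fam <- family_structure(ped)
  expect_equal(fam$n_families, 141L)
  expect_equal(fam$n_sires, 81L)
  expect_equal(fam$n_dams, 124L)
  expect_equal(sum(fam$family_sizes), 141L * 80L)

  # fully nested small case: every sire exactly two dams
  f2 <- family_structure(sim_design(design_spec(2, 4, 4, 5), seed = 1))
  expect_equal(f2$n_families, 4L)
  dam_per_sire <- table(sub("/.*", "", unique(stats::na.omit(f2$family))))
  expect_true(all(dam_per_sire == 2))

  # monogamous pairs: no half-sib links
  ped3 <- sim_design(design_spec(3, 3, 3, 5), seed = 1)
  A <- build_A(ped3)
  off <- ped3$id[!is.na(ped3$sire)]
  expect_true(all(A[off, off][A[off, off] > 0 & A[off, off] < 1] == 0.5))

  # infeasible triples rejected
  expect_error(design_spec(3, 8, 8), "infeasible")
  expect_error(design_spec(10, 4, 20), "infeasible")
})

test_that("breeding values follow the pedigree covariance", {
  spec <- small_spec()
  cal <- default_calibration()
  ped <- sim_design(spec, seed = 2)

  # zero genetic variance -> all zero
  bv0 <- simulate_breeding_values(ped, matrix(0, 1, 1,
                                              dimnames = list("t", "t")), seed = 5)
  expect_true(all(bv0 == 0))

  # seed reproducibility
  expect_identical(simulate_breeding_values(ped, cal$G, seed = 8),
                   simulate_breeding_values(ped, cal$G, seed = 8))

  # empirical covariances across replicates match the dense-A oracle
  A <- build_A(ped)
  off <- which(!is.na(ped$sire))
  G1 <- matrix(1, 1, 1, dimnames = list("t", "t"))
  reps <- 200
  a_mat <- sapply(seq_len(reps), function(r)
    simulate_breeding_values(ped, G1, seed = 1000 + r)[off, 1])
  emp <- tcrossprod(a_mat - rowMeans(a_mat)) / (reps - 1)
  Ao <- A[off, off]
  fs <- Ao == 0.5 & upper.tri(Ao)
  expect_equal(mean(emp[fs]), 0.5, tolerance = 0.12)
  expect_equal(mean(diag(emp)), 1, tolerance = 0.12)

  # cross-trait genetic correlation is reproduced
  G2 <- matrix(c(1, 0.9, 0.9, 1), 2, dimnames = list(c("a", "b"), c("a", "b")))
  bv2 <- simulate_breeding_values(sim_design(design_spec(), seed = 1), G2, seed = 3)
  expect_equal(stats::cor(bv2[, 1], bv2[, 2]), 0.9, tolerance = 0.02)

  expect_error(simulate_breeding_values(ped, matrix(c(1, 2, 2, 1), 2), seed = 1),
               "PSD")
})

test_that("phenotype model degenerates and conserves correctly", {
  spec <- small_spec()
  cal <- default_calibration()
  # zero variances and zero gender effects -> phenotype equals mu exactly
  cal0 <- cal
  cal0$G[] <- 0; cal0$E[] <- 1e-12 * diag(nrow(cal0$E))
  cal0$gender_delta[] <- 0
  ped <- sim_design(spec, seed = 3, sex_prob = cal$sex_prob)
  bv <- simulate_breeding_values(ped, cal0$G, seed = 3)
  phe <- simulate_phenotypes(ped, bv, cal0, seed = 3)
  expect_equal(mean(phe$SL_30, na.rm = TRUE), 76.68, tolerance = 1e-6)
  expect_equal(mean(phe$SL_6, na.rm = TRUE), 23.85, tolerance = 1e-6)
  expect_lt(stats::sd(phe$Tww, na.rm = TRUE), 1e-4)

  # conservation: family sizes sum to tagged count; no dead individual has
  # trait records
  pop <- sim_population(spec, cal, seed = 6)
  fam <- family_structure(pop$pedigree)
  expect_equal(sum(fam$family_sizes), nrow(pop$phenotypes))
  dead <- pop$phenotypes$survival == 0
  for (t_ in c("SL_6", "SL_30", "Tww", "Fc", "Mw", "My"))
    expect_true(all(is.na(pop$phenotypes[[t_]][dead])))

  # byte-identical under a fixed seed
  expect_identical(sim_population(spec, cal, seed = 11)$phenotypes,
                   sim_population(spec, cal, seed = 11)$phenotypes)

  # increasing cutpoints enforced
  calbad <- cal
  calbad$fc$cutpoints <- c(1, 0.5, 2)
  expect_error(simulate_phenotypes(ped, bv, calbad, seed = 1), "increasing")
})

test_that("sib phenotypic covariances match quantitative-genetic theory", {
  # single trait, known variances, no missingness noise beyond survival
  cal <- default_calibration()
  spec <- design_spec(n_sires = 30, n_dams = 45, n_families = 52,
                      offspring_per_family = 12)
  sa2 <- cal$G["SL_30", "SL_30"]
  covs_fs <- c(); covs_hs <- c()
  for (r in 1:10) {
    pop <- sim_population(spec, cal, seed = 100 + r)
    phe <- pop$phenotypes
    ok <- !is.na(phe$SL_30)
    d <- phe[ok, ]
    y <- d$SL_30 - stats::ave(d$SL_30, d$sex)
    fs <- outer(d$family, d$family, "==") & upper.tri(diag(nrow(d)))
    hs <- (outer(d$sire, d$sire, "==") & !outer(d$family, d$family, "==")) &
      upper.tri(diag(nrow(d)))
    yc <- y - mean(y)
    cp <- tcrossprod(yc)
    covs_fs <- c(covs_fs, mean(cp[fs]))
    covs_hs <- c(covs_hs, mean(cp[hs]))
  }
  expect_equal(mean(covs_fs), 0.5 * sa2, tolerance = 0.15 * sa2)
  expect_equal(mean(covs_hs), 0.25 * sa2, tolerance = 0.15 * sa2)
})

test_that("calibration structure is coherent", {
  cal <- default_calibration()
  # heritability fractions hold exactly by construction
  h2_implied <- diag(cal$G) / (diag(cal$G) + diag(cal$E))
  expect_equal(unname(h2_implied), cal$traits$h2, tolerance = 1e-10)
  # latent foot-color share equals the packaged value
  expect_equal(with(cal$fc, (sigma_s2 + sigma_d2) / (sigma_s2 + sigma_d2 + 1)),
               0.46, tolerance = 1e-10)
  # covariance matrices PSD
  expect_gt(min(eigen(cal$G, symmetric = TRUE, only.values = TRUE)$values), 0)
  expect_gt(min(eigen(cal$E, symmetric = TRUE, only.values = TRUE)$values), 0)
  # gender effects centred: population means unchanged
  expect_equal(max(abs(drop(cal$sex_prob %*% cal$gender_delta))), 0,
               tolerance = 1e-12)
  # cutpoints increasing
  expect_true(!is.unsorted(cal$fc$cutpoints, strictly = TRUE))
})

test_that("population round-trips through the plain-text interchange files", {
  pop <- sim_population(small_spec(), seed = 13)
  dir <- tempfile()
  paths <- write_population(pop, dir)
  ped2 <- read_pedigree(paths[1])
  expect_equal(nrow(ped2), nrow(pop$pedigree))
  phe2 <- utils::read.csv(paths[2])
  expect_equal(nrow(phe2), nrow(pop$phenotypes))
  expect_equal(phe2$Tww, pop$phenotypes$Tww, tolerance = 1e-12)
  truth <- jsonlite::read_json(paths[3], simplifyVector = TRUE)
  expect_equal(truth$fc_h2_latent, pop$truth$fc_h2_latent, tolerance = 1e-12)
})
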