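test_that("REML agrees with the balanced half-sib ANOVA estimator", {
  diffs <- sapply(1:5, function(r) {
    hs <- balanced_halfsib(ns = 20, k = 10, sigma_a2 = 2, sigma_e2 = 3,
                           seed = 40 + r)
    fit <- animal_reml(y ~ 1, hs$data, hs$ped)
    fit$G[1, 1] - anova_sigma_a2(hs)
  })
  # same data, two estimators of the same quantity: differences are small
  # relative to the sampling spread of sigma_a2-hat itself (~0.7 here)
  expect_lt(mean(abs(diffs)), 0.35)
  expect_lt(max(abs(diffs)), 0.9)
})

test_that("REML optimum attains the dense-grid likelihood maximum", {
  pop <- sim_population(small_spec(), seed = 17)
  d <- utils::head(pop$phenotypes[!is.na(pop$phenotypes$SL_30), ], 150)
  fit <- animal_reml(SL_30 ~ sex, d, pop$pedigree)

  ga <- fit$G[1, 1]; ge <- fit$E[1, 1]
  grid <- profile_loglik(SL_30 ~ sex, d, pop$pedigree,
                         sigma_a2 = seq(0.4, 2.5, length.out = 15) * ga,
                         sigma_e2 = seq(0.5, 2, length.out = 15) * ge)
  best <- grid[which.max(grid$loglik), ]
  # the fitter's maximum dominates the whole grid ...
  expect_gte(fit$loglik + 1e-6, max(grid$loglik))
  # ... and the grid argmax sits within one grid step of the estimate
  expect_lt(abs(best$sigma_a2 - ga), 0.16 * ga + 1e-9)
  expect_lt(abs(best$sigma_e2 - ge), 0.12 * ge + 1e-9)
  # exact agreement of the two likelihood code paths at the optimum
  pt <- profile_loglik(SL_30 ~ sex, d, pop$pedigree, ga, ge)
  expect_equal(pt$loglik, fit$loglik, tolerance = 1e-9)

  # likelihood at the generating truth never exceeds the optimum
  cal <- default_calibration()
  tru <- profile_loglik(SL_30 ~ sex, d, pop$pedigree,
                        cal$G["SL_30", "SL_30"], cal$E["SL_30", "SL_30"])
  expect_lte(tru$loglik, fit$loglik + 1e-9)

  # single-point grid returns that point's likelihood
  expect_equal(nrow(profile_loglik(SL_30 ~ sex, d, pop$pedigree, ga, ge)), 1L)
  # oracle refuses large problems (it is intentionally dense)
  big <- data.frame(id = sprintf("B%03d", 1:600), SL_30 = rnorm(600),
                    sex = rep(c("F", "M"), 300))
  expect_error(profile_loglik(SL_30 ~ sex, big, pop$pedigree, 1, 1), "500")
})

test_that("restricted log-likelihood is non-decreasing across EM iterations", {
  pop <- sim_population(small_spec(), seed = 19)
  fit <- animal_reml(cbind(SL_30, Tww) ~ sex, pop$phenotypes, pop$pedigree,
                     method = "em", max_iter = 40, tol = 1e-12)
  expect_true(all(diff(fit$loglik_trace) > -1e-8))
  expect_true(all(fit$step_types == "em"))
})

test_that("null data yield near-zero heritability estimates", {
  h2s <- sapply(1:5, function(r) {
    ped <- sim_design(small_spec(), seed = 60 + r)
    off <- ped$id[!is.na(ped$sire)]
    set.seed(60 + r)
    d <- data.frame(id = off, y = stats::rnorm(length(off)),
                    sex = sample(c("F", "M"), length(off), TRUE))
    fit <- animal_reml(y ~ sex, d, ped)
    h2(fit)$h2
  })
  expect_lt(mean(h2s), 0.06)
  expect_true(all(h2s < 0.2))
})

test_that("estimates are invariant to record order, relabeling and rescaling", {
  pop <- sim_population(small_spec(), seed = 23)
  phe <- pop$phenotypes
  base <- animal_reml(cbind(SL_30, Tww) ~ sex, phe, pop$pedigree)

  # record order
  perm <- animal_reml(cbind(SL_30, Tww) ~ sex, phe[sample(nrow(phe)), ],
                      pop$pedigree)
  expect_equal(base$G, perm$G, tolerance = 1e-6)
  expect_equal(base$loglik, perm$loglik, tolerance = 1e-6)

  # individual id relabeling (consistent in pedigree and data)
  relab <- function(x) paste0("zz", x)
  ped2 <- as.data.frame(pop$pedigree)
  ped2$id <- relab(ped2$id)
  ped2$sire <- ifelse(is.na(ped2$sire), NA, relab(ped2$sire))
  ped2$dam <- ifelse(is.na(ped2$dam), NA, relab(ped2$dam))
  phe2 <- phe; phe2$id <- relab(phe2$id)
  rel <- animal_reml(cbind(SL_30, Tww) ~ sex, phe2, as_pedigree(ped2))
  expect_equal(base$G, rel$G, tolerance = 1e-8, ignore_attr = TRUE)

  # trait rescaling: components scale by k^2, h2 and correlations unchanged
  k <- 1000
  phe3 <- phe; phe3$Tww <- phe3$Tww * k
  sc <- animal_reml(cbind(SL_30, Tww) ~ sex, phe3, pop$pedigree)
  expect_equal(sc$G[2, 2], base$G[2, 2] * k^2, tolerance = 1e-4 * k^2)
  expect_equal(sc$G[1, 2], base$G[1, 2] * k, tolerance = 1e-4 * k)
  expect_equal(h2(sc)$h2, h2(base)$h2, tolerance = 1e-5)
  gp_b <- genetic_parameters(base); gp_s <- genetic_parameters(sc)
  expect_equal(gp_s$estimate[1, 2], gp_b$estimate[1, 2], tolerance = 1e-5)
  expect_equal(gp_s$estimate[2, 1], gp_b$estimate[2, 1], tolerance = 1e-5)
})

test_that("a cross-covariance-free bivariate fit reproduces the univariate fits", {
  pop <- sim_population(small_spec(), seed = 29)
  f1 <- animal_reml(SL_30 ~ sex, pop$phenotypes, pop$pedigree)
  f2 <- animal_reml(Tww ~ sex, pop$phenotypes, pop$pedigree)
  fb <- animal_reml(cbind(SL_30, Tww) ~ sex, pop$phenotypes, pop$pedigree,
                    independent_traits = TRUE)
  expect_equal(unname(diag(fb$G)), c(f1$G[1, 1], f2$G[1, 1]), tolerance = 1e-6)
  expect_equal(unname(diag(fb$E)), c(f1$E[1, 1], f2$E[1, 1]), tolerance = 1e-6)
  expect_equal(fb$G[1, 2], 0)
})

test_that("unbalanced designs keep trait-specific record sets", {
  pop <- sim_population(design_spec(n_sires = 40, n_dams = 60, n_families = 70,
                                    offspring_per_family = 30), seed = 31)
  fit <- animal_reml(cbind(Tww, Mw) ~ sex, pop$phenotypes, pop$pedigree)
  expect_equal(unname(fit$n_records["Mw"]),
               sum(!is.na(pop$phenotypes$Mw)))
  expect_gt(fit$n_records["Tww"], 2 * fit$n_records["Mw"])
  expect_equal(unname(fit$n_co_observed[1, 2]),
               sum(!is.na(pop$phenotypes$Mw) & !is.na(pop$phenotypes$Tww)))
})

test_that("phenotyped individuals missing from the pedigree are reported", {
  pop <- sim_population(small_spec(), seed = 37)
  phe <- pop$phenotypes
  phe$id[1:3] <- c("ghost1", "ghost2", "ghost3")
  expect_error(animal_reml(SL_30 ~ sex, phe, pop$pedigree),
               "ghost1.*ghost2|absent from the pedigree")
})
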