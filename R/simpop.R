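# Synthetic-population generator for nested full-sib/half-sib mating designs:
# design construction, Mendelian-sampling breeding values, continuous and
# ordinal phenotypes, and the missingness process (mortality, tag loss,
# stratified dissection subsample).

#' Specify a nested mating design
#'
#' A sire x dam factorial in which every sire is mated to one or two dams and
#' a limited number of dams serve two sires, so that the triple
#' (sires, dams, families) reconciles: `n_families - n_sires` sires receive a
#' second dam and `n_families - n_dams` dams are reused across sires
#' (creating maternal half-sib links).
#'
#' @param n_sires number of sires (default 81).
#' @param n_dams number of unique dams (default 124).
#' @param n_families number of full-sib families (default 141).
#' @param offspring_per_family tagged offspring per family (default 80).
#' @return a list of class `design_spec`.
#' @export
design_spec <- function(n_sires = 81L, n_dams = 124L, n_families = 141L,
                        offspring_per_family = 80L) {
  n_sires <- as.integer(n_sires); n_dams <- as.integer(n_dams)
  n_families <- as.integer(n_families)
  offspring_per_family <- as.integer(offspring_per_family)
  if (n_families > 2L * n_sires)
    stop("infeasible design: ", n_families, " families need more than two dams for some of the ",
         n_sires, " sires")
  if (n_families < n_sires)
    stop("infeasible design: fewer families than sires (every sire needs >= 1 dam)")
  if (n_dams > n_families)
    stop("infeasible design: more dams than families (every dam must found >= 1 family)")
  if (n_families - n_dams > n_dams)
    stop("infeasible design: dam reuse would require some dam in > 2 families")
  if (offspring_per_family < 1L) stop("offspring_per_family must be >= 1")
  structure(list(n_sires = n_sires, n_dams = n_dams, n_families = n_families,
                 offspring_per_family = offspring_per_family),
            class = "design_spec")
}

#' Generate the pedigree of a nested mating design
#'
#' Realizes a [design_spec()]: `n_families - n_sires` sires are mated to two
#' dams, the remainder to one; `n_families - n_dams` dams are reused by a
#' second (different) sire. Offspring sex is drawn i.i.d. from the
#' female/male/unidentifiable frequencies observed in large grow-out
#' populations (not balanced within family).
#'
#' @param spec a [design_spec()].
#' @param seed integer seed; the same seed reproduces the design exactly.
#' @param sex_prob length-3 probabilities for sex classes `F`, `M`, `U`.
#' @return a [as_pedigree()] object (founder parents + tagged offspring).
#' @examples
#' ped <- sim_design(design_spec(), seed = 1)
#' family_structure(ped)$n_families   # 141
#' @export
sim_design <- function(spec = design_spec(), seed = 1,
                       sex_prob = c(F = 4210, M = 2983, U = 898) / 8091) {
  stopifnot(inherits(spec, "design_spec"))
  ns <- spec$n_sires; nd <- spec$n_dams; nf <- spec$n_families
  with_seed(sub_seed(seed, 1L), {
    sires <- sprintf("S%03d", seq_len(ns))
    dams  <- sprintf("D%03d", seq_len(nd))
    n2 <- nf - ns                      # sires with a second dam
    sire_of_slot <- c(rep(sires[seq_len(n2)], each = 2L),
                      sires[seq.int(n2 + 1L, length.out = ns - n2)])
    # dams in randomized order; the first (nf - nd) are reused at the end,
    # where the slot owner is a different sire by construction.
    dperm <- sample(dams)
    n_reuse <- nf - nd
    dam_of_slot <- c(dperm, if (n_reuse > 0L) dperm[seq_len(n_reuse)])
    if (anyDuplicated(paste(sire_of_slot, dam_of_slot)))
      stop("infeasible design: a sire-dam pair would repeat")
    k <- spec$offspring_per_family
    off_id <- sprintf("A%05d", seq_len(nf * k))
    ped <- data.frame(
      id   = c(sires, dams, off_id),
      sire = c(rep(NA, ns + nd), rep(sire_of_slot, each = k)),
      dam  = c(rep(NA, ns + nd), rep(dam_of_slot, each = k)),
      sex  = c(rep("M", ns), rep("F", nd),
               sample(c("F", "M", "U"), nf * k, replace = TRUE, prob = sex_prob)),
      stringsAsFactors = FALSE)
    as_pedigree(ped)
  })
}

# ---------------------------------------------------------------------------
# Default calibration: trait moments, variance fractions and correlation
# structure of a harvest-age Pacific abalone population measured for shell
# lengths at 6/18/24/30 months, total wet weight, meat weight, meat yield,
# a 4-category foot-color score and survival.
# ---------------------------------------------------------------------------

.calib_traits <- function() {
  data.frame(
    trait = c("SL_6", "SL_18", "SL_24", "SL_30", "Tww", "Mw", "My"),
    mean  = c(23.85, 46.53, 62.64, 76.68, 63.36, 30.64, 0.51),
    sd    = c(2.68, 4.33, 4.46, 5.34, 14.6, 13.03, 0.04),
    h2    = c(0.71, 0.62, 0.45, 0.48, 0.48, 0.31, 0.14),
    stringsAsFactors = FALSE)
}

# known pairwise correlations; missing cross pairs (e.g. SL_6-Mw) are closed
# by the path rule r(i,j) = r(i,Tww) r(Tww,j) and the matrix bent to PSD.
.fill_corr <- function(known, traits) {
  R <- diag(length(traits)); dimnames(R) <- list(traits, traits)
  for (k in seq_len(nrow(known))) {
    i <- known$a[k]; j <- known$b[k]
    R[i, j] <- R[j, i] <- known$r[k]
  }
  for (i in traits) for (j in traits) {
    if (i != j && R[i, j] == 0 && i != "Tww" && j != "Tww")
      R[i, j] <- R[i, "Tww"] * R["Tww", j]
  }
  R2 <- cov2cor_safe(bend_psd(R, 1e-4))
  dimnames(R2) <- dimnames(R)
  R2
}

#' Default generator calibration
#'
#' Packages the parameter set the simulator is calibrated to: per-trait
#' means, phenotypic SDs and heritabilities of the seven measured traits;
#' genetic and residual correlation matrices (closed to PSD); centred gender
#' effects; the sire-dam liability decomposition and equally spaced
#' cutpoints of the 4-category foot-color score (solved so the score mean is
#' 1.42 and SD 0.64, with category 1 the mode); the survival liability; and
#' the missingness model (mortality, tag retention, per-trait record
#' retention, 680-individual dissection subsample from 30 families).
#'
#' @return a list of class `qg_calibration` with elements `traits`, `G`,
#'   `E`, `sigma_f2`, `gender_delta`, `sex_prob`, `fc`, `survival`,
#'   `missing`.
#' @export
default_calibration <- function() {
  tr <- .calib_traits()
  traits <- tr$trait
  sig_a <- tr$sd * sqrt(tr$h2)
  sig_e <- tr$sd * sqrt(1 - tr$h2)

  rg <- data.frame(
    a = c("SL_6", "SL_6", "SL_6", "SL_6", "SL_18", "SL_18", "SL_18",
          "SL_24", "SL_24", "SL_30", "Tww", "Tww"),
    b = c("SL_18", "SL_24", "SL_30", "Tww", "SL_24", "SL_30", "Tww",
          "SL_30", "Tww", "Tww", "Mw", "My"),
    r = c(0.51, 0.31, 0.34, 0.31, 0.31, 0.46, 0.38,
          0.71, 0.53, 0.90, 0.92, -0.60),
    stringsAsFactors = FALSE)
  rp <- data.frame(
    a = c("SL_6", "SL_6", "SL_6", "SL_6", "SL_18", "SL_18", "SL_18",
          "SL_24", "SL_24", "SL_30", "Tww", "Tww"),
    b = c("SL_18", "SL_24", "SL_30", "Tww", "SL_24", "SL_30", "Tww",
          "SL_30", "Tww", "Tww", "Mw", "My"),
    r = c(0.38, 0.30, 0.24, 0.22, 0.49, 0.44, 0.37,
          0.63, 0.50, 0.82, 0.89, -0.10),
    stringsAsFactors = FALSE)

  Rg <- .fill_corr(rg, traits)
  Rp <- .fill_corr(rp, traits)
  G <- Rg * outer(sig_a, sig_a)
  # residual covariance from the phenotypic decomposition cov_p = cov_g + cov_e
  covP <- Rp * outer(tr$sd, tr$sd)
  E <- covP - G
  diag(E) <- sig_e^2
  Re <- cov2cor_safe(bend_psd(cov2cor_safe(E), 1e-4))
  E <- Re * outer(sig_e, sig_e)
  dimnames(G) <- dimnames(E) <- list(traits, traits)

  sex_prob <- c(F = 4210, M = 2983, U = 898) / 8091
  w <- c(F = 1, M = -1, U = 0)
  w <- w - sum(sex_prob * w)            # exact centring: means unaffected
  gender_delta <- outer(w, stats::setNames(0.1 * tr$sd, traits))

  # foot color: sire-dam liability with unit residual; the latent-scale
  # heritability (ss + sd) / (ss + sd + sf + 1) equals 0.46
  h2fc <- 0.46
  ssd <- h2fc / (1 - h2fc)
  fc <- list(sigma_s2 = ssd / 2, sigma_d2 = ssd / 2, sigma_f2 = 0,
             r_g_tww = -0.04, n_categories = 4L,
             target_mean = 1.42, target_sd = 0.64)
  fc$cutpoints <- .solve_cutpoints(fc$target_mean, fc$target_sd,
                                   sqrt(1 + ssd), fc$n_categories)

  # survival: binary liability; latent variance shares set once (typical
  # low-heritability survival signal), overall rate from tag accounting
  surv <- list(sigma_s2 = 1 / 18, sigma_d2 = 1 / 18,
               p_survive = 9006 / 12800)
  surv$threshold <- stats::qnorm(surv$p_survive,
                                 sd = sqrt(1 + surv$sigma_s2 + surv$sigma_d2))

  missing <- list(
    tag_retention = 8001 / 9006,
    trait_retention = c(SL_6 = 6259, SL_18 = 5492, SL_24 = 6843,
                        SL_30 = 7948, Tww = 7993, Fc = 7913) / 8001,
    meat = list(n_families = 30L, total = 680L,
                per_family_min = 20L, per_family_max = 25L))

  structure(list(traits = tr, G = G, E = E,
                 sigma_f2 = stats::setNames(rep(0, length(traits)), traits),
                 gender_delta = gender_delta, sex_prob = sex_prob,
                 fc = fc, survival = surv, missing = missing),
            class = "qg_calibration")
}

# Equally spaced cutpoints (2 free parameters: first cutpoint + gap) on a
# liability with SD `sigma_l`, solved so the K-category score matches the
# target mean and SD.
.solve_cutpoints <- function(mean_target, sd_target, sigma_l, K = 4L) {
  obj <- function(par) {
    t1 <- par[1]; g <- exp(par[2])
    cuts <- t1 + g * (seq_len(K - 1L) - 1)
    p <- diff(c(0, stats::pnorm(cuts), 1))
    m <- sum(seq_len(K) * p)
    v <- sum(seq_len(K)^2 * p) - m^2
    (m - mean_target)^2 + (sqrt(max(v, 0)) - sd_target)^2
  }
  fit <- stats::optim(c(0.4, 0), obj, method = "Nelder-Mead",
                      control = list(reltol = 1e-14, maxit = 2000))
  t1 <- fit$par[1]; g <- exp(fit$par[2])
  std <- t1 + g * (seq_len(K - 1L) - 1)
  std * sigma_l                        # back to the liability scale
}

#' @export
print.qg_calibration <- function(x, ...) {
  cat("Simulator calibration:", nrow(x$traits), "continuous traits +",
      "ordinal foot color +", "binary survival\n")
  print(x$traits, row.names = FALSE)
  cat("latent foot-color shares: sire", signif(x$fc$sigma_s2, 4),
      "dam", signif(x$fc$sigma_d2, 4), "\n")
  invisible(x)
}

#' Simulate breeding values along a pedigree
#'
#' Draws multi-trait additive genetic values by founder sampling from
#' `N(0, G)` and the Mendelian-sampling recursion
#' `a_i = 0.5 (a_s + a_d) + phi_i` with
#' `Var(phi_i) = d_i G`, `d_i = 0.5 (1 - 0.5 (F_s + F_d))` (adjusted for
#' unknown parents), so that `Cov(vec(a)) = A (x) G`.
#'
#' @param ped a [as_pedigree()] object.
#' @param G genetic covariance matrix (traits x traits); must be PSD.
#' @param seed integer seed.
#' @return matrix (individuals x traits), rows in pedigree order.
#' @export
simulate_breeding_values <- function(ped, G, seed = 1) {
  stopifnot(inherits(ped, "pedigree"))
  G <- as.matrix(G)
  ev <- eigen(G, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev), 1))
    stop("genetic covariance matrix is not PSD; eigenvalues: ",
         paste(signif(ev, 4), collapse = ", "))
  L <- mat_sqrt(G)
  n <- nrow(ped); p <- ncol(G)
  si <- attr(ped, "sire_idx"); di <- attr(ped, "dam_idx")
  d <- mendelian_d(ped)
  with_seed(sub_seed(seed, 2L), {
    Z <- matrix(stats::rnorm(n * p), n, p) %*% L
    a <- matrix(0, n, p, dimnames = list(ped$id, colnames(G)))
    for (g in sort(unique(ped$generation))) {
      idx <- which(ped$generation == g)
      par_mean <- 0.5 * (ifelse(si[idx] > 0L, 1, 0) * a[pmax(si[idx], 1L), , drop = FALSE] +
                         ifelse(di[idx] > 0L, 1, 0) * a[pmax(di[idx], 1L), , drop = FALSE])
      a[idx, ] <- par_mean + sqrt(d[idx]) * Z[idx, , drop = FALSE]
    }
    a
  })
}

#' Simulate phenotypes for a pedigreed population
#'
#' Continuous traits follow `y = mu + gender + a + f + e` with residuals
#' drawn jointly across traits; the foot-color score is the category of a
#' sire-dam liability against fixed cutpoints; survival is a Bernoulli draw
#' from its own liability threshold; missingness applies mortality first,
#' then tag loss, then per-trait record retention, then restricts meat
#' traits to a stratified dissection subsample of survivors.
#'
#' @param ped a [as_pedigree()] object (phenotypes are generated for
#'   individuals with both parents known).
#' @param bv breeding-value matrix from [simulate_breeding_values()].
#' @param calib a [default_calibration()]-style list.
#' @param seed integer seed.
#' @param meat_mode `"direct"` (meat yield simulated as a Gaussian trait at
#'   its calibrated moments) or `"composite"` (meat yield computed as
#'   Mw/Tww). Meat weight is simulated either way, so the composite ratio is
#'   always available.
#' @return data.frame with columns `id`, `family`, `sire`, `dam`, `sex`, the
#'   seven continuous traits, `Fc`, `survival`; unobserved cells are `NA`.
#' @export
simulate_phenotypes <- function(ped, bv, calib = default_calibration(),
                                seed = 1, meat_mode = c("direct", "composite")) {
  stopifnot(inherits(ped, "pedigree"))
  meat_mode <- match.arg(meat_mode)
  fc <- calib$fc
  if (is.unsorted(fc$cutpoints, strictly = TRUE))
    stop("foot-color cutpoints must be strictly increasing")
  tr <- calib$traits; traits <- tr$trait
  off <- which(!is.na(ped$sire) & !is.na(ped$dam))
  n <- length(off)
  fam <- family_structure(ped)
  famid <- fam$family[off]
  sire <- ped$sire[off]; dam <- ped$dam[off]
  sex <- ped$sex[off]; sex[is.na(sex)] <- "U"

  with_seed(sub_seed(seed, 3L), {
    # continuous traits
    Ech <- mat_sqrt(calib$E)
    e <- matrix(stats::rnorm(n * length(traits)), n) %*% Ech
    y <- matrix(NA_real_, n, length(traits), dimnames = list(NULL, traits))
    f_dev <- matrix(0, n, length(traits))
    if (any(calib$sigma_f2 > 0)) {
      ufam <- unique(famid)
      fdraw <- matrix(stats::rnorm(length(ufam) * length(traits)), length(ufam)) %*%
        diag(sqrt(calib$sigma_f2), length(traits))
      f_dev <- fdraw[match(famid, ufam), , drop = FALSE]
    }
    for (k in seq_along(traits)) {
      y[, k] <- tr$mean[k] + calib$gender_delta[sex, traits[k]] +
        bv[off, traits[k]] + f_dev[, k] + e[, k]
    }

    # foot-color liability: sire/dam transmitting effects, optionally
    # correlated with the parental Tww breeding values
    r <- fc$r_g_tww
    mk_eff <- function(parents, s2) {
      up <- unique(parents)
      zt <- bv[up, "Tww"] / sqrt(calib$G["Tww", "Tww"])
      u <- (r * zt + sqrt(max(0, 1 - r^2)) * stats::rnorm(length(up))) * sqrt(s2)
      u[match(parents, up)]
    }
    s_eff <- mk_eff(sire, fc$sigma_s2)
    d_eff <- mk_eff(dam, fc$sigma_d2)
    f_fc <- if (fc$sigma_f2 > 0) {
      ufam <- unique(famid)
      stats::rnorm(length(ufam), 0, sqrt(fc$sigma_f2))[match(famid, ufam)]
    } else 0
    liab <- s_eff + d_eff + f_fc + stats::rnorm(n)
    Fc <- findInterval(liab, fc$cutpoints) + 1L

    # survival liability (independent of the measured traits)
    sv <- calib$survival
    mk_ind <- function(parents, s2) {
      up <- unique(parents)
      stats::rnorm(length(up), 0, sqrt(s2))[match(parents, up)]
    }
    surv_liab <- mk_ind(sire, sv$sigma_s2) + mk_ind(dam, sv$sigma_d2) +
      stats::rnorm(n)
    survival <- as.integer(surv_liab < sv$threshold)

    # meat yield
    My <- if (meat_mode == "composite") y[, "Mw"] / y[, "Tww"] else y[, "My"]

    # missingness: dead -> everything but survival missing; tag loss ->
    # identity lost; per-trait retention on identified survivors
    ms <- calib$missing
    identified <- survival == 1L &
      stats::runif(n) < ms$tag_retention
    keep <- function(tr_name) identified &
      stats::runif(n) < ms$trait_retention[[tr_name]]
    obs <- list(SL_6 = keep("SL_6"), SL_18 = keep("SL_18"),
                SL_24 = keep("SL_24"), SL_30 = keep("SL_30"),
                Tww = keep("Tww"), Fc = keep("Fc"))

    # stratified dissection subsample: per-family takes drawn from the
    # allowed range, scaled to the requested total
    mt <- ms$meat
    fam_counts <- table(famid[identified])
    nf_use <- min(mt$n_families, length(fam_counts))
    sizes <- rep(mt$total %/% mt$n_families, nf_use)
    extra <- min(mt$total - sum(sizes), nf_use)
    if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
    fam_ok <- names(which(fam_counts >= max(sizes)))
    if (length(fam_ok) >= nf_use) {
      fam_pick <- sample(fam_ok, nf_use)
      sizes <- sample(sizes)
    } else {
      # small designs: stratify over the best-covered families and cap the
      # per-family take at what is available
      fam_pick <- names(sort(fam_counts, decreasing = TRUE))[seq_len(nf_use)]
      sizes <- pmin(sizes, as.integer(fam_counts[fam_pick]))
    }
    meat_rows <- unlist(lapply(seq_along(fam_pick), function(i) {
      sample(which(famid == fam_pick[i] & identified), sizes[i])
    }))
    meat_obs <- logical(n); meat_obs[meat_rows] <- TRUE

    out <- data.frame(id = ped$id[off], family = famid, sire = sire,
                      dam = dam, sex = sex, stringsAsFactors = FALSE)
    for (t_ in c("SL_6", "SL_18", "SL_24", "SL_30", "Tww"))
      out[[t_]] <- ifelse(obs[[t_]], y[, t_], NA_real_)
    out$Fc <- ifelse(obs$Fc, Fc, NA_integer_)
    out$Mw <- ifelse(meat_obs, y[, "Mw"], NA_real_)
    out$My <- ifelse(meat_obs, My, NA_real_)
    out$survival <- survival
    out
  })
}

#' Simulate a complete study population
#'
#' Convenience wrapper: design pedigree, breeding values, phenotypes and the
#' generating truth in one object.
#'
#' @inheritParams sim_design
#' @inheritParams simulate_phenotypes
#' @param calib a [default_calibration()]-style list.
#' @return list of class `sim_population`: `pedigree`, `phenotypes`,
#'   `breeding_values`, `calibration`, `truth` (named list of generating
#'   parameters), `seed`, `meat_mode`.
#' @examples
#' pop <- sim_population(design_spec(n_sires = 4, n_dams = 6, n_families = 7,
#'                                   offspring_per_family = 10), seed = 7)
#' descriptive_stats(pop$phenotypes)
#' @export
sim_population <- function(spec = design_spec(), calib = default_calibration(),
                           seed = 1, meat_mode = c("direct", "composite")) {
  meat_mode <- match.arg(meat_mode)
  ped <- sim_design(spec, seed = seed, sex_prob = calib$sex_prob)
  bv <- simulate_breeding_values(ped, calib$G, seed = seed)
  phe <- simulate_phenotypes(ped, bv, calib, seed = seed, meat_mode = meat_mode)
  truth <- list(
    G = calib$G, E = calib$E, sigma_f2 = calib$sigma_f2,
    h2 = stats::setNames(diag(calib$G) / (diag(calib$G) + diag(calib$E)),
                         calib$traits$trait),
    fc = calib$fc[c("sigma_s2", "sigma_d2", "sigma_f2")],
    fc_h2_latent = with(calib$fc, (sigma_s2 + sigma_d2) /
                          (sigma_s2 + sigma_d2 + sigma_f2 + 1)),
    survival = calib$survival[c("sigma_s2", "sigma_d2", "p_survive")])
  structure(list(pedigree = ped, phenotypes = phe, breeding_values = bv,
                 calibration = calib, truth = truth, seed = seed,
                 meat_mode = meat_mode),
            class = "sim_population")
}

#' @export
print.sim_population <- function(x, ...) {
  fam <- family_structure(x$pedigree)
  cat("Simulated population (seed ", x$seed, ", meat mode ", x$meat_mode, ")\n",
      "  ", fam$n_families, " families from ", fam$n_sires, " sires x ",
      fam$n_dams, " dams; ", nrow(x$phenotypes), " tagged offspring\n",
      "  identified survivors: ", sum(!is.na(x$phenotypes$Tww) | !is.na(x$phenotypes$Fc)),
      "\n", sep = "")
  invisible(x)
}

#' Write a simulated population to plain-text files
#'
#' Emits `pedigree.csv`, `phenotypes.csv` (empty cell = missing) and
#' `truth.json` (the generating parameters, for recovery scoring).
#'
#' @param pop a [sim_population()] object.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_population <- function(pop, dir) {
  stopifnot(inherits(pop, "sim_population"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("pedigree.csv", "phenotypes.csv", "truth.json"))
  utils::write.csv(as.data.frame(pop$pedigree)[, c("id", "sire", "dam", "sex")],
                   paths[1], row.names = FALSE, na = "")
  utils::write.csv(pop$phenotypes, paths[2], row.names = FALSE, na = "")
  truth <- pop$truth
  truth$G <- as.data.frame(truth$G); truth$E <- as.data.frame(truth$E)
  jsonlite::write_json(truth, paths[3], digits = NA, auto_unbox = TRUE)
  invisible(paths)
}
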