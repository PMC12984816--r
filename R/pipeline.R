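# Orchestration: descriptive statistics, the standard model suite
# (multi-trait growth model, three bivariate meat/color models, threshold
# fits), and replicate-level parameter-recovery studies.

#' Descriptive statistics of a phenotype table
#'
#' Missing-aware N/mean/SD/min/max per trait column.
#'
#' @param data phenotype data.frame.
#' @param traits columns to summarize; defaults to the standard trait set
#'   intersected with the available columns.
#' @return data.frame of class `descriptive_table`.
#' @export
descriptive_stats <- function(data,
                              traits = intersect(c("SL_6", "SL_18", "SL_24",
                                                   "SL_30", "Tww", "Fc",
                                                   "Mw", "My", "survival"),
                                                 names(data))) {
  out <- do.call(rbind, lapply(traits, function(t_) {
    v <- data[[t_]]
    v <- v[!is.na(v)]
    if (!length(v))
      return(data.frame(trait = t_, n = 0L, mean = NA_real_, sd = NA_real_,
                        min = NA_real_, max = NA_real_))
    data.frame(trait = t_, n = length(v), mean = mean(v),
               sd = if (length(v) > 1) stats::sd(v) else 0,
               min = min(v), max = max(v))
  }))
  rownames(out) <- NULL
  class(out) <- c("descriptive_table", "data.frame")
  out
}

#' @export
print.descriptive_table <- function(x, digits = 3, ...) {
  y <- as.data.frame(x)
  y$mean <- round(y$mean, digits); y$sd <- round(y$sd, digits)
  y$min <- round(y$min, digits); y$max <- round(y$max, digits)
  print(y, row.names = FALSE)
  invisible(x)
}

#' Run the standard analysis suite on a population
#'
#' Executes, in order: the descriptive table; the 5-trait multivariate REML
#' model (shell lengths at four ages + total wet weight); three bivariate
#' REML models pairing total wet weight with foot color, meat weight and
#' meat yield; the univariate threshold sire-dam model for foot color; the
#' univariate linear animal model for the foot-color score; and the binary
#' threshold model for survival. Any stage failure marks the bundle partial
#' and is recorded in the stage log rather than aborting the rest.
#'
#' @param data phenotype data.frame (with `id`, `sire`, `dam`, `family`,
#'   `sex` and trait columns).
#' @param pedigree a [as_pedigree()] object.
#' @param models subset of `c("multi5", "biv_fc", "biv_mw", "biv_my",
#'   "thresh_fc", "linear_fc", "thresh_survival")`.
#' @param chain_length,burn_in,thin MCMC settings forwarded to the
#'   threshold fits.
#' @param seed seed for the samplers.
#' @return object of class `suite_report`: `descriptives`, `fits` (named
#'   list), `params` (named list of [genetic_parameters()] reports), `log`
#'   (stage status data.frame), `partial` flag.
#' @export
run_design_suite <- function(data, pedigree,
                             models = c("multi5", "biv_fc", "biv_mw",
                                        "biv_my", "thresh_fc", "linear_fc",
                                        "thresh_survival"),
                             chain_length = 4000L, burn_in = 1000L,
                             thin = 3L, seed = 1) {
  models <- match.arg(models, several.ok = TRUE)
  fits <- list(); params <- list(); log <- list()
  run_stage <- function(name, expr) {
    t0 <- Sys.time()
    res <- tryCatch(expr, error = function(e) e)
    ok <- !inherits(res, "error")
    log[[length(log) + 1]] <<- data.frame(
      stage = name, ok = ok,
      seconds = as.numeric(difftime(Sys.time(), t0, units = "secs")),
      message = if (ok) "" else conditionMessage(res))
    if (ok) res else NULL
  }
  desc <- run_stage("descriptives", descriptive_stats(data))
  specs <- list(
    multi5 = quote(animal_reml(cbind(SL_6, SL_18, SL_24, SL_30, Tww) ~ sex,
                               data, pedigree)),
    biv_fc = quote(animal_reml(cbind(Tww, Fc) ~ sex, data, pedigree)),
    biv_mw = quote(animal_reml(cbind(Tww, Mw) ~ sex, data, pedigree)),
    biv_my = quote(animal_reml(cbind(Tww, My) ~ sex, data, pedigree)),
    thresh_fc = quote(threshold_sire_dam(Fc ~ sex, data,
                                         chain_length = chain_length,
                                         burn_in = burn_in, thin = thin,
                                         seed = seed)),
    linear_fc = quote(linear_score_fit(Fc ~ sex, data, pedigree)),
    thresh_survival = quote(threshold_sire_dam(survival ~ sex, data,
                                               chain_length = chain_length,
                                               burn_in = burn_in, thin = thin,
                                               seed = seed + 1)))
  for (mname in models) {
    fit <- run_stage(mname, eval(specs[[mname]]))
    if (!is.null(fit)) {
      fits[[mname]] <- fit
      params[[mname]] <- tryCatch(genetic_parameters(fit),
                                  error = function(e) NULL)
    }
  }
  log <- do.call(rbind, log)
  structure(list(descriptives = desc, fits = fits, params = params,
                 log = log, partial = !all(log$ok),
                 models = models, seed = seed),
            class = "suite_report")
}

#' @export
print.suite_report <- function(x, ...) {
  cat("Analysis suite (", if (x$partial) "PARTIAL" else "complete", ")\n", sep = "")
  print(x$log[, c("stage", "ok", "seconds")], row.names = FALSE)
  if (!is.null(x$descriptives)) { cat("\n"); print(x$descriptives) }
  for (m in names(x$params)) {
    cat("\n== ", m, " ==\n", sep = "")
    print(x$params[[m]])
  }
  invisible(x)
}

# ---------------------------------------------------------------------------
# Replicate-level parameter recovery
# ---------------------------------------------------------------------------

#' Heritability recovery across replicate simulations
#'
#' Simulates `n_reps` populations at the calibrated truth and refits a
#' univariate animal model for `trait`, returning per-replicate estimates
#' (for bias / empirical-SE / coverage scoring against the generating
#' value).
#'
#' @param trait trait name (e.g. `"SL_30"`, `"My"`).
#' @param n_reps number of replicates.
#' @param seed base seed; replicate r uses `seed + r`.
#' @param spec,calib design and calibration (defaults as packaged).
#' @param meat_mode forwarded to [sim_population()].
#' @return data.frame with `rep`, `h2`, `se`; attribute `truth`.
#' @export
recover_univariate_h2 <- function(trait = "SL_30", n_reps = 10, seed = 1,
                                  spec = design_spec(),
                                  calib = default_calibration(),
                                  meat_mode = "direct") {
  out <- do.call(rbind, lapply(seq_len(n_reps), function(r) {
    pop <- sim_population(spec, calib, seed = seed + r, meat_mode = meat_mode)
    f <- stats::as.formula(paste(trait, "~ sex"))
    fit <- animal_reml(f, pop$phenotypes, pop$pedigree)
    hh <- h2(fit)
    data.frame(rep = r, h2 = hh$h2, se = hh$se, converged = fit$converged)
  }))
  attr(out, "truth") <- default_calibration()$traits$h2[
    match(trait, default_calibration()$traits$trait)]
  out
}

#' Genetic-correlation recovery across replicate simulations
#'
#' Bivariate REML refits of a trait pair at the calibrated truth.
#'
#' @param traits character vector of two trait names.
#' @inheritParams recover_univariate_h2
#' @return data.frame with `rep`, `r_g`, `se`, per-trait `h2`; attribute
#'   `truth` (the generating genetic correlation).
#' @export
recover_bivariate_rg <- function(traits = c("Tww", "Mw"), n_reps = 10,
                                 seed = 1, spec = design_spec(),
                                 calib = default_calibration(),
                                 meat_mode = "direct") {
  stopifnot(length(traits) == 2)
  out <- do.call(rbind, lapply(seq_len(n_reps), function(r) {
    pop <- sim_population(spec, calib, seed = seed + r, meat_mode = meat_mode)
    f <- stats::as.formula(paste0("cbind(", traits[1], ", ", traits[2], ") ~ sex"))
    fit <- animal_reml(f, pop$phenotypes, pop$pedigree)
    gp <- genetic_parameters(fit)
    data.frame(rep = r, r_g = gp$estimate[1, 2], se = gp$se[1, 2],
               h2_1 = gp$estimate[1, 1], h2_2 = gp$estimate[2, 2],
               converged = fit$converged)
  }))
  G <- calib$G
  attr(out, "truth") <- G[traits[1], traits[2]] /
    sqrt(G[traits[1], traits[1]] * G[traits[2], traits[2]])
  out
}

#' Threshold-vs-linear recovery for the ordinal trait
#'
#' Simulates replicate populations, fits the Gibbs threshold sire-dam model
#' to the foot-color scores and, on the same data, the linear animal model
#' treating the score as continuous. The threshold fit omits the
#' common-environment term (`family = NULL`): the generating share is zero
#' and the single-generation design identifies it only through the few
#' dam-sharing links, so the f-free model is the reference analysis (see
#' [threshold_sire_dam()]).
#'
#' @inheritParams recover_univariate_h2
#' @param chain_length,burn_in,thin MCMC settings per replicate.
#' @return data.frame with `rep`, `h2_latent`, `h2_latent_sd`, `h2_linear`;
#'   attribute `truth` (generating latent heritability).
#' @export
recover_threshold_h2 <- function(n_reps = 10, seed = 1,
                                 spec = design_spec(),
                                 calib = default_calibration(),
                                 chain_length = 4000L, burn_in = 1000L,
                                 thin = 3L) {
  out <- do.call(rbind, lapply(seq_len(n_reps), function(r) {
    pop <- sim_population(spec, calib, seed = seed + r)
    d <- pop$phenotypes[!is.na(pop$phenotypes$Fc), ]
    tf <- threshold_sire_dam(Fc ~ sex, d, family = NULL,
                             chain_length = chain_length,
                             burn_in = burn_in, thin = thin, seed = seed + r)
    lf <- linear_score_fit(Fc ~ sex, pop$phenotypes, pop$pedigree)
    data.frame(rep = r,
               h2_latent = tf$posterior["h2_latent", "mean"],
               h2_latent_sd = tf$posterior["h2_latent", "sd"],
               h2_linear = h2(lf)$h2)
  }))
  attr(out, "truth") <- with(calib$fc, (sigma_s2 + sigma_d2) /
                               (sigma_s2 + sigma_d2 + sigma_f2 + 1))
  out
}

#' Summarize a recovery study against its generating truth
#'
#' @param est vector of replicate estimates.
#' @param truth generating value.
#' @return one-row data.frame: mean, bias, empirical SE, Monte-Carlo SE of
#'   the mean, and whether the truth lies within 2 Monte-Carlo SEs.
#' @export
recovery_summary <- function(est, truth) {
  m <- mean(est); s <- stats::sd(est); mcse <- s / sqrt(length(est))
  data.frame(n_reps = length(est), truth = truth, mean = m, bias = m - truth,
             empirical_se = s, mc_se = mcse,
             within_2se = abs(m - truth) <= 2 * mcse)
}
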