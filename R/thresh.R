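# Ordinal probit threshold sire-dam model on the liability scale, fitted by
# Gibbs sampling with latent-liability data augmentation (truncated-normal
# draws for the liabilities, conjugate normal/inverse-chi-square draws for
# location effects and variances, and a Metropolis step for the free
# cutpoints using the marginal ordinal likelihood). The residual liability
# variance is fixed at 1 (probit identification); the first cutpoint is
# anchored at 0 and the overall mean retained.

#' Fit a threshold (liability) sire-dam model to an ordinal trait
#'
#' The observed category `c` is generated by an unobserved liability
#' `l = m + G + sire + dam + f + e`, `e ~ N(0, 1)`, cut at thresholds
#' `tau_1 < ... < tau_{K-1}` (`tau_1 = 0` fixed). Sire, dam and full-sib
#' family effects are i.i.d. normal with variances `sigma_s^2`,
#' `sigma_d^2`, `sigma_f^2`; priors are flat on fixed effects and cutpoints
#' and flat on the variances (proper conditionals given >= 3 levels each).
#' Binary traits (e.g. survival) are the two-category special case with no
#' free cutpoint.
#'
#' @param formula e.g. `Fc ~ sex`; the response must be coercible to
#'   integer categories.
#' @param data data.frame with the response, covariates and the `sire`,
#'   `dam`, `family` columns.
#' @param sire,dam,family names of the parent/family columns. Setting
#'   `family = NULL` drops the common-environment term: with a single
#'   generation and few dam-sharing links, `sigma_f^2` is separated from
#'   `sigma_d^2` only weakly, and under a diffuse prior its posterior mass
#'   spreads along that ridge; the f-free model is then the Bayesian
#'   analogue of a REML fit pinning the component at its boundary and is
#'   the recommended reference analysis when the design provides little
#'   common-environment information.
#' @param chain_length,burn_in,thin MCMC settings (post burn-in draws are
#'   kept every `thin`-th iteration).
#' @param seed integer seed.
#' @param verbose print progress.
#' @return object of class `threshold_fit`: `posterior` (summary matrix with
#'   mean/sd/ess/rhat rows for variances, latent h2, c2, cutpoints),
#'   `draws` (matrix of kept samples), `acceptance` (cutpoint MH rate),
#'   `categories`, `n`, `chain` settings.
#' @examples
#' pop <- sim_population(design_spec(n_sires = 6, n_dams = 9, n_families = 10,
#'                                   offspring_per_family = 25), seed = 3)
#' d <- pop$phenotypes[!is.na(pop$phenotypes$Fc), ]
#' fit <- threshold_sire_dam(Fc ~ sex, d, chain_length = 600, burn_in = 100,
#'                           thin = 2, seed = 1)
#' @export
threshold_sire_dam <- function(formula, data, sire = "sire", dam = "dam",
                               family = "family", chain_length = 20000L,
                               burn_in = 5000L, thin = 10L, seed = 1,
                               verbose = FALSE) {
  resp <- .parse_traits(formula, data)
  if (length(resp) != 1L) stop("threshold model is univariate")
  has_f <- !is.null(family)
  for (col in c(sire, dam, if (has_f) family))
    if (!col %in% names(data)) stop("column '", col, "' not found in data")
  keep <- !is.na(data[[resp]]) & !is.na(data[[sire]]) & !is.na(data[[dam]])
  if (has_f) keep <- keep & !is.na(data[[family]])
  d <- data[keep, , drop = FALSE]
  yraw <- d[[resp]]

  # map to consecutive categories; collapse empty ones
  lev <- sort(unique(yraw))
  y <- match(yraw, lev)
  K <- length(lev)
  if (K < 2L) stop("response '", resp, "' has no variation")
  if (is.numeric(yraw) && K < diff(range(yraw)) + 1)
    warning("category(ies) with zero observations collapsed with their neighbor",
            call. = FALSE)

  rhs <- formula; rhs[[2]] <- NULL
  X <- stats::model.matrix(rhs, stats::model.frame(rhs, d, na.action = stats::na.pass))
  qx <- qr(X); X <- X[, qx$pivot[seq_len(qx$rank)], drop = FALSE]
  n <- nrow(X); p <- ncol(X)

  sfac <- factor(d[[sire]]); dfac <- factor(d[[dam]])
  qs <- nlevels(sfac); qd <- nlevels(dfac)
  qf <- if (has_f) nlevels(factor(d[[family]])) else 0L
  if (min(qs, qd, if (has_f) qf else Inf) < 3L)
    stop("need >= 3 sires, dams (and families) for proper variance conditionals")
  Zs <- Matrix::sparse.model.matrix(~ sfac - 1)
  Zd <- Matrix::sparse.model.matrix(~ dfac - 1)
  Zf <- if (has_f) Matrix::sparse.model.matrix(~ factor(d[[family]]) - 1)
  W <- cbind(methods::as(Matrix::Matrix(X, sparse = TRUE), "generalMatrix"),
             Zs, Zd, if (has_f) Zf)
  WtW <- as.matrix(Matrix::crossprod(W))
  q_all <- p + qs + qd + qf
  i_s <- p + seq_len(qs); i_d <- p + qs + seq_len(qd)
  i_f <- if (has_f) p + qs + qd + seq_len(qf) else integer(0)

  n_keep <- (chain_length - burn_in) %/% thin
  if (n_keep < 10L) stop("chain too short for the requested burn-in/thinning")
  free_tau <- max(K - 2L, 0L)
  draws <- matrix(NA_real_, n_keep,
                  5L + free_tau,
                  dimnames = list(NULL, c("sigma_s2", "sigma_d2", "sigma_f2",
                                          "h2_latent", "c2_latent",
                                          if (free_tau)
                                            paste0("tau", seq.int(2, K - 1)))))
  beta_keep <- matrix(NA_real_, n_keep, p, dimnames = list(NULL, colnames(X)))

  with_seed(sub_seed(seed, 7L), {
    # initialization from marginal frequencies
    pfreq <- tabulate(y, K) / n
    cum <- cumsum(pfreq)[-K]
    tau0 <- stats::qnorm(pmin(pmax(cum, 1e-4), 1 - 1e-4))
    tau <- tau0 - tau0[1]                    # anchor tau_1 = 0
    theta <- numeric(q_all)
    theta[1] <- -tau0[1]                     # intercept absorbs the shift
    vs <- vd <- 0.05
    vf <- if (has_f) 0.05 else 0
    mh_step <- 0.05; mh_acc <- 0; mh_try <- 0
    kk <- 0L

    for (it in seq_len(chain_length)) {
      eta <- as.numeric(W %*% theta)
      bnd_lo <- c(-Inf, tau)[y]
      bnd_hi <- c(tau, Inf)[y]
      l <- rtruncnorm(n, eta, 1, bnd_lo, bnd_hi)

      # location effects: N(C^{-1} W'l, C^{-1}), C = W'W + diag(lambda)
      lam <- c(rep(0, p), rep(1 / vs, qs), rep(1 / vd, qd),
               if (has_f) rep(1 / vf, qf))
      C <- WtW; diag(C) <- diag(C) + lam
      R <- chol(C)
      mu <- backsolve(R, forwardsolve(t(R), as.numeric(Matrix::crossprod(W, l))))
      theta <- mu + backsolve(R, stats::rnorm(q_all))

      # variances: flat prior on sigma^2 -> scaled inverse chi-square
      vs <- sum(theta[i_s]^2) / stats::rchisq(1, qs - 2)
      vd <- sum(theta[i_d]^2) / stats::rchisq(1, qd - 2)
      if (has_f) vf <- sum(theta[i_f]^2) / stats::rchisq(1, qf - 2)

      # cutpoints: random-walk Metropolis on log-gaps, ordinal likelihood
      if (free_tau > 0L) {
        eta <- as.numeric(W %*% theta)
        z <- log(diff(c(0, tau)))[-1]        # gaps above tau_1 = 0
        z_new <- z + stats::rnorm(free_tau, 0, mh_step)
        tau_new <- cumsum(c(0, exp(z_new)))
        ll_of <- function(tt) {
          lo <- c(-Inf, tt)[y]; hi <- c(tt, Inf)[y]
          sum(log(pmax(stats::pnorm(hi - eta) - stats::pnorm(lo - eta), 1e-300)))
        }
        log_r <- ll_of(tau_new) - ll_of(tau) + sum(z_new) - sum(z)
        mh_try <- mh_try + 1
        if (is.finite(log_r) && log(stats::runif(1)) < log_r) {
          tau <- tau_new; mh_acc <- mh_acc + 1
        }
        if (it <= burn_in && it %% 100 == 0) {   # adapt during burn-in only
          rate <- mh_acc / max(mh_try, 1)
          mh_step <- mh_step * exp(0.5 * (rate - 0.3))
          mh_acc <- 0; mh_try <- 0
        }
      }

      if (it > burn_in && (it - burn_in) %% thin == 0L) {
        kk <- kk + 1L
        h2l <- (vs + vd) / (vs + vd + vf + 1)
        c2l <- vf / (vs + vd + vf + 1)
        draws[kk, seq_len(5L + free_tau)] <-
          c(vs, vd, vf, h2l, c2l, if (free_tau) tau[-1])
        beta_keep[kk, ] <- theta[seq_len(p)]
      }
      if (verbose && it %% 2000 == 0)
        message("iteration ", it, " / ", chain_length)
    }
    acc_rate <- if (free_tau) mh_acc / max(mh_try, 1) else NA_real_

    summ <- t(apply(draws, 2, function(v) {
      c(mean = mean(v), sd = stats::sd(v), ess = .ess(v), rhat = .split_rhat(v))
    }))
    flagged <- rownames(summ)[summ[, "rhat"] > 1.1 & is.finite(summ[, "rhat"])]
    if (length(flagged))
      warning("split-Rhat > 1.1 for: ", paste(flagged, collapse = ", "),
              " - consider a longer chain", call. = FALSE)

    structure(list(posterior = summ, draws = draws, beta = beta_keep,
                   acceptance = acc_rate, categories = lev, n = n,
                   n_sires = qs, n_dams = qd,
                   n_families = if (has_f) qf else NA_integer_,
                   family_effect = has_f,
                   chain = list(chain_length = chain_length, burn_in = burn_in,
                                thin = thin, seed = seed),
                   response = resp, convergence_flagged = flagged,
                   call = match.call()),
              class = "threshold_fit")
  })
}

# effective sample size from the initial positive sequence of autocorrelations
.ess <- function(v) {
  n <- length(v)
  if (stats::sd(v) == 0) return(NA_real_)
  ac <- stats::acf(v, lag.max = min(n - 1, 200), plot = FALSE)$acf[-1]
  s <- 0
  for (k in seq_along(ac)) {
    if (ac[k] < 0.05) break
    s <- s + ac[k]
  }
  n / (1 + 2 * s)
}

# split-Rhat from a single chain cut in two halves
.split_rhat <- function(v) {
  n <- length(v) %/% 2
  if (n < 5) return(NA_real_)
  x <- matrix(v[seq_len(2 * n)], n, 2)
  W <- mean(apply(x, 2, stats::var))
  B <- n * stats::var(colMeans(x))
  if (W == 0) return(NA_real_)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' @export
print.threshold_fit <- function(x, ...) {
  cat("Threshold sire-dam model for '", x$response, "' (",
      length(x$categories), " categories, n = ", x$n, ")\n",
      "  chain ", x$chain$chain_length, " (burn-in ", x$chain$burn_in,
      ", thin ", x$chain$thin, "); cutpoint MH acceptance ",
      ifelse(is.finite(x$acceptance), sprintf("%.2f", x$acceptance), "-"),
      "\n", sep = "")
  print(signif(x$posterior, 4))
  if (length(x$convergence_flagged))
    cat("note: split-Rhat > 1.1 for ",
        paste(x$convergence_flagged, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
summary.threshold_fit <- function(object, ...) genetic_parameters(object)

#' @export
coef.threshold_fit <- function(object, ...) colMeans(object$beta)

#' Linear animal-model fit of an ordinal score
#'
#' Fits the 1..K score as a continuous trait with [animal_reml()] — the
#' conventional companion analysis to a threshold fit, quantifying how much
#' of the latent-scale signal survives when the ordinal scale is treated as
#' linear.
#'
#' @param formula e.g. `Fc ~ sex`.
#' @param data data.frame including an `id` column.
#' @param pedigree a [as_pedigree()] object.
#' @param ... passed to [animal_reml()].
#' @return an [animal_reml()] fit.
#' @export
linear_score_fit <- function(formula, data, pedigree, ...) {
  resp <- .parse_traits(formula, data)
  v <- data[[resp]]
  if (stats::var(v, na.rm = TRUE) == 0)
    stop("ordinal score '", resp, "' has zero variance; nothing to fit")
  animal_reml(formula, data, pedigree, ...)
}
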