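# REML estimation of variance components for linear animal models with
# pedigree covariance: y = Xb + a (+ f) + e, Var(a) = A sigma_a^2 (per-trait
# blocks of an unstructured cross-trait G), Var(e) = I sigma_e^2 (unstructured
# E over co-observed traits), optional full-sib common environment F.
#
# The marginal covariance of the records is block-diagonal over the connected
# components of the pedigree graph, so the restricted likelihood, the EM
# updates (with exact conditional traces), the exact score and the exact
# average-information matrix are all computed densely per component and
# accumulated. Record-level missingness: each trait equation uses its own
# observed set; residual cross-trait covariance binds co-observed pairs only.

# ancestors closure (ped row indices), preserving pedigree order
.ancestor_closure <- function(ped, rows) {
  si <- attr(ped, "sire_idx"); di <- attr(ped, "dam_idx")
  keep <- logical(nrow(ped))
  keep[rows] <- TRUE
  for (i in sort(rows, decreasing = TRUE)) {
    if (si[i] > 0L) keep[si[i]] <- TRUE
    if (di[i] > 0L) keep[di[i]] <- TRUE
  }
  # parents precede offspring, so a single reverse sweep closes the set
  for (i in rev(which(keep))) {
    if (si[i] > 0L) keep[si[i]] <- TRUE
    if (di[i] > 0L) keep[di[i]] <- TRUE
  }
  which(keep)
}

# parse cbind(Tww, Mw) ~ sex style formulas
.parse_traits <- function(formula, data) {
  lhs <- formula[[2]]
  if (is.call(lhs) && identical(lhs[[1]], as.name("cbind")))
    vapply(as.list(lhs)[-1], deparse, character(1))
  else deparse(lhs)
}

#' Fit a linear animal model by REML
#'
#' Estimates unstructured genetic (`G`), residual (`E`) and optionally
#' full-sib common-environment (`F`) covariance matrices for one or more
#' traits, with the additive genetic effect carrying the pedigree numerator
#' relationship structure. Estimation is restricted maximum likelihood:
#' monotone EM iterations to warm up, then average-information (AI) updates
#' with step-halving; standard errors derive from the inverse AI matrix at
#' the optimum. Individuals enter each trait's equations only where
#' observed, so unbalanced multi-trait records (e.g. a dissected subsample)
#' are handled exactly.
#'
#' @param formula model formula; left side a trait name or
#'   `cbind(trait1, trait2, ...)`, right side the fixed effects (e.g.
#'   `~ sex`). An intercept is always included.
#' @param data data.frame with an `id` column matching the pedigree plus the
#'   trait and covariate columns; `NA` marks a missing record.
#' @param pedigree a [as_pedigree()] object covering every phenotyped
#'   individual.
#' @param family_effect include a full-sib common-environment covariance
#'   (default `FALSE`).
#' @param independent_traits constrain all cross-trait covariances (genetic
#'   and residual) to zero, making a multi-trait fit equivalent to the
#'   stacked univariate fits (default `FALSE`).
#' @param method `"em+ai"` (default), `"em"` (pure EM, guaranteed monotone)
#'   or `"ai"` (AI from the start).
#' @param max_iter,tol iteration cap and relative log-likelihood tolerance.
#' @param em_warmup number of EM iterations before switching to AI.
#' @param start optional list with starting `G`, `E` (and `F`).
#' @param verbose print per-iteration log-likelihoods.
#' @return an object of class `animal_reml` with components `G`, `E`, `F`,
#'   `beta`, `vcov_beta`, `loglik`, `loglik_trace`, `vcov_vc` (inverse AI),
#'   `param_index`, `converged`, `n_iter`, `boundary`, `n_records`,
#'   `n_co_observed`, `traits`.
#' @examples
#' pop <- sim_population(design_spec(n_sires = 6, n_dams = 9, n_families = 10,
#'                                   offspring_per_family = 20), seed = 2)
#' fit <- animal_reml(SL_30 ~ sex, pop$phenotypes, pop$pedigree)
#' h2(fit)
#' @export
animal_reml <- function(formula, data, pedigree, family_effect = FALSE,
                        independent_traits = FALSE,
                        method = c("em+ai", "em", "ai"),
                        max_iter = 200L, tol = 1e-8, em_warmup = 5L,
                        start = NULL, verbose = FALSE) {
  method <- match.arg(method)
  stopifnot(inherits(pedigree, "pedigree"))
  if (!"id" %in% names(data)) stop("data must contain an 'id' column")
  traits <- .parse_traits(formula, data)
  Tn <- length(traits)
  missing_tr <- setdiff(traits, names(data))
  if (length(missing_tr)) stop("trait(s) not in data: ", paste(missing_tr, collapse = ", "))

  pidx <- match(as.character(data$id), pedigree$id)
  if (anyNA(pidx)) {
    bad <- unique(as.character(data$id)[is.na(pidx)])
    stop("phenotyped individual(s) absent from the pedigree: ",
         paste(utils::head(bad, 10), collapse = ", "),
         if (length(bad) > 10) paste0(" (and ", length(bad) - 10, " more)"))
  }

  rhs <- formula; rhs[[2]] <- NULL
  mf <- stats::model.frame(rhs, data, na.action = stats::na.pass)
  X0 <- stats::model.matrix(rhs, mf)
  x_ok <- stats::complete.cases(X0)

  fammap <- family_structure(pedigree)
  fam_of_row <- fammap$family[pidx]
  comp_of_ped <- ped_components(pedigree)
  comp_of_row <- comp_of_ped[pidx]

  # observation matrix: row x trait
  obs <- sapply(traits, function(t_) !is.na(data[[t_]]) & x_ok)
  if (is.null(dim(obs))) obs <- matrix(obs, ncol = Tn)
  n_rec_tr <- colSums(obs)
  if (any(n_rec_tr < 2L))
    stop("trait(s) with fewer than 2 records: ",
         paste(traits[n_rec_tr < 2L], collapse = ", "))
  co_obs <- crossprod(obs)

  # per-trait fixed-effect columns, dropped if aliased on that trait's subset
  keep_cols <- lapply(seq_len(Tn), function(k) {
    q <- qr(X0[obs[, k], , drop = FALSE])
    sort(q$pivot[seq_len(q$rank)])
  })
  p_tr <- lengths(keep_cols)
  p_tot <- sum(p_tr)
  p_off <- c(0L, cumsum(p_tr))[seq_len(Tn)]

  # internal standardization for numerical balance across trait scales
  y_sd <- vapply(seq_len(Tn), function(k) stats::sd(data[[traits[k]]][obs[, k]]), numeric(1))
  vp_scaled <- rep(1, Tn)

  if (family_effect && all(is.na(fam_of_row)))
    stop("family_effect = TRUE but no individual has both parents known")

  # ---- per-component precomputation -------------------------------------
  comps <- sort(unique(comp_of_row[rowSums(obs) > 0]))
  blocks <- vector("list", length(comps))
  n_ind_total <- 0L
  fam_all <- character(0)
  for (ci in seq_along(comps)) {
    rows_c <- which(comp_of_row == comps[ci] & rowSums(obs) > 0)
    ped_rows <- unique(pidx[rows_c])
    sub_rows <- .ancestor_closure(pedigree, ped_rows)
    subped <- as_pedigree(as.data.frame(pedigree)[sub_rows, c("id", "sire", "dam", "sex")])
    A_sub <- build_A(subped)
    ids_obs <- pedigree$id[ped_rows]
    A_obs <- A_sub[ids_obs, ids_obs, drop = FALSE]
    # records: stacked by trait
    rec_row <- integer(0); rec_tr <- integer(0)
    for (k in seq_len(Tn)) {
      rk <- rows_c[obs[rows_c, k]]
      rec_row <- c(rec_row, rk)
      rec_tr <- c(rec_tr, rep(k, length(rk)))
    }
    li <- match(pidx[rec_row], ped_rows)     # local individual index
    nr <- length(rec_row)
    Amat <- A_obs[li, li, drop = FALSE]
    IndM <- matrix(0, nr, nr); IndM[outer(li, li, "==")] <- 1
    FamM <- NULL
    if (family_effect) {
      fm <- fam_of_row[rec_row]
      FamM <- matrix(0, nr, nr)
      same <- outer(fm, fm, "==") & !is.na(outer(fm, fm, paste))
      same[is.na(same)] <- FALSE
      FamM[same] <- 1
      fam_all <- c(fam_all, unique(fm[!is.na(fm)]))
    }
    TT <- matrix(rec_tr[rep(seq_len(nr), nr)] +
                   (rec_tr[rep(seq_len(nr), each = nr)] - 1L) * Tn, nr, nr)
    X_c <- matrix(0, nr, p_tot)
    for (k in seq_len(Tn)) {
      sel <- rec_tr == k
      if (any(sel))
        X_c[sel, p_off[k] + seq_len(p_tr[k])] <-
          X0[rec_row[sel], keep_cols[[k]], drop = FALSE]
    }
    y_c <- numeric(nr)
    for (k in seq_len(Tn)) {
      sel <- rec_tr == k
      y_c[sel] <- data[[traits[k]]][rec_row[sel]] / y_sd[k]
    }
    rows_by_tr <- lapply(seq_len(Tn), function(k) which(rec_tr == k))
    n_ind_total <- n_ind_total + length(ped_rows)
    blocks[[ci]] <- list(Amat = Amat, IndM = IndM, FamM = FamM, TT = TT,
                         X = X_c, y = y_c, tr = rec_tr, li = li,
                         rows_by_tr = rows_by_tr, nr = nr,
                         ids = ids_obs, rec_row = rec_row)
  }
  n_fam_total <- length(unique(fam_all))
  N_rec <- sum(vapply(blocks, function(b) b$nr, numeric(1)))

  # ---- parameter bookkeeping --------------------------------------------
  structs <- c("G", "E", if (family_effect) "F")
  offdiag <- !diag(Tn)
  pin <- list(G = offdiag & independent_traits,
              E = (co_obs == 0) | (offdiag & independent_traits),
              F = offdiag & independent_traits)
  pidx_tab <- do.call(rbind, lapply(structs, function(s) {
    idx <- which(upper.tri(diag(Tn), diag = TRUE), arr.ind = TRUE)
    d <- data.frame(struct = s, t = idx[, 1], u = idx[, 2])
    d[!pin[[s]][cbind(d$t, d$u)], , drop = FALSE]
  }))
  K <- nrow(pidx_tab)

  mats_from_theta <- function(theta) {
    out <- list(G = matrix(0, Tn, Tn), E = matrix(0, Tn, Tn),
                F = if (family_effect) matrix(0, Tn, Tn))
    for (k in seq_len(K)) {
      s <- pidx_tab$struct[k]; t_ <- pidx_tab$t[k]; u_ <- pidx_tab$u[k]
      out[[s]][t_, u_] <- out[[s]][u_, t_] <- theta[k]
    }
    out
  }
  theta_from_mats <- function(m) {
    vapply(seq_len(K), function(k)
      m[[pidx_tab$struct[k]]][pidx_tab$t[k], pidx_tab$u[k]], numeric(1))
  }

  # ---- likelihood / moment evaluation -----------------------------------
  build_V <- function(b, m) {
    V <- m$G[b$TT] * b$Amat + m$E[b$TT] * b$IndM
    if (family_effect) V <- V + m$F[b$TT] * b$FamM
    dim(V) <- c(b$nr, b$nr)
    V
  }

  eval_loglik <- function(m) {
    logdet <- 0; ytViy <- 0
    XtViX <- matrix(0, p_tot, p_tot); XtViy <- numeric(p_tot)
    cache <- vector("list", length(blocks))
    for (ci in seq_along(blocks)) {
      b <- blocks[[ci]]
      V <- build_V(b, m)
      R <- tryCatch(chol(V), error = function(e) NULL)
      if (is.null(R)) return(NULL)
      logdet <- logdet + 2 * sum(log(diag(R)))
      Vi <- chol2inv(R)
      ViX <- Vi %*% b$X
      Viy <- drop(Vi %*% b$y)
      XtViX <- XtViX + crossprod(b$X, ViX)
      XtViy <- XtViy + drop(crossprod(ViX, b$y))
      ytViy <- ytViy + sum(b$y * Viy)
      cache[[ci]] <- list(Vi = Vi, ViX = ViX, Viy = Viy)
    }
    Rx <- tryCatch(chol(XtViX), error = function(e) NULL)
    if (is.null(Rx)) return(NULL)
    Q <- chol2inv(Rx)
    beta <- drop(Q %*% XtViy)
    yPy <- ytViy - sum(XtViy * beta)
    ll <- -0.5 * (logdet + 2 * sum(log(diag(Rx))) + yPy +
                    (N_rec - p_tot) * log(2 * pi))
    list(ll = ll, beta = beta, Q = Q, cache = cache)
  }

  eval_moments <- function(m, base) {
    Str <- list(G = matrix(0, Tn, Tn), E = matrix(0, Tn, Tn),
                F = if (family_effect) matrix(0, Tn, Tn))
    Syy <- Str
    M1 <- matrix(0, K, K)
    Nmat <- matrix(0, p_tot, K)
    wt_of <- function(b, s) switch(s, G = b$Amat, E = b$IndM, F = b$FamM)
    for (ci in seq_along(blocks)) {
      b <- blocks[[ci]]; cc <- base$cache[[ci]]
      r <- cc$Viy - drop(cc$ViX %*% base$beta)          # (P y) block
      P <- cc$Vi - cc$ViX %*% base$Q %*% t(cc$ViX)      # block-diagonal of P
      H <- matrix(0, b$nr, K)
      for (k in seq_len(K)) {
        s <- pidx_tab$struct[k]; t_ <- pidx_tab$t[k]; u_ <- pidx_tab$u[k]
        W <- wt_of(b, s)
        rt <- b$rows_by_tr[[t_]]; ru <- b$rows_by_tr[[u_]]
        if (length(rt) && length(ru)) {
          H[rt, k] <- H[rt, k] + W[rt, ru, drop = FALSE] %*% r[ru]
          if (t_ != u_)
            H[ru, k] <- H[ru, k] + W[ru, rt, drop = FALSE] %*% r[rt]
        }
      }
      for (s in structs) {
        W <- wt_of(b, s)
        PW <- P * W
        rW <- r * W                                     # r_i W_ij (row-scaled)
        for (t_ in seq_len(Tn)) for (u_ in seq_len(Tn)) {
          rt <- b$rows_by_tr[[t_]]; ru <- b$rows_by_tr[[u_]]
          if (length(rt) && length(ru)) {
            Str[[s]][t_, u_] <- Str[[s]][t_, u_] + sum(PW[rt, ru])
            Syy[[s]][t_, u_] <- Syy[[s]][t_, u_] +
              sum(r[rt] * (W[rt, ru, drop = FALSE] %*% r[ru]))
          }
        }
      }
      M1 <- M1 + crossprod(H, cc$Vi %*% H)
      Nmat <- Nmat + crossprod(cc$ViX, H)
    }
    grad <- numeric(K)
    for (k in seq_len(K)) {
      s <- pidx_tab$struct[k]; t_ <- pidx_tab$t[k]; u_ <- pidx_tab$u[k]
      mult <- if (t_ == u_) 1 else 2
      grad[k] <- -0.5 * mult * (Str[[s]][t_, u_] - Syy[[s]][t_, u_])
    }
    AI <- 0.5 * (M1 - t(Nmat) %*% base$Q %*% Nmat)
    list(Str = Str, Syy = Syy, grad = grad, AI = AI)
  }

  em_update <- function(m, mo) {
    q_of <- list(G = n_ind_total, E = n_ind_total, F = n_fam_total)
    out <- m
    for (s in structs) {
      M <- m[[s]]; q <- q_of[[s]]
      Mn <- (M %*% mo$Syy[[s]] %*% M + q * M - M %*% mo$Str[[s]] %*% M) / q
      out[[s]] <- (Mn + t(Mn)) / 2
      out[[s]][pin[[s]]] <- 0
    }
    out
  }

  guard <- function(m) {
    eps <- 1e-8
    for (s in structs) {
      d <- diag(m[[s]])
      d[d < eps * vp_scaled] <- eps * vp_scaled[d < eps * vp_scaled]
      diag(m[[s]]) <- d
      # keep implied correlations inside (-1, 1)
      sdv <- sqrt(d)
      R <- m[[s]] / outer(sdv, sdv)
      R[R > 0.999] <- 0.999; R[R < -0.999] <- -0.999
      diag(R) <- 1
      m[[s]] <- R * outer(sdv, sdv)
      m[[s]][pin[[s]]] <- 0
    }
    m
  }

  # ---- starting values ---------------------------------------------------
  if (!is.null(start)) {
    m <- list(G = as.matrix(start$G) / outer(y_sd, y_sd),
              E = as.matrix(start$E) / outer(y_sd, y_sd),
              F = if (family_effect)
                (start$F %||% diag(0.05, Tn)) / outer(y_sd, y_sd))
  } else {
    covp <- diag(1, Tn)
    for (t_ in seq_len(Tn)) for (u_ in seq_len(Tn)) {
      if (t_ != u_ && co_obs[t_, u_] > 2) {
        sel <- obs[, t_] & obs[, u_]
        covp[t_, u_] <- stats::cor(data[[traits[t_]]][sel],
                                   data[[traits[u_]]][sel])
      }
    }
    covp <- bend_psd(covp, 1e-4)
    fshare <- if (family_effect) 0.1 else 0
    m <- list(G = 0.4 * covp, E = (0.6 - fshare) * covp,
              F = if (family_effect) fshare * covp)
  }
  m <- guard(m)

  # ---- main loop ---------------------------------------------------------
  ll_trace <- numeric(0); step_types <- character(0)
  base <- eval_loglik(m)
  if (is.null(base)) stop("initial covariance matrices are not positive definite")
  converged <- FALSE
  iter <- 0L
  mo <- NULL
  while (iter < max_iter) {
    iter <- iter + 1L
    mo <- eval_moments(m, base)
    use_em <- method == "em" || (method == "em+ai" && iter <= em_warmup)
    stepped <- FALSE
    if (!use_em) {
      theta <- theta_from_mats(m)
      AI <- mo$AI
      ridge <- 1e-8 * max(diag(AI))
      delta <- tryCatch(solve(AI + diag(ridge, K), mo$grad),
                        error = function(e) NULL)
      if (!is.null(delta)) {
        fac <- 1
        for (h in seq_len(20L)) {
          cand <- guard(mats_from_theta(theta + fac * delta))
          cand_base <- eval_loglik(cand)
          if (!is.null(cand_base) && cand_base$ll >= base$ll - 1e-10) {
            m_new <- cand; base_new <- cand_base
            stepped <- TRUE; step_types <- c(step_types, "ai")
            break
          }
          fac <- fac / 2
        }
      }
    }
    if (!stepped) {
      m_new <- guard(em_update(m, mo))
      base_new <- eval_loglik(m_new)
      if (is.null(base_new)) stop("EM update produced a non-PD covariance")
      step_types <- c(step_types, "em")
    }
    dll <- base_new$ll - base$ll
    dtheta <- max(abs(theta_from_mats(m_new) - theta_from_mats(m)))
    m <- m_new; base <- base_new
    ll_trace <- c(ll_trace, base$ll)
    if (verbose)
      message(sprintf("iter %3d [%s] logLik %.6f", iter,
                      utils::tail(step_types, 1), base$ll))
    if (abs(dll) < tol * (1 + abs(base$ll)) && dtheta < 1e-6) {
      converged <- TRUE
      break
    }
  }
  mo <- eval_moments(m, base)

  # ---- back-transform to the data scale ---------------------------------
  scale_fac <- vapply(seq_len(K), function(k)
    y_sd[pidx_tab$t[k]] * y_sd[pidx_tab$u[k]], numeric(1))
  unscale <- function(M) M * outer(y_sd, y_sd)
  G_out <- unscale(m$G); E_out <- unscale(m$E)
  dimnames(G_out) <- dimnames(E_out) <- list(traits, traits)
  F_out <- if (family_effect) {
    f <- unscale(m$F); dimnames(f) <- list(traits, traits); f
  }
  AIs <- mo$AI / outer(scale_fac, scale_fac)
  vcov_vc <- tryCatch(solve(AIs + diag(1e-12 * max(diag(AIs)), K)),
                      error = function(e) matrix(NA_real_, K, K))

  beta <- base$beta
  beta_names <- unlist(lapply(seq_len(Tn), function(k)
    paste(traits[k], colnames(X0)[keep_cols[[k]]], sep = ":")))
  # fixed effects back on the data scale
  beta_scale <- unlist(lapply(seq_len(Tn), function(k) rep(y_sd[k], p_tr[k])))
  beta <- beta * beta_scale
  names(beta) <- beta_names
  vcov_beta <- base$Q * outer(beta_scale, beta_scale)
  dimnames(vcov_beta) <- list(beta_names, beta_names)

  boundary <- diag(m$G) <= 1.5e-8 * vp_scaled | diag(m$E) <= 1.5e-8 * vp_scaled

  structure(list(G = G_out, E = E_out, F = F_out,
                 beta = beta, vcov_beta = vcov_beta,
                 # Jacobian of the internal per-trait standardization, so the
                 # reported value is on the data scale
                 loglik = base$ll - sum((n_rec_tr - p_tr) * log(y_sd)),
                 loglik_trace = ll_trace, step_types = step_types,
                 vcov_vc = vcov_vc, param_index = pidx_tab,
                 converged = converged, n_iter = iter,
                 boundary = boundary, traits = traits,
                 n_records = stats::setNames(n_rec_tr, traits),
                 n_co_observed = co_obs, n_individuals = n_ind_total,
                 family_effect = family_effect, method = method,
                 y_sd = y_sd, call = match.call()),
            class = "animal_reml")
}

#' @export
print.animal_reml <- function(x, ...) {
  cat("Animal-model REML fit (", paste(x$traits, collapse = ", "), ")\n",
      "  ", x$n_iter, " iterations (",
      sum(x$step_types == "em"), " EM, ", sum(x$step_types == "ai"), " AI), ",
      if (x$converged) "converged" else "NOT converged",
      "; logLik ", format(x$loglik, digits = 8), "\n", sep = "")
  cat("Genetic covariance (G):\n"); print(signif(x$G, 4))
  cat("Residual covariance (E):\n"); print(signif(x$E, 4))
  if (!is.null(x$F)) { cat("Common-environment covariance (F):\n"); print(signif(x$F, 4)) }
  if (any(x$boundary))
    cat("note: variance component(s) pinned at the boundary for trait(s): ",
        paste(x$traits[x$boundary], collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
summary.animal_reml <- function(object, ...) {
  gp <- genetic_parameters(object)
  structure(list(fit = object, params = gp), class = "summary.animal_reml")
}

#' @export
print.summary.animal_reml <- function(x, ...) {
  print(x$fit)
  cat("\n")
  print(x$params)
  invisible(x)
}

#' @export
coef.animal_reml <- function(object, ...) object$beta

#' @export
logLik.animal_reml <- function(object, ...) {
  structure(object$loglik, df = nrow(object$param_index) + length(object$beta),
            class = "logLik")
}

#' @export
vcov.animal_reml <- function(object, which = c("beta", "varcomp"), ...) {
  which <- match.arg(which)
  if (which == "beta") object$vcov_beta else object$vcov_vc
}

#' @export
residuals.animal_reml <- function(object, data, ...) {
  stop("residuals require the original data; use fitted_residuals(fit, data, pedigree)")
}

#' Marginal residuals of an animal-model fit
#'
#' Returns `y - X beta-hat` for every observed record.
#'
#' @param fit an [animal_reml()] object.
#' @param data the data used for fitting.
#' @return data.frame with `id`, `trait`, `residual`.
#' @export
fitted_residuals <- function(fit, data) {
  rhs <- fit$call$formula
  rhs <- eval(rhs)
  rhs[[2]] <- NULL
  X0 <- stats::model.matrix(rhs, stats::model.frame(rhs, data, na.action = stats::na.pass))
  out <- do.call(rbind, lapply(fit$traits, function(t_) {
    sel <- !is.na(data[[t_]])
    bn <- grep(paste0("^", t_, ":"), names(fit$beta))
    cols <- sub(paste0("^", t_, ":"), "", names(fit$beta)[bn])
    eta <- drop(X0[sel, cols, drop = FALSE] %*% fit$beta[bn])
    data.frame(id = data$id[sel], trait = t_,
               residual = data[[t_]][sel] - eta)
  }))
  rownames(out) <- NULL
  out
}

#' Dense restricted log-likelihood grid (oracle)
#'
#' Evaluates the univariate animal-model restricted log-likelihood on a grid
#' of `(sigma_a^2, sigma_e^2)` values by the direct dense formula
#' `V = sigma_a^2 A + sigma_e^2 I`, independently of the iterative fitter.
#' Intentionally dense and refused beyond 500 records, this serves as a
#' brute-force check that the REML optimum attains the grid maximum.
#'
#' @param formula univariate model formula (e.g. `SL_30 ~ sex`).
#' @param data,pedigree as in [animal_reml()].
#' @param sigma_a2,sigma_e2 numeric vectors; the grid is their cross product.
#' @return data.frame with columns `sigma_a2`, `sigma_e2`, `loglik`.
#' @export
profile_loglik <- function(formula, data, pedigree, sigma_a2, sigma_e2) {
  traits <- .parse_traits(formula, data)
  if (length(traits) != 1L) stop("profile_loglik is univariate")
  rhs <- formula; rhs[[2]] <- NULL
  X0 <- stats::model.matrix(rhs, stats::model.frame(rhs, data, na.action = stats::na.pass))
  sel <- !is.na(data[[traits]]) & stats::complete.cases(X0)
  n <- sum(sel)
  if (n > 500L) stop("dense likelihood oracle limited to n <= 500 records")
  pidx <- match(as.character(data$id)[sel], pedigree$id)
  if (anyNA(pidx)) stop("individual(s) missing from pedigree")
  sub_rows <- .ancestor_closure(pedigree, unique(pidx))
  subped <- as_pedigree(as.data.frame(pedigree)[sub_rows, c("id", "sire", "dam", "sex")])
  A <- build_A(subped)[pedigree$id[pidx], pedigree$id[pidx]]
  y <- data[[traits]][sel]
  X <- X0[sel, , drop = FALSE]
  X <- X[, qr(X)$pivot[seq_len(qr(X)$rank)], drop = FALSE]
  p <- ncol(X)
  grid <- expand.grid(sigma_a2 = sigma_a2, sigma_e2 = sigma_e2)
  grid$loglik <- vapply(seq_len(nrow(grid)), function(i) {
    V <- grid$sigma_a2[i] * A + diag(grid$sigma_e2[i], n)
    R <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(R)) return(-Inf)
    Vi <- chol2inv(R)
    XtViX <- crossprod(X, Vi %*% X)
    Rx <- chol(XtViX)
    beta <- drop(chol2inv(Rx) %*% crossprod(X, Vi %*% y))
    r <- y - drop(X %*% beta)
    -0.5 * (2 * sum(log(diag(R))) + 2 * sum(log(diag(Rx))) +
              sum(r * (Vi %*% r)) + (n - p) * log(2 * pi))
  }, numeric(1))
  grid
}
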