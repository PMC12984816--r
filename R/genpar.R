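# Derived genetic parameters: heritabilities, latent-scale shares for
# threshold models, genetic/phenotypic correlations, delta-method SEs.

#' Narrow-sense heritability from linear-model components
#'
#' `h2 = sigma_a^2 / (sigma_a^2 + sigma_e^2)`.
#'
#' @param sigma_a2 additive genetic variance (>= 0).
#' @param sigma_e2 residual variance (> 0 unless `sigma_a2 > 0`).
#' @return heritability in `[0, 1]`.
#' @export
h2_linear <- function(sigma_a2, sigma_e2) {
  if (any(sigma_a2 < 0) || any(sigma_e2 < 0)) stop("variances must be >= 0")
  tot <- sigma_a2 + sigma_e2
  if (any(tot == 0)) stop("sigma_a2 + sigma_e2 must be > 0")
  sigma_a2 / tot
}

#' Latent-scale heritability of a threshold sire-dam model
#'
#' With the residual variance fixed to 1 on the liability scale,
#' `h2 = (sigma_s^2 + sigma_d^2) / (sigma_s^2 + sigma_d^2 + sigma_f^2 + 1)`.
#'
#' @param sigma_s2,sigma_d2 sire and dam variance components.
#' @param sigma_f2 full-sib common-environment variance (default 0).
#' @return latent heritability in `[0, 1)`.
#' @export
h2_latent <- function(sigma_s2, sigma_d2, sigma_f2 = 0) {
  if (any(c(sigma_s2, sigma_d2, sigma_f2) < 0)) stop("variances must be >= 0")
  (sigma_s2 + sigma_d2) / (sigma_s2 + sigma_d2 + sigma_f2 + 1)
}

#' Latent-scale common-environment fraction
#'
#' `c2 = sigma_f^2 / (sigma_s^2 + sigma_d^2 + sigma_f^2 + 1)`.
#'
#' @inheritParams h2_latent
#' @return `c2` in `[0, 1)`.
#' @export
c2_latent <- function(sigma_f2, sigma_s2, sigma_d2) {
  if (any(c(sigma_s2, sigma_d2, sigma_f2) < 0)) stop("variances must be >= 0")
  sigma_f2 / (sigma_s2 + sigma_d2 + sigma_f2 + 1)
}

#' Genetic and phenotypic correlation matrices from covariance components
#'
#' `r_g(i,j) = G_ij / sqrt(G_ii G_jj)`;
#' `r_p(i,j) = (G_ij + E_ij) / sqrt((G_ii + E_ii)(G_jj + E_jj))`.
#' Entries with a zero diagonal are returned as `NA` rather than failing.
#'
#' @param G genetic covariance matrix.
#' @param E residual covariance matrix (same dimension).
#' @return list with matrices `r_g` and `r_p`.
#' @export
correlations <- function(G, E) {
  stopifnot(all(dim(G) == dim(E)))
  list(r_g = cov2cor_safe(as.matrix(G)),
       r_p = cov2cor_safe(as.matrix(G) + as.matrix(E)))
}

# position of component (struct, t, u) in the fit's parameter vector
.vc_pos <- function(fit, struct, t, u) {
  pi <- fit$param_index
  which(pi$struct == struct & pi$t == min(t, u) & pi$u == max(t, u))
}

# delta-method SE for a smooth function of the variance components.
# grad_list: named positions -> partial derivatives.
.delta_se <- function(fit, grad_pos, grad_val) {
  Vc <- fit$vcov_vc
  if (anyNA(Vc)) return(NA_real_)
  g <- numeric(nrow(fit$param_index))
  g[grad_pos] <- grad_val
  v <- drop(t(g) %*% Vc %*% g)
  if (!is.finite(v) || v < 0) NA_real_ else sqrt(v)
}

#' Heritabilities (with SEs) from an animal-model fit
#'
#' @param fit an [animal_reml()] object.
#' @return data.frame with `trait`, `h2`, `se` (first-order delta method on
#'   the inverse average-information matrix).
#' @export
h2 <- function(fit) {
  stopifnot(inherits(fit, "animal_reml"))
  out <- do.call(rbind, lapply(seq_along(fit$traits), function(k) {
    ga <- fit$G[k, k]; ge <- fit$E[k, k]
    if (!is.null(fit$F)) ge <- ge + 0  # h2 defined against a + e only
    tot <- ga + ge
    se <- .delta_se(fit,
                    c(.vc_pos(fit, "G", k, k), .vc_pos(fit, "E", k, k)),
                    c(ge / tot^2, -ga / tot^2))
    data.frame(trait = fit$traits[k], h2 = ga / tot, se = se)
  }))
  rownames(out) <- NULL
  out
}

# r_g(i,j) and its delta SE from fit
.rg_se <- function(fit, i, j) {
  gii <- fit$G[i, i]; gjj <- fit$G[j, j]; gij <- fit$G[i, j]
  r <- gij / sqrt(gii * gjj)
  se <- .delta_se(fit,
                  c(.vc_pos(fit, "G", i, j), .vc_pos(fit, "G", i, i),
                    .vc_pos(fit, "G", j, j)),
                  c(1 / sqrt(gii * gjj), -r / (2 * gii), -r / (2 * gjj)))
  c(r, se)
}

.rp_se <- function(fit, i, j) {
  pii <- fit$G[i, i] + fit$E[i, i]; pjj <- fit$G[j, j] + fit$E[j, j]
  pij <- fit$G[i, j] + fit$E[i, j]
  r <- pij / sqrt(pii * pjj)
  pos <- list(.vc_pos(fit, "G", i, j), .vc_pos(fit, "E", i, j),
              .vc_pos(fit, "G", i, i), .vc_pos(fit, "E", i, i),
              .vc_pos(fit, "G", j, j), .vc_pos(fit, "E", j, j))
  val <- c(1 / sqrt(pii * pjj), 1 / sqrt(pii * pjj),
           -r / (2 * pii), -r / (2 * pii), -r / (2 * pjj), -r / (2 * pjj))
  keep <- vapply(pos, length, integer(1)) == 1L   # pinned entries are absent
  se <- .delta_se(fit, unlist(pos[keep]), val[keep])
  c(r, se)
}

#' Genetic-parameter report from a fitted model
#'
#' Collects the quantities breeders report: per-trait heritabilities with
#' SEs, and for multi-trait fits the genetic correlations (above the
#' diagonal), phenotypic correlations (below the diagonal) and
#' heritabilities (on the diagonal), each with a delta-method SE and a Wald
#' z significance label (`*` p < 0.05, `**` p < 0.01, approximate). Point
#' estimates that fall outside the admissible range through sampling noise
#' are clipped to the boundary and flagged.
#'
#' For threshold fits the report carries the latent-scale heritability and
#' common-environment fraction with posterior SDs.
#'
#' @param fit an [animal_reml()] or `threshold_fit` object.
#' @return an object of class `param_report`.
#' @export
genetic_parameters <- function(fit) {
  if (inherits(fit, "threshold_fit")) {
    s <- fit$posterior
    out <- structure(list(
      type = "threshold",
      h2_latent = s["h2_latent", "mean"], h2_latent_se = s["h2_latent", "sd"],
      c2_latent = s["c2_latent", "mean"], c2_latent_se = s["c2_latent", "sd"],
      sigma_s2 = s["sigma_s2", "mean"], sigma_d2 = s["sigma_d2", "mean"],
      sigma_f2 = s["sigma_f2", "mean"],
      n = fit$n), class = "param_report")
    return(out)
  }
  stopifnot(inherits(fit, "animal_reml"))
  Tn <- length(fit$traits)
  est <- matrix(NA_real_, Tn, Tn, dimnames = list(fit$traits, fit$traits))
  se <- est
  clipped <- matrix(FALSE, Tn, Tn)
  h <- h2(fit)
  diag(est) <- h$h2; diag(se) <- h$se
  if (Tn > 1) {
    for (i in seq_len(Tn - 1)) for (j in seq.int(i + 1, Tn)) {
      rg <- .rg_se(fit, i, j)
      rp <- .rp_se(fit, i, j)
      if (is.finite(rg[1]) && abs(rg[1]) > 1) { rg[1] <- sign(rg[1]); clipped[i, j] <- TRUE }
      if (is.finite(rp[1]) && abs(rp[1]) > 1) { rp[1] <- sign(rp[1]); clipped[j, i] <- TRUE }
      est[i, j] <- rg[1]; se[i, j] <- rg[2]
      est[j, i] <- rp[1]; se[j, i] <- rp[2]
    }
  }
  structure(list(type = "linear", estimate = est, se = se, clipped = clipped,
                 n = fit$n_records, traits = fit$traits),
            class = "param_report")
}

# Wald-z star label (approximate; reported as such)
.stars <- function(est, se) {
  if (!is.finite(est) || !is.finite(se) || se <= 0) return("")
  z <- abs(est / se)
  if (z > stats::qnorm(0.995)) "**" else if (z > stats::qnorm(0.975)) "*" else ""
}

#' @export
print.param_report <- function(x, digits = 2, ...) {
  if (x$type == "threshold") {
    cat("Threshold-model latent-scale parameters (posterior mean +/- SD)\n")
    cat(sprintf("  h2 (latent) = %.3f +/- %.3f\n", x$h2_latent, x$h2_latent_se))
    cat(sprintf("  c2          = %.3f +/- %.3f\n", x$c2_latent, x$c2_latent_se))
    cat(sprintf("  sire %.4f  dam %.4f  family %.4f  residual 1 (fixed)\n",
                x$sigma_s2, x$sigma_d2, x$sigma_f2))
    return(invisible(x))
  }
  Tn <- length(x$traits)
  cat("Genetic parameters: genetic correlations above the diagonal,\n",
      "phenotypic correlations below, heritabilities on the diagonal\n",
      "(SE in parentheses; *,** approximate Wald z)\n", sep = "")
  M <- matrix("", Tn, Tn, dimnames = list(x$traits, x$traits))
  for (i in seq_len(Tn)) for (j in seq_len(Tn)) {
    e <- x$estimate[i, j]; s <- x$se[i, j]
    M[i, j] <- sprintf("%.*f(%s)%s%s", digits, e,
                       ifelse(is.finite(s), sprintf("%.*f", digits, s), "NA"),
                       .stars(e, s),
                       if (isTRUE(x$clipped[i, j])) "c" else "")
  }
  print(M, quote = FALSE)
  invisible(x)
}

#' @export
as.data.frame.param_report <- function(x, ...) {
  if (x$type == "threshold")
    return(data.frame(quantity = c("h2_latent", "c2_latent"),
                      estimate = c(x$h2_latent, x$c2_latent),
                      se = c(x$h2_latent_se, x$c2_latent_se)))
  Tn <- length(x$traits)
  rows <- list()
  for (i in seq_len(Tn)) {
    rows[[length(rows) + 1]] <-
      data.frame(quantity = "h2", trait1 = x$traits[i], trait2 = x$traits[i],
                 estimate = x$estimate[i, i], se = x$se[i, i])
  }
  if (Tn > 1) for (i in seq_len(Tn - 1)) for (j in seq.int(i + 1, Tn)) {
    rows[[length(rows) + 1]] <-
      data.frame(quantity = "r_g", trait1 = x$traits[i], trait2 = x$traits[j],
                 estimate = x$estimate[i, j], se = x$se[i, j])
    rows[[length(rows) + 1]] <-
      data.frame(quantity = "r_p", trait1 = x$traits[i], trait2 = x$traits[j],
                 estimate = x$estimate[j, i], se = x$se[j, i])
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
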