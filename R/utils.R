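# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG state
#'
#' Runs `expr` with the RNG seeded to `seed`, then restores the caller's
#' RNG state, so simulation helpers never trample the session stream.
#' @noRd
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Deterministic sub-seed per pipeline stage; keeps results independent of the
# order in which stages consume random numbers. Stays well below 2^31.
sub_seed <- function(seed, stage) {
  (as.integer(seed) %% 1000000L) * 1000L + as.integer(stage) %% 1000L
}

# Truncated standard-normal-family draws by inverse CDF, vectorized.
# mean, lower, upper recycled to common length; sd is scalar.
rtruncnorm <- function(n, mean, sd, lower, upper) {
  plo <- pnorm(lower, mean, sd)
  phi <- pnorm(upper, mean, sd)
  # guard against both bounds collapsing in one tail
  plo <- pmin(pmax(plo, 0), 1 - 1e-12)
  phi <- pmax(pmin(phi, 1), plo + 1e-12)
  u <- runif(n, plo, phi)
  qnorm(pmin(pmax(u, 1e-12), 1 - 1e-12), mean, sd)
}

# Symmetrize and, if needed, bend a covariance matrix to the PSD cone by
# eigenvalue truncation (smallest eigenvalues raised to `floor` times the
# largest). Used to close correlation tables that are reported pairwise.
bend_psd <- function(S, floor = 1e-6) {
  S <- (S + t(S)) / 2
  e <- eigen(S, symmetric = TRUE)
  lo <- floor * max(e$values)
  if (min(e$values) >= lo) return(S)
  v <- pmax(e$values, lo)
  S2 <- e$vectors %*% (v * t(e$vectors))
  dimnames(S2) <- dimnames(S)
  (S2 + t(S2)) / 2
}

# covariance -> correlation with guard for zero diagonals
cov2cor_safe <- function(S) {
  d <- sqrt(diag(S))
  r <- S / outer(d, d)
  r[!is.finite(r)] <- NA_real_
  diag(r)[is.finite(diag(r))] <- 1
  r
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# symmetric PSD square root (handles rank-deficient and zero matrices,
# where chol() would fail)
mat_sqrt <- function(S) {
  e <- eigen((S + t(S)) / 2, symmetric = TRUE)
  e$vectors %*% (sqrt(pmax(e$values, 0)) * t(e$vectors))
}
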