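# Pedigree ingestion, validation, relationship matrices and family structure.

#' Build a validated, topologically sorted pedigree
#'
#' Constructs a `pedigree` object from individual/sire/dam (and optionally
#' sex) records. Parents that are named but never declared as individuals are
#' auto-created as founders. Records are re-ordered so that parents always
#' precede offspring; ties are broken by input order so the result is
#' reproducible.
#'
#' @param x a data.frame with columns `id`, `sire`, `dam` and optionally
#'   `sex` (`"F"`, `"M"`, `"U"` or `NA`). `individual` is accepted as an
#'   alias for `id`.
#' @param unknown_codes character vector of tokens denoting an unknown
#'   parent. Defaults to `c("0", "NA", "")`.
#' @return an object of class `pedigree`: a data.frame with columns `id`,
#'   `sire`, `dam`, `sex`, `generation`, plus attributes `sire_idx`/`dam_idx`
#'   (integer row indices, 0 = unknown) and `founder_count`.
#' @examples
#' ped <- as_pedigree(data.frame(id = c("S", "D", "X"),
#'                               sire = c(0, 0, "S"), dam = c(0, 0, "D")))
#' ped$generation   # 0, 0, 1
#' @export
as_pedigree <- function(x, unknown_codes = c("0", "NA", "")) {
  nm <- names(x)
  if ("individual" %in% nm && !"id" %in% nm) names(x)[nm == "individual"] <- "id"
  req <- c("id", "sire", "dam")
  if (!all(req %in% names(x)))
    stop("pedigree needs columns id, sire and dam (got: ",
         paste(names(x), collapse = ", "), ")")
  id   <- trimws(as.character(x$id))
  sire <- trimws(as.character(x$sire))
  dam  <- trimws(as.character(x$dam))
  sex  <- if ("sex" %in% names(x)) toupper(trimws(as.character(x$sex))) else rep(NA_character_, length(id))
  sex[!sex %in% c("F", "M", "U")] <- NA_character_

  dup <- unique(id[duplicated(id)])
  if (length(dup))
    stop("duplicate individual id(s): ", paste(utils::head(dup, 5), collapse = ", "))
  unk <- function(p) is.na(p) | p %in% unknown_codes
  sire[unk(sire)] <- NA_character_
  dam[unk(dam)]   <- NA_character_
  self_par <- !is.na(sire) & !is.na(dam) & sire == dam
  if (any(self_par))
    stop("sire and dam identical for: ", paste(id[self_par], collapse = ", "))
  if (any(bad <- (!is.na(sire) & sire == id) | (!is.na(dam) & dam == id)))
    stop("individual listed as its own parent: ", paste(id[bad], collapse = ", "))

  # auto-create founders for named-but-undeclared parents (input order)
  named <- unique(c(sire[!is.na(sire)], dam[!is.na(dam)]))
  implied <- setdiff(named, id)
  if (length(implied)) {
    id   <- c(implied, id)
    sire <- c(rep(NA_character_, length(implied)), sire)
    dam  <- c(rep(NA_character_, length(implied)), dam)
    sex  <- c(rep(NA_character_, length(implied)), sex)
  }
  n <- length(id)
  si <- match(sire, id); si[is.na(si)] <- 0L
  di <- match(dam, id);  di[is.na(di)] <- 0L

  # Kahn-style repeated passes; stable with respect to input order.
  placed <- logical(n)
  gen <- rep(NA_integer_, n)
  ord <- integer(0)
  repeat {
    ready <- !placed &
      (si == 0L | placed[pmax(si, 1L)]) &
      (di == 0L | placed[pmax(di, 1L)])
    if (!any(ready)) break
    idx <- which(ready)
    g_s <- ifelse(si[idx] == 0L, -1L, gen[pmax(si[idx], 1L)])
    g_d <- ifelse(di[idx] == 0L, -1L, gen[pmax(di[idx], 1L)])
    gen[idx] <- pmax(g_s, g_d) + 1L
    placed[idx] <- TRUE
    ord <- c(ord, idx)
  }
  if (!all(placed)) {
    # walk parent pointers from a stuck node to name the offending cycle
    start <- which(!placed)[1]
    chain <- integer(0); cur <- start
    while (!cur %in% chain) {
      chain <- c(chain, cur)
      nxt <- c(si[cur], di[cur])
      nxt <- nxt[nxt != 0L & !placed[pmax(nxt, 1L)]]
      cur <- nxt[1]
    }
    chain <- c(chain[which(chain == cur):length(chain)], cur)
    stop("pedigree cycle detected: ", paste(id[chain], collapse = " -> "))
  }

  perm <- ord
  id <- id[perm]; sire <- sire[perm]; dam <- dam[perm]
  sex <- sex[perm]; gen <- gen[perm]
  si <- match(sire, id); si[is.na(si)] <- 0L
  di <- match(dam, id);  di[is.na(di)] <- 0L

  out <- data.frame(id = id, sire = sire, dam = dam, sex = sex,
                    generation = gen, stringsAsFactors = FALSE)
  attr(out, "sire_idx") <- si
  attr(out, "dam_idx") <- di
  attr(out, "founder_count") <- sum(si == 0L & di == 0L)
  class(out) <- c("pedigree", "data.frame")
  out
}

#' Read a pedigree from a CSV file
#'
#' Expects a header with columns `id` (or `individual`), `sire`, `dam` and
#' optionally `sex` coded `F`/`M`/`U`.
#'
#' @inheritParams as_pedigree
#' @param path path to the CSV file.
#' @return a [as_pedigree()] object.
#' @export
read_pedigree <- function(path, unknown_codes = c("0", "NA", "")) {
  df <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
  as_pedigree(df, unknown_codes = unknown_codes)
}

#' @export
print.pedigree <- function(x, ...) {
  cat("Pedigree: ", nrow(x), " individuals (",
      attr(x, "founder_count"), " founders), max depth ",
      max(x$generation), "\n", sep = "")
  print.data.frame(utils::head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat("... (", nrow(x) - 10, " more rows)\n", sep = "")
  invisible(x)
}

#' @export
summary.pedigree <- function(object, ...) {
  fam <- family_structure(object)
  structure(list(n = nrow(object),
                 founders = attr(object, "founder_count"),
                 depth = max(object$generation),
                 families = fam$n_families,
                 sires = fam$n_sires, dams = fam$n_dams,
                 mean_F = mean(inbreeding(object))),
            class = "summary.pedigree")
}

#' @export
print.summary.pedigree <- function(x, ...) {
  cat("Pedigree summary\n",
      "  individuals: ", x$n, " (", x$founders, " founders)\n",
      "  generation depth: ", x$depth, "\n",
      "  full-sib families: ", x$families, " from ", x$sires,
      " sires x ", x$dams, " dams\n",
      "  mean inbreeding: ", signif(x$mean_F, 4), "\n", sep = "")
  invisible(x)
}

# kinship f(i,j) with memoisation; indices are row positions (0 = unknown).
# Desk-scale recursion: pedigrees here are shallow, the memo keeps it linear
# in the number of distinct pairs actually visited.
.kinship_env <- function(ped) {
  si <- attr(ped, "sire_idx"); di <- attr(ped, "dam_idx")
  memo <- new.env(hash = TRUE, parent = emptyenv())
  f <- function(i, j) {
    if (i == 0L || j == 0L) return(0)
    if (i > j) { k <- i; i <- j; j <- k }
    key <- paste0(i, ":", j)
    v <- memo[[key]]
    if (!is.null(v)) return(v)
    v <- if (i == j) 0.5 * (1 + f(si[i], di[i]))
         else 0.5 * (f(i, si[j]) + f(i, di[j]))
    memo[[key]] <- v
    v
  }
  f
}

#' Inbreeding coefficients from a pedigree
#'
#' @param ped a [as_pedigree()] object.
#' @return numeric vector `F` (one per individual, pedigree order).
#' @export
inbreeding <- function(ped) {
  stopifnot(inherits(ped, "pedigree"))
  si <- attr(ped, "sire_idx"); di <- attr(ped, "dam_idx")
  f <- .kinship_env(ped)
  vapply(seq_len(nrow(ped)), function(i) {
    if (si[i] == 0L || di[i] == 0L) 0 else f(si[i], di[i])
  }, numeric(1))
}

# Mendelian-sampling variance multipliers d_i (fraction of sigma_a^2):
# both parents known: 0.5 - 0.25 (F_s + F_d); one known: 0.75 - 0.25 F_p;
# none: 1.
mendelian_d <- function(ped, Fcoef = inbreeding(ped)) {
  si <- attr(ped, "sire_idx"); di <- attr(ped, "dam_idx")
  Fs <- ifelse(si == 0L, NA, Fcoef[pmax(si, 1L)])
  Fd <- ifelse(di == 0L, NA, Fcoef[pmax(di, 1L)])
  d <- ifelse(si > 0L & di > 0L, 0.5 - 0.25 * (Fs + Fd),
       ifelse(si > 0L, 0.75 - 0.25 * Fs,
       ifelse(di > 0L, 0.75 - 0.25 * Fd, 1)))
  as.numeric(d)
}

#' Numerator relationship matrix (tabular method)
#'
#' Builds the dense additive relationship matrix A by the tabular method:
#' `a_ij = 0.5 (a_{i,s(j)} + a_{i,d(j)})` for `i < j` and
#' `a_jj = 1 + 0.5 a_{s(j),d(j)}`.
#'
#' @param ped a [as_pedigree()] object.
#' @return dense symmetric matrix with dimnames = individual ids and an
#'   attribute `inbreeding` (`diag(A) - 1`).
#' @examples
#' ped <- as_pedigree(data.frame(id = c("S", "D", "X"),
#'                               sire = c(0, 0, "S"), dam = c(0, 0, "D")))
#' build_A(ped)["X", "S"]   # 0.5
#' @export
build_A <- function(ped) {
  stopifnot(inherits(ped, "pedigree"))
  n <- nrow(ped)
  si <- attr(ped, "sire_idx"); di <- attr(ped, "dam_idx")
  A <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  for (j in seq_len(n)) {
    s <- si[j]; d <- di[j]
    if (j > 1L) {
      i <- seq_len(j - 1L)
      as_ <- if (s > 0L) A[i, s] else 0
      ad_ <- if (d > 0L) A[i, d] else 0
      v <- 0.5 * (as_ + ad_)
      A[i, j] <- v
      A[j, i] <- v
    }
    A[j, j] <- 1 + if (s > 0L && d > 0L) 0.5 * A[s, d] else 0
  }
  attr(A, "inbreeding") <- diag(A) - 1
  A
}

#' Sparse inverse of the numerator relationship matrix
#'
#' Direct construction of `A^{-1}` by the Henderson rules with the
#' Meuwissen-Luo inbreeding adjustment (no inversion of A involved):
#' for each individual the Mendelian-sampling variance
#' `d_i = 0.5 - 0.25 (F_s + F_d)` (adjusted when parents are unknown)
#' contributes `1/d_i` blocks over the (individual, sire, dam) triple.
#'
#' @param ped a [as_pedigree()] object.
#' @return a symmetric sparse `Matrix::dsCMatrix` with dimnames.
#' @export
build_A_inverse <- function(ped) {
  stopifnot(inherits(ped, "pedigree"))
  n <- nrow(ped)
  si <- attr(ped, "sire_idx"); di <- attr(ped, "dam_idx")
  d <- mendelian_d(ped)
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  add <- function(i, j, v) {
    ii <<- c(ii, i); jj <<- c(jj, j); xx <<- c(xx, v)
  }
  # vectorized triplet assembly
  b <- 1 / d
  add(seq_len(n), seq_len(n), b)
  hs <- which(si > 0L); hd <- which(di > 0L); hb <- which(si > 0L & di > 0L)
  if (length(hs)) { add(hs, si[hs], -b[hs] / 2); add(si[hs], hs, -b[hs] / 2)
                    add(si[hs], si[hs], b[hs] / 4) }
  if (length(hd)) { add(hd, di[hd], -b[hd] / 2); add(di[hd], hd, -b[hd] / 2)
                    add(di[hd], di[hd], b[hd] / 4) }
  if (length(hb)) { add(si[hb], di[hb], b[hb] / 4); add(di[hb], si[hb], b[hb] / 4) }
  M <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n),
                            dimnames = list(ped$id, ped$id))
  methods::as(Matrix::forceSymmetric(M), "symmetricMatrix")
}

#' Full-sib family structure of a pedigree
#'
#' Two individuals belong to the same full-sib family iff they share both
#' (known) parents. Individuals with any unknown parent get `NA` family.
#'
#' @param ped a [as_pedigree()] object.
#' @return a list of class `family_map`: `family` (named character vector),
#'   `n_families`, `family_sizes`, `n_sires`, `n_dams`, `sire_of`, `dam_of`.
#' @export
family_structure <- function(ped) {
  stopifnot(inherits(ped, "pedigree"))
  both <- !is.na(ped$sire) & !is.na(ped$dam)
  fam <- rep(NA_character_, nrow(ped))
  fam[both] <- paste(ped$sire[both], ped$dam[both], sep = "/")
  names(fam) <- ped$id
  sizes <- table(fam[both])
  # order families by first appearance, not alphabetically
  sizes <- sizes[unique(fam[both])]
  structure(list(family = fam,
                 n_families = length(sizes),
                 family_sizes = as.integer(sizes),
                 n_sires = length(unique(ped$sire[both])),
                 n_dams = length(unique(ped$dam[both])),
                 sire_of = stats::setNames(ped$sire, ped$id),
                 dam_of = stats::setNames(ped$dam, ped$id)),
            class = "family_map")
}

#' @export
print.family_map <- function(x, ...) {
  cat("Full-sib family map: ", x$n_families, " families from ",
      x$n_sires, " sires x ", x$n_dams, " dams\n",
      "  family sizes: ", paste(range(x$family_sizes), collapse = "-"),
      " (median ", stats::median(x$family_sizes), ")\n", sep = "")
  invisible(x)
}

# Connected components of the pedigree graph (individual -- known parents).
# Returns an integer component label per row. Used by the REML engine to
# block-diagonalize the phenotypic covariance.
ped_components <- function(ped) {
  n <- nrow(ped)
  si <- attr(ped, "sire_idx"); di <- attr(ped, "dam_idx")
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  union_ <- function(i, j) { ri <- find(i); rj <- find(j); if (ri != rj) parent[ri] <<- rj }
  for (k in seq_len(n)) {
    if (si[k] > 0L) union_(k, si[k])
    if (di[k] > 0L) union_(k, di[k])
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots))
}
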