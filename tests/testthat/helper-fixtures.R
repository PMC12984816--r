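# Shared fixtures, all generated in code.

trio_ped <- function() {
  as_pedigree(data.frame(id = c("S", "D", "X"),
                         sire = c("0", "0", "S"),
                         dam = c("0", "0", "D")))
}

small_spec <- function(...) {
  design_spec(n_sires = 8, n_dams = 12, n_families = 14,
              offspring_per_family = 15, ...)
}

# random multi-generation pedigree for matrix identities
random_pedigree <- function(n, n_founders = 30, seed = 1) {
  set.seed(seed)
  id <- sprintf("i%04d", seq_len(n))
  sire <- dam <- rep(NA_character_, n)
  for (k in seq.int(n_founders + 1, n)) {
    pick <- sample(k - 1, 2)
    sire[k] <- id[pick[1]]
    if (stats::runif(1) < 0.9) dam[k] <- id[pick[2]]
  }
  as_pedigree(data.frame(id = id, sire = sire, dam = dam))
}

# balanced paternal half-sib design: ns sires x 2 dams x k offspring,
# phenotypes generated directly from the sire/dam/residual decomposition
balanced_halfsib <- function(ns = 20, k = 10, sigma_a2 = 2, sigma_e2 = 3,
                             seed = 1) {
  set.seed(seed)
  sires <- sprintf("HS%02d", seq_len(ns))
  dams <- sprintf("HD%03d", seq_len(2 * ns))
  sire_of_fam <- rep(sires, each = 2)
  n <- 2 * ns * k
  off <- sprintf("HO%04d", seq_len(n))
  ped <- as_pedigree(data.frame(
    id = c(sires, dams, off),
    sire = c(rep(NA, 3 * ns), rep(sire_of_fam, each = k)),
    dam = c(rep(NA, 3 * ns), rep(dams, each = k))))
  s_eff <- stats::rnorm(ns, 0, sqrt(sigma_a2 / 4))
  d_eff <- stats::rnorm(2 * ns, 0, sqrt(sigma_a2 / 4))
  y <- rep(s_eff, each = 2 * k) + rep(d_eff, each = k) +
    stats::rnorm(n, 0, sqrt(sigma_a2 / 2 + sigma_e2))
  list(ped = ped,
       data = data.frame(id = off, y = y,
                         sire = rep(sire_of_fam, each = k),
                         dam = rep(dams, each = k)),
       sigma_a2 = sigma_a2, sigma_e2 = sigma_e2, ns = ns, k = k)
}

# method-of-moments additive variance from the balanced nested ANOVA
anova_sigma_a2 <- function(hs) {
  d <- hs$data
  gm <- mean(d$y)
  sire_means <- tapply(d$y, d$sire, mean)
  dam_means <- tapply(d$y, d$dam, mean)
  sire_of_dam <- tapply(d$sire, d$dam, function(x) x[1])
  k <- hs$k; ns <- hs$ns
  ss_sire <- 2 * k * sum((sire_means - gm)^2)
  ss_dam <- k * sum((dam_means - sire_means[sire_of_dam])^2)
  ss_within <- sum((d$y - dam_means[d$dam])^2)
  ms_sire <- ss_sire / (ns - 1)
  ms_dam <- ss_dam / ns                     # ns dams-within-sires df
  ms_within <- ss_within / (2 * ns * (k - 1))
  sigma_d2 <- (ms_dam - ms_within) / k
  sigma_s2 <- (ms_sire - ms_dam) / (2 * k)
  # sire and dam components each estimate sigma_a2 / 4
  2 * (sigma_s2 + sigma_d2)
}

# i.i.d. ordinal scores with structured-looking (but inert) parent labels
ordinal_null_data <- function(n = 1500, probs = c(0.6, 0.25, 0.1, 0.05),
                              n_sires = 25, n_dams = 40, seed = 1) {
  set.seed(seed)
  data.frame(id = sprintf("N%04d", seq_len(n)),
             score = sample(seq_along(probs), n, TRUE, probs),
             sire = sample(sprintf("ns%02d", seq_len(n_sires)), n, TRUE),
             dam = sample(sprintf("nd%02d", seq_len(n_dams)), n, TRUE),
             family = sample(sprintf("nf%02d", seq_len(n_dams)), n, TRUE),
             sex = sample(c("F", "M", "U"), n, TRUE))
}
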