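## Independent brute-force oracles used across the test suite.  These are
## deliberately written as literal transcriptions of the definitions
## (double loops, enumeration), independent of the package's vectorised
## code paths.

randomAlignment <- function(n, L, gapProb = 0, nProb = 0,
                            alphabet = c("A", "C", "G", "T")) {
  m <- matrix(sample(alphabet, n * L, replace = TRUE), n, L)
  if (gapProb > 0) m[runif(n * L) < gapProb] <- "-"
  if (nProb > 0) m[runif(n * L) < nProb] <- "N"
  SeqAlignment(apply(m, 1L, paste, collapse = ""),
               ids = paste0("s", seq_len(n)))
}

## complete-deletion column mask, by literal loop
oracleAnalysedSites <- function(aln) {
  m <- alignmentMatrix(aln)
  keep <- logical(ncol(m))
  for (s in seq_len(ncol(m))) {
    ok <- TRUE
    for (i in seq_len(nrow(m)))
      if (m[i, s] == "-" || m[i, s] == "N") ok <- FALSE
    keep[s] <- ok
  }
  keep
}

## haplotype partition via unique strings restricted to analysed sites
oracleHaplotypes <- function(aln) {
  m <- alignmentMatrix(aln)
  keep <- oracleAnalysedSites(aln)
  keys <- character(nrow(m))
  for (i in seq_len(nrow(m)))
    keys[i] <- paste(m[i, keep], collapse = "")
  keys
}

oracleHd <- function(counts, n = sum(counts)) {
  p <- counts / n
  n * (1 - sum(p^2)) / (n - 1)
}

oracleHdVar <- function(counts, n = sum(counts)) {
  p <- counts / n
  s2 <- sum(p^2); s3 <- sum(p^3)
  2 / (n * (n - 1)) * (2 * (n - 2) * (s3 - s2^2) + s2 - s2^2)
}

## pi and k by explicit pair enumeration
oraclePiK <- function(aln) {
  m <- alignmentMatrix(aln)
  keep <- oracleAnalysedSites(aln)
  n <- nrow(m)
  tot <- 0; np <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    d <- 0
    for (s in which(keep)) if (m[i, s] != m[j, s]) d <- d + 1
    tot <- tot + d; np <- np + 1
  }
  k <- tot / np
  list(k = k, pi = if (sum(keep) > 0) k / sum(keep) else NA_real_)
}

## per-column tally classification
oracleSiteClasses <- function(aln) {
  m <- alignmentMatrix(aln)
  n_gap <- 0; n_var <- 0; s2 <- 0; p2 <- 0; p3 <- 0
  for (s in seq_len(ncol(m))) {
    col <- m[, s]
    if (any(col %in% c("-", "N"))) { n_gap <- n_gap + 1; next }
    tab <- table(col)
    if (length(tab) < 2) next
    n_var <- n_var + 1
    pi_site <- sum(tab >= 2) >= 2
    if (length(tab) == 2 && !pi_site) s2 <- s2 + 1
    if (length(tab) == 2 && pi_site) p2 <- p2 + 1
    if (length(tab) == 3 && pi_site) p3 <- p3 + 1
  }
  list(n_variable = n_var, n_gap_sites = n_gap, n_singleton_2var = s2,
       n_pi_2var = p2, n_pi_3var = p3)
}

## Tajima's D transcribed step by step from the 1989 definitions
oracleTajimaD <- function(aln) {
  m <- alignmentMatrix(aln)
  keep <- oracleAnalysedSites(aln)
  n <- nrow(m)
  S <- 0
  for (s in which(keep)) if (length(unique(m[, s])) > 1) S <- S + 1
  if (S == 0) return(NA_real_)
  k <- oraclePiK(aln)$k
  a1 <- 0; a2 <- 0
  for (i in 1:(n - 1)) { a1 <- a1 + 1 / i; a2 <- a2 + 1 / i^2 }
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  (k - S / a1) / sqrt(c1 / a1 * S + c2 / (a1^2 + a2) * S * (S - 1))
}

## Fu & Li's D* (1993, with the Simonsen et al. 1995 variance terms)
oracleFuLiDstar <- function(aln) {
  m <- alignmentMatrix(aln)
  keep <- oracleAnalysedSites(aln)
  n <- nrow(m)
  eta <- 0; eta_s <- 0
  for (s in which(keep)) {
    tab <- table(m[, s])
    if (length(tab) > 1) {
      eta <- eta + length(tab) - 1
      eta_s <- eta_s + sum(tab == 1)
    }
  }
  if (eta == 0) return(NA_real_)
  a <- sum(1 / seq_len(n - 1)); b <- sum(1 / seq_len(n - 1)^2)
  an1 <- a + 1 / n
  cn <- 2 * (n * a - 2 * (n - 1)) / ((n - 1) * (n - 2))
  dn <- cn + (n - 2) / (n - 1)^2 +
    (2 / (n - 1)) * (3 / 2 - (2 * an1 - 3) / (n - 2) - 1 / n)
  vD <- ((n / (n - 1))^2 * b + a^2 * dn -
         2 * (n * a * (a + 1)) / (n - 1)^2) / (a^2 + b)
  uD <- (n / (n - 1)) * (a - n / (n - 1)) - vD
  ((n / (n - 1)) * eta - a * eta_s) / sqrt(uD * eta + vD * eta^2)
}

## unsigned Stirling numbers of the first kind by brute-force permutation
## cycle counting (n <= 7)
oracleStirlingByCycles <- function(n) {
  perms <- allPerms(n)
  counts <- integer(n)
  for (p in perms) {
    seen <- logical(n); ncyc <- 0
    for (i in seq_len(n)) if (!seen[i]) {
      ncyc <- ncyc + 1
      j <- i
      while (!seen[j]) { seen[j] <- TRUE; j <- p[j] }
    }
    counts[ncyc] <- counts[ncyc] + 1L
  }
  counts
}

allPerms <- function(n) {
  if (n == 1L) return(list(1L))
  sub <- allPerms(n - 1L)
  out <- list()
  for (p in sub) for (pos in seq_len(n))
    out[[length(out) + 1L]] <- append(p, n, after = pos - 1L)
  out
}

## exact P(K >= k | theta, n) by Ewens enumeration from brute-force
## Stirling numbers
oracleEwensTail <- function(n, k, theta) {
  s <- oracleStirlingByCycles(n)
  probs <- s * theta^(seq_len(n)) / prod(theta + 0:(n - 1))
  sum(probs[k:n])
}

## AMOVA sums of squares by literal double loops over the definitions
oracleAmova <- function(aln, pop) {
  m <- alignmentMatrix(aln)
  keep <- oracleAnalysedSites(aln)
  n <- nrow(m)
  d2 <- matrix(0, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    d <- 0
    for (s in which(keep)) if (m[i, s] != m[j, s]) d <- d + 1
    d2[i, j] <- d2[j, i] <- d
  }
  pops <- unique(pop)
  N <- n; P <- length(pops)
  SS_tot <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) SS_tot <- SS_tot + d2[i, j]
  SS_tot <- SS_tot / N
  SS_w <- 0
  for (g in pops) {
    idx <- which(pop == g)
    if (length(idx) > 1) {
      s <- 0
      for (a in seq_along(idx)) for (b in seq_along(idx))
        if (a < b) s <- s + d2[idx[a], idx[b]]
      SS_w <- SS_w + s / length(idx)
    }
  }
  SS_a <- SS_tot - SS_w
  sizes <- as.numeric(table(pop)[pops])
  s2w <- SS_w / (N - P)
  nprime <- (N - sum(sizes^2) / N) / (P - 1)
  s2a <- (SS_a / (P - 1) - s2w) / nprime
  list(SSD_among = SS_a, SSD_within = SS_w, sigma2_among = s2a,
       sigma2_within = s2w,
       Phi_ST = if (s2a + s2w > 0) s2a / (s2a + s2w) else NA_real_)
}

## exact Mantel permutation p by full enumeration
oracleMantelExact <- function(genM, geoM, two_sided = TRUE) {
  n <- nrow(genM)
  ut <- upper.tri(genM)
  r_obs <- cor(genM[ut], geoM[ut])
  rs <- vapply(allPerms(n), function(p) cor(genM[ut], geoM[p, p][ut]),
               numeric(1))
  if (two_sided) mean(abs(rs) >= abs(r_obs) - 1e-12)
  else mean(rs >= r_obs - 1e-12)
}

## Monte-Carlo oracle for the parsimony probability: simulate the same
## finite-sites Jukes-Cantor chain (Poisson substitution count, uniform
## sites, 1/3 reversion) and estimate P(M = j | D = j) directly.
oracleParsimonyProbMC <- function(j, m, nSim = 200000) {
  p <- j / m
  lambda <- -0.75 * m * log(1 - 4 * p / 3)
  M <- rpois(nSim, lambda)
  hits_j <- 0; hits_pars <- 0
  for (r in seq_len(nSim)) {
    d <- 0L
    if (M[r] > 0) for (s in seq_len(M[r])) {
      if (runif(1) * m < d) {           # hit a differing site
        if (runif(1) < 1 / 3) d <- d - 1L
      } else d <- d + 1L
    }
    if (d == j) {
      hits_j <- hits_j + 1
      if (M[r] == j) hits_pars <- hits_pars + 1
    }
  }
  hits_pars / hits_j
}

## build a single-population HaplotypeTable directly from sequences
.mkHaps <- function(seqs, counts = rep(1, length(seqs))) {
  ids <- paste0("Hap_", seq_along(seqs))
  cnt <- matrix(as.integer(counts), ncol = 1,
                dimnames = list(ids, "all"))
  names(seqs) <- ids
  new("HaplotypeTable", sequences = seqs, counts = cnt,
      locus = "demo", inheritance = "autosomal")
}

## one-population scenario with a size prior: fast ABC exercise model
.lowDivModel <- function(name = "low", Nmin = 500, Nmax = 2000)
  scenarioModel(name,
    data.frame(name = "P1", sampled = TRUE, size = "N1",
               stringsAsFactors = FALSE),
    NULL, priors = list(N1 = c(Nmin, Nmax)))

.abcDesign <- function(n = 10, L = 300)
  studyDesign(
    data.frame(pop = "P1", deme = "P1", lat = 0, lon = 0,
               n_control_region = n, stringsAsFactors = FALSE),
    data.frame(locus = "control_region", L = L, inheritance = "autosomal",
               mu_min = 2e-7, mu_max = 2e-7, kappa_min = 2, kappa_max = 2,
               p_inv = 0.1, stringsAsFactors = FALSE))

## neutral single-population scenario + single-locus design for
## coalescent calibration tests
constModel <- function() {
  scenarioModel("const",
    data.frame(name = "P1", sampled = TRUE, size = "N1",
               stringsAsFactors = FALSE),
    NULL, priors = list(N1 = c(999, 1001)))
}

oneLocusDesign <- function(n, L, inheritance = "autosomal", p_inv = 0) {
  studyDesign(
    data.frame(pop = "P1", deme = "P1", lat = 0, lon = 0,
               n_control_region = n, stringsAsFactors = FALSE),
    data.frame(locus = "control_region", L = L, inheritance = inheritance,
               mu_min = 1e-9, mu_max = 1e-9, kappa_min = 2, kappa_max = 2,
               p_inv = p_inv, stringsAsFactors = FALSE))
}
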