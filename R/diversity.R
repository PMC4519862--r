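#' @include seq_io.R
NULL

## Pairwise difference counts at analysed sites (complete deletion).
## Computed at haplotype level and expanded, which keeps the cost at
## O(H^2 L) rather than O(n^2 L).
.pairDiffMatrix <- function(aln) {
  keep <- analysedSites(aln)
  m <- aln@mat
  n <- nrow(m)
  if (!any(keep)) return(matrix(0, n, n, dimnames = list(rownames(m), rownames(m))))
  sub <- m[, keep, drop = FALSE]
  key <- apply(sub, 1L, paste, collapse = "")
  uk <- unique(key)
  idx <- match(key, uk)
  H <- length(uk)
  reps <- sub[!duplicated(key), , drop = FALSE]
  dh <- matrix(0, H, H)
  if (H > 1L) for (i in seq_len(H - 1L)) for (j in (i + 1L):H) {
    d <- sum(reps[i, ] != reps[j, ])
    dh[i, j] <- d; dh[j, i] <- d
  }
  D <- dh[idx, idx, drop = FALSE]
  dimnames(D) <- list(rownames(m), rownames(m))
  D
}

.nAnalysedSites <- function(aln) sum(analysedSites(aln))

#' Haplotype diversity
#'
#' Nei's (1987) haplotype (gene) diversity
#' \eqn{H_d = n(1 - \sum \hat p_i^2)/(n-1)} with its sampling variance
#' \deqn{V(H_d) = \frac{2}{n(n-1)}\left\{2(n-2)\left[\sum p_i^3 -
#'   \left(\sum p_i^2\right)^2\right] + \sum p_i^2 -
#'   \left(\sum p_i^2\right)^2\right\}.}
#'
#' @param counts vector of haplotype frequencies (counts).
#' @param n sample size; defaults to `sum(counts)`.
#' @return list with `Hd`, `var_Hd`, `sd_Hd` and a logical `defined` flag
#'   (`FALSE` for `n < 2`, in which case the values are `NA`).
#' @examples
#' haplotypeDiversity(c(2, 2))  # 0.6667
#' @export
haplotypeDiversity <- function(counts, n = sum(counts)) {
  counts <- counts[counts > 0]
  if (length(counts) && sum(counts) != n)
    stop("counts must sum to n")
  if (n < 2)
    return(list(Hd = NA_real_, var_Hd = NA_real_, sd_Hd = NA_real_,
                defined = FALSE))
  p <- counts / n
  s2 <- sum(p^2); s3 <- sum(p^3)
  Hd <- n * (1 - s2) / (n - 1)
  v <- 2 / (n * (n - 1)) * (2 * (n - 2) * (s3 - s2^2) + s2 - s2^2)
  list(Hd = Hd, var_Hd = v, sd_Hd = sqrt(max(v, 0)), defined = TRUE)
}

#' Nucleotide diversity and mean pairwise differences
#'
#' `k` is the mean number of pairwise differences over all `C(n,2)` sequence
#' pairs at analysed sites (complete deletion; see [analysedSites()]);
#' `pi = k / (number of analysed sites)`.  No additional `n/(n-1)` factor is
#' applied: averaging over all unordered pairs is already the sample
#' estimator used throughout the package.
#'
#' @param aln a [SeqAlignment-class] with at least 2 sequences.
#' @return list with `pi`, `k` and `n_sites` (analysed sites).
#' @export
nucleotideDiversity <- function(aln) {
  stopifnot(is(aln, "SeqAlignment"))
  n <- nSequences(aln)
  if (n < 2) stop("nucleotide diversity needs at least 2 sequences")
  D <- .pairDiffMatrix(aln)
  k <- mean(D[upper.tri(D)])
  ns <- .nAnalysedSites(aln)
  list(pi = if (ns > 0) k / ns else NA_real_, k = k, n_sites = ns)
}

## transition partner under the purine/pyrimidine pairing A<->G, C<->T
.isTransition <- function(a, b) {
  (a == "A" & b == "G") | (a == "G" & b == "A") |
  (a == "C" & b == "T") | (a == "T" & b == "C")
}

#' Pairwise genetic distances between haplotypes
#'
#' Distances are computed at sites free of gaps/`N` across the whole
#' haplotype set (complete deletion).  Available models: `"p"` (mismatch
#' proportion), `"JC69"` (\eqn{-\frac34\log(1-\frac43 p)}), `"K2P"`
#' (\eqn{-\frac12\log(1-2P-Q)-\frac14\log(1-2Q)} from the transition
#' proportion `P` and transversion proportion `Q`) and `"MCL"`, a
#' Tamura–Nei (1993) distance whose substitution pattern (transition
#' proportions and base frequencies) is pooled over all pairs in the spirit
#' of the composite-likelihood method, with uniform rates.
#'
#' Saturated pairs (logarithm of a non-positive number) yield `NaN`, are
#' flagged with a warning and excluded from the reported mean.
#'
#' @param haps a [HaplotypeTable-class] (or [SeqAlignment-class]) with at
#'   least 2 sequences.
#' @param model one of `"K2P"`, `"p"`, `"JC69"`, `"MCL"`.
#' @return list with `model`, the symmetric `entries` matrix and the `mean`
#'   of the off-diagonal upper triangle.
#' @export
distanceMatrix <- function(haps, model = c("K2P", "p", "JC69", "MCL")) {
  model <- match.arg(model)
  if (is(haps, "HaplotypeTable")) {
    seqs <- haps@sequences
    aln <- SeqAlignment(seqs, ids = names(seqs), locus = haps@locus,
                        inheritance = haps@inheritance)
  } else aln <- haps
  if (nSequences(aln) < 2) stop("need at least 2 haplotypes")
  keep <- analysedSites(aln)
  m <- aln@mat[, keep, drop = FALSE]
  n <- nrow(m); L <- ncol(m)
  d <- matrix(0, n, n, dimnames = list(rownames(aln@mat), rownames(aln@mat)))
  if (L == 0L) return(list(model = model, entries = d, mean = 0))

  ## per-pair mismatch, transition and transversion proportions
  P <- Q <- pp <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    a <- m[i, ]; b <- m[j, ]
    diff <- a != b
    ti <- sum(.isTransition(a[diff], b[diff]))
    tv <- sum(diff) - ti
    pp[i, j] <- pp[j, i] <- sum(diff) / L
    P[i, j] <- P[j, i] <- ti / L
    Q[i, j] <- Q[j, i] <- tv / L
  }

  if (model == "p") {
    d <- pp
  } else if (model == "JC69") {
    d <- -3 / 4 * log(1 - 4 * pp / 3)
  } else if (model == "K2P") {
    d <- -0.5 * log(1 - 2 * P - Q) - 0.25 * log(1 - 2 * Q)
  } else {
    ## MCL: TN93 with pooled substitution pattern.  The pooled ratios of
    ## purine transitions, pyrimidine transitions and transversions are
    ## applied to each pair's total divergence, then the TN93 correction is
    ## evaluated with pooled base frequencies.
    base <- table(factor(as.vector(m), levels = c("A", "C", "G", "T")))
    g <- as.numeric(base) / sum(base)
    names(g) <- c("A", "C", "G", "T")
    gR <- g["A"] + g["G"]; gY <- g["C"] + g["T"]
    P1tot <- P2tot <- Qtot <- ptot <- 0
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      a <- m[i, ]; b <- m[j, ]
      diff <- a != b
      pur <- (a %in% c("A", "G")) & (b %in% c("A", "G"))
      P1tot <- P1tot + sum(diff & pur)
      P2tot <- P2tot + sum(diff & (a %in% c("C", "T")) & (b %in% c("C", "T")))
      Qtot <- Qtot + sum(diff) - sum(diff & pur) -
        sum(diff & (a %in% c("C", "T")) & (b %in% c("C", "T")))
      ptot <- ptot + sum(diff)
    }
    if (ptot == 0) {
      d[] <- 0
    } else {
      f1 <- P1tot / ptot; f2 <- P2tot / ptot; fq <- Qtot / ptot
      k1 <- 2 * g["A"] * g["G"] / gR
      k2 <- 2 * g["C"] * g["T"] / gY
      k3 <- 2 * (gR * gY - g["A"] * g["G"] * gY / gR -
                 g["C"] * g["T"] * gR / gY)
      for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
        p1 <- pp[i, j] * f1; p2 <- pp[i, j] * f2; q <- pp[i, j] * fq
        w1 <- 1 - p1 / k1 - q / (2 * gR)
        w2 <- 1 - p2 / k2 - q / (2 * gY)
        w3 <- 1 - q / (2 * gR * gY)
        dd <- if (w1 <= 0 || w2 <= 0 || w3 <= 0) NaN else
          -k1 * log(w1) - k2 * log(w2) - k3 * log(w3)
        d[i, j] <- d[j, i] <- unname(dd)
      }
    }
  }
  diag(d) <- 0
  ut <- d[upper.tri(d)]
  if (any(!is.finite(ut)))
    warning(sprintf("%d saturated distance(s) flagged as undefined and excluded from the mean",
                    sum(!is.finite(ut))))
  list(model = model, entries = d, mean = mean(ut[is.finite(ut)]))
}

## number of segregating (analysed, >=2 variants) sites; eta (total minimum
## mutations = variants-1 per site); eta_s (mutations carried by exactly one
## sequence)
.segSites <- function(aln) {
  keep <- analysedSites(aln)
  m <- aln@mat[, keep, drop = FALSE]
  S <- 0L; eta <- 0L; eta_s <- 0L
  if (ncol(m)) for (s in seq_len(ncol(m))) {
    tab <- table(m[, s])
    if (length(tab) > 1L) {
      S <- S + 1L
      eta <- eta + length(tab) - 1L
      eta_s <- eta_s + sum(tab == 1L)
    }
  }
  list(S = S, eta = eta, eta_s = eta_s)
}

#' Tajima's D
#'
#' Tajima's (1989) statistic comparing the mean pairwise difference
#' estimator of theta with the segregating-sites (Watterson) estimator,
#' using the standard `a1, a2, b1, b2, c1, c2, e1, e2` constants.
#'
#' @param aln a [SeqAlignment-class] with `n >= 4`.
#' @return list with `D`, `S`, `k`, `n` and a `defined` flag (`FALSE` when
#'   `S == 0`).
#' @export
tajimaD <- function(aln) {
  stopifnot(is(aln, "SeqAlignment"))
  n <- nSequences(aln)
  if (n < 4) stop("Tajima's D needs at least 4 sequences")
  S <- .segSites(aln)$S
  D <- .pairDiffMatrix(aln)
  k <- mean(D[upper.tri(D)])
  if (S == 0L)
    return(list(D = NA_real_, S = 0L, k = k, n = n, defined = FALSE))
  i <- seq_len(n - 1)
  a1 <- sum(1 / i); a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  Dstat <- (k - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
  list(D = Dstat, S = S, k = k, n = n, defined = TRUE)
}

#' Fu and Li's D* (no outgroup)
#'
#' Fu and Li's (1993) D* contrasts the total number of mutations
#' \eqn{\eta} with the number of singleton mutations \eqn{\eta_s}, using the
#' variance correction of Simonsen et al. (1995):
#' \deqn{D^* = \frac{\frac{n}{n-1}\eta - a_n \eta_s}
#'   {\sqrt{u_{D^*}\eta + v_{D^*}\eta^2}}.}
#'
#' @param aln a [SeqAlignment-class] with `n >= 4`.
#' @return list with `Dstar`, `eta`, `eta_s`, `n`, `defined`.
#' @export
fuLiDstar <- function(aln) {
  stopifnot(is(aln, "SeqAlignment"))
  n <- nSequences(aln)
  if (n < 4) stop("Fu and Li's D* needs at least 4 sequences")
  ss <- .segSites(aln)
  if (ss$S == 0L)
    return(list(Dstar = NA_real_, eta = 0L, eta_s = 0L, n = n,
                defined = FALSE))
  i <- seq_len(n - 1)
  a <- sum(1 / i); b <- sum(1 / i^2)
  an1 <- a + 1 / n   # a_{n+1}
  cn <- 2 * (n * a - 2 * (n - 1)) / ((n - 1) * (n - 2))
  dn <- cn + (n - 2) / (n - 1)^2 +
    (2 / (n - 1)) * (3 / 2 - (2 * an1 - 3) / (n - 2) - 1 / n)
  vD <- ((n / (n - 1))^2 * b + a^2 * dn -
         2 * (n * a * (a + 1)) / (n - 1)^2) / (a^2 + b)
  uD <- (n / (n - 1)) * (a - n / (n - 1)) - vD
  eta <- ss$eta; eta_s <- ss$eta_s
  Dstar <- ((n / (n - 1)) * eta - a * eta_s) /
    sqrt(uD * eta + vD * eta^2)
  list(Dstar = Dstar, eta = eta, eta_s = eta_s, n = n, defined = TRUE)
}

## log |s(n, k)| for unsigned Stirling numbers of the first kind, row n,
## via the recursion |s(n,k)| = (n-1)|s(n-1,k)| + |s(n-1,k-1)| in log space.
## Cached per n because Fu's Fs null simulations reuse the same row.
.stirlingCache <- new.env(parent = emptyenv())

.logStirlingRow <- function(n) {
  key <- as.character(n)
  if (!is.null(.stirlingCache[[key]])) return(.stirlingCache[[key]])
  row <- c(0)                      # n = 1: |s(1,1)| = 1
  if (n > 1) for (m in 2:n) {
    new <- numeric(m)
    prev <- c(row, -Inf)           # index k of previous row, k = 1..m-1
    for (k in seq_len(m)) {
      t1 <- if (k <= m - 1) log(m - 1) + prev[k] else -Inf
      t2 <- if (k >= 2) prev[k - 1] else -Inf
      hi <- max(t1, t2)
      new[k] <- if (is.infinite(hi)) -Inf else
        hi + log1p(exp(min(t1, t2) - hi))
    }
    row <- new
  }
  .stirlingCache[[key]] <- row
  row
}

## P(K >= k | theta, n) under the Ewens sampling formula
.ewensTail <- function(n, k, theta) {
  ls <- .logStirlingRow(n)
  lpoch <- sum(log(theta + 0:(n - 1)))
  lp <- ls + seq_len(n) * log(theta) - lpoch
  sum(exp(lp[k:n]))
}

## neutral coalescent sample at given theta (infinite sites): returns the
## number of distinct alleles K and mean pairwise differences k.  A
## mutation on a branch subtending c tips contributes 2 c (n - c) pairwise
## differences; alleles are counted by hashing each tip's mutation set
## with per-mutation random weights (exact for identical sets).
.neutralSample <- function(n, theta) {
  anc <- vector("list", 2L * n - 1L)
  for (i in seq_len(n)) anc[[i]] <- i
  active <- seq_len(n)
  blen <- numeric(2L * n - 1L)
  nxt <- n + 1L
  k <- n
  while (k > 1L) {
    t <- rexp(1L, rate = k * (k - 1) / 2)
    blen[active] <- blen[active] + t
    pick <- sample(k, 2L)
    a <- active[pick[1L]]; b <- active[pick[2L]]
    anc[[nxt]] <- c(anc[[a]], anc[[b]])
    active <- c(active[-pick], nxt)
    nxt <- nxt + 1L
    k <- k - 1L
  }
  nodes <- seq_len(2L * n - 2L)          # exclude root
  muts <- rpois(length(nodes), theta / 2 * blen[nodes])
  dsum <- 0
  hash1 <- hash2 <- numeric(n)
  for (nd in nodes[muts > 0]) {
    c_nd <- length(anc[[nd]])
    dsum <- dsum + muts[nd] * 2 * c_nd * (n - c_nd)
    hash1[anc[[nd]]] <- hash1[anc[[nd]]] +
      muts[nd] * sin(nd * 12.9898) * 43758.5453
    hash2[anc[[nd]]] <- hash2[anc[[nd]]] +
      muts[nd] * sin(nd * 78.2331) * 26951.3721
  }
  K <- nrow(unique(cbind(hash1, hash2)))
  list(K = K, k = dsum / (n * (n - 1)))
}

.fsFromKk <- function(n, K, kbar) {
  if (kbar <= 0 || K <= 1L) return(NA_real_)
  Sp <- .ewensTail(n, K, kbar)
  if (Sp >= 1 - 1e-12 || Sp <= 0) return(NA_real_)
  log(Sp / (1 - Sp))
}

#' Fu's Fs with a simulated p-value
#'
#' Computes \eqn{S' = P(K \ge k_{obs} \mid \hat\theta_\pi)} from the Ewens
#' sampling formula (unsigned Stirling numbers of the first kind, evaluated
#' in log space) and \eqn{F_s = \ln(S'/(1-S'))}.  The p-value is the
#' proportion of `nNullSims` neutral constant-size coalescent samples at
#' \eqn{\hat\theta_\pi} whose Fs is less than or equal to the observed value
#' (small Fs signals an excess of alleles, i.e. expansion).
#'
#' @param aln a [SeqAlignment-class] with `n >= 2`.
#' @param nNullSims number of null coalescent simulations for the p-value.
#' @param seed optional integer seed for the null simulations.
#' @return list with `Fs`, `Sprime`, `p`, `K`, `theta_pi`, `defined`.
#' @export
fuFs <- function(aln, nNullSims = 1000, seed = NULL) {
  stopifnot(is(aln, "SeqAlignment"))
  n <- nSequences(aln)
  if (n < 2) stop("Fu's Fs needs at least 2 sequences")
  K <- length(collapseHaplotypes(aln)@sequences)
  D <- .pairDiffMatrix(aln)
  theta <- mean(D[upper.tri(D)])
  if (theta <= 0)
    return(list(Fs = NA_real_, Sprime = NA_real_, p = NA_real_, K = K,
                theta_pi = theta, defined = FALSE))
  Sp <- .ewensTail(n, K, theta)
  if (Sp >= 1 - 1e-12)   # K = 1: P(K >= 1) = 1, log-odds diverge
    return(list(Fs = NA_real_, Sprime = 1, p = NA_real_, K = K,
                theta_pi = theta, defined = FALSE))
  Fs <- log(Sp / (1 - Sp))
  if (!is.null(seed)) set.seed(seed)
  fs_null <- vapply(seq_len(nNullSims), function(i) {
    s <- .neutralSample(n, theta)
    .fsFromKk(n, s$K, s$k)
  }, numeric(1))
  fs_null <- fs_null[is.finite(fs_null)]
  p <- (1 + sum(fs_null <= Fs)) / (length(fs_null) + 1)
  list(Fs = Fs, Sprime = Sp, p = p, K = K, theta_pi = theta, defined = TRUE)
}

#' Per-population diversity report
#'
#' Table-1-shaped report: one row per population plus an overall row with
#' `n`, `H`, `Hd`, `var_Hd`, `sd_Hd`, `pi`, `k`, `S` and (for the overall
#' row, where sample sizes permit) `D`, `Dstar`, `Fs`, `p_Fs`.  Statistics
#' are computed on the full sequence multiset, not the collapsed haplotype
#' set, since haplotype frequencies enter all of them.
#'
#' @param aln a [SeqAlignment-class].
#' @param popmap data.frame (see [readPopmap()]).
#' @param nNullSims null simulations for Fu's Fs.
#' @param seed seed for the Fs p-value simulations.
#' @return data.frame, one row per population plus `"overall"`.
#' @export
diversityReport <- function(aln, popmap, nNullSims = 1000, seed = NULL) {
  pop <- populationOf(aln, popmap)
  pops <- unique(pop)
  one <- function(sub, label) {
    n <- nSequences(sub)
    ht <- collapseHaplotypes(sub)
    H <- length(ht@sequences)
    hd <- haplotypeDiversity(rowSums(ht@counts), n)
    nd <- if (n >= 2) nucleotideDiversity(sub) else
      list(pi = NA_real_, k = NA_real_)
    S <- .segSites(sub)$S
    data.frame(population = label, n = n, H = H, Hd = hd$Hd,
               var_Hd = hd$var_Hd, sd_Hd = hd$sd_Hd, pi = nd$pi, k = nd$k,
               S = S, stringsAsFactors = FALSE)
  }
  rows <- lapply(pops, function(p) {
    sub <- new("SeqAlignment", locus = aln@locus,
               inheritance = aln@inheritance,
               mat = aln@mat[pop == p, , drop = FALSE])
    one(sub, p)
  })
  out <- do.call(rbind, c(rows, list(one(aln, "overall"))))
  out$D <- out$Dstar <- out$Fs <- out$p_Fs <- NA_real_
  i <- nrow(out)
  if (out$n[i] >= 4) {
    out$D[i] <- tajimaD(aln)$D
    out$Dstar[i] <- fuLiDstar(aln)$Dstar
    fs <- fuFs(aln, nNullSims = nNullSims, seed = seed)
    out$Fs[i] <- fs$Fs; out$p_Fs[i] <- fs$p
  }
  rownames(out) <- NULL
  out
}
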