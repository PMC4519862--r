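#' @include diversity.R
NULL

## variance components for a two-level AMOVA given a matrix of squared
## distances (here: pairwise difference counts) and population labels
.amovaComponents <- function(d2, pop) {
  N <- nrow(d2)
  pops <- unique(pop)
  P <- length(pops)
  ut <- upper.tri(d2)
  SS_tot <- sum(d2[ut]) / N
  SS_w <- 0
  sizes <- numeric(P)
  for (i in seq_len(P)) {
    sel <- pop == pops[i]
    sizes[i] <- sum(sel)
    if (sizes[i] > 1) {
      sub <- d2[sel, sel, drop = FALSE]
      SS_w <- SS_w + sum(sub[upper.tri(sub)]) / sizes[i]
    }
  }
  SS_a <- SS_tot - SS_w
  df_a <- P - 1L
  df_w <- N - P
  s2_w <- if (df_w > 0) SS_w / df_w else 0
  nprime <- (N - sum(sizes^2) / N) / df_a
  s2_a <- (SS_a / df_a - s2_w) / nprime
  tot <- s2_a + s2_w
  list(df_among = df_a, df_within = df_w, SSD_among = SS_a,
       SSD_within = SS_w, SSD_total = SS_tot, sigma2_among = s2_a,
       sigma2_within = s2_w,
       Phi_ST = if (tot > 0) s2_a / tot else NA_real_,
       pct_among = if (tot > 0) 100 * s2_a / tot else NA_real_,
       pct_within = if (tot > 0) 100 * s2_w / tot else NA_real_,
       defined = tot > 0)
}

#' Two-level AMOVA (among / within populations)
#'
#' Excoffier-style analysis of molecular variance on pairwise sequence
#' difference counts (the squared-Euclidean convention for haplotypic data).
#' Sums of squared differences are partitioned among and within populations,
#' variance components are obtained by the method of moments and the
#' significance of \eqn{\Phi_{ST}} by permuting individuals among
#' populations.  The permutation p-value includes the observed statistic in
#' numerator and denominator.
#'
#' @param aln a [SeqAlignment-class].
#' @param popmap data.frame (see [readPopmap()]); at least two populations,
#'   at least one of them with two or more sequences.
#' @param nPerm number of permutations.
#' @param seed optional integer seed.
#' @return list with degrees of freedom, SSDs, variance components,
#'   percentages, `Phi_ST`, `p_value` and a `defined` flag (all sequences
#'   identical leaves the components at zero and `Phi_ST` undefined).
#' @export
amovaTwoLevel <- function(aln, popmap, nPerm = 1000, seed = NULL) {
  stopifnot(is(aln, "SeqAlignment"))
  pop <- populationOf(aln, popmap)
  if (length(unique(pop)) < 2)
    stop("AMOVA needs at least 2 populations")
  if (!any(table(pop) >= 2))
    stop("AMOVA needs at least one population with 2 or more sequences")
  d2 <- .pairDiffMatrix(aln)
  obs <- .amovaComponents(d2, pop)
  p_value <- NA_real_
  if (obs$defined && nPerm > 0) {
    if (!is.null(seed)) set.seed(seed)
    ge <- 0L
    for (b in seq_len(nPerm)) {
      perm <- .amovaComponents(d2, sample(pop))
      if (!is.na(perm$Phi_ST) && perm$Phi_ST >= obs$Phi_ST) ge <- ge + 1L
    }
    p_value <- (ge + 1) / (nPerm + 1)
  }
  c(obs, list(p_value = p_value, n_perm = nPerm))
}

#' Pairwise Phi_ST matrix between populations
#'
#' For every pair of populations, the two-level AMOVA Phi_ST computed on the
#' pair alone.  Used as the genetic distance matrix for isolation-by-distance
#' testing; values can be slightly negative for undifferentiated pairs and
#' are reported as computed.
#'
#' @param aln a [SeqAlignment-class].
#' @param popmap data.frame (see [readPopmap()]).
#' @return symmetric matrix of pairwise Phi_ST (diagonal 0; `NA` where a
#'   pair carries no variation).
#' @export
pairwisePhiST <- function(aln, popmap) {
  pop <- populationOf(aln, popmap)
  pops <- unique(pop)
  P <- length(pops)
  d2 <- .pairDiffMatrix(aln)
  out <- matrix(0, P, P, dimnames = list(pops, pops))
  for (i in seq_len(P - 1L)) for (j in (i + 1L):P) {
    sel <- pop %in% pops[c(i, j)]
    cmp <- .amovaComponents(d2[sel, sel, drop = FALSE], pop[sel])
    out[i, j] <- out[j, i] <- cmp$Phi_ST
  }
  out
}

#' Great-circle distance matrix
#'
#' Haversine distances in kilometres (Earth radius 6371 km) between
#' population coordinates.
#'
#' @param coords data.frame as returned by [readCoords()].
#' @return symmetric matrix of distances in km, labelled by population.
#' @export
geographicDistanceMatrix <- function(coords) {
  need <- c("population", "latitude_deg", "longitude_deg")
  if (!all(need %in% names(coords)))
    stop("input error: coords needs columns population, latitude_deg, longitude_deg")
  if (any(abs(coords$latitude_deg) > 90) ||
      any(abs(coords$longitude_deg) > 180))
    stop("input error: coordinates out of range")
  pts <- cbind(coords$longitude_deg, coords$latitude_deg)
  P <- nrow(pts)
  out <- matrix(0, P, P, dimnames = list(coords$population, coords$population))
  for (i in seq_len(P))
    out[i, ] <- geosphere::distHaversine(pts[i, ], pts, r = 6371000) / 1000
  out[abs(out) < 1e-12] <- 0
  (out + t(out)) / 2
}

#' Mantel test between two distance matrices
#'
#' Pearson correlation of the upper triangles with a permutation test
#' (rows and columns of the second matrix permuted jointly).  The p-value
#' includes the observed statistic; the default test is two-sided
#' (`|r_perm| >= |r_obs|`).  For `n <= 7` with `exact = TRUE` all `n!`
#' permutations are enumerated instead of sampled.
#'
#' @param genMatrix,geoMatrix symmetric matrices of the same order.
#' @param nPerm number of sampled permutations.
#' @param seed optional integer seed.
#' @param alternative `"two.sided"`, `"greater"` or `"less"`.
#' @param exact enumerate all permutations (only for `n <= 7`).
#' @return list with `r`, `p`, `n_perm`, `defined`.
#' @export
mantelTest <- function(genMatrix, geoMatrix, nPerm = 10000, seed = NULL,
                       alternative = c("two.sided", "greater", "less"),
                       exact = FALSE) {
  alternative <- match.arg(alternative)
  if (!all(dim(genMatrix) == dim(geoMatrix)))
    stop("matrices must have the same order")
  n <- nrow(genMatrix)
  ut <- upper.tri(genMatrix)
  x <- genMatrix[ut]
  keep <- is.finite(x)
  score <- function(perm) {
    g <- geoMatrix[perm, perm][ut]
    suppressWarnings(cor(x[keep], g[keep]))
  }
  r <- score(seq_len(n))
  if (!is.finite(r))
    return(list(r = NA_real_, p = NA_real_, n_perm = 0L, defined = FALSE))
  tail_stat <- switch(alternative,
    two.sided = function(rp) abs(rp) >= abs(r) - 1e-12,
    greater = function(rp) rp >= r - 1e-12,
    less = function(rp) rp <= r + 1e-12)
  if (exact) {
    if (n > 7) stop("exact enumeration limited to n <= 7")
    perms <- .allPermutations(n)
    rs <- vapply(perms, score, numeric(1))
    p <- mean(tail_stat(rs[is.finite(rs)]))
    return(list(r = r, p = p, n_perm = length(perms), defined = TRUE))
  }
  if (!is.null(seed)) set.seed(seed)
  hits <- 0L; used <- 0L
  for (b in seq_len(nPerm)) {
    rp <- score(sample.int(n))
    if (is.finite(rp)) {
      used <- used + 1L
      if (tail_stat(rp)) hits <- hits + 1L
    }
  }
  list(r = r, p = (hits + 1) / (used + 1), n_perm = nPerm, defined = TRUE)
}

.allPermutations <- function(n) {
  if (n == 1L) return(list(1L))
  sub <- .allPermutations(n - 1L)
  out <- vector("list", n * length(sub))
  k <- 0L
  for (p in sub) for (pos in seq_len(n)) {
    k <- k + 1L
    out[[k]] <- append(p, n, after = pos - 1L)
  }
  out
}
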