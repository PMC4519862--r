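#' @include diversity.R
NULL

## P(D = j | M mutations) for the pairwise difference chain under a
## Jukes-Cantor finite-sites model with m sites: a mutation hits one of the
## m sites uniformly; hitting a currently-identical site always creates a
## difference, hitting a currently-different site reverts it with
## probability 1/3.  Returns the vector over M = j .. j + extra.
.diffChainProbs <- function(j, m, extra) {
  dmax <- min(m, j + extra)
  v <- numeric(dmax + 1L)
  v[1L] <- 1                                   # d = 0
  out <- numeric(extra + 1L)
  for (M in seq_len(j + extra)) {
    d <- 0:dmax
    up <- (m - d) / m
    down <- d / m / 3
    stay <- d / m * 2 / 3
    nv <- v * stay
    nv[-1L] <- nv[-1L] + v[-length(v)] * up[-length(up)]
    nv[-length(nv)] <- nv[-length(nv)] + v[-1L] * down[-1L]
    v <- nv
    if (M >= j) out[M - j + 1L] <- if (j <= dmax) v[j + 1L] else 0
  }
  out
}

#' Probability of a parsimonious connection
#'
#' Probability that two haplotypes observed to differ at `j` of `m` sites
#' differ by exactly `j` substitutions (no superimposed or reverted
#' changes).  Substitutions follow a finite-sites Jukes-Cantor chain; the
#' unknown substitution count is given a Poisson prior whose mean is the
#' Jukes-Cantor-corrected divergence estimated from the observation itself
#' (an empirical-Bayes version of the statistical-parsimony argument of
#' Templeton, Crandall and Sing 1992).  The probability decreases with `j`
#' and increases with `m`.
#'
#' @param j observed number of differing sites (mutational steps).
#' @param m number of compared sites.
#' @param extra truncation of the substitution-count posterior beyond `j`.
#' @return probability in `[0, 1]`.
#' @export
parsimonyProbability <- function(j, m, extra = 60L) {
  if (j == 0L) return(1)
  if (j >= 0.75 * m) return(0)
  p <- j / m
  lambda <- -0.75 * m * log(1 - 4 * p / 3)     # JC-corrected substitution count
  lik <- .diffChainProbs(j, m, extra)
  M <- j + 0:extra
  w <- exp(M * log(lambda) - lambda - lgamma(M + 1))
  post <- lik * w
  if (sum(post) <= 0) return(0)
  post[1L] / sum(post)
}

#' Statistical parsimony connection limit
#'
#' The largest number of mutational steps `j` for which
#' [parsimonyProbability()] at sequence length `L` stays at or above
#' `alpha` (the conventional 95\% connection limit).
#'
#' @param L number of sites.
#' @param alpha confidence level, default 0.95.
#' @param maxSteps search bound.
#' @return integer connection limit (at least 1 for any realistic `L`).
#' @export
connectionLimit <- function(L, alpha = 0.95, maxSteps = 100L) {
  stopifnot(L >= 1, alpha > 0, alpha < 1)
  limit <- 0L
  for (j in seq_len(maxSteps)) {
    if (parsimonyProbability(j, L) >= alpha) limit <- j else break
  }
  limit
}

## mutational step distance between two stored haplotype strings: number of
## differing sites among sites free of gaps/N in BOTH sequences (pairwise
## deletion, consistent with the haplotype identity rule)
.stepDistanceMatrix <- function(seqs) {
  H <- length(seqs)
  mats <- strsplit(seqs, "", fixed = TRUE)
  d <- matrix(0L, H, H, dimnames = list(names(seqs), names(seqs)))
  if (H < 2) return(d)
  for (i in seq_len(H - 1L)) for (j in (i + 1L):H) {
    a <- mats[[i]]; b <- mats[[j]]
    ok <- a != "-" & a != "N" & b != "-" & b != "N"
    d[i, j] <- d[j, i] <- sum(a[ok] != b[ok])
  }
  d
}

#' Build statistical parsimony networks
#'
#' Haplotype pairs within the connection limit are joined through a
#' minimum-spanning network: candidate edges are processed by increasing
#' step distance and every edge that links two hitherto separate
#' sub-networks at the current distance is retained, so alternative
#' equal-length connections produce loops instead of being resolved
#' arbitrarily.  Retained multi-step edges are expanded through inferred
#' (missing) intermediate nodes carrying zero frequency.
#'
#' @param haps a [HaplotypeTable-class].
#' @param limit connection limit in steps; computed from the alignment
#'   length via [connectionLimit()] when `NULL`.
#' @param alpha confidence level used when `limit` is `NULL`.
#' @return a [ParsimonyNetwork-class] (outgroup weights already attached,
#'   see [outgroupWeights()]).
#' @export
buildNetworks <- function(haps, limit = NULL, alpha = 0.95) {
  stopifnot(is(haps, "HaplotypeTable"))
  seqs <- haps@sequences
  H <- length(seqs)
  if (is.null(limit)) limit <- connectionLimit(nchar(seqs[[1L]]), alpha)
  limit <- as.integer(limit)
  d <- .stepDistanceMatrix(seqs)
  counts <- rowSums(haps@counts)

  ## minimum-spanning network via union-find; all minimal alternatives kept
  parent <- seq_len(H)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  edges <- data.frame(i = integer(), j = integer(), w = integer())
  if (H > 1) {
    cand <- which(upper.tri(d) & d <= limit & d >= 1L, arr.ind = TRUE)
    if (nrow(cand)) {
      w <- d[cand]
      for (wk in sort(unique(w))) {
        sel <- which(w == wk)
        roots <- cbind(vapply(cand[sel, 1L], find, 1L),
                       vapply(cand[sel, 2L], find, 1L))
        keep <- roots[, 1L] != roots[, 2L]
        if (any(keep)) {
          edges <- rbind(edges, data.frame(i = cand[sel[keep], 1L],
                                           j = cand[sel[keep], 2L], w = wk))
          for (r in which(keep)) {
            a <- find(cand[sel[r], 1L]); b <- find(cand[sel[r], 2L])
            if (a != b) parent[a] <- b
          }
        }
      }
    }
  }

  ## expand multi-step edges through inferred intermediates
  vnames <- names(seqs)
  vcount <- as.numeric(counts)
  vinf <- rep(FALSE, H)
  el <- matrix(integer(), ncol = 2)
  mv <- 0L
  if (nrow(edges)) for (r in seq_len(nrow(edges))) {
    path <- edges$i[r]
    if (edges$w[r] > 1L) for (s in seq_len(edges$w[r] - 1L)) {
      mv <- mv + 1L
      vnames <- c(vnames, paste0("mv_", mv))
      vcount <- c(vcount, 0)
      vinf <- c(vinf, TRUE)
      path <- c(path, length(vnames))
    }
    path <- c(path, edges$j[r])
    el <- rbind(el, cbind(path[-length(path)], path[-1L]))
  }
  g <- igraph::make_empty_graph(n = length(vnames), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = vnames)
  g <- igraph::set_vertex_attr(g, "count", value = vcount)
  g <- igraph::set_vertex_attr(g, "is_inferred", value = vinf)
  if (nrow(el)) g <- igraph::add_edges(g, t(el))
  g <- igraph::set_edge_attr(g, "step", value = rep(1L, igraph::ecount(g)))
  ## component labelling in order of first observed haplotype
  comp <- igraph::components(g)$membership
  obs_first <- vapply(unique(comp[seq_len(H)]), function(cc)
    min(which(comp[seq_len(H)] == cc)), 1L)
  relabel <- order(obs_first)
  map <- match(comp, unique(comp[seq_len(H)])[relabel])
  g <- igraph::set_vertex_attr(g, "component", value = map)
  ## per-population counts as vertex attributes
  for (p in colnames(haps@counts))
    g <- igraph::set_vertex_attr(g, paste0("count_", p),
      value = c(haps@counts[, p], rep(0L, length(vnames) - H)))
  net <- new("ParsimonyNetwork", graph = g, limit = limit)
  outgroupWeights(net)
}

#' Outgroup (root) weights per network component
#'
#' Per-component root probabilities in the spirit of Castelloe and
#' Templeton's (1994) neutral-coalescent argument: older haplotypes tend to
#' be both frequent and highly connected, so the weight of an observed
#' haplotype is proportional to its frequency times a connectivity bonus
#' `1 + deg / sum(deg)` (degrees taken over the component).  Weights are
#' normalised to sum to one within each component; inferred intermediates
#' carry zero frequency and are excluded from the normalisation.  The
#' arg-max node of a component is its inferred ancestral haplotype.
#'
#' @param net a [ParsimonyNetwork-class].
#' @param haps ignored (counts are carried on the network); kept for
#'   call-site symmetry.
#' @return the network with a `weight` vertex attribute updated; retrieve
#'   weights with `igraph::V(net@graph)$weight`.
#' @export
outgroupWeights <- function(net, haps = NULL) {
  g <- net@graph
  comp <- igraph::V(g)$component
  obs <- !igraph::V(g)$is_inferred
  cnt <- igraph::V(g)$count
  deg <- igraph::degree(g)
  w <- rep(NA_real_, igraph::vcount(g))
  for (cc in unique(comp)) {
    sel <- which(comp == cc & obs)
    sumdeg <- sum(deg[sel])
    raw <- cnt[sel] * (1 + if (sumdeg > 0) deg[sel] / sumdeg else 0)
    w[sel] <- raw / sum(raw)
  }
  g <- igraph::set_vertex_attr(g, "weight", value = w)
  new("ParsimonyNetwork", graph = g, limit = net@limit)
}

#' Summarise network components
#'
#' @param net a [ParsimonyNetwork-class].
#' @return data.frame with `component`, `n_haplotypes`, `n_inferred`,
#'   `ancestral`, `max_weight`, `has_loop`.
#' @export
networkSummary <- function(net) {
  g <- net@graph
  comp <- igraph::V(g)$component
  obs <- !igraph::V(g)$is_inferred
  w <- igraph::V(g)$weight
  nm <- igraph::V(g)$name
  out <- lapply(sort(unique(comp)), function(cc) {
    sel <- comp == cc
    so <- which(sel & obs)
    best <- so[which.max(w[so])]
    sub <- igraph::induced_subgraph(g, which(sel))
    data.frame(component = cc, n_haplotypes = sum(sel & obs),
               n_inferred = sum(sel & !obs), ancestral = nm[best],
               max_weight = w[best],
               has_loop = igraph::ecount(sub) >= igraph::vcount(sub),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Export a parsimony network as GraphML
#'
#' Node attributes: `haplotype_id` (name), total `count`, per-population
#' counts, `outgroup weight`, `is_inferred`, `component`; edge attribute
#' `step = 1`.
#'
#' @param net a [ParsimonyNetwork-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeGraphML <- function(net, path) {
  g <- net@graph
  g <- igraph::set_vertex_attr(g, "is_inferred",
    value = as.integer(igraph::V(g)$is_inferred))
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
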