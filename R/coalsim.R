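#' @include AllClasses.R
NULL

.GENE_COPY_SCALE <- c(mitochondrial = 0.5, x_linked = 1.5, autosomal = 2)

#' Construct a demographic scenario
#'
#' @param name scenario label.
#' @param populations data.frame with columns `name`, `sampled`, `size`
#'   (size is the name of the stable-size parameter).
#' @param events data.frame with columns `time`, `source`, `target`,
#'   `founder`, `duration` (all but source/target are parameter names);
#'   may have zero rows for a single panmictic population.
#' @param priors named list of priors `list(dist = "unif"|"logunif", min,
#'   max)`; a length-2 numeric is shorthand for a uniform prior.
#' @param orderings list of character vectors of parameter names that must
#'   be strictly increasing in every draw (e.g. `c("t1", "t2", "t3")`).
#' @return a validated [ScenarioModel-class].
#' @export
scenarioModel <- function(name, populations, events = NULL, priors,
                          orderings = list()) {
  if (is.null(events))
    events <- data.frame(time = character(), source = character(),
                         target = character(), founder = character(),
                         duration = character(), stringsAsFactors = FALSE)
  priors <- lapply(priors, function(p) {
    if (is.numeric(p) && length(p) == 2L)
      p <- list(dist = "unif", min = p[1L], max = p[2L])
    stopifnot(p$dist %in% c("unif", "logunif"), p$min < p$max)
    if (p$dist == "logunif") stopifnot(p$min > 0)
    p
  })
  new("ScenarioModel", name = name,
      populations = as.data.frame(populations, stringsAsFactors = FALSE),
      events = as.data.frame(events, stringsAsFactors = FALSE),
      priors = priors, orderings = orderings)
}

#' Parse a scenario from a YAML config
#'
#' The config mirrors [scenarioModel()]: top-level keys `name`,
#' `populations` (list of `{name, sampled, size}`), `events` (list of
#' `{time, source, target, founder, duration}`), `priors` (map of parameter
#' to `{dist, min, max}`) and `orderings` (list of parameter-name lists).
#' Only pure-divergence events are expressible; two-source admixture events
#' are not supported.
#'
#' @param x path to a YAML file, or a YAML string.
#' @return a validated [ScenarioModel-class].
#' @examples
#' f <- system.file("extdata", "ghost_source_scenario.yaml",
#'                  package = "seqABC")
#' parseScenario(f)
#' @export
parseScenario <- function(x) {
  cfg <- if (length(x) == 1L && file.exists(x)) yaml::read_yaml(x) else
    yaml::yaml.load(paste(x, collapse = "\n"))
  pops <- do.call(rbind, lapply(cfg$populations, function(p)
    data.frame(name = p$name, sampled = isTRUE(p$sampled),
               size = p$size, stringsAsFactors = FALSE)))
  ev <- if (length(cfg$events))
    do.call(rbind, lapply(cfg$events, function(e)
      data.frame(time = e$time, source = e$source, target = e$target,
                 founder = e$founder, duration = e$duration,
                 stringsAsFactors = FALSE))) else NULL
  ords <- lapply(cfg$orderings, unlist)
  scenarioModel(cfg$name, pops, ev, cfg$priors, ords)
}

.drawPrior <- function(p) {
  if (p$dist == "logunif") exp(runif(1L, log(p$min), log(p$max)))
  else runif(1L, p$min, p$max)
}

#' Draw parameters from a scenario's priors
#'
#' Uniform/log-uniform draws with ordering constraints enforced by
#' rejection.  When a [StudyDesign-class] is supplied, per-locus mutation
#' parameters `mu_<locus>` (log-uniform) and `kappa_<locus>` (uniform) are
#' drawn from the loci table's ranges as well.
#'
#' @param model a [ScenarioModel-class].
#' @param design optional [StudyDesign-class].
#' @param maxAttempts rejection bound before an error is raised (guards
#'   against infeasible constraint systems).
#' @return named numeric vector of parameter values.
#' @export
sampleParameters <- function(model, design = NULL, maxAttempts = 10000L) {
  for (att in seq_len(maxAttempts)) {
    v <- vapply(model@priors, .drawPrior, numeric(1))
    ok <- all(vapply(model@orderings, function(o)
      all(diff(v[o]) > 0), logical(1)))
    if (ok) {
      if (!is.null(design)) {
        l <- design@loci
        mu <- exp(runif(nrow(l), log(l$mu_min), log(l$mu_max)))
        kp <- runif(nrow(l), l$kappa_min, l$kappa_max)
        names(mu) <- paste0("mu_", l$locus)
        names(kp) <- paste0("kappa_", l$locus)
        v <- c(v, mu, kp)
      }
      return(v)
    }
  }
  stop("infeasible prior constraints: rejection bound exceeded")
}

## Concrete demography for one locus: gene-copy sizes and a sorted
## breakpoint schedule (size changes at t - db, merges at t).
.concreteDemography <- function(model, draw, inheritance) {
  scale <- .GENE_COPY_SCALE[[inheritance]]
  pops <- model@populations
  G <- scale * unname(draw[pops$size])
  ev <- model@events
  ne <- nrow(ev)
  if (ne) {
    ti <- unname(draw[ev$time])
    tgt <- match(ev$target, pops$name)
    src <- match(ev$source, pops$name)
    Gf <- scale * unname(draw[ev$founder])
    db <- unname(draw[ev$duration])
    time <- c(pmax(ti - db, 0), ti)
    merge <- c(rep(FALSE, ne), rep(TRUE, ne))
    pop <- c(tgt, tgt)
    srcv <- c(rep(NA_integer_, ne), src)
    Gv <- c(Gf, rep(NA_real_, ne))
    o <- order(time, merge)
    bps <- list(time = time[o], merge = merge[o], pop = pop[o],
                src = srcv[o], G = Gv[o])
  } else bps <- list(time = numeric(), merge = logical(), pop = integer(),
                     src = integer(), G = numeric())
  list(G = G, bps = bps, npop = nrow(pops), popNames = pops$name,
       sampled = pops$sampled)
}

#' Simulate a coalescent genealogy under a scenario
#'
#' Backward-in-time structured coalescent with piecewise-constant sizes.
#' The per-population gene-copy number is `N/2` for mitochondrial, `3N/2`
#' for X-linked and `2N` for autosomal loci.  Looking backward, a founding
#' event at time `t` switches the target population to its founder size for
#' the bottleneck interval `(t - db, t]` and then merges its lineages into
#' the source.  Branch lengths are in generations.
#'
#' @param model a [ScenarioModel-class].
#' @param draw named parameter vector (see [sampleParameters()]).
#' @param sampleSizes named integer vector of sample sizes for (a subset of)
#'   the sampled populations.
#' @param inheritance locus inheritance mode.
#' @return list with `parent` (0 for the root), `time` (node ages in
#'   generations), `tip_pop` (population index per tip), `n` tips,
#'   `pop_names`.
#' @export
simulateGenealogy <- function(model, draw, sampleSizes,
                              inheritance = "autosomal") {
  dem <- .concreteDemography(model, draw, inheritance)
  sizes <- integer(dem$npop)
  idx <- match(names(sampleSizes), dem$popNames)
  if (anyNA(idx)) stop("sampleSizes name unknown population")
  if (any(!dem$sampled[idx] & sampleSizes > 0))
    stop("cannot sample from a ghost population")
  sizes[idx] <- as.integer(sampleSizes)
  .coalescentTree(dem, sizes)
}

.coalescentTree <- function(dem, sizes) {
  n <- sum(sizes)
  if (n < 1L) stop("need at least one sampled gene copy")
  ntot <- 2L * n - 1L
  parent <- integer(ntot)
  age <- numeric(ntot)
  tip_pop <- rep(seq_len(dem$npop), sizes)
  lin_node <- seq_len(n)
  lin_pop <- tip_pop
  nlin <- n
  nxt <- n + 1L
  Gcur <- dem$G
  bp_time <- dem$bps$time
  bp_merge <- dem$bps$merge
  bp_pop <- dem$bps$pop
  bp_src <- dem$bps$src
  bp_G <- dem$bps$G
  nbp <- length(bp_time)
  bpi <- 1L
  k <- tabulate(lin_pop, dem$npop)
  now <- 0
  while (nlin > 1L) {
    rate <- k * (k - 1) / (2 * Gcur)
    tot <- sum(rate)
    t_bp <- if (bpi <= nbp) bp_time[bpi] else Inf
    dt <- if (tot > 0) rexp(1L, tot) else Inf
    if (now + dt < t_bp) {
      now <- now + dt
      p <- which(runif(1L) * tot <= cumsum(rate))[1L]
      in_p <- which(lin_pop[seq_len(nlin)] == p)
      pick <- in_p[sample.int(length(in_p), 2L)]
      node <- nxt; nxt <- nxt + 1L
      parent[lin_node[pick]] <- node
      age[node] <- now
      lin_node[pick[1L]] <- node                  # new node replaces first
      lin_node[pick[2L]] <- lin_node[nlin]        # swap-remove second
      lin_pop[pick[2L]] <- lin_pop[nlin]
      nlin <- nlin - 1L
      k[p] <- k[p] - 1L
    } else {
      if (!is.finite(t_bp))
        stop("internal error: lineages cannot reach a common ancestor")
      now <- t_bp
      if (bp_merge[bpi]) {
        sel <- lin_pop[seq_len(nlin)] == bp_pop[bpi]
        lin_pop[seq_len(nlin)][sel] <- bp_src[bpi]
        k[bp_src[bpi]] <- k[bp_src[bpi]] + k[bp_pop[bpi]]
        k[bp_pop[bpi]] <- 0L
      } else {
        Gcur[bp_pop[bpi]] <- bp_G[bpi]
      }
      bpi <- bpi + 1L
    }
  }
  list(parent = parent, time = age, tip_pop = tip_pop, n = n,
       pop_names = dem$popNames)
}

## K2P mutation events on a genealogy: returns per-mutation branch (child
## node), site index within the variable sites, time on the branch, and
## whether it is a transition; plus tip states at mutated sites.
.mutateCore <- function(tree, nVarSites, mu, kappa) {
  n <- tree$n
  ntot <- length(tree$parent)
  if (n == 1L)
    return(list(m = 0L, siteIdx = integer(), tipStates = matrix(0L, n, 0L)))
  nodes <- which(tree$parent > 0L)
  bl <- tree$time[tree$parent[nodes]] - tree$time[nodes]
  totlen <- sum(bl)
  M <- rpois(1L, mu * nVarSites * totlen)
  if (M == 0L)
    return(list(m = 0L, siteIdx = integer(), tipStates = matrix(0L, n, 0L)))
  br <- nodes[sample.int(length(nodes), M, replace = TRUE, prob = bl)]
  site <- sample.int(nVarSites, M, replace = TRUE)
  mt <- runif(M, tree$time[br], tree$time[tree$parent[br]])
  is_ti <- runif(M) < kappa / (kappa + 2)
  tv_pick <- sample.int(2L, M, replace = TRUE)

  sites <- sort(unique(site))
  m <- length(sites)
  scol <- match(site, sites)
  state <- matrix(0L, ntot, m)
  root <- which(tree$parent == 0L)
  state[root, ] <- sample.int(4L, m, replace = TRUE) - 1L
  ## pre-order: nodes by decreasing age (root first)
  ord <- order(tree$time, decreasing = TRUE)
  ord <- ord[ord != root]
  mut_by_branch <- split(seq_len(M), br)
  for (nd in ord) {
    state[nd, ] <- state[tree$parent[nd], ]
    key <- as.character(nd)
    ms <- mut_by_branch[[key]]
    if (!is.null(ms)) {
      ms <- ms[order(mt[ms], decreasing = TRUE)]   # forward in time
      for (mm in ms) {
        cc <- scol[mm]
        b <- state[nd, cc]
        state[nd, cc] <- if (is_ti[mm]) (b + 2L) %% 4L else {
          ## transversion: swap purine/pyrimidine class (A=0,C=1,G=2,T=3)
          if (b == 0L || b == 2L) c(1L, 3L)[tv_pick[mm]] else
            c(0L, 2L)[tv_pick[mm]]
        }
      }
    }
  }
  tips <- state[seq_len(n), , drop = FALSE]
  keep <- colSums(tips != rep(tips[1L, ], each = n)) > 0L
  list(m = sum(keep), siteIdx = sites[keep],
       tipStates = tips[, keep, drop = FALSE])
}

#' Drop K2P mutations on a genealogy and return an alignment
#'
#' Poisson mutations at rate `mu` per variable site per generation along the
#' branches, with transition:transversion kinetics governed by `kappa`
#' (a mutation is a transition with probability `kappa/(kappa+2)`).
#' `floor(pInv * L)` invariant sites are chosen once and never mutate.
#' Multiple hits are allowed (finite sites).
#'
#' @param tree genealogy from [simulateGenealogy()].
#' @param L sequence length in sites.
#' @param mu mutation rate per site per generation.
#' @param kappa transition/transversion rate ratio.
#' @param pInv invariant-site fraction (default 0.10).
#' @param locus,inheritance labels for the resulting alignment.
#' @param ids tip sample ids; defaults to `<population>_<i>`.
#' @return a [SeqAlignment-class] with `n` sequences of length `L`.
#' @export
applyMutations <- function(tree, L, mu, kappa, pInv = 0.1,
                           locus = "locus", inheritance = "autosomal",
                           ids = NULL) {
  nVar <- L - floor(pInv * L)
  core <- .mutateCore(tree, nVar, mu, kappa)
  .materializeAlignment(tree, core, L, nVar, locus, inheritance, ids)
}

.BASES <- c("A", "C", "G", "T")

.materializeAlignment <- function(tree, core, L, nVar, locus, inheritance,
                                  ids = NULL) {
  n <- tree$n
  varPos <- if (nVar < L) sort(sample.int(L, nVar)) else seq_len(L)
  rootSeq <- sample.int(4L, L, replace = TRUE)
  mat <- matrix(.BASES[rootSeq], nrow = n, ncol = L, byrow = TRUE)
  if (core$m > 0L) {
    pos <- varPos[core$siteIdx]
    for (cc in seq_len(core$m))
      mat[, pos[cc]] <- .BASES[core$tipStates[, cc] + 1L]
  }
  if (is.null(ids))
    ids <- paste0(tree$pop_names[tree$tip_pop], "_",
                  stats::ave(tree$tip_pop, tree$tip_pop, FUN = seq_along))
  rownames(mat) <- ids
  new("SeqAlignment", locus = locus, inheritance = inheritance, mat = mat)
}

## Summary statistics from mutated-site tip states.
## For each deme: number of haplotypes, segregating sites, mean pairwise
## differences; for each deme pair: pooled within (W) and between (B) mean
## pairwise differences.  Demes with fewer than 2 copies contribute 0 to
## within-type statistics (mask convention, so observed and simulated
## vectors stay comparable).
## count distinct rows of a small integer matrix via two deterministic
## hash projections (exact for identical rows; a double collision of both
## 53-bit keys is negligible and would only affect a haplotype count)
.nDistinctRows <- function(X) {
  m <- ncol(X)
  w1 <- sin(seq_len(m) * 12.9898) * 43758.5453
  w2 <- sin(seq_len(m) * 78.2331) * 26951.3721
  nrow(unique(cbind(X %*% w1, X %*% w2)))
}

.statsFromTips <- function(X, tip_pop, ndeme) {
  n <- nrow(X); m <- ncol(X)
  sizes <- tabulate(tip_pop, ndeme)
  if (m == 0L) {
    D <- matrix(0, n, n)
  } else {
    mt <- matrix(0, n, n)
    for (b in 0:3) {
      A <- (X == b) * 1
      mt <- mt + tcrossprod(A)
    }
    D <- m - mt
  }
  fac <- factor(tip_pop, levels = seq_len(ndeme))
  S1 <- rowsum(D, fac, reorder = TRUE)
  S2 <- t(rowsum(t(S1), fac, reorder = TRUE))
  H <- S <- k <- numeric(ndeme)
  for (p in seq_len(ndeme)) {
    sel <- tip_pop == p
    np <- sizes[p]
    if (np == 0L) next
    sub <- X[sel, , drop = FALSE]
    H[p] <- if (m == 0L) 1 else .nDistinctRows(sub)
    if (np >= 2L && m > 0L) {
      S[p] <- sum(colSums(sub != rep(sub[1L, ], each = np)) > 0L)
      k[p] <- S2[p, p] / (np * (np - 1))
    }
  }
  W <- B <- matrix(0, ndeme, ndeme)
  for (p in seq_len(ndeme - 1L)) for (q in (p + 1L):ndeme) {
    npairs <- sizes[p] * (sizes[p] - 1) / 2 + sizes[q] * (sizes[q] - 1) / 2
    W[p, q] <- if (npairs > 0) (S2[p, p] / 2 + S2[q, q] / 2) / npairs else 0
    B[p, q] <- if (sizes[p] > 0 && sizes[q] > 0)
      S2[p, q] / (sizes[p] * sizes[q]) else 0
  }
  list(H = H, S = S, k = k, W = W, B = B)
}

.statNameCache <- new.env(parent = emptyenv())

.statNamesForDesign <- function(loci, demes) {
  key <- paste(c(loci, "|", demes), collapse = "\r")
  hit <- .statNameCache[[key]]
  if (!is.null(hit)) return(hit)
  out <- .statNameCache[[key]] <- .statNamesBuild(loci, demes)
  out
}

.statNamesBuild <- function(loci, demes) {
  unlist(lapply(loci, function(lc) {
    one <- c(paste0(lc, ".H.", demes), paste0(lc, ".S.", demes),
             paste0(lc, ".k.", demes))
    pairs <- if (length(demes) >= 2) combn(demes, 2L, paste, collapse = "-")
             else character()
    c(one, if (length(pairs)) c(paste0(lc, ".W.", pairs),
                                paste0(lc, ".B.", pairs)))
  }))
}

.flattenStats <- function(st, ndeme) {
  ut <- upper.tri(matrix(0, ndeme, ndeme))
  c(st$H, st$S, st$k, st$W[ut], st$B[ut])
}

## deme-level sample sizes per locus from a StudyDesign, ordered like the
## model's sampled populations
.demeSampleSizes <- function(design, demes) {
  p <- design@populations
  out <- lapply(design@loci$locus, function(lc) {
    agg <- tapply(p[[paste0("n_", lc)]], p$deme, sum)
    v <- agg[demes]
    v[is.na(v)] <- 0L
    setNames(as.integer(v), demes)
  })
  names(out) <- design@loci$locus
  out
}

#' Simulate a multi-locus dataset under one parameter draw
#'
#' Independent genealogies per locus under the same demographic draw; each
#' locus uses its own inheritance scaling, length, mutation rate and
#' transition/transversion ratio (`mu_<locus>`, `kappa_<locus>` entries of
#' the draw).
#'
#' @param model a [ScenarioModel-class].
#' @param draw named parameter vector from [sampleParameters()] (with
#'   per-locus mutation parameters).
#' @param design a [StudyDesign-class]; its demes must match the model's
#'   sampled populations.
#' @param seed optional integer seed (byte-identical output on re-run).
#' @param output `"alignments"` for a list of [SeqAlignment-class] objects
#'   plus a popmap, `"stats"` for the summary-statistic vector only.
#' @return for `"alignments"`: list with `alignments` (named list) and
#'   `popmap` (data.frame); for `"stats"`: named numeric vector.
#' @export
simulateDataset <- function(model, draw, design, seed = NULL,
                            output = c("alignments", "stats")) {
  output <- match.arg(output)
  if (!is.null(seed)) set.seed(seed)
  demes <- model@populations$name[model@populations$sampled]
  sizes <- .demeSampleSizes(design, demes)
  loci <- design@loci
  cores <- vector("list", nrow(loci))
  for (i in seq_len(nrow(loci))) {
    dem <- .concreteDemography(model, draw, loci$inheritance[i])
    szAll <- integer(dem$npop)
    szAll[match(demes, dem$popNames)] <- sizes[[i]]
    tree <- .coalescentTree(dem, szAll)
    nVar <- loci$L[i] - floor(loci$p_inv[i] * loci$L[i])
    core <- .mutateCore(tree, nVar, draw[[paste0("mu_", loci$locus[i])]],
                        draw[[paste0("kappa_", loci$locus[i])]])
    cores[[i]] <- list(tree = tree, core = core, nVar = nVar)
  }
  if (output == "stats") {
    ndeme <- length(demes)
    vals <- unlist(lapply(seq_len(nrow(loci)), function(i) {
      tp <- match(cores[[i]]$tree$pop_names[cores[[i]]$tree$tip_pop], demes)
      .flattenStats(.statsFromTips(cores[[i]]$core$tipStates, tp, ndeme),
                    ndeme)
    }))
    names(vals) <- .statNamesForDesign(loci$locus, demes)
    return(vals)
  }
  alns <- vector("list", nrow(loci))
  popmaps <- vector("list", nrow(loci))
  for (i in seq_len(nrow(loci))) {
    tree <- cores[[i]]$tree
    ids <- paste0(tree$pop_names[tree$tip_pop], "_", loci$locus[i], "_",
                  stats::ave(tree$tip_pop, tree$tip_pop, FUN = seq_along))
    alns[[i]] <- .materializeAlignment(tree, cores[[i]]$core, loci$L[i],
      cores[[i]]$nVar, loci$locus[i], loci$inheritance[i], ids)
    popmaps[[i]] <- data.frame(sample_id = ids,
      population = tree$pop_names[tree$tip_pop],
      region = tree$pop_names[tree$tip_pop], stringsAsFactors = FALSE)
  }
  names(alns) <- loci$locus
  list(alignments = alns, popmap = do.call(rbind, popmaps))
}
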