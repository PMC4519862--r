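#' @include coalsim.R
NULL

#' Summary statistics of an observed multi-locus dataset
#'
#' Computes, per locus and deme, the number of haplotypes, the number of
#' segregating sites and the mean of pairwise differences, and per locus
#' and deme pair the pooled within-deme (`W`) and between-deme (`B`) mean
#' pairwise differences, concatenated in the same fixed order the simulator
#' uses.  Sites with gaps or `N` are removed by complete deletion; samples
#' whose deme is not in `demes` are ignored.  Demes with fewer than two
#' sequences report zero for their within-type statistics (mask
#' convention).
#'
#' @param alignments named list of [SeqAlignment-class] objects (one per
#'   locus; list order fixes the statistic order).
#' @param popmap data.frame (see [readPopmap()]).
#' @param demes character vector of deme codes, in order; defaults to the
#'   unique values of the deme column.
#' @param demeColumn popmap column holding the deme code (default
#'   `"region"`).
#' @return named numeric vector of length
#'   `loci * (3 * demes + 2 * choose(demes, 2))`.
#' @export
summaryStats <- function(alignments, popmap, demes = NULL,
                         demeColumn = "region") {
  if (is(alignments, "SeqAlignment")) alignments <- list(alignments)
  if (is.null(names(alignments)))
    names(alignments) <- vapply(alignments, locusName, "")
  if (is.null(demes)) demes <- unique(popmap[[demeColumn]])
  ndeme <- length(demes)
  vals <- unlist(lapply(alignments, function(aln) {
    dm <- popmap[[demeColumn]][match(sampleIDs(aln), popmap$sample_id)]
    sel <- !is.na(dm) & dm %in% demes
    m <- aln@mat[sel, , drop = FALSE]
    sub <- new("SeqAlignment", locus = aln@locus,
               inheritance = aln@inheritance, mat = m)
    keep <- analysedSites(sub)
    mm <- m[, keep, drop = FALSE]
    X <- matrix(match(mm, .BASES) - 1L, nrow = nrow(mm))
    varcol <- colSums(X != rep(X[1L, ], each = nrow(X))) > 0L
    X <- X[, varcol, drop = FALSE]
    tp <- match(dm[sel], demes)
    .flattenStats(.statsFromTips(X, tp, ndeme), ndeme)
  }))
  names(vals) <- .statNamesForDesign(names(alignments), demes)
  vals
}

#' Build an ABC reference table
#'
#' For each scenario, draws parameters from the priors, simulates a
#' multi-locus dataset under the study design and stores the summary
#' statistics.  Normalisation constants (per-statistic median absolute
#' deviations over the pooled table) are attached; statistics with zero MAD
#' keep a constant of 1.
#'
#' @param models a [ScenarioModel-class] or list of them; all scenarios
#'   must share the same set of sampled populations (the design's demes).
#' @param nSimsPerScenario simulations per scenario.
#' @param design a [StudyDesign-class].
#' @param seed integer seed (the table is reproducible from it).
#' @param verbose print progress every 1000 simulations.
#' @return a [ReferenceTable-class].
#' @export
buildReferenceTable <- function(models, nSimsPerScenario, design, seed,
                                verbose = FALSE) {
  if (is(models, "ScenarioModel")) models <- list(models)
  demes0 <- sort(models[[1L]]@populations$name[models[[1L]]@populations$sampled])
  for (m in models)
    if (!identical(sort(m@populations$name[m@populations$sampled]), demes0))
      stop("all scenarios must share the same sampled populations")
  set.seed(as.integer(seed))
  scen <- character(0)
  parlist <- vector("list", 0L)
  statrows <- NULL
  row <- 0L
  total <- nSimsPerScenario * length(models)
  for (m in models) {
    for (i in seq_len(nSimsPerScenario)) {
      draw <- sampleParameters(m, design)
      st <- simulateDataset(m, draw, design, output = "stats")
      row <- row + 1L
      if (is.null(statrows))
        statrows <- matrix(NA_real_, total, length(st),
                           dimnames = list(NULL, names(st)))
      statrows[row, ] <- st
      scen[row] <- m@name
      parlist[[row]] <- draw
      if (verbose && row %% 1000L == 0L)
        message(sprintf("reference table: %d / %d", row, total))
    }
  }
  pn <- unique(unlist(lapply(parlist, names)))
  params <- matrix(NA_real_, total, length(pn), dimnames = list(NULL, pn))
  for (r in seq_len(total)) params[r, names(parlist[[r]])] <- parlist[[r]]
  norm <- apply(statrows, 2L, mad)
  norm[!is.finite(norm) | norm <= 0] <- 1
  new("ReferenceTable", scenario = scen, params = params, stats = statrows,
      norm = norm, seed = as.integer(seed))
}

.normalizedDistances <- function(ref, observed) {
  obs <- observed
  if (!is.null(names(obs)) && !is.null(colnames(ref@stats)))
    obs <- obs[colnames(ref@stats)]
  z <- sweep(ref@stats, 2L, obs, "-")
  z <- sweep(z, 2L, ref@norm, "/")
  rowSums(z^2)
}

.wilson <- function(p, n, z = 1.96) {
  den <- 1 + z^2 / n
  ctr <- (p + z^2 / (2 * n)) / den
  hw <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
  c(max(0, ctr - hw), min(1, ctr + hw))
}

#' Direct-estimate ABC model choice
#'
#' Posterior probability of each scenario estimated as its frequency among
#' the `nClosest` reference simulations by normalised Euclidean distance to
#' the observed summary vector, with a Wilson 95\% binomial interval on
#' each frequency.  Ties at the cutoff distance are broken by row order (a
#' message is emitted).
#'
#' @param ref a [ReferenceTable-class].
#' @param observed named summary vector (see [summaryStats()]).
#' @param nClosest number of accepted simulations (default 500).
#' @return data.frame with `scenario`, `pp`, `ci_lo`, `ci_hi`; attribute
#'   `n_closest`.
#' @export
chooseModelDirect <- function(ref, observed, nClosest = 500L) {
  n <- length(ref@scenario)
  if (nClosest > n) stop("nClosest exceeds the table size")
  d2 <- .normalizedDistances(ref, observed)
  ord <- order(d2)
  if (nClosest < n && d2[ord[nClosest]] == d2[ord[nClosest + 1L]])
    message("tie at the cutoff distance; broken by row order")
  sel <- ord[seq_len(nClosest)]
  levs <- unique(ref@scenario)
  pp <- as.numeric(table(factor(ref@scenario[sel], levels = levs))) / nClosest
  ci <- t(vapply(pp, .wilson, numeric(2), n = nClosest))
  out <- data.frame(scenario = levs, pp = pp, ci_lo = ci[, 1L],
                    ci_hi = ci[, 2L], stringsAsFactors = FALSE)
  attr(out, "n_closest") <- nClosest
  out
}

#' Regression-adjusted ABC parameter estimation
#'
#' Rejection step (the `nClosest` simulations of the target scenario by
#' normalised distance) followed by a local linear regression adjustment of
#' the accepted parameter draws on the normalised summary deviations
#' (parameters regressed on log scale; adjusted draws are clipped to the
#' range covered by the prior draws).  Reports the posterior median and the
#' 2.5/97.5 percent quantiles per parameter.  A singular regression design
#' falls back to the unadjusted rejection posterior with a message.
#'
#' @param ref a [ReferenceTable-class].
#' @param observed named summary vector.
#' @param nClosest accepted simulations (default 500).
#' @param scenario scenario id whose parameters are estimated.
#' @return data.frame with `parameter`, `median`, `q025`, `q975`,
#'   `adjusted`.
#' @export
estimateParameters <- function(ref, observed, nClosest = 500L, scenario) {
  rows <- which(ref@scenario == scenario)
  if (length(rows) < nClosest)
    stop("fewer scenario rows than nClosest")
  d2 <- .normalizedDistances(ref, observed)[rows]
  acc <- rows[order(d2)[seq_len(nClosest)]]
  P <- ref@params[acc, , drop = FALSE]
  P <- P[, colSums(!is.na(P)) == nrow(P), drop = FALSE]
  lo <- apply(ref@params[rows, colnames(P), drop = FALSE], 2L, min, na.rm = TRUE)
  hi <- apply(ref@params[rows, colnames(P), drop = FALSE], 2L, max, na.rm = TRUE)
  obs <- observed[colnames(ref@stats)]
  Z <- sweep(ref@stats[acc, , drop = FALSE], 2L, obs, "-")
  Z <- sweep(Z, 2L, ref@norm, "/")
  Z <- Z[, apply(Z, 2L, function(col) stats::var(col) > 0), drop = FALSE]
  LP <- log(P)
  adjusted <- TRUE
  fit <- tryCatch(stats::lm.fit(cbind(1, Z), LP), error = function(e) NULL)
  if (is.null(fit) || fit$rank < ncol(Z) + 1L) {
    message("singular regression design; falling back to rejection posterior")
    adj <- LP
    adjusted <- FALSE
  } else {
    cf <- fit$coefficients
    if (is.null(dim(cf)))
      cf <- matrix(cf, ncol = 1L, dimnames = list(NULL, colnames(LP)))
    beta <- cf[-1L, , drop = FALSE]
    adj <- LP - Z %*% beta
  }
  est <- exp(adj)
  for (j in seq_len(ncol(est)))
    est[, j] <- pmin(pmax(est[, j], lo[j]), hi[j])
  data.frame(parameter = colnames(est),
             median = apply(est, 2L, median),
             q025 = apply(est, 2L, quantile, 0.025),
             q975 = apply(est, 2L, quantile, 0.975),
             adjusted = adjusted, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Type I/II error rates and parameter-estimation performance
#'
#' Simulates `nTestSets` pseudo-observed datasets (PODs) per scenario from
#' prior draws, runs [chooseModelDirect()] on each against the supplied
#' reference table and reports, per scenario, the type I error (proportion
#' of PODs from that scenario in which it did not attain the highest PP)
#' and the type II error (proportion of PODs from other scenarios in which
#' it did).  Optionally the true scenario's parameters are re-estimated for
#' every POD and summarised as relative bias `(median estimate -
#' truth)/truth` and relative RMSE (RMSE of the point estimates divided by
#' the truth), averaged over test sets.
#'
#' @param models scenario list the table was built from.
#' @param design the [StudyDesign-class] used for the table.
#' @param nTestSets PODs per scenario.
#' @param ref the [ReferenceTable-class].
#' @param seed integer seed for the PODs.
#' @param nClosest accepted simulations for each choice/estimate.
#' @param estimateParams also score parameter recovery (slower).
#' @return list with `errors` (scenario, type_I, type_II), `params`
#'   (scenario, parameter, rel_bias, rel_rmse; `NULL` unless requested) and
#'   `n_test_sets`.
#' @export
evaluateConfidence <- function(models, design, nTestSets, ref, seed = NULL,
                               nClosest = 500L, estimateParams = FALSE) {
  if (is(models, "ScenarioModel")) models <- list(models)
  if (!is.null(seed)) set.seed(as.integer(seed))
  scen_names <- vapply(models, function(m) m@name, "")
  truth <- winner <- character(0)
  relerr <- list()
  for (m in models) {
    for (i in seq_len(nTestSets)) {
      draw <- sampleParameters(m, design)
      st <- simulateDataset(m, draw, design, output = "stats")
      mc <- chooseModelDirect(ref, st, nClosest = nClosest)
      truth <- c(truth, m@name)
      winner <- c(winner, mc$scenario[which.max(mc$pp)])
      if (estimateParams) {
        est <- estimateParameters(ref, st, nClosest = nClosest,
                                  scenario = m@name)
        tr <- draw[est$parameter]
        relerr[[length(relerr) + 1L]] <- data.frame(
          scenario = m@name, parameter = est$parameter,
          err = (est$median - tr) / tr, stringsAsFactors = FALSE)
      }
    }
  }
  errors <- do.call(rbind, lapply(scen_names, function(s) {
    own <- truth == s
    data.frame(scenario = s,
               type_I = mean(winner[own] != s),
               type_II = if (any(!own)) mean(winner[!own] == s) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  params <- NULL
  if (estimateParams && length(relerr)) {
    re <- do.call(rbind, relerr)
    params <- do.call(rbind, lapply(split(re, list(re$scenario, re$parameter),
                                          drop = TRUE), function(g)
      data.frame(scenario = g$scenario[1L], parameter = g$parameter[1L],
                 rel_bias = mean(g$err), rel_rmse = sqrt(mean(g$err^2)),
                 stringsAsFactors = FALSE)))
    rownames(params) <- NULL
  }
  list(errors = errors, params = params, n_test_sets = nTestSets)
}

#' PCA prior/scenario adequacy check
#'
#' Principal component analysis of (a subsample of) the normalised
#' reference summary vectors with the observed vector projected onto the
#' leading components.  For each scenario the observed point is compared
#' with the 99th percentile of the simulated points' standardised radii
#' around the scenario centroid; an observation outside every scenario's
#' envelope indicates a prior/scenario combination unable to reproduce the
#' data.  Zero-variance statistics are dropped with a warning.
#'
#' @param ref a [ReferenceTable-class].
#' @param observed named summary vector.
#' @param nComp number of leading components (default 2).
#' @param nMax subsample size for the PCA.
#' @return list with `coords` (data.frame: scenario, PC scores),
#'   `observed` (score vector), `inside` (named logical per scenario) and
#'   the `prcomp` fit.
#' @export
pcaPriorCheck <- function(ref, observed, nComp = 2L, nMax = 5000L) {
  obs <- observed[colnames(ref@stats)]
  n <- nrow(ref@stats)
  idx <- if (n > nMax) sort(sample.int(n, nMax)) else seq_len(n)
  X <- sweep(ref@stats[idx, , drop = FALSE], 2L, ref@norm, "/")
  keep <- apply(X, 2L, function(col) stats::var(col) > 0)
  if (!all(keep))
    warning(sprintf("%d zero-variance statistic(s) dropped", sum(!keep)))
  X <- X[, keep, drop = FALSE]
  pc <- prcomp(X, center = TRUE, scale. = FALSE)
  nComp <- min(nComp, ncol(pc$x))
  sc <- pc$x[, seq_len(nComp), drop = FALSE]
  ov <- (obs / ref@norm)[keep]
  os <- drop((ov - pc$center) %*% pc$rotation[, seq_len(nComp), drop = FALSE])
  scen <- ref@scenario[idx]
  inside <- vapply(unique(scen), function(s) {
    S <- sc[scen == s, , drop = FALSE]
    mu <- colMeans(S)
    sdv <- apply(S, 2L, sd); sdv[sdv == 0] <- 1
    rad <- sqrt(rowSums(sweep(sweep(S, 2L, mu), 2L, sdv, "/")^2))
    orad <- sqrt(sum(((os - mu) / sdv)^2))
    orad <= quantile(rad, 0.99)
  }, logical(1))
  list(coords = data.frame(scenario = scen, sc, stringsAsFactors = FALSE),
       observed = os, inside = inside, fit = pc)
}
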