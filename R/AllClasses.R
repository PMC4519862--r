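#' @importFrom methods new validObject is setValidity show
#' @importFrom stats cor mad median prcomp quantile rexp rpois runif sd setNames rbinom
#' @importFrom utils combn head read.delim read.table write.table
NULL

.INHERITANCE_MODES <- c("mitochondrial", "x_linked", "autosomal")
.ALPHABET <- c("A", "C", "G", "T", "N", "-")

## ---------------------------------------------------------------------------
## SeqAlignment
## ---------------------------------------------------------------------------

#' Aligned sequences for a single locus
#'
#' A `SeqAlignment` holds equal-length aligned DNA sequences for one locus,
#' together with the locus name and its mode of inheritance (which determines
#' the gene-copy scaling used by the coalescent simulator: N/2 for
#' mitochondrial, 3N/2 for X-linked and 2N for autosomal loci).
#'
#' Sequences are stored as a character matrix (one row per sample, one column
#' per alignment site) over the alphabet `A,C,G,T,N,-`.  Gaps (`-`) and
#' missing data (`N`) are treated identically by all downstream statistics:
#' any site carrying either symbol in any sequence is excluded
#' (complete deletion).
#'
#' @slot locus single character, locus label.
#' @slot inheritance one of `"mitochondrial"`, `"x_linked"`, `"autosomal"`.
#' @slot mat character matrix of single upper-case symbols; row names are the
#'   (unique) sample identifiers.
#'
#' @seealso [readFastaAlignment()], [collapseHaplotypes()], [classifySites()]
#' @export
setClass("SeqAlignment",
  slots = c(locus = "character", inheritance = "character", mat = "matrix"))

setValidity("SeqAlignment", function(object) {
  msg <- character()
  if (length(object@locus) != 1L || is.na(object@locus))
    msg <- c(msg, "'locus' must be a single string")
  if (length(object@inheritance) != 1L ||
      !object@inheritance %in% .INHERITANCE_MODES)
    msg <- c(msg, sprintf("'inheritance' must be one of %s",
                          paste(.INHERITANCE_MODES, collapse = ", ")))
  m <- object@mat
  if (!is.character(m)) msg <- c(msg, "'mat' must be a character matrix")
  else {
    if (nrow(m) < 1L) msg <- c(msg, "alignment must contain at least one sequence")
    ids <- rownames(m)
    if (is.null(ids) || anyNA(ids) || any(ids == ""))
      msg <- c(msg, "all sequences must carry a sample id (row name)")
    else if (anyDuplicated(ids))
      msg <- c(msg, "sample ids must be unique")
    bad <- setdiff(unique(as.vector(m)), .ALPHABET)
    if (length(bad))
      msg <- c(msg, sprintf("illegal characters in alignment: %s",
                            paste(bad, collapse = ", ")))
  }
  if (length(msg)) msg else TRUE
})

#' Construct a SeqAlignment from character strings
#'
#' @param seqs character vector of aligned sequences (all the same length).
#'   Lower-case input is upper-cased.
#' @param ids sample identifiers; defaults to `names(seqs)`.
#' @param locus locus label.
#' @param inheritance inheritance mode, see [SeqAlignment-class].
#' @return a [SeqAlignment-class] object.
#' @examples
#' aln <- SeqAlignment(c(s1 = "ACGTACGTAA", s2 = "ACGTACGTAA"),
#'                     locus = "demo", inheritance = "mitochondrial")
#' seqLength(aln)
#' @export
SeqAlignment <- function(seqs, ids = names(seqs), locus = "locus",
                         inheritance = "autosomal") {
  if (length(seqs) == 0L) stop("input error: no sequences")
  if (is.null(ids)) ids <- paste0("seq_", seq_along(seqs))
  seqs <- toupper(as.character(seqs))
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L)
    stop(sprintf("alignment error: unequal sequence lengths (%s)",
                 paste(unique(lens), collapse = ", ")))
  for (i in seq_along(seqs)) {
    bad <- setdiff(unique(strsplit(seqs[i], "", fixed = TRUE)[[1L]]), .ALPHABET)
    if (length(bad))
      stop(sprintf("input error: illegal character(s) '%s' in record '%s'",
                   paste(bad, collapse = ""), ids[i]))
  }
  m <- matrix(unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE),
              nrow = length(seqs), byrow = TRUE)
  rownames(m) <- ids
  new("SeqAlignment", locus = locus, inheritance = inheritance, mat = m)
}

## ---------------------------------------------------------------------------
## HaplotypeTable
## ---------------------------------------------------------------------------

#' Distinct haplotypes with per-population counts
#'
#' Produced by [collapseHaplotypes()].  Haplotypes are distinct under
#' complete deletion (sequences compared only at sites free of gaps and `N`
#' in every sequence of the parent alignment) and are labelled
#' `Hap_1, Hap_2, ...` in order of first occurrence.
#'
#' @slot sequences named character vector of representative full-length
#'   sequences (first occurrence of each haplotype).
#' @slot counts integer matrix, haplotypes x populations.
#' @slot locus,inheritance carried over from the parent alignment.
#' @export
setClass("HaplotypeTable",
  slots = c(sequences = "character", counts = "matrix",
            locus = "character", inheritance = "character"))

setValidity("HaplotypeTable", function(object) {
  msg <- character()
  cnt <- object@counts
  if (!is.numeric(cnt) || any(cnt < 0) || any(cnt != round(cnt)))
    msg <- c(msg, "'counts' must be a non-negative integer matrix")
  if (nrow(cnt) != length(object@sequences))
    msg <- c(msg, "one count row per haplotype required")
  else {
    if (any(rowSums(cnt) < 1))
      msg <- c(msg, "every haplotype must be observed at least once")
    if (!identical(rownames(cnt), names(object@sequences)))
      msg <- c(msg, "count row names must match haplotype ids")
  }
  if (anyDuplicated(object@sequences))
    msg <- c(msg, "haplotype sequences must be distinct")
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## ScenarioModel
## ---------------------------------------------------------------------------

#' A demographic invasion scenario
#'
#' Describes a set of populations (sampled plus optional unsampled "ghost"
#' sources), a list of founding/divergence events and uniform or log-uniform
#' priors with ordering constraints.  Looking backward in time, an event at
#' time `t` merges the lineages of `target` into `source`; during the
#' bottleneck interval `(t - db, t]` the target population has founder size
#' `Nf` instead of its stable size `N`.  Times are measured in generations,
#' sizes in individuals.
#'
#' @slot name scenario label.
#' @slot populations data.frame with columns `name`, `sampled` (logical) and
#'   `size` (name of the stable-size parameter).
#' @slot events data.frame with columns `time`, `source`, `target`,
#'   `founder`, `duration`; `time`, `founder` and `duration` are parameter
#'   names, `source`/`target` population names.
#' @slot priors named list; each element is `list(dist, min, max)` with
#'   `dist` either `"unif"` or `"logunif"`.
#' @slot orderings list of character vectors; each vector lists parameter
#'   names that must be strictly increasing in any draw.
#' @seealso [scenarioModel()], [parseScenario()], [scenarioLibrary()]
#' @export
setClass("ScenarioModel",
  slots = c(name = "character", populations = "data.frame",
            events = "data.frame", priors = "list", orderings = "list"))

setValidity("ScenarioModel", function(object) {
  msg <- character()
  pops <- object@populations
  ev <- object@events
  need <- c("name", "sampled", "size")
  if (!all(need %in% names(pops)))
    return("'populations' needs columns name, sampled, size")
  if (nrow(ev) > 0 &&
      !all(c("time", "source", "target", "founder", "duration") %in% names(ev)))
    return("'events' needs columns time, source, target, founder, duration")
  if (anyDuplicated(pops$name)) msg <- c(msg, "duplicate population names")
  if (nrow(ev) > 0) {
    if (!all(c(ev$source, ev$target) %in% pops$name))
      msg <- c(msg, "event source/target must be declared populations")
    if (anyDuplicated(ev$target))
      msg <- c(msg, "a population may be the target of at most one event")
    if (any(ev$source == ev$target))
      msg <- c(msg, "event source and target must differ")
  }
  ## every parameter referenced must have a prior
  pars <- unique(c(pops$size, if (nrow(ev)) c(ev$time, ev$founder, ev$duration)))
  miss <- setdiff(pars, names(object@priors))
  if (length(miss))
    msg <- c(msg, sprintf("parameters without priors: %s",
                          paste(miss, collapse = ", ")))
  ## ancestry: targets merge away; exactly one population is never a target
  root <- setdiff(pops$name, ev$target)
  if (length(root) != 1L)
    msg <- c(msg, "scenario must have exactly one root population (all sampled populations must trace to a common ancestor)")
  ## ghosts may act as sources or root, never as targets
  ghosts <- pops$name[!pops$sampled]
  if (any(ghosts %in% ev$target))
    msg <- c(msg, "ghost populations may appear as sources only")
  ## acyclicity: follow target -> source links; must reach root
  if (length(root) == 1L && nrow(ev) > 0) {
    parent <- setNames(ev$source, ev$target)
    for (p in pops$name) {
      seen <- character(); cur <- p
      while (cur %in% names(parent)) {
        if (cur %in% seen) { msg <- c(msg, "cycle in founding events"); break }
        seen <- c(seen, cur); cur <- parent[[cur]]
      }
    }
  }
  ## declared orderings must reference known priors
  op <- unlist(object@orderings)
  if (length(op) && !all(op %in% names(object@priors)))
    msg <- c(msg, "ordering constraints reference unknown parameters")
  if (length(msg)) unique(msg) else TRUE
})

## ---------------------------------------------------------------------------
## ParsimonyNetwork
## ---------------------------------------------------------------------------

#' Statistical parsimony haplotype network
#'
#' A minimum-spanning haplotype network built at a mutational connection
#' limit.  Vertices are observed haplotypes plus inferred (missing)
#' intermediates; every edge represents a single mutational step.
#' Alternative equal-length connections are retained, so closed loops mark
#' homoplasy rather than being resolved arbitrarily.
#'
#' @slot graph an `igraph` object with vertex attributes `name`, `count`,
#'   `is_inferred`, `component` and (after [outgroupWeights()]) `weight`.
#' @slot limit integer, the connection limit (maximum parsimonious steps).
#' @export
setClass("ParsimonyNetwork", slots = c(graph = "ANY", limit = "integer"))

## ---------------------------------------------------------------------------
## ReferenceTable
## ---------------------------------------------------------------------------

#' ABC reference table
#'
#' Rows are independent simulations: a scenario id, the parameter draw that
#' generated the dataset, and its summary-statistic vector.  Normalisation
#' constants (median absolute deviations pooled over all rows) are stored so
#' that observed and simulated vectors are compared on a common scale.
#'
#' @slot scenario character vector, scenario id per row.
#' @slot params numeric matrix of parameter draws (columns are the union of
#'   parameter names over scenarios; `NA` where a scenario lacks a parameter).
#' @slot stats numeric matrix of summary statistics.
#' @slot norm numeric vector of per-statistic MADs (zero-variance statistics
#'   get a constant 1).
#' @slot seed integer seed the table was built with.
#' @export
setClass("ReferenceTable",
  slots = c(scenario = "character", params = "matrix", stats = "matrix",
            norm = "numeric", seed = "integer"))

setValidity("ReferenceTable", function(object) {
  msg <- character()
  n <- length(object@scenario)
  if (nrow(object@params) != n || nrow(object@stats) != n)
    msg <- c(msg, "params/stats must have one row per simulation")
  if (length(object@norm) != ncol(object@stats))
    msg <- c(msg, "one normalisation constant per statistic required")
  if (any(!is.finite(object@norm)) || any(object@norm <= 0))
    msg <- c(msg, "normalisation constants must be positive and finite")
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## StudyDesign
## ---------------------------------------------------------------------------

#' Sampling design for simulation and synthetic data
#'
#' Couples a table of sampled populations (with per-locus sample sizes,
#' coordinates and the demographic deme each population belongs to) with a
#' table of loci (length, inheritance, mutation-model priors).  Scenario
#' populations correspond to demes; when a deme contains several sampled
#' populations their sample sizes are pooled for simulation and split again
#' when datasets are written to disk.
#'
#' @slot populations data.frame with columns `pop`, `deme`, `lat`, `lon` and
#'   one `n_<locus>` column per locus.
#' @slot loci data.frame with columns `locus`, `L`, `inheritance`, `mu_min`,
#'   `mu_max`, `kappa_min`, `kappa_max`, `p_inv`.
#' @seealso [table1Design()], [generateStudy()]
#' @export
setClass("StudyDesign",
  slots = c(populations = "data.frame", loci = "data.frame"))

setValidity("StudyDesign", function(object) {
  msg <- character()
  p <- object@populations; l <- object@loci
  if (!all(c("pop", "deme", "lat", "lon") %in% names(p)))
    msg <- c(msg, "'populations' needs columns pop, deme, lat, lon")
  need <- c("locus", "L", "inheritance", "mu_min", "mu_max",
            "kappa_min", "kappa_max", "p_inv")
  if (!all(need %in% names(l)))
    msg <- c(msg, "'loci' is missing required columns")
  else {
    if (!all(l$inheritance %in% .INHERITANCE_MODES))
      msg <- c(msg, "unknown inheritance mode in loci table")
    if (any(l$p_inv < 0 | l$p_inv >= 1))
      msg <- c(msg, "p_inv must lie in [0, 1)")
    ncols <- paste0("n_", l$locus)
    if (!all(ncols %in% names(p)))
      msg <- c(msg, "populations table needs one n_<locus> column per locus")
    else if (any(as.matrix(p[, ncols]) < 0))
      msg <- c(msg, "sample sizes must be non-negative")
  }
  if (length(msg)) msg else TRUE
})
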