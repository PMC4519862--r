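#' @include abc.R
NULL

## Sampling design of the crayfish survey: 37 populations (35 in China,
## one each in Japan and the USA), per-population sample sizes for the
## mitochondrial control region and the nuclear proPOx intron, decimal
## coordinates (west longitudes negative) and the demographic deme each
## population belongs to (regions R1-R5 for the Chinese populations, Sa for
## Japan, La for the USA).
.TABLE1 <- local({
  txt <- "pop lon lat n_cr n_in deme
SH 121.23 31.03 7 3 R5
NB 121.55 29.88 8 4 R5
JX 120.77 30.75 7 2 R5
XYc 118.50 33.00 7 6 R1
XYw 118.42 33.03 7 4 R1
WXb 120.28 31.52 9 6 R5
NT 120.87 32.02 7 6 R5
XG 118.75 32.08 8 7 R1
XBv 118.87 32.20 7 6 R1
BGt 118.82 32.17 7 7 R1
WX 120.30 31.57 6 7 R5
WJ 116.70 30.12 7 8 R4
MAS 118.50 31.55 8 6 R1
CJr 116.87 30.12 7 7 R4
CH 117.87 31.62 7 7 R1
HF 117.23 31.82 8 6 R1
DY 117.83 32.28 6 3 R1
SLt 116.22 29.75 8 5 R4
NBp 116.17 29.72 8 7 R4
PYL 116.43 28.87 7 2 R4
NCyl 116.12 28.52 8 3 R4
NHL 114.03 30.02 7 4 R3
YNL 112.20 30.00 8 6 R3
XT 113.40 30.30 8 6 R3
QJ 112.60 30.40 7 4 R3
LZL 114.00 30.00 6 2 R3
HHL 113.40 29.70 8 2 R3
CHL 112.10 30.30 7 6 R3
YJ 112.37 28.85 7 5 R3
NX 112.55 28.28 8 4 R3
DTL 113.02 29.30 6 2 R3
DTLs 113.13 29.35 8 4 R3
CQs 106.53 29.55 7 8 R2
ZX 108.03 30.28 6 7 R2
JY 104.55 30.38 6 6 R2
Sa 139.65 35.85 18 9 Sa
LA -93.26 29.87 20 9 La"
  read.table(text = txt, header = TRUE, stringsAsFactors = FALSE)
})

.NJ_POPS <- c("XG", "BGt", "XBv")

#' Construct a study design
#'
#' @param populations data.frame with columns `pop`, `deme`, `lat`, `lon`
#'   and one `n_<locus>` column per locus.
#' @param loci data.frame with columns `locus`, `L`, `inheritance`,
#'   `mu_min`, `mu_max`, `kappa_min`, `kappa_max`, `p_inv`.
#' @return a validated [StudyDesign-class].
#' @export
studyDesign <- function(populations, loci) {
  new("StudyDesign",
      populations = as.data.frame(populations, stringsAsFactors = FALSE),
      loci = as.data.frame(loci, stringsAsFactors = FALSE))
}

.defaultLoci <- function(lengths = c(control_region = 400L,
                                     propox_intron = 250L)) {
  data.frame(
    locus = c("control_region", "propox_intron"),
    L = as.integer(lengths[c("control_region", "propox_intron")]),
    inheritance = c("mitochondrial", "x_linked"),
    mu_min = 1e-9, mu_max = 1e-7,
    kappa_min = 0.05, kappa_max = 20,
    p_inv = 0.1, stringsAsFactors = FALSE)
}

#' Survey sampling design (37 populations, two loci)
#'
#' The default design mirrors the crayfish survey: 291 control-region and
#' 196 intron sequences over 37 populations with their coordinates.  The
#' deme column groups populations into the units the demographic scenarios
#' act on: `"cluster1"` keeps the USA (La), Japan (Sa) and the pooled
#' Nanjing populations (NJ); `"cluster2"` keeps the Chinese populations
#' grouped into regions R1-R5; `"full"` keeps everything (Chinese regions
#' plus Sa and La).  Locus lengths default to a desk-scale surrogate of 400
#' (control region) and 250 (intron) sites; pass `lengths` to use
#' field-scale lengths instead.  Mutation-model priors: log-uniform mean
#' rate in `[1e-9, 1e-7]` per site per generation, uniform
#' transition/transversion ratio in `[0.05, 20]`, 10\% invariant sites.
#'
#' @param cluster `"full"`, `"cluster1"` or `"cluster2"`.
#' @param lengths named integer vector with entries `control_region` and
#'   `propox_intron`.
#' @return a [StudyDesign-class].
#' @export
table1Design <- function(cluster = c("full", "cluster1", "cluster2"),
                         lengths = c(control_region = 400L,
                                     propox_intron = 250L)) {
  cluster <- match.arg(cluster)
  t1 <- .TABLE1
  if (cluster == "cluster1") {
    t1 <- t1[t1$pop %in% c("LA", "Sa", .NJ_POPS), ]
    t1$deme <- ifelse(t1$pop %in% .NJ_POPS, "NJ", t1$deme)
  } else if (cluster == "cluster2") {
    t1 <- t1[grepl("^R", t1$deme), ]
  }
  pops <- data.frame(pop = t1$pop, deme = t1$deme, lat = t1$lat,
                     lon = t1$lon, n_control_region = t1$n_cr,
                     n_propox_intron = t1$n_in, stringsAsFactors = FALSE)
  studyDesign(pops, .defaultLoci(lengths))
}

.STUDY_PRIORS <- list(
  t = c(1, 100), db = c(5, 25), N = c(1000, 1e6), Nf = c(1, 1e4))

.priorsFor <- function(tpars, Npars, Nfpars, db = "db") {
  pr <- list()
  for (p in tpars) pr[[p]] <- .STUDY_PRIORS$t
  pr[[db]] <- .STUDY_PRIORS$db
  for (p in Npars) pr[[p]] <- .STUDY_PRIORS$N
  for (p in Nfpars) pr[[p]] <- .STUDY_PRIORS$Nf
  pr
}

#' Library of named invasion scenarios
#'
#' All scenarios use the study priors (`1 < t1 < t2 < ... < 100`
#' generations, bottleneck duration `5 < db < 25`, stable sizes
#' `1000 < N < 1e6`, founder sizes `1 < Nf < 10000`) with a single shared
#' bottleneck-duration parameter.
#'
#' Cluster 1 (La = USA, Sa = Japan, NJ = Nanjing):
#' \describe{
#'   \item{cluster1_scenario5}{Japan founded from an unsampled (ghost)
#'     source, then a serial introduction Japan -> NJ; the USA population
#'     shares only the ghost ancestry (the best-supported hypothesis).}
#'   \item{cluster1_serial_usa}{USA origin with a serial chain
#'     La -> Sa -> NJ.}
#'   \item{cluster1_independent_usa}{independent introductions La -> Sa
#'     and La -> NJ.}
#' }
#' Cluster 2 (Chinese regions R1-R5):
#' \describe{
#'   \item{cluster2_scenario8}{R1 is the origin of R2, R3 and R4, with a
#'     subsequent serial introduction R4 -> R5.}
#'   \item{cluster2_serial}{stepping-stone chain R1 -> R2 -> R3 -> R4 ->
#'     R5.}
#'   \item{cluster2_star}{independent radiations R1 -> each of R2-R5.}
#' }
#' `table1_full` combines both levels for whole-survey synthesis: ghost ->
#' Sa -> R1, R1 -> R2/R3/R4, R4 -> R5, with La attached to the ghost.
#'
#' @return named list of [ScenarioModel-class] objects.
#' @export
scenarioLibrary <- function() {
  lib <- list()

  pops1g <- data.frame(
    name = c("La", "Sa", "NJ", "ghost"),
    sampled = c(TRUE, TRUE, TRUE, FALSE),
    size = c("N1", "N2", "N3", "N4"), stringsAsFactors = FALSE)
  lib$cluster1_scenario5 <- scenarioModel(
    "cluster1_scenario5", pops1g,
    data.frame(time = c("t1", "t2", "t3"),
               source = c("Sa", "ghost", "ghost"),
               target = c("NJ", "Sa", "La"),
               founder = c("Nf3", "Nf2", "Nf1"),
               duration = "db", stringsAsFactors = FALSE),
    .priorsFor(c("t1", "t2", "t3"), paste0("N", 1:4), paste0("Nf", 1:3)),
    list(c("t1", "t2", "t3")))

  pops1 <- pops1g[pops1g$name != "ghost", ]
  lib$cluster1_serial_usa <- scenarioModel(
    "cluster1_serial_usa", pops1,
    data.frame(time = c("t1", "t2"), source = c("Sa", "La"),
               target = c("NJ", "Sa"), founder = c("Nf3", "Nf2"),
               duration = "db", stringsAsFactors = FALSE),
    .priorsFor(c("t1", "t2"), paste0("N", 1:3), c("Nf2", "Nf3")),
    list(c("t1", "t2")))
  lib$cluster1_independent_usa <- scenarioModel(
    "cluster1_independent_usa", pops1,
    data.frame(time = c("t1", "t2"), source = c("La", "La"),
               target = c("NJ", "Sa"), founder = c("Nf3", "Nf2"),
               duration = "db", stringsAsFactors = FALSE),
    .priorsFor(c("t1", "t2"), paste0("N", 1:3), c("Nf2", "Nf3")),
    list(c("t1", "t2")))

  pops2 <- data.frame(
    name = paste0("R", 1:5), sampled = TRUE,
    size = paste0("N", 1:5), stringsAsFactors = FALSE)
  lib$cluster2_scenario8 <- scenarioModel(
    "cluster2_scenario8", pops2,
    data.frame(time = c("t1", "t2", "t3", "t4"),
               source = c("R4", "R1", "R1", "R1"),
               target = c("R5", "R4", "R3", "R2"),
               founder = c("Nf5", "Nf4", "Nf3", "Nf2"),
               duration = "db", stringsAsFactors = FALSE),
    .priorsFor(paste0("t", 1:4), paste0("N", 1:5), paste0("Nf", 2:5)),
    list(paste0("t", 1:4)))
  lib$cluster2_serial <- scenarioModel(
    "cluster2_serial", pops2,
    data.frame(time = c("t1", "t2", "t3", "t4"),
               source = c("R4", "R3", "R2", "R1"),
               target = c("R5", "R4", "R3", "R2"),
               founder = c("Nf5", "Nf4", "Nf3", "Nf2"),
               duration = "db", stringsAsFactors = FALSE),
    .priorsFor(paste0("t", 1:4), paste0("N", 1:5), paste0("Nf", 2:5)),
    list(paste0("t", 1:4)))
  lib$cluster2_star <- scenarioModel(
    "cluster2_star", pops2,
    data.frame(time = c("t1", "t2", "t3", "t4"),
               source = "R1",
               target = c("R5", "R4", "R3", "R2"),
               founder = c("Nf5", "Nf4", "Nf3", "Nf2"),
               duration = "db", stringsAsFactors = FALSE),
    .priorsFor(paste0("t", 1:4), paste0("N", 1:5), paste0("Nf", 2:5)),
    list(paste0("t", 1:4)))

  popsF <- data.frame(
    name = c("La", "Sa", paste0("R", 1:5), "ghost"),
    sampled = c(rep(TRUE, 7), FALSE),
    size = paste0("N", 1:8), stringsAsFactors = FALSE)
  lib$table1_full <- scenarioModel(
    "table1_full", popsF,
    data.frame(time = c("t1", "t2", "t3", "t4", "t5", "t6", "t7"),
               source = c("R4", "R1", "R1", "R1", "Sa", "ghost", "ghost"),
               target = c("R5", "R2", "R3", "R4", "R1", "Sa", "La"),
               founder = paste0("Nf", 1:7),
               duration = "db", stringsAsFactors = FALSE),
    .priorsFor(paste0("t", 1:7), paste0("N", 1:8), paste0("Nf", 1:7)),
    list(c("t1", "t4", "t5", "t6"), c("t2", "t5"), c("t3", "t5")))

  lib
}

#' Generate a synthetic study dataset on disk
#'
#' Simulates a complete survey-like dataset under a named (or supplied)
#' scenario and writes FASTA files per locus, a popmap TSV, a coordinates
#' TSV and a machine-readable truth file (scenario id, parameter values,
#' seed) so downstream recovery can be scored automatically.  Deme-level
#' samples are split deterministically among the member populations of
#' each deme according to the design's per-population sizes.
#'
#' @param design a [StudyDesign-class] (see [table1Design()]).
#' @param scenario scenario name in [scenarioLibrary()] or a
#'   [ScenarioModel-class].
#' @param params optional named parameter vector; drawn from the priors
#'   when `NULL`.
#' @param seed integer seed (mandatory; the dataset is reproducible from
#'   it).
#' @param outDir output directory (created if needed).
#' @return invisibly, a list with the written `paths`, the `truth` record
#'   and the scenario name.
#' @export
generateStudy <- function(design, scenario = "table1_full", params = NULL,
                          seed, outDir) {
  stopifnot(is(design, "StudyDesign"))
  model <- if (is.character(scenario)) {
    lib <- scenarioLibrary()
    if (!scenario %in% names(lib))
      stop(sprintf("unknown scenario '%s'", scenario))
    lib[[scenario]]
  } else scenario
  set.seed(as.integer(seed))
  if (is.null(params)) params <- sampleParameters(model, design)
  ds <- simulateDataset(model, params, design, output = "alignments")
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)

  pops <- design@populations
  paths <- list()
  popmap <- NULL
  for (lc in names(ds$alignments)) {
    aln <- ds$alignments[[lc]]
    deme_of <- ds$popmap$population[match(sampleIDs(aln),
                                          ds$popmap$sample_id)]
    ncol_ <- paste0("n_", lc)
    newids <- character(nSequences(aln))
    rows <- NULL
    for (d in unique(deme_of)) {
      sel <- which(deme_of == d)
      members <- pops[pops$deme == d, ]
      assign_pop <- rep(members$pop, members[[ncol_]])
      stopifnot(length(assign_pop) == length(sel))
      idx <- stats::ave(seq_along(sel), assign_pop, FUN = seq_along)
      newids[sel] <- paste0(assign_pop, "_", lc, "_", idx)
      rows <- rbind(rows, data.frame(sample_id = newids[sel],
        population = assign_pop, region = d, stringsAsFactors = FALSE))
    }
    m <- aln@mat
    rownames(m) <- newids
    aln2 <- new("SeqAlignment", locus = lc, inheritance = aln@inheritance,
                mat = m)
    p <- file.path(outDir, paste0(lc, ".fasta"))
    writeFastaAlignment(aln2, p)
    paths[[lc]] <- p
    popmap <- rbind(popmap, rows)
  }
  pm_path <- file.path(outDir, "popmap.tsv")
  write.table(popmap, pm_path, sep = "\t", quote = FALSE, row.names = FALSE)
  coords <- data.frame(population = pops$pop, latitude_deg = pops$lat,
                       longitude_deg = pops$lon, stringsAsFactors = FALSE)
  co_path <- file.path(outDir, "coords.tsv")
  write.table(coords, co_path, sep = "\t", quote = FALSE, row.names = FALSE)
  truth <- list(scenario = model@name, seed = as.integer(seed),
                params = as.list(params),
                n_sequences = lapply(ds$alignments, nSequences))
  tr_path <- file.path(outDir, "truth.json")
  jsonlite::write_json(truth, tr_path, auto_unbox = TRUE, digits = NA)
  invisible(list(paths = c(paths, popmap = pm_path, coords = co_path,
                           truth = tr_path),
                 truth = truth, scenario = model@name))
}
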