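cluster1YAML <- '
name: demo_ghost
populations:
  - {name: La, sampled: yes, size: N1}
  - {name: Sa, sampled: yes, size: N2}
  - {name: NJ, sampled: yes, size: N3}
  - {name: ghost, sampled: no, size: N4}
events:
  - {time: t1, source: Sa, target: NJ, founder: Nf3, duration: db}
  - {time: t2, source: ghost, target: Sa, founder: Nf2, duration: db}
  - {time: t3, source: ghost, target: La, founder: Nf1, duration: db}
priors:
  t1: {dist: unif, min: 1, max: 100}
  t2: {dist: unif, min: 1, max: 100}
  t3: {dist: unif, min: 1, max: 100}
  db: {dist: unif, min: 5, max: 25}
  N1: {dist: unif, min: 1000, max: 1.0e+6}
  N2: {dist: unif, min: 1000, max: 1.0e+6}
  N3: {dist: unif, min: 1000, max: 1.0e+6}
  N4: {dist: unif, min: 1000, max: 1.0e+6}
  Nf1: {dist: unif, min: 1, max: 10000}
  Nf2: {dist: unif, min: 1, max: 10000}
  Nf3: {dist: unif, min: 1, max: 10000}
orderings:
  - [t1, t2, t3]
'

test_that("a ghost-source scenario parses from YAML with 4 populations", {
  m <- parseScenario(cluster1YAML)
  expect_s4_class(m, "ScenarioModel")
  expect_equal(nrow(m@populations), 4L)
  expect_equal(sum(m@populations$sampled), 3L)
  expect_equal(nrow(m@events), 3L)
  ## file round trip
  f <- tempfile(fileext = ".yaml")
  writeLines(cluster1YAML, f)
  expect_equal(parseScenario(f)@name, "demo_ghost")
})

test_that("invalid scenarios are rejected by the validity checks", {
  pops <- data.frame(name = c("A", "B"), sampled = TRUE,
                     size = c("N1", "N2"))
  ## sampled population with no ancestry path to a single root
  expect_error(scenarioModel("bad", pops, NULL,
    priors = list(N1 = c(1, 2), N2 = c(1, 2))), "root")
  ## cycle: A -> B and B -> A
  expect_error(scenarioModel("cyc", pops,
    data.frame(time = c("t1", "t2"), source = c("A", "B"),
               target = c("B", "A"), founder = c("f", "f"),
               duration = c("d", "d")),
    priors = list(N1 = c(1, 2), N2 = c(1, 2), t1 = c(1, 2), t2 = c(2, 3),
                  f = c(1, 2), d = c(1, 2))), "root|cycle")
  ## ghost as a target
  popsg <- rbind(pops, data.frame(name = "G", sampled = FALSE, size = "N3"))
  expect_error(scenarioModel("ghost_target", popsg,
    data.frame(time = c("t1", "t2"), source = c("A", "A"),
               target = c("G", "B"), founder = c("f", "f"),
               duration = c("d", "d")),
    priors = list(N1 = c(1, 2), N2 = c(1, 2), N3 = c(1, 2),
                  t1 = c(1, 2), t2 = c(2, 3), f = c(1, 2), d = c(1, 2))),
    "ghost")
})

test_that("prior draws respect supports and ordering constraints", {
  m <- parseScenario(cluster1YAML)
  set.seed(1)
  draws <- replicate(2000, sampleParameters(m))
  expect_true(all(draws["db", ] > 5 & draws["db", ] < 25))
  expect_true(all(draws["t1", ] < draws["t2", ]))
  expect_true(all(draws["t2", ] < draws["t3", ]))
  expect_true(all(draws["N1", ] > 1000 & draws["N1", ] < 1e6))
  expect_true(all(draws["Nf1", ] > 1 & draws["Nf1", ] < 1e4))
})

test_that("constrained marginals match a brute-force rejection oracle", {
  m <- scenarioModel("ord",
    data.frame(name = "P1", sampled = TRUE, size = "N1"), NULL,
    priors = list(N1 = c(1, 2), t1 = c(0, 1), t2 = c(0, 1)),
    orderings = list(c("t1", "t2")))
  set.seed(2)
  got <- replicate(4000, sampleParameters(m)["t1"])
  ## oracle: plain rejection on independent uniforms
  ora <- c()
  while (length(ora) < 4000) {
    u <- runif(2)
    if (u[1] < u[2]) ora <- c(ora, u[1])
  }
  ks <- suppressWarnings(stats::ks.test(got, ora))
  expect_gt(ks$p.value, 0.01)
  ## infeasible constraints error out
  bad <- scenarioModel("bad",
    data.frame(name = "P1", sampled = TRUE, size = "N1"), NULL,
    priors = list(N1 = c(1, 2), t1 = c(2, 3), t2 = c(0, 1)),
    orderings = list(c("t1", "t2")))
  expect_error(sampleParameters(bad, maxAttempts = 50), "infeasible")
})

test_that("pairwise TMRCA matches the constant-size expectation", {
  set.seed(3)
  m <- constModel()
  t2 <- replicate(3000, max(simulateGenealogy(m, c(N1 = 10000),
    c(P1 = 2), "autosomal")$time))
  expect_lt(abs(mean(t2) / 20000 - 1), 0.08)
  ## inheritance scalings: mitochondrial G = N/2, X-linked 3N/2
  tm <- replicate(3000, max(simulateGenealogy(m, c(N1 = 10000),
    c(P1 = 2), "mitochondrial")$time))
  expect_lt(abs(mean(tm) / 5000 - 1), 0.08)
})

test_that("no cross-population coalescence occurs before the split", {
  m <- scenarioModel("split",
    data.frame(name = c("A", "B"), sampled = TRUE, size = c("N1", "N2")),
    data.frame(time = "t1", source = "A", target = "B", founder = "Nf",
               duration = "db"),
    priors = list(N1 = c(1, 2), N2 = c(1, 2), t1 = c(1, 2), Nf = c(1, 2),
                  db = c(1, 2)))
  draw <- c(N1 = 200, N2 = 200, t1 = 50, Nf = 200, db = 10)
  set.seed(4)
  for (rep in 1:50) {
    tr <- simulateGenealogy(m, draw, c(A = 3, B = 3), "autosomal")
    ## cross-population MRCA: walk tip ancestries
    anc <- function(i) {
      path <- c(); while (tr$parent[i] > 0) { i <- tr$parent[i]
        path <- c(path, i) }
      path
    }
    for (i in which(tr$tip_pop == 1)) for (j in which(tr$tip_pop == 2)) {
      mrca <- intersect(anc(i), anc(j))[1]
      expect_gte(tr$time[mrca], 50)
    }
  }
})

test_that("a severe founder bottleneck reduces within-target diversity", {
  mk <- function(nf) scenarioModel("b",
    data.frame(name = c("A", "B"), sampled = TRUE, size = c("N1", "N2")),
    data.frame(time = "t1", source = "A", target = "B", founder = "Nf",
               duration = "db"),
    priors = list(N1 = c(1, 2), N2 = c(1, 2), t1 = c(1, 2), Nf = c(1, 2),
                  db = c(1, 2)))
  des <- studyDesign(
    data.frame(pop = c("A", "B"), deme = c("A", "B"), lat = 0, lon = 0,
               n_control_region = c(2, 8)),
    data.frame(locus = "control_region", L = 500,
               inheritance = "autosomal", mu_min = 1e-9, mu_max = 1e-9,
               kappa_min = 2, kappa_max = 2, p_inv = 0))
  m <- mk(1)
  base <- c(N1 = 20000, N2 = 20000, t1 = 40, db = 20,
            mu_control_region = 1e-6, kappa_control_region = 2)
  set.seed(5)
  kB_tight <- replicate(400, simulateDataset(m, c(base, Nf = 4), des,
    output = "stats")[["control_region.k.B"]])
  kB_none <- replicate(400, simulateDataset(m, c(base, Nf = 20000), des,
    output = "stats")[["control_region.k.B"]])
  expect_lt(mean(kB_tight), 0.7 * mean(kB_none))
})

test_that("mu = 0 yields identical sequences and kappa controls kinetics", {
  m <- constModel()
  des0 <- oneLocusDesign(6, 100)
  set.seed(6)
  ds <- simulateDataset(m, c(N1 = 1000, mu_control_region = 0,
    kappa_control_region = 2), des0, output = "alignments")
  aln <- ds$alignments[[1]]
  expect_equal(length(unique(apply(alignmentMatrix(aln), 1, paste,
                                   collapse = ""))), 1L)
  ## large kappa: transversions vanish
  set.seed(7)
  counts <- c(ti = 0, tv = 0)
  for (rep in 1:200) {
    ds <- simulateDataset(m, c(N1 = 2000, mu_control_region = 5e-6,
      kappa_control_region = 2000), oneLocusDesign(2, 200),
      output = "alignments")
    mm <- alignmentMatrix(ds$alignments[[1]])
    diff <- which(mm[1, ] != mm[2, ])
    for (s in diff) {
      ti <- paste(sort(mm[, s]), collapse = "")
      if (ti %in% c("AG", "CT")) counts["ti"] <- counts["ti"] + 1
      else counts["tv"] <- counts["tv"] + 1
    }
  }
  expect_gt(sum(counts), 50)
  expect_lt(counts[["tv"]] / sum(counts), 0.02)
})

test_that("mean pairwise differences match the coalescent identity", {
  set.seed(8)
  m <- constModel()
  des <- oneLocusDesign(10, 1000)
  draw <- c(N1 = 10000, mu_control_region = 5e-8, kappa_control_region = 2)
  theta <- 2 * 20000 * 5e-8 * 1000
  k <- replicate(2500, simulateDataset(m, draw, des,
    output = "stats")[["control_region.k.P1"]])
  expect_lt(abs(mean(k) / theta - 1), 0.07)
})

test_that("fixed seeds reproduce datasets byte for byte", {
  m <- parseScenario(cluster1YAML)
  des <- table1Design("cluster1")
  draw <- sampleParameters(m, des)
  a <- simulateDataset(m, draw, des, seed = 99, output = "alignments")
  b <- simulateDataset(m, draw, des, seed = 99, output = "alignments")
  expect_identical(lapply(a$alignments, alignmentMatrix),
                   lapply(b$alignments, alignmentMatrix))
  ## the stats path sees the same genealogies and mutations
  s <- simulateDataset(m, draw, des, seed = 99, output = "stats")
  obs <- summaryStats(a$alignments, a$popmap,
                      demes = c("La", "Sa", "NJ"))
  expect_equal(s, obs, tolerance = 1e-9)
  ## two loci: shared demography but independent gene trees
  expect_false(identical(a$alignments[[1]]@mat, a$alignments[[2]]@mat))
})

test_that("time rescaling (2N, mu/2) leaves expected diversity unchanged", {
  set.seed(10)
  m <- constModel()
  des <- oneLocusDesign(8, 800)
  k1 <- replicate(1500, simulateDataset(m,
    c(N1 = 5000, mu_control_region = 8e-8, kappa_control_region = 2),
    des, output = "stats")[["control_region.k.P1"]])
  k2 <- replicate(1500, simulateDataset(m,
    c(N1 = 10000, mu_control_region = 4e-8, kappa_control_region = 2),
    des, output = "stats")[["control_region.k.P1"]])
  expect_lt(abs(mean(k1) / mean(k2) - 1), 0.1)
})

test_that("tip labels are exchangeable within a population", {
  set.seed(11)
  m <- constModel()
  des <- oneLocusDesign(8, 500)
  draw <- c(N1 = 10000, mu_control_region = 5e-8,
            kappa_control_region = 2)
  ## statistic symmetric under exchangeability: per-tip mean distance of
  ## tip 1 vs tip 8 across replicates should be identically distributed
  d1 <- d8 <- numeric(400)
  for (i in 1:400) {
    ds <- simulateDataset(m, draw, des, output = "alignments")
    D <- seqABC:::.pairDiffMatrix(ds$alignments[[1]])
    d1[i] <- mean(D[1, -1]); d8[i] <- mean(D[8, -8])
  }
  ks <- suppressWarnings(stats::ks.test(d1, d8))
  expect_gt(ks$p.value, 0.01)
})
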