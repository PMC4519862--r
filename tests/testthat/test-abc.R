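## the fast one-population models (.lowDivModel) and single-locus design
## (.abcDesign) used below live in helper-oracles.R

test_that("summary vectors follow the documented layout and counting formula", {
  ## all sequences identical
  aln <- SeqAlignment(rep("ACGTACGT", 4), ids = paste0("s", 1:4),
                      locus = "l1")
  pm <- data.frame(sample_id = sampleIDs(aln),
                   population = rep(c("A", "B"), each = 2),
                   region = rep(c("A", "B"), each = 2))
  st <- summaryStats(list(l1 = aln), pm, demes = c("A", "B"))
  expect_equal(unname(st[c("l1.H.A", "l1.H.B")]), c(1, 1))
  expect_true(all(st[c("l1.S.A", "l1.S.B", "l1.k.A", "l1.k.B",
                       "l1.W.A-B", "l1.B.A-B")] == 0))

  ## 2 pops of 2: within differences 0, all cross differences 3
  aln2 <- SeqAlignment(c(a1 = "AAAAAA", a2 = "AAAAAA",
                         b1 = "TTTAAA", b2 = "TTTAAA"), locus = "l1")
  pm2 <- data.frame(sample_id = sampleIDs(aln2),
                    population = c("A", "A", "B", "B"),
                    region = c("A", "A", "B", "B"))
  st2 <- summaryStats(list(l1 = aln2), pm2, demes = c("A", "B"))
  expect_equal(unname(st2["l1.W.A-B"]), 0)
  expect_equal(unname(st2["l1.B.A-B"]), 3)
  expect_equal(unname(st2[c("l1.k.A", "l1.k.B")]), c(0, 0))

  ## 2 loci x 3 demes -> 2 (3*3) + 2 (3*2) = 30 entries
  nm <- seqABC:::.statNamesForDesign(c("l1", "l2"), c("A", "B", "C"))
  expect_equal(length(nm), 30L)
})

test_that("reference tables have the right shape and are reproducible", {
  mods <- list(.lowDivModel("s1"), .lowDivModel("s2"))
  des <- .abcDesign(n = 6, L = 120)
  ref1 <- buildReferenceTable(mods, 100, des, seed = 5)
  ref2 <- buildReferenceTable(mods, 100, des, seed = 5)
  expect_equal(length(ref1@scenario), 200L)
  expect_equal(as.integer(table(ref1@scenario)), c(100L, 100L))
  expect_identical(ref1@stats, ref2@stats)
  expect_identical(ref1@params, ref2@params)
  ## MAD normalisation identity on the non-degenerate statistics
  norm <- sweep(ref1@stats, 2L, ref1@norm, "/")
  raw_mad <- apply(ref1@stats, 2L, mad)
  for (j in which(raw_mad > 0))
    expect_equal(mad(norm[, j]), 1, tolerance = 1e-9)
})

test_that("direct model choice obeys its limiting cases", {
  des <- .abcDesign(n = 6, L = 120)
  solo <- buildReferenceTable(.lowDivModel("only"), 200, des, seed = 6)
  obs <- simulateDataset(.lowDivModel("only"),
    c(N1 = 1000, mu_control_region = 2e-7, kappa_control_region = 2),
    des, seed = 1, output = "stats")
  ## single scenario: PP = 1 regardless of the observation
  mc <- chooseModelDirect(solo, obs, nClosest = 50)
  expect_equal(mc$pp, 1)
  expect_true(mc$ci_lo <= 1 && mc$ci_hi >= mc$pp)
  ## nClosest = all rows in a balanced table: uniform PP
  mods <- list(.lowDivModel("s1"), .lowDivModel("s2"))
  ref <- buildReferenceTable(mods, 150, des, seed = 7)
  mcu <- chooseModelDirect(ref, obs, nClosest = 300)
  expect_equal(mcu$pp, c(0.5, 0.5))
  expect_equal(sum(mcu$pp), 1, tolerance = 1e-12)
})

test_that("disjoint summary distributions give PP = 1 for the source scenario", {
  ## low vs high diversity: effectively disjoint statistics
  mods <- list(.lowDivModel("low", 500, 1500),
               .lowDivModel("high", 2e5, 6e5))
  des <- .abcDesign(n = 10, L = 300)
  ref <- buildReferenceTable(mods, 400, des, seed = 8)
  obs <- simulateDataset(mods[[1]],
    c(N1 = 1000, mu_control_region = 2e-7, kappa_control_region = 2),
    des, seed = 2, output = "stats")
  mc <- chooseModelDirect(ref, obs, nClosest = 100)
  expect_equal(mc$pp[mc$scenario == "low"], 1)
  expect_equal(sum(mc$pp), 1, tolerance = 1e-12)
})

test_that("PP vectors always sum to one", {
  mods <- list(.lowDivModel("s1"), .lowDivModel("s2", 3000, 9000),
               .lowDivModel("s3", 2e4, 8e4))
  des <- .abcDesign(n = 8, L = 200)
  ref <- buildReferenceTable(mods, 80, des, seed = 9)
  set.seed(10)
  for (i in 1:20) {
    obs <- simulateDataset(mods[[sample(3, 1)]],
      c(N1 = runif(1, 500, 8e4), mu_control_region = 2e-7,
        kappa_control_region = 2), des, output = "stats")
    mc <- suppressMessages(chooseModelDirect(ref, obs, nClosest = 60))
    expect_equal(sum(mc$pp), 1, tolerance = 1e-12)
    expect_true(all(mc$ci_lo <= mc$pp & mc$pp <= mc$ci_hi))
  }
})

test_that("parameter estimation collapses onto exact relations", {
  ## degenerate accepted set: all draws equal -> point estimate
  ref <- new("ReferenceTable", scenario = rep("s", 50),
             params = matrix(7, 50, 1, dimnames = list(NULL, "N1")),
             stats = matrix(rnorm(100), 50, 2,
                            dimnames = list(NULL, c("a", "b"))),
             norm = c(1, 1), seed = 1L)
  est <- suppressMessages(estimateParameters(ref, c(a = 0, b = 0),
    nClosest = 50, scenario = "s"))
  expect_equal(est$median, 7, tolerance = 1e-9)

  ## noiseless linear (log-scale) relation: adjustment recovers the truth
  set.seed(11)
  x <- runif(200, 1, 3)
  stats <- cbind(a = x, b = rnorm(200))
  params <- matrix(exp(2 * x), 200, 1, dimnames = list(NULL, "N1"))
  ref2 <- new("ReferenceTable", scenario = rep("s", 200), params = params,
              stats = stats, norm = c(1, 1), seed = 1L)
  obs <- c(a = 2, b = 0)
  est2 <- estimateParameters(ref2, obs, nClosest = 100, scenario = "s")
  expect_true(est2$adjusted[1])
  expect_equal(est2[est2$parameter == "N1", "median"], exp(4),
               tolerance = 0.02)
  width <- est2$q975[1] - est2$q025[1]
  expect_lt(width, 0.1 * exp(4))
})

test_that("confidence evaluation separates separable scenarios", {
  mods <- list(.lowDivModel("low", 500, 1500),
               .lowDivModel("high", 2e5, 6e5))
  des <- .abcDesign(n = 10, L = 300)
  ref <- buildReferenceTable(mods, 300, des, seed = 12)
  cf <- evaluateConfidence(mods, des, nTestSets = 30, ref, seed = 13,
                           nClosest = 75)
  expect_true(all(cf$errors$type_I <= 0.05))
  expect_true(all(cf$errors$type_II <= 0.05))
  expect_true(all(cf$errors$type_I >= 0 & cf$errors$type_II >= 0))
})

test_that("parameter recovery is scored with relative bias and RMSE", {
  mods <- list(.lowDivModel("only", 1000, 50000))
  des <- .abcDesign(n = 10, L = 300)
  ref <- buildReferenceTable(mods, 400, des, seed = 14)
  cf <- evaluateConfidence(mods, des, nTestSets = 10, ref, seed = 15,
                           nClosest = 100, estimateParams = TRUE)
  prow <- cf$params[cf$params$parameter == "N1", ]
  expect_equal(nrow(prow), 1L)
  expect_true(is.finite(prow$rel_bias))
  expect_gte(prow$rel_rmse, abs(prow$rel_bias) - 1e-12)
})

test_that("the PCA prior check centres, projects and flags correctly", {
  mods <- list(.lowDivModel("s1"), .lowDivModel("s2", 3000, 9000))
  des <- .abcDesign(n = 8, L = 200)
  ref <- buildReferenceTable(mods, 150, des, seed = 16)
  ## observed at the mean of the simulated vectors projects at the origin
  obs_mean <- colMeans(ref@stats)
  pc <- suppressWarnings(pcaPriorCheck(ref, obs_mean))
  expect_equal(unname(pc$observed), rep(0, length(pc$observed)),
               tolerance = 1e-8)
  expect_true(any(pc$inside))
  ## an observation 10 MADs outside the cloud is flagged out of envelope
  obs_far <- colMeans(ref@stats) + 50 * ref@norm
  pc_far <- suppressWarnings(pcaPriorCheck(ref, obs_far))
  expect_false(any(pc_far$inside))
  ## rank bound
  expect_lte(ncol(pc$fit$x), min(nrow(ref@stats), ncol(ref@stats)))
})
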