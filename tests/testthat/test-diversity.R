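test_that("haplotype diversity matches hand evaluation and handles edge cases", {
  hd <- haplotypeDiversity(c(2, 2))
  expect_equal(hd$Hd, 2 / 3, tolerance = 1e-12)
  expect_equal(haplotypeDiversity(c(5))$Hd, 0)
  expect_equal(haplotypeDiversity(c(5))$var_Hd, 0)
  expect_false(haplotypeDiversity(c(1), n = 1)$defined)
  expect_error(haplotypeDiversity(c(2, 2), n = 5), "sum to n")
})

test_that("Hd and pi match brute-force oracles on random alignments", {
  set.seed(303)
  for (rep in 1:500) {
    n <- sample(2:10, 1)
    aln <- randomAlignment(n, sample(2:25, 1), gapProb = 0.04,
                           alphabet = c("A", "C", "G"))
    cnt <- as.integer(table(oracleHaplotypes(aln)))
    hd <- haplotypeDiversity(cnt, n)
    expect_equal(hd$Hd, oracleHd(cnt, n), tolerance = 1e-12)
    expect_equal(hd$var_Hd, oracleHdVar(cnt, n), tolerance = 1e-12)
    nd <- nucleotideDiversity(aln)
    ora <- oraclePiK(aln)
    expect_equal(nd$k, ora$k, tolerance = 1e-12)
    if (!is.na(ora$pi)) expect_equal(nd$pi, ora$pi, tolerance = 1e-12)
  }
})

test_that("nucleotide diversity reproduces the enumerated example", {
  ## 3 sequences, pairwise differences 0, 2, 2 over 10 sites
  aln <- SeqAlignment(c(a = "AAAAAAAAAA", b = "AAAAAAAAAA",
                        c = "TTAAAAAAAA"))
  nd <- nucleotideDiversity(aln)
  expect_equal(nd$k, 4 / 3, tolerance = 1e-9)
  expect_equal(nd$pi, 4 / 30, tolerance = 1e-9)
  ident <- SeqAlignment(rep("ACGT", 4), ids = paste0("s", 1:4))
  expect_equal(nucleotideDiversity(ident)$pi, 0)
})

test_that("K2P distance agrees with the closed form and model relations hold", {
  ## 100 sites, 10 transitions (A<->G), no transversions
  a <- paste(rep("A", 100), collapse = "")
  b <- paste(c(rep("G", 10), rep("A", 90)), collapse = "")
  d <- distanceMatrix(SeqAlignment(c(x = a, y = b)), model = "K2P")
  expect_equal(d$entries[1, 2],
               -0.5 * log(1 - 2 * 0.1) - 0.25 * log(1), tolerance = 1e-9)
  expect_equal(d$entries[1, 2], 0.11157, tolerance = 1e-4)

  ident <- SeqAlignment(rep("ACGTACGT", 3), ids = paste0("s", 1:3))
  for (mod in c("p", "JC69", "K2P", "MCL"))
    expect_equal(distanceMatrix(ident, mod)$mean, 0)

  ## K2P reduces to JC69 when transitions:transversions are 1:2
  L <- 3000
  base <- rep("A", L)
  mut <- base
  mut[1:4]  <- "G"            # 4 transitions
  mut[5:12] <- c(rep("C", 4), rep("T", 4))  # 8 transversions
  pair <- SeqAlignment(c(x = paste(base, collapse = ""),
                         y = paste(mut, collapse = "")))
  dk <- distanceMatrix(pair, "K2P")$entries[1, 2]
  dj <- distanceMatrix(pair, "JC69")$entries[1, 2]
  expect_equal(dk, dj, tolerance = 1e-5)

  ## distances are symmetric with zero diagonal, mean recomputable
  set.seed(9)
  base <- sample(c("A", "C", "G", "T"), 60, replace = TRUE)
  seqs <- vapply(1:6, function(i) {
    s <- base
    pos <- sample(60, 3)
    s[pos] <- sample(c("A", "C", "G", "T"), 3, replace = TRUE)
    paste(s, collapse = "")
  }, "")
  haps <- collapseHaplotypes(SeqAlignment(seqs, ids = paste0("s", 1:6)))
  dm <- distanceMatrix(haps, "K2P")
  expect_equal(dm$entries, t(dm$entries))
  expect_equal(unname(diag(dm$entries)), rep(0, nrow(dm$entries)))
  expect_equal(dm$mean, mean(dm$entries[upper.tri(dm$entries)]))
})

test_that("K2P/JC69/MCL agree with ape::dist.dna as an independent check", {
  skip_if_not_installed("ape")
  set.seed(11)
  base <- sample(c("A", "C", "G", "T"), 200, replace = TRUE)
  seqs <- vapply(1:5, function(i) {
    s <- base
    pos <- sample(200, 12)
    s[pos] <- sample(c("A", "C", "G", "T"), 12, replace = TRUE)
    paste(s, collapse = "")
  }, "")
  aln <- SeqAlignment(seqs, ids = paste0("s", 1:5))
  bin <- ape::as.DNAbin(strsplit(tolower(apply(alignmentMatrix(aln), 1,
                                               paste, collapse = "")), ""))
  for (pair in list(c("JC69", "JC69"), c("K2P", "K80"))) {
    ours <- distanceMatrix(aln, pair[1])$entries
    theirs <- as.matrix(ape::dist.dna(bin, model = pair[2]))
    expect_equal(unname(ours), unname(theirs), tolerance = 1e-9)
  }
})

test_that("Tajima's D and Fu & Li's D* match independent transcriptions", {
  set.seed(404)
  found <- 0
  for (rep in 1:200) {
    aln <- randomAlignment(sample(4:12, 1), sample(5:30, 1),
                           gapProb = 0.02, alphabet = c("A", "T"))
    td <- tajimaD(aln)
    dd <- fuLiDstar(aln)
    o_td <- oracleTajimaD(aln)
    o_dd <- oracleFuLiDstar(aln)
    if (td$defined) {
      found <- found + 1
      expect_equal(td$D, o_td, tolerance = 1e-12)
      expect_equal(dd$Dstar, o_dd, tolerance = 1e-12)
    } else {
      expect_true(is.na(o_td))
    }
  }
  expect_gt(found, 100)
})

test_that("neutrality statistics are flagged undefined when S = 0", {
  aln <- SeqAlignment(rep("ACGTACGT", 5), ids = paste0("s", 1:5))
  expect_false(tajimaD(aln)$defined)
  expect_false(fuLiDstar(aln)$defined)
  expect_false(fuFs(aln, nNullSims = 10)$defined)
})

test_that("Stirling recursion satisfies the rising-factorial identity", {
  ## sum_k |s(n,k)| x^k = x (x+1) ... (x+n-1)
  for (n in 2:10) {
    ls <- seqABC:::.logStirlingRow(n)
    for (x in c(0.3, 1, 2.7)) {
      lhs <- sum(exp(ls) * x^seq_len(n))
      rhs <- prod(x + 0:(n - 1))
      expect_equal(lhs, rhs, tolerance = 1e-9)
    }
  }
})

test_that("Fu's Fs S' equals exhaustive Ewens enumeration for n <= 6", {
  for (n in 3:6) for (k in 2:n) for (theta in c(0.4, 1.3, 3)) {
    expect_equal(seqABC:::.ewensTail(n, k, theta),
                 oracleEwensTail(n, k, theta), tolerance = 1e-10)
  }
})

test_that("Fu's Fs behaves sensibly on data and flags the K = 1 case", {
  ## one haplotype (K = 1): S' = 1, Fs undefined
  aln1 <- SeqAlignment(rep("AAAA", 4), ids = paste0("s", 1:4))
  expect_false(fuFs(aln1, nNullSims = 10)$defined)

  set.seed(505)
  aln <- randomAlignment(8, 30, alphabet = c("A", "G"))
  fs <- fuFs(aln, nNullSims = 200, seed = 42)
  expect_true(fs$defined)
  expect_equal(fs$Fs, log(fs$Sprime / (1 - fs$Sprime)), tolerance = 1e-12)
  expect_true(fs$p > 0 && fs$p <= 1)
  ## deterministic under a seed
  fs2 <- fuFs(aln, nNullSims = 200, seed = 42)
  expect_equal(fs$p, fs2$p)
})

test_that("the per-population diversity report mirrors the per-population stats", {
  set.seed(66)
  aln <- randomAlignment(12, 40, alphabet = c("A", "C", "G"))
  pm <- data.frame(sample_id = sampleIDs(aln),
                   population = rep(c("P1", "P2", "P3"), each = 4),
                   region = "R")
  rep_ <- diversityReport(aln, pm, nNullSims = 50, seed = 1)
  expect_equal(rep_$population, c("P1", "P2", "P3", "overall"))
  expect_equal(rep_$n, c(4, 4, 4, 12))
  sub <- SeqAlignment(apply(alignmentMatrix(aln)[1:4, ], 1, paste,
                            collapse = ""))
  expect_equal(rep_$pi[1], nucleotideDiversity(sub)$pi)
  expect_equal(rep_$D[4], tajimaD(aln)$D)
})
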