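# exhaustive pair-counting oracle for the Mann-Whitney U statistic
u_oracle <- function(x, y) {
  tot <- 0
  for (xi in x) tot <- tot + sum(xi > y) + 0.5 * sum(xi == y)
  tot
}

test_that("Mann-Whitney U equals exhaustive pair counting for small groups", {
  mw <- mannWhitneyU(c(1, 2), c(3, 4))
  expect_equal(mw$U, 0)
  withr::with_seed(11, {
    for (i in 1:50) {
      n1 <- sample(2:8, 1); n2 <- sample(2:8, 1)
      x <- sample(1:5, n1, replace = TRUE)  # ties across and within groups
      y <- sample(1:5, n2, replace = TRUE)
      expect_equal(mannWhitneyU(x, y)$U, u_oracle(x, y))
    }
  })
  expect_error(mannWhitneyU(1, c(1, 2)), "at least 2")
})

test_that("codon minima take the per-position minimum over three alts", {
  hg <- hand_gene()
  # CDS 26..37: score all 3 alts per coding position
  vs <- enumerateAllSnvs(hg$genome, "chrH", 26L, 37L)
  withr::with_seed(5, s <- round(runif(length(vs)), 3))
  scores <- data.frame(chrom = variantChrom(vs), pos = variantPos(vs),
                       ref = variantRef(vs), alt = variantAlt(vs),
                       score = s)
  minima <- codonMinScores(scores, hg$models)
  expect_equal(nrow(minima), 12L)  # 4 codons x 3 positions
  expect_equal(sort(unique(minima$codon_pos)), 1:3)
  agg <- tapply(scores$score, scores$pos, min)
  expect_equal(minima$min_score, as.numeric(agg[as.character(minima$pos)]))
  # a position with fewer than 3 scored alts is excluded
  minima2 <- codonMinScores(scores[-1, ], hg$models)
  expect_equal(nrow(minima2), 11L)
  expect_equal(attr(minima2, "excluded_positions"), 1L)
})

test_that("multi-transcript and antisense genes are excluded from codon stats", {
  gff <- write_tmp(c(
    "##gff-version 3",
    "c1\tt\tgene\t1\t60\t.\t+\t.\tID=gA",
    "c1\tt\tmRNA\t1\t30\t.\t+\t.\tID=txA1;Parent=gA",
    "c1\tt\tCDS\t1\t12\t.\t+\t0\tID=cA1;Parent=txA1",
    "c1\tt\tmRNA\t31\t60\t.\t+\t.\tID=txA2;Parent=gA",
    "c1\tt\tCDS\t31\t42\t.\t+\t0\tID=cA2;Parent=txA2",
    "c1\tt\tgene\t70\t90\t.\t-\t.\tID=gB",
    "c1\tt\tmRNA\t70\t81\t.\t-\t.\tID=txB;Parent=gB",
    "c1\tt\tCDS\t70\t81\t.\t-\t0\tID=cB;Parent=txB"), ".gff3")
  gm <- readGeneModels(gff)
  scores <- data.frame(chrom = "c1", pos = rep(1:100, each = 3),
                       ref = "A", alt = rep(c("C", "G", "T"), 100),
                       score = 0.5)
  minima <- codonMinScores(scores, gm)
  expect_equal(nrow(minima), 0L)
  expect_true(all(c("gA", "gB") %in% attr(minima, "excluded_genes")))
})

test_that("codon-position comparisons recover a planted ordering", {
  withr::with_seed(23, {
    n_codon <- 500
    minima <- data.frame(
      gene = rep(sprintf("g%02d", 1:20), length.out = n_codon * 3),
      codon_pos = rep(1:3, each = n_codon),
      min_score = c(rnorm(n_codon, 0.5, 0.1), rnorm(n_codon, 0.6, 0.1),
                    rnorm(n_codon, 0.3, 0.1)))
  })
  res <- compareCodonPositions(minima, scope = "genome")
  expect_equal(nrow(res), 3L)
  expect_true(all(res$p_bonferroni < 0.05))
  expect_equal(res$higher[res$pair == "pos1_vs_pos2"], "pos2")
  expect_equal(res$higher[res$pair == "pos1_vs_pos3"], "pos1")
  expect_equal(res$higher[res$pair == "pos2_vs_pos3"], "pos2")
  expect_equal(res$p_bonferroni, pmin(1, res$p_raw * 3))
})

test_that("identical codon-position distributions stay insignificant", {
  withr::with_seed(29, {
    minima <- data.frame(gene = "g", codon_pos = rep(1:3, each = 50),
                         min_score = rep(round(runif(50), 2), 3))
  })
  res <- compareCodonPositions(minima, scope = "genome")
  expect_true(all(res$p_bonferroni > 0.9))
})

test_that("per-gene codon comparisons report both Bonferroni families", {
  withr::with_seed(31, {
    minima <- data.frame(
      gene = rep(c("g1", "g2"), each = 90),
      codon_pos = rep(rep(1:3, each = 30), 2),
      min_score = c(rnorm(30, 0.5, 0.05), rnorm(30, 0.6, 0.05),
                    rnorm(30, 0.3, 0.05),
                    rnorm(90, 0.5, 0.05)))  # g2: no signal
  })
  res <- compareCodonPositions(minima, scope = "per_gene")
  expect_equal(res$n_tests, 6L)
  expect_equal(res$per_gene$p_bonf_within,
               pmin(1, res$per_gene$p_raw * 3))
  expect_equal(res$per_gene$p_bonf_global,
               pmin(1, res$per_gene$p_raw * 6))
  expect_equal(unname(res$fraction_significant["pos2_vs_pos3"]), 0.5)
})

test_that("AF bins are left-open right-closed with rare/common means", {
  out <- afBinSummary(c(0.2, 0.4, 0.6), c(0.01, 0.01, 0.5))
  expect_equal(out$rare_mean, 0.3)
  expect_equal(out$overall_mean, 0.4)
  expect_equal(out$common_mean, 0.6)
  expect_equal(sum(out$bins$count), 3L)

  one <- afBinSummary(0.7, 0.3)
  expect_equal(one$bins$mean[one$bins$count == 1], 0.7)

  # AF exactly 0.025 falls in the first bin
  edge <- afBinSummary(c(1, 0), c(0.025, 0.026))
  expect_equal(edge$bins$count[1], 1L)
  expect_equal(edge$bins$count[2], 1L)

  expect_warning(r <- afBinSummary(c(0.5, 0.6), c(0, 0.5)), "rejected")
  expect_equal(r$n_rejected, 1L)
})

test_that("threshold fractions honor strict and inclusive comparators", {
  s <- c(rep(0.7, 9), 0.1)
  fr <- fractionAbove(s)
  expect_equal(unname(fr[">0.6"]), 0.9)
  expect_equal(unname(fractionAbove(rep(0, 5))), c(0, 0))
  at08 <- fractionAbove(c(0.8), thresholds = c(0.8, 0.8),
                        comparators = c(">", ">="))
  expect_equal(unname(at08), c(0, 1))
  # monotone non-increasing in the threshold
  withr::with_seed(2, x <- runif(200))
  fr2 <- fractionAbove(x, thresholds = seq(0.1, 0.9, 0.1),
                       comparators = ">")
  expect_true(all(diff(unname(fr2)) <= 0))
})

test_that("gene-window means average the three alts per position", {
  scores <- data.frame(chrom = "c1", pos = rep(1:2000, each = 3),
                       ref = "A", alt = rep(c("C", "G", "T"), 2000),
                       score = rep(c(0.1, 0.2, 0.3), 2000))
  gw <- geneWindowMeans(scores, "c1", 1000L, 1200L, flank = 500L)
  expect_equal(nrow(gw), 1201L)  # gene length + 1000
  expect_true(all(abs(gw$mean_score - 0.2) < 1e-12))
  obs <- variantSet("c1", 1100L, "A", "C")
  gw2 <- geneWindowMeans(scores, "c1", 1000L, 1200L, observed = obs)
  expect_true(gw2$observed[gw2$pos == 1100])
  expect_equal(sum(gw2$observed), 1L)
  expect_warning(geneWindowMeans(scores, "c1", 300L, 400L, flank = 500L),
                 "clipped")
})

test_that("candidate ranking joins scores with p-value tie-breaks", {
  scores <- data.frame(chrom = "c1", pos = c(1L, 2L, 3L), ref = "A",
                       alt = "G", score = c(0.9, 0.1, 0.9))
  cand <- data.frame(chrom = "c1", pos = c(1L, 2L, 3L, 9L), alt = "G",
                     p = c(1e-6, 1e-9, 1e-3, 1e-4))
  res <- rankCandidates(cand, scores)
  expect_equal(res$ranked$pos, c(1L, 3L, 2L))  # equal scores: smaller p first
  expect_equal(res$unscoreable$pos, 9L)
  # identical rankings give Spearman 1
  scores2 <- data.frame(chrom = "c1", pos = 1:3, ref = "A", alt = "G",
                        score = c(0.9, 0.5, 0.1))
  cand2 <- data.frame(chrom = "c1", pos = 1:3, alt = "G",
                      p = c(1e-9, 1e-6, 1e-3))
  expect_equal(rankCandidates(cand2, scores2)$spearman, 1)
})
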