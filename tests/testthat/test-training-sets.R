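mini_genome <- function(seqtext, chrom = "c1") {
  g <- Biostrings::DNAStringSet(seqtext)
  names(g) <- chrom
  g
}

anc_map <- function(chars, chrom = "c1") {
  new("AncestorMap", bases = setNames(list(chars), chrom), conflicts = 0L)
}

af_table <- function(chrom = character(), pos = integer(),
                     alt = character(), af = numeric()) {
  new("PopulationAF", records = data.frame(chrom = chrom, pos = pos,
                                           alt = alt, af = af,
                                           stringsAsFactors = FALSE))
}

test_that("CpG context follows the dinucleotide on the given strand", {
  expect_equal(cpgContext(c("A", "C", "G", "T")),
               c(FALSE, TRUE, TRUE, FALSE))
  expect_equal(cpgContext(c("C", "C", "G", "G")),
               c(FALSE, TRUE, TRUE, FALSE))
  expect_false(any(cpgContext(c("G", "C"))))  # GpC is not CpG
})

test_that("ancestral context marks gap-adjacent C/G indeterminate", {
  expect_equal(ancestorContext(c("C", "G", "A")),
               c("CpG", "CpG", "nonCpG"))
  expect_equal(ancestorContext(c("C", "-", "G")),
               c("indeterminate", "indeterminate", "indeterminate"))
  expect_equal(ancestorContext(c("A", "T", "C", "A")),
               c("nonCpG", "nonCpG", "nonCpG", "nonCpG"))
  # terminal C has no next base: indeterminate
  expect_equal(ancestorContext(c("A", "C"))[2], "indeterminate")
})

test_that("derived calling applies the derived-allele frequency filter", {
  g <- mini_genome("AAGAA")
  anc <- anc_map(c("A", "A", "C", "A", "A"))
  # ref G vs anc C at pos 3; ALT C segregates at 0.05 -> derived AF 0.95
  keep <- callDerived(g, anc, af_table("c1", 3L, "C", 0.05))
  expect_length(keep, 1L)
  expect_equal(variantPos(keep), 3L)
  expect_equal(variantRef(keep), "G")
  expect_equal(variantAlt(keep), "C")  # ancestral allele kept as alt
  # derived AF 0.5 < 0.9 -> dropped
  expect_length(callDerived(g, anc, af_table("c1", 3L, "C", 0.5)), 0L)
  # no population record -> treated as fixed
  expect_length(callDerived(g, anc, af_table()), 1L)
  expect_error(callDerived(g, anc, af_table(), afThreshold = 0), "\\(0, 1]")
  expect_error(callDerived(g, anc, af_table(), afThreshold = 1.2),
               "\\(0, 1]")
})

test_that("lowering the AF threshold never removes derived variants", {
  fx <- full_fixture()
  n_default <- length(callDerived(fx$genome, fx$anc, fx$af, 0.9))
  n_looser <- length(callDerived(fx$genome, fx$anc, fx$af, 0.5))
  n_strict <- length(callDerived(fx$genome, fx$anc, fx$af, 0.99))
  expect_true(n_looser >= n_default)
  expect_true(n_default >= n_strict)
})

test_that("rate estimation counts substitutions over aligned bases", {
  # 100 ancestral A's in non-CpG context, 2 of them G in the reference
  refc <- c(rep("A", 98), "G", "G")
  ancc <- rep("A", 100)
  m <- estimateRates(mini_genome(paste(refc, collapse = "")), anc_map(ancc))
  tab <- rateTable(m)
  expect_equal(tab$rate[tab$context == "nonCpG" & tab$from == "A" &
                          tab$to == "G"], 0.02)
  expect_equal(tab$denom[tab$context == "nonCpG" & tab$from == "A" &
                           tab$to == "G"], 100L)

  # ancestor == reference -> every defined rate 0
  g <- makeReference(500, 0.5, seed = 3)
  anc_id <- anc_map(genomeChars(g, "chrS"), "chrS")
  tab2 <- rateTable(estimateRates(g, anc_id))
  expect_true(all(tab2$rate[!is.na(tab2$rate)] == 0))

  # 10 CpG-context ancestral C's (anc "CG" pairs), 3 are T in reference
  ancc3 <- rep(c("C", "G"), 10)
  refc3 <- ancc3
  refc3[c(1, 3, 5)] <- "T"
  m3 <- estimateRates(mini_genome(paste(refc3, collapse = "")),
                      anc_map(ancc3))
  tab3 <- rateTable(m3)
  expect_equal(tab3$rate[tab3$context == "CpG" & tab3$from == "C" &
                           tab3$to == "T"], 0.3)
})

test_that("zero ancestor coverage on a chromosome is an error", {
  g <- mini_genome("ACGT")
  expect_error(estimateRates(g, anc_map(rep("-", 4))), "coverage is zero")
})

test_that("simulation yields distinct admissible variants, seeded", {
  g <- makeReference(1000, 0.5, seed = 11)
  anc <- anc_map(genomeChars(g, "chrS"), "chrS")
  rates <- syntheticRateModel("chrS", transition = 0.05,
                              transversion = 0.05, cpgFactor = 1)
  vs <- simulateVariants(g, anc, rates, nTarget = 100, seed = 5)
  expect_length(vs, 100L)
  expect_true(all(variantRef(vs) != variantAlt(vs)))
  key <- paste(variantPos(vs), variantAlt(vs))
  expect_false(anyDuplicated(key) > 0)
  # determinism
  vs2 <- simulateVariants(g, anc, rates, nTarget = 100, seed = 5)
  expect_identical(as.data.frame(vs), as.data.frame(vs2))
  # exclusions never emitted
  excl <- vs[1:10]
  vs3 <- simulateVariants(g, anc, rates, nTarget = 100, seed = 6,
                          exclusions = excl)
  expect_length(intersect(paste(variantPos(vs3), variantAlt(vs3)),
                          paste(variantPos(excl), variantAlt(excl))), 0L)
  # infeasible target
  expect_error(simulateVariants(g, anc, rates, nTarget = 10000, seed = 1),
               "exceeds")
})

test_that("simulated substitution types track the configured rates", {
  g <- makeReference(100000, 0.42, seed = 21)
  anc <- anc_map(genomeChars(g, "chrS"), "chrS")
  rates <- syntheticRateModel("chrS", transition = 0.008,
                              transversion = 0.002, cpgFactor = 10)
  vs <- simulateVariants(g, anc, rates, nTarget = 10000, seed = 9)
  ctx <- cpgContext(genomeChars(g, "chrS"))
  cat_of <- paste(ifelse(ctx[variantPos(vs)], "CpG", "nonCpG"),
                  variantRef(vs), variantAlt(vs))
  # expected proportions: total configured weight per category
  tab <- rateTable(rates)
  refc <- genomeChars(g, "chrS")
  w <- numeric(0)
  for (context in c("CpG", "nonCpG")) {
    sel <- if (context == "CpG") ctx else !ctx
    nb <- table(factor(refc[sel], levels = c("A", "C", "G", "T")))
    sub <- tab[tab$context == context & !is.na(tab$rate), ]
    w <- c(w, setNames(sub$rate * as.numeric(nb[sub$from]),
                       paste(context, sub$from, sub$to)))
  }
  w <- w[w > 0]
  obs <- table(factor(cat_of, levels = names(w)))
  gof <- chisq.test(as.numeric(obs), p = w / sum(w))
  expect_gt(gof$p.value, 0.001)
  # the CpG C->T excess is visible at roughly the configured 10x ratio
  r_cpg <- obs[["CpG C T"]] / sum(refc[ctx] == "C")
  r_non <- obs[["nonCpG C T"]] / sum(refc[!ctx] == "C")
  expect_gt(r_cpg / r_non, 5)
})

test_that("trimming matches class sizes exactly and is seeded", {
  g <- makeReference(2000, 0.5, seed = 2)
  anc <- anc_map(genomeChars(g, "chrS"), "chrS")
  rates <- syntheticRateModel("chrS", 0.05, 0.05, 1)
  sim <- simulateVariants(g, anc, rates, nTarget = 1500, seed = 1)
  kept <- trimToMatch(sim, 1000, seed = 4)
  expect_length(kept, 1000L)
  expect_identical(as.data.frame(trimToMatch(sim, 1000, seed = 4)),
                   as.data.frame(kept))
  expect_error(trimToMatch(kept, 1500, seed = 1), "larger nTarget")
  same <- trimToMatch(sim, length(sim), seed = 1)
  expect_identical(as.data.frame(same), as.data.frame(sim))
})

test_that("labeled sets merge disjoint classes with 1/0 labels", {
  d <- variantSet(rep("c1", 3), 1:3, c("A", "A", "A"), c("G", "G", "G"))
  s <- variantSet(rep("c1", 3), 4:6, c("A", "A", "A"), c("C", "C", "C"))
  ls <- buildLabeledSet(d, s)
  expect_equal(variantLabel(ls), c(1L, 1L, 1L, 0L, 0L, 0L))
  cc <- classCounts(ls)
  expect_equal(cc$derived, 3L)
  expect_equal(cc$simulated, 3L)
  overlap <- variantSet("c1", 1L, "A", "G")
  expect_error(buildLabeledSet(d, overlap), "overlap")
})
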