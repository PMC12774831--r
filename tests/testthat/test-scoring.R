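zero_model <- function(features) {
  new("TrainedModel",
      weights = setNames(rep(0, length(features)), features),
      intercept = 0, l2 = 1,
      scaling = new("ScalingParams",
                    sds = setNames(rep(1, length(features)), features),
                    dropped = character()),
      specChecksum = NA_character_, meta = list())
}

test_that("SNV enumeration emits exactly the three alts per usable base", {
  g <- readGenome(write_tmp(c(">c1", "ACGTACGTAC"), ".fa"))
  vs <- enumerateAllSnvs(g, "c1")
  expect_length(vs, 30L)
  expect_true(all(variantRef(vs) != variantAlt(vs)))
  expect_false(anyDuplicated(paste(variantPos(vs), variantAlt(vs))) > 0)
  # ordered by (pos, alt)
  expect_equal(variantPos(vs), rep(1:10, each = 3))

  gn <- readGenome(write_tmp(c(">c1", "ACGTNNACGT"), ".fa"))
  vn <- enumerateAllSnvs(gn, "c1")
  expect_length(vn, 24L)
  expect_equal(attr(vn, "skipped"), 2L)
  expect_error(enumerateAllSnvs(g, "c1", 5, 11), "outside")
})

test_that("a zero-weight model scores everything 0.5", {
  fx <- full_fixture()
  spec <- fx$spec
  model <- zero_model(expandedColumnNames(spec))
  model@specChecksum <- spec@checksum
  cols <- expandedColumnNames(spec)
  scaler <- new("ScalingParams", sds = setNames(rep(1, length(cols)), cols),
                dropped = character())
  vs <- fx$labeled[1:20]
  sc <- scoreVariants(model, scaler, spec, vs, fx$genome,
                      genes = fx$models, tracks = fx$tracks,
                      intervals = fx$intervals)
  expect_equal(sc$score, rep(0.5, 20))
  expect_equal(sc$pos, variantPos(vs))  # order preserved
})

test_that("score orientation is P(simulated): label-0-leaning features raise it", {
  # weight +3 on PhyloP toward the derived class (label 1): higher PhyloP
  # must LOWER the impact score; weight -3 must raise it
  spec <- featureSpec(bases = list(list(name = "PhyloP", type = "numeric",
                                        default = 0)))
  scaler <- new("ScalingParams", sds = c(PhyloP = 1), dropped = character())
  g <- readGenome(write_tmp(c(">c1", strrep("A", 40)), ".fa"))
  tr <- GenomicRanges::GRanges("c1", IRanges::IRanges(1:40, width = 1),
                               score = seq(-2, 2, length.out = 40))
  vs <- variantSet(rep("c1", 2), c(5L, 35L), c("A", "A"), c("G", "G"))
  m_pos <- new("TrainedModel", weights = c(PhyloP = 3), intercept = 0,
               l2 = 1, scaling = scaler, specChecksum = spec@checksum,
               meta = list())
  sc <- scoreVariants(m_pos, scaler, spec, vs, g,
                      tracks = list(PhyloP = tr))
  expect_lt(sc$score[2], sc$score[1])
  expect_equal(sc$score, 1 - plogis(3 * trackValueAt(tr, "c1", c(5, 35))))
})

test_that("ref-mismatching variants error per record, others proceed", {
  spec <- featureSpec(bases = list(list(name = "GC", type = "numeric",
                                        default = 0)))
  scaler <- new("ScalingParams", sds = c(GC = 1), dropped = character())
  model <- zero_model("GC")
  model@specChecksum <- spec@checksum
  g <- readGenome(write_tmp(c(">c1", "AAAAAAAAAA"), ".fa"))
  vs <- variantSet(c("c1", "c1"), c(2L, 3L), c("A", "C"), c("G", "T"))
  sc <- scoreVariants(model, scaler, spec, vs, g)
  expect_equal(attr(sc, "errors"), 2L)
  expect_equal(sc$score[1], 0.5)
  expect_true(is.na(sc$score[2]))
})

test_that("precomputed region scores are complete, bounded, reproducible", {
  fx <- full_fixture()
  feat <- fixture_features()
  sp <- splitTrainTest(nrow(featureMatrix(feat$fm)), 0.9, seed = 1)
  tr_fm <- new("FeatureMatrix",
               mat = featureMatrix(feat$fm)[sp$train, , drop = FALSE],
               scaled = FALSE, checksum = feat$fm@checksum)
  scaler <- fitScaler(tr_fm)
  model <- trainLogistic(applyScaler(tr_fm, scaler),
                         feat$labels[sp$train], l2 = 1,
                         scaling = scaler,
                         specChecksum = fx$spec@checksum)
  out1 <- tempfile(fileext = ".tsv")
  out2 <- tempfile(fileext = ".tsv")
  precomputeScores(model, scaler, fx$spec, fx$genome, "chrS",
                   2001L, 3000L, genes = fx$models, tracks = fx$tracks,
                   intervals = fx$intervals, out = out1, chunkSize = 400L)
  precomputeScores(model, scaler, fx$spec, fx$genome, "chrS",
                   2001L, 3000L, genes = fx$models, tracks = fx$tracks,
                   intervals = fx$intervals, out = out2, chunkSize = 400L)
  expect_identical(readLines(out1), readLines(out2))  # byte-identical
  sc <- readScores(out1)
  expect_lte(nrow(sc), 3000L)
  expect_true(all(sc$score >= 0 & sc$score <= 1))
  # histogram machinery: hand-binned oracle over 0, 0.1, ..., 1.0
  edges <- seq(0, 1, 0.1)
  h <- hist(sc$score, breaks = edges, plot = FALSE)$counts
  oracle <- vapply(seq_len(10), function(b) {
    lo <- edges[b]; hi <- edges[b + 1]
    if (b == 1) sum(sc$score >= lo & sc$score <= hi)
    else sum(sc$score > lo & sc$score <= hi)
  }, numeric(1))
  expect_equal(h, oracle)
  .fx_cache$model <- model
  .fx_cache$scaler <- scaler
})

test_that("scoring the training variants reproduces the evaluation metrics", {
  fx <- full_fixture()
  feat <- fixture_features()
  model <- .fx_cache$model
  scaler <- .fx_cache$scaler
  sp <- splitTrainTest(nrow(featureMatrix(feat$fm)), 0.9, seed = 1)
  test_fm <- new("FeatureMatrix",
                 mat = featureMatrix(feat$fm)[sp$test, , drop = FALSE],
                 scaled = FALSE, checksum = feat$fm@checksum)
  ev <- evaluateModel(model, applyScaler(test_fm, scaler),
                      feat$labels[sp$test])
  sc <- scoreVariants(model, scaler, fx$spec, fx$labeled[sp$test],
                      fx$genome, genes = fx$models, tracks = fx$tracks,
                      intervals = fx$intervals)
  # score = P(simulated); AUC of (1 - score) against labels must agree
  expect_equal(rocAuc(1 - sc$score, feat$labels[sp$test]), ev$roc_auc)
  expect_equal(mean(as.numeric(1 - sc$score >= 0.5) ==
                      feat$labels[sp$test]), ev$accuracy)
})

test_that("class probabilities from scoring sum to one within 1e-12", {
  fx <- full_fixture()
  feat <- fixture_features()
  model <- .fx_cache$model
  sfm <- applyScaler(new("FeatureMatrix",
                         mat = featureMatrix(feat$fm)[1:50, , drop = FALSE],
                         scaled = FALSE, checksum = feat$fm@checksum),
                     .fx_cache$scaler)
  pr <- predictProba(model, sfm)
  expect_lt(max(abs(rowSums(pr) - 1)), 1e-12)
})
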