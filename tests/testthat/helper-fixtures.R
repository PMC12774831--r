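# Shared fixtures, built once per test run and cached.

.fx_cache <- new.env(parent = emptyenv())

# full default synthetic fixture (100 kb, 20 genes, ~2k + ~2k variants)
full_fixture <- function() {
  if (is.null(.fx_cache$fx))
    .fx_cache$fx <- makeFullFixture(file.path(tempdir(), "fx_full"),
                                    seed = 1L)
  .fx_cache$fx
}

# expanded + labeled feature matrix of the full fixture
fixture_features <- function() {
  if (is.null(.fx_cache$feat)) {
    fx <- full_fixture()
    ann <- annotateVariants(fx$labeled, fx$genome, genes = fx$models,
                            tracks = fx$tracks, intervals = fx$intervals,
                            spec = fx$spec)
    .fx_cache$feat <- list(fm = expandFeatures(ann, fx$spec),
                           labels = variantLabel(fx$labeled))
  }
  .fx_cache$feat
}

# a 3-gene toy genome with deterministic structure for classifier tests
toy_genes <- function() {
  if (is.null(.fx_cache$toy)) {
    ref <- makeReference(6000L, gc = 0.5, seed = 7L, chrom = "chrT")
    gff <- file.path(tempdir(), "toy_genes.gff3")
    gm <- makeGeneModels(ref, 3L, seed = 7L, gffPath = gff)
    .fx_cache$toy <- list(genome = gm$genome, models = gm$models,
                          gff = gff)
  }
  .fx_cache$toy
}

# hand-built single-gene locus: 100 bp chromosome, + strand, no intron
# layout: 1..20 upstream, 21..25 five prime UTR (exon), CDS 26..37
# ("ATG GCT TGG TAA"), 38..42 three prime UTR, 43.. downstream
hand_gene <- function() {
  chars <- rep("A", 100L)
  chars[seq(2, 100, by = 7)] <- "C"   # avoid accidental ATG/stop context
  cds <- strsplit("ATGGCTTGGTAA", "")[[1]]
  chars[26:37] <- cds
  genome <- Biostrings::DNAStringSet(paste(chars, collapse = ""))
  names(genome) <- "chrH"
  gff <- tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chrH\ttest\tgene\t21\t42\t.\t+\t.\tID=geneH",
    "chrH\ttest\tmRNA\t21\t42\t.\t+\t.\tID=txH;Parent=geneH",
    "chrH\ttest\texon\t21\t42\t.\t+\t.\tID=txH.e1;Parent=txH",
    "chrH\ttest\tCDS\t26\t37\t.\t+\t0\tID=txH.c1;Parent=txH"), gff)
  list(genome = genome, models = readGeneModels(gff))
}

write_tmp <- function(lines, ext = ".txt") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}
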