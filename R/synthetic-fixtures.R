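#' Generate a random reference chromosome
#'
#' I.i.d. bases with P(G) + P(C) = \code{gc}; deterministic per seed.
#'
#' @param length chromosome length (bp)
#' @param gc GC fraction in (0, 1)
#' @param seed integer seed
#' @param chrom chromosome name
#' @return DNAStringSet with one sequence
#' @export
makeReference <- function(length, gc = 0.42, seed = 1L, chrom = "chrS") {
  stopifnot(length > 0, gc > 0 && gc < 1)
  probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  chars <- with_seed(seed,
    sample(names(probs), length, replace = TRUE, prob = probs))
  seqs <- Biostrings::DNAStringSet(paste(chars, collapse = ""))
  names(seqs) <- chrom
  seqs
}

#' Synthetic CpG-stratified rate model
#'
#' Transitions and transversions at configurable per-branch substitution
#' rates, with CpG-context transitions (C->T and G->A) elevated by
#' \code{cpgFactor}.
#'
#' @param chroms chromosome names
#' @param transition,transversion non-CpG rates
#' @param cpgFactor CpG transition multiplier (applied to C->T and G->A in
#'   CpG context, the deamination signature)
#' @return a \linkS4class{MutationRateModel} (denominators set to 1 as
#'   placeholders: these are design rates, not estimates)
#' @export
syntheticRateModel <- function(chroms, transition = 0.008,
                               transversion = 0.002, cpgFactor = 10) {
  transitions <- c(A = "G", G = "A", C = "T", T = "C")
  rows <- list()
  for (chrom in chroms) for (context in c("CpG", "nonCpG")) {
    for (b1 in DNA_BASES) for (b2 in setdiff(DNA_BASES, b1)) {
      r <- if (transitions[b1] == b2) transition else transversion
      if (context == "CpG" && ((b1 == "C" && b2 == "T") ||
                               (b1 == "G" && b2 == "A")))
        r <- r * cpgFactor
      # a source A/T can never sit in CpG context: not applicable
      if (context == "CpG" && b1 %in% c("A", "T")) r <- NA_real_
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = chrom, context = context, from = b1, to = b2,
        count = NA_integer_, denom = 1L, rate = r,
        stringsAsFactors = FALSE)
    }
  }
  new("MutationRateModel", table = do.call(rbind, rows))
}

#' Generate an ancestor/reference pair with known substitution rates
#'
#' Takes the supplied sequence as the ancestral template, computes the
#' ancestral CpG context, and mutates every position forward with
#' probability rate[anc -> b | context] to produce the reference, so the
#' conditional ancestor-to-reference substitution rates equal the
#' configured rates exactly in expectation. Each position is then observed
#' (carried into the \linkS4class{AncestorMap}) independently with
#' probability \code{coverage}; unobserved positions are gaps. Optionally
#' writes a two-row MAF block per chromosome so the extraction path can be
#' exercised end to end.
#'
#' @param template DNAStringSet: the ancestral sequence
#' @param rates true \linkS4class{MutationRateModel}
#' @param coverage fraction of positions with a reconstructed base
#' @param seed integer seed
#' @param mafPath optional MAF output path
#' @param referenceLabel,ancestorLabel MAF row source labels
#' @return list with reference (DNAStringSet) and anc
#'   (\linkS4class{AncestorMap} on reference coordinates)
#' @export
makeAncestor <- function(template, rates, coverage = 0.164, seed = 1L,
                         mafPath = NULL, referenceLabel = "ref",
                         ancestorLabel = "anc") {
  tab <- rateTable(rates)
  rate_of <- setNames(tab$rate, paste(tab$chrom, tab$context, tab$from,
                                      tab$to))
  bases <- list()
  ref_seqs <- list()
  for (chrom in names(template)) {
    ancc <- genomeChars(template, chrom)
    n <- length(ancc)
    ctx <- ifelse(cpgContext(ancc), "CpG", "nonCpG")
    refc <- with_seed(derive_seed(seed, paste0("mut", chrom)), {
      out <- ancc
      u <- runif(n)
      cum <- rep(0, n)
      for (b in DNA_BASES) {
        w <- rate_of[paste(chrom, ctx, ancc, b)]
        w[is.na(w)] <- 0  # anc == b rows have no rate entry
        pick <- ancc != b & u >= cum & u < cum + w
        out[pick] <- b
        cum <- cum + w
      }
      out
    })
    covered <- with_seed(derive_seed(seed, paste0("cov", chrom)),
                         runif(n) < coverage)
    obs <- ifelse(covered, ancc, "-")
    bases[[chrom]] <- obs
    ref_seqs[[chrom]] <- paste(refc, collapse = "")
  }
  reference <- Biostrings::DNAStringSet(unlist(ref_seqs))
  names(reference) <- names(template)
  anc <- new("AncestorMap", bases = bases, conflicts = 0L)
  if (!is.null(mafPath))
    writeAncestorMaf(reference, anc, mafPath, referenceLabel,
                     ancestorLabel)
  list(reference = reference, anc = anc)
}

#' Serialize an ancestor map against its reference as a 2-row MAF
#'
#' @param genome DNAStringSet reference
#' @param anc \linkS4class{AncestorMap}
#' @param path MAF output path
#' @param referenceLabel,ancestorLabel row source labels
#' @export
writeAncestorMaf <- function(genome, anc, path, referenceLabel = "ref",
                             ancestorLabel = "anc") {
  maf_lines <- c("##maf version=1")
  for (chrom in names(anc@bases)) {
    refc <- genomeChars(genome, chrom)
    ancc <- anc@bases[[chrom]]
    n <- length(refc)
    maf_lines <- c(maf_lines, "", "a score=0.0",
      sprintf("s %s.%s 0 %d + %d %s", referenceLabel, chrom, n, n,
              paste(refc, collapse = "")),
      sprintf("s %s.%s 0 %d + %d %s", ancestorLabel, chrom,
              sum(ancc != "-"), n, paste(ancc, collapse = "")))
  }
  writeLines(maf_lines, path)
  invisible(path)
}

#' Write a population VCF with known AF-filter outcomes
#'
#' At every site where ancestor and reference differ, the ancestral allele
#' segregates as the ALT with a residual frequency; a configurable subset
#' of sites instead gets a high residual frequency so the derived-allele
#' AF filter has known true negatives.
#'
#' @param genome DNAStringSet reference
#' @param anc \linkS4class{AncestorMap}
#' @param path VCF output path
#' @param residualAF ancestral-allele frequency at passing sites (derived
#'   AF = 1 - residualAF)
#' @param failFraction fraction of sites given \code{failResidual} instead
#' @param failResidual ancestral-allele frequency at failing sites
#' @param seed integer seed (selects the failing sites)
#' @return list with path, n_sites, fail (data.frame chrom, pos)
#' @export
makePopulation <- function(genome, anc, path, residualAF = 0.05,
                           failFraction = 0, failResidual = 0.5,
                           seed = 1L) {
  recs <- list()
  for (chrom in names(anc@bases)) {
    refc <- genomeChars(genome, chrom)
    ancc <- anc@bases[[chrom]]
    idx <- which(ancc != "-" & refc %in% DNA_BASES & ancc != refc)
    if (length(idx) == 0L) next
    recs[[chrom]] <- data.frame(chrom = chrom, pos = idx, ref = refc[idx],
                                alt = ancc[idx], stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, recs)
  if (is.null(df)) stop("ancestor equals reference everywhere; no sites")
  nfail <- round(nrow(df) * failFraction)
  fail_idx <- with_seed(derive_seed(seed, "popfail"),
                        sort(sample(nrow(df), nfail)))
  df$af <- residualAF
  df$af[fail_idx] <- failResidual
  lines <- c("##fileformat=VCFv4.2",
             "##INFO=<ID=AF,Number=A,Type=Float,Description=\"Allele Frequency\">",
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO"), collapse = "\t"),
             sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\tAF=%g",
                     df$chrom, df$pos, df$ref, df$alt, df$af))
  writeLines(lines, path)
  list(path = path, n_sites = nrow(df),
       fail = df[fail_idx, c("chrom", "pos"), drop = FALSE])
}

STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Insert valid gene models into a reference
#'
#' Places non-overlapping single-transcript sense-strand genes with a
#' 5' UTR exon segment, a CDS split by one intron (canonical GT..AG ends),
#' and a 3' UTR segment; CDS starts with ATG, ends with a stop codon, has
#' no internal stop and a length divisible by 3. 500 bp flanks around each
#' gene are kept clear of other genes. The reference is edited in place
#' (returned) and a GFF3 written.
#'
#' @param genome DNAStringSet reference
#' @param nGenes number of genes
#' @param seed integer seed
#' @param gffPath GFF3 output path
#' @param minCodons,maxCodons CDS size range (codons, excluding the stop)
#' @return list with genome (edited DNAStringSet) and models
#'   (\linkS4class{GeneModels}); the GFF3 is written to \code{gffPath}
#' @export
makeGeneModels <- function(genome, nGenes, seed = 1L, gffPath,
                           minCodons = 30L, maxCodons = 80L) {
  chrom <- names(genome)[1]
  chars <- genomeChars(genome, chrom)
  len <- length(chars)
  utr5 <- 30L; utr3 <- 30L; intron_len <- 60L
  gap <- 1200L  # keeps 500 bp flanks clear between genes
  gff <- c("##gff-version 3")
  tx_rows <- list()
  cursor <- 600L
  codons_all <- apply(expand.grid(DNA_BASES, DNA_BASES, DNA_BASES), 1L,
                      paste, collapse = "")
  sense_codons <- setdiff(codons_all, STOP_CODONS)
  with_seed(derive_seed(seed, "genes"), {
    for (g in seq_len(nGenes)) {
      n_codons <- sample(minCodons:maxCodons, 1L)
      cds_len <- 3L * (n_codons + 1L)  # + stop codon
      cdsA <- 3L * sample(5L:(n_codons - 5L), 1L)  # split point, in-frame
      cdsB <- cds_len - cdsA
      gene_len <- utr5 + cdsA + intron_len + cdsB + utr3
      if (cursor + gene_len + gap > len)
        stop("genome too short for ", nGenes, " gene models")
      tx_start <- cursor
      cds_seq <- c(strsplit(paste(c("ATG",
        sample(sense_codons, n_codons - 1L, replace = TRUE)),
        collapse = ""), "")[[1]],
        strsplit(sample(STOP_CODONS, 1L), "")[[1]])
      e1_start <- tx_start
      e1_end <- tx_start + utr5 + cdsA - 1L
      i_start <- e1_end + 1L
      i_end <- i_start + intron_len - 1L
      e2_start <- i_end + 1L
      e2_end <- e2_start + cdsB + utr3 - 1L
      cds1 <- (tx_start + utr5):(e1_end)
      cds2 <- e2_start:(e2_start + cdsB - 1L)
      chars[c(cds1, cds2)] <- cds_seq
      # canonical splice dinucleotides
      chars[i_start:(i_start + 1L)] <- c("G", "T")
      chars[(i_end - 1L):i_end] <- c("A", "G")
      gid <- sprintf("gene%02d", g)
      tid <- sprintf("tx%02d", g)
      gff <- c(gff,
        sprintf("%s\tsynth\tgene\t%d\t%d\t.\t+\t.\tID=%s", chrom, tx_start,
                e2_end, gid),
        sprintf("%s\tsynth\tmRNA\t%d\t%d\t.\t+\t.\tID=%s;Parent=%s", chrom,
                tx_start, e2_end, tid, gid),
        sprintf("%s\tsynth\texon\t%d\t%d\t.\t+\t.\tID=%s.e1;Parent=%s",
                chrom, e1_start, e1_end, tid, tid),
        sprintf("%s\tsynth\texon\t%d\t%d\t.\t+\t.\tID=%s.e2;Parent=%s",
                chrom, e2_start, e2_end, tid, tid),
        sprintf("%s\tsynth\tCDS\t%d\t%d\t.\t+\t0\tID=%s.c1;Parent=%s",
                chrom, min(cds1), max(cds1), tid, tid),
        sprintf("%s\tsynth\tCDS\t%d\t%d\t.\t+\t%d\tID=%s.c2;Parent=%s",
                chrom, min(cds2), max(cds2), cdsA %% 3L, tid, tid))
      cursor <- e2_end + gap
    }
  })
  writeLines(gff, gffPath)
  seqs <- Biostrings::DNAStringSet(paste(chars, collapse = ""))
  names(seqs) <- chrom
  list(genome = seqs, models = readGeneModels(gffPath))
}

#' Plant a class-separating numeric track and uninformative intervals
#'
#' The conservation-like track takes value N(effectSize, noiseSd^2) at
#' simulated-class variant positions and N(0, noiseSd^2) everywhere else,
#' so a classifier trained on it has a closed-form Gaussian oracle AUC of
#' Phi(effectSize / (noiseSd * sqrt(2))). Interval tracks are placed
#' uniformly at random, independent of class.
#'
#' @param genome DNAStringSet reference
#' @param labeled \linkS4class{LabeledVariantSet} (the training classes)
#' @param effectSize planted mean shift at simulated positions
#' @param noiseSd Gaussian noise SD
#' @param seed integer seed
#' @return list(tracks = list(PhyloP = GRanges), intervals = list(TFBS =
#'   GRanges, CRM = GRanges))
#' @export
makeTracks <- function(genome, labeled, effectSize = 2, noiseSd = 1,
                       seed = 1L) {
  chrom <- names(genome)[1]
  n <- genomeLength(genome, chrom)
  vals <- with_seed(derive_seed(seed, "track"), {
    v <- rnorm(n, 0, noiseSd)
    sim_pos <- unique(variantPos(labeled)[variantLabel(labeled) == 0L &
                                            variantChrom(labeled) == chrom])
    v[sim_pos] <- rnorm(length(sim_pos), effectSize, noiseSd)
    v
  })
  cons <- GenomicRanges::GRanges(chrom, IRanges::IRanges(seq_len(n),
                                                         width = 1L),
                                 score = vals)
  ivs <- with_seed(derive_seed(seed, "intervals"), {
    lapply(c(TFBS = 40L, CRM = 25L), function(k) {
      st <- sort(sample(seq_len(n - 200L), k))
      GenomicRanges::GRanges(chrom, IRanges::IRanges(st, st + 149L))
    })
  })
  list(tracks = list(PhyloP = cons), intervals = ivs)
}

#' Feature spec used by the synthetic fixture
#'
#' Consequence one-hot (14 categories), the planted conservation-like
#' track, their combination columns, plus the uninformative interval
#' indicators.
#'
#' @return a \linkS4class{FeatureSpec} (29 + 2 = 31 columns)
#' @export
fixtureFeatureSpec <- function() {
  featureSpec(
    bases = list(
      list(name = "Consequence", type = "categorical",
           categories = c("UP", "DN", "U5", "U3", "S", "SN", "NS", "NC",
                          "IG", "I", "CS", "SL", "SG", "O"),
           default = "IG", other = "O", combo_label = "category"),
      list(name = "PhyloP", type = "numeric", default = 0),
      list(name = "TFBS", type = "indicator", default = 0),
      list(name = "CRM", type = "indicator", default = 0)),
    combos = list(list(categorical = "Consequence", numeric = "PhyloP")))
}

#' Default fixture configuration
#'
#' 100 kb genome, 20 genes, ancestral coverage 0.30 and divergence chosen
#' to yield about 2,000 derived variants; simulated variants are drawn
#' with 25% head-room and trimmed to match the derived count exactly.
#'
#' @param ... overrides
#' @return named list of fixture parameters
#' @export
fixtureConfig <- function(...) {
  cfg <- list(chromLength = 100000L, gc = 0.42, nGenes = 20L,
              coverage = 0.30, transition = 0.05, transversion = 0.0125,
              cpgFactor = 2, residualAF = 0.05, failFraction = 0.10,
              failResidual = 0.5, afThreshold = 0.9,
              effectSize = 2, noiseSd = 1, simHeadroom = 1.25)
  override <- list(...)
  cfg[names(override)] <- override
  cfg
}

#' Build the complete synthetic fixture bundle
#'
#' Generates reference FASTA, gene models (GFF3), ancestor (MAF),
#' population VCF, the planted annotation tracks, runs the training-set
#' pipeline on them and serializes everything plus a truth file to
#' \code{dir}. Regeneration with the same seed is byte-identical.
#'
#' @param dir output directory (created)
#' @param config from \code{\link{fixtureConfig}}
#' @param seed master integer seed
#' @return list with genome, models, anc, rates_true, rates_est, af,
#'   derived, simulated, labeled, tracks, intervals, spec, paths
#' @export
makeFullFixture <- function(dir, config = fixtureConfig(), seed = 1L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(fasta = file.path(dir, "reference.fa"),
                gff = file.path(dir, "genes.gff3"),
                maf = file.path(dir, "alignment.maf"),
                vcf = file.path(dir, "population.vcf"),
                track = file.path(dir, "phylop.tsv"),
                labeled = file.path(dir, "training_set.tsv"),
                rates = file.path(dir, "rates.tsv"),
                spec = file.path(dir, "feature_spec.yaml"),
                tfbs = file.path(dir, "TFBS.bed"),
                crm = file.path(dir, "CRM.bed"),
                truth = file.path(dir, "truth.json"))
  template <- makeReference(config$chromLength, config$gc,
                            seed = derive_seed(seed, "ref"))
  rates_true <- syntheticRateModel(names(template), config$transition,
                                   config$transversion, config$cpgFactor)
  pair <- makeAncestor(template, rates_true, config$coverage,
                       seed = derive_seed(seed, "anc"))
  gm <- makeGeneModels(pair$reference, config$nGenes,
                       seed = derive_seed(seed, "genes"),
                       gffPath = paths$gff)
  genome <- gm$genome
  anc <- pair$anc
  # gene insertion rewrites the reference after the divergence process;
  # mask the edited footprints out of the ancestor map so rate estimation
  # and variant calling only see the modeled divergence
  tx <- gm$models@transcripts
  for (i in seq_along(tx)) {
    ch <- as.character(GenomicRanges::seqnames(tx))[i]
    anc@bases[[ch]][GenomicRanges::start(tx)[i]:GenomicRanges::end(tx)[i]] <-
      "-"
  }
  Biostrings::writeXStringSet(genome, paths$fasta, width = 80L)
  writeAncestorMaf(genome, anc, paths$maf)
  pop <- makePopulation(genome, anc, paths$vcf,
                        residualAF = config$residualAF,
                        failFraction = config$failFraction,
                        failResidual = config$failResidual,
                        seed = derive_seed(seed, "pop"))
  af <- readPopulationAF(paths$vcf, sampleFilter = "PASS")
  derived <- callDerived(genome, anc, af, afThreshold = config$afThreshold)
  rates_est <- estimateRates(genome, anc)
  writeRateModel(rates_est, paths$rates)
  n_derived <- length(derived)
  # exclude every alt at derived positions so the two classes occupy
  # disjoint positions and the planted per-position track signal stays a
  # clean class separator (closed-form AUC oracle applies exactly)
  dch <- variantChrom(derived); dpos <- variantPos(derived)
  dref <- variantRef(derived)
  excl <- variantSet(rep(dch, each = 3L), rep(dpos, each = 3L),
                     rep(dref, each = 3L),
                     unlist(lapply(dref, function(b)
                       setdiff(DNA_BASES, b))))
  simulated <- simulateVariants(genome, anc, rates_est,
                                nTarget = round(config$simHeadroom *
                                                  n_derived),
                                seed = derive_seed(seed, "sim"),
                                exclusions = excl)
  trimmed <- trimToMatch(simulated, n_derived,
                         seed = derive_seed(seed, "trim"))
  labeled <- buildLabeledSet(derived, trimmed)
  writeVariants(labeled, paths$labeled)
  tr <- makeTracks(genome, labeled, config$effectSize, config$noiseSd,
                   seed = derive_seed(seed, "tracks"))
  tk <- tr$tracks$PhyloP
  write.table(data.frame(chrom = as.character(GenomicRanges::seqnames(tk)),
                         pos = GenomicRanges::start(tk),
                         value = sprintf("%.6f", tk$score)),
              paths$track, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  rtracklayer::export(tr$intervals$TFBS, paths$tfbs, format = "bed")
  rtracklayer::export(tr$intervals$CRM, paths$crm, format = "bed")
  writeFeatureSpec(fixtureFeatureSpec(), paths$spec)
  truth <- list(seed = seed, config = config, n_derived = n_derived,
                n_sites = pop$n_sites,
                n_fail_sites = nrow(pop$fail),
                oracle_auc = pnorm(config$effectSize /
                                     (config$noiseSd * sqrt(2))))
  jsonlite::write_json(truth, paths$truth, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  list(genome = genome, models = gm$models, anc = anc,
       rates_true = rates_true, rates_est = rates_est, af = af,
       derived = derived, simulated = trimmed, labeled = labeled,
       tracks = tr$tracks, intervals = tr$intervals,
       spec = fixtureFeatureSpec(), truth = truth, paths = paths)
}
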