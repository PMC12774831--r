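#' Read a reference genome from FASTA
#'
#' Wraps \code{Biostrings::readDNAStringSet} with the package's contract:
#' record names are unique, sequences are folded to upper case, and only
#' IUPAC nucleotide characters are accepted. All downstream coordinates are
#' 1-based and inclusive.
#'
#' @param path FASTA file
#' @return a \code{DNAStringSet}, names = chromosome identifiers (first word
#'   of each header)
#' @export
readGenome <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  seqs <- tryCatch(Biostrings::readDNAStringSet(path),
                   error = function(e) stop("FASTA format error: ",
                                            conditionMessage(e), call. = FALSE))
  if (length(seqs) == 0L) stop("no records in FASTA file ", path)
  names(seqs) <- vapply(strsplit(names(seqs), "\\s+"), `[`, character(1), 1L)
  if (anyDuplicated(names(seqs)))
    stop("duplicate chromosome name in ", path, ": ",
         paste(unique(names(seqs)[duplicated(names(seqs))]), collapse = ", "))
  Biostrings::DNAStringSet(toupper(seqs))
}

#' Base and length lookups on a genome
#'
#' @param genome a DNAStringSet from \code{\link{readGenome}}
#' @param chrom chromosome name
#' @param pos 1-based position(s); rejected outside [1, length]
#' @return character vector of upper-case bases
#' @export
genomeBase <- function(genome, chrom, pos) {
  if (!chrom %in% names(genome)) stop("unknown chromosome: ", chrom)
  len <- length(genome[[chrom]])
  if (any(pos < 1L | pos > len))
    stop("position outside [1, ", len, "] on ", chrom)
  as.character(Biostrings::extractAt(
    genome[[chrom]], IRanges::IRanges(pos, width = 1L)))
}

#' @rdname genomeBase
#' @export
genomeLength <- function(genome, chrom) {
  if (!chrom %in% names(genome)) stop("unknown chromosome: ", chrom)
  length(genome[[chrom]])
}

#' Chromosome sequence as a character vector of single bases
#' @inheritParams genomeBase
#' @export
genomeChars <- function(genome, chrom) {
  if (!chrom %in% names(genome)) stop("unknown chromosome: ", chrom)
  strsplit(as.character(genome[[chrom]]), "")[[1]]
}

#' Read a MAF multiple-alignment file into blocks
#'
#' Parses the "a"/"s" line grammar. Starts in the returned rows are kept in
#' native MAF convention (0-based, strand-relative); conversion to 1-based
#' sense-strand reference coordinates is done by
#' \code{\link{extractAncestor}}, nowhere else.
#'
#' @param path MAF file
#' @return list of blocks; each block is a data.frame with columns
#'   src, start, size, strand, srcSize, text
#' @export
readAlignmentBlocks <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  blocks <- list()
  cur <- NULL
  cur_line <- NA_integer_
  flush <- function(cur, at) {
    if (is.null(cur) || nrow(cur) == 0L)
      stop("truncated alignment block at line ", at)
    if (length(unique(nchar(cur$text))) != 1L)
      stop("rows of unequal gapped length in block at line ", at)
    cur
  }
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (ln == "" || startsWith(ln, "#")) next
    f <- strsplit(ln, "\\s+")[[1]]
    if (f[1] == "a") {
      if (!is.null(cur)) blocks[[length(blocks) + 1L]] <- flush(cur, cur_line)
      cur <- data.frame(src = character(), start = integer(), size = integer(),
                        strand = character(), srcSize = integer(),
                        text = character(), stringsAsFactors = FALSE)
      cur_line <- i
    } else if (f[1] == "s") {
      if (is.null(cur)) stop("'s' line outside a block at line ", i)
      if (length(f) < 7L) stop("malformed 's' line at line ", i)
      cur <- rbind(cur, data.frame(
        src = f[2], start = as.integer(f[3]), size = as.integer(f[4]),
        strand = f[5], srcSize = as.integer(f[6]), text = toupper(f[7]),
        stringsAsFactors = FALSE))
    }
    # other MAF line types (i/e/q) carry no sequence and are skipped
  }
  if (!is.null(cur)) blocks[[length(blocks) + 1L]] <- flush(cur, cur_line)
  blocks
}

# ---- population allele frequencies ------------------------------------------

#' PopulationAF: alt-allele frequencies at segregating sites
#'
#' @slot records data.frame with columns chrom, pos, alt, af
#' @export
setClass("PopulationAF", representation(records = "data.frame"))

setValidity("PopulationAF", function(object) {
  need <- c("chrom", "pos", "alt", "af")
  if (!all(need %in% colnames(object@records)))
    return(paste("records need columns:", paste(need, collapse = ", ")))
  if (nrow(object@records) > 0L &&
      any(object@records$af < 0 | object@records$af > 1))
    return("allele frequencies must lie in [0,1]")
  TRUE
})

setMethod("show", "PopulationAF", function(object) {
  cat("PopulationAF with", nrow(object@records), "site/alt records\n")
})

#' Read population allele frequencies from VCF
#'
#' AF comes from the INFO AF field when present, otherwise from genotype
#' allele counts; a site with neither is an error. With
#' \code{sampleFilter = "PASS"}, sites whose FILTER is anything else are
#' excluded. Multiple VCFs are pooled by unweighted averaging of the
#' per-file frequencies at shared (chrom,pos,alt) records
#' (\code{pooling = "mean"}) or restricted to records present in every file
#' (\code{pooling = "intersect"}).
#'
#' @param paths one or more VCF files
#' @param sampleFilter optional FILTER label to require (e.g. "PASS")
#' @param pooling "mean" or "intersect" for multiple files
#' @return a \linkS4class{PopulationAF}
#' @export
readPopulationAF <- function(paths, sampleFilter = NULL, pooling = c("mean", "intersect")) {
  pooling <- match.arg(pooling)
  tabs <- lapply(paths, read_af_one, sampleFilter = sampleFilter)
  if (length(tabs) == 1L) {
    rec <- tabs[[1]]
  } else {
    all <- do.call(rbind, tabs)
    key <- paste(all$chrom, all$pos, all$alt, sep = "\r")
    agg <- aggregate(all$af, by = list(key = key), FUN = mean)
    cnt <- table(key)
    if (pooling == "intersect")
      agg <- agg[cnt[agg$key] == length(tabs), , drop = FALSE]
    parts <- strsplit(agg$key, "\r", fixed = TRUE)
    rec <- data.frame(chrom = vapply(parts, `[`, "", 1L),
                      pos = as.integer(vapply(parts, `[`, "", 2L)),
                      alt = vapply(parts, `[`, "", 3L),
                      af = agg$x, stringsAsFactors = FALSE)
  }
  rec <- rec[order(rec$chrom, rec$pos, rec$alt), , drop = FALSE]
  rownames(rec) <- NULL
  new("PopulationAF", records = rec)
}

read_af_one <- function(path, sampleFilter = NULL) {
  vcf <- VariantAnnotation::readVcf(path, genome = "custom")
  rr <- SummarizedExperiment::rowRanges(vcf)
  keep <- rep(TRUE, length(rr))
  if (!is.null(sampleFilter)) keep <- rr$FILTER == sampleFilter
  info <- VariantAnnotation::info(vcf)
  has_af <- "AF" %in% colnames(info)
  gt <- tryCatch(VariantAnnotation::geno(vcf)$GT, error = function(e) NULL)
  out <- vector("list", length(rr))
  alt_list <- VariantAnnotation::alt(vcf)
  for (i in which(keep)) {
    alts <- as.character(alt_list[[i]])
    alts <- alts[alts %in% DNA_BASES]
    if (length(alts) == 0L) next
    afs <- NULL
    if (has_af) {
      v <- info$AF[[i]]
      if (length(v) >= length(alts) && !all(is.na(v))) afs <- as.numeric(v[seq_along(alts)])
    }
    if (is.null(afs)) {
      if (is.null(gt) || ncol(gt) == 0L)
        stop(sprintf("site %s:%d has neither INFO AF nor genotypes",
                     as.character(GenomicRanges::seqnames(rr))[i],
                     GenomicRanges::start(rr)[i]))
      alleles <- unlist(strsplit(gt[i, ], "[/|]"))
      alleles <- suppressWarnings(as.integer(alleles[alleles != "."]))
      alleles <- alleles[!is.na(alleles)]
      if (length(alleles) == 0L)
        stop(sprintf("site %s:%d has no called genotypes",
                     as.character(GenomicRanges::seqnames(rr))[i],
                     GenomicRanges::start(rr)[i]))
      afs <- vapply(seq_along(alts), function(k) mean(alleles == k), numeric(1))
    }
    out[[i]] <- data.frame(
      chrom = as.character(GenomicRanges::seqnames(rr))[i],
      pos = GenomicRanges::start(rr)[i], alt = alts, af = afs,
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(chrom = character(), pos = integer(), alt = character(),
                      af = numeric(), stringsAsFactors = FALSE)
  res
}

#' Alt-allele frequency records at a site
#'
#' @param af a \linkS4class{PopulationAF}
#' @param chrom,pos site (1-based)
#' @return data.frame of (alt, af) records; zero rows = "no record"
#' @export
afLookup <- function(af, chrom, pos) {
  r <- af@records
  r[r$chrom == chrom & r$pos == pos, c("alt", "af"), drop = FALSE]
}

# ---- score tables -----------------------------------------------------------

#' Write an impact-score table as TSV
#'
#' Columns chrom, pos (1-based), ref, alt, score; rows sorted by
#' (chrom, pos, alt) so reruns are byte-identical; scores printed with six
#' decimals. Scores outside [0,1] are refused.
#'
#' @param records data.frame with columns chrom, pos, ref, alt, score
#' @param path output file
#' @export
writeScores <- function(records, path) {
  need <- c("chrom", "pos", "ref", "alt", "score")
  if (!all(need %in% colnames(records)))
    stop("score records need columns: ", paste(need, collapse = ", "))
  if (nrow(records) > 0 && (any(records$score < 0) || any(records$score > 1)))
    stop("refusing to write scores outside [0,1]")
  ord <- order(records$chrom, records$pos, records$alt)
  rec <- records[ord, need, drop = FALSE]
  rec$score <- sprintf("%.6f", rec$score)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(need, collapse = "\t"), con)
  if (nrow(rec) > 0)
    writeLines(do.call(paste, c(rec, sep = "\t")), con)
  invisible(path)
}

#' @rdname writeScores
#' @export
readScores <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t",
                   colClasses = c("character", "integer", "character",
                                  "character", "numeric"))
  df
}

# ---- mutation-rate model serialization --------------------------------------

#' Serialize / deserialize a MutationRateModel as TSV
#'
#' Columns chrom, context, from, to, count, denom, rate. Undefined rates
#' (zero denominator) are written as NA.
#'
#' @param model a \linkS4class{MutationRateModel}
#' @param path TSV file
#' @export
writeRateModel <- function(model, path) {
  tab <- rateTable(model)
  tab <- tab[order(tab$chrom, tab$context, tab$from, tab$to), , drop = FALSE]
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeRateModel
#' @export
readRateModel <- function(path) {
  tab <- read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
  new("MutationRateModel", table = tab)
}

# ---- trained-model artifact -------------------------------------------------

#' Persist a TrainedModel as a JSON text artifact
#'
#' The artifact carries weights, intercept, L2, feature names, the training
#' scaling SDs and the feature-spec checksum, so scoring can refuse a
#' mismatched feature layout.
#'
#' @param model a \linkS4class{TrainedModel}
#' @param path output JSON file
#' @export
writeModel <- function(model, path) {
  obj <- list(
    featureNames = names(model@weights),
    weights = unname(model@weights),
    intercept = model@intercept,
    l2 = model@l2,
    scaling = list(sds = as.list(model@scaling@sds),
                   dropped = model@scaling@dropped),
    specChecksum = model@specChecksum,
    meta = model@meta)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname writeModel
#' @export
readModel <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  sds <- unlist(obj$scaling$sds)
  cs <- obj$specChecksum
  if (is.null(cs) || length(cs) == 0L) cs <- NA_character_
  new("TrainedModel",
      weights = setNames(as.numeric(obj$weights), obj$featureNames),
      intercept = as.numeric(obj$intercept),
      l2 = as.numeric(obj$l2),
      scaling = new("ScalingParams", sds = sds,
                    dropped = as.character(obj$scaling$dropped %||% character())),
      specChecksum = as.character(cs),
      meta = as.list(obj$meta))
}

# ---- tracks and intervals ---------------------------------------------------

#' Read a per-base numeric track
#'
#' Accepts bedGraph, fixed/variable-step wiggle (both via rtracklayer, which
#' converts 0-based half-open starts to the package's 1-based inclusive
#' convention) and a 3-column TSV dialect (chrom, pos, value; already
#' 1-based). Missing positions are reported as NA by
#' \code{\link{trackValueAt}}, never as 0.
#'
#' @param path track file; format inferred from extension
#'   (.bedgraph/.bg, .wig, otherwise TSV)
#' @return GRanges with a numeric \code{score} column
#' @export
readNumericTrack <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("bedgraph", "bg")) {
    gr <- rtracklayer::import(path, format = "bedGraph")
  } else if (ext == "wig") {
    gr <- rtracklayer::import(path, format = "wig")
  } else {
    df <- read.table(path, header = FALSE, sep = "\t",
                     col.names = c("chrom", "pos", "value"),
                     stringsAsFactors = FALSE)
    gr <- GenomicRanges::GRanges(df$chrom, IRanges::IRanges(df$pos, width = 1L),
                                 score = df$value)
  }
  if (!all(is.finite(gr$score))) stop("non-finite values in track ", path)
  gr
}

#' Read an interval annotation track (BED or GFF3)
#'
#' rtracklayer handles the BED 0-based half-open to 1-based inclusive
#' conversion; the returned ranges follow the package convention.
#'
#' @param path BED or GFF3 file
#' @return GRanges (1-based, both ends inclusive)
#' @export
readIntervalTrack <- function(path) {
  ext <- tolower(tools::file_ext(path))
  fmt <- if (ext %in% c("gff", "gff3")) "gff3" else "bed"
  rtracklayer::import(path, format = fmt)
}

#' Look up per-base track values at positions
#'
#' @param track GRanges with a score column
#' @param chrom chromosome
#' @param pos 1-based positions
#' @return numeric vector; NA where the track has no value
#' @export
trackValueAt <- function(track, chrom, pos) {
  q <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, width = 1L))
  hits <- GenomicRanges::findOverlaps(q, track, select = "first")
  ifelse(is.na(hits), NA_real_, track$score[hits])
}

#' Count interval records covering positions
#' @param track GRanges
#' @inheritParams trackValueAt
#' @return integer vector of overlap counts
#' @export
intervalCountAt <- function(track, chrom, pos) {
  q <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, width = 1L))
  GenomicRanges::countOverlaps(q, track)
}

# ---- gene models ------------------------------------------------------------

#' Read minimal transcript models from GFF3
#'
#' Recognizes transcript-level features (mRNA, transcript, ncRNA and
#' friends) with exon and CDS children keyed by Parent. CDS phase/order
#' follows coordinate order, strand-aware.
#'
#' @param path GFF3 file
#' @return a \linkS4class{GeneModels}
#' @export
readGeneModels <- function(path) {
  gff <- rtracklayer::import(path, format = "gff3")
  txtypes <- c("mRNA", "transcript", "ncRNA", "lnc_RNA", "tRNA", "rRNA",
               "snRNA", "snoRNA", "miRNA", "pre_miRNA")
  tx <- gff[as.character(gff$type) %in% txtypes]
  if (length(tx) == 0L) stop("no transcript features in ", path)
  tx_id <- as.character(tx$ID)
  gene_id <- vapply(as.list(tx$Parent), function(p)
    if (length(p)) as.character(p[[1]]) else NA_character_, character(1))
  transcripts <- GenomicRanges::granges(tx)
  S4Vectors::mcols(transcripts)$tx_id <- tx_id
  S4Vectors::mcols(transcripts)$gene_id <- gene_id
  pick_children <- function(type) {
    ch <- gff[as.character(gff$type) == type]
    if (length(ch) == 0L)
      return(setNames(GenomicRanges::GRangesList(lapply(tx_id, function(i)
        GenomicRanges::GRanges())), tx_id))
    parent <- vapply(as.list(ch$Parent), function(p)
      if (length(p)) as.character(p[[1]]) else NA_character_, character(1))
    out <- lapply(tx_id, function(i) {
      g <- GenomicRanges::granges(ch[!is.na(parent) & parent == i])
      sort(g)
    })
    setNames(GenomicRanges::GRangesList(out), tx_id)
  }
  exons <- pick_children("exon")
  cds <- pick_children("CDS")
  # transcripts without explicit exon rows: use CDS, else the tx extent
  for (i in seq_along(tx_id)) {
    if (length(exons[[i]]) == 0L) {
      exons[[i]] <- if (length(cds[[i]]) > 0L) cds[[i]]
                    else GenomicRanges::granges(transcripts[i])
    }
  }
  new("GeneModels", transcripts = transcripts, exons = exons, cds = cds)
}

# ---- variant tables ---------------------------------------------------------

#' Read/write variant tables (TSV with chrom, pos, ref, alt [, label])
#'
#' \code{readVariants} also accepts a VCF (sniffed from the header), taking
#' one record per (site, alt).
#'
#' @param path file
#' @export
readVariants <- function(path) {
  first <- readLines(path, n = 1L)
  if (startsWith(first, "##fileformat=VCF")) {
    vcf <- VariantAnnotation::readVcf(path, genome = "custom")
    rr <- SummarizedExperiment::rowRanges(vcf)
    alt_list <- VariantAnnotation::alt(vcf)
    recs <- lapply(seq_along(rr), function(i) {
      alts <- as.character(alt_list[[i]])
      alts <- alts[alts %in% DNA_BASES]
      if (length(alts) == 0L) return(NULL)
      data.frame(chrom = as.character(GenomicRanges::seqnames(rr))[i],
                 pos = GenomicRanges::start(rr)[i],
                 ref = as.character(VariantAnnotation::ref(vcf)[i]),
                 alt = alts, stringsAsFactors = FALSE)
    })
    df <- do.call(rbind, recs)
  } else {
    df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  }
  if ("label" %in% colnames(df))
    labeledVariantSet(df$chrom, df$pos, df$ref, df$alt, df$label)
  else
    variantSet(df$chrom, df$pos, df$ref, df$alt)
}

#' @rdname readVariants
#' @param x a VariantSet (or LabeledVariantSet)
#' @export
writeVariants <- function(x, path) {
  df <- as.data.frame(x)
  df <- df[order(df$chrom, df$pos, df$alt), , drop = FALSE]
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
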