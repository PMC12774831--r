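# Consequence categories, most severe first. The order is fixed for
# reproducibility; multi-transcript variants take the most severe call.
CONSEQUENCE_PRIORITY <- c("CS", "SG", "SL", "NS", "SN", "S", "U5", "U3",
                          "NC", "I", "UP", "DN", "IG", "O")

GENE_FLANK <- 500L          # upstream/downstream window, bp
SPLICE_CANONICAL <- 2L      # first/last bases of an intron
SPLICE_REGION_EXON <- 3L    # exonic splice-region width
SPLICE_REGION_INTRON <- 8L  # intronic splice-region width

.pkg_cache <- new.env(parent = emptyenv())

#' Grantham amino-acid distance
#'
#' Symmetric lookup in the published Grantham (1974) matrix, shipped as
#' plain-text package data. Identical residues score 0; the maximal entry is
#' Cys-Trp at 215. Stop symbols are "not applicable" (NA).
#'
#' @param oAA,nAA one-letter amino acid codes (vectors recycle)
#' @return numeric vector of distances; NA where either side is a stop
#' @export
granthamDistance <- function(oAA, nAA) {
  m <- granthamMatrix()
  n <- max(length(oAA), length(nAA))
  oAA <- rep_len(oAA, n); nAA <- rep_len(nAA, n)
  out <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (is.na(oAA[i]) || is.na(nAA[i]) || oAA[i] == "*" || nAA[i] == "*")
      next
    if (!oAA[i] %in% rownames(m) || !nAA[i] %in% rownames(m))
      stop("not a standard amino acid: ", oAA[i], "/", nAA[i])
    out[i] <- m[oAA[i], nAA[i]]
  }
  out
}

#' @rdname granthamDistance
#' @export
granthamMatrix <- function() {
  if (is.null(.pkg_cache$grantham)) {
    path <- system.file("extdata", "grantham.tsv", package = "snvimpact",
                        mustWork = TRUE)
    df <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE)
    m <- as.matrix(df[, -1])
    rownames(m) <- df$aa
    storage.mode(m) <- "numeric"
    .pkg_cache$grantham <- m
  }
  .pkg_cache$grantham
}

# ---- transcript cache -------------------------------------------------------

# Precompute, per transcript, everything the classifier needs: sorted exons,
# introns, CDS, the spliced coding-strand CDS characters and a genomic->CDS
# offset map.
tx_cache <- function(genes, genome) {
  lapply(seq_along(genes@transcripts), function(i) {
    tx <- genes@transcripts[i]
    id <- S4Vectors::mcols(tx)$tx_id
    strand <- as.character(GenomicRanges::strand(tx))
    if (!strand %in% c("+", "-")) strand <- "+"
    chrom <- as.character(GenomicRanges::seqnames(tx))
    ex <- sort(genes@exons[[id]])
    cds <- sort(genes@cds[[id]])
    introns <- NULL
    if (length(ex) > 1L) {
      st <- GenomicRanges::end(ex)[-length(ex)] + 1L
      en <- GenomicRanges::start(ex)[-1L] - 1L
      keep <- en >= st
      introns <- data.frame(start = st[keep], end = en[keep])
    }
    cds_chars <- NULL; cds_len <- 0L; valid_cds <- FALSE
    if (length(cds) > 0L) {
      seqs <- lapply(seq_along(cds), function(k)
        genomeChars(genome, chrom)[
          GenomicRanges::start(cds)[k]:GenomicRanges::end(cds)[k]])
      chars <- unlist(seqs)
      if (strand == "-") chars <- revcomp_chars(chars)
      cds_len <- length(chars)
      valid_cds <- cds_len %% 3L == 0L && cds_len >= 3L
      cds_chars <- chars
    }
    list(id = id, gene_id = S4Vectors::mcols(tx)$gene_id, chrom = chrom,
         strand = strand,
         start = GenomicRanges::start(tx), end = GenomicRanges::end(tx),
         exons = data.frame(start = GenomicRanges::start(ex),
                            end = GenomicRanges::end(ex)),
         cds = data.frame(start = GenomicRanges::start(cds),
                          end = GenomicRanges::end(cds)),
         introns = introns, cds_chars = cds_chars, cds_len = cds_len,
         valid_cds = valid_cds, coding = length(cds) > 0L)
  })
}

# genomic position -> 1-based offset within the spliced CDS on the coding
# strand; NA if the position is not in the CDS
cds_offset <- function(txi, pos) {
  cds <- txi$cds
  if (nrow(cds) == 0L) return(NA_integer_)
  widths <- cds$end - cds$start + 1L
  hit <- which(pos >= cds$start & pos <= cds$end)
  if (length(hit) == 0L) return(NA_integer_)
  before <- if (hit > 1L) sum(widths[seq_len(hit - 1L)]) else 0L
  off_plus <- before + (pos - cds$start[hit] + 1L)
  if (txi$strand == "+") off_plus else txi$cds_len - off_plus + 1L
}

# genomic position -> offset in the spliced exonic (cDNA) sequence
cdna_offset <- function(txi, pos) {
  ex <- txi$exons
  widths <- ex$end - ex$start + 1L
  hit <- which(pos >= ex$start & pos <= ex$end)
  if (length(hit) == 0L) return(NA_integer_)
  before <- if (hit > 1L) sum(widths[seq_len(hit - 1L)]) else 0L
  off_plus <- before + (pos - ex$start[hit] + 1L)
  if (txi$strand == "+") off_plus else sum(widths) - off_plus + 1L
}

empty_consequence <- function() {
  list(consequence = "IG", oAA = NA_character_, nAA = NA_character_,
       CDSpos = NA_integer_, protPos = NA_integer_,
       relCDSpos = NA_real_, relProtPos = NA_real_,
       cDNApos = NA_integer_, relcDNApos = NA_real_)
}

# classify one variant against one cached transcript
classify_one_tx <- function(txi, pos, ref, alt) {
  rec <- empty_consequence()
  in_tx <- pos >= txi$start && pos <= txi$end
  if (!in_tx) {
    upstream5 <- (txi$strand == "+" && pos < txi$start) ||
                 (txi$strand == "-" && pos > txi$end)
    dist <- if (pos < txi$start) txi$start - pos else pos - txi$end
    if (dist <= GENE_FLANK) rec$consequence <- if (upstream5) "UP" else "DN"
    return(rec)
  }
  # intron?
  if (!is.null(txi$introns) && nrow(txi$introns) > 0L) {
    itr <- txi$introns
    h <- which(pos >= itr$start & pos <= itr$end)
    if (length(h) == 1L) {
      d <- min(pos - itr$start[h], itr$end[h] - pos) + 1L  # 1 = first base
      rec$consequence <- if (d <= SPLICE_CANONICAL) "CS"
                         else if (d <= SPLICE_REGION_INTRON) "S" else "I"
      return(rec)
    }
  }
  # exonic
  co <- cdna_offset(txi, pos)
  rec$cDNApos <- co
  total <- sum(txi$exons$end - txi$exons$start + 1L)
  rec$relcDNApos <- if (!is.na(co)) co / total else NA_real_
  off <- if (txi$valid_cds) cds_offset(txi, pos) else NA_integer_
  if (!is.na(off)) {
    codon_idx <- (off - 1L) %/% 3L + 1L
    within <- (off - 1L) %% 3L + 1L
    codon <- txi$cds_chars[((codon_idx - 1L) * 3L + 1L):(codon_idx * 3L)]
    base_ref <- if (txi$strand == "+") ref else unname(COMPLEMENT[ref])
    base_alt <- if (txi$strand == "+") alt else unname(COMPLEMENT[alt])
    if (codon[within] != base_ref)
      stop(sprintf("reference mismatch at %s:%d (codon has %s, variant ref %s)",
                   txi$chrom, pos, codon[within], ref))
    alt_codon <- codon
    alt_codon[within] <- base_alt
    code <- Biostrings::GENETIC_CODE
    oAA <- unname(code[paste(codon, collapse = "")])
    nAA <- unname(code[paste(alt_codon, collapse = "")])
    rec$oAA <- oAA; rec$nAA <- nAA
    rec$CDSpos <- off; rec$protPos <- codon_idx
    rec$relCDSpos <- off / txi$cds_len
    rec$relProtPos <- codon_idx / (txi$cds_len %/% 3L)
    rec$consequence <-
      if (oAA != "*" && nAA == "*") "SG"
      else if (oAA == "*" && nAA != "*") "SL"
      else if (oAA == nAA) "SN" else "NS"
    return(rec)
  }
  # exonic, non-coding position: splice region, UTR, or non-coding exon
  edge <- c(txi$exons$start, txi$exons$end)
  edge <- edge[edge != txi$start & edge != txi$end]  # only internal edges
  if (length(edge) > 0L && min(abs(pos - edge)) < SPLICE_REGION_EXON) {
    rec$consequence <- "S"
    return(rec)
  }
  if (txi$coding && txi$valid_cds) {
    cds_lo <- min(txi$cds$start); cds_hi <- max(txi$cds$end)
    before5 <- (txi$strand == "+" && pos < cds_lo) ||
               (txi$strand == "-" && pos > cds_hi)
    rec$consequence <- if (before5) "U5" else "U3"
  } else if (!txi$coding) {
    rec$consequence <- "NC"
  } else {
    rec$consequence <- "O"  # coding transcript with an invalid CDS
  }
  rec
}

#' Classify the molecular consequence of variants
#'
#' Assigns one of the 14 categories UP, DN, U5, U3, S, SN, NS, NC, IG, I,
#' CS, SL, SG, O per variant, using the fixed severity order
#' CS > SG > SL > NS > SN > S > U5 > U3 > NC > I > UP > DN > IG; with
#' multiple overlapping transcripts the most severe call wins. Coding calls
#' carry the original/new amino acid from the standard genetic code, CDS
#' and protein positions and their relative forms. Upstream/downstream are
#' assigned within a 500 bp flank. Transcripts whose CDS length is not a
#' multiple of 3 are skipped with a warning.
#'
#' @param variants a \linkS4class{VariantSet}
#' @param genes a \linkS4class{GeneModels} (or NULL: everything intergenic)
#' @param genome DNAStringSet reference
#' @return data.frame with columns consequence, oAA, nAA, CDSpos, protPos,
#'   relCDSpos, relProtPos, cDNApos, relcDNApos
#' @export
classifyConsequence <- function(variants, genes, genome) {
  n <- length(variants)
  chrom <- variantChrom(variants); pos <- variantPos(variants)
  ref <- variantRef(variants); alt <- variantAlt(variants)
  gb <- character(n)
  for (ch in unique(chrom)) {
    i <- which(chrom == ch)
    gb[i] <- genomeBase(genome, ch, pos[i])
  }
  bad <- which(gb != ref)
  if (length(bad) > 0L)
    stop(sprintf("variant ref mismatch vs genome at %s:%d (%s vs %s)",
                 chrom[bad[1]], pos[bad[1]], ref[bad[1]], gb[bad[1]]))
  txs <- if (is.null(genes)) list() else tx_cache(genes, genome)
  invalid <- vapply(txs, function(t) t$coding && !t$valid_cds, logical(1))
  if (any(invalid))
    warning(sum(invalid), " transcript(s) with CDS length not divisible by",
            " 3 skipped for coding calls", call. = FALSE)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    recs <- list(empty_consequence())
    for (txi in txs) {
      if (txi$chrom != chrom[i]) next
      if (pos[i] < txi$start - GENE_FLANK || pos[i] > txi$end + GENE_FLANK)
        next
      recs[[length(recs) + 1L]] <- classify_one_tx(txi, pos[i], ref[i], alt[i])
    }
    sev <- vapply(recs, function(r)
      match(r$consequence, CONSEQUENCE_PRIORITY), integer(1))
    out[[i]] <- recs[[which.min(sev)]]
  }
  df <- do.call(rbind, lapply(out, function(r)
    data.frame(consequence = r$consequence, oAA = r$oAA, nAA = r$nAA,
               CDSpos = r$CDSpos, protPos = r$protPos,
               relCDSpos = r$relCDSpos, relProtPos = r$relProtPos,
               cDNApos = r$cDNApos, relcDNApos = r$relcDNApos,
               stringsAsFactors = FALSE)))
  rownames(df) <- NULL
  df
}

#' Regulatory-record density at variant positions
#'
#' Number of interval records (e.g. ReMap regulatory elements) covering
#' each variant position; nested and overlapping records each count once.
#'
#' @param variants a \linkS4class{VariantSet}
#' @param records GRanges of records
#' @return integer vector of counts
#' @export
remapDensity <- function(variants, records) {
  if (is.null(records)) return(rep(NA_integer_, length(variants)))
  intervalCountAt(records, variantChrom(variants), variantPos(variants))
}

# distance from positions to the nearest interval in gr: 0 inside, else
# base-pair offset from the closest interval end (adjacent position = 1)
dist_to_nearest <- function(chrom, pos, gr) {
  if (is.null(gr) || length(gr) == 0L) return(rep(NA_real_, length(pos)))
  q <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, width = 1L))
  out <- rep(NA_real_, length(pos))
  ni <- suppressWarnings(GenomicRanges::nearest(q, gr))
  ok <- !is.na(ni)
  s <- GenomicRanges::start(gr)[ni[ok]]
  e <- GenomicRanges::end(gr)[ni[ok]]
  p <- pos[ok]
  out[ok] <- ifelse(p >= s & p <= e, 0, pmin(abs(p - s), abs(p - e)))
  out
}

#' Annotate variants with every base annotation
#'
#' Produces one column per base annotation: the consequence record,
#' Grantham distance (non-synonymous calls only), GC fraction in a 75 bp
#' window, CpG-context indicator, distances to transcription start/end,
#' splice sites and coding sequence, per-base numeric track values,
#' interval memberships, categorical interval labels and regulatory-record
#' density. Values the supplied inputs cannot provide are NA ("missing")
#' and are imputed later by \code{\link{expandFeatures}} using the feature
#' spec defaults.
#'
#' @param variants a \linkS4class{VariantSet}
#' @param genome DNAStringSet reference
#' @param genes optional \linkS4class{GeneModels}
#' @param tracks named list of per-base numeric tracks (GRanges with score)
#' @param intervals named list of interval tracks; elements with a
#'   \code{name} metadata column become categorical label columns, others
#'   0/1 membership indicators
#' @param remap optional GRanges whose per-position record count becomes
#'   the ReMapDensity column
#' @param spec optional \linkS4class{FeatureSpec}; when given, every
#'   declared base must be a computed annotation or a supplied track name,
#'   otherwise an error is raised before any work
#' @return data.frame of base annotations, one row per variant
#' @export
annotateVariants <- function(variants, genome, genes = NULL,
                             tracks = list(), intervals = list(),
                             remap = NULL, spec = NULL) {
  computed <- c("Consequence", "oAA", "nAA", "Grantham", "CDSpos",
                "relCDSpos", "protPos", "relProtPos", "cDNApos",
                "relcDNApos", "minDistTSS", "minDistTSE", "spliceDist",
                "cdsDist", "GC", "CpG", "inCDS", "ReMapDensity")
  if (!is.null(spec)) {
    declared <- vapply(spec@bases, function(b) b$name, character(1))
    known <- c(computed, names(tracks), names(intervals))
    missing <- setdiff(declared, known)
    if (length(missing) > 0L)
      stop("feature spec references undeclared track(s): ",
           paste(missing, collapse = ", "))
  }
  n <- length(variants)
  chrom <- variantChrom(variants); pos <- variantPos(variants)
  cons <- classifyConsequence(variants, genes, genome)
  df <- data.frame(Consequence = cons$consequence, oAA = cons$oAA,
                   nAA = cons$nAA, stringsAsFactors = FALSE)
  df$Grantham <- ifelse(cons$consequence == "NS",
                        granthamDistance(cons$oAA, cons$nAA), NA_real_)
  df$CDSpos <- cons$CDSpos; df$relCDSpos <- cons$relCDSpos
  df$protPos <- cons$protPos; df$relProtPos <- cons$relProtPos
  df$cDNApos <- cons$cDNApos; df$relcDNApos <- cons$relcDNApos
  # sequence context
  gc <- numeric(n); cpg <- numeric(n)
  for (ch in unique(chrom)) {
    i <- which(chrom == ch)
    chars <- genomeChars(genome, ch)
    ctx <- cpgContext(chars)
    len <- length(chars)
    half <- 37L
    gc[i] <- vapply(pos[i], function(p) {
      w <- chars[max(1L, p - half):min(len, p + half)]
      mean(w %in% c("G", "C"))
    }, numeric(1))
    cpg[i] <- as.numeric(ctx[pos[i]])
  }
  df$GC <- gc; df$CpG <- cpg
  # gene-geometry distances
  if (!is.null(genes) && length(genes@transcripts) > 0L) {
    tx <- genes@transcripts
    plus <- as.character(GenomicRanges::strand(tx)) != "-"
    tss <- ifelse(plus, GenomicRanges::start(tx), GenomicRanges::end(tx))
    tse <- ifelse(plus, GenomicRanges::end(tx), GenomicRanges::start(tx))
    tss_gr <- GenomicRanges::GRanges(GenomicRanges::seqnames(tx),
                                     IRanges::IRanges(tss, width = 1L))
    tse_gr <- GenomicRanges::GRanges(GenomicRanges::seqnames(tx),
                                     IRanges::IRanges(tse, width = 1L))
    df$minDistTSS <- dist_to_nearest(chrom, pos, tss_gr)
    df$minDistTSE <- dist_to_nearest(chrom, pos, tse_gr)
    cds_all <- unlist(genes@cds)
    df$cdsDist <- dist_to_nearest(chrom, pos, cds_all)
    df$inCDS <- as.numeric(!is.na(df$cdsDist) & df$cdsDist == 0)
    splice <- list()
    for (id in names(genes@exons)) {
      ex <- sort(genes@exons[[id]])
      if (length(ex) > 1L) {
        chx <- as.character(GenomicRanges::seqnames(ex))[1]
        sites <- c(GenomicRanges::end(ex)[-length(ex)],
                   GenomicRanges::start(ex)[-1L])
        splice[[length(splice) + 1L]] <- GenomicRanges::GRanges(
          chx, IRanges::IRanges(sites, width = 1L))
      }
    }
    df$spliceDist <- if (length(splice))
      dist_to_nearest(chrom, pos, do.call(c, splice)) else NA_real_
  } else {
    df$minDistTSS <- NA_real_; df$minDistTSE <- NA_real_
    df$cdsDist <- NA_real_; df$inCDS <- NA_real_; df$spliceDist <- NA_real_
  }
  # numeric tracks
  for (nm in names(tracks))
    df[[nm]] <- trackValueAt(tracks[[nm]], chrom, pos)
  # interval tracks: categorical label or membership indicator
  for (nm in names(intervals)) {
    gr <- intervals[[nm]]
    if (!is.null(gr) && "name" %in% colnames(S4Vectors::mcols(gr))) {
      q <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, width = 1L))
      hit <- GenomicRanges::findOverlaps(q, gr, select = "first")
      df[[nm]] <- ifelse(is.na(hit), NA_character_,
                         as.character(gr$name[hit]))
    } else {
      df[[nm]] <- as.numeric(intervalCountAt(gr, chrom, pos) > 0L)
    }
  }
  df$ReMapDensity <- if (!is.null(remap))
    as.numeric(remapDensity(variants, remap)) else NA_real_
  df
}
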