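#' Extract the reconstructed ancestral sequence on reference coordinates
#'
#' Walks alignment blocks and, for every alignment column where both the
#' reference row and the ancestor row carry a non-gap base, stores the
#' ancestral base at the reference 1-based sense-strand coordinate.
#' Reference rows on the minus strand are mapped back to sense-strand
#' coordinates using the MAF srcSize convention, with the ancestor base
#' complemented. Ambiguity codes (N, IUPAC) in the ancestor row are treated
#' as unreconstructed. Overlapping blocks are resolved first-block-wins and
#' disagreements counted.
#'
#' @param blocks alignment blocks from \code{\link{readAlignmentBlocks}}
#' @param ancestorLabel row source label of the reconstructed ancestor;
#'   matched against the full src or its prefix before the first "."
#' @param referenceLabel row source label of the reference genome
#' @param refLengths named integer vector of reference chromosome lengths
#'   (required so minus-strand rows can be oriented and the map sized)
#' @return an \linkS4class{AncestorMap}
#' @export
extractAncestor <- function(blocks, ancestorLabel, referenceLabel, refLengths) {
  stopifnot(!is.null(names(refLengths)))
  bases <- lapply(refLengths, function(n) rep("-", n))
  conflicts <- 0L
  saw_ancestor <- FALSE
  match_row <- function(src, label) {
    src == label | startsWith(src, paste0(label, "."))
  }
  strip_chrom <- function(src, label) {
    ifelse(src == label, src, sub(paste0("^", label, "\\."), "", src))
  }
  for (b in blocks) {
    ref_i <- which(match_row(b$src, referenceLabel))
    anc_i <- which(match_row(b$src, ancestorLabel))
    if (length(anc_i) > 1L) {
      warning("duplicated ancestor rows in one block (possible paralogy); ",
              "using the first", call. = FALSE)
      anc_i <- anc_i[1L]
    }
    if (length(anc_i) == 1L) saw_ancestor <- TRUE
    if (length(ref_i) == 0L || length(anc_i) == 0L) next
    ref_i <- ref_i[1L]
    chrom <- strip_chrom(b$src[ref_i], referenceLabel)
    if (!chrom %in% names(bases)) next
    ref_txt <- strsplit(b$text[ref_i], "")[[1]]
    anc_txt <- strsplit(b$text[anc_i], "")[[1]]
    nongap <- ref_txt != "-"
    offs <- cumsum(nongap)          # 1..size along the strand-relative seq
    idx <- which(nongap)
    if (b$strand[ref_i] == "+") {
      sense_pos <- b$start[ref_i] + offs[idx]          # 0-based start -> 1-based
      anc_base <- anc_txt[idx]
    } else {
      if (is.na(b$srcSize[ref_i]))
        stop("reference row on '-' strand without srcSize metadata")
      # MAF minus-strand starts count from the end of the sense strand
      sense_pos <- b$srcSize[ref_i] - b$start[ref_i] - offs[idx] + 1L
      anc_base <- unname(COMPLEMENT[anc_txt[idx]])
      anc_base[is.na(anc_base)] <- "-"
    }
    anc_base[!(anc_base %in% DNA_BASES)] <- "-"  # gaps + ambiguity codes
    keep <- anc_base != "-"
    sense_pos <- sense_pos[keep]
    anc_base <- anc_base[keep]
    inside <- sense_pos >= 1L & sense_pos <= length(bases[[chrom]])
    sense_pos <- sense_pos[inside]
    anc_base <- anc_base[inside]
    existing <- bases[[chrom]][sense_pos]
    clash <- existing != "-"
    conflicts <- conflicts + sum(clash & existing != anc_base)
    put <- !clash
    bases[[chrom]][sense_pos[put]] <- anc_base[put]
  }
  if (!saw_ancestor)
    stop("ancestor label '", ancestorLabel, "' absent from all blocks")
  new("AncestorMap", bases = bases, conflicts = conflicts)
}

#' Coverage and bias diagnostics for an ancestor map
#'
#' Reports genome-wide, per-chromosome and CDS-restricted coverage, and
#' flags chromosomes whose coverage deviates from the genome-wide value by
#' more than \code{biasRatio}-fold in either direction.
#'
#' @param anc an \linkS4class{AncestorMap}
#' @param genome DNAStringSet reference
#' @param cds optional GRanges of coding intervals for CDS-restricted
#'   coverage
#' @param biasRatio flag threshold (default 2)
#' @return list with genome_coverage, per_chrom_coverage, cds_coverage,
#'   biased_chromosomes
#' @export
coverageReport <- function(anc, genome, cds = NULL, biasRatio = 2) {
  per <- ancestorCoverage(anc)
  lens <- vapply(names(per), function(ch) genomeLength(genome, ch), numeric(1))
  genome_cov <- sum(per * lens) / sum(lens)
  cds_cov <- NA_real_
  if (!is.null(cds) && length(cds) > 0L) {
    covered <- 0L; total <- 0L
    for (i in seq_along(cds)) {
      ch <- as.character(GenomicRanges::seqnames(cds))[i]
      if (!ch %in% names(anc@bases)) next
      span <- GenomicRanges::start(cds)[i]:GenomicRanges::end(cds)[i]
      covered <- covered + sum(anc@bases[[ch]][span] != "-")
      total <- total + length(span)
    }
    if (total > 0L) cds_cov <- covered / total
  }
  ratio <- ifelse(per > 0, pmax(per / genome_cov, genome_cov / per), Inf)
  biased <- names(per)[genome_cov > 0 & ratio > biasRatio]
  list(genome_coverage = genome_cov,
       per_chrom_coverage = per,
       cds_coverage = cds_cov,
       biased_chromosomes = biased)
}
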