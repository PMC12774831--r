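#' Score variants with a trained model
#'
#' Annotate -> expand -> scale with the training SDs -> predict. The
#' reported impact score is P(simulated class): 0 means neutral-like,
#' 1 means impact-like. Input order is preserved. Variants whose ref
#' disagrees with the genome are reported in an \code{errors} attribute and
#' receive NA, the rest proceed.
#'
#' @param model a \linkS4class{TrainedModel}
#' @param scaler \linkS4class{ScalingParams} fitted on the training rows
#' @param spec the \linkS4class{FeatureSpec} the model was trained with
#' @param variants a \linkS4class{VariantSet}
#' @param genome,genes,tracks,intervals,remap annotation inputs, as in
#'   \code{\link{annotateVariants}}
#' @return data.frame chrom, pos, ref, alt, score (attribute "errors":
#'   indices of refused records)
#' @export
scoreVariants <- function(model, scaler, spec, variants, genome,
                          genes = NULL, tracks = list(), intervals = list(),
                          remap = NULL) {
  if (!is.na(model@specChecksum) && model@specChecksum != spec@checksum)
    stop("model was trained with a different feature spec (checksum mismatch)")
  n <- length(variants)
  chrom <- variantChrom(variants); pos <- variantPos(variants)
  ref <- variantRef(variants); alt <- variantAlt(variants)
  ok <- rep(TRUE, n)
  for (ch in unique(chrom)) {
    i <- which(chrom == ch)
    ok[i] <- genomeBase(genome, ch, pos[i]) == ref[i]
  }
  score <- rep(NA_real_, n)
  if (any(ok)) {
    ann <- annotateVariants(variants[which(ok)], genome, genes = genes,
                            tracks = tracks, intervals = intervals,
                            remap = remap, spec = spec)
    fm <- applyScaler(expandFeatures(ann, spec), scaler)
    prob <- predictProba(model, fm)
    score[ok] <- prob[, "simulated"]
  }
  out <- data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
                    score = score, stringsAsFactors = FALSE)
  attr(out, "errors") <- which(!ok)
  out
}

#' Enumerate all possible SNVs over a region
#'
#' For every position whose reference base is A/C/G/T, exactly the three
#' variants with alt != ref, ordered by (pos, alt). Positions with other
#' bases (N) are skipped and counted.
#'
#' @param genome DNAStringSet reference
#' @param chrom chromosome
#' @param start,end 1-based inclusive bounds (defaults: whole chromosome)
#' @return a \linkS4class{VariantSet}; attribute "skipped" counts non-ACGT
#'   positions
#' @export
enumerateAllSnvs <- function(genome, chrom, start = 1L,
                             end = genomeLength(genome, chrom)) {
  len <- genomeLength(genome, chrom)
  if (start < 1L || end > len || start > end)
    stop("region outside [1, ", len, "]")
  refc <- genomeChars(genome, chrom)[start:end]
  posv <- start:end
  usable <- refc %in% DNA_BASES
  skipped <- sum(!usable)
  refc <- refc[usable]; posv <- posv[usable]
  pos3 <- rep(posv, each = 3L)
  ref3 <- rep(refc, each = 3L)
  alt3 <- unlist(lapply(refc, function(b) sort(setdiff(DNA_BASES, b))))
  vs <- variantSet(rep(chrom, length(pos3)), pos3, ref3, alt3)
  attr(vs, "skipped") <- skipped
  vs
}

#' Precompute scores for every possible SNV over a region
#'
#' Streams \code{\link{enumerateAllSnvs}} through
#' \code{\link{scoreVariants}} in fixed-size chunks (constant memory in the
#' region length) and writes the sorted score TSV.
#'
#' @inheritParams scoreVariants
#' @inheritParams enumerateAllSnvs
#' @param out output TSV path
#' @param chunkSize positions per annotation chunk
#' @return the output path, invisibly
#' @export
precomputeScores <- function(model, scaler, spec, genome, chrom,
                             start = 1L, end = genomeLength(genome, chrom),
                             genes = NULL, tracks = list(),
                             intervals = list(), remap = NULL,
                             out, chunkSize = 10000L) {
  chunks <- split(start:end, ((start:end) - start) %/% chunkSize)
  parts <- lapply(chunks, function(posv) {
    vs <- enumerateAllSnvs(genome, chrom, min(posv), max(posv))
    if (length(vs) == 0L) return(NULL)
    sc <- scoreVariants(model, scaler, spec, vs, genome, genes = genes,
                        tracks = tracks, intervals = intervals,
                        remap = remap)
    sc[!is.na(sc$score), , drop = FALSE]
  })
  res <- do.call(rbind, parts)
  writeScores(res, out)
  invisible(out)
}
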