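#' @import methods
#' @importClassesFrom GenomicRanges GRanges
#' @importClassesFrom IRanges IRanges
NULL

#' AncestorMap: reconstructed ancestral bases on reference coordinates
#'
#' Per-chromosome character vectors, one element per reference position
#' (1-based), holding the ancestral base on the reference sense strand or
#' \code{"-"} where the ancestor is unreconstructed (alignment gap, missing
#' block, or an ambiguity code). Conflicting overlapping alignment blocks are
#' resolved first-block-wins; the number of conflicting column assignments is
#' kept for auditing.
#'
#' @slot bases named list of character vectors (one per chromosome)
#' @slot conflicts integer count of overlapping-block disagreements
#' @export
setClass("AncestorMap",
  representation(bases = "list", conflicts = "integer"),
  prototype(bases = list(), conflicts = 0L))

setValidity("AncestorMap", function(object) {
  if (is.null(names(object@bases)) && length(object@bases) > 0L)
    return("bases must be a named list (chromosome names)")
  ok <- vapply(object@bases, function(b) {
    is.character(b) && all(b %in% c(DNA_BASES, "-"))
  }, logical(1))
  if (!all(ok)) return("ancestral bases must be A/C/G/T or '-'")
  TRUE
})

#' VariantSet: single nucleotide variants on a reference genome
#'
#' Thin S4 wrapper around a \linkS4class{GRanges} of width-1 positions with
#' metadata columns \code{ref} and \code{alt}. All coordinates are 1-based.
#'
#' @slot gr GRanges with mcols ref and alt (single upper-case bases)
#' @export
setClass("VariantSet", representation(gr = "GRanges"))

setValidity("VariantSet", function(object) {
  gr <- object@gr
  mc <- S4Vectors::mcols(gr)
  if (!all(c("ref", "alt") %in% colnames(mc)))
    return("variant GRanges needs 'ref' and 'alt' metadata columns")
  if (length(gr) == 0L) return(TRUE)
  if (any(GenomicRanges::width(gr) != 1L))
    return("variants must be single positions (width 1)")
  if (!all(mc$ref %in% DNA_BASES) || !all(mc$alt %in% DNA_BASES))
    return("ref/alt must be single bases A/C/G/T")
  if (any(mc$ref == mc$alt)) return("ref must differ from alt")
  TRUE
})

#' LabeledVariantSet: variants carrying a training class label
#'
#' Label 1 marks derived (proxy-benign) variants, 0 marks simulated
#' (proxy-impactful) variants.
#'
#' @export
setClass("LabeledVariantSet", contains = "VariantSet")

setValidity("LabeledVariantSet", function(object) {
  mc <- S4Vectors::mcols(object@gr)
  if (!"label" %in% colnames(mc))
    return("labeled variant GRanges needs a 'label' metadata column")
  if (length(object@gr) > 0L && !all(mc$label %in% c(0L, 1L)))
    return("labels must be 0 (simulated) or 1 (derived)")
  key <- paste(GenomicRanges::seqnames(object@gr),
               GenomicRanges::start(object@gr), mc$alt, mc$label)
  if (anyDuplicated(key)) return("duplicate (chrom,pos,alt) within a label")
  TRUE
})

#' MutationRateModel: per-chromosome, CpG-stratified substitution rates
#'
#' One row per (chromosome, context, from, to) with the aligned-base counts
#' used as denominators, so every rate is auditable. Context is "CpG" or
#' "nonCpG", defined on the reference sense strand.
#'
#' @slot table data.frame with columns chrom, context, from, to, count,
#'   denom, rate
#' @export
setClass("MutationRateModel", representation(table = "data.frame"))

setValidity("MutationRateModel", function(object) {
  tab <- object@table
  need <- c("chrom", "context", "from", "to", "count", "denom", "rate")
  if (!all(need %in% colnames(tab)))
    return(paste("rate table needs columns:", paste(need, collapse = ", ")))
  if (nrow(tab) == 0L) return(TRUE)
  if (!all(tab$context %in% c("CpG", "nonCpG"))) return("bad context value")
  defined <- !is.na(tab$rate)
  if (any(tab$rate[defined] < 0 | tab$rate[defined] > 1))
    return("rates must lie in [0,1]")
  if (any(defined & tab$denom <= 0))
    return("defined rates require positive denominators")
  TRUE
})

#' FeatureSpec: declarative base-annotation + combination feature layout
#'
#' @slot bases list of base-annotation declarations (name, type, categories,
#'   default, missing_indicator)
#' @slot combos list of combination rules (categorical base x numeric base)
#' @slot checksum character; digest of the normalized spec, stamped into
#'   trained models so scoring refuses mismatched layouts
#' @export
setClass("FeatureSpec",
  representation(bases = "list", combos = "list", checksum = "character"))

setValidity("FeatureSpec", function(object) {
  nms <- vapply(object@bases, function(b) b$name, character(1))
  if (anyDuplicated(nms)) return("duplicate base annotation names")
  types <- vapply(object@bases, function(b) b$type, character(1))
  if (!all(types %in% c("numeric", "categorical", "indicator")))
    return("base type must be numeric, categorical or indicator")
  for (cmb in object@combos) {
    if (!cmb$categorical %in% nms)
      return(sprintf("combination references undeclared base '%s'",
                     cmb$categorical))
    if (!cmb$numeric %in% nms)
      return(sprintf("combination references undeclared base '%s'",
                     cmb$numeric))
  }
  TRUE
})

#' ScalingParams: per-feature training-set standard deviations
#'
#' @slot sds named numeric vector of population SDs for retained columns
#' @slot dropped character vector of constant columns removed from the
#'   model's view
#' @export
setClass("ScalingParams",
  representation(sds = "numeric", dropped = "character"))

setValidity("ScalingParams", function(object) {
  if (length(object@sds) > 0L && any(object@sds <= 0))
    return("retained scaling SDs must be > 0")
  TRUE
})

#' FeatureMatrix: expanded (and optionally scaled) feature values
#'
#' @slot mat numeric matrix, rows = variants, columns = expanded features
#' @slot scaled logical flag guarding against double division by the SDs
#' @slot checksum character, checksum of the FeatureSpec that produced it
#' @export
setClass("FeatureMatrix",
  representation(mat = "matrix", scaled = "logical", checksum = "character"),
  prototype(scaled = FALSE, checksum = NA_character_))

setValidity("FeatureMatrix", function(object) {
  if (!is.numeric(object@mat)) return("feature matrix must be numeric")
  if (anyNA(object@mat)) return("feature matrix must have no missing values")
  TRUE
})

#' TrainedModel: L2-regularized logistic regression classifier
#'
#' Weights are on the scaled feature space; the scaling parameters and the
#' feature-spec checksum travel with the model so new variants are scaled
#' with the training SDs and layout mismatches are refused.
#'
#' @slot weights named numeric vector, one per retained feature
#' @slot intercept numeric, unpenalized
#' @slot l2 numeric, the selected ridge penalty
#' @slot scaling ScalingParams used at training time
#' @slot specChecksum character
#' @slot meta list (seed, iterations, converged, objective)
#' @export
setClass("TrainedModel",
  representation(weights = "numeric", intercept = "numeric", l2 = "numeric",
                 scaling = "ScalingParams", specChecksum = "character",
                 meta = "list"))

setValidity("TrainedModel", function(object) {
  if (!all(is.finite(object@weights))) return("weights must be finite")
  if (length(object@intercept) != 1L || !is.finite(object@intercept))
    return("intercept must be a single finite number")
  if (object@l2 < 0) return("l2 must be non-negative")
  TRUE
})

#' GeneModels: minimal transcript models parsed from GFF3
#'
#' Holds transcript extents plus exon and CDS ranges grouped by transcript.
#' Only what the consequence classifier and codon analyses need; not a TxDb.
#'
#' @slot transcripts GRanges with mcols tx_id, gene_id
#' @slot exons GRangesList keyed by tx_id
#' @slot cds GRangesList keyed by tx_id (empty element = non-coding)
#' @export
setClass("GeneModels",
  representation(transcripts = "GRanges", exons = "CompressedGRangesList",
                 cds = "CompressedGRangesList"))

setValidity("GeneModels", function(object) {
  tx <- S4Vectors::mcols(object@transcripts)$tx_id
  if (is.null(tx)) return("transcripts need a tx_id metadata column")
  if (!all(tx %in% names(object@exons)))
    return("every transcript needs an exons entry")
  TRUE
})

setMethod("show", "AncestorMap", function(object) {
  cov <- vapply(object@bases, function(b) mean(b != "-"), numeric(1))
  cat("AncestorMap over", length(object@bases), "chromosome(s);",
      "coverage:", paste(sprintf("%s=%.3f", names(cov), cov), collapse = ", "),
      "\n  block conflicts:", object@conflicts, "\n")
})

setMethod("show", "VariantSet", function(object) {
  cat(class(object), "with", length(object@gr), "variant(s)\n")
  if (length(object@gr) > 0L) show(head(object@gr, 3))
})

setMethod("show", "MutationRateModel", function(object) {
  cat("MutationRateModel:", nrow(object@table), "rate entries over",
      length(unique(object@table$chrom)), "chromosome(s)\n")
})

setMethod("show", "FeatureSpec", function(object) {
  cat("FeatureSpec:", length(object@bases), "base annotations,",
      length(object@combos), "combination rules ->",
      length(expandedColumnNames(object)), "columns\n")
})

setMethod("show", "TrainedModel", function(object) {
  cat("TrainedModel:", length(object@weights), "features, L2 =", object@l2,
      "| converged:", isTRUE(object@meta$converged), "\n")
})
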