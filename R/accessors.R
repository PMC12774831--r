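#' Construct a VariantSet
#'
#' @param chrom character vector of chromosome names
#' @param pos integer vector of 1-based positions
#' @param ref,alt single upper-case bases; ref must differ from alt
#' @return a \linkS4class{VariantSet}
#' @export
variantSet <- function(chrom = character(), pos = integer(),
                       ref = character(), alt = character()) {
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, width = 1L),
                               ref = toupper(ref), alt = toupper(alt))
  new("VariantSet", gr = gr)
}

#' Construct a LabeledVariantSet from parallel vectors
#' @inheritParams variantSet
#' @param label integer vector of 0/1 class labels (1 = derived)
#' @export
labeledVariantSet <- function(chrom, pos, ref, alt, label) {
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, width = 1L),
                               ref = toupper(ref), alt = toupper(alt),
                               label = as.integer(label))
  new("LabeledVariantSet", gr = gr)
}

#' @describeIn variantSet number of variants
#' @param x a VariantSet
#' @export
setMethod("length", "VariantSet", function(x) length(x@gr))

#' Variant accessors
#'
#' Column-wise views of a \linkS4class{VariantSet}.
#' @param x a VariantSet
#' @return atomic vector, one element per variant
#' @export
variantChrom <- function(x) as.character(GenomicRanges::seqnames(x@gr))

#' @rdname variantChrom
#' @export
variantPos <- function(x) GenomicRanges::start(x@gr)

#' @rdname variantChrom
#' @export
variantRef <- function(x) S4Vectors::mcols(x@gr)$ref

#' @rdname variantChrom
#' @export
variantAlt <- function(x) S4Vectors::mcols(x@gr)$alt

#' @rdname variantChrom
#' @export
variantLabel <- function(x) S4Vectors::mcols(x@gr)$label

#' @rdname variantChrom
#' @param row.names,optional,... passed on conventions of as.data.frame
#' @export
setMethod("as.data.frame", "VariantSet",
  function(x, row.names = NULL, optional = FALSE, ...) {
    df <- data.frame(chrom = variantChrom(x), pos = variantPos(x),
                     ref = variantRef(x), alt = variantAlt(x),
                     stringsAsFactors = FALSE)
    lab <- variantLabel(x)
    if (!is.null(lab)) df$label <- lab
    df
  })

#' Subset a VariantSet
#' @param x a VariantSet
#' @param i index vector
#' @param j,drop ignored
#' @export
setMethod("[", "VariantSet", function(x, i, j, ..., drop = TRUE) {
  methods::initialize(x, gr = x@gr[i])
})

#' Ancestral base lookup
#'
#' @param anc an \linkS4class{AncestorMap}
#' @param chrom chromosome name
#' @param pos 1-based position(s)
#' @return character vector of bases, "-" where unreconstructed
#' @export
ancestorBase <- function(anc, chrom, pos) {
  b <- anc@bases[[chrom]]
  if (is.null(b)) stop("unknown chromosome: ", chrom)
  if (any(pos < 1L | pos > length(b)))
    stop("position outside [1, ", length(b), "] on ", chrom)
  b[pos]
}

#' Per-chromosome ancestral coverage
#' @param anc an AncestorMap
#' @return named numeric vector, fraction of positions with an ancestral base
#' @export
ancestorCoverage <- function(anc) {
  vapply(anc@bases, function(b) mean(b != "-"), numeric(1))
}

#' Rate lookup table of a MutationRateModel
#' @param x a MutationRateModel
#' @return the underlying data.frame
#' @export
rateTable <- function(x) x@table

#' Feature-matrix accessors
#' @param x a FeatureMatrix
#' @return the numeric matrix / scaled flag
#' @export
featureMatrix <- function(x) x@mat

#' @rdname featureMatrix
#' @export
isScaled <- function(x) x@scaled

#' Model weight vector (named) and intercept
#' @param model a TrainedModel
#' @export
modelWeights <- function(model) model@weights

#' @rdname modelWeights
#' @export
modelIntercept <- function(model) model@intercept
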