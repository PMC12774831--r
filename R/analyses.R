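#' Mann-Whitney U test (wrapper)
#'
#' Two-sided test via \code{stats::wilcox.test}: exact enumeration when
#' both groups have at most 8 observations and no ties, otherwise the
#' normal approximation with continuity and tie correction. The statistic
#' is U for the first group (ties counted one half).
#'
#' @param x,y numeric samples
#' @return list with U, p_value, n1, n2
#' @export
mannWhitneyU <- function(x, y) {
  if (length(x) < 2L || length(y) < 2L)
    stop("need at least 2 observations per group")
  exact <- length(x) <= 8L && length(y) <= 8L &&
    !anyDuplicated(c(x, y))
  wt <- suppressWarnings(
    wilcox.test(x, y, alternative = "two.sided", exact = exact,
                correct = TRUE))
  list(U = unname(wt$statistic), p_value = wt$p.value,
       n1 = length(x), n2 = length(y))
}

#' Per-position minimum scores within codons
#'
#' Restricts to single-transcript, sense-strand genes with a valid CDS,
#' maps every coding position to its codon and within-codon position
#' (1, 2, 3), and takes the minimum score over the three alternative
#' alleles at each position (a conservative per-position impact estimate).
#' Positions with fewer than three scored alleles are excluded and
#' counted.
#'
#' @param scores score table (data.frame chrom, pos, ref, alt, score)
#' @param genes a \linkS4class{GeneModels}
#' @return data.frame gene, chrom, pos, codon, codon_pos, min_score;
#'   attribute "excluded_positions" counts under-covered positions,
#'   attribute "excluded_genes" lists skipped genes
#' @export
codonMinScores <- function(scores, genes) {
  tx <- genes@transcripts
  gene_ids <- S4Vectors::mcols(tx)$gene_id
  multi <- names(table(gene_ids))[table(gene_ids) > 1L]
  keep_tx <- which(!(gene_ids %in% multi) &
                     as.character(GenomicRanges::strand(tx)) == "+")
  excluded_genes <- unique(gene_ids[!(seq_along(tx) %in% keep_tx)])
  per_pos <- aggregate(scores$score,
                       by = list(chrom = scores$chrom, pos = scores$pos),
                       FUN = min)
  cnt <- aggregate(scores$score,
                   by = list(chrom = scores$chrom, pos = scores$pos),
                   FUN = length)
  per_pos$n_alt <- cnt$x
  excluded_positions <- 0L
  out <- list()
  for (i in keep_tx) {
    id <- S4Vectors::mcols(tx)$tx_id[i]
    cds <- sort(genes@cds[[id]])
    if (length(cds) == 0L) next
    widths <- GenomicRanges::end(cds) - GenomicRanges::start(cds) + 1L
    if (sum(widths) %% 3L != 0L) next
    chrom <- as.character(GenomicRanges::seqnames(tx))[i]
    gpos <- unlist(lapply(seq_along(cds), function(k)
      GenomicRanges::start(cds)[k]:GenomicRanges::end(cds)[k]))
    off <- seq_along(gpos)
    hit <- per_pos[per_pos$chrom == chrom & per_pos$pos %in% gpos, ,
                   drop = FALSE]
    m <- match(gpos, hit$pos)
    covered <- !is.na(m) & hit$n_alt[m] >= 3L
    excluded_positions <- excluded_positions + sum(!covered)
    if (!any(covered)) next
    out[[length(out) + 1L]] <- data.frame(
      gene = gene_ids[i], chrom = chrom, pos = gpos[covered],
      codon = (off[covered] - 1L) %/% 3L + 1L,
      codon_pos = (off[covered] - 1L) %% 3L + 1L,
      min_score = hit$x[m[covered]], stringsAsFactors = FALSE)
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(gene = character(), chrom = character(), pos = integer(),
               codon = integer(), codon_pos = integer(),
               min_score = numeric())
  attr(res, "excluded_positions") <- excluded_positions
  attr(res, "excluded_genes") <- excluded_genes
  res
}

#' Compare minimum-score distributions across codon positions
#'
#' Two-sided Mann-Whitney U tests for the three position pairs, Bonferroni
#' corrected. Genome-wide scope corrects by 3 (the number of tests);
#' per-gene scope runs the 3 tests within every gene and reports corrected
#' p-values under both families (within-gene factor 3 and global factor
#' 3 x number of genes), plus the fraction of genes significant per pair
#' at \code{alpha}, with the higher-scoring side.
#'
#' @param minima output of \code{\link{codonMinScores}}
#' @param scope "genome" or "per_gene"
#' @param alpha significance level applied to corrected p-values
#' @param family for per-gene significance: "global" (3 x genes) or
#'   "within_gene" (3)
#' @return for genome scope: data.frame pair, U, p_raw, p_bonferroni,
#'   higher; for per-gene scope: list(per_gene = data.frame,
#'   fraction_significant = named vector, n_tests = count)
#' @export
compareCodonPositions <- function(minima, scope = c("genome", "per_gene"),
                                  alpha = 0.05,
                                  family = c("global", "within_gene")) {
  scope <- match.arg(scope)
  family <- match.arg(family)
  pairs <- list(c(1L, 2L), c(1L, 3L), c(2L, 3L))
  test_pair <- function(df, a, b) {
    x <- df$min_score[df$codon_pos == a]
    y <- df$min_score[df$codon_pos == b]
    if (length(x) < 2L || length(y) < 2L) return(NULL)
    mw <- mannWhitneyU(x, y)
    data.frame(pair = sprintf("pos%d_vs_pos%d", a, b), U = mw$U,
               p_raw = mw$p_value,
               higher = if (mw$U > mw$n1 * mw$n2 / 2) sprintf("pos%d", a)
                        else if (mw$U < mw$n1 * mw$n2 / 2) sprintf("pos%d", b)
                        else "tie",
               stringsAsFactors = FALSE)
  }
  if (scope == "genome") {
    res <- do.call(rbind, lapply(pairs, function(p)
      test_pair(minima, p[1], p[2])))
    if (is.null(res)) stop("not enough observations per codon position")
    res$p_bonferroni <- pmin(1, res$p_raw * nrow(res))
    return(res)
  }
  genes <- unique(minima$gene)
  rows <- list()
  for (g in genes) {
    df <- minima[minima$gene == g, , drop = FALSE]
    for (p in pairs) {
      r <- test_pair(df, p[1], p[2])
      if (!is.null(r)) { r$gene <- g; rows[[length(rows) + 1L]] <- r }
    }
  }
  per_gene <- do.call(rbind, rows)
  n_tests <- nrow(per_gene)
  per_gene$p_bonf_within <- pmin(1, per_gene$p_raw * 3)
  per_gene$p_bonf_global <- pmin(1, per_gene$p_raw * n_tests)
  pcol <- if (family == "global") "p_bonf_global" else "p_bonf_within"
  frac <- vapply(c("pos1_vs_pos2", "pos1_vs_pos3", "pos2_vs_pos3"),
                 function(pr) {
    sub <- per_gene[per_gene$pair == pr, , drop = FALSE]
    if (nrow(sub) == 0L) return(NA_real_)
    mean(sub[[pcol]] < alpha)
  }, numeric(1))
  list(per_gene = per_gene, fraction_significant = frac,
       n_tests = n_tests, family = family)
}

#' Summarize scores across allele-frequency bins
#'
#' Bins are left-open right-closed with width \code{binWidth}, the first
#' bin (0, binWidth]. AF is the non-reference allele frequency. Reports
#' per-bin count/mean/quartiles plus the overall mean, the rare-allele
#' mean (AF < rareCut) and the common-allele mean (AF >= rareCut).
#'
#' @param score,af parallel numeric vectors; af must lie in (0, 1]
#' @param binWidth bin width (default 0.025)
#' @param rareCut rare-allele frequency cut (default 0.05, strict <)
#' @return list with bins (data.frame), overall_mean, rare_mean,
#'   common_mean, n_rejected
#' @export
afBinSummary <- function(score, af, binWidth = 0.025, rareCut = 0.05) {
  stopifnot(length(score) == length(af))
  bad <- !is.finite(af) | af <= 0 | af > 1
  if (any(bad)) {
    warning(sum(bad), " record(s) with AF outside (0,1] rejected",
            call. = FALSE)
    score <- score[!bad]; af <- af[!bad]
  }
  if (length(af) == 0L) stop("no records with AF in (0,1]")
  nbin <- ceiling(1 / binWidth)
  idx <- pmin(nbin, ceiling(af / binWidth - 1e-12))
  edges_lo <- (seq_len(nbin) - 1L) * binWidth
  edges_hi <- pmin(1, seq_len(nbin) * binWidth)
  bins <- do.call(rbind, lapply(seq_len(nbin), function(b) {
    s <- score[idx == b]
    data.frame(bin_low = edges_lo[b], bin_high = edges_hi[b],
               count = length(s),
               mean = if (length(s)) mean(s) else NA_real_,
               q25 = if (length(s)) unname(quantile(s, 0.25)) else NA_real_,
               median = if (length(s)) median(s) else NA_real_,
               q75 = if (length(s)) unname(quantile(s, 0.75)) else NA_real_)
  }))
  list(bins = bins,
       overall_mean = mean(score),
       rare_mean = if (any(af < rareCut)) mean(score[af < rareCut])
                   else NA_real_,
       common_mean = if (any(af >= rareCut)) mean(score[af >= rareCut])
                     else NA_real_,
       n_rejected = sum(bad))
}

#' Fraction of scores above impact thresholds
#'
#' Mirrors the reporting convention: strictly above 0.6 ("above 0.6"),
#' inclusive at 0.8 ("0.8 and higher"). Both comparators are exposed.
#'
#' @param scores numeric vector
#' @param thresholds numeric thresholds
#' @param comparators ">" or ">=" per threshold (recycled)
#' @return named numeric vector of fractions
#' @export
fractionAbove <- function(scores, thresholds = c(0.6, 0.8),
                          comparators = c(">", ">=")) {
  if (length(scores) == 0L) stop("no scores")
  comparators <- rep_len(comparators, length(thresholds))
  out <- vapply(seq_along(thresholds), function(i) {
    if (comparators[i] == ">") mean(scores > thresholds[i])
    else mean(scores >= thresholds[i])
  }, numeric(1))
  setNames(out, paste0(comparators, thresholds))
}

#' Per-position mean scores across a gene window
#'
#' Arithmetic mean of the three alternative-allele scores at every position
#' in [gene start - flank, gene end + flank], clipped to the chromosome
#' with a warning. Positions present in an optional natural-variant set
#' are flagged.
#'
#' @param scores score table (chrom, pos, ref, alt, score)
#' @param chrom,geneStart,geneEnd gene extent (1-based)
#' @param flank flank width in bp (default 500)
#' @param chromLength optional chromosome length for clipping
#' @param observed optional \linkS4class{VariantSet} of natural variants
#' @return data.frame pos, mean_score, n_alt, observed
#' @export
geneWindowMeans <- function(scores, chrom, geneStart, geneEnd, flank = 500L,
                            chromLength = NULL, observed = NULL) {
  lo <- geneStart - flank
  hi <- geneEnd + flank
  if (lo < 1L || (!is.null(chromLength) && hi > chromLength)) {
    warning("window clipped to chromosome bounds", call. = FALSE)
    lo <- max(1L, lo)
    if (!is.null(chromLength)) hi <- min(chromLength, hi)
  }
  sub <- scores[scores$chrom == chrom & scores$pos >= lo & scores$pos <= hi,
                , drop = FALSE]
  agg <- aggregate(sub$score, by = list(pos = sub$pos), FUN = mean)
  cnt <- aggregate(sub$score, by = list(pos = sub$pos), FUN = length)
  out <- data.frame(pos = agg$pos, mean_score = agg$x, n_alt = cnt$x)
  obs_pos <- if (!is.null(observed))
    variantPos(observed)[variantChrom(observed) == chrom] else integer()
  out$observed <- out$pos %in% obs_pos
  out[order(out$pos), , drop = FALSE]
}

#' Re-rank candidate variants by impact score
#'
#' Joins candidates to a score table, orders by score (descending) with
#' p-value (ascending) as tie-break, and reports the Spearman correlation
#' between the score ranking and the p-value ranking. Candidates missing
#' from the score table are listed separately.
#'
#' @param candidates data.frame with chrom, pos, alt and optionally
#'   \code{p} (association p-values)
#' @param scores score table (chrom, pos, ref, alt, score)
#' @return list with ranked (data.frame with rank_by_score, rank_by_p),
#'   unscoreable (data.frame), spearman (NA when no p-values)
#' @export
rankCandidates <- function(candidates, scores) {
  key_c <- paste(candidates$chrom, candidates$pos, candidates$alt)
  key_s <- paste(scores$chrom, scores$pos, scores$alt)
  m <- match(key_c, key_s)
  unscoreable <- candidates[is.na(m), , drop = FALSE]
  ranked <- candidates[!is.na(m), , drop = FALSE]
  ranked$score <- scores$score[m[!is.na(m)]]
  has_p <- "p" %in% colnames(ranked)
  ord <- if (has_p) order(-ranked$score, ranked$p) else order(-ranked$score)
  ranked <- ranked[ord, , drop = FALSE]
  ranked$rank_by_score <- rank(-ranked$score, ties.method = "average")
  sp <- NA_real_
  if (has_p) {
    ranked$rank_by_p <- rank(ranked$p, ties.method = "average")
    if (nrow(ranked) >= 3L)
      sp <- suppressWarnings(cor(ranked$rank_by_score, ranked$rank_by_p,
                                 method = "spearman"))
  }
  rownames(ranked) <- NULL
  list(ranked = ranked, unscoreable = unscoreable, spearman = sp)
}
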