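#' CpG context of a fully defined sequence
#'
#' A position is CpG-context when it is the C of a "CG" dinucleotide or the
#' G of a "CG" dinucleotide on the sense strand. Context always follows the
#' sequence being mutated: the reference for de novo simulation and the
#' CpG annotation feature, the ancestor for rate estimation (see
#' \code{\link{ancestorContext}}).
#'
#' @param refChars character vector of single bases for one chromosome
#' @return logical vector, TRUE at CpG-context positions
#' @export
cpgContext <- function(refChars) {
  n <- length(refChars)
  nxt <- c(refChars[-1], "N")
  prv <- c("N", refChars[-n])
  (refChars == "C" & nxt == "G") | (refChars == "G" & prv == "C")
}

#' CpG context of an ancestral (gapped) sequence
#'
#' Context of the mutation source: a C is CpG iff the next ancestral base
#' is G, a G iff the previous ancestral base is C. A C or G whose deciding
#' neighbor is unreconstructed has indeterminate context and is excluded
#' from rate estimation; A/T positions are never CpG and need no neighbor.
#'
#' @param ancChars character vector of ancestral bases ("-" = gap)
#' @return character vector: "CpG", "nonCpG" or "indeterminate"
#' @export
ancestorContext <- function(ancChars) {
  n <- length(ancChars)
  nxt <- c(ancChars[-1], "-")
  prv <- c("-", ancChars[-n])
  out <- rep("nonCpG", n)
  isC <- ancChars == "C"; isG <- ancChars == "G"
  out[(isC & nxt == "G") | (isG & prv == "C")] <- "CpG"
  out[(isC & nxt == "-") | (isG & prv == "-")] <- "indeterminate"
  out[ancChars == "-"] <- "indeterminate"
  out
}

#' Call derived variants against a reconstructed ancestor
#'
#' A derived variant is a position where reference and ancestral bases are
#' both defined and differ; the reference allele is the derived allele. The
#' stored \code{alt} is the ancestral allele, so both training classes are
#' annotated as substitutions on the reference genome. Sites whose derived
#' (reference) allele segregates below \code{afThreshold} are removed;
#' positions absent from the population records are treated as fixed
#' (derived-allele frequency 1.0).
#'
#' @param genome DNAStringSet reference
#' @param anc \linkS4class{AncestorMap}
#' @param af \linkS4class{PopulationAF}
#' @param afThreshold minimum derived-allele frequency, in (0, 1]
#' @return a \linkS4class{VariantSet} (ref = reference base, alt = ancestral
#'   base)
#' @export
callDerived <- function(genome, anc, af, afThreshold = 0.9) {
  if (!is.numeric(afThreshold) || afThreshold <= 0 || afThreshold > 1)
    stop("afThreshold must lie in (0, 1]")
  out <- list()
  for (chrom in names(anc@bases)) {
    refc <- genomeChars(genome, chrom)
    ancc <- anc@bases[[chrom]]
    stopifnot(length(refc) == length(ancc))
    idx <- which(ancc != "-" & refc %in% DNA_BASES & ancc != refc)
    if (length(idx) == 0L) next
    # derived-allele (reference-allele) frequency = 1 - sum of alt AFs
    rec <- af@records
    rec <- rec[rec$chrom == chrom & rec$pos %in% idx, , drop = FALSE]
    alt_sum <- setNames(rep(0, length(idx)), idx)
    if (nrow(rec) > 0L) {
      s <- tapply(rec$af, rec$pos, sum)
      alt_sum[names(s)] <- s
    }
    derived_af <- 1 - unname(alt_sum)
    keep <- derived_af >= afThreshold
    if (!any(keep)) next
    out[[chrom]] <- data.frame(chrom = chrom, pos = idx[keep],
                               ref = refc[idx[keep]], alt = ancc[idx[keep]],
                               stringsAsFactors = FALSE)
  }
  df <- if (length(out)) do.call(rbind, out) else
    data.frame(chrom = character(), pos = integer(), ref = character(),
               alt = character())
  variantSet(df$chrom, df$pos, df$ref, df$alt)
}

#' Estimate CpG-stratified substitution rates per chromosome
#'
#' For every ordered base pair (b1, b2), b1 != b2, and context (CpG /
#' non-CpG of the ancestral source sequence),
#' rate = #\{ancestral b1, reference b2, context\} /
#' #\{ancestral b1, context\}, counted over positions where both sequences
#' have a defined base and the ancestral context is determinate (a C or G
#' whose deciding ancestral neighbor is unreconstructed is excluded). Zero
#' denominators yield NA rates, which the simulator refuses to use.
#'
#' @inheritParams callDerived
#' @return a \linkS4class{MutationRateModel}
#' @export
estimateRates <- function(genome, anc) {
  rows <- list()
  pairs <- expand.grid(from = DNA_BASES, to = DNA_BASES,
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$from != pairs$to, , drop = FALSE]
  for (chrom in names(anc@bases)) {
    refc <- genomeChars(genome, chrom)
    ancc <- anc@bases[[chrom]]
    aligned <- ancc != "-" & refc %in% DNA_BASES
    if (!any(aligned))
      stop("ancestor coverage is zero on chromosome ", chrom)
    ctx <- ancestorContext(ancc)
    for (context in c("CpG", "nonCpG")) {
      sel <- aligned & ctx == context
      a <- ancc[sel]; r <- refc[sel]
      denoms <- table(factor(a, levels = DNA_BASES))
      cnt <- table(factor(a, levels = DNA_BASES),
                   factor(r, levels = DNA_BASES))
      for (k in seq_len(nrow(pairs))) {
        b1 <- pairs$from[k]; b2 <- pairs$to[k]
        den <- as.integer(denoms[b1])
        num <- as.integer(cnt[b1, b2])
        rows[[length(rows) + 1L]] <- data.frame(
          chrom = chrom, context = context, from = b1, to = b2,
          count = num, denom = den,
          rate = if (den > 0L) num / den else NA_real_,
          stringsAsFactors = FALSE)
      }
    }
  }
  new("MutationRateModel", table = do.call(rbind, rows))
}

#' Simulate de novo variants from a mutation-rate model
#'
#' Emulates the mutation process over positions carrying a reconstructed
#' ancestral base: every admissible (position, alt) pair is included
#' independently with probability proportional to
#' rate[from -> alt | context], calibrated so the expected yield slightly
#' exceeds \code{nTarget}, then uniformly trimmed to exactly \code{nTarget}.
#' Inclusion probabilities are therefore exactly proportional to the
#' configured rates and each pair occurs at most once. Deterministic given
#' \code{seed}.
#'
#' @inheritParams callDerived
#' @param rates \linkS4class{MutationRateModel}
#' @param nTarget number of variants to draw
#' @param seed integer seed (required; no global random state)
#' @param exclusions optional \linkS4class{VariantSet} of (pos, alt) pairs
#'   never to emit (e.g. the derived set)
#' @param mutateFrom "reference" mutates the reference base (default);
#'   "ancestor" mutates the ancestral base instead
#' @return a \linkS4class{VariantSet}
#' @export
simulateVariants <- function(genome, anc, rates, nTarget, seed,
                             exclusions = NULL,
                             mutateFrom = c("reference", "ancestor")) {
  mutateFrom <- match.arg(mutateFrom)
  assert_scalar_number(nTarget, "nTarget", lower = 1)
  tab <- rateTable(rates)
  key <- paste(tab$chrom, tab$context, tab$from, tab$to)
  rate_of <- setNames(tab$rate, key)
  cand <- list()
  for (chrom in names(anc@bases)) {
    refc <- genomeChars(genome, chrom)
    ancc <- anc@bases[[chrom]]
    ok <- which(ancc != "-" & refc %in% DNA_BASES)
    if (length(ok) == 0L) next
    ctx <- ifelse(cpgContext(refc)[ok], "CpG", "nonCpG")
    fromb <- if (mutateFrom == "reference") refc[ok] else ancc[ok]
    for (alt in DNA_BASES) {
      sel <- fromb != alt & refc[ok] != alt
      if (!any(sel)) next
      w <- rate_of[paste(chrom, ctx[sel], fromb[sel], alt)]
      if (anyNA(w))
        stop("undefined rate (zero denominator) needed for simulation on ",
             chrom, "; refusing")
      cand[[length(cand) + 1L]] <- data.frame(
        chrom = chrom, pos = ok[sel], ref = refc[ok][sel], alt = alt,
        w = unname(w), stringsAsFactors = FALSE)
    }
  }
  cand <- do.call(rbind, cand)
  cand <- cand[cand$w > 0, , drop = FALSE]
  if (!is.null(exclusions) && length(exclusions) > 0L) {
    ex <- paste(variantChrom(exclusions), variantPos(exclusions),
                variantAlt(exclusions))
    cand <- cand[!(paste(cand$chrom, cand$pos, cand$alt) %in% ex), ,
                 drop = FALSE]
  }
  if (nTarget > nrow(cand))
    stop("nTarget (", nTarget, ") exceeds the ", nrow(cand),
         " admissible (pos,alt) pairs")
  with_seed(seed, {
    # Bernoulli thinning proportional to rates, then uniform trim; the
    # head-room keeps the pre-trim yield above nTarget with near certainty
    yield <- 1.1 * nTarget + 4 * sqrt(nTarget) + 5
    scale <- min(yield / sum(cand$w), 1 / max(cand$w))
    hit <- runif(nrow(cand)) < cand$w * scale
    drawn <- which(hit)
    if (length(drawn) < nTarget)
      stop("simulation yielded ", length(drawn), " < nTarget = ", nTarget,
           "; use a larger fixture or smaller nTarget")
    drawn <- sort(sample(drawn, nTarget))
    cand <- cand[drawn, , drop = FALSE]
  })
  ord <- order(cand$chrom, cand$pos, cand$alt)
  cand <- cand[ord, , drop = FALSE]
  variantSet(cand$chrom, cand$pos, cand$ref, cand$alt)
}

#' Randomly trim a simulated set to match the derived count
#'
#' @param simulated a \linkS4class{VariantSet}
#' @param nDerived target size
#' @param seed integer seed
#' @return uniform random subset of size \code{nDerived}, in genomic order
#' @export
trimToMatch <- function(simulated, nDerived, seed) {
  n <- length(simulated)
  if (n < nDerived)
    stop("only ", n, " simulated variants but ", nDerived,
         " derived; rerun the simulation with a larger nTarget")
  keep <- with_seed(seed, sort(sample(seq_len(n), nDerived)))
  simulated[keep]
}

#' Merge derived and simulated variants into a labeled training set
#'
#' Derived variants get label 1, simulated variants label 0. The two
#' classes must be disjoint on (chrom, pos, alt).
#'
#' @param derived,simulated \linkS4class{VariantSet}s
#' @return a \linkS4class{LabeledVariantSet}
#' @export
buildLabeledSet <- function(derived, simulated) {
  kd <- paste(variantChrom(derived), variantPos(derived), variantAlt(derived))
  ks <- paste(variantChrom(simulated), variantPos(simulated),
              variantAlt(simulated))
  overlap <- intersect(kd, ks)
  if (length(overlap) > 0L)
    stop("classes overlap on (chrom,pos,alt): ",
         paste(head(overlap, 5), collapse = "; "),
         if (length(overlap) > 5) " ...")
  labeledVariantSet(
    chrom = c(variantChrom(derived), variantChrom(simulated)),
    pos = c(variantPos(derived), variantPos(simulated)),
    ref = c(variantRef(derived), variantRef(simulated)),
    alt = c(variantAlt(derived), variantAlt(simulated)),
    label = c(rep(1L, length(derived)), rep(0L, length(simulated))))
}

#' Per-chromosome class counts of a labeled set
#'
#' @param x a \linkS4class{LabeledVariantSet}
#' @return data.frame with columns chrom, derived, simulated
#' @export
classCounts <- function(x) {
  df <- as.data.frame(x)
  chroms <- sort(unique(df$chrom))
  data.frame(
    chrom = chroms,
    derived = vapply(chroms, function(ch)
      sum(df$chrom == ch & df$label == 1L), integer(1)),
    simulated = vapply(chroms, function(ch)
      sum(df$chrom == ch & df$label == 0L), integer(1)),
    row.names = NULL)
}
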