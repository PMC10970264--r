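#' One-vs-rest Weir-Cockerham F_ST at a single locus
#'
#' Computes the Weir & Cockerham (1984) ratio-of-averages F_ST estimate
#' for two populations: the focal group versus all remaining samples
#' pooled. Chloroplast calls are haploid and effectively homozygous, so
#' each sample enters as a homozygous pseudo-diploid and every
#' heterozygosity term vanishes; this mirrors the estimator used by
#' common VCF tooling on such data. Multi-allelic loci are collapsed to
#' focal-group allele versus pooled others before estimation. A fixed
#' difference returns exactly 1; equal allele frequencies return a value
#' <= 0. Negative estimates are reported as computed, never clamped.
#'
#' @param calls Character vector of allele calls per sample (\code{NA} =
#'   missing), or a \linkS4class{VariantLocus} (with \code{groups} taken
#'   from \code{samples}).
#' @param groups Group label per sample.
#' @param focal The focal group label.
#' @return The F_ST estimate (may be negative); \code{NA} with a warning
#'   if the locus is monomorphic across the non-missing samples.
#' @export
fstOneVsRest <- function(calls, groups, focal) {
  if (is(calls, "VariantLocus")) calls <- allelesAt(calls)
  if (length(calls) != length(groups))
    stopf("calls and groups differ in length")
  if (!focal %in% groups) stopf("focal group '%s' has no samples", focal)
  keep <- !is.na(calls)
  x <- calls[keep]; g <- groups[keep]
  inFocal <- g == focal
  n1 <- sum(inFocal); n2 <- sum(!inFocal)
  if (n1 < 2L || n2 < 2L)
    stopf("insufficient data: need >= 2 non-missing samples in the focal group (%d) and the rest (%d)",
          n1, n2)
  if (length(unique(x)) < 2L) {
    warning("monomorphic locus: F_ST undefined")
    return(NA_real_)
  }
  ## collapse: focal-group majority allele vs pooled others
  focalAllele <- orderedAlleles(x[inFocal])[1L]
  p1 <- mean(x[inFocal] == focalAllele)
  p2 <- mean(x[!inFocal] == focalAllele)
  wcFstTwoPop(n1, p1, n2, p2)
}

## WC84 variance components for two populations of homozygous
## pseudo-diploids (observed heterozygosity 0, r = 2):
##   a = (nbar/nc) * [ s2 - (pbar*qbar - s2/2) / (nbar - 1) ]
##   b = (nbar/(nbar-1)) * (pbar*qbar - s2/2) ,  c = 0
## and F_ST = a / (a + b).
wcFstTwoPop <- function(n1, p1, n2, p2) {
  ## a fixed difference gives b = 0 analytically; return the exact value
  ## rather than its floating-point image
  if ((p1 == 1 && p2 == 0) || (p1 == 0 && p2 == 1)) return(1)
  nt <- n1 + n2
  nbar <- nt / 2
  nc <- nt - (n1^2 + n2^2) / nt
  pbar <- (n1 * p1 + n2 * p2) / nt
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / nbar
  inner <- pbar * (1 - pbar) - s2 / 2
  a <- (nbar / nc) * (s2 - inner / (nbar - 1))
  b <- (nbar / (nbar - 1)) * inner
  if (a + b == 0) return(NA_real_)
  a / (a + b)
}

#' Allele call per sample at one locus
#'
#' @param locus A \linkS4class{VariantLocus}.
#' @return Character vector of allele strings (\code{""} = deletion,
#'   \code{NA} = missing), one per sample.
#' @export
allelesAt <- function(locus) {
  out <- locus@alleles[locus@genotypes]
  out[is.na(locus@genotypes)] <- NA_character_
  out
}

#' Assign group specificity to loci at an F_ST threshold
#'
#' For every locus, computes the one-vs-rest F_ST against every group
#' and assigns the locus a specific type iff exactly one group's value
#' exceeds the threshold (values above 0.9 being taken as indicative of
#' group correlation); a locus exceeding the threshold for several
#' groups, or for none, is assigned none. The allele at elevated
#' frequency in the assigned group is recorded as the group allele.
#'
#' @param loci List of \linkS4class{VariantLocus}.
#' @param samples Sample sheet (or \linkS4class{PlastomeAlignment});
#'   every sample must carry a group label.
#' @param threshold F_ST threshold (default 0.9).
#' @param groups Group labels to scan (default: those present).
#' @return A \linkS4class{SpecificityResults}.
#' @export
assignSpecificity <- function(loci, samples, threshold = 0.9,
                              groups = NULL) {
  if (is(samples, "PlastomeAlignment")) samples <- sampleSheet(samples)
  glab <- samples$group
  if (any(is.na(glab) | glab == "unknown"))
    stopf("ungrouped sample(s): %s",
          paste(samples$sample_id[is.na(glab) | glab == "unknown"],
                collapse = ", "))
  groups <- groups %||% sort(unique(glab))
  ids <- vapply(loci, slot, character(1L), "id")
  fst <- matrix(NA_real_, length(loci), length(groups),
                dimnames = list(ids, groups))
  alleleMat <- matrix(NA_character_, length(groups), length(loci),
                      dimnames = list(groups, ids))
  assigned <- rep(NA_character_, length(loci))
  groupAllele <- rep(NA_character_, length(loci))
  for (i in seq_along(loci)) {
    calls <- allelesAt(loci[[i]])
    for (j in seq_along(groups)) {
      alleleMat[j, i] <- majorityAllele(calls[glab == groups[j]])
      fst[i, j] <- suppressWarnings(fstOneVsRest(calls, glab, groups[j]))
    }
    hits <- which(!is.na(fst[i, ]) & fst[i, ] > threshold)
    if (length(hits) == 1L) {
      assigned[i] <- groups[hits]
      groupAllele[i] <- alleleMat[hits, i]
    }
  }
  new("SpecificityResults", lociIds = ids, groups = groups, fst = fst,
      assigned = assigned, groupAllele = groupAllele,
      alleleMatrix = alleleMat, threshold = threshold)
}

majorityAllele <- function(calls) {
  obs <- calls[!is.na(calls)]
  if (!length(obs)) return(NA_character_)
  orderedAlleles(obs)[1L]
}

#' Build specificity results from a published marker table
#'
#' Reconstructs the groups x loci signature allele matrix from a marker
#' table's \code{specific_type} / \code{corresponding_allele} columns:
#' the assigned group carries the corresponding allele and every other
#' group carries the alternative allele of the FAM/HEX pair. The InDel
#' shorthand \code{I}/\code{D} (insertion/deletion) resolves to the
#' longer/shorter allele. F_ST values are not recomputable from a table
#' and stay \code{NA}; panel selection then breaks ties lexicographically.
#'
#' @param markers Marker-table data.frame
#'   (\code{\link{readMarkerTable}}).
#' @param groups Group labels (default the five chloroplast groups).
#' @param threshold Threshold recorded on the result (annotation only).
#' @return A \linkS4class{SpecificityResults} over the specific rows of
#'   the table (rows with no specific type keep assignment \code{NA}).
#' @export
specificityFromMarkerTable <- function(markers, groups = GROUP_LEVELS,
                                       threshold = 0.9) {
  n <- nrow(markers)
  ids <- markers$locus_id
  alleleMat <- matrix(NA_character_, length(groups), n,
                      dimnames = list(groups, ids))
  assigned <- markers$specific_type
  groupAllele <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    fam <- markers$allele_fam[i]; hex <- markers$allele_hex[i]
    corr <- markers$corresponding_allele[i]
    if (is.na(assigned[i])) next
    ga <- if (is.na(corr)) NA_character_
    else if (corr == "I") c(fam, hex)[which.max(nchar(c(fam, hex)))]
    else if (corr == "D") c(fam, hex)[which.min(nchar(c(fam, hex)))]
    else corr
    other <- setdiff(c(fam, hex), ga)[1L]
    alleleMat[, i] <- other
    alleleMat[assigned[i], i] <- ga
    groupAllele[i] <- ga
  }
  new("SpecificityResults", lociIds = ids, groups = groups,
      fst = matrix(NA_real_, n, length(groups),
                   dimnames = list(ids, groups)),
      assigned = assigned, groupAllele = groupAllele,
      alleleMatrix = alleleMat, threshold = threshold)
}
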