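#' Call SNP loci from a plastome alignment
#'
#' Scans alignment columns (the column scan is equivalent to exhaustive
#' pairwise comparison on aligned data). A column yields a SNP locus iff
#' it contains no gap and at least two distinct non-N bases; \code{N} is
#' missing data and never creates an allele, so a column polymorphic only
#' because of \code{N} is not a locus. Columns containing any gap belong
#' to InDel events and are excluded (see \code{\link{callIndels}}).
#'
#' @param aln A \linkS4class{PlastomeAlignment}.
#' @return List of \linkS4class{VariantLocus} (possibly empty), in
#'   column order, ids \code{CPMSNP01}, \code{CPMSNP02}, ...
#' @export
callSNPs <- function(aln) {
  m <- if (is.matrix(aln)) aln else alignmentMatrix(aln)
  gapCol <- colSums(m == "-") > 0L
  present <- vapply(c("A", "C", "G", "T"),
                    function(b) colSums(m == b) > 0L,
                    logical(ncol(m)))
  poly <- rowSums(present) >= 2L & !gapCol
  cols <- which(poly)
  lapply(seq_along(cols), function(i) {
    cc <- m[, cols[i]]
    calls <- ifelse(cc == "N", NA_character_, cc)
    alleles <- orderedAlleles(calls[!is.na(calls)])
    VariantLocus(sprintf("CPMSNP%02d", i), "SNP", cols[i], cols[i],
                 alleles, match(calls, alleles))
  })
}

#' Call InDel loci from a plastome alignment, merging gap columns into
#' events
#'
#' Maximal runs of adjacent gap-containing columns whose per-sample gap
#' pattern is identical are emitted as one InDel locus; a change in the
#' gap pattern splits the run (two overlapping but different-sample gap
#' runs stay separate loci). Alleles are the gap-stripped subsequences;
#' a deletion allele is the empty string. A sample with \code{N} inside
#' the event is missing at that locus.
#'
#' @inheritParams callSNPs
#' @return List of \linkS4class{VariantLocus}, ids \code{CPMIDP01}, ...
#' @export
callIndels <- function(aln) {
  m <- if (is.matrix(aln)) aln else alignmentMatrix(aln)
  gapCol <- which(colSums(m == "-") > 0L)
  if (!length(gapCol)) return(list())
  pattern <- vapply(gapCol, function(j) paste(m[, j] == "-", collapse = ""),
                    character(1L))
  newRun <- c(TRUE, diff(gapCol) != 1L | pattern[-1L] != pattern[-length(gapCol)])
  runId <- cumsum(newRun)
  loci <- list()
  for (r in unique(runId)) {
    colsR <- gapCol[runId == r]
    sub <- m[, colsR, drop = FALSE]
    alleleStr <- apply(sub, 1L, function(x) paste(x[x != "-"], collapse = ""))
    missing <- grepl("N", alleleStr, fixed = TRUE)
    calls <- ifelse(missing, NA_character_, alleleStr)
    obs <- calls[!is.na(calls)]
    if (length(unique(obs)) < 2L) next
    alleles <- orderedAlleles(obs)
    loci[[length(loci) + 1L]] <-
      list(cols = colsR, alleles = alleles, genotypes = match(calls, alleles))
  }
  lapply(seq_along(loci), function(i) {
    lc <- loci[[i]]
    VariantLocus(sprintf("CPMIDP%02d", i), "InDel", min(lc$cols),
                 max(lc$cols), lc$alleles, lc$genotypes)
  })
}

#' Call all variant loci (SNPs + merged InDel events)
#'
#' Convenience wrapper: \code{\link{callSNPs}} plus
#' \code{\link{callIndels}}, with flanks extracted and (optionally)
#' annotation attached. No alignment column contributes to more than one
#' locus.
#'
#' @inheritParams callSNPs
#' @param map Optional gene map for annotation.
#' @param flankWidth Flank width in bp (default 60).
#' @param refSample Reference sample (index or id) for the ungapped
#'   coordinate frame.
#' @return List of \linkS4class{VariantLocus} sorted by start column.
#' @export
callVariants <- function(aln, map = NULL, flankWidth = 60L, refSample = 1L) {
  m <- alignmentMatrix(aln)   # materialized once and shared by all steps
  loci <- c(callSNPs(m), callIndels(m))
  loci <- loci[order(vapply(loci, slot, integer(1L), "start"))]
  loci <- addFlanks(loci, m, flankWidth)
  if (!is.null(map)) loci <- annotateVariants(loci, map, m, refSample)
  loci
}

#' Annotate variant loci against a gene map
#'
#' Maps each locus into the ungapped coordinate frame of the designated
#' reference sample and intersects it with the gene map: a locus is genic
#' iff its reference-frame interval intersects any gene interval,
#' otherwise intergenic with the bracketing gene pair recorded. If the
#' reference sample is gapped across the entire locus, the locus is
#' annotated at the nearest reference coordinate with a warning.
#'
#' @param loci List of \linkS4class{VariantLocus}.
#' @param map Gene map \code{GRanges}.
#' @param aln The alignment the loci were called on.
#' @param refSample Reference sample index or id (default first sample,
#'   the package-wide convention).
#' @return The loci with \code{annotation}, \code{genes},
#'   \code{refStart}, \code{refEnd} filled in.
#' @export
annotateVariants <- function(loci, map, aln, refSample = 1L) {
  m <- if (is.matrix(aln)) aln else alignmentMatrix(aln)
  if (is.character(refSample)) refSample <- match(refSample, rownames(m))
  refRow <- m[refSample, ]
  notGap <- refRow != "-"
  cum <- cumsum(notGap)
  gst <- GenomicRanges::start(map); gen <- GenomicRanges::end(map)
  lapply(loci, function(lc) {
    span <- lc@start:lc@end
    if (!any(notGap[span])) {
      warning(sprintf("locus %s falls in a reference gap; annotated at the nearest reference coordinate",
                      lc@id))
      rs <- max(cum[lc@start], 1L); re <- rs
    } else {
      rs <- cum[span][which(notGap[span])[1L]]
      re <- cum[lc@end]
    }
    hit <- which(gst <= re & gen >= rs)
    if (length(hit)) {
      lc@annotation <- "genic"
      lc@genes <- unique(map$gene[hit])
    } else {
      lc@annotation <- "intergenic"
      before <- which(gen < rs); after <- which(gst > re)
      lc@genes <- c(if (length(before)) map$gene[before[which.max(gen[before])]]
                    else NA_character_,
                    if (length(after)) map$gene[after[which.min(gst[after])]]
                    else NA_character_)
    }
    lc@refStart <- as.integer(rs); lc@refEnd <- as.integer(re)
    lc
  })
}

#' Extract and vet the conserved flanks of a locus
#'
#' Takes \code{width} alignment columns on each side of the locus.
#' \code{flanksConserved} is \code{TRUE} iff both flanks are identical
#' across all samples and contain no gap and no \code{N} - the
#' eligibility condition for KASP primer design. A locus closer than
#' \code{width} to an alignment edge gets a truncated flank and is
#' flagged (\code{flanksTruncated}).
#'
#' @param locus A \linkS4class{VariantLocus}.
#' @param aln The alignment.
#' @param width Flank width in bp (>= 1).
#' @return The locus with flank slots filled.
#' @export
extractFlanks <- function(locus, aln, width = 60L) {
  stopifnot(width >= 1L)
  m <- if (is.matrix(aln)) aln else alignmentMatrix(aln)
  n <- ncol(m)
  lcols <- seq(max(1L, locus@start - width), locus@start - 1L)
  rcols <- seq(locus@end + 1L, min(n, locus@end + width))
  if (locus@start == 1L) lcols <- integer(0L)
  if (locus@end == n) rcols <- integer(0L)
  truncated <- length(lcols) < width || length(rcols) < width
  conservedBlock <- function(cols) {
    if (!length(cols)) return(list(seq = "", ok = FALSE))
    sub <- m[, cols, drop = FALSE]
    same <- all(sub == rep(sub[1L, ], each = nrow(sub)))
    clean <- same && !any(sub[1L, ] %in% c("-", "N"))
    list(seq = paste(sub[1L, ], collapse = ""), ok = clean)
  }
  lf <- conservedBlock(lcols); rf <- conservedBlock(rcols)
  locus@flankLeft <- lf$seq
  locus@flankRight <- rf$seq
  locus@flanksConserved <- lf$ok && rf$ok && !truncated
  locus@flanksTruncated <- truncated
  locus
}

#' @rdname extractFlanks
#' @param loci List of loci.
#' @export
addFlanks <- function(loci, aln, width = 60L) {
  lapply(loci, extractFlanks, aln = aln, width = width)
}

#' Variant inventory and density
#'
#' Tabulates loci by kind and annotation and computes the variant
#' density as genome length divided by locus count (bp per variant).
#'
#' @param loci List of \linkS4class{VariantLocus}.
#' @param genomeLength Ungapped genome length in bp used as the density
#'   denominator.
#' @return A list: \code{counts} (by kind), \code{annotation} (kind x
#'   genic/intergenic table), \code{n}, \code{density} (bp per variant).
#' @export
variantInventory <- function(loci, genomeLength) {
  kinds <- vapply(loci, slot, character(1L), "kind")
  anns <- vapply(loci, slot, character(1L), "annotation")
  list(n = length(loci),
       counts = table(factor(kinds, levels = c("SNP", "InDel"))),
       annotation = table(factor(kinds, levels = c("SNP", "InDel")),
                          factor(anns, levels = c("genic", "intergenic"))),
       density = variantDensity(length(loci), genomeLength))
}

#' @rdname variantInventory
#' @param nLoci Locus count (>= 1).
#' @export
variantDensity <- function(nLoci, genomeLength) {
  if (nLoci < 1L)
    stopf("variant density is undefined for zero loci")
  genomeLength / nLoci
}
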