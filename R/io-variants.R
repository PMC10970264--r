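#' Write called variants as minimal VCF 4.2 plus a flat TSV mirror
#'
#' Emits (a) a minimal VCF 4.2 (CHROM/POS/ID/REF/ALT and one haploid GT
#' column per sample) and (b) a flat TSV with the same content in
#' spreadsheet-friendly form. Alignment columns are converted to 1-based
#' positions on the ungapped reference sample; InDels are left-anchored
#' with one reference base, per VCF convention.
#'
#' @param loci List of \linkS4class{VariantLocus}.
#' @param aln The \linkS4class{PlastomeAlignment} the loci were called on.
#' @param vcf,tsv Output paths (either may be \code{NULL} to skip).
#' @param refSample Index or sample id of the reference sample defining
#'   the ungapped coordinate frame (default: first sample).
#' @param contig Contig name written to the VCF.
#' @return Invisibly, the written paths.
#' @export
writeVariants <- function(loci, aln, vcf = NULL, tsv = NULL,
                          refSample = 1L, contig = "plastome") {
  mat <- alignmentMatrix(aln)
  if (is.character(refSample)) refSample <- match(refSample, rownames(mat))
  refRow <- mat[refSample, ]
  notGap <- refRow != "-"
  cum <- cumsum(notGap)
  rows <- lapply(loci, function(lc) vcfRecord(lc, refRow, notGap, cum))
  ids <- rownames(mat)

  if (!is.null(vcf)) {
    hdr <- c("##fileformat=VCFv4.2",
             "##source=chloroPanel",
             sprintf("##contig=<ID=%s,length=%d>", contig, sum(notGap)),
             "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Haploid genotype\">",
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", ids), collapse = "\t"))
    body <- vapply(seq_along(loci), function(i) {
      r <- rows[[i]]; lc <- loci[[i]]
      vcfAll <- c(r$ref, r$alts)
      gt <- ifelse(is.na(lc@genotypes), ".",
                   match(lc@alleles[lc@genotypes], r$order) - 1L)
      paste(c(contig, r$pos, lc@id, r$refField, paste(r$altFields,
                                                      collapse = ","),
              ".", "PASS", ".", "GT", gt), collapse = "\t")
    }, character(1L))
    ord <- order(vapply(rows, `[[`, numeric(1L), "pos"))
    writeLines(c(hdr, body[ord]), vcf)
  }

  if (!is.null(tsv)) {
    fixed <- data.frame(
      locus_id = vapply(loci, slot, character(1L), "id"),
      kind = vapply(loci, slot, character(1L), "kind"),
      aln_start = vapply(loci, slot, integer(1L), "start"),
      aln_end = vapply(loci, slot, integer(1L), "end"),
      pos = vapply(rows, function(r) r$pos, numeric(1L)),
      ref = vapply(rows, function(r) sentinel(r$ref), character(1L)),
      alt = vapply(rows, function(r)
        paste(vapply(r$alts, sentinel, character(1L)), collapse = ","),
        character(1L)),
      annotation = vapply(loci, slot, character(1L), "annotation"),
      genes = vapply(loci, function(lc)
        paste(lc@genes, collapse = ";"), character(1L)),
      flanks_conserved = vapply(loci, slot, logical(1L), "flanksConserved"),
      stringsAsFactors = FALSE)
    gts <- t(vapply(loci, function(lc)
      ifelse(is.na(lc@genotypes), ".", vapply(lc@alleles[lc@genotypes],
                                              sentinel, character(1L))),
      character(nrow(mat))))
    if (!length(loci))
      gts <- matrix(character(0L), ncol = nrow(mat))
    colnames(gts) <- ids
    utils::write.table(cbind(fixed, gts), tsv, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(c(vcf = vcf, tsv = tsv))
}

sentinel <- function(x) ifelse(nzchar(x), x, "-")

## One VCF record: reference-frame position, left-anchored REF/ALT fields.
vcfRecord <- function(lc, refRow, notGap, cum) {
  refAllele <- NA_character_
  refChars <- refRow[lc@start:lc@end]
  if (!any(refChars == "N")) refAllele <- paste(refChars[refChars != "-"],
                                                collapse = "")
  if (is.na(refAllele))
    stopf("unresolvable reference allele at locus %s (N in reference sample)",
          lc@id)
  alts <- setdiff(lc@alleles, refAllele)
  if (lc@kind == "SNP") {
    return(list(pos = cum[lc@start], ref = refAllele, alts = alts,
                refField = refAllele, altFields = alts,
                order = c(refAllele, alts)))
  }
  ## InDel: anchor on the last reference base before the event
  anchorCol <- max(which(notGap[seq_len(lc@start - 1L)]), -Inf)
  if (!is.finite(anchorCol)) {
    nxt <- which(notGap)[which(notGap) > lc@end][1L]
    if (is.na(nxt))
      stopf("cannot left- or right-anchor locus %s", lc@id)
    anchor <- refRow[nxt]
    return(list(pos = cum[lc@end] + 1L, ref = refAllele, alts = alts,
                refField = paste0(refAllele, anchor),
                altFields = paste0(alts, anchor),
                order = c(refAllele, alts)))
  }
  anchor <- refRow[anchorCol]
  list(pos = cum[anchorCol], ref = refAllele, alts = alts,
       refField = paste0(anchor, refAllele),
       altFields = paste0(anchor, alts),
       order = c(refAllele, alts))
}

#' Read back the flat TSV mirror written by \code{\link{writeVariants}}
#'
#' @param path TSV path.
#' @return The table as a data.frame (all columns character except the
#'   coordinates), exactly as written.
#' @export
readVariantTable <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                    colClasses = "character")
}
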