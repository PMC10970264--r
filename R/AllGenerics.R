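#' Accessor generics
#'
#' Small accessor layer so user code never touches slots directly.
#'
#' @param x An object of the relevant class.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("sampleSheet", function(x) standardGeneric("sampleSheet"))
#' @rdname accessors
#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))
#' @rdname accessors
#' @export
setGeneric("alignmentWidth", function(x) standardGeneric("alignmentWidth"))
#' @rdname accessors
#' @export
setGeneric("alignmentMatrix", function(x) standardGeneric("alignmentMatrix"))
#' @rdname accessors
#' @export
setGeneric("lociIds", function(x) standardGeneric("lociIds"))
#' @rdname accessors
#' @export
setGeneric("signatureMatrix", function(x) standardGeneric("signatureMatrix"))
#' @rdname accessors
#' @export
setGeneric("fstMatrix", function(x) standardGeneric("fstMatrix"))
#' @rdname accessors
#' @export
setGeneric("assignedGroups", function(x) standardGeneric("assignedGroups"))
#' @rdname accessors
#' @export
setGeneric("groupAlleles", function(x) standardGeneric("groupAlleles"))
#' @rdname accessors
#' @export
setGeneric("truthLoci", function(x) standardGeneric("truthLoci"))
#' @rdname accessors
#' @export
setGeneric("truthSamples", function(x) standardGeneric("truthSamples"))

#' @rdname accessors
#' @export
setMethod("sampleSheet", "PlastomeAlignment", function(x) x@samples)
#' @rdname accessors
#' @export
setMethod("nSamples", "PlastomeAlignment", function(x) length(x@seqs))
#' @rdname accessors
#' @export
setMethod("alignmentWidth", "PlastomeAlignment",
          function(x) Biostrings::width(x@seqs)[1L])
#' @rdname accessors
#' @export
setMethod("alignmentMatrix", "PlastomeAlignment", function(x) {
  m <- as.matrix(x@seqs)
  rownames(m) <- names(x@seqs)
  m
})

#' @rdname accessors
#' @export
setMethod("lociIds", "SpecificityResults", function(x) x@lociIds)
#' @rdname accessors
#' @export
setMethod("lociIds", "Panel", function(x) x@lociIds)
#' @rdname accessors
#' @export
setMethod("signatureMatrix", "Panel", function(x) x@signature)
#' @rdname accessors
#' @export
setMethod("fstMatrix", "SpecificityResults", function(x) x@fst)
#' @rdname accessors
#' @export
setMethod("assignedGroups", "SpecificityResults",
          function(x) setNames(x@assigned, x@lociIds))
#' @rdname accessors
#' @export
setMethod("groupAlleles", "SpecificityResults",
          function(x) setNames(x@groupAllele, x@lociIds))
#' @rdname accessors
#' @export
setMethod("truthLoci", "TruthSet", function(x) x@loci)
#' @rdname accessors
#' @export
setMethod("truthSamples", "TruthSet", function(x) x@samples)

setMethod("show", "PlastomeAlignment", function(object) {
  cat(sprintf("PlastomeAlignment: %d samples x %d columns\n",
              nSamples(object), alignmentWidth(object)))
  tab <- table(object@samples$group)
  cat("  groups:", paste(sprintf("%s=%d", names(tab), tab), collapse = " "),
      "\n")
  roles <- table(object@samples$role)
  cat("  roles: ", paste(sprintf("%s=%d", names(roles), roles),
                         collapse = " "), "\n")
})

setMethod("show", "VariantLocus", function(object) {
  al <- ifelse(nzchar(object@alleles), object@alleles, "<del>")
  cat(sprintf("VariantLocus %s [%s] cols %d-%d alleles %s\n",
              object@id, object@kind, object@start, object@end,
              paste(al, collapse = "/")))
})

setMethod("show", "SpecificityResults", function(object) {
  n <- length(object@lociIds)
  assigned <- sum(!is.na(object@assigned))
  cat(sprintf("SpecificityResults: %d loci x %d groups (threshold %.2f)\n",
              n, length(object@groups), object@threshold))
  cat(sprintf("  specific: %d; unassigned: %d\n", assigned, n - assigned))
  if (assigned) {
    tab <- table(factor(object@assigned, levels = object@groups))
    cat("  by group:", paste(sprintf("%s=%d", names(tab), tab),
                             collapse = " "), "\n")
  }
})

setMethod("show", "Panel", function(object) {
  cat(sprintf("Panel (%s): %d loci over %d groups\n", object@policy,
              length(object@lociIds), nrow(object@signature)))
  sig <- object@signature
  sig[sig == ""] <- "<del>"
  print(sig, quote = FALSE)
})

setMethod("show", "GenomeSummary", function(object) {
  cat("GenomeSummary\n")
  cat(sprintf("  total %d bp (LSC %d / IR %d / SSC %d); GC %.2f%%\n",
              object@totalLength, object@lscLength, object@irLength,
              object@sscLength, 100 * object@gcFraction))
  gc <- object@geneCounts
  cat(sprintf("  genes: %d (%d protein-coding, %d tRNA, %d rRNA)\n",
              gc[["total"]], gc[["protein_coding"]], gc[["tRNA"]],
              gc[["rRNA"]]))
})

setMethod("show", "KaspMarker", function(object) {
  cat(sprintf("KaspMarker %s (%s, %s)\n", object@markerId, object@locusId,
              object@orientation))
  fam <- ifelse(nzchar(object@alleleFam), object@alleleFam, "<del>")
  hex <- ifelse(nzchar(object@alleleHex), object@alleleHex, "<del>")
  cat(sprintf("  FAM allele %s: %s (Tm %.1f)\n", fam, object@primerFam,
              object@tm[["fam"]]))
  cat(sprintf("  HEX allele %s: %s (Tm %.1f)\n", hex, object@primerHex,
              object@tm[["hex"]]))
  if (nzchar(object@primerCommon))
    cat(sprintf("  common: %s (Tm %.1f)\n", object@primerCommon,
                object@tm[["common"]]))
  else
    cat("  common: <two-flank layout, no common primer>\n")
})

setMethod("show", "TruthSet", function(object) {
  cat(sprintf("TruthSet: %d planted loci, %d samples\n",
              nrow(object@loci), nrow(object@samples)))
  tab <- table(object@loci$class)
  cat("  loci:", paste(sprintf("%s=%d", names(tab), tab), collapse = " "),
      "\n")
})

setMethod("show", "SimulationConfig", function(object) {
  cat(sprintf("SimulationConfig: seed %d, %d bp (LSC/IR/SSC %s), %d groups x %d samples\n",
              object@seed, object@genomeLength,
              paste(object@regionLengths, collapse = "/"),
              length(object@groups), object@samplesPerGroup))
  cat(sprintf("  planted: %d diagnostic SNP/group, %d shared SNP, %d InDel (%d diagnostic), %d singletons\n",
              object@nDiagnosticPerGroup, object@nSharedSnps,
              object@nIndels, object@nDiagnosticIndels, object@nRareAlleles))
  cat(sprintf("  %d crosses; flank width %d bp\n", nrow(object@trios),
              object@flankWidth))
})
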