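#' @import methods
#' @importFrom Biostrings DNAStringSet DNAString reverseComplement width
#'   alphabetFrequency readDNAStringSet writeXStringSet
#' @importFrom S4Vectors mcols mcols<-
#' @importFrom stats setNames
#' @importFrom utils read.delim write.table combn head tail
NULL

ALN_ALPHABET <- c("A", "C", "G", "T", "N", "-")
GROUP_LEVELS <- c("B", "C", "D", "H", "T")
SAMPLE_ROLES <- c("cultivar", "wild", "parent", "hybrid", "outgroup")
FERTILITY_LEVELS <- c("fertile", "sterile", "unknown")
GENE_CATEGORIES <- c("protein_coding", "tRNA", "rRNA")
REGION_LEVELS <- c("LSC", "IRa", "IRb", "SSC")

## ---- PlastomeAlignment ------------------------------------------------

#' PlastomeAlignment: an aligned plastome panel with sample metadata
#'
#' Holds equal-length aligned haploid plastome sequences (alphabet
#' \code{A,C,G,T,N,-}) together with the per-sample metadata sheet
#' (group label, role, pedigree links, fertility status). The object is
#' the substrate for variant calling, specificity scanning and lineage
#' tracing.
#'
#' @slot seqs A \code{DNAStringSet} of equal-width aligned sequences,
#'   named by sample id.
#' @slot samples A \code{data.frame} with columns \code{sample_id},
#'   \code{group}, \code{role}, \code{mother_id}, \code{father_id},
#'   \code{fertility}; row order defines sample order.
#' @exportClass PlastomeAlignment
setClass("PlastomeAlignment",
         slots = c(seqs = "DNAStringSet", samples = "data.frame"))

validSampleSheet <- function(df) {
  req <- c("sample_id", "group", "role", "mother_id", "father_id", "fertility")
  missing_cols <- setdiff(req, colnames(df))
  if (length(missing_cols))
    return(sprintf("sample sheet lacks column(s): %s",
                   paste(missing_cols, collapse = ", ")))
  if (anyDuplicated(df$sample_id))
    return(sprintf("duplicated sample_id: %s",
                   paste(unique(df$sample_id[duplicated(df$sample_id)]),
                         collapse = ", ")))
  bad_grp <- !(df$group %in% c(GROUP_LEVELS, "unknown"))
  if (any(bad_grp))
    return(sprintf("unknown group label for sample(s): %s",
                   paste(df$sample_id[bad_grp], collapse = ", ")))
  bad_role <- !(df$role %in% SAMPLE_ROLES)
  if (any(bad_role))
    return(sprintf("invalid role for sample(s): %s",
                   paste(df$sample_id[bad_role], collapse = ", ")))
  bad_fert <- !(df$fertility %in% FERTILITY_LEVELS)
  if (any(bad_fert))
    return(sprintf("invalid fertility for sample(s): %s",
                   paste(df$sample_id[bad_fert], collapse = ", ")))
  for (col in c("mother_id", "father_id")) {
    ref <- df[[col]]
    set <- !is.na(ref) & nzchar(ref)
    if (any(set & !(ref %in% df$sample_id)))
      return(sprintf("%s refers to sample(s) absent from the sheet: %s",
                     col, paste(ref[set & !(ref %in% df$sample_id)],
                                collapse = ", ")))
  }
  hyb <- df$role == "hybrid"
  orphan <- hyb & (is.na(df$mother_id) | !nzchar(df$mother_id) |
                     is.na(df$father_id) | !nzchar(df$father_id))
  if (any(orphan))
    return(sprintf("hybrid sample(s) without both parent ids: %s",
                   paste(df$sample_id[orphan], collapse = ", ")))
  TRUE
}

setValidity("PlastomeAlignment", function(object) {
  s <- object@seqs
  if (length(s) < 2L)
    return("an alignment needs at least 2 samples")
  w <- Biostrings::width(s)
  if (length(unique(w)) != 1L) {
    off <- names(s)[w != w[1L]]
    return(sprintf("aligned sequences differ in length (offending sample(s): %s)",
                   paste(off, collapse = ", ")))
  }
  af <- Biostrings::alphabetFrequency(s)
  extra <- setdiff(colnames(af)[colSums(af) > 0L], ALN_ALPHABET)
  if (length(extra))
    return(sprintf("alignment contains letters outside {A,C,G,T,N,-}: %s",
                   paste(extra, collapse = ", ")))
  ok <- validSampleSheet(object@samples)
  if (!isTRUE(ok)) return(ok)
  if (length(s) != nrow(object@samples))
    return("number of sequences differs from number of sheet rows")
  if (!identical(names(s), object@samples$sample_id))
    return("sequence names do not match sample_id order in the sheet")
  TRUE
})

#' Construct a PlastomeAlignment
#'
#' @param seqs Named character vector or \code{DNAStringSet} of aligned
#'   sequences (upper-cased on construction).
#' @param samples Sample sheet \code{data.frame}; see
#'   \linkS4class{PlastomeAlignment}. Missing pedigree/fertility columns
#'   are filled with \code{NA}/\code{"unknown"}.
#' @return A validated \linkS4class{PlastomeAlignment}.
#' @export
PlastomeAlignment <- function(seqs, samples) {
  if (is.character(seqs)) seqs <- Biostrings::DNAStringSet(toupper(seqs))
  samples <- completeSampleSheet(samples)
  seqs <- seqs[match(samples$sample_id, names(seqs))]
  if (anyNA(names(seqs)))
    stop("sample sheet lists id(s) absent from the sequences: ",
         paste(samples$sample_id[is.na(names(seqs))], collapse = ", "))
  new("PlastomeAlignment", seqs = seqs, samples = samples)
}

completeSampleSheet <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  if (is.null(df$role)) df$role <- "cultivar"
  if (is.null(df$mother_id)) df$mother_id <- NA_character_
  if (is.null(df$father_id)) df$father_id <- NA_character_
  if (is.null(df$fertility)) df$fertility <- "unknown"
  for (col in c("mother_id", "father_id"))
    df[[col]][!is.na(df[[col]]) & df[[col]] == ""] <- NA_character_
  rownames(df) <- NULL
  df
}

## ---- VariantLocus -----------------------------------------------------

#' VariantLocus: one SNP or merged InDel event
#'
#' A single polymorphic locus in alignment coordinates (1-based, closed).
#' SNPs span one column; InDels span the maximal run of adjacent
#' gap-containing columns sharing one per-sample gap pattern. Deletion
#' alleles are encoded as the empty string, never as \code{"-"}.
#'
#' @slot id Locus identifier (e.g. \code{CPMSNP01}).
#' @slot kind \code{"SNP"} or \code{"InDel"}.
#' @slot start,end First and last alignment column of the event.
#' @slot alleles Character vector of distinct allele strings, ordered by
#'   decreasing count (ties alphabetical); \code{""} encodes deletion.
#' @slot genotypes Integer index into \code{alleles} per sample
#'   (\code{NA} = missing, i.e. \code{N} at the locus).
#' @slot annotation \code{"genic"}, \code{"intergenic"} or \code{NA}.
#' @slot genes Gene name (genic) or bracketing gene pair (intergenic).
#' @slot refStart,refEnd Locus interval in reference-frame (ungapped)
#'   coordinates of the designated reference sample.
#' @slot flankLeft,flankRight Flanking sequence of the configured width.
#' @slot flanksConserved \code{TRUE} iff both flanks are identical,
#'   gap-free and N-free across all samples.
#' @slot flanksTruncated \code{TRUE} if the locus sits closer than the
#'   flank width to an alignment edge.
#' @exportClass VariantLocus
setClass("VariantLocus",
         slots = c(id = "character", kind = "character",
                   start = "integer", end = "integer",
                   alleles = "character", genotypes = "integer",
                   annotation = "character", genes = "character",
                   refStart = "integer", refEnd = "integer",
                   flankLeft = "character", flankRight = "character",
                   flanksConserved = "logical", flanksTruncated = "logical"),
         prototype = list(annotation = NA_character_, genes = NA_character_,
                          refStart = NA_integer_, refEnd = NA_integer_,
                          flankLeft = NA_character_, flankRight = NA_character_,
                          flanksConserved = NA, flanksTruncated = NA))

setValidity("VariantLocus", function(object) {
  if (!object@kind %in% c("SNP", "InDel"))
    return("kind must be 'SNP' or 'InDel'")
  if (length(object@alleles) < 2L)
    return("a locus needs at least 2 distinct alleles")
  if (anyDuplicated(object@alleles))
    return("alleles must be distinct")
  if (object@start > object@end)
    return("start must be <= end")
  gt <- object@genotypes[!is.na(object@genotypes)]
  if (length(gt) && (min(gt) < 1L || max(gt) > length(object@alleles)))
    return("genotype indices out of allele range")
  if (object@kind == "SNP") {
    if (object@end != object@start)
      return("a SNP spans exactly one column")
    if (any(nchar(object@alleles) != 1L))
      return("SNP alleles must be single bases")
  } else {
    if (length(unique(nchar(object@alleles))) == 1L)
      return("InDel alleles must differ in length")
  }
  if (any(grepl("-", object@alleles, fixed = TRUE)))
    return("alleles must be gap-free ('' encodes deletion)")
  TRUE
})

#' @describeIn VariantLocus-class Constructor.
#' @param id,kind,start,end,alleles,genotypes See slots.
#' @param ... Optional further slots (annotation, flanks, ...).
#' @export
VariantLocus <- function(id, kind, start, end, alleles, genotypes, ...) {
  new("VariantLocus", id = as.character(id), kind = kind,
      start = as.integer(start), end = as.integer(end),
      alleles = as.character(alleles), genotypes = as.integer(genotypes), ...)
}

## ---- SpecificityResults -----------------------------------------------

#' SpecificityResults: per-locus one-vs-rest F_ST and group assignment
#'
#' One row per locus, one column per chloroplast group. A locus is
#' assigned a specific type iff exactly one group's one-vs-rest F_ST
#' exceeds the threshold; otherwise the assignment is \code{NA}
#' (printed \code{"/"} in the marker-table dialect).
#'
#' @slot lociIds Locus identifiers (row order of \code{fst}).
#' @slot groups Group labels (column order of \code{fst}).
#' @slot fst Numeric matrix loci x groups of one-vs-rest Weir-Cockerham
#'   F_ST estimates (\code{NA} when not computed, e.g. for a published
#'   marker table).
#' @slot assigned Assigned group per locus, \code{NA} for none.
#' @slot groupAllele Allele at elevated frequency in the assigned group.
#' @slot alleleMatrix Character matrix groups x loci of per-group
#'   majority alleles (the group signature source).
#' @slot threshold F_ST threshold used for assignment.
#' @exportClass SpecificityResults
setClass("SpecificityResults",
         slots = c(lociIds = "character", groups = "character",
                   fst = "matrix", assigned = "character",
                   groupAllele = "character", alleleMatrix = "matrix",
                   threshold = "numeric"))

setValidity("SpecificityResults", function(object) {
  n <- length(object@lociIds); g <- length(object@groups)
  if (!identical(dim(object@fst), c(n, g)))
    return("fst matrix dimensions do not match loci x groups")
  if (!identical(dim(object@alleleMatrix), c(g, n)))
    return("alleleMatrix dimensions do not match groups x loci")
  if (length(object@assigned) != n || length(object@groupAllele) != n)
    return("assigned/groupAllele length must equal number of loci")
  bad <- !is.na(object@assigned) & !(object@assigned %in% object@groups)
  if (any(bad)) return("assigned group not among groups")
  fin <- object@fst[is.finite(object@fst)]
  if (length(fin) && max(fin) > 1 + 1e-9)
    return("F_ST estimates cannot exceed 1")
  TRUE
})

## ---- Panel ------------------------------------------------------------

#' Panel: an ordered discriminating marker set with group signatures
#'
#' @slot lociIds Ordered locus identifiers.
#' @slot signature Character matrix groups x loci; entry = the allele
#'   expected in that group at that locus (\code{""} = deletion). All
#'   rows are pairwise distinct - a valid panel discriminates all its
#'   groups.
#' @slot columns Integer matrix loci x 2 (alignment start/end column;
#'   \code{NA} when the panel derives from a published table).
#' @slot kinds \code{"SNP"}/\code{"InDel"} per locus.
#' @slot policy Selection policy tag (\code{"one-per-group"},
#'   \code{"minimal"}, or \code{"manual"}).
#' @exportClass Panel
setClass("Panel",
         slots = c(lociIds = "character", signature = "matrix",
                   columns = "matrix", kinds = "character",
                   policy = "character"))

setValidity("Panel", function(object) {
  if (ncol(object@signature) != length(object@lociIds))
    return("signature columns must match loci")
  if (!is.null(colnames(object@signature)) &&
      !identical(colnames(object@signature), object@lociIds))
    return("signature colnames must equal lociIds")
  rows <- apply(object@signature, 1L, paste, collapse = "\r")
  if (anyDuplicated(rows)) {
    dup <- rownames(object@signature)[duplicated(rows) |
                                        duplicated(rows, fromLast = TRUE)]
    return(sprintf("panel does not discriminate group(s): %s",
                   paste(unique(dup), collapse = ", ")))
  }
  if (nrow(object@columns) != length(object@lociIds))
    return("columns rows must match loci")
  TRUE
})

Panel <- function(lociIds, signature, columns = NULL, kinds = NULL,
                  policy = "manual") {
  lociIds <- as.character(lociIds)
  if (is.null(columns))
    columns <- matrix(NA_integer_, nrow = length(lociIds), ncol = 2L,
                      dimnames = list(lociIds, c("start", "end")))
  if (is.null(kinds)) kinds <- rep(NA_character_, length(lociIds))
  colnames(signature) <- lociIds
  new("Panel", lociIds = lociIds, signature = signature,
      columns = columns, kinds = kinds, policy = policy)
}

## ---- GenomeSummary ----------------------------------------------------

#' GenomeSummary: quadripartite structure and gene-content summary
#'
#' @slot totalLength,lscLength,irLength,sscLength Region lengths in bp;
#'   \code{lsc + 2*ir + ssc == total} is enforced.
#' @slot gcFraction GC content over A/C/G/T calls only.
#' @slot geneCounts Named integer vector: total, protein_coding, tRNA,
#'   rRNA.
#' @slot regionGeneCounts Integer matrix region x category.
#' @exportClass GenomeSummary
setClass("GenomeSummary",
         slots = c(totalLength = "integer", lscLength = "integer",
                   irLength = "integer", sscLength = "integer",
                   gcFraction = "numeric", geneCounts = "integer",
                   regionGeneCounts = "matrix"))

setValidity("GenomeSummary", function(object) {
  if (object@lscLength + 2L * object@irLength + object@sscLength !=
      object@totalLength)
    return("LSC + 2*IR + SSC must equal the total genome length")
  if (!is.na(object@gcFraction) &&
      (object@gcFraction < 0 || object@gcFraction > 1))
    return("gc fraction must lie in [0, 1]")
  gc <- object@geneCounts
  if (length(gc) && !is.na(gc["total"]) &&
      gc["total"] != sum(gc[GENE_CATEGORIES]))
    return("gene category counts must sum to the total gene count")
  TRUE
})

## ---- SimulationConfig & TruthSet --------------------------------------

#' SimulationConfig: parameters of the synthetic plastome-panel generator
#'
#' See \code{\link{simulationConfig}} for defaults and semantics.
#'
#' @slot seed Integer master seed; fully determines all output.
#' @slot genomeLength,regionLengths Genome size (bp) and named vector
#'   \code{c(LSC=, IR=, SSC=)} with \code{LSC + 2*IR + SSC == genomeLength}.
#' @slot groups Group labels.
#' @slot samplesPerGroup Haploid samples simulated per group.
#' @slot nDiagnosticPerGroup Group-diagnostic (fixed-difference) SNPs per
#'   group.
#' @slot nSharedSnps Non-diagnostic SNPs segregating across group subsets.
#' @slot nIndels,indelLenRange,nDiagnosticIndels InDel events (contiguous
#'   alignment gap blocks), their length range, and how many of them are
#'   group-diagnostic.
#' @slot nRareAlleles Singleton (private-allele) SNPs.
#' @slot flankWidth Conserved flank width (bp) guaranteed around every
#'   planted locus.
#' @slot trios Data frame \code{mother_group}, \code{father_group},
#'   \code{type} (\code{trio}/\code{reciprocal}/\code{cms}).
#' @slot cmsGroups Groups whose cytoplasm is male-sterile.
#' @slot geneCounts Named vector of genes to plant per category.
#' @exportClass SimulationConfig
setClass("SimulationConfig",
         slots = c(seed = "integer", genomeLength = "integer",
                   regionLengths = "integer", groups = "character",
                   samplesPerGroup = "integer",
                   nDiagnosticPerGroup = "integer", nSharedSnps = "integer",
                   nIndels = "integer", indelLenRange = "integer",
                   nDiagnosticIndels = "integer", nRareAlleles = "integer",
                   flankWidth = "integer", trios = "data.frame",
                   cmsGroups = "character", geneCounts = "integer"))

setValidity("SimulationConfig", function(object) {
  rl <- object@regionLengths
  if (!identical(names(rl), c("LSC", "IR", "SSC")))
    return("regionLengths must be named c(LSC=, IR=, SSC=)")
  if (rl[["LSC"]] + 2L * rl[["IR"]] + rl[["SSC"]] != object@genomeLength)
    return("LSC + 2*IR + SSC must equal genomeLength")
  if (object@samplesPerGroup < 2L)
    return("need at least 2 samples per group")
  if (length(object@indelLenRange) != 2L ||
      object@indelLenRange[1L] < 1L ||
      object@indelLenRange[1L] > object@indelLenRange[2L])
    return("indelLenRange must be c(min, max) with 1 <= min <= max")
  if (object@nDiagnosticIndels > object@nIndels)
    return("nDiagnosticIndels cannot exceed nIndels")
  if (object@flankWidth < 1L) return("flankWidth must be >= 1")
  if (!all(object@cmsGroups %in% object@groups))
    return("cmsGroups must be a subset of groups")
  tr <- object@trios
  if (nrow(tr)) {
    if (!all(c("mother_group", "father_group", "type") %in% colnames(tr)))
      return("trios needs columns mother_group, father_group, type")
    if (!all(tr$mother_group %in% object@groups) ||
        !all(tr$father_group %in% object@groups))
      return("trio parent groups must be simulated groups")
    if (!all(tr$type %in% c("trio", "reciprocal", "cms")))
      return("trio type must be trio, reciprocal or cms")
  }
  TRUE
})

#' TruthSet: planted ground truth of a synthetic panel
#'
#' @slot loci Data frame: \code{locus_id}, \code{kind}, \code{start},
#'   \code{end} (alignment columns), \code{class}
#'   (diagnostic/shared/rare), \code{group} (diagnostic loci),
#'   \code{ref_allele}, \code{alt_allele}, \code{carriers}
#'   (semicolon-joined ids of alt-allele samples).
#' @slot samples Data frame: \code{sample_id}, \code{group}, \code{role},
#'   \code{mother_id}, \code{father_id}, \code{fertility} - the true
#'   group and maternal parent of every sample.
#' @exportClass TruthSet
setClass("TruthSet",
         slots = c(loci = "data.frame", samples = "data.frame"))

setValidity("TruthSet", function(object) {
  if (anyDuplicated(object@loci$locus_id))
    return("every planted locus must appear exactly once")
  TRUE
})

## ---- KaspMarker --------------------------------------------------------

#' KaspMarker: a designed KASP assay for one variant locus
#'
#' Two allele-specific primers (read on the FAM and HEX fluorescence
#' channels) whose 3'-terminal base discriminates the alleles, plus a
#' common reverse-orientation primer from the opposite flank. Orientation
#' \code{"forward"} means the allele primers read the given strand (3'
#' base = allele); \code{"reverse"} means they read the complement.
#'
#' @slot markerId,locusId Identifiers.
#' @slot alleleFam,alleleHex Allele strings (\code{""} = deletion).
#' @slot primerFam,primerHex,primerCommon Primer sequences (5'->3');
#'   \code{primerCommon} may be empty for large-insertion two-flank
#'   assays.
#' @slot flank1,flank2 Auxiliary flank records for the two-flank InDel
#'   layout (empty otherwise).
#' @slot orientation \code{"forward"} or \code{"reverse"}.
#' @slot tm Named numeric: estimated melting temperatures (deg C) of the
#'   three primers.
#' @exportClass KaspMarker
setClass("KaspMarker",
         slots = c(markerId = "character", locusId = "character",
                   alleleFam = "character", alleleHex = "character",
                   primerFam = "character", primerHex = "character",
                   primerCommon = "character", flank1 = "character",
                   flank2 = "character", orientation = "character",
                   tm = "numeric"))

setValidity("KaspMarker", function(object) {
  for (p in c(object@primerFam, object@primerHex)) {
    if (!nzchar(p)) return("allele primers must be non-empty")
    if (grepl("[^ACGT]", p)) return("primers must be over {A,C,G,T}")
  }
  if (nzchar(object@primerCommon) && grepl("[^ACGT]", object@primerCommon))
    return("primers must be over {A,C,G,T}")
  if (substring(object@primerFam, nchar(object@primerFam)) ==
      substring(object@primerHex, nchar(object@primerHex)) &&
      object@alleleFam != object@alleleHex)
    return("allele primers must differ at the 3'-terminal base")
  if (!object@orientation %in% c("forward", "reverse"))
    return("orientation must be forward or reverse")
  TRUE
})
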