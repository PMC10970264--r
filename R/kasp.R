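#' Design a KASP assay for a biallelic variant locus
#'
#' Constructs the two allele-specific primers and the common primer from
#' the locus's conserved flanks. Each allele primer is a suffix of
#' (left flank + allele) ending exactly at the first base that differs
#' between the two allele haplotypes (for a SNP, the variant base
#' itself), at the shortest length within \code{lenRange} whose
#' estimated Tm reaches \code{tmTarget}; the common primer is the
#' reverse complement of a prefix window of the right flank chosen the
#' same way. The design is computed on both strands: the reverse-strand
#' design (allele primers reading the complement, 3' bases =
#' complemented alleles) is returned when the forward strand cannot
#' reach the target Tm in range but the reverse can, or when the reverse
#' design's Tm balance |Tm_FAM - Tm_HEX| is strictly better. For an
#' insertion allele of 50 bp or more the assay switches to the
#' two-flank layout: no common primer, and the two flanks are recorded
#' alongside the allele primers.
#'
#' Flanks must be conserved across the panel (the marker-eligibility
#' criterion); loci with non-conserved flanks are refused.
#'
#' @param locus A \linkS4class{VariantLocus} with flanks attached (see
#'   \code{\link{extractFlanks}}), or \code{NULL} when \code{alleles}
#'   and flanks are given directly.
#' @param alleles Two allele strings (\code{""} = deletion); defaults to
#'   the locus alleles (first = FAM, second = HEX).
#' @param flankLeft,flankRight Conserved flanking sequences.
#' @param tmTarget Target melting temperature in deg C (default 58, the
#'   assay's annealing temperature).
#' @param lenRange Allowed primer length range in nt.
#' @param method Tm model for \code{\link{estimateTm}}.
#' @param markerId,locusId Identifiers (derived from the locus id when
#'   omitted).
#' @return A \linkS4class{KaspMarker}.
#' @export
designKasp <- function(locus = NULL, alleles = NULL, flankLeft = NULL,
                       flankRight = NULL, tmTarget = 58,
                       lenRange = c(18L, 35L), method = "nn",
                       markerId = NULL, locusId = NULL) {
  if (!is.null(locus)) {
    stopifnot(is(locus, "VariantLocus"))
    if (!isTRUE(locus@flanksConserved))
      stopf("locus %s: flanks are not conserved across the panel; design refused",
            locus@id)
    alleles <- alleles %||% locus@alleles[1:2]
    flankLeft <- flankLeft %||% locus@flankLeft
    flankRight <- flankRight %||% locus@flankRight
    locusId <- locusId %||% locus@id
  }
  if (length(alleles) != 2L || alleles[1L] == alleles[2L])
    stopf("design needs exactly two distinct alleles")
  if (any(grepl("[^ACGT]", c(alleles, flankLeft, flankRight))))
    stopf("alleles and flanks must be over {A,C,G,T}")
  if (min(nchar(flankLeft), nchar(flankRight)) < lenRange[1L])
    stopf("flanks shorter than the minimum primer length (%d nt)",
          lenRange[1L])
  locusId <- locusId %||% "LOCUS"
  markerId <- markerId %||% markerIdFor(locusId)

  fwd <- strandDesign(alleles, flankLeft, flankRight, tmTarget, lenRange,
                      method)
  rev <- strandDesign(revcomp(alleles), revcomp(flankRight),
                      revcomp(flankLeft), tmTarget, lenRange, method)
  orientation <- "forward"
  des <- fwd
  if (!fwd$ok && rev$ok) {
    orientation <- "reverse"; des <- rev
  } else if (fwd$ok && rev$ok && rev$balance < fwd$balance) {
    orientation <- "reverse"; des <- rev
  } else if (!fwd$ok && !rev$ok) {
    stopf("locus %s: target Tm %.1f unreachable within %d-%d nt on either strand",
          locusId, tmTarget, lenRange[1L], lenRange[2L])
  }

  twoFlank <- max(nchar(alleles)) >= 50L
  new("KaspMarker", markerId = markerId, locusId = locusId,
      alleleFam = alleles[1L], alleleHex = alleles[2L],
      primerFam = des$primers[1L], primerHex = des$primers[2L],
      primerCommon = if (twoFlank) "" else des$common,
      flank1 = if (twoFlank) flankLeft else "",
      flank2 = if (twoFlank) flankRight else "",
      orientation = orientation,
      tm = c(fam = des$tm[1L], hex = des$tm[2L],
             common = if (twoFlank) NA_real_ else des$commonTm))
}

## One-strand design: allele primers end at the first inter-haplotype
## difference; the common primer is revcomp of a right-flank prefix.
strandDesign <- function(alleles, flankLeft, flankRight, tmTarget, lenRange,
                         method) {
  if (is.null(flankLeft)) return(list(ok = FALSE))
  hap <- paste0(flankLeft, alleles, flankRight)
  d <- firstDifference(hap[1L], hap[2L])
  primers <- character(2L); tms <- numeric(2L); ok <- TRUE
  for (i in 1:2) {
    sel <- shortestAtTm(substring(hap[i], 1L, d), tmTarget, lenRange, method,
                        anchor = "suffix")
    primers[i] <- sel$seq; tms[i] <- sel$tm; ok <- ok && sel$ok
  }
  com <- shortestAtTm(flankRight, tmTarget, lenRange, method,
                      anchor = "prefix")
  list(ok = ok && com$ok, primers = primers, tm = tms,
       common = revcomp(com$seq), commonTm = com$tm,
       balance = abs(tms[1L] - tms[2L]))
}

firstDifference <- function(a, b) {
  n <- min(nchar(a), nchar(b))
  ca <- strsplit(substring(a, 1L, n), "")[[1L]]
  cb <- strsplit(substring(b, 1L, n), "")[[1L]]
  d <- which(ca != cb)[1L]
  if (is.na(d)) n + 1L else d
}

## Shortest window in lenRange reaching tmTarget; ties (same length) are
## impossible, longer-window fallback returns the max-length window with
## ok = FALSE so the caller can flip strands or refuse.
shortestAtTm <- function(seqStr, tmTarget, lenRange, method, anchor) {
  nmax <- min(lenRange[2L], nchar(seqStr))
  for (L in seq(min(lenRange[1L], nmax), nmax)) {
    cand <- if (anchor == "suffix")
      substring(seqStr, nchar(seqStr) - L + 1L, nchar(seqStr))
    else substring(seqStr, 1L, L)
    tm <- estimateTm(cand, method)
    if (tm >= tmTarget) return(list(seq = cand, tm = tm, ok = TRUE))
  }
  cand <- if (anchor == "suffix")
    substring(seqStr, nchar(seqStr) - nmax + 1L, nchar(seqStr))
  else substring(seqStr, 1L, nmax)
  list(seq = cand, tm = estimateTm(cand, method), ok = FALSE)
}

#' Audit a marker table for internal consistency
#'
#' The in-silico analogue of assay validation: for every SNP row, the
#' two allele primers' 3'-terminal bases must jointly equal either the
#' two alleles (forward orientation) or their complements (reverse);
#' anything else is inconsistent. Rows carrying flank sequence are
#' additionally checked for primer containment: each primer must occur
#' within the reconstructed local sequence (flank + allele + flank) on
#' either strand. InDel rows are audited for allele length difference
#' only. The audit reports and never mutates.
#'
#' @param markers Marker-table data.frame
#'   (\code{\link{readMarkerTable}}) or a list of
#'   \linkS4class{KaspMarker}.
#' @return Data.frame: \code{marker_id}, \code{kind},
#'   \code{orientation_call} (\code{forward}/\code{reverse}/
#'   \code{inconsistent}/\code{not-applicable}), \code{flank_check}
#'   (\code{pass}/\code{fail}/\code{not-checkable}), \code{note}.
#' @export
auditMarkerTable <- function(markers) {
  if (is.list(markers) && !is.data.frame(markers))
    markers <- do.call(rbind, lapply(markers, markerRow))
  rows <- lapply(seq_len(nrow(markers)), function(i) auditRow(markers[i, ]))
  do.call(rbind, rows)
}

last1 <- function(x) substring(x, nchar(x), nchar(x))

auditRow <- function(r) {
  kind <- if (nchar(r$allele_fam) == 1L && nchar(r$allele_hex) == 1L)
    "SNP" else "InDel"
  note <- character(0L)
  if (kind == "SNP") {
    f3 <- last1(r$primer_fam); h3 <- last1(r$primer_hex)
    orientation <- if (f3 == r$allele_fam && h3 == r$allele_hex) "forward"
    else if (f3 == complementBases(r$allele_fam) &&
             h3 == complementBases(r$allele_hex)) "reverse"
    else "inconsistent"
  } else {
    orientation <- "not-applicable"
    if (nchar(r$allele_fam) == nchar(r$allele_hex))
      note <- c(note, "InDel alleles do not differ in length")
    if (!nzchar(r$primer_common))
      note <- c(note, "no common primer (two-flank layout)")
  }
  flank_check <- "not-checkable"
  if (nzchar(r$flank1) || nzchar(r$flank2)) {
    locals <- paste0(r$flank1, c(r$allele_fam, r$allele_hex), r$flank2)
    locals <- c(locals, revcomp(locals))
    primers <- c(r$primer_fam, r$primer_hex,
                 if (nzchar(r$primer_common)) r$primer_common)
    hitAll <- all(vapply(primers, function(p)
      any(vapply(locals, grepl, logical(1L), pattern = p, fixed = TRUE)),
      logical(1L)))
    flank_check <- if (hitAll) "pass" else "fail"
  }
  data.frame(marker_id = r$marker_id, kind = kind,
             orientation_call = orientation, flank_check = flank_check,
             note = paste(note, collapse = "; "), stringsAsFactors = FALSE)
}

#' Marker-table row for a designed KASP marker
#'
#' @param marker A \linkS4class{KaspMarker}.
#' @param specificType,correspondingAllele Optional specificity
#'   annotation for the row.
#' @return One marker-table row (internal column layout; see
#'   \code{\link{writeMarkerTable}}).
#' @export
markerRow <- function(marker, specificType = NA_character_,
                      correspondingAllele = NA_character_) {
  data.frame(marker_id = marker@markerId, locus_id = marker@locusId,
             allele_fam = marker@alleleFam, allele_hex = marker@alleleHex,
             specific_type = specificType,
             corresponding_allele = correspondingAllele,
             primer_fam = marker@primerFam, primer_hex = marker@primerHex,
             primer_common = marker@primerCommon,
             flank1 = marker@flank1, flank2 = marker@flank2,
             stringsAsFactors = FALSE)
}
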