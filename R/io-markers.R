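## The published marker-table dialect: one row per KASP marker, with these
## exact column headers. "/" marks a marker with no specific type and "-"
## marks a deletion allele; both sentinels are resolved at parse time and
## restored on write so the pair round-trips losslessly.
MARKER_TABLE_HEADER <- c("Marker", "Variation Loci", "AlleleFAM", "AlleleHEX",
                         "Specific Type",
                         "Corresponding Alleles of cpGenome Groups",
                         "Primer_AlleleFAM", "Primer_AlleleHEX",
                         "Primer_Common", "Flank1", "Flank2")

MARKER_TABLE_INTERNAL <- c("marker_id", "locus_id", "allele_fam", "allele_hex",
                           "specific_type", "corresponding_allele",
                           "primer_fam", "primer_hex", "primer_common",
                           "flank1", "flank2")

#' Read a KASP marker table
#'
#' Parses a marker table in the published Varietal Chloroplast Panel
#' dialect. The \code{"/"} sentinel (no specific type) becomes \code{NA};
#' the \code{"-"} deletion-allele sentinel becomes the empty string; the
#' sentinels never propagate past the parser. A row with an empty common
#' primer (the two-flank large-InDel layout) is accepted and flagged in
#' the \code{note} column rather than rejected; an empty allele-specific
#' primer is an error.
#'
#' @param path TSV path with the dialect's exact column headers.
#' @return A data.frame with columns \code{marker_id}, \code{locus_id},
#'   \code{allele_fam}, \code{allele_hex}, \code{specific_type},
#'   \code{corresponding_allele}, \code{primer_fam}, \code{primer_hex},
#'   \code{primer_common}, \code{flank1}, \code{flank2}, plus derived
#'   \code{kind} (\code{SNP}/\code{InDel}) and \code{note}.
#' @export
readMarkerTable <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                          colClasses = "character")
  if (!identical(colnames(df), MARKER_TABLE_HEADER))
    stopf("marker table '%s' does not match the expected column headers (%s)",
          path, paste(setdiff(MARKER_TABLE_HEADER, colnames(df)),
                      collapse = ", "))
  colnames(df) <- MARKER_TABLE_INTERNAL
  if (!nrow(df)) {
    df$kind <- character(0L); df$note <- character(0L)
    return(df)
  }
  df[is.na(df)] <- ""
  df$specific_type[df$specific_type == "/"] <- NA_character_
  df$corresponding_allele[df$corresponding_allele == "/"] <- NA_character_
  df$allele_fam[df$allele_fam == "-"] <- ""
  df$allele_hex[df$allele_hex == "-"] <- ""
  df$kind <- ifelse(nchar(df$allele_fam) == 1L & nchar(df$allele_hex) == 1L,
                    "SNP", "InDel")
  bad <- !nzchar(df$primer_fam) | !nzchar(df$primer_hex)
  if (any(bad))
    stopf("marker(s) with empty allele-specific primer: %s",
          paste(df$marker_id[bad], collapse = ", "))
  badseq <- grepl("[^ACGT]", df$primer_fam) | grepl("[^ACGT]", df$primer_hex) |
    (nzchar(df$primer_common) & grepl("[^ACGT]", df$primer_common))
  if (any(badseq))
    stopf("marker(s) with non-ACGT primer sequence: %s",
          paste(df$marker_id[badseq], collapse = ", "))
  df$note <- ifelse(nzchar(df$primer_common), "",
                    "missing common primer (two-flank layout)")
  snp_noflank <- df$kind == "SNP" & !nzchar(df$primer_common)
  if (any(snp_noflank))
    stopf("SNP marker(s) lacking a common primer: %s",
          paste(df$marker_id[snp_noflank], collapse = ", "))
  rownames(df) <- NULL
  df
}

#' Write a KASP marker table
#'
#' Emits the published dialect; \code{NA} specific types print as
#' \code{"/"} and empty (deletion) alleles as \code{"-"}, so
#' \code{readMarkerTable(writeMarkerTable(x))} is the identity.
#'
#' @param markers Data.frame as returned by \code{\link{readMarkerTable}}
#'   or built from \linkS4class{KaspMarker} objects.
#' @param path Output TSV path.
#' @export
writeMarkerTable <- function(markers, path) {
  df <- markers[, MARKER_TABLE_INTERNAL, drop = FALSE]
  df$specific_type[is.na(df$specific_type)] <- "/"
  df$corresponding_allele[is.na(df$corresponding_allele)] <- "/"
  df$allele_fam[!nzchar(df$allele_fam)] <- "-"
  df$allele_hex[!nzchar(df$allele_hex)] <- "-"
  colnames(df) <- MARKER_TABLE_HEADER
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' The packaged Varietal Chloroplast Panel marker table
#'
#' The published 59-marker maize VCP set (56 SNP + 3 InDel markers), as
#' distributed with the package, parsed with \code{\link{readMarkerTable}}.
#'
#' @return Marker-table data.frame (59 rows).
#' @export
vcpMarkers <- function() {
  readMarkerTable(system.file("extdata", "vcp_markers.tsv",
                              package = "chloroPanel", mustWork = TRUE))
}
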