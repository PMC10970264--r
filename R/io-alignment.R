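#' Read an aligned plastome panel
#'
#' Reads an aligned multi-FASTA plus its sample sheet and returns a
#' validated \linkS4class{PlastomeAlignment}. Sequence order follows the
#' sheet; sequences are upper-cased on read.
#'
#' @param fasta Path to the aligned multi-FASTA; record ids must match
#'   \code{sample_id}s in the sheet.
#' @param sheet Path to the sample-sheet TSV (columns \code{sample_id},
#'   \code{group}, \code{role}, \code{mother_id}, \code{father_id},
#'   \code{fertility}), or a data.frame already in that layout.
#' @return A \linkS4class{PlastomeAlignment}.
#' @export
readAlignment <- function(fasta, sheet) {
  seqs <- Biostrings::readDNAStringSet(fasta)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  samples <- if (is.character(sheet)) readSampleSheet(sheet) else
    completeSampleSheet(sheet)
  extra <- setdiff(names(seqs), samples$sample_id)
  if (length(extra))
    stopf("FASTA id(s) absent from the sample sheet: %s",
          paste(extra, collapse = ", "))
  PlastomeAlignment(seqs, samples)
}

#' Write an aligned plastome panel
#'
#' Inverse of \code{\link{readAlignment}}; the pair round-trips losslessly.
#'
#' @param aln A \linkS4class{PlastomeAlignment}.
#' @param fasta,sheet Output paths for the aligned FASTA and the
#'   sample-sheet TSV.
#' @return Invisibly, the two paths.
#' @export
writeAlignment <- function(aln, fasta, sheet) {
  stopifnot(is(aln, "PlastomeAlignment"))
  Biostrings::writeXStringSet(aln@seqs, fasta, width = 80L)
  writeSampleSheet(aln@samples, sheet)
  invisible(c(fasta = fasta, sheet = sheet))
}

#' @rdname readAlignment
#' @param path Sample-sheet TSV path.
#' @export
readSampleSheet <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character", na.strings = c("NA", ""))
  ok <- validSampleSheet(completeSampleSheet(df))
  if (!isTRUE(ok)) stopf("invalid sample sheet '%s': %s", path, ok)
  completeSampleSheet(df)
}

#' @rdname readAlignment
#' @param samples Sample-sheet data.frame.
#' @export
writeSampleSheet <- function(samples, path) {
  utils::write.table(samples, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}
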