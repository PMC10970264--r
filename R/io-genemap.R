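#' Gene maps
#'
#' A gene map is a \code{GRanges} on a single plastome sequence with
#' metadata columns \code{gene} (name), \code{category}
#' (\code{protein_coding}/\code{tRNA}/\code{rRNA}) and optional
#' \code{region} (\code{LSC}/\code{IRa}/\code{IRb}/\code{SSC}).
#' Coordinates are 1-based closed internally (the \code{GRanges}
#' convention); the BED reader/writer converts at the boundary.
#'
#' @param genes Gene names.
#' @param start,end 1-based closed interval per gene.
#' @param category Gene category per gene.
#' @param region Optional region label per gene.
#' @param seqname Sequence name (single plastome).
#' @return A \code{GRanges} gene map.
#' @export
geneMap <- function(genes, start, end, category,
                    region = NA_character_, seqname = "plastome") {
  if (any(end < start)) stopf("gene intervals must satisfy start <= end")
  if (!all(category %in% GENE_CATEGORIES))
    stopf("gene categories must be one of %s",
          paste(GENE_CATEGORIES, collapse = ", "))
  gr <- GenomicRanges::GRanges(seqname,
                               IRanges::IRanges(as.integer(start),
                                                as.integer(end)))
  S4Vectors::mcols(gr)$gene <- as.character(genes)
  S4Vectors::mcols(gr)$category <- as.character(category)
  S4Vectors::mcols(gr)$region <- rep_len(as.character(region), length(gr))
  for (cat in unique(gr$category)) {
    sub <- gr[gr$category == cat]
    hits <- GenomicRanges::findOverlaps(sub, drop.self = TRUE)
    if (length(hits))
      stopf("overlapping %s gene intervals: %s", cat,
            paste(unique(sub$gene[S4Vectors::queryHits(hits)]),
                  collapse = ", "))
  }
  gr
}

#' Read a gene map
#'
#' Reads the 6-column BED-like dialect (\code{chrom start end name
#' category region}; 0-based half-open starts) or, as a fallback, a
#' minimal GFF3 whose feature types map onto the three gene categories.
#'
#' @param path Input path; format chosen by extension (\code{.bed} vs
#'   \code{.gff}/\code{.gff3}) unless \code{format} is given.
#' @param format \code{"bed"}, \code{"gff3"} or \code{NULL} (auto).
#' @return A \code{GRanges} gene map (see \code{\link{geneMap}}).
#' @export
readGeneMap <- function(path, format = NULL) {
  format <- format %||%
    (if (grepl("\\.gff3?$", path, ignore.case = TRUE)) "gff3" else "bed")
  if (format == "bed") {
    df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                            col.names = c("chrom", "start", "end", "name",
                                          "category", "region"))
    geneMap(df$name, df$start + 1L, df$end, df$category,
            ifelse(df$region %in% REGION_LEVELS, df$region, NA_character_),
            seqname = df$chrom[1L] %||% "plastome")
  } else {
    gff <- utils::read.delim(path, header = FALSE, comment.char = "#",
                             stringsAsFactors = FALSE)[, 1:9]
    colnames(gff) <- c("seqid", "source", "type", "start", "end", "score",
                       "strand", "phase", "attributes")
    catmap <- c(gene = "protein_coding", CDS = "protein_coding",
                mRNA = "protein_coding", tRNA = "tRNA", rRNA = "rRNA")
    gff <- gff[gff$type %in% names(catmap), , drop = FALSE]
    if (!nrow(gff)) stopf("no gene features found in '%s'", path)
    nm <- sub(".*(?:Name|ID)=([^;]+).*", "\\1", gff$attributes)
    geneMap(nm, gff$start, gff$end, unname(catmap[gff$type]),
            seqname = gff$seqid[1L])
  }
}

#' Write a gene map in the BED-like dialect
#'
#' @param map \code{GRanges} gene map.
#' @param path Output BED path (0-based half-open starts).
#' @export
writeGeneMap <- function(map, path) {
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(map)),
                   start = GenomicRanges::start(map) - 1L,
                   end = GenomicRanges::end(map),
                   name = map$gene, category = map$category,
                   region = ifelse(is.na(map$region), ".", map$region))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
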