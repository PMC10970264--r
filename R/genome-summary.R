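#' Summarize a plastome: region lengths, GC content, gene counts
#'
#' Computes the structural summary of one ungapped plastome: the
#' quadripartite partition (detected with
#' \code{\link{detectQuadripartite}} unless intervals are supplied), GC
#' fraction over A/C/G/T calls only, and gene counts by category and by
#' region. A gene spanning a region boundary counts toward the region
#' containing its start (fixed convention).
#'
#' @param genome Ungapped genome sequence (character or \code{DNAString}).
#' @param map Gene map \code{GRanges} (see \code{\link{geneMap}}).
#' @param intervals Region table as returned by
#'   \code{\link{detectQuadripartite}}, or \code{NULL} to detect.
#' @param minIR Passed to \code{\link{detectQuadripartite}}.
#' @return A \linkS4class{GenomeSummary}.
#' @export
summarizeGenome <- function(genome, map, intervals = NULL, minIR = 1000L) {
  genome <- toupper(as.character(genome))
  n <- nchar(genome)
  if (is.null(intervals)) intervals <- detectQuadripartite(genome, minIR)
  if (sum(intervals$length) != n)
    stopf("supplied intervals do not partition the %d bp genome", n)
  if (length(map)) {
    st <- GenomicRanges::start(map); en <- GenomicRanges::end(map)
    if (any(st < 1L | en > n))
      stopf("gene(s) outside [1, %d]: %s", n,
            paste(map$gene[st < 1L | en > n], collapse = ", "))
  }
  comp <- table(factor(strsplit(genome, "")[[1L]],
                       levels = c("A", "C", "G", "T", "N")))
  acgt <- sum(comp[c("A", "C", "G", "T")])
  gc <- if (acgt) sum(comp[c("G", "C")]) / acgt else NA_real_

  cats <- factor(map$category, levels = GENE_CATEGORIES)
  geneCounts <- c(total = length(map), table(cats))
  reg <- regionOf(GenomicRanges::start(map), intervals, n)
  regionGeneCounts <- table(factor(reg, levels = intervals$region), cats)

  irLen <- intervals$length[intervals$region == "IRa"]
  new("GenomeSummary", totalLength = as.integer(n),
      lscLength = as.integer(intervals$length[intervals$region == "LSC"]),
      irLength = as.integer(irLen),
      sscLength = as.integer(intervals$length[intervals$region == "SSC"]),
      gcFraction = gc,
      geneCounts = setNames(as.integer(geneCounts), names(geneCounts)),
      regionGeneCounts = unclass(as.matrix(regionGeneCounts)))
}

#' Assemble region intervals from known lengths
#'
#' Convenience constructor for the canonical LSC-IRa-SSC-IRb layout when
#' the region lengths are known (e.g. from a published genome record);
#' validates that \code{LSC + 2*IR + SSC} equals the stated total.
#'
#' @param lsc,ir,ssc Region lengths in bp.
#' @param total Optional expected total genome length to check against.
#' @return Region table in the \code{\link{detectQuadripartite}} layout.
#' @export
regionIntervals <- function(lsc, ir, ssc, total = NULL) {
  n <- lsc + 2L * ir + ssc
  if (!is.null(total) && n != total)
    stopf("LSC + 2*IR + SSC = %d does not match the stated total %d", n,
          total)
  data.frame(region = c("LSC", "IRa", "SSC", "IRb"),
             start = as.integer(c(1L, lsc + 1L, lsc + ir + 1L,
                                  lsc + ir + ssc + 1L)),
             end = as.integer(c(lsc, lsc + ir, lsc + ir + ssc, n)),
             length = as.integer(c(lsc, ir, ssc, ir)))
}

regionOf <- function(pos, intervals, n) {
  vapply(pos, function(p) {
    for (i in seq_len(nrow(intervals))) {
      s <- intervals$start[i]; e <- intervals$end[i]
      inside <- if (s <= e) p >= s && p <= e else p >= s || p <= e
      if (inside) return(intervals$region[i])
    }
    NA_character_
  }, character(1L))
}

#' @rdname accessors
#' @export
setGeneric("regionLengths", function(x) standardGeneric("regionLengths"))
#' @rdname accessors
#' @export
setMethod("regionLengths", "GenomeSummary", function(x)
  c(total = x@totalLength, LSC = x@lscLength, IR = x@irLength,
    SSC = x@sscLength))
#' @rdname accessors
#' @export
setGeneric("gcFraction", function(x) standardGeneric("gcFraction"))
#' @rdname accessors
#' @export
setMethod("gcFraction", "GenomeSummary", function(x) x@gcFraction)
#' @rdname accessors
#' @export
setGeneric("geneCounts", function(x) standardGeneric("geneCounts"))
#' @rdname accessors
#' @export
setMethod("geneCounts", "GenomeSummary", function(x) x@geneCounts)
#' @rdname accessors
#' @export
setGeneric("regionGeneCounts", function(x) standardGeneric("regionGeneCounts"))
#' @rdname accessors
#' @export
setMethod("regionGeneCounts", "GenomeSummary", function(x) x@regionGeneCounts)
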