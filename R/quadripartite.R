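#' Detect the quadripartite structure of a plastome
#'
#' Finds the longest pair of disjoint, exact reverse-complement repeats
#' of at least \code{minIR} bp (the inverted repeats IRa/IRb) and
#' partitions the genome into LSC / IRa / SSC / IRb. Detection anchors
#' shared k-mers (default k = 31) between the sequence and its reverse
#' complement and extends each anchor to a maximal exact match, so a
#' single internal mismatch splits a repeat and the detected pair shrinks
#' to the longest exact segment. The sequence is treated as linear;
#' plastome FASTA records are conventionally rotated so that position 1
#' lies in a single-copy region, and the single-copy segment flanking
#' both sequence ends is reported as one circular region.
#'
#' @param genome Ungapped genome sequence (character or \code{DNAString}).
#' @param minIR Minimum acceptable IR length in bp (default 1000; use
#'   ~500 for scaled-down genomes).
#' @param k Anchor k-mer size.
#' @return A data.frame with rows LSC/IRa/SSC/IRb and columns
#'   \code{region}, \code{start}, \code{end}, \code{length}. A region
#'   wrapping the origin has \code{start > end}. Region lengths always
#'   sum to the genome length. The longer single-copy segment is labelled
#'   LSC, the shorter SSC.
#' @export
detectQuadripartite <- function(genome, minIR = 1000L, k = 31L) {
  genome <- toupper(as.character(genome))
  n <- nchar(genome)
  if (n <= 4L * minIR)
    stopf("sequence length %d must exceed 4*minIR = %d", n, 4L * minIR)
  s <- strsplit(genome, "")[[1L]]
  rc <- rev(unname(COMPLEMENT[s]))
  hit <- longestInvertedRepeat(s, rc, n, k)
  if (is.null(hit) || hit$len < minIR)
    stopf("no reverse-complement repeat of >= %d bp found (supply region intervals manually)",
          minIR)
  a <- hit$a; b <- hit$b       # a = first copy interval, b = second
  gap1 <- c(a[2L] + 1L, b[1L] - 1L)            # between the copies
  len1 <- gap1[2L] - gap1[1L] + 1L
  len2 <- n - (hit$len * 2L) - len1            # wraps the origin
  if (len1 <= 0L || len2 <= 0L)
    stopf("inverted-repeat copies leave no single-copy sequence")
  wrapStart <- if (b[2L] == n) 1L else b[2L] + 1L
  wrapEnd <- if (b[2L] == n) a[1L] - 1L else
    (if (a[1L] == 1L) n else a[1L] - 1L)
  sc2 <- c(wrapStart, wrapEnd)
  if (len1 >= len2) {
    out <- rbind(
      data.frame(region = "LSC", start = gap1[1L], end = gap1[2L]),
      data.frame(region = "IRa", start = b[1L], end = b[2L]),
      data.frame(region = "SSC", start = sc2[1L], end = sc2[2L]),
      data.frame(region = "IRb", start = a[1L], end = a[2L]))
    lens <- c(len1, hit$len, len2, hit$len)
  } else {
    out <- rbind(
      data.frame(region = "LSC", start = sc2[1L], end = sc2[2L]),
      data.frame(region = "IRa", start = a[1L], end = a[2L]),
      data.frame(region = "SSC", start = gap1[1L], end = gap1[2L]),
      data.frame(region = "IRb", start = b[1L], end = b[2L]))
    lens <- c(len2, hit$len, len1, hit$len)
  }
  out$length <- as.integer(lens)
  stopifnot(sum(out$length) == n)   # partition conservation
  out
}

## k-mer anchored longest exact reverse-complement repeat. rc[j] maps to
## s[n - j + 1]; an anchor (i, j) asserts s[i..i+k-1] == rc(s[p..q]) with
## p = n - j - k + 2, q = n - j + 1. Extension keeps the pair maximal;
## anchors falling inside an already-extended pair are skipped.
longestInvertedRepeat <- function(s, rc, n, k) {
  if (n < k) return(NULL)
  starts <- seq_len(n - k + 1L)
  seqStr <- paste(s, collapse = "")
  rcStr <- paste(rc, collapse = "")
  kmS <- substring(seqStr, starts, starts + k - 1L)
  kmR <- substring(rcStr, starts, starts + k - 1L)
  j <- match(kmS, kmR)
  anchors <- which(!is.na(j))
  if (!length(anchors)) return(NULL)
  best <- NULL
  done <- logical(n)
  for (i in anchors) {
    if (done[i]) next
    jj <- j[i]
    p <- n - jj - k + 2L; q <- n - jj + 1L
    i2 <- i + k - 1L
    ## extend left of copy 1 / right of copy 2
    while (i > 1L && q < n && s[i - 1L] == COMPLEMENT[[s[q + 1L]]]) {
      i <- i - 1L; q <- q + 1L
    }
    ## extend right of copy 1 / left of copy 2
    while (i2 < n && p > 1L && s[i2 + 1L] == COMPLEMENT[[s[p - 1L]]]) {
      i2 <- i2 + 1L; p <- p - 1L
    }
    done[i:i2] <- TRUE
    if (p <= i2) next                       # overlapping (palindromic) pair
    done[p:q] <- TRUE                       # partner anchors are redundant
    len <- i2 - i + 1L
    if (is.null(best) || len > best$len)
      best <- list(a = c(i, i2), b = c(p, q), len = len)
  }
  best
}
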