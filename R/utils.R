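# Internal sequence helpers on plain character vectors. Biostrings does the
# heavy lifting for I/O; these cover per-base work where XString round-trips
# would dominate runtime.

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N", "-" = "-")

complementBases <- function(x) unname(COMPLEMENT[x])

revcomp <- function(x) {
  vapply(x, function(s) {
    if (!nchar(s)) return("")
    paste(rev(unname(COMPLEMENT[strsplit(s, "")[[1L]]])), collapse = "")
  }, character(1L), USE.NAMES = FALSE)
}

randomDna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

## Allele ordering convention: decreasing count, ties alphabetical.
orderedAlleles <- function(calls) {
  tab <- table(calls)
  names(tab)[order(-as.integer(tab), names(tab))]
}

## CPMSNP01 -> CSNP01K ; CPMIDP02 -> CIDP02K (the published marker-id dialect)
markerIdFor <- function(locusId) {
  paste0(sub("^CPM", "C", locusId), "K")
}

## sample() treats a length-1 numeric x as 1:x; resample never does
resample <- function(x, size) x[sample.int(length(x), size)]

stopf <- function(...) stop(sprintf(...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a
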