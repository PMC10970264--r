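# Independent oracles, written before the implementations they check.

## Weir & Cockerham (1984) theta-hat from the published general
## r-population variance components (arbitrary observed heterozygosity),
## independent of the package's two-population specialization.
wc84Oracle <- function(n, p, h = rep(0, length(n))) {
  r <- length(n)
  nbar <- mean(n)
  nc <- (sum(n) - sum(n^2) / sum(n)) / (r - 1)
  pbar <- sum(n * p) / (r * nbar)
  s2 <- sum(n * (p - pbar)^2) / ((r - 1) * nbar)
  hbar <- sum(n * h) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - ((r - 1) / r) * s2 -
       ((2 * nbar - 1) / (4 * nbar)) * hbar)
  cc <- hbar / 2
  a / (a + b + cc)
}

## Hudson estimator (Bhatia et al. 2013 form) -- cross-check at fixed
## differences, where it equals 1 exactly.
hudsonFst <- function(n1, p1, n2, p2) {
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  num / den
}

## Quadratic brute force: longest exact reverse-complement repeat pair
## with disjoint copies (first copy before the second). For toy genomes.
bruteForceIR <- function(genome) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  s <- strsplit(toupper(genome), "")[[1L]]
  n <- length(s)
  rc <- rev(unname(comp[s]))
  L <- matrix(0L, n + 1L, n + 1L)
  for (i in seq_len(n)) {
    eq <- s[i] == rc
    L[i + 1L, 2L:(n + 1L)] <- ifelse(eq, L[i, 1L:n] + 1L, 0L)
  }
  best <- list(len = 0L)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    len <- L[i + 1L, j + 1L]
    if (len <= best$len) next
    a <- c(i - len + 1L, i)                 # copy in s
    b <- c(n - j + 1L, n - j + len)         # rc interval mapped back to s
    if (a[2L] < b[1L]) best <- list(len = len, a = a, b = b)
  }
  best
}

## Exhaustive smallest discriminating subset, straight over all locus
## combinations (no pattern deduplication) -- feasible for small panels.
bruteForceMinimalPanel <- function(sig, kmax = ncol(sig)) {
  for (k in seq_len(kmax)) {
    combos <- combn(ncol(sig), k)
    for (ci in seq_len(ncol(combos))) {
      rows <- apply(sig[, combos[, ci], drop = FALSE], 1L, paste,
                    collapse = "|")
      if (!anyDuplicated(rows)) return(colnames(sig)[combos[, ci]])
    }
  }
  NULL
}

## Frozen nearest-neighbor Tm reference values (independent external
## implementation, SantaLucia unified parameters, 50 mM Na+, 200 nM
## primer), for the cross-check oracle.
TM_REFERENCE <- c(
  ACGTACGTACGTACGTACGT = 56.7752,
  AAAAAAAAAAAAAAAAAAAA = 39.6217,
  GCGCGCGCGCATATATATAT = 57.4029,
  AGCAATCTGAGTTTTTCATTTTTACTAACTTA = 55.8292,
  AGGATCCATTTGACCCCCAATATG = 57.6697,
  CTTCATTTACCAAATCCAAAAATTTGGGAA = 56.9882)

## Reduced-scale simulation config for property loops.
smallConfig <- function(seed,
                        trios = data.frame(
                          mother_group = c("H", "C", "B"),
                          father_group = c("B", "D", "T"),
                          type = c("trio", "cms", "reciprocal"),
                          stringsAsFactors = FALSE),
                        ...) {
  simulationConfig(
    seed = seed, genomeLength = 8000L, samplesPerGroup = 6L,
    nDiagnosticPerGroup = 2L, nSharedSnps = 6L, nIndels = 3L,
    indelLenRange = c(1L, 30L), nDiagnosticIndels = 1L, nRareAlleles = 3L,
    trios = trios, ...)
}

## Tiny hand-built alignment helper: rows of equal-length strings.
toyAlignment <- function(seqs, groups = NULL, roles = NULL) {
  ids <- names(seqs) %||% sprintf("S%02d", seq_along(seqs))
  chloroPanel::PlastomeAlignment(
    setNames(unname(seqs), ids),
    data.frame(sample_id = ids,
               group = groups %||% rep("B", length(seqs)),
               role = roles %||% rep("cultivar", length(seqs)),
               stringsAsFactors = FALSE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

lociById <- function(loci) {
  setNames(loci, vapply(loci, function(l) l@id, character(1L)))
}
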