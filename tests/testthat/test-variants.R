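test_that("SNP calling follows the column rules", {
  ## {A x2, T x1} column -> one SNP; N-only polymorphism -> none
  aln <- toyAlignment(c(S1 = "AAGAA", S2 = "AAGAA", S3 = "ATGAA",
                        S4 = "AAGNA"))
  loci <- callSNPs(aln)
  expect_length(loci, 1L)
  expect_equal(loci[[1]]@start, 2L)
  expect_equal(loci[[1]]@alleles, c("A", "T"))
  expect_equal(allelesAt(loci[[1]]), c("A", "A", "T", "A"))

  ## column polymorphic only because of N is not a locus; gap columns
  ## are excluded from SNP calling
  aln2 <- toyAlignment(c(S1 = "ANGCA", S2 = "AAG-A", S3 = "AAGCA"))
  expect_length(callSNPs(aln2), 0L)
})

test_that("InDel events merge on identical gap patterns and split otherwise", {
  ## 5 adjacent columns gapped in the same samples -> one locus of span 5
  aln <- toyAlignment(c(S1 = "ACGTTCTTTGCAT", S2 = "ACGT-----GCAT",
                        S3 = "ACGT-----GCAT"))
  loci <- callIndels(aln)
  expect_length(loci, 1L)
  expect_equal(c(loci[[1]]@start, loci[[1]]@end), c(5L, 9L))
  expect_setequal(loci[[1]]@alleles, c("TCTTT", ""))
  expect_equal(allelesAt(loci[[1]]), c("TCTTT", "", ""))

  ## adjacent gap columns with different sample patterns -> two loci
  aln2 <- toyAlignment(c(S1 = "ACG--TCA", S2 = "ACG-ATCA", S3 = "ACGGATCA"))
  loci2 <- callIndels(aln2)
  expect_length(loci2, 2L)
  expect_equal(vapply(loci2, function(l) l@start, 1L), c(4L, 5L))

  ## InDel alleles differ in length by the event span
  d <- nchar(loci[[1]]@alleles[1]) - nchar(loci[[1]]@alleles[2])
  expect_equal(abs(d), 5L)
})

test_that("annotation places loci in genes or between bracketing genes", {
  aln <- toyAlignment(c(S1 = strrep("A", 30), S2 = paste0(strrep("A", 9),
                        "T", strrep("A", 10), "C", strrep("A", 9))))
  map <- geneMap(c("g1", "g2"), c(5, 25), c(12, 30),
                 c("protein_coding", "tRNA"))
  loci <- annotateVariants(callSNPs(aln), map, aln)
  expect_equal(loci[[1]]@annotation, "genic")
  expect_equal(loci[[1]]@genes, "g1")
  expect_equal(loci[[2]]@annotation, "intergenic")
  expect_equal(loci[[2]]@genes, c("g1", "g2"))
})

test_that("flank extraction vets conservation and truncation", {
  ## conserved flanks
  base <- strrep("ACGT", 10)
  s2 <- base; substr(s2, 20, 20) <- "A"
  aln <- toyAlignment(c(S1 = base, S2 = s2))
  lc <- extractFlanks(callSNPs(aln)[[1]], aln, width = 10L)
  expect_true(lc@flanksConserved)
  expect_equal(nchar(lc@flankLeft), 10L)
  expect_equal(lc@flankRight, substr(base, 21, 30))

  ## a second variant inside the flank breaks conservation
  s3 <- s2; substr(s3, 25, 25) <- "C"
  aln2 <- toyAlignment(c(S1 = base, S2 = s3))
  loci2 <- callSNPs(aln2)
  lc2 <- extractFlanks(loci2[[1]], aln2, width = 10L)
  expect_false(lc2@flanksConserved)

  ## locus near the alignment edge is truncated and flagged
  lc3 <- extractFlanks(callSNPs(aln)[[1]], aln, width = 25L)
  expect_true(lc3@flanksTruncated)
  expect_false(lc3@flanksConserved)
})

test_that("variant density is genome length over locus count", {
  expect_equal(variantDensity(100L, 140600L), 1406)
  expect_equal(variantDensity(1L, 714L), 714)
  expect_error(variantDensity(0L, 1000L), "undefined")
  panel <- generatePanel(smallConfig(3L))
  inv <- variantInventory(callVariants(panel$alignment),
                          nchar(panel$reference))
  expect_equal(inv$n, nrow(truthLoci(panel$truth)))
  expect_equal(inv$density, nchar(panel$reference) / inv$n)
})

test_that("truth recovery is exact across seeds and calling is idempotent", {
  for (seed in 1:8) {
    panel <- generatePanel(smallConfig(seed))
    tr <- truthLoci(panel$truth)
    loci <- callVariants(panel$alignment)
    expect_length(loci, nrow(tr))
    key <- function(st, en, kind) paste(st, en, kind)
    expect_setequal(key(vapply(loci, function(l) l@start, 1L),
                        vapply(loci, function(l) l@end, 1L),
                        vapply(loci, function(l) l@kind, "")),
                    key(tr$start, tr$end, tr$kind))
    ## genotype vectors: carriers of the alt allele match the truth
    ids <- sampleSheet(panel$alignment)$sample_id
    for (i in seq_along(loci)) {
      l <- loci[[i]]
      trow <- tr[tr$start == l@start, ]
      expect_setequal(ids[which(allelesAt(l) == trow$alt_allele)],
                      strsplit(trow$carriers, ";")[[1]])
    }
    ## no alignment column contributes to more than one locus
    cols <- unlist(lapply(loci, function(l) l@start:l@end))
    expect_false(anyDuplicated(cols) > 0L)
  }

  ## idempotence: re-emitting the alignment and re-calling changes nothing
  panel <- generatePanel(smallConfig(9L))
  fa <- tempfile(fileext = ".fa"); sh <- tempfile(fileext = ".tsv")
  writeAlignment(panel$alignment, fa, sh)
  again <- callVariants(readAlignment(fa, sh))
  first <- callVariants(panel$alignment)
  expect_equal(lapply(first, allelesAt), lapply(again, allelesAt))
  expect_equal(vapply(first, function(l) l@start, 1L),
               vapply(again, function(l) l@start, 1L))
})
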