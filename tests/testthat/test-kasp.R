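test_that("Tm models: Wallace closed form and NN against the reference oracle", {
  expect_equal(estimateTm("ACGT", method = "wallace"), 12)
  expect_equal(estimateTm(strrep("A", 20), method = "wallace"), 40)
  expect_equal(estimateTm("AATT", method = "wallace"), 8)
  for (s in names(TM_REFERENCE))
    expect_lt(abs(estimateTm(s) - TM_REFERENCE[[s]]), 0.5)
  ## determinism and input validation
  expect_identical(estimateTm("ACGTACGTACGTACGT"),
                   estimateTm("ACGTACGTACGTACGT"))
  expect_error(estimateTm("ACGTN"), "A,C,G,T")
  expect_error(estimateTm("ACGTACG"), ">= 8")
})

test_that("allele primers end at the discriminating base on the chosen strand", {
  flank <- strrep("ATGC", 8)          # 32 nt
  mk <- designKasp(alleles = c("A", "G"), flankLeft = flank,
                   flankRight = strrep("GATC", 8), locusId = "CPMSNP99")
  ## identical except the 3' terminus, which carries the allele under
  ## the declared orientation
  pf <- mk@primerFam; ph <- mk@primerHex
  expect_false(substring(pf, nchar(pf)) == substring(ph, nchar(ph)))
  if (mk@orientation == "forward") {
    expect_equal(substring(pf, nchar(pf)), "A")
    expect_equal(substring(ph, nchar(ph)), "G")
  } else {
    expect_equal(substring(pf, nchar(pf)), "T")
    expect_equal(substring(ph, nchar(ph)), "C")
  }
  expect_equal(mk@markerId, "CSNP99K")
  ## both primers reach the target Tm within the length range
  expect_gte(min(mk@tm[c("fam", "hex", "common")]), 58)
  expect_true(all(nchar(c(pf, ph, mk@primerCommon)) >= 18 &
                    nchar(c(pf, ph, mk@primerCommon)) <= 35))

  ## InDel: primers end at the first base differing between alleles
  mkI <- designKasp(alleles = c("", "TCTTT"), flankLeft = flank,
                    flankRight = strrep("GGAC", 8), locusId = "CPMIDP77")
  expect_false(substring(mkI@primerFam, nchar(mkI@primerFam)) ==
                 substring(mkI@primerHex, nchar(mkI@primerHex)))

  ## non-conserved flanks refuse design
  lc <- VariantLocus("CPMSNP01", "SNP", 100L, 100L, c("A", "G"),
                     c(1L, 2L), flanksConserved = FALSE)
  expect_error(designKasp(lc), "not conserved")
})

test_that("published marker rows orient by the 3'-terminal base rule", {
  mk <- vcpMarkers()
  aud <- auditMarkerTable(mk)
  row <- function(id) aud[aud$marker_id == id, ]
  ## forward rows: 3' bases equal the alleles
  expect_equal(row("CSNP17K")$orientation_call, "forward")
  expect_equal(row("CSNP08K")$orientation_call, "forward")
  ## reverse rows: 3' bases equal the complemented alleles
  expect_equal(row("CSNP01K")$orientation_call, "reverse")
  expect_equal(row("CSNP03K")$orientation_call, "reverse")
  ## every SNP row classifies; nothing is inconsistent
  snp <- aud[aud$kind == "SNP", ]
  expect_equal(nrow(snp), 56L)
  expect_true(all(snp$orientation_call %in% c("forward", "reverse")))

  ## a constructed broken row is reported, not repaired
  bad <- mk[mk$marker_id == "CSNP17K", ]
  bad$primer_fam <- paste0(bad$primer_fam, "A")
  bad$primer_hex <- paste0(bad$primer_hex, "A")
  expect_equal(auditMarkerTable(bad)$orientation_call, "inconsistent")
})

test_that("designed markers always pass their own audit", {
  set.seed(99)
  dna <- function(n) paste(sample(c("A","C","G","T"), n, TRUE), collapse = "")
  for (i in 1:25) {
    kind <- sample(c("snp", "indel"), 1)
    alleles <- if (kind == "snp") sample(c("A", "C", "G", "T"), 2) else
      c("", dna(sample(1:12, 1)))
    mk <- designKasp(alleles = alleles, flankLeft = dna(60),
                     flankRight = dna(60),
                     locusId = sprintf("CPMSNP%02d", i))
    aud <- auditMarkerTable(markerRow(mk))
    if (kind == "snp") {
      expect_equal(aud$orientation_call, mk@orientation)
    } else {
      expect_equal(aud$orientation_call, "not-applicable")
      expect_equal(aud$note, "")
    }
  }
})

test_that("designed primers sit inside the reconstructed local sequence", {
  set.seed(7)
  dna <- function(n) paste(sample(c("A","C","G","T"), n, TRUE), collapse = "")
  fl <- dna(60); fr <- dna(60)
  mk <- designKasp(alleles = c("C", "T"), flankLeft = fl, flankRight = fr,
                   locusId = "CPMSNP55")
  rowDf <- markerRow(mk)
  rowDf$flank1 <- fl; rowDf$flank2 <- fr
  expect_equal(auditMarkerTable(rowDf)$flank_check, "pass")
})

test_that("large insertions fall back to the two-flank layout", {
  set.seed(13)
  dna <- function(n) paste(sample(c("A","C","G","T"), n, TRUE), collapse = "")
  mk <- designKasp(alleles = c(dna(83), ""), flankLeft = dna(60),
                   flankRight = dna(60), locusId = "CPMIDP01")
  expect_identical(mk@primerCommon, "")
  expect_true(nzchar(mk@flank1) && nzchar(mk@flank2))
  aud <- auditMarkerTable(markerRow(mk))
  expect_match(aud$note, "two-flank")
})
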