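test_that("generation is a pure function of the seed", {
  a <- generatePanel(smallConfig(7L))
  b <- generatePanel(smallConfig(7L))
  expect_identical(as.character(a$alignment@seqs), as.character(b$alignment@seqs))
  expect_identical(truthLoci(a$truth), truthLoci(b$truth))
  expect_identical(a$reference, b$reference)
  c <- generatePanel(smallConfig(8L))
  expect_false(identical(a$reference, c$reference))
})

test_that("planted structure honours the generator guarantees", {
  panel <- generatePanel(smallConfig(2L))
  aln <- panel$alignment
  m <- alignmentMatrix(aln)
  tr <- truthLoci(panel$truth)
  sheet <- sampleSheet(aln)
  fw <- 60L

  ## IRa is the exact reverse complement of IRb in the reference
  reg <- panel$regions
  ira <- substr(panel$reference, reg$start[2], reg$end[2])
  irb <- substr(panel$reference, reg$start[4], reg$end[4])
  expect_identical(chartr("ACGT", "TGCA", paste(rev(strsplit(irb, "")[[1]]),
                                                collapse = "")), ira)

  ## diagnostic loci: within-group allele frequency 1, out-group 0
  for (i in which(tr$class == "diagnostic" & tr$kind == "SNP")) {
    calls <- m[, tr$start[i]]
    inG <- sheet$group == tr$group[i]
    expect_true(all(calls[inG] == tr$alt_allele[i]))
    expect_true(all(calls[!inG] == tr$ref_allele[i]))
  }

  ## singletons occur in exactly one sample
  for (i in which(tr$class == "rare"))
    expect_equal(sum(m[, tr$start[i]] == tr$alt_allele[i]), 1L)

  ## flanks around every planted locus are invariant across samples
  for (i in seq_len(nrow(tr))) {
    cols <- c((tr$start[i] - fw):(tr$start[i] - 1L),
              (tr$end[i] + 1L):(tr$end[i] + fw))
    cols <- cols[cols >= 1L & cols <= ncol(m)]
    expect_true(all(m[, cols] == rep(m[1L, cols], each = nrow(m))))
  }

  ## planted starts pairwise separated by > 2 * flankWidth
  expect_true(all(diff(sort(tr$start)) > 2L * fw))

  ## hybrids byte-identical to their mothers, labelled with her group
  hyb <- sheet[sheet$role == "hybrid", ]
  expect_gt(nrow(hyb), 0L)
  for (i in seq_len(nrow(hyb))) {
    expect_identical(m[hyb$sample_id[i], ], m[hyb$mother_id[i], ])
    expect_equal(hyb$group[i],
                 sheet$group[sheet$sample_id == hyb$mother_id[i]])
  }
})

test_that("over-full configurations raise a capacity error", {
  expect_error(generatePanel(simulationConfig(
    seed = 1L, samplesPerGroup = 3L,
    nDiagnosticPerGroup = 200L, nSharedSnps = 0L, nIndels = 0L,
    nDiagnosticIndels = 0L, nRareAlleles = 0L,
    trios = defaultCrosses()[0, ])),
    "capacity")
})

test_that("config invariants are enforced", {
  expect_error(simulationConfig(regionLengths = c(LSC = 100L, IR = 10L,
                                                  SSC = 10L)),
               "equal genomeLength")
  expect_error(simulationConfig(samplesPerGroup = 1L), "at least 2")
  expect_error(simulationConfig(nDiagnosticIndels = 9L, nIndels = 2L),
               "cannot exceed")
})
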