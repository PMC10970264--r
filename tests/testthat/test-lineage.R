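## A tiny 2-locus panel over 3 groups used by the unit cases below.
toyPanel <- function() {
  sig <- matrix(c("A", "G", "A",
                  "C", "C", "T"), nrow = 3,
                dimnames = list(c("B", "C", "H"), c("L1", "L2")))
  Panel(c("L1", "L2"), sig,
        columns = matrix(c(2L, 2L, 5L, 5L), 2, 2, byrow = TRUE,
                         dimnames = list(c("L1", "L2"),
                                         c("start", "end"))),
        kinds = c("SNP", "SNP"))
}

test_that("panel genotyping reads calls off the alignment", {
  aln <- toyAlignment(c(S1 = "TATTCTT", S2 = "TGTTCTT", S3 = "TATTTTT",
                        S4 = "TNTT-TT"),
                      groups = c("B", "C", "H", "B"))
  gt <- genotypeAtPanel(aln, toyPanel())
  expect_identical(gt["S1", ], c(L1 = "A", L2 = "C"))
  expect_identical(gt["S2", ], c(L1 = "G", L2 = "C"))
  ## N and gap at a SNP locus are missing, other loci unaffected
  expect_identical(gt["S4", ], c(L1 = NA_character_, L2 = NA_character_))
  ## identical sequences give identical vectors
  expect_identical(gt["S1", ], genotypeAtPanel(aln, toyPanel())["S1", ])
})

test_that("maternal assignment follows strict concordance", {
  ## hybrid identical to mother, mother differs from father at 2 loci
  r <- assignMaternal(c(L1 = "A", L2 = "C"), c(L1 = "A", L2 = "C"),
                      c(L1 = "G", L2 = "T"))
  expect_equal(r$verdict, "maternal=mother")
  expect_equal(r$match_mother, 2L)
  expect_equal(r$match_father, 0L)

  ## reciprocal sibling carries the father-line plastotype
  r2 <- assignMaternal(c(L1 = "G", L2 = "T"), c(L1 = "A", L2 = "C"),
                       c(L1 = "G", L2 = "T"))
  expect_equal(r2$verdict, "maternal=father")

  ## parents identical at all loci: ambiguous, never a guess
  r3 <- assignMaternal(c(L1 = "A", L2 = "C"), c(L1 = "A", L2 = "C"),
                       c(L1 = "A", L2 = "C"))
  expect_equal(r3$verdict, "ambiguous")

  ## hybrid matching neither parent
  r4 <- assignMaternal(c(L1 = "T", L2 = "T"), c(L1 = "A", L2 = "C"),
                       c(L1 = "G", L2 = "C"))
  expect_equal(r4$verdict, "inconsistent")

  ## symmetry: swapping the parents flips the verdict
  r5 <- assignMaternal(c(L1 = "A", L2 = "C"), c(L1 = "G", L2 = "T"),
                       c(L1 = "A", L2 = "C"))
  expect_equal(r5$verdict, "maternal=father")

  ## missing calls are excluded; all-missing overlap is ambiguous
  r6 <- assignMaternal(c(L1 = NA, L2 = NA), c(L1 = "A", L2 = "C"),
                       c(L1 = "G", L2 = "T"))
  expect_equal(r6$verdict, "ambiguous")

  expect_error(assignMaternal(c("A"), c("A", "C"), c("G", "T")),
               "different panels")
})

test_that("cytoplasm classification needs exactly one compatible signature", {
  p <- toyPanel()
  expect_equal(classifyCytoplasm(c(L1 = "G", L2 = "C"), p)$group, "C")
  expect_equal(classifyCytoplasm(c(L1 = "G", L2 = "C"), p)$labels, "C-CMS")
  expect_equal(classifyCytoplasm(c(L1 = "A", L2 = "T"), p)$group, "H")
  expect_identical(classifyCytoplasm(c(L1 = "A", L2 = "T"), p)$labels,
                   "S-CMS;Huanggai")
  ## no signature match -> unclassified
  expect_true(is.na(classifyCytoplasm(c(L1 = "T", L2 = "T"), p)$group))
  ## missing call at the only discriminating locus -> unclassified
  expect_true(is.na(classifyCytoplasm(c(L1 = NA, L2 = "C"), p)$group))
  ## fertility knowledge restricts the candidates
  r <- classifyCytoplasm(c(L1 = "A", L2 = "C"), p,
                         fertilityKnown = "fertile")
  expect_equal(r$group, "B")
})

test_that("the residual group of a one-per-group panel is identifiable", {
  ## 5 indicator loci, panel drops one under the minimal policy: the
  ## residual group's signature is all-rest yet still unique
  groups <- c("B", "C", "D", "H", "T")
  sig <- matrix("A", 5, 5, dimnames = list(groups, paste0("L", 1:5)))
  for (i in 1:5) sig[i, i] <- "G"
  res <- new("SpecificityResults", lociIds = paste0("L", 1:5),
             groups = groups,
             fst = matrix(NA_real_, 5, 5,
                          dimnames = list(paste0("L", 1:5), groups)),
             assigned = groups, groupAllele = rep("G", 5),
             alleleMatrix = sig, threshold = 0.9)
  pm <- selectCorePanel(res, "minimal")
  dropped <- setdiff(groups, unlist(lapply(lociIds(pm), function(id)
    groups[sig[, id] == "G"])))
  expect_length(dropped, 1L)
  allRest <- setNames(rep("A", length(lociIds(pm))), lociIds(pm))
  expect_equal(classifyCytoplasm(allRest, pm)$group, dropped)
})

test_that("synthetic trios resolve to the true mother whenever parents differ", {
  panel0 <- generatePanel(smallConfig(12L))
  aln <- panel0$alignment
  loci <- callVariants(aln)
  spec <- assignSpecificity(loci, aln)
  panel <- selectCorePanel(spec, "one-per-group",
                           columns = lociColumns(loci))
  trios <- traceTrios(aln, panel)
  sheet <- sampleSheet(aln)
  gt <- genotypeAtPanel(aln, panel)
  for (i in seq_len(nrow(trios))) {
    informative <- any(gt[trios$mother_id[i], ] != gt[trios$father_id[i], ],
                       na.rm = TRUE)
    if (informative) {
      expect_equal(trios$verdict[i], "maternal=mother")
    } else {
      expect_equal(trios$verdict[i], "ambiguous")
    }
  }
  ## classification recovers the true group of every sample
  cyto <- vapply(rownames(gt), function(sid)
    classifyCytoplasm(gt[sid, ], panel, sampleId = sid)$group,
    character(1L))
  expect_identical(unname(cyto), sheet$group)
})
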