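test_that("Weir-Cockerham one-vs-rest behaves at the analytic anchors", {
  ## fixed difference -> exactly 1, any sample sizes
  g <- rep(c("X", "rest"), c(10, 20))
  expect_identical(fstOneVsRest(rep(c("A", "T"), c(10, 20)), g, "X"), 1)
  g2 <- rep(c("X", "rest"), c(3, 17))
  expect_identical(fstOneVsRest(rep(c("G", "C"), c(3, 17)), g2, "X"), 1)
  ## and it agrees with the Hudson estimator there
  expect_equal(hudsonFst(10, 1, 20, 0), 1)

  ## equal frequencies -> no differentiation, estimate <= 0
  calls <- c(rep(c("A", "T"), 5), rep(c("A", "T"), 10))
  g3 <- rep(c("X", "rest"), c(10, 20))
  expect_lte(fstOneVsRest(calls, g3, "X"), 0)

  ## monomorphic locus is an explicit NA signal
  expect_warning(v <- fstOneVsRest(rep("A", 30), g3, "X"), "monomorphic")
  expect_true(is.na(v))

  ## too few samples in a population is an error
  expect_error(fstOneVsRest(c("A", "T", "T"), c("X", "r", "r"), "X"),
               "insufficient")
})

test_that("implementation matches the direct-formula oracle on random configurations", {
  set.seed(20240301)
  for (i in 1:200) {
    n1 <- sample(2:60, 1); n2 <- sample(2:120, 1)
    k1 <- sample(0:n1, 1); k2 <- sample(0:n2, 1)
    if (k1 + k2 == 0 || k1 + k2 == n1 + n2) next  # monomorphic
    calls <- c(rep(c("A", "T"), c(k1, n1 - k1)),
               rep(c("A", "T"), c(k2, n2 - k2)))
    groups <- rep(c("X", "rest"), c(n1, n2))
    got <- fstOneVsRest(calls, groups, "X")
    ## oracle works on the focal-group majority allele, as the
    ## implementation collapses to it
    focalAllele <- names(sort(table(calls[groups == "X"]),
                              decreasing = TRUE))[1]
    p1 <- mean(calls[groups == "X"] == focalAllele)
    p2 <- mean(calls[groups != "X"] == focalAllele)
    want <- wc84Oracle(c(n1, n2), c(p1, p2))
    expect_equal(got, want, tolerance = 1e-10)
  }
  ## the worked configuration: focal n=12 at 0.9, rest n=30 at 0.1
  calls <- c(rep(c("A", "T"), c(11, 1)), rep(c("A", "T"), c(3, 27)))
  groups <- rep(c("X", "rest"), c(12, 30))
  expect_equal(fstOneVsRest(calls, groups, "X"),
               wc84Oracle(c(12, 30), c(11 / 12, 3 / 30)),
               tolerance = 1e-12)
})

test_that("specificity assignment recovers planted groups and rejects multi-hits", {
  panel <- generatePanel(smallConfig(6L))
  loci <- callVariants(panel$alignment)
  tr <- truthLoci(panel$truth)
  spec <- assignSpecificity(loci, panel$alignment)
  byStart <- setNames(spec@assigned,
                      vapply(loci, function(l) l@start, 1L)[
                        match(spec@lociIds,
                              vapply(loci, function(l) l@id, ""))])
  for (i in seq_len(nrow(tr))) {
    got <- unname(byStart[as.character(tr$start[i])])
    if (tr$class[i] == "diagnostic") {
      expect_equal(got, tr$group[i])
      ## diagnostic loci score exactly 1 against their group
      j <- match(as.character(tr$start[i]), names(byStart))
      expect_equal(unname(spec@fst[j, tr$group[i]]), 1)
    } else {
      expect_true(is.na(got))
    }
  }

  ## shared allele across H and C: neither one-vs-rest contrast reaches
  ## the threshold (the pooled H-union-C contrast would be fixed, per the
  ## oracle), so no specific type is assigned
  sheet <- data.frame(sample_id = sprintf("s%02d", 1:20),
                      group = rep(c("B", "C", "D", "H", "T"), each = 4),
                      stringsAsFactors = FALSE)
  calls <- ifelse(sheet$group %in% c("H", "C"), "G", "A")
  lc <- VariantLocus("L1", "SNP", 1L, 1L, c("A", "G"),
                     match(calls, c("A", "G")))
  res <- assignSpecificity(list(lc), sheet)
  expect_true(is.na(res@assigned[1]))
  expect_true(all(res@fst[1, ] < 0.9))
  expect_equal(wc84Oracle(c(8, 12), c(1, 0)), 1)

  ## genuine multi-hit: two groups fixed for two different private
  ## alleles both score 1 one-vs-rest -> exactly-one rule assigns none
  calls3 <- ifelse(sheet$group == "H", "G",
                   ifelse(sheet$group == "C", "C", "A"))
  lc3 <- VariantLocus("L2", "SNP", 1L, 1L, c("A", "C", "G"),
                      match(calls3, c("A", "C", "G")))
  res3 <- assignSpecificity(list(lc3), sheet)
  expect_equal(unname(res3@fst[1, "H"]), 1)
  expect_equal(unname(res3@fst[1, "C"]), 1)
  expect_true(is.na(res3@assigned[1]))

  ## ungrouped samples are a labelling error
  bad <- sheet; bad$group[1] <- "unknown"
  expect_error(assignSpecificity(list(lc), bad), "ungrouped")
})

test_that("panel selection: one-per-group, minimal, constrained", {
  ## five groups with one indicator each
  groups <- c("B", "C", "D", "H", "T")
  alleleMat <- matrix("A", 5, 5, dimnames = list(groups,
                                                 paste0("L", 1:5)))
  for (i in 1:5) alleleMat[i, i] <- "G"
  res <- new("SpecificityResults", lociIds = paste0("L", 1:5),
             groups = groups,
             fst = matrix(NA_real_, 5, 5,
                          dimnames = list(paste0("L", 1:5), groups)),
             assigned = groups, groupAllele = rep("G", 5),
             alleleMatrix = alleleMat, threshold = 0.9)
  p5 <- selectCorePanel(res, "one-per-group")
  expect_length(lociIds(p5), 5L)
  expect_false(anyDuplicated(apply(signatureMatrix(p5), 1, paste,
                                   collapse = "|")) > 0)
  ## minimal policy: dropping any one indicator keeps rows distinct
  pm <- selectCorePanel(res, "minimal")
  expect_length(lociIds(pm), 4L)
  expect_identical(lociIds(pm),
                   bruteForceMinimalPanel(alleleMat))

  ## two groups: one-per-group 2, minimal 1
  res2 <- new("SpecificityResults", lociIds = c("L1", "L2"),
              groups = c("B", "D"),
              fst = matrix(NA_real_, 2, 2,
                           dimnames = list(c("L1", "L2"), c("B", "D"))),
              assigned = c("B", "D"), groupAllele = c("G", "G"),
              alleleMatrix = matrix(c("G", "A", "A", "G"), 2, 2,
                                    dimnames = list(c("B", "D"),
                                                    c("L1", "L2"))),
              threshold = 0.9)
  expect_length(lociIds(selectCorePanel(res2, "one-per-group")), 2L)
  expect_length(lociIds(selectCorePanel(res2, "minimal")), 1L)

  ## constrained to sterile-cytoplasm candidates {C, H, T}
  pc <- constrainedPanel(res, c("C", "H", "T"), policy = "minimal")
  expect_length(lociIds(pc), 2L)
  p3 <- constrainedPanel(res, c("C", "H", "T"), policy = "one-per-group")
  expect_length(lociIds(p3), 3L)
  expect_length(lociIds(constrainedPanel(res, c("B", "D"))), 1L)
  expect_error(constrainedPanel(res, "C"), "at least 2")

  ## an uncovered group names itself in the error
  res3 <- res; res3@assigned[2] <- NA_character_
  expect_error(selectCorePanel(res3, "one-per-group"), "C")

  ## monotonicity: adding loci to a valid panel never breaks validity
  sigBig <- cbind(signatureMatrix(pm), alleleMat[, "L5", drop = FALSE])
  expect_s4_class(Panel(colnames(sigBig), sigBig, policy = "manual"),
                  "Panel")
})

test_that("MAF filter eliminates strictly below the threshold", {
  mkLocus <- function(nA, nT) {
    calls <- rep(c("A", "T"), c(nA, nT))
    VariantLocus("L", "SNP", 1L, 1L, c("A", "T"), match(calls, c("A", "T")))
  }
  ## singleton among 176 haploid samples: 1/176 < 1% -> eliminated
  out <- mafFilter(list(mkLocus(175, 1)))
  expect_length(out$eliminated, 1L)
  expect_equal(out$table$maf, 1 / 176, tolerance = 1e-12)
  ## exactly at the boundary -> kept (strict less-than)
  out2 <- mafFilter(list(mkLocus(99, 1)), threshold = 0.01)
  expect_length(out2$kept, 1L)
  expect_length(out2$eliminated, 0L)
  ## partition is exhaustive
  loci <- list(mkLocus(175, 1), mkLocus(100, 76), mkLocus(199, 2))
  out3 <- mafFilter(loci)
  expect_equal(length(out3$kept) + length(out3$eliminated), 3L)
  expect_error(mafFilter(loci, threshold = 0.6), "0.5")
})
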