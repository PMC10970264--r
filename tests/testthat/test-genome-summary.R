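revcompStr <- function(x)
  chartr("ACGT", "TGCA", paste(rev(strsplit(x, "")[[1]]), collapse = ""))

test_that("planted inverted repeats are detected at their exact boundaries", {
  set.seed(42)
  dna <- function(n) paste(sample(c("A","C","G","T"), n, TRUE), collapse = "")
  ir <- dna(2000)
  ## "AA" bookends block chance single-base extension of the planted
  ## repeat across the SSC boundaries, keeping the truth boundaries exact
  mid <- paste0("A", dna(1998), "A")
  genome <- paste0(dna(8000), ir, mid, revcompStr(ir))
  iv <- detectQuadripartite(genome, minIR = 1000)
  expect_equal(iv$length[iv$region == "IRa"], 2000L)
  expect_equal(iv$start[iv$region == "IRa"], 8001L)
  expect_equal(iv$end[iv$region == "IRb"], 14000L)
  expect_equal(iv$region[which.max(iv$length)], "LSC")
  expect_equal(sum(iv$length), nchar(genome))

  ## no repeat above the threshold -> structure-not-found
  expect_error(detectQuadripartite(dna(9000), minIR = 2000),
               "no reverse-complement repeat")

  ## one internal mismatch shrinks detection to the longest exact segment
  irMut <- ir
  substr(irMut, 500, 500) <- setdiff(c("A","C","G","T"),
                                     substr(ir, 500, 500))[1]
  genome2 <- paste0(dna(8000), irMut, mid, revcompStr(ir))
  iv2 <- detectQuadripartite(genome2, minIR = 1000)
  expect_equal(iv2$length[iv2$region == "IRa"], 1500L)
})

test_that("detection equals the quadratic brute-force repeat search", {
  set.seed(11)
  dna <- function(n) paste(sample(c("A","C","G","T"), n, TRUE), collapse = "")
  for (rep in 1:5) {
    ir <- dna(sample(120:200, 1))
    genome <- paste0(dna(300), ir, dna(150), revcompStr(ir))
    oracle <- bruteForceIR(genome)
    iv <- detectQuadripartite(genome, minIR = 100, k = 15)
    expect_equal(iv$length[iv$region == "IRa"], oracle$len)
    expect_equal(unname(unlist(
      iv[iv$region %in% c("IRa", "IRb"), c("start", "end")])),
      c(oracle$a[1], oracle$b[1], oracle$a[2], oracle$b[2]))
  }
})

test_that("genome summary computes GC, gene counts and the partition", {
  genome <- strrep("ATGC", 500)        # GC exactly 0.5
  map <- geneMap(c("g1", "g2", "g3"), c(11, 301, 1301), c(100, 400, 1380),
                 c("protein_coding", "tRNA", "rRNA"))
  iv <- regionIntervals(1200, 300, 200, total = 2000)
  s <- summarizeGenome(genome, map, iv)
  expect_equal(gcFraction(s), 0.5)
  expect_equal(unname(geneCounts(s)[c("total", "protein_coding", "tRNA",
                                      "rRNA")]), c(3L, 1L, 1L, 1L))
  ## genes count toward the region containing their start
  expect_equal(unname(regionGeneCounts(s)["LSC", "protein_coding"]), 1L)
  expect_equal(unname(regionGeneCounts(s)["IRa", "rRNA"]), 1L)
  expect_equal(sum(regionLengths(s)[c("LSC", "SSC")]) +
                 2 * regionLengths(s)[["IR"]], 2000)

  ## gene outside the genome is a coordinate error
  bad <- geneMap("g", 1999, 2100, "tRNA")
  expect_error(summarizeGenome(genome, bad, iv), "outside")
  ## intervals that do not partition the genome are rejected
  expect_error(summarizeGenome(genome, map, regionIntervals(100, 10, 20)),
               "partition")
})

test_that("summary of a synthetic panel matches its planted structure", {
  panel <- generatePanel(smallConfig(5L))
  s <- summarizeGenome(panel$reference, panel$geneMap,
                       minIR = 400)
  rl <- regionLengths(s)
  planted <- with(panel$regions, end - start + 1L)
  expect_equal(unname(rl[c("LSC", "IR", "SSC")]), planted[1:3])
  expect_equal(unname(geneCounts(s)[["total"]]), length(panel$geneMap))
  cats <- table(panel$geneMap$category)
  expect_equal(unname(geneCounts(s)[["protein_coding"]]),
               unname(cats[["protein_coding"]]))
})
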