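## Synthetic plastome-panel generator. Plants every feature the analysis
## assumes -- quadripartite reference, group-diagnostic loci, shared and
## singleton variants, gap-block InDels, invariant flanks, strictly
## maternal trios -- and records the complete truth, so downstream stages
## are testable without any external genome.

#' Configure the synthetic plastome-panel generator
#'
#' Defaults emulate the published study conditions at desk scale: five
#' chloroplast groups, a quadripartite genome whose region proportions
#' follow the outgroup reference genome (LSC 58.8\%, IR 16.1\%, SSC
#' 8.9\%), 60 bp invariant flanks around every planted locus, InDel
#' events from 1 to 85 bp, singleton private alleles rare enough to fall
#' under a 1\% minor-allele-frequency rule (175 base samples, so a
#' singleton has frequency ~0.006), and the study's cross structure
#' (13 trios, 3 reciprocal pairs, 3 CMS crosses) with strict maternal
#' plastome inheritance. The default 20 kb genome is a proportional
#' scale-down; the full ~140.6 kb scale is reachable by configuration.
#'
#' @param seed Master seed; all output is a pure function of the config.
#' @param genomeLength Genome size in bp.
#' @param regionLengths Named \code{c(LSC=, IR=, SSC=)}; default derived
#'   proportionally from \code{genomeLength}.
#' @param groups Chloroplast group labels.
#' @param samplesPerGroup Base (non-hybrid) samples per group.
#' @param nDiagnosticPerGroup Fixed-difference SNPs planted per group.
#' @param nSharedSnps SNPs segregating across multi-group subsets.
#' @param nIndels,indelLenRange,nDiagnosticIndels Gap-block InDel events,
#'   their span range in bp, and how many are group-diagnostic.
#' @param nRareAlleles Singleton SNPs (one carrier sample each).
#' @param flankWidth Invariant flank width around each planted locus;
#'   planted loci are pairwise separated by more than \code{2*flankWidth}.
#' @param trios Cross table (\code{mother_group}, \code{father_group},
#'   \code{type} in \code{trio}/\code{reciprocal}/\code{cms}); default
#'   \code{defaultCrosses()}.
#' @param cmsGroups Groups carrying male-sterile cytoplasm.
#' @param geneCounts Genes planted per category.
#' @return A validated \linkS4class{SimulationConfig}.
#' @export
simulationConfig <- function(seed = 1L, genomeLength = 20000L,
                             regionLengths = NULL,
                             groups = c("B", "C", "D", "H", "T"),
                             samplesPerGroup = 35L,
                             nDiagnosticPerGroup = 4L, nSharedSnps = 25L,
                             nIndels = 5L, indelLenRange = c(1L, 85L),
                             nDiagnosticIndels = 2L, nRareAlleles = 12L,
                             flankWidth = 60L, trios = defaultCrosses(),
                             cmsGroups = c("C", "T"),
                             geneCounts = c(protein_coding = 77L,
                                            tRNA = 29L, rRNA = 4L)) {
  genomeLength <- as.integer(genomeLength)
  if (is.null(regionLengths)) {
    ## proportions of the outgroup reference plastome (82,928 / 22,750 /
    ## 12,554 over 140,982 bp)
    lsc <- as.integer(round(genomeLength * 82928 / 140982))
    ir <- as.integer(round(genomeLength * 22750 / 140982))
    regionLengths <- c(LSC = lsc, IR = ir,
                       SSC = genomeLength - lsc - 2L * ir)
  }
  new("SimulationConfig", seed = as.integer(seed),
      genomeLength = genomeLength,
      regionLengths = setNames(as.integer(regionLengths),
                               names(regionLengths)),
      groups = groups, samplesPerGroup = as.integer(samplesPerGroup),
      nDiagnosticPerGroup = as.integer(nDiagnosticPerGroup),
      nSharedSnps = as.integer(nSharedSnps), nIndels = as.integer(nIndels),
      indelLenRange = as.integer(indelLenRange),
      nDiagnosticIndels = as.integer(nDiagnosticIndels),
      nRareAlleles = as.integer(nRareAlleles),
      flankWidth = as.integer(flankWidth), trios = trios,
      cmsGroups = cmsGroups,
      geneCounts = setNames(as.integer(geneCounts), names(geneCounts)))
}

#' @rdname simulationConfig
#' @export
defaultCrosses <- function() {
  g <- c("B", "C", "D", "H", "T")
  trio <- data.frame(mother_group = rep(g, length.out = 13L),
                     father_group = rep(c(g[-1L], g[1L]), length.out = 13L),
                     type = "trio", stringsAsFactors = FALSE)
  recip <- data.frame(mother_group = c("B", "C", "T"),
                      father_group = c("H", "D", "B"),
                      type = "reciprocal", stringsAsFactors = FALSE)
  cms <- data.frame(mother_group = c("C", "T", "H"),
                    father_group = c("B", "B", "D"),
                    type = "cms", stringsAsFactors = FALSE)
  rbind(trio, recip, cms)
}

#' Generate a synthetic aligned plastome panel with planted truth
#'
#' Produces an alignment panel, gene map and \linkS4class{TruthSet}.
#' Guarantees by construction: the reference genome's IRa is the exact
#' reverse complement of IRb; every group-diagnostic locus is fixed for
#' one allele inside its group and for the other allele everywhere else;
#' singleton alleles occur in exactly one sample; \code{flankWidth}
#' alignment columns on each side of every planted locus are invariant
#' across all samples; InDels are contiguous gap blocks with one shared
#' per-sample gap pattern; every hybrid's sequence is byte-identical to
#' its mother's. The first sample carries the ancestral state at all
#' InDel events so the emitted gene map and VCF share its ungapped
#' coordinate frame. There is no background mutation beyond the planted
#' loci, so truth recovery is exact.
#'
#' @param config A \linkS4class{SimulationConfig}.
#' @return List with elements \code{alignment}
#'   (\linkS4class{PlastomeAlignment}), \code{geneMap} (\code{GRanges}),
#'   \code{truth} (\linkS4class{TruthSet}), \code{reference} (ancestral
#'   genome string) and \code{regions} (planted LSC/IRa/SSC/IRb
#'   intervals).
#' @export
generatePanel <- function(config) {
  stopifnot(is(config, "SimulationConfig"))
  validObject(config)
  set.seed(config@seed)
  ## stream splitting: one pre-drawn sub-seed per stage, so later stages
  ## never perturb earlier draws
  sseed <- sample.int(.Machine$integer.max - 1L, 6L)

  rl <- config@regionLengths
  L <- rl[["LSC"]]; I <- rl[["IR"]]; S <- rl[["SSC"]]
  n <- config@genomeLength
  fw <- config@flankWidth

  ## stage 1: ancestral quadripartite genome
  set.seed(sseed[1L])
  lsc <- randomDna(L); ira <- randomDna(I); ssc <- randomDna(S)
  genome <- paste0(lsc, ira, ssc, revcomp(ira))
  chars <- strsplit(genome, "")[[1L]]
  regions <- data.frame(region = c("LSC", "IRa", "SSC", "IRb"),
                        start = c(1L, L + 1L, L + I + 1L, L + I + S + 1L),
                        end = c(L, L + I, L + I + S, n))

  ## stage 2: gene map
  set.seed(sseed[2L])
  map <- plantGenes(config, regions)

  ## stage 3: planted locus positions (single-copy regions only; pairwise
  ## start separation > 2*flankWidth + max InDel span keeps every flank
  ## invariant and every event inside its region)
  set.seed(sseed[3L])
  counts <- c(diagnostic = config@nDiagnosticPerGroup * length(config@groups),
              shared = config@nSharedSnps, indel = config@nIndels,
              rare = config@nRareAlleles)
  nLoci <- sum(counts)
  maxSpan <- if (config@nIndels > 0L) config@indelLenRange[2L] else 1L
  gap <- 2L * fw + maxSpan
  avail <- list(c(fw + 1L, L - maxSpan),
                c(L + I + 1L, L + I + S - maxSpan))
  lens <- vapply(avail, function(iv) iv[2L] - iv[1L] + 1L, integer(1L))
  virt <- sum(lens) - (nLoci - 1L) * gap
  if (virt < nLoci)
    stopf(paste0("capacity error: %d loci separated by > %d bp do not fit ",
                 "the %d bp of single-copy sequence"),
          nLoci, gap, sum(lens))
  vpos <- sort(sample.int(virt, nLoci)) + (seq_len(nLoci) - 1L) * gap
  pos <- ifelse(vpos <= lens[1L], avail[[1L]][1L] + vpos - 1L,
                avail[[2L]][1L] + (vpos - lens[1L]) - 1L)
  classes <- sample(rep(names(counts), counts))

  ## stage 4: samples, pedigree, allele patterns
  set.seed(sseed[4L])
  base <- data.frame(
    sample_id = unlist(lapply(config@groups, function(g)
      sprintf("%s%02d", g, seq_len(config@samplesPerGroup)))),
    group = rep(config@groups, each = config@samplesPerGroup),
    role = "cultivar", mother_id = NA_character_,
    father_id = NA_character_, stringsAsFactors = FALSE)
  ped <- assignPedigree(base, config)
  base <- ped$base
  mothers <- unique(ped$hybrids$mother_id)

  eligibleRare <- setdiff(base$sample_id[-1L], mothers)
  if (length(eligibleRare) < counts[["rare"]])
    stopf("not enough non-mother samples to host %d singletons",
          counts[["rare"]])
  rareHosts <- sample(eligibleRare, counts[["rare"]])

  nBase <- nrow(base)
  m <- matrix(rep(chars, each = nBase), nrow = nBase)
  rownames(m) <- base$sample_id

  diagGroups <- rep(config@groups, config@nDiagnosticPerGroup)
  indelDiag <- rep(c(TRUE, FALSE), c(config@nDiagnosticIndels,
                                     config@nIndels -
                                       config@nDiagnosticIndels))
  nonRefGroups <- setdiff(config@groups, base$group[1L])
  loci <- vector("list", nLoci)
  iDiag <- 0L; iIndel <- 0L; iRare <- 0L; iSnp <- 0L; iIdp <- 0L
  for (k in seq_len(nLoci)) {
    p <- pos[k]; cls <- classes[k]; ref <- chars[p]
    if (cls == "indel") {
      iIdp <- iIdp + 1L; iIndel <- iIndel + 1L
      span <- resample(seq(config@indelLenRange[1L],
                           config@indelLenRange[2L]), 1L)
      if (indelDiag[iIndel]) {
        grp <- resample(nonRefGroups, 1L); cls <- "diagnostic"
        carrierGroups <- grp
      } else {
        cls <- "shared"
        carrierGroups <- sort(resample(nonRefGroups, resample(2:3, 1L)))
        grp <- NA_character_
      }
      rows <- base$group %in% carrierGroups
      m[rows, p:(p + span - 1L)] <- "-"
      loci[[k]] <- data.frame(
        locus_id = sprintf("CPMIDP%02d", iIdp), kind = "InDel",
        start = p, end = p + span - 1L, class = cls, group = grp,
        ref_allele = substr(genome, p, p + span - 1L), alt_allele = "",
        carrier_groups = paste(carrierGroups, collapse = ";"),
        carriers = NA_character_, stringsAsFactors = FALSE)
    } else {
      iSnp <- iSnp + 1L
      alt <- resample(setdiff(c("A", "C", "G", "T"), ref), 1L)
      if (cls == "diagnostic") {
        iDiag <- iDiag + 1L; grp <- diagGroups[iDiag]
        rows <- base$group == grp
        cgs <- grp
      } else if (cls == "shared") {
        cgs <- sort(resample(config@groups, resample(2:3, 1L)))
        rows <- base$group %in% cgs
        grp <- NA_character_
      } else { # rare singleton
        iRare <- iRare + 1L
        host <- rareHosts[iRare]
        rows <- base$sample_id == host
        cgs <- NA_character_
        grp <- NA_character_
      }
      m[rows, p] <- alt
      loci[[k]] <- data.frame(
        locus_id = sprintf("CPMSNP%02d", iSnp), kind = "SNP",
        start = p, end = p, class = cls, group = grp,
        ref_allele = ref, alt_allele = alt,
        carrier_groups = paste(cgs, collapse = ";"),
        carriers = NA_character_, stringsAsFactors = FALSE)
    }
  }
  lociDf <- do.call(rbind, loci)

  ## hybrids: byte-identical copies of their mothers
  hyb <- ped$hybrids
  if (nrow(hyb)) {
    hm <- m[hyb$mother_id, , drop = FALSE]
    rownames(hm) <- hyb$sample_id
    m <- rbind(m, hm)
  }
  sheet <- rbind(base, hyb[, colnames(base)])
  sheet$fertility <- fertilityFor(sheet$group, config@cmsGroups)
  sheet <- completeSampleSheet(sheet)

  ## truth carriers = every sample (hybrids included) holding the alt
  lociDf$carriers <- vapply(seq_len(nrow(lociDf)), function(i) {
    cls <- lociDf$class[i]
    if (cls == "rare") {
      host <- rownames(m)[m[, lociDf$start[i]] == lociDf$alt_allele[i]]
      return(paste(host, collapse = ";"))
    }
    cgs <- strsplit(lociDf$carrier_groups[i], ";")[[1L]]
    paste(sheet$sample_id[sheet$group %in% cgs], collapse = ";")
  }, character(1L))

  seqs <- apply(m, 1L, paste, collapse = "")
  aln <- PlastomeAlignment(seqs, sheet)
  truth <- new("TruthSet", loci = lociDf, samples = sheet)
  list(alignment = aln, geneMap = map, truth = truth,
       reference = genome, regions = regions)
}

fertilityFor <- function(group, cmsGroups) {
  ifelse(group %in% cmsGroups, "sterile",
         ifelse(group == "H", "unknown", "fertile"))
}

## Consume samples of each group as parents; returns updated base sheet
## (roles) and the hybrid rows. Reciprocal crosses reuse one parent pair in
## both directions; CMS crosses are plain trios whose mother carries
## sterile cytoplasm.
assignPedigree <- function(base, config) {
  used <- setNames(integer(length(config@groups)), config@groups)
  ## sample 1 is the coordinate reference; never a parent
  used[base$group[1L]] <- 1L
  takeParent <- function(grp) {
    used[grp] <<- used[grp] + 1L
    if (used[grp] > config@samplesPerGroup)
      stopf("samplesPerGroup too small to supply parents for group %s", grp)
    base$sample_id[base$group == grp][used[grp]]
  }
  hybrids <- list(); k <- 0L
  for (i in seq_len(nrow(config@trios))) {
    tr <- config@trios[i, ]
    mo <- takeParent(tr$mother_group); fa <- takeParent(tr$father_group)
    k <- k + 1L
    hybrids[[length(hybrids) + 1L]] <- data.frame(
      sample_id = sprintf("HYB%02d", k), group = tr$mother_group,
      role = "hybrid", mother_id = mo, father_id = fa,
      stringsAsFactors = FALSE)
    if (tr$type == "reciprocal") {
      k <- k + 1L
      hybrids[[length(hybrids) + 1L]] <- data.frame(
        sample_id = sprintf("HYB%02d", k), group = tr$father_group,
        role = "hybrid", mother_id = fa, father_id = mo,
        stringsAsFactors = FALSE)
    }
  }
  hybrids <- if (length(hybrids)) do.call(rbind, hybrids) else
    data.frame(sample_id = character(0L), group = character(0L),
               role = character(0L), mother_id = character(0L),
               father_id = character(0L), stringsAsFactors = FALSE)
  base$role[base$sample_id %in% c(hybrids$mother_id, hybrids$father_id)] <-
    "parent"
  list(base = base, hybrids = hybrids)
}

## Deterministic gene placement: per category, region quotas follow the
## published per-region distribution (protein 62/11/4, tRNA 24/1/4, rRNA
## 0/0/4 over LSC/SSC/IR), rescaled to the configured counts. Genes are
## laid out on an even grid inside each region; IR genes sit in IRa only.
plantGenes <- function(config, regions) {
  quota <- list(protein_coding = c(LSC = 62, SSC = 11, IRa = 4),
                tRNA = c(LSC = 24, SSC = 1, IRa = 4),
                rRNA = c(LSC = 0, SSC = 0, IRa = 4))
  rows <- list()
  for (cat in names(config@geneCounts)) {
    total <- config@geneCounts[[cat]]
    if (total == 0L) next
    q <- quota[[cat]]
    cnt <- round(q / sum(q) * total)
    cnt[1L] <- total - sum(cnt[-1L])
    for (reg in names(cnt)) {
      nr <- cnt[[reg]]
      if (nr <= 0L) next
      iv <- regions[regions$region == reg, ]
      slot <- (iv$end - iv$start + 1L) %/% nr
      if (slot < 45L)
        stopf("region %s too small for %d %s genes", reg, nr, cat)
      phase <- 5L + 11L * (match(cat, names(config@geneCounts)) - 1L)
      starts <- iv$start + (seq_len(nr) - 1L) * slot + phase
      len <- pmin(sample(60:120, nr, replace = TRUE), slot - 10L,
                  iv$end - starts + 1L)
      rows[[length(rows) + 1L]] <- data.frame(
        gene = sprintf("%s%03d_%s", switch(cat, protein_coding = "pcg",
                                           tRNA = "trn", rRNA = "rrn"),
                       seq_len(nr), reg),
        start = starts, end = starts + len - 1L, category = cat,
        region = reg, stringsAsFactors = FALSE)
    }
  }
  df <- do.call(rbind, rows)
  geneMap(df$gene, df$start, df$end, df$category, df$region)
}

#' Write a synthetic scenario to disk
#'
#' Emits exactly the four files the pipeline consumes: \code{panel.fasta}
#' (aligned panel), \code{samples.tsv} (sample sheet),
#' \code{genes.bed} (gene map) and \code{truth.tsv} (planted loci).
#'
#' @param config A \linkS4class{SimulationConfig}.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the generated panel (as \code{\link{generatePanel}}).
#' @export
emitFixture <- function(config, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  panel <- generatePanel(config)
  writeAlignment(panel$alignment, file.path(dir, "panel.fasta"),
                 file.path(dir, "samples.tsv"))
  writeGeneMap(panel$geneMap, file.path(dir, "genes.bed"))
  writeTruthSet(panel$truth, file.path(dir, "truth.tsv"))
  invisible(panel)
}

#' @rdname emitFixture
#' @param truth A \linkS4class{TruthSet}.
#' @param path Truth TSV path (columns: locus id, alignment columns,
#'   kind, class, group, alleles, carriers).
#' @export
writeTruthSet <- function(truth, path) {
  df <- truthLoci(truth)
  df$ref_allele[!nzchar(df$ref_allele)] <- "-"
  df$alt_allele[!nzchar(df$alt_allele)] <- "-"
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' @rdname emitFixture
#' @param lociPath,sheetPath Paths to the truth TSV and (optionally) the
#'   matching sample sheet.
#' @export
readTruthSet <- function(lociPath, sheetPath = NULL) {
  df <- utils::read.delim(lociPath, stringsAsFactors = FALSE,
                          colClasses = "character", na.strings = "")
  for (col in c("start", "end")) df[[col]] <- as.integer(df[[col]])
  df$ref_allele[df$ref_allele == "-"] <- ""
  df$alt_allele[df$alt_allele == "-"] <- ""
  samples <- if (is.null(sheetPath))
    data.frame(sample_id = character(0L)) else readSampleSheet(sheetPath)
  new("TruthSet", loci = df, samples = samples)
}
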