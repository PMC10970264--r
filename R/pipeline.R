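#' Configure an end-to-end pipeline run
#'
#' Bundles the stage parameters (flank width, MAF and F_ST thresholds,
#' panel policy, Tm target) with either input paths or a simulation
#' config. Thresholds are validated here so a bad value fails before
#' any stage runs; the resolved configuration is logged and written into
#' the run manifest.
#'
#' @param outDir Run directory (created by \code{\link{runPipeline}}).
#' @param fasta,sheet,genes Input paths; all \code{NULL} to simulate.
#' @param simulation A \linkS4class{SimulationConfig} used when no
#'   inputs are given.
#' @param flankWidth Flank width in bp (default 60).
#' @param mafThreshold MAF elimination threshold (default 0.01).
#' @param fstThreshold Specificity threshold (default 0.9).
#' @param panelPolicy \code{"one-per-group"} or \code{"minimal"}.
#' @param tmTarget KASP primer target Tm in deg C (default 58).
#' @param minIR Minimum IR length for structure detection; default
#'   scales with the genome.
#' @param seed Seed recorded for the simulation stage.
#' @return A validated config list of class \code{pipelineConfig}.
#' @export
pipelineConfig <- function(outDir, fasta = NULL, sheet = NULL, genes = NULL,
                           simulation = NULL, flankWidth = 60L,
                           mafThreshold = 0.01, fstThreshold = 0.9,
                           panelPolicy = c("one-per-group", "minimal"),
                           tmTarget = 58, minIR = NULL, seed = 1L) {
  panelPolicy <- match.arg(panelPolicy)
  if (fstThreshold <= 0 || fstThreshold > 1)
    stopf("fstThreshold must lie in (0, 1]")
  if (mafThreshold <= 0 || mafThreshold >= 0.5)
    stopf("mafThreshold must lie in (0, 0.5)")
  if (flankWidth < 1L) stopf("flankWidth must be >= 1")
  if (tmTarget < 30 || tmTarget > 80)
    stopf("tmTarget of %.1f deg C is outside any usable assay range", tmTarget)
  if (is.null(fasta) != is.null(sheet))
    stopf("fasta and sheet must be supplied together")
  if (is.null(fasta) && is.null(simulation))
    simulation <- simulationConfig(seed = seed)
  structure(list(outDir = outDir, fasta = fasta, sheet = sheet,
                 genes = genes, simulation = simulation,
                 flankWidth = as.integer(flankWidth),
                 mafThreshold = mafThreshold, fstThreshold = fstThreshold,
                 panelPolicy = panelPolicy, tmTarget = tmTarget,
                 minIR = minIR, seed = as.integer(seed)),
            class = "pipelineConfig")
}

#' Run the full marker-panel pipeline
#'
#' Stages: (simulate if no inputs) -> genome summary -> variant calling
#' (SNPs + merged InDels, annotation, flanks) -> VCF/TSV export -> MAF
#' filter -> one-vs-rest F_ST specificity scan -> core panel selection
#' -> KASP design for the panel loci -> trio lineage tracing ->
#' cytoplasm classification. Every artifact lands in \code{outDir} and
#' is listed with its MD5 in \code{manifest.json}; reruns with an
#' identical config produce byte-identical tracked outputs (no stage
#' reads the clock or unseeded randomness). A stage failure halts the
#' run with the stage name in the error.
#'
#' @param config A \code{\link{pipelineConfig}}.
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list with the main in-memory results
#'   (alignment, loci, specificity, panel, markers, trios, cytoplasm,
#'   summary, manifest path).
#' @export
runPipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "pipelineConfig"))
  dir.create(config$outDir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message(sprintf(...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
  }
  out <- function(f) file.path(config$outDir, f)

  if (is.null(config$fasta)) {
    say("stage simulate: seed %d", config$simulation@seed)
    panel0 <- stage("simulate", emitFixture(config$simulation,
                                            out("inputs")))
    aln <- panel0$alignment; map <- panel0$geneMap
  } else {
    say("stage load: %s", config$fasta)
    aln <- stage("load", readAlignment(config$fasta, config$sheet))
    map <- if (is.null(config$genes)) geneMap(character(0L), integer(0L),
                                              integer(0L), character(0L))
    else stage("load", readGeneMap(config$genes))
  }

  refSeq <- gsub("-", "", as.character(aln@seqs[[1L]]))
  minIR <- config$minIR %||% max(200L, nchar(refSeq) %/% 40L)
  summary <- stage("summarize", {
    s <- summarizeGenome(refSeq, map, minIR = minIR)
    writeSummaryTsv(s, out("genome_summary.tsv"))
    s
  })

  say("stage call-variants")
  loci <- stage("call-variants",
                callVariants(aln, map, config$flankWidth))
  stage("call-variants",
        writeVariants(loci, aln, out("variants.vcf"), out("variants.tsv")))
  inv <- variantInventory(loci, nchar(refSeq))
  jsonlite::write_json(list(n = inv$n, snp = inv$counts[["SNP"]],
                            indel = inv$counts[["InDel"]],
                            bp_per_variant = inv$density),
                       out("inventory.json"), auto_unbox = TRUE)

  say("stage select-panel (MAF < %.3f, F_ST > %.2f, %s)",
      config$mafThreshold, config$fstThreshold, config$panelPolicy)
  maf <- stage("select-panel", mafFilter(loci, config$mafThreshold))
  spec <- stage("select-panel",
                assignSpecificity(maf$kept, aln, config$fstThreshold))
  writeFstTable(spec, out("fst_by_group.tsv"))
  panel <- stage("select-panel",
                 selectCorePanel(spec, config$panelPolicy,
                                 columns = lociColumns(maf$kept)))

  say("stage design-kasp (%d panel loci)", length(lociIds(panel)))
  kept <- setNames(maf$kept, vapply(maf$kept, slot, character(1L), "id"))
  markers <- stage("design-kasp", lapply(lociIds(panel), function(id) {
    lc <- kept[[id]]
    designKasp(lc, tmTarget = config$tmTarget)
  }))
  rows <- do.call(rbind, lapply(seq_along(markers), function(i) {
    id <- lociIds(panel)[i]
    j <- match(id, spec@lociIds)
    markerRow(markers[[i]], spec@assigned[j], spec@groupAllele[j])
  }))
  writeMarkerTable(rows, out("panel_markers.tsv"))
  audit <- auditMarkerTable(rows)
  utils::write.table(audit, out("marker_audit.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  say("stage trace-lineage")
  trios <- stage("trace-lineage", traceTrios(aln, panel))
  utils::write.table(trios, out("trios.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  gt <- genotypeAtPanel(aln, panel)
  cyto <- do.call(rbind, lapply(rownames(gt), function(sid)
    classifyCytoplasm(gt[sid, ], panel, sampleId = sid)))
  utils::write.table(cyto, out("cytoplasm.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)

  manifest <- writeManifest(config, out)
  say("run complete: %s", config$outDir)
  invisible(list(alignment = aln, geneMap = map, summary = summary,
                 loci = loci, maf = maf, specificity = spec, panel = panel,
                 markers = markers, audit = audit, trios = trios,
                 cytoplasm = cyto, manifest = manifest))
}

writeSummaryTsv <- function(s, path) {
  rl <- regionLengths(s); gc <- geneCounts(s)
  df <- data.frame(
    metric = c("total_bp", "lsc_bp", "ir_bp", "ssc_bp", "gc_fraction",
               "genes_total", "genes_protein_coding", "genes_tRNA",
               "genes_rRNA"),
    value = c(rl[["total"]], rl[["LSC"]], rl[["IR"]], rl[["SSC"]],
              round(s@gcFraction, 4L), gc[["total"]],
              gc[["protein_coding"]], gc[["tRNA"]], gc[["rRNA"]]))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

writeFstTable <- function(spec, path) {
  df <- data.frame(locus_id = spec@lociIds, round(spec@fst, 6L),
                   assigned = ifelse(is.na(spec@assigned), "/",
                                     spec@assigned),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

## manifest: resolved config + md5 of every tracked artifact (no clock,
## so identical configs give identical manifests)
writeManifest <- function(config, out) {
  files <- sort(setdiff(list.files(config$outDir, recursive = TRUE),
                        "manifest.json"))
  md5 <- tools::md5sum(file.path(config$outDir, files))
  cfg <- config
  cfg$simulation <- if (!is.null(config$simulation))
    list(seed = config$simulation@seed,
         genomeLength = config$simulation@genomeLength,
         samplesPerGroup = config$simulation@samplesPerGroup)
  path <- out("manifest.json")
  jsonlite::write_json(list(config = cfg[!vapply(cfg, is.null, logical(1L))],
                            files = as.list(setNames(unname(md5), files))),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
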