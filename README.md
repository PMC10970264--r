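# chloroPanel

Chloroplast marker-panel discovery, KASP assay design and maternal
lineage tracing for plastome alignment panels.

## The problem

Maize breeding needs two calls that nuclear markers cannot make:
*which parent was the mother* of a hybrid (a reciprocal cross pair
A×B / B×A is nuclear-identical) and *which cytoplasm* a line carries
(C-, S- and T-type cytoplasmic male sterility ride on distinct
chloroplast lineages). The plastome is maternally inherited, haploid,
homozygous and highly conserved, so a small panel of plastome SNP and
InDel markers — a **Varietal Chloroplast Panel (VCP)** — genotyped by
allele-specific PCR (KASP) resolves both.

`chloroPanel` implements the complete in-silico pipeline around such a
panel, for anyone designing or validating organellar marker sets from
aligned genomes:

* **Variant discovery** from an aligned plastome panel: SNP column
  scan plus merging of adjacent gap columns with one shared gap
  pattern into single InDel events; gene-map annotation; extraction
  and vetting of 60 bp conserved flanks.
* **Specificity scan**: per locus and chloroplast group, one-vs-rest
  Weir–Cockerham F_ST on homozygous pseudo-diploids,

      theta = a / (a + b),   a,b = WC84 variance components (h = 0)

  with a locus assigned a *specific type* iff exactly one group
  exceeds the threshold (default 0.9). A fixed difference scores
  exactly 1.
* **Panel selection**: the `one-per-group` core-set rule (best locus
  per group) or an exact `minimal` search for the smallest locus set
  whose group signature rows are pairwise distinct; constrained panels
  for restricted candidate sets (e.g. material known sterile).
* **KASP design**: two allele-specific primers ending on the
  discriminating base (shortest 18–35-mer reaching a 58 °C
  nearest-neighbor Tm) plus a common primer from the opposite flank,
  on whichever strand balances the assay; an **audit** that checks any
  marker table (including the packaged published one) for 3′-terminus
  / allele consistency and primer-in-flank containment.
* **Lineage tracing**: strict-concordance trio maternal assignment,
  reciprocal-cross resolution and cytoplasm-type classification.
* **Synthetic plastome panels** with planted ground truth
  (quadripartite genome, diagnostic/shared/singleton loci, gap-block
  InDels, strictly maternal trios), so every stage is testable offline
  and truth recovery is exact.

The published 59-marker maize VCP table ships with the package
(`vcpMarkers()`).

## Worked example

```r
library(chloroPanel)

## the packaged published marker set: 59 markers, 49 with a specific type
mk   <- vcpMarkers()
spec <- specificityFromMarkerTable(mk)
selectCorePanel(spec, "one-per-group")
#> Panel (one-per-group): 5 loci over 5 groups
#>   CPMSNP01 CPMSNP18 CPMSNP07 CPMIDP01  CPMSNP03
#> B T        T        G        <del>     C
#> C G        G        G        <del>     C
#> D G        T        T        <del>     C
#> H G        T        G        ACTGT...  C
#> T G        T        G        <del>     G
length(lociIds(selectCorePanel(spec, "minimal")))
#> [1] 4
```

One locus per group discriminates all five chloroplast groups; the
exact minimal search drops one indicator because the residual group's
all-"rest" signature row is still unique. (Published F_ST values are
not recomputable from a table, so the one-per-group choice above falls
back to lexicographic locus order within each group.)

End to end on a synthetic panel (seed 1, 20 kb desk-scale genome, 175
samples + 22 hybrids):

```r
sim  <- generatePanel(simulationConfig(seed = 1))
loci <- callVariants(sim$alignment, sim$geneMap)
variantInventory(loci, nchar(sim$reference))$counts
#>   SNP InDel
#>    57     5            # 62 loci, one per 323 bp

res   <- assignSpecificity(mafFilter(loci)$kept, sim$alignment)
res
#> SpecificityResults: 50 loci x 5 groups (threshold 0.90)
#>   specific: 22; unassigned: 28
#>   by group: B=4 C=4 D=5 H=5 T=4
panel <- selectCorePanel(res, "one-per-group", columns = lociColumns(loci))
table(traceTrios(sim$alignment, panel)$verdict)
#> maternal=mother
#>              22
```

The 12 planted singletons fall below the 1 % minor-allele-frequency
rule (62 − 12 = 50 loci survive), the 22 planted diagnostic loci are
the 22 assigned specific types, and every hybrid traces to its true
mother — as the generator guarantees by construction.

A thin command-line wrapper over the same functions is installed at
`inst/scripts/chloropanel` (subcommands `simulate`, `summarize`,
`call-variants`, `select-panel`, `design-kasp`, `trace-lineage`,
`validate-table2`, `run-all`).

## Package layout

| Area | Functions |
| --- | --- |
| I/O | `readAlignment`, `writeAlignment`, `readMarkerTable`, `writeMarkerTable`, `readGeneMap`, `writeVariants` (VCF 4.2 + TSV), `readTruthSet` |
| Simulation | `simulationConfig`, `generatePanel`, `emitFixture` |
| Genome structure | `detectQuadripartite`, `summarizeGenome`, `regionIntervals` |
| Variants | `callSNPs`, `callIndels`, `callVariants`, `annotateVariants`, `extractFlanks`, `variantInventory` |
| Specificity & panels | `fstOneVsRest`, `assignSpecificity`, `mafFilter`, `selectCorePanel`, `constrainedPanel` |
| KASP | `estimateTm`, `designKasp`, `auditMarkerTable` |
| Lineage | `genotypeAtPanel`, `assignMaternal`, `traceTrios`, `classifyCytoplasm` |
| Orchestration | `pipelineConfig`, `runPipeline` |

See the methods vignette (`vignettes/chloroPanel-methods.Rmd`) for the
models, parameter defaults and design rationale.
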