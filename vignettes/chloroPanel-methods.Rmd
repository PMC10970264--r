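---
title: "Chloroplast marker panels: models, parameters and design choices"
author: "chloroPanel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Chloroplast marker panels: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chloroPanel)
```

# The problem

Nuclear markers cannot see two things breeders routinely need to see in
maize: which parent was the mother of a hybrid (reciprocal crosses have
identical nuclear expectations) and which cytoplasm a line carries
(cytoplasmic male sterility — CMS — rides on the organellar genomes).
The chloroplast genome (plastome) is maternally inherited, effectively
haploid and homozygous, and highly conserved within a species, so a
small panel of plastome SNP/InDel markers — a *Varietal Chloroplast
Panel* (VCP) — genotyped on an allele-specific PCR platform (KASP)
answers both questions cheaply.

`chloroPanel` implements the full in-silico side of building and using
such a panel: variant discovery from an aligned plastome panel, locus
filtering, group-specificity assignment by one-vs-rest F~ST~, minimal
discriminating panel selection, KASP primer construction from conserved
flanks, and trio/reciprocal/CMS validation logic. A synthetic plastome
generator with planted ground truth makes every stage testable without
any external genomes.

# Data model

The central container is the `PlastomeAlignment`: an aligned,
equal-width set of haploid sequences over `{A,C,G,T,N,-}` (a
`DNAStringSet`) plus a sample sheet carrying the chloroplast group
label (`B`, `C`, `D`, `H`, `T`), role, pedigree links and fertility
status. All analysis coordinates are **1-based, closed** alignment
columns — the IRanges/GRanges convention used throughout Bioconductor —
and conversion to other conventions happens only at format boundaries
(0-based half-open at BED, 1-based with left-anchoring at VCF). Keeping
the single internal convention of the host ecosystem, rather than a
0-based one, avoids adapter code at every Bioconductor touch point.

Variant loci (`VariantLocus`) are SNP columns or merged InDel events;
deletion alleles are the empty string internally, and the `-` sentinel
exists only in external tables. Group-specificity scans return a
`SpecificityResults` (per-locus, per-group F~ST~ matrix plus the
per-group majority-allele matrix), and panels are `Panel` objects whose
validity *is* the discrimination property: construction fails unless
all group signature rows are pairwise distinct.

# Variant discovery

SNP calling is a column scan — on aligned sequences this is equivalent
to exhaustive pairwise comparison. A column yields a SNP iff it is
gap-free and shows at least two distinct non-`N` bases. `N` is missing
data, never an allele: a column polymorphic only because of `N` is not
a locus, because a marker whose "polymorphism" is an artifact of
missing calls cannot produce the unambiguous fluorescence clusters the
assay requires.

Gap-containing columns belong to InDel events. Maximal runs of
adjacent gap columns sharing one per-sample gap pattern are merged
into a single locus; a pattern change splits the run. Pattern-identity
merging (not mere adjacency) is deliberate: two overlapping deletions
carried by different sample sets are genuinely different events and
must stay separate markers, while one multi-column event mistakenly
treated as several markers would be redundant — the published panel
itself had to retroactively merge two such InDel markers into one.

Each locus's flanks (default 60 bp each side) are vetted: a marker is
designable only when both flanks are identical, gap-free and N-free
across *all* samples, since the allele-specific primers must anneal
identically in every line. Variant density is reported as ungapped
genome length divided by locus count; the denominator choice is stated
in the function documentation because published densities are often
not reconstructible from published counts.

# One-vs-rest Weir–Cockerham F~ST~ and specificity

For each locus and each group we compute the Weir–Cockerham (1984)
ratio-of-averages estimator between two populations: the focal group
and all remaining samples pooled. One-vs-rest is the only contrast
that yields one value per (locus, group) pair, which is what a
per-group specificity display requires. Chloroplast calls are haploid
and homozygous, so samples enter as homozygous pseudo-diploids and all
heterozygosity terms vanish — this mirrors what standard VCF tooling
does when handed such data, so the numbers are comparable to published
ones. With observed heterozygosity zero and two populations the
components reduce to

$$a = \frac{\bar n}{n_c}\left[s^2 - \frac{\bar p\bar q - s^2/2}{\bar n - 1}\right],
\qquad b = \frac{\bar n}{\bar n - 1}\left(\bar p\bar q - s^2/2\right),
\qquad \hat\theta = \frac{a}{a+b}.$$

A fixed difference gives $b = 0$ and hence exactly 1 (the
implementation returns the analytic 1, not its floating-point image);
equal frequencies give an estimate at or below 0. Negative estimates
are reported as computed, never clamped, and compared to the threshold
as-is. Multi-allelic loci are collapsed to focal-group majority allele
versus everything else before estimation; a full multi-allelic
estimator is out of scope and would change the semantics of the
published threshold.

A locus is assigned a specific type iff **exactly one** group exceeds
the threshold (default 0.9, the published rule). The exactly-one rule
matters: a locus whose derived allele is shared by two groups can
exceed the threshold for neither — or, at a multi-allelic locus, for
both — and in either case it identifies no single group, which is what
a single "specific type" column can express.

# Panel selection

Two policies are exposed because the published material uses both
framings. `one-per-group` picks, per group, the specific locus with
maximal F~ST~ (ties, and the all-`NA` F~ST~ of a published table,
resolve to the lexicographically earliest locus id — deterministic and
reproducible); the panel size equals the group count. `minimal` finds
the smallest subset whose group signature rows are pairwise distinct,
by exhaustive search over *distinct signature patterns* — duplicate
patterns can never separate an additional pair of groups, so
deduplicating first keeps the search exact while making it trivially
cheap at realistic panel sizes (patterns are few even when specific
loci are many). With one indicator locus per group the minimal panel
drops exactly one indicator: the residual group is the unique row
carrying the "rest" allele everywhere.

`constrainedPanel` applies the same machinery to a candidate subset of
groups, which is how external knowledge (e.g. material known sterile
restricts candidates to the sterile-cytoplasm groups C/H/T) shrinks
the assay further: three candidates need two loci under `minimal`,
three under `one-per-group`.

# KASP design and the marker-table audit

A KASP assay is two allele-specific primers (FAM and HEX channels)
whose 3′-terminal base discriminates the alleles, plus a common primer
on the opposite strand. The designer takes each allele primer as the
suffix of (left flank + allele) ending exactly at the first base that
differs between the two allele haplotypes — for SNPs the variant base
itself — at the shortest length in 18–35 nt reaching the target Tm
(default 58 °C, the assay's annealing temperature); the common primer
is the reverse complement of a right-flank prefix window chosen the
same way. Both strands are tried; the reverse-strand design wins when
the forward strand cannot reach the target Tm or when its
FAM/HEX Tm balance is strictly better. Published tables contain both
orientations without stating a rule, so the audit records orientation
and the designer's strand rule is the package's own. Universal FAM/HEX
tail sequences are not prepended — published tables print tail-less
primers — and no deliberate secondary mismatches are introduced, since
the published primers are exact flank substrings.

Tm uses nearest-neighbor thermodynamics (unified SantaLucia parameter
set, 50 mM monovalent salt, 200 nM primer, entropy-based salt
correction), pinned in the package source so results are
deterministic; the Wallace 2+4 rule is available for quick estimates.
The test suite cross-checks the model against an independent reference
implementation to within 0.5 °C.

Insertions of 50 bp or more cannot be bridged by a 35 nt allele primer
ending at the discriminating base and reading into ordinary flank, so
the designer switches to a two-flank layout (no common primer, both
flank records emitted) mirroring the layout the published table uses
for its large-InDel marker; such rows are flagged, not rejected — one
published row prints no common primer at all, and a parser that
rejected it would lose a real marker.

The audit (`auditMarkerTable`) is the in-silico analogue of assay
validation: SNP rows must have 3′ bases jointly equal to the alleles
(forward) or their complements (reverse); rows with flank data must
contain every primer within flank + allele + flank on one strand;
InDel rows are checked for allele length difference. The audit reports
findings and never repairs data.

# Lineage logic

Maternal assignment is strict: the verdict names a parent only when
the hybrid matches that parent at **every** locus where both calls are
non-missing and differs from the other parent at one or more. Parents
with identical panel signatures give `ambiguous` — with maternally
inherited, non-recombining markers that is an information-theoretic
limit, and guessing would be wrong. A configurable mismatch budget
(default 0) exists for noisy real data; any nonzero use is announced
loudly because it weakens the guarantee. Cytoplasm classification
returns candidate labels, not a fertility verdict: group H contains
both the S-type CMS lineage and fertile cultivars, so markers alone
cannot call fertility, and the package does not pretend otherwise.
Known fertility instead restricts the candidate groups before
matching.

# The synthetic generator: what it emulates, and what it does not

`generatePanel` plants, on a quadripartite reference
(LSC–IRa–SSC–IRb, IRa the exact reverse complement of IRb, region
proportions those of a published outgroup plastome):

* group-diagnostic SNPs and InDels — fixed for one allele in their
  group, the other allele everywhere else;
* shared variants segregating across 2–3 group subsets (plastome
  variation is haplotype-structured, not sample-random);
* singleton private alleles, hosted only by samples that are never
  mothers, so they stay singletons after hybrids are added;
* InDels as contiguous gap blocks of 1–85 bp with one shared gap
  pattern (the pipeline consumes alignments, so simulating
  post-alignment state is faithful and avoids bundling an aligner);
* a cross structure of 13 trios, 3 reciprocal pairs and 3 CMS crosses,
  every hybrid byte-identical to its mother;
* a 110-gene map (77 protein-coding, 29 tRNA, 4 rRNA) distributed over
  the regions in the published per-region proportions.

Planted loci are pairwise separated by more than twice the flank width
plus the maximal InDel span, so every flank is invariant by
construction. There is **no background mutation** (an intentionally
conservative model of a highly conserved intraspecific plastome
panel), which is what makes truth recovery exact: on any seed, called
loci must equal planted loci one-for-one. Passing those tests
therefore demonstrates correctness of the calling/merging/filtering
logic under the stated model — it does not demonstrate robustness to
alignment error, sequencing error or paralogous IR variation, none of
which the generator emulates. The first sample always carries the
ancestral state at InDel events so that the emitted gene map and VCF
share its ungapped coordinate frame.

Seeding is split into per-stage streams drawn once from the master
seed, so extending one stage never perturbs the draws of another.
Defaults are desk-scale: a 20 kb genome (proportionally scaled
regions) with 35 samples per group, which keeps a singleton's
frequency (≈0.006 among ~197 samples) below the 1 % MAF rule exactly
as at full scale; the full ~140.6 kb × 176-sample scale is reachable
by configuration. The test suite runs its broad property sweeps at a
further-reduced 8 kb scale and its 20-seed truth-recovery sweep at
20 kb with 20 samples per group — above the 100-sample point where the
strict <1 % rule still eliminates singletons — sizes chosen to keep
the default check fast while preserving every regime the assertions
depend on.

# Numerical and degenerate-input choices

* F~ST~ at a fixed difference returns the analytic 1; monomorphic loci
  return `NA` with a warning (an explicit "undefined", not a silent
  0); fewer than two non-missing samples on either side is an error.
* MAF uses a strict `<` at the boundary, so frequency exactly 1 % is
  kept, matching the published "less than 1 %" elimination wording.
  For multi-allelic loci the MAF is the frequency of the most frequent
  non-major allele, which is always in [0, 0.5].
* Quadripartite detection anchors 31-mers between the sequence and its
  reverse complement and extends to maximal exact matches, so an IR
  with one internal mismatch resolves to the longest exact segment
  pair; sequences are treated as linear (plastome records are
  conventionally rotated to start in a single-copy region, and the
  single-copy region spanning the ends is reported as one wrapping
  segment). The detector is tested for equality against a quadratic
  brute-force repeat search on toy genomes.
* Genes spanning a region boundary count toward the region containing
  their start — arbitrary but fixed and documented.
* VCF output left-anchors InDels on the last reference base before the
  event (falling back to right-anchoring only at position 1), writes
  haploid genotypes, and is validated in the test suite by re-parsing
  with an independent VCF reader.
* Primer-length ties cannot occur (the shortest window reaching Tm is
  unique); orientation ties prefer the forward strand.

# Limitations

The package analyses alignments; it does not assemble, align or
annotate genomes, call variants from reads, model KASP chemistry, or
screen primers against a genome for off-target annealing. The
multi-allelic F~ST~ collapse and the strict-identity lineage rule are
the stated simplifications. Specificity thresholds calibrated on one
sample of lineages do not guarantee specificity in wider germplasm —
rare-allele behavior under panel expansion is exactly why the MAF
filter and the singleton machinery exist — and the synthetic
generator's noise-free model means its guarantees are about logic, not
about field data.
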