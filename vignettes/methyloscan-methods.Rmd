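---
title: "Detecting and quantifying anaerobic corrinoid-dependent methylotrophy in MAGs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and quantifying anaerobic corrinoid-dependent methylotrophy in MAGs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Methylotrophic methanogenesis — CH4 production from methylated amines,
methylated sulfides, and methylated oxygen compounds such as methanol and
methoxylated aromatics — is catalyzed by substrate-specific three-component
(corrinoid-dependent) methyltransferase systems: a substrate:corrinoid
methyltransferase (MtxB), a corrinoid-binding protein (MtxC), a
methylcorrinoid:carbon-carrier methyltransferase (MtxA), and a reductive
activase (RamX) that reactivates adventitiously oxidized corrinoid. Homologous
systems occur in anaerobic bacteria (notably acetogens), where the same
substrates feed carbon and energy metabolism instead of methanogenesis. Most
of the known biochemical diversity of these systems is missing from the
databases behind automated annotators, so genome-resolved surveys that rely
on KEGG-style annotation alone systematically under-detect the metabolism.

`methyloscan` implements, as a tested and reusable pipeline, a
curation-grade screening procedure for metagenome-assembled genomes (MAGs):
homology screening against a curated reference catalog, substrate-resolved
gene identity assignment with synteny and pyrrolysine evidence, rule-based
physiology calls, and expression/abundance rollups. Every stage is testable
without sequencing data through a fully labeled synthetic community
generator.

## Pipeline stages and the rules they implement

### Reference catalog

The screening catalog contains reference proteins for each system role and
substrate subtype (methanol-specific *mtaB*, trimethylamine *mttB*,
dimethylamine *mtbB*, monomethylamine *mtmB*, quaternary-amine non-Pyl
*mttB*, methoxylated-compound *mtvB*, the methyl-sulfide *mtsA*/*mtsB* pair
and tri-functional fused MtsD/F/H homologs, the corrinoid proteins and
MtxA-type methyltransferases of each system, and RamX activases). The
packaged catalog is a **synthetic stand-in**: it reproduces the composition
of the curated set used for this kind of survey (20 MtxB, 16 MtxC, 10 MtxA,
7 RamX gene types; 53 in total, with the three fused MtsD/F/H types shipped
as a supplement) and its family structure (members of a subtype family are
~80% identical; families are unrelated), but the sequences themselves are
seeded BLOSUM62-guided mutants of random ancestors. This keeps the whole
pipeline runnable and testable offline; a user with a curated FASTA +
metadata table loads it with `load_catalog()` and everything downstream is
unchanged. Passing tests therefore demonstrate the correctness of the
machinery on sequence data with realistic family structure, not the
biological fidelity of the packaged sequences.

RamX references always carry the `ambiguous` substrate category: activases
are promiscuous across corrinoid proteins and are never used to infer a
MAG's substrate range.

### Homology screen

Proteins are aligned to every reference by Smith-Waterman local alignment
with affine gaps (BLOSUM62, gap open 11, extend 1; unknown residues X score
0), and raw scores are converted to bitscores with the Karlin-Altschul
transform \((\lambda S - \ln K)/\ln 2\) using the gapped-BLOSUM62 constants
\(\lambda = 0.267\), \(K = 0.041\), so bitscore thresholds carry standard
protein-search semantics (exact parity with any particular search tool is
not claimed). Thresholds are strict inequalities: the archaeal screen keeps
hits with bitscore > 60 and then drops *all* hits from MAGs lacking an mtxB
(or fused MtsD/F/H) homolog; the bacterial screen queries only mtxB — the
best single marker of the metabolism, and the guard against nonspecific
hits to other bacterial cobalamin-binding proteins — at bitscore > 200. All
passing references per gene are retained so that assignment can weigh
competing substrate categories. Tabular 12-column search output from an
external tool can be ingested instead of running the internal aligner.

### Identity assignment

Tree placement with manual inspection is replaced by an automated
surrogate: a gene takes the role and substrate category of its
best-bitscore reference (ties broken lexicographically, making assignment
order-independent), and the substrate call is retained only when no
reference from a *different* non-ambiguous category scores within a
configurable margin (default 10 bits) of the best hit. Otherwise the gene
is recorded as methylotrophy-relevant but substrate-ambiguous, mirroring
how equivocal tree placements are reported. The margin is a surrogate
decision rule, not a claim about how any particular study resolved its
trees; it is deterministic, auditable (the margin is reported per gene),
and configurable.

Synteny: *mtxBCA*/*ramX* genes are frequently co-encoded, so assigned genes
on one contig separated by at most `max_intergenic` (default 2) intervening
genes are clustered, and clusters spanning two or more roles are recorded
as operon evidence with members flagged syntenic. Intervening genes are
counted on the contig-wide gene order and strand-agnostically — operons in
draft bins are not guaranteed to be called on a single strand — which also
makes detection invariant to reversing contig coordinates. Synteny is
evidence and confidence metadata only; the methylotrophy verdict is gated
on component completeness, not on synteny.

### Pyrrolysine detection

Pyl-containing mttB-family genes (tri/di/monomethylamine-specific) carry an
in-frame amber (TAG) codon that standard gene callers read as a stop, so
they surface as truncated CDS. `detect_pyl()` calls a gene `pyl` when the
called protein is shorter than `min_truncation` (default 0.7) of the
reference length, the terminating codon is TAG, and in-frame translation
past the TAG continues for at least `min_readthrough_aa` (default 30)
codons before the next stop. Full-length-like genes or TAA/TGA-terminated
genes are `non_pyl` — the quaternary-amine-specific class. The two
thresholds are package choices standing in for by-eye inspection in a
sequence editor; both are exposed. With insufficient downstream context
the call falls back to truncation + stop identity and is flagged
low-confidence; ambiguous nucleotides flag low confidence rather than
erroring.

### Physiology rules

* **Methanogen**: the Mcr and Hdr complex marker sets both meet their
  presence thresholds.
* **Pathways**: hydrogenotrophic and acetoclastic indicator sets are
  configurable (`marker_config()`). Defaults: hydrogenotrophic =
  fwd/fmd + mtd + mer + frh/ech at ≥ 30% of the set; acetoclastic =
  ackA + pta both present, or ≥ 60% of the cdh complex. These defaults are
  this package's documented choice — the rule engine is written so the sets
  are data, not code, and should be swapped for a study's own curated sets.
* **Methylotroph (archaeal)**: at least two of the three core system
  members (MtxB/MtxC/MtxA) present, one of which must be the
  substrate-demethylating mtxB; for methyl-sulfide metabolism a single
  fused MtsD/F/H gene, or either of mtsA/mtsB, suffices (a both-required
  reading of the two-part rule is available behind a flag).
* **Methylotroph (bacterial)**: any mtxB homolog at the bacterial
  threshold; the archaeal completeness rule is never applied to bacteria.
* **Substrate profile**: union of categories over non-ambiguous
  demethylating genes (MtxB, fused, mtsA/mtsB); RamX and ambiguous
  MtxA/MtxC never contribute.
* **Lifestyle** (methanogens only): obligate methylotroph when
  methylotrophy is the only encoded pathway, facultative when it co-occurs
  with hydrogenotrophic and/or acetoclastic potential. Lifestyle here is
  genotype-only; expression does not enter the designation.

Every verdict carries an ordered rule trace (JSON-serializable) sufficient
to replay the decision.

### Quantification

* **Count floor**: metatranscriptome counts below 5 are zeroed per cell
  (gene × sample). A row-wise variant is deliberately not the default:
  the floor models per-observation mapping noise.
* **geTMM**: counts are converted to reads per kilobase, TMM scaling
  factors are computed on the RPK matrix (reference sample by
  75th-percentile count fraction; 30%/5% M/A trims; precision-weighted
  trimmed mean; factors rescaled to geometric mean 1 — the canonical TMM
  recipe, delegated to edgeR), and each cell is scaled per million of its
  sample's effective library size, so
  \(\mathrm{geTMM}_{gs} = \mathrm{RPK}_{gs} / (\sum_g \mathrm{RPK}_{gs}
  \cdot f_s) \times 10^6\) and column \(s\) sums to \(10^6/f_s\).
  Normalization is run jointly across all samples by default (a per-group
  run is a matter of subsetting columns). One numerical subtlety is worth
  stating: because TMM's precision weights depend on library size, scaling
  one sample's counts by a constant perturbs the weighted factors slightly
  (order 1%); with `normalization_params(weighted = FALSE)` the factors
  are exactly invariant to per-sample depth changes. The weighted default
  is kept because it is the canonical estimator.
* **Expressed** means group-mean geTMM > 0 after the count floor; no
  additional expression threshold is imposed.
* **Active methylotroph**: for at least one identified system — a syntenic
  operon cluster, a single fused MtsD/F/H gene, the mtsA/mtsB pair, or the
  core-role gene set — more than half of the member genes are expressed
  *including* the demethylating member. Group means use the replicate
  design (n = 3 in the emulated field layout); missing replicates are
  means of what is available.
* **Abundance**: per-MAG trimmed-mean coverage (mean of per-position
  depths between the 10th and 90th coverage percentiles; the sorted ranks
  \((\lfloor 0.1n \rfloor + 1) .. \lceil 0.9n \rceil\) are kept, so a
  length-1 vector degenerates to its value), then nested relative
  abundances against any denominator set (all MAGs, archaea, methanogens).
  Groups whose denominator is zero — e.g. methanogens in unthawed palsa —
  are reported missing, never as zero or infinity. Read mapping itself is
  out of scope; depth tables are consumed as produced upstream.
* **Rollups**: order-level activity fractions (replicate-averaged geTMM
  summed per order / total over methanogen genes; columns sum to 1 where
  defined) and abundance-normalized expression (group-mean geTMM divided
  by the gene's MAG relative abundance in the matched group; zero
  abundance with expression is missing, zero expression is zero). The
  matched abundance is the habitat × depth group value.

### Porewater CH4

Dissolved CH4 is recovered from headspace equilibration by the standard
mass balance \([CH_4]_{aq} = c_{head} V_{head} / (V_{water}\, e)\) with
extraction efficiency \(e = 0.95\) by default; Henry's-law partitioning of
the residual dissolved fraction is folded into that single constant, which
matches how a single-efficiency correction is used in practice. Headspace
mol-fraction readings are converted with the ideal gas law. Volumes are
required inputs, not defaults.

## The synthetic community generator

`default_community_design()` encodes a 30-MAG community emulating the
structure of a thaw-gradient peatland survey: obligate methylotrophic
Methanomassiliicoccales (Pyl-mttB methylamine operons, fused methyl-sulfide
genes, one MAG carrying *only* a fused gene to exercise that route),
facultative Methanobacteriales (hydrogenotrophic + methanol) and
Methanosarcinales (all three pathways; methanol + methoxy genes),
hydrogenotrophic and acetoclastic non-methylotrophs, and three
methylotrophic bacteria (non-Pyl mttB Proteobacteria, Pyl mttB
Actinobacteriota, methanol-specific Acidobacteriota). Planted genes are
BLOSUM62-guided mutants of catalog references at 68–85% identity (sampled
per gene, seeded); substitutions are sampled proportional to
exchangeability so derived genes look like diverged homologs. Decoys are
random proteins plus 30–45% identity mutants of corrinoid-binding MtxC
references — the documented nonspecific-hit stressor — drawn from the
non-methyl-S MtxC families, since an mtsB homolog is by itself
methylotrophy evidence under the rules and would be a planted positive,
not a decoy. Back-translation uses uniform synonymous codon choice; codon
bias is not modeled because nothing downstream depends on it.

Counts are negative binomial (size 3 by default) with group means
proportional to designed expression × designed relative abundance × a depth
factor; methylotrophy genes of designed-inactive MAGs are exactly silent.
Abundances are Dirichlet-like (1 + Gamma(2) weights, normalized per group);
the unit offset keeps every present MAG's expressed genes above the count
floor at the default depth factor, so designed-active labels are
recoverable by construction rather than by luck. Methanogens have zero
designed abundance in the palsa groups, reproducing the below-detection
situation the abundance code must handle. The emulated design is 3 habitats
× 3 depths × 3 replicates = 27 samples. Depth vectors (150 positions per
MAG × sample) are Gaussian-jittered around designed coverage with the
trimmed mean as the recovery statistic; `noise = "none"` replaces all
sampling with expectations for exact-recovery tests.

What the generator does *not* emulate: assembly and binning artifacts
(chimeras, contamination, fragmented operons), read-level noise (no FASTQ),
strain heterogeneity, compositional count structure beyond the designed
simplex, and real homology between gene families (catalog families are
unrelated by construction, so cross-family margins are easier than in real
data). Passing round-trip tests therefore demonstrates that the machinery
recovers what it is defined to recover; sensitivity on real MAGs is bounded
above by these results.

## Problem sizes used in the checks

The packaged test suite and the acceptance script run, on one CPU in a few
minutes: the 30-MAG round trip once (screen ~160 proteins × 56 references),
activity recovery over 20 simulated count matrices, alignment-vs-enumeration
on a few hundred short peptide pairs (the brute-force oracle is
\(O(n^2m^2)\) per pair), and the normalization invariants on 100 random
matrices. These sizes were chosen as the smallest that exercise every rule
and every degenerate branch; all scale linearly if enlarged.

## Known limitations

* The packaged catalog is composition-faithful, not sequence-faithful; real
  surveys must supply the curated reference FASTA.
* The margin rule approximates, but is not, phylogenetic placement; genes
  near the margin threshold deserve manual review (the per-gene margin and
  the optional synteny flags are reported for exactly this purpose).
* Bitscore constants are fixed per scoring scheme; no composition-based
  score adjustment or E-values (filtering is bitscore-only by design).
* Pyl detection requires CDS-downstream context; without it, calls are
  flagged low-confidence rather than withheld.
* No HMM search, no DNA-level search, no differential-expression testing,
  and no tree building — these are out of scope by design.
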