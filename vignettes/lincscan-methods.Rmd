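---
title: "lincscan: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{lincscan: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models and procedures implemented in
`lincscan`, the assumptions behind them, the parameters that matter, and
the design choices made where the design was genuinely open. It states no
empirical result that the package's own tests and acceptance script do not
themselves compute.

## The problem

Long intergenic noncoding RNAs (lincRNAs) are transcripts of at least
200 bp transcribed outside annotated protein-coding loci, with no
protein-coding capacity. In organisms without curated noncoding
annotation — the package's motivating setting is a bivalve mollusc with
nine adult tissues and a densely sampled larval time course — lincRNAs
are catalogued by filtering a reference-guided transcriptome assembly
through sequence-level rules, and characterized by tissue specificity,
developmental-stage specificity, cross-species conservation, and
membership in co-expression modules that track development.

`lincscan` consumes assembled transcript models (GTF), a genome and gene
annotation, a housekeeping-RNA FASTA, and FPKM expression matrices with
sample metadata. Read alignment, transcript assembly and FPKM
quantification are upstream of the package and out of scope.

## The identification cascade

`run_pipeline()` applies six stages in a fixed order; each stage's
survivors are a subset of its input and every removal is recorded with a
reason, so the audit invariants (`check_filter_report()`) are exact:

1. **Length**: keep transcripts with summed exon length ≥ 200 bp
   (`min_length`; the 199/200 boundary is inclusive on 200).
2. **Intergenic**: keep transcripts whose genomic span has zero overlap
   with any protein-coding gene expanded by `flank_bp = 500` on both
   sides. The test is strand-blind: an antisense-overlapping transcript
   is *not* intergenic, matching the field's use of "intergenic".
   Intergenicity is re-derived from coordinates rather than assembler
   class codes, which keeps the rule independent of any specific
   assembler's vocabulary.
3. **Coding potential**: a hexamer log-likelihood score over the longest
   ORF (read in frame, stride 3, stop codon included); transcripts with
   score strictly greater than zero are eliminated. This single
   implemented classifier replaces external black-box tools while
   preserving their decision boundary ("score > 0 is coding"); ID lists
   from external classifiers can additionally be supplied and are
   unioned with the internal calls.
4. **ORF length**: remove transcripts whose longest ORF is ≥ 100 amino
   acids (stop excluded). "100" is interpreted in amino acids, the
   standard lncRNA convention. All six frames are scanned because most
   single-exon assembled transcripts are unstranded; this is the
   conservative direction (it can only remove more).
5. **Housekeeping similarity**: remove candidates with a hit against the
   housekeeping RNA database (tRNA/rRNA/miRNA and similar) at E ≤ 1e-5,
   inclusive at the boundary. The filter runs against whatever FASTA is
   supplied; pre-computed tabular hits are accepted in place of the
   built-in aligner.
6. **Redundancy clustering**: greedy incremental clustering at 95%
   identity. Sequences are processed by length descending (ties by ID
   ascending); each joins the first cluster whose representative it
   matches, else founds one. Identity is matching positions of the best
   local alignment divided by the **shorter** sequence's length, so
   containment duplicates collapse; the representative is the longest
   member. Tie-breaking everywhere is length-descending then
   ID-ascending, which makes outputs reproducible byte for byte.

The hexamer model is built deterministically in code from a fixed
internal seed: a coding corpus sampled from a codon distribution with a
three-fold preference for G/C-ending codons (a GC3-style bias), a
noncoding corpus of uniform nucleotides, in-frame hexamer counts with a
pseudocount of 1, and the per-hexamer log2 ratio of the two frequency
tables. Generating the model in code avoids shipping a table while
keeping it byte-stable across sessions. Hexamers containing N are
skipped during scoring; a sequence with no ORF is scored over its whole
length in frame +1.

## Conservation search

`local_align()` is a seed-and-extend ungapped aligner: exact 11-mer
seeds from a subject k-mer index, x-drop extension in both directions
(stop when the running score falls 20 below its maximum, then trim back
to the maximum), +1/−2 match/mismatch scoring, and Karlin–Altschul
E-values E = K·m·n·exp(−λS) with the published ungapped parameters for
+1/−2 (λ = 1.28, K = 0.46). Hits are filtered at E ≤ 1e-5 and identity
≥ 20% — the identity floor is permissive by design, acting as a
pass-through sanity bound rather than a meaningful threshold. Ungapped
extension suffices because the package's own conservation questions are
about recognisable sequence homology, and the bundled generator's
mutation model is substitution-only; gapped alignment is a non-goal. A
lincRNA counts as conserved in a species if at least one hit survives;
the all-species intersection is reported.

## Expression profiling

* **Expressed** means max FPKM over samples ≥ 1 (inclusive); "moderate
  and high" expression means FPKM ≥ 5. Both are knobs.
* **Tissue specificity** uses τ = Σᵢ(1 − xᵢ/x_max)/(N − 1) on per-tissue
  mean FPKM; τ > 0.95 (strict) flags a feature as tissue-specific,
  assigned to its argmax tissue. τ is computed on the raw FPKM scale by
  default with a `log2p1` alternative, because the index's original
  preprocessing is not fixed by the literature that uses it; multi-sample
  tissues are averaged first (with one library per tissue this is a
  no-op).
* **Stage specificity**: a feature is expressed in a stage if any sample
  of that stage reaches the FPKM floor; specific when exactly one stage
  qualifies.
* **Settlement contrast**: on in stage A (max FPKM ≥ 5) and off in
  stage B (max FPKM < 1), and vice versa — an on/off screen for the
  eyed-larva → spat transition, not a differential-expression test.
* **lincRNA vs mRNA levels**: Gaussian KDE with Silverman's bandwidth on
  log2(FPKM+1) and the two-sample Kolmogorov–Smirnov test with the
  asymptotic p-value (reported p-values in this setting are floors, so
  exact small-sample corrections would change nothing of interest).
* **Neighbors**: nearest protein-coding gene per lincRNA, distance being
  the gap between closest interval ends (0 when overlapping or abutting),
  with the < 10 kb window and the nearest-neighbor gene set exported for
  enrichment.

## The co-expression network

Gene–gene correlation defaults to Pearson on log2(FPKM+1) (the
conventional choice for weighted networks); trait relations use Spearman,
implemented as rank-Pearson with the t-approximation on n−2 degrees of
freedom. The unsigned adjacency is A = |cor|^β with β = 6 by default;
`pick_soft_power()` offers the scale-free criterion (smallest β whose
log-log connectivity fit reaches R² ≥ 0.8 over ≥ 8 bins, falling back to
6 with a warning), and a signed variant is available. The topological
overlap matrix is

TOM_ij = (Σ_u A_iu·A_uj + A_ij) / (min(k_i, k_j) + 1 − A_ij),

with the diagonal excluded from k and TOM_ii = 1. Modules are detected by
average-linkage clustering of 1 − TOM with a **static** tree cut — chosen
over dynamic tree cutting because it is deterministic, easy to reason
about, and sufficient for planted-block structure; the default cut height
is 0.90. A lower cut (e.g. 0.25) would be appropriate only if within-
module topological overlap approached 1, which it does not even for
strongly correlated blocks: with within-module correlations near 0.8 and
β = 6, within-module 1 − TOM sits near 0.75, and separation from the
background (near 1.0) is what the cut must resolve. Clusters below
`min_module_size = 20` join the grey (unassigned) pool; labels follow the
conventional module color sequence by decreasing size, a purely cosmetic
choice.

Module eigengenes are the unit-norm first principal component of the
standardized member × sample submatrix, sign-oriented along the members'
mean profile. Module–trait relations are Spearman correlations of
eigengenes with three traits — development time in days, its rank
("time order", the more robust choice when expression is a non-linear
function of time), and an ordinal stage code; a module is flagged
trait-related at |ρ| ≥ 0.6 and p < 0.01 against a development-time
trait. Per-gene trait correlations are direct Spearman correlations with
the trait (not eigengene-based module membership), BH-adjusted within
each module's feature set (a global-FDR mode exists). Hubs are the top
1% or 5% (ceiling) of intramodular connectivity kIM_i = Σ_j∈module A_ij;
"directly connected" lincRNAs are lincRNA members whose edge to a hub
falls within the module's exported top-k strongest edges — an explicit
operationalization of what a visualization tool would show after edge
thresholding, with k = 100 by default.

## GO enrichment

`go_enrich()` performs one upper-tail hypergeometric test per term with
at least one hit in the set, through the log-space-stable tail of the
hypergeometric distribution, with Bonferroni correction over the tested
terms. Both raw p < 0.05 and corrected p < 0.05 flags are reported, since
both conventions are common. The term map is taken as given; no GO-graph
ancestor propagation is performed. Default backgrounds: all annotated
protein-coding genes for neighbor analyses, all matrix features for
module analyses.

## The synthetic scene

The generator's defaults are the study conditions the package is built
around: nine tissues; 34 development time points in six stages (embryo,
trochophore, D-shaped, umbo, pediveliger, spat); 200 coding genes with
genuine ORFs of 160–240 codons carrying the hexamer bias; 50 planted
lincRNA loci of 300–600 bp placed > 500 bp from any gene; and ten decoys
in each of five classes — shorter than 200 bp, inside a gene, within the
gene flank, intergenic with an ORF ≥ 100 aa, and a housekeeping
look-alike (5% substitutions over a 150–250 bp window of a database
entry) — plus ten near-duplicates of planted lincRNAs at 2% substitution,
30 bp shorter than their source so the source remains the cluster
representative. The generator self-checks every planted object against
the same rules the cascade applies (re-drawing on failure), so by
construction every planted lincRNA passes and every decoy fails its
designated filter; this is what makes exact recovery a meaningful
end-to-end test. Twenty lincRNAs are copied at 2% substitution into all
four subject genomes for the conservation search.

Expression: tissue-specific lincRNAs are log-normal (median 30 FPKM) in
their tissue and < 0.5 FPKM elsewhere, which guarantees τ > 0.95 at nine
tissues; broad features vary ±15% (log-normal) around a per-feature base
and are verified to stay below τ = 0.5. Development modules follow
logistic ramps in the time rank with staggered onsets — strictly
monotone (so each eigen-profile has |Spearman| = 1 with time order) yet
mutually separable, since two ramps with different onsets correlate far
less than two members of one ramp. Members add Gaussian noise
(SD 0.5 on the log2 scale; the designated hub 0.2×, the designated
hub-linked lincRNA 0.3× of that), and FPKM = 2^v − 1 so that the
network's log2(FPKM+1) transform recovers the simulated scale exactly.
Stage-specific lincRNAs are ≥ 5 FPKM in all samples of one
pre-settlement stage and < 1 elsewhere; two settlement sets are on in
pediveliger/off in spat and vice versa (kept disjoint from the
stage-specific class so both recover exactly against truth). All
randomness flows from one integer seed through a saved-and-restored RNG
state; identical seeds give byte-identical FASTA/GTF/matrices.

What the generator does **not** emulate: splice isoforms (planted
features are single-exon, as the large majority of assembled lincRNAs
are; multi-exon handling is exercised by unit tests), indel mutations,
read-level noise, batch effects, and library-size artifacts. Passing the
planted-recovery tests therefore demonstrates the correctness of the
implemented rules and their composition, not robustness to assembler
artifacts in real data.

## Numerical choices and degenerate inputs

* Coordinates are held in the Bioconductor-standard 1-based closed
  `GRanges`/`IRanges` representation; GTF (1-based) and BED (0-based
  half-open) conversions are delegated to `rtracklayer` at the I/O
  boundary, which eliminates hand-rolled off-by-one arithmetic.
* Unstranded transcripts are kept and read as plus-strand for sequence
  extraction; the six-frame ORF scan makes the choice immaterial for
  coding filters.
* τ is undefined for all-zero vectors and fewer than two tissues
  (errors); constant expression features get zero network adjacency with
  a warning; constant traits yield NA correlations and unflagged modules
  with a warning; an all-equal TOM collapses to a single module or pool,
  the documented degenerate outcome.
* `hypergeom_upper(k = 0, ...)` is exactly 1; E-values are monotone
  decreasing in score for fixed sequence lengths.
* Problem sizes in the bundled tests (a 60-gene unit scene, the
  200-gene default scene, 350-feature network recovery, 500-replicate
  calibration) were chosen as the smallest scenes in which each planted
  property is comfortably identifiable.

## Known limitations

* The coding-potential score is a single hexamer likelihood-ratio
  classifier; it preserves the "score > 0" decision rule but is not a
  reimplementation of any external tool's feature set, and on real data
  external classifier ID lists should be supplied alongside it.
* The aligner is ungapped; diverged homologs separated by indels will be
  found only via their longest conserved block, so conservation rates
  on real genomes are conservative.
* Static tree cutting requires well-separated modules; gradual module
  boundaries in real co-expression data are better served by dynamic
  cutting, which is deliberately out of scope.
* Whole-genome conservation hits do not prove the homologous segment is
  itself a lincRNA in the other species.
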