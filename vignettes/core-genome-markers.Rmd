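---
title: "Designing and genotyping transferable core-genome haplotype markers"
author: "coremark"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing and genotyping transferable core-genome haplotype markers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coremark)
```

## The problem

Markers developed on one accession of a structurally diverse genus often
fail in its relatives: a primer or probe site may carry local variation, the
locus may be monomorphic in the new background, or the whole region may be
absent from some genomes (the *dispensable* genome), producing null alleles
and phantom map positions. `coremark` implements a marker strategy that
confronts all three failure modes at once:

1. restrict marker design to the **collinear core genome** — reference
   regions that align one-to-one and syntenically with *every* assembly in a
   taxon panel, i.e. regions under selection against structural variation;
2. place amplicons in **moderately polymorphic** windows of that core, with
   **variant-free, k-mer-unique primer sites**, so a single PCR multiplex
   amplifies across the whole genus while the amplicon itself stays
   informative; and
3. genotype the amplicons as **microhaplotypes** — the full amplicon
   sequence is the allele tag — with explicit Mendelian and hemizygosity
   (null-allele) quality control in biparental families, and a
   kinship-corrected mixed model for marker-trait association.

Every stage is driven by a built-in simulator that produces pan-genomes,
panel variation, families and reads with known truth, so the full pipeline
is testable end to end on a desk machine.

## Core-genome construction

### Repeat masking

Repetitive sequence is masked by k-mer frequency before alignment-based
analysis: every base covered by a k-mer (default `k = 31`) whose canonical
(strand-collapsed) count exceeds `max_freq = 2` becomes `N`. Masking is
**per genome** by default: each sequence is masked against a k-mer table
built from that sequence alone, so the threshold measures repetitiveness
within a genome. A pooled table across reference plus assemblies is
available (`scope = "pooled"`), but at a threshold of 2 it would mask every
single-copy locus shared by three or more genomes — exactly the conserved
sequence the pipeline needs — so it is only sensible for intra-genome
corpora. Counting is canonical because downstream alignment is
strand-symmetric. Masking marks positions, not whole sequences: output
lengths always equal input lengths, masking is idempotent, and lowering
`max_freq` can only add `N`s.

### Chaining and one-to-one selection

Pairwise alignments enter as PAF (0-based, half-open; all internal
intervals use the same convention). `chain_anchors()` groups anchor
alignments per (reference sequence, query sequence, strand) and extracts
maximal-score collinear chains by dynamic programming: anchor starts must
strictly increase on both genomes (decrease on the query for `-` strand)
and inter-anchor gaps may not exceed `max_gap` on either genome. Chains are
peeled off greedily by score; chains with fewer than `min_anchors = 3`
anchors are discarded.

`max_gap` defaults to 10 kb. This value is the scale separator between the
two kinds of alignment gap: gaps from small local tandem duplications or
indels (up to a few kb) should be *bridged*, because the flanking sequence
is still one collinear block, while gaps from presence/absence variation
(tens of kb and larger) must *break* the chain — a block bounding interval
that spanned them would count dispensable sequence as core. Both the gap
limit and the anchor minimum are exposed as arguments.

`select_one_to_one()` realizes the one-to-one (quota 1:1) criterion
greedily: chains are processed in descending score order and accepted only
if their reference span and their query span each overlap the already
accepted spans of the same assembly by at most `overlap_tol = 0.1` of their
own length. Accepted chains are collapsed to their bounding intervals,
which smooths over collapsed local duplicates, and blocks whose reference
span is not larger than `min_block_len = 10` kb are dropped. The greedy
rule is deterministic (score ties break by reference position) but not
globally score-maximal; it mirrors how quota-based syntenic screening
behaves in practice, and the test suite verifies it against an independent
re-derivation rather than a combinatorial optimum.

### Coverage, core and convergence

`coverage_and_core()` sweeps the accepted blocks into a run-length coverage
profile — at every reference position, the number of assemblies with a
covering block (each assembly counted once) — and defines the **core
genome** as the maximal intervals where that count equals the number of
assemblies. The per-count lengths always partition the reference exactly.

How big would the core be with more assemblies? `core_size_by_k()`
averages the intersection of k randomly ordered assemblies' covered
intervals (100 random orderings by default, seeded), and
`fit_core_decay()` fits

$$y(k) = A + B\,e^{-ck}$$

by nonlinear least squares (`minpack.lm`). `A` is the plateau — the
predicted asymptotic core size — and `n_converge` is the smallest k at
which the predicted excess `B e^{-ck}` drops below `eps * A`
(`eps = 0.01`). The three-parameter form is the simplest decay with a free
plateau; a constant series short-circuits to `A = mean, B = 0` with a
flag, and an optimizer failure is flagged, never silent. With 2%
multiplicative noise on a nine-point series the plateau is recovered with a
mean relative error of about 2%, though individual replicates can exceed
5% — the fit has three parameters and nine observations.

`window_feature_correlation()` reproduces the windowed comparison of core
coverage against genomic feature density (genes, transposable elements) in
fixed windows (default 1 Mb) with a two-sided Spearman rank correlation
(midranks for ties).

## Marker design

`region_stats()` scores each core region against a diversity-panel VCF:
`diversity` is variant sites per base, `missing_rate` the mean missing
fraction over the region's sites, plus mean core coverage and gene density.
`filter_candidates()` removes regions shorter than 200 bp, with diversity
strictly above 7% or strictly below 2%, or with missing rate above 50%
(the strictness of each inequality follows the removal rules exactly; a
percentile mode swaps the diversity bounds for the empirical 25th/75th
percentiles). `select_spaced_markers()` tiles the genome into 200-kb bins
and draws one candidate per bin with probability proportional to
`1 + gene_weight * gene_density` (`gene_weight = 1`; the gene-density
enrichment strength is a free choice), falling back in any empty 1-Mb
window to the region with the highest core coverage even if it failed the
polymorphism filters.

`design_amplicons()` scans each selected region for a primer-window pair
that is variant-free (indel-aware: any VCF record whose reference span
touches the window disqualifies it), free of masked bases, and k-mer-unique
in the masked reference (every unmasked 31-mer covering the window must
occur exactly once). Among feasible pairs with amplicon length in
270–330 bp it maximizes the number of enclosed variant sites, ties going
leftmost. Primer length is fixed at the minimum of the allowed range
(18 bp): conservation and uniqueness are what this stage checks; melting
temperature, GC content and multiplex compatibility belong to the
synthesis vendor and are deliberately out of scope. Marker ids are
`chrom_pos` with the 1-based amplicon start. Per-region failure is a
reported status, not an error — design success is data-dependent.

## Amplicon genotyping

`demultiplex_reads()` assigns a read pair to a marker iff R1 starts with
the forward primer and R2 with the reverse primer, each within one
substitution but with the five 3'-terminal bases exact — the same 3'
specificity that RNase-H2-activated primers enforce chemically. Inserts are
trimmed and merged when the mates overlap by at least 10 bases with at most
one mismatch (the expected overlap, known from the panel's amplicon length,
is tried first); otherwise they are joined with a `'+'` sentinel. A
non-overlapping pair therefore tags the haplotype by its two ends — the
unread middle bases are simply not part of the allele tag.

`collapse_haplotypes()` removes error-derived alleles. Per marker, every
observed haplotype is aligned to the most frequent one (global alignment
with unit gap costs, implemented in C++ for speed) and projected onto its
coordinates. Candidate variant columns are nominated only by haplotypes
seen at least `min_hap_count = 3` times family-wide — a specific sequencing
error rarely recurs identically — and a column survives only if it is

* outside homopolymer runs of length ≥ 4 in the dominant haplotype (where
  polymerase slippage concentrates),
* polymorphic among called genotypes (a constant column carries no allelic
  information and would keep every error haplotype distinct), and
* consistent with Mendelian segregation given the parents' column
  genotypes (chi-squared at `seg_alpha = 1e-3`), where up to 10% of
  progeny may sit in classes impossible under the parental model before
  the column fails — such calls are allele-dropout artifacts at low depth,
  not evidence against the column.

If no column passes, the single column with the largest minor allele
frequency represents the marker. Haplotypes are re-keyed on the retained
columns, counts summed — conserved exactly — and each collapsed allele is
reported as its highest-count member's full sequence.

`call_genotypes()` calls a diploid genotype per cell: depth below 5 is
missing; alleles below a 20% count fraction are dropped; one survivor is a
homozygote, two a heterozygote, more than two an ambiguous missing call.
These thresholds are exposed; they are operating points, not published
constants. `filter_marker_matrix()` flags markers above 75% missingness
(removed) and single-allele markers (monomorphic, retained but excluded
from mapping exports). The `hapgeno` TSV dialect (`I/J:dI,dJ` cells with a
sidecar allele catalog) round-trips losslessly, and `write_pseudo_vcf()`
recodes the four most frequent alleles per marker as pseudo-bases A, C, G,
T (descending frequency, ties lexicographic; carriers of rarer alleles
become missing) for downstream tools that expect biallelic-style VCF.

## Mendelian and hemizygosity QC

`expected_offspring_ratios()` enumerates the four gamete unions of a cross
model. The null symbol `"0"` marks a hemizygous/non-amplifying allele: a
genotype with one null is *observed* as homozygous for the visible allele,
null/null is unobservable and the remaining classes renormalize.
`segregation_chi2()` is the Pearson goodness-of-fit test with df =
classes − 1; the distortion tolerance defaults to `1e-3` for F1/backcross
families and `1e-10` for F2. `hemizygosity_scan()` retries the test under
every model with one parental allele nulled (or one per parent) and
declares a marker rescued when the best such model reaches the tolerance —
the mechanism by which apparently distorted or monomorphic markers turn out
to follow Mendel once hemizygosity is admitted. `classify_markers()`
applies the hierarchy failed (mean depth < 1) → monomorphic → distorted →
mappable, and `primer_variant_check()` audits parents' whole-genome VCFs
for variants inside primer windows — the expected physical cause of
null alleles that are not genuine deletions. `ibs_mds()` supplies
identity-by-state distances (shared-allele fraction per marker) and
classical metric MDS for pedigree QC.

## Association

`centered_ibs_kinship()` double-centers the IBS matrix.
`mlm_associate()` fits `y = Xa + Pb + u + e`, `Var(u) = sg2 K`,
`Var(e) = se2 I`, through the spectral decomposition of K: the variance
ratio is REML-estimated once on the covariate-only model (log-spaced grid
with golden-section refinement, with the pure-OLS boundary always in
contention), then held fixed per marker — the standard
population-parameters-previously-determined shortcut. Markers are coded as
genotype-class indicators by default (suiting multiallelic haplotype
markers; dosage coding is available), tested by F-test, with R² the
generalized residual-sum-of-squares reduction. Missing genotypes at a
marker are mean-imputed so all samples share one rotation. With K
proportional to the identity the model collapses to ordinary least squares
exactly. `bonferroni_threshold(n, alpha)` returns `-log10(alpha/n)`, and
`sex_concordance()` scores a marker against a categorical trait by
exhaustive genotype-to-phenotype mapping under a stated dominance order.

## The simulator: what it does and does not emulate

The simulator is first-class, tested code. Its defaults define the study
conditions used throughout the test suite:

* `simulate_pangenome()`: 2 Mb single-chromosome reference, 5 assemblies,
  1% SNP divergence, 30% dispensable fraction per assembly (segments
  20–100 kb, merged by union), 5% tandem-repeat tracts (unit ≤ 100 bp).
  Truth PAF anchors tile exactly the kept segments (split at every
  dispensable boundary), so the synteny stage can be validated without an
  external aligner; intersecting the per-assembly kept intervals *is* the
  truth core.
* `simulate_panel_variants()`: 40 accessions, 0.032 variants per base
  (the genus-wide core SNP density scale), 10% missingness.
* `simulate_family()`: Poisson-count crossovers at 3 cM/Mb; F1 crosses the
  parents, F2 selfs a single F1, BC backcrosses an F1 to parent 1; null
  alleles are allele index 0 — transmitted Mendelian-ly, invisible to
  sequencing.
* `simulate_amplicon_reads()`: per-marker mean depth lognormal
  (log10 mean 1.5, sd 0.5 — most markers between 1x and 100x), per-base
  substitution errors at 0.005, single-base indels in homopolymer runs ≥ 4
  at 0.002 per run, 150 bp reads, constant Q30 qualities.

Every output stream derives its own RNG seed from the master seed plus a
stable hash of the stream's role, so identical seeds give byte-identical
files and adding an output never perturbs existing ones.

Deliberately not modeled: inversions/translocations (presence/absence is
the only structural class), PCR chimeras, index hopping, quality-score
variation, base-composition biases, and linked-read assembly artifacts.
Passing tests on simulated data therefore demonstrate the pipeline's
*logic* — interval arithmetic, chaining, error collapsing, segregation
models — under a clean error model; they do not certify performance on
real sequencing artifacts outside that model.

## Numerical and scale choices

Problem sizes in the test suite are chosen to exercise each property at
desk scale: core recovery on a 2 Mb / 5-assembly pan-genome, genotyping
recovery on an F1 family of 100 progeny across 50 markers at mean depth
50, segregation calibration on 1,000 multinomially simulated Mendelian
markers with 150 progeny, and mixed-model calibration on 80 samples by
400–500 markers. Exhaustive oracles (chain enumeration, mapping
enumeration) are confined to instances of at most ~12 anchors where
enumeration is exact and fast.

Tie-breaking is deterministic throughout: chain score ties break by
reference position, allele-frequency ties lexicographically by haplotype
string (byte order, locale-independent), and the dominant haplotype by
count then string. Degenerate inputs are handled explicitly: empty PAF
files parse to empty record sets, a constant decay series returns a flagged
degenerate fit, markers with a single haplotype pass through collapsing
untouched, and zero-depth cells are missing rather than errors.

## Known limitations

* The synteny stage consumes alignments; it does not compute them. Truth
  anchors from the simulator are idealized (no spurious or split
  alignments beyond dispensable boundaries).
* The one-to-one selection is greedy; adversarial chain configurations can
  admit a higher-scoring feasible subset.
* Column-level Mendelian filtering needs callable parents; when a parent is
  uncallable at a column the column is kept untested.
* The mixed model fits one random effect and one trait; multi-locus and
  multi-trait models are out of scope, as is imputation.
* Genetic-map construction (linkage grouping, marker ordering) is
  deliberately not implemented; the pseudo-VCF export exists to feed
  external mapping software.
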