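---
title: "Methods: identifying and characterizing plant nsLTP families"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: identifying and characterizing plant nsLTP families}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nsltp)
```

# The problem

Non-specific lipid transfer proteins (nsLTPs) are small secreted plant
proteins that shuttle fatty acids and phospholipids; in cotton they are
of particular interest because several members are expressed in
elongating fiber cells. Family surveys follow a stereotyped recipe:
harvest candidates by homology, peel off the N-terminal signal peptide,
demand the eight cysteine motif (ECM) that forms the four disulfide
bonds of the lipid cavity, classify members by the spacing of those
cysteines, and then characterize the family's duplication history and
expression. This package implements that recipe end to end, calibrated
against the 138-gene *Gossypium hirsutum* catalog that ships as a
fixture, and pairs it with seeded synthetic-data generators so every
stage can be exercised — and its recovery verified against planted
truth — without any genome download.

# The identification cascade

`filter_candidates()` applies five stages in a fixed order, removing
each candidate at the *first* stage it fails:

1. **Signal peptide.** Candidates whose annotated signal-peptide length
   is unknown or zero are dropped. Signal peptides are consumed as
   annotations (a per-gene cleavage position), never predicted: the
   upstream predictor is replaceable and its output is an input here.
2. **Mature length.** Mature proteins (precursor minus signal peptide)
   longer than `max_mature_len = 120` residues are dropped. The
   threshold is strict: exactly 120 residues is retained.
3. **Eight-cysteine motif.** Mature proteins on which `scan_ecm()`
   finds no valid backbone are dropped.
4. **Start methionine.** Precursors not beginning with M are dropped.
5. **Domain verification** (optional, off by default). An external
   boolean flag — e.g. from a conserved-domain search — may remove
   remaining candidates; missing flags count as verified.

Because removal is at the first failing stage, a candidate lacking both
a signal peptide and a start methionine is tallied once, at stage 1;
the per-stage counts plus survivors always sum to the input size.

# ECM detection and the type system

The ECM backbone reads

```
C  X^g1  C  X^g2  C C  X^g3  C  X^i  C  X^g4  C  X^g5  C
```

eight cysteines with an adjacent **CC dyad** at slots 3–4 and a **CXC
triplet** at slots 5–6. The published pattern notation is parsed and
emitted byte-identically by `parse_pattern()` / `format_pattern()`;
`"CC19"` denotes the dyad followed by 19 spacer residues and `"C-X1C"`
the triplet — the only reading that yields eight cysteines for every
published cotton pattern.

`scan_ecm()` searches the cysteines of the *mature* protein (never the
precursor, matching the order of operations of the cascade) for a
backbone. When several 8-subsets qualify, the match minimizing (number
of stray cysteines inside the motif span, then leftmost first cysteine,
then lexicographically smallest position vector) is chosen. The
original surveys scanned by eye, so this objective is a design choice
of the package; it is pinned by tests against an exhaustive oracle that
enumerates every 8-subset under the same objective. The CXC inner gap
is allowed to range over 0–3 during scanning even though every cotton
member shows exactly 1, so that nsLTPs of other species remain
scannable; classification is free to reject unusual inner gaps.

**Typing.** The literature classifies nsLTPs by sequence similarity,
but the catalog records only ECM patterns. We therefore use a
data-backed surrogate: a decision tree on the gap signature, shipped as
an editable rule table (`inst/extdata/type_rules.tsv`). The first gap
separates most types outright (6 → VIII, 7 → II, 8 → nsLTPy, 10 → VI,
13 → IX, 14 → V), and `g1 = 9` splits on `g3`/`g4` (19–20 → I, 13 →
XI, 9 with g4 = 12 → III, 9 or 12 with g4 22–24 → IV). The acceptance
contract for this surrogate is exact agreement with all 138 published
labels, which the test suite verifies. Signatures matched by no rule
are `"unknown"`; an optional nearest-reference fallback (smallest
Euclidean distance in gap space to a catalog signature) can lend a
label, but is off by default because it can never answer "unknown" and
therefore silently mislabels genuinely novel spacings. Type VII exists
in the nomenclature but has no cotton member; it is a legal label for
user-supplied rule tables and unreachable with the shipped one.

# Physicochemical properties

Molecular weight is the sum of average (not monoisotopic) residue
masses plus one water — the convention of the usual web calculators.
The isoelectric point is the root of a composition-only
Henderson–Hasselbalch charge model (N/C termini plus D, E, C, Y, H, K,
R) under the Bjellqvist pK set documented in the source
(N-term 7.5, C-term 3.55, K 10.0, R 12.0, H 5.98, D 4.05, E 4.45,
C 9.0, Y 10.0), found by bisection on pH 0–14 to `1e-3`. The charge is
strictly decreasing in pH, so the root is unique; tests compare the
bisection result to a brute-force pH grid at step `1e-4`. The
catalog's printed MW/pI columns are treated as reference metadata, not
oracles: the underlying protein sequences are not printed, and several
MW values repeat implausibly across unrelated rows (e.g. 7947.31
appears for four different type-I genes), so internal consistency of
the implementation — additivity, monotonicity, the defining root
property — is the contract instead.

# Duplications and Ka/Ks

Candidate duplication pairs are gene pairs whose global
Needleman–Wunsch CDS alignment exceeds **both** thresholds: identity
> 0.8 over aligned columns and coverage > 0.8 of the longer gene.
Identity counts gap columns as mismatches; coverage is the alignment
length over the longer input, capped at 1 (the cap matters only in the
pathological case where the optimizer places gaps in the longer row —
such pairs are in any case eliminated by the identity criterion).
Nucleotide-level alignment is the default because the published
criteria speak of genes; both statistics are also available from
protein alignments via `global_align()` directly.

A passing pair is **tandem** when both genes share a chromosome and are
separated by at most 15 annotated ORFs *or* at most 30 kb (both
inclusive; spacing is the intergenic gap, later start minus earlier
end). Intervening ORFs count *all* annotated genes between the pair,
not just family members. Everything else is **segmental**. Tightly
linked tandem pairs are collapsed into one event per connected
component, so a chain of adjacent duplicates counts once.

`ng86_kaks()` implements Nei–Gojobori (1986): per-codon
synonymous-site fractions averaged over the two sequences (mutations
creating stop codons count as non-synonymous), pathway-averaged
difference counts for multi-hit codons with stop-visiting pathways
excluded (unless every pathway visits a stop), and Jukes–Cantor
correction of both proportions. Proportions ≥ 3/4 leave the correction
undefined and flag the result; `ks = 0` leaves the ratio undefined.
The implementation is pinned to an independent counting oracle (naive
loops and explicit pathway recursion) to `1e-6` on random codon pairs.
Other estimators in the KaKs-calculator family (LWL85, YN00, model
averaging) are out of scope.

# Trees

`neighbor_joining()` is a from-scratch Saitou–Nei implementation with
two pinned determinism rules: Q-criterion ties break to the smallest
`(i, j)` index pair of the current matrix, and negative branch lengths
are clamped to zero with the deficit moved to the sister edge so the
joined pair's distance is preserved. Distances come from
`pdist_matrix()`, the amino-acid p-distance under pairwise deletion
(columns with a gap in either row are excluded per pair).
`bootstrap_support()` resamples alignment columns with replacement and
reports, per internal edge of the full-data tree, the percentage of
replicate trees containing the same bipartition. Trees are returned as
`ape` `phylo` objects and serialize to Newick; tests verify exact
topology recovery on random additive metrics and cross-check against
`ape::nj()`, which is never used as the implementation. Maximum
likelihood trees are out of scope.

# Expression

RPKM follows its definition
(`count / (length_kb × library_millions)`); log transforms use a
pseudocount of 1 (configurable) everywhere. `trend_cluster()`
standardizes each gene's stage profile to z-scores, diverts
zero-variance profiles to a dedicated `"flat"` cluster, derives `k`
templates as seeded k-means centroids (`k = 4` by default, matching
the four fiber-development trend groups of the cotton survey), and
assigns genes to the template with the highest Pearson correlation.
Cluster labels are canonicalized by sorting centroids, so results do
not depend on gene order. The published trend analysis used an online
service with an unspecified template set; seeded k-means is this
package's replacement, and planted-archetype recovery on synthetic
profiles is the test of adequacy.

`differential()` computes per-stage log2 fold changes of pseudocounted
group means; with ≥ 2 replicates per group it attaches a two-sided
Welch t-test, Benjamini–Hochberg adjusted across genes within the
stage, and calls a gene differential when `|log2FC| ≥ 1` (fold change
2) *and* adjusted significance < 0.05. Unreplicated designs — the
realistic case for per-cultivar RNA-seq time courses — fall back to
a clearly flagged fold-change-only mode. The published volcano plot
came from an online service with unspecified statistics; Welch t + BH
is the labelled stand-in. `welch_t_one_tailed()` exposes the one-tailed
unequal-variance test used for trichome-length comparisons (the
spreadsheet convention "tail = 1, type = 3"), and `delta_ct()`
implements qPCR quantification as `2^−ΔCt` with the reference gene a
parameter (different experiments normalize against different
references, e.g. a ubiquitin or a tubulin).

# The synthetic-data generators

All generators are pure functions of a `simulation_spec()` and its
seed.

* `gen_nsltp_gene()` samples a gap signature from the catalog rows of
  the requested type, fills all gaps with random **non-cysteine**
  residues — making the planted backbone the unique 8-subset — adds a
  short N-terminal cap and tail within the 120-residue mature budget,
  prepends a 20–30 residue signal peptide starting with M, and
  back-translates with uniform synonymous codon choice.
* `gen_candidate_pool()` defaults to the published pool structure: the
  catalog's per-type counts (138 valid genes) plus 18 signal-less, 46
  over-long, 16 cysteine-less, and 1 start-less decoys — 219
  candidates — each decoy constructed to pass every stage before its
  designated one.
* `gen_genome_layout()` plants a 2-gene tandem pair (10 kb apart, 2
  intervening ORFs), a 3-gene tandem chain, a cross-chromosome
  segmental pair, a same-chromosome pair straddling the boundary from
  the wrong side (31 kb *and* 16 ORFs — segmental, not tandem), and a
  pair at identity 0.79 (no event), plus unrelated singletons and
  filler ORFs. Copies differ at an exact number of sites, so planted
  identities are realized exactly under gapless alignment.
* `gen_expression()` draws four temporal archetypes over stages
  0/5/10/15/20 days post anthesis (initiation peak, early-elongation
  peak, monotone decline, flat/silent) with multiplicative lognormal
  noise (σ = 0.1), two cultivars, three replicates, and a planted
  4-fold change for a gene subset in the first cultivar.

What the generators deliberately do **not** emulate: homology structure
between family members (gap fillers are i.i.d., so generated "genes"
of one type are unrelated in sequence), codon bias (available only as
an option), introns in the planted layouts, signal-peptide sequence
realism, and library-level RNA-seq noise (counts are not generated, so
the RPKM step is tested on its arithmetic, not on sampling noise).
Passing the planted-truth tests therefore demonstrates that the
pipeline's logic is correct under the stated conditions, not that the
thresholds themselves are optimal for any particular real genome.

# Numerical choices and degenerate inputs

* Coordinates are 1-based inclusive everywhere, matching the catalog's
  location strings; scaffold locations with an embedded chromosome
  (`scaffold2284A09`) are attributed to that chromosome, bare scaffolds
  are unplaced. The embedded-chromosome rule is an inference from the
  catalog's three-unplaced-genes accounting and is the package's own
  reading; it is flagged as such here.
* pI bisection tolerance `1e-3` pH units; MW reported to 2 decimals.
* Alignment scoring defaults to match 2, mismatch −1, gap opening 4,
  gap extension 1; all four are parameters.
* `scan_ecm()` returns `NULL` (absence is a value, not an error) for
  fewer than eight cysteines or no valid backbone.
* `ng86_kaks()` on identical sequences returns `ka = ks = 0` with an
  undefined ratio; saturated proportions flag the result rather than
  fabricating a distance.
* Empty inputs return empty results (`read_fasta()` on an empty file,
  `filter_candidates()` on an empty list, `report_type_tally()` on no
  assignments); malformed GFF lines and orphan exons are skipped with
  warnings rather than aborting a whole annotation.

# Problem sizes used by the checks

The packaged suite exercises the oracle comparisons at desk scale: 500
random sequences (≤ 160 aa, ≤ 12 cysteines) for the ECM scan oracle, 50
random additive trees (n ≤ 12) for NJ recovery, 20 seeded layouts for
duplication recovery, 100 random 30-codon pairs for the NG86 oracle,
and 20 null expression matrices (120 genes, 3 + 3 replicates) for the
false-positive control. These sizes are the package's chosen balance
between coverage and a suite that runs comfortably on one CPU.

# Known limitations

* The type decision tree is exactly as general as the catalog behind
  it; novel spacings in other species will come back `"unknown"`
  (by design) until the rule table is extended.
* Classification from ECM spacing cannot separate types whose spacing
  ranges overlap in some other species; the published cotton catalog
  happens to be separable.
* Ka/Ks requires an in-frame, gap-free, equal-length pair; the package
  does not perform codon-aware alignment of diverged pairs.
* The expression statistics emulate, rather than reproduce, the online
  services used for the published figures; with unreplicated designs
  only fold-change calls are possible.
* `coverage_longer` of a global alignment is nearly always 1 for
  near-equal-length inputs; it becomes informative only together with
  the identity criterion, which is why both thresholds are applied
  jointly.
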