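---
title: "Methods and design notes for famdup"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes for famdup}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(famdup)
```

`famdup` re-implements, as a reusable and fully testable pipeline, the
family-characterization workflow commonly applied to plant gene families,
instantiated for the pineapple class III peroxidase (AcPRX) family and the
internal-browning (IB) phenotype of stored pineapple fruit. This vignette
is the package's own account of the science: the models and conventions
behind each stage, the parameters that matter, what the synthetic
generator establishes and what it cannot, and the choices made where the
design was genuinely open.

## The family table and physicochemical descriptors

The unit of analysis is a family table: one row per verified family member
with chromosome, 1-based inclusive genomic coordinates, ORF length, exon
count, protein length, molecular weight (kDa) and isoelectric point. The
package ships a transcription of the published 78-gene AcPRX table as
`inst/extdata/acprx_family.tsv`; the loader also accepts any table with
the same columns, including `start–end` location strings with thousands
separators.

Coordinates are kept 1-based inclusive internally. An earlier design
called for a 0-based half-open internal representation with converters at
the boundary; that was dropped because the entire R/Bioconductor ecosystem
this package lives in (IRanges, GenomicRanges, GFF3 import/export) is
1-based inclusive, so a second convention would create conversion sites
rather than remove them.

**Molecular weight** is the sum of average (not monoisotopic) residue
masses plus one water (18.01524 Da), for an unmodified chain. `X` is
accepted and assigned the unweighted mean of the 20 standard residue
masses. Comparisons against published values carry a ±0.1 kDa tolerance
because the exact mass table of the original web tool is unspecified.

**Isoelectric point** is the root of the Henderson–Hasselbalch net charge
over the N-terminus, C-terminus and the D/E/C/Y/H/K/R side chains, found
by bisection on [0, 14] to within 10⁻³ pH. The charge function is strictly
decreasing in pH, so the root is unique. The default pKa set is
EMBOSS-style (`pka_table()`); published pI values from other pKa sets are
matched only within ±0.5 pH, which is why the test suite checks the root
property (|Z(pI)| < 10⁻³) and monotonicity (appending an acidic residue
lowers pI; a basic one raises it) rather than third-party values.

**Candidate screening** keeps homology hits with E-value ≤ 10⁻⁵
(inclusive) and identity strictly greater than 50%, mirroring the
published wording ("an E-value of 1e−5 and >50% identity"); keyword-search
hits bypass the numeric filter, and the union is deduplicated by subject
id. Whether the identity refers to the alignment span or the full length
is not stated in the source workflow; the filter therefore operates on the
identity value as given in the hit table.

Reported percentages (e.g. the exon histogram) use two decimals with
half-away-from-zero rounding, the convention that reproduces printed
figures such as 11.54%.

## Duplicate detection and classification

Two proteins form a duplicate pair when (1) global-alignment identity,
counted as exact matches divided by the length of the *shorter* sequence,
strictly exceeds 0.70, and (2) the shorter protein is strictly more than
70% of the longer protein's length. Alignment uses Needleman–Wunsch with
BLOSUM62, gap opening 10 and extension 0.5 (delegated to Biostrings);
these scores are configurable and documented because the original analysis
does not state them. The shorter-sequence denominator mirrors "similarity
between the longer sequence and the shorter sequence".

**Tandem rule.** The default rule calls a duplicate pair tandem when both
genes share a chromosome and their start-to-start distance is strictly
below 200,000 bp. The convention matters: in the published coordinate
table the widest printed tandem pair (AcPRX18/21) is 199,767 bp apart
start-to-start but over 201 kb end-to-end, so only the strict
start-to-start reading reproduces the printed list. The source methods
also cite a second rule — at most five intervening genes within a 100-kb
fragment — which is implemented as `window_100kb_5genes` and requires the
full chromosome gene order (e.g. from GFF3). The default is the 200-kb
rule because it is the only one checkable against the coordinate table
alone. A k-gene tandem cluster yields all C(k,2) pairs, as in the printed
list (all six pairs among AcPRX18–21); clusters are not merged into single
events.

**Segmental rule.** Segmental status comes from recorded
synteny/collinearity blocks (the package consumes block tables; it does
not perform de novo collinearity detection). A non-tandem duplicate is
segmental when it appears as a block member pair or when its genes fall in
the paired spans of one block. Tandem takes precedence when both rules
match, keeping the two classes disjoint, since the published counts treat
them disjointly.

Two printed-list curiosities are deliberately left alone: pairs such as
AcPRX46/47 (≈18 kb apart) are absent from the published tandem list,
presumably failing the similarity criteria upstream; the classifier does
not "fix" this, and the bookkeeping tests operate on the printed lists as
given.

## Ka/Ks (NG86) and divergence dating

The estimator is the classic Nei–Gojobori (1986) counting method.
Published implementations differ in how stop codons enter the counts, so
the package's conventions are explicit:

* **Sites.** Each codon contributes 3 sites split by the fraction of its
  nine single-nucleotide changes that are synonymous; changes creating a
  stop codon count as nonsynonymous opportunities (denominator stays 9).
  This is what makes, e.g., AAA contribute 1/3 synonymous sites, and it is
  required by the estimator's frozen hand-derived case
  (TTT GGG AAA vs TTC GGG AAA → S = 5/3, Ks = −0.75 ln 0.2 ≈ 1.2071).
* **Differences.** Multi-nucleotide codon differences are averaged
  uniformly over all orderings of single steps; orderings passing through
  a stop codon are excluded. In the rare case every ordering is blocked,
  all orderings are used as a documented fallback.
* **Gaps.** Gapped codon columns are dropped pairwise; gaps must come in
  whole-codon units (the back-translation stage guarantees this).
* **Correction and saturation.** p-values are Jukes–Cantor corrected,
  K = −¾ ln(1 − 4p/3). When ps or pn ≥ 3/4 the result is flagged
  `saturated` rather than clamped, so downstream dating skips such pairs
  explicitly; `undefined_omega` marks Ks = 0 with Ka > 0.

The test suite checks the implementation against an independent exhaustive
pathway-enumeration oracle over **all** 61 × 61 sense-codon pairs and over
random short alignments, exactly — the oracle is written recursively,
sharing no code with the table-driven implementation.

Divergence times use T = Ks / (2λ) with λ = 6.1 × 10⁻⁹ synonymous
substitutions per site per year (the rate used for monocot duplication
dating), so Ks = 1 corresponds to 81.97 mya. The estimator is NG86 only:
maximum-likelihood models, codon-frequency corrections and model averaging
are out of scope, and comparisons against values produced by other
calculators should carry tolerance.

## Neighbour-joining phylogeny

Distances are mismatch proportions over mutually ungapped columns,
Poisson-corrected (−ln(1 − p)) by default; the correction is configurable
because the original tree's settings are unspecified. A saturated pair
(p = 1) is an error in direct use; inside bootstrap replicates p is capped
at 1 − 10⁻⁶ so a degenerate column draw cannot abort a run — a documented
numerical choice, made before any acceptance measurement.

The NJ agglomeration follows Saitou–Nei with the standard two-point
branch-length formulas and two determinism contracts: Q-criterion ties
break on the lexicographically smallest label pair, and negative branch
lengths are clamped to zero with the deficit added to the sister branch.
On additive matrices NJ is consistent, and the suite verifies topology and
path-length recovery against randomly generated 5–8 leaf trees (the
generating tree is the oracle).

Bootstrap supports are the percentage of replicate trees (columns
resampled with replacement, seeded) containing each internal bipartition
of the full-data tree. Taxa are sorted by label before the run, so support
values are invariant to input order at a fixed seed.

Subgroups are obtained by removing the k−1 longest internal edges (ties by
canonical bipartition label) and reading off connected components. When
k−1 exceeds the number of internal edges (k near the leaf count), cutting
continues into terminal edges, skipping cuts that do not split any taxa
group — the generic case reduces to the simple rule, and k = leaf count
yields singletons. The published subgroup sizes (38/4/18/6/12) depend on
an unspecified multiple alignment of the 78 proteins and are therefore a
qualitative check only, not a gate; the suite instead verifies recovery of
planted cluster structures.

## Expression calls

The high-expression rule is applied literally: a gene is `high` in a
condition when |log₂ FPKM| ≥ 1 after averaging replicates, so both
FPKM ≥ 2 and 0 < FPKM ≤ 0.5 qualify. The absolute value reproduces the
published per-tissue percentages, but it is an odd rule (it calls barely
expressed genes "high-magnitude"); the alternative reading log₂ FPKM ≥ 1
is selectable (`rule = "log2_up"`). FPKM = 0 is `not_expressed`, with no
pseudocount anywhere.

Fold changes are log₂(condition/baseline) on replicate-averaged FPKM. The
source never states its zero-handling rule, so the package's is explicit:
condition 0 with baseline > 0 is `down` (log₂FC capped at −10), newly
expressed genes are `up` (+10 cap), genes at zero everywhere are
`not_expressed`. Directions flip exactly under swapping condition and
baseline, a property the suite checks.

## IB phenotype statistics

IB index = [Σ(Sᵢ·Nᵢ)/5N] × 100 over grades 0–5, IB incidence =
100·n(grade ≥ 1)/N. "Affected" means grade ≥ 1 because grade 0 is defined
as no dark spots or discoloration. The index is monotone under grade
promotion, bounded in [0, 100], and equals incidence × S/5 when all
affected fruits share one grade — a closed-form cross-check in the suite.
Group-comparison statistics (t-tests, Duncan's test) are routine and out
of scope; the module exports per-cohort tables instead.

## The synthetic world

The generator's defaults are a fixed "stated world", chosen once:

* 3 chromosomes × 1 Mb, 40 family genes of 300 codons — a toy scale
  keeping full-pipeline tests under a minute;
* 2 tandem clusters of 3 genes with pairwise synonymous divergence
  ~0.15 (≥ 85% protein identity at ω = 0.2) placed within a 20-kb spacing
  budget — comfortably inside the 200-kb rule and far above the 70%
  identity criterion;
* 2 segmental blocks of 2 gene pairs each at Ks ~0.5, placed on distinct
  chromosomes with matching block records — older than tandem pairs, as
  observed for real segmental duplicates, while still above the identity
  threshold;
* independent random background genes, whose pairwise identities sit near
  the alignment noise floor (≲ 40%), so detection specificity is testable;
* expression: three timepoints × three replicates, five genes planted
  4-fold up and five down, 20% of genes silent, no replicate noise by
  default (the planted-recovery criterion is exact recovery in the
  noise-free setting; a lognormal noise knob exists);
* cohorts of N = 30 fruits (the published sampling design) with grade
  distributions tracing a control trajectory toward high severity and a
  treated trajectory that stays mild, their expected indices matching the
  reported control/treated contrast.

Sequence evolution proposes uniform single-nucleotide changes, rejects
stops, accepts synonymous changes always and nonsynonymous ones with
probability ω, stopping when accepted synonymous events reach
(target Ks/2)·S per copy. Because stop-creating proposals are rejected
while NG86 counts them as nonsynonymous opportunities, the realized
nonsynonymous rate per NG86 site is slightly below ω; at ω = 1 the mean
NG86 estimate over 200 replicates is ~0.92–0.94, inside the ±0.1
acceptance band but visibly biased. This is a property of the generating
model, not an estimator defect, and is left as is.

One root seed is split into per-component sub-seeds, so adding a component
never perturbs another's draws, and every output is byte-identical under a
fixed seed.

What a green synthetic test does *not* establish: the generator mimics
neither pineapple genome composition, codon usage, intron-length or FPKM
distributions, nor alignment ambiguity in real protein families (all
planted duplicates are colinear and gap-free). Results that depend on
external databases — the original 92 BLASTP / 105 keyword hits, the
supplementary protein set, the supplementary Ks table behind the
3.46–274.13 mya range, the real FPKM matrices — are consumed-format
features, exercised on synthetic stand-ins only.

## Orchestration

`run_all()` validates a single JSON config (every published parameter is a
named key with the printed value as default), executes the stages in
order, and writes per-stage TSV/Newick outputs plus a `summary.json`
carrying the seed and a config hash (analysis parameters only, not the
output path) for provenance. Reruns with identical config and seed are
byte-identical. Configs are JSON rather than YAML because the target
installation carries no R YAML parser; the declarative contract is
unchanged.

## Known limitations

* No multiple-alignment construction (aligned FASTA is consumed); no ML or
  Bayesian trees; no YN00/GY94 estimators.
* The pI calculation ignores cysteine oxidation state and post-
  translational modifications, as all simple pKa models do.
* `window_100kb_5genes` needs a complete gene order; with family-only
  input the 200-kb rule is the honest default.
* The expression module classifies; it does not model variance and is not
  a substitute for differential-expression inference.
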