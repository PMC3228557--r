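---
title: "Promoter motif scanning, co-occurrence and enrichment: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Promoter motif scanning, co-occurrence and enrichment: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(promscan)
```

This vignette is the package's account of its methods: the coordinate
and scoring conventions, the statistical machinery, the decisions taken
where more than one convention is defensible, what the synthetic-data
generator does and does not emulate, and the problem sizes used in the
shipped validation.

## Coordinates

All sequences are **upstream (promoter) sequences**: sense-strand DNA
ending at the base immediately 5′ of the transcription start site
(TSS). The TSS is position 0 and is not part of the sequence; a
sequence of length $M$ covers TSS-relative positions $-M..-1$, and the
character at 0-based string index $i$ sits at position $i - M$.
Intervals are inclusive on both ends, so an interval $[-119, -111]$
spans 9 bp. This convention reproduces published promoter-site
coordinates directly (for example, the human *Caspase1* promoter
carries a HIPPI binding site at $-119..-111$ overlapping a P53
half-site at $-117..-98$ — the package's standard worked example for
co-occurrence). Internally all indexing is 0-based; conversion to
TSS-relative coordinates happens at a single reporting boundary to
prevent off-by-one drift.

Sequences shorter than a requested extent are kept at their full
available length rather than discarded: there is no principled discard
rule, and keeping them maximizes data. `N` bases are retained on load;
their handling is a scanner decision (below).

## Motifs and the similarity score

Motifs enter either as bracketed degenerate consensus strings
(`AAAGA[G/C]A[A/C/T][T/G]`, one position per plain base or bracket
group) or as TRANSFAC-format count matrices, normalized per column to
frequencies. Consensus motifs are converted to the equivalent
uniform-within-column frequency matrix so a single scanning code path
serves both kinds.

A window $w$ of motif length $L$ scores

$$\mathrm{score}(w) = \frac{S - S_{\min}}{S_{\max} - S_{\min}},
\qquad S = \sum_{i=1}^{L} f_i(w_i),$$

with $S_{\max}$ and $S_{\min}$ the sums of per-column maxima and
minima. Properties that motivate this definition:

* it lies in $[0,1]$ for every window;
* it equals exactly 1.0 **iff** every column is at its best base, so
  for a consensus-derived matrix "cutoff 1.0" is literally exact
  consensus matching (this equivalence is tested exhaustively and
  against an independent string-matching oracle);
* it behaves like the familiar additive matrix-similarity scores used
  with absolute cutoffs such as 0.9.

No pseudocounts and no log-odds transformation are applied: the score
is used with absolute cutoffs (1.0 for anchors, 0.9 for secondary
motifs by convention), not as a likelihood ratio. This score
definition is the package's own; published genome-scale hit counts
obtained with unpublished in-house scoring schemes should not be
expected to reproduce exactly, and no such count is asserted anywhere
in the test suite. An `N` base contributes the column minimum — the
conservative choice that prevents N-rich sequence from generating
hits. A matrix whose columns are all uniform has $S_{\max} =
S_{\min}$ and is rejected as unscorable.

## Scanning

The scanner slides the matrix over every window position on the plus
strand and over the reverse complement for the minus strand;
minus-strand hits are reported as the interval of matched bases in
sense coordinates. All overlapping hits are reported (one per offset
per strand; a palindromic site matching both strands at one offset
yields two hits) — downstream summaries deduplicate at the gene
level, so nothing is lost and nothing is double-counted where it
matters. Implementation note: a sequence set is encoded once as an
integer vector with sentinel separators whose score contribution is
$-\infty$, so a single vectorized pass scores every window of every
gene and windows spanning two genes can never pass a cutoff.

Positional histograms bin hits by their **start** (the 5′-most matched
base in sense coordinates); bin $j$ covers $[-j\cdot w, -(j-1)\cdot w
- 1]$ for bin width $w$ (default 1000 bp over a 10 kb extent). A hit
straddling a boundary belongs to its start's bin — a 9–12 bp site
almost always lies inside one 1 kb bin, and the start is
deterministic. Because the conventional "frequency per kb" y-axis is
ambiguous between per-sequence and per-hit normalization, raw counts
are always retained alongside the per-sequence per-kb frequency.

## Co-occurrence

Given anchor and secondary hit tables over the same gene universe, a
co-occurrence is any same-gene pair whose intervals overlap or whose
**gap** — bases strictly between the intervals — is at most the window
$W$ (default 100 bp, inclusive at exactly $W$, applied on either side
of the anchor). Overlapping intervals count with gap 0; the
*Caspase1* example above requires this. A hit never pairs with itself.

Enrichment of a secondary motif near the anchor is counted at the
**gene level**: the universes are the anchored genes ($n$ of the
target, $N$ of the background — co-occurrence is undefined without an
anchor), and a gene is a success when it carries at least one
co-occurrence. Gene-level counting is what the hypergeometric urn
models; occurrence-level counting would break exchangeability. The
background defaults to all anchored genes of the supplied background
set; callers who want a different universe pass a different set.

## Statistics

* **Cumulative hypergeometric**: $P(X \ge k)$ for $X \sim
  \mathrm{Hypergeom}(N, K, n)$, computed through `stats::phyper`
  (log-gamma based, stable at genome scale). Exactness is verified
  against exhaustive subset enumeration on every urn with $N \le 12$.
* **Chi-square**: Pearson 2×2 without continuity correction, 1 df,
  contrasting the target against the background *excluding* the
  target — each test in its textbook-valid form (the hypergeometric
  uses the standard nested urn). Zero-margin tables are degenerate and
  rejected.
* **Benjamini–Hochberg**: classic step-up via `stats::p.adjust`,
  verified against hand arithmetic.
* The **decision rule** for motif enrichment is the disjunction:
  significant when either the hypergeometric or the chi-square p falls
  below $\alpha = 0.05$; the BH-adjusted hypergeometric p across the
  tested library is always reported alongside, and annotation-term
  enrichment selects on the adjusted p (correction is applied over
  *all* tested terms, not only the reported ones). When $K = 0$ the
  ratio is undefined; the record is flagged and its p set to 1.

## Differential lists

Differential tables carry ratio fold changes (neutral = 1) and
p-values. Selection applies BH first (the corrected filter; a raw-p
variant is available via `correct = FALSE`) and keeps genes with
adjusted $p < \alpha$, split by fold-change direction. A selected gene
at exactly the neutral fold belongs to neither direction and is
counted separately rather than silently routed.

The two-experiment "common set" applies a diminished-response rule
with a 10% cutoff: a gene significantly up in experiment A belongs to
the common set when its fold change in B satisfies $f_B/f_A \le 0.9$;
for down-regulated genes the rule is applied to magnitudes, and since
the magnitude of a repression is the reciprocal fold this becomes
$f_A/f_B \le 0.9$. The rule's phrasing in the literature is ambiguous
between absolute and relative diminution; the relative reading is
implemented because it is scale-free and symmetric under
up/down reflection. Genes absent from B are excluded and counted.

## Synthetic data

The generator emulates the *structure* of a promoter-motif study:
i.i.d. bases with a single GC parameter, motifs planted by
**overwriting** (never inserting, so coordinates stay comparable),
uniform choice among consensus expansions, optional reverse-complement
planting, and position models — fixed offset, uniform, or
TSS-proximal (a fraction $f$, default 0.7, within 2 kb of the TSS,
uniform beyond), the latter reproducing the empirical concentration of
functional sites near the TSS. Collisions with previously planted
sites are resampled (bounded, then an error) so truth tables stay
exact.

Two-group designs parameterize presence rates as **the quantities the
enrichment statistics consume**: `rate_target` is the expected carrier
fraction of the target subset and `rate_background` the expected
carrier fraction of the *whole* background set (the target is nested
inside the background urn). The non-target planting rate is derived
as $(N r_b - n r_t)/(N - n)$; infeasible combinations are an error in
`plant_two_group` (and clamped at zero in the demonstration
simulator, where convenience outranks strictness). Under this
parameterization a design with $r_t = 0.5$, $r_b = 0.05$ over
$200/2000$ genes has expected ratio $0.5/0.05 = 10$.

Enrichment validation designs use a non-degenerate 12-mer rather than
the degenerate 9 bp anchor consensus: the latter's chance-hit rate in
uniform 1 kb sequence is $2(M-8)\cdot 12/4^9 \approx 0.09$ per
sequence, enough to halve a planted enrichment ratio, whereas a
12-mer's ($\approx 10^{-4}$) is negligible. The degenerate consensus
is still what the chance-hit calibration and the positional-shape
checks exercise, since its analytic chance rate is known in closed
form.

The differential-table generator labels each gene true or null. The
default null p-value model is Uniform(0,1); note that with uniform
nulls BH at 5% *will* typically admit a handful of nulls alongside 100
planted true positives at $p = 10^{-4}$ in a 2000-gene table — that is
FDR control working as designed, not a defect. The exact-recovery
demonstration therefore constructs its table with nulls at a fixed
high p (0.5), where the step-up arithmetic is deterministic; the
uniform-null model keeps its own property (empty selection under the
global null in ≥ 95% of seeds).

What the generator does **not** emulate: dinucleotide composition,
CpG islands, repeat structure, alternative TSSs, homolog structure,
or correlated expression noise. Passing tests therefore demonstrate
algorithmic and statistical correctness under the stated models, not
biological recall on real genomes.

## Numerical choices and degenerate inputs

* Cutoff comparison uses a $10^{-9}$ epsilon to absorb floating-point
  summation noise; perfect matches score bitwise 1.0 because the
  window sum and $S_{\max}$ accumulate identical terms in identical
  order.
* Ties in BH share their rank block's value (inherited from the
  step-up definition); enrichment tables break p-value ties by item
  id for deterministic output.
* A motif longer than a sequence yields an empty result, not an
  error; an empty target set, an empty annotation map, a target with
  no anchored genes, and zero-margin chi-square tables are errors.
* All generators take explicit integer seeds and restore the caller's
  RNG state; identical seed and configuration give byte-identical
  FASTA and truth tables. The pipeline manifest deliberately omits
  timestamps so reruns are byte-identical.

## Problem sizes in the shipped validation

The test suite validates at sizes chosen to make sampling bounds
tight while remaining desk-scale: scanner-oracle agreement on 1000
random 1 kb sequences; the full hypergeometric grid to $N = 12$; 500
null BH replicates at $m = 100$; enrichment and co-occurrence power
designs of 200 target vs 2000 background genes (1 kb and 600 bp
promoters respectively) over 100 seeds each; positional-shape
recovery on 100 × 10 kb promoters over 100 seeds; and chance-hit
calibration over 10,000 kb of uniform sequence. The acceptance script
(`scripts/acceptance.R`) re-runs single-seed versions of the same
designs end to end.

## Known limitations

* The similarity score is a reconstruction choice; absolute hit
  counts from tools with unpublished scores will differ even at the
  same nominal cutoff.
* No information-content (conservation-index) weighting of matrix
  columns.
* Annotation enrichment is flat: no ontology DAG traversal or
  ancestor propagation.
* One upstream record per gene id; collapsing multiple transcripts
  per gene is upstream of this package.
* The chi-square p-value is asymptotic; at small expected counts the
  hypergeometric companion is the trustworthy one of the pair.
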