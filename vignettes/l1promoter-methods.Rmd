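---
title: "Methods: monomer census and reporter statistics for mouse L1 promoters"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: monomer census and reporter statistics for mouse L1 promoters}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(l1promoter)
```

## The problem

Mouse LINE-1 (L1) retrotransposons carry their promoter inside the 5'UTR,
which — unlike the human L1 5'UTR — is organized as a tandem array of
~200-bp repeats called *monomers*, separated from ORF1 by a non-monomeric
*tether*. Because reverse transcription frequently aborts, most genomic L1
copies are 5'-truncated: an insertion can begin anywhere inside the monomer
array. Two questions follow directly from this architecture:

1. **Census**: for the copies of a given subfamily, where in the array do
   they start? How many intact monomers does a typical copy retain, and
   does that number shrink with subfamily age?
2. **Activity**: how strong are the promoters built from these monomers
   and tethers, measured by dual-luciferase reporter assays, and how do
   sense and antisense orientations compare?

`l1promoter` implements both analyses as a tested pipeline, with a
synthetic-data generator standing in for genome-scale inputs and wet-lab
plates so that every stage can be verified against known truth.

## The extended query and coordinate system

For a subfamily with consensus monomers $M_k, \dots, M_1$ (5' to 3'; $M_1$
abuts the tether $T$) the pipeline builds an *extended query* by
prepending copies of the 5'-most full monomer until the query carries
`total_monomers` (default 11) monomers, followed by the tether:

$$\underbrace{M_{11}\,M_{10}\cdots}_{\text{prepended copies}}\;M_3\,M_2\,M_1\,T$$

The supplied model must already have the consensus's 5' *partial* monomer
removed; the duplicated unit is therefore the 5'-most *full* monomer
(e.g. a 212-bp unit for a Tf-like model). Every query position maps
bijectively to a `(domain, offset)` pair with 1-based inclusive offsets
(`map_query_position()` / `query_position()`); this is property-tested
over random models.

## Alignment

Each candidate locus (in element orientation, 5'→3') is aligned to the
extended query with an exact affine-gap Smith–Waterman
(`local_align()`, implemented in C++). Scoring defaults to
+2/−3 with gap open 5 and extend 2 — a length-$L$ gap costs
$5 + 2L$ — approximating default nucleotide BLAST behaviour; no identity
threshold is applied. Design choices that the tests rely on:

* ties among equal-scoring optima are broken by smallest subject start,
  then smallest query start, then longest alignment;
* no hit is reported when the best score is ≤ 0;
* `N` is forbidden in queries, scores as a mismatch in subjects, and
  never counts toward identity.

The implementation is checked for exact score equality against an
independent brute-force dynamic-programming oracle on hundreds of
perturbed random pairs, and against `Biostrings::pairwiseAlignment`.
Alignments computed externally in the standard 12-column tabular layout
can be imported instead (`import_hits_tabular()`); minus-orientation rows
(`sstart > send`) are flagged and rejected downstream.

## Filtering and binning

Two anchoring windows (`filter_config()`, both 10 bp) remove artefacts:

* **tether tail**: the alignment must end in the last 10 bases of the
  query, i.e. reach the tether's 3' end — otherwise the locus has a
  3'-truncated tether (`qend ≥ L_q − 9`);
* **subject head**: the alignment must start within the first 10 bases of
  the locus (`sstart ≤ 10`) — otherwise the locus's 5' end is not the
  element start (e.g. a chimera of divergent subfamilies).

Both windows are inclusive; shrinking either never admits a previously
rejected hit (property-tested). For each passing locus the query start
maps to a bin — tether (`T`), monomers `M1` … `M10`, or `M11+` — and a
fractional monomer count. A start at offset $o$ of monomer $M_i$ with
domain length $L_i$ yields

$$\text{monomer count} = (i - 1) + \frac{L_i - o + 1}{L_i},$$

so a locus starting at offset 1 of `M3` carries exactly 3.0 monomers and
one starting at offset 83 of a 212-bp `M3` carries 2.613. The formula is
the package's own; only the existence of a fractional-length calculation
is prescribed by the source analysis. `T` loci have count 0 and `M11+`
loci exceed 10; both are excluded from subfamily averages, which are
means of the fractional counts.

Subfamilies with several monomer-organization patterns (the Gf_I case)
are aligned against one query per pattern; a locus passing under several
patterns is kept once, under the highest-precedence pattern
(`dedup_patterns()`, default precedence II > I > IV, pattern III excluded
because its alignments are short and redundant).

The census (`census()`) reports per-bin counts and percentages,
per-bin start-offset histograms, and cumulative "≥ k intact monomers"
categories. *Intact* is offset-independent bin membership: a locus has at
least $k$ complete monomers iff it starts in $M_{k+1}$ or beyond, or
exactly at offset 1 of $M_k$. The wording "more than k" and "at least k"
is used interchangeably in the source literature's percentages; the ≥
reading is adopted because it reproduces the printed worked examples
(e.g. 1032/1125 with at least two intact monomers).

All reported fractions use one convention (`percent()`): $100\,n/d$
rounded half away from zero to one decimal, applied only at reporting
time. The regression of average monomer count on subfamily age
(`age_regression()`) is ordinary least squares via `stats::lm`; the
signed Pearson correlation $r$ and the two-sided slope p-value
($t = r\sqrt{n-2}/\sqrt{1-r^2}$ on $n-2$ df) are reported. Ages are user
input — only three of the seven published subfamily ages (0.21, 0.75,
2.15 Myr) are printed in the source text, the rest live in external
supplementary material.

## Dual-luciferase statistics

`normalize_plate()` implements the stepwise normalization: per-well
firefly/Renilla ratio → mean ratio of the no-promoter control → every
ratio divided by that mean (the control then averages exactly 1, the
assay background) → per-construct means over replicate wells. Two
uncertainties are reported:

* `sem` — the replicate standard error $s/\sqrt{n}$ of the normalized
  wells, the quantity conventionally drawn as error bars;
* `se_activity` — the standard error of the *normalized activity
  estimator* $\overline{r}_X/\overline{r}_{\text{ctrl}}$, which
  propagates the control-mean uncertainty by the delta method:
  $\sqrt{\text{sem}_X^2 + (\hat A_X \cdot \text{sem}_{\text{ctrl}})^2}$.

The distinction matters when comparing an estimate with truth: with
$n = 4$ wells the control mean is itself noisy, and a ±3·`sem` band
covers the truth for only ~87% of constructs in simulation, whereas
±3·`se_activity` covers ~97%. Recovery checks in this package therefore
use `se_activity`; figures and tables report `sem`.

Pairwise comparisons use `stats::pairwise.t.test` with a standard
deviation pooled across **all** groups (residual df $N - k$), two-sided,
with Benjamini–Hochberg adjustment across exactly the pairs reported in
one run (`pairwise_tests()`). Whether the source analysis pooled across
all groups or per pair is not stated; pooling across groups is that
function's default and is adopted here, with a hand-computed pooled-SD +
BH step-up oracle in the tests. No background subtraction of mock wells
is performed. Relative activities (`relative_activity()`) are
$100\,\bar A/\bar A_{\text{ref}}$ with one-decimal reporting.

`summarize_titration()` summarizes dose series and fits a least-squares
line through the origin on a user-chosen dose subset, reporting each
dose's relative deviation — saturation appears as growing negative
deviation at high dose; no automatic plateau call is made.

## The synthetic-data generator

`simulate_loci()` draws, per locus: a start monomer from a categorical
distribution over slots 1–11 (default peaked at the third monomer, the
shape seen in young subfamilies); a truncation offset from a mixture of
a uniform background and single-nucleotide hotspots (defaults: offsets
83 and 86 with weights 0.166 and 0.263, echoing the dominant peaks
reported at those positions); then emits the exact suffix of the
extended promoter sequence from that point through the tether, mutated
at the configured substitution/indel rates (default 1% substitutions, no
indels). Two confounder classes are mixed in (5% each by default):
3'-tether-truncated loci missing ≥ 11 bp of tether (guaranteed to fail
the 10-bp tether-tail window) and random-composition decoys with the
same length distribution. A truth table accompanies the FASTA; identical
configs and seeds reproduce identical bytes.

`simulate_plate()` draws a shared log-normal per-well transfection
efficiency (CV 30% by default) that multiplies firefly and Renilla
identically — encoding why the internal Renilla control works: the
per-well ratio cancels it — plus independent log-normal measurement
noise (CV 10%) per signal, and an optional saturating dose factor
$d/(1 + d/K)$ common to both signals.

Synthetic models (`random_promoter_model()`) use a random ancestral
monomer with substitution-diverged copies (default 10% divergence,
within the 3–25% monomer-to-monomer divergence seen in real
subfamilies) and an unrelated random tether. What the simulations do
**not** emulate: phylogenetically realistic substitution processes,
monomer subtype structure, 5'-inversions and internal rearrangements,
CpG-biased mutation, or promoter-strength biophysics. Passing recovery
tests therefore demonstrate that the pipeline's coordinate arithmetic,
filters and statistics are correct under the stated noise model — not
that a particular genome assembly would yield particular counts.

## Numerical choices and problem sizes

* Rounding: half away from zero, one decimal, only at reporting.
* Aligner tie-breaks and gap convention: as above, documented and tested.
* Empty census inputs return totals of 0 with `NA` percentages rather
  than dividing by zero; a zero percentage denominator is an error.
* Degenerate regressions (n < 3, constant age) and under-replicated
  plate groups (< 2 wells) are errors, not silent results.
* Test problem sizes were chosen to exercise every code path at
  comfortable desk scale: 200 random pairs for the aligner oracle,
  500 simulated loci (~2.5-kb query) for census recovery, and 200
  seeded plate simulations for the 3-SE recovery rate; a full test run
  completes in a few minutes on one CPU.

## Known limitations

* The built-in aligner reports a single best local alignment per locus;
  multi-HSP chaining and E-values are out of scope (imported tabular
  hits can carry an external tool's scoring instead). How the source
  analysis resolved multiple HSPs per locus is unstated; maximum score
  with the documented tie-breaks is this package's convention.
* Genome-scale locus counts depend on a specific assembly and repeat
  library and are not reproduced here; the package reproduces the
  *arithmetic* of the published worked examples and validates the
  pipeline on synthetic truth instead.
* The fractional-count formula and the ≥ reading of "intact monomers"
  are documented conventions; alternative readings would shift averages
  by at most one offset unit per locus.
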