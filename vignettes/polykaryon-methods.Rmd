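---
title: "Methods: calling more than two parental haplotypes from cloned amplicons"
author: "polykaryon"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: calling more than two parental haplotypes from cloned amplicons}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polykaryon)
```

## The question

A basidiomycete fruit body (basidioma) normally develops from a dikaryon and
should therefore carry exactly two parental nuclear haplotypes at any
single-copy locus. When a single-locus amplicon from one basidioma is
plasmid-cloned and many clones are Sanger-sequenced, more than two distinct
sequences are routinely observed. Three explanations compete:

1. **Cloning/PCR point error** — a polymerase misincorporation propagated by
   cloning; expected to appear in a single clone.
2. **Recombination** — a PCR-mediated chimera or a meiotic recombinant of
   the two parental haplotypes; expected to look like a mosaic of the two
   dominant sequences.
3. **A genuine third parental haplotype** — evidence that the basidioma is
   polykaryotic or chimeric.

`polykaryon` formalises the published line of reasoning into a testable
pipeline: collapse clones into supported haplotypes, excise the
explanations one at a time, and call the number of parents per basidioma.

## Data model

The substrate is a pre-aligned FASTA of clone sequences (alphabet
`A,C,G,T,N,-`), a BED-style exon/intron map, and a sample sheet mapping each
clone record to its basidioma and locality with a `clone_count` giving the
number of identical sequenced clones the record stands for. Internally all
coordinates are 1-based inclusive alignment columns, so reported positions
can be read directly off the alignment; BED input (0-based half-open) is
converted on read. Input is case-insensitive and `U` is mapped to `T` with
a warning. Columns containing `N` in any sequence are excluded from
polymorphism calling entirely — the simplest defensible rule for ambiguity,
since per-sequence masking would make site counts depend on which sequence
is ambiguous.

## Polymorphism spectrum

`findPolymorphicSites()` scans alignment columns. Substitutions are
classified by the purine–pyrimidine rule (A–G and C–T transitions; A–C,
A–T, C–G, G–T transversions). Two conventions matter:

* **Merged indels.** A maximal run of consecutive gap-containing columns
  with an identical gap pattern across sequences is one indel event of that
  run length. A 4-bp deletion is one mutation, not four; this matches how
  indels of 1–4 bp are conventionally counted in spectrum tables.
* **Multi-allelic sites.** A column with $k$ distinct non-gap states
  contributes $k-1$ events, pairing each minor state with the majority
  state (ties broken alphabetically). This yields one event for biallelic
  sites and a defensible minimum for tri-allelic ones; the published
  counting convention for such sites is not stated, so all-pairs counting
  is available via `pairing = "all_pairs"`.

`spectrumTable()` aggregates events by class and region; totals and
percentages are always recomputed from the counts. Integer percentages are
rounded half away from zero. Per-region mutation frequencies
(100 × events / region length) are returned exactly; the printed convention
for such frequencies at one decimal is truncation toward zero (97/207 =
46.86% prints as 46.8%), so `polymorphismFrequency()` exposes `style =
"truncate"` alongside exact and rounded output.

## Collapsing clones and excluding singletons

`collapseClones()` groups a basidioma's clones by exact sequence identity;
support is the summed `clone_count`. Haplotypes seen in fewer than
`minSupport = 2` clones are excluded as potential cloning artefacts (the
singleton-exclusion rule). Of the retained haplotypes the two best
supported are the *dominant* pair — the dikaryon null expectation — and any
further retained haplotype is *minor_supported*, a candidate extra parent.
A support tie for the second dominant slot is broken by haplotype id and
logged; the two-parent null is always instantiated by exactly two
dominants.

## The birthday-paradox error model

Could a minor haplotype's private mutations have arisen independently in
several clones? With $n$ clones and mutations scattering at random over $L$
polymorphic regions, where at a site the single transition outcome carries
weight 2 against 1 for each of the two transversions, the chance that one
specific transition recurs in a given clone is $q = 1/(2L)$. The default
closed form approximates the probability of $k$ coincident occurrences by
the expected number of coincident $k$-tuples,

$$P_{\mathrm{ts}}(k) = \binom{n}{k} q^k, \qquad
  P_{\mathrm{tv}}(k) = \tfrac12 P_{\mathrm{ts}}(k),$$

with the class asymmetry applied once, reproducing the conventional rule
that a transversion coincidence is half as probable as a transition
coincidence at every $k$. Probabilities of several independent private
mutations multiply. At $n = 16$ clones and $L = 16$ polymorphic regions
this gives $P_{\mathrm{ts}}(2) \approx 0.117$ and $P_{\mathrm{ts}}(3)
\approx 0.017$ — the right scale for the coincidence probabilities such
data sets demand, and the package treats the published ~0.148/~0.022
values as calibration anchors (within a factor of two) rather than exact
targets, because the exact published formula is not restated anywhere
usable. An exact binomial-tail variant ($P(X \ge k)$, $X \sim
\mathrm{Bin}(n, q_{\mathrm{class}})$ with $q_{\mathrm{tv}} = q/2$) is
exposed through `errorModel(..., variant = "binomial")`; it abandons the
exact halving in favour of a strict per-clone generative model. A
Monte-Carlo oracle in the test suite (random mutations scattered over $L$
regions with 2:1:1 weights, coincident $k$-tuples counted) matches the
default closed form within three standard errors.

Whether $n$ should count all clones sequenced or only retained clones is
unstated in the source reasoning; the package uses all clones sequenced
for the basidioma, the more conservative (larger-$n$, larger-$P$) choice.
Indel coincidences carry transversion weight, a conservative default for a
class whose error rate is not modelled separately.

## Minimal template switches

`minCrossovers()` asks whether a clone is explainable as a mosaic of the
dominant pair. Informative sites are the columns where the candidate
parents differ; gaps are matched as a fifth state because indels are real
haplotype markers at a cloned locus. The minimal number of template
switches is found by dynamic programming over the ordered informative
sites (states = parents, unit cost per switch); the suite proves the DP
equal to exhaustive path enumeration on all toys with up to 12 informative
sites and 3 parents. Among co-minimal paths, switches are placed as early
as possible and ties broken by parent order, making breakpoint reporting
deterministic; breakpoints are open intervals between consecutive
informative sites assigned to different parents. Positions where the clone
matches *no* parent — whether or not the parents differ there — are its
unique polymorphisms: they are reported separately and never force a
switch.

## Calling the parent number

A minor haplotype counts as an additional parent iff

* the joint shared-error probability of its unique polymorphisms at its
  observed support is below `alpha = 0.05`, **and**
* it is not explainable as a recombinant of the dominant pair with at most
  `maxCrossoversRecent = 2` switches and zero unique polymorphisms.

The crossover budget separates *recent* recombination (a PCR chimera or a
single meiotic event, one or two template switches) from mosaic patterns
requiring many close-spaced switches, which instead indicate a long
recombination history of distinct parental lineages. A basidioma with one
retained haplotype is called 1 parent with an explicit caveat (homozygosity
or an undetected second parent); with none, `uncallable`.

## PHI recombination test

`phiTest()` implements the pairwise homoplasy index. For every pair of
parsimony-informative sites within `window` alignment columns (default
100 nt) it computes the refined incompatibility — the minimum number of
extra mutations any genealogy needs to accommodate the pair, obtained as
the cyclomatic number (edges − vertices + components) of the pair's
partition intersection graph — and averages over pairs. Recombination
decouples distant sites while leaving nearby sites compatible, so a low
nearby-pair mean relative to the site-order permutation distribution is
evidence of recombination; the p-value is the fraction of permutations at
or below the observed mean (a normal approximation to the permutation
distribution is optional). The permutation test is seeded and
deterministic. Its null assumes exchangeable site columns: pronounced
rate heterogeneity along the locus (e.g. intron blocks nine times more
polymorphic than exons) biases the statistic conservative, so the type-I
calibration experiment in the test suite uses a rate-homogeneous clonal
locus; on real mixed exon/intron alignments the test remains valid but
conservative.

## Gene diversity, Fst and networks

Individuals are haploid units: each retained haplotype of a basidioma
enters once, unweighted by clone support (support reflects PCR/cloning
sampling, not population frequency). The default estimator is the haploid
Weir–Cockerham θ (variance components, ratio-of-sums across polymorphic
sites, negative values possible under panmixia), with spread by jackknife
over polymorphic sites; Nei's $G_{ST} = (H_T - H_S)/H_T$ on plain
haplotype frequencies is the cross-check, with bootstrap spread over
individuals when the input is unlinked haplotype labels.

`buildNetwork()` connects haplotypes by mutation distance (a merged indel
= one step). The default is the minimum-spanning network: edges added in
increasing distance order whenever their endpoints are not yet connected
through strictly shorter edges, keeping all co-minimal edges —
deterministic and topology-only. A quasi-median (median-joining style,
ε = 0) augmentation is available and flagged experimental; it adds
site-wise majority consensus nodes of triplets until closure and is not
guaranteed to match reference median-joining implementations.

## The simulator

`simConfig()`/`simulateDataset()` generate cloned-amplicon data sets with
ground truth, emulating the statistical structure the analysis assumes: a
586-nt coding region interleaved with four introns of 50–58 nt; intron
mutation-event density ~9× the exon density (defaults 0.468 vs 0.054
events per nt across the pool); a transition-dominated spectrum (27/32 of
exon substitutions, 51/85 of intron substitutions) with C/T-enriched
ancestral base frequencies so C–T transitions dominate; intron-only 1–4 nt
deletions (12/97 of intron mutations); a pool of 20 parental haplotypes
derived from one ancestor by independent mutation (a star genealogy — the
pipeline uses only polymorphism structure, never genealogy depth, so a
coalescent would add cost without changing what is tested); basidiomata
drawing 2 parents (or 3, with probability 0.25, matching the observed 3
of 11 fruit bodies with a third haplotype); multinomial clone allocation
over contribution proportions (uniform by default — observed skewed counts
like 7/7/2 are single multinomial draws, and the underlying contribution
is unknown; skewed proportions are a config knob used to emulate the
published three-haplotype pattern); PCR point errors at $10^{-4}$ per base
per clone with 2:1:1 transition:transversion weighting and PCR chimeras at
0.02 per clone with a uniform breakpoint (order-of-magnitude choices — no
published estimates exist for this protocol). Population structure for
Fst scenarios allocates basidiomata to demes, with deme-private mutations
as the divergence knob; the default of zero private mutations is
panmixia.

Per-region per-site mutation rates are calibrated by inverting the
expected number of *distinct mutation events* per site across the pool
(one transition target, two transversion targets, indels essentially
always distinct), because mutation frequencies are reported as events per
nt; calibrating on the fraction of polymorphic sites instead would
overshoot the event frequencies once multi-hit sites appear at intron-like
densities. All randomness flows through the single config seed; identical
seed and config give byte-identical outputs.

What the simulator does *not* emulate: chromatogram-level sequencing
error, alignment uncertainty (inputs are pre-aligned by construction),
insertion polymorphism (deletions only, so the alignment length is fixed),
codon structure and selection, and genealogical depth. Passing tests
therefore demonstrate correct behaviour under the assumed polymorphism
structure, not robustness to misalignment or base-calling artefacts.

## Numerical and design choices

* Problem sizes in the test and acceptance experiments — 200 basidiomata
  per recovery condition, 200 clonal replicates for PHI type-I at 100
  permutations, 100 replicates for panmixia and calibration, toys of ≤ 12
  informative sites for the exhaustive crossover oracle — were chosen to
  keep each Monte-Carlo bound at least three standard errors away from its
  threshold while remaining desk-scale.
* The PHI type-I calibration uses a 300-nt single-region locus at
  intron-like density so the permutation null (exchangeable columns) holds
  exactly and the incompatibility matrix is informative.
* Ties: majority states and second-dominant slots break alphabetically /
  by id, and are logged when they decide a dominant.
* Degenerate inputs are flagged, not thrown, where the analysis can
  continue: empty retained haplotype sets are `uncallable`, PHI with < 4
  sequences or < 2 informative sites is `not computable`.
* Percentages: integer percents round half away from zero; 1-dp
  frequencies use truncation toward zero, matching the printed convention
  of the tables this package reproduces.

## Limitations

The parent-count call inherits every assumption above; in particular it
cannot distinguish a true third parent from a recombinant *of unseen
parents*, and its error model treats private indels at transversion
weight. The shared-error closed form is a first-moment approximation,
accurate when $q$ is small ($nq \ll 1$); for very small $L$ or very large
$n$ the binomial-tail variant is the safer choice. Fst estimates on
haplotypes-within-basidiomata treat haplotypes as independent haploid
draws from their locality, ignoring the pairing of haplotypes within fruit
bodies. The experimental median-joining mode is a heuristic
approximation, not a reference implementation.
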