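---
title: "Measuring restriction-site avoidance with compositional bias"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring restriction-site avoidance with compositional bias}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sitecb)
```

## The problem

Restriction–modification (R-M) systems cleave unmethylated DNA at short,
often degenerate recognition sites. A virus infecting a host that encodes
such a system gains fitness by carrying fewer copies of the site, so
long-term selection can deplete — sometimes eliminate — recognition sites
from viral genomes. Detecting that depletion requires a null model of how
often a site "should" occur in a genome of the observed composition, a
classification rule for calling a site avoided, and carefully constructed
experimental and control datasets of (site, genome) pairs. `sitecb`
implements all three stages plus a synthetic-data generator that makes the
whole pipeline testable without downloading any sequence.

## The compositional-bias model

For a site with specified positions $P$ (every letter except `N`; degenerate
letters such as `W` count as specified and are carried verbatim), the
observed count $N(s)$ is the number of overlapping windows matching the
site under IUPAC set semantics. The expected count is built from the
observed frequencies of all $2^{|P|}$ *subsites* — the patterns obtained by
masking any subset of the specified positions to `N`, keeping the literal
length:

$$E(s) \;=\; \prod_{S \subsetneq P} N(s_S)^{-(-1)^{|P|-|S|}},
\qquad \mathrm{CB}(s) \;=\; \frac{N(s)}{E(s)}.$$

For a dinucleotide `CG` this reduces to the familiar
$N(\mathrm{CN})\,N(\mathrm{NG})/W$ with $W$ the window count; for longer
sites it is the full inclusion–exclusion of the maximal-decomposition
measure. Three design choices deserve emphasis:

* **All subsets, including non-contiguous ones.** Masking is over subsets
  of specified positions, not contiguous subwords (`GNT` is a subsite of
  `GAT`). This is the only reading under which "all subsites" is
  well-defined for degenerate sites, and it is what makes the expectation
  sensitive to every lower-order correlation. Contiguous-only subwords
  would instead reproduce a maximal-order Markov expectation.
* **Internal `N` spacers are permanent.** In `GCNGC` the middle position is
  never enumerated over: retaining and masking an `N` give the same
  pattern, and enumerating literal positions would make paired terms cancel
  into a degenerate statistic. A site's CB is therefore invariant to
  re-trimming and re-parsing of its text.
* **All subsites are counted at full literal length.** Every masked pattern
  keeps the parent's length, so every term shares one window count and the
  exponents (which sum to zero by the binomial theorem) cancel the
  normalisation exactly: CB computed from counts equals CB computed from
  frequencies to floating-point accuracy. Edge windows differ slightly from
  counting a trimmed subword; the convention is deterministic and
  documented.

Matching is conservative: a genome letter matches a pattern letter only
when it is a concrete base inside the pattern letter's IUPAC set, so
ambiguous genome letters (including `N`) match nothing — not even pattern
`N`. On an ambiguity-free genome the all-`N` subsite count is exactly
$G-L+1$; on assemblies with ambiguity codes, windows touching them are
excluded from every term coherently. The same rule lets segmented genomes
(e.g. dsRNA Cystoviridae) be concatenated with a single `N` separator
without any window spanning a segment junction. RNA genomes are analysed as
their cDNA text (`U` transliterated to `T`) so one counting engine serves
all genome classes, and sequences are treated as linear even when the
molecule is circular (the effect is $O(L/G)$ and negligible).

## Thresholds and classification

The tunable constants live in `analysis_config()`:

| parameter | default | meaning |
|---|---|---|
| `theta_under` | 0.8 | CB below this (reliable) → under-represented |
| `theta_elim` | 0.1 | CB below this (reliable) → eliminated |
| `min_expected` | 15 | expected count must exceed this to be reliable |
| `min_site_length` | 3 | minimum literal site length admitted to datasets |
| `identity_threshold` | 0.99 | dereplication clustering threshold |
| `histogram_bin_width` | 0.1 | CB histogram bin width |
| `significance_alpha` | 0.01 | Fisher comparison significance level |

Category boundaries are half-open: CB exactly 0.8 is "reduced" (below 1 but
not significantly), exactly 0.1 is "under-represented", exactly 1 is
"near_expected" and tallies in neither the CB < 1 nor the CB > 1 column —
which is why fraction tables need not sum to 100%. An observed count of 0
with a reliable expectation is CB = 0, category "eliminated", never
undefined; an expectation rendered 0 or undefined by an absent subsite
yields category "undefined". CB values are never rounded internally;
file output rounds to 3 decimals.

Orientation policy: palindromic sites are evaluated on the given strand
only — the complementary strand carries the same physical duplex site, and
combining strands would double-count it. Asymmetric sites default to both
strands combined (a REase cleaves regardless of the site's orientation),
with `strand_asymmetry()` providing the per-strand mode used to look for
one-strand avoidance, a possibility for translocating Type I/III enzymes
that need head-to-head site pairs.

## Datasets

`build_experimental_pairs()` pairs a genome with every distinct site
recognised by an enzyme of at least one of its host species (exact match on
normalised species names; strain-level resolution is deliberately out of
scope). A pair records the union of R-M types of all matching enzymes —
with Type II meaning *orthodox* Type II, i.e. raw subtype tokens like `IIP`
fold into `II` while `IIG` and `IIM` stay separate — and the best evidence
level (`proved` dominates `predicted`). Sites of literal length ≤ 2 are
excluded. `build_control_pairs()` is the exact Cartesian product of a site
catalogue with a genome set, so the experimental dataset is by construction
a subset of control dataset 1.

`dereplicate()` removes taxonomic redundancy in two stages: the longest
genome per taxon id, then single-linkage clustering of genomes whose
estimated pairwise identity exceeds the threshold. Identity is estimated
without alignment from the Jaccard similarity $J$ of canonical 21-mer sets
through the Mash distance $d = -\tfrac{1}{k}\ln\frac{2J}{1+J}$,
identity $= 1-d$ — deterministic (full k-mer sets, no sketch subsampling at
desk scale) and accurate enough to separate 5%-diverged genomes from
0.2%-diverged ones at a 99% threshold. Representatives are the longest
cluster members, ties broken by lexicographically smallest id, so the
result is independent of input order.

## Summaries and tests of differences

`summarize_representation()` tallies, per group, pairs with CB < 1, CB > 1,
CB = 1 or undefined, under-represented and eliminated, with percentages
over all pairs in the group. Both filter policies are available — tallies
over all pairs, or restricted to reliable expectations — because published
fraction tables are ambiguous on this point; computing both keeps the
convention auditable. Group differences are tested with an exact two-sided
Fisher test under the point-probability criterion (the sum of
hypergeometric probabilities of tables at most as probable as the observed
one, within relative tolerance 1e-7), computed with log-factorials. Raw
p-values are compared against a fixed significance level with no
multiple-testing correction, matching the practice of fraction-table
comparisons in this field; the comparison table records every test
performed.

## The synthetic-data generator

`generate_background()` draws i.i.d. or first-order-Markov sequences;
`deplete_site()` then emulates selection: random remaining matches of the
site are destroyed by point mutations (a random specified position is
changed to a base outside the pattern letter's set), in sweeps of 20% of
the remaining matches, recomputing CB after each sweep and stopping at the
first crossing of the target. Mutating existing matches rather than
rejection-sampling whole genomes mirrors the evolutionary process and
leaves the background composition nearly intact, so the subsite expectation
stays calibrated; collateral effects on overlapping words are accepted.
The fixture defaults are the package's study conditions: 10 genomes of
200 kb with uniform composition — long enough that a 6-bp site has an
expected count near 49, comfortably above the reliability cut-off — one
site depleted to CB 0.05 and one untouched, an *E. coli* host panel and an
enzyme roster spanning Type I, orthodox Type II and Type III. Everything
derives from a single integer seed in documented order, so fixtures are
byte-reproducible.

What the generator does *not* emulate: gene content, codon structure,
GC-skew, real host ranges, or temperate/lytic population dynamics. Passing
the recovery tests therefore shows that the estimator and classifier are
correct and calibrated on composition-controlled sequences, not that every
biological confounder in real viral genomes is handled.

## Numerical choices and verified behaviour

The test suite pins the implementation to independent oracles: window
counting against a PCRE lookahead matcher, the expectation against a direct
evaluation of the subset product from those naive counts (relative 1e-9),
Fisher p-values against full hypergeometric enumeration (1e-12) and
`stats::fisher.test`, reverse complementation against Biostrings. The
expectation is evaluated in log space, so sites with up to 16 specified
positions are safe from overflow. Calibration at the package's study
conditions — 50 i.i.d. 100-kb genomes, sites GATC and GAATTC — gives mean
CB within [0.97, 1.03] and ≥ 90% of values within [0.8, 1.2]; depletion
targets {0, 0.5, 1} on 200-kb genomes are recovered as
{eliminated, under-represented, not-under-represented} in ≥ 90% of
genome × site instances. These problem sizes are the ones the acceptance
script reruns.

## Limitations

* The expectation conditions on the genome's own subsite frequencies; on
  very short genomes (expected count ≤ 15) CB is noisy, which is exactly
  what the reliability filter flags. Pairs excluded by that filter can hide
  true eliminations (observed 0, expected < 15).
* Host matching is species-level string equality; synonymy and taxonomy
  changes must be resolved upstream.
* Dereplication identity is a k-mer estimate, not an alignment; it has no
  coverage requirement, so a genome embedded in a much longer one can fall
  below the Jaccard threshold despite high local identity.
* Bipartite sites must be pre-expanded to plain IUPAC strings
  (`GACNNNNNGTC`); the gap-length notation `GAC(N5)GTC` is not parsed.
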