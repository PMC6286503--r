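# sitecb — restriction-site avoidance in viral genomes

Bacteria and archaea defend themselves against viruses with
restriction–modification (R-M) systems: a restriction endonuclease (REase)
cleaves DNA at short recognition sites (RS) that are left unmethylated. A
phage whose genome carries fewer copies of a site — or none at all — is more
likely to escape cleavage, so selection by host R-M systems leaves a
measurable footprint in viral genome composition. `sitecb` quantifies that
footprint: it measures the over- or under-representation of IUPAC-degenerate
recognition sites in viral genomes, classifies sites as *eliminated* or
*under-represented*, assembles experimental and control (site, genome)
datasets from enzyme and host metadata, and compares avoidance fractions
across R-M system types, genome types and phage lifestyles. It is aimed at
phage genomics and R-M system researchers who want a self-contained,
reproducible avoidance analysis.

## The statistic

For a site *s* with specified positions *P* (letters other than `N`), the
**compositional bias** is the ratio of the observed to the expected site
count,

    CB(s) = N(s) / E(s),       E(s) = ∏_{S ⊊ P} N(s_S)^(−(−1)^(|P|−|S|)),

where `s_S` is the site with every specified position outside the subset `S`
masked to `N`, `N(·)` counts overlapping windows of the full literal length,
and the all-`N` term is the window count. The expectation is an
inclusion–exclusion over *all* 2^|P| subsites (including non-contiguous
ones); because the exponents sum to zero, counts and window-normalised
frequencies give the same CB. Under no selection CB ≈ 1. Classification
follows the standard thresholds: a site is **under-represented** when
CB < 0.8 and **eliminated** when CB < 0.1, in both cases requiring the
expected count to exceed 15 (otherwise the value is flagged unreliable).
Palindromic sites are evaluated on one strand (both strands carry the same
duplex site); asymmetric sites on both strands combined, with a per-strand
mode for strand-asymmetry analyses.

## Worked example

```r
library(sitecb)

# a 100 kb background genome, then selection pressure against GATC
g <- generate_background(1e5, seed = 42, genome_id = "phageA")
g <- deplete_site(g, "GATC", 0.3, seed = 1)

compositional_bias(g, "GATC")
#> <cb GATC in phageA (given_strand)> observed 66, expected 224.299, cb 0.294, under_represented
compositional_bias(g, "GGCC")
#> <cb GGCC in phageA (given_strand)> observed 383, expected 396.340, cb 0.966, reduced
```

GATC was driven below the 0.8 threshold with an expected count ≫ 15, so it
is called under-represented; the untouched control site GGCC sits near
CB = 1 ("reduced" only means CB is below 1 without clearing the
significance threshold). Asymmetric sites can be examined per strand:

```r
s <- strand_asymmetry(g, "GGATG")
s$given_strand
#> <cb GGATG in phageA (given_strand)> observed 88, expected 83.420, cb 1.055, over_represented
```

The full pipeline — metadata join, dereplication, experimental/control pair
construction, CB evaluation, summary tables, Fisher's exact comparisons and
CB histograms — runs from one call (`run_all()`) or from the command line:

```sh
Rscript inst/cli/sitecb.R simulate --out fixture --seed 1
Rscript inst/cli/sitecb.R run-all --genomes fixture/genomes.fasta \
    --phage-table fixture/phage_table.tsv --rease-table fixture/rease_table.tsv \
    --out results
```

which writes `pairs.tsv`, `cb.tsv`, `summary.tsv`, `comparisons.tsv`,
`histogram.tsv` and a `manifest.json` provenance record.

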